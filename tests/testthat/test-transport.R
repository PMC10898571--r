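test_that("fluence matches the semi-infinite analytic solution within 5%", {
  g <- homogeneousGrid("skin", lateralExtent = 30)
  ts <- transportSystem(g)
  phi <- solveFluence(ts, pointSource())
  op <- opticalDefaults()
  rho <- c(3, 5, 7, 10)
  P <- DiffuseRaman:::.interpMatrix(g, cbind(rho, 0, 0))
  fd <- as.numeric(P %*% fieldValues(phi))
  an <- dipoleFluence(rho, 0, mua = op$mua[1], musp = op$musp[1])
  expect_true(all(abs(fd / an - 1) < 0.05))
})

test_that("fluence is strictly positive and reflection-symmetric", {
  phi <- fieldValues(fixture("Epoint"))
  expect_true(all(phi > 0))
  g <- fixture("grid100")
  d <- g@dims
  arr <- array(phi, d)
  ## centred source on the symmetric grid: x -> -x mirror
  expect_lt(max(abs(arr - arr[d[1]:1, , ]) / max(arr)), 1e-8)
})

test_that("adjoint sensitivity satisfies reciprocity and additivity", {
  ts <- fixture("ts100")
  g <- fixture("grid100")
  ptA <- matrix(c(2, 0), 1)
  sA <- detectorSensitivity(ts, ptA)
  ## reciprocity: detected signal from an interior emitter equals the
  ## sensitivity interpolated at the emitter location
  p <- c(1.3, -0.7, 2.5)
  q <- as.numeric(Matrix::crossprod(
    DiffuseRaman:::.interpMatrix(g, matrix(p, 1)), 1))
  phiP <- DiffuseRaman:::.solveSystem(ts, q)[, 1]
  C <- DiffuseRaman:::.detectorMatrix(ts, ptA, 0.01)
  detected <- sum(C[, 1] * phiP)
  sAtP <- as.numeric(DiffuseRaman:::.interpMatrix(g, matrix(p, 1)) %*%
                       fieldValues(sA))
  expect_equal(detected, sAtP, tolerance = 1e-8)
  ## additivity over disjoint detectors
  ptB <- matrix(c(-2, 1), 1)
  sB <- detectorSensitivity(ts, ptB)
  sAB <- detectorSensitivity(ts, rbind(ptA, ptB))
  expect_equal(fieldValues(sAB), fieldValues(sA) + fieldValues(sB),
               tolerance = 1e-10)
  ## homogeneous-medium sensitivity matches the analytic oracle
  gh <- homogeneousGrid("skin", lateralExtent = 30)
  tsh <- transportSystem(gh)
  sh <- detectorSensitivity(tsh, matrix(c(0, 0), 1))
  op <- opticalDefaults()
  pts <- cbind(c(3, 5, 7), 0, 1.2)
  fd <- as.numeric(DiffuseRaman:::.interpMatrix(gh, pts) %*% fieldValues(sh))
  ## reciprocity: sensitivity at p = (area / 2A) x fluence at the surface
  ## point from an isotropic emitter at p (images about the surface)
  afac <- DiffuseRaman:::.aFactor(1.4)
  kap <- 1 / (3 * (op$mua[1] + op$musp[1]))
  mueff <- sqrt(op$mua[1] / kap); zb <- 2 * afac * kap
  an <- vapply(seq_len(nrow(pts)), function(i) {
    r1 <- sqrt(pts[i, 1]^2 + pts[i, 3]^2)
    r2 <- sqrt(pts[i, 1]^2 + (pts[i, 3] + 2 * zb)^2)
    g <- (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * kap)
    0.01 / (2 * afac) * g
  }, numeric(1))
  expect_true(all(abs(fd / an - 1) < 0.05))
})

test_that("raman yields integrate materials consistently", {
  ts <- fixture("ts100")
  g <- fixture("grid100")
  fbr <- fixture("fbr100")
  E <- fixture("Epoint")
  S <- detectorSensitivity(ts, matrix(c(2, 0), 1))
  ## absent material
  expect_identical(ramanYield(E, S, g, "collagen", initialConditions(fbr)), 0)
  expect_error(ramanYield(E, S, g, "glass", fbr), "unknown material")
  ## partition additivity: per-material yields sum to the all-label yield
  mats <- g@materials
  total <- sum(vapply(mats, function(m) ramanYield(E, S, g, m, fbr),
                      numeric(1)))
  expect_equal(total, ramanYield(E, S, g, "all", fbr), tolerance = 1e-12)
  ## thin-layer volume linearity: t = 200 vs 2 x t = 100 (the ~4%
  ## departure is the depth decay of the excitation-sensitivity product
  ## across the extra 100 um)
  y100 <- ramanYield(E, S, g, "collagen", fbr)
  y200 <- ramanYield(E, S, g, "collagen",
                     buildPhantom(collagenThickness = 200))
  expect_lt(abs(y200 / (2 * y100) - 1), 0.05)
  expect_gt(y100, 0)
})

test_that("yield tables cover both samples and are reproducible", {
  fbr <- fixture("fbr100")
  yt <- yieldTable(pointSource(), matrix(c(2, 0), 1), fbr,
                   grid = fixture("grid100"))
  df <- yields(yt)
  expect_setequal(unique(df$sample), c("FBR", "InitialConditions"))
  expect_true(all(df$yield >= 0))
  expect_identical(df$yield[df$sample == "InitialConditions" &
                              df$material == "collagen"], 0)
  ## dense recomputation from scratch (fresh grid, fresh factorization)
  yt2 <- yieldTable(pointSource(), matrix(c(2, 0), 1), fbr,
                    grid = buildPhantomGrid(fbr))
  nz <- df$yield > 0
  expect_equal(yields(yt2)$yield[nz] / df$yield[nz], rep(1, sum(nz)),
               tolerance = 1e-10)
})

test_that("one factorization reused across a sweep matches refactorizing", {
  fbr <- fixture("fbr100")
  gc <- buildPhantomGrid(fbr, spacing = 1)
  model <- snrModel(pointSource(), fbr, grid = gc, refs = fixture("refs"))
  pts <- as.matrix(expand.grid(x = c(-1, 0, 1), y = c(-1, 0, 1)))
  swept <- detectorSNR(model, pts)
  fresh <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    m <- snrModel(pointSource(), fbr, grid = buildPhantomGrid(fbr, spacing = 1),
                  refs = fixture("refs"))
    detectorSNR(m, pts[i, , drop = FALSE])
  }))
  expect_equal(swept$snr, fresh$snr, tolerance = 1e-10)
})
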