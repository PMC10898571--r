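test_that("SNR surface is symmetric with an off-centre maximum", {
  surf <- fixture("surfPoint11")
  s <- surf@snr
  n <- nrow(s)
  expect_lt(max(abs(s - s[n:1, n:1])) / max(s), 0.01)
  expect_gt(surfaceArgmax(surf)$offset, 0)
  expect_true(all(s >= 0))
})

test_that("surface values equal independent per-point SNR evaluations", {
  model <- fixture("modelPoint")
  surf <- fixture("surfPoint11")
  for (pt in list(c(2, 0), c(-1, 3), c(0, -2))) {
    i <- which(surf@x == pt[1]); j <- which(surf@y == pt[2])
    yt <- yieldTable(pointSource(), matrix(pt, 1), fixture("fbr100"),
                     grid = fixture("grid100"))
    ref <- computeSNR(yt, fixture("refs"), scale = model@scale)
    expect_equal(surf@snr[i, j], snrValue(ref), tolerance = 1e-8)
  }
})

test_that("rectangular integration equals explicit detector combination", {
  model <- fixture("modelPoint")
  surf <- fixture("surfPoint11")
  ## single grid point
  one <- integrateDetectorArea(surf, c(1.9, 2.1), c(-0.1, 0.1))
  i <- which(surf@x == 2); j <- which(surf@y == 0)
  expect_equal(snrValue(one), surf@snr[i, j])
  ## strip: equals combineDetectors over the enumerated points
  strip <- integrateDetectorArea(surf, c(1.9, 3.1), c(-5, 5))
  inX <- which(surf@x >= 1.9 & surf@x <= 3.1)
  expl <- combineDetectors(as.numeric(surf@signal[inX, ]),
                           as.numeric(surf@noise[inX, ]))
  expect_equal(snrValue(strip), snrValue(expl), tolerance = 1e-12)
  ## symmetric pair combines as sqrt(2) on the symmetric phantom
  left <- integrateDetectorArea(surf, c(-3.1, -1.9), c(-5, 5))
  pair <- combineDetectors(list(strip, left))
  expect_equal(snrValue(pair), sqrt(2) * snrValue(strip), tolerance = 0.01)
  expect_error(integrateDetectorArea(surf, c(20, 30)), "no grid points")
})

test_that("fiber-array SNR equals explicit combination of its points", {
  model <- fixture("modelPoint")
  fib <- fiberSubsetSNR(model, offset = 2)
  pts <- cbind(2, seq(-0.5, 0.5, length.out = 7))
  df <- detectorSNR(model, pts)
  expl <- combineDetectors(df$signal, df$noise)
  expect_equal(snrValue(fib), snrValue(expl), tolerance = 1e-12)
  ## two symmetric arrays scale by sqrt(2)
  both <- combineDetectors(list(fib, fiberSubsetSNR(model, offset = -2)))
  expect_equal(snrValue(both), sqrt(2) * snrValue(fib), tolerance = 0.01)
})

test_that("photon budget is conserved when spreading an interior source", {
  model <- fixture("modelPoint")
  surfP <- snrSurface(model, n = 11)
  modelL <- DiffuseRaman:::.withSource(
    model, lineSource(length = 2, width = 1))
  surfL <- snrSurface(modelL, n = 11)
  ## total detected band counts over the grid (noise^2 is the raw total)
  expect_lt(abs(sum(surfL@noise^2) / sum(surfP@noise^2) - 1), 0.02)
})

test_that("geometry search ranks the MPE-feasible line above the point", {
  opt <- optimizeGeometry(fbr = fixture("fbr100"), grid = fixture("grid100"),
                          refs = fixture("refs"), surfaceN = 11)
  ## the 45 mW point beam violates the 3 mW/mm^2 MPE
  expect_match(opt$infeasible$source, "point")
  expect_gt(nrow(opt$ranked), 0)
  expect_match(opt$ranked$source[1], "line")
  expect_true(all(opt$ranked$powerDensity <= 3))
  ## the dual-rectangle detector wins and its SNR re-evaluates identically
  expect_match(opt$ranked$detector[1], "rectanglePair")
  m <- snrModel(lineSource(), fixture("fbr100"), grid = fixture("grid100"),
                refs = fixture("refs"))
  surf <- snrSurface(m, n = 11)
  off <- as.numeric(sub(".*offset ", "", opt$ranked$detector[1]))
  r1 <- integrateDetectorArea(surf, off + c(-1, 1), c(-5, 5))
  r2 <- integrateDetectorArea(surf, -off + c(-1, 1), c(-5, 5))
  expect_equal(opt$ranked$snr[1], snrValue(combineDetectors(list(r1, r2))),
               tolerance = 1e-10)
  ## LODs follow the t_LOD = criterion * 100 / SNR contract
  expect_equal(opt$ranked$lod, 1.645 * 100 / opt$ranked$snr)
})

test_that("a single fixed configuration is returned as such", {
  opt <- optimizeGeometry(
    sources = list(lineSource()),
    detectors = list(list(type = "point", x = 2, y = 0)),
    fbr = fixture("fbr100"), grid = fixture("grid100"),
    refs = fixture("refs"), surfaceN = 11)
  expect_identical(nrow(opt$ranked), 1L)
  m <- snrModel(lineSource(), fixture("fbr100"), grid = fixture("grid100"),
                refs = fixture("refs"))
  expect_equal(opt$ranked$snr,
               detectorSNR(m, matrix(c(2, 0), 1))$snr, tolerance = 1e-10)
})

test_that("an empty feasible set is reported explicitly", {
  opt <- optimizeGeometry(sources = list(pointSource()),
                          fbr = fixture("fbr100"),
                          grid = fixture("grid100"),
                          refs = fixture("refs"), surfaceN = 11)
  expect_identical(nrow(opt$ranked), 0L)
  expect_identical(opt$message, "no feasible configuration")
})
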