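test_that("polystyrene normalization maps the window to [0, 1]", {
  s <- makeReferenceSpectrum("polystyrene", generatorSpec(seed = 7))
  ns <- normalizeToPolystyrene(s)
  w <- wavenumber(ns)
  win <- counts(ns)[w >= 990 & w <= 1020]
  expect_equal(min(win), 0)
  expect_equal(max(win), 1)
  ## affine invariance: c * S + d normalizes identically
  s2 <- RamanSpectrum(w, 3.7 * counts(s) + 11)
  expect_equal(counts(normalizeToPolystyrene(s2)), counts(ns),
               tolerance = 1e-12)
  ## independent min-max re-implementation
  v <- counts(s)
  lo <- min(v[w >= 990 & w <= 1020]); hi <- max(v[w >= 990 & w <= 1020])
  expect_equal(counts(ns), (v - lo) / (hi - lo), tolerance = 1e-12)
  ## flat window is an error
  flat <- RamanSpectrum(w, rep(1, length(w)))
  expect_error(normalizeToPolystyrene(flat), "flat")
})

test_that("difference spectra recover an added collagen component", {
  spec <- generatorSpec(noise = FALSE)
  ic <- makeCompositeSpectrum(c(polystyrene = 1, skin = 0.8), spec)
  col <- makeReferenceSpectrum("collagen", spec, noise = FALSE)
  alpha <- 0.37
  fbr <- RamanSpectrum(wavenumber(ic), counts(ic) + alpha * counts(col))
  d <- differenceSpectrum(fbr, ic)
  expect_equal(counts(d), alpha * counts(col), tolerance = 1e-10)
  ## identical inputs give the zero spectrum
  expect_true(all(counts(differenceSpectrum(ic, ic)) == 0))
  ## mismatched axes are an error, not a resample
  short <- RamanSpectrum(wavenumber(ic)[-1], counts(ic)[-1])
  expect_error(differenceSpectrum(fbr, short), "axes do not match")
  ## band area is linear in the added component
  expect_equal(collagenBandArea(d),
               alpha * collagenBandArea(
                 RamanSpectrum(wavenumber(col), counts(col))),
               tolerance = 1e-10)
  expect_equal(collagenBandArea(differenceSpectrum(ic, ic)), 0)
})

test_that("polystyrene features cancel in normalized difference spectra", {
  spec <- generatorSpec(noise = FALSE)
  pair <- DiffuseRaman:::.pairExpectation(spec, 100)
  d <- differenceSpectrum(normalizeToPolystyrene(pair$fbr),
                          normalizeToPolystyrene(pair$initial))
  w <- wavenumber(d)
  polyResidual <- sum(abs(counts(d)[w >= 995 & w <= 1015]))
  expect_lt(polyResidual, 0.05 * collagenBandArea(d))
})

test_that("PLS recovers an exact linear structure with one component", {
  spec <- generatorSpec(noise = FALSE)
  col <- counts(makeReferenceSpectrum("collagen", spec, noise = FALSE))
  thickness <- rep(c(10, 20, 40, 60, 80, 100, 150, 200), each = 2)
  X <- outer(thickness / 100, col)
  colnames(X) <- paste0("wn", wavenumber(
    makeReferenceSpectrum("collagen", spec, noise = FALSE)))
  m <- fitPLS(X, thickness)
  expect_identical(m@ncomp, 1L)
  expect_lt(m@looRMSE, 1e-6)
  ## noise-free prediction is exact
  pr <- predictThickness(m, X, thickness)
  expect_lt(pr$rmse, 1e-6)
})

test_that("the calibration design yields sixteen difference spectra", {
  spec <- calibrateNoiseToSNR(generatorSpec(seed = 5), 4.0)
  se <- makeThicknessSeries(spec = spec)
  expect_identical(ncol(se), 32L) # 16 FBR + 16 paired initial
  ds <- differenceSet(se)
  expect_identical(nrow(ds$X), 16L)
  expect_identical(sort(unique(ds$thickness)),
                   c(10, 20, 40, 60, 80, 100, 150, 200))
  m <- fitPLS(ds)
  expect_true(is.finite(m@looRMSE))
  ## predicting the training set cannot beat the LOO estimate
  pr <- predictThickness(m, ds)
  expect_lte(pr$rmse, m@looRMSE)
  ## portable (linear-map) form predicts identically
  pm <- portableCalibration(m)
  expect_equal(predictThickness(pm, ds)$predictions, pr$predictions,
               tolerance = 1e-8)
})

test_that("independent test RMSE is consistent with the LOO estimate", {
  loo <- test <- numeric(5)
  for (k in seq_len(5)) {
    specTrain <- calibrateNoiseToSNR(generatorSpec(seed = 100 + k), 4.0)
    specTest <- calibrateNoiseToSNR(generatorSpec(seed = 200 + k), 4.0)
    m <- fitPLS(differenceSet(makeThicknessSeries(spec = specTrain)))
    dsT <- differenceSet(makeThicknessSeries(spec = specTest))
    loo[k] <- m@looRMSE
    test[k] <- predictThickness(m, dsT)$rmse
  }
  expect_lt(abs(mean(test) / mean(loo) - 1), 0.5)
})

test_that("band-area regression LOD follows the OLS contract", {
  ## perfectly linear pairs
  perfect <- fitRegressionLOD(2 * c(10, 50, 100, 200) + 3,
                              c(10, 50, 100, 200))
  expect_equal(perfect@r2, 1)
  expect_equal(lodValue(perfect), 0, tolerance = 1e-10)
  ## slope 1, residual RMSE 10 -> 16.45 um (balanced residuals keep the
  ## fitted line at y = x)
  x <- c(0, 10, 20, 30)
  y <- x + c(10, -10, -10, 10)
  r <- fitRegressionLOD(y, x)
  expect_equal(r@slope, 1)
  expect_equal(r@rmse, 10)
  expect_equal(lodValue(r), 16.45)
  expect_equal(r@lodUnitCriterion, 10)
  ## closed-form OLS oracle on a noisy synthetic series
  set.seed(9)
  t4 <- rep(c(15, 37, 62, 83), each = 2)
  a4 <- 0.02 * t4 + rnorm(8, sd = 0.1)
  fit <- fitRegressionLOD(a4, t4)
  or <- olsClosed(t4, a4)
  expect_equal(fit@slope, or$slope, tolerance = 1e-10)
  expect_equal(fit@intercept, or$intercept, tolerance = 1e-10)
  expect_equal(fit@r2, or$r2, tolerance = 1e-10)
  expect_equal(fit@rmse, or$rmse, tolerance = 1e-10)
  expect_error(fitRegressionLOD(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fitRegressionLOD(c(1, 2, 3), c(5, 5, 5)), "spread")
})

test_that("the pipeline is invariant to per-spectrum gain", {
  spec <- calibrateNoiseToSNR(generatorSpec(seed = 31), 4.0)
  se <- makeThicknessSeries(thicknesses = c(20, 60, 120), replicates = 2,
                            spec = spec)
  ds1 <- differenceSet(se)
  ## rescale every raw spectrum by its own arbitrary gain
  se2 <- se
  m <- SummarizedExperiment::assay(se2, "counts")
  set.seed(1)
  gains <- runif(ncol(m), 0.5, 2)
  SummarizedExperiment::assay(se2, "counts") <- sweep(m, 2, gains, `*`)
  ds2 <- differenceSet(se2)
  expect_equal(ds2$X, ds1$X, tolerance = 1e-10)
})
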