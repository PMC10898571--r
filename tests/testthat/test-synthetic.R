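test_that("reference spectra show the characteristic band positions", {
  spec <- generatorSpec(noise = FALSE)
  poly <- makeReferenceSpectrum("polystyrene", spec)
  w <- wavenumber(poly)
  ## polystyrene global maximum at the 1004 cm^-1 ring-breathing band
  expect_true(abs(w[which.max(counts(poly))] - 1004) <= 4)
  ## collagen local maxima near 850 and 930 cm^-1
  col <- counts(makeReferenceSpectrum("collagen", spec))
  isLocalMax <- function(target) {
    k <- which(w >= target - 4 & w <= target + 4)
    any(vapply(k[k > 1 & k < length(w)], function(i)
      col[i] >= col[i - 1] && col[i] >= col[i + 1], logical(1)))
  }
  expect_true(isLocalMax(850))
  expect_true(isLocalMax(930))
  expect_error(makeReferenceSpectrum("teflon", spec), "unknown material")
})

test_that("noise-free spectra equal the closed-form band sum", {
  spec <- generatorSpec(noise = FALSE)
  s <- makeReferenceSpectrum("collagen", spec)
  w <- wavenumber(s)
  bands <- ramanBandTable()
  bands <- bands[bands$material == "collagen", ]
  bg <- DiffuseRaman:::.defaultBackground()
  bg <- bg[bg$material == "collagen", ]
  expected <- bg$b0 + bg$b1 * (w - 800) / 1000 + bg$b2 * ((w - 800) / 1000)^2
  for (r in seq_len(nrow(bands))) {
    u <- (w - bands$center[r]) / bands$width[r]
    expected <- expected + bands$height[r] *
      (if (bands$profile[r] == "lorentzian") 1 / (1 + u^2)
       else exp(-u^2 / 2))
  }
  expect_equal(counts(s), 1000 * expected, tolerance = 1e-12)
})

test_that("composite spectra have Poisson statistics around the mixture", {
  spec <- generatorSpec(seed = 21)
  ## single material, weight one, noise-free equals the reference
  one <- makeCompositeSpectrum(c(skin = 1), spec, noise = FALSE)
  ref <- makeReferenceSpectrum("skin", spec, noise = FALSE)
  expect_equal(counts(one), counts(ref))
  expect_error(makeCompositeSpectrum(c(skin = 0), spec), "positive")
  ## many draws: mean near expectation, variance near mean
  wts <- c(polystyrene = 1, skin = 0.8)
  lam <- counts(makeCompositeSpectrum(wts, spec, noise = FALSE))
  draws <- vapply(seq_len(1000), function(k)
    counts(makeCompositeSpectrum(wts, spec, noise = TRUE, counter = k)),
    numeric(length(lam)))
  z <- (rowMeans(draws) - lam) / (sqrt(lam) / sqrt(1000))
  expect_gt(mean(abs(z) < 3), 0.99) # 3 sigma / sqrt(1000) per channel
  expect_lt(max(abs(z)), 5)
  vm <- apply(draws, 1, var) / rowMeans(draws)
  big <- lam >= 100
  expect_gt(mean(abs(vm[big] - 1) < 0.1), 0.95)
  expect_lt(abs(mean(vm[big]) - 1), 0.02)
})

test_that("thickness series are paired, labeled and deterministic", {
  spec <- generatorSpec(seed = 13)
  se <- makeThicknessSeries(thicknesses = c(0, 50, 100), replicates = 1,
                            spec = spec)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  expect_identical(sum(cd$role == "fbr"), 3L)
  expect_identical(sum(cd$role == "initial"), 3L)
  expect_true(all(c("thickness", "replicate", "seed") %in% names(cd)))
  ## thickness 0: FBR and initial-conditions expectations coincide
  e <- DiffuseRaman:::.pairExpectation(spec, 0)
  expect_equal(counts(e$fbr), counts(e$initial))
  ## byte-identical regeneration under the same master seed
  se2 <- makeThicknessSeries(thicknesses = c(0, 50, 100), replicates = 1,
                             spec = generatorSpec(seed = 13))
  expect_identical(SummarizedExperiment::assay(se, "counts"),
                   SummarizedExperiment::assay(se2, "counts"))
  ## a different master seed reshuffles the noise
  se3 <- makeThicknessSeries(thicknesses = c(0, 50, 100), replicates = 1,
                             spec = generatorSpec(seed = 14))
  expect_false(identical(SummarizedExperiment::assay(se, "counts"),
                         SummarizedExperiment::assay(se3, "counts")))
})

test_that("noise calibration reaches the target band SNR", {
  spec <- generatorSpec(seed = 17)
  s32 <- calibrateNoiseToSNR(spec, 3.2)
  achieved <- DiffuseRaman:::.expectedPairSNR(s32, 100)
  expect_true(achieved >= 3.14 && achieved <= 3.26)
  ## square law: doubling the target quadruples the count scale
  s64 <- calibrateNoiseToSNR(spec, 6.4)
  expect_equal(s64@countScale / s32@countScale, 4, tolerance = 1e-10)
  ## empirical check over 200 noisy pairs
  s4 <- calibrateNoiseToSNR(spec, 4.0)
  sig <- raw <- numeric(200)
  for (k in seq_len(200)) {
    wts <- s4@weights
    fbr <- makeCompositeSpectrum(c(wts, collagen = 0.2), s4, noise = TRUE,
                                 counter = 2 * k)
    ic <- makeCompositeSpectrum(wts, s4, noise = TRUE, counter = 2 * k + 1)
    d <- differenceSpectrum(fbr, ic)
    sig[k] <- collagenBandArea(d)
    raw[k] <- bandIntensities(fbr)$iRaw + bandIntensities(ic)$iRaw
  }
  empirical <- mean(sig) / sqrt(mean(raw))
  expect_lt(abs(empirical / 4.0 - 1), 0.1)
  expect_error(calibrateNoiseToSNR(spec, -1), "positive")
})
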