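test_that("band intensities handle flat and triangular spectra", {
  w <- seq(900, 960, 2)
  flat <- RamanSpectrum(w, rep(5, length(w)))
  bi <- bandIntensities(flat)
  expect_equal(bi$iRaman, 0, tolerance = 1e-12)
  expect_equal(bi$iRaw, 5 * 21) # 21 channels in 910-950 at 2 cm^-1
  ## symmetric triangle spanning the band on zero background: with anchors
  ## exactly at the band edges the baseline is zero
  tri <- RamanSpectrum(w, pmax(0, 8 * (1 - abs(w - 930) / 20)))
  bt <- bandIntensities(tri, edgeChannels = 1)
  expect_equal(bt$iRaw, 8 * 10) # h * (1 + 2 * (0.9 + ... + 0.1))
  expect_equal(bt$iRaman, bt$iRaw, tolerance = 1e-12)
  expect_error(bandIntensities(flat, band = c(100, 200)), "outside")
})

test_that("band intensities agree with the brute-force oracle", {
  s <- makeReferenceSpectrum("collagen", generatorSpec(seed = 1))
  bi <- bandIntensities(s)
  or <- bruteBandSums(wavenumber(s), counts(s))
  expect_equal(bi$iRaman, or$iRaman, tolerance = 1e-9)
  expect_equal(bi$iRaw, or$iRaw, tolerance = 1e-9)
})

test_that("reference intensities satisfy iRaw >= iRaman >= 0", {
  refs <- fixture("refs")
  expect_true(all(refs$iRaman >= 0))
  expect_true(all(refs$iRaw >= refs$iRaman))
  expect_setequal(refs$material,
                  c("skin", "fat", "muscle", "polystyrene", "collagen"))
})

test_that("the SNR formula reproduces a hand-computed toy table", {
  yt <- data.frame(sample = c("FBR", "FBR", "InitialConditions"),
                   material = c("collagen", "skin", "skin"),
                   yield = c(10, 100, 100))
  refs <- data.frame(material = c("collagen", "skin"),
                     iRaman = c(50, 5), iRaw = c(80, 20))
  r <- computeSNR(yt, refs)
  ## signal 10 * 50; noise sqrt(10*80 + 100*20 + 100*20)
  expect_equal(snrValue(r), 500 / sqrt(4800), tolerance = 1e-12)
  expect_equal(r@signal, 500)
  expect_equal(r@noise, sqrt(4800))
  ## zero collagen yield -> zero SNR
  yt0 <- yt; yt0$yield[1] <- 0
  expect_equal(snrValue(computeSNR(yt0, refs)), 0)
  ## shot-noise scaling: yields x4 doubles SNR
  yt4 <- yt; yt4$yield <- yt$yield * 4
  expect_equal(snrValue(computeSNR(yt4, refs)), 2 * snrValue(r))
  ## same via the photon-budget scale
  expect_equal(snrValue(computeSNR(yt, refs, scale = 4)), 2 * snrValue(r))
  ## unit freedom: refs x c with yields x 1/c leaves SNR unchanged
  refsC <- refs; refsC$iRaman <- refs$iRaman * 3; refsC$iRaw <- refs$iRaw * 3
  ytC <- yt; ytC$yield <- yt$yield / 3
  expect_equal(snrValue(computeSNR(ytC, refsC)), snrValue(r))
  ## degenerate inputs
  ytz <- yt; ytz$yield[] <- 0
  expect_error(computeSNR(ytz, refs), "zero total count")
  expect_error(computeSNR(yt[yt$sample == "FBR", ], refs), "both samples")
})

test_that("the LOD formula reproduces the printed values", {
  expect_equal(round(lodFromSNR(3.2)), 51)
  expect_equal(round(lodFromSNR(4.0)), 41)
  expect_equal(lodFromSNR(1.645), 100)
  ## restated: t_LOD * SNR_100 = 164.5 um identically
  for (s in c(0.5, 1, 3.2, 9.5, 20))
    expect_equal(lodFromSNR(s) * s, 164.5)
  expect_error(lodFromSNR(0), "positive")
  expect_error(lodFromSNR(-2), "positive")
})

test_that("detector combination adds signals and noises in quadrature", {
  one <- combineDetectors(6.7, 1)
  expect_equal(snrValue(one), 6.7)
  two <- combineDetectors(c(6.7, 6.7), c(1, 1))
  expect_equal(snrValue(two), 6.7 * sqrt(2), tolerance = 1e-12)
  expect_equal(round(snrValue(two), 1), 9.5) # the dual-rectangle total
  for (k in c(3, 7)) {
    many <- combineDetectors(rep(6.7, k), rep(1, k))
    expect_equal(snrValue(many), 6.7 * sqrt(k), tolerance = 1e-12)
  }
  ## list-of-results interface
  expect_equal(snrValue(combineDetectors(list(one, one))),
               snrValue(two))
  expect_error(combineDetectors(list()), "empty")
  expect_error(combineDetectors(c(1, 1), c(1, 0)), "positive")
})

test_that("detection criterion is the standard-normal quantile", {
  expect_equal(round(detectionCriterion(0.95), 3), 1.645)
  expect_equal(detectionCriterion(0.5), 0)
  ## against the bisection-on-the-integral oracle
  expect_equal(detectionCriterion(0.975), qnormBisect(0.975),
               tolerance = 1e-5)
  expect_equal(round(detectionCriterion(0.975), 5), 1.95996)
  expect_error(detectionCriterion(1), "between 0 and 1")
  expect_error(detectionCriterion(0), "between 0 and 1")
})
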