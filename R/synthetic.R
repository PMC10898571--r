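#' Default Raman band table for the phantom materials
#'
#' Band positions, widths, relative heights and profiles used by the
#' synthetic spectrum generator. Positions follow the characteristic bands
#' of the materials: the dominant polystyrene ring-breathing band at
#' 1004 cm^-1 (plus 1032, 1450, 1583, 1602 and 1634 cm^-1), the collagen
#' proline/hydroxyproline bands at 850 and 930 cm^-1 with the amide III,
#' C-H deformation and amide I regions, and the usual protein/lipid bands of
#' skin, fat and muscle (1300, 1440-1450, 1655, 1745 cm^-1). Relative
#' heights are free generator parameters (true relative Raman cross-sections
#' of the materials are not published); polystyrene is by far the most
#' intense, consistent with reference spectra needing ~5-fold scaling for
#' display.
#'
#' @return data.frame with columns material, center (cm^-1), width (sigma
#'   for Gaussian, half-width for Lorentzian; cm^-1), height (relative),
#'   profile ("gaussian" or "lorentzian").
#' @export
ramanBandTable <- function() {
  b <- function(material, center, width, height, profile = "gaussian")
    data.frame(material = material, center = center, width = width,
               height = height, profile = profile)
  rbind(
    b("polystyrene", 1004, 3, 10, "lorentzian"),
    b("polystyrene", 1032, 4, 2.5),
    b("polystyrene", 1155, 6, 0.5),
    b("polystyrene", 1450, 9, 1.2),
    b("polystyrene", 1583, 6, 0.8),
    b("polystyrene", 1602, 5, 2.0),
    b("polystyrene", 1634, 6, 1.5),
    b("collagen", 850, 5, 1.0),
    b("collagen", 875, 5, 0.6),
    b("collagen", 930, 5, 1.0),
    b("collagen", 1065, 10, 0.5),
    b("collagen", 1245, 14, 0.9),
    b("collagen", 1270, 10, 0.7),
    b("collagen", 1450, 10, 0.8),
    b("collagen", 1670, 12, 1.0),
    b("skin", 850, 7, 0.40),
    b("skin", 935, 7, 0.35),
    b("skin", 1004, 4, 0.50),
    b("skin", 1080, 12, 0.40),
    b("skin", 1270, 12, 0.50),
    b("skin", 1300, 10, 0.60),
    b("skin", 1450, 10, 1.00),
    b("skin", 1655, 12, 0.90),
    b("fat", 1080, 12, 0.50),
    b("fat", 1300, 9, 1.00),
    b("fat", 1440, 9, 1.50),
    b("fat", 1655, 10, 0.40),
    b("fat", 1745, 9, 0.60),
    b("muscle", 1004, 4, 0.40),
    b("muscle", 1320, 12, 0.50),
    b("muscle", 1340, 12, 0.50),
    b("muscle", 1450, 10, 0.90),
    b("muscle", 1655, 12, 1.00))
}

## fluorescence-like broad background: b0 + b1 u + b2 u^2, u = (w-800)/1000
.defaultBackground <- function() {
  data.frame(
    material = c("polystyrene", "collagen", "skin", "fat", "muscle"),
    b0 = c(0.10, 0.40, 0.60, 0.50, 0.50),
    b1 = c(0.05, 0.30, 0.50, 0.40, 0.40),
    b2 = c(0.00, -0.10, -0.20, -0.20, -0.15))
}

#' Configure the synthetic spectrum generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' material reference spectra as sums of Gaussian/Lorentzian bands over a
#' smooth fluorescence-like background, composite phantom spectra as
#' yield-weighted mixtures of the references, and Poisson photon shot noise
#' (detector read noise is omitted: counts are shot-noise dominated).
#' The mixture model weights the initial-conditions materials and adds a
#' collagen weight proportional to layer thickness
#' (\code{collagenSlope} per micrometre).
#'
#' @param axis numeric (start, stop, step) wavenumber axis in cm^-1
#'   (default 800-1800 at 2 cm^-1, covering every named band).
#' @param countScale photon counts per unit profile height at the reference
#'   acquisition (45 mW, 900 s).
#' @param integrationTime acquisition time (s), recorded in metadata.
#' @param noise draw Poisson counts (TRUE) or return expectations (FALSE).
#' @param seed master seed; every generated spectrum derives its own seed
#'   from it (counter-based), so datasets are extensible without
#'   reshuffling.
#' @param bands band table (see [ramanBandTable()]).
#' @param background per-material quadratic background coefficients.
#' @param weights named initial-conditions mixture weights.
#' @param collagenSlope collagen mixture weight per micrometre.
#' @return A [GeneratorSpec-class].
#' @export
generatorSpec <- function(axis = c(800, 1800, 2), countScale = 1000,
                          integrationTime = 900, noise = TRUE, seed = 1L,
                          bands = ramanBandTable(),
                          background = .defaultBackground(),
                          weights = c(polystyrene = 1, skin = 0.8,
                                      fat = 0.5, muscle = 0.3),
                          collagenSlope = 0.002) {
  new("GeneratorSpec", axis = as.numeric(axis), countScale = countScale,
      integrationTime = integrationTime, noise = noise,
      seed = as.integer(seed), bands = bands, background = background,
      weights = weights, collagenSlope = collagenSlope)
}

.axisOf <- function(spec) seq(spec@axis[1], spec@axis[2], by = spec@axis[3])

## per-sample seed derived from the master seed and an item counter
.deriveSeed <- function(master, counter) {
  as.integer((abs(master) %% 1000000L) * 1009L + counter %% 1009L)
}

## noise-free unit profile of a material (bands + background)
.materialProfile <- function(material, spec) {
  w <- .axisOf(spec)
  bt <- spec@bands[spec@bands$material == material, , drop = FALSE]
  bg <- spec@background[spec@background$material == material, , drop = FALSE]
  if (!nrow(bt) && !nrow(bg))
    stop("unknown material: ", material)
  y <- numeric(length(w))
  for (r in seq_len(nrow(bt))) {
    u <- (w - bt$center[r]) / bt$width[r]
    y <- y + bt$height[r] *
      (if (bt$profile[r] == "lorentzian") 1 / (1 + u^2) else exp(-0.5 * u^2))
  }
  if (nrow(bg)) {
    u <- (w - 800) / 1000
    y <- y + bg$b0 + bg$b1 * u + bg$b2 * u^2
  }
  y
}

#' Synthetic material reference spectrum
#'
#' Noise-free profile (band sum plus background) scaled to the count scale;
#' Poisson-sampled when noise is enabled. Metadata records the material,
#' the derived seed and the generator settings.
#'
#' @param material one of the phantom materials.
#' @param spec a [GeneratorSpec-class].
#' @param noise override the spec's noise switch.
#' @param counter item counter for seed derivation.
#' @return A [RamanSpectrum-class].
#' @examples
#' s <- makeReferenceSpectrum("collagen", generatorSpec(noise = FALSE))
#' @export
makeReferenceSpectrum <- function(material, spec = generatorSpec(),
                                  noise = spec@noise, counter = 0L) {
  w <- .axisOf(spec)
  lam <- spec@countScale * .materialProfile(material, spec)
  seed <- .deriveSeed(spec@seed, counter + match(material, c(
    "skin", "fat", "muscle", "polystyrene", "collagen"), nomatch = 0L))
  cnt <- if (noise) .withSeed(seed, rpois(length(lam), lam)) else lam
  RamanSpectrum(w, cnt, metadata = list(
    material = material, seed = seed, noise = noise,
    integrationTime = spec@integrationTime, laserPower = 45,
    generator = .generatorVersion()))
}

#' All five material references
#'
#' @param spec a [GeneratorSpec-class].
#' @return Named list of [RamanSpectrum-class], one per material.
#' @export
syntheticReferences <- function(spec = generatorSpec(noise = FALSE)) {
  mats <- c("skin", "fat", "muscle", "polystyrene", "collagen")
  stats::setNames(lapply(mats, makeReferenceSpectrum, spec = spec), mats)
}

#' Composite phantom spectrum from material weights
#'
#' Expected spectrum is the weight-sum of the noise-free material
#' references; counts are drawn Poisson per channel when noise is enabled,
#' so the mean of many draws converges to the expectation and the
#' per-channel variance equals the mean.
#'
#' @param weights named nonnegative material weights (at least one
#'   positive).
#' @param spec a [GeneratorSpec-class].
#' @param noise override the spec's noise switch.
#' @param counter item counter for seed derivation.
#' @param label sample label recorded in metadata.
#' @return A [RamanSpectrum-class].
#' @export
makeCompositeSpectrum <- function(weights, spec = generatorSpec(),
                                  noise = spec@noise, counter = 0L,
                                  label = "composite") {
  weights <- weights[weights != 0]
  if (!length(weights) || any(weights < 0))
    stop("need nonnegative weights with at least one positive")
  w <- .axisOf(spec)
  lam <- numeric(length(w))
  for (m in names(weights))
    lam <- lam + weights[[m]] * spec@countScale * .materialProfile(m, spec)
  seed <- .deriveSeed(spec@seed, counter)
  cnt <- if (noise) .withSeed(seed, rpois(length(lam), lam)) else lam
  RamanSpectrum(w, cnt, metadata = list(
    label = label, weights = as.list(weights), seed = seed, noise = noise,
    integrationTime = spec@integrationTime,
    generator = .generatorVersion()))
}

## expected (noise-free) FBR / initial-condition pair at a thickness
.pairExpectation <- function(spec, thickness) {
  wIC <- spec@weights
  wFBR <- c(wIC, collagen = unname(spec@collagenSlope * thickness))
  list(initial = makeCompositeSpectrum(wIC, spec, noise = FALSE),
       fbr = makeCompositeSpectrum(wFBR, spec, noise = FALSE))
}

#' Generate a collagen thickness series
#'
#' For each (thickness, replicate) the generator produces a paired
#' initial-conditions spectrum and an FBR spectrum whose collagen weight
#' scales linearly with thickness. The default series is the calibration
#' design: thicknesses 10, 20, 40, 60, 80, 100, 150 and 200 um with two
#' replicates, i.e. sixteen FBR spectra and their paired initial-conditions
#' spectra. Each spectrum gets its own seed derived from the master seed, so
#' regeneration with the same master seed is byte-identical.
#'
#' @param thicknesses collagen thicknesses (micrometres).
#' @param replicates replicates per thickness.
#' @param spec a [GeneratorSpec-class].
#' @return A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]:
#'   assay "counts" (channels x spectra), rowData wavenumber, colData with
#'   role ("fbr"/"initial"), thickness, replicate and seed; the generator
#'   spec in the metadata.
#' @export
makeThicknessSeries <- function(thicknesses = c(10, 20, 40, 60, 80, 100,
                                                150, 200),
                                replicates = 2, spec = generatorSpec()) {
  if (any(thicknesses < 0)) stop("thicknesses must be nonnegative")
  w <- .axisOf(spec)
  items <- expand.grid(replicate = seq_len(replicates),
                       thickness = thicknesses)
  cols <- list(); cnt <- list()
  counter <- 100L
  for (r in seq_len(nrow(items))) {
    t <- items$thickness[r]; rep <- items$replicate[r]
    for (role in c("initial", "fbr")) {
      wts <- spec@weights
      if (role == "fbr" && t > 0)
        wts <- c(wts, collagen = unname(spec@collagenSlope * t))
      counter <- counter + 1L
      s <- makeCompositeSpectrum(wts, spec, counter = counter,
                                 label = sprintf("%s_t%g_r%d", role, t, rep))
      cols[[length(cols) + 1L]] <- data.frame(
        role = role, thickness = t, replicate = rep,
        seed = s@metadata$seed)
      cnt[[length(cnt) + 1L]] <- counts(s)
    }
  }
  cd <- do.call(rbind, cols)
  rownames(cd) <- sprintf("%s_t%g_r%d", cd$role, cd$thickness, cd$replicate)
  m <- do.call(cbind, cnt)
  dimnames(m) <- list(NULL, rownames(cd))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    rowData = S4Vectors::DataFrame(wavenumber = w),
    colData = S4Vectors::DataFrame(cd),
    metadata = list(generator = .specToList(spec),
                    version = .generatorVersion()))
}

#' Calibrate the generator count scale to a target band SNR
#'
#' Rescales the photon count scale so that the expected collagen-band SNR of
#' a generated FBR / initial-conditions pair at the reference thickness
#' equals the target: the signal is the baseline-subtracted collagen band of
#' the expected difference spectrum, the noise the square root of the summed
#' raw band counts of both spectra. Because signal scales linearly and noise
#' as the square root of the count scale, the required rescale is
#' (target / current)^2, and doubling the target quadruples the count scale.
#'
#' @param spec a [GeneratorSpec-class].
#' @param targetSNR desired band SNR at \code{thickness}.
#' @param thickness reference thickness (micrometres; default 100).
#' @param band integration band (cm^-1).
#' @return The spec with \code{countScale} rescaled.
#' @export
calibrateNoiseToSNR <- function(spec, targetSNR, thickness = 100,
                                band = c(910, 950)) {
  if (targetSNR <= 0) stop("targetSNR must be positive")
  cur <- .expectedPairSNR(spec, thickness, band)
  if (cur <= 0)
    stop("target unreachable: expected collagen band signal is zero")
  spec@countScale <- spec@countScale * (targetSNR / cur)^2
  validObject(spec)
  spec
}

## expected band SNR of the generated pair, from noise-free expectations
.expectedPairSNR <- function(spec, thickness = 100, band = c(910, 950)) {
  pair <- .pairExpectation(spec, thickness)
  diffExp <- RamanSpectrum(wavenumber(pair$fbr),
                           counts(pair$fbr) - counts(pair$initial))
  signal <- bandIntensities(diffExp, band)$iRaman
  noise <- sqrt(bandIntensities(pair$fbr, band)$iRaw +
                bandIntensities(pair$initial, band)$iRaw)
  signal / noise
}

.generatorVersion <- function() "DiffuseRaman-generator-1"

## portable representation of a GeneratorSpec (JSON-friendly)
.specToList <- function(spec) {
  list(axis = spec@axis, countScale = spec@countScale,
       integrationTime = spec@integrationTime, noise = spec@noise,
       seed = spec@seed, weights = as.list(spec@weights),
       collagenSlope = spec@collagenSlope,
       bands = spec@bands, background = spec@background)
}

.specFromList <- function(x) {
  generatorSpec(axis = unlist(x$axis), countScale = x$countScale,
                integrationTime = x$integrationTime, noise = x$noise,
                seed = x$seed,
                bands = as.data.frame(x$bands),
                background = as.data.frame(x$background),
                weights = unlist(x$weights),
                collagenSlope = x$collagenSlope)
}
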