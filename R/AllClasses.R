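#' @import methods
#' @importFrom stats approx lm coef predict qnorm rpois sd
#' @importFrom utils read.csv write.csv head modifyList
NULL

#' RamanSpectrum: a single Raman spectrum
#'
#' A wavenumber axis (cm^-1, strictly ascending) with photon counts per
#' channel and free-form acquisition metadata (integration time, laser power,
#' material or sample label, generator seed, ...). Raw spectra have
#' nonnegative counts; difference spectra may be negative.
#'
#' @slot wavenumber numeric, strictly ascending wavenumber axis in cm^-1.
#' @slot counts numeric, one value per channel.
#' @slot metadata named list of acquisition metadata.
#' @exportClass RamanSpectrum
setClass("RamanSpectrum",
  slots = c(wavenumber = "numeric", counts = "numeric", metadata = "list"))

setValidity("RamanSpectrum", function(object) {
  if (length(object@wavenumber) != length(object@counts))
    return("wavenumber and counts must have equal length")
  if (length(object@wavenumber) >= 2 && any(diff(object@wavenumber) <= 0))
    return("wavenumber axis must be strictly increasing")
  if (anyNA(object@wavenumber) || anyNA(object@counts))
    return("wavenumber and counts must not contain NA")
  TRUE
})

#' Construct a RamanSpectrum
#'
#' @param wavenumber numeric ascending axis (cm^-1).
#' @param counts numeric photon counts per channel.
#' @param metadata named list of metadata.
#' @return A [RamanSpectrum-class] object.
#' @examples
#' s <- RamanSpectrum(seq(800, 1800, 2), rep(10, 501))
#' @export
RamanSpectrum <- function(wavenumber, counts, metadata = list()) {
  new("RamanSpectrum", wavenumber = as.numeric(wavenumber),
      counts = as.numeric(counts), metadata = metadata)
}

#' PhantomModel: layered tissue phantom with implant and collagen slab
#'
#' A square-footprint slab of tissue (skin over fat over muscle) containing a
#' polystyrene implant disk at a configurable depth below the surface. The
#' collagen layer, when present, is a cylindrical slab of the implant radius
#' sitting on the implant's top face (the implant is displaced downwards by
#' the collagen thickness). Coordinates: origin at the centre of the sample
#' surface, z increasing downwards into the tissue (mm).
#'
#' A model with \code{collagenThickness == 0} represents the
#' "initial conditions" sample (implant as freshly placed); a positive
#' thickness represents the foreign-body-response ("FBR") sample with a
#' fibrotic capsule mimic.
#'
#' @slot lateralExtent square footprint side length (mm).
#' @slot depthExtent domain depth (mm).
#' @slot skinThickness,fatThickness layer thicknesses (mm); muscle fills the
#'   remainder.
#' @slot implantRadius,implantThickness implant disk dimensions (mm).
#' @slot implantTopDepth depth of the top of the implant assembly
#'   (collagen face) below the surface (mm).
#' @slot collagenThickness collagen slab thickness in micrometres.
#' @exportClass PhantomModel
setClass("PhantomModel",
  slots = c(lateralExtent = "numeric", depthExtent = "numeric",
            skinThickness = "numeric", fatThickness = "numeric",
            implantRadius = "numeric", implantThickness = "numeric",
            implantTopDepth = "numeric", collagenThickness = "numeric"))

setValidity("PhantomModel", function(object) {
  len <- c(lateralExtent = object@lateralExtent,
           depthExtent = object@depthExtent,
           skinThickness = object@skinThickness,
           fatThickness = object@fatThickness,
           implantRadius = object@implantRadius,
           implantThickness = object@implantThickness,
           implantTopDepth = object@implantTopDepth)
  if (any(len <= 0))
    return(paste("all lengths must be positive:",
                 paste(names(len)[len <= 0], collapse = ", ")))
  if (object@collagenThickness < 0 || object@collagenThickness > 500)
    return("collagenThickness must lie in [0, 500] micrometres")
  if (object@lateralExtent < 20 || object@depthExtent < 20)
    return("domain must be at least 20 x 20 x 20 mm")
  tmm <- object@collagenThickness / 1000
  if (object@implantTopDepth + tmm + object@implantThickness >
      object@depthExtent)
    return("implant (plus collagen layer) extends below the domain")
  if (2 * object@implantRadius > object@lateralExtent)
    return("implant wider than the domain")
  TRUE
})

#' PhantomGrid: structured discretization of a phantom
#'
#' Node-centred structured grid used by the transport solver: uniform base
#' spacing across the domain, with a fine integration sub-grid (fields
#' evaluated by trilinear interpolation) inside the collagen neighbourhood at
#' an effective spacing of \code{baseSpacing / ceiling(baseSpacing /
#' refinedSpacing)}. Nodes are at x, y centred on the implant axis and z from
#' 0 (surface) downwards.
#'
#' @slot dims integer (nx, ny, nz) node counts.
#' @slot spacing base node spacing (mm).
#' @slot refinedSpacing requested fine sub-grid spacing (mm).
#' @slot labels integer material code per node (index into \code{materials}).
#' @slot materials character vector of material names.
#' @slot phantom the [PhantomModel-class] the grid discretizes.
#' @exportClass PhantomGrid
setClass("PhantomGrid",
  slots = c(dims = "integer", spacing = "numeric",
            refinedSpacing = "numeric", labels = "integer",
            materials = "character", phantom = "PhantomModel"))

setValidity("PhantomGrid", function(object) {
  if (length(object@dims) != 3L || any(object@dims < 2L))
    return("dims must be three node counts >= 2")
  if (length(object@labels) != prod(object@dims))
    return("labels must have one entry per node")
  if (any(object@labels < 1L) || any(object@labels > length(object@materials)))
    return("labels must index into materials")
  if (object@refinedSpacing > object@spacing)
    return("refinedSpacing must not exceed base spacing")
  TRUE
})

#' SurfacePattern: excitation or detection pattern on the sample surface
#'
#' Simple geometric shapes (point, circle outline, disk, line, rectangle)
#' placed on the sample surface, used either as a laser excitation pattern
#' (with a total power) or as a Raman collection pattern. Lines and
#' rectangles are axis-aligned; \code{orientation} names the long axis.
#'
#' @slot shape one of "point", "circle", "disk", "line", "rectangle".
#' @slot center (x, y) centre on the surface (mm).
#' @slot spotDiameter point-beam diameter (mm; point only).
#' @slot radius circle/disk radius (mm).
#' @slot length,width long and short extents (mm; line/rectangle), or the
#'   stroke width for a circle outline.
#' @slot orientation "x" or "y": axis of the long dimension.
#' @slot role "source" or "detector".
#' @slot power total laser power (mW; sources).
#' @exportClass SurfacePattern
setClass("SurfacePattern",
  slots = c(shape = "character", center = "numeric", spotDiameter = "numeric",
            radius = "numeric", length = "numeric", width = "numeric",
            orientation = "character", role = "character", power = "numeric"))

setValidity("SurfacePattern", function(object) {
  if (!object@shape %in% c("point", "circle", "disk", "line", "rectangle"))
    return("unknown shape")
  if (length(object@center) != 2L)
    return("center must be (x, y)")
  if (!object@role %in% c("source", "detector"))
    return("role must be 'source' or 'detector'")
  if (object@power < 0) return("power must be nonnegative")
  TRUE
})

#' FluenceField: nodal field from a transport solve
#'
#' Steady-state diffusion-approximation fluence (per launched photon,
#' mm^-2) for an excitation pattern, or the adjoint detector sensitivity
#' (detected fraction per isotropically emitted photon) for a collection
#' pattern, sampled at the nodes of a [PhantomGrid-class].
#'
#' @slot values numeric nodal values (length prod(dims)).
#' @slot role "excitation" or "sensitivity".
#' @slot band wavelength band tag (e.g. "excitation", "emission").
#' @exportClass FluenceField
setClass("FluenceField",
  slots = c(values = "numeric", role = "character", band = "character"))

#' RamanYieldTable: detected Raman photon yields per sample and material
#'
#' Yields n (detected Raman photons per launched excitation photon, per unit
#' Raman conversion efficiency) for a fixed source/detector pair, for every
#' material of the FBR sample and of the initial-conditions sample.
#'
#' @slot yields data.frame with columns \code{sample} ("FBR" or
#'   "InitialConditions"), \code{material}, \code{yield}.
#' @slot source,detector human-readable pattern descriptions.
#' @exportClass RamanYieldTable
setClass("RamanYieldTable",
  slots = c(yields = "data.frame", source = "character",
            detector = "character"))

setValidity("RamanYieldTable", function(object) {
  need <- c("sample", "material", "yield")
  if (!all(need %in% names(object@yields)))
    return("yields must have columns sample, material, yield")
  if (any(object@yields$yield < 0))
    return("yields must be nonnegative")
  TRUE
})

#' SNRResult: signal-to-noise ratio of the collagen band with derived LOD
#'
#' SNR of the 910-950 cm^-1 collagen band under the shot-noise model:
#' signal is the collagen yield times the baseline-subtracted collagen band
#' intensity; noise is the square root of the total raw band counts from both
#' the FBR and the initial-conditions sample. The thickness limit of
#' detection follows from the linearity of the collagen signal in thickness.
#'
#' @slot snr unitless signal-to-noise ratio.
#' @slot signal collagen band signal (photons).
#' @slot noise shot-noise standard deviation (photons).
#' @slot thickness collagen thickness of the FBR model used (micrometres).
#' @slot criterion one-sided detection criterion (default 1.645).
#' @slot referenceThickness thickness at which snr was evaluated (micrometres).
#' @slot lod derived thickness limit of detection (micrometres).
#' @exportClass SNRResult
setClass("SNRResult",
  slots = c(snr = "numeric", signal = "numeric", noise = "numeric",
            thickness = "numeric", criterion = "numeric",
            referenceThickness = "numeric", lod = "numeric"))

setValidity("SNRResult", function(object) {
  if (length(object@noise) && any(object@noise <= 0))
    return("noise must be positive")
  TRUE
})

#' SNRSurface: SNR evaluated over the detector grid
#'
#' Per-detector SNR for a fixed source pattern over the optimization grid
#' (default 21 x 21 point detectors from -5 to +5 mm). Signal and noise grids
#' are retained so that detector areas can be combined in quadrature.
#'
#' @slot x,y grid axes (mm).
#' @slot snr,signal,noise matrices (length(x) by length(y)).
#' @slot source the source [SurfacePattern-class].
#' @exportClass SNRSurface
setClass("SNRSurface",
  slots = c(x = "numeric", y = "numeric", snr = "matrix", signal = "matrix",
            noise = "matrix", source = "SurfacePattern"))

#' SNRModel: phantom pair + transport machinery for SNR evaluation
#'
#' Bundles the FBR and initial-conditions phantoms, the discretization,
#' optical properties, material reference band intensities and an excitation
#' pattern, and caches the factorized transport system so that the many
#' adjoint (detector) solves of a grid sweep reuse one factorization.
#'
#' @slot fbr,initial the phantom pair ([PhantomModel-class]).
#' @slot grid shared [PhantomGrid-class].
#' @slot optics optical-property table (see [opticalDefaults()]).
#' @slot refs reference band intensities (see [referenceIntensities()]).
#' @slot source excitation [SurfacePattern-class].
#' @slot scale photon-budget scale applied to yields (launched photons times
#'   Raman conversion efficiency).
#' @slot detectorArea area of a point detector (mm^2; default 0.01).
#' @slot cache environment holding the factorization and solved fields.
#' @exportClass SNRModel
setClass("SNRModel",
  slots = c(fbr = "PhantomModel", initial = "PhantomModel",
            grid = "PhantomGrid", optics = "data.frame", refs = "data.frame",
            source = "SurfacePattern", scale = "numeric",
            detectorArea = "numeric", cache = "environment"))

#' CalibrationModel: PLS calibration of collagen thickness
#'
#' Partial least squares regression from full difference spectra to collagen
#' thickness, with the component count chosen by minimum leave-one-out
#' cross-validation RMSE.
#'
#' @slot ncomp selected number of PLS components.
#' @slot fit fitted model: a mixOmics pls fit, or a portable linear map
#'   (list with B, xMeans, yMean) when loaded from disk.
#' @slot wavenumber training axis (cm^-1).
#' @slot thickness training thicknesses (micrometres).
#' @slot looRMSE leave-one-out RMSE at the selected component count
#'   (micrometres).
#' @slot looPredictions LOO-CV predictions for the training set.
#' @slot preprocessing description of the preprocessing chain.
#' @exportClass CalibrationModel
setClass("CalibrationModel",
  slots = c(ncomp = "integer", fit = "ANY", wavenumber = "numeric",
            thickness = "numeric", looRMSE = "numeric",
            looPredictions = "numeric", preprocessing = "character"))

#' RegressionLOD: band-area regression limit of detection
#'
#' Ordinary least squares of collagen band area against thickness, with the
#' limit of detection taken as criterion * residual RMSE / |slope|. The
#' variant with criterion 1 (residual RMSE expressed in thickness units) is
#' reported alongside.
#'
#' @slot slope,intercept fitted line (area units per micrometre; area units).
#' @slot r2 coefficient of determination.
#' @slot rmse residual RMSE (area units).
#' @slot criterion detection criterion used for \code{lod}.
#' @slot lod criterion * rmse / |slope| (micrometres).
#' @slot lodUnitCriterion rmse / |slope| (micrometres; criterion = 1).
#' @exportClass RegressionLOD
setClass("RegressionLOD",
  slots = c(slope = "numeric", intercept = "numeric", r2 = "numeric",
            rmse = "numeric", criterion = "numeric", lod = "numeric",
            lodUnitCriterion = "numeric"))

#' GeneratorSpec: configuration of the synthetic spectrum generator
#'
#' Wavenumber axis, photon count scale at reference acquisition conditions,
#' Poisson noise switch, master seed, the per-material Raman band table and
#' fluorescence-like background coefficients, and the mixture model (initial
#' conditions material weights plus the collagen weight per micrometre of
#' layer thickness).
#'
#' @slot axis numeric (start, stop, step) in cm^-1.
#' @slot countScale photon counts per unit profile height at reference
#'   conditions (45 mW, 900 s).
#' @slot integrationTime acquisition time (s), recorded in metadata.
#' @slot noise logical: draw Poisson counts (TRUE) or return expectations.
#' @slot seed master seed; per-sample seeds are derived from it.
#' @slot bands data.frame: material, center, width, height, profile.
#' @slot background data.frame: material, b0, b1, b2 (quadratic in
#'   (wavenumber - 800)/1000).
#' @slot weights named numeric: initial-conditions mixture weights.
#' @slot collagenSlope collagen mixture weight per micrometre of thickness.
#' @exportClass GeneratorSpec
setClass("GeneratorSpec",
  slots = c(axis = "numeric", countScale = "numeric",
            integrationTime = "numeric", noise = "logical", seed = "integer",
            bands = "data.frame", background = "data.frame",
            weights = "numeric", collagenSlope = "numeric"))

setValidity("GeneratorSpec", function(object) {
  if (length(object@axis) != 3L || object@axis[3] <= 0 ||
      object@axis[2] <= object@axis[1])
    return("axis must be (start, stop, step) with step > 0 and stop > start")
  if (object@countScale <= 0) return("countScale must be positive")
  ax <- c(object@axis[1], object@axis[2])
  if (nrow(object@bands) &&
      (any(object@bands$center < ax[1]) || any(object@bands$center > ax[2])))
    return("band centers must lie within the axis")
  if (nrow(object@bands) && any(object@bands$height < 0))
    return("band heights must be nonnegative")
  if (any(object@weights < 0) || object@collagenSlope < 0)
    return("mixture weights must be nonnegative")
  TRUE
})
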