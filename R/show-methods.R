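#' @describeIn RamanSpectrum-class compact display
#' @param object object to display.
#' @export
setMethod("show", "RamanSpectrum", function(object) {
  w <- object@wavenumber
  cat(sprintf("RamanSpectrum: %d channels, %.6g-%.6g cm^-1\n",
              length(w), min(w), max(w)))
  lab <- object@metadata$material %||% object@metadata$label
  if (!is.null(lab)) cat("  label:", lab, "\n")
  cat(sprintf("  counts: total %.6g, max %.6g\n",
              sum(object@counts), max(object@counts)))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn PhantomModel-class compact display
#' @param object object to display.
#' @export
setMethod("show", "PhantomModel", function(object) {
  cat(sprintf("PhantomModel (%s): %g x %g x %g mm\n", sampleKind(object),
              object@lateralExtent, object@lateralExtent,
              object@depthExtent))
  cat(sprintf("  skin %.3g mm | fat %.3g mm | muscle\n",
              object@skinThickness, object@fatThickness))
  cat(sprintf("  implant r=%g mm x %g mm at depth %g mm; collagen %g um\n",
              object@implantRadius, object@implantThickness,
              object@implantTopDepth, object@collagenThickness))
})

#' @describeIn PhantomGrid-class compact display
#' @param object object to display.
#' @export
setMethod("show", "PhantomGrid", function(object) {
  cat(sprintf("PhantomGrid: %d x %d x %d nodes (%d) at %g mm\n",
              object@dims[1], object@dims[2], object@dims[3],
              prod(object@dims), object@spacing))
  nsub <- ceiling(object@spacing / object@refinedSpacing)
  cat(sprintf("  refined sub-grid: %g mm effective (requested %g mm)\n",
              object@spacing / nsub, object@refinedSpacing))
  tab <- table(object@materials[object@labels])
  cat("  nodes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

#' @describeIn SNRResult-class compact display
#' @param object object to display.
#' @export
setMethod("show", "SNRResult", function(object) {
  cat(sprintf("SNRResult: SNR_%g = %.4g (signal %.4g, noise %.4g)\n",
              object@referenceThickness, object@snr, object@signal,
              object@noise))
  cat(sprintf("  t_LOD = %.0f um (criterion %.4g)\n",
              round(object@lod), object@criterion))
})

#' @describeIn SNRSurface-class compact display
#' @param object object to display.
#' @export
setMethod("show", "SNRSurface", function(object) {
  am <- surfaceArgmax(object)
  cat(sprintf("SNRSurface: %d x %d detectors, x,y in [%g, %g] mm\n",
              length(object@x), length(object@y), min(object@x),
              max(object@x)))
  cat("  source:", describePattern(object@source), "\n")
  cat(sprintf("  max SNR %.4g at (%g, %g), offset %.3g mm\n",
              am$snr, am$x, am$y, am$offset))
})

#' @describeIn SurfacePattern-class compact display
#' @param object object to display.
#' @export
setMethod("show", "SurfacePattern", function(object) {
  cat("SurfacePattern:", describePattern(object), "\n")
})

#' @describeIn RamanYieldTable-class compact display
#' @param object object to display.
#' @export
setMethod("show", "RamanYieldTable", function(object) {
  cat("RamanYieldTable: source", object@source, "| detector",
      object@detector, "\n")
  print(object@yields)
})

#' @describeIn SNRModel-class compact display
#' @param object object to display.
#' @export
setMethod("show", "SNRModel", function(object) {
  cat("SNRModel\n  source:", describePattern(object@source), "\n")
  cat(sprintf("  FBR collagen %g um; grid %d nodes\n",
              object@fbr@collagenThickness, prod(object@grid@dims)))
})

#' @describeIn CalibrationModel-class compact display
#' @param object object to display.
#' @export
setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel: PLS, %d component(s), %d training spectra\n",
              object@ncomp, length(object@thickness)))
  cat(sprintf("  LOO-CV RMSE %.3g um\n  preprocessing: %s\n",
              object@looRMSE, object@preprocessing))
})

#' @describeIn RegressionLOD-class compact display
#' @param object object to display.
#' @export
setMethod("show", "RegressionLOD", function(object) {
  cat(sprintf("RegressionLOD: slope %.4g /um, R^2 %.3g, RMSE %.4g\n",
              object@slope, object@r2, object@rmse))
  cat(sprintf("  t_LOD = %.3g um (criterion %.4g); %.3g um at criterion 1\n",
              object@lod, object@criterion, object@lodUnitCriterion))
})

#' @describeIn GeneratorSpec-class compact display
#' @param object object to display.
#' @export
setMethod("show", "GeneratorSpec", function(object) {
  cat(sprintf("GeneratorSpec: axis %g-%g cm^-1 step %g; countScale %.4g\n",
              object@axis[1], object@axis[2], object@axis[3],
              object@countScale))
  cat(sprintf("  noise %s; seed %d; %d bands over %d materials\n",
              object@noise, object@seed, nrow(object@bands),
              length(unique(object@bands$material))))
})
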