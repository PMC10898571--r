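#' Wavenumber axis of a spectrum
#' @param object a [RamanSpectrum-class].
#' @return numeric wavenumber axis (cm^-1).
#' @export
setGeneric("wavenumber", function(object) standardGeneric("wavenumber"))

#' @rdname wavenumber
#' @export
setMethod("wavenumber", "RamanSpectrum", function(object) object@wavenumber)

#' Photon counts of a spectrum
#' @param object a [RamanSpectrum-class].
#' @return numeric counts per channel.
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname counts
#' @export
setMethod("counts", "RamanSpectrum", function(object) object@counts)

#' Acquisition metadata of a spectrum
#' @param object a [RamanSpectrum-class].
#' @return named list.
#' @export
setGeneric("spectrumMetadata",
           function(object) standardGeneric("spectrumMetadata"))

#' @rdname spectrumMetadata
#' @export
setMethod("spectrumMetadata", "RamanSpectrum", function(object) object@metadata)

#' Material membership query
#'
#' Label the material at arbitrary 3-D points of a phantom. Every point
#' inside the domain receives exactly one label from \{skin, fat, muscle,
#' polystyrene, collagen\}.
#'
#' @param object a [PhantomModel-class].
#' @param points numeric matrix with columns (x, y, z) in mm, or a length-3
#'   vector for a single point.
#' @return character vector of material labels.
#' @export
setGeneric("materialAt", function(object, points) standardGeneric("materialAt"))

#' SNR value accessors
#' @param object an [SNRResult-class].
#' @return numeric.
#' @export
setGeneric("snrValue", function(object) standardGeneric("snrValue"))

#' @rdname snrValue
#' @export
setMethod("snrValue", "SNRResult", function(object) object@snr)

#' @rdname snrValue
#' @export
setGeneric("lodValue", function(object) standardGeneric("lodValue"))

#' @rdname snrValue
#' @export
setMethod("lodValue", "SNRResult", function(object) object@lod)

#' @rdname snrValue
#' @export
setMethod("lodValue", "RegressionLOD", function(object) object@lod)

#' Field values of a fluence or sensitivity field
#' @param object a [FluenceField-class].
#' @return numeric nodal values.
#' @export
setGeneric("fieldValues", function(object) standardGeneric("fieldValues"))

#' @rdname fieldValues
#' @export
setMethod("fieldValues", "FluenceField", function(object) object@values)

#' Yield table accessor
#' @param object a [RamanYieldTable-class].
#' @return data.frame with columns sample, material, yield.
#' @export
setGeneric("yields", function(object) standardGeneric("yields"))

#' @rdname yields
#' @export
setMethod("yields", "RamanYieldTable", function(object) object@yields)
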