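#' Default optical properties at 785 nm
#'
#' Literature-style absorption (mua, mm^-1) and reduced scattering (musp,
#' mm^-1) coefficients and refractive indices for the phantom materials at
#' the 785 nm excitation band. These values are assumptions chosen to be
#' representative of soft tissue in the NIR window; they are not measured
#' values, and all downstream geometry conclusions that depend on them are
#' treated as qualitative (symmetry, offsets, ratios) rather than absolute.
#' Collagen is assigned skin-like properties; polystyrene is treated as a
#' low-absorption scatterer. By default the Raman-shifted emission band uses
#' the same properties as the excitation band.
#'
#' @return data.frame with columns material, mua, musp, n.
#' @examples
#' opticalDefaults()
#' @export
opticalDefaults <- function() {
  data.frame(
    material = c("skin", "fat", "muscle", "polystyrene", "collagen"),
    mua  = c(0.02, 0.01, 0.03, 0.002, 0.02),
    musp = c(1.6, 1.0, 0.7, 2.5, 1.6),
    n    = c(1.4, 1.4, 1.4, 1.4, 1.4))
}

## effective internal-reflection parameter (A-factor) for a refractive
## index mismatch, from the Egan-Hilgeman fit for R_eff
.aFactor <- function(nref) {
  reff <- -1.440 / nref^2 + 0.710 / nref + 0.668 + 0.0636 * nref
  (1 + reff) / (1 - reff)
}

## optics rows aligned to a set of material names, with checks
.opticsFor <- function(optics, materials) {
  need <- c("material", "mua", "musp", "n")
  if (!all(need %in% names(optics)))
    stop("optics must have columns material, mua, musp, n")
  idx <- match(materials, optics$material)
  if (anyNA(idx))
    stop("no optical properties for material(s): ",
         paste(materials[is.na(idx)], collapse = ", "))
  op <- optics[idx, , drop = FALSE]
  if (any(op$mua <= 0) || any(op$musp <= 0) || any(op$n < 1))
    stop("require mua > 0, musp > 0, n >= 1")
  op
}
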