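#' Build the layered implant phantom
#'
#' Construct the digital phantom: a skin layer over a fat layer over muscle,
#' with a polystyrene implant disk whose top face (or the collagen slab
#' coating it) sits at \code{implantTopDepth} below the surface. The
#' collagen slab occupies \code{[implantTopDepth, implantTopDepth + t]} over
#' the disk footprint and displaces the implant downwards, so that it lies
#' directly above the implant's top face. With \code{collagenThickness = 0}
#' the phantom is the "initial conditions" sample.
#'
#' Defaults follow the chicken-skin phantom: ~0.75 mm skin and ~0.75 mm fat
#' over thick muscle, an 8 mm diameter x 2 mm polystyrene disk placed 1.5 mm
#' below the surface (the depth of the subcutaneous pocket), in a domain of
#' at least 20 x 20 x 20 mm.
#'
#' @param lateralExtent,depthExtent domain size (mm).
#' @param skinThickness,fatThickness layer thicknesses (mm).
#' @param implantRadius,implantThickness implant disk dimensions (mm).
#' @param implantTopDepth depth of the top of the collagen/implant assembly
#'   (mm); defaults to skin + fat.
#' @param collagenThickness collagen slab thickness (micrometres, 0-500).
#' @return A [PhantomModel-class].
#' @examples
#' fbr <- buildPhantom(collagenThickness = 100)
#' materialAt(fbr, c(0, 0, 1.55))  # "collagen"
#' materialAt(fbr, c(0, 0, 2.00))  # "polystyrene"
#' @export
buildPhantom <- function(lateralExtent = 20, depthExtent = 20,
                         skinThickness = 0.75, fatThickness = 0.75,
                         implantRadius = 4, implantThickness = 2,
                         implantTopDepth = skinThickness + fatThickness,
                         collagenThickness = 0) {
  if (collagenThickness < 0)
    stop("collagenThickness must be nonnegative")
  new("PhantomModel", lateralExtent = lateralExtent,
      depthExtent = depthExtent, skinThickness = skinThickness,
      fatThickness = fatThickness, implantRadius = implantRadius,
      implantThickness = implantThickness,
      implantTopDepth = implantTopDepth,
      collagenThickness = collagenThickness)
}

#' @rdname materialAt
#' @export
setMethod("materialAt", "PhantomModel", function(object, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  tmm <- object@collagenThickness / 1000
  top <- object@implantTopDepth
  rho2 <- x^2 + y^2
  inDisk <- rho2 <= object@implantRadius^2
  lab <- character(nrow(points))
  ## layered background, top-down
  lab[] <- "muscle"
  lab[z < object@skinThickness + object@fatThickness] <- "fat"
  lab[z < object@skinThickness] <- "skin"
  ## implant assembly carved out (half-open intervals: exact partition)
  if (tmm > 0)
    lab[inDisk & z >= top & z < top + tmm] <- "collagen"
  lab[inDisk & z >= top + tmm &
        z < top + tmm + object@implantThickness] <- "polystyrene"
  lab
})

#' Sample identity of a phantom
#'
#' @param phantom a [PhantomModel-class].
#' @return "FBR" if the collagen layer is present, otherwise
#'   "InitialConditions".
#' @export
sampleKind <- function(phantom) {
  if (phantom@collagenThickness > 0) "FBR" else "InitialConditions"
}

#' Initial-conditions counterpart of an FBR phantom
#'
#' @param phantom a [PhantomModel-class].
#' @return The same phantom with the collagen layer removed.
#' @export
initialConditions <- function(phantom) {
  phantom@collagenThickness <- 0
  validObject(phantom)
  phantom
}

#' Mimicked collagen thickness from deposited mass
#'
#' Thickness of the collagen layer mimicked by depositing a collagen
#' solution on the implant: t = mass * collagenFraction / (density * area),
#' using the implant surface area and the density of collagen in a fibrotic
#' capsule (500 ug/mm^3).
#'
#' @param massDeposited mass of deposited solution (g).
#' @param collagenFraction collagen mass fraction of the solution (unitless,
#'   in (0, 1]); a 1:10 collagen:KOH solution gives 1/11.
#' @param area implant surface area (mm^2); default pi * 4^2 for the 8 mm
#'   disk.
#' @param density collagen density in a fibrotic capsule (ug/mm^3).
#' @return Mimicked thickness in micrometres.
#' @examples
#' thicknessFromMass(0.01, 1 / 11) / 1000  # mm of pure-layer equivalent
#' @export
thicknessFromMass <- function(massDeposited, collagenFraction = 1,
                              area = pi * 4^2, density = 500) {
  if (massDeposited < 0) stop("massDeposited must be nonnegative")
  if (collagenFraction <= 0 || collagenFraction > 1)
    stop("collagenFraction must lie in (0, 1]")
  if (area <= 0 || density <= 0)
    stop("area and density must be positive")
  massUg <- massDeposited * 1e6
  tMm <- massUg * collagenFraction / (density * area)
  tMm * 1000
}
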