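#' Assemble the diffusion-approximation transport system
#'
#' Discretizes the steady-state diffusion equation
#' \code{-div(kappa grad Phi) + mua Phi = q} on the structured grid with a
#' 7-point stencil (face conductances from the harmonic mean of the nodal
#' diffusion coefficients kappa = 1/(3(mua + musp))) and Robin
#' (partial-current) boundary conditions \code{Phi + 2 A kappa dPhi/dn = 0},
#' with the internal-reflection parameter A derived from the refractive
#' index mismatch. The symmetric positive-definite system is factorized
#' once (sparse Cholesky) and the factorization is reused for every
#' excitation and adjoint detector solve on the grid.
#'
#' @param grid a [PhantomGrid-class].
#' @param optics optical-property table (see [opticalDefaults()]).
#' @param band wavelength band tag recorded on solved fields.
#' @return A list with the grid, optics, assembled matrix, and a cache
#'   environment holding the factorization (class \code{"drsTransport"}).
#' @export
transportSystem <- function(grid, optics = opticalDefaults(),
                            band = "excitation") {
  op <- .opticsFor(optics, grid@materials)
  d <- grid@dims; h <- grid@spacing; N <- prod(d)
  mua <- op$mua[grid@labels]
  kap <- 1 / (3 * (op$mua + op$musp))[grid@labels]
  nref <- op$n[grid@labels]

  nxy <- d[1] * d[2]
  ## neighbour index offsets: +x, +y, +z
  tri <- function(offset, mask) {
    a <- which(mask)
    b <- a + offset
    g <- h * 2 * kap[a] * kap[b] / (kap[a] + kap[b])
    list(a = a, b = b, g = g)
  }
  ix <- rep(seq_len(d[1]), times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]), each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]), each = nxy)
  ts <- list(tri(1L, ix < d[1]), tri(d[1], iy < d[2]), tri(nxy, iz < d[3]))
  a <- unlist(lapply(ts, `[[`, "a"))
  b <- unlist(lapply(ts, `[[`, "b"))
  g <- unlist(lapply(ts, `[[`, "g"))

  diagv <- mua * h^3
  ## Robin boundary: h^2 / (2A) per exposed face
  afac <- .aFactor(nref)
  nBndFaces <- (ix == 1) + (ix == d[1]) + (iy == 1) + (iy == d[2]) +
    (iz == 1) + (iz == d[3])
  diagv <- diagv + nBndFaces * h^2 / (2 * afac)

  Aoff <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = c(-g, -g),
                               dims = c(N, N))
  A <- Aoff + Matrix::Diagonal(N, diagv - Matrix::rowSums(Aoff))

  cache <- new.env(parent = emptyenv())
  obj <- structure(list(grid = grid, optics = op, band = band, A = A,
                        afac = afac, musp = op$musp[grid@labels],
                        cache = cache),
                   class = "drsTransport")
  obj
}

## sparse Cholesky factor, computed once per system
.factor <- function(ts) {
  if (is.null(ts$cache$chol))
    ts$cache$chol <- Matrix::Cholesky(Matrix::forceSymmetric(ts$A),
                                      LDL = FALSE, super = TRUE)
  ts$cache$chol
}

.solveSystem <- function(ts, b) {
  as.matrix(Matrix::solve(.factor(ts), b, system = "A"))
}

## reduced scattering coefficient of the surface material at (x, y)
.surfaceMusp <- function(ts, pts2d) {
  surf <- cbind(pts2d[, 1, drop = TRUE], pts2d[, 2, drop = TRUE], 0)
  lab <- materialAt(ts$grid@phantom, surf)
  op <- ts$optics
  op$musp[match(lab, op$material)]
}

## right-hand side for an excitation pattern: each surface point becomes an
## isotropic point source buried at one transport mean free path (1/musp),
## trilinear-spread onto the grid; total power normalized to 1.
.sourceVector <- function(ts, pattern) {
  pp <- patternPoints(pattern)
  z0 <- 1 / .surfaceMusp(ts, pp$points)
  pts3 <- cbind(pp$points, z0)
  P <- .interpMatrix(ts$grid, pts3)
  as.numeric(Matrix::crossprod(P, pp$weights))
}

## measurement matrix for point detectors at surface positions pts2d
## (one column per detector): detected signal = area * Phi_surface / (2A),
## with Phi at the detector position bilinear-interpolated from surface
## nodes.
.detectorMatrix <- function(ts, pts2d, area) {
  pts3 <- cbind(pts2d[, 1, drop = TRUE], pts2d[, 2, drop = TRUE], 0)
  P <- .interpMatrix(ts$grid, pts3)
  afacLocal <- as.numeric(P %*% ts$afac)
  Matrix::t(P * (area / (2 * afacLocal)))
}

#' Solve the excitation fluence for a surface pattern
#'
#' Steady-state diffusion solution for a collimated excitation pattern,
#' represented as isotropic point sources buried at one transport mean free
#' path below each pattern point, with total launched power normalized to 1
#' (results scale linearly with power).
#'
#' @param ts a transport system from [transportSystem()].
#' @param pattern a source [SurfacePattern-class].
#' @return A [FluenceField-class] of nodal fluence values (mm^-2 per
#'   launched photon).
#' @export
solveFluence <- function(ts, pattern) {
  q <- .sourceVector(ts, pattern)
  phi <- .solveSystem(ts, q)[, 1]
  new("FluenceField", values = phi, role = "excitation", band = ts$band)
}

#' Adjoint detector sensitivity field
#'
#' Sensitivity field s such that the detected signal from an interior
#' isotropic emitter equals emitter strength times s at its location
#' (reciprocity). Point detectors measure the outward partial current
#' \code{Phi / (2A)} times the detector area; extended patterns sum the
#' point functionals with the pattern area split uniformly over its points.
#'
#' @param ts a transport system from [transportSystem()].
#' @param pattern a detector [SurfacePattern-class], or a 2-column matrix of
#'   surface points.
#' @param area total collection area (mm^2); defaults to the pattern area,
#'   or 0.01 mm^2 (the 0.1 x 0.1 mm point detector) per point for a matrix
#'   of points.
#' @return A [FluenceField-class] of nodal sensitivity values.
#' @export
detectorSensitivity <- function(ts, pattern, area = NULL) {
  if (is.matrix(pattern)) {
    pts <- pattern
    if (is.null(area)) area <- 0.01 * nrow(pts)
  } else {
    pp <- patternPoints(pattern)
    pts <- pp$points
    if (is.null(area)) area <- patternArea(pattern)
  }
  C <- .detectorMatrix(ts, pts, area / nrow(pts))
  cvec <- Matrix::rowSums(C) # C is N x npts: sum the point functionals
  s <- .solveSystem(ts, as.numeric(cvec))[, 1]
  new("FluenceField", values = s, role = "sensitivity", band = ts$band)
}

#' Material-resolved detected Raman yield
#'
#' Born (single-conversion) Raman emission model: the detected yield from a
#' material is the integral of excitation fluence times detector sensitivity
#' over the region occupied by that material,
#' \code{sum(excitation * sensitivity * cell volume)}. For the thin collagen
#' slab (and its neighbourhood) the integral runs on the fine sub-grid with
#' trilinear-interpolated fields, so yields remain accurate and linear in
#' thickness well below the base node spacing.
#'
#' @param excitation,sensitivity [FluenceField-class] fields on \code{grid}.
#' @param grid the shared [PhantomGrid-class].
#' @param material material label to integrate over.
#' @param phantom phantom defining material membership; defaults to the
#'   grid's phantom.
#' @return Numeric yield (detected photons per launched photon per unit
#'   Raman conversion efficiency).
#' @export
ramanYield <- function(excitation, sensitivity, grid, material,
                       phantom = grid@phantom) {
  if (length(excitation@values) != prod(grid@dims) ||
      length(sensitivity@values) != prod(grid@dims))
    stop("fields and grid sizes do not match")
  if (!material %in% c(grid@materials, "all"))
    stop("unknown material label: ", material)
  intdata <- .integrationData(grid, list(phantom))
  mats <- if (identical(material, "all")) grid@materials else material
  E <- excitation@values
  V <- .yieldVectors(intdata, E, mats)
  sum(as.numeric(crossprod(V, sensitivity@values)))
}

#' Yield table for an FBR / initial-conditions phantom pair
#'
#' Computes detected Raman yields for every material of the FBR sample and
#' of the initial-conditions sample, for one source pattern and one detector
#' pattern, sharing a single discretization and factorized transport system.
#'
#' @param source source [SurfacePattern-class].
#' @param detector detector [SurfacePattern-class] or 2-column point matrix.
#' @param fbr FBR [PhantomModel-class] (collagen layer present).
#' @param initial initial-conditions phantom; defaults to \code{fbr} with
#'   the collagen removed.
#' @param grid optional [PhantomGrid-class]; built from \code{fbr} if
#'   missing.
#' @param optics optical-property table.
#' @param detectorArea collection area for point-matrix detectors (mm^2).
#' @return A [RamanYieldTable-class].
#' @export
yieldTable <- function(source, detector, fbr, initial = initialConditions(fbr),
                       grid = buildPhantomGrid(fbr),
                       optics = opticalDefaults(), detectorArea = NULL) {
  ts <- transportSystem(grid, optics)
  E <- solveFluence(ts, source)
  S <- detectorSensitivity(ts, detector, area = detectorArea)
  intdata <- .integrationData(grid, list(FBR = fbr,
                                         InitialConditions = initial))
  V <- .yieldVectors(intdata, E@values, grid@materials)
  y <- as.numeric(crossprod(V, S@values))
  ## columns of V are ordered sample-major (phantom 1 then 2), material minor
  df <- data.frame(sample = rep(c("FBR", "InitialConditions"),
                                each = length(grid@materials)),
                   material = rep(grid@materials, times = 2),
                   yield = pmax(y, 0))
  new("RamanYieldTable", yields = df,
      source = describePattern(source),
      detector = if (is.matrix(detector)) "point set"
                 else describePattern(detector))
}
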