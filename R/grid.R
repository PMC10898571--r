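#' Discretize a phantom on a structured grid
#'
#' Node-centred uniform grid over the phantom domain: node counts per axis
#' are \code{floor(extent / spacing) + 1}, x and y centred on the implant
#' axis and z from 0 (surface) downwards. Each node carries the material
#' label of the phantom at its coordinates. The 0.08 mm resolution around
#' the collagen layer is realized as a fine integration sub-grid (see
#' [ramanYield()]): fields are trilinear-interpolated onto sub-cells of the
#' base cells intersecting the collagen neighbourhood, at an effective
#' spacing of \code{spacing / ceiling(spacing / refinedSpacing)}.
#'
#' @param phantom a [PhantomModel-class].
#' @param spacing base node spacing (mm; default 0.6).
#' @param refinedSpacing requested fine sub-grid spacing (mm; default 0.08).
#' @return A [PhantomGrid-class].
#' @examples
#' g <- buildPhantomGrid(buildPhantom())
#' prod(g@dims)  # about 34^3 nodes for the default 20 mm cube
#' @export
buildPhantomGrid <- function(phantom, spacing = 0.6, refinedSpacing = 0.08) {
  if (spacing <= 0 || refinedSpacing <= 0)
    stop("spacings must be positive")
  if (refinedSpacing > spacing)
    stop("refinedSpacing must not exceed the base spacing")
  if (spacing > min(phantom@lateralExtent, phantom@depthExtent))
    stop("spacing larger than the domain")
  nx <- as.integer(floor(phantom@lateralExtent / spacing) + 1)
  nz <- as.integer(floor(phantom@depthExtent / spacing) + 1)
  dims <- c(nx, nx, nz)
  ax <- gridAxes(dims, spacing)
  pts <- cbind(rep(ax$x, times = nx * nz),
               rep(rep(ax$y, each = nx), times = nz),
               rep(ax$z, each = nx * nx))
  lab <- materialAt(phantom, pts)
  materials <- c("skin", "fat", "muscle", "polystyrene", "collagen")
  new("PhantomGrid", dims = dims, spacing = spacing,
      refinedSpacing = refinedSpacing,
      labels = match(lab, materials), materials = materials,
      phantom = phantom)
}

## node coordinate axes for a dims/spacing pair (x, y centred; z from 0)
gridAxes <- function(dims, spacing) {
  list(x = (seq_len(dims[1]) - 1 - (dims[1] - 1) / 2) * spacing,
       y = (seq_len(dims[2]) - 1 - (dims[2] - 1) / 2) * spacing,
       z = (seq_len(dims[3]) - 1) * spacing)
}

#' Node coordinates of a grid
#'
#' @param grid a [PhantomGrid-class].
#' @return numeric matrix (nodes x 3) of (x, y, z) in mm, in node order
#'   (x fastest, then y, then z).
#' @export
gridCoordinates <- function(grid) {
  ax <- gridAxes(grid@dims, grid@spacing)
  cbind(x = rep(ax$x, times = grid@dims[2] * grid@dims[3]),
        y = rep(rep(ax$y, each = grid@dims[1]), times = grid@dims[3]),
        z = rep(ax$z, each = grid@dims[1] * grid@dims[2]))
}

## node-centred cell weights: h per axis, halved on boundary planes.
## total equals the domain volume spanned by the node cells.
.cellWeights <- function(grid) {
  d <- grid@dims; h <- grid@spacing
  wAxis <- function(n) { w <- rep(h, n); w[c(1, n)] <- h / 2; w }
  wx <- wAxis(d[1]); wy <- wAxis(d[2]); wz <- wAxis(d[3])
  rep(wz, each = d[1] * d[2]) *
    rep(rep(wy, each = d[1]), times = d[3]) *
    rep(wx, times = d[2] * d[3])
}

## trilinear interpolation of nodal fields at arbitrary points:
## returns sparse matrix P (npts x nnodes), rows sum to 1.
.interpMatrix <- function(grid, pts) {
  d <- grid@dims; h <- grid@spacing
  cx <- (d[1] - 1) / 2; cy <- (d[2] - 1) / 2
  fi <- pts[, 1] / h + cx + 1
  fj <- pts[, 2] / h + cy + 1
  fk <- pts[, 3] / h + 1
  clamp <- function(f, n) pmin(pmax(f, 1), n)
  fi <- clamp(fi, d[1]); fj <- clamp(fj, d[2]); fk <- clamp(fk, d[3])
  i0 <- pmin(floor(fi), d[1] - 1); j0 <- pmin(floor(fj), d[2] - 1)
  k0 <- pmin(floor(fk), d[3] - 1)
  di <- fi - i0; dj <- fj - j0; dk <- fk - k0
  n <- nrow(pts)
  ii <- jj <- integer(8L * n); xx <- numeric(8L * n)
  pos <- 0L
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    w <- (if (a) di else 1 - di) * (if (b) dj else 1 - dj) *
         (if (cc) dk else 1 - dk)
    node <- (k0 + cc - 1) * d[1] * d[2] + (j0 + b - 1) * d[1] + (i0 + a)
    ii[pos + seq_len(n)] <- seq_len(n)
    jj[pos + seq_len(n)] <- node
    xx[pos + seq_len(n)] <- w
    pos <- pos + n
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, prod(d)))
}

## Integration machinery for material-resolved yields.
##
## Exact partition of the node-cell volume into:
##   * coarse nodes outside the refined region (weight = cell volume), and
##   * fine sub-cell centres tiling the cells of the refined region
##     (weight = cell volume / (nsub^2 * nsubZ)),
## where the refined region is the set of base cells intersecting the
## collagen slab's depth range (over the dilated disk footprint). The
## sub-grid is anisotropic: lateral spacing spacing/nsub (the requested
## refined spacing), axial spacing capped at 0.01 mm so that 10 um-scale
## collagen slabs are resolved (the fields vary on the mm scale; only
## membership needs the axial resolution). Material labels are evaluated
## per phantom, so an FBR / initial-conditions pair shares the
## discretization and differs only in the labels of the collagen slab.
.integrationData <- function(grid, phantoms, maxThickness = 0.5) {
  d <- grid@dims; h <- grid@spacing
  ph1 <- phantoms[[1]]
  top <- ph1@implantTopDepth
  crd <- gridCoordinates(grid)
  w <- .cellWeights(grid)
  inRef <- crd[, 3] + h / 2 > top + 1e-9 &
    crd[, 3] - h / 2 < top + maxThickness - 1e-9 &
    sqrt(crd[, 1]^2 + crd[, 2]^2) <= ph1@implantRadius + h
  nsub <- as.integer(ceiling(h / grid@refinedSpacing))
  nsubZ <- max(nsub, as.integer(ceiling(h / 0.01)))
  ## fine points: sub-cell centres of each refined cell
  offXY <- ((seq_len(nsub) - 0.5) / nsub - 0.5) * h
  offZ <- ((seq_len(nsubZ) - 0.5) / nsubZ - 0.5) * h
  ref <- which(inRef)
  perCell <- nsub^2 * nsubZ
  finePts <- cbind(
    rep(crd[ref, 1], each = perCell) +
      rep(rep(offXY, times = nsub * nsubZ), times = length(ref)),
    rep(crd[ref, 2], each = perCell) +
      rep(rep(rep(offXY, each = nsub), times = nsubZ),
          times = length(ref)),
    rep(crd[ref, 3], each = perCell) +
      rep(rep(offZ, each = nsub^2), times = length(ref)))
  fineW <- rep(w[ref] / perCell, each = perCell)
  P <- .interpMatrix(grid, finePts)
  coarseW <- w
  coarseW[ref] <- 0
  labs <- lapply(phantoms, function(ph)
    list(coarse = materialAt(ph, crd), fine = materialAt(ph, finePts)))
  list(coarseW = coarseW, fineW = fineW, P = P, labels = labs,
       finePts = finePts, nsub = nsub, nsubZ = nsubZ)
}

## per-(phantom, material) yield vectors v such that yield = sum(S * v)
## for a sensitivity field S; E is the excitation field (nodal values).
.yieldVectors <- function(intdata, E, materials) {
  Ef <- as.numeric(intdata$P %*% E)
  out <- list()
  for (s in seq_along(intdata$labels)) {
    lab <- intdata$labels[[s]]
    for (m in materials) {
      vc <- intdata$coarseW * E * (lab$coarse == m)
      vf <- as.numeric(Matrix::crossprod(
        intdata$P, intdata$fineW * Ef * (lab$fine == m)))
      out[[paste(s, m, sep = ".")]] <- vc + vf
    }
  }
  do.call(cbind, out)
}
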