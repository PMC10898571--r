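#' Build an SNR model for a phantom pair and excitation pattern
#'
#' Bundles everything needed to evaluate the collagen-band SNR at arbitrary
#' detector positions: the FBR / initial-conditions phantom pair, the shared
#' discretization, optical properties, reference band intensities, and the
#' excitation pattern. The assembled transport system, its sparse Cholesky
#' factorization, the excitation field and the material yield vectors are
#' cached, so a 441-detector grid sweep performs one factorization and one
#' triangular solve per detector.
#'
#' @param source excitation [SurfacePattern-class].
#' @param fbr FBR phantom ([PhantomModel-class]; collagen layer present).
#' @param initial initial-conditions phantom; default removes the collagen.
#' @param grid shared [PhantomGrid-class]; built from \code{fbr} by default.
#' @param optics optical-property table ([opticalDefaults()]).
#' @param refs reference band intensities ([referenceIntensities()]); by
#'   default computed from noise-free synthetic reference spectra.
#' @param scale photon-budget scale (launched photons times Raman conversion
#'   efficiency) applied to yields; SNR scales as sqrt(scale).
#' @param detectorArea point-detector collection area (mm^2; default the
#'   0.1 x 0.1 mm detector).
#' @param criterion detection criterion for derived LODs.
#' @return An [SNRModel-class].
#' @export
snrModel <- function(source, fbr = buildPhantom(collagenThickness = 100),
                     initial = initialConditions(fbr),
                     grid = buildPhantomGrid(fbr),
                     optics = opticalDefaults(),
                     refs = referenceIntensities(
                       syntheticReferences(generatorSpec(noise = FALSE))),
                     scale = defaultPhotonScale(), detectorArea = 0.01,
                     criterion = 1.645) {
  new("SNRModel", fbr = fbr, initial = initial, grid = grid, optics = optics,
      refs = refs, source = source, scale = scale,
      detectorArea = detectorArea, cache = new.env(parent = emptyenv()))
}

#' Default photon-budget scale
#'
#' Launched-photon count for the reference acquisition (45 mW at 785 nm for
#' 900 s, about 1.6e20 photons) times a nominal Raman conversion efficiency
#' per material unit (1e-16). The absolute SNR scale depends on unpublished
#' conversion efficiencies, so this constant is a documented unit
#' convention: ratios of SNR values, symmetry and argmax locations do not
#' depend on it.
#'
#' @param power laser power (mW).
#' @param time integration time (s).
#' @param wavelength excitation wavelength (nm).
#' @param conversion nominal Raman conversion efficiency.
#' @return numeric scale.
#' @export
defaultPhotonScale <- function(power = 45, time = 900, wavelength = 785,
                               conversion = 1e-16) {
  ePhoton <- 6.62607015e-34 * 2.99792458e8 / (wavelength * 1e-9)
  (power * 1e-3) * time / ePhoton * conversion
}

## cached transport system / excitation field / yield vectors
.modelTS <- function(model) {
  if (is.null(model@cache$ts))
    model@cache$ts <- transportSystem(model@grid, model@optics)
  model@cache$ts
}

.modelIntdata <- function(model) {
  if (is.null(model@cache$intdata))
    model@cache$intdata <- .integrationData(
      model@grid, list(FBR = model@fbr, InitialConditions = model@initial))
  model@cache$intdata
}

.modelE <- function(model) {
  sig <- describePattern(model@source)
  if (is.null(model@cache$E)) model@cache$E <- list()
  if (is.null(model@cache$E[[sig]]))
    model@cache$E[[sig]] <- solveFluence(.modelTS(model), model@source)
  model@cache$E[[sig]]
}

.modelV <- function(model) {
  sig <- describePattern(model@source)
  if (is.null(model@cache$V)) model@cache$V <- list()
  if (is.null(model@cache$V[[sig]]))
    model@cache$V[[sig]] <- .yieldVectors(.modelIntdata(model),
                                          .modelE(model)@values,
                                          model@grid@materials)
  model@cache$V[[sig]]
}

## same model with a different source, sharing the cache (factorization and
## detector solves are source-independent)
.withSource <- function(model, source) {
  model@source <- source
  model
}

#' Collagen-band SNR at point detectors
#'
#' Evaluates signal, shot noise and SNR at one or more point detector
#' positions on the surface, via one adjoint solve per detector against the
#' cached factorization.
#'
#' @param model an [SNRModel-class].
#' @param points 2-column matrix (x, y) of detector positions (mm).
#' @param combine if TRUE, combine all points into one detector
#'   (signals add, noises add in quadrature) and return an
#'   [SNRResult-class]; otherwise return a per-point data.frame.
#' @return data.frame (x, y, signal, noise, snr) or an [SNRResult-class].
#' @export
detectorSNR <- function(model, points, combine = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  ts <- .modelTS(model)
  V <- .modelV(model)
  C <- .detectorMatrix(ts, points, model@detectorArea)
  S <- .solveSystem(ts, C)
  Y <- pmax(crossprod(S, V), 0) # npts x (sample.material)
  mats <- model@grid@materials
  cols <- expand.grid(material = mats,
                      sample = c("FBR", "InitialConditions"),
                      stringsAsFactors = FALSE)
  idx <- match(cols$material, model@refs$material)
  if (anyNA(idx))
    stop("no reference intensities for material(s): ",
         paste(unique(cols$material[is.na(idx)]), collapse = ", "))
  iRamanCol <- model@refs$iRaman[model@refs$material == "collagen"]
  colIdx <- which(cols$sample == "FBR" & cols$material == "collagen")
  signal <- model@scale * Y[, colIdx] * iRamanCol
  total <- model@scale * as.numeric(Y %*% model@refs$iRaw[idx])
  if (any(total <= 0)) stop("zero total count at a detector position")
  noise <- sqrt(total)
  df <- data.frame(x = points[, 1], y = points[, 2], signal = signal,
                   noise = noise, snr = signal / noise)
  if (combine)
    combineDetectors(df$signal, df$noise,
                     thickness = model@fbr@collagenThickness,
                     criterion = 1.645)
  else df
}

#' SNR surface over the detector grid
#'
#' Evaluates the per-detector SNR over the optimization grid (default
#' 21 x 21 point detectors, x and y from -5 to +5 mm at 0.5 mm pitch, 441
#' positions) for the model's source pattern, reusing one factorization for
#' all adjoint solves.
#'
#' @param model an [SNRModel-class].
#' @param n grid points per axis (default 21).
#' @param span grid extent (mm; default c(-5, 5)).
#' @return An [SNRSurface-class].
#' @export
snrSurface <- function(model, n = 21, span = c(-5, 5)) {
  ax <- seq(span[1], span[2], length.out = n)
  pts <- as.matrix(expand.grid(x = ax, y = ax))
  df <- detectorSNR(model, pts)
  new("SNRSurface", x = ax, y = ax,
      snr = matrix(df$snr, n, n), signal = matrix(df$signal, n, n),
      noise = matrix(df$noise, n, n), source = model@source)
}

#' Location and value of the surface maximum
#'
#' @param surface an [SNRSurface-class].
#' @return list with \code{x}, \code{y}, \code{snr}, \code{offset} (radial
#'   distance from the surface centre, mm).
#' @export
surfaceArgmax <- function(surface) {
  k <- which.max(surface@snr)
  i <- (k - 1) %% length(surface@x) + 1
  j <- (k - 1) %/% length(surface@x) + 1
  list(x = surface@x[i], y = surface@y[j], snr = surface@snr[k],
       offset = sqrt(surface@x[i]^2 + surface@y[j]^2))
}

#' Integrate collection over a rectangular detector area
#'
#' Combines the grid points of an [SNRSurface-class] lying inside an
#' axis-aligned rectangle: signals summed, noises combined in quadrature
#' (the [combineDetectors()] contract).
#'
#' @param surface an [SNRSurface-class].
#' @param xlim,ylim rectangle extents (mm).
#' @param thickness,criterion recorded on the result.
#' @return An [SNRResult-class].
#' @export
integrateDetectorArea <- function(surface, xlim, ylim = c(-5, 5),
                                  thickness = 100, criterion = 1.645) {
  inX <- surface@x >= min(xlim) & surface@x <= max(xlim)
  inY <- surface@y >= min(ylim) & surface@y <= max(ylim)
  if (!any(inX) || !any(inY))
    stop("rectangle contains no grid points")
  sig <- surface@signal[inX, inY, drop = FALSE]
  noi <- surface@noise[inX, inY, drop = FALSE]
  combineDetectors(as.numeric(sig), as.numeric(noi),
                   thickness = thickness, criterion = criterion)
}

#' SNR of a linear fiber-bundle detector
#'
#' Combines a short linear array of detection points (default seven points
#' spanning -0.5 to +0.5 mm, the fibre spacing of the bundle head) placed at
#' a lateral offset from the excitation line: signals summed, noises in
#' quadrature.
#'
#' @param model an [SNRModel-class].
#' @param offset lateral offset of the array from the source axis (mm).
#' @param nFibers number of detection points (default 7).
#' @param span extent of the array along the line direction (mm).
#' @param orientation "y" if the array runs along y at x = offset.
#' @return An [SNRResult-class].
#' @export
fiberSubsetSNR <- function(model, offset = 1.5, nFibers = 7,
                           span = c(-0.5, 0.5), orientation = "y") {
  along <- seq(span[1], span[2], length.out = nFibers)
  pts <- if (orientation == "y") cbind(offset, along) else
    cbind(along, offset)
  detectorSNR(model, pts, combine = TRUE)
}

## does any of pts fall within `clearance` of the source footprint?
.nearSource <- function(source, pts, clearance = 0.25) {
  sp <- patternPoints(source, 0.25)$points
  dmin <- sqrt(outer(pts[, 1], sp[, 1], `-`)^2 +
               outer(pts[, 2], sp[, 2], `-`)^2)
  apply(dmin, 1, min) <= clearance
}

## evaluate one detector specification against a model + its surface
.evalDetector <- function(model, surface, spec) {
  thick <- model@fbr@collagenThickness
  switch(spec$type,
    point = {
      if (is.null(spec$x)) {
        pts <- as.matrix(expand.grid(x = surface@x, y = surface@y))
        ok <- !.nearSource(model@source, pts)
        snrs <- as.numeric(surface@snr)
        k <- which(ok)[which.max(snrs[ok])]
        spec$x <- pts[k, 1]; spec$y <- pts[k, 2]
      }
      i <- which.min(abs(surface@x - spec$x))
      j <- which.min(abs(surface@y - spec$y))
      res <- combineDetectors(surface@signal[i, j], surface@noise[i, j],
                              thickness = thick)
      list(res = res, area = model@detectorArea,
           label = sprintf("point detector at (%.2g, %.2g)",
                           surface@x[i], surface@y[j]))
    },
    rectangle = ,
    rectanglePair = {
      width <- if (is.null(spec$width)) 2 else spec$width
      len <- if (is.null(spec$length)) 10 else spec$length
      offs <- if (is.null(spec$offset)) {
        cand <- surface@x[surface@x - width / 2 > 0]
        cand[cand - width / 2 >= .sourceHalfWidth(model@source)]
      } else spec$offset
      if (!length(offs)) return(NULL)
      best <- NULL
      for (off in offs) {
        r1 <- integrateDetectorArea(surface, off + c(-1, 1) * width / 2,
                                    c(-len / 2, len / 2), thickness = thick)
        res <- if (spec$type == "rectanglePair") {
          r2 <- integrateDetectorArea(surface, -off + c(-1, 1) * width / 2,
                                      c(-len / 2, len / 2),
                                      thickness = thick)
          combineDetectors(list(r1, r2))
        } else r1
        if (is.null(best) || res@snr > best$res@snr)
          best <- list(res = res, off = off)
      }
      nrect <- if (spec$type == "rectanglePair") 2 else 1
      list(res = best$res, area = nrect * width * len,
           label = sprintf("%s %g x %g mm at offset %.2g",
                           spec$type, len, width, best$off))
    },
    fiberArray = {
      off <- if (is.null(spec$offset)) 1.5 else spec$offset
      res <- fiberSubsetSNR(model, offset = off,
                            nFibers = if (is.null(spec$nFibers)) 7
                                      else spec$nFibers)
      list(res = res, area = model@detectorArea *
             (if (is.null(spec$nFibers)) 7 else spec$nFibers),
           label = sprintf("fiber array at offset %.2g", off))
    },
    stop("unknown detector spec type: ", spec$type))
}

## half-width of the source footprint along x (for disjointness of
## x-offset rectangles)
.sourceHalfWidth <- function(source) {
  switch(source@shape,
    point = source@spotDiameter / 2,
    disk = ,
    circle = source@radius,
    if (source@orientation == "y") source@width / 2 else source@length / 2)
}

#' Search constrained excitation/detection geometries for maximum SNR
#'
#' Enumerates candidate source patterns and detector configurations over the
#' search area, filters sources by the skin maximum permissible exposure and
#' detectors by disjointness from the source, evaluates each configuration's
#' collagen-band SNR (sharing one transport factorization across all
#' candidates), and returns the feasible configurations ranked by SNR with
#' the thickness limit of detection attached. Ties are broken towards the
#' smaller detector area, then lexicographically.
#'
#' @param sources list of source [SurfacePattern-class] candidates; default
#'   the centred 45 mW point beam and the 10 x 2 mm line.
#' @param detectors list of detector specifications: each a list with
#'   \code{type} in "point", "rectangle", "rectanglePair", "fiberArray" and
#'   optional placement parameters (auto-placed from the SNR surface when
#'   omitted).
#' @param fbr,initial,grid,optics,refs,scale,detectorArea as [snrModel()].
#' @param mpe maximum permissible exposure (mW/mm^2).
#' @param surfaceN detector grid points per axis.
#' @param criterion detection criterion for LODs.
#' @return list (class \code{drsOptimization}): \code{ranked} data.frame of
#'   feasible configurations (snr, lod, power density, ...), \code{infeasible}
#'   data.frame of rejected sources, \code{surfaces} per-source
#'   [SNRSurface-class] list. If nothing is feasible, \code{ranked} has zero
#'   rows and \code{message} says so.
#' @export
optimizeGeometry <- function(sources = list(pointSource(), lineSource()),
                             detectors = list(list(type = "point"),
                                              list(type = "rectangle"),
                                              list(type = "rectanglePair")),
                             fbr = buildPhantom(collagenThickness = 100),
                             initial = initialConditions(fbr),
                             grid = buildPhantomGrid(fbr),
                             optics = opticalDefaults(),
                             refs = referenceIntensities(
                               syntheticReferences(generatorSpec(noise = FALSE))),
                             scale = defaultPhotonScale(),
                             detectorArea = 0.01, mpe = 3, surfaceN = 21,
                             criterion = 1.645) {
  model0 <- snrModel(sources[[1]], fbr, initial, grid, optics, refs,
                     scale, detectorArea)
  rows <- list(); bad <- list(); surfaces <- list()
  for (src in sources) {
    chk <- mpeCheck(src, mpe)
    slab <- describePattern(src)
    if (!chk$pass) {
      bad[[length(bad) + 1L]] <- data.frame(
        source = slab, powerDensity = chk$density,
        reason = sprintf("power density %.3g mW/mm^2 exceeds MPE %g",
                         chk$density, mpe))
      next
    }
    model <- .withSource(model0, src)
    surf <- snrSurface(model, n = surfaceN)
    surfaces[[slab]] <- surf
    for (spec in detectors) {
      ev <- .evalDetector(model, surf, spec)
      if (is.null(ev)) next
      rows[[length(rows) + 1L]] <- data.frame(
        source = slab, detector = ev$label, snr = ev$res@snr,
        signal = ev$res@signal, noise = ev$res@noise,
        lod = lodFromSNR(ev$res@snr,
                         referenceThickness = fbr@collagenThickness,
                         criterion = criterion),
        detectorAreaTotal = ev$area, powerDensity = chk$density)
    }
  }
  ranked <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), detector = character(),
               snr = numeric(), signal = numeric(), noise = numeric(),
               lod = numeric(), detectorAreaTotal = numeric(),
               powerDensity = numeric())
  ord <- order(-ranked$snr, ranked$detectorAreaTotal, ranked$source,
               ranked$detector)
  ranked <- ranked[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  out <- list(ranked = ranked,
              infeasible = if (length(bad)) do.call(rbind, bad) else
                data.frame(source = character(), powerDensity = numeric(),
                           reason = character()),
              surfaces = surfaces)
  if (!nrow(ranked)) out$message <- "no feasible configuration"
  class(out) <- "drsOptimization"
  out
}
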