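#' Normalize a spectrum to the polystyrene 1004 cm^-1 band
#'
#' Affine min-max transform anchored on the polystyrene ring-breathing band:
#' the minimum over the normalization window maps to 0 and the maximum to 1,
#' and the same affine map is applied to the whole spectrum. This removes
#' per-acquisition gain and offset (normalization is invariant to
#' \code{c * S + d}, c > 0) and makes the implant's own bands cancel in
#' difference spectra.
#'
#' @param spectrum a [RamanSpectrum-class].
#' @param window normalization window (cm^-1) around the 1004 cm^-1 band.
#' @return The normalized [RamanSpectrum-class].
#' @export
normalizeToPolystyrene <- function(spectrum, window = c(990, 1020)) {
  w <- wavenumber(spectrum); v <- counts(spectrum)
  inWin <- w >= window[1] & w <= window[2]
  if (!any(inWin)) stop("normalization window outside the spectrum axis")
  lo <- min(v[inWin]); hi <- max(v[inWin])
  if (hi <= lo) stop("flat normalization window: cannot normalize")
  md <- spectrum@metadata
  md$normalization <- list(window = window, min = lo, max = hi)
  RamanSpectrum(w, (v - lo) / (hi - lo), metadata = md)
}

#' Difference spectrum: FBR minus initial conditions
#'
#' Channel-wise subtraction of the normalized initial-conditions spectrum
#' from the normalized FBR spectrum. Axes must match exactly (no
#' resampling); the metadata records the pair.
#'
#' @param fbr,initial normalized [RamanSpectrum-class] objects on the same
#'   axis.
#' @return A [RamanSpectrum-class] difference spectrum (may be negative).
#' @export
differenceSpectrum <- function(fbr, initial) {
  if (length(wavenumber(fbr)) != length(wavenumber(initial)) ||
      any(wavenumber(fbr) != wavenumber(initial)))
    stop("axes do not match; no resampling is performed")
  RamanSpectrum(wavenumber(fbr), counts(fbr) - counts(initial),
                metadata = list(
                  pair = list(fbr = fbr@metadata$label,
                              initial = initial@metadata$label)))
}

#' Collagen band area of a difference spectrum
#'
#' Baseline-subtracted area of the 910-950 cm^-1 band (the
#' [bandIntensities()] contract), the single-band collagen measure used for
#' the band-area regression.
#'
#' @param diff a difference [RamanSpectrum-class].
#' @param band band edges (cm^-1).
#' @param edgeChannels baseline anchor window width (channels).
#' @return Numeric band area (normalized units).
#' @export
collagenBandArea <- function(diff, band = c(910, 950), edgeChannels = 3) {
  bandIntensities(diff, band, edgeChannels)$iRaman
}

#' Normalized difference spectra of a thickness series
#'
#' Applies the experimental preprocessing chain to a generated thickness
#' series: each spectrum is normalized to the polystyrene band, and each
#' FBR spectrum has its paired initial-conditions spectrum subtracted.
#'
#' @param se a thickness series from [makeThicknessSeries()].
#' @param window polystyrene normalization window (cm^-1).
#' @param normalize apply the polystyrene normalization (TRUE, the
#'   experimental chain) or difference the raw counts.
#' @return list: \code{X} (spectra x channels matrix of difference spectra),
#'   \code{thickness}, \code{wavenumber}.
#' @export
differenceSet <- function(se, window = c(990, 1020), normalize = TRUE) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  w <- SummarizedExperiment::rowData(se)$wavenumber
  m <- SummarizedExperiment::assay(se, "counts")
  fbrIdx <- which(cd$role == "fbr")
  X <- matrix(0, length(fbrIdx), length(w))
  thick <- numeric(length(fbrIdx))
  for (q in seq_along(fbrIdx)) {
    i <- fbrIdx[q]
    j <- which(cd$role == "initial" & cd$thickness == cd$thickness[i] &
                 cd$replicate == cd$replicate[i])
    if (length(j) != 1) stop("unpaired FBR spectrum in series")
    fbr <- RamanSpectrum(w, m[, i]); ic <- RamanSpectrum(w, m[, j])
    if (normalize) {
      fbr <- normalizeToPolystyrene(fbr, window)
      ic <- normalizeToPolystyrene(ic, window)
    }
    X[q, ] <- counts(differenceSpectrum(fbr, ic))
    thick[q] <- cd$thickness[i]
  }
  colnames(X) <- paste0("wn", w)
  list(X = X, thickness = thick, wavenumber = w)
}

#' Fit a PLS calibration of collagen thickness
#'
#' Partial least squares regression from full difference spectra to
#' thickness. The component count is chosen by minimum leave-one-out
#' cross-validation RMSE up to a cap (ties broken towards fewer
#' components); the LOO RMSE at the chosen count is the calibration's
#' limit-of-detection surrogate.
#'
#' @param X spectra x channels matrix of difference spectra (or the list
#'   returned by [differenceSet()]).
#' @param thickness training thicknesses (micrometres).
#' @param ncompMax component cap (default 8; further capped by the training
#'   rank).
#' @return A [CalibrationModel-class].
#' @export
fitPLS <- function(X, thickness = NULL, ncompMax = 8) {
  if (is.list(X) && !is.null(X$X)) {
    thickness <- X$thickness
    wn <- X$wavenumber
    X <- X$X
  } else {
    wn <- as.numeric(sub("^wn", "", colnames(X)))
  }
  n <- nrow(X)
  if (n < 4) stop("need at least 4 training spectra")
  if (length(unique(thickness)) < 2)
    stop("degenerate response: thicknesses all equal")
  if (is.null(colnames(X))) colnames(X) <- paste0("ch", seq_len(ncol(X)))
  rank <- qr(scale(X, scale = FALSE))$rank
  ncompMax <- max(1L, min(ncompMax, rank, n - 2L))
  ## constant channels (e.g. the normalization anchor) trip harmless
  ## zero-sd warnings in the underlying correlation bookkeeping
  plsQuiet <- function(...) withCallingHandlers(
    mixOmics::pls(..., mode = "regression", scale = FALSE),
    warning = function(w) {
      if (grepl("standard deviation is zero", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  looPred <- matrix(NA_real_, n, ncompMax)
  for (i in seq_len(n)) {
    fit <- plsQuiet(X[-i, , drop = FALSE], thickness[-i], ncomp = ncompMax)
    pr <- predict(fit, X[i, , drop = FALSE])$predict
    looPred[i, ] <- pr[1, 1, ]
  }
  rmsePerComp <- sqrt(colMeans((looPred - thickness)^2))
  ncomp <- which.min(rmsePerComp) # which.min takes the first (fewest) tie
  fit <- plsQuiet(X, thickness, ncomp = ncomp)
  new("CalibrationModel", ncomp = as.integer(ncomp), fit = fit,
      wavenumber = wn, thickness = thickness,
      looRMSE = rmsePerComp[ncomp], looPredictions = looPred[, ncomp],
      preprocessing = "polystyrene 990-1020 min-max; FBR - initial")
}

#' Predict collagen thickness from difference spectra
#'
#' @param model a [CalibrationModel-class].
#' @param X spectra x channels matrix (or [differenceSet()] list) on the
#'   training axis.
#' @param truth optional true thicknesses; when given, the RMSE of the
#'   residuals is reported.
#' @return list with \code{predictions} (micrometres) and \code{rmse}
#'   (NA without truth).
#' @export
predictThickness <- function(model, X, truth = NULL) {
  if (is.list(X) && !is.null(X$X)) {
    if (is.null(truth)) truth <- X$thickness
    wn <- X$wavenumber
    X <- X$X
    if (length(wn) != length(model@wavenumber) ||
        any(wn != model@wavenumber))
      stop("axis does not match the training axis")
  }
  if (ncol(X) != length(model@wavenumber))
    stop("axis does not match the training axis")
  pred <- if (is.list(model@fit) && !is.null(model@fit$B)) {
    as.numeric(sweep(X, 2, model@fit$xMeans) %*% model@fit$B +
                 model@fit$yMean)
  } else {
    if (is.null(colnames(X))) colnames(X) <- colnames(model@fit$X)
    as.numeric(predict(model@fit, X)$predict[, 1, model@ncomp])
  }
  list(predictions = pred,
       rmse = if (is.null(truth)) NA_real_ else .rmse(pred, truth))
}

#' Band-area regression limit of detection
#'
#' Ordinary least squares of collagen band area against layer thickness.
#' The limit of detection is the thickness whose expected signal equals
#' \code{criterion} times the residual scatter:
#' \code{t_LOD = criterion * RMSE_residual / |slope|}. The variant with
#' criterion 1 (the residual RMSE expressed in thickness units) is reported
#' alongside, since published band-area LODs are sometimes quoted that way.
#'
#' @param area band areas (normalized units).
#' @param thickness layer thicknesses (micrometres).
#' @param criterion detection criterion (default 1.645).
#' @return A [RegressionLOD-class].
#' @export
fitRegressionLOD <- function(area, thickness, criterion = 1.645) {
  if (length(area) < 3) stop("need at least 3 (area, thickness) pairs")
  if (length(unique(thickness)) < 2)
    stop("no thickness spread: regression undefined")
  fit <- lm(area ~ thickness)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (slope == 0) stop("zero slope: LOD undefined")
  res <- area - (intercept + slope * thickness)
  rmse <- sqrt(mean(res^2))
  r2 <- 1 - sum(res^2) / sum((area - mean(area))^2)
  new("RegressionLOD", slope = slope, intercept = intercept, r2 = r2,
      rmse = rmse, criterion = criterion,
      lod = criterion * rmse / abs(slope),
      lodUnitCriterion = rmse / abs(slope))
}

#' Portable form of a PLS calibration
#'
#' Reduces the fitted PLS model to its equivalent linear map (coefficient
#' vector, column means, response mean), which predicts identically to the
#' fitted model at the selected component count and serializes to plain
#' text.
#'
#' @param model a [CalibrationModel-class].
#' @return The model with \code{fit} replaced by the linear map.
#' @export
portableCalibration <- function(model) {
  if (is.list(model@fit) && !is.null(model@fit$B)) return(model)
  X <- model@fit$X
  mx <- colMeans(X)
  my <- mean(model@thickness)
  basis <- diag(ncol(X))
  colnames(basis) <- colnames(X)
  p0 <- as.numeric(predict(model@fit,
                           matrix(mx, 1, dimnames = list(NULL, colnames(X))))
                   $predict[, 1, model@ncomp])
  pb <- predict(model@fit, sweep(basis, 2, mx, `+`))$predict[, 1, model@ncomp]
  model@fit <- list(B = as.numeric(pb) - p0, xMeans = mx, yMean = p0)
  model
}
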