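## Independent oracles used to freeze expected values. These deliberately
## re-derive quantities through different code paths than the package.

## extrapolated-boundary dipole solution for a point source buried at
## z0 = 1/musp in a homogeneous semi-infinite medium
dipoleFluence <- function(rho, z, mua, musp, nref = 1.4) {
  kap <- 1 / (3 * (mua + musp))
  mueff <- sqrt(mua / kap)
  reff <- -1.440 / nref^2 + 0.710 / nref + 0.668 + 0.0636 * nref
  afac <- (1 + reff) / (1 - reff)
  zb <- 2 * afac * kap
  z0 <- 1 / musp
  r1 <- sqrt(rho^2 + (z - z0)^2)
  r2 <- sqrt(rho^2 + (z + z0 + 2 * zb)^2)
  (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * kap)
}

## brute-force band integration: explicit loop, no vector tricks
bruteBandSums <- function(w, v, band = c(910, 950), edgeChannels = 3) {
  idx <- integer(0)
  for (i in seq_along(w)) if (w[i] >= band[1] && w[i] <= band[2])
    idx <- c(idx, i)
  anchorMean <- function(edge) {
    c0 <- 1
    for (i in seq_along(w)) if (abs(w[i] - edge) < abs(w[c0] - edge)) c0 <- i
    half <- (edgeChannels - 1) %/% 2
    win <- max(1, c0 - half):min(length(w), c0 + half)
    c(mean(w[win]), mean(v[win]))
  }
  a1 <- anchorMean(band[1]); a2 <- anchorMean(band[2])
  raw <- 0; raman <- 0
  for (i in idx) {
    base <- a1[2] + (a2[2] - a1[2]) * (w[i] - a1[1]) / (a2[1] - a1[1])
    raw <- raw + v[i]
    raman <- raman + v[i] - base
  }
  list(iRaman = raman, iRaw = raw)
}

## inverse standard-normal CDF by bisection on the numeric integral of the
## density (no qnorm)
qnormBisect <- function(p, tol = 1e-8) {
  cdf <- function(x)
    0.5 + stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi),
                           0, x)$value * sign(x) * ifelse(x == 0, 0, 1)
  lo <- -10; hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

## closed-form ordinary least squares
olsClosed <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  list(slope = slope, intercept = intercept,
       rmse = sqrt(mean(res^2)),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

## grid with all nodes labeled as a single material (homogeneous medium)
homogeneousGrid <- function(material = "skin", lateralExtent = 30,
                            spacing = 0.6) {
  ph <- buildPhantom(lateralExtent = lateralExtent)
  g <- buildPhantomGrid(ph, spacing = spacing)
  g@labels[] <- match(material, g@materials)
  g
}
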