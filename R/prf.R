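#' @include AllClasses.R stimulus.R
NULL

#' Double-gamma hemodynamic response function
#'
#' The HRF is a difference of two gamma densities parameterized by five
#' values: peak delay, undershoot delay, peak dispersion, undershoot
#' dispersion, and the peak:undershoot amplitude ratio. Gamma shapes are
#' delay / dispersion with scale = dispersion, so the positive lobe of the
#' canonical kernel (delays 6 and 16 s, unit dispersions, ratio 6) peaks
#' near 5 s. The sampled kernel is normalized to unit peak.
#'
#' @param params named list with `peakDelay`, `underDelay`, `peakDisp`,
#'   `underDisp`, `ratio` (all positive). Defaults are the canonical values.
#' @param dt sampling interval, s.
#' @param duration kernel length, s; must cover the undershoot.
#' @return Numeric vector of the kernel sampled at `0, dt, 2 dt, ...`.
#' @examples
#' h <- hrfDoubleGamma(dt = 1)
#' which.max(h)  # sample nearest the ~5 s peak
#' @export
hrfDoubleGamma <- function(params = list(peakDelay = 6, underDelay = 16,
                                         peakDisp = 1, underDisp = 1,
                                         ratio = 6),
                           dt = 1, duration = 32) {
  p <- params
  vals <- unlist(p[c("peakDelay", "underDelay", "peakDisp", "underDisp",
                     "ratio")])
  if (length(vals) != 5 || any(!is.finite(vals)) || any(vals <= 0))
    stop("HRF parameters must be five positive values")
  stopifnot(dt > 0, duration > dt)
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = p$peakDelay / p$peakDisp,
                     scale = p$peakDisp) -
       stats::dgamma(t, shape = p$underDelay / p$underDisp,
                     scale = p$underDisp) / p$ratio
  h / max(h)
}

## Causal convolution of each column of x (time x k) with kernel h,
## truncated to nrow(x) samples.
convolveHRF <- function(x, h) {
  x <- as.matrix(x)
  n <- nrow(x)
  out <- apply(x, 2, function(col)
    stats::convolve(col, rev(h), type = "open")[seq_len(n)])
  matrix(out, nrow = n)
}

## 2D-Gaussian pRF evaluated at pixel centres (unnormalized, peak 1).
gaussianField <- function(x, y, sigma, px, py) {
  exp(-((px - x)^2 + (py - y)^2) / (2 * sigma^2))
}

#' Predict the BOLD time course of a pRF
#'
#' The pRF is a circular 2D Gaussian with centre (x, y) and SD `sigma` (deg).
#' Each aperture frame is multiplied pointwise by the Gaussian and summed
#' over pixels (times pixel area); the resulting neural time course is
#' convolved with the HRF kernel and truncated to the frame count.
#'
#' @param prf numeric vector or list with `x`, `y`, `sigma` (deg; sigma > 0).
#' @param aperture a [StimulusAperture-class].
#' @param hrf HRF kernel sampled at the frame duration, e.g. from
#'   [hrfDoubleGamma()].
#' @return Numeric vector of length `nFrames(aperture)`.
#' @export
predictTimecourse <- function(prf, aperture, hrf) {
  prf <- as.list(prf)
  stopifnot(is.finite(prf$x), is.finite(prf$y), prf$sigma > 0)
  px <- pixelCoords(aperture@gridSize, aperture@radius)
  g <- gaussianField(prf$x, prf$y, prf$sigma, px$x, px$y)
  neural <- as.numeric(aperture@frames %*% g) * aperture@degPerPix^2
  as.numeric(convolveHRF(neural, hrf))
}

#' Convert pRF centre coordinates to polar angle and eccentricity
#'
#' Polar angle follows the package convention: 0 deg at the right horizontal
#' meridian, 90 at the upper vertical meridian, counter-clockwise, in
#' [0, 360). The origin maps to angle 0 by convention.
#'
#' @param x,y pRF centre coordinates in deg (vectors allowed).
#' @return List with `angle` (deg in [0, 360)) and `ecc` (deg, >= 0).
#' @examples
#' cartesianToPolar(0, 4.5)  # angle 90, ecc 4.5
#' @export
cartesianToPolar <- function(x, y) {
  ecc <- sqrt(x^2 + y^2)
  angle <- ifelse(ecc == 0, 0, wrapAngle(atan2(y, x) * 180 / pi))
  list(angle = angle, ecc = ecc)
}

#' Default coarse search grid for the pRF fit
#'
#' Log-spaced eccentricities crossed with equally spaced polar angles (plus
#' the origin), crossed with log-spaced sigma values.
#'
#' @param radius stimulus radius, deg.
#' @param nEcc,nAngles,nSigma grid resolution per dimension.
#' @param sigmaRange range of pRF sizes searched, deg.
#' @return data.frame with columns `x`, `y`, `sigma`.
#' @export
prfGridSpec <- function(radius = 12.4, nEcc = 8, nAngles = 16, nSigma = 4,
                        sigmaRange = c(0.25, 6)) {
  ecc <- exp(seq(log(0.5), log(radius * 0.9), length.out = nEcc))
  ang <- seq(0, 360 - 360 / nAngles, by = 360 / nAngles)
  centres <- expand.grid(ecc = ecc, ang = ang)
  xy <- data.frame(
    x = c(0, centres$ecc * cospi(centres$ang / 180)),
    y = c(0, centres$ecc * sinpi(centres$ang / 180))
  )
  sig <- exp(seq(log(sigmaRange[1]), log(sigmaRange[2]), length.out = nSigma))
  out <- merge(xy, data.frame(sigma = sig))
  out[, c("x", "y", "sigma")]
}

#' Fit pRFs to vertex time series by coarse-to-fine search
#'
#' Stage 1 evaluates every candidate on a coarse (x, y, sigma) grid, with the
#' response gain fitted per candidate by non-negative least squares on the
#' mean-removed series; ties break to the first-encountered minimum in the
#' fixed grid order. Stage 2 refines the best grid point by a bounded
#' derivative-free local search (Nelder-Mead on (x, y, log sigma), relative
#' tolerance 1e-10). R^2 is 1 - RSS/TSS against the mean-removed series and
#' is invariant to affine rescaling of the input. Vertices with R^2 > 10%
#' are flagged as included; flat (zero-variance) series are excluded with
#' R^2 = 0.
#'
#' @param series numeric matrix, time x vertices (or a vector for a single
#'   vertex), e.g. BOLD percent signal change.
#' @param aperture the [StimulusAperture-class] shown during the scan.
#' @param hrf HRF kernel at the frame duration (default canonical
#'   [hrfDoubleGamma()]).
#' @param gridSpec data.frame of coarse candidates from [prfGridSpec()].
#' @param refine logical; run the continuous stage 2 (default TRUE).
#' @return A [RetinotopyMap-class] with one entry per vertex.
#' @export
fitPRF <- function(series, aperture, hrf = hrfDoubleGamma(
                     dt = aperture@frameDuration),
                   gridSpec = prfGridSpec(aperture@radius),
                   refine = TRUE) {
  series <- as.matrix(series)
  if (nrow(series) != nFrames(aperture))
    stop("series length must equal the aperture frame count")
  nV <- ncol(series)

  ## restrict to pixels the stimulus can ever light (the disc)
  px <- pixelCoords(aperture@gridSize, aperture@radius)
  lit <- px$x^2 + px$y^2 <= aperture@radius^2
  B <- convolveHRF(aperture@frames[, lit, drop = FALSE], hrf) *
       aperture@degPerPix^2
  pxl <- px$x[lit]
  pyl <- px$y[lit]

  predictOf <- function(x, y, sigma)
    as.numeric(B %*% gaussianField(x, y, sigma, pxl, pyl))

  ## stage 1: all candidate predictions, demeaned and normalized
  G <- mapply(function(x, y, s) gaussianField(x, y, s, pxl, pyl),
              gridSpec$x, gridSpec$y, gridSpec$sigma)
  P <- B %*% G
  P <- sweep(P, 2, colMeans(P))
  pn <- sqrt(colSums(P^2))
  pn[pn == 0] <- Inf

  bs <- sweep(series, 2, colMeans(series))
  tss <- colSums(bs^2)
  dots <- crossprod(P, bs)                  # candidates x vertices
  r2grid <- pmax(dots, 0)^2 / (pn^2 %o% tss)
  best <- apply(r2grid, 2, which.max)

  x <- y <- sigma <- gain <- r2 <- numeric(nV)
  for (v in seq_len(nV)) {
    if (tss[v] <= 0 || !all(is.finite(bs[, v]))) {
      x[v] <- y[v] <- 0; sigma[v] <- 1; gain[v] <- 0; r2[v] <- 0
      next
    }
    b <- bs[, v]
    obj <- function(par) {
      p <- predictOf(par[1], par[2], exp(par[3]))
      p <- p - mean(p)
      pp <- sum(p^2)
      if (pp == 0) return(sum(b^2))
      g <- max(0, sum(p * b) / pp)
      sum((b - g * p)^2)
    }
    ord <- order(r2grid[, v], decreasing = TRUE)
    starts <- ord[1:2]  # two best coarse candidates guard against local minima
    par <- c(gridSpec$x[starts[1]], gridSpec$y[starts[1]],
             log(gridSpec$sigma[starts[1]]))
    if (refine) {
      bestVal <- Inf
      for (s in starts) {
        par0 <- c(gridSpec$x[s], gridSpec$y[s], log(gridSpec$sigma[s]))
        opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                            control = list(reltol = 1e-10, maxit = 500))
        opt <- stats::optim(opt$par, obj, method = "BFGS",
                            control = list(reltol = 1e-12, maxit = 100))
        if (opt$value < bestVal) {
          bestVal <- opt$value
          par <- opt$par
        }
      }
    }
    x[v] <- par[1]; y[v] <- par[2]; sigma[v] <- exp(par[3])
    p <- predictOf(x[v], y[v], sigma[v])
    p <- p - mean(p)
    pp <- sum(p^2)
    gain[v] <- if (pp > 0) max(0, sum(p * b) / pp) else 0
    rss <- sum((b - gain[v] * p)^2)
    r2[v] <- max(0, min(1, 1 - rss / tss[v]))
  }

  pol <- cartesianToPolar(x, y)
  new("RetinotopyMap",
      x = x, y = y, sigma = sigma, gain = gain, r2 = r2,
      polarAngle = pol$angle, eccentricity = pol$ecc,
      included = r2 > 0.10)
}

#' Build a RetinotopyMap from ground-truth mesh retinotopy
#'
#' Wraps a mesh's planted (polar angle, eccentricity) retinotopy as a
#' [RetinotopyMap-class] with perfect fits (R^2 = 1), for running the
#' wedge-ROI analysis against ground truth.
#'
#' @param mesh a [CorticalMesh-class].
#' @param sigma per-vertex pRF size to record (default from
#'   [sigmaFromEccentricity()]).
#' @return A [RetinotopyMap-class].
#' @export
groundTruthRetinotopy <- function(mesh,
                                  sigma = sigmaFromEccentricity(
                                    eccentricities(mesh))) {
  ang <- polarAngles(mesh)
  ecc <- eccentricities(mesh)
  n <- length(ang)
  new("RetinotopyMap",
      x = ecc * cospi(ang / 180), y = ecc * sinpi(ang / 180),
      sigma = rep_len(sigma, n), gain = rep(1, n), r2 = rep(1, n),
      polarAngle = ang, eccentricity = ecc, included = rep(TRUE, n))
}

#' Typical V1 pRF size as a function of eccentricity
#'
#' A linear size-eccentricity rule, sigma = intercept + slope * ecc, with
#' defaults in the range reported for human V1.
#'
#' @param ecc eccentricity, deg.
#' @param intercept,slope linear coefficients (deg, unitless).
#' @return pRF sigma in deg.
#' @export
sigmaFromEccentricity <- function(ecc, intercept = 0.5, slope = 0.1) {
  intercept + slope * ecc
}
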