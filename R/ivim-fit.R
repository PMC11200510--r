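## Voxel-wise IVIM estimation: segmented initialization + bounded
## Levenberg-Marquardt (compiled in src/ivim_fit.cpp), and ADC mapping with
## mask-restricted Gaussian smoothing as the continuity correction.

.STATUS_LEVELS <- c("converged", "max-iter", "degenerate-input", "failed",
                    "not-fitted")

## Segmented initialization for a matrix of curves (rows = voxels).
## Returns list(init = n x 4 matrix (s0, f, d, dstar), s0Hi = vector).
segmentedInit <- function(curves, bvalues, config) {
  bd <- config@bounds
  hi <- bvalues >= config@highBThreshold
  n <- nrow(curves)
  m0 <- curves[, 1]

  x <- bvalues[hi]
  yRaw <- curves[, hi, drop = FALSE]
  w <- yRaw > 0
  y <- log(ifelse(w, yRaw, 1))          # masked entries contribute 0 via w
  nW <- rowSums(w)
  Sx <- as.numeric(w %*% x)
  Sxx <- as.numeric(w %*% x^2)
  Sy <- rowSums(y * w)
  Sxy <- as.numeric(rowSums(sweep(y * w, 2, x, `*`)))
  den <- nW * Sxx - Sx^2
  slope <- ifelse(nW >= 2 & den > 0, (nW * Sxy - Sx * Sy) / den, NA_real_)
  intercept <- ifelse(nW >= 2, (Sy - slope * Sx) / nW, NA_real_)

  dInit <- pmin(pmax(-slope, bd$d[1]), bd$d[2])
  dInit[is.na(dInit)] <- 1e-3
  fInit <- 1 - exp(intercept) / ifelse(m0 > 0, m0, NA_real_)
  fInit <- pmin(pmax(fInit, bd$f[1]), bd$f[2])
  fInit[is.na(fInit)] <- 0.1
  dstarInit <- pmin(pmax(config@dstarInitMultiplier * dInit, dInit), bd$dstar[2])
  s0Init <- ifelse(m0 > 0, m0, apply(curves, 1, max))
  s0Hi <- bd$s0Factor * pmax(s0Init, 1e-12)
  list(init = cbind(s0Init, fInit, dInit, dstarInit), s0Hi = s0Hi)
}

## Fit a matrix of curves; returns the raw n x 7 result matrix.
## Two deterministic starts per curve guard against the local minimum on the
## mirror branch of the model (dominant weight on the fast rate): the
## segmented start, and a high-f start with D at its lower bound and D* at
## the mono-exponential rate. The better SSR wins; ties keep the segmented
## start.
fitCurvesMatrix <- function(curves, bvalues, config) {
  keep <- bvalues <= config@maxB
  if (sum(keep) < 4L) stop("maxB leaves fewer than 4 b-values for fitting")
  bFit <- bvalues[keep]
  cFit <- curves[, keep, drop = FALSE]
  ini <- segmentedInit(cFit, bFit, config)
  bd <- config@bounds
  run <- function(init) cpp_fit_ivim(cFit, bFit, init, ini$s0Hi,
                                     bd$f[1], bd$f[2], bd$d[1], bd$d[2],
                                     bd$dstar[1], bd$dstar[2],
                                     config@maxIterations, config@costTolerance)
  res1 <- run(ini$init)
  altInit <- cbind(ini$init[, 1], pmin(0.95, bd$f[2]), bd$d[1],
                   pmax(ini$init[, 3], bd$d[1] * 2))
  res2 <- run(altInit)
  better <- !is.na(res2[, 5]) & !is.na(res1[, 5]) &
    res2[, 5] < res1[, 5] - pmax(1e-12, 1e-9 * res1[, 5])
  res1[better, ] <- res2[better, ]
  res1
}

#' Fit the IVIM model to one decay curve
#'
#' Bounded nonlinear least squares on (S0, f, D, D*) by Levenberg-Marquardt,
#' initialized with the segmented scheme: D and the log-intercept come from a
#' mono-exponential fit over `b >= highBThreshold`, the perfusion fraction
#' from `1 - exp(intercept) / S(0)`, D* at `dstarInitMultiplier` times the D
#' estimate, and S0 at the measured `S(0)`. Only SSR-decreasing steps are
#' accepted, so the returned SSR never exceeds the SSR at initialization.
#' The constraint D <= D* is enforced structurally (D* is fitted as D plus a
#' non-negative increment), which also breaks the (f, D) vs (1-f, D*) label
#' symmetry of the model.
#'
#' @param curve A [SignalCurve-class] (must include b = 0).
#' @param config A [FitConfig-class]; see [fitConfig()] for the defaults.
#' @return A [FitResult-class].
#' @examples
#' truth <- ivimParams(1000, 0.15, 0.9e-3, 12e-3)
#' cur <- signalCurve(defaultBValues(), ivimSignal(truth, defaultBValues()))
#' fitIvimCurve(cur)
#' @export
fitIvimCurve <- function(curve, config = fitConfig()) {
  stopifnot(is(curve, "SignalCurve"), is(config, "FitConfig"))
  validObject(curve)
  degenerate <- function() new("FitResult", params = ivimParams(1, 0, 1e-3, 1e-3),
                               ssr = NA_real_, nIterations = 0L,
                               status = "degenerate-input")
  if (sum(curve@bvalues <= config@maxB) < 4L)
    stop("maxB leaves fewer than 4 b-values for fitting")
  if (max(curve@intensities) <= 0) return(degenerate())
  res <- tryCatch(
    fitCurvesMatrix(matrix(curve@intensities, nrow = 1), curve@bvalues, config),
    error = function(e) NULL)
  if (is.null(res))
    return(new("FitResult", params = ivimParams(1, 0, 1e-3, 1e-3),
               ssr = NA_real_, nIterations = 0L, status = "failed"))
  if (res[1, 7] == 2) return(degenerate())
  new("FitResult",
      params = ivimParams(res[1, 1], min(max(res[1, 2], 0), 1), res[1, 3],
                          max(res[1, 4], res[1, 3])),
      ssr = res[1, 5], nIterations = as.integer(res[1, 6]),
      status = if (res[1, 7] == 0) "converged" else "max-iter")
}

#' Fit the IVIM model voxel-wise over a masked volume
#'
#' Fits every in-mask voxel's decay curve (see [fitIvimCurve()]) and computes
#' an ADC map at `adcB`, then applies the continuity correction: in-plane
#' Gaussian smoothing of the ADC map with kernel weights renormalized within
#' the mask, so a constant field passes through unchanged and no out-of-mask
#' values bleed in. Voxels outside the mask carry `NA` and status
#' `"not-fitted"`; voxels with degenerate signal are flagged, never fatal.
#'
#' @param dwi A [DWIVolume-class].
#' @param mask Logical 3D array on the volume's spatial grid.
#' @param config A [FitConfig-class].
#' @param adcB b-value (present in the series) at which ADC is computed;
#'   defaults to the largest acquired b.
#' @param smoothSigma In-plane Gaussian sigma for the ADC continuity
#'   correction, in voxels; 0 disables smoothing.
#' @return A [ParameterMaps-class].
#' @export
fitIvimVolume <- function(dwi, mask, config = fitConfig(),
                          adcB = max(bValues(dwi)), smoothSigma = 1) {
  stopifnot(is(dwi, "DWIVolume"))
  validObject(dwi)
  d4 <- dim(dwi@intensities)
  if (!identical(dim(mask), d4[1:3]))
    stop("mask shape does not match the volume's spatial grid")
  mask <- array(as.logical(mask), dim = d4[1:3])
  idx <- which(mask)
  shape <- d4[1:3]
  blank <- array(NA_real_, dim = shape)
  status <- array("not-fitted", dim = shape)
  if (length(idx) == 0L) {
    warning("empty mask: returning empty parameter maps")
    return(parameterMaps(blank, blank, blank, blank, blank, status))
  }

  nb <- d4[4]
  flat <- matrix(dwi@intensities, ncol = nb)   # voxel-major, b in columns
  curves <- flat[idx, , drop = FALSE]
  res <- fitCurvesMatrix(curves, dwi@bvalues, config)

  s0 <- f <- dmap <- dstar <- adc <- blank
  s0[idx] <- res[, 1]; f[idx] <- res[, 2]
  dmap[idx] <- res[, 3]; dstar[idx] <- res[, 4]
  status[idx] <- .STATUS_LEVELS[res[, 7] + 1]

  bIdx <- match(adcB, dwi@bvalues)
  if (is.na(bIdx) || adcB <= 0)
    stop(sprintf("adcB = %g is not a positive b-value of the series", adcB))
  m0 <- curves[, 1]
  sb <- pmax(curves[, bIdx], 1e-6 * m0)
  adcVox <- ifelse(m0 > 0, -log(sb / m0) / adcB, NA_real_)
  adc[idx] <- adcVox
  if (smoothSigma > 0) adc <- smoothAdcInPlane(adc, mask, smoothSigma)

  parameterMaps(s0, f, dmap, dstar, adc, status)
}

## In-plane (per-slice) Gaussian smoothing restricted to a mask: weights are
## renormalized over in-mask voxels so constants are preserved.
smoothAdcInPlane <- function(adc, mask, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  off <- -r:r
  k1 <- exp(-off^2 / (2 * sigma^2))
  kern <- outer(k1, k1)
  out <- adc
  for (z in seq_len(dim(adc)[3])) {
    sl <- adc[, , z]
    ms <- mask[, , z]
    if (!any(ms)) next
    vals <- ifelse(ms & is.finite(sl), sl, 0)
    wts <- ifelse(ms & is.finite(sl), 1, 0)
    num <- matrix(0, nrow(sl), ncol(sl))
    den <- num
    for (i in seq_along(off)) {
      for (j in seq_along(off)) {
        w <- kern[i, j]
        num <- num + w * shiftMatrix(vals, off[i], off[j])
        den <- den + w * shiftMatrix(wts, off[i], off[j])
      }
    }
    sm <- ifelse(ms & den > 0, num / den, NA_real_)
    out[, , z] <- ifelse(ms, sm, sl)
  }
  out
}

## Shift a matrix by (dx, dy) with zero padding.
shiftMatrix <- function(m, dx, dy) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0, n1, n2)
  xs <- seq_len(n1) - dx
  ys <- seq_len(n2) - dy
  okx <- xs >= 1 & xs <= n1
  oky <- ys >= 1 & ys <= n2
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}
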