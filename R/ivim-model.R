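## The bi-exponential IVIM forward model and its least-squares objective.

#' Evaluate the bi-exponential IVIM signal model
#'
#' The measured DWI signal is modelled as a weighted sum of two exponential
#' decays, `S(b) = S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D))`:
#' a fast pseudo-diffusion (perfusion) compartment with weight `f` and a
#' molecular-diffusion compartment with weight `1 - f`. At `b = 0` the weights
#' sum to one and the model returns `S0` exactly.
#'
#' @param params An [IVIMParams-class] object, or a numeric vector
#'   `c(s0, f, d, dstar)`.
#' @param b Non-negative b-value(s), s/mm^2 (vectorized).
#' @return Predicted signal intensities, strictly positive.
#' @examples
#' ivimSignal(ivimParams(1000, 0.1, 1e-3, 10e-3), c(0, 500))
#' @export
ivimSignal <- function(params, b) {
  p <- asIvimVector(params)
  if (any(!is.finite(b)) || any(b < 0)) stop("b must be finite and >= 0")
  p[1] * (p[2] * exp(-b * p[4]) + (1 - p[2]) * exp(-b * p[3]))
}

asIvimVector <- function(params) {
  if (is(params, "IVIMParams")) {
    validObject(params)
    return(c(params@s0, params@f, params@d, params@dstar))
  }
  if (is.numeric(params) && length(params) == 4L) {
    validObject(ivimParams(params[1], params[2], params[3], params[4]))
    return(as.numeric(params))
  }
  stop("params must be an IVIMParams object or a numeric vector of length 4")
}

#' Residuals and sum of squared residuals of an IVIM fit
#'
#' Residuals are `measured - predicted` at each b-value; the fitting objective
#' is their sum of squares (SSR).
#'
#' @param curve A [SignalCurve-class].
#' @param params IVIM parameters (see [ivimSignal()]).
#' @return `ivimResiduals`: numeric vector of per-b residuals.
#' @examples
#' cur <- signalCurve(defaultBValues(),
#'                    ivimSignal(ivimParams(1000, 0.1, 1e-3, 10e-3),
#'                               defaultBValues()))
#' ivimSSR(cur, ivimParams(1000, 0.1, 1e-3, 10e-3))  # 0
#' @export
ivimResiduals <- function(curve, params) {
  stopifnot(is(curve, "SignalCurve"))
  validObject(curve)
  curve@intensities - ivimSignal(params, curve@bvalues)
}

#' @rdname ivimResiduals
#' @return `ivimSSR`: the scalar sum of squared residuals.
#' @export
ivimSSR <- function(curve, params) {
  sum(ivimResiduals(curve, params)^2)
}

#' Mono-exponential log-linear fit over high b-values
#'
#' Ordinary least squares of `log(intensity)` on `b` restricted to
#' `b >= bMin`, the first stage of segmented IVIM initialization: at high b
#' the perfusion compartment has decayed away and the slope estimates `-D`.
#' Non-positive intensities cannot enter the logarithm and are excluded.
#'
#' @param curve A [SignalCurve-class].
#' @param bMin Lower b cutoff, s/mm^2.
#' @return A list with `d` (the `-slope` estimate of D), `logIntercept`,
#'   `nExcluded` (non-positive intensities dropped) and `status`
#'   (`"ok"` or `"degenerate-input"` when fewer than 2 usable points remain).
#' @export
monoExpFit <- function(curve, bMin = 200) {
  stopifnot(is(curve, "SignalCurve"))
  validObject(curve)
  sel <- curve@bvalues >= bMin
  pos <- curve@intensities > 0
  nExcluded <- sum(sel & !pos)
  if (nExcluded > 0)
    warning(sprintf("%d non-positive intensities excluded from log-linear fit",
                    nExcluded))
  use <- sel & pos
  if (sum(use) < 2L)
    return(list(d = NA_real_, logIntercept = NA_real_,
                nExcluded = nExcluded, status = "degenerate-input"))
  x <- curve@bvalues[use]
  y <- log(curve@intensities[use])
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  list(d = -slope, logIntercept = mean(y) - slope * mean(x),
       nExcluded = nExcluded, status = "ok")
}

#' Apparent diffusion coefficient from a decay curve
#'
#' Conventional mono-exponential ADC, `-log(S(b)/S(0)) / b`, evaluated at one
#' target b-value. As part of the continuity correction, the signal is floored
#' at `1e-6 * S(0)` before the logarithm so that noise-suppressed voxels yield
#' a finite value.
#'
#' @param curve A [SignalCurve-class] whose series contains `bTarget`.
#' @param bTarget Positive b-value present in the curve, s/mm^2.
#' @return The ADC in mm^2/s, or `NA` with attribute `status =
#'   "degenerate-input"` when `S(0) = 0`.
#' @examples
#' adcFromCurve(signalCurve(c(0, 100, 500, 1000), c(1000, 933, 717, 500)), 1000)
#' @export
adcFromCurve <- function(curve, bTarget) {
  stopifnot(is(curve, "SignalCurve"))
  validObject(curve)
  if (bTarget <= 0) stop("bTarget must be > 0")
  idx <- match(bTarget, curve@bvalues)
  if (is.na(idx)) stop(sprintf("bTarget %g not present in the curve", bTarget))
  s0 <- curve@intensities[1]
  if (s0 <= 0) {
    out <- NA_real_
    attr(out, "status") <- "degenerate-input"
    return(out)
  }
  sb <- max(curve@intensities[idx], 1e-6 * s0)
  -log(sb / s0) / bTarget
}
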