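#' @import methods
#' @importFrom stats quantile rnorm runif sd setNames median predict coef optim prcomp
#' @importFrom utils read.csv write.csv head
#' @useDynLib ivimcad, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---- b-value series ---------------------------------------------------------

#' Validate a diffusion b-value series
#'
#' A valid series is non-negative, strictly increasing, starts at b = 0 (the
#' unweighted reference image must exist) and has at least four entries, the
#' minimum for four-parameter IVIM identifiability.
#'
#' @param bvalues Numeric vector of diffusion weightings in s/mm^2.
#' @return The validated vector, invisibly usable downstream.
#' @examples
#' checkBValues(c(0, 100, 200, 700))
#' @export
checkBValues <- function(bvalues) {
  if (!is.numeric(bvalues) || length(bvalues) < 4L)
    stop("b-value series must be numeric with at least 4 entries")
  if (anyNA(bvalues) || any(!is.finite(bvalues)))
    stop("b-value series must be finite")
  if (any(bvalues < 0))
    stop("b-values must be >= 0")
  if (bvalues[1] != 0)
    stop("first b-value must be 0 (reference S(0) must exist)")
  if (any(diff(bvalues) <= 0))
    stop("b-values must be strictly increasing")
  invisible(as.numeric(bvalues))
}

#' The default 9-point acquisition b-value grid
#'
#' @return Numeric vector `c(0, 100, ..., 700, 1400)` s/mm^2.
#' @export
defaultBValues <- function() c(0, 100, 200, 300, 400, 500, 600, 700, 1400)

## ---- IVIMParams -------------------------------------------------------------

#' IVIM parameter quadruple
#'
#' Holds (S0, f, D, D*) for one voxel or one tissue class. Invariants:
#' S0 > 0, 0 <= f <= 1, 0 < D <= D*.
#'
#' @slot s0 Baseline signal at b = 0 (arbitrary units).
#' @slot f Perfusion fraction (dimensionless).
#' @slot d Diffusion coefficient (mm^2/s).
#' @slot dstar Pseudo-diffusion coefficient (mm^2/s).
#' @export
setClass("IVIMParams",
  representation(s0 = "numeric", f = "numeric", d = "numeric", dstar = "numeric"),
  validity = function(object) {
    v <- c(object@s0, object@f, object@d, object@dstar)
    if (length(v) != 4L || any(!is.finite(v)))
      return("S0, f, D, D* must each be a single finite number")
    if (object@s0 <= 0) return("S0 must be > 0")
    if (object@f < 0 || object@f > 1) return("f must lie in [0, 1]")
    if (object@d <= 0) return("D must be > 0")
    if (object@dstar < object@d) return("D* must be >= D")
    TRUE
  })

#' Construct an [IVIMParams-class] object
#'
#' @param s0,f,d,dstar The four IVIM parameters.
#' @return An `IVIMParams` object.
#' @examples
#' ivimParams(1000, 0.15, 0.9e-3, 12e-3)
#' @export
ivimParams <- function(s0, f, d, dstar) {
  new("IVIMParams", s0 = as.numeric(s0), f = as.numeric(f),
      d = as.numeric(d), dstar = as.numeric(dstar))
}

setMethod("show", "IVIMParams", function(object) {
  cat(sprintf("IVIMParams: S0 = %.4g, f = %.4g, D = %.4g mm^2/s, D* = %.4g mm^2/s\n",
              object@s0, object@f, object@d, object@dstar))
})

## ---- SignalCurve ------------------------------------------------------------

#' A measured diffusion signal decay curve
#'
#' @slot bvalues Numeric b-value series (see [checkBValues()]).
#' @slot intensities Measured signal per b-value, finite and >= 0.
#' @export
setClass("SignalCurve",
  representation(bvalues = "numeric", intensities = "numeric"),
  validity = function(object) {
    ok <- tryCatch({ checkBValues(object@bvalues); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(ok)
    if (length(object@intensities) != length(object@bvalues))
      return(sprintf("length mismatch: %d intensities vs %d b-values",
                     length(object@intensities), length(object@bvalues)))
    if (any(!is.finite(object@intensities)) || any(object@intensities < 0))
      return("intensities must be finite and >= 0")
    TRUE
  })

#' Construct a [SignalCurve-class]
#' @param bvalues b-value series, s/mm^2.
#' @param intensities Signal intensities, same length.
#' @return A `SignalCurve`.
#' @export
signalCurve <- function(bvalues, intensities) {
  new("SignalCurve", bvalues = as.numeric(bvalues),
      intensities = as.numeric(intensities))
}

setMethod("show", "SignalCurve", function(object) {
  cat(sprintf("SignalCurve over %d b-values (%g..%g s/mm^2)\n",
              length(object@bvalues), min(object@bvalues), max(object@bvalues)))
})

## ---- DWIVolume --------------------------------------------------------------

#' 4D diffusion-weighted volume
#'
#' Intensities are indexed (x, y, z, b-index); the 4th dimension length must
#' equal the b-value series length.
#'
#' @slot intensities 4D non-negative numeric array.
#' @slot spacing Voxel spacing per spatial axis, mm.
#' @slot bvalues b-value series, s/mm^2.
#' @export
setClass("DWIVolume",
  representation(intensities = "array", spacing = "numeric", bvalues = "numeric"),
  validity = function(object) {
    d <- dim(object@intensities)
    if (length(d) != 4L) return("intensities must be a 4D array (x, y, z, b)")
    ok <- tryCatch({ checkBValues(object@bvalues); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(ok)
    if (d[4] != length(object@bvalues))
      return(sprintf("4th dimension (%d) must match b-value count (%d)",
                     d[4], length(object@bvalues)))
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    if (any(!is.finite(object@intensities)))
      return("intensities must be finite")
    if (min(object@intensities) < 0) return("intensities must be >= 0")
    TRUE
  })

#' Construct a [DWIVolume-class]
#' @param intensities 4D array (x, y, z, b-index), non-negative.
#' @param bvalues b-value series matching the 4th dimension.
#' @param spacing Voxel spacing (mm), length 3.
#' @return A `DWIVolume`.
#' @export
dwiVolume <- function(intensities, bvalues, spacing = c(3, 3, 3.5)) {
  new("DWIVolume", intensities = intensities, spacing = as.numeric(spacing),
      bvalues = as.numeric(bvalues))
}

#' @describeIn DWIVolume-class b-value series accessor
#' @param x A `DWIVolume`.
#' @export
bValues <- function(x) x@bvalues

#' @describeIn DWIVolume-class intensity array accessor
#' @export
dwiData <- function(x) x@intensities

#' @describeIn DWIVolume-class voxel spacing accessor
#' @export
voxelSpacing <- function(x) x@spacing

#' Extract one voxel's decay curve from a volume
#' @param dwi A [DWIVolume-class].
#' @param i,j,k Voxel indices (1-based).
#' @return A [SignalCurve-class].
#' @export
voxelCurve <- function(dwi, i, j, k) {
  signalCurve(dwi@bvalues, dwi@intensities[i, j, k, ])
}

setMethod("show", "DWIVolume", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("DWIVolume %dx%dx%d voxels, %d b-values (%s s/mm^2)\n",
              d[1], d[2], d[3], d[4],
              paste(object@bvalues, collapse = ", ")))
})

## ---- ZoneMaskSet ------------------------------------------------------------

#' Binary anatomical masks on one spatial grid
#'
#' Prostate, central-zone (CZ), peripheral-zone (PZ) and lesion masks.
#' CZ and PZ must be disjoint and contained in the prostate mask.
#'
#' @slot prostate,cz,pz,lesion Logical 3D arrays, one shape.
#' @export
setClass("ZoneMaskSet",
  representation(prostate = "array", cz = "array", pz = "array", lesion = "array"),
  validity = function(object) {
    ms <- list(object@prostate, object@cz, object@pz, object@lesion)
    dims <- lapply(ms, dim)
    if (any(vapply(dims, length, 1L) != 3L)) return("masks must be 3D arrays")
    if (!all(vapply(dims, identical, TRUE, dims[[1]])))
      return("all masks must share one shape")
    if (!all(vapply(ms, is.logical, TRUE))) return("masks must be logical")
    nOverlap <- sum(object@cz & object@pz)
    if (nOverlap > 0)
      return(sprintf("CZ and PZ masks overlap in %d voxel(s)", nOverlap))
    nOutside <- sum((object@cz | object@pz) & !object@prostate)
    if (nOutside > 0)
      return(sprintf("%d zone voxel(s) fall outside the prostate mask", nOutside))
    TRUE
  })

#' Construct a [ZoneMaskSet-class]
#' @param prostate,cz,pz,lesion Logical (or 0/1 numeric) 3D arrays.
#' @return A `ZoneMaskSet`.
#' @export
zoneMaskSet <- function(prostate, cz, pz, lesion = NULL) {
  asMask <- function(m) {
    if (is.logical(m)) return(m)
    array(m > 0.5, dim = dim(m))
  }
  prostate <- asMask(prostate)
  if (is.null(lesion)) lesion <- array(FALSE, dim = dim(prostate))
  new("ZoneMaskSet", prostate = prostate, cz = asMask(cz),
      pz = asMask(pz), lesion = asMask(lesion))
}

setMethod("show", "ZoneMaskSet", function(object) {
  cat(sprintf("ZoneMaskSet %s: prostate %d, CZ %d, PZ %d, lesion %d voxels\n",
              paste(dim(object@prostate), collapse = "x"),
              sum(object@prostate), sum(object@cz), sum(object@pz),
              sum(object@lesion)))
})

## ---- FitConfig / FitResult --------------------------------------------------

#' Configuration of the IVIM curve fit
#'
#' @slot highBThreshold High-b cutoff (s/mm^2) for the segmented log-linear
#'   initialization of D.
#' @slot maxB b-values above this are excluded from fitting (Inf keeps all).
#' @slot maxIterations Levenberg-Marquardt iteration cap.
#' @slot costTolerance Relative SSR change declaring convergence.
#' @slot dstarInitMultiplier D* initial value as a multiple of the D estimate.
#' @slot bounds Named list with `f`, `d`, `dstar` two-element (lo, hi) vectors
#'   and `s0Factor`, the S0 upper bound as a multiple of the measured S(0).
#' @export
setClass("FitConfig",
  representation(highBThreshold = "numeric", maxB = "numeric",
                 maxIterations = "integer", costTolerance = "numeric",
                 dstarInitMultiplier = "numeric", bounds = "list"),
  validity = function(object) {
    if (object@maxIterations < 1L) return("maxIterations must be >= 1")
    if (object@costTolerance <= 0) return("costTolerance must be > 0")
    b <- object@bounds
    need <- c("f", "d", "dstar", "s0Factor")
    if (!all(need %in% names(b))) return("bounds must name f, d, dstar, s0Factor")
    if (b$f[1] < 0 || b$f[2] > 1) return("f bounds must lie in [0, 1]")
    if (b$d[1] <= 0) return("D lower bound must be > 0")
    if (b$dstar[2] < b$d[1]) return("D* upper bound below D lower bound")
    TRUE
  })

#' Construct a [FitConfig-class]
#'
#' Defaults: segmented initialization above 200 s/mm^2, D* initialized at
#' 10x the mono-exponential D estimate, bounds f in \[0, 1\],
#' D in \[1e-5, 5e-3\], D* in \[D, 0.5\] mm^2/s, S0 capped at 10x the
#' measured S(0), at most 500 iterations, relative SSR tolerance 1e-10.
#'
#' @param highBThreshold,maxB,maxIterations,costTolerance,dstarInitMultiplier,bounds
#'   See [FitConfig-class]; any may be overridden.
#' @return A `FitConfig`.
#' @export
fitConfig <- function(highBThreshold = 200, maxB = Inf, maxIterations = 500L,
                      costTolerance = 1e-10, dstarInitMultiplier = 10,
                      bounds = list()) {
  def <- list(f = c(0, 1), d = c(1e-5, 5e-3), dstar = c(1e-5, 0.5),
              s0Factor = 10)
  for (nm in names(bounds)) def[[nm]] <- bounds[[nm]]
  new("FitConfig", highBThreshold = highBThreshold, maxB = maxB,
      maxIterations = as.integer(maxIterations), costTolerance = costTolerance,
      dstarInitMultiplier = dstarInitMultiplier, bounds = def)
}

#' Result of one IVIM curve fit
#'
#' @slot params Fitted [IVIMParams-class] (may be a degenerate placeholder when
#'   status is not `"converged"` or `"max-iter"`).
#' @slot ssr Sum of squared residuals at the fitted parameters.
#' @slot nIterations Iterations used.
#' @slot status One of `"converged"`, `"max-iter"`, `"degenerate-input"`,
#'   `"failed"`.
#' @export
setClass("FitResult",
  representation(params = "IVIMParams", ssr = "numeric",
                 nIterations = "integer", status = "character"),
  validity = function(object) {
    if (!object@status %in% c("converged", "max-iter", "degenerate-input", "failed"))
      return("unknown status")
    if (is.finite(object@ssr) && object@ssr < 0) return("ssr must be >= 0")
    TRUE
  })

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s] after %d iterations, SSR = %.6g\n",
              object@status, object@nIterations, object@ssr))
  if (object@status %in% c("converged", "max-iter")) show(object@params)
})

## ---- ParameterMaps ----------------------------------------------------------

#' Voxel-wise IVIM and ADC parameter maps
#'
#' Each slot is a 3D array on the DWI spatial grid; voxels never fitted carry
#' `NA`. The status map uses the [FitResult-class] vocabulary plus
#' `"not-fitted"` outside the mask.
#'
#' @slot s0,f,d,dstar,adc Numeric 3D arrays.
#' @slot status Character 3D array of fit statuses.
#' @export
setClass("ParameterMaps",
  representation(s0 = "array", f = "array", d = "array", dstar = "array",
                 adc = "array", status = "array"),
  validity = function(object) {
    dims <- lapply(list(object@s0, object@f, object@d, object@dstar,
                        object@adc, object@status), dim)
    if (!all(vapply(dims, identical, TRUE, dims[[1]])))
      return("all maps must share one shape")
    ok <- object@status == "converged"
    ok[is.na(ok)] <- FALSE
    if (any(ok)) {
      fv <- object@f[ok]; dv <- object@d[ok]; sv <- object@dstar[ok]
      if (any(fv < -1e-12 | fv > 1 + 1e-12, na.rm = TRUE))
        return("converged f values outside [0, 1]")
      if (any(dv <= 0, na.rm = TRUE)) return("converged D values must be > 0")
      if (any(sv < dv - 1e-12, na.rm = TRUE))
        return("converged D* values below D")
    }
    TRUE
  })

#' Construct a [ParameterMaps-class]
#' @param s0,f,d,dstar,adc Numeric 3D arrays (same shape).
#' @param status Character 3D array of per-voxel fit statuses.
#' @return A `ParameterMaps`.
#' @export
parameterMaps <- function(s0, f, d, dstar, adc, status) {
  new("ParameterMaps", s0 = s0, f = f, d = d, dstar = dstar, adc = adc,
      status = status)
}

#' Extract one parameter map
#' @param maps A [ParameterMaps-class].
#' @param parameter One of `"S0"`, `"f"`, `"D"`, `"Dstar"`, `"ADC"`, `"status"`.
#' @return The 3D array.
#' @export
parameterMap <- function(maps, parameter = c("S0", "f", "D", "Dstar", "ADC", "status")) {
  parameter <- match.arg(parameter)
  switch(parameter, S0 = maps@s0, f = maps@f, D = maps@d,
         Dstar = maps@dstar, ADC = maps@adc, status = maps@status)
}

setMethod("show", "ParameterMaps", function(object) {
  tab <- table(object@status)
  cat(sprintf("ParameterMaps %s; status: %s\n",
              paste(dim(object@s0), collapse = "x"),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")))
})
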