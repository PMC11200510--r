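## Dataset normalization and principal-component projection. Scalers and
## projections are fitted on training rows only and then applied to any rows,
## which is what keeps the cross-validation loop leakage-free.

.SCALER_KINDS <- c("none", "standardization", "min-max", "robust",
                   "l1-normalizer")

#' Fit a feature scaler
#'
#' Column-wise kinds store fitted state from the training rows:
#' `standardization` centres by the mean and divides by the population
#' standard deviation; `min-max` maps the training range to \[0, 1\];
#' `robust` centres by the median and divides by the IQR (linear-interpolation
#' percentiles). Zero-spread features pass through unchanged and are flagged
#' rather than producing divisions by zero. `l1-normalizer` is row-wise
#' (each record divided by its L1 norm) and needs no fitted state.
#'
#' @param x Numeric matrix or data.frame of features (training rows).
#' @param kind One of `"none"`, `"standardization"`, `"min-max"`, `"robust"`,
#'   `"l1-normalizer"`.
#' @return A `ScalerSpec` list (kind + fitted state), for [applyScaler()].
#' @export
fitScaler <- function(x, kind = .SCALER_KINDS) {
  kind <- match.arg(kind)
  x <- asFeatureMatrix(x)
  state <- switch(kind,
    none = NULL,
    `l1-normalizer` = NULL,
    standardization = {
      mu <- colMeans(x)
      sdev <- sqrt(colMeans(sweep(x, 2, mu)^2))   # population sd
      flat <- sdev == 0
      sdev[flat] <- 1; mu[flat] <- 0
      list(center = mu, scale = sdev, flat = flat)
    },
    `min-max` = {
      lo <- apply(x, 2, min); hi <- apply(x, 2, max)
      flat <- hi == lo
      rng <- hi - lo
      rng[flat] <- 1; lo[flat] <- 0
      list(center = lo, scale = rng, flat = flat)
    },
    robust = {
      med <- apply(x, 2, median)
      iqr <- apply(x, 2, function(v)
        unname(diff(quantile(v, c(0.25, 0.75), type = 7))))
      flat <- iqr == 0
      iqr[flat] <- 1; med[flat] <- 0
      list(center = med, scale = iqr, flat = flat)
    })
  structure(list(kind = kind, state = state), class = "ScalerSpec")
}

#' Apply a fitted scaler
#' @param x Numeric matrix or data.frame of features (any rows).
#' @param spec A `ScalerSpec` from [fitScaler()].
#' @return Transformed matrix.
#' @export
applyScaler <- function(x, spec) {
  stopifnot(inherits(spec, "ScalerSpec"))
  x <- asFeatureMatrix(x)
  switch(spec$kind,
    none = x,
    `l1-normalizer` = {
      nrm <- rowSums(abs(x))
      nrm[nrm == 0] <- 1
      x / nrm
    },
    sweep(sweep(x, 2, spec$state$center), 2, spec$state$scale, `/`))
}

asFeatureMatrix <- function(x) {
  if (is.data.frame(x))
    x <- as.matrix(x[, setdiff(names(x), c("case_id", "label")), drop = FALSE])
  if (!is.numeric(x)) stop("features must be numeric")
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite value in feature '%s'",
                 colnames(x)[bad[1, 2]] %||% bad[1, 2]))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a principal-component projection
#'
#' Principal components of the centred training matrix, ordered by decreasing
#' explained variance, with a deterministic sign convention: each component's
#' largest-magnitude loading is made positive.
#'
#' @param x Training feature matrix.
#' @param nComponents Number of components to keep; `NULL` keeps none
#'   (identity projection). Values above the matrix rank are truncated.
#' @return A `ProjectionSpec` list with `center`, orthonormal `rotation`,
#'   `explainedVarianceFractions` (over all components) and `nComponents`.
#' @export
fitProjection <- function(x, nComponents = NULL) {
  x <- asFeatureMatrix(x)
  if (is.null(nComponents))
    return(structure(list(identity = TRUE), class = "ProjectionSpec"))
  p <- ncol(x)
  if (nComponents > p)
    stop(sprintf("nComponents (%d) exceeds the feature count (%d)",
                 nComponents, p))
  if (nComponents < 1) stop("nComponents must be >= 1")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(nComponents, ncol(pc$rotation))
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(identity = FALSE, center = pc$center,
                 rotation = rot[, seq_len(k), drop = FALSE],
                 fullRotation = rot,
                 explainedVarianceFractions = evf, nComponents = k),
            class = "ProjectionSpec")
}

#' Apply a fitted projection
#' @param x Feature matrix (any rows).
#' @param spec A `ProjectionSpec` from [fitProjection()].
#' @return The projected matrix (`n x nComponents`), or `x` unchanged for the
#'   identity projection.
#' @export
applyProjection <- function(x, spec) {
  stopifnot(inherits(spec, "ProjectionSpec"))
  x <- asFeatureMatrix(x)
  if (isTRUE(spec$identity)) return(x)
  sweep(x, 2, spec$center) %*% spec$rotation
}
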