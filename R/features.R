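## Per-case zonal histogram features from voxel-wise parameter maps.

#' Zonal feature extraction specification
#'
#' @slot parameters Subset of `"f"`, `"D"`, `"Dstar"`, `"ADC"`.
#' @slot statistics Subset of `"mean"`, `"median"`, `"p10"`, `"p90"`,
#'   `"skewness"`, `"kurtosis"`.
#' @slot zones Subset of `"CZ"`, `"PZ"`.
#' @slot laterality If `TRUE`, each zone is split left/right at the
#'   midsagittal plane, doubling the feature count.
#' @export
setClass("FeatureSpec",
  representation(parameters = "character", statistics = "character",
                 zones = "character", laterality = "logical"),
  validity = function(object) {
    if (length(object@parameters) == 0 ||
        !all(object@parameters %in% c("f", "D", "Dstar", "ADC")))
      return("parameters must be a non-empty subset of f, D, Dstar, ADC")
    if (length(object@statistics) == 0 ||
        !all(object@statistics %in% c("mean", "median", "p10", "p90",
                                      "skewness", "kurtosis")))
      return("statistics must be a non-empty subset of the 6 histogram statistics")
    if (length(object@zones) == 0 || !all(object@zones %in% c("CZ", "PZ")))
      return("zones must be a non-empty subset of CZ, PZ")
    TRUE
  })

#' Construct a [FeatureSpec-class]
#' @param parameters,statistics,zones,laterality See [FeatureSpec-class].
#' @return A `FeatureSpec`.
#' @export
featureSpec <- function(parameters = c("f", "D", "Dstar"),
                        statistics = c("mean", "median", "p10", "p90",
                                       "skewness", "kurtosis"),
                        zones = c("CZ", "PZ"), laterality = FALSE) {
  new("FeatureSpec", parameters = parameters, statistics = statistics,
      zones = zones, laterality = laterality)
}

#' The four modality feature sets of the model-selection loop
#'
#' `"ADC"` uses the six histogram statistics of the ADC map in both zones
#' split by laterality (24 features); `"PZ"` and `"CZ"` use the IVIM
#' parameters (f, D, D*) of a single zone (18 features each); `"CZ+PZ"`
#' concatenates both zones (36 features).
#'
#' @param modality One of `"ADC"`, `"PZ"`, `"CZ"`, `"CZ+PZ"`.
#' @return A [FeatureSpec-class].
#' @export
modalityFeatureSpec <- function(modality = c("ADC", "PZ", "CZ", "CZ+PZ")) {
  modality <- match.arg(modality)
  switch(modality,
    "ADC" = featureSpec(parameters = "ADC", zones = c("CZ", "PZ"),
                        laterality = TRUE),
    "PZ" = featureSpec(zones = "PZ"),
    "CZ" = featureSpec(zones = "CZ"),
    "CZ+PZ" = featureSpec(zones = c("CZ", "PZ")))
}

#' Histogram statistics of the voxel values in one zone
#'
#' Percentiles use linear interpolation between closest ranks; skewness and
#' kurtosis are the standardized third and fourth central moments (so a
#' normal distribution has kurtosis 3, not 0). For a constant zone both
#' moments are degenerate and emitted as 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param values Finite numeric vector (>= 1 value).
#' @param statistics Which statistics to compute.
#' @return Named numeric vector.
#' @examples
#' zoneStatistics(1:100, c("p10", "p90"))
#' @export
zoneStatistics <- function(values,
                           statistics = c("mean", "median", "p10", "p90",
                                          "skewness", "kurtosis")) {
  if (length(values) < 1L || any(!is.finite(values)))
    stop("zone values must be finite and non-empty")
  n <- length(values)
  m <- mean(values)
  cm <- values - m
  m2 <- mean(cm^2)
  degenerate <- m2 == 0
  out <- vapply(statistics, function(s) {
    switch(s,
      mean = m,
      median = median(values),
      p10 = unname(quantile(values, 0.10, type = 7)),
      p90 = unname(quantile(values, 0.90, type = 7)),
      skewness = if (degenerate) 0 else mean(cm^3) / m2^1.5,
      kurtosis = if (degenerate) 0 else mean(cm^4) / m2^2)
  }, numeric(1))
  names(out) <- statistics
  if (degenerate && any(c("skewness", "kurtosis") %in% statistics))
    attr(out, "degenerate") <- TRUE
  out
}

#' Extract one case's zonal feature record
#'
#' Statistics are computed over converged voxels only. Feature names follow
#' `<zone>[_<side>]_<parameter>_<statistic>` (lower-case zone and side). A
#' requested zone with fewer than `minVoxels` converged voxels is a per-case
#' error naming the zone.
#'
#' @param maps A [ParameterMaps-class].
#' @param masks A [ZoneMaskSet-class] on the same grid.
#' @param spec A [FeatureSpec-class].
#' @param caseId Used in error messages.
#' @param minVoxels Minimum converged voxels per zone.
#' @return Named numeric vector (the feature record).
#' @export
extractFeatures <- function(maps, masks, spec = featureSpec(),
                            caseId = "case", minVoxels = 5L) {
  stopifnot(is(maps, "ParameterMaps"), is(masks, "ZoneMaskSet"),
            is(spec, "FeatureSpec"))
  validObject(spec)
  if (!identical(dim(maps@s0), dim(masks@prostate)))
    stop("maps and masks do not share a grid")
  conv <- maps@status == "converged"
  nx <- dim(conv)[1]
  xIndex <- array(rep(seq_len(nx), times = prod(dim(conv)[2:3])), dim = dim(conv))
  sides <- if (spec@laterality) c(left = TRUE, right = FALSE) else NULL

  record <- numeric(0)
  for (zone in spec@zones) {
    zmask <- if (zone == "CZ") masks@cz else masks@pz
    parts <- if (is.null(sides)) setNames(list(zmask), "") else {
      half <- xIndex <= floor(nx / 2)
      list(left = zmask & half, right = zmask & !half)
    }
    for (si in seq_along(parts)) {
      sideName <- names(parts)[si]
      sel <- parts[[si]] & conv
      if (sum(sel) < minVoxels)
        stop(sprintf("case %s: zone %s%s has %d converged voxels (< %d)",
                     caseId, zone,
                     if (nzchar(sideName)) paste0(" ", sideName) else "",
                     sum(sel), minVoxels))
      for (param in spec@parameters) {
        vals <- parameterMap(maps, param)[sel]
        stats <- zoneStatistics(vals, spec@statistics)
        prefix <- paste0(tolower(zone),
                         if (nzchar(sideName)) paste0("_", sideName) else "")
        names(stats) <- paste(prefix, param, spec@statistics, sep = "_")
        record <- c(record, stats)
      }
    }
  }
  record
}

#' Fit parameter maps for every case of a cohort
#'
#' @param cases List of [PhantomCase-class] objects (or any objects with
#'   `dwi` and `masks` slots).
#' @param config A [FitConfig-class].
#' @param adcB,smoothSigma Passed to [fitIvimVolume()].
#' @return Named list of [ParameterMaps-class], one per case.
#' @export
cohortParameterMaps <- function(cases, config = fitConfig(),
                                adcB = NULL, smoothSigma = 1) {
  out <- lapply(cases, function(cs) {
    b <- if (is.null(adcB)) max(bValues(cs@dwi)) else adcB
    fitIvimVolume(cs@dwi, cs@masks@prostate, config, adcB = b,
                  smoothSigma = smoothSigma)
  })
  names(out) <- vapply(cases, function(cs) cs@caseId, "")
  out
}

#' Build a labelled feature table for a cohort
#'
#' One row per case: `case_id`, the named features of `spec`, `label`.
#'
#' @param cases List of [PhantomCase-class] objects.
#' @param maps Named list of [ParameterMaps-class] aligned with `cases`
#'   (e.g. from [cohortParameterMaps()], or the cases' truth maps).
#' @param spec A [FeatureSpec-class].
#' @return A data.frame passing [checkFeatureTable()].
#' @export
cohortFeatureTable <- function(cases, maps, spec = featureSpec()) {
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    rec <- extractFeatures(maps[[i]], cs@masks, spec, caseId = cs@caseId)
    cbind(data.frame(case_id = cs@caseId, stringsAsFactors = FALSE),
          as.data.frame(as.list(rec), check.names = FALSE),
          data.frame(label = cs@label, stringsAsFactors = FALSE))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  checkFeatureTable(tab)
  tab
}
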