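## Stratified repeated cross-validation with per-fold scaler -> PCA ->
## classifier pipelines, and the exhaustive model-selection loop.

#' Cross-validation protocol
#'
#' @slot nFolds Number of folds (>= 2).
#' @slot nRepeats Number of repeats.
#' @slot stratified Stratify folds by class (always recommended at n = 80).
#' @slot seed Seed for fold assignment.
#' @export
setClass("CVSpec",
  representation(nFolds = "integer", nRepeats = "integer",
                 stratified = "logical", seed = "integer"),
  validity = function(object) {
    if (object@nFolds < 2L) return("nFolds must be >= 2")
    if (object@nRepeats < 1L) return("nRepeats must be >= 1")
    TRUE
  })

#' Construct a [CVSpec-class]
#'
#' Default protocol: stratified 5-fold, 10 repeats, case-level splits.
#'
#' @param nFolds,nRepeats,stratified,seed See [CVSpec-class].
#' @return A `CVSpec`.
#' @export
cvSpec <- function(nFolds = 5L, nRepeats = 10L, stratified = TRUE, seed = 0L) {
  new("CVSpec", nFolds = as.integer(nFolds), nRepeats = as.integer(nRepeats),
      stratified = stratified, seed = as.integer(seed))
}

#' Cross-validation report
#'
#' @slot evaluations One row per repeat x fold with the seven metrics
#'   (undefined metrics are `NA`).
#' @slot summary `mean`, `std` and `nDefined` per metric; means are the
#'   arithmetic means of the defined per-evaluation values.
#' @slot spec The evaluated [ModelSpec-class].
#' @slot cv The [CVSpec-class] used.
#' @export
setClass("CVReport",
  representation(evaluations = "data.frame", summary = "data.frame",
                 spec = "ModelSpec", cv = "CVSpec"))

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: %s on %s, %dx%d CV\n", object@spec@classifier,
              object@spec@modality, object@cv@nFolds, object@cv@nRepeats))
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-17s %6.2f%% +/- %.3f\n", s$metric[i],
                100 * s$mean[i], 100 * s$std[i]))
})

.METRIC_NAMES <- c("accuracy", "sensitivity", "specificity", "precision",
                   "f1", "roc_auc", "balanced_accuracy")

## Stratified fold assignment: within each class, shuffle and deal
## round-robin, so every fold holds both classes whenever each class has at
## least nFolds members (a precondition of crossValidate).
assignFolds <- function(labels, nFolds, stratified) {
  n <- length(labels)
  folds <- integer(n)
  if (stratified) {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      folds[idx] <- rep_len(seq_len(nFolds), length(idx))
    }
  } else {
    folds[sample(n)] <- rep_len(seq_len(nFolds), n)
  }
  folds
}

#' Cross-validate one model configuration
#'
#' For every repeat a fresh stratified case-level fold assignment is drawn;
#' within each fold the scaler, the PCA projection and the classifier are
#' fitted on the training cases only and applied to the held-out cases
#' (leakage-safe by call order). All seven metrics are computed per
#' evaluation; the report aggregates over the `nRepeats x nFolds`
#' evaluations. Fully deterministic given the two seeds.
#'
#' @param table Feature table (see [checkFeatureTable()]) with at least
#'   `nFolds` cases per class.
#' @param spec A [ModelSpec-class].
#' @param cv A [CVSpec-class].
#' @return A [CVReport-class].
#' @export
crossValidate <- function(table, spec, cv = cvSpec()) {
  stopifnot(is(spec, "ModelSpec"), is(cv, "CVSpec"))
  checkFeatureTable(table)
  y <- factor(table$label, levels = .classLevels)
  if (any(table(y) < cv@nFolds))
    stop("each class needs at least nFolds cases")
  x <- asFeatureMatrix(table)
  factory <- makeClassifier(spec)
  nComp <- if (is.na(spec@nComponents)) NULL else spec@nComponents

  rows <- list()
  set.seed(cv@seed)
  for (rep in seq_len(cv@nRepeats)) {
    folds <- assignFolds(as.character(y), cv@nFolds, cv@stratified)
    for (k in seq_len(cv@nFolds)) {
      trainIdx <- which(folds != k)
      testIdx <- which(folds == k)
      scaler <- fitScaler(x[trainIdx, , drop = FALSE], spec@scalerKind)
      xTrain <- applyScaler(x[trainIdx, , drop = FALSE], scaler)
      xTest <- applyScaler(x[testIdx, , drop = FALSE], scaler)
      proj <- fitProjection(xTrain, nComp)
      xTrain <- applyProjection(xTrain, proj)
      xTest <- applyProjection(xTest, proj)
      model <- factory$fit(xTrain, y[trainIdx])
      scores <- factory$score(model, xTest)
      pred <- ifelse(scores > 0.5, "PCa", "BPH")
      truth <- as.character(y[testIdx])
      cm <- confusionMetrics(tp = sum(pred == "PCa" & truth == "PCa"),
                             fp = sum(pred == "PCa" & truth == "BPH"),
                             tn = sum(pred == "BPH" & truth == "BPH"),
                             fn = sum(pred == "BPH" & truth == "PCa"))
      rows[[length(rows) + 1]] <- data.frame(
        repeat_ = rep, fold = k,
        accuracy = cm[["accuracy"]], sensitivity = cm[["sensitivity"]],
        specificity = cm[["specificity"]], precision = cm[["precision"]],
        f1 = cm[["f1"]], roc_auc = rocAuc(truth, scores),
        balanced_accuracy = cm[["balanced_accuracy"]])
    }
  }
  evals <- do.call(rbind, rows)
  summary <- data.frame(
    metric = .METRIC_NAMES,
    mean = vapply(.METRIC_NAMES, function(m) mean(evals[[m]], na.rm = TRUE), 0),
    std = vapply(.METRIC_NAMES, function(m) sd(evals[[m]], na.rm = TRUE), 0),
    nDefined = vapply(.METRIC_NAMES, function(m) sum(!is.na(evals[[m]])), 0L),
    row.names = NULL)
  new("CVReport", evaluations = evals, summary = summary, spec = spec, cv = cv)
}

cvMean <- function(report, metric) {
  report@summary$mean[report@summary$metric == metric]
}

#' Evaluate a grid of model configurations and pick the best
#'
#' Exhaustively cross-validates every candidate [ModelSpec-class] on the
#' feature table of its modality. The best configuration has the highest
#' mean balanced accuracy, ties broken by higher mean F1 and then by grid
#' order. The leaderboard carries one row per configuration with mean and
#' std of all seven metrics.
#'
#' @param tables Named list of feature tables, keyed by modality (a single
#'   unnamed table is accepted when all specs share one modality).
#' @param grid List of [ModelSpec-class] candidates.
#' @param cv A [CVSpec-class].
#' @return List with `best` (ModelSpec), `bestReport` (CVReport),
#'   `leaderboard` (data.frame) and `reports` (all CVReports).
#' @export
gridSearch <- function(tables, grid, cv = cvSpec()) {
  if (length(grid) == 0) stop("empty candidate grid")
  if (is.data.frame(tables)) tables <- list(tables)
  reports <- lapply(grid, function(spec) {
    tab <- if (length(tables) == 1L && is.null(names(tables))) tables[[1]]
           else tables[[spec@modality]]
    if (is.null(tab)) stop(sprintf("no feature table for modality '%s'",
                                   spec@modality))
    crossValidate(tab, spec, cv)
  })
  lb <- do.call(rbind, lapply(reports, leaderboardRow))
  rownames(lb) <- NULL
  ba <- vapply(reports, cvMean, 0, metric = "balanced_accuracy")
  f1 <- vapply(reports, cvMean, 0, metric = "f1")
  best <- order(-ba, -f1, seq_along(grid))[1]
  list(best = grid[[best]], bestReport = reports[[best]],
       leaderboard = lb, reports = reports)
}

leaderboardRow <- function(report) {
  s <- report@summary
  row <- data.frame(Features = report@spec@modality,
                    Classifier = report@spec@classifier,
                    PCA = if (is.na(report@spec@nComponents)) "N/A"
                          else as.character(report@spec@nComponents))
  for (m in c("accuracy", "sensitivity", "specificity", "precision", "f1",
              "roc_auc", "balanced_accuracy")) {
    row[[paste0(m, "_mean")]] <- s$mean[s$metric == m]
    row[[paste0(m, "_std")]] <- s$std[s$metric == m]
  }
  row$Scaler <- report@spec@scalerKind
  row$BestParams <- formatBestParams(report@spec)
  row
}

#' The eight benchmark model configurations
#'
#' The modality / classifier / scaler / PCA / hyperparameter combinations of
#' the reference benchmark (see [referenceMetrics()]): two per modality among
#' ADC, PZ, CZ and CZ+PZ.
#'
#' @param seed Seed copied into every spec.
#' @return List of eight [ModelSpec-class] objects.
#' @export
defaultStudyConfigurations <- function(seed = 0L) {
  list(
    modelSpec("MLP", list(activation = "TanH", hidden_layer_sizes = 100L,
                          learning_rate = "Adaptive", solver = "LBFGS"),
              scalerKind = "l1-normalizer", modality = "ADC", seed = seed),
    modelSpec("MLP", list(activation = "ReLU", hidden_layer_sizes = 200L,
                          learning_rate = "Adaptive", solver = "LBFGS"),
              scalerKind = "none", nComponents = 17L, modality = "ADC",
              seed = seed),
    modelSpec("ADA", list(learning_rate = 1.0, n_estimators = 300L),
              scalerKind = "robust", modality = "PZ", seed = seed),
    modelSpec("RFC", list(class_weight = "Balanced", criterion = "Gini",
                          max_depth = 15L, n_estimators = 200L),
              scalerKind = "none", nComponents = 6L, modality = "PZ",
              seed = seed),
    modelSpec("DT", list(criterion = "Entropy", max_depth = 5L,
                         splitter = "Random"),
              scalerKind = "robust", modality = "CZ", seed = seed),
    modelSpec("MLP", list(activation = "ReLU", hidden_layer_sizes = 100L,
                          learning_rate = "Adaptive", solver = "LBFGS"),
              scalerKind = "min-max", nComponents = 4L, modality = "CZ",
              seed = seed),
    modelSpec("RFC", list(class_weight = "None", criterion = "Gini",
                          max_depth = 5L, n_estimators = 100L),
              scalerKind = "standardization", modality = "CZ+PZ", seed = seed),
    modelSpec("DT", list(criterion = "Entropy", max_depth = 5L,
                         splitter = "Best"),
              scalerKind = "none", nComponents = 8L, modality = "CZ+PZ",
              seed = seed))
}

#' Bundled reference benchmark metrics
#'
#' Cross-validated mean/std metrics reported for eight modality / classifier
#' configurations on a clinical prostate DW-MRI cohort, shipped with the
#' package for internal-consistency checks (e.g. the balanced-accuracy
#' identity: the reported balanced accuracy must equal the mean of the
#' reported sensitivity and specificity after two-decimal rounding).
#' Percentages are on the 0-100 scale.
#'
#' @return data.frame with one row per configuration.
#' @export
referenceMetrics <- function() {
  path <- system.file("extdata", "reference_cv_metrics.csv",
                      package = "ivimcad", mustWork = TRUE)
  read.csv(path, check.names = FALSE)
}
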