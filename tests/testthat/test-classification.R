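# Classifier registry, cross-validation driver and model selection.

test_that("the registry accepts the benchmark configurations and names offenders", {
  rfc <- modelSpec("RFC", list(class_weight = "None", criterion = "Gini",
                               max_depth = 5, n_estimators = 100))
  expect_s4_class(rfc, "ModelSpec")
  mlp <- modelSpec("MLP", list(activation = "TanH", hidden_layer_sizes = 100,
                               learning_rate = "Adaptive", solver = "LBFGS"))
  expect_s4_class(mlp, "ModelSpec")
  expect_error(modelSpec("RFC", list(depthh = 5)), "depthh")
  expect_error(modelSpec("SVMX"), "SVMX")
  expect_error(modelSpec("RFC", scalerKind = "zscore"), "zscore")
})

test_that("every registry classifier separates linearly separable data", {
  tab <- separableTable(n = 36, gap = 3)
  cv <- cvSpec(nFolds = 3L, nRepeats = 1L, seed = 2L)
  specs <- list(
    modelSpec("MLP", list(hidden_layer_sizes = 20), seed = 1L),
    modelSpec("DT", list(max_depth = 3)),
    modelSpec("KNN", list(n_neighbors = 3)),
    modelSpec("ERTC", list(n_estimators = 50)),
    modelSpec("ADA", list(n_estimators = 20, learning_rate = 1.0)),
    modelSpec("RFC", list(n_estimators = 50)),
    modelSpec("ETC", list(n_estimators = 50)),
    modelSpec("GB", list(n_estimators = 30)),
    modelSpec("HGB", list(n_estimators = 30)),
    modelSpec("XGB", list(n_estimators = 30)),
    modelSpec("LGBM", list(n_estimators = 30)))
  for (spec in specs) {
    rep <- crossValidate(tab, spec, cv)
    expect_equal(ivimcad:::cvMean(rep, "balanced_accuracy"), 1,
                 tolerance = 1e-12, label = spec@classifier)
  }
})

test_that("permuted labels give chance-level balanced accuracy", {
  set.seed(99)
  n <- 200
  tab <- data.frame(case_id = sprintf("c%03d", 1:n),
                    f1 = rnorm(n), f2 = rnorm(n),
                    label = sample(rep(c("PCa", "BPH"), each = n / 2)))
  rep <- crossValidate(tab, modelSpec("RFC", list(n_estimators = 100), seed = 1L),
                       cvSpec(nFolds = 5L, nRepeats = 10L, seed = 7L))
  expect_lt(abs(ivimcad:::cvMean(rep, "balanced_accuracy") - 0.5), 0.05)
})

test_that("cross-validation is deterministic and internally consistent", {
  tab <- separableTable(n = 30, gap = 1, sd = 2)   # imperfect separation
  spec <- modelSpec("RFC", list(n_estimators = 50), seed = 3L)
  cv <- cvSpec(nFolds = 3L, nRepeats = 2L, seed = 11L)
  a <- crossValidate(tab, spec, cv)
  b <- crossValidate(tab, spec, cv)
  expect_identical(a@evaluations, b@evaluations)
  expect_identical(a@summary, b@summary)

  ev <- a@evaluations
  # reported means are the arithmetic means of the per-evaluation values
  for (m in c("accuracy", "sensitivity", "specificity", "balanced_accuracy"))
    expect_equal(a@summary$mean[a@summary$metric == m], mean(ev[[m]]),
                 tolerance = 1e-12)
  # balanced-accuracy linearity across evaluations
  expect_equal(mean(ev$balanced_accuracy),
               (mean(ev$sensitivity) + mean(ev$specificity)) / 2,
               tolerance = 1e-12)
})

test_that("folds partition cases and keep both classes", {
  set.seed(5)
  labels <- rep(c("PCa", "BPH"), c(9, 12))
  folds <- ivimcad:::assignFolds(labels, 4L, TRUE)
  expect_identical(sort(unique(folds)), 1:4)
  for (k in 1:4) expect_setequal(unique(labels[folds == k]), c("PCa", "BPH"))
  expect_error(crossValidate(
    data.frame(case_id = c("a", "b"), x = c(1, 2), label = c("PCa", "PCa")),
    modelSpec("DT"), cvSpec(nFolds = 2L)), "PCa|class")
})

test_that("grid search ranks dominating configurations first", {
  tab <- separableTable(n = 30, gap = 3)
  cv <- cvSpec(nFolds = 3L, nRepeats = 1L, seed = 1L)
  one <- list(modelSpec("DT", list(max_depth = 2), modality = "CZ+PZ"))
  gs1 <- gridSearch(list("CZ+PZ" = tab), one, cv)
  expect_identical(gs1$best, one[[1]])

  # KNN with k = n (always predicts the majority by vote) versus RFC
  grid <- list(modelSpec("KNN", list(n_neighbors = 29), modality = "CZ+PZ"),
               modelSpec("RFC", list(n_estimators = 50), modality = "CZ+PZ"))
  gs <- gridSearch(list("CZ+PZ" = tab), grid, cv)
  expect_identical(gs$best@classifier, "RFC")
  expect_identical(nrow(gs$leaderboard), 2L)
  expect_true(all(c("Features", "Classifier", "PCA", "Scaler", "BestParams",
                    "balanced_accuracy_mean", "balanced_accuracy_std")
                  %in% names(gs$leaderboard)))
})

test_that("classification on true parameters separates disjoint classes perfectly", {
  # disjoint D supports: downstream balanced accuracy must reach 1.0
  classes <- defaultTissueClasses()
  classes[["PCa-lesion"]]@dist["d", ] <- c(0.5e-3, 0.05e-3, 0.4e-3, 0.6e-3)
  classes[["BPH-lesion"]]@dist["d", ] <- c(1.5e-3, 0.05e-3, 1.4e-3, 1.6e-3)
  spec <- phantomSpec(cohortSize = 16L, nPositive = 8L,
                      gridShape = c(24L, 24L, 2L), lesionRadius = 2,
                      tissueClasses = classes, noiseSigma = 0, seed = 13L,
                      pzLesionProb = 1)
  cohort <- generateCohort(spec)
  tab <- cohortFeatureTable(cohort, lapply(cohort, function(cs) cs@truth),
                            modalityFeatureSpec("PZ"))
  rep <- crossValidate(tab, modelSpec("RFC", list(n_estimators = 100), seed = 1L),
                       cvSpec(nFolds = 4L, nRepeats = 2L, seed = 5L))
  expect_equal(ivimcad:::cvMean(rep, "balanced_accuracy"), 1, tolerance = 1e-12)
})

test_that("the eight benchmark configurations are well-formed", {
  cfgs <- defaultStudyConfigurations(seed = 1L)
  expect_length(cfgs, 8L)
  expect_setequal(vapply(cfgs, function(s) s@modality, ""),
                  c("ADC", "PZ", "CZ", "CZ+PZ"))
  for (s in cfgs) expect_true(validObject(s))
  # leaderboard vocabulary
  expect_match(formatBestParams(cfgs[[7]]), "CW: None")
  expect_match(formatBestParams(cfgs[[7]]), "# Estimators: 100")
})
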