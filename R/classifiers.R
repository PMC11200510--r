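## Classifier registry for the model-selection loop. Each entry declares the
## hyperparameter names its grid may use and provides fit / score functions
## behind one interface; PCa is always the positive class.

.CLASSIFIER_REGISTRY <- list(
  MLP  = c("activation", "hidden_layer_sizes", "learning_rate", "solver",
           "alpha", "max_iter"),
  DT   = c("criterion", "max_depth", "splitter"),
  KNN  = c("n_neighbors"),
  ERTC = c("n_estimators", "max_depth", "class_weight"),
  ADA  = c("learning_rate", "n_estimators"),
  RFC  = c("class_weight", "criterion", "max_depth", "n_estimators"),
  ETC  = c("n_estimators", "max_depth", "class_weight"),
  GB   = c("n_estimators", "learning_rate", "max_depth"),
  HGB  = c("n_estimators", "learning_rate", "max_depth"),
  XGB  = c("n_estimators", "learning_rate", "max_depth"),
  LGBM = c("n_estimators", "learning_rate", "max_depth")
)

#' Model configuration for the selection loop
#'
#' @slot classifier One of the registry names (MLP, DT, KNN, ERTC, ADA, RFC,
#'   ETC, GB, HGB, XGB, LGBM).
#' @slot hyperparameters Named list; names must belong to the classifier's
#'   declared grid.
#' @slot scalerKind Scaler applied per fold (see [fitScaler()]).
#' @slot nComponents PCA components kept per fold; `NA` disables projection.
#' @slot modality Which feature set the spec is evaluated on (see
#'   [modalityFeatureSpec()]); informational for the leaderboard.
#' @slot seed Seed for the classifier's internal randomness.
#' @export
setClass("ModelSpec",
  representation(classifier = "character", hyperparameters = "list",
                 scalerKind = "character", nComponents = "integer",
                 modality = "character", seed = "integer"),
  validity = function(object) {
    allowed <- .CLASSIFIER_REGISTRY[[object@classifier]]
    if (is.null(allowed))
      return(sprintf("unknown classifier '%s'", object@classifier))
    bad <- setdiff(names(object@hyperparameters), allowed)
    if (length(bad) > 0)
      return(sprintf("unknown hyperparameter '%s' for %s", bad[1],
                     object@classifier))
    if (!object@scalerKind %in% .SCALER_KINDS)
      return(sprintf("unknown scaler '%s'", object@scalerKind))
    TRUE
  })

#' Construct a [ModelSpec-class]
#' @param classifier Registry name.
#' @param hyperparameters Named list of hyperparameter values.
#' @param scalerKind Scaler kind (default `"none"`).
#' @param nComponents PCA components (`NULL` = no projection).
#' @param modality Feature-set name, e.g. `"CZ+PZ"`.
#' @param seed Classifier seed.
#' @return A `ModelSpec`.
#' @examples
#' modelSpec("RFC", list(class_weight = "None", criterion = "Gini",
#'                       max_depth = 5, n_estimators = 100),
#'           scalerKind = "standardization")
#' @export
modelSpec <- function(classifier, hyperparameters = list(),
                      scalerKind = "none", nComponents = NULL,
                      modality = "CZ+PZ", seed = 0L) {
  new("ModelSpec", classifier = classifier,
      hyperparameters = hyperparameters, scalerKind = scalerKind,
      nComponents = if (is.null(nComponents)) NA_integer_
                    else as.integer(nComponents),
      modality = modality, seed = as.integer(seed))
}

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s on %s [scaler: %s, PCA: %s]\n  %s\n",
              object@classifier, object@modality, object@scalerKind,
              if (is.na(object@nComponents)) "none" else object@nComponents,
              formatBestParams(object)))
})

hp <- function(spec, name, default) {
  v <- spec@hyperparameters[[name]]
  if (is.null(v)) default else v
}

#' Build a trained-model factory from a [ModelSpec-class]
#'
#' Returns an untrained factory: `fit(x, y)` trains on a numeric matrix and a
#' factor with levels `c("BPH", "PCa")` (PCa positive); `score(model, x)`
#' returns the positive-class score in \[0, 1\]. Unknown classifiers or
#' hyperparameter names are configuration errors naming the offender.
#'
#' @param spec A [ModelSpec-class].
#' @return List with `fit` and `score` functions.
#' @export
makeClassifier <- function(spec) {
  stopifnot(is(spec, "ModelSpec"))
  validObject(spec)
  switch(spec@classifier,
    MLP = mlpFactory(spec),
    DT = dtFactory(spec),
    KNN = knnFactory(spec),
    ADA = adaFactory(spec),
    RFC = rangerFactory(spec, splitrule = "gini"),
    ERTC = rangerFactory(spec, splitrule = "extratrees"),
    ETC = rangerFactory(spec, splitrule = "extratrees"),
    GB = xgbFactory(spec, treeMethod = "exact", growPolicy = "depthwise",
                    defaultDepth = 3),
    HGB = xgbFactory(spec, treeMethod = "hist", growPolicy = "depthwise",
                     defaultDepth = 6),
    XGB = xgbFactory(spec, treeMethod = "exact", growPolicy = "depthwise",
                     defaultDepth = 6),
    LGBM = xgbFactory(spec, treeMethod = "hist", growPolicy = "lossguide",
                      defaultDepth = 6))
}

.classLevels <- c("BPH", "PCa")

checkXY <- function(x, y) {
  stopifnot(is.matrix(x), is.numeric(x))
  y <- factor(as.character(y), levels = .classLevels)
  if (anyNA(y)) stop("labels must be PCa or BPH")
  list(x = x, y = y)
}

## ---- MLP: single-hidden-layer network trained by L-BFGS --------------------
## Log-loss with L2 penalty alpha/(2n); supports ReLU / TanH / Logistic
## activations, which is why this is implemented here rather than delegated.

mlpFactory <- function(spec) {
  act <- tolower(hp(spec, "activation", "ReLU"))
  if (!act %in% c("relu", "tanh", "logistic"))
    stop(sprintf("unknown MLP activation '%s'", hp(spec, "activation", "")))
  solver <- tolower(hp(spec, "solver", "LBFGS"))
  if (solver != "lbfgs")
    stop(sprintf("unsupported MLP solver '%s' (only LBFGS)", solver))
  h <- as.integer(hp(spec, "hidden_layer_sizes", 100L))
  alpha <- hp(spec, "alpha", 1e-4)
  maxit <- as.integer(hp(spec, "max_iter", 200L))
  # learning_rate is accepted for grid compatibility; it only affects SGD
  # solvers, so with LBFGS it is inert.

  actFun <- switch(act,
    relu = list(f = function(z) pmax(z, 0), g = function(z, a) (z > 0) * 1),
    tanh = list(f = tanh, g = function(z, a) 1 - a^2),
    logistic = list(f = function(z) 1 / (1 + exp(-z)),
                    g = function(z, a) a * (1 - a)))

  fit <- function(x, y) {
    d <- checkXY(x, y); x <- d$x
    yBin <- as.numeric(d$y == "PCa")
    n <- nrow(x); p <- ncol(x)
    set.seed(spec@seed)
    lim1 <- sqrt(6 / (p + h)); lim2 <- sqrt(6 / (h + 1))
    theta0 <- c(runif(p * h, -lim1, lim1), rep(0, h),
                runif(h, -lim2, lim2), 0)
    unpack <- function(th) list(
      W1 = matrix(th[seq_len(p * h)], p, h),
      b1 = th[p * h + seq_len(h)],
      w2 = th[p * h + h + seq_len(h)],
      b2 = th[p * h + 2 * h + 1])
    fwd <- function(par, xx) {
      z <- sweep(xx %*% par$W1, 2, par$b1, `+`)
      a <- actFun$f(z)
      eta <- drop(a %*% par$w2) + par$b2
      list(z = z, a = a, prob = 1 / (1 + exp(-eta)))
    }
    loss <- function(th) {
      par <- unpack(th); fw <- fwd(par, x)
      pr <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
      -mean(yBin * log(pr) + (1 - yBin) * log(1 - pr)) +
        alpha / (2 * n) * (sum(par$W1^2) + sum(par$w2^2))
    }
    grad <- function(th) {
      par <- unpack(th); fw <- fwd(par, x)
      dEta <- (fw$prob - yBin) / n
      dW2 <- drop(crossprod(fw$a, dEta)) + alpha / n * par$w2
      dB2 <- sum(dEta)
      dA <- outer(dEta, par$w2)
      dZ <- dA * actFun$g(fw$z, fw$a)
      dW1 <- crossprod(x, dZ) + alpha / n * par$W1
      dB1 <- colSums(dZ)
      c(as.numeric(dW1), dB1, dW2, dB2)
    }
    opt <- optim(theta0, loss, grad, method = "L-BFGS-B",
                 control = list(maxit = maxit))
    list(par = unpack(opt$par), fwd = fwd)
  }
  score <- function(model, x) model$fwd(model$par, x)$prob
  list(fit = fit, score = score)
}

## ---- Decision tree (rpart) -------------------------------------------------

dtFactory <- function(spec) {
  criterion <- hp(spec, "criterion", "Gini")
  split <- switch(criterion, Gini = "gini", Entropy = "information",
                  stop(sprintf("unknown DT criterion '%s'", criterion)))
  depth <- as.integer(hp(spec, "max_depth", 5L))
  splitter <- hp(spec, "splitter", "Best")
  if (!splitter %in% c("Best", "Random"))
    stop(sprintf("unknown DT splitter '%s'", splitter))
  fit <- function(x, y) {
    d <- checkXY(x, y)
    feats <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
    colnames(x) <- feats
    set.seed(spec@seed)
    # "Random" splitter: a randomized tree over a feature subset of size
    # about sqrt(p) (rpart itself always takes the best split).
    use <- if (splitter == "Random" && ncol(x) > 2)
      sort(sample(ncol(x), max(2L, ceiling(sqrt(ncol(x)))))) else seq_len(ncol(x))
    df <- data.frame(x[, use, drop = FALSE], .y = d$y, check.names = TRUE)
    tree <- rpart::rpart(.y ~ ., data = df, method = "class",
                         parms = list(split = split),
                         control = rpart::rpart.control(
                           maxdepth = depth, cp = 0, xval = 0,
                           minsplit = 2, minbucket = 1))
    list(tree = tree, use = use)
  }
  score <- function(model, x) {
    colnames(x) <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
    df <- data.frame(x[, model$use, drop = FALSE], check.names = TRUE)
    predict(model$tree, df, type = "prob")[, "PCa"]
  }
  list(fit = fit, score = score)
}

## ---- K nearest neighbours (class::knn) -------------------------------------

knnFactory <- function(spec) {
  k <- as.integer(hp(spec, "n_neighbors", 5L))
  fit <- function(x, y) {
    d <- checkXY(x, y)
    list(x = x, y = d$y, k = min(k, nrow(x)))
  }
  score <- function(model, x) {
    set.seed(spec@seed)           # deterministic tie-breaking
    pred <- class::knn(model$x, x, model$y, k = model$k, prob = TRUE)
    pWin <- attr(pred, "prob")
    ifelse(pred == "PCa", pWin, 1 - pWin)
  }
  list(fit = fit, score = score)
}

## ---- AdaBoost (SAMME with depth-1 rpart stumps) ----------------------------
## No boosting package with AdaBoost semantics is available, so the discrete
## SAMME weight-update is implemented directly over weighted rpart stumps.

adaFactory <- function(spec) {
  lr <- hp(spec, "learning_rate", 1.0)
  m <- as.integer(hp(spec, "n_estimators", 50L))
  fit <- function(x, y) {
    d <- checkXY(x, y)
    n <- nrow(x)
    feats <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
    colnames(x) <- feats
    df <- data.frame(x, .y = d$y, check.names = TRUE)
    w <- rep(1 / n, n)
    stumps <- list(); alphas <- numeric(0)
    set.seed(spec@seed)
    for (i in seq_len(m)) {
      stump <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                            control = rpart::rpart.control(
                              maxdepth = 1, cp = 0, xval = 0,
                              minsplit = 2, minbucket = 1))
      pred <- predict(stump, df, type = "class")
      mis <- pred != d$y
      err <- sum(w * mis) / sum(w)
      if (err >= 0.5) { if (length(stumps) == 0) {
          stumps <- list(stump); alphas <- 0 }
        break }
      err <- max(err, 1e-10)
      a <- lr * log((1 - err) / err)
      stumps[[length(stumps) + 1]] <- stump
      alphas <- c(alphas, a)
      w <- w * exp(a * mis)
      w <- w / sum(w)
      if (err <= 1e-10) break
    }
    list(stumps = stumps, alphas = alphas)
  }
  score <- function(model, x) {
    colnames(x) <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
    df <- data.frame(x, check.names = TRUE)
    margin <- rep(0, nrow(x))
    for (i in seq_along(model$stumps)) {
      pred <- predict(model$stumps[[i]], df, type = "class")
      margin <- margin + model$alphas[i] * ifelse(pred == "PCa", 1, -1)
    }
    tot <- sum(abs(model$alphas))
    if (tot == 0) return(rep(0.5, nrow(x)))
    (margin / tot + 1) / 2
  }
  list(fit = fit, score = score)
}

## ---- Random forest / extra trees (ranger) ----------------------------------

rangerFactory <- function(spec, splitrule) {
  nTrees <- as.integer(hp(spec, "n_estimators", 100L))
  depth <- as.integer(hp(spec, "max_depth", 0L))   # 0 = unlimited in ranger
  cw <- hp(spec, "class_weight", "None")
  criterion <- hp(spec, "criterion", "Gini")
  if (splitrule == "gini" && !identical(criterion, "Gini"))
    stop(sprintf("unknown RFC criterion '%s' (registry declares Gini)",
                 criterion))
  fit <- function(x, y) {
    d <- checkXY(x, y)
    weights <- if (identical(cw, "Balanced")) {
      tab <- table(d$y)
      as.numeric(length(d$y) / (2 * tab[.classLevels]))
    } else NULL
    ranger::ranger(x = x, y = d$y, num.trees = nTrees,
                   max.depth = if (depth > 0) depth else NULL,
                   probability = TRUE, splitrule = splitrule,
                   replace = splitrule == "gini",
                   sample.fraction = 1,
                   num.random.splits = 1,
                   class.weights = weights, seed = spec@seed,
                   num.threads = 1)
  }
  score <- function(model, x) predict(model, x, num.threads = 1)$predictions[, "PCa"]
  list(fit = fit, score = score)
}

## ---- Gradient boosting family (xgboost) ------------------------------------
## HGB = histogram-binned depth-wise boosting; LGBM entry = leaf-wise
## histogram boosting (grow_policy "lossguide").

xgbFactory <- function(spec, treeMethod, growPolicy, defaultDepth) {
  nRounds <- as.integer(hp(spec, "n_estimators", 100L))
  eta <- hp(spec, "learning_rate", 0.1)
  depth <- as.integer(hp(spec, "max_depth", defaultDepth))
  fit <- function(x, y) {
    d <- checkXY(x, y)
    yBin <- as.numeric(d$y == "PCa")
    dtrain <- xgboost::xgb.DMatrix(x, label = yBin, nthread = 1)
    params <- list(objective = "binary:logistic", max_depth = depth,
                   eta = eta, nthread = 1, tree_method = treeMethod,
                   grow_policy = growPolicy, seed = spec@seed)
    xgboost::xgb.train(params = params, data = dtrain, nrounds = nRounds,
                       verbose = 0)
  }
  score <- function(model, x)
    predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
  list(fit = fit, score = score)
}

## ---- Leaderboard formatting -------------------------------------------------

#' Format a spec's hyperparameters in the leaderboard vocabulary
#' @param spec A [ModelSpec-class].
#' @return A single string such as
#'   `"CW: None, Criterion: Gini, MD: 5, # Estimators: 100"`.
#' @export
formatBestParams <- function(spec) {
  abbrev <- c(class_weight = "CW", criterion = "Criterion", max_depth = "MD",
              n_estimators = "# Estimators", learning_rate = "LR",
              activation = "Activation", hidden_layer_sizes = "HLS",
              solver = "Solver", splitter = "Splitter", n_neighbors = "K",
              alpha = "Alpha", max_iter = "Max Iter")
  parts <- vapply(names(spec@hyperparameters), function(nm)
    sprintf("%s: %s", abbrev[[nm]] %||% nm, spec@hyperparameters[[nm]]), "")
  if (!is.na(spec@nComponents))
    parts <- c(parts, sprintf("# PCA Components: %d", spec@nComponents))
  paste(sort(parts), collapse = ", ")
}
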