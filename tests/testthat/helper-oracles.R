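# Shared fixtures and independent oracles used across the suite.

# A small phantom spec that keeps per-test runtimes low while exercising the
# full zoned geometry (in-plane dims stay >= 8).
tinySpec <- function(..., lesionRadius = 2, seed = 11L) {
  phantomSpec(cohortSize = 6L, nPositive = 3L, gridShape = c(24L, 24L, 2L),
              lesionRadius = lesionRadius, seed = seed, ...)
}

# Random valid IVIM parameters within the physiologic ranges the phantom
# generator uses (f bounded away from 0 keeps the model identifiable).
randomIvimParams <- function(n = 1) {
  cbind(s0 = runif(n, 500, 1500), f = runif(n, 0.05, 0.35),
        d = runif(n, 0.4e-3, 2.5e-3), dstar = runif(n, 5e-3, 30e-3))
}

curveFromVector <- function(p, bvalues = defaultBValues()) {
  signalCurve(bvalues, ivimSignal(ivimParams(p[1], p[2], p[3], p[4]), bvalues))
}

# Dense brute-force SSR oracle: grid over (f, D, D*) with S0 profiled out
# linearly (for fixed shape g(b), the optimal S0 is <g,m>/<g,g>). The grid
# design matrix is built once; the returned closure scores one curve.
makeGridOracle <- function(bvalues,
                           fGrid = seq(0, 0.4, by = 0.01),
                           dGrid = seq(1e-4, 2.5e-3, length.out = 50),
                           dsGrid = seq(2e-3, 0.05, length.out = 50)) {
  combos <- expand.grid(f = fGrid, d = dGrid, ds = dsGrid)
  combos <- combos[combos$ds >= combos$d, ]
  E0 <- exp(-outer(combos$d, bvalues))
  E1 <- exp(-outer(combos$ds, bvalues))
  G <- combos$f * E1 + (1 - combos$f) * E0
  gg <- rowSums(G^2)
  function(intensities) {
    gm <- as.numeric(G %*% intensities)
    min(sum(intensities^2) - gm^2 / gg)
  }
}

# Independent bounded-LM fit via minpack.lm, used as the reference fitter.
nlsLmFit <- function(intensities, bvalues, start = NULL) {
  m0 <- intensities[1]
  if (is.null(start)) start <- c(m0, 0.1, 1e-3, 10e-3)
  resid <- function(p)
    intensities - p[1] * (p[2] * exp(-bvalues * p[4]) +
                          (1 - p[2]) * exp(-bvalues * p[3]))
  fit <- minpack.lm::nls.lm(par = start, fn = resid,
                            lower = c(1e-6, 0, 1e-5, 1e-5),
                            upper = c(10 * max(m0, 1), 1, 5e-3, 0.5),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  coef(fit)
}

# O(n^2) pair-enumeration AUC oracle (concordant pairs + half the ties).
aucPairOracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Counting oracle for confusion metrics: build explicit label/prediction
# vectors and count.
confusionOracle <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  total <- length(truth)
  sens <- if (sum(truth) == 0) NA_real_ else sum(pred & truth) / sum(truth)
  spec <- if (sum(!truth) == 0) NA_real_ else sum(!pred & !truth) / sum(!truth)
  prec <- if (sum(pred) == 0) NA_real_ else sum(pred & truth) / sum(pred)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  c(accuracy = sum(pred == truth) / total, sensitivity = sens,
    specificity = spec, precision = prec, f1 = f1,
    balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_
                        else (sens + spec) / 2)
}

# Two-feature toy table: class centres at -gap / +gap on feat_a with
# within-class spread sd, so gap >> sd is cleanly separable and gap << sd is
# near-chance.
separableTable <- function(n = 40, gap = 2, sd = 0, seed = 3) {
  set.seed(seed)
  half <- n %/% 2
  x1 <- c(rnorm(half, -gap, sd), rnorm(n - half, gap, sd))
  x2 <- rnorm(n)
  data.frame(case_id = sprintf("c%02d", seq_len(n)),
             feat_a = x1, feat_b = x2,
             label = rep(c("BPH", "PCa"), c(half, n - half)))
}
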