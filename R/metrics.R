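## Confusion-matrix metrics, ROC-AUC, and the Dice / IoU overlap measures.

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall of the positive class), specificity,
#' precision, F1 (harmonic mean of precision and sensitivity) and balanced
#' accuracy, the arithmetic mean of sensitivity and specificity. Metrics
#' whose denominator is zero are returned as `NA` (undefined-flagged), never
#' silently coerced to 0.
#'
#' @param tp,fp,tn,fn Non-negative integer confusion counts (total >= 1).
#' @return Named numeric vector with `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `balanced_accuracy`.
#' @examples
#' confusionMetrics(tp = 9, fp = 3, tn = 7, fn = 1)
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || any(counts != round(counts)) || any(!is.finite(counts)))
    stop("confusion counts must be non-negative integers")
  total <- sum(counts)
  if (total < 1) stop("at least one sample is required")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- frac(tp, tp + fn)
  spec <- frac(tn, tn + fp)
  prec <- frac(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
        else 2 * prec * sens / (prec + sens)
  bal <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  c(accuracy = (tp + tn) / total, sensitivity = sens, specificity = spec,
    precision = prec, f1 = f1, balanced_accuracy = bal)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formulation with mid-rank tie
#' handling, which equals the trapezoidal ROC integral:
#' `P(score+ > score-) + 0.5 * P(score+ = score-)`.
#'
#' @param labels Logical / 0-1 / factor vector; `TRUE`, `1` or `"PCa"` marks
#'   the positive class.
#' @param scores Finite numeric scores, higher = more positive.
#' @return The AUC in \[0, 1\], or `NA` when only one class is present.
#' @examples
#' rocAuc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))  # 0.75
#' @export
rocAuc <- function(labels, scores) {
  pos <- asPositive(labels)
  if (length(pos) != length(scores)) stop("labels and scores lengths differ")
  if (any(!is.finite(scores))) stop("scores must be finite")
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

asPositive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) return(labels == "PCa")
  labels > 0
}

#' Dice coefficient and intersection-over-union of two binary masks
#'
#' `dice = 2|intersection| / (|A| + |B|)`,
#' `iou = |intersection| / |union|`. Two empty
#' masks are a perfect (if vacuous) agreement: both measures are defined as 1
#' with attribute `bothEmpty = TRUE`.
#'
#' @param maskA,maskB Logical (or 0/1) arrays of identical shape.
#' @return Named numeric vector `c(dice, iou)`.
#' @examples
#' diceIou(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
diceIou <- function(maskA, maskB) {
  if (!identical(dim(maskA) %||% length(maskA), dim(maskB) %||% length(maskB)))
    stop("mask shapes differ")
  a <- as.logical(maskA); b <- as.logical(maskB)
  nA <- sum(a); nB <- sum(b)
  inter <- sum(a & b)
  if (nA + nB == 0) {
    out <- c(dice = 1, iou = 1)
    attr(out, "bothEmpty") <- TRUE
    return(out)
  }
  c(dice = 2 * inter / (nA + nB), iou = inter / (nA + nB - inter))
}

#' Round half away from zero for display
#'
#' Two-decimal presentation rounding used for reported percentages (e.g.
#' 82.605 -> 82.61, -0.005 -> -0.01), as opposed to R's banker's rounding.
#' A tiny relative guard absorbs binary floating-point representation error
#' so that values like `(93.24 + 71.96) / 2` round as their decimal value.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
roundHalfUp <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}
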