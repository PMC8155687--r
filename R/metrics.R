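#' Confusion summary
#'
#' Cross-tabulates true against predicted classes over a common level set.
#'
#' @param truth factor of true classes.
#' @param pred factor (or vector) of predicted classes.
#' @return an l-by-l integer matrix, rows = truth, columns = prediction,
#'   with class `confusion_summary`.
#' @export
confusion_summary <- function(truth, pred) {
  truth <- factor(truth)
  pred <- factor(pred, levels = union(levels(truth), levels(factor(pred))))
  truth <- factor(truth, levels = levels(pred))
  structure(unclass(table(truth = truth, pred = pred)),
            class = c("confusion_summary", "matrix"))
}

# ratio with the zero-denominator convention: 0/0 -> 0
.ratio0 <- function(num, den) if (den == 0) 0 else num / den

#' F2-measure from precision and negative precision
#'
#' Harmonic-style combination `2 p np / (p + np)` of the precision (positive
#' predictive value) and the "negative precision" (negative predictive
#' value). Unlike the classical F-measure it does not ignore the negative
#' class, which matters for imbalanced data. Defined as 0 when both inputs
#' are 0.
#'
#' @param precision,neg_precision values in `[0, 1]`.
#' @return a value in `[0, 1]`.
#' @export
#' @examples
#' f2_binary(0.8, 0.6)  # 0.6857143
f2_binary <- function(precision, neg_precision) {
  stopifnot(precision >= 0, precision <= 1,
            neg_precision >= 0, neg_precision <= 1)
  den <- precision + neg_precision
  ifelse(den == 0, 0, 2 * precision * neg_precision / den)
}

# Pairwise binary reduction used by the one-vs-one aggregates.
# Within the samples whose true class is i or j, a "positive" prediction is
# predicted class i and anything else counts as negative (a third-class
# prediction is a negative prediction). Reduces to the usual binary
# definitions when l = 2. All zero-denominator ratios are 0.
.pair_stats <- function(cm, i, j) {
  lev <- colnames(cm)
  tp <- cm[i, i]
  fp <- cm[j, i]
  fn <- sum(cm[i, ]) - tp
  tn <- sum(cm[j, ]) - fp
  list(
    precision = .ratio0(tp, tp + fp),
    neg_precision = .ratio0(tn, tn + fn),
    sensitivity = .ratio0(tp, tp + fn),
    specificity = .ratio0(tn, tn + fp)
  )
}

# Average a per-pair statistic over all unordered class pairs with the
# 2 / (l (l - 1)) weighting; pairs with no test samples contribute 0.
.pair_average <- function(cm, fun) {
  l <- ncol(cm)
  pairs <- utils::combn(l, 2L)
  vals <- apply(pairs, 2L, function(p) fun(.pair_stats(cm, p[1L], p[2L])))
  mean(vals)
}

#' Multiclass F2-measure
#'
#' One-vs-one aggregation: the classification problem over `l` classes is
#' decomposed into `l (l - 1) / 2` class pairs; for each pair the F2 term
#' `p * np / (p + np)` is computed over the test samples whose true class is
#' in the pair, and the terms are averaged with weight `4 / (l (l - 1))`.
#' With `l = 2` this equals [f2_binary()] on the single pair. Pairs with a
#' zero denominator contribute 0.
#'
#' @param confusion a `confusion_summary` (or truth/pred pair via `...`).
#' @return a value in `[0, 1]`.
#' @export
f2_multiclass <- function(confusion) {
  stopifnot(inherits(confusion, "confusion_summary"))
  if (ncol(confusion) < 2L) stop("need at least 2 classes")
  # 4/(l(l-1)) * sum of p*np/(p+np) over pairs reduces to the mean of the
  # pairwise binary F2 values
  .pair_average(confusion, function(s) {
    f2_binary(s$precision, s$neg_precision)
  })
}

#' Sensitivity and specificity
#'
#' Binary: `TP / (TP + FN)` and `TN / (TN + FP)`, with the first class level
#' as the positive class. Multiclass: one-vs-one pairwise values averaged
#' with the same `2 / (l (l - 1))` weighting as the multiclass F2.
#' Zero-denominator ratios are 0.
#'
#' @param confusion a `confusion_summary`.
#' @return named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sensitivity_specificity <- function(confusion) {
  stopifnot(inherits(confusion, "confusion_summary"))
  if (ncol(confusion) < 2L) stop("need at least 2 classes")
  c(sensitivity = .pair_average(confusion, function(s) s$sensitivity),
    specificity = .pair_average(confusion, function(s) s$specificity))
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a randomly chosen positive sample receives a higher
#' score than a randomly chosen negative one, with ties counted half —
#' computed from midranks.
#'
#' @param scores numeric decision values, larger = more positive.
#' @param truth factor or logical of true classes.
#' @param positive the positive class (default: first factor level).
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
#' @examples
#' rank_auc(c(0.9, 0.8, 0.3), factor(c("p", "n", "p"), levels = c("p", "n")))
rank_auc <- function(scores, truth, positive = NULL) {
  truth <- factor(truth)
  if (is.null(positive)) positive <- levels(truth)[1L]
  pos <- truth == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass AUC (MAUC)
#'
#' Mean of pairwise one-vs-one rank AUCs in the style of Hand and Till: for
#' each unordered class pair (i, j), restricted to test samples of those two
#' classes, `A(i, j) = (A(i|j) + A(j|i)) / 2` where `A(i|j)` ranks by the
#' class-i score. Pairs missing a class in the test set are skipped and the
#' average renormalized over the remaining pairs.
#'
#' @param scores numeric matrix, samples x classes, columns named by class.
#' @param truth factor of true classes.
#' @return MAUC in `[0, 1]`.
#' @export
multiclass_auc <- function(scores, truth) {
  truth <- factor(truth)
  lev <- levels(truth)
  if (is.null(colnames(scores)) || !all(lev %in% colnames(scores))) {
    stop("scores must have one named column per class")
  }
  pairs <- utils::combn(length(lev), 2L)
  vals <- apply(pairs, 2L, function(p) {
    i <- lev[p[1L]]; j <- lev[p[2L]]
    sub <- truth %in% c(i, j)
    if (!any(truth[sub] == i) || !any(truth[sub] == j)) return(NA_real_)
    a_ij <- rank_auc(scores[sub, i], truth[sub], positive = i)
    a_ji <- rank_auc(scores[sub, j], truth[sub], positive = j)
    (a_ij + a_ji) / 2
  })
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' All evaluation metrics for one test fold
#'
#' @param truth factor of true classes.
#' @param pred predicted classes.
#' @param scores optional samples-by-classes decision-value matrix for the
#'   AUC/MAUC; when absent the AUC is `NA`.
#' @return named vector with `acc`, `auc`, `f2`, `sensitivity`,
#'   `specificity`.
#' @export
classification_metrics <- function(truth, pred, scores = NULL) {
  truth <- factor(truth)
  cm <- confusion_summary(truth, pred)
  # restrict to the true class set; predictions outside it keep their column
  auc <- NA_real_
  if (!is.null(scores)) {
    auc <- if (nlevels(truth) == 2L) {
      rank_auc(scores[, levels(truth)[1L]], truth)
    } else {
      multiclass_auc(scores, truth)
    }
  }
  ss <- sensitivity_specificity(cm)
  c(acc = mean(as.character(truth) == as.character(pred)),
    auc = auc,
    f2 = f2_multiclass(cm),
    ss)
}
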