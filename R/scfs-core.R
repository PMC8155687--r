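#' Feature discernibility
#'
#' The discernibility of a feature is its sample standard deviation (with
#' the m-1 denominator) over all samples: a feature whose values vary a lot
#' across samples is presumed to separate the underlying groups better. It
#' is zero exactly for constant features.
#'
#' @param x samples-by-features numeric matrix without missing values,
#'   m >= 2 samples.
#' @return named numeric vector of length `ncol(x)`.
#' @export
#' @examples
#' compute_discernibility(cbind(a = c(0, 2), b = c(1, 1)))
compute_discernibility <- function(x) {
  validate_feature_matrix(x, allow_missing = FALSE)
  apply(x, 2L, stats::sd)
}

#' Absolute cosine similarity between features
#'
#' Computes the d-by-d matrix `C` with
#' `c_ij = |f_i . f_j| / (||f_i|| ||f_j||)`, the absolute cosine of the
#' angle between feature columns. Entries lie in `[0, 1]`; the diagonal is 1
#' for every feature with non-zero norm. Any entry involving a zero-norm
#' feature is defined as 0 (such features also have zero discernibility, so
#' their score is 0 regardless).
#'
#' @param x samples-by-features numeric matrix without missing values.
#' @return symmetric `ncol(x)` x `ncol(x)` matrix.
#' @export
compute_similarity <- function(x) {
  validate_feature_matrix(x, allow_missing = FALSE)
  nrm <- sqrt(colSums(x^2))
  C <- abs(crossprod(x))
  denom <- outer(nrm, nrm)
  zero <- nrm == 0
  denom[zero, ] <- 1
  denom[, zero] <- 1
  C <- C / denom
  C[zero, ] <- 0
  C[, zero] <- 0
  # guard against rounding pushing |cos| just past 1
  C[C > 1] <- 1
  diag(C)[!zero] <- 1
  C
}

# For every feature, the similarity that drives its independence:
#  * the (unique) top-discernibility feature uses min_{k != i} c_ik, so the
#    max-form of the defining equations is attained;
#  * every other feature uses max over its "higher set" H_i, the features
#    with strictly higher discernibility; features tied at the maximum fall
#    back to tied features of lower column index so H_i is never empty.
# Returned as a list(c = numeric(d), top = index of the argmax feature).
.reference_similarity <- function(dis, C) {
  d <- length(dis)
  if (d < 2L) stop("independence needs at least 2 features")
  if (nrow(C) != d || ncol(C) != d) stop("dis / C dimension mismatch")
  top <- which.max(dis)  # lowest index among tied maxima
  m <- numeric(d)
  running <- rep(-Inf, d)  # running[i] = max c_ik over processed features k
  mx <- max(dis)
  for (v in sort(unique(dis), decreasing = TRUE)) {
    grp <- which(dis == v)  # ascending index order
    if (v == mx) {
      # tied maxima: prefix max over lower-index members of the tie group
      prefix <- rep(-Inf, d)
      for (i in grp) {
        m[i] <- max(prefix[i], running[i])
        prefix <- pmax(prefix, C[i, ])
      }
    } else {
      m[grp] <- running[grp]
    }
    for (i in grp) running <- pmax(running, C[i, ])
  }
  m[top] <- min(C[top, -top])
  list(c = m, top = top)
}

#' Feature independence
#'
#' Quantifies how non-redundant each feature is, from the absolute cosine
#' similarity to the features that out-rank it in discernibility. Writing
#' `c*` for the maximum similarity between feature i and its
#' higher-discernibility set (for the single top-discernibility feature,
#' the *minimum* similarity to any other feature, so that the top feature
#' gets the maximal independence its neighbourhood allows), the variants are
#'
#' * `"scefs"` (exponential): `ind_i = exp(-c*)`, in `[exp(-1), 1]`;
#' * `"scrfs"` (reciprocal): `ind_i = 1 / c*`, with `c*` clamped below at
#'   `eps` so orthogonal features get large finite independence; `>= 1`;
#' * `"scafs"` (anti-cosine): `ind_i = 1 - c*`, in `[0, 1]`.
#'
#' Ties: the argmax of discernibility is the lowest-index feature among tied
#' maxima; other tied-maximum features compare against tied features of
#' lower index, so every feature has a non-empty reference set.
#'
#' @param dis discernibility vector from [compute_discernibility()].
#' @param C similarity matrix from [compute_similarity()], same features.
#' @param variant `"scefs"`, `"scrfs"` or `"scafs"`.
#' @param eps lower clamp for the reciprocal variant.
#' @return numeric vector of independence values.
#' @export
compute_independence <- function(dis, C,
                                 variant = c("scefs", "scrfs", "scafs"),
                                 eps = 1e-12) {
  variant <- match.arg(variant)
  ref <- .reference_similarity(dis, C)
  cc <- ref$c
  out <- switch(variant,
    scefs = exp(-cc),
    scrfs = 1 / pmax(cc, eps),
    scafs = 1 - cc
  )
  names(out) <- names(dis)
  out
}

#' Feature scores and ranking
#'
#' The score of a feature is `dis_i * ind_i` — geometrically, the area of
#' the rectangle under the feature's point in the decision plot. Features
#' are ranked by descending score; ties are broken by ascending column
#' index, so the ranking is deterministic.
#'
#' @param dis discernibility vector.
#' @param ind independence vector of the same length.
#' @param feature_ids optional identifiers (defaults to names of `dis`).
#' @return a data frame with columns `feature_id`, `dis`, `ind`, `score`,
#'   `rank` (1 = best), in original feature order.
#' @export
compute_scores <- function(dis, ind, feature_ids = names(dis)) {
  if (length(dis) != length(ind)) stop("dis and ind length mismatch")
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_along(dis))
  score <- dis * ind
  ord <- order(-score, seq_along(score))
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  data.frame(feature_id = feature_ids, dis = as.numeric(dis),
             ind = as.numeric(ind), score = as.numeric(score),
             rank = rank, stringsAsFactors = FALSE)
}

#' Select the top-k features
#'
#' Runs the full chain — discernibility, similarity, independence, score,
#' rank — on the matrix as given and returns the `k` best-scoring features.
#' The selector is fully unsupervised and uses the values it is handed;
#' impute missing data first (see [impute_missing()]).
#'
#' @param x samples-by-features numeric matrix without missing values.
#' @param k number of features to select, `1 <= k <= ncol(x)`.
#' @param variant `"scefs"`, `"scrfs"` or `"scafs"`.
#' @return an object of class `scfs_selection`: a list with `selected`
#'   (feature ids ordered by rank), `k`, `variant`, and `score_table`
#'   (the full ranking from [compute_scores()]).
#' @export
#' @examples
#' toy <- generate_toy(seed = 1)
#' sel <- select_features(toy$x, k = 5, variant = "scefs")
#' sel$selected
select_features <- function(x, k, variant = c("scefs", "scrfs", "scafs")) {
  variant <- match.arg(variant)
  x <- .default_dimnames(x)
  validate_feature_matrix(x, allow_missing = FALSE)
  d <- ncol(x)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1 || k > d ||
      k != floor(k)) {
    stop("k must be an integer in [1, ", d, "]")
  }
  dis <- compute_discernibility(x)
  C <- compute_similarity(x)
  ind <- compute_independence(dis, C, variant)
  tab <- compute_scores(dis, ind, colnames(x))
  sel <- tab$feature_id[order(tab$rank)][seq_len(k)]
  structure(list(selected = sel, k = as.integer(k), variant = variant,
                 score_table = tab),
            class = "scfs_selection")
}

#' @export
print.scfs_selection <- function(x, ...) {
  cat(sprintf("%s selection: top %d of %d features\n",
              toupper(x$variant), x$k, nrow(x$score_table)))
  top <- x$score_table[order(x$score_table$rank), ][seq_len(x$k), ]
  print(top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Decision-plot coordinates
#'
#' Exports the two scatter plots used to inspect a ranking: every feature as
#' a point with discernibility on x and independence on y (the selected
#' subset sits in the upper-right corner), and the score curve with rank
#' position on x and score on y.
#'
#' @param table a score table from [compute_scores()], or an
#'   `scfs_selection`.
#' @return a list with data frames `features` (`feature_id`, `dis`, `ind`)
#'   and `scores` (`position`, `feature_id`, `score`, non-increasing).
#' @export
decision_plot_coordinates <- function(table) {
  if (inherits(table, "scfs_selection")) table <- table$score_table
  ord <- order(table$rank)
  list(
    features = data.frame(feature_id = table$feature_id, dis = table$dis,
                          ind = table$ind, stringsAsFactors = FALSE),
    scores = data.frame(position = seq_len(nrow(table)),
                        feature_id = table$feature_id[ord],
                        score = table$score[ord], stringsAsFactors = FALSE)
  )
}

#' Suggest a subset size from the score curve
#'
#' Heuristic extension (not part of the core ranking definition): picks the
#' cut just before the largest relative drop on the sorted score curve,
#' mimicking the visual "upper-right corner is far from the rest" reading of
#' the decision plot. Use as a starting point only; `k` remains an explicit
#' input everywhere else.
#'
#' @param table score table or `scfs_selection`.
#' @param max_k largest subset size considered.
#' @return a single integer suggestion for `k`.
#' @export
suggest_k <- function(table, max_k = 30L) {
  if (inherits(table, "scfs_selection")) table <- table$score_table
  s <- sort(table$score, decreasing = TRUE)
  n <- min(max_k + 1L, length(s))
  if (n < 2L) return(1L)
  s <- s[seq_len(n)]
  denom <- pmax(s[-1L], .Machine$double.eps)
  which.max(s[-n] / denom - 1)
}
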