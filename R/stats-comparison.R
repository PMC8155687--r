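#' Per-dataset ranks of algorithms
#'
#' Ranks algorithms within each dataset row, 1 = best (highest value),
#' with average ranks for ties, so each row sums to `M (M + 1) / 2`.
#'
#' @param perf numeric matrix, N datasets x M algorithms, higher better,
#'   no missing cells.
#' @return matrix of the same shape holding the ranks.
#' @export
rank_algorithms <- function(perf) {
  perf <- as.matrix(perf)
  if (anyNA(perf)) {
    bad <- which(is.na(perf), arr.ind = TRUE)[1L, ]
    stop("missing cell in performance matrix (dataset ",
         if (is.null(rownames(perf))) bad[1L] else rownames(perf)[bad[1L]],
         ", algorithm ",
         if (is.null(colnames(perf))) bad[2L] else colnames(perf)[bad[2L]],
         "); exclude incomplete algorithms before ranking")
  }
  t(apply(perf, 1L, function(r) rank(-r, ties.method = "average")))
}

#' Friedman rank test across algorithms and datasets
#'
#' Classical Friedman chi-square over an N-datasets-by-M-algorithms
#' performance matrix:
#' `chi2 = 12 N / (M (M + 1)) * (sum_j Rbar_j^2 - M (M + 1)^2 / 4)`,
#' with average ranks for ties, `df = M - 1`, and the p-value from the
#' upper chi-square tail. The statistic depends on the data only through
#' within-dataset ranks, so it is invariant to any strictly monotone
#' transform of each dataset's row.
#'
#' @param perf numeric matrix, datasets x algorithms, higher better.
#' @return list with `statistic`, `df`, `p.value`, `mean_ranks`,
#'   `rank_matrix`, `M`, `N`.
#' @export
friedman_rank_test <- function(perf) {
  perf <- as.matrix(perf)
  M <- ncol(perf)
  N <- nrow(perf)
  if (M < 3L) stop("Friedman test needs at least 3 algorithms")
  if (N < 2L) stop("Friedman test needs at least 2 datasets")
  rk <- rank_algorithms(perf)
  rbar <- colMeans(rk)
  chi2 <- 12 * N / (M * (M + 1)) * (sum(rbar^2) - M * (M + 1)^2 / 4)
  chi2 <- max(chi2, 0)
  list(statistic = chi2, df = M - 1L,
       p.value = stats::pchisq(chi2, M - 1L, lower.tail = FALSE),
       mean_ranks = rbar, rank_matrix = rk, M = M, N = N)
}

#' Nemenyi critical difference
#'
#' `CD = q_alpha * sqrt(M (M + 1) / (6 N))`: two algorithms among M,
#' compared over N datasets, perform significantly differently when their
#' mean ranks differ by more than CD. The constant `q_alpha` is the
#' Studentized-range quantile at infinite degrees of freedom divided by
#' `sqrt(2)`; it is computed from [stats::qtukey()] unless supplied
#' explicitly (e.g. a textbook value such as 3.219 for M = 11 at
#' alpha = 0.05).
#'
#' @param M number of algorithms.
#' @param N number of datasets.
#' @param alpha significance level (used when `q_alpha` is `NULL`).
#' @param q_alpha optional explicit critical constant.
#' @return list with `cd`, `q_alpha`, `alpha`, `M`, `N`.
#' @export
#' @examples
#' nemenyi_cd(M = 11, N = 18, q_alpha = 3.219)$cd  # 3.5587
nemenyi_cd <- function(M, N, alpha = 0.05, q_alpha = NULL) {
  if (M < 2L || N < 1L) stop("need M >= 2 algorithms and N >= 1 datasets")
  if (is.null(q_alpha)) q_alpha <- nemenyi_q_alpha(M, alpha)
  if (q_alpha <= 0) stop("q_alpha must be positive")
  list(cd = q_alpha * sqrt(M * (M + 1) / (6 * N)),
       q_alpha = q_alpha, alpha = alpha, M = M, N = N)
}

#' Nemenyi critical constant
#'
#' @param M number of algorithms.
#' @param alpha significance level.
#' @return `qtukey(1 - alpha, M, Inf) / sqrt(2)`.
#' @export
nemenyi_q_alpha <- function(M, alpha = 0.05) {
  stats::qtukey(1 - alpha, M, Inf) / sqrt(2)
}

#' Pairwise significance calls from mean ranks
#'
#' @param mean_ranks named vector of mean ranks (from
#'   [friedman_rank_test()]).
#' @param cd a [nemenyi_cd()] result or a single positive number.
#' @return symmetric logical M x M matrix, `TRUE` where the mean-rank
#'   difference exceeds CD; diagonal `FALSE`.
#' @export
pairwise_significance <- function(mean_ranks, cd) {
  if (is.list(cd)) cd <- cd$cd
  out <- abs(outer(mean_ranks, mean_ranks, "-")) > cd
  diag(out) <- FALSE
  out
}

#' Full algorithm comparison report
#'
#' Friedman test followed by the Nemenyi post-hoc critical difference and
#' the pairwise significance matrix.
#'
#' @inheritParams friedman_rank_test
#' @inheritParams nemenyi_cd
#' @return list of class `scfs_comparison` with elements `friedman`, `cd`,
#'   `significant`, `mean_ranks`.
#' @export
compare_algorithms <- function(perf, alpha = 0.05, q_alpha = NULL) {
  fr <- friedman_rank_test(perf)
  cd <- nemenyi_cd(fr$M, fr$N, alpha = alpha, q_alpha = q_alpha)
  structure(list(friedman = fr, cd = cd,
                 significant = pairwise_significance(fr$mean_ranks, cd),
                 mean_ranks = fr$mean_ranks),
            class = "scfs_comparison")
}

#' @export
print.scfs_comparison <- function(x, ...) {
  cat(sprintf("Friedman chi-square = %.4g, df = %d, p = %.4g\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p.value))
  cat(sprintf("Nemenyi CD = %.4f (q = %.4g, M = %d, N = %d)\n",
              x$cd$cd, x$cd$q_alpha, x$cd$M, x$cd$N))
  cat("mean ranks:\n")
  print(round(sort(x$mean_ranks), 3))
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' @param x an `scfs_comparison`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(x, path) {
  stopifnot(inherits(x, "scfs_comparison"))
  rep <- list(chi_square = x$friedman$statistic, df = x$friedman$df,
              p = x$friedman$p.value,
              mean_ranks = as.list(x$mean_ranks),
              cd = x$cd$cd, q_alpha = x$cd$q_alpha, alpha = x$cd$alpha,
              M = x$cd$M, N = x$cd$N,
              significant = x$significant)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
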