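#' Impute missing values
#'
#' Replaces `NA` entries by per-feature means. The default, fully
#' unsupervised mode uses the global (column) mean. The supervised
#' `"intra_class_mean"` mode uses the mean of the observed values of the same
#' feature within the sample's class, falling back to the feature's global
#' mean when a (class, feature) cell has no observed value. Observed values
#' are never changed.
#'
#' @param x samples-by-features numeric matrix, `NA` marking missing entries.
#' @param y class labels (required for `mode = "intra_class_mean"`).
#' @param mode `"global_mean"` (default) or `"intra_class_mean"`.
#' @param reference optional complete matrix (same features) whose column
#'   means are used instead of `x`'s own, e.g. training-fold statistics
#'   applied to a test fold; only meaningful with `mode = "global_mean"`.
#' @return `x` with no missing values.
#' @export
impute_missing <- function(x, y = NULL,
                           mode = c("global_mean", "intra_class_mean"),
                           reference = NULL) {
  mode <- match.arg(mode)
  validate_feature_matrix(x)
  if (!anyNA(x)) return(x)
  all_missing <- colSums(!is.na(x)) == 0L
  if (any(all_missing) && is.null(reference)) {
    stop("feature(s) entirely missing: ",
         paste(utils::head(colnames(x)[all_missing], 5L), collapse = ", "))
  }
  global <- if (is.null(reference)) {
    colMeans(x, na.rm = TRUE)
  } else {
    if (ncol(reference) != ncol(x)) stop("reference feature count mismatch")
    colMeans(reference, na.rm = TRUE)
  }
  if (mode == "global_mean") {
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- global[idx[, 2L]]
    return(x)
  }
  if (is.null(y)) stop("intra_class_mean imputation requires labels")
  y <- .match_labels(x, y)
  for (cl in levels(y)) {
    rows <- which(y == cl)
    cls_mean <- colMeans(x[rows, , drop = FALSE], na.rm = TRUE)
    cls_mean[is.nan(cls_mean)] <- global[is.nan(cls_mean)]
    sub <- x[rows, , drop = FALSE]
    idx <- which(is.na(sub), arr.ind = TRUE)
    sub[idx] <- cls_mean[idx[, 2L]]
    x[rows, ] <- sub
  }
  x
}

#' Per-feature min-max normalization
#'
#' Maps every feature to `(f - min(f)) / (max(f) - min(f))` so that, within
#' the fitting matrix, non-constant features span exactly `[0, 1]`. Constant
#' features map to 0 everywhere (they carry no distinguishing power, and this
#' keeps their downstream discernibility at zero). When `reference` is given
#' its per-feature minima and maxima are used instead — the intended use is
#' fitting on a training fold and applying to a test fold — and values
#' outside the reference range are *not* clipped.
#'
#' @param x samples-by-features numeric matrix without missing values.
#' @param reference optional matrix supplying the min/max statistics.
#' @return the normalized matrix.
#' @export
#' @examples
#' minmax_normalize(cbind(a = c(0, 5, 10), b = c(4, 4, 4)))
minmax_normalize <- function(x, reference = NULL) {
  validate_feature_matrix(x, allow_missing = FALSE)
  src <- if (is.null(reference)) x else reference
  if (ncol(src) != ncol(x)) stop("reference feature count mismatch")
  if (anyNA(src)) stop("normalization statistics require complete data")
  mn <- apply(src, 2L, min)
  mx <- apply(src, 2L, max)
  rng <- mx - mn
  constant <- rng == 0
  rng[constant] <- 1  # arbitrary; constant columns are zeroed below
  out <- sweep(sweep(x, 2L, mn, "-"), 2L, rng, "/")
  out[, constant] <- 0
  out
}
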