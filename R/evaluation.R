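#' Stratified round-robin fold plan
#'
#' Builds the repeated cross-validation layout: per repeat, each class's
#' samples are shuffled and dealt one by one into the folds (round-robin
#' over a per-class random fold order), so per-class fold sizes differ by at
#' most one, every fold contains every class that has at least `n_folds`
#' members, and smaller classes are spread over distinct folds. Deterministic
#' given `seed`.
#'
#' @param y class labels, one per sample.
#' @param n_folds number of folds (default 10).
#' @param n_repeats number of repeats (default 5).
#' @param seed master seed; per-repeat shuffle seeds are derived from it.
#' @return an object of class `fold_plan`: list with `assignment` (samples
#'   x repeats integer matrix of fold ids), `n_folds`, `n_repeats`, `seed`,
#'   `repeat_seeds`, `y`.
#' @export
make_fold_plan <- function(y, n_folds = 10L, n_repeats = 5L, seed = 1L) {
  y <- factor(y)
  m <- length(y)
  if (any(table(y) < 1L)) stop("every class needs at least one sample")
  if (n_folds > m) stop("more folds than samples")
  if (n_folds < 2L) stop("need at least 2 folds")
  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  assignment <- matrix(NA_integer_, m, n_repeats)
  for (r in seq_len(n_repeats)) {
    set.seed(repeat_seeds[r])
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold_order <- sample.int(n_folds)
      assignment[idx, r] <- fold_order[(seq_along(idx) - 1L) %% n_folds + 1L]
    }
  }
  rownames(assignment) <- names(y)
  structure(list(assignment = assignment, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = seed,
                 repeat_seeds = repeat_seeds, y = y),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold plan: %d samples, %d folds x %d repeats (seed %s)\n",
              nrow(x$assignment), x$n_folds, x$n_repeats,
              format(x$seed)))
  invisible(x)
}

#' K-nearest-neighbour classifier adapter
#'
#' Deterministic Euclidean KNN used by the evaluation harness (default
#' K = 5, as in the protocol this package reproduces). Distance ties are
#' broken by smallest training-sample index; vote ties by the class with
#' the nearest supporting neighbour, then by class order. The per-class
#' decision value is the fraction of the K neighbours voting for that
#' class, which feeds the rank-based AUC.
#'
#' @param k number of neighbours.
#' @return an `scfs_classifier` with `fit(x, y)` and
#'   `predict(model, newx)` returning `list(class =, scores =)`.
#' @export
knn_classifier <- function(k = 5L) {
  structure(list(
    name = sprintf("knn%d", k),
    fit = function(x, y) list(x = x, y = factor(y), k = min(k, nrow(x))),
    predict = function(model, newx) {
      lev <- levels(model$y)
      kk <- model$k
      scores <- matrix(0, nrow(newx), length(lev),
                       dimnames = list(NULL, lev))
      cls <- character(nrow(newx))
      for (i in seq_len(nrow(newx))) {
        d2 <- colSums((t(model$x) - newx[i, ])^2)
        nn <- order(d2)[seq_len(kk)]  # order() breaks ties by index
        votes <- table(factor(model$y[nn], levels = lev))
        scores[i, ] <- as.numeric(votes) / kk
        best <- which(votes == max(votes))
        if (length(best) > 1L) {
          # among vote-tied classes, prefer the one with the closest
          # supporting neighbour
          nearest <- vapply(lev[best], function(cl) {
            min(d2[nn][model$y[nn] == cl])
          }, numeric(1L))
          best <- best[which.min(nearest)]
        }
        cls[i] <- lev[best]
      }
      list(class = factor(cls, levels = lev), scores = scores)
    }), class = "scfs_classifier")
}

#' Linear SVM classifier adapter
#'
#' Wraps [e1071::svm()] with a linear kernel and penalty `cost = 20` (the
#' protocol default). Per-class decision values are accumulated from the
#' one-vs-one decision values (each pairwise value is added to the winner's
#' class and subtracted from the loser's), giving continuous scores for the
#' AUC/MAUC without stochastic probability fitting.
#'
#' @param cost penalty parameter C.
#' @return an `scfs_classifier`.
#' @export
svm_classifier <- function(cost = 20) {
  structure(list(
    name = "svm_linear",
    fit = function(x, y) {
      e1071::svm(x, factor(y), kernel = "linear", cost = cost, scale = FALSE)
    },
    predict = function(model, newx) {
      pr <- stats::predict(model, newx, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      lev <- model$levels
      scores <- matrix(0, nrow(newx), length(lev),
                       dimnames = list(NULL, lev))
      for (j in seq_len(ncol(dv))) {
        pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1L]]
        scores[, pair[1L]] <- scores[, pair[1L]] + dv[, j]
        scores[, pair[2L]] <- scores[, pair[2L]] - dv[, j]
      }
      list(class = factor(as.character(pr), levels = lev), scores = scores)
    }), class = "scfs_classifier")
}

#' Run the repeated cross-validation protocol
#'
#' For every repeat and fold of `plan`: the training fold is imputed
#' (global mean) and the selector is run on it *alone* to rank features
#' (no test-fold information enters the selection); min-max normalization
#' is fitted on the training fold and applied, unclipped, to both folds
#' before the classifier sees them; for each requested subset size `k` the
#' classifier is trained on the top-k features and all metrics are computed
#' on the held-out fold. The selector scores the imputed, unnormalized
#' training data — min-max rescaling is applied to classifier inputs only
#' (see the package vignette for the rationale).
#'
#' @param x samples-by-features matrix (may contain `NA`).
#' @param y class labels.
#' @param plan a [make_fold_plan()] object for the same samples.
#' @param variant selector variant, or `"random"` for the random-subset
#'   baseline (features drawn per fold; seeded from the plan).
#' @param k_grid integer vector of subset sizes to evaluate.
#' @param classifier an `scfs_classifier` (default [knn_classifier()]).
#' @param dataset label recorded in the output rows.
#' @return long-format data frame: `dataset`, `variant`, `classifier`, `k`,
#'   `rep`, `fold`, `metric`, `value`.
#' @export
run_cv <- function(x, y, plan, variant = c("scefs", "scrfs", "scafs",
                                           "random"),
                   k_grid = 5L, classifier = knn_classifier(),
                   dataset = "data") {
  variant <- match.arg(variant)
  x <- .default_dimnames(x)
  validate_feature_matrix(x)
  y <- .match_labels(x, y)
  if (nrow(plan$assignment) != nrow(x)) stop("fold plan does not match x")
  stopifnot(inherits(classifier, "scfs_classifier"))
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L) || any(k_grid > ncol(x))) stop("k out of range")
  kmax <- max(k_grid)
  rows <- list()
  for (r in seq_len(plan$n_repeats)) {
    for (f in seq_len(plan$n_folds)) {
      test_idx <- which(plan$assignment[, r] == f)
      train_idx <- which(plan$assignment[, r] != f)
      if (length(test_idx) == 0L) next
      xtr <- x[train_idx, , drop = FALSE]
      xte <- x[test_idx, , drop = FALSE]
      xtr <- impute_missing(xtr)
      if (anyNA(xte)) xte <- impute_missing(xte, reference = xtr)
      ranked <- if (variant == "random") {
        set.seed(plan$repeat_seeds[r] %% 1000003L * 1000L + f)
        colnames(x)[sample.int(ncol(x))]
      } else {
        sel <- select_features(xtr, k = kmax, variant = variant)
        sel$score_table$feature_id[order(sel$score_table$rank)]
      }
      ntr <- minmax_normalize(xtr)
      nte <- minmax_normalize(xte, reference = xtr)
      ytr <- y[train_idx]
      yte <- y[test_idx]
      for (k in k_grid) {
        feats <- ranked[seq_len(k)]
        model <- classifier$fit(ntr[, feats, drop = FALSE], ytr)
        pred <- classifier$predict(model, nte[, feats, drop = FALSE])
        met <- classification_metrics(yte, pred$class, pred$scores)
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = dataset, variant = variant, classifier = classifier$name,
          k = k, rep = r, fold = f, metric = names(met),
          value = as.numeric(met), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize cross-validation records
#'
#' Means are taken over all repeat-fold results; the reported standard
#' deviation is that of the per-repeat means (the spread across the 5 runs
#' of the 10-fold protocol, i.e. the error bars of a repeat-level
#' comparison).
#'
#' @param records long-format output of [run_cv()] (rows from several calls
#'   may be concatenated).
#' @return data frame with one row per (dataset, variant, classifier, k,
#'   metric) holding `mean` and `sd_repeats`.
#' @export
summarize_cv <- function(records) {
  key <- c("dataset", "variant", "classifier", "k", "metric")
  rep_means <- stats::aggregate(value ~ dataset + variant + classifier +
                                  k + metric + rep,
                                data = records, FUN = mean, na.rm = TRUE)
  overall <- stats::aggregate(value ~ dataset + variant + classifier +
                                k + metric,
                              data = records, FUN = mean, na.rm = TRUE)
  names(overall)[names(overall) == "value"] <- "mean"
  sds <- stats::aggregate(value ~ dataset + variant + classifier + k +
                            metric,
                          data = rep_means, FUN = stats::sd)
  names(sds)[names(sds) == "value"] <- "sd_repeats"
  merge(overall, sds, by = key, sort = TRUE)
}
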