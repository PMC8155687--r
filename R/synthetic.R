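#' Generate a two-class toy expression matrix with planted features
#'
#' Draws two Gaussian classes (defaults: 20 samples each, 100 features)
#' with a small planted set of informative features that differ in class
#' mean (centered offsets of minus/plus `offset / 2`) and have a larger
#' standard deviation than the noise features. Under the default `"block"`
#' covariance the features form co-expression modules: the matrix is
#' partitioned into `n_blocks` groups sharing a latent factor with loading
#' `sqrt(rho)`, and each planted feature anchors one module, so noise
#' features are correlated with a higher-variance informative neighbour —
#' the redundancy structure the selector is designed to exploit.
#' `"diagonal"` gives fully independent features instead.
#'
#' @param n_per_class integer vector of two class sizes.
#' @param d number of features.
#' @param n_informative number of planted informative features (may be 0).
#' @param offset difference in class means on informative features.
#' @param sd_informative,sd_noise standard deviations of informative and
#'   noise features.
#' @param cov_structure `"block"` (default) or `"diagonal"`.
#' @param rho within-module latent-factor loading for `"block"`.
#' @param n_blocks number of modules (default `max(n_informative, 5)`).
#' @param seed RNG seed; output is bit-identical across runs for a fixed
#'   seed.
#' @return list with `x` (samples x features matrix, ids `s1..`/`f1..`),
#'   `y` (factor of classes `"c1"`, `"c2"`), `planted` (ids of the
#'   informative features), and the generator settings used.
#' @export
#' @examples
#' toy <- generate_toy(seed = 42)
#' dim(toy$x)
generate_toy <- function(n_per_class = c(20L, 20L), d = 100L,
                         n_informative = 5L, offset = 3,
                         sd_informative = 2, sd_noise = 1,
                         cov_structure = c("block", "diagonal"),
                         rho = 0.5, n_blocks = NULL, seed = 1L) {
  cov_structure <- match.arg(cov_structure)
  stopifnot(length(n_per_class) == 2L, all(n_per_class >= 1L),
            n_informative >= 0L, n_informative <= d,
            sd_informative > 0, sd_noise > 0, rho >= 0, rho < 1)
  set.seed(seed)
  m <- sum(n_per_class)
  y <- factor(rep(c("c1", "c2"), n_per_class))
  planted_idx <- if (n_informative > 0L) sort(sample.int(d, n_informative))
                 else integer(0)
  shift <- ifelse(y == "c1", -offset / 2, offset / 2)
  if (cov_structure == "block") {
    if (is.null(n_blocks)) n_blocks <- max(n_informative, 5L)
    n_blocks <- min(n_blocks, d)
    # random module membership; each planted feature anchors its own module
    bid <- sample(rep(seq_len(n_blocks), length.out = d))
    if (n_informative > 0L) {
      bid[planted_idx] <- rep(seq_len(n_blocks),
                              length.out = n_informative)
    }
    z_block <- matrix(stats::rnorm(m * n_blocks), m, n_blocks)
    x <- matrix(0, m, d)
    for (j in seq_len(d)) {
      latent <- sqrt(rho) * z_block[, bid[j]] +
        sqrt(1 - rho) * stats::rnorm(m)
      x[, j] <- if (j %in% planted_idx) {
        shift + sd_informative * latent
      } else {
        sd_noise * latent
      }
    }
  } else {
    x <- matrix(stats::rnorm(m * d, sd = sd_noise), m, d)
    for (j in planted_idx) {
      x[, j] <- shift + stats::rnorm(m, sd = sd_informative)
    }
  }
  dimnames(x) <- list(paste0("s", seq_len(m)), paste0("f", seq_len(d)))
  names(y) <- rownames(x)
  list(x = x, y = y, planted = colnames(x)[planted_idx],
       n_per_class = n_per_class, d = d, n_informative = n_informative,
       offset = offset, sd_informative = sd_informative,
       sd_noise = sd_noise, cov_structure = cov_structure, rho = rho,
       seed = seed)
}

#' Bootstrap (or holdout) train/test split
#'
#' `"bootstrap"`: per class, draws the stated number of training samples
#' *with replacement*; the test set is the out-of-bag samples — class
#' members never drawn. A sample identity therefore never appears in both
#' sets. `"holdout"` draws without replacement and tests on the remainder.
#'
#' @param x samples-by-features matrix.
#' @param y class labels.
#' @param train_sizes per-class training draw counts, in class-level order
#'   (default: 70 percent of each class, rounded).
#' @param scheme `"bootstrap"` (default) or `"holdout"`.
#' @param seed RNG seed.
#' @return list with `x_train`, `y_train`, `x_test`, `y_test`,
#'   `train_index` (with repeats under bootstrap) and `test_index`.
#' @export
bootstrap_split <- function(x, y, train_sizes = NULL,
                            scheme = c("bootstrap", "holdout"), seed = 1L) {
  scheme <- match.arg(scheme)
  x <- .default_dimnames(x)
  y <- .match_labels(x, y)
  sizes <- table(y)
  if (is.null(train_sizes)) train_sizes <- pmax(1L, round(0.7 * sizes))
  if (length(train_sizes) != nlevels(y)) {
    stop("train_sizes must give one count per class")
  }
  set.seed(seed)
  train_index <- integer(0)
  test_index <- integer(0)
  for (i in seq_len(nlevels(y))) {
    idx <- which(y == levels(y)[i])
    n_tr <- train_sizes[i]
    if (scheme == "bootstrap") {
      draw <- idx[sample.int(length(idx), n_tr, replace = TRUE)]
      oob <- setdiff(idx, draw)
      if (length(oob) == 0L) {
        stop("class ", levels(y)[i], " has an empty out-of-bag test set; ",
             "use scheme = \"holdout\" or reduce train_sizes")
      }
      train_index <- c(train_index, draw)
      test_index <- c(test_index, oob)
    } else {
      if (n_tr >= length(idx)) stop("holdout train size must leave a test set")
      draw <- idx[sample.int(length(idx), n_tr)]
      train_index <- c(train_index, draw)
      test_index <- c(test_index, setdiff(idx, draw))
    }
  }
  x_train <- x[train_index, , drop = FALSE]
  # bootstrap draws repeat samples; keep identifiers unique
  rownames(x_train) <- make.unique(rownames(x_train))
  list(x_train = x_train, y_train = y[train_index],
       x_test = x[test_index, , drop = FALSE], y_test = y[test_index],
       train_index = train_index, test_index = test_index)
}

#' Generate a Gaussian multiclass dataset
#'
#' Supports the multiclass metrics: `l >= 2` classes with (possibly
#' imbalanced) sizes and distinct, equally spaced class means on the
#' informative features; independent Gaussian noise elsewhere.
#'
#' @param sizes integer vector of class sizes (`l = length(sizes)`).
#' @param d number of features.
#' @param n_informative number of informative features.
#' @param offset spacing of adjacent class means on informative features.
#' @param sd within-class standard deviation.
#' @param seed RNG seed.
#' @return list with `x`, `y` (factor `"c1"..`), `planted`.
#' @export
generate_multiclass <- function(sizes, d = 50L, n_informative = 5L,
                                offset = 3, sd = 1, seed = 1L) {
  l <- length(sizes)
  stopifnot(l >= 2L, all(sizes >= 1L), n_informative <= d)
  set.seed(seed)
  m <- sum(sizes)
  y <- factor(rep(paste0("c", seq_len(l)), sizes))
  x <- matrix(stats::rnorm(m * d, sd = sd), m, d)
  planted_idx <- if (n_informative > 0L) sort(sample.int(d, n_informative))
                 else integer(0)
  centered <- (as.integer(y) - (l + 1) / 2) * offset
  for (j in planted_idx) x[, j] <- x[, j] + centered
  dimnames(x) <- list(paste0("s", seq_len(m)), paste0("f", seq_len(d)))
  names(y) <- rownames(x)
  list(x = x, y = y, planted = colnames(x)[planted_idx])
}
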