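# Independent, deliberately naive reference implementations used to check
# the vectorized package code. These mirror the defining formulas with
# literal loops and are kept free of any package internals.

oracle_discernibility <- function(x) {
  m <- nrow(x)
  vapply(seq_len(ncol(x)), function(i) {
    mu <- sum(x[, i]) / m
    sqrt(sum((x[, i] - mu)^2) / (m - 1))
  }, numeric(1L))
}

oracle_similarity <- function(x) {
  d <- ncol(x)
  C <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      ni <- sqrt(sum(x[, i]^2))
      nj <- sqrt(sum(x[, j]^2))
      C[i, j] <- if (ni == 0 || nj == 0) 0 else {
        min(abs(sum(x[, i] * x[, j])) / (ni * nj), 1)
      }
    }
  }
  C
}

# literal case split of the three independence definitions, with the same
# documented tie conventions (argmax = lowest index; tied maxima fall back
# to tied lower-index features)
oracle_independence <- function(dis, C, variant, eps = 1e-12) {
  d <- length(dis)
  form <- switch(variant,
    scefs = function(c) exp(-c),
    scrfs = function(c) 1 / max(c, eps),
    scafs = function(c) 1 - c)
  top <- which(dis == max(dis))[1L]
  ind <- numeric(d)
  for (i in seq_len(d)) {
    if (i == top) {
      ind[i] <- max(vapply(setdiff(seq_len(d), i),
                           function(k) form(C[i, k]), numeric(1L)))
    } else {
      H <- which(dis > dis[i])
      if (length(H) == 0L) H <- which(dis == dis[i] & seq_len(d) < i)
      ind[i] <- min(vapply(H, function(k) form(C[i, k]), numeric(1L)))
    }
  }
  ind
}

oracle_scores <- function(x, variant) {
  dis <- oracle_discernibility(x)
  oracle_independence(dis, oracle_similarity(x), variant) * dis
}

# literal one-vs-one multiclass F2 built directly from label vectors
oracle_f2_multiclass <- function(truth, pred, classes) {
  l <- length(classes)
  total <- 0
  for (i in seq_len(l - 1L)) {
    for (j in seq(i + 1L, l)) {
      sub <- truth %in% classes[c(i, j)]
      tt <- truth[sub]
      pp <- pred[sub]
      tp <- sum(tt == classes[i] & pp == classes[i])
      fp <- sum(tt == classes[j] & pp == classes[i])
      tn <- sum(tt == classes[j] & pp != classes[i])
      fn <- sum(tt == classes[i] & pp != classes[i])
      p <- if (tp + fp == 0) 0 else tp / (tp + fp)
      np <- if (tn + fn == 0) 0 else tn / (tn + fn)
      if (p + np > 0) total <- total + p * np / (p + np)
    }
  }
  4 / (l * (l - 1)) * total
}

# exhaustive pair-counting AUC, ties counted half
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

random_feature_matrix <- function(m, d) {
  matrix(stats::rnorm(m * d), m, d,
         dimnames = list(paste0("s", seq_len(m)), paste0("f", seq_len(d))))
}
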