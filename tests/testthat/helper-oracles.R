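# Independent brute-force oracles used to cross-check the package's
# vectorised implementations, plus small fixture builders.

# Element-by-element min-max normalisation, straight from the definition.
oracle_minmax <- function(fit_mat, new_mat) {
  out <- new_mat
  for (j in seq_len(ncol(fit_mat))) {
    lo <- min(fit_mat[, j]); hi <- max(fit_mat[, j])
    for (i in seq_len(nrow(new_mat))) {
      out[i, j] <- (new_mat[i, j] - lo) / (hi - lo)
    }
  }
  out
}

# Loop-based three-sigma flags with population sd over finite entries.
oracle_sigma_flags <- function(v, k = 3) {
  fin <- v[is.finite(v)]
  m <- sum(fin) / length(fin)
  s <- sqrt(sum((fin - m)^2) / length(fin))
  flags <- logical(length(v))
  for (i in seq_along(v)) {
    flags[i] <- !is.finite(v[i]) || abs(v[i] - m) > k * s
  }
  flags
}

# Index-scanning neighbour-mean imputation.
oracle_impute <- function(v, mask) {
  out <- v
  for (i in which(mask)) {
    lo <- NA_real_; hi <- NA_real_
    j <- i - 1
    while (j >= 1) {
      if (!mask[j]) { lo <- v[j]; break }
      j <- j - 1
    }
    j <- i + 1
    while (j <= length(v)) {
      if (!mask[j]) { hi <- v[j]; break }
      j <- j + 1
    }
    out[i] <- mean(c(lo, hi), na.rm = TRUE)
  }
  out
}

# Textbook one-way ANOVA F for two groups (between/within mean squares).
oracle_anova_F <- function(a, b) {
  g <- mean(c(a, b))
  ssb <- length(a) * (mean(a) - g)^2 + length(b) * (mean(b) - g)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  (ssb / 1) / (ssw / (length(a) + length(b) - 2))
}

# Direct TP/FP/FN/TN counting for one-vs-rest metrics.
oracle_class_metrics <- function(y_true, y_pred, cl) {
  tp <- sum(y_true == cl & y_pred == cl)
  fp <- sum(y_true != cl & y_pred == cl)
  fn <- sum(y_true == cl & y_pred != cl)
  tn <- sum(y_true != cl & y_pred != cl)
  list(accuracy = (tp + tn) / length(y_true),
       precision = if (tp + fp == 0) 0 else tp / (tp + fp),
       recall = if (tp + fn == 0) 0 else tp / (tp + fn))
}

# A tiny well-formed dataset with hand-set coordinates.
tiny_dataset <- function(n = 6, seed = 1) {
  set.seed(seed)
  base <- template_face()$coords
  coords <- matrix(rep(base, each = n), n, 136) + runif(n * 136, -1, 1)
  mfd_data(coords, kss = rep_len(1:5, n),
           participant_id = rep_len(c("a", "b"), n))
}

# A small, strongly separable feature matrix with planted informative
# columns (used by selection and model tests).
planted_matrix <- function(n = 120, p = 10, informative = 2, n_classes = 3,
                           effect = 2, seed = 1) {
  set.seed(seed)
  y <- sample(seq_len(n_classes), n, replace = TRUE)
  x <- matrix(rnorm(n * p), n, p)
  for (j in seq_len(informative)) x[, j] <- x[, j] + effect * y
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}
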