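#' Split a dataset into training, validation and test parts
#'
#' Default fractions follow the published protocol: 70% training, 15%
#' validation, 15% test. With `stratified = TRUE` the label mix is
#' preserved in every part; with `group_by_participant = TRUE` whole
#' participants are assigned to one part (avoiding identity leakage at the
#' cost of exact fractions — see the package vignette for the caveat that
#' label-stratified splitting lets a participant appear in several parts).
#'
#' @param ds an `mfd_data` dataset, or any vector of labels when only
#'   indices are needed.
#' @param fractions length-3 numeric summing to 1.
#' @param stratified preserve label proportions per part (default `TRUE`).
#' @param group_by_participant assign whole participants to parts
#'   (default `FALSE`; requires `ds` to be an `mfd_data`).
#' @param seed integer seed; the same seed reproduces the same partition.
#' @return list of integer index vectors `train`, `validation`, `test`
#'   forming a partition of the rows.
#' @export
split_mfd <- function(ds, fractions = c(0.70, 0.15, 0.15),
                      stratified = TRUE, group_by_participant = FALSE,
                      seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3) {
    abort_mfd("fractions must be three numbers summing to 1",
              "mfd_validation_error")
  }
  y <- if (inherits(ds, "mfd_data")) ds$kss else ds
  n <- length(y)
  if (n < 20) abort_mfd("need at least 20 rows to split", "mfd_validation_error")
  assign_split <- function(idx) {
    # cumulative rounding keeps part sizes within one frame of the target
    b <- round(cumsum(fractions) * length(idx))
    list(train = idx[seq_len(b[1])],
         validation = idx[seq_len(b[2] - b[1]) + b[1]],
         test = idx[seq_len(length(idx) - b[2]) + b[2]])
  }
  out <- rng_local(seed, {
    if (group_by_participant) {
      if (!inherits(ds, "mfd_data")) {
        abort_mfd("participant-grouped splitting needs an mfd_data input",
                  "mfd_validation_error")
      }
      parts <- unique(ds$participant_id)
      parts <- parts[sample.int(length(parts))]
      sp <- assign_split(seq_along(parts))
      lapply(sp, function(i) which(ds$participant_id %in% parts[i]))
    } else if (stratified) {
      acc <- list(train = integer(0), validation = integer(0),
                  test = integer(0))
      for (cl in sort(unique(y))) {
        idx <- which(y == cl)
        idx <- idx[sample.int(length(idx))]
        sp <- assign_split(idx)
        acc <- Map(c, acc, sp)
      }
      lapply(acc, sort)
    } else {
      assign_split(sample.int(n))
    }
  })
  if (stratified && !group_by_participant &&
      !all(sort(unique(y)) %in% y[out$train])) {
    abort_mfd("a class is absent from the training part", "mfd_validation_error")
  }
  out
}

#' Classification accuracy
#' @param y_true,y_pred label vectors of equal length.
#' @return fraction of matching labels.
#' @export
accuracy <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  mean(y_true == y_pred)
}

#' Signed ordinal deviation
#'
#' Mean of (predicted level - true level) over samples. Levels are ordinal
#' (1 alert ... 5 extremely sleepy), so a positive deviation means the model
#' systematically over-predicts sleepiness and a negative one (as reference
#' results report for KNN) under-predicts; magnitude near 0 indicates an
#' unbiased classifier. Note this is a bias measure, not a spread measure.
#'
#' @param y_true,y_pred integer level vectors.
#' @return signed mean difference.
#' @export
deviation <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (!length(y_true)) abort_mfd("empty input", "mfd_validation_error")
  mean(as.numeric(y_pred) - as.numeric(y_true))
}

#' Confusion matrix (rows = reference, columns = prediction)
#' @param y_true,y_pred label vectors.
#' @param levels class levels defining the matrix order (default `1:5`).
#' @return integer matrix with `levels` as dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred, levels = 1:5) {
  t(unclass(table(factor(y_pred, levels = levels),
                  factor(y_true, levels = levels))))
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For class `c`: accuracy `(TP + TN) / n`, precision `TP / (TP + FP)`,
#' recall `TP / (TP + FN)`, and sensitivity (identical to recall for a
#' one-vs-rest dichotomy). A zero denominator yields 0 with the metric
#' name recorded in `flagged`, keeping report tables total.
#'
#' @param confusion square matrix, rows = reference, columns = prediction.
#' @param class class label (matched against the dimnames).
#' @return list with `accuracy`, `precision`, `recall`, `sensitivity`,
#'   `flagged`.
#' @export
per_class_metrics <- function(confusion, class) {
  i <- match(as.character(class), rownames(confusion))
  if (is.na(i)) abort_mfd("class not found in confusion matrix",
                          "mfd_validation_error")
  n <- sum(confusion)
  tp <- confusion[i, i]
  fp <- sum(confusion[-i, i])
  fn <- sum(confusion[i, -i])
  tn <- n - tp - fp - fn
  flagged <- character(0)
  safe <- function(num, den, nm) {
    if (den == 0) {
      flagged <<- c(flagged, nm)
      return(0)
    }
    num / den
  }
  prec <- safe(tp, tp + fp, "precision")
  rec <- safe(tp, tp + fn, "recall")
  list(accuracy = (tp + tn) / n, precision = prec, recall = rec,
       sensitivity = rec, flagged = flagged)
}

#' One-way ANOVA between two groups of trial metrics
#'
#' Tests whether two methods' repeated-trial scores differ, at significance
#' level `alpha` (published protocol: 5%). For two groups the F statistic
#' equals the square of the pooled two-sample t statistic. When both groups
#' are constant with equal means the statistic is undefined and reported as
#' `NA`.
#'
#' @param scores_a,scores_b numeric vectors of per-trial metrics (length
#'   >= 2 each).
#' @param alpha significance level (default 0.05).
#' @return list with `F`, `p`, `significant` (`p < alpha`).
#' @export
anova_compare <- function(scores_a, scores_b, alpha = 0.05) {
  if (length(scores_a) < 2 || length(scores_b) < 2) {
    abort_mfd("need at least 2 trials per group", "mfd_validation_error")
  }
  vals <- c(scores_a, scores_b)
  grp <- factor(rep(c("a", "b"), c(length(scores_a), length(scores_b))))
  ssw <- sum((scores_a - mean(scores_a))^2) +
    sum((scores_b - mean(scores_b))^2)
  if (ssw == 0) {
    if (mean(scores_a) == mean(scores_b)) {
      return(list(F = NA_real_, p = NA_real_, significant = FALSE))
    }
    return(list(F = Inf, p = 0, significant = TRUE))
  }
  ft <- stats::oneway.test(vals ~ grp, var.equal = TRUE)
  f <- unname(ft$statistic)
  p <- unname(ft$p.value)
  list(F = f, p = p, significant = is.finite(p) && p < alpha)
}

#' Pearson correlation matrix of features
#'
#' Pairwise Pearson coefficients between feature columns, the basis of the
#' feature-correlation heat map. Thin wrapper over [stats::cor()]; constant
#' columns yield `NA` entries with a warning.
#'
#' @param x numeric matrix (samples x features).
#' @return features x features matrix in `[-1, 1]`.
#' @export
pearson_correlation_matrix <- function(x) {
  stats::cor(as.matrix(x))
}

#' Plot a feature-correlation heat map
#' @param x numeric matrix (samples x features) or a precomputed
#'   correlation matrix.
#' @param ... passed to [stats::heatmap()].
#' @return the correlation matrix, invisibly.
#' @export
plot_correlation_heatmap <- function(x, ...) {
  cm <- if (isSymmetric(unname(as.matrix(x)))) as.matrix(x)
        else pearson_correlation_matrix(x)
  stats::heatmap(cm, Rowv = NA, Colv = NA, scale = "none", ...)
  invisible(cm)
}
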