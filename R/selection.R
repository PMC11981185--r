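#' Random-forest estimator configuration
#'
#' Parameters of the random forest used as the importance estimator inside
#' recursive feature elimination and as the stacking meta-learner / baseline.
#' Defaults follow the published classifier settings: 100 trees, minimum
#' node size 1 (fully grown trees), no depth or leaf bound, `mtry` the usual
#' floor of the square root of the feature count.
#'
#' @param num_trees number of trees.
#' @param mtry features tried per split (`NULL` = `floor(sqrt(p))`).
#' @param min_node_size minimum terminal-node size.
#' @param max_depth maximum tree depth (`NULL` = unbounded).
#' @return a list of class `rf_config`.
#' @export
rf_config <- function(num_trees = 100, mtry = NULL, min_node_size = 1,
                      max_depth = NULL) {
  stopifnot(num_trees >= 1, min_node_size >= 1)
  structure(list(num_trees = num_trees, mtry = mtry,
                 min_node_size = min_node_size, max_depth = max_depth),
            class = "rf_config")
}

# One seeded, single-threaded forest fit with impurity importance.
fit_rf_estimator <- function(x, y, config, seed) {
  mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(x))))
  ranger::ranger(
    x = x, y = factor(y), num.trees = config$num_trees,
    mtry = min(mtry, ncol(x)), min.node.size = config$min_node_size,
    max.depth = config$max_depth %||% 0,
    importance = "impurity", num.threads = 1, seed = seed,
    verbose = FALSE)
}

path_sizes <- function(p, n_target, step) {
  sizes <- p
  while (p > n_target) {
    drop <- if (step < 1) max(1L, floor(step * p)) else as.integer(step)
    p <- max(n_target, p - drop)
    sizes <- c(sizes, p)
  }
  sizes
}

#' Recursive feature elimination
#'
#' Repeatedly fits the estimator and removes the `step` least-important
#' features (mean impurity decrease) until `n_target` remain; a final fit on
#' the retained set completes the importance ranking. With `step = 1` on `p`
#' features the estimator is fitted exactly `p - n_target + 1` times.
#'
#' @param x numeric matrix (samples x features) with column names.
#' @param y class labels (at least two classes present).
#' @param n_target number of features to retain.
#' @param config an [rf_config()].
#' @param step features dropped per iteration: an integer count (`>= 1`) or
#'   a fraction of the remaining features (`0 < step < 1`).
#' @param seed integer seed.
#' @return list with `retained` (feature names, most important first),
#'   `ranking` (all features, best to worst: final importance order for the
#'   retained set, then reverse elimination order), and `n_fits`.
#' @export
rfe <- function(x, y, n_target, config = rf_config(), step = 1, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (n_target < 1 || n_target > ncol(x)) {
    abort_mfd("n_target must be in 1..ncol(x)", "mfd_validation_error")
  }
  if (length(unique(y)) < 2) {
    abort_mfd("need at least two classes", "mfd_degenerate_error")
  }
  remaining <- colnames(x)
  eliminated <- character(0)
  n_fits <- 0L
  while (length(remaining) > n_target) {
    fit <- fit_rf_estimator(x[, remaining, drop = FALSE], y, config,
                            derive_seed(seed, n_fits))
    n_fits <- n_fits + 1L
    imp <- fit$variable.importance[remaining]
    drop_n <- if (step < 1) max(1L, floor(step * length(remaining))) else step
    drop_n <- min(as.integer(drop_n), length(remaining) - n_target)
    worst <- names(sort(imp))[seq_len(drop_n)] # least important first
    eliminated <- c(rev(worst), eliminated)
    remaining <- setdiff(remaining, worst)
  }
  fit <- fit_rf_estimator(x[, remaining, drop = FALSE], y, config,
                          derive_seed(seed, n_fits))
  n_fits <- n_fits + 1L
  imp <- fit$variable.importance[remaining]
  retained <- names(sort(imp, decreasing = TRUE))
  list(retained = retained, ranking = c(retained, eliminated),
       n_fits = n_fits)
}

#' Recursive feature elimination with cross-validated size choice
#'
#' For each of `k_folds` stratified folds, an elimination path is fitted on
#' the training part and the estimator at every candidate size is scored by
#' accuracy on the held-out part. The size with the highest mean score is
#' chosen (ties favour the smaller size) and a final elimination on all rows
#' yields the selected set.
#'
#' @inheritParams rfe
#' @param k_folds number of stratified folds (default 5).
#' @param step per-iteration drop; the default removes 20% of the remaining
#'   features, giving a geometric path that is fine-grained at small sizes.
#' @return list with `selected` (feature names), `best_size`, `sizes`
#'   (candidate sizes along the path), `scores` (mean CV accuracy per size)
#'   and `fold_scores` (folds x sizes matrix).
#' @export
rfecv <- function(x, y, config = rf_config(num_trees = 50), k_folds = 5,
                  step = 0.2, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  tab <- table(y)
  if (length(tab) < 2) abort_mfd("need at least two classes",
                                 "mfd_degenerate_error")
  if (k_folds < 2 || min(tab) < k_folds) {
    abort_mfd("too few samples per class for the requested fold count",
              "mfd_validation_error")
  }
  sizes <- path_sizes(ncol(x), 1L, step)
  fold <- stratified_folds(y, k_folds, derive_seed(seed, 0))
  fold_scores <- matrix(NA_real_, k_folds, length(sizes),
                        dimnames = list(NULL, sizes))
  for (f in seq_len(k_folds)) {
    tr <- fold != f; te <- !tr
    remaining <- colnames(x)
    for (s in seq_along(sizes)) {
      target <- sizes[s]
      if (length(remaining) > target) {
        # eliminate down to this size using the previous fit's importance
        drop_n <- length(remaining) - target
        worst <- names(sort(imp))[seq_len(drop_n)]
        remaining <- setdiff(remaining, worst)
      }
      fit <- fit_rf_estimator(x[tr, remaining, drop = FALSE], y[tr], config,
                              derive_seed(seed, f, s))
      imp <- fit$variable.importance[remaining]
      pred <- stats::predict(fit, data = x[te, remaining, drop = FALSE],
                             num.threads = 1,
                             seed = derive_seed(seed, f, s, 1))$predictions
      fold_scores[f, s] <- mean(as.character(pred) == as.character(y[te]))
    }
  }
  scores <- colMeans(fold_scores)
  # highest mean score wins; on ties the smaller size (later path position)
  best_pos <- max(which(scores == max(scores)))
  best_size <- sizes[best_pos]
  sel <- rfe(x, y, n_target = best_size, config = config, step = step,
             seed = derive_seed(seed, 999))
  list(selected = sel$retained, best_size = best_size, sizes = sizes,
       scores = unname(scores), fold_scores = fold_scores)
}

#' Monte-Carlo RFECV stability selection
#'
#' Repeats [rfecv()] `n_reps` times under independently derived seeds (fresh
#' fold partition and estimator seeds each repetition) and retains every
#' feature whose selection frequency reaches `threshold`. Aggregating over
#' repetitions suppresses the randomness a single RFECV run inherits from
#' its fold split and forest seeds.
#'
#' @inheritParams rfecv
#' @param n_reps number of repetitions (published protocol: 100; scale down
#'   for desk experiments).
#' @param threshold retention frequency threshold in `[0, 1]`; a feature is
#'   retained when `frequency >= threshold`.
#' @return an object of class `mfd_selection`: list with `frequency` (named,
#'   per feature), `threshold`, `retained` (feature names), `n_reps` and
#'   `reps` (per-repetition selected sets, for audit).
#' @export
monte_carlo_rfecv <- function(x, y, n_reps = 100, threshold = 0.1,
                              config = rf_config(num_trees = 50),
                              k_folds = 5, step = 0.2, seed = 1L) {
  if (threshold < 0 || threshold > 1) {
    abort_mfd("threshold must lie in [0, 1]", "mfd_validation_error")
  }
  stopifnot(n_reps >= 1)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  reps <- vector("list", n_reps)
  count <- stats::setNames(numeric(ncol(x)), colnames(x))
  for (r in seq_len(n_reps)) {
    res <- rfecv(x, y, config = config, k_folds = k_folds, step = step,
                 seed = derive_seed(seed, r))
    reps[[r]] <- res$selected
    count[res$selected] <- count[res$selected] + 1
  }
  freq <- count / n_reps
  structure(list(frequency = freq, threshold = threshold,
                 retained = names(freq)[freq >= threshold],
                 n_reps = n_reps, reps = reps),
            class = "mfd_selection")
}

#' @export
print.mfd_selection <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo RFECV selection: %d/%d features retained (threshold %.2f, %d reps)\n",
    length(x$retained), length(x$frequency), x$threshold, x$n_reps))
  invisible(x)
}

#' Pick the best retention threshold from candidate scores
#'
#' Pure argmax over `(threshold, score)` pairs; ties favour the smaller
#' threshold (retaining more features).
#'
#' @param scores named numeric vector, or a data.frame with columns
#'   `threshold` and `score`.
#' @return the winning threshold (numeric).
#' @export
#' @examples
#' best_threshold(mfd_reference("threshold_scores"))
best_threshold <- function(scores) {
  if (is.data.frame(scores)) {
    th <- scores$threshold; sc <- scores$score
  } else {
    th <- as.numeric(names(scores)); sc <- as.numeric(scores)
  }
  o <- order(th)
  th <- th[o]; sc <- sc[o]
  th[which.max(sc)] # which.max returns the first (smallest threshold) on ties
}

#' Cross-validated retention-threshold selection
#'
#' For each candidate threshold, builds the retained set from a Monte-Carlo
#' selection result and scores it by mean stratified K-fold accuracy of the
#' random-forest classifier restricted to those columns. An empty retained
#' set scores 0 and is flagged.
#'
#' @inheritParams monte_carlo_rfecv
#' @param candidates candidate thresholds.
#' @param selection an existing `mfd_selection`; when `NULL` one is computed
#'   from `x`, `y` with `n_reps` repetitions.
#' @return list with `best` (winning threshold), `scores` (named per
#'   candidate), `flagged` (candidates whose retained set was empty) and
#'   `selection` (the `mfd_selection` used).
#' @export
select_threshold <- function(x, y, candidates = c(0.1, 0.25, 0.5, 0.75, 0.9),
                             selection = NULL, n_reps = 20,
                             config = rf_config(num_trees = 50),
                             k_folds = 5, step = 0.2, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(selection)) {
    selection <- monte_carlo_rfecv(x, y, n_reps = n_reps, threshold = 0,
                                   config = config, k_folds = k_folds,
                                   step = step, seed = derive_seed(seed, 1))
  }
  fold <- stratified_folds(y, k_folds, derive_seed(seed, 2))
  scores <- stats::setNames(numeric(length(candidates)), candidates)
  flagged <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    keep <- names(selection$frequency)[selection$frequency >= candidates[i]]
    if (!length(keep)) {
      scores[i] <- 0; flagged[i] <- TRUE
      next
    }
    acc <- numeric(k_folds)
    for (f in seq_len(k_folds)) {
      tr <- fold != f
      fit <- fit_rf_estimator(x[tr, keep, drop = FALSE], y[tr], config,
                              derive_seed(seed, 3, i, f))
      pred <- stats::predict(fit, data = x[!tr, keep, drop = FALSE],
                             num.threads = 1,
                             seed = derive_seed(seed, 4, i, f))$predictions
      acc[f] <- mean(as.character(pred) == as.character(y[!tr]))
    }
    scores[i] <- mean(acc)
  }
  list(best = best_threshold(scores), scores = scores,
       flagged = candidates[flagged], selection = selection)
}
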