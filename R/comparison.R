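#' Evaluate predictions into a structured report
#'
#' @param y_true,y_pred integer fatigue levels.
#' @param levels class levels (default `1:5`).
#' @return an object of class `mfd_report`: `accuracy`, `deviation`,
#'   `confusion` (rows = reference), `per_class` (data.frame of one-vs-rest
#'   accuracy / precision / recall / sensitivity), `flagged`, `n`.
#' @export
evaluate_predictions <- function(y_true, y_pred, levels = 1:5) {
  cm <- confusion_matrix(y_true, y_pred, levels = levels)
  pc <- lapply(levels, function(cl) per_class_metrics(cm, cl))
  per_class <- data.frame(
    class = levels,
    accuracy = vapply(pc, `[[`, 0, "accuracy"),
    precision = vapply(pc, `[[`, 0, "precision"),
    recall = vapply(pc, `[[`, 0, "recall"),
    sensitivity = vapply(pc, `[[`, 0, "sensitivity"))
  flagged <- unlist(Map(function(cl, p) {
    if (length(p$flagged)) paste0(cl, ":", p$flagged) else character(0)
  }, levels, pc), use.names = FALSE)
  structure(list(accuracy = accuracy(y_true, y_pred),
                 deviation = deviation(y_true, y_pred),
                 confusion = cm, per_class = per_class,
                 flagged = flagged, n = length(y_true)),
            class = "mfd_report")
}

#' @export
print.mfd_report <- function(x, ...) {
  cat(sprintf("Evaluation of %d frames: accuracy %.3f, deviation %+.3f\n",
              x$n, x$accuracy, x$deviation))
  print(x$confusion)
  invisible(x)
}

fit_any_method <- function(method, x, y, seed, drn = NULL, rf = rf_config()) {
  if (method == "drnrf") {
    cfg <- drn %||% drn_config(ncol(x), classes = sort(unique(y)))
    cfg$input_dim <- ncol(x)
    drnrf(x, y, drn = cfg, rf = rf, seed = seed)
  } else {
    fit_baseline(method, x, y, seed = seed)
  }
}

predict_any_method <- function(fit, x) {
  if (inherits(fit, "drnrf")) predict(fit, x) else predict_baseline(fit, x)
}

#' Repeated-trial comparison of detection methods
#'
#' Reproduces the published evaluation protocol on a dataset: for each of
#' `n_trials` trials, a fresh 70/15/15 stratified split is drawn under a
#' derived seed, the data are preprocessed (normalisation fitted on the
#' training part only), every method is fitted on the training part and
#' scored on the test part by accuracy and signed deviation — overall and
#' restricted to the two highest fatigue levels ("Sleepy" and "Extremely
#' Sleepy"), the states whose detection matters most. Trial means, pairwise
#' one-way ANOVA of the first method against each other method, and mean
#' improvements are reported. Both the split and every model's own
#' randomness vary across trials through derived seeds. A failing method is
#' recorded and excluded from the statistics; the run continues.
#'
#' @param ds an `mfd_data` dataset (raw coordinates; preprocessing happens
#'   inside each trial).
#' @param methods methods to compare; the first is the reference for ANOVA
#'   and improvement columns.
#' @param n_trials number of repeated trials (published protocol: 10).
#' @param features optional character vector of retained feature names
#'   (e.g. from [monte_carlo_rfecv()]); default uses all 136 coordinates.
#' @param drn optional [drn_config()] override for the stacked model.
#' @param rf [rf_config()] for the stacked model's meta-learner.
#' @param sleepy_levels labels forming the high-fatigue subset.
#' @param seed master seed.
#' @return an object of class `mfd_comparison`: `trials` (long data.frame of
#'   per-trial metrics), `means`, `anova`, `improvements`, `confusion`
#'   (per-method confusion matrices summed over trials), `failures`,
#'   `majority_rate` (mean test-part majority-class rate), `n_trials`,
#'   `seed`.
#' @export
run_comparison <- function(ds, methods = c("drnrf", "ann", "gbm", "knn", "rf"),
                           n_trials = 10, features = NULL, drn = NULL,
                           rf = rf_config(), sleepy_levels = c(4, 5),
                           seed = 1L) {
  levels_all <- 1:5
  rows <- list()
  confusion <- stats::setNames(
    rep(list(matrix(0L, 5, 5, dimnames = list(levels_all, levels_all))),
        length(methods)), methods)
  failures <- character(0)
  majority <- numeric(n_trials)
  for (t in seq_len(n_trials)) {
    st <- derive_seed(seed, 100, t)
    sp <- split_mfd(ds, seed = st)
    pre <- preprocess_mfd(ds, fit_index = sp$train)
    x <- landmark_matrix(pre$dataset)
    if (!is.null(features)) x <- x[, features, drop = FALSE]
    ytr <- pre$dataset$kss[sp$train]; yte <- pre$dataset$kss[sp$test]
    majority[t] <- max(table(yte)) / length(yte)
    sleepy <- yte %in% sleepy_levels
    for (m in methods) {
      res <- tryCatch({
        fit <- fit_any_method(m, x[sp$train, , drop = FALSE], ytr,
                              seed = derive_seed(st, match(m, methods)),
                              drn = drn, rf = rf)
        pred <- predict_any_method(fit, x[sp$test, , drop = FALSE])
        list(pred = pred)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures,
                      sprintf("trial %d, %s: %s", t, m, conditionMessage(res)))
        rows[[length(rows) + 1]] <- data.frame(
          trial = t, method = m, accuracy = NA_real_, deviation = NA_real_,
          accuracy_sleepy = NA_real_, deviation_sleepy = NA_real_,
          failed = TRUE)
        next
      }
      pred <- res$pred
      confusion[[m]] <- confusion[[m]] +
        confusion_matrix(yte, pred, levels = levels_all)
      rows[[length(rows) + 1]] <- data.frame(
        trial = t, method = m,
        accuracy = accuracy(yte, pred),
        deviation = deviation(yte, pred),
        accuracy_sleepy = if (any(sleepy))
          accuracy(yte[sleepy], pred[sleepy]) else NA_real_,
        deviation_sleepy = if (any(sleepy))
          deviation(yte[sleepy], pred[sleepy]) else NA_real_,
        failed = FALSE)
    }
  }
  trials <- do.call(rbind, rows)
  ok <- trials[!trials$failed, , drop = FALSE]
  agg <- function(col) {
    vapply(methods, function(m) mean(ok[[col]][ok$method == m], na.rm = TRUE),
           0)
  }
  means <- data.frame(method = methods,
                      accuracy = agg("accuracy"),
                      deviation = agg("deviation"),
                      accuracy_sleepy = agg("accuracy_sleepy"),
                      deviation_sleepy = agg("deviation_sleepy"),
                      row.names = NULL)
  ref <- methods[1]
  anova_rows <- list()
  improvements <- list()
  for (m in setdiff(methods, ref)) {
    a_acc <- ok$accuracy[ok$method == ref]
    b_acc <- ok$accuracy[ok$method == m]
    a_dev <- ok$deviation[ok$method == ref]
    b_dev <- ok$deviation[ok$method == m]
    av_a <- if (length(a_acc) >= 2 && length(b_acc) >= 2) {
      anova_compare(a_acc, b_acc)
    } else list(F = NA_real_, p = NA_real_, significant = FALSE)
    av_d <- if (length(a_dev) >= 2 && length(b_dev) >= 2) {
      anova_compare(a_dev, b_dev)
    } else list(F = NA_real_, p = NA_real_, significant = FALSE)
    anova_rows[[m]] <- data.frame(
      reference = ref, method = m,
      F_accuracy = av_a$F, p_accuracy = av_a$p,
      F_deviation = av_d$F, p_deviation = av_d$p,
      significant_accuracy = av_a$significant,
      significant_deviation = av_d$significant)
    improvements[[m]] <- data.frame(
      reference = ref, method = m,
      accuracy_improvement = mean(a_acc) - mean(b_acc),
      deviation_improvement = abs(mean(b_dev) - mean(a_dev)))
  }
  structure(list(trials = trials, means = means,
                 anova = do.call(rbind, c(anova_rows,
                                          list(make.row.names = FALSE))),
                 improvements = do.call(rbind, c(improvements,
                                                 list(make.row.names = FALSE))),
                 confusion = confusion, failures = failures,
                 majority_rate = mean(majority), n_trials = n_trials,
                 seed = seed, methods = methods, features = features),
            class = "mfd_comparison")
}

#' @export
print.mfd_comparison <- function(x, ...) {
  cat(sprintf("Method comparison over %d trial(s) (mean test metrics):\n",
              x$n_trials))
  print(x$means, row.names = FALSE, digits = 4)
  if (length(x$failures)) {
    cat(sprintf("  %d failure(s) recorded\n", length(x$failures)))
  }
  invisible(x)
}

#' Serialise a comparison report to JSON
#'
#' Output is byte-stable for a fixed master seed, which is the package's
#' reproducibility contract for comparison runs.
#'
#' @param cmp an `mfd_comparison`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(cmp, path) {
  obj <- list(
    n_trials = cmp$n_trials, seed = cmp$seed, methods = cmp$methods,
    majority_rate = cmp$majority_rate,
    means = cmp$means, trials = cmp$trials,
    anova = cmp$anova, improvements = cmp$improvements,
    confusion = lapply(cmp$confusion, unclass),
    failures = cmp$failures)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", na = "null")
  invisible(path)
}
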