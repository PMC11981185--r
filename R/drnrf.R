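#' Fit a stacked residual-network + random-forest fatigue classifier
#'
#' The estimator at the heart of the package. Training data is split into
#' `k` stratified folds; for each fold a deep residual network (the base
#' learner) is trained on the other `k - 1` folds and predicts class
#' probabilities for the held-out fold. The stacked out-of-fold probability
#' matrix (`n x n_classes`) — in which no row was seen by the network that
#' produced it — becomes the training input of a random-forest
#' meta-learner, whose vote is the final fatigue level. All `k` fold
#' networks are retained; at prediction time their probability outputs are
#' averaged to form the meta-features of new rows.
#'
#' @param x numeric feature matrix (rows = frames, columns = selected
#'   landmark features), or a data.frame coercible to one.
#' @param y fatigue labels; every class must have at least `k` samples.
#' @param k fold count of the stacking layer (default 5).
#' @param drn a [drn_config()]; `input_dim` and `classes` are filled in
#'   from the data when missing.
#' @param rf an [rf_config()] for the meta-learner (published defaults:
#'   100 fully grown trees).
#' @param features optional character vector naming the columns of `x` to
#'   use (default: all columns).
#' @param norm_state optional `minmax_state` to store with the model so
#'   new raw data can be normalised identically at prediction time.
#' @param seed master seed; folds, network initialisation and the
#'   meta-forest all derive from it.
#' @param ... unused.
#' @return an object of class `drnrf` with components `fold_models`,
#'   `folds` (fold id per training row), `meta_features` (out-of-fold
#'   probability matrix), `meta_model`, `classes`, `feature_names`,
#'   `norm_state`, `y` and `configs`.
#' @export
#' @examples
#' \donttest{
#' sim <- generate_dataset(synthetic_config(n_participants = 4,
#'   frames_per_participant = 60, seed = 1))
#' pre <- preprocess_mfd(sim$dataset)
#' x <- landmark_matrix(pre$dataset)
#' fit <- drnrf(x, pre$dataset$kss,
#'   drn = drn_config(ncol(x), epochs = 5), seed = 1)
#' table(predict(fit, x), pre$dataset$kss)
#' }
drnrf <- function(x, ...) UseMethod("drnrf")

#' @rdname drnrf
#' @export
drnrf.default <- function(x, y, k = 5, drn = NULL, rf = rf_config(),
                          features = NULL, norm_state = NULL, seed = 1L,
                          ...) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (!is.null(features)) {
    miss <- setdiff(features, colnames(x))
    if (length(miss)) {
      abort_mfd(sprintf("features absent from x: %s",
                        paste(utils::head(miss, 5), collapse = ", ")),
                "mfd_validation_error")
    }
    x <- x[, features, drop = FALSE]
  }
  n <- nrow(x)
  stopifnot(length(y) == n)
  classes <- sort(unique(y))
  tab <- table(y)
  if (min(tab) < k) {
    abort_mfd(sprintf("class %s has fewer than k = %d samples",
                      names(tab)[which.min(tab)], k), "mfd_validation_error")
  }
  drn <- drn %||% drn_config(ncol(x), classes = classes,
                             seed = derive_seed(seed, 10))
  drn$input_dim <- ncol(x)
  if (!all(classes %in% drn$classes)) drn$classes <- classes
  folds <- stratified_folds(y, k, derive_seed(seed, 1))
  meta <- matrix(NA_real_, n, length(drn$classes),
                 dimnames = list(NULL, as.character(drn$classes)))
  fold_models <- vector("list", k)
  for (f in seq_len(k)) {
    cfg_f <- drn
    cfg_f$seed <- derive_seed(seed, 2, f)
    tr <- folds != f
    model <- build_drn(cfg_f)
    model <- train_drn(model, x[tr, , drop = FALSE], y[tr])
    fold_models[[f]] <- model
    meta[!tr, ] <- predict_drn(model, x[!tr, , drop = FALSE])
  }
  meta_model <- rng_local(derive_seed(seed, 3), {
    randomForest::randomForest(
      x = meta, y = factor(y, levels = drn$classes),
      ntree = rf$num_trees, nodesize = rf$min_node_size)
  })
  structure(list(fold_models = fold_models, folds = folds,
                 meta_features = meta, meta_model = meta_model,
                 classes = drn$classes, feature_names = colnames(x),
                 norm_state = norm_state, y = y, k = k,
                 configs = list(drn = drn, rf = rf, seed = seed)),
            class = "drnrf")
}

#' @rdname drnrf
#' @param formula model formula of the form `label ~ .` evaluated in `data`.
#' @param data a data.frame holding the label column and feature columns.
#' @export
drnrf.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- as.matrix(mf[, -1, drop = FALSE])
  drnrf.default(x, y, ...)
}

#' Predict fatigue levels from a fitted stacked classifier
#'
#' New rows are normalised with the stored state when `raw = TRUE`, reduced
#' to the training feature set, passed through every fold network, and the
#' averaged probability vectors are classified by the meta-forest.
#'
#' @param object a fitted [drnrf()] model.
#' @param newdata numeric matrix or data.frame of features.
#' @param type `"class"` for labels (default) or `"prob"` for averaged
#'   base-learner class probabilities.
#' @param raw if `TRUE`, apply the stored normalisation state first.
#' @param ... unused.
#' @return predicted labels (same type as the training labels) or a
#'   probability matrix.
#' @export
predict.drnrf <- function(object, newdata, type = c("class", "prob"),
                          raw = FALSE, ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (raw) {
    if (is.null(object$norm_state)) {
      abort_mfd("model holds no normalisation state", "mfd_validation_error")
    }
    x <- apply_minmax(object$norm_state, x)
  }
  if (!is.null(colnames(x))) {
    miss <- setdiff(object$feature_names, colnames(x))
    if (length(miss)) {
      abort_mfd("newdata lacks training features", "mfd_validation_error")
    }
    x <- x[, object$feature_names, drop = FALSE]
  } else if (ncol(x) != length(object$feature_names)) {
    abort_mfd("newdata width does not match the training feature set",
              "mfd_validation_error")
  }
  meta <- Reduce(`+`, lapply(object$fold_models, predict_drn, x = x)) /
    length(object$fold_models)
  if (type == "prob") return(meta)
  # tie votes in the forest are broken through R's RNG; pin them locally so
  # prediction is a pure function of its inputs
  pred <- rng_local(760123L, stats::predict(object$meta_model, meta))
  out <- object$classes[match(as.character(pred),
                              as.character(object$classes))]
  out
}

#' @export
print.drnrf <- function(x, ...) {
  cat("Stacked DRN-RF fatigue classifier\n")
  cat(sprintf("  base learners : %d residual networks (%d layers, width %d, %d epochs)\n",
              x$k, x$configs$drn$n_layers, x$configs$drn$hidden_width,
              x$configs$drn$epochs))
  cat(sprintf("  meta learner  : random forest, %d trees\n",
              x$configs$rf$num_trees))
  cat(sprintf("  features      : %d; training frames: %d; classes: %s\n",
              length(x$feature_names), length(x$y),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' @export
summary.drnrf <- function(object, ...) {
  oof <- rng_local(760123L,
                   stats::predict(object$meta_model, object$meta_features))
  oof <- object$classes[match(as.character(oof),
                              as.character(object$classes))]
  acc <- mean(oof == object$y)
  dev <- mean(as.numeric(oof) - as.numeric(object$y))
  out <- list(oof_accuracy = acc, oof_deviation = dev,
              confusion = confusion_matrix(object$y, oof,
                                           levels = object$classes),
              model = object)
  class(out) <- "summary.drnrf"
  out
}

#' @export
print.summary.drnrf <- function(x, ...) {
  print(x$model)
  cat(sprintf("  out-of-fold accuracy : %.3f\n", x$oof_accuracy))
  cat(sprintf("  out-of-fold deviation: %+.3f\n", x$oof_deviation))
  cat("  out-of-fold confusion (rows = reference):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
residuals.drnrf <- function(object, ...) {
  oof <- rng_local(760123L,
                   stats::predict(object$meta_model, object$meta_features))
  oof <- object$classes[match(as.character(oof),
                              as.character(object$classes))]
  as.numeric(oof) - as.numeric(object$y)
}

#' @export
plot.drnrf <- function(x, ...) {
  hist <- lapply(x$fold_models, `[[`, "loss_history")
  ylim <- range(unlist(hist))
  graphics::plot(NULL, xlim = c(1, max(lengths(hist))), ylim = ylim,
                 xlab = "epoch", ylab = "training loss",
                 main = "Base-learner training loss by fold")
  for (i in seq_along(hist)) {
    graphics::lines(hist[[i]], col = i)
  }
  graphics::legend("topright", legend = paste("fold", seq_along(hist)),
                   col = seq_along(hist), lty = 1, cex = 0.8)
  invisible(x)
}
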