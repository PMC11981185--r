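# Small stacked fits for structural checks: few epochs keep them quick
# while exercising the full out-of-fold machinery.
fit_small_stack <- function(n = 100, seed = 1, k = 5, epochs = 5) {
  pm <- planted_matrix(n = n, p = 8, informative = 3, n_classes = 5,
                       effect = 2, seed = seed)
  fit <- drnrf(pm$x, pm$y, k = k,
               drn = drn_config(8, classes = 1:5, epochs = epochs),
               seed = seed)
  list(fit = fit, pm = pm)
}

test_that("stacking produces an (n, n_classes) out-of-fold meta matrix with unit rows", {
  res <- fit_small_stack(n = 100)
  fit <- res$fit
  expect_identical(dim(fit$meta_features), c(100L, 5L))
  expect_equal(rowSums(fit$meta_features), rep(1, 100), tolerance = 1e-6)
  expect_length(fit$fold_models, 5)
  # folds partition the training rows
  expect_identical(sort(unique(fit$folds)), 1:5)
})

test_that("no fold model ever saw the rows it produced meta-features for", {
  res <- fit_small_stack(n = 100, seed = 3)
  fit <- res$fit
  for (f in 1:5) {
    held <- fit$folds == f
    # the stored meta-features of the held-out rows reproduce exactly from
    # the fold model, which was trained on the complement
    expect_equal(fit$meta_features[held, ],
                 predict_drn(fit$fold_models[[f]],
                             res$pm$x[held, , drop = FALSE]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("two-class stacking yields a two-column meta matrix", {
  set.seed(8)
  y <- rep(1:2, each = 5)
  x <- matrix(rnorm(10 * 3), 10, 3) + y
  colnames(x) <- paste0("f", 1:3)
  fit <- drnrf(x, y, k = 5, drn = drn_config(3, classes = 1:2, epochs = 2),
               seed = 1)
  expect_identical(dim(fit$meta_features), c(10L, 2L))
  # each held-out fold has 2 samples
  expect_identical(as.integer(table(fit$folds)), rep(2L, 5))
})

test_that("a class with fewer than k samples is rejected", {
  set.seed(9)
  y <- c(rep(1, 3), rep(2, 20))
  x <- matrix(rnorm(23 * 4), 23, 4)
  expect_error(drnrf(x, y, k = 5), class = "mfd_validation_error")
})

test_that("predictions are deterministic, class-valued and duplicate-consistent", {
  res <- fit_small_stack(n = 100, seed = 5)
  fit <- res$fit
  newx <- res$pm$x[c(1:10, 1:10), ]
  p <- predict(fit, newx)
  expect_true(all(p %in% 1:5))
  expect_identical(p[1:10], p[11:20]) # duplicated rows agree
  pr <- predict(fit, newx, type = "prob")
  expect_equal(rowSums(pr), rep(1, 20), tolerance = 1e-6)
  # refitting under the same master seed reproduces predictions exactly
  refit <- drnrf(res$pm$x, res$pm$y, k = 5,
                 drn = drn_config(8, classes = 1:5, epochs = 5), seed = 5)
  expect_identical(predict(refit, res$pm$x), predict(fit, res$pm$x))
  expect_error(predict(fit, res$pm$x[, 1:3]), class = "mfd_validation_error")
})

test_that("model methods report coherently", {
  res <- fit_small_stack(n = 100, seed = 2)
  fit <- res$fit
  expect_output(print(fit), "Stacked DRN-RF")
  s <- summary(fit)
  expect_s3_class(s, "summary.drnrf")
  expect_true(s$oof_accuracy >= 0 && s$oof_accuracy <= 1)
  r <- residuals(fit)
  expect_length(r, 100)
  expect_true(all(r >= -4 & r <= 4))
  expect_equal(mean(r), s$oof_deviation)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("the formula interface matches the default interface", {
  pm <- planted_matrix(n = 60, p = 4, n_classes = 2, seed = 11)
  df <- data.frame(level = pm$y, pm$x)
  f1 <- drnrf(level ~ ., data = df, k = 3,
              drn = drn_config(4, classes = 1:2, epochs = 2), seed = 4)
  f2 <- drnrf(pm$x, pm$y, k = 3,
              drn = drn_config(4, classes = 1:2, epochs = 2), seed = 4)
  expect_identical(predict(f1, pm$x), predict(f2, pm$x))
})

test_that("stacking does not trail a plain random forest on separable data", {
  wins <- 0
  for (s in 1:10) {
    pm <- planted_matrix(n = 220, p = 10, informative = 4, n_classes = 5,
                         effect = 2.5, seed = 300 + s)
    tr <- seq_len(160); te <- 161:220
    stack <- drnrf(pm$x[tr, ], pm$y[tr],
                   drn = drn_config(10, classes = 1:5, epochs = 25),
                   seed = s)
    rf <- fit_baseline("rf", pm$x[tr, ], pm$y[tr], seed = s)
    acc_stack <- mean(predict(stack, pm$x[te, ]) == pm$y[te])
    acc_rf <- mean(predict_baseline(rf, pm$x[te, ]) == pm$y[te])
    wins <- wins + (acc_stack >= acc_rf - 0.02)
  }
  expect_gte(wins, 6)
})
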