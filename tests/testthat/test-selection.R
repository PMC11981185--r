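test_that("RFE with step 1 fits the estimator exactly p - n_target + 1 times", {
  pm <- planted_matrix(n = 60, p = 6, seed = 2)
  for (target in c(1, 3, 6)) {
    r <- rfe(pm$x, pm$y, n_target = target, step = 1, seed = 1)
    expect_identical(r$n_fits, ncol(pm$x) - as.integer(target) + 1L)
    expect_length(r$retained, target)
    # ranking covers every feature exactly once
    expect_setequal(r$ranking, colnames(pm$x))
  }
  # n_target == p keeps everything
  expect_setequal(rfe(pm$x, pm$y, n_target = 6, seed = 1)$retained,
                  colnames(pm$x))
  expect_error(rfe(pm$x, pm$y, n_target = 0), class = "mfd_validation_error")
  expect_error(rfe(pm$x, rep(1, 60), n_target = 2),
               class = "mfd_degenerate_error")
})

test_that("RFE recovers a column that equals the label", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    y <- sample(1:2, 60, replace = TRUE)
    x <- cbind(y + rnorm(60, 0, 0.05), matrix(rnorm(180), 60, 3))
    colnames(x) <- paste0("f", 1:4)
    r <- rfe(x, y, n_target = 1, seed = s)
    hits <- hits + (r$retained == "f1")
  }
  expect_gte(hits, 19)
})

test_that("RFECV finds the informative pair among noise", {
  hits <- 0
  for (s in 1:20) {
    pm <- planted_matrix(n = 150, p = 22, informative = 2, n_classes = 2,
                         effect = 3, seed = 100 + s)
    res <- rfecv(pm$x, pm$y, k_folds = 3, seed = s)
    hits <- hits + all(c("f1", "f2") %in% res$selected)
  }
  expect_gte(hits, 18)
})

test_that("RFECV honours its size/score contract", {
  pm <- planted_matrix(n = 80, p = 8, seed = 4)
  res <- rfecv(pm$x, pm$y, k_folds = 4, seed = 9)
  expect_length(res$scores, length(res$sizes))
  expect_identical(dim(res$fold_scores), c(4L, length(res$sizes)))
  expect_identical(length(res$selected), as.integer(res$best_size))
  expect_true(res$best_size %in% res$sizes)
  # single-feature input: the only candidate size is returned
  one <- rfecv(pm$x[, 1, drop = FALSE], pm$y, k_folds = 3, seed = 2)
  expect_identical(one$best_size, 1L)
  expect_identical(one$selected, "f1")
  expect_error(rfecv(pm$x, pm$y, k_folds = 200),
               class = "mfd_validation_error")
})

test_that("Monte-Carlo frequencies obey their defining identities", {
  pm <- planted_matrix(n = 90, p = 8, seed = 5)
  one <- monte_carlo_rfecv(pm$x, pm$y, n_reps = 1, threshold = 0.5,
                           k_folds = 3, seed = 3)
  expect_true(all(one$frequency %in% c(0, 1)))
  expect_setequal(one$retained, one$reps[[1]])
  several <- monte_carlo_rfecv(pm$x, pm$y, n_reps = 4, threshold = 0,
                               k_folds = 3, seed = 3)
  expect_true(all(several$frequency >= 0 & several$frequency <= 1))
  # threshold 0 retains every feature
  expect_setequal(several$retained, colnames(pm$x))
  # frequency really is the fraction of selecting repetitions
  f_manual <- vapply(colnames(pm$x), function(f) {
    mean(vapply(several$reps, function(r) f %in% r, TRUE))
  }, 0)
  expect_equal(unname(several$frequency[names(f_manual)]), unname(f_manual))
  # retained sets shrink monotonically as the threshold grows
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  sets <- lapply(grid, function(th) {
    names(several$frequency)[several$frequency >= th]
  })
  for (i in seq_along(grid)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  expect_error(monte_carlo_rfecv(pm$x, pm$y, threshold = 1.2),
               class = "mfd_validation_error")
})

test_that("threshold argmax picks the highest-scoring candidate", {
  # published cross-validation scores: 0.1 wins
  expect_identical(best_threshold(mfd_reference("threshold_scores")), 0.1)
  # ties resolve toward the smaller threshold
  tied <- data.frame(threshold = c(0.1, 0.25, 0.5), score = c(0.7, 0.7, 0.7))
  expect_identical(best_threshold(tied), 0.1)
  expect_identical(best_threshold(c(`0.5` = 0.9)), 0.5)
})

test_that("cross-validated threshold selection scores candidate sets", {
  pm <- planted_matrix(n = 90, p = 6, seed = 6)
  sel <- monte_carlo_rfecv(pm$x, pm$y, n_reps = 3, threshold = 0,
                           k_folds = 3, seed = 8)
  res <- select_threshold(pm$x, pm$y, candidates = c(0.5, 1),
                          selection = sel, k_folds = 3, seed = 8)
  expect_named(res$scores, c("0.5", "1"))
  expect_true(res$best %in% c(0.5, 1))
  # a candidate whose retained set is empty scores zero and is flagged
  sel$frequency[] <- 0.2
  res2 <- select_threshold(pm$x, pm$y, candidates = c(0.1, 0.9),
                           selection = sel, k_folds = 3, seed = 8)
  expect_identical(unname(res2$scores["0.9"]), 0)
  expect_identical(res2$flagged, 0.9)
})
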