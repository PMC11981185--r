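test_that("splitting yields the published 70/15/15 partition", {
  y <- sample(1:5, 100, replace = TRUE)
  sp <- split_mfd(y, stratified = FALSE, seed = 1)
  expect_identical(lengths(sp), c(train = 70L, validation = 15L, test = 15L))
  # partition property: union is everything, parts are disjoint
  all_idx <- sort(unname(unlist(sp)))
  expect_identical(all_idx, 1:100)
  # reproducibility
  sp2 <- split_mfd(y, stratified = FALSE, seed = 1)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_mfd(y, stratified = FALSE, seed = 2)))
})

test_that("stratified splits preserve the class mix and cover every class", {
  y <- rep(1:5, times = c(20, 40, 100, 60, 20)) # counts divisible by 20
  sp <- split_mfd(y, seed = 3)
  expect_identical(sort(unname(unlist(sp))), seq_along(y))
  for (part in sp) {
    tab <- table(factor(y[part], levels = 1:5))
    expect_equal(as.numeric(tab / length(part)),
                 c(20, 40, 100, 60, 20) / 240, tolerance = 0.02)
  }
  expect_identical(lengths(sp), c(train = 168L, validation = 36L,
                                  test = 36L))
})

test_that("participant-grouped splitting keeps participants whole", {
  sim <- generate_dataset(synthetic_config(n_participants = 10,
                                           frames_per_participant = 10,
                                           seed = 2))
  sp <- split_mfd(sim$dataset, group_by_participant = TRUE, seed = 4)
  ids <- lapply(sp, function(i) unique(sim$dataset$participant_id[i]))
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$train, ids$validation), 0)
  expect_identical(sort(unname(unlist(sp))), seq_len(100))
})

test_that("split preconditions are enforced", {
  expect_error(split_mfd(1:30, fractions = c(0.5, 0.2, 0.2)),
               class = "mfd_validation_error")
  expect_error(split_mfd(1:10), class = "mfd_validation_error")
})

test_that("accuracy and deviation follow their definitions", {
  expect_identical(accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(accuracy(c(1, 2), c(2, 1)), 0)
  expect_identical(accuracy(c(1, 2, 3, 4), c(1, 2, 3, 5)), 0.75)
  expect_identical(deviation(c(2, 3), c(2, 3)), 0)
  expect_identical(deviation(c(1, 2, 3), c(2, 3, 4)), 1)
  expect_identical(deviation(c(2, 3), c(1, 3)), -0.5)
  expect_error(deviation(integer(0), integer(0)),
               class = "mfd_validation_error")
  # ordinal residuals on a 5-level scale are bounded
  set.seed(10)
  for (i in 1:20) {
    yt <- sample(1:5, 30, TRUE); yp <- sample(1:5, 30, TRUE)
    expect_true(abs(deviation(yt, yp)) <= 4)
  }
})

test_that("confusion matrices reconcile with accuracy and orient rows as reference", {
  yt <- c(1, 1, 2, 3, 5); yp <- c(1, 2, 2, 3, 4)
  cm <- confusion_matrix(yt, yp)
  expect_identical(sum(cm), 5L)
  expect_identical(cm["1", "2"], 1L) # reference 1 predicted as 2
  expect_identical(cm["5", "4"], 1L)
  set.seed(13)
  for (i in 1:20) {
    yt <- sample(1:5, 50, TRUE); yp <- sample(1:5, 50, TRUE)
    cm <- confusion_matrix(yt, yp)
    expect_equal(sum(diag(cm)) / sum(cm), accuracy(yt, yp))
  }
})

test_that("per-class one-vs-rest metrics match direct counting", {
  cm <- matrix(c(5, 1, 2, 2), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  m <- per_class_metrics(cm, "A")
  expect_equal(m$precision, 5 / 7)
  expect_equal(m$recall, 5 / 6)
  expect_equal(m$accuracy, 7 / 10)
  expect_identical(m$recall, m$sensitivity)
  # diagonal matrix: everything perfect
  dm <- diag(3) * 4
  dimnames(dm) <- list(1:3, 1:3)
  d <- per_class_metrics(dm, 2)
  expect_identical(c(d$accuracy, d$precision, d$recall), c(1, 1, 1))
  # empty prediction column: precision 0, flagged
  cm0 <- matrix(c(0, 3, 0, 4), 2, byrow = TRUE,
                dimnames = list(c("A", "B"), c("A", "B")))
  mA <- per_class_metrics(cm0, "A")
  expect_identical(mA$precision, 0)
  expect_true("precision" %in% mA$flagged)
  # randomized equivalence with the counting oracle
  set.seed(14)
  for (i in 1:100) {
    yt <- sample(1:4, 40, TRUE); yp <- sample(1:4, 40, TRUE)
    cm <- confusion_matrix(yt, yp, levels = 1:4)
    cl <- sample(1:4, 1)
    got <- per_class_metrics(cm, cl)
    want <- oracle_class_metrics(yt, yp, cl)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
  }
})

test_that("two-group ANOVA matches the textbook formula", {
  # hand-checkable case: SSB 13.5, SSW 4 on 4 df
  res <- anova_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$F, 13.5, tolerance = 1e-12)
  expect_true(res$significant)
  # identical groups: no between-group variance at all
  same <- anova_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  # degenerate: both constant and equal -> undefined
  und <- anova_compare(c(2, 2), c(2, 2))
  expect_true(is.na(und$F))
  expect_false(und$significant)
  expect_error(anova_compare(1, c(1, 2)), class = "mfd_validation_error")
  set.seed(15)
  for (i in 1:100) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), mean = runif(1))
    got <- anova_compare(a, b)
    expect_equal(got$F, oracle_anova_F(a, b), tolerance = 1e-10)
    # two-group F is the squared pooled t statistic
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(got$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(got$p, unname(tt$p.value), tolerance = 1e-10)
  }
})

test_that("Pearson correlation behaves at its fixed points", {
  set.seed(16)
  x <- matrix(rnorm(10000 * 2), ncol = 2)
  cm <- pearson_correlation_matrix(cbind(x, lin = 2 * x[, 1] + 3))
  expect_equal(diag(cm), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm[1, 3], 1, tolerance = 1e-12) # exact linear dependence
  expect_lt(abs(cm[1, 2]), 0.05) # independent columns, n = 10000
  expect_true(all(cm >= -1 - 1e-12 & cm <= 1 + 1e-12))
})

test_that("prediction reports aggregate metrics, confusion and flags", {
  yt <- rep(1:5, each = 4)
  yp <- yt; yp[1] <- 2
  rep <- evaluate_predictions(yt, yp)
  expect_equal(rep$accuracy, 19 / 20)
  expect_identical(sum(rep$confusion), 20L)
  expect_identical(nrow(rep$per_class), 5L)
  expect_true(all(rep$per_class$recall == rep$per_class$sensitivity))
  expect_output(print(rep), "accuracy")
})
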