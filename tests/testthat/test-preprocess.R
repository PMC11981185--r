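test_that("three-sigma detection flags exactly what the band rule says", {
  # constant sequence: sigma 0, nothing flagged
  expect_false(any(detect_outliers(rep(7, 10))))
  # short sequence [1,2,3]: band covers everything (sigma ~ 0.816)
  expect_false(any(detect_outliers(c(1, 2, 3))))
  # planted spike among unit normals is the only flag
  set.seed(42)
  v <- c(rnorm(100), 10)
  expect_identical(which(detect_outliers(v)), 101L)
  # non-finite cells are always flagged
  v[5] <- NA
  expect_true(detect_outliers(v)[5])
  # a value exactly on the band edge is kept (strict inequality)
  w <- c(-1, -1, 1, 1) # mean 0, sigma 1
  expect_false(any(detect_outliers(w, k_sigma = 1)))
  expect_error(detect_outliers(c(NA, NA, 1)), class = "mfd_degenerate_error")
})

test_that("three-sigma detection matches the brute-force oracle", {
  set.seed(7)
  for (case in 1:100) {
    n <- sample(5:40, 1)
    v <- rnorm(n, sd = runif(1, 0.5, 5))
    if (runif(1) < 0.5) v[sample(n, 1)] <- rnorm(1, 0, 30)
    if (runif(1) < 0.3) v[sample(n, 1)] <- NA
    if (sum(is.finite(v)) < 2) next
    expect_identical(detect_outliers(v), oracle_sigma_flags(v))
  }
})

test_that("neighbour-mean imputation repairs flagged cells only", {
  expect_equal(impute_outliers(c(1, 99, 3), c(FALSE, TRUE, FALSE)),
               c(1, 2, 3))
  expect_equal(impute_outliers(c(50, 1, 2), c(TRUE, FALSE, FALSE)),
               c(1, 1, 2))
  v <- c(4, 2, 8, 1)
  expect_identical(impute_outliers(v, rep(FALSE, 4)), v)
  expect_error(impute_outliers(1:3, rep(TRUE, 3)),
               class = "mfd_degenerate_error")
})

test_that("imputation matches the oracle and detect->impute is idempotent", {
  set.seed(11)
  for (case in 1:100) {
    n <- sample(4:30, 1)
    v <- rnorm(n)
    mask <- runif(n) < 0.3
    if (all(mask)) mask[sample(n, 1)] <- FALSE
    got <- impute_outliers(v, mask)
    expect_equal(got, oracle_impute(v, mask), tolerance = 1e-12)
    expect_identical(got[!mask], v[!mask]) # unflagged cells untouched
  }
  # repairing a repaired sequence changes nothing
  set.seed(12)
  v <- c(rnorm(60), 25)
  once <- impute_outliers(v, detect_outliers(v))
  twice <- impute_outliers(once, detect_outliers(once))
  expect_identical(twice, once)
})

test_that("relativisation is exactly translation- and scale-invariant", {
  base <- template_face()$coords
  ref <- relativize_frame(base)
  # centroid of the output is the origin
  expect_equal(mean(ref[1:68]), 0, tolerance = 1e-12)
  expect_equal(mean(ref[69:136]), 0, tolerance = 1e-12)
  set.seed(3)
  for (case in 1:25) {
    dx <- runif(1, -100, 100); dy <- runif(1, -100, 100)
    s <- runif(1, 0.25, 4)
    px <- runif(1, -50, 250); py <- runif(1, -50, 250) # scaling centre
    v <- base
    v[1:68] <- px + s * (v[1:68] - px) + dx
    v[69:136] <- py + s * (v[69:136] - py) + dy
    expect_equal(relativize_frame(v), ref, tolerance = 1e-9)
  }
  expect_error(relativize_frame(rep(1, 136)), class = "mfd_degenerate_error")
})

test_that("min-max normalisation follows the endpoint-forcing definition", {
  m <- cbind(a = c(0, 5, 10), b = c(3, 1, 2))
  st <- fit_minmax(m)
  got <- apply_minmax(st, m)
  expect_equal(got[, "a"], c(0, 0.5, 1))
  expect_equal(got[, "b"], c(1, 0, 0.5))
  expect_error(fit_minmax(cbind(c = c(7, 7, 7))),
               class = "mfd_degenerate_error")
  expect_error(fit_minmax(cbind(ok = 1:3, bad = c(2, 2, 2))), "bad")
})

test_that("min-max matches the oracle; fitted rows land in [0,1]; inverse recovers", {
  set.seed(21)
  for (case in 1:100) {
    n <- sample(3:20, 1); p <- sample(1:6, 1)
    m <- matrix(rnorm(n * p, sd = runif(1, 0.1, 10)), n, p)
    if (any(apply(m, 2, function(col) diff(range(col))) == 0)) next
    st <- fit_minmax(m)
    got <- apply_minmax(st, m)
    expect_equal(got, oracle_minmax(m, m), tolerance = 1e-12)
    expect_true(all(got >= -1e-12 & got <= 1 + 1e-12))
    expect_equal(invert_minmax(st, got), m, tolerance = 1e-9)
  }
  # new rows may exceed [0,1] and are not clipped
  st <- fit_minmax(cbind(0:10))
  expect_equal(apply_minmax(st, cbind(c(-5, 20))), cbind(c(-0.5, 2)))
})

test_that("normalisation state survives a JSON round trip", {
  st <- fit_minmax(landmark_matrix(tiny_dataset(8)))
  path <- withr::local_tempfile(fileext = ".json")
  write_minmax_json(st, path)
  back <- read_minmax_json(path)
  expect_equal(unname(unlist(back$min)), unname(st$min))
  expect_equal(unname(unlist(back$max)), unname(st$max))
})

test_that("full preprocessing repairs every planted corrupt cell", {
  sim <- generate_dataset(synthetic_config(
    n_participants = 3, frames_per_participant = 80,
    occlusion_rate = 0.01, seed = 5))
  raw <- landmark_matrix(sim$dataset)
  expect_gt(sum(!is.finite(raw)), 0) # corruption really present
  pre <- preprocess_mfd(sim$dataset)
  clean <- landmark_matrix(pre$dataset)
  expect_true(all(is.finite(clean)))
  expect_true(all(clean >= 0 & clean <= 1)) # fitted rows span [0,1]
  # every non-finite raw cell was flagged
  expect_true(all(pre$mask[!is.finite(raw)]))
})

test_that("a dataset without outliers passes through repairs unchanged", {
  set.seed(6)
  n <- 40
  base <- template_face()$coords
  # uniform noise keeps every value within ~1.7 population sigma of the mean
  coords <- matrix(rep(base, each = n), n, 136) + runif(n * 136, -2, 2)
  ds <- mfd_data(coords, rep_len(1:5, n))
  pre <- preprocess_mfd(ds, relativize = FALSE, normalize = FALSE)
  expect_false(any(pre$mask))
  expect_equal(landmark_matrix(pre$dataset), landmark_matrix(ds),
               tolerance = 1e-12)
  # with all stages on, the result equals relativise + min-max of the input
  pre2 <- preprocess_mfd(ds)
  direct <- t(apply(landmark_matrix(ds), 1, relativize_frame))
  st <- fit_minmax(direct)
  expect_equal(unname(landmark_matrix(pre2$dataset)),
               unname(apply_minmax(st, direct)), tolerance = 1e-12)
})

test_that("normalisation is fitted on the requested rows only", {
  ds <- tiny_dataset(n = 10, seed = 2)
  pre <- preprocess_mfd(ds, fit_index = 1:6)
  m <- landmark_matrix(pre$dataset)
  expect_true(all(m[1:6, ] >= -1e-12 & m[1:6, ] <= 1 + 1e-12))
  expect_identical(pre$state$l, 6L)
})
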