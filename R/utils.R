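#' Derive a reproducible child seed from a master seed
#'
#' Expands one master seed into independent per-stage / per-repetition seeds
#' via a counter-based linear-congruential hash, so that every stochastic
#' stage of the pipeline can be replayed in isolation. The result always
#' lies in `[1, 2^31 - 2]` and is safe to pass to [set.seed()].
#'
#' @param master integer master seed.
#' @param ... one or more integer counters (stream id, repetition index, ...).
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, 3, 7)
derive_seed <- function(master, ...) {
  idx <- c(...)
  stopifnot(length(master) == 1, is.finite(master))
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(master) %% m
  for (k in as.numeric(idx)) {
    # multipliers are classic MINSTD constants; all arithmetic stays < 2^53
    s <- (s * 48271 + (k %% m) * 16807 + 1) %% m
  }
  as.integer(s %% (m - 2L) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds so that every class is
#' spread as evenly as possible across folds.
#'
#' @param y class labels (any atomic vector).
#' @param k number of folds.
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1..k`, same length as `y`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  stopifnot(k >= 2)
  n <- length(y)
  fold <- integer(n)
  rng_local(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  fold
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
rng_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

abort_mfd <- function(msg, class) {
  stop(structure(
    class = c(class, "mfd_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
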