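#' Deep residual network configuration
#'
#' The base learner of the stacked classifier is a residual multilayer
#' perceptron for tabular input: an input projection, a chain of residual
#' blocks (two dense layers each, with batch normalisation, ReLU and
#' dropout on the inner branch and an identity shortcut), a pre-output
#' dense layer and a softmax output. Counting trainable dense layers gives
#' `n_layers = 1 + 2 * n_blocks + 1 + 1`; the published depth of 15 layers
#' with hidden width 32 corresponds to 6 residual blocks.
#'
#' @param input_dim number of input features.
#' @param classes vector of class labels the network discriminates
#'   (default the five fatigue levels `1:5`).
#' @param hidden_width neurons per hidden layer (published value 32).
#' @param n_layers total trainable dense layers (published value 15); must
#'   equal `3 + 2 * b` for a positive integer `b`.
#' @param epochs training epochs (published value 100).
#' @param batch_size minibatch size (published value 32).
#' @param dropout dropout rate on the residual branch.
#' @param l2 L2 weight-decay coefficient.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed for initialisation, shuffling and dropout.
#' @param shortcut keep the identity shortcut connections (default `TRUE`).
#'   Setting `FALSE` yields an equally deep plain MLP — an ablation switch
#'   for studying the degradation problem shortcuts are meant to mitigate.
#' @return a list of class `drn_config`.
#' @export
drn_config <- function(input_dim, classes = 1:5, hidden_width = 32,
                       n_layers = 15, epochs = 100, batch_size = 32,
                       dropout = 0.2, l2 = 1e-4, learning_rate = 1e-3,
                       seed = 1L, shortcut = TRUE) {
  structure(list(input_dim = input_dim, classes = classes,
                 hidden_width = hidden_width, n_layers = n_layers,
                 epochs = epochs, batch_size = batch_size,
                 dropout = dropout, l2 = l2, learning_rate = learning_rate,
                 seed = seed, shortcut = shortcut),
            class = "drn_config")
}

drn_n_blocks <- function(n_layers) {
  b <- (n_layers - 3) / 2
  if (n_layers < 5 || b != round(b)) {
    abort_mfd(sprintf(
      "n_layers = %d cannot be decomposed as 1 input + 2b residual + 1 pre-output + 1 output",
      n_layers), "mfd_validation_error")
  }
  as.integer(b)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

rowmat <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

#' Build an untrained deep residual network
#'
#' He-initialised weights; batch-normalisation scale 1, shift 0, running
#' mean 0 and running variance 1, so an untrained block in inference mode
#' with zero weights is the identity map.
#'
#' @param config a [drn_config()].
#' @return an object of class `drn_model`.
#' @export
build_drn <- function(config) {
  stopifnot(inherits(config, "drn_config"))
  b <- drn_n_blocks(config$n_layers)
  h <- config$hidden_width
  d <- config$input_dim
  k <- length(config$classes)
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)),
                                   nin, nout)
  params <- list()
  bn <- list()
  rng_local(config$seed, {
    params$W_in <- he(d, h); params$b_in <- numeric(h)
    for (i in seq_len(b)) {
      params[[paste0("W1_", i)]] <- he(h, h)
      params[[paste0("b1_", i)]] <- numeric(h)
      params[[paste0("gamma_", i)]] <- rep(1, h)
      params[[paste0("beta_", i)]] <- numeric(h)
      params[[paste0("W2_", i)]] <- he(h, h)
      params[[paste0("b2_", i)]] <- numeric(h)
      bn[[i]] <- list(mean = numeric(h), var = rep(1, h))
    }
    params$W_pre <- he(h, h); params$b_pre <- numeric(h)
    params$W_out <- he(h, k); params$b_out <- numeric(k)
  })
  structure(list(config = config, n_blocks = b, params = params, bn = bn,
                 trained_epochs = 0L, loss_history = numeric(0)),
            class = "drn_model")
}

#' Number of trainable dense layers in a network
#' @param model a `drn_model`.
#' @return integer layer count, by introspection of the parameter list.
#' @export
count_dense_layers <- function(model) {
  sum(grepl("^W", names(model$params)))
}

#' Extract one residual block
#' @param model a `drn_model`.
#' @param i block index.
#' @return list with the block's parameters and running statistics.
#' @export
drn_block <- function(model, i) {
  stopifnot(i >= 1, i <= model$n_blocks)
  p <- model$params
  list(W1 = p[[paste0("W1_", i)]], b1 = p[[paste0("b1_", i)]],
       gamma = p[[paste0("gamma_", i)]], beta = p[[paste0("beta_", i)]],
       W2 = p[[paste0("W2_", i)]], b2 = p[[paste0("b2_", i)]],
       mean = model$bn[[i]]$mean, var = model$bn[[i]]$var)
}

#' Forward pass through one residual block (inference mode)
#'
#' Computes `F(X) + X`: the branch applies dense, batch normalisation with
#' the stored running statistics, ReLU, then a second dense layer, and the
#' shortcut adds the unmodified input. With all-zero weights and identity
#' normalisation the block is exactly the identity map.
#'
#' @param block a block as returned by [drn_block()].
#' @param x numeric vector of length `width`, or a matrix with `width`
#'   columns.
#' @return same shape as `x`.
#' @export
residual_forward <- function(block, x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, 1) else as.matrix(x)
  if (ncol(xm) != ncol(block$W1)) {
    abort_mfd("input width does not match the block width",
              "mfd_validation_error")
  }
  n <- nrow(xm)
  z1 <- xm %*% block$W1 + rowmat(block$b1, n)
  xhat <- (z1 - rowmat(block$mean, n)) / rowmat(sqrt(block$var + 1e-5), n)
  a <- relu(xhat * rowmat(block$gamma, n) + rowmat(block$beta, n))
  out <- xm + a %*% block$W2 + rowmat(block$b2, n)
  if (vec) drop(out) else out
}

# Full forward pass. training = TRUE uses batch statistics and dropout and
# returns the cache needed by the backward pass.
drn_forward <- function(model, x, training = FALSE) {
  p <- model$params
  cfg <- model$config
  n <- nrow(x)
  eps <- 1e-5
  cache <- list()
  h1 <- x %*% p$W_in + rowmat(p$b_in, n)
  h <- relu(h1)
  if (training) cache$h1 <- h1
  if (training) cache$h_in <- x
  hs <- vector("list", model$n_blocks)
  for (i in seq_len(model$n_blocks)) {
    W1 <- p[[paste0("W1_", i)]]; b1 <- p[[paste0("b1_", i)]]
    g <- p[[paste0("gamma_", i)]]; be <- p[[paste0("beta_", i)]]
    W2 <- p[[paste0("W2_", i)]]; b2 <- p[[paste0("b2_", i)]]
    z1 <- h %*% W1 + rowmat(b1, n)
    if (training) {
      mu <- colMeans(z1)
      va <- colMeans(z1^2) - mu^2
      xhat <- (z1 - rowmat(mu, n)) / rowmat(sqrt(va + eps), n)
    } else {
      xhat <- (z1 - rowmat(model$bn[[i]]$mean, n)) /
        rowmat(sqrt(model$bn[[i]]$var + eps), n)
    }
    z1n <- xhat * rowmat(g, n) + rowmat(be, n)
    a <- relu(z1n)
    if (training && cfg$dropout > 0) {
      mask <- (matrix(stats::runif(n * ncol(a)), n) >= cfg$dropout) /
        (1 - cfg$dropout)
      ad <- a * mask
    } else {
      mask <- NULL
      ad <- a
    }
    z2 <- ad %*% W2 + rowmat(b2, n)
    if (training) {
      hs[[i]] <- list(h = h, xhat = xhat, z1n = z1n, ad = ad, mask = mask,
                      mu = mu, va = va)
    }
    h <- if (isFALSE(cfg$shortcut)) z2 else h + z2
  }
  zp <- h %*% p$W_pre + rowmat(p$b_pre, n)
  hp <- relu(zp)
  logits <- hp %*% p$W_out + rowmat(p$b_out, n)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  if (training) {
    cache$blocks <- hs
    cache$h_res <- h
    cache$zp <- zp
    cache$hp <- hp
  }
  list(probs = probs, cache = cache)
}

# Backward pass; returns gradients named like the parameters.
drn_backward <- function(model, probs, yind, cache) {
  p <- model$params
  cfg <- model$config
  n <- nrow(probs)
  eps <- 1e-5
  grads <- list()
  Y <- matrix(0, n, ncol(probs))
  Y[cbind(seq_len(n), yind)] <- 1
  dlogits <- (probs - Y) / n
  grads$W_out <- crossprod(cache$hp, dlogits) + cfg$l2 * p$W_out
  grads$b_out <- colSums(dlogits)
  dhp <- tcrossprod(dlogits, p$W_out)
  dzp <- dhp * (cache$zp > 0)
  grads$W_pre <- crossprod(cache$h_res, dzp) + cfg$l2 * p$W_pre
  grads$b_pre <- colSums(dzp)
  dh <- tcrossprod(dzp, p$W_pre)
  for (i in rev(seq_len(model$n_blocks))) {
    bl <- cache$blocks[[i]]
    W1 <- p[[paste0("W1_", i)]]; W2 <- p[[paste0("W2_", i)]]
    g <- p[[paste0("gamma_", i)]]
    dz2 <- dh
    grads[[paste0("W2_", i)]] <- crossprod(bl$ad, dz2) + cfg$l2 * W2
    grads[[paste0("b2_", i)]] <- colSums(dz2)
    dad <- tcrossprod(dz2, W2)
    da <- if (is.null(bl$mask)) dad else dad * bl$mask
    dz1n <- da * (bl$z1n > 0)
    grads[[paste0("gamma_", i)]] <- colSums(dz1n * bl$xhat)
    grads[[paste0("beta_", i)]] <- colSums(dz1n)
    dxhat <- dz1n * rowmat(g, nrow(dz1n))
    inv_sd <- 1 / sqrt(bl$va + eps)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * bl$xhat)
    dz1 <- (dxhat - rowmat(m1, n) - bl$xhat * rowmat(m2, n)) *
      rowmat(inv_sd, n)
    grads[[paste0("W1_", i)]] <- crossprod(bl$h, dz1) + cfg$l2 * W1
    grads[[paste0("b1_", i)]] <- colSums(dz1)
    branch <- tcrossprod(dz1, W1)
    dh <- if (isFALSE(cfg$shortcut)) branch else dh + branch
  }
  dh1 <- dh * (cache$h1 > 0)
  grads$W_in <- crossprod(cache$h_in, dh1) + cfg$l2 * p$W_in
  grads$b_in <- colSums(dh1)
  grads
}

#' Train a deep residual network
#'
#' Minimises the softmax cross-entropy plus L2 penalty with the Adam
#' optimiser over shuffled minibatches. Training is deterministic given the
#' configuration seed (single-threaded base-R linear algebra throughout).
#' With `epochs = 0` the model is returned untrained.
#'
#' @param model a `drn_model` from [build_drn()].
#' @param x numeric matrix (samples x `input_dim`).
#' @param y labels; every value must be one of `config$classes`.
#' @param epochs optional override of the configured epoch count.
#' @return the trained `drn_model`, with `loss_history` (mean minibatch
#'   loss per epoch) appended.
#' @export
train_drn <- function(model, x, y, epochs = NULL) {
  cfg <- model$config
  x <- as.matrix(x)
  epochs <- epochs %||% cfg$epochs
  yind <- match(y, cfg$classes)
  if (anyNA(yind)) {
    abort_mfd("labels outside the configured class set", "mfd_validation_error")
  }
  if (epochs == 0) return(model)
  n <- nrow(x)
  adam <- list(m = lapply(model$params, function(w) w * 0),
               v = lapply(model$params, function(w) w * 0), t = 0)
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  mom <- 0.9
  history <- numeric(epochs)
  rng_local(derive_seed(cfg$seed, 1), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        xb <- x[idx, , drop = FALSE]
        fw <- drn_forward(model, xb, training = TRUE)
        pr <- pmax(fw$probs, 1e-12)
        ll <- -mean(log(pr[cbind(seq_along(idx), yind[idx])]))
        wpen <- sum(vapply(model$params[grep("^W", names(model$params))],
                           function(w) sum(w^2), 0))
        loss <- ll + cfg$l2 / 2 * wpen
        if (!is.finite(loss)) {
          abort_mfd(sprintf("non-finite loss at epoch %d", ep),
                    "mfd_numeric_error")
        }
        losses <- c(losses, loss)
        # update running batch-norm statistics
        for (i in seq_len(model$n_blocks)) {
          bl <- fw$cache$blocks[[i]]
          model$bn[[i]]$mean <- mom * model$bn[[i]]$mean + (1 - mom) * bl$mu
          model$bn[[i]]$var <- mom * model$bn[[i]]$var + (1 - mom) * bl$va
        }
        grads <- drn_backward(model, fw$probs, yind[idx], fw$cache)
        adam$t <- adam$t + 1
        sc <- cfg$learning_rate * sqrt(1 - b2^adam$t) / (1 - b1^adam$t)
        for (nm in names(model$params)) {
          gnm <- grads[[nm]]
          adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * gnm
          adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * gnm^2
          model$params[[nm]] <- model$params[[nm]] -
            sc * adam$m[[nm]] / (sqrt(adam$v[[nm]]) + aeps)
        }
      }
      history[ep] <- mean(losses)
    }
  })
  model$trained_epochs <- model$trained_epochs + epochs
  model$loss_history <- c(model$loss_history, history)
  model
}

#' Predict class probabilities from a deep residual network
#' @param model a `drn_model`.
#' @param x numeric matrix (samples x `input_dim`).
#' @return matrix of class probabilities (columns named by class).
#' @export
predict_drn <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$config$input_dim) {
    abort_mfd("feature-set mismatch with the network input width",
              "mfd_validation_error")
  }
  pr <- drn_forward(model, x, training = FALSE)$probs
  colnames(pr) <- as.character(model$config$classes)
  pr
}
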