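# Minimal feed-forward neural-network engine.
#
# All models in this package (supervised encoder, decoder, CGAN generator and
# discriminator) are plain multilayer perceptrons, so a small dense-layer
# engine with Adam, batch normalization, inverted dropout and seeded
# initialisation suffices. Everything is vectorised over mini-batches through
# BLAS matrix products; all randomness (init, shuffling, dropout masks) comes
# from R's RNG so a single set.seed() makes training fully reproducible.

#' Define a dense layer
#'
#' @param input_dim,output_dim layer dimensions.
#' @param activation one of "linear", "relu", "sigmoid", "softmax".
#' @param batchnorm apply batch normalization between the affine map and the
#'   activation.
#' @param dropout inverted-dropout rate applied to the layer's output during
#'   training (0 disables).
#' @return a layer description list.
#' @keywords internal
nn_dense <- function(input_dim, output_dim, activation = "linear",
                     batchnorm = FALSE, dropout = 0) {
  activation <- match.arg(activation, c("linear", "relu", "sigmoid", "softmax"))
  stopifnot(input_dim >= 1, output_dim >= 1, dropout >= 0, dropout < 1)
  list(input_dim = as.integer(input_dim), output_dim = as.integer(output_dim),
       activation = activation, batchnorm = isTRUE(batchnorm),
       dropout = dropout)
}

#' Build and initialise a network from layer descriptions
#'
#' He initialisation for ReLU layers, Glorot for the rest. Consumes the
#' current RNG stream; call set.seed() beforehand for reproducibility.
#' @param layers list of [nn_dense()] descriptions; consecutive dims must chain.
#' @return a network object (list of initialised layers).
#' @keywords internal
nn_network <- function(layers) {
  for (i in seq_along(layers)[-1]) {
    if (layers[[i]]$input_dim != layers[[i - 1]]$output_dim)
      stop("layer dimension mismatch between layers ", i - 1, " and ", i)
  }
  net <- lapply(layers, function(ly) {
    fan_in <- ly$input_dim; fan_out <- ly$output_dim
    sd <- if (ly$activation == "relu") sqrt(2 / fan_in) else
      sqrt(2 / (fan_in + fan_out))
    ly$W <- matrix(stats::rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out)
    ly$b <- numeric(fan_out)
    if (ly$batchnorm) {
      ly$bn <- list(gamma = rep(1, fan_out), beta = numeric(fan_out),
                    rmean = numeric(fan_out), rvar = rep(1, fan_out),
                    momentum = 0.9, eps = 1e-5)
    }
    ly
  })
  structure(list(layers = net), class = "nn_net")
}

#' Weight matrices of a network (for the L2 penalty)
#' @keywords internal
nn_weights <- function(net) lapply(net$layers, `[[`, "W")

.nn_activate <- function(z, activation) {
  switch(activation,
    linear  = z,
    relu    = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    softmax = {
      e <- exp(z - apply(z, 1, max))
      e / rowSums(e)
    })
}

#' Forward pass
#'
#' @param net network from [nn_network()].
#' @param x input matrix (batch x input_dim).
#' @param training if TRUE, use batch statistics for batch norm, apply dropout
#'   (consuming RNG), and cache intermediates for [nn_backward()].
#' @return list with `output` and, when training, per-layer caches; `acts`
#'   always holds each layer's post-activation output (pre-dropout), so the
#'   latent layer of an encoder can be read out directly.
#' @keywords internal
nn_forward <- function(net, x, training = FALSE) {
  stopifnot(is.matrix(x), ncol(x) == net$layers[[1]]$input_dim)
  n <- nrow(x)
  L <- length(net$layers)
  caches <- vector("list", L)
  acts <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    z <- a %*% ly$W
    z <- sweep(z, 2, ly$b, "+")
    if (ly$batchnorm) {
      bn <- ly$bn
      if (training) {
        mu <- colMeans(z)
        v <- colMeans(z^2) - mu^2
        zc <- sweep(z, 2, mu, "-")
        zhat <- sweep(zc, 2, sqrt(v + bn$eps), "/")
        # running stats are updated in nn_train loops via the returned cache
        caches_bn <- list(mu = mu, v = v, zhat = zhat)
      } else {
        zc <- sweep(z, 2, bn$rmean, "-")
        zhat <- sweep(zc, 2, sqrt(bn$rvar + bn$eps), "/")
        caches_bn <- NULL
      }
      z2 <- sweep(sweep(zhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
    } else {
      z2 <- z
      caches_bn <- NULL
    }
    out <- .nn_activate(z2, ly$activation)
    acts[[l]] <- out
    mask <- NULL
    if (training && ly$dropout > 0) {
      keep <- 1 - ly$dropout
      mask <- matrix(stats::runif(n * ly$output_dim) < keep, n, ly$output_dim)
      out <- out * mask / keep
    }
    if (training)
      caches[[l]] <- list(input = a, z2 = z2, act = acts[[l]], mask = mask,
                          bn = caches_bn)
    a <- out
  }
  list(output = a, acts = acts, caches = if (training) caches else NULL)
}

#' Backward pass
#'
#' @param net network.
#' @param fwd result of `nn_forward(..., training = TRUE)`.
#' @param d_preact gradient of the loss with respect to the *pre-activation*
#'   of the final layer (the usual softmax/sigmoid/linear loss shortcuts).
#' @return list with `grads` (per layer: W, b, and gamma/beta for batch-norm
#'   layers) and `d_input`, the gradient with respect to the network input
#'   (used to chain the discriminator's gradient into the generator).
#' @keywords internal
nn_backward <- function(net, fwd, d_preact) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dz2 <- d_preact
  for (l in rev(seq_len(L))) {
    ly <- net$layers[[l]]
    cache <- fwd$caches[[l]]
    if (l < L) {
      da <- dz2  # grad w.r.t. this layer's (post-dropout) output
      if (!is.null(cache$mask)) da <- da * cache$mask / (1 - ly$dropout)
      dz2 <- switch(ly$activation,
        linear  = da,
        relu    = da * (cache$z2 > 0),
        sigmoid = da * cache$act * (1 - cache$act),
        softmax = stop("softmax is only supported as the output layer"))
    }
    if (ly$batchnorm) {
      bn <- ly$bn; cb <- cache$bn
      dgamma <- colSums(dz2 * cb$zhat)
      dbeta <- colSums(dz2)
      m <- nrow(dz2)
      dzhat <- sweep(dz2, 2, bn$gamma, "*")
      inv_sd <- 1 / sqrt(cb$v + bn$eps)
      dz <- sweep(dzhat - rep(1, m) %o% (colMeans(dzhat)) -
                    cb$zhat * (rep(1, m) %o% colMeans(dzhat * cb$zhat)),
                  2, inv_sd, "*")
    } else {
      dgamma <- dbeta <- NULL
      dz <- dz2
    }
    grads[[l]] <- list(W = crossprod(cache$input, dz), b = colSums(dz),
                       gamma = dgamma, beta = dbeta)
    dz2 <- tcrossprod(dz, ly$W)  # grad w.r.t. this layer's input
  }
  list(grads = grads, d_input = dz2)
}

#' Initialise Adam optimiser state for a network
#' @keywords internal
nn_adam_init <- function(net) {
  state <- lapply(net$layers, function(ly) {
    s <- list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    if (ly$batchnorm) {
      s$mg <- s$vg <- ly$bn$gamma * 0
      s$mB <- s$vB <- ly$bn$beta * 0
    }
    s
  })
  list(t = 0L, layers = state)
}

#' One Adam update
#'
#' @param l2 coefficient of the L2 penalty lambda * sum_l ||W_l||^2; applied
#'   to weight matrices only (not biases or batch-norm parameters).
#' @keywords internal
nn_adam_step <- function(net, grads, state, lr, l2 = 0,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / c1) / (sqrt(v / c2) + eps)
    list(p = p, m = m, v = v)
  }
  for (l in seq_along(net$layers)) {
    g <- grads[[l]]
    st <- state$layers[[l]]
    gW <- g$W + 2 * l2 * net$layers[[l]]$W
    u <- upd(net$layers[[l]]$W, gW, st$mW, st$vW)
    net$layers[[l]]$W <- u$p; st$mW <- u$m; st$vW <- u$v
    u <- upd(net$layers[[l]]$b, g$b, st$mb, st$vb)
    net$layers[[l]]$b <- u$p; st$mb <- u$m; st$vb <- u$v
    if (net$layers[[l]]$batchnorm) {
      u <- upd(net$layers[[l]]$bn$gamma, g$gamma, st$mg, st$vg)
      net$layers[[l]]$bn$gamma <- u$p; st$mg <- u$m; st$vg <- u$v
      u <- upd(net$layers[[l]]$bn$beta, g$beta, st$mB, st$vB)
      net$layers[[l]]$bn$beta <- u$p; st$mB <- u$m; st$vB <- u$v
    }
    state$layers[[l]] <- st
  }
  list(net = net, state = state)
}

#' Update batch-norm running statistics from a training-mode forward cache
#' @keywords internal
nn_update_bn <- function(net, fwd) {
  for (l in seq_along(net$layers)) {
    if (net$layers[[l]]$batchnorm) {
      cb <- fwd$caches[[l]]$bn
      mom <- net$layers[[l]]$bn$momentum
      net$layers[[l]]$bn$rmean <- mom * net$layers[[l]]$bn$rmean +
        (1 - mom) * cb$mu
      net$layers[[l]]$bn$rvar <- mom * net$layers[[l]]$bn$rvar +
        (1 - mom) * cb$v
    }
  }
  net
}

#' Early-stopping controller
#'
#' Tracks a monitored validation quantity across epochs; signals a stop after
#' `patience` epochs without improvement and remembers the best epoch so the
#' model can be reverted to its state there. Shared by all training loops and
#' directly testable on a scripted loss sequence.
#'
#' @param patience number of epochs without a decrease before stopping.
#' @param min_delta minimal decrease counted as an improvement.
#' @return an environment with `update(value)` returning
#'   `list(improved, stop)`, plus fields `best_value`, `best_epoch`, `epoch`.
#' @export
#' @examples
#' es <- make_early_stopper(patience = 2)
#' for (v in c(1.0, 0.5, 0.6, 0.7, 0.8)) print(es$update(v))
#' es$best_epoch  # 2
make_early_stopper <- function(patience = 100, min_delta = 0) {
  stopifnot(patience >= 1)
  self <- new.env(parent = emptyenv())
  self$patience <- patience
  self$epoch <- 0L
  self$best_value <- Inf
  self$best_epoch <- 0L
  self$wait <- 0L
  self$update <- function(value) {
    stopifnot(is.finite(value))
    self$epoch <- self$epoch + 1L
    improved <- value < self$best_value - min_delta
    if (improved) {
      self$best_value <- value
      self$best_epoch <- self$epoch
      self$wait <- 0L
    } else {
      self$wait <- self$wait + 1L
    }
    list(improved = improved, stop = self$wait >= self$patience)
  }
  self
}

# Mini-batch index generator: seeded shuffle, last batch may be smaller but
# never of size 1 (folded into the previous batch to keep batch-norm sane).
.nn_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  starts <- seq(1, n, by = batch_size)
  batches <- lapply(starts, function(s) idx[s:min(s + batch_size - 1, n)])
  k <- length(batches)
  if (k > 1 && length(batches[[k]]) == 1) {
    batches[[k - 1]] <- c(batches[[k - 1]], batches[[k]])
    batches[[k]] <- NULL
  }
  batches
}
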