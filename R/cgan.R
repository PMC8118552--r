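# Conditional GAN in the latent space.
#
# The generator maps [32-dim uniform(-1,1) noise, K-dim condition profile] to
# a 64-dim latent vector; the discriminator scores [latent, condition] pairs.
# Training alternates one discriminator and one generator Adam step per
# mini-batch with the standard non-saturating generator objective. Working in
# the autoencoder's low-dimensional latent space sidesteps the instability of
# adversarial training directly in gene space; only the discriminator ever
# observes real latent encodings.

#' Generator hyperparameters
#'
#' @param noise_dim size of the uniform(-1,1) noise vector (32).
#' @param condition_dim number of condition channels K (8).
#' @param hidden_dims ReLU hidden widths (256, 512).
#' @param output_dim latent dimension of the autoencoder (64, linear output).
#' @return list of class `generator_spec`.
#' @export
generator_spec <- function(noise_dim = 32, condition_dim = 8,
                           hidden_dims = c(256, 512), output_dim = 64) {
  stopifnot(noise_dim >= 1, condition_dim >= 1, output_dim >= 1)
  structure(as.list(environment()), class = "generator_spec")
}

#' Discriminator hyperparameters
#'
#' @param latent_dim latent dimension (64).
#' @param condition_dim number of condition channels K (8).
#' @param hidden_dims ReLU hidden widths (a single layer of 512).
#' @return list of class `discriminator_spec`.
#' @export
discriminator_spec <- function(latent_dim = 64, condition_dim = 8,
                               hidden_dims = 512) {
  stopifnot(latent_dim >= 1, condition_dim >= 1)
  structure(as.list(environment()), class = "discriminator_spec")
}

#' CGAN training configuration
#'
#' @param learning_rate Adam learning rate for both networks (5e-5).
#' @param max_epochs maximum full passes over the data (50000 at full scale;
#'   reduce for small validation runs).
#' @param batch_size mini-batch size.
#' @param d_steps discriminator updates per generator update.
#' @param equilibrium_window epochs over which the plateau/divergence monitor
#'   looks back.
#' @param plateau_tol relative loss change under which training may stop
#'   early as converged (set to 0 to disable).
#' @param ema_decay exponential-moving-average decay for the inference copy
#'   of the generator weights; adversarial updates oscillate around the
#'   equilibrium, and the averaged generator is the stable one used for
#'   generation (0 disables).
#' @return list of class `gan_train_config`.
#' @export
gan_train_config <- function(learning_rate = 5e-5, max_epochs = 50000,
                             batch_size = 128, d_steps = 1,
                             equilibrium_window = 500, plateau_tol = 1e-4,
                             ema_decay = 0.999) {
  stopifnot(learning_rate > 0, max_epochs >= 1, d_steps >= 1,
            ema_decay >= 0, ema_decay < 1)
  structure(as.list(environment()), class = "gan_train_config")
}

# exponential moving average of all trainable parameters of a network
.nn_ema <- function(ema, net, decay) {
  for (l in seq_along(net$layers)) {
    ema$layers[[l]]$W <- decay * ema$layers[[l]]$W +
      (1 - decay) * net$layers[[l]]$W
    ema$layers[[l]]$b <- decay * ema$layers[[l]]$b +
      (1 - decay) * net$layers[[l]]$b
  }
  ema
}

.clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Discriminator loss
#'
#' `(1/n) sum_i [ -log D(z_i) - log(1 - D(G(r_i))) ]`, probabilities clipped
#' to `[1e-7, 1-1e-7]` before the logarithm. At maximal confusion
#' (all outputs 0.5) the loss equals `2 log 2`.
#'
#' @param d_real discriminator outputs on real latents.
#' @param d_fake discriminator outputs on generated latents.
#' @return scalar loss.
#' @export
discriminator_loss <- function(d_real, d_fake) {
  d_real <- as.numeric(d_real); d_fake <- as.numeric(d_fake)
  if (length(d_real) == 0 || length(d_fake) == 0) stop("empty batch")
  if (length(d_real) != length(d_fake))
    stop("d_real and d_fake lengths differ")
  mean(-log(.clip_prob(d_real)) - log(1 - .clip_prob(d_fake)))
}

#' Generator loss (non-saturating form)
#'
#' The generator maximizes `(1/n) sum_i log D(G(r_i))`; the returned value is
#' the quantity actually minimized, `-(1/n) sum_i log D(G(r_i))`, which
#' avoids the vanishing gradient of the saturating `log(1 - D)` objective
#' early in training. At D = 0.5 the value is `log 2`.
#'
#' @param d_fake discriminator outputs on generated latents.
#' @return scalar loss (minimized).
#' @export
generator_loss <- function(d_fake) {
  d_fake <- as.numeric(d_fake)
  if (length(d_fake) == 0) stop("empty batch")
  -mean(log(.clip_prob(d_fake)))
}

.build_generator <- function(gspec) {
  dims <- c(gspec$noise_dim + gspec$condition_dim, gspec$hidden_dims,
            gspec$output_dim)
  layers <- list()
  for (i in seq_along(gspec$hidden_dims))
    layers[[i]] <- nn_dense(dims[i], dims[i + 1], "relu")
  layers[[length(layers) + 1]] <-
    nn_dense(dims[length(dims) - 1], dims[length(dims)], "linear")
  nn_network(layers)
}

.build_discriminator <- function(dspec) {
  dims <- c(dspec$latent_dim + dspec$condition_dim, dspec$hidden_dims, 1)
  layers <- list()
  for (i in seq_along(dspec$hidden_dims))
    layers[[i]] <- nn_dense(dims[i], dims[i + 1], "relu")
  layers[[length(layers) + 1]] <-
    nn_dense(dims[length(dims) - 1], 1, "sigmoid")
  nn_network(layers)
}

#' Train the conditional GAN
#'
#' Latent encodings must come from the supervised encoder trained on the same
#' cells; the generator never sees them directly — real latents enter only
#' the discriminator's input, and the generator learns exclusively through
#' the discriminator's gradient.
#'
#' @param latents cells x latent_dim matrix from [encode()].
#' @param profiles row-aligned cells x K conditioning profiles.
#' @param gspec a [generator_spec()].
#' @param dspec a [discriminator_spec()].
#' @param cfg a [gan_train_config()].
#' @param seed integer seed.
#' @param verbose print progress every 500 epochs.
#' @return object of class `cgan` with the trained generator, discriminator,
#'   and per-epoch history (`loss_d`, `loss_g`, `d_real_mean`,
#'   `d_fake_mean`).
#' @export
train_cgan <- function(latents, profiles, gspec = generator_spec(),
                       dspec = discriminator_spec(), cfg = gan_train_config(),
                       seed = 1, verbose = FALSE) {
  latents <- as.matrix(latents)
  profiles <- as.matrix(profiles)
  if (nrow(latents) != nrow(profiles))
    stop("latents and profiles are not row-aligned")
  if (ncol(latents) != gspec$output_dim)
    stop("generator output_dim does not match the latent dimension")
  if (ncol(latents) != dspec$latent_dim)
    stop("discriminator latent_dim does not match the latent dimension")
  if (ncol(profiles) != gspec$condition_dim)
    stop("condition_dim does not match the number of channels")
  n <- nrow(latents)

  set.seed(seed)
  gen <- .build_generator(gspec)
  dis <- .build_discriminator(dspec)
  gen_ema <- gen
  g_state <- nn_adam_init(gen)
  d_state <- nn_adam_init(dis)

  history <- data.frame(epoch = integer(0), loss_d = numeric(0),
                        loss_g = numeric(0), d_real_mean = numeric(0),
                        d_fake_mean = numeric(0))
  for (epoch in seq_len(cfg$max_epochs)) {
    ep <- c(loss_d = 0, loss_g = 0, d_real = 0, d_fake = 0, nb = 0)
    for (idx in .nn_batches(n, cfg$batch_size)) {
      m <- length(idx)
      z_real <- latents[idx, , drop = FALSE]
      r <- profiles[idx, , drop = FALSE]
      # --- discriminator step(s): real up, fake (detached) down
      for (s in seq_len(cfg$d_steps)) {
        noise <- matrix(stats::runif(m * gspec$noise_dim, -1, 1),
                        m, gspec$noise_dim)
        z_fake <- nn_forward(gen, cbind(noise, r), training = FALSE)$output
        fwd_r <- nn_forward(dis, cbind(z_real, r), training = TRUE)
        fwd_f <- nn_forward(dis, cbind(z_fake, r), training = TRUE)
        p_r <- .clip_prob(fwd_r$output)
        p_f <- .clip_prob(fwd_f$output)
        # d/dlogit of -log(sigma): sigma-1 ; of -log(1-sigma): sigma
        bwd_r <- nn_backward(dis, fwd_r, (p_r - 1) / m)
        bwd_f <- nn_backward(dis, fwd_f, p_f / m)
        grads <- mapply(function(a, b) {
          list(W = a$W + b$W, b = a$b + b$b,
               gamma = if (!is.null(a$gamma)) a$gamma + b$gamma,
               beta = if (!is.null(a$beta)) a$beta + b$beta)
        }, bwd_r$grads, bwd_f$grads, SIMPLIFY = FALSE)
        upd <- nn_adam_step(dis, grads, d_state, lr = cfg$learning_rate)
        dis <- upd$net; d_state <- upd$state
      }
      # --- generator step: non-saturating loss through a frozen D
      noise <- matrix(stats::runif(m * gspec$noise_dim, -1, 1),
                      m, gspec$noise_dim)
      fwd_g <- nn_forward(gen, cbind(noise, r), training = TRUE)
      fwd_d <- nn_forward(dis, cbind(fwd_g$output, r), training = TRUE)
      p_g <- .clip_prob(fwd_d$output)
      bwd_d <- nn_backward(dis, fwd_d, (p_g - 1) / m)
      d_latent <- bwd_d$d_input[, seq_len(gspec$output_dim), drop = FALSE]
      bwd_g <- nn_backward(gen, fwd_g, d_latent)
      upd <- nn_adam_step(gen, bwd_g$grads, g_state, lr = cfg$learning_rate)
      gen <- upd$net; g_state <- upd$state
      if (cfg$ema_decay > 0) gen_ema <- .nn_ema(gen_ema, gen, cfg$ema_decay)

      ep["loss_d"] <- ep["loss_d"] + discriminator_loss(p_r, p_f)
      ep["loss_g"] <- ep["loss_g"] + generator_loss(p_g)
      ep["d_real"] <- ep["d_real"] + mean(p_r)
      ep["d_fake"] <- ep["d_fake"] + mean(p_f)
      ep["nb"] <- ep["nb"] + 1
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss_d = ep[["loss_d"]] / ep[["nb"]],
      loss_g = ep[["loss_g"]] / ep[["nb"]],
      d_real_mean = ep[["d_real"]] / ep[["nb"]],
      d_fake_mean = ep[["d_fake"]] / ep[["nb"]]))
    if (verbose && epoch %% 500 == 0)
      message(sprintf("epoch %d  L_D %.4f  L_G %.4f  D(real) %.3f D(fake) %.3f",
                      epoch, history$loss_d[epoch], history$loss_g[epoch],
                      history$d_real_mean[epoch], history$d_fake_mean[epoch]))
    if (!all(is.finite(unlist(history[epoch, -1]))))
      stop("CGAN diverged (non-finite loss) at epoch ", epoch)
    w <- cfg$equilibrium_window
    if (epoch >= 2 * w && w > 0) {
      recent <- history[(epoch - w + 1):epoch, ]
      # pinned discriminator = divergence; plateau of both losses = converged
      if (all(recent$d_real_mean > 0.999) && all(recent$d_fake_mean < 0.001))
        stop("CGAN diverged: discriminator pinned at perfect accuracy for ",
             w, " epochs")
      if (cfg$plateau_tol > 0) {
        prev <- history[(epoch - 2 * w + 1):(epoch - w), ]
        rel <- function(a, b) abs(mean(a) - mean(b)) /
          max(abs(mean(b)), 1e-8)
        if (rel(recent$loss_d, prev$loss_d) < cfg$plateau_tol &&
            rel(recent$loss_g, prev$loss_g) < cfg$plateau_tol) break
      }
    }
  }
  structure(list(generator = gen,
                 generator_ema = if (cfg$ema_decay > 0) gen_ema,
                 discriminator = dis, gspec = gspec,
                 dspec = dspec, cfg = cfg, seed = seed, history = history),
            class = "cgan")
}

#' @export
print.cgan <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(paste0("cgan: noise %d + %d channels -> latent %d ",
                     "(%d epochs, D(real) %.3f, D(fake) %.3f)\n"),
              x$gspec$noise_dim, x$gspec$condition_dim, x$gspec$output_dim,
              nrow(x$history), last$d_real_mean, last$d_fake_mean))
  invisible(x)
}

#' Score latents with the trained discriminator
#'
#' @param model a trained [train_cgan()] object.
#' @param latents cells x latent_dim matrix.
#' @param profiles row-aligned conditioning profiles.
#' @return vector of probabilities in (0,1).
#' @export
discriminate <- function(model, latents, profiles) {
  stopifnot(inherits(model, "cgan"))
  latents <- as.matrix(latents); profiles <- as.matrix(profiles)
  as.numeric(nn_forward(model$discriminator, cbind(latents, profiles),
                        training = FALSE)$output)
}

#' Simulate latent encodings conditioned on adjacent profiles
#'
#' Draws `n_per_profile` uniform(-1,1) noise vectors per conditioning profile
#' and maps each [noise, profile] pair through the trained generator.
#'
#' @param model a trained [train_cgan()] object (or its generator with a
#'   `gspec` attribute via the `cgan` class).
#' @param profiles matrix of conditioning profiles, each row on the simplex
#'   (|sum - 1| <= 1e-6).
#' @param n_per_profile replicate latents per profile (100 in the reference
#'   protocol, giving the 95% confidence band downstream).
#' @param seed integer seed.
#' @param use_ema use the moving-average generator weights (the stable
#'   inference copy) when available.
#' @return array of dim (profiles, n_per_profile, latent_dim).
#' @export
generate_latents <- function(model, profiles, n_per_profile = 100, seed = 1,
                             use_ema = TRUE) {
  stopifnot(inherits(model, "cgan"), n_per_profile >= 1)
  profiles <- as.matrix(profiles)
  gspec <- model$gspec
  if (ncol(profiles) != gspec$condition_dim)
    stop("profiles have ", ncol(profiles), " channels; generator expects ",
         gspec$condition_dim)
  dev <- abs(rowSums(profiles) - 1)
  if (any(dev > 1e-6))
    stop("profiles off the simplex (|sum - 1| > 1e-6) at rows: ",
         paste(utils::head(which(dev > 1e-6), 10), collapse = ", "))
  set.seed(seed)
  p <- nrow(profiles)
  noise <- matrix(stats::runif(p * n_per_profile * gspec$noise_dim, -1, 1),
                  p * n_per_profile, gspec$noise_dim)
  cond <- profiles[rep(seq_len(p), each = n_per_profile), , drop = FALSE]
  gen <- if (use_ema && !is.null(model$generator_ema)) model$generator_ema
         else model$generator
  z <- nn_forward(gen, cbind(noise, cond), training = FALSE)$output
  if (any(!is.finite(z))) stop("generator produced non-finite latents")
  array(z, dim = c(n_per_profile, p, gspec$output_dim)) |>
    aperm(c(2, 1, 3))
}
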