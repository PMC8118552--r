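# Supervised autoencoder.
#
# Two-step training: (1) a supervised encoder maps normalized expression to a
# bounded 64-dim latent space and, through a prediction head, to the relative
# isotype profile; it is trained with a Kullback-Leibler divergence loss so
# that the latent space is shaped by the adjacent information. (2) a decoder
# reconstructs full expression profiles from the (frozen) latent encodings
# with a mean-squared-error loss. Both steps use Adam, L2 weight penalties,
# and early stopping on a held-out validation split with best-weight restore
# followed by a few epochs on the full training data.

#' Encoder hyperparameters
#'
#' Defaults follow the reference configuration used throughout this package:
#' hidden layers 512/256 (ReLU), a 64-unit sigmoid latent layer, a 128-unit
#' head predicting the K-channel profile through a softmax output, dropout
#' 0.3 at every hidden layer, L2 penalty 1e-5 and Adam learning rate 1e-4.
#'
#' @param input_dim number of genes (set from data when NULL).
#' @param hidden_dims encoder trunk widths.
#' @param latent_dim size of the bounded (sigmoid) latent layer.
#' @param head_hidden_dim width of the profile-prediction head.
#' @param output_dim number of condition channels K.
#' @param dropout_rate dropout at hidden layers.
#' @param l2_weight L2 penalty coefficient lambda.
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @return list of class `encoder_spec`.
#' @export
encoder_spec <- function(input_dim = NULL, hidden_dims = c(512, 256),
                         latent_dim = 64, head_hidden_dim = 128,
                         output_dim = 8, dropout_rate = 0.3,
                         l2_weight = 1e-5, learning_rate = 1e-4,
                         batch_size = 128) {
  stopifnot(latent_dim >= 1, output_dim >= 2,
            dropout_rate >= 0, dropout_rate < 1, l2_weight >= 0,
            learning_rate > 0)
  structure(as.list(environment()), class = "encoder_spec")
}

#' Decoder hyperparameters
#'
#' Hidden layers 256/512 (ReLU) with batch normalization, linear output of
#' one unit per gene, L2 penalty 1e-5, Adam learning rate 1e-4.
#'
#' @param latent_dim must match the encoder's latent dimension.
#' @param hidden_dims decoder widths.
#' @param output_dim number of genes (set from data when NULL).
#' @param l2_weight,learning_rate,batch_size as in [encoder_spec()].
#' @return list of class `decoder_spec`.
#' @export
decoder_spec <- function(latent_dim = 64, hidden_dims = c(256, 512),
                         output_dim = NULL, l2_weight = 1e-5,
                         learning_rate = 1e-4, batch_size = 128) {
  stopifnot(latent_dim >= 1, l2_weight >= 0, learning_rate > 0)
  structure(as.list(environment()), class = "decoder_spec")
}

#' Early-stopping configuration
#'
#' @param validation_fraction fraction of the training data held out to
#'   monitor the loss (0.10).
#' @param patience_epochs epochs without improvement before stopping (100).
#' @param post_restore_epochs epochs of training on the full data (including
#'   the validation split) after reverting to the best weights (5).
#' @param max_epochs hard cap on training epochs.
#' @return list of class `early_stop_config`.
#' @export
early_stop_config <- function(validation_fraction = 0.10,
                              patience_epochs = 100,
                              post_restore_epochs = 5,
                              max_epochs = 10000) {
  stopifnot(validation_fraction > 0, validation_fraction < 1,
            patience_epochs >= 1, post_restore_epochs >= 0, max_epochs >= 1)
  structure(as.list(environment()), class = "early_stop_config")
}

.sum_sq <- function(weights) sum(vapply(weights, function(w) sum(w^2), 0))

#' Supervised-encoder loss (mean KLD + L2 penalty)
#'
#' `(1/n) sum_i KLD(Y_i || Yhat_i) + lambda * sum_l ||W_l||^2`, with
#' `KLD(Y||Yhat) = sum_k Y_k log(Y_k / Yhat_k)`, the convention
#' `0 * log(0/q) = 0`, and predictions clipped to `[1e-12, 1]` before the log.
#'
#' @param y_true,y_pred batches of simplex profiles (rows on the simplex).
#' @param layer_weights list of weight matrices entering the penalty.
#' @param lambda L2 coefficient.
#' @return non-negative scalar.
#' @export
encoder_loss <- function(y_true, y_pred, layer_weights = list(), lambda = 0) {
  y_true <- as.matrix(y_true); y_pred <- as.matrix(y_pred)
  if (!all(dim(y_true) == dim(y_pred)))
    stop("y_true and y_pred shapes differ")
  if (nrow(y_true) == 0) stop("empty batch")
  q <- pmin(pmax(y_pred, 1e-12), 1)
  terms <- y_true * (log(y_true / q))
  terms[y_true == 0] <- 0
  kld <- mean(rowSums(terms))
  if (!is.finite(kld)) {
    bad <- which(!is.finite(rowSums(terms)))[1]
    stop("non-finite KLD at batch row ", bad)
  }
  kld + lambda * .sum_sq(layer_weights)
}

#' Decoder loss (mean squared error + L2 penalty)
#'
#' Mean of squared errors over all cells and genes (so the value is
#' comparable across gene-set sizes) plus `lambda * sum_l ||W_l||^2`.
#'
#' @param x_true,x_pred expression batches of identical shape.
#' @param layer_weights,lambda as in [encoder_loss()].
#' @return non-negative scalar.
#' @export
decoder_loss <- function(x_true, x_pred, layer_weights = list(), lambda = 0) {
  x_true <- as.matrix(x_true); x_pred <- as.matrix(x_pred)
  if (!all(dim(x_true) == dim(x_pred)))
    stop("x_true and x_pred shapes differ")
  if (nrow(x_true) == 0) stop("empty batch")
  mean((x_true - x_pred)^2) + lambda * .sum_sq(layer_weights)
}

# Stratified validation split: stratify by each cell's dominant channel so
# that rare isotypes are represented in both partitions. Seeded by caller.
.val_split <- function(profiles, fraction) {
  n <- nrow(profiles)
  dominant <- max.col(profiles, ties.method = "first")
  val <- integer(0)
  for (g in unique(dominant)) {
    idx <- which(dominant == g)
    n_val <- max(1L, round(length(idx) * fraction))
    if (length(idx) <= 1) next       # singleton stratum stays in training
    val <- c(val, sample(idx, min(n_val, length(idx) - 1L)))
  }
  if (length(val) == 0 || length(val) >= n)
    val <- sample.int(n, max(1L, round(n * fraction)))
  sort(val)
}

# Shared mini-batch training loop for encoder ("kld") and decoder ("mse").
# Returns the trained net, per-epoch history, and the validation loss of the
# restored best model (monitored term only, inference mode).
.train_loop <- function(net, x, y, loss_type, lr, l2, batch_size, stop_cfg,
                        verbose = FALSE) {
  n <- nrow(x)
  # encoder: stratify the validation split by dominant channel; decoder
  # targets have no channel structure, so use a plain random split
  val_idx <- if (loss_type == "kld") {
    .val_split(y, stop_cfg$validation_fraction)
  } else {
    sort(sample.int(n, max(1L, round(n * stop_cfg$validation_fraction))))
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  xt <- x[train_idx, , drop = FALSE]; yt <- y[train_idx, , drop = FALSE]
  xv <- x[val_idx, , drop = FALSE];   yv <- y[val_idx, , drop = FALSE]

  monitored <- function(net, xx, yy) {
    pred <- nn_forward(net, xx, training = FALSE)$output
    if (loss_type == "kld") encoder_loss(yy, pred) else decoder_loss(yy, pred)
  }
  grad_out <- function(pred, yy) {
    if (loss_type == "kld") (pred - yy) / nrow(yy)
    else 2 * (pred - yy) / length(yy)
  }

  state <- nn_adam_init(net)
  es <- make_early_stopper(stop_cfg$patience_epochs)
  best_net <- net
  history <- data.frame(epoch = integer(0), train = numeric(0),
                        val = numeric(0))
  for (epoch in seq_len(stop_cfg$max_epochs)) {
    batch_losses <- numeric(0)
    for (idx in .nn_batches(nrow(xt), batch_size)) {
      fwd <- nn_forward(net, xt[idx, , drop = FALSE], training = TRUE)
      net <- nn_update_bn(net, fwd)
      yb <- yt[idx, , drop = FALSE]
      bl <- if (loss_type == "kld") encoder_loss(yb, fwd$output) else
        decoder_loss(yb, fwd$output)
      if (!is.finite(bl)) stop("non-finite training loss at epoch ", epoch)
      batch_losses <- c(batch_losses, bl)
      bwd <- nn_backward(net, fwd, grad_out(fwd$output, yb))
      upd <- nn_adam_step(net, bwd$grads, state, lr = lr, l2 = l2)
      net <- upd$net; state <- upd$state
    }
    val_loss <- monitored(net, xv, yv)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train = mean(batch_losses),
                                         val = val_loss))
    if (verbose && epoch %% 50 == 0)
      message(sprintf("epoch %d train %.5f val %.5f", epoch,
                      mean(batch_losses), val_loss))
    st <- es$update(val_loss)
    if (st$improved) best_net <- net
    if (st$stop) break
  }
  net <- best_net
  val_at_restore <- monitored(net, xv, yv)
  # final epochs on the entire training data, validation split included
  if (stop_cfg$post_restore_epochs > 0) {
    for (epoch in seq_len(stop_cfg$post_restore_epochs)) {
      for (idx in .nn_batches(n, batch_size)) {
        fwd <- nn_forward(net, x[idx, , drop = FALSE], training = TRUE)
        net <- nn_update_bn(net, fwd)
        yb <- y[idx, , drop = FALSE]
        bwd <- nn_backward(net, fwd, grad_out(fwd$output, yb))
        upd <- nn_adam_step(net, bwd$grads, state, lr = lr, l2 = l2)
        net <- upd$net; state <- upd$state
      }
    }
  }
  list(net = net, history = history, best_epoch = es$best_epoch,
       best_val = es$best_value, val_at_restore = val_at_restore,
       val_idx = val_idx)
}

#' Train the supervised encoder
#'
#' Maps expression to the bounded latent space and, through the prediction
#' head, to the adjacent profile; trained with the KLD loss so that cells
#' with similar relative isotype expression receive similar latent encodings.
#' Early stopping monitors the KLD term (penalty excluded) on a stratified
#' validation split; on patience exhaustion the weights revert to the best
#' validation state and training continues for `post_restore_epochs` on the
#' full data.
#'
#' @param expr [expression_matrix()] on the log2_tpm1 scale.
#' @param profiles row-aligned cells x K simplex matrix
#'   ([compute_adjacent_profiles()]).
#' @param spec an [encoder_spec()].
#' @param stop an [early_stop_config()].
#' @param seed integer seed controlling initialisation, splits, shuffling and
#'   dropout.
#' @param verbose print progress.
#' @return an object of class `supervised_encoder` with the trained network,
#'   training history, and the gene/channel orders it expects.
#' @export
train_supervised_encoder <- function(expr, profiles, spec = encoder_spec(),
                                     stop = early_stop_config(), seed = 1,
                                     verbose = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  x <- expr$values
  profiles <- as.matrix(profiles)
  if (nrow(x) != nrow(profiles))
    stop("expression matrix and profiles are not row-aligned")
  if (nrow(x) < 20) stop("need at least 20 cells to train")
  if (is.null(spec$input_dim)) spec$input_dim <- ncol(x)
  if (spec$input_dim != ncol(x))
    stop("spec$input_dim does not match the gene count")
  if (spec$output_dim != ncol(profiles))
    stop("spec$output_dim does not match the number of channels")
  if (spec$latent_dim >= spec$input_dim)
    stop("latent_dim must be smaller than input_dim")

  set.seed(seed)
  dims <- c(spec$input_dim, spec$hidden_dims, spec$latent_dim,
            spec$head_hidden_dim, spec$output_dim)
  nh <- length(spec$hidden_dims)
  layers <- list()
  for (i in seq_len(nh))
    layers[[i]] <- nn_dense(dims[i], dims[i + 1], "relu",
                            dropout = spec$dropout_rate)
  layers[[nh + 1]] <- nn_dense(dims[nh + 1], dims[nh + 2], "sigmoid")
  layers[[nh + 2]] <- nn_dense(dims[nh + 2], dims[nh + 3], "relu",
                               dropout = spec$dropout_rate)
  layers[[nh + 3]] <- nn_dense(dims[nh + 3], dims[nh + 4], "softmax")
  net <- nn_network(layers)

  fit <- .train_loop(net, x, profiles, "kld", lr = spec$learning_rate,
                     l2 = spec$l2_weight, batch_size = spec$batch_size,
                     stop_cfg = stop, verbose = verbose)
  structure(list(net = fit$net, spec = spec, stop = stop, seed = seed,
                 latent_index = nh + 1L, gene_ids = expr$gene_ids,
                 channel_ids = colnames(profiles), history = fit$history,
                 best_epoch = fit$best_epoch, best_val = fit$best_val,
                 val_at_restore = fit$val_at_restore),
            class = "supervised_encoder")
}

#' @export
print.supervised_encoder <- function(x, ...) {
  cat(sprintf(paste0("supervised_encoder: %d genes -> latent %d -> %d",
                     " channels (%d epochs, best val KLD %.4f)\n"),
              x$spec$input_dim, x$spec$latent_dim, x$spec$output_dim,
              nrow(x$history), x$best_val))
  invisible(x)
}

.check_genes <- function(model, expr) {
  if (!identical(expr$gene_ids, model$gene_ids)) {
    missing <- setdiff(model$gene_ids, expr$gene_ids)
    if (length(missing))
      stop("input is missing genes the model was trained on: ",
           paste(utils::head(missing, 10), collapse = ", "),
           if (length(missing) > 10) sprintf(" (and %d more)",
                                             length(missing) - 10))
    stop("gene order differs from the training data")
  }
}

#' Encode expression into the latent space
#'
#' Deterministic inference pass (dropout off); every latent coordinate lies
#' in (0,1) because the latent layer is sigmoid-activated.
#'
#' @param model a trained [train_supervised_encoder()] model.
#' @param expr [expression_matrix()] with the training gene set and order.
#' @return cells x latent_dim matrix.
#' @export
encode <- function(model, expr) {
  stopifnot(inherits(model, "supervised_encoder"))
  if (inherits(expr, "ExpressionMatrix")) {
    .check_genes(model, expr)
    x <- expr$values
  } else x <- as.matrix(expr)
  fwd <- nn_forward(model$net, x, training = FALSE)
  z <- fwd$acts[[model$latent_index]]
  rownames(z) <- rownames(x)
  z
}

#' Predict adjacent profiles (encoder head)
#'
#' Runs the full encoder including the softmax prediction head. Accepts
#' either expression input or latent encodings (e.g. CGAN-generated latents,
#' to audit how well generated cells respect their conditioning).
#'
#' @param model a trained `supervised_encoder`.
#' @param expr [expression_matrix()] (or plain matrix) of expression, or
#'   `NULL` if `latents` is given.
#' @param latents optional cells x latent_dim matrix fed directly to the head.
#' @return cells x K matrix of simplex profiles.
#' @export
predict_profiles <- function(model, expr = NULL, latents = NULL) {
  stopifnot(inherits(model, "supervised_encoder"))
  if (is.null(latents)) {
    if (inherits(expr, "ExpressionMatrix")) {
      .check_genes(model, expr)
      x <- expr$values
    } else x <- as.matrix(expr)
    fwd <- nn_forward(model$net, x, training = FALSE)
    out <- fwd$output
    dimnames(out) <- list(rownames(x), model$channel_ids)
    return(out)
  }
  latents <- as.matrix(latents)
  stopifnot(ncol(latents) == model$spec$latent_dim)
  head_net <- structure(
    list(layers = model$net$layers[(model$latent_index + 1):
                                     length(model$net$layers)]),
    class = "nn_net")
  out <- nn_forward(head_net, latents, training = FALSE)$output
  dimnames(out) <- list(rownames(latents), model$channel_ids)
  out
}

#' Train the decoder
#'
#' Reconstructs normalized expression from latent encodings (the encoder is
#' frozen; its latents are the decoder's fixed inputs). Early stopping
#' monitors the MSE term on a random validation split.
#'
#' @param latents cells x latent_dim matrix from [encode()].
#' @param expr row-aligned [expression_matrix()] the decoder learns to
#'   reconstruct.
#' @param spec a [decoder_spec()].
#' @param stop an [early_stop_config()].
#' @param seed integer seed.
#' @param verbose print progress.
#' @return object of class `latent_decoder`.
#' @export
train_decoder <- function(latents, expr, spec = decoder_spec(),
                          stop = early_stop_config(), seed = 1,
                          verbose = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  latents <- as.matrix(latents)
  x <- expr$values
  if (nrow(latents) != nrow(x))
    stop("latents and expression are not row-aligned")
  if (is.null(spec$output_dim)) spec$output_dim <- ncol(x)
  if (spec$output_dim != ncol(x))
    stop("spec$output_dim does not match the gene count")
  if (spec$latent_dim != ncol(latents))
    stop("spec$latent_dim does not match the latent matrix")

  set.seed(seed)
  dims <- c(spec$latent_dim, spec$hidden_dims, spec$output_dim)
  layers <- list()
  for (i in seq_along(spec$hidden_dims))
    layers[[i]] <- nn_dense(dims[i], dims[i + 1], "relu", batchnorm = TRUE)
  layers[[length(layers) + 1]] <-
    nn_dense(dims[length(dims) - 1], dims[length(dims)], "linear")
  net <- nn_network(layers)

  fit <- .train_loop(net, latents, x, "mse", lr = spec$learning_rate,
                     l2 = spec$l2_weight, batch_size = spec$batch_size,
                     stop_cfg = stop, verbose = verbose)
  structure(list(net = fit$net, spec = spec, stop = stop, seed = seed,
                 gene_ids = expr$gene_ids, history = fit$history,
                 best_epoch = fit$best_epoch, best_val = fit$best_val,
                 val_at_restore = fit$val_at_restore),
            class = "latent_decoder")
}

#' @export
print.latent_decoder <- function(x, ...) {
  cat(sprintf("latent_decoder: latent %d -> %d genes (best val MSE %.4f)\n",
              x$spec$latent_dim, x$spec$output_dim, x$best_val))
  invisible(x)
}

#' Decode latent encodings to expression profiles
#'
#' @param model a trained [train_decoder()] model.
#' @param latents cells x latent_dim matrix.
#' @param clip_negative truncate decoded values at 0 (the decoder output is
#'   linear; raw values are returned by default).
#' @return cells x genes matrix of reconstructed log2(TPM+1) expression.
#' @export
decode <- function(model, latents, clip_negative = FALSE) {
  stopifnot(inherits(model, "latent_decoder"))
  latents <- as.matrix(latents)
  stopifnot(ncol(latents) == model$spec$latent_dim)
  out <- nn_forward(model$net, latents, training = FALSE)$output
  if (clip_negative) out <- pmax(out, 0)
  colnames(out) <- model$gene_ids
  rownames(out) <- rownames(latents)
  out
}

#' k-fold cross-validation of the supervised autoencoder
#'
#' Partitions cells into `folds` test folds of near-equal size; for each
#' fold, the full two-step training (encoder, then decoder on the frozen
#' latents) runs from scratch on the remaining cells and the held-out fold is
#' encoded, head-predicted and decoded. Reports per-channel Pearson
#' correlations between observed and predicted profiles and per-gene
#' correlations between observed and reconstructed expression.
#'
#' @param expr [expression_matrix()] on the log2_tpm1 scale.
#' @param profiles row-aligned adjacent-profile matrix.
#' @param folds number of folds (default 10).
#' @param enc_spec,dec_spec,stop model configurations.
#' @param components train "encoder" only, or c("encoder", "decoder").
#' @param genes optional gene subset for the per-gene reconstruction report.
#' @param seed integer seed (fold assignment and per-fold training).
#' @param verbose print fold progress.
#' @return list with `fold` (per-cell fold id), `channel_r` (named
#'   per-channel r), `gene_r` (named per-gene r, if decoding), and
#'   `predicted_profiles` / `predicted_expression` matrices of held-out
#'   predictions.
#' @export
crossvalidate_autoencoder <- function(expr, profiles, folds = 10,
                                      enc_spec = encoder_spec(),
                                      dec_spec = decoder_spec(),
                                      stop = early_stop_config(),
                                      components = c("encoder", "decoder"),
                                      genes = NULL, seed = 1,
                                      verbose = FALSE) {
  stopifnot(inherits(expr, "ExpressionMatrix"), folds >= 2)
  n <- nrow(expr$values)
  if (folds > n) stop("more folds than cells")
  profiles <- as.matrix(profiles)
  components <- match.arg(components, several.ok = TRUE)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))

  pred_prof <- matrix(NA_real_, n, ncol(profiles),
                      dimnames = dimnames(profiles))
  do_decode <- "decoder" %in% components
  gene_idx <- if (is.null(genes)) seq_len(ncol(expr$values)) else {
    gi <- match(genes, expr$gene_ids)
    if (anyNA(gi)) stop("unknown genes: ",
                        paste(genes[is.na(gi)], collapse = ", "))
    gi
  }
  pred_expr <- if (do_decode)
    matrix(NA_real_, n, length(gene_idx),
           dimnames = list(expr$cell_ids, expr$gene_ids[gene_idx]))

  for (f in seq_len(folds)) {
    if (verbose) message("fold ", f, "/", folds)
    test <- which(fold == f)
    train <- which(fold != f)
    tr_expr <- expression_matrix(expr$values[train, , drop = FALSE],
                                 gene_ids = expr$gene_ids,
                                 cell_ids = expr$cell_ids[train],
                                 normalization_tag = expr$normalization_tag)
    enc <- train_supervised_encoder(tr_expr, profiles[train, , drop = FALSE],
                                    spec = enc_spec, stop = stop,
                                    seed = seed + f)
    te_x <- expr$values[test, , drop = FALSE]
    pred_prof[test, ] <- predict_profiles(enc, te_x)
    if (do_decode) {
      z_tr <- encode(enc, tr_expr)
      dec <- train_decoder(z_tr, tr_expr, spec = dec_spec, stop = stop,
                           seed = seed + folds + f)
      z_te <- encode(enc, te_x)
      pred_expr[test, ] <- decode(dec, z_te)[, gene_idx, drop = FALSE]
    }
  }
  channel_r <- vapply(seq_len(ncol(profiles)), function(k) {
    # a channel that never varies in this dataset has no defined correlation
    if (stats::sd(profiles[, k]) == 0 || stats::sd(pred_prof[, k]) == 0)
      return(NA_real_)
    stats::cor(profiles[, k], pred_prof[, k])
  }, 0)
  names(channel_r) <- colnames(profiles)
  gene_r <- NULL
  if (do_decode) {
    obs <- expr$values[, gene_idx, drop = FALSE]
    gene_r <- vapply(seq_along(gene_idx), function(j) {
      if (stats::sd(obs[, j]) == 0 || stats::sd(pred_expr[, j]) == 0)
        return(NA_real_)
      stats::cor(obs[, j], pred_expr[, j])
    }, 0)
    names(gene_r) <- expr$gene_ids[gene_idx]
  }
  list(fold = fold, channel_r = channel_r, gene_r = gene_r,
       predicted_profiles = pred_prof,
       predicted_expression = if (do_decode) pred_expr)
}
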