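# Shared fixtures, built lazily and memoized for the whole test session.
#
# Model-based tests share one tiny dataset (200 cells x 300 genes) and one
# set of trained models on it, plus one small dataset (1,000 x 2,000, cut to
# its 500 most variable genes) for the cross-validation and trajectory
# checks. Architectures are reduced relative to the full-scale defaults so
# the suite trains in minutes; the properties under test are scale-free.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  .fixtures[[name]]
}

subset_cells <- function(expr, idx) {
  expression_matrix(expr$values[idx, , drop = FALSE],
                    gene_ids = expr$gene_ids,
                    cell_ids = expr$cell_ids[idx],
                    normalization_tag = expr$normalization_tag)
}

# reduced architectures used throughout the suite
test_enc_spec <- function(...) {
  encoder_spec(hidden_dims = c(64, 32), latent_dim = 16, head_hidden_dim = 32,
               dropout_rate = 0.1, learning_rate = 1e-3, ...)
}
test_dec_spec <- function(...) {
  decoder_spec(latent_dim = 16, hidden_dims = c(32, 64),
               learning_rate = 1e-3, ...)
}
test_gspec <- generator_spec(noise_dim = 16, hidden_dims = c(64, 128),
                             output_dim = 16)
test_dspec <- discriminator_spec(latent_dim = 16, hidden_dims = 128)

tiny_data <- function() fixture("tiny_data", function() {
  sim <- simulate_csr_dataset(simulation_config(
    n_cells = 200, n_genes = 300,
    module_sizes = c(early = 25, middle = 25, late = 25),
    confounder_genes = 50, seed = 7))
  expr <- suppressMessages(normalize_log2_tpm1(filter_zero_genes(sim$counts)))
  prof <- suppressWarnings(compute_adjacent_profiles(expr))
  list(sim = sim, expr = expr, prof = prof)
})

tiny_encoder <- function() fixture("tiny_encoder", function() {
  d <- tiny_data()
  train_supervised_encoder(d$expr, d$prof, spec = test_enc_spec(),
                           stop = early_stop_config(patience_epochs = 30,
                                                    max_epochs = 400),
                           seed = 1)
})

tiny_decoder <- function() fixture("tiny_decoder", function() {
  d <- tiny_data()
  z <- encode(tiny_encoder(), d$expr)
  train_decoder(z, d$expr, spec = test_dec_spec(),
                stop = early_stop_config(patience_epochs = 30,
                                         max_epochs = 400),
                seed = 2)
})

tiny_gan <- function() fixture("tiny_gan", function() {
  d <- tiny_data()
  z <- encode(tiny_encoder(), d$expr)
  train_cgan(z, d$prof, gspec = test_gspec, dspec = test_dspec,
             cfg = gan_train_config(learning_rate = 2e-4, max_epochs = 25000,
                                    plateau_tol = 0),
             seed = 3)
})

small_data <- function() fixture("small_data", function() {
  sim <- simulate_csr_dataset(simulation_config(n_cells = 1000,
                                                n_genes = 2000, seed = 11))
  expr <- suppressMessages(normalize_log2_tpm1(filter_zero_genes(sim$counts)))
  prof <- suppressWarnings(compute_adjacent_profiles(expr))
  expr <- select_variable_genes(expr, k = 500)
  list(sim = sim, expr = expr, prof = prof)
})

# full-data encoder + CGAN on the small fixture (for trajectory checks)
small_models <- function() fixture("small_models", function() {
  d <- small_data()
  enc <- train_supervised_encoder(d$expr, d$prof, spec = test_enc_spec(),
                                  stop = early_stop_config(
                                    patience_epochs = 30, max_epochs = 400),
                                  seed = 5)
  z <- encode(enc, d$expr)
  gan <- train_cgan(z, d$prof, gspec = test_gspec, dspec = test_dspec,
                    cfg = gan_train_config(learning_rate = 2e-4,
                                           max_epochs = 3000,
                                           plateau_tol = 0),
                    seed = 6)
  list(encoder = enc, gan = gan, latents = z)
})
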