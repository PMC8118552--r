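# Loss oracles, training protocol, latent properties, reconstruction, CV.

test_that("encoder loss matches an independent KLD oracle", {
  # hand-computed cases
  y <- matrix(c(1, rep(0, 7)), 1, 8)
  yhat <- matrix(c(0.5, 0.5, rep(0, 6)), 1, 8)
  expect_equal(encoder_loss(y, y), 0)
  expect_equal(encoder_loss(y, yhat), log(2), tolerance = 1e-12)
  # L2 penalty: lambda * Frobenius norm squared
  expect_equal(encoder_loss(y, y, layer_weights = list(diag(2)),
                            lambda = 1e-5), 1e-5 * 2)
  # random simplex batches against a scalar double-loop oracle
  set.seed(10)
  for (rep in 1:5) {
    a <- matrix(rexp(6 * 8), 6, 8); a <- a / rowSums(a)
    b <- matrix(rexp(6 * 8), 6, 8); b <- b / rowSums(b)
    oracle <- 0
    for (i in 1:6) for (k in 1:8) {
      if (a[i, k] > 0) oracle <- oracle + a[i, k] * log(a[i, k] / b[i, k])
    }
    oracle <- oracle / 6
    expect_equal(encoder_loss(a, b), oracle, tolerance = 1e-9)
    expect_gte(encoder_loss(a, b), 0)
  }
  expect_error(encoder_loss(y, yhat[, 1:4]), "shape")
})

test_that("decoder loss matches the hand MSE oracle", {
  expect_equal(decoder_loss(matrix(1:2, 1), matrix(1:2, 1)), 0)
  expect_equal(decoder_loss(matrix(c(1, 2), 1), matrix(0, 1, 2)), 2.5)
  set.seed(11)
  a <- matrix(rnorm(12), 3, 4); b <- matrix(rnorm(12), 3, 4)
  oracle <- sum((a - b)^2) / 12
  expect_equal(decoder_loss(a, b), oracle, tolerance = 1e-12)
  expect_equal(decoder_loss(a, b, list(matrix(2, 1, 1)), lambda = 0.5),
               oracle + 2)
  expect_error(decoder_loss(a[0, , drop = FALSE], b[0, , drop = FALSE]),
               "empty")
  expect_error(decoder_loss(a, b[, 1:2]), "shape")
})

test_that("encoder training is reproducible and obeys the early-stop protocol", {
  d <- tiny_data()
  st <- early_stop_config(patience_epochs = 10, max_epochs = 60)
  run <- function() train_supervised_encoder(d$expr, d$prof,
                                             spec = test_enc_spec(),
                                             stop = st, seed = 123)
  m1 <- run(); m2 <- run()
  expect_identical(m1$history, m2$history)           # bitwise-identical logs
  expect_identical(encode(m1, d$expr), encode(m2, d$expr))
  # restored model's monitored validation loss equals the minimum seen
  expect_equal(m1$val_at_restore, min(m1$history$val), tolerance = 1e-12)
  expect_equal(m1$best_val, min(m1$history$val))
  # with patience exhausted before the cap, training stops patience epochs
  # after the best epoch
  if (nrow(m1$history) < 60)
    expect_equal(nrow(m1$history), m1$best_epoch + 10)
})

test_that("misaligned or undersized inputs are rejected", {
  d <- tiny_data()
  expect_error(train_supervised_encoder(d$expr, d$prof[1:50, ],
                                        spec = test_enc_spec()),
               "row-aligned")
  small <- subset_cells(d$expr, 1:10)
  expect_error(train_supervised_encoder(small, d$prof[1:10, ],
                                        spec = test_enc_spec()),
               "at least 20")
})

test_that("latents are bounded, deterministic, and gene-order-checked", {
  d <- tiny_data()
  enc <- tiny_encoder()
  z <- encode(enc, d$expr)
  expect_true(all(z > 0 & z < 1))
  expect_equal(ncol(z), enc$spec$latent_dim)
  # identical cells encode identically
  dup <- expression_matrix(d$expr$values[c(1, 1), ], d$expr$gene_ids,
                           c("a", "b"), "log2_tpm1")
  zz <- encode(enc, dup)
  expect_equal(zz[1, ], zz[2, ])
  # gene mismatch errors name the problem
  wrong <- expression_matrix(d$expr$values[, -5], d$expr$gene_ids[-5],
                             d$expr$cell_ids, "log2_tpm1")
  expect_error(encode(enc, wrong), "missing genes")
  shuffled <- expression_matrix(d$expr$values[, rev(seq_len(ncol(d$expr$values)))],
                                rev(d$expr$gene_ids), d$expr$cell_ids,
                                "log2_tpm1")
  expect_error(encode(enc, shuffled), "order")
})

test_that("latent space clusters cells by dominant isotype above chance", {
  d <- tiny_data()
  z <- encode(tiny_encoder(), d$expr)
  lab <- colnames(d$prof)[max.col(d$prof)]
  # 5-NN majority-vote purity against the majority-class baseline
  dm <- as.matrix(dist(z))
  diag(dm) <- Inf
  votes <- vapply(seq_len(nrow(z)), function(i) {
    nn <- order(dm[i, ])[1:5]
    names(which.max(table(lab[nn])))
  }, "")
  purity <- mean(votes == lab)
  chance <- max(table(lab)) / length(lab)
  expect_gt(purity, chance)
  expect_gt(purity, 0.8)
})

test_that("predicted profiles lie on the simplex and recover planted signal", {
  d <- tiny_data()
  p <- predict_profiles(tiny_encoder(), d$expr)
  expect_true(all(abs(rowSums(p) - 1) <= 1e-6))
  # held-out KLD on a dataset whose profiles are fully determined by the
  # eight channel genes (balanced isotypes, low noise)
  sim <- simulate_csr_dataset(simulation_config(
    n_cells = 400, n_genes = 100,
    channel_dominance = setNames(rep(0.125, 8), IGH_CHANNELS),
    transitioning_fraction = 0.2,
    module_sizes = c(early = 10, middle = 10, late = 10),
    confounder_genes = 0, confounder_strength = 0,
    nb_size = 100, dropout_max = 0, depth_mean = 2e5, seed = 31))
  expr <- suppressMessages(normalize_log2_tpm1(filter_zero_genes(sim$counts)))
  prof <- suppressWarnings(compute_adjacent_profiles(expr))
  test <- seq(1, 400, by = 5)
  train <- setdiff(seq_len(400), test)
  enc <- train_supervised_encoder(subset_cells(expr, train), prof[train, ],
                                  spec = test_enc_spec(),
                                  stop = early_stop_config(
                                    patience_epochs = 40, max_epochs = 800),
                                  seed = 1)
  kld <- encoder_loss(prof[test, ],
                      predict_profiles(enc, subset_cells(expr, test)))
  expect_lt(kld, 0.05)
})

test_that("decoder reconstructs signal genes faithfully on low-noise data", {
  sim <- simulate_csr_dataset(simulation_config(
    n_cells = 300, n_genes = 150,
    module_sizes = c(early = 35, middle = 35, late = 35),
    confounder_genes = 0, confounder_strength = 0,
    transitioning_fraction = 0.5, nb_size = 50, dropout_max = 0,
    depth_mean = 2e5, seed = 21))
  expr <- suppressMessages(normalize_log2_tpm1(filter_zero_genes(sim$counts)))
  prof <- suppressWarnings(compute_adjacent_profiles(expr))
  enc <- train_supervised_encoder(expr, prof, spec = test_enc_spec(),
                                  stop = early_stop_config(
                                    patience_epochs = 30, max_epochs = 500),
                                  seed = 1)
  z <- encode(enc, expr)
  dec <- train_decoder(z, expr, spec = test_dec_spec(),
                       stop = early_stop_config(patience_epochs = 40,
                                                max_epochs = 800),
                       seed = 2)
  xh <- decode(dec, z)
  truth_mod <- sim$truth$genes$module[match(expr$gene_ids,
                                            sim$truth$genes$gene_id)]
  signal <- which(truth_mod %in% c("early", "middle", "late") |
                    expr$gene_ids %in% IGH_CHANNELS)
  r <- vapply(signal, function(j)
    suppressWarnings(cor(expr$values[, j], xh[, j])), 0)
  expect_gte(median(r, na.rm = TRUE), 0.9)
  # near-constant background genes are reconstructed near their constant
  flat <- setdiff(seq_along(expr$gene_ids), signal)
  dev <- abs(colMeans(xh[, flat, drop = FALSE]) -
               colMeans(expr$values[, flat, drop = FALSE]))
  expect_lt(max(dev), 0.1)
  # decoder training logs are reproducible under the same seed
  dec2 <- train_decoder(z, expr, spec = test_dec_spec(),
                        stop = early_stop_config(patience_epochs = 40,
                                                 max_epochs = 800),
                        seed = 2)
  expect_identical(dec$history, dec2$history)
})

test_that("cross-validation folds partition cells evenly", {
  d <- tiny_data()
  sub <- subset_cells(d$expr, 1:83)
  cv <- crossvalidate_autoencoder(sub, d$prof[1:83, ], folds = 5,
                                  enc_spec = test_enc_spec(),
                                  stop = early_stop_config(
                                    patience_epochs = 2, max_epochs = 3),
                                  components = "encoder", seed = 9)
  expect_equal(length(cv$fold), 83)
  sizes <- table(cv$fold)
  expect_lte(diff(range(sizes)), 1)
  expect_setequal(names(sizes), as.character(1:5))
  expect_false(anyNA(cv$predicted_profiles))  # every cell predicted once
  expect_error(crossvalidate_autoencoder(subset_cells(d$expr, 1:3),
                                         d$prof[1:3, ], folds = 5,
                                         enc_spec = test_enc_spec()),
               "folds")
})
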