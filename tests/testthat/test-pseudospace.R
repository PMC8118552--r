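# Trajectory construction, pseudocell summaries, phase clustering, NN audit.

make_summary <- function(mu, coordinate = seq(0, 1, length.out = ncol(mu))) {
  # assemble a trajectory_summary directly (zero-width CI) for clustering
  sds <- apply(mu, 1, sd)
  zm <- (mu - rowMeans(mu)) / ifelse(sds > 0, sds, 1)
  zm[sds == 0, ] <- 0
  structure(list(mean = mu, lower = mu, upper = mu, coordinate = coordinate,
                 gene_ids = rownames(mu), ci_method = "percentile",
                 zmean = zm),
            class = "trajectory_summary")
}

test_that("trajectories interpolate linearly between one-hot endpoints", {
  traj <- build_trajectory(trajectory_spec("Ighm", "Ighg1", step = 0.01))
  expect_equal(nrow(traj), 101)
  expect_equal(unname(traj[1, ]), c(1, rep(0, 7)))
  expect_equal(unname(traj[101, ]), c(0, 1, rep(0, 6)))
  # affine segment: profile(t) = (1-t) e_src + t e_tgt, exactly
  t <- attr(traj, "coordinate")
  expected <- outer(1 - t, diag(8)[1, ]) + outer(t, diag(8)[2, ])
  expect_identical(unname(traj[, ]), expected)
  expect_true(all(abs(rowSums(traj) - 1) < 1e-12))
  # closed form at step 0.5
  t3 <- build_trajectory(trajectory_spec("Ighm", "Igha", step = 0.5))
  expect_equal(unname(t3[, c("Ighm", "Igha")]),
               cbind(c(1, 0.5, 0), c(0, 0.5, 1)))
  expect_error(trajectory_spec(step = 0.3), "integer")
  expect_error(trajectory_spec("Ighm", "Ighm"), "differ")
})

test_that("pseudocell generation is deterministic with consistent shapes", {
  d <- tiny_data()
  gan <- tiny_gan(); dec <- tiny_decoder()
  traj <- build_trajectory(trajectory_spec(step = 0.25))
  pc <- generate_pseudocells(traj, gan, dec, replicates = 4, seed = 2)
  expect_equal(dim(pc$expression), c(5, 4, ncol(d$expr$values)))
  expect_equal(dim(pc$latents), c(5, 4, 16))
  pc2 <- generate_pseudocells(traj, gan, dec, replicates = 4, seed = 2)
  expect_identical(pc$expression, pc2$expression)
  pc1 <- generate_pseudocells(traj, gan, dec, replicates = 1, seed = 2)
  expect_equal(dim(pc1$expression)[2], 1)
  # latent-dimension mismatch between generator and decoder is caught
  bad_dec <- tiny_decoder(); bad_dec$spec$latent_dim <- 8
  expect_error(generate_pseudocells(traj, gan, bad_dec, replicates = 2),
               "does not match")
})

test_that("trajectory summaries match empirical-quantile oracles", {
  # hand-built pseudocell set: one gene, one point, replicates 1..100
  pc <- structure(list(
    profiles = matrix(1, 1, 1), replicates = 100, coordinate = 0,
    latents = array(0, c(1, 100, 1)),
    expression = array(1:100, c(1, 100, 1)), gene_ids = "g1", seed = 1),
    class = "pseudocell_set")
  s <- summarize_trajectory(pc, zscore = FALSE)
  expect_equal(unname(s$mean[1, 1]), 50.5)
  expect_equal(unname(s$lower[1, 1]), unname(quantile(1:100, 0.025)))
  expect_equal(unname(s$upper[1, 1]), unname(quantile(1:100, 0.975)))
  sn <- summarize_trajectory(pc, zscore = FALSE, ci_method = "normal")
  expect_equal(unname(sn$lower[1, 1]), 50.5 - 1.96 * sd(1:100) / 10)
  # constant replicates give zero-width intervals
  pc$expression <- array(3, c(1, 100, 1))
  s0 <- summarize_trajectory(pc, zscore = FALSE)
  expect_equal(unname(s0$lower[1, 1]), 3)
  expect_equal(unname(s0$upper[1, 1]), 3)
})

test_that("summaries order bands correctly and z-score to mean 0 sd 1", {
  d <- tiny_data()
  pc <- generate_pseudocells(build_trajectory(trajectory_spec(step = 0.1)),
                             tiny_gan(), tiny_decoder(), replicates = 30,
                             seed = 3)
  s <- summarize_trajectory(pc, zscore = TRUE)
  expect_true(all(s$lower <= s$mean + 1e-12))
  expect_true(all(s$mean <= s$upper + 1e-12))
  nonconst <- apply(s$mean, 1, sd) > 0
  expect_true(all(abs(rowMeans(s$zmean[nonconst, ])) < 1e-9))
  expect_true(all(abs(apply(s$zmean[nonconst, ], 1, sd) - 1) < 1e-9))
  df <- as.data.frame(s)
  expect_equal(nrow(df), length(s$gene_ids) * 11)
  expect_error(summarize_trajectory(pc, genes = "nope"), "unknown gene")
})

test_that("phase clustering recovers planted early/middle/late modules", {
  set.seed(30)
  coord <- seq(0, 1, length.out = 101)
  curve_at <- function(peak) exp(-(coord - peak)^2 / (2 * 0.15^2))
  mu <- rbind(
    t(replicate(40, curve_at(0.10) * runif(1, 1, 3) + rnorm(101, sd = 0.05))),
    t(replicate(40, curve_at(0.50) * runif(1, 1, 3) + rnorm(101, sd = 0.05))),
    t(replicate(40, curve_at(0.90) * runif(1, 1, 3) + rnorm(101, sd = 0.05))))
  rownames(mu) <- paste0("g", 1:120)
  planted <- rep(c("early", "middle", "late"), each = 40)
  res <- phase_cluster(make_summary(mu, coord), n_phases = 3)
  expect_gte(mean(as.character(res$phase) == planted), 0.95)
  # heatmap order keeps phases contiguous
  ord_phase <- as.character(res$phase[res$order])
  expect_equal(ord_phase, ord_phase[order(match(ord_phase,
                                                c("early", "middle", "late")))])
  # n_phases = number of genes puts every gene in its own cluster
  few <- make_summary(mu[1:4, ], coord)
  res4 <- phase_cluster(few, n_phases = 4)
  expect_equal(length(unique(res4$phase)), 4)
  # all-constant input is an error
  const <- make_summary(matrix(1, 3, 101,
                               dimnames = list(paste0("c", 1:3), NULL)), coord)
  expect_error(phase_cluster(const), "non-constant")
})

test_that("nearest-real-cell search matches a brute-force scan", {
  set.seed(31)
  ref <- matrix(rnorm(50 * 20), 50, 20,
                dimnames = list(paste0("cell", 1:50), paste0("g", 1:20)))
  q <- ref[c(3, 17), ] + 0  # pseudocells equal to real cells
  pc <- structure(list(profiles = matrix(1, 2, 1), replicates = 1,
                       coordinate = c(0, 1),
                       latents = array(0, c(2, 1, 2)),
                       expression = array(q, c(2, 1, 20)),
                       gene_ids = paste0("g", 1:20), seed = 1),
                  class = "pseudocell_set")
  nn <- nearest_real_cell(pc, ref)
  expect_equal(nn$cell_id, c("cell3", "cell17"))
  expect_equal(nn$distance, c(0, 0), tolerance = 1e-6)
  # random queries against an all-pairs oracle
  qs <- matrix(rnorm(10 * 20), 10, 20)
  pc$expression <- array(qs, c(10, 1, 20))
  pc$profiles <- matrix(1, 10, 1); pc$coordinate <- seq_len(10)
  nn2 <- nearest_real_cell(pc, ref)
  for (i in 1:10) {
    dists <- sqrt(colSums((t(ref) - qs[i, ])^2))
    expect_equal(nn2$cell_id[i], names(which.min(dists)))
    expect_equal(nn2$distance[i], min(dists), tolerance = 1e-10)
  }
  nnc <- nearest_real_cell(pc, ref, metric = "cosine")
  expect_true(all(nnc$distance >= 0 & nnc$distance <= 2))
})
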