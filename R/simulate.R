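# Ground-truth scRNA-seq simulator.
#
# Emulates the statistical structure the pseudospace method assumes: each
# cell sits at a coordinate t on a source -> target isotype axis (stable
# cells at the endpoints, a minority of transitioning cells in between); the
# eight isotype transcripts are expressed so that the computed relative
# profile of a cell at coordinate t is approximately (1-t, t) on its two
# active channels; condition-driven gene modules follow early/middle/late
# response curves in t; an oscillatory cell-cycle-like confounder program is
# orthogonal to t; counts are negative binomial with mean-dependent dropout.

#' Simulation configuration
#'
#' Defaults describe a mid-sized germinal-center-like dataset: 1,000 cells x
#' 2,000 genes, eight isotype channels with IgM dominant and switching mainly
#' to IgG1/IgG2b/IgG3, 15% transitioning cells, three 60-gene phase modules,
#' a rank-2 oscillatory confounder, negative-binomial counts (size 10) at a
#' ~50k depth with mild expression-dependent dropout.
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param channels channel (isotype) gene ids; the first is the CSR source.
#' @param channel_dominance named non-negative weights over channels giving
#'   the composition of stable (non-transitioning) cells; normalized
#'   internally.
#' @param transitioning_fraction fraction of cells placed at t ~ U(0,1) (or
#'   Beta) along a source -> target axis.
#' @param target_weights weights over switched channels for transitioning
#'   cells' targets.
#' @param t_distribution "uniform" or "beta" (sparse intermediate sampling).
#' @param t_beta_shape shape parameters when `t_distribution = "beta"`.
#' @param module_sizes named vector: genes per early/middle/late module.
#' @param module_amplitude log2 amplitude of the module response curves.
#' @param confounder_strength log2 amplitude of the cell-cycle-like program
#'   (0 disables).
#' @param confounder_genes number of genes carrying the confounder.
#' @param isotype_scale total log2(TPM+1) expression budget of a cell's
#'   active isotype transcripts (planted channel value = 2^(scale * w) - 1).
#' @param depth_mean,depth_sd_log sequencing depth lognormal parameters.
#' @param nb_size negative-binomial size (inverse dispersion).
#' @param dropout_max maximal extra dropout probability at zero mean
#'   (p = dropout_max * exp(-mu)).
#' @param seed integer seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 1000, n_genes = 2000,
                              channels = IGH_CHANNELS,
                              channel_dominance = c(Ighm = 0.40, Ighg1 = 0.25,
                                                    Ighg2b = 0.15,
                                                    Ighg3 = 0.10,
                                                    Ighg2c = 0.04,
                                                    Igha = 0.03, Ighd = 0.02,
                                                    Ighe = 0.01),
                              transitioning_fraction = 0.15,
                              target_weights = c(Ighg1 = 0.5, Ighg2b = 0.3,
                                                 Ighg3 = 0.2),
                              t_distribution = c("uniform", "beta"),
                              t_beta_shape = c(0.5, 0.5),
                              module_sizes = c(early = 60, middle = 60,
                                               late = 60),
                              module_amplitude = 2.5,
                              confounder_strength = 1,
                              confounder_genes = 200,
                              isotype_scale = 10,
                              depth_mean = 5e4, depth_sd_log = 0.1,
                              nb_size = 10, dropout_max = 0.15,
                              seed = 1) {
  t_distribution <- match.arg(t_distribution)
  if (transitioning_fraction < 0 || transitioning_fraction > 1)
    stop("transitioning_fraction must be in [0, 1]")
  if (!all(names(channel_dominance) %in% channels))
    stop("channel_dominance names must be channels")
  if (!all(names(target_weights) %in% channels[-1]))
    stop("target_weights must name switched (non-source) channels")
  if (n_genes < length(channels) + sum(module_sizes))
    stop("n_genes too small for the requested channel and module genes")
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a CSR-like scRNA-seq dataset with ground truth
#'
#' Builds a planted TPM matrix (channel genes from each cell's trajectory
#' coordinate, module genes from phase response curves, a low-rank
#' oscillatory confounder, and a lognormal background), row-normalizes it to
#' one million, draws negative-binomial counts at the cell's depth and
#' applies mean-dependent dropout. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return list with `counts` (an [expression_matrix()], raw_counts),
#'   `profiles` (adjacent profiles computed from the simulated counts through
#'   the standard normalization path), and `truth` (per-cell `t`, source,
#'   target, confounder phase; per-gene module membership and peak).
#' @export
simulate_csr_dataset <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cells; g <- cfg$n_genes
  K <- length(cfg$channels)
  source_ch <- cfg$channels[1]

  ## --- per-cell states -----------------------------------------------------
  n_trans <- round(n * cfg$transitioning_fraction)
  is_trans <- seq_len(n) %in% sample.int(n, n_trans)
  dom <- cfg$channel_dominance[cfg$channels]
  dom[is.na(dom)] <- 0
  dom <- dom / sum(dom)
  stable_state <- sample(cfg$channels, n, replace = TRUE, prob = dom)
  tw <- cfg$target_weights / sum(cfg$target_weights)
  target <- ifelse(is_trans,
                   sample(names(tw), n, replace = TRUE, prob = tw),
                   ifelse(stable_state == source_ch, source_ch,
                          stable_state))
  t_coord <- ifelse(is_trans,
                    if (cfg$t_distribution == "uniform") stats::runif(n)
                    else stats::rbeta(n, cfg$t_beta_shape[1],
                                      cfg$t_beta_shape[2]),
                    ifelse(stable_state == source_ch, 0, 1))

  ## --- planted log2 expression of channel genes ----------------------------
  w <- matrix(0, n, K, dimnames = list(NULL, cfg$channels))
  w[cbind(seq_len(n), match(source_ch, cfg$channels))] <- 1 - t_coord
  w[cbind(seq_len(n), match(target, cfg$channels))] <-
    w[cbind(seq_len(n), match(target, cfg$channels))] + t_coord
  # planted TPM so that log2(TPM+1) = isotype_scale * weight
  tpm <- matrix(0, n, g)
  gene_ids <- c(cfg$channels, sprintf("gene%04d", seq_len(g - K)))
  tpm[, seq_len(K)] <- 2^(cfg$isotype_scale * w) - 1

  ## --- phase-module genes ---------------------------------------------------
  # module genes sit on a low expression base so their dynamic range stays
  # small relative to the high-expressed background; the background absorbs
  # the per-cell TPM budget, keeping the planted channel log-values intact
  # after normalization to one million.
  module <- rep("none", g)
  peak <- rep(NA_real_, g)
  peaks <- c(early = 0.1, middle = 0.5, late = 0.9)
  width <- 0.22
  n_module <- sum(cfg$module_sizes)
  base_log <- c(stats::runif(n_module, 2, 6),
                stats::runif(g - K - n_module, 8, 12))
  logtpm_rest <- matrix(rep(base_log, each = n), n, g - K)
  gi <- K + 1
  for (ph in names(cfg$module_sizes)) {
    sz <- cfg$module_sizes[[ph]]
    if (sz == 0) next
    idx <- gi:(gi + sz - 1)
    module[idx] <- ph
    peak[idx] <- peaks[[ph]]
    resp <- exp(-(t_coord - peaks[[ph]])^2 / (2 * width^2))
    amp <- stats::runif(sz, 0.7, 1.3) * cfg$module_amplitude
    logtpm_rest[, idx - K] <- logtpm_rest[, idx - K] +
      outer(resp, amp)
    gi <- gi + sz
  }

  ## --- cell-cycle-like oscillatory confounder ------------------------------
  phase <- stats::runif(n, 0, 2 * pi)
  if (cfg$confounder_strength > 0 && cfg$confounder_genes > 0 && gi <= g) {
    cand <- seq(gi, g)
    cg <- cand[sample.int(length(cand),
                          min(cfg$confounder_genes, length(cand)))]
    u <- stats::runif(length(cg), 0.5, 1.5)
    v <- stats::runif(length(cg), 0.5, 1.5) *
      sample(c(-1, 1), length(cg), replace = TRUE)
    logtpm_rest[, cg - K] <- logtpm_rest[, cg - K] +
      cfg$confounder_strength * (outer(sin(phase), u) + outer(cos(phase), v))
    module[cg] <- ifelse(module[cg] == "none", "confounder", module[cg])
  }
  tpm[, (K + 1):g] <- 2^pmax(logtpm_rest, 0) - 1

  ## --- counts: fill TPM budget with background, NB noise, dropout ----------
  # scale non-channel genes so rows sum to exactly 1e6; the channel genes
  # keep their planted values, and because the background dominates the
  # non-channel mass the per-cell log-shift on other genes is small.
  s_ch <- rowSums(tpm[, seq_len(K), drop = FALSE])
  s_rest <- rowSums(tpm[, (K + 1):g, drop = FALSE])
  stopifnot(all(s_ch < 1e6), all(s_rest > 0))
  tpm[, (K + 1):g] <- tpm[, (K + 1):g] * (1e6 - s_ch) / s_rest
  depth <- stats::rlnorm(n, log(cfg$depth_mean), cfg$depth_sd_log)
  mu <- tpm * depth / 1e6
  counts <- matrix(stats::rnbinom(n * g, size = cfg$nb_size, mu = mu), n, g)
  keep <- matrix(stats::runif(n * g) >= cfg$dropout_max * exp(-mu), n, g)
  counts <- counts * keep
  expr <- expression_matrix(counts, gene_ids = gene_ids,
                            cell_ids = sprintf("cell%05d", seq_len(n)),
                            normalization_tag = "raw_counts")

  profiles <- suppressMessages(suppressWarnings(
    compute_adjacent_profiles(normalize_log2_tpm1(expr),
                              channel_ids = cfg$channels)))
  truth <- list(
    cells = data.frame(cell_id = expr$cell_ids, t = t_coord,
                       source = source_ch, target = target,
                       transitioning = is_trans, confounder_phase = phase),
    genes = data.frame(gene_id = gene_ids, module = module, peak = peak))
  list(counts = expr, profiles = profiles, truth = truth, config = cfg)
}

#' Write a ready-made synthetic fixture to disk
#'
#' Presets: `tiny` = 200 cells x 300 genes (fast end-to-end runs), `small` =
#' 1,000 x 2,000, `paper_scale` = 7,065 x 6,617. Written as MTX + 10x-style
#' companion TSVs plus ground-truth TSVs and the configuration as YAML, so
#' the files load through [load_expression()] like real data.
#'
#' @param size preset name.
#' @param dir output directory.
#' @param seed integer seed.
#' @return the simulation result of [simulate_csr_dataset()], invisibly.
#' @export
make_fixture <- function(size = c("tiny", "small", "paper_scale"),
                         dir, seed = 1) {
  size <- match.arg(size)
  dims <- switch(size,
    tiny = list(n_cells = 200, n_genes = 300,
                module_sizes = c(early = 25, middle = 25, late = 25),
                confounder_genes = 50),
    small = list(n_cells = 1000, n_genes = 2000,
                 module_sizes = c(early = 60, middle = 60, late = 60),
                 confounder_genes = 200),
    paper_scale = list(n_cells = 7065, n_genes = 6617,
                       module_sizes = c(early = 200, middle = 200,
                                        late = 200),
                       confounder_genes = 600))
  cfg <- do.call(simulation_config, c(dims, list(seed = seed)))
  sim <- simulate_csr_dataset(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_mtx(sim$counts, dir)
  data.table::fwrite(sim$truth$cells, file.path(dir, "truth_cells.tsv"),
                     sep = "\t")
  data.table::fwrite(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t")
  cfg_out <- sim$config
  cfg_out$module_sizes <- as.list(cfg_out$module_sizes)
  cfg_out$channel_dominance <- as.list(cfg_out$channel_dominance)
  cfg_out$target_weights <- as.list(cfg_out$target_weights)
  yaml::write_yaml(unclass(cfg_out), file.path(dir, "config.yaml"))
  invisible(sim)
}
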