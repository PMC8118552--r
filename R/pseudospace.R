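# Pseudospace: conditioning trajectories and pseudocell summaries.
#
# A trajectory is a sequence of conditioning profiles interpolating linearly
# between two channels (e.g. IgM -> IgG1 in 1% steps: 101 profiles). For each
# point the trained generator simulates replicate latent encodings, the
# decoder maps them to expression, and per-gene mean curves with empirical
# 95% bands summarize the dynamics; clustering the z-scored curves groups
# genes into early/middle/late transcriptional phases by peak position.

#' Define a source-to-target conditioning trajectory
#'
#' @param source_channel,target_channel channel ids (must differ).
#' @param channels full ordered channel vector (default [IGH_CHANNELS]).
#' @param step increment per point in (0,1]; 1/step must be an integer
#'   (default 0.01, i.e. 1% steps giving 101 points).
#' @return list of class `trajectory_spec`.
#' @export
trajectory_spec <- function(source_channel = "Ighm", target_channel = "Ighg1",
                            channels = IGH_CHANNELS, step = 0.01) {
  if (identical(source_channel, target_channel))
    stop("source and target channels must differ")
  if (!source_channel %in% channels) stop("unknown source channel")
  if (!target_channel %in% channels) stop("unknown target channel")
  if (step <= 0 || step > 1) stop("step must be in (0, 1]")
  if (abs(1 / step - round(1 / step)) > 1e-9)
    stop("1/step must be an integer (step must divide 1 evenly)")
  structure(list(source_channel = source_channel,
                 target_channel = target_channel,
                 channels = channels, step = step),
            class = "trajectory_spec")
}

#' Build the ordered conditioning profiles of a trajectory
#'
#' Point t (t = 0..1/step) has source weight `1 - t*step`, target weight
#' `t*step`, all other channels 0: the first profile is 100% source, the last
#' 100% target, and every intermediate profile lies on the segment between
#' the two one-hot endpoints.
#'
#' @param spec a [trajectory_spec()].
#' @return matrix of `1/step + 1` rows x K channels, rows on the simplex.
#' @export
build_trajectory <- function(spec = trajectory_spec()) {
  stopifnot(inherits(spec, "trajectory_spec"))
  n_steps <- round(1 / spec$step)
  t <- seq(0, n_steps) * spec$step
  K <- length(spec$channels)
  prof <- matrix(0, length(t), K, dimnames = list(NULL, spec$channels))
  prof[, spec$source_channel] <- 1 - t
  prof[, spec$target_channel] <- t
  attr(prof, "coordinate") <- t
  prof
}

#' Generate and decode pseudocells along a trajectory
#'
#' For each conditioning profile, `replicates` latent encodings are simulated
#' by the trained generator and decoded to full expression profiles.
#'
#' @param traj conditioning-profile matrix from [build_trajectory()] (or any
#'   points x K simplex matrix).
#' @param generator a trained [train_cgan()] object.
#' @param decoder a trained [train_decoder()] object.
#' @param replicates latents per point (default 100; with the default 1%
#'   step this yields 101 x 100 = 10,100 pseudocells).
#' @param seed integer seed.
#' @param clip_negative truncate decoded expression at 0.
#' @return object of class `pseudocell_set`: `profiles`, `latents`
#'   (points x replicates x latent_dim), `expression`
#'   (points x replicates x genes), `gene_ids`, `coordinate`.
#' @export
generate_pseudocells <- function(traj, generator, decoder, replicates = 100,
                                 seed = 1, clip_negative = FALSE) {
  stopifnot(inherits(generator, "cgan"), inherits(decoder, "latent_decoder"))
  traj <- as.matrix(traj)
  if (generator$gspec$output_dim != decoder$spec$latent_dim)
    stop("generator latent dimension (", generator$gspec$output_dim,
         ") does not match decoder input (", decoder$spec$latent_dim, ")")
  lat <- generate_latents(generator, traj, n_per_profile = replicates,
                          seed = seed)
  p <- nrow(traj); ld <- dim(lat)[3]
  flat <- matrix(aperm(lat, c(2, 1, 3)), p * replicates, ld)
  expr <- decode(decoder, flat, clip_negative = clip_negative)
  g <- ncol(expr)
  expr_arr <- aperm(array(expr, dim = c(replicates, p, g)), c(2, 1, 3))
  coord <- attr(traj, "coordinate")
  if (is.null(coord)) coord <- seq(0, 1, length.out = p)
  structure(list(profiles = traj, latents = lat, expression = expr_arr,
                 gene_ids = decoder$gene_ids, replicates = replicates,
                 coordinate = coord, seed = seed),
            class = "pseudocell_set")
}

#' @export
print.pseudocell_set <- function(x, ...) {
  d <- dim(x$expression)
  cat(sprintf("pseudocell_set: %d points x %d replicates = %d pseudocells, %d genes\n",
              d[1], d[2], d[1] * d[2], d[3]))
  invisible(x)
}

#' Summarize per-gene expression dynamics along a trajectory
#'
#' Mean over replicates at each point, with a 95% confidence band: empirical
#' 2.5/97.5 percentiles of the replicates by default, or a normal
#' approximation (mean +/- 1.96 SE) behind a flag. Optionally z-scores each
#' gene's mean curve across trajectory points.
#'
#' @param pc a [generate_pseudocells()] result.
#' @param genes optional subset of gene ids.
#' @param zscore add per-gene z-scored mean curves (`zmean`); genes with
#'   constant curves get 0.
#' @param ci_method "percentile" (default) or "normal".
#' @return object of class `trajectory_summary`: matrices `mean`, `lower`,
#'   `upper` (genes x points), optional `zmean`, plus `coordinate` and
#'   `gene_ids`; `as.data.frame()` gives a tidy (gene, point, mean, lo, hi)
#'   table.
#' @export
summarize_trajectory <- function(pc, genes = NULL, zscore = TRUE,
                                 ci_method = c("percentile", "normal")) {
  stopifnot(inherits(pc, "pseudocell_set"))
  ci_method <- match.arg(ci_method)
  if (pc$replicates < 2) stop("need at least 2 replicates for a CI")
  gene_idx <- if (is.null(genes)) seq_along(pc$gene_ids) else {
    gi <- match(genes, pc$gene_ids)
    if (anyNA(gi)) stop("unknown gene ids: ",
                        paste(genes[is.na(gi)], collapse = ", "))
    gi
  }
  x <- pc$expression[, , gene_idx, drop = FALSE]  # points x reps x genes
  p <- dim(x)[1]; g <- dim(x)[3]
  mu <- t(apply(x, c(1, 3), mean))                # genes x points
  if (ci_method == "percentile") {
    lo <- t(apply(x, c(1, 3), stats::quantile, probs = 0.025, names = FALSE))
    hi <- t(apply(x, c(1, 3), stats::quantile, probs = 0.975, names = FALSE))
  } else {
    se <- t(apply(x, c(1, 3), stats::sd)) / sqrt(pc$replicates)
    lo <- mu - 1.96 * se
    hi <- mu + 1.96 * se
  }
  ids <- pc$gene_ids[gene_idx]
  dimnames(mu) <- dimnames(lo) <- dimnames(hi) <- list(ids, NULL)
  out <- list(mean = mu, lower = lo, upper = hi, coordinate = pc$coordinate,
              gene_ids = ids, ci_method = ci_method)
  if (zscore) {
    sds <- apply(mu, 1, stats::sd)
    zm <- (mu - rowMeans(mu)) / ifelse(sds > 0, sds, 1)
    zm[sds == 0, ] <- 0
    out$zmean <- zm
  }
  structure(out, class = "trajectory_summary")
}

#' @export
as.data.frame.trajectory_summary <- function(x, ...) {
  p <- length(x$coordinate)
  data.frame(gene = rep(x$gene_ids, each = p),
             coordinate = rep(x$coordinate, length(x$gene_ids)),
             mean = as.vector(t(x$mean)),
             lower = as.vector(t(x$lower)),
             upper = as.vector(t(x$upper)))
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat(sprintf("trajectory_summary: %d genes x %d points (%s CI)\n",
              length(x$gene_ids), length(x$coordinate), x$ci_method))
  invisible(x)
}

#' Cluster genes into transcriptional phases along the trajectory
#'
#' Clusters z-scored mean curves (k-means with seeded restarts by default, or
#' average-linkage hierarchical clustering) and labels each cluster by the
#' trajectory position of its mean curve's peak: the cluster peaking earliest
#' is "early", then "middle", then "late" (numbered phases when
#' `n_phases != 3`).
#'
#' @param summary a [summarize_trajectory()] result (with `zmean`).
#' @param n_phases number of phases (default 3).
#' @param method "kmeans" or "hclust".
#' @param seed integer seed for the k-means restarts.
#' @return list with `phase` (named factor, ordered early -> late), `order`
#'   (heatmap row order: genes grouped by phase, by peak position within),
#'   and `peak` (each gene's peak coordinate).
#' @export
phase_cluster <- function(summary, n_phases = 3,
                          method = c("kmeans", "hclust"), seed = 1) {
  stopifnot(inherits(summary, "trajectory_summary"))
  method <- match.arg(method)
  if (is.null(summary$zmean))
    stop("summary lacks z-scored curves; rerun summarize_trajectory(zscore = TRUE)")
  z <- summary$zmean
  nonconst <- apply(summary$mean, 1, stats::sd) > 0
  if (sum(nonconst) < n_phases)
    stop("need at least ", n_phases, " genes with non-constant curves")
  z <- z[nonconst, , drop = FALSE]
  g <- nrow(z)
  n_phases <- min(n_phases, g)
  cl <- if (method == "kmeans") {
    set.seed(seed)
    if (n_phases == g) seq_len(g) else
      stats::kmeans(z, centers = n_phases, nstart = 10,
                    iter.max = 100)$cluster
  } else {
    stats::cutree(stats::hclust(stats::dist(z), method = "average"),
                  k = n_phases)
  }
  coord <- summary$coordinate
  peak_pos <- coord[apply(z, 1, which.max)]
  cluster_peak <- vapply(seq_len(n_phases), function(k)
    mean(peak_pos[cl == k]), 0)
  phase_names <- if (n_phases == 3) c("early", "middle", "late") else
    paste0("phase_", seq_len(n_phases))
  rank_of <- rank(cluster_peak, ties.method = "first")
  phase <- factor(phase_names[rank_of[cl]], levels = phase_names)
  names(phase) <- rownames(z)
  ord <- order(as.integer(phase), peak_pos, names(phase))
  list(phase = phase, order = rownames(z)[ord],
       peak = stats::setNames(peak_pos, rownames(z)))
}

#' Nearest real cell for each pseudocell
#'
#' Exact nearest-neighbour search of every pseudocell against a reference
#' expression matrix (shared gene space), used to audit whether generated
#' cells fall near observed ones.
#'
#' @param pc a [generate_pseudocells()] result.
#' @param expr reference [expression_matrix()] on the decoder's gene set.
#' @param metric "euclidean" or "cosine" (cosine distance = 1 - cosine
#'   similarity, in `[0, 2]`).
#' @return data.frame with point, replicate, nearest cell id and distance.
#' @export
nearest_real_cell <- function(pc, expr, metric = c("euclidean", "cosine")) {
  stopifnot(inherits(pc, "pseudocell_set"))
  metric <- match.arg(metric)
  if (inherits(expr, "ExpressionMatrix")) {
    if (!identical(expr$gene_ids, pc$gene_ids))
      stop("reference gene set/order differs from the pseudocells'")
    ref <- expr$values
  } else ref <- as.matrix(expr)
  if (nrow(ref) == 0) stop("empty reference")
  d <- dim(pc$expression)
  q <- matrix(aperm(pc$expression, c(2, 1, 3)), d[1] * d[2], d[3])
  if (metric == "euclidean") {
    cross <- tcrossprod(q, ref)
    d2 <- outer(rowSums(q^2), rep(1, nrow(ref))) - 2 * cross +
      outer(rep(1, nrow(q)), rowSums(ref^2))
    d2[d2 < 0] <- 0
    dist <- sqrt(d2)
  } else {
    qn <- q / pmax(sqrt(rowSums(q^2)), 1e-12)
    rn <- ref / pmax(sqrt(rowSums(ref^2)), 1e-12)
    dist <- 1 - tcrossprod(qn, rn)
  }
  nn <- max.col(-dist, ties.method = "first")
  data.frame(point = rep(seq_len(d[1]), each = d[2]),
             replicate = rep(seq_len(d[2]), d[1]),
             cell_id = rownames(ref)[nn],
             distance = dist[cbind(seq_len(nrow(dist)), nn)])
}
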