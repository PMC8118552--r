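---
title: "Supervised pseudocell tracing: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised pseudocell tracing: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Trajectory inference from scRNA-seq usually orders *observed* cells along a
pseudotime axis found by unsupervised dimensionality reduction. In
heterogeneous compartments this fails in two characteristic ways: concurrent
transcriptional programs (cell cycle above all) dominate the leading axes of
variation, and intermediate states may be so sparsely sampled that no
continuum is visible to order. Germinal-center B cells undergoing class
switch recombination (CSR) are a textbook case: cells progress from IgM
towards IgG1/IgG2b/IgG3 expression, but an unsupervised embedding groups
them by cell-cycle phase, not by switching state.

This package takes the opposite route: instead of ordering observed cells,
it *generates* hypothetical cells ("pseudocells") at regular intervals along
a user-defined cell-state axis ("pseudospace"). The axis is anchored in
**adjacent biological information** — a per-cell measurement known to track
the process monotonically. For CSR this is the relative isotype expression:
for cell $i$ with log-expression $x_{ik}$ of the eight IgH constant-region
transcripts (Ighm, Ighg1, Ighg2b, Ighg2c, Ighg3, Igha, Ighd, Ighe),

$$Y_{ik} = \frac{\log_2(\mathrm{TPM}_{ik}+1)}{\sum_{k'}\log_2(\mathrm{TPM}_{ik'}+1)},$$

a simplex vector that moves from $e_{\mathrm{IgM}}$ towards
$e_{\mathrm{IgG1}}$ as a cell switches.

## Model

Three networks are trained in sequence.

**Supervised encoder.** $f_{enc}: x_i \mapsto z_i \in (0,1)^{64}$, a
multilayer perceptron (hidden 512/256, ReLU, dropout 0.3) with a sigmoid
latent layer, followed by a prediction head (hidden 128, softmax output over
the $K=8$ channels) producing $\hat Y_i$. The loss is

$$L_{enc} = \frac1n \sum_i \mathrm{KLD}(Y_i \,\|\, \hat Y_i)
  + \lambda \sum_l \|W_l\|^2,$$

with $\lambda = 10^{-5}$ and Adam at learning rate $10^{-4}$. Because the
profile prediction must pass through the latent bottleneck, cells with
similar isotype profiles receive similar latent encodings — the latent
space is *shaped* by the adjacent information rather than by total variance.

**Decoder.** $f_{dec}: z_i \mapsto \hat x_i$, hidden 256/512 with batch
normalization, linear output over all genes, trained on the frozen encoder's
latents with $L_{dec} = \frac1n\sum_i (x_i - \hat x_i)^2 + \lambda\sum_l
\|W_l\|^2$ (mean squared error; we average over cells *and* genes so the
value is comparable across gene-set sizes).

**Conditional GAN.** A generator $G(\varepsilon, r)$ maps 32 uniform(−1,1)
noise values concatenated with a conditioning profile $r$ to a latent vector
(hidden 256/512, linear output); a discriminator $D(z, r)$ (single hidden
layer of 512, sigmoid output) scores latent/condition pairs. Losses:

$$L_D = \frac1n\sum_i -\log D(z_i) - \log(1 - D(G(r_i))), \qquad
  L_G = \frac1n\sum_i \log D(G(r_i)).$$

$L_G$ as printed is the objective the generator *maximizes*; the
implementation minimizes its negation (the standard non-saturating form,
which avoids vanishing gradients early in training, when
$D(G(\cdot)) \approx 0$). Training is simultaneous (one discriminator and
one generator Adam step per mini-batch, learning rate $5\times10^{-5}$)
until equilibrium. Critically, the GAN operates in the 64-dimensional latent
space, not gene space — adversarial training directly over $10^3$–$10^4$
genes is unstable — and the real latents $z_i$ enter only the
discriminator: the generator learns exclusively through the discriminator's
gradient.

**Pseudospace tracing.** A trajectory from channel $s$ to channel $t$ with
step 0.01 is the profile sequence $r(\tau) = (1-\tau) e_s + \tau e_t$,
$\tau = 0, 0.01, \ldots, 1$ — 101 points. At each point we draw 100
latents from the generator and decode them, giving 10,100 pseudocells; the
per-gene summary is the mean over replicates with an empirical 95% band,
optionally z-scored across trajectory points, and genes are grouped into
early/middle/late phases by clustering the z-scored curves.

## Training protocol

Early stopping is identical for encoder and decoder: 10% of the training
data is held out (stratified by dominant channel for the encoder, so rare
isotypes are represented); the *monitored term only* (KLD or MSE, penalty
excluded) is evaluated on it each epoch; training stops after 100 epochs
without a decrease (`patience_epochs`); weights revert to the best epoch;
then 5 further epochs run on the full training data including the
validation split (`post_restore_epochs`). A hard cap of 10,000 epochs
bounds runtime. Batch size defaults to 128 (unstated in the reference
protocol; configurable), Adam uses the conventional
$\beta_1=0.9,\ \beta_2=0.999$.

"Epoch" for the CGAN means a full pass over the dataset. The default cap is
50,000 epochs with an optional plateau monitor (relative change of both
losses below $10^{-4}$ over a 500-epoch window) and a divergence detector
(non-finite losses, or a discriminator pinned at perfect accuracy for a full
window, abort with diagnostics).

**EMA generator.** The adversarial iterate oscillates around the
equilibrium, so the generator weights at an arbitrary stopping epoch are a
noisy draw from that oscillation. We therefore keep an exponential moving
average of the generator weights (decay 0.999) and use it for generation;
the raw final iterate remains available (`use_ema = FALSE`), and the
discriminator-equilibrium diagnostics score the raw generator, which is the
discriminator's actual adversary.

## Numerical choices

* KLD guard: predictions are clipped to $[10^{-12}, 1]$ before the log, and
  $Y_k = 0$ terms contribute exactly 0. Discriminator probabilities are
  clipped to $[10^{-7}, 1-10^{-7}]$.
* Cells with zero total channel expression receive the uniform profile
  $1/K$ with a warning naming them — the simplex invariant holds for every
  cell and none is silently dropped.
* TPM from UMI counts: counts-per-million is used as the TPM surrogate
  (droplet data has no gene-length bias); a message records the choice.
* Variable genes are ranked by plain variance on the log2(TPM+1) scale
  (`cv2` is available); ties and order are resolved by keeping the original
  gene order among the selected.
* Profile clustering uses Euclidean distance with average linkage; leaf
  order is the deterministic `hclust` order.
* The 95% band is the empirical 2.5/97.5 percentile of the 100 replicates —
  distribution-free and exactly what 100 draws support; a normal
  approximation (mean ± 1.96 SE) is available behind `ci_method`.
* z-scoring is applied to the per-gene *mean curve* across trajectory
  points (not to individual replicates); phase clustering is seeded k-means
  with 10 restarts on those curves (hierarchical clustering available), and
  phases are named by the trajectory position of each cluster's peak.
* Decoded expression is reported raw (the decoder output is linear);
  `clip_negative` truncates at 0 on request.

## Open design points, resolved

* The decoder trains on latents from a *frozen* encoder — the two-step
  protocol implies the encoder is fixed once trained, and we follow that.
* Isotype channel genes are retained in the encoder's input (they are
  genuine transcripts of the cell state; excluding them is possible by
  subsetting the input matrix beforehand).
* Encoder inputs are raw log2(TPM+1) without per-gene standardization.
* The encoder's input width is whatever survives zero-count filtering; the
  top-6,500 variable-gene cut is an analysis-time filter for heatmaps and
  can also be applied before training via `top_genes`.
* HDF5 I/O is not provided; MTX (10x convention) and dense CSV/TSV are.
  Model archives are single RDS files containing weights, specs, gene and
  channel order, and seeds.

## The synthetic-data generator

Real data for this biology (NP-KLH-induced germinal-center B cells) has no
public accession, so validation rests on a simulator that reproduces the
statistical structure the method assumes, with full ground truth:

* each cell has a trajectory coordinate $t$: stable cells at $t \in \{0,1\}$
  (composition: IgM 40%, IgG1 25%, IgG2b 15%, IgG3 10%, the remaining
  isotypes rare), and a 15% minority of transitioning cells with
  $t \sim U(0,1)$ (a beta option models sparse intermediate sampling);
* channel transcripts are planted so that the *computed* relative profile
  of a cell at $t$ is approximately $(1-t, t)$ on its two active channels
  (planted channel TPM $= 2^{10\,y}-1$, i.e. a ~10 log2-unit expression
  budget, realistic for Ig transcripts in B cells);
* three gene modules follow Gaussian response curves in $t$ peaking at 0.1,
  0.5 and 0.9 (log2 amplitude ~2.5) — the planted early/middle/late phases;
* a rank-2 oscillatory program with random per-cell phase emulates the
  cell-cycle confounder; at high amplitude it dominates PC1, reproducing
  the failure mode that motivates supervision;
* counts are negative binomial (size 10) at a ~50,000-read depth with
  mean-dependent dropout ($p = 0.15\,e^{-\mu}$), and the planted TPM matrix
  is row-normalized to $10^6$ with a high-expressed background absorbing
  the budget, so the planted channel values survive CPM re-normalization.

What it does **not** emulate: batch effects, doublets, gene-length bias,
somatic-hypermutation lineage structure, and realistic zero-inflation
beyond the simple dropout model. Passing tests on this simulator therefore
demonstrate that the implementation recovers planted structure under the
method's assumptions — not that the method is robust to everything real
data can do.

## Validation problem sizes

The packaged tests and the acceptance script train reduced architectures
(hidden 64/32, latent 16, head 32, dropout 0.1, learning rate $10^{-3}$;
CGAN noise 16, hidden 64/128, learning rate $2\times10^{-4}$, 25,000
epochs) on a tiny fixture (200 cells × 300 genes) and a small fixture
(1,000 × 2,000, cut to the 500 most variable genes), with a 500/1,000/5,000
cell sweep at a fixed 80-epoch budget. These are the package's validation
sizes; the full-scale defaults (512/256, latent 64, dropout 0.3, learning
rates $10^{-4}$/$5\times10^{-5}$, patience 100) remain the package
defaults and correspond to datasets of several thousand cells.

## Known limitations

* Channels dominated by a handful of cells (here Ighd/Ighe at ~1–2%) are
  hard to learn and their held-out per-channel correlations are unstable at
  small sample sizes; the well-populated channels are consistently
  recovered at $r > 0.9$.
* GAN training is stochastic across seeds; all randomness is drawn from R's
  RNG so any single seed is exactly reproducible, but quantitative results
  (e.g. discriminator equilibrium values) vary between seeds.
* Pseudocells are generated, not observed: a trajectory summary is a model
  interpolation conditioned on the adjacent information and inherits any
  bias of the decoder; the `nearest_real_cell()` audit is the built-in
  sanity check against the observed population.
* Trajectories are single-segment source→target interpolations; branching
  topologies are out of scope.
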