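---
title: "Model and methods behind zivae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind zivae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Single-cell RNA-seq measures the transcriptome of individual cells, but
the measurements are far noisier than bulk RNA-seq: transcriptional
bursting, minute amounts of starting material, and — most
characteristically — *dropout events*, where a transcript that is
present in the cell fails to be captured and reads out as a zero or
near-zero value. Visualization and most downstream analyses (cell-type
identification, lineage reconstruction) start from a low-dimensional
representation of the cell-by-gene matrix, and linear methods or
methods that ignore the dropout process tend to blur cluster structure.

`zivae` learns a two-dimensional (by default) embedding of cells with a
deep variational autoencoder whose *output* layer explicitly models the
dropout process, so that the latent space is not forced to explain
technical zeros as biology.

# The model

## Input space

The model consumes values in the unit interval. Preprocessing is:

1. optional cell filtering (minimum number of detected genes) and, for
   UMI data, library-size normalization to a fixed per-cell total
   (default 10,000);
2. `log2(x + 1)` transformation;
3. per-cell rescaling: each cell's row is divided by that cell's
   maximum, so every cell has maximum exactly 1.

The per-cell reading of the rescaling step is a deliberate design
choice: the decoder ends in a sigmoid, so its reconstruction space is
per-cell unit-interval profiles, and dividing each cell by its own
maximum puts every cell into exactly that space regardless of
sequencing depth. A per-gene reading would tie the scale of a cell's
profile to other cells in the batch. All-zero cells are passed through
unchanged rather than silently dropped (dropping would silently
misalign label files); the command-line interface warns and recommends
filtering them.

## Architecture

* **Input dropout** (rate 0.5): during training each input entry is
  independently zeroed with probability 0.5 — unusually aggressive for
  an input layer, and intentionally so: zeroing mimics additional
  dropout events, forcing the encoder to be robust to them. Entries are
  *not* rescaled by `1/(1-rate)`; the layer is pure zero-noise
  injection, matching the view of the layer as artificial dropout
  rather than standard magnitude-preserving dropout regularization.
* **Encoder** 512 → 128 → 32. The first layer is linear (an embedded
  PCA-like projection) and carries an L1 penalty on its weights
  (default 0.01), encouraging a sparse gene loading; the remaining
  layers use ReLU.
* **Latent posterior**: a diagonal Gaussian `Q(z|X)` with a standard
  normal prior. The mean head is linear. The covariance is either fixed
  to the identity (log-variance ≡ 0) or learned through a softplus head
  for the log-variance. The sample-size rule (`sigma_mode = "auto"`)
  fixes the covariance for datasets of ≤ 1000 cells and learns it
  above: with few cells, per-cell variance estimation destabilizes
  training. We read "fix the covariance" as the identity covariance
  (log-variance 0); the softplus head's non-negative log-variance makes
  the learned mode consistent with that convention (variances ≥ 1).
* **Reparameterization**: `z = mu + exp(log_var/2) * eps`,
  `eps ~ N(0, I)`, so gradients flow through the sampling step.
* **Decoder** 32 → 128 → 512 with ReLU, then a sigmoid output layer
  producing the reconstruction `y_tilde` in (0, 1).
* **Zero-inflation (ZI) layer**: the probability that an entry drops
  out is modeled as a double-exponential decay in the reconstructed
  expression, `p = exp(-y_tilde^2)` — certain dropout at zero
  expression, probability `e^{-1}` at the per-cell maximum. A hard
  Bernoulli draw would block backpropagation, so the dropout indicator
  is sampled from the Gumbel-softmax relaxation
  `s = sigmoid((log p - log(1-p) + g0 - g1)/tau)` with Gumbel(0,1)
  noise `g = -log(-log u)`, and the output is the soft mask
  `y = (1 - s) * y_tilde`. As the temperature `tau` goes to 0, `round(s)`
  converges to a Bernoulli(p) draw, recovering discrete zero-setting;
  at moderate `tau` the layer also produces *near*-zero outputs, which
  matches the near-zero dropout events seen in real data. `p` is
  clamped to `[1e-7, 1 - 1e-7]` before the logs (at `y_tilde = 0` the
  probability is exactly 1 and `log(1-p)` would be `-Inf`); the clamp
  region contributes zero gradient.

The orientation of `s` (1 = dropout, reconstruction multiplied by
`1 - s`) is a convention we fixed; the soft product is equivalent to
Bernoulli zero-setting in the low-temperature limit and keeps the layer
differentiable.

## Loss and optimization

The objective is the negative evidence lower bound: per cell, binary
cross-entropy between the original profile `x` and the zero-inflated
reconstruction `y` (appropriate because both live in `[0,1]`), plus the
KL divergence from the posterior to the prior, computed analytically as
`-0.5 * sum(1 + log_var - mu^2 - exp(log_var))`; with fixed covariance
this reduces to `||mu||^2 / 2`. The L1 penalty on the first encoder
layer is added to the batch mean.

Training uses RMSprop (learning rate 1e-4, decay 0.9, epsilon 1e-8,
recorded in the returned history) over shuffled mini-batches (default
`min(n_cells, 256)`; full batch for small data keeps gradients stable).
Training stops when the best epoch loss has not improved by more than
`min_loss_delta` for 50 consecutive epochs, or at `max_epochs`; the
weights of the best epoch are restored (the stopping rule already
tracks the best loss, so restoring it is the consistent choice). The
"obvious decrease" in the stopping rule is operationalized as an
absolute improvement threshold, default `1e-4`. A non-finite loss
aborts with a diagnostic naming the offending term rather than training
onward from a poisoned state.

The Gumbel temperature is either constant (default 0.75, inside the
recommended 0.5–1 range for small datasets) or annealed linearly from
1.0 at epoch 0 to 0.5 at epoch 200 and held there — the schedule we
recommend beyond roughly 1000 cells, where the longer training run
benefits from starting smooth and sharpening.

At inference every stochastic layer is disabled: the embedding is the
posterior mean `mu`, input dropout is off, and the ZI layer passes the
reconstruction through. Coordinates are therefore a pure function of
the data and weights — the property that makes embeddings reproducible
and checkpoint replay byte-identical. (Whether to embed at `mu` or at a
posterior sample is a genuine choice; `mu` is the only option that
yields deterministic, replayable coordinates.)

The network, its reverse-mode gradients and the RMSprop loop are
implemented directly on BLAS-backed matrix operations; the gradient of
every layer (including the Gumbel-softmax and the clamps, which
propagate zero gradient outside their active range) is written out
explicitly in `.backward_pass()`.

# Evaluation protocol

Embedding quality is scored by clustering the 2D coordinates with
k-means (k set to the number of known cell types, 10 restarts, seeded;
`stats::kmeans` supplies the algorithm) and comparing the predicted
partition with the known labels using four agreement measures,
implemented from their definitions with natural-log entropies:

* **NMI** `= MI(P,T) / sqrt(H(P) H(T))` (geometric-mean
  normalization). Degenerate zero-entropy cases are defined by
  convention: 1 when both partitions are the identical single cluster,
  0 when exactly one entropy vanishes.
* **ARI**: pair-counting agreement corrected for chance; the
  tests cross-check it against an exhaustive `O(n^2)` pair-enumeration
  oracle. When the denominator vanishes both partitions are necessarily
  identical (both all-singletons or both one cluster) and the value is 1.
* **Homogeneity** `1 - H(T|P)/H(T)` and **completeness**
  `1 - H(P|T)/H(P)`, each defined as 1 when the reference entropy is
  zero; the two are duals (`completeness(P,T) = homogeneity(T,P)`).

Candidate marker genes are ranked by the Spearman correlation between
each gene's expression and each embedding axis (ties by average rank;
constant genes are flagged and assigned correlation 0).

# The synthetic-data generator

The generator produces the minimal structure that exercises the model:
cluster-structured log-scale expression with expression-dependent
dropout. Each gene receives one center per cluster from
`Normal(mean_log_expression, between_cluster_sd^2)`; cells draw values
around their cluster's centers with `within_cluster_sd`, clipped at
zero; entries then drop out independently with probability
`exp(-lambda x^2)`, the same double-exponential law the model's ZI
layer assumes (`lambda = 1` on unit-scaled data reproduces it exactly;
exposing `lambda` lets tests sweep dropout severity — note the
documented degenerate case `lambda = 0`, which zeroes everything).

Defaults — 300 cells, 500 genes, 3 balanced clusters, centers at
`log2` expression 2 with between/within spread 1.0/0.2 (a 5:1
separation-to-noise ratio), moderate dropout `lambda = 0.5` (about 25%
zeros) — describe a clearly separable but noisy regime typical of a
small, well-annotated scRNA-seq dataset. The pinned `heavy_dropout`
fixture uses `lambda = 0.08` (about 70% zeros), comparable to
droplet-based data. Cluster sizes follow largest-remainder rounding of
the proportions, so sizes are deterministic.

What the generator does **not** emulate: count-level sampling (negative
binomial dispersion), library-size variation, batch effects, gene–gene
correlation beyond cluster structure, or continuous trajectories.
Passing the recovery tests therefore demonstrates that the pipeline
learns well-separated cluster structure under expression-dependent
dropout — not that it resolves the harder regimes of real data.

# Numerical choices and problem sizes

* Probabilities and reconstructions are clamped by `1e-7` before logs;
  clamps backpropagate zero gradient.
* Softplus is computed as `log1p(exp(x))` with a linear branch above
  30 to avoid overflow.
* Weights initialize from symmetric uniform draws with fan-based limits
  (`sqrt(6/(fan_in+fan_out))`), from a dedicated seed; every stochastic
  element of training (shuffling, masks, latent noise, Gumbel draws)
  derives from the training seed, making runs bit-reproducible.
* Variable-gene selection uses a variance-over-mean dispersion on log
  values with ties broken by gene order — a standard deterministic
  proxy; the retained count is a parameter, not a fixed list.
* The test suite and the acceptance script train on the pinned 300-cell
  by 500-gene fixtures for up to 250–300 epochs (cluster recovery
  saturates there across seeds) and demonstrate the early-stopping rule
  once with the full patience criterion; the 60-cell `tiny3` fixture
  backs the fast unit tests.

# Known limitations

* Pure-R training is practical to a few thousand cells; beyond that a
  GPU implementation of the same architecture is the right tool.
* The embedding is as good as k-means can see: strongly non-convex
  cluster shapes in the latent space are scored conservatively.
* The sample-size thresholds (1000 cells for the covariance mode and
  the annealing recommendation) are heuristics, not fitted values.
* With `sigma_mode = "fixed"` the KL term regularizes only the
  posterior mean; uncertainty in the embedding is not represented.
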