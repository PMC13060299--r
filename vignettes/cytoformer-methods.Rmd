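---
title: "Set-transformer modelling of flow cytometry samples: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-transformer modelling of flow cytometry samples: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A flow cytometry sample is a *set* of cells, each described by the
fluorescence intensities of the antibody markers measured in that
experiment's panel. Two properties make sample-level prediction hard for
ordinary models: the cells carry no order (any row permutation of the event
matrix is the same sample), and different experiments measure different
marker subsets of a larger vocabulary, so the per-cell feature space is not
aligned across samples. `cytoformer` models such data with a
permutation-invariant transformer encoder–decoder trained in two stages:
masked self-supervised pretraining of a cell-level encoder, followed by
supervised training of a cross-attention pooling decoder whose attention
weights provide per-cell attribution.

# Panel-augmented cell embedding

Let $M$ be the global marker vocabulary ($|M|$ slots, fixed for the lifetime
of a model) and $M_s \subseteq M$ the markers measured for sample $s$. Each
cell $i$ is embedded as the concatenation $c_i = [a_i; e_i] \in
\mathbb{R}^{2|M|}$ of

* an availability indicator $a_i \in \{0,1\}^{|M|}$, with $a_i(j) = 1$ iff
  marker $j$ is measured *and* not masked for this cell, and
* a sparse expression vector $e_i$, carrying the measured intensity where
  available and a learnable per-marker value $\mu_j$ everywhere else.

Because the availability bit always differs, a measured-but-unexpressed
marker (value 0) is never confused with an unmeasured one. A vocabulary slot
that is never measured contributes the constant pair $(0, \mu_j)$, which the
network learns to ignore; extending the vocabulary with such a slot changes
dimensions but (with zero-extended projection weights) not the projected
output. Masked entries during pretraining are embedded exactly like
unmeasured ones — the distinction exists only in the loss bookkeeping. The
augmented vector is projected to the hidden size $h$ by one affine layer
with ReLU (a second layer is configurable; one suffices at the scales we
train). $\mu$ is initialised at zero — a "no signal" prior — and trained
only during pretraining.

# Encoder, decoder, attention

The encoder is a stack of Pre-LN blocks: multi-head scaled dot-product
self-attention and a two-layer position-wise feed-forward network, each
inside a residual connection whose input is layer-normalised, with a final
LayerNorm after the last block (standard Pre-LN practice). No positional
encoding is used, so the encoder is exactly permutation-equivariant over
cells. The decoder refines a single learnable, task-specific prediction
token through cross-attention blocks in which the token provides the query
and the encoder's cell latents provide keys and values; with one query
token, query self-attention is vacuous and is omitted. The final token state
feeds a linear task head (class scores, or a scalar for regression). The
prediction is permutation-invariant; the post-softmax attention weights,
captured per layer and head in evaluation mode, sum to one over cells and
are the package's per-cell importance measure.

Defaults follow the reference setting: hidden size 128, 4 encoder and 4
decoder layers, 4 heads, feed-forward inner width $4h$. Heads emit
log-variances, exponentiated with a floor of $10^{-6}$ (clamp events are
counted and surfaced); the floor makes the Gaussian likelihood safe for
degenerate columns.

# Pretraining targets and objective

For each sample's event matrix $X \in \mathbb{R}^{n\times m}$ three per-cell
targets are computed per marker column: the raw expression $X$; the
percentile matrix $P_{ij} = \mathrm{rank}(X_{ij} \mid X_{\cdot j})/n$ with
*average* ranks for ties (keeping every column mean at $(n{+}1)/2n$ and the
entries in $(0,1]$); and the log Gaussian-kernel density
$D_{ij} = \log\left[\tfrac{1}{n\sigma}\sum_{i'} K\!\big((X_{ij} -
X_{i'j})/\sigma\big)\right]$ with bandwidth $\sigma = 0.05$ on the
transformed scale, the query point included in the sum, evaluated in
log-space with log-sum-exp so isolated points do not underflow. Percentile
and density are rank- and shape-based views of the same column and are less
sensitive to affine batch shifts than raw intensities. Targets are
precomputed per sample (up to 50 000 cells) and cached on disk keyed by
(sample, $\sigma$, cap, seed).

Two complementary masked views supervise the model. *Uniform-random*
masking first draws a sample-wide dropout ratio $r_{drop} \sim
\mathrm{Beta}(\alpha_1,\beta_1)$ and removes $\mathrm{round}(m\,r_{drop})$
markers entirely (they become unmeasured and contribute nothing to the
loss), then masks each remaining entry independently with probability
$r_{mask} \sim \mathrm{Beta}(\alpha_2,\beta_2)$. *Marker-wise* masking
masks $\mathrm{round}(m\,r_{mask})$ whole columns, mimicking a smaller
panel. Rounding is half-away-from-zero and at least one marker always
survives. Defaults $\mathrm{Beta}(1,9)$ for dropout (mean 0.1) and
$\mathrm{Beta}(2,6)$ for both masking ratios (mean 0.25) are this package's
choices — mild dropout, moderate masking, in line with masked-modelling
practice — and are recorded in every checkpoint. Masks are redrawn each
epoch from streams keyed by (seed, sample, epoch, pattern).

Each view passes through embedding, encoder and three heteroscedastic heads
predicting mean and variance for every vocabulary slot. The loss per target
is the Gaussian negative log-likelihood — mean over included entries of
$\tfrac12[\log v + (t-\hat t)^2/v + \log 2\pi]$, the constant included so
the value is the actual negative log density — evaluated on masked entries
plus $\beta$ times the unmasked measured entries, with $\beta = 0.5$ by
default (the weight must be below 1; the exact value is this package's
choice and is configurable). Only measured, non-dropped slots are ever
supervised. Targets combine with weights $w_x = w_p = w_d = 1$ and the two
patterns average with weights $0.5/0.5$; the scalar loss equals the weighted
sum of its 12 logged components to numerical precision. The mean (not sum)
reduction within each component keeps $\beta$'s effect independent of mask
size.

# Downstream training

The decoder and task head are trained with cross-entropy (classification) or
mean squared error (regression) while the embedding, mask bank and encoder
stay frozen — bitwise, which the tests assert; an unfreeze flag exists for
data-rich regimes. In place of neuron dropout, a marker-wise input dropout
at a fixed rate (default 0.1) reuses the marker-wise masking machinery at
training time only. Samples are capped at 7000 cells downstream and 5000
during pretraining (per epoch, seeded); a 90–10 train/validation split
drives early stopping on validation loss with patience 10. The optimiser is
AdamW (decoupled decay 0.01 on weight matrices only) with a cosine-decayed
learning rate — 1e-3 for pretraining, 1e-4 downstream as conservative
defaults for data-rich use — and global-norm gradient clipping at 1. These
optimisation constants are the package's own stand-ins where the original
description leaves them open; all are configurable.

## Latent standardisation

Before decoder training the package computes, once, the per-dimension mean
and standard deviation of the encoder latents over all training cells, and
the decoder consumes standardised latents thereafter (the statistics are
stored in the checkpoint and applied identically at inference). This is pure
preconditioning: an affine map that could be absorbed into the decoder's
query/key/value projections. It matters at small problem sizes because the
cross-attention pooled features vary across samples by far less than their
constant offset; without the rescaling, the linear task head needs weight
norms that first-order optimisers only reach after tens of thousands of
steps, and decoder training stalls near the chance-level loss. With it, the
same architecture fits in tens of epochs. For unfrozen (end-to-end)
training the statistics are computed from the initial encoder and kept
fixed.

# Synthetic data generator

The simulator is the test bed for the whole pipeline and defines the study
conditions of the package's own experiments. It draws cells from a Gaussian
mixture over the vocabulary: five immune-like populations (T helper,
cytotoxic T, B, NK, myeloid) with characteristic mean profiles on a
logicle-like $[0,1]$ scale and common within-population spread (sd 0.08),
an 8-marker vocabulary, and three overlapping panels sharing a CD3/B220
backbone so the panel-heterogeneity path is genuinely exercised. Batches
(three, round-robin) perturb each marker with a per-(batch, marker) affine
map — additive sd 0.02, log-scale multiplicative sd 0.03, mild systematic
shifts of the kind the percentile/density targets are meant to resist. The
planted class effect shifts the NK population's frequency by +0.10 in the
case class (renormalising the others), optionally with a mean shift;
per-cell population identities are recorded as ground truth for the
attention-enrichment oracle. The generator makes no biophysical claims: no
spillover, no instrument-scale raw values, Gaussians untruncated. Passing
tests on it demonstrates that the machinery recovers planted signal under
panel and batch heterogeneity — not that it reaches any particular accuracy
on real cytometry data.

# The scaled-down recovery experiment

`synthetic_recovery_experiment()` is the package's end-to-end benchmark:
100 samples (50 per class, 1000 cells each), split 60/40 train/test, a
small model ($h = 32$, 2 encoder + 2 decoder layers, 4 heads). Three fits
are compared: pretrained encoder + decoder fine-tuned on all training
labels; the same pretrained encoder fine-tuned on 5 labels per class; and
the identical architecture trained end-to-end from scratch on those same 10
labels. Problem sizes are deliberately small — 8 pretraining epochs on
256-cell subsamples, up to 15 downstream epochs on 600-cell subsamples,
full samples at evaluation — so the experiment runs in a few minutes on one
core. Two scale-specific choices are documented here: marker-wise input
dropout is disabled (with 6–7-marker panels a fixed 0.1 rate removes a whole
marker every step, frequently the only informative one for a planted
single-population effect), and the downstream learning rate is raised to
3e-3 (tiny corpus, few steps). Attention attribution is assessed on the
full model by the hypergeometric enrichment of the planted population among
the top-5% attended cells (final decoder layer, head-averaged); the
per-seed summary is the median p-value over correctly classified *case*
samples, since the planted effect elevates that population in the case
class and attending to it is how the evidence presents.

# Numerical and interface choices

* **Logicle.** The forward transform solves the standard biexponential by
  safeguarded bisection (60 iterations, ~1e-13), with the closed-form
  inverse exported; outputs live on the normalised display scale $[0,1]$
  over $M{+}A$ decades, raw 0 mapping to $(A{+}W)/(M{+}A)$. Parameters
  default to the community-standard $T{=}262144, W{=}0.5, M{=}4.5, A{=}0$
  (the source description names none), overridable per file. Inputs may be
  declared pre-transformed; no compensation is applied.
* **FCS.** A minimal list-mode FCS 3.0/3.1 reader (float, double, integer;
  both byte orders) is included because no installed package provides one;
  channels resolve to markers through the `$PnS` stain keyword or an
  explicit channel map, and unannotated channels are dropped. Writing FCS is
  out of scope; the on-disk corpus form is a TSV + JSON sidecar store that
  round-trips exactly.
* **Permutation invariance** holds mathematically everywhere, but floating
  point addition is not associative: permuting cells reorders summations
  inside BLAS, so tests assert invariance at 1e-8 rather than bitwise;
  duplicate-cell symmetry and the single-cell case are exact.
* **Ties and rounding.** Percentile ranks use average ties (order-independent,
  mean-preserving); marker-count rounding is half-away-from-zero.
* **Gradients.** All backward passes are hand-written and verified against
  central finite differences; mismatches at ReLU kinks (one-sided
  derivatives) are expected and excluded by using small steps.
* **Determinism.** Every stochastic step draws from a stream derived from
  (seed, sample id, epoch, purpose) via a rolling hash, so results are
  independent of iteration order and identical across runs with the same
  seed.

# Known limitations

The quadratic cost of self-attention in the number of cells is accepted, as
in the original design; at R speeds this binds earlier, which is why the
package's experiments subsample cells per training step. Multi-task
decoders, attention-rollout-style attribution, batch-effect alignment and
marker-name ontology matching are out of scope. The simulator's Gaussian
populations are a deliberately idealised stand-in for real immunophenotype
data; conclusions about real-data accuracy require real data.
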