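# cytoformer

Sample-level predictive modelling of flow cytometry data with a
permutation-invariant transformer encoder–decoder, for immunologists and
computational biologists who need one model across heterogeneous marker
panels — plus per-cell attribution telling them *which* cells drove each
prediction.

## The model

A cytometry sample is a set of cells $s = \{v_1,\dots,v_{n_s}\}$, each cell
a vector of intensities over the measured markers $M_s \subseteq M$ of a
global vocabulary $M$. `cytoformer` handles panel heterogeneity with a
fixed-size per-cell embedding $c_i = [a_i; e_i] \in \mathbb{R}^{2|M|}$: a
binary availability indicator concatenated with a sparse expression vector
that carries a learnable value $\mu_j$ wherever marker $j$ is unmeasured,
so a measured zero is never confused with a missing marker. Embedded cells
pass through a Pre-LN self-attention encoder (no positional encoding:
exactly permutation-equivariant), and a decoder pools them by
cross-attention between a learnable prediction token (query) and the cell
latents (keys/values); the final token state feeds the task head, making
predictions permutation-invariant, and the softmax attention weights —
which sum to one over cells per layer and head — quantify per-cell
importance.

Training is two-stage:

1. **Masked pretraining** (no labels): three per-cell targets per marker —
   raw expression $X$, percentile rank
   $P_{ij}=\mathrm{rank}(X_{ij}\mid X_{\cdot j})/n$, and log Gaussian-KDE
   density $D_{ij}$ with bandwidth $\sigma = 0.05$ — are predicted under two
   complementary masking patterns (uniform-random per cell after optional
   sample-wide marker dropout, and whole-marker masking), with a
   heteroscedastic Gaussian negative log-likelihood on masked entries plus
   $\beta<1$ times the unmasked entries:
   $\mathcal{L}_t = \ell_{GNLL}^{masked} + \beta\,\ell_{GNLL}^{unmasked}$,
   combined as
   $\mathcal{L} = \sum_k w_k \sum_{t\in\{X,P,D\}} w_t\,\mathcal{L}_t^{(k)}$.
2. **Downstream training**: the encoder is frozen; the decoder and task
   head train on cross-entropy (or MSE) with marker-wise input dropout.

The package also includes a minimal FCS 3.0/3.1 reader with the logicle
transformation, a sample store, batch-grouped stratified cross-validation,
attention attribution export, and a synthetic-cytometry corpus generator
with planted class effects that serves as the test bed.

## Worked example

Simulate a small two-class corpus (planted +0.10 NK frequency shift in the
case class, three overlapping 6–7-marker panels over an 8-marker
vocabulary), pretrain, fine-tune, predict, and attribute:

```r
library(cytoformer)

spec   <- default_generator_spec(n_samples_per_class = c(control = 10L, case = 10L),
                                 cells_per_sample = c(400L, 400L), seed = 7)
corpus <- generate_corpus(spec)
train  <- c(1:7, 11:17); test <- c(8:10, 18:20)

model <- init_cytoformer(spec$vocabulary,
                         model_config(hidden_size = 32, encoder_layers = 2,
                                      decoder_layers = 2, heads = 4,
                                      feedforward_multiplier = 2),
                         classes = c("control", "case"), seed = 1)
model <- pretrain(model, corpus$samples[train],
                  pretrain_config(epochs = 6, max_cells = 256), seed = 1)
model <- finetune(model, corpus$samples[train],
                  downstream_config(epochs = 12, lr = 3e-3,
                                    marker_dropout_rate = 0,
                                    validation_fraction = 0), seed = 1)
model
#> cytoformer model
#>   vocabulary: 8 markers | hidden 32 | 2 enc + 2 dec layers, 4 heads
#>   task: classification (control/case)
#>   stage: task-trained

round(predict(model, corpus$samples[test], type = "prob"), 3)
#>              control  case
#> S008_control   0.626 0.374
#> S009_control   0.615 0.385
#> S010_control   0.963 0.037
#> S018_case      0.416 0.584
#> S019_case      0.460 0.540
#> S020_case      0.513 0.487
```

All six held-out samples rank correctly (AUC 1.00; accuracy 0.83 at the 0.5
threshold — one case sits at 0.487). Attribution shows *why*: the top
attended cells are strongly enriched for the planted NK population,

```r
rec <- extract_attention(model, corpus$samples[[test[1]]])
enr <- attention_enrichment(rec, attr(corpus$samples[[test[1]]], "cell_populations"), "NK")
#> NK enrichment in top-5% attended cells: overlap 15 (expected 1.8), p = 6.23e-14
```

i.e. of the 20 most-attended cells, 15 are NK against a chance expectation
of 1.8 — the model's decision rests on the population that actually carries
the class signal. `export_attribution()` writes a per-cell TSV (marker
values + per-layer attention) for external plotting, and `cytoformer_cli()`
(wrapper script in `inst/cli/`) drives the same workflow from a shell:
`simulate / prepare / pretrain / finetune / evaluate / attribute`.

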