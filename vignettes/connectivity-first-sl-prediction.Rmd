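---
title: "Connectivity-first prediction of synthetic lethality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity-first prediction of synthetic lethality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Synthetic lethality (SL) is the gene-pair relationship in which losing
either gene alone leaves a cell viable but losing both kills it. CRISPR
double-knockout (CDKO) screens measure a genetic-interaction (GI) score per
gene pair in one cell line; strongly negative scores indicate SL (here,
pairs with GI below -3 are labeled SL, strictly — a score of exactly -3 is
non-SL). Models trained directly on pair labels generalize poorly to genes
absent from training: in a *nonoverlap* split, where train and test gene
sets are disjoint, pair-level learners collapse toward chance.

The quantity that does transfer across genes is *SL connectivity*: the
number of SL partners a gene has in the labeled SL network. Empirical SL
networks are scale-free — a few hub genes carry most SL interactions — and
hubness is predictable from a gene's omics profile and its position in
biological networks. `slconnect` therefore predicts in two steps:

1. **Connectivity regression.** A multilayer encoder maps each gene to a
   predicted SL connectivity $\hat c_g$:
   - a *gene encoder*: two parallel feed-forward branches for
     population-scope and cell-specific omics features, fused by
     concatenation and a linear projection;
   - a *multiview graph encoder*: per network view (physical PPI, genetic
     interaction, pathway), rounds of symmetric-normalized neighbor
     averaging $D^{-1/2}(A+I)D^{-1/2}H W$ with a nonlinearity, view outputs
     fused by concatenation + projection. Isolated genes propagate only
     their own features;
   - a *transformer encoder*: dense multihead self-attention over all gene
     tokens (no positional encoding; the gene set is unordered), with
     residual connections, layer normalization and feed-forward sublayers,
     lifting the encoder from local to global network topology;
   - an MLP head that outputs the predicted connectivity.
2. **Pair classification.** A ridge-penalized logistic regression maps the
   two predicted connectivities of a pair to an SL probability through the
   symmetric features $(\min, \max, \text{product})$, entered on the
   `log1p` scale: in a scale-free network the log-odds of an edge grow
   roughly as $\log d_a + \log d_b$, so the logistic is linear in the
   right parametrization. The fit is an exact Newton ridge solution —
   deterministic to machine precision and exactly invariant under
   duplication of training rows.

The decision to train on connectivity first and pairs second is the
package's core assumption: connectivity is a per-gene, scalable property,
so step 1 can generalize to unseen genes, and step 2 needs only two
numbers per pair.

## Tunable parameters

Training defaults follow the published protocol: Adam with learning rate
5e-5 (low, to limit overfitting), dropout 0.5 after each encoder stage and
0.7 before the predictor head, up to 1000 epochs with early stopping after
200 epochs without improvement of the internal-validation loss.
Architectural sizes (embedding width 64, 2 graph layers, 1 transformer
layer, 4 heads, feed-forward width 2x) are this package's desk-scale CPU
defaults — the reference description does not fix them — and every one is a
`model_config()` argument. The examples and tests in this package use a
smaller, faster configuration (width 16, one layer per stage, learning
rate 1e-3, up to 150 epochs, dropouts 0.1) suited to benchmarks of a few
hundred genes.

Implementation notes, all visible in `model_config()`:

- **Loss and target transform.** Mean squared error on `log1p`
  connectivity. Scale-free targets are heavy-tailed; plain MSE on counts
  lets a few hubs dominate the gradient. Predictions are inverted with
  `expm1` and clipped at zero.
- **Optimization regime.** Full-batch over genes: the gene count in a CDKO
  screen (hundreds) makes minibatching unnecessary. The dense attention
  matrix bounds practical problem size to a few thousand genes; the
  supported scaling path is restricting the gene universe, not sparse
  attention.
- **Fusion scheme.** Concatenation + learned linear projection for both
  branch fusion and view fusion — the simplest scheme consistent with
  "encode separately, then integrate". Attention-weighted view fusion is a
  known alternative; it adds parameters without changing the contracts
  tested here.
- **Initialization and determinism.** Glorot-uniform weights, seeded; every
  stochastic element (initialization, dropout masks, the internal monitor
  split) derives from `model_config(seed)`, so identical inputs and
  configuration train to byte-identical parameters and histories.

## Leakage control

Three places could silently leak held-out information; all three are
closed:

- **Connectivity targets.** In a nonoverlap split, targets for training
  genes are computed from training-side pairs only, and evaluation targets
  for test genes from test pairs only. Deriving targets from the full
  screen would import test labels into step-1 supervision.
- **Feature standardization** uses mean/sd statistics of training genes
  only (after per-feature median imputation).
- **Cross pairs** (one endpoint per side) are discarded, not assigned to
  training — the strictest reading of gene-nonoverlap; assigning them to
  training would let test genes shape the encoder.

The internal early-stopping monitor is a seeded 20% subset of the
*training* genes. The split object also carries pair-level validation
pairs on the training side; gene-level monitoring was chosen for step 1
because its loss is per-gene, and a pair-level monitor of a gene-level
regression would mix scales. Both constructions keep every held-out test
gene invisible to training.

## The synthetic benchmark

`make_benchmark()` generates the study conditions the model assumes, with
no downloads:

- **SL graph**: preferential attachment (Barabási–Albert scheme) over
  `n_genes` (default 500) with `attachment_m = 2` edges per new node,
  giving exactly $m(n-m)$ edges and a power-law degree tail with exponent
  near 3 — the scale-free connectivity pattern seen in real SL data. The
  seed graph is `m` initially edgeless nodes (first attachments are
  uniform while all degrees are zero), which keeps the edge-count identity
  exact.
- **GI scores**: every pair receives a Gaussian score, true SL pairs
  around -5, others around 0, both with sd `gi_noise_sd` (default 1). The
  -3 labeling threshold then sits between the classes, and label noise
  follows the per-class Gaussian tails: at sd 1, true SL pairs flip with
  probability $\Phi(-2) \approx 0.023$ and non-SL pairs with
  $\Phi(-3) \approx 0.0013$. The class means are arbitrary but
  configurable; they were chosen once so the published threshold is
  meaningful on simulated data.
- **Features**: each feature is
  $s \cdot z_g + (1-s)\cdot \varepsilon$, where $z_g$ is standardized
  log1p true connectivity, $s$ = `feature_signal` (default 0.7) and
  $\varepsilon$ is standard normal, so the population
  feature–connectivity correlation is $s/\sqrt{s^2+(1-s)^2}$. One
  continuous population expression block and one cell-specific mutation
  block (Poisson counts with rate $e^{\min(\text{raw},3)}$ — sparse
  non-negative integers) are produced.
- **Network views**: three copies of the true SL graph, each edge
  independently replaced by a uniform non-edge with probability
  `network_rewire_prob` (default 0.2). Edge counts are conserved; rewire 0
  is an exact copy, rewire 1 an unrelated random graph.

What this generator does *not* emulate: real CCLE/DepMap marginal
distributions, correlated noise between omics modalities, BioGRID's
topology beyond degree coupling, or biological pathway structure. Passing
the recovery tests therefore shows that the implementation can extract the
statistical couplings the method postulates — not that the method attains
any particular performance on real screens.

A note on prevalence: at the defaults, about 1,000 of 125,000 simulated
pairs are SL (~0.8%), matching the 0.5–1.5% prevalence of real CDKO
screens; class-balanced weighting in step 2 is the default for exactly
this regime.

## Evaluation machinery

- `split_nonoverlap()` / `split_overlap()` implement the two published
  split protocols (80/20 by default, 20% validation pairs inside the
  training side).
- `auc_roc()` uses the Mann–Whitney rank statistic (ties at half weight);
  `aupr()` uses step-wise precision-at-each-recall-change with tied scores
  grouped — interpolated PR areas overestimate, so none is used;
  `precision_at_k()` takes the top `ceiling(k% · N)` items with a
  deterministic lexicographic tie key. All three are verified against
  exhaustive brute-force oracles on every small instance.
- `repeated_evaluation()` reports mean ± sd (n−1 denominator) over
  repeated seeded splits, 10 by default with seeds 0..9.
- `ablation_run()` replaces disabled sources by shape-matched random
  stand-ins — standard-normal feature matrices, equal-size uniform random
  edge sets — rather than removing them, so every ablation row trains an
  architecture of identical shape. With all sources disabled the run is
  the all-random control; `use_transformer = FALSE` is the
  graph-encoder-only row.

## Numerical choices and degenerate inputs

- Zero-variance features standardize to zero (scale forced to 1); genes
  missing from a feature table get median-imputed rows; genes missing from
  a network view are isolated nodes with a unit self-connection.
- A screen pair duplicated with consistent scores collapses silently;
  conflicting duplicates are an integrity error, not a silent average.
- Hub ties break alphabetically; Precision@k ties break by lexicographic
  pair key; both make reports platform-independent.
- The chi-square screen comparison defaults to no continuity correction
  (counts in the motivating comparisons are in the hundreds); Yates
  correction is a flag.
- Stratified-report metrics that are undefined within a stratum (single
  class, no positives, empty call set) are reported as `NA` rather than 0.
- Layer normalization uses eps 1e-5; softmax subtracts the row maximum.

## Problem sizes used in tests

The bundled checks run the full two-step pipeline at 500 genes
(~125,000 pairs) over 5 seeds for recovery and 10 runs for the null
control, with the small configuration above; property tests for
monotonicity use 200-gene benchmarks over 3 seeds, and unit tests use
30–100 genes. These sizes were chosen so the whole suite trains dozens of
models on one CPU core while leaving the recovery signal far from
threshold.

## Known limitations

- The encoder is dense in both attention and adjacency; beyond a few
  thousand genes, memory grows quadratically.
- Step 2 sees only connectivity-derived features. Whether adding raw
  embeddings to the pair classifier helps is untested here by design; the
  two-step premise is that connectivity suffices.
- The synthetic generator couples features to connectivity monotonically;
  it cannot reveal failure modes that arise from non-monotone or
  interaction-driven omics signals. For the same reason it cannot
  demonstrate the *advantage* of connectivity-first prediction over
  direct pair-level learning: because every simulated feature is a
  monotone function of connectivity plus independent noise, a pair-level
  logistic model on raw features implicitly averages its way to a
  near-noiseless connectivity estimate and ties the two-step pipeline.
  Both are limited by the same degree information. The benchmarks
  therefore test *recovery* (the pipeline extracts the couplings it
  assumes, and collapses to chance when they are absent), not
  superiority over alternatives.
- No calibration of predicted probabilities is attempted; rankings and
  top-k selections are the intended use.
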