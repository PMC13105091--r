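---
title: "Methods: odorant-receptor affinity models in loraxr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: odorant-receptor affinity models in loraxr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Predicting whether (and how strongly) an odorant molecule activates an
olfactory receptor is hard because structure-activity relationships in
olfaction are famously irregular: similar molecules can evoke very different
receptor responses. Two families of data exist at very different scales:
dense *full-factorial electrophysiology panels* — every odorant in a small
library measured against every receptor in a small panel, with continuous
responses (spikes per second) — and large, sparse, *imbalanced binary
screens* compiled from heterogeneous sources with quality tiers (EC50-grade
measurements down to primary screening calls). `loraxr` implements, at desk
scale, a complete modelling stack for this problem: representation
benchmarking, representation-geometry comparison, and a fine-tuned
multi-modal transformer with a gradient-boosted ensemble (the LORAX
architecture).

# Data model and normalization

The universal container is the `interaction_dataset`: odorants (SMILES),
receptors (amino-acid sequences), and interaction records carrying either a
continuous `response` or a binary `label`, plus an optional weight and
quality tier. All joins are keyed on string IDs, never on row positions.

Continuous panels are normalized by **global z-scoring**: one mean and one
standard deviation computed over every response in the dataset pooled, not
per receptor. Per-receptor scaling would erase genuine differences in
receptor excitability, which the downstream models are supposed to learn. We
use the population (divisor-*n*) standard deviation; the choice is
arbitrary at these sample sizes but fixed and documented. `zscore_global()`
is idempotent up to floating tolerance, which the test suite asserts.

One leakage subtlety: scaling with whole-dataset statistics slightly couples
training and test folds. The cross-validated benchmarks in this package
operate on datasets that are already globally scaled (matching how such
panels are usually distributed); because the transformation is a single
affine map applied to all responses it does not change the ordering of
models, and R² is invariant to it on any fold whose responses are not
constant. Fitting fold-local normalizers is possible by z-scoring after
splitting, but it is not the default.

The **neural representation** (`build_neural_representation()`) treats the
measured panel itself as a feature space: odorant *i* is the vector of its
responses across the receptor panel. It requires a full-factorial
regression panel (missing pairs either error or are zero-filled, at the
caller's choice) and participates in shape analyses like any molecular
representation.

# Featurizers

Featurizers live in a registry (`register_featurizer()`) and are pure
functions of their parameters and input; rows always align to input order.
Three reference featurizers ship with the package:

* `reference_counts` / `reference_counts_norm` — character counts (or
  compositions) of the SMILES string. Deliberately transparent, chemically
  naive, and sufficient for planting recoverable signal in synthetic data.
* `random64` — the lower-bound representation: i.i.d. standard-normal
  vectors. The stream is keyed to (seed, SMILES hash), **not** to row
  position, so a molecule gets the same vector in every dataset and fold.
  Per-row noise would make the molecule+protein benchmark's behaviour on
  the random representation impossible to reproduce, because the model
  could never exploit receptor identity consistently across folds.
* `kmer_protein_featurizer()` — normalized k-mer compositions for receptor
  sequences, standing in for frozen protein-language-model embeddings at
  desk scale.

Real chemistry backends (descriptor packages, pre-trained encoders) attach
through the same registry interface; nothing in the pipeline assumes more
than an items × features matrix. Where token-level encoders are pooled into
fixed vectors, the default is the mean over non-padding tokens
(`pool_tokens()`); first-token pooling is provided because both conventions
are common in practice and the better choice is model-dependent.

# Shape metrics

`procrustes_distance()` and `cca_distance()` quantify how similar two
representation *spaces* are, irrespective of nuisance transformations. Both
operate after `align_and_center()`: rows matched by item ID, columns
mean-centered, and the narrower matrix zero-padded to the wider one's
column count (zero-padding embeds the smaller space isometrically, so
distances are preserved while allowing, say, a 7-dimensional count space to
be compared with a 64-dimensional embedding).

* **Orthogonal Procrustes distance**: scale both matrices to unit Frobenius
  norm and compute `arccos` of the nuclear norm of the cross-product. Zero
  iff one configuration is an orthogonal transform + isotropic rescaling of
  the other; sensitive to anisotropic stretching.
* **CCA distance**: whiten each matrix onto its retained principal subspace
  (relative eigenvalue cutoff `rank_tol = 1e-9`), take the singular values
  of the whitened cross-product (the canonical correlations, clipped to
  [0, 1]), and return `arccos(sum(rho)/sqrt(k_x k_y))`. Invariant to *any*
  invertible linear map, hence blind to everything except the subspace
  geometry.

The angular (`arccos`) form bounds both metrics in [0, π/2] and makes
self-distance exactly zero. Numerically, `acos` near cosine 1 amplifies
machine-epsilon error into ~1e-8 angles; cosines within 1e-12 of 1 are
therefore snapped to angle 0, which keeps self-distance exact and symmetry
within 1e-8 even for degenerate inputs. The test suite checks the metric
axioms (identity, symmetry, triangle inequality over random triples) and
agreement with brute-force alignment searches and `stats::cancor`.

Because published distances of this kind depend on unstated normalization
conventions, distances computed here should be compared *qualitatively*
(orderings, block structure) with published values, not digit-by-digit.

# Ridge baselines

Two feature-based benchmarks frame any learned model:

* **MO (molecule-only)**: one ridge regression per receptor on odorant
  features alone, per-receptor R² averaged unweighted over receptors. This
  asks whether chemistry alone predicts activation.
* **MP (molecule + protein)**: a single ridge regression on the
  concatenated odorant and receptor features across all interactions.

`ridge_fit()` is the closed-form estimator on internally standardized
features with an unpenalized intercept; constant columns get a unit scale
guard. The penalty is selected per fit by inner 3-fold cross-validation
over a 13-point log-spaced grid (1e-3 … 1e3) — conventional, and wide
enough that the endpoints are never selected on the synthetic panels. R²
always uses the test-fold mean in the total sum of squares, so predicting
the training mean scores ≤ 0 on a shifted test fold; negative benchmark
entries are meaningful, not bugs.

# The LORAX model

`lorax()` fits the two-stage architecture:

**Stage 1 — multi-modal transformer.** Tiny built-in encoders (2-layer
self-attention over SMILES characters / amino-acid tokens, sinusoidal
positions, post-layer-norm blocks without learnable affine parameters) feed
`n_cross_attention_layers` fusion layers in which chemical tokens attend to
protein tokens and vice versa. A learned `<cls>` token is prepended to the
fused sequence, one readout self-attention layer runs over it, and a linear
(or logistic) head maps the `<cls>` state to the prediction. LoRA adapters
— rank-`r` updates `(alpha/r)·B·A` with `A` random (SD `1/sqrt(d_in)`) and
`B` zero-initialized — sit on the query and value projections of the
chemical encoder (optionally also the protein encoder). Zero-initialized
`B` guarantees the model starts exactly at the frozen-encoder function,
which the tests assert bit-for-bit. Only the adapters in
`trainable_scope`, the fusion stack, the `<cls>` token and the head
receive gradients; base encoder weights are checked to be bit-identical
after training. Setting `trainable_scope = "head_and_fusion_only"` with
adapters disabled yields the frozen-representation comparator: identical
architecture and ensemble, no fine-tuning — the in-package stand-in for
feature-based multi-modal transformers.

The network, its backpropagation, and Adam are implemented in base R
matrix code; there is no deep-learning framework dependency. Gradients are
hand-derived and validated against central finite differences (relative
error below 1e-4 at `eps = 1e-5`) in the test suite. Sequences are
processed without padding (each pair's token matrices are dense), so mask
invariance holds by construction: `fuse_forward()` drops padded positions
before any computation touches them.

Defaults: `model_dim = 16`, 2 heads, feed-forward width 32, one fusion
layer, `r = 4`, `alpha = r` (unit effective scale), dropout 0, MSE loss for
regression and weighted binary cross-entropy (per-record weights from
quality tiers) for classification, Adam at 3e-3, batch size 64, early
stopping on the validation metric (R² or MCC) with patience 6 and
restoration of the best checkpoint. These sizes are deliberately small:
they train in seconds to minutes on one CPU core while leaving the model
expressive enough to fit bilinear interaction structure. The published
architecture this emulates uses pre-trained foundation encoders several
orders of magnitude larger; the package reproduces the *mechanism*
(adapter fine-tuning of a frozen multi-modal transformer), not the scale.

**Stage 2 — tree ensemble.** The trained transformer is frozen. Three
XGBoost models with identical hyperparameters (150 rounds, depth 4,
eta 0.1, single-threaded for determinism) are fitted on (1) the `<cls>`
vectors, (2) the concatenated *original* (adapter-free, mean-pooled)
encoder representations, and (3) their concatenation. Simplex weights over
the three models are chosen by exhaustive search on the validation set at
step 0.05 (231 candidates), first-in-lexicographic-order tie-break — the
simplest deterministic reading of a validation-tuned weighted sum. Because
the simplex vertices are in the grid, the combined validation score can
never fall below the best single model. The weight on the ORIG-only model
is reported (`ensemble_report()`) as the interpretability statistic: a
large ORIG weight means the ensemble ignores the learned `<cls>`
representation; a fine-tuned model should shift weight toward `<cls>`-based
features, and its standalone transformer validation score (also reported)
should be materially higher than a frozen comparator's. In classification
mode the weighted sum combines probabilities, not logits; with monotone
thresholds downstream the choice only matters for weight optimization, and
probabilities keep the combined output in [0, 1].

# Evaluation

`make_splits()` builds three scenarios: random interaction folds;
unseen-odorant folds (odorant IDs folded, so no test odorant ever appears
in training or validation); unseen-receptor symmetric. A validation
fraction (default 0.15 of the training side, entity-respecting under the
entity scenarios) supports stage-1 early stopping and stage-2 weight
tuning. The naive baseline predicts the training mean; under the test-mean
R² convention it scores ≤ 0, and the generalization question is whether a
model's mean test R² clears it.

Classification metrics follow fixed conventions, pinned by tests against
enumeration oracles: AUROC as the tie-averaged rank statistic; average
precision by the step-interpolated precision-recall curve evaluated at
distinct thresholds (tie-aware); precision/recall/F/MCC at threshold 0.5;
MCC returns 0 when any denominator factor is 0 (the standard convention
for degenerate confusion matrices); single-class truth flags the ranking
metrics as undefined rather than propagating NaN. Metrics are computed per
fold and then averaged, not pooled across folds. On imbalanced screens,
accuracy and AUROC flatter trivial classifiers; MCC and F-score are the
headline numbers, which is why MCC drives classification-mode weight
optimization and early stopping.

`compare_models()` offers pairwise paired t-tests, a Friedman omnibus with
Benjamini-Hochberg-corrected pairwise paired Wilcoxon post-hocs, and
one-way ANOVA with Tukey HSD plus an additional Bonferroni correction.
Identical score vectors are flagged degenerate rather than given a
fabricated p-value.

# Synthetic data and what it does (not) show

`gen_molecules()` enumerates a fixed template grammar (alkanes, alcohols,
esters, ketones, aldehydes, amines, ethers, nitriles, substituted
benzenes — a few hundred distinct, syntactically valid SMILES);
`gen_receptors()` draws uniform-random sequences over the 20 canonical
residues. `gen_panel()` plants responses as the bilinear form
`u' M v` over `(1, chemical composition)` and `(1, residue composition)`
features, standardizes the noiseless signal to unit SD (so `noise_sd`
reads as a relative noise level), adds Gaussian noise, and returns the
ground truth alongside the dataset. Structured interaction matrices
(`planted_additive`, `planted_receptor_only`, `planted_bilinear`) make
specific recovery questions answerable: a noiseless additive panel must be
fully explained by the concatenated-features ridge model; a receptor-only
panel must leave the molecule-only model at chance; a bilinear panel is
learnable from raw strings by the transformer but not by additive models.
`gen_sparse_screen()` emulates the screening-compilation shape: a random
subset of the pair grid, labels cut at the empirical latent quantile so the
positive rate hits its target up to rounding, and quality tiers drawn from
a configurable distribution.

Default generator conditions used by the recovery checks: panels at the
two study shapes (110 odorants × 24 or 50 receptors) for cardinality
checks; a 50 × 40 panel (2,000 pairs, generator seed 7, noise SD 0.1) for
transformer recovery; a 30 × 20 panel for unseen-odorant generalization;
20 × 25 (500 pairs, noise SD 0.5) for the chemistry-free null. These sizes
are large enough for the planted effects to dominate sampling noise and
small enough to run on a single CPU core in minutes.

What passing on synthetic data shows: the estimators, splits, metrics, and
training loop do what they claim on data whose generating process is known.
What it does not show: anything about real chemistry. The grammar has no
stereochemistry, the planted bilinear map is far smoother than real
structure-activity relationships, and random receptor sequences carry none
of the phylogenetic structure of real receptor families. Real-data
performance claims require real data through the same interfaces.

# Numerical and design choices

* Angle snapping at cosine 1 − 1e-12 (shape metrics) — see above.
* Duplicate interaction rows: averaged (regression) or majority-vote
  (classification) at load time, with ties an error naming the pair;
  silent overwriting would hide upstream data problems.
* Ridge with `lambda = 0` refuses rank-deficient designs instead of
  pseudo-inverting; the benchmark never needs the unpenalized fit.
* `acos`/clipping guards on canonical correlations; eigenvalue cutoff
  relative to the largest eigenvalue so whitening never divides by ~0.
* Weight-grid tie-break is lexicographic-first, making ensemble weights
  reproducible even when models tie.
* All stochastic steps (generators, splits, initialization, batch order,
  dropout, XGBoost) run on explicit seeds through a private RNG wrapper
  that never disturbs the caller's `.Random.seed`. Training histories are
  reproducible per seed on a fixed single-threaded configuration.
* The package exposes one model-fitting entry point (`lorax()`) returning
  a classed object with `print`/`summary`/`predict`/`plot`/`residuals`
  methods, in the style of classic R modelling interfaces; benchmarks,
  metrics and generators are plain functions around it. A thin command-line
  wrapper (`inst/cli/loraxr-cli.R`) exposes the same functions as
  subcommands for shell pipelines.

# Known limitations

* The built-in encoders are character/residue-level toys; attaching real
  pre-trained encoders is supported through the encoder interface but no
  weights ship with the package.
* No GPU, no mixed precision, no distributed training; the training loop is
  plain R and scales to thousands, not millions, of pairs.
* The CCA distance between spaces of very different retained rank
  normalizes by `sqrt(k_x k_y)`; comparisons across pairs with wildly
  different ranks should be read with care.
* Classification-mode ensemble weighting combines probabilities; models
  producing poorly calibrated probabilities may deserve logit-space
  combination, which is not implemented.
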