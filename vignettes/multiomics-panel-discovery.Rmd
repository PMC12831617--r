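---
title: "Multi-omics biomarker panel discovery: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics biomarker panel discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Hepatocellular carcinoma (HCC) surveillance in cirrhotic patients is a
two-class problem with an unusually hostile geometry: targeted mass
spectrometry yields a few hundred quantified molecular features (proteins,
N-glycans, metabolites) on fewer than a hundred blood samples, and the goal
is a *small* panel — around five features — that separates cases from the
high-risk cirrhotic background. `omicspanel` implements the full
discovery loop for this setting: per-feature screening, six multivariate
feature-ranking methods on the combined multi-omics matrix, cross-method
consensus, and honest cross-validated evaluation of candidate panels,
together with a synthetic-cohort generator that makes every stage testable
against known ground truth.

The default geometry throughout is 40 cases vs 49 controls with
100 proteomic + 82 glycomic + 60 metabolomic features. Feature identifiers
carry their layer as a namespace prefix (`prot:`, `gly:`, `met:`), so the
combined 242-column matrix is self-describing.

## Preprocessing contract

All rankers consume a standardized matrix produced by
`impute_and_standardize()`: missing cells (at most ~1 percent by contract)
are replaced by the per-feature *median* of a designated fit subset, and
each feature is z-scored with the mean and sample standard deviation of
that subset. The fit subset is the whole cohort when ranking on the full
data, and the training rows of each fold inside cross-validation — held-out
rows are always transformed with statistics they did not contribute to.
Median rather than mean imputation is used because intensity data are
right-skewed; at under 1 percent missingness the choice is low-impact.
Zero-variance features are mapped to all zeros and flagged with a warning
rather than dropped, so feature indices stay stable.

Whether targeted intensities should be log-transformed before statistics is
left open by the data; the generator exposes `keep_log` and the pipeline
operates on whichever scale it is given. Statistics default to the raw
intensity scale. One visible consequence: the Student *t* screen on
log-normal intensities is very slightly conservative (empirical type-I
error ≈ 0.044 at nominal 0.05 in the calibration suite) because the raw
scale is skewed; on the log scale it is exact.

## Univariate screening

Per feature, the two-sided pooled-variance (classical Student) *t* test is
used — not Welch — matching the screening convention of targeted panel
studies; counts of features with raw p ≤ 0.05 are reported per layer with
no multiplicity correction, since the screen is descriptive, not
confirmatory. Each feature's discriminative value is summarized by the
ROC AUC computed as the Mann–Whitney statistic U/(n₁n₂) with ties counted
one half; orientation is kept raw (AUC < 0.5 means lower in cases).
Cohort characteristics are compared with the two-sided Fisher's exact
test under the point-probability rule: the p-value sums the probabilities
of all tables with the observed margins whose probability does not exceed
that of the observed table. Ranking ties break deterministically
(ascending p, then |t| descending, then feature id).

## The six rankers

All six return the same `feature_ranking` contract: a permutation of the
input features with non-increasing scores and a selected top subset.

**Univariate F filter.** One-way ANOVA F per feature; for two groups
F = t² exactly, so this ordering coincides with the t-test screen. Constant
features get F = 0 and sink to the bottom.

**Elastic net.** The penalized *linear-regression* objective on 0/1 labels
(not the logistic one — the regression form is the common default in this
workflow and keeps coefficients directly comparable), with mixing
parameter fixed at 0.5 and overall penalty weight chosen by seeded
internal cross-validation over a fixed logarithmic grid
(10^0.5 … 10⁻⁴, 60 points). Features are ranked by |coefficient|;
zero-coefficient features follow in input order, and a fully-shrunk fit
degenerates to input order with a warning.

**SVM-RFE.** A soft-margin linear SVM (C = 1) is trained, features are
scored by the squared weight-vector component wᵢ², the lowest-scoring
`step` features (default 1) are removed, and the process repeats until
`n_select` remain. The reversed elimination order defines the full
ranking; survivors are ordered by their final-fit weights.

**Transformer-RFE** (the method this package exists for). The SVM is
replaced by a lightweight cross-attention transformer and the weight
criterion by Shapley importance:

- *Architecture.* Each feature becomes a token: its scalar standardized
  value times a learned projection vector, plus a learned per-feature
  embedding and a learned omics-layer embedding (all width `d_model`,
  default 32). A single learned query token cross-attends over all feature
  tokens through `n_attention_layers` (default 2) multi-head attention +
  feed-forward blocks with residual connections; the refined query feeds a
  logistic head. Keeping the query as the only updating token makes the
  parameter count O(p·d_model) and the model trainable at n = 89. No layer
  normalization is used; at this depth and width it proved unnecessary and
  its omission keeps the backward pass simple and exactly reproducible.
- *Training.* Full-batch Adam with weight decay 10⁻⁴, early stopping on a
  20 percent stratified validation split, best-validation parameters
  restored. Training exhibits a characteristic warm-up plateau of tens of
  epochs before the loss drops; the patience default (40) is set above
  that plateau, because a smaller patience can stop inside it and return a
  chance-level model. All randomness (initialization, split, optional
  dropout) derives from `config$seed`; two runs are bit-identical.
- *Importance.* Model-agnostic Monte-Carlo permutation Shapley values of
  the predicted case probability: features are inserted in random orders
  starting from the training-mean background, and a feature's attribution
  is its average marginal change in the prediction (default 128
  permutations; the per-sample attributions telescope, so efficiency —
  attributions summing to f(x) − f(background) — holds exactly at any
  permutation count). The importance score is the mean absolute
  attribution over the evaluation samples.
- *Elimination.* Exactly one feature is removed per iteration (ties break
  lexicographically), and the model is retrained from a fresh
  seed-derived initialization on the reduced set — no warm starts, so the
  procedure is a pure function of (data, config, seed). Eliminated
  features keep the score they had when eliminated; these are stored in
  the trace and in `raw_scores`, while the `scores` field of the ranking
  uses a monotone surrogate (final-fit Shapley scores for survivors,
  minus-elimination-index for the rest) so the ranking contract's
  non-increasing-score invariant holds.

**Random forest.** 500 trees, √p features per split, bootstrap
resampling, seed-controlled. The default importance is exact
path-dependent TreeSHAP of the predicted case probability, implemented in
C++ over the fitted trees with node covers rebuilt from each tree's
in-bag samples; attributions satisfy local accuracy to machine precision
(verified in tests against a brute-force Shapley enumeration oracle).
Gini impurity importance is available as the alternative mode.
Projection-based importance (VIP) is deliberately not implemented: which
post-hoc importance belongs to which model is ambiguous in this workflow's
lineage, and Shapley-based attribution subsumes the role.

**Graph-convolution fusion (mogonet-lite).** A compact reimplementation of
the sample-similarity-network fusion idea: per omics view, cosine
similarity between sample profiles sparsified to each sample's
`knn_k = 10` nearest neighbours (k-NN rather than a similarity threshold,
which guarantees connectivity at n = 89; kept edges are floored at a small
positive weight so standardization-induced negative similarities cannot
disconnect a selected neighbour), symmetrized by maximum, self-loops
added, symmetrically degree-normalized. Each view gets a two-layer GCN
producing per-sample class probabilities; the flattened cross-view outer
product of those probability vectors (2^V values for V views) feeds a
small dense head producing the final probabilities. The loss is the sum of
per-view and fusion cross-entropies on the training mask only; the model
is transductive. Feature importance is single-feature mean-replacement
ablation (the view's similarity network is rebuilt on the ablated matrix;
importance = increase in training loss, clamped at zero): per-sample
Shapley values are ill-defined across a transductive sample graph, and
ablation is the closest testable analog. This component exists so the
benchmark harness covers the deep-fusion family; it is a faithful
miniature, not a port of any published implementation.

## Panel evaluation

A panel is evaluated the way it would be deployed: as the covariates of an
L2-regularized logistic regression (ridge penalty 1/(C·n_train), C = 1 —
the conventional unit-strength setting; no threshold or penalty tuning)
under seeded stratified 5-fold cross-validation, with imputation and
standardization refit inside every training fold. Accuracy uses the 0.5
probability threshold; AUC is computed per fold by the Mann–Whitney
statistic and reported as mean ± sd across folds (fold-averaged, not
pooled — the mean ± sd reporting style implies per-fold values); pooled
out-of-fold scores are used only for the plotted ROC curve, canonically
completed to run from (0,0) to (1,1).

`benchmark_all()` replicates the conventional protocol by default:
features are selected on the *full* data set, then the panel is
cross-validated. This is a known optimism source — the held-out folds
already influenced the selection — and the harness therefore also offers
`leakage_safe = TRUE`, which re-runs selection inside each training fold.
On null data the select-then-evaluate AUC exceeds the leakage-safe AUC in
expectation; the test suite asserts this optimism gap directly. Consensus
extraction counts, for each feature, the number of method top-5 lists
containing it; the consensus set is every feature selected by more than
one method.

## The synthetic cohort generator

The generator emulates the downstream *quantified* feature table of a
targeted two-group study — not the mass spectrometry that produced it.
Per layer, log-scale values are multivariate Gaussian with unit marginal
variance and exchangeable correlation `block_rho` (default 0.3) inside
consecutive blocks of `block_size` (default 10) features, emulating the
correlated families (co-regulated proteins, glycans sharing a synthesis
pathway) seen in targeted panels. Per-feature baseline log-intensities are
drawn from N(12, 1), values are exponentiated to intensity scale, and
cells are masked completely at random at `missing_rate` (default 0.005,
under the 1-percent contract). Informative features receive a location
shift of `effect_size` standard deviations in cases on the log scale —
fold-change semantics — and are spread evenly across the combined feature
list so every layer carries signal. Because a shifted Gaussian feature has
closed-form ROC AUC Φ(d/√2), planted effects double as analytic oracles
(d = 1 → 0.760, d = 2 → 0.921).

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: batch effects and run-order drift,
intensity-dependent missingness (masking is MCAR), heavy-tailed and
zero-inflated features, cross-layer biological correlation (configurable
in principle but defaulted to independence between layers), and any
structured relation between effect size and baseline abundance. Recovery
rates on synthetic cohorts are upper bounds on what identical methods
achieve on real tables.

## Numerical choices and degenerate inputs

- All stochastic components draw from locally scoped, seed-derived RNG
  streams (`Mersenne-Twister`/`Inversion`); no global seed state leaks.
  RFE retraining seeds are `seed + 7919·iteration`.
- Ranking ties break by descending score then lexicographic feature id
  everywhere, so orderings are total and reproducible.
- Zero pooled variance in the t test: equal means give p = 1, separated
  means p = 0, both flagged `degenerate` rather than erroring.
- Softmax computations subtract row maxima; the binary cross-entropy is
  computed in its logit-stable form.
- glmnet requires two columns, so single-feature logistic panels are
  padded with an all-zero dummy column (coefficient exactly 0, predictions
  unaffected).
- Fisher's test comparisons use the point-probability rule with the
  customary (1 + 10⁻⁷) tolerance on the observed-table probability.

## Problem sizes used by the test and acceptance suites

Chosen to exercise the stated study conditions while keeping a laptop-scale
run: t-screen calibration pools 200 replicate null cohorts of 89 × 100;
the leakage-safe null benchmark runs all six methods on ten 89 × 15
cohorts; classical-ranker recovery plants a single d = 3 feature in
89 × 50 cohorts (20 seeds) and Transformer-RFE recovery plants three d = 2
features among 30 (20 seeds); the closed-form AUC limit uses n = 5000.
The transformer inside the suites uses a reduced configuration
(d_model 16, 2 heads, 1 attention block, learning rate 0.03, 8 Shapley
permutations) — recovery under it is 20/20 seeds with at least 2 of 3
planted features, so the reduction costs little fidelity at these sizes.

## Known limitations

- The transformer and GCN are trained full-batch on CPU; cohorts beyond a
  few hundred samples or a few thousand features would need mini-batching
  and a compiled training loop.
- Transformer-RFE retrains once per eliminated feature; from 242 features
  down to 5 that is 237 retrainings (~10–15 minutes on one CPU with the
  default configuration). The classical rankers are near-instant.
- The graph-fusion model's ablation importance is coarse (one feature at a
  time, ignoring interactions) and is known to concentrate on whichever
  view dominates the fusion.
- Only binary phenotypes are supported; no covariate adjustment (age,
  clinical scores) is provided.
- `evaluate_panel` reports fold-averaged AUC; with 8–10 held-out samples
  per class per fold, individual fold AUCs are coarse-grained, and the sd
  across folds should be read accordingly.
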