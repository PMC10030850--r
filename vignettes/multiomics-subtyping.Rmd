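---
title: "Methods: multi-omics subgroup discovery and classifier fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics subgroup discovery and classifier fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the modeling choices in `omicsubtyper`: what each
stage assumes, which parameters matter and why their defaults are what they
are, what the synthetic generator does and does not emulate, and the
numerical conventions adopted where the method description leaves room.

## 1. The data model

The pipeline consumes up to four omic levels, each a samples × features
numeric matrix:

| Kind | Content | Range | Missingness |
|---|---|---|---|
| `F1_mrna` | mRNA expression (FPKM-like) | ≥ 0 | none expected |
| `F2_mirna` | miRNA expression (RPKM-like) | ≥ 0 | none expected |
| `F3_methylation` | CpG beta values | [0, 1] | common |
| `F4_protein` | RPPA protein abundance (level-4) | real | common |

Sample identifiers are the join key; all integration happens over the
intersection of sample sets. Features are treated as exchangeable columns —
no genomic coordinates or annotation are used, which is why probe
blacklists (sex chromosomes, SNP-overlapping or cross-hybridizing CpGs) are
an *input*, not something the package computes.

## 2. Preprocessing

Per-kind recipes, in the stated order:

* **F1/F2**: drop features with zero expression in *more than* 20 % of
  samples; F1 additionally keeps the 2000 highest-sd features; min-max
  scale each feature to [0, 1].
* **F3**: optional probe blacklist → drop samples, then probes, with more
  than 10 % missing → KNN imputation (K = 5) → top-2000 sd selection. Beta
  values are already bounded, so no rescaling.
* **F4**: drop proteins with more than 10 % missing → KNN imputation.
  Level-4 RPPA arrives normalized, so no rescaling.

Conventions worth knowing:

* **Thresholds are strict-greater** ("more than X %"): a feature exactly at
  the boundary is retained.
* **KNN imputation** ranks neighbor samples by squared Euclidean distance
  over mutually observed coordinates, without rescaling by the number of
  shared coordinates; the imputed value is the unweighted mean of the k
  nearest neighbors observing the feature, falling back to all available
  neighbors and finally to the feature's global mean. Distance ties resolve
  by sample order. Observed entries are never modified.
* **Variance ties** at the top-n boundary break by feature id, so selection
  is deterministic.
* **Constant features** min-max to all zeros (the 0/0 case is defined, not
  an error).
* Min-max statistics are computed on the full matrix handed in — the
  clustering stage is unsupervised, so there is no train/test leakage
  concern at this point. The classifier stage stores the per-feature
  min/range and replays them on new samples (clamping to [0, 1]).

## 3. Autoencoder integration

The stacked matrix (all blocks in [0, 1] or pre-normalized) is compressed
by an under-complete autoencoder: encoder widths 2000–1000–500, a 100-unit
bottleneck, and a mirrored decoder. ReLU activations on all hidden layers,
linear decoder output, mean-squared-error loss, Adam, minibatches of 24,
at most 100 epochs with early stopping: training stops after 5 consecutive
epochs without strict improvement of the validation loss (90/10 split),
and the best-epoch weights are restored.

Choices the method description leaves open, fixed here and recorded in the
configuration objects:

* weight initialization: uniform fan-in, `U(±sqrt(6 / fan_in))`;
* learning rate 1e-3 (overridable);
* linear (identity) decoder output — inputs are continuous;
* batch order reshuffled each epoch from the run seed.

Architecture selection among user-supplied candidates minimizes the
absolute gap between final training and validation loss (an overfitting
criterion, not an absolute-loss criterion); ties go to the first candidate.
Runs are bit-reproducible under a fixed seed on a fixed platform; across
platforms, compare losses at 1e-6 rather than bitwise.

A PCA baseline (`pca_reduce`) standardizes features (zero-variance columns
become all-zero) and returns the top principal-component scores.

## 4. Consensus clustering and PAC

For each K, the latent matrix is clustered on 1000 random subsamples of
80 % of the samples (defaults; tests use fewer resamples purely as a
precision/budget knob). For each co-sampled pair the consensus value is
the fraction of co-sampled runs in which the pair co-clustered. The
proportion of ambiguously clustered pairs is

\[ \mathrm{PAC}_K = \mathrm{CDF}_K(u_2) - \mathrm{CDF}_K(u_1), \quad
   u_1 = 0.1,\; u_2 = 0.9, \]

with the CDF taken right-continuously over off-diagonal, co-sampled pairs
only — pairs never drawn together carry no evidence and are excluded
rather than imputed as zero.

**Single initialization per resample (a deliberate deviation).** The inner
K-means uses k-means++ seeding with *one* initialization per resample.
With a multi-restart inner loop the subsample clustering becomes
effectively deterministic, and on well-separated data the PAC is exactly 0
for several K at once (merging five clean clusters into three is also
perfectly stable), so the statistic loses its ability to discriminate K.
Consensus resampling measures stability *including* initialization
variability; suppressing that variability defeats it. The restart count is
an exposed argument for users who want the other behavior. The final label
assignment — K-means on the rows of the selected consensus matrix — keeps
10 restarts, because there stability is exactly what is wanted; it retries
with a fresh sub-seed (≤ 10 times) in the unlikely event of an empty
cluster.

**K selection** takes the non-excluded K with minimal PAC (ties → smaller
K). Exclusion is explicit and user-driven: `flag_known_partition` reports
whether a candidate clustering essentially reproduces an already-known
partition (adjusted Rand index ≥ 0.8 by default), and the user passes such
K values to `select_k(excluded = ...)`. This mirrors the judgment step in
which a two-way split that merely rediscovers known histology is passed
over for the next-smallest PAC. It is never applied silently.

Cluster quality reports the mean silhouette width and the
Calinski–Harabasz index \((B/(K-1)) / (W/(n-K))\).

## 5. Characterization

* **Survival**: product-limit (Kaplan–Meier) curves per cluster; the
  median is the earliest time the curve reaches 0.5, reported as missing
  ("not reached") otherwise; G-group log-rank test with G − 1 degrees of
  freedom. Times are months; events are 1 = observed.
* **Differential features (expression omics)**: per-feature one-way ANOVA
  across clusters, Benjamini–Hochberg across features, Tukey HSD pairwise
  tests for selected features using the studentized range with the
  harmonic-mean pair size (Tukey–Kramer) — exact for balanced designs,
  standard for unbalanced ones. An all-constant feature is defined to have
  F = 0, p = 1 so batch runs never crash. Zero within-group variance with
  a real between-group difference yields F = ∞, p = 0.
* **Methylation**: probes with sd > 0.2 are quantile normalized across
  samples, log2-transformed with a 1e-3 offset (beta values can be exactly
  0), and tested per probe with an ordinary linear-model F. Moderated
  (empirical-Bayes) statistics are deliberately not used: at the feature
  and sample counts involved the ordinary F-test preserves the selection
  behavior, and it keeps the package free of a modeling dependency. This
  is a documented substitution.
* **Mutations**: per gene × cluster one-vs-rest 2×2 tables, two-sided
  Fisher exact tests, BH across all gene × cluster tests, selection at
  q ≤ 0.05.
* **Copy number**: cytoband segment means are binarized at
  |SegMean| ≥ 0.3 (inclusive) into gains and losses, then tested like
  mutations but selected at *unadjusted* p ≤ 0.01, per the stated
  protocol. One-vs-rest per cluster is the adopted convention.

## 6. Classifier fusion

Three L0 learners per feature representation, all implemented in the
package (the environment provides no SVM/forest library, and none is
needed):

* **SVM-RBF**: primal kernel SVM — one-vs-rest squared-hinge loss plus the
  RKHS-norm penalty, optimized by full-batch Adam over the dual
  coefficients from a zero start (hence deterministic). Class
  probabilities by per-class Platt sigmoid calibration of the decision
  values, renormalized to the simplex. Hyperparameters: cost
  ∈ {0.1, 1, 10, 100} and kernel width = scale heuristic × {0.1, 1, 10},
  chosen by stratified 5-fold CV repeated 10 times on mean accuracy.
* **Random forest** (C++): CART with Gini impurity on bootstrap samples,
  `mtry` random candidate features per split, probabilities as averaged
  leaf class proportions. Grid: trees ∈ {200, 500},
  mtry ∈ {√p, log2 p}, same CV.
* **FFNN**: one hidden layer of `min(256, max(16, p/2))` units, softmax
  output, cross-entropy, dropout 0.1, L2 activity penalty 1e-4, L1 weight
  penalty 1e-5; the learning rate is picked from
  {0.1, 1e-2, 1e-3, 1e-4, 1e-5} by internal stratified-validation
  accuracy, then the network is refit on the full training data.

CV ties go to the first grid row, making selection deterministic under the
seed.

Fusion modes:

* **Linear**: \(P_L = \alpha P_{SVM} + \beta P_{RF} + \gamma P_{FFNN}\)
  with (α, β, γ) on the 0.05-step simplex grid (231 triples). The grid is
  enumerated in *decreasing* lexicographic order, so accuracy ties resolve
  toward the SVM corner and the degenerate "one perfect learner" case
  lands exactly on that learner's corner. Because the corners are grid
  members, the selected accuracy can never fall below any single learner
  on the selection set. Weights are selected on the full training
  predictions by default (the without-holdout convention).
* **Stacked**: the concatenated probabilities \(P_C\) (3K columns, block
  order SVM/RF/FFNN) feed an L1 meta-learner — multinomial logistic
  regression (a zero-hidden-layer softmax network) or a small FFNN —
  either trained on the same full training set (without holdout) or with
  L0 on a stratified 60 % and L1 on L0's probabilities for the remaining
  40 %.

Prediction ties at the argmax resolve to the lowest class index. For new
samples, a model bundle stores, per trained variant, the omic kinds, the
feature schema and the min-max statistics; `predict_new` routes each
sample set to the first variant whose schema is covered — which is how a
methylation-only sample is served by the F3-trained model while the
multi-omics variant is skipped.

## 7. The synthetic world

`simulate_multiomics` draws cluster labels uniformly and gives each
cluster a disjoint set of signal features per omic, shifted by
`effect_size` within-cluster standard deviations on a latent Gaussian
scale; F1/F2 are exponentiated (non-negative, right-skewed like
FPKM/RPKM), F3 is inverse-logit (strictly inside (0, 1)), F4 stays
Gaussian. Missingness is completely at random, by default 5 % in F3 and
F4 only. `simulate_clinical` adds exponential survival with per-cluster
hazards (defaults span a 4× ratio, ~0.01–0.04 events/month), independent
exponential censoring tuned to the target censored fraction via
\(P(\text{censor}) = r_c / (r_c + \lambda)\), Bernoulli mutations with
designated genes enriched (0.6 vs 0.05) in their cluster, and Gaussian
segment means with ±0.5 shifts on designated cytobands.

Default dimensions (400/80/400/60 features) are a scaled-down version of
the real cohort's post-preprocessing dimensions (2000/407/2000/216,
restorable with `paper_scale = TRUE`) so the suite runs in minutes;
`signal_features_per_cluster = 20` and `effect_size = 3` give a clearly
detectable but not degenerate signal, comparable to the separation a
subtype-bearing cohort shows after variance selection.

**What a green test establishes — and what it does not.** The generator
produces independent features within blocks, missingness that ignores the
data, exponential survival, and disjoint cluster signatures. Real tumors
have correlated features (co-methylation, co-expression), informative
missingness, non-proportional hazards, overlapping signatures and batch
effects. Green recovery tests therefore establish that the machinery is
correct and well-calibrated on its stated model, not that it will find
clinically meaningful subgroups in any particular cohort.

## 8. Numerical conventions and degenerate inputs

* PAC thresholds must satisfy 0 ≤ u1 < u2 ≤ 1; the empirical CDF is
  right-continuous (`cdf(u)` = fraction of entries ≤ u).
* Probability-matrix rows must sum to 1 within 1e-6 on input; fused rows
  inherit unit sums algebraically from the weight simplex.
* Subsample size is `floor(n × fraction)`, drawn without replacement;
  every resample gets an independent seed stream derived from the master
  seed, so consensus runs are reproducible and order-independent.
* Stage seeds derive from the master seed by a small string hash of the
  stage name (stable across runs, distinct across stages, < 2³¹).
* All empty-result paths are explicit errors ("no features survive", "no
  samples shared", "all K excluded", schema mismatches listing the missing
  features) rather than silent empties; the one exception is the
  methylation sd filter, which warns and returns an empty table, because
  a characterization batch should not die on one quiet omic.

## 9. Known limitations

* The autoencoder is plain dense MLP; no convolutional, variational or
  denoising variants, and no GPU path. At the full 4623-feature, 100-unit
  default on hundreds of samples, training is minutes on one CPU.
* The SVM probability calibration is one-vs-rest sigmoid with
  renormalization, not pairwise coupling; for well-separated classes (the
  regime the pipeline operates in after integration) the difference is
  immaterial, but heavily overlapping classes may see miscalibrated
  posteriors.
* Immune deconvolution, gene-set enrichment, segmentation (GISTIC-style)
  and network analysis are out of scope: the package consumes their
  outputs (e.g. a cytoband × sample matrix) but never computes them.
* The final-label rule (K-means on consensus rows) is one reasonable
  choice among several (e.g. hierarchical cut of 1 − consensus); the
  underlying method description does not pin one down.
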