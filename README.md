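# omicsubtyper

Molecular subgroup discovery from multi-omics data, with classifiers that
assign new — possibly single-omic — samples to the discovered subgroups.

Cancer cohorts profiled at several molecular levels (mRNA expression, miRNA
expression, DNA methylation, protein expression) often harbor subgroups that
no single level reveals. `omicsubtyper` implements an end-to-end pipeline
for this setting:

1. **Preprocess** each omic level: drop features with > 20 % zeros
   (expression) or > 10 % missingness (methylation probes, proteins; also
   methylation samples), impute remaining gaps by K-nearest neighbors
   (K = 5), keep the top-variance features, min-max scale to [0, 1], and
   stack the blocks over the samples common to all levels.
2. **Integrate** the stacked matrix with an under-complete autoencoder
   (default 2000–1000–500 hidden units, 100-unit bottleneck; ReLU, MSE,
   Adam, batches of 24, early stopping with patience 5 on a 90/10
   train–validation split). The bottleneck activations F_AE are the latent
   representation; PCA is available as a linear baseline.
3. **Cluster** by consensus K-means: 1000 subsamples of 80 % of the
   samples, each K-means-partitioned, accumulated into a consensus matrix.
   Model selection uses the proportion of ambiguously clustered pairs,

       PAC_K = CDF_K(u2) − CDF_K(u1),   u1 = 0.1, u2 = 0.9,

   where CDF_K is the empirical distribution of consensus values over
   co-sampled pairs; the K with minimal PAC wins, with an explicit
   mechanism to exclude a K that merely reproduces an already-known
   partition (e.g. histology).
4. **Characterize** the clusters: Kaplan–Meier curves and multi-group
   log-rank tests for overall and disease-free survival; per-feature
   one-way ANOVA with Tukey HSD post hoc (BH-adjusted) for expression
   omics; an sd > 0.2 filter → quantile normalization → log2 → F-test
   pipeline for methylation; two-sided Fisher exact tests with BH FDR for
   driver-gene mutations; |SegMean| ≥ 0.3 binarization and Fisher tests at
   raw p ≤ 0.01 for copy-number cytobands.
5. **Classify** new samples with a two-level ensemble: per-omic L0
   learners — an RBF-kernel SVM, a random forest, and a feed-forward
   network — produce class probabilities P_SVM, P_RF, P_FFNN that an L1
   fusion combines either linearly,

       P_L = α·P_SVM + β·P_RF + γ·P_FFNN,   α + β + γ = 1,

   with (α, β, γ) chosen on a 0.05-step simplex grid (231 candidates), or
   by a stacked meta-learner (logistic regression or FFNN) on the
   concatenated probabilities P_C, with or without a 60/40 L0/L1 holdout.
   A methylation-only model serves samples lacking the other omics.

A seeded synthetic multi-omics generator (`sim_config()`,
`simulate_multiomics()`, `simulate_clinical()`) reproduces the statistical
shape of this world — four omic blocks with latent cluster structure,
bounded beta values, missingness, cluster-linked survival, mutations and
copy-number alterations — so the whole pipeline is testable offline.

## Worked example

```r
library(omicsubtyper)

cfg    <- sim_config(n_samples = 150, seed = 42)   # 5 latent subgroups
sim    <- simulate_multiomics(cfg)
proc   <- lapply(sim$omics, preprocess_omic,
                 config = preprocess_config(top_n_variable = 200))
stack  <- stack_omics(proc)
enc    <- train_autoencoder(stack, ae_architecture(c(64, 32), 16),
                            ae_train_config(max_epochs = 100, seed = 1))
latent <- encode(enc, stack)
profile <- build_pac_profile(latent, 2:8, n_resamples = 100, seed = 1)
profile$pac
#>  K        pac
#>  2 0.02782998
#>  3 0.28921700
#>  4 0.18595078
#>  5 0.05458613
#>  6 0.09020134
#>  7 0.09816555
#>  8 0.12295302
```

K = 2 has the smallest PAC — a very stable two-way split, the analogue of
rediscovering a known coarse partition (in lung cohorts, the two
histological subtypes). After excluding it, the next-smallest PAC picks the
true structure:

```r
K <- select_k(profile, excluded = 2)               # -> 5
labels <- final_labels(profile$records$K5$consensus, K, seed = 1)
adjusted_rand_index(labels$labels, sim$labels)     # -> 1
```

The clusters differ in survival, and a fused classifier predicts them from
the latent features:

```r
clin <- simulate_clinical(sim$labels, cfg, sim$sample_ids)
surv <- survival_table(labels$sample_ids, clin$survival$time,
                       clin$survival$event, labels$labels)
logrank_test(surv)
#> chi2 = 20.10, df = 4, p = 0.00048
sapply(km_estimate(surv), function(g) g$median)    # median OS, months
#>    1    2    3    4    5
#> 61.4 14.4 34.3 39.6 20.1

sp <- split_train_test(latent, labels$labels, 0.1, seed = 2)
fm <- train_fused(latent[sp$train, ], labels$labels[sp$train],
                  mode = "linear",
                  specs = default_base_specs(2, fast = TRUE), seed = 2)
fm$weights                                         # (alpha, beta, gamma) = (1, 0, 0)
pred <- predict(fm, latent[sp$test, ])
evaluate_accuracy(pred$labels, labels$labels[sp$test])  # -> 1
```

So: the PAC profile identifies five stable subgroups (after setting aside
the trivial two-way split), the log-rank test confirms they carry survival
signal (p < 0.001, median OS from 14 to 61 months), and the decision-level
fused classifier recovers the subgroup of held-out samples perfectly on
this synthetic cohort.

The whole pipeline also runs from a single YAML config:

```sh
Rscript inst/cli/omicsubtyper simulate --n 300 --clusters 5 --seed 7 --out data/
Rscript inst/cli/omicsubtyper run --config pipeline.yaml
```

## Package layout

- `R/preprocess.R`, `R/omic-matrix.R` — per-omic filtering, imputation,
  scaling, stacking
- `R/mlp.R`, `R/autoencoder.R` — dense-network core, autoencoder, PCA
  baseline
- `R/consensus.R` — consensus K-means, PAC, K selection, cluster quality
- `R/characterize.R` — survival, differential features, enrichment
- `R/classifiers.R`, `R/fusion.R`, `src/rf.cpp` — base learners and fusion
- `R/simulate.R` — synthetic multi-omics generator
- `R/pipeline.R` — YAML-driven orchestration and CLI
- `vignettes/multiomics-subtyping.Rmd` — methods notes: model assumptions,
  parameter choices, numerical conventions, limitations
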