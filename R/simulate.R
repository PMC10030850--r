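#' Synthetic multi-omics simulation configuration
#'
#' The generator emulates the pipeline's stated data world: four omic blocks
#' with latent cluster structure, methylation-style bounded values,
#' completely-at-random missingness in the omics that carry it (F3, F4),
#' cluster-linked survival, and cluster-enriched mutations and copy-number
#' alterations. Block widths default to a scaled-down version of the real
#' cohort's dimensions (400/80/400/60 vs 2000/407/2000/216) so tests run in
#' minutes; `paper_scale = TRUE` restores the full widths.
#'
#' @param n_samples number of samples
#' @param n_clusters number of latent subgroups (default 5)
#' @param block_widths named widths for F1/F2/F3/F4
#' @param signal_features_per_cluster informative features per cluster per
#'   omic (disjoint across clusters)
#' @param effect_size mean shift on signal features, in within-cluster sd
#'   units (default 3)
#' @param missing_fraction named per-omic missingness rates (F3/F4 only by
#'   default)
#' @param censor_fraction target censoring proportion
#' @param hazard_per_cluster exponential event hazards per cluster (per
#'   month); defaults span a 4x ratio
#' @param mutation_genes number of mutation genes
#' @param enriched_genes_per_cluster enriched genes per cluster
#' @param mutation_rates background and enriched Bernoulli rates
#' @param n_cytobands number of copy-number cytobands
#' @param paper_scale use the full-cohort block widths
#' @param seed integer seed
#' @return a `sim_config`
#' @export
sim_config <- function(n_samples = 300L, n_clusters = 5L,
                       block_widths = c(F1_mrna = 400L, F2_mirna = 80L,
                                        F3_methylation = 400L,
                                        F4_protein = 60L),
                       signal_features_per_cluster = 20L,
                       effect_size = 3,
                       missing_fraction = c(F1_mrna = 0, F2_mirna = 0,
                                            F3_methylation = 0.05,
                                            F4_protein = 0.05),
                       censor_fraction = 0.5,
                       hazard_per_cluster = NULL,
                       mutation_genes = 50L,
                       enriched_genes_per_cluster = 2L,
                       mutation_rates = c(background = 0.05,
                                          enriched = 0.6),
                       n_cytobands = 40L,
                       paper_scale = FALSE,
                       seed = 1L) {
  if (paper_scale)
    block_widths <- c(F1_mrna = 2000L, F2_mirna = 407L,
                      F3_methylation = 2000L, F4_protein = 216L)
  hazard_per_cluster <- hazard_per_cluster %||%
    exp(seq(log(0.01), log(0.04), length.out = n_clusters))
  stopifnot(n_samples >= 2, n_clusters >= 2,
            all(missing_fraction >= 0), all(missing_fraction < 1),
            censor_fraction >= 0, censor_fraction < 1,
            all(hazard_per_cluster > 0),
            length(hazard_per_cluster) == n_clusters)
  structure(list(n_samples = as.integer(n_samples),
                 n_clusters = as.integer(n_clusters),
                 block_widths = block_widths,
                 signal_features_per_cluster =
                   as.integer(signal_features_per_cluster),
                 effect_size = effect_size,
                 missing_fraction = missing_fraction,
                 censor_fraction = censor_fraction,
                 hazard_per_cluster = hazard_per_cluster,
                 mutation_genes = as.integer(mutation_genes),
                 enriched_genes_per_cluster =
                   as.integer(enriched_genes_per_cluster),
                 mutation_rates = mutation_rates,
                 n_cytobands = as.integer(n_cytobands),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the four omic matrices with latent cluster structure
#'
#' Cluster labels are drawn uniformly. Each cluster owns a disjoint set of
#' signal features per omic, shifted by `effect_size` within-cluster
#' standard deviations on the latent Gaussian scale. F1/F2 are
#' exponentiated Gaussians (non-negative, FPKM/RPKM-like), F3 is the
#' inverse-logit of shifted Gaussians (beta values strictly inside (0, 1)),
#' F4 stays Gaussian (RPPA-like). Missingness is injected completely at
#' random at the configured per-omic rates.
#'
#' @param cfg a [sim_config()]
#' @return list with `omics` (named list of [omic_matrix()]) and `labels`
#'   (true integer cluster per sample)
#' @export
simulate_multiomics <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, "omics"), {
    n <- cfg$n_samples
    K <- cfg$n_clusters
    labels <- sample.int(K, n, replace = TRUE)
    ids <- sprintf("S%03d", seq_len(n))
    omics <- list()
    for (kind in names(cfg$block_widths)) {
      p <- cfg$block_widths[[kind]]
      z <- matrix(rnorm(n * p), n, p)
      spc <- min(cfg$signal_features_per_cluster, floor(p / K))
      for (k in seq_len(K)) {
        feats <- ((k - 1) * spc + 1):(k * spc)
        z[labels == k, feats] <- z[labels == k, feats] + cfg$effect_size
      }
      vals <- switch(kind,
        F1_mrna = exp(z),
        F2_mirna = exp(z),
        F3_methylation = plogis(z),
        F4_protein = z)
      mf <- cfg$missing_fraction[[kind]] %||% 0
      if (mf > 0) vals[runif(n * p) < mf] <- NA
      rownames(vals) <- ids
      colnames(vals) <- sprintf("%s_f%04d", sub("_.*", "", kind),
                                seq_len(p))
      omics[[kind]] <- omic_matrix(vals, kind)
    }
    list(omics = omics, labels = labels, sample_ids = ids)
  })
}

#' Simulate cluster-linked clinical, mutation, and copy-number data
#'
#' Survival times are exponential with the cluster's hazard; censoring times
#' are independent exponentials whose rate is tuned so the expected censored
#' fraction matches `censor_fraction`. Mutations are Bernoulli, with each
#' cluster's designated genes at the elevated rate inside that cluster.
#' Segment means are Gaussian noise (sd 0.05) plus cluster-specific shifts
#' of magnitude >= 0.3 on designated cytobands.
#'
#' @param labels true cluster labels from [simulate_multiomics()]
#' @param cfg the same [sim_config()]
#' @param sample_ids sample identifiers (defaults to `S001...`)
#' @return list with `survival` ([survival_table()], OS), `dfs`
#'   ([survival_table()], DFS), `mutations` (genes x samples 0/1),
#'   `segmeans` (cytobands x samples), `enriched_genes` (named list:
#'   cluster -> gene ids), `altered_cytobands`
#' @export
simulate_clinical <- function(labels, cfg,
                              sample_ids = sprintf("S%03d",
                                                   seq_along(labels))) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- length(labels)
  K <- cfg$n_clusters
  with_seed(derive_seed(cfg$seed, "clinical"), {
    haz <- cfg$hazard_per_cluster[labels]
    make_surv <- function(endpoint) {
      t_event <- rexp(n, rate = haz)
      if (cfg$censor_fraction > 0) {
        # P(censor) = rc / (rc + lambda) for independent exponentials
        rc <- haz * cfg$censor_fraction / (1 - cfg$censor_fraction)
        t_cens <- rexp(n, rate = rc)
      } else {
        t_cens <- rep(Inf, n)
      }
      survival_table(sample_ids, pmin(t_event, t_cens),
                     as.integer(t_event <= t_cens), labels,
                     endpoint = endpoint)
    }
    surv_os <- make_surv("OS")
    surv_dfs <- make_surv("DFS")

    genes <- sprintf("GENE%03d", seq_len(cfg$mutation_genes))
    rate <- matrix(cfg$mutation_rates[["background"]],
                   cfg$mutation_genes, n,
                   dimnames = list(genes, sample_ids))
    enriched <- list()
    g <- 0L
    for (k in seq_len(K)) {
      pick <- genes[g + seq_len(cfg$enriched_genes_per_cluster)]
      g <- g + cfg$enriched_genes_per_cluster
      enriched[[as.character(k)]] <- pick
      rate[pick, labels == k] <- cfg$mutation_rates[["enriched"]]
    }
    mutations <- matrix(rbinom(length(rate), 1, rate),
                        nrow(rate), ncol(rate), dimnames = dimnames(rate))

    bands <- sprintf("cyto%02d", seq_len(cfg$n_cytobands))
    seg <- matrix(rnorm(cfg$n_cytobands * n, sd = 0.05),
                  cfg$n_cytobands, n, dimnames = list(bands, sample_ids))
    altered <- list()
    bands_per <- max(1L, floor(cfg$n_cytobands / (2 * K)))
    b <- 0L
    for (k in seq_len(K)) {
      gain_b <- bands[b + seq_len(bands_per)]
      loss_b <- bands[b + bands_per + seq_len(bands_per)]
      b <- b + 2L * bands_per
      seg[gain_b, labels == k] <- seg[gain_b, labels == k] + 0.5
      seg[loss_b, labels == k] <- seg[loss_b, labels == k] - 0.5
      altered[[as.character(k)]] <- list(gain = gain_b, loss = loss_b)
    }
    list(survival = surv_os, dfs = surv_dfs, mutations = mutations,
         segmeans = seg, enriched_genes = enriched,
         altered_cytobands = altered)
  })
}

#' Write a simulated dataset to a directory
#'
#' Emits the exact text formats the pipeline consumes: per-omic TSV
#' (samples in rows), clinical TSV, mutation and segment-mean TSVs, and the
#' truth labels.
#'
#' @param cfg a [sim_config()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_simulated_dataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_multiomics(cfg)
  clin <- simulate_clinical(sim$labels, cfg, sim$sample_ids)
  for (kind in names(sim$omics))
    write_matrix_tsv(sim$omics[[kind]]$values,
                     file.path(dir, paste0(kind, ".tsv")))
  cl <- data.frame(sample_id = sim$sample_ids,
                   os_time_months = clin$survival$time,
                   os_event = clin$survival$event,
                   dfs_time_months = clin$dfs$time,
                   dfs_event = clin$dfs$event)
  write.table(cl, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_matrix_tsv(clin$mutations, file.path(dir, "mutations.tsv"),
                   id_col = "gene")
  write_matrix_tsv(clin$segmeans, file.path(dir, "segmeans.tsv"),
                   id_col = "cytoband")
  write.table(data.frame(sample_id = sim$sample_ids,
                         true_cluster = sim$labels),
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
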