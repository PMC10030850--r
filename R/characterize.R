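#' @importFrom survival Surv survfit survdiff
NULL

#' Per-sample survival table
#'
#' @param sample_ids sample identifiers
#' @param time follow-up times in months (non-negative)
#' @param event 1 = event observed (death / recurrence), 0 = censored
#' @param cluster cluster label per sample
#' @param endpoint `"OS"` (overall) or `"DFS"` (disease-free)
#' @return a `survival_table` data.frame
#' @export
survival_table <- function(sample_ids, time, event, cluster,
                           endpoint = c("OS", "DFS")) {
  endpoint <- match.arg(endpoint)
  if (any(time < 0)) stop_omics("negative survival times")
  stopifnot(length(sample_ids) == length(time),
            length(time) == length(event),
            length(event) == length(cluster))
  df <- data.frame(sample_id = as.character(sample_ids),
                   time = as.numeric(time),
                   event = as.integer(event),
                   cluster = cluster,
                   stringsAsFactors = FALSE)
  attr(df, "endpoint") <- endpoint
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Kaplan-Meier estimate for one group or all groups
#'
#' Product-limit estimator per cluster; the median is the earliest time at
#' which the survival curve drops to 0.5 or below, `NA` ("not reached") when
#' it never does.
#'
#' @param surv a [survival_table()]
#' @param group a single cluster label, or `NULL` for every cluster
#' @return for one group, a list with `curve` (data.frame time / n_risk /
#'   n_event / survival) and `median`; for `NULL`, a named list of those
#' @export
km_estimate <- function(surv, group = NULL) {
  stopifnot(inherits(surv, "survival_table"))
  one <- function(g) {
    d <- surv[surv$cluster == g, ]
    if (nrow(d) == 0) stop_omics("empty group '%s'", g)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
    curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, survival = fit$surv)
    med_idx <- which(curve$survival <= 0.5)
    med <- if (length(med_idx)) curve$time[min(med_idx)] else NA_real_
    list(curve = curve, median = med)
  }
  if (!is.null(group)) return(one(group))
  groups <- sort(unique(surv$cluster))
  res <- lapply(groups, one)
  names(res) <- as.character(groups)
  res
}

#' Multi-group log-rank test
#'
#' Standard G-sample log-rank test of equal survival across clusters
#' (chi-square with G - 1 degrees of freedom).
#'
#' @param surv a [survival_table()]
#' @return list with `statistic`, `df`, `p`
#' @export
logrank_test <- function(surv) {
  stopifnot(inherits(surv, "survival_table"))
  groups <- unique(surv$cluster)
  if (length(groups) < 2) stop_omics("log-rank needs at least 2 groups")
  fit <- survival::survdiff(survival::Surv(time, event) ~ cluster,
                            data = surv)
  df <- length(groups) - 1L
  list(statistic = as.numeric(fit$chisq), df = df,
       p = pchisq(as.numeric(fit$chisq), df, lower.tail = FALSE))
}

# vectorized one-way ANOVA across feature columns: returns F, p per feature
# plus the per-group means and the pooled within mean square for Tukey.
anova_by_feature <- function(x, lab) {
  groups <- sort(unique(lab))
  K <- length(groups)
  n <- nrow(x)
  sizes <- vapply(groups, function(g) sum(lab == g), numeric(1))
  gm <- colMeans(x)
  means <- t(vapply(groups, function(g)
    colMeans(x[lab == g, , drop = FALSE]), numeric(ncol(x))))
  ssb <- colSums(sizes * sweep(means, 2, gm, "-")^2)
  sst <- colSums(sweep(x, 2, gm, "-")^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (K - 1)
  msw <- ssw / (n - K)
  eps <- 1e-12 * pmax(sst, 1)
  f <- ifelse(msw > eps, msb / msw,
              ifelse(ssb > eps, Inf, 0))
  p <- ifelse(is.infinite(f), 0,
              pf(f, K - 1, n - K, lower.tail = FALSE))
  p[f == 0] <- 1
  list(f = f, p = p, means = means, msw = msw, sizes = sizes,
       groups = groups, K = K, n = n)
}

#' Differential features by one-way ANOVA with Tukey post hoc
#'
#' Per feature: one-way ANOVA F across clusters, BH adjustment across
#' features, and Tukey HSD pairwise comparisons (studentized-range with the
#' harmonic-mean pair size, i.e. Tukey-Kramer) for features passing the
#' q-value threshold. All-constant features get F = 0, p = 1.
#'
#' @param m an [omic_matrix()] or samples x features matrix
#' @param labels a `cluster_assignment` or integer vector aligned to rows
#' @param q_threshold BH q-value selection cutoff (default 0.05)
#' @return data.frame (feature_id, statistic, p, q, selected) with a
#'   `pairwise` attribute: per selected feature, Tukey adjusted p and mean
#'   difference per cluster pair
#' @export
anova_tukey_de <- function(m, labels, q_threshold = 0.05) {
  x <- if (inherits(m, "omic_matrix")) m$values else as.matrix(m)
  lab <- if (inherits(labels, "cluster_assignment")) labels$labels else labels
  stopifnot(nrow(x) == length(lab))
  groups <- sort(unique(lab))
  if (length(groups) < 2) stop_omics("need at least 2 clusters")
  if (any(table(lab) < 2)) stop_omics("each cluster needs >= 2 samples")
  av <- anova_by_feature(x, lab)
  q <- p.adjust(av$p, method = "BH")
  res <- data.frame(feature_id = colnames(x), statistic = av$f,
                    p = av$p, q = q, selected = q <= q_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  pairs <- utils::combn(seq_along(groups), 2)
  pairwise <- lapply(which(res$selected), function(j) {
    out <- data.frame(
      group1 = av$groups[pairs[1, ]], group2 = av$groups[pairs[2, ]],
      diff = av$means[pairs[2, ], j] - av$means[pairs[1, ], j])
    nh <- 2 / (1 / av$sizes[pairs[1, ]] + 1 / av$sizes[pairs[2, ]])
    se <- sqrt(pmax(av$msw[j], .Machine$double.xmin) / nh)
    qstat <- abs(out$diff) / se
    out$p_adj <- ptukey(qstat, av$K, av$n - av$K, lower.tail = FALSE)
    out
  })
  names(pairwise) <- res$feature_id[res$selected]
  attr(res, "pairwise") <- pairwise
  res
}

#' Differential methylation pipeline
#'
#' Probes with standard deviation above `sd_min` are quantile normalized
#' across samples, log2 transformed with a small offset (beta values can be
#' exactly 0), then tested per probe with an ordinary linear-model F across
#' clusters and BH-adjusted. Moderated (empirical-Bayes) statistics are
#' deliberately not used; at these scales ordinary F-tests give the same
#' selection behavior.
#'
#' @param m an [omic_matrix()] of kind `F3_methylation`
#' @param labels cluster labels aligned to rows
#' @param sd_min minimum probe standard deviation (default 0.2, strict)
#' @param q_threshold BH cutoff (default 0.05)
#' @param log_offset offset inside the log2 (default 1e-3)
#' @return data.frame as in [anova_tukey_de()] (without pairwise tests)
#' @export
methylation_de <- function(m, labels, sd_min = 0.2, q_threshold = 0.05,
                           log_offset = 1e-3) {
  stopifnot(inherits(m, "omic_matrix"))
  if (m$kind != "F3_methylation")
    stop_omics("methylation_de expects an F3 matrix")
  lab <- if (inherits(labels, "cluster_assignment")) labels$labels else labels
  x <- m$values
  sds <- matrixStats::colSds(x)
  keep <- sds > sd_min
  if (!any(keep)) {
    warning("no probe passes the sd filter")
    return(data.frame(feature_id = character(), statistic = numeric(),
                      p = numeric(), q = numeric(), selected = logical()))
  }
  x <- x[, keep, drop = FALSE]
  x <- t(limma::normalizeQuantiles(t(x)))       # samples are distributions
  x <- log2(x + log_offset)
  av <- anova_by_feature(x, lab)
  q <- p.adjust(av$p, method = "BH")
  data.frame(feature_id = colnames(x), statistic = av$f, p = av$p, q = q,
             selected = q <= q_threshold, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Fisher enrichment of binary alterations per cluster
#'
#' For every feature x cluster pair, builds the 2x2 table (altered vs not,
#' in-cluster vs rest) and computes the two-sided Fisher exact p; BH is
#' applied across all feature x cluster tests (set `adjust = FALSE` to use
#' raw p-values, as for copy-number cytobands).
#'
#' @param binary features x samples 0/1 matrix (genes or cytobands)
#' @param labels a `cluster_assignment` (sample ids must match columns) or
#'   an integer vector aligned to columns
#' @param q_threshold selection cutoff on q (or on p when `adjust = FALSE`)
#' @param adjust apply BH across tests (default TRUE)
#' @return data.frame feature_id / cluster / a,b,c,d counts / p / q /
#'   selected
#' @export
fisher_enrichment <- function(binary, labels, q_threshold = 0.05,
                              adjust = TRUE) {
  if (inherits(labels, "cluster_assignment")) {
    if (!all(labels$sample_ids %in% colnames(binary)))
      stop_omics("binary matrix misses labeled samples")
    binary <- binary[, labels$sample_ids, drop = FALSE]
    lab <- labels$labels
  } else {
    lab <- labels
    stopifnot(ncol(binary) == length(lab))
  }
  clusters <- sort(unique(lab))
  if (any(vapply(clusters, function(g) sum(lab == g), numeric(1)) == 0))
    stop_omics("empty cluster")
  binary <- (as.matrix(binary) != 0) * 1
  rows <- list()
  for (g in clusters) {
    inc <- lab == g
    a <- rowSums(binary[, inc, drop = FALSE])          # altered, in cluster
    b <- rowSums(binary[, !inc, drop = FALSE])         # altered, rest
    c_ <- sum(inc) - a
    d <- sum(!inc) - b
    p <- vapply(seq_along(a), function(i)
      fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2, 2))$p.value,
      numeric(1))
    rows[[as.character(g)]] <- data.frame(
      feature_id = rownames(binary), cluster = g,
      altered_in = a, altered_out = b, unaltered_in = c_, unaltered_out = d,
      p = p, stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q <- if (adjust) p.adjust(res$p, method = "BH") else res$p
  res$selected <- if (adjust) res$q <= q_threshold else res$p <= q_threshold
  res
}

#' Binarize copy-number segment means
#'
#' Gain when the segment mean is at least `+threshold`, loss when at most
#' `-threshold` (boundary inclusive on both sides).
#'
#' @param segmean cytobands x samples real matrix
#' @param threshold absolute segment-mean cutoff (default 0.3)
#' @return list of 0/1 matrices `gain` and `loss`
#' @export
cnv_binarize <- function(segmean, threshold = 0.3) {
  segmean <- as.matrix(segmean)
  if (any(!is.finite(segmean))) stop_omics("non-finite segment means")
  list(gain = (segmean >= threshold) * 1,
       loss = (segmean <= -threshold) * 1)
}

#' Copy-number enrichment per cluster
#'
#' Binarizes segment means at `|SegMean| >= threshold` and runs one-vs-rest
#' Fisher tests per cytoband for gains and losses separately; selection uses
#' the unadjusted p-value at `p_threshold` (default 0.01).
#'
#' @param segmean cytobands x samples matrix
#' @param labels cluster labels (see [fisher_enrichment()])
#' @param threshold segment-mean cutoff (default 0.3)
#' @param p_threshold raw p-value cutoff (default 0.01)
#' @return list of [fisher_enrichment()] tables `gain` and `loss`
#' @export
cnv_enrichment <- function(segmean, labels, threshold = 0.3,
                           p_threshold = 0.01) {
  bin <- cnv_binarize(segmean, threshold)
  list(gain = fisher_enrichment(bin$gain, labels, p_threshold, adjust = FALSE),
       loss = fisher_enrichment(bin$loss, labels, p_threshold, adjust = FALSE))
}
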