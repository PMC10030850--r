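#' Preprocessing configuration
#'
#' Defaults follow the pipeline's stated filters: drop features with zero
#' expression in more than 20% of samples (F1/F2), drop features or samples
#' with more than 10% missing (F3/F4), impute by KNN with K = 5, keep the
#' top 2000 most variable features (F1/F3), min-max scale to \[0, 1\].
#'
#' @param max_zero_fraction dropped when zero fraction strictly exceeds this
#' @param max_missing_fraction dropped when missing fraction strictly exceeds
#' @param knn_k neighbors for KNN imputation
#' @param top_n_variable number of most-variable features retained
#' @return a `preprocess_config` list
#' @export
preprocess_config <- function(max_zero_fraction = 0.20,
                              max_missing_fraction = 0.10,
                              knn_k = 5L,
                              top_n_variable = 2000L) {
  stopifnot(max_zero_fraction >= 0, max_zero_fraction <= 1,
            max_missing_fraction >= 0, max_missing_fraction <= 1,
            knn_k >= 1, top_n_variable >= 1)
  structure(list(max_zero_fraction = max_zero_fraction,
                 max_missing_fraction = max_missing_fraction,
                 knn_k = as.integer(knn_k),
                 top_n_variable = as.integer(top_n_variable)),
            class = "preprocess_config")
}

#' Drop sparse features
#'
#' Removes features whose fraction of "bad" entries (zeros or missing values)
#' strictly exceeds `max_bad_fraction`; a feature exactly at the threshold is
#' retained. Sample set and feature order are unchanged.
#'
#' @param m an [omic_matrix()]
#' @param max_bad_fraction tolerated bad-entry fraction
#' @param criterion `"zero"` (expression omics) or `"missing"`
#' @return filtered `omic_matrix`
#' @export
filter_sparse_features <- function(m, max_bad_fraction,
                                   criterion = c("zero", "missing")) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(m, "omic_matrix"), ncol(m$values) > 0)
  if (criterion == "zero" && !(m$kind %in% c("F1_mrna", "F2_mirna")))
    stop_omics("zero-based filtering applies to expression omics (F1/F2)")
  bad <- if (criterion == "zero") {
    colMeans(m$values == 0, na.rm = TRUE)
  } else {
    colMeans(is.na(m$values))
  }
  keep <- bad <= max_bad_fraction
  if (!any(keep))
    stop_omics("no features survive the %s filter at %.3g",
               criterion, max_bad_fraction)
  omic_matrix(m$values[, keep, drop = FALSE], m$kind)
}

#' Drop samples with excessive missingness
#'
#' Used for methylation, where samples with more than 10% missing probes are
#' removed before probe-level filtering; strict-greater boundary as for
#' features.
#'
#' @param m an [omic_matrix()]
#' @param max_missing_fraction tolerated per-sample missing fraction
#' @return filtered `omic_matrix`
#' @export
filter_sparse_samples <- function(m, max_missing_fraction) {
  stopifnot(inherits(m, "omic_matrix"))
  frac <- rowMeans(is.na(m$values))
  keep <- frac <= max_missing_fraction
  if (!any(keep))
    stop_omics("no samples survive the missingness filter at %.3g",
               max_missing_fraction)
  omic_matrix(m$values[keep, , drop = FALSE], m$kind)
}

#' KNN imputation of missing entries
#'
#' For each sample with missing values, neighbors are the other samples,
#' ranked by Euclidean distance over mutually observed coordinates. A
#' missing entry is the unweighted mean of that feature's values in the k
#' nearest neighbors that observe it; if fewer than k neighbors observe it,
#' all available are used; if none, the feature's global mean. Observed
#' entries are never altered. Ties in distance resolve by sample order.
#'
#' @param m an [omic_matrix()]
#' @param k neighbor count (default 5)
#' @return fully observed `omic_matrix`
#' @export
knn_impute <- function(m, k = 5L) {
  stopifnot(inherits(m, "omic_matrix"), k >= 1)
  x <- m$values
  if (all(is.na(x))) stop_omics("matrix is entirely missing; cannot impute")
  if (!anyNA(x)) return(m)
  n <- nrow(x)
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  # squared Euclidean distance over mutually observed coordinates, all pairs
  obs_n <- obs * 1
  shared <- tcrossprod(obs_n)                      # counts of shared coords
  sq <- x0^2
  cross <- tcrossprod(x0)
  sumsq_i <- sq %*% t(obs_n)                       # sum x_i^2 over shared
  msd <- pmax(sumsq_i + t(sumsq_i) - 2 * cross, 0)
  msd[shared == 0] <- Inf
  diag(msd) <- Inf
  gmean <- colMeans(x, na.rm = TRUE)
  out <- x
  need <- which(rowSums(!obs) > 0)
  for (i in need) {
    ord <- order(msd[i, ])                         # nearest first, ties by index
    miss_j <- which(!obs[i, ])
    for (j in miss_j) {
      donors <- ord[obs[ord, j] & is.finite(msd[i, ord])]
      if (length(donors) == 0) {
        out[i, j] <- gmean[j]
      } else {
        out[i, j] <- mean(x[head(donors, k), j])
      }
    }
  }
  if (anyNA(out)) {
    nasum <- which(is.na(out), arr.ind = TRUE)     # all-NA feature columns
    out[nasum] <- 0
  }
  omic_matrix(out, m$kind)
}

#' Keep the most variable features
#'
#' Retains the `n` features with the largest sample standard deviation,
#' returned in decreasing-sd order; ties at the boundary are broken by
#' feature id (lexicographic) for determinism.
#'
#' @param m an [omic_matrix()]
#' @param n number of features to keep
#' @return `omic_matrix` with `min(n, p)` features
#' @export
select_top_variable <- function(m, n) {
  stopifnot(inherits(m, "omic_matrix"), n >= 1)
  sds <- matrixStats::colSds(m$values, na.rm = TRUE)
  ord <- order(-sds, colnames(m$values))
  keep <- head(ord, n)
  omic_matrix(m$values[, keep, drop = FALSE], m$kind)
}

#' Min-max scale each feature to \[0, 1\]
#'
#' Per feature, the minimum maps to 0 and the maximum to 1; a constant
#' feature maps to all zeros. Requires a fully observed matrix. The
#' per-feature minima and ranges are attached as attributes so stored
#' statistics can be replayed on new samples.
#'
#' @param m an [omic_matrix()]
#' @param stats optional list with `min` and `range` vectors (stored
#'   statistics from a previous call) to apply instead of recomputing
#' @return normalized `omic_matrix` with `minmax_stats` attribute
#' @export
minmax_normalize <- function(m, stats = NULL) {
  stopifnot(inherits(m, "omic_matrix"))
  if (anyNA(m$values)) stop_omics("impute before min-max normalization")
  x <- m$values
  if (is.null(stats)) {
    mins <- matrixStats::colMins(x)
    rng <- matrixStats::colMaxs(x) - mins
  } else {
    mins <- stats$min
    rng <- stats$range
  }
  scl <- ifelse(rng > 0, rng, 1)
  out <- sweep(sweep(x, 2, mins, "-"), 2, scl, "/")
  out[, rng == 0] <- 0
  out <- pmin(pmax(out, 0), 1)                     # clamp replayed new samples
  res <- omic_matrix(out, m$kind)
  attr(res, "minmax_stats") <- list(min = mins, range = rng)
  res
}

#' Stack processed omics into one multi-omics matrix
#'
#' Column-wise concatenation over the intersection of sample sets, with
#' per-column omic provenance and per-block offsets recorded.
#'
#' @param ms named or unnamed list of fully processed [omic_matrix()] objects
#' @return a `multi_omics_stack`: list with `values`, `column_kind`,
#'   `block_offsets` (data.frame kind/start/stop)
#' @export
stack_omics <- function(ms) {
  stopifnot(is.list(ms), length(ms) >= 1)
  for (m in ms) {
    stopifnot(inherits(m, "omic_matrix"))
    if (anyNA(m$values)) stop_omics("stack requires fully imputed inputs")
  }
  common <- Reduce(intersect, lapply(ms, sample_ids))
  if (length(common) == 0) stop_omics("no samples shared across omics")
  blocks <- lapply(ms, function(m) m$values[common, , drop = FALSE])
  widths <- vapply(blocks, ncol, integer(1))
  values <- do.call(cbind, blocks)
  kinds <- vapply(ms, function(m) m$kind, character(1))
  colnames(values) <- unlist(lapply(seq_along(blocks), function(i)
    paste(kinds[i], colnames(blocks[[i]]), sep = ".")))
  stops <- cumsum(widths)
  structure(list(
    values = values,
    column_kind = rep(kinds, widths),
    block_offsets = data.frame(kind = kinds,
                               start = c(1L, head(stops, -1) + 1L),
                               stop = stops,
                               stringsAsFactors = FALSE)
  ), class = "multi_omics_stack")
}

#' @export
print.multi_omics_stack <- function(x, ...) {
  cat(sprintf("<multi_omics_stack: %d samples x %d features (%s)>\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", x$block_offsets$kind,
                            x$block_offsets$stop - x$block_offsets$start + 1L),
                    collapse = ", ")))
  invisible(x)
}

#' Run the per-omic preprocessing recipe
#'
#' Applies the stated per-kind order: F1/F2 zero-filter, variance selection
#' (F1 only), min-max; F3 optional probe blacklist, sample filter, probe
#' filter, KNN imputation, variance selection (no rescaling — beta values are
#' already in \[0, 1\]); F4 missingness filter and KNN imputation only
#' (level-4 data arrives normalized).
#'
#' @param m an [omic_matrix()]
#' @param config a [preprocess_config()]
#' @param probe_blacklist optional character vector of feature ids to drop
#'   first (methylation X/Y/SNP/cross-hybridizing probes)
#' @return processed `omic_matrix`
#' @export
preprocess_omic <- function(m, config = preprocess_config(),
                            probe_blacklist = NULL) {
  stopifnot(inherits(m, "omic_matrix"), inherits(config, "preprocess_config"))
  switch(m$kind,
    F1_mrna = {
      m <- filter_sparse_features(m, config$max_zero_fraction, "zero")
      m <- select_top_variable(m, config$top_n_variable)
      minmax_normalize(m)
    },
    F2_mirna = {
      m <- filter_sparse_features(m, config$max_zero_fraction, "zero")
      minmax_normalize(m)
    },
    F3_methylation = {
      if (!is.null(probe_blacklist)) {
        keep <- setdiff(feature_ids(m), probe_blacklist)
        if (length(keep) == 0) stop_omics("blacklist removes every probe")
        m <- omic_matrix(m$values[, keep, drop = FALSE], m$kind)
      }
      m <- filter_sparse_samples(m, config$max_missing_fraction)
      m <- filter_sparse_features(m, config$max_missing_fraction, "missing")
      m <- knn_impute(m, config$knn_k)
      select_top_variable(m, config$top_n_variable)
    },
    F4_protein = {
      m <- filter_sparse_features(m, config$max_missing_fraction, "missing")
      knn_impute(m, config$knn_k)
    })
}
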