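#' @importFrom cluster silhouette
NULL

# k-means++ center seeding followed by stats::kmeans, best of `restarts`
# random initializations by total within-cluster sum of squares.
kmeans_pp <- function(x, k, restarts = 10L, iter_max = 100L) {
  n <- nrow(x)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- matrix(NA_real_, k, ncol(x))
    centers[1, ] <- x[sample.int(n, 1L), ]
    d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
    if (k > 1) {
      for (j in 2:k) {
        pr <- d2 / sum(d2)
        if (!all(is.finite(pr)) || sum(d2) <= 0)
          pick <- sample.int(n, 1L)
        else
          pick <- sample.int(n, 1L, prob = pr)
        centers[j, ] <- x[pick, ]
        d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ], "-")^2))
      }
    }
    centers <- centers[!duplicated(centers), , drop = FALSE]
    fit <- suppressWarnings(tryCatch(
      stats::kmeans(x, centers = centers, iter.max = iter_max),
      error = function(e) NULL))
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop_omics("k-means failed for k = %d", k)
  best
}

#' Consensus matrix from resampled K-means
#'
#' Repeatedly subsamples `floor(n * subsample_fraction)` samples without
#' replacement, K-means-clusters each subsample (k-means++ seeding), and
#' accumulates, per sample pair, how often the pair was drawn together
#' (`cosample`) and how often it co-clustered (`cooccur`). The consensus
#' value is their ratio; the stated regime is 1000 resamples at 80%.
#'
#' A single K-means initialization per resample is deliberate: the PAC
#' statistic discriminates K through run-to-run assignment variability, and
#' multi-restart inner loops make under-partitioned solutions spuriously
#' stable (PAC exactly 0 for several K at once).
#'
#' @param latent samples x dims matrix (e.g. the bottleneck representation)
#' @param K number of clusters per resample
#' @param n_resamples resampling iterations
#' @param subsample_fraction per-iteration sample fraction
#' @param seed integer seed (independent stream per resample)
#' @param restarts k-means++ restarts per resample (default 1, see above)
#' @return a `consensus_matrix`: list with `consensus`, `cooccur`, `cosample`
#' @export
consensus_kmeans <- function(latent, K, n_resamples = 1000L,
                             subsample_fraction = 0.8, seed = 1L,
                             restarts = 1L) {
  x <- as.matrix(latent)
  n <- nrow(x)
  m <- floor(n * subsample_fraction)
  if (K < 2) stop_omics("K must be at least 2")
  if (m < K) stop_omics("subsample size %d below K = %d", m, K)
  cooccur <- matrix(0, n, n)
  cosample <- matrix(0, n, n)
  for (b in seq_len(n_resamples)) {
    with_seed(derive_seed(seed, sprintf("resample_%d_%d", K, b)), {
      idx <- sample.int(n, m)
      fit <- kmeans_pp(x[idx, , drop = FALSE], K, restarts = restarts)
      ind <- matrix(0, m, K)
      ind[cbind(seq_len(m), fit$cluster)] <- 1
      cooccur[idx, idx] <- cooccur[idx, idx] + tcrossprod(ind)
      cosample[idx, idx] <- cosample[idx, idx] + 1
    })
  }
  consensus <- ifelse(cosample > 0, cooccur / pmax(cosample, 1), 0)
  dimnames(consensus) <- dimnames(cooccur) <- dimnames(cosample) <-
    list(rownames(x), rownames(x))
  structure(list(consensus = consensus, cooccur = cooccur,
                 cosample = cosample),
            class = "consensus_matrix")
}

#' Empirical CDF of consensus values
#'
#' Right-continuous empirical CDF over the off-diagonal upper-triangle
#' consensus entries of pairs that were co-sampled at least once (pairs never
#' drawn together carry no evidence).
#'
#' @param cm a [consensus_kmeans()] result
#' @return a function `F(u) = fraction of entries <= u`, with the entry
#'   multiset attached as attribute `entries`
#' @export
empirical_cdf <- function(cm) {
  stopifnot(inherits(cm, "consensus_matrix"))
  ut <- upper.tri(cm$consensus)
  eligible <- ut & cm$cosample > 0
  if (!any(eligible)) stop_omics("no co-sampled off-diagonal pairs")
  entries <- sort(cm$consensus[eligible])
  f <- function(u) vapply(u, function(ui) mean(entries <= ui), numeric(1))
  attr(f, "entries") <- entries
  f
}

#' Proportion of ambiguously clustered pairs
#'
#' `PAC = CDF(u2) - CDF(u1)`: the mass of consensus values falling strictly
#' between "never co-cluster" and "always co-cluster". Lower is more stable.
#'
#' @param cdf an [empirical_cdf()] function
#' @param u1,u2 thresholds with `0 <= u1 < u2 <= 1` (defaults 0.1, 0.9)
#' @return PAC in `[0, 1]`
#' @export
compute_pac <- function(cdf, u1 = 0.1, u2 = 0.9) {
  if (!(u1 >= 0 && u1 < u2 && u2 <= 1))
    stop_omics("need 0 <= u1 < u2 <= 1")
  as.numeric(cdf(u2) - cdf(u1))
}

#' PAC profile over a range of K
#'
#' Runs [consensus_kmeans()] for each K and records the consensus matrix,
#' CDF, and PAC value; the stated sweep is K = 2..10.
#'
#' @param latent samples x dims matrix
#' @param k_range integer vector of K values
#' @param n_resamples,subsample_fraction,seed see [consensus_kmeans()]
#' @param u1,u2 PAC thresholds
#' @return a `pac_profile`: named list (one record per K) with `pac` table
#'   attached
#' @export
build_pac_profile <- function(latent, k_range = 2:10, n_resamples = 1000L,
                              subsample_fraction = 0.8, u1 = 0.1, u2 = 0.9,
                              seed = 1L) {
  if (length(k_range) == 0) stop_omics("empty k_range")
  records <- lapply(k_range, function(K) {
    cm <- consensus_kmeans(latent, K, n_resamples, subsample_fraction, seed)
    cdf <- empirical_cdf(cm)
    list(K = K, consensus = cm, cdf = cdf, pac = compute_pac(cdf, u1, u2))
  })
  names(records) <- paste0("K", k_range)
  structure(list(records = records,
                 pac = data.frame(K = k_range,
                                  pac = vapply(records, `[[`, numeric(1),
                                               "pac")),
                 u1 = u1, u2 = u2),
            class = "pac_profile")
}

#' Select K by minimal PAC
#'
#' Returns the non-excluded K with the smallest PAC; ties go to the smaller
#' K. Exclusion supports the judgment step where a K merely reproducing an
#' already-known partition (e.g. histology) is passed over in favor of the
#' next smallest PAC.
#'
#' @param profile a [build_pac_profile()] result
#' @param excluded integer vector of K values to skip
#' @return selected K
#' @export
select_k <- function(profile, excluded = integer(0)) {
  stopifnot(inherits(profile, "pac_profile"))
  tab <- profile$pac[!(profile$pac$K %in% excluded), , drop = FALSE]
  if (nrow(tab) == 0) stop_omics("all K values excluded")
  tab <- tab[order(tab$pac, tab$K), ]
  tab$K[1]
}

#' Does a clustering merely reproduce a known partition?
#'
#' True when the adjusted Rand index between the cluster labels and a known
#' categorical labeling reaches `threshold`; single-category known labels
#' are never flagged.
#'
#' @param labels a [final_labels()] result or integer vector
#' @param known categorical vector over the same samples
#' @param threshold ARI cutoff (default 0.8)
#' @return logical
#' @export
flag_known_partition <- function(labels, known, threshold = 0.8) {
  lab <- if (inherits(labels, "cluster_assignment")) labels$labels else labels
  stopifnot(length(lab) == length(known))
  if (length(unique(known)) < 2) return(FALSE)
  adjusted_rand_index(lab, known) >= threshold
}

#' Final cluster labels from the consensus matrix
#'
#' K-means (k-means++ seeding, 10 restarts) on the rows of the consensus
#' matrix; retried with a fresh sub-seed (up to 10 times) if any cluster
#' comes back empty.
#'
#' @param cm a [consensus_kmeans()] result
#' @param K number of clusters
#' @param seed integer seed
#' @return a `cluster_assignment`: list with `sample_ids`, `labels`, `K`
#' @export
final_labels <- function(cm, K, seed = 1L) {
  stopifnot(inherits(cm, "consensus_matrix"))
  for (attempt in seq_len(10L)) {
    fit <- with_seed(derive_seed(seed, sprintf("final_%d_%d", K, attempt)),
                     kmeans_pp(cm$consensus, K))
    if (length(unique(fit$cluster)) == K) {
      return(structure(list(sample_ids = rownames(cm$consensus),
                            labels = as.integer(fit$cluster), K = K),
                       class = "cluster_assignment"))
    }
  }
  stop_omics("could not produce %d non-empty clusters", K)
}

#' Cluster quality metrics
#'
#' Mean silhouette width and the Calinski-Harabasz index
#' `(B / (K - 1)) / (W / (n - K))` on the given feature space.
#'
#' @param x samples x dims matrix
#' @param labels a `cluster_assignment` or integer vector
#' @return list with `silhouette` and `calinski_harabasz`
#' @export
cluster_quality <- function(x, labels) {
  lab <- if (inherits(labels, "cluster_assignment")) labels$labels else labels
  x <- as.matrix(x)
  K <- length(unique(lab))
  n <- nrow(x)
  if (K < 2) stop_omics("cluster quality needs at least 2 clusters")
  sil <- mean(cluster::silhouette(lab, stats::dist(x))[, "sil_width"])
  centroid <- colMeans(x)
  W <- 0
  B <- 0
  for (g in unique(lab)) {
    xi <- x[lab == g, , drop = FALSE]
    cg <- colMeans(xi)
    W <- W + sum(sweep(xi, 2, cg, "-")^2)
    B <- B + nrow(xi) * sum((cg - centroid)^2)
  }
  list(silhouette = sil,
       calinski_harabasz = (B / (K - 1)) / (W / (n - K)))
}
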