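two_clouds <- function(n_per = 20, sep = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * 2), n_per, 2),
             matrix(rnorm(n_per * 2, mean = sep), n_per, 2))
  rownames(x) <- sprintf("S%02d", seq_len(2 * n_per))
  x
}

test_that("consensus matrix is symmetric with unit diagonal and exact ratios", {
  x <- two_clouds(8, sep = 4)
  cm <- consensus_kmeans(x, 2, n_resamples = 20, seed = 3)
  expect_equal(cm$consensus, t(cm$consensus))
  expect_equal(cm$cooccur, t(cm$cooccur))
  sampled <- diag(cm$cosample) > 0
  expect_true(all(diag(cm$consensus)[sampled] == 1))
  # consensus = cooccur / cosample wherever co-sampled (exact rational check)
  idx <- cm$cosample > 0
  expect_identical(cm$consensus[idx], cm$cooccur[idx] / cm$cosample[idx])
  expect_true(all(cm$consensus >= 0 & cm$consensus <= 1))
  expect_error(consensus_kmeans(x[1:4, ], 5, 10), "below K")
})

test_that("well-separated clouds give a clean consensus partition", {
  x <- two_clouds(20, sep = 10, seed = 2)
  truth <- rep(1:2, each = 20)
  cm <- consensus_kmeans(x, 2, n_resamples = 50, seed = 7)
  within <- outer(truth, truth, "==") & upper.tri(cm$consensus) &
    cm$cosample > 0
  across <- outer(truth, truth, "!=") & upper.tri(cm$consensus) &
    cm$cosample > 0
  expect_true(all(cm$consensus[within] >= 0.99))
  expect_true(all(cm$consensus[across] <= 0.01))
  # distance-threshold oracle partition agrees with final labels
  oracle <- as.integer(x[, 1] + x[, 2] > 10)
  fl <- final_labels(cm, 2, seed = 1)
  expect_equal(adjusted_rand_index(fl$labels, oracle), 1)
})

test_that("empirical_cdf matches closed forms and a sort oracle", {
  mk_cm <- function(entries) {
    # fabricate a consensus_matrix whose eligible upper triangle = entries
    m <- length(entries)
    n <- ceiling((1 + sqrt(1 + 8 * m)) / 2)
    cons <- matrix(0, n, n)
    cos <- matrix(0, n, n)
    ut <- which(upper.tri(cons))
    cons[ut[seq_len(m)]] <- entries
    cos[ut[seq_len(m)]] <- 1
    cons <- cons + t(cons)
    cos <- cos + t(cos)
    diag(cos) <- 1
    diag(cons) <- 1
    structure(list(consensus = cons, cooccur = cons * cos, cosample = cos),
              class = "consensus_matrix")
  }
  cdf0 <- empirical_cdf(mk_cm(c(0, 0, 0)))
  expect_equal(cdf0(c(0, 0.5, 1)), c(1, 1, 1))

  cdf3 <- empirical_cdf(mk_cm(c(0, 0.5, 1)))
  expect_equal(cdf3(0.1), 1 / 3)
  expect_equal(cdf3(0.9), 2 / 3)

  set.seed(4)
  entries <- runif(45)
  cdfr <- empirical_cdf(mk_cm(entries))
  grid <- seq(0, 1, length.out = 101)
  oracle <- vapply(grid, function(u) sum(sort(entries) <= u) / 45, numeric(1))
  expect_equal(cdfr(grid), oracle)
})

test_that("compute_pac applies the CDF difference", {
  fake_cdf <- function(u) ifelse(u >= 0.9, 0.20, ifelse(u >= 0.1, 0.06, 0))
  expect_equal(compute_pac(fake_cdf, 0.1, 0.9), 0.14)
  # perfect consensus (entries only 0 or 1) -> PAC 0
  perfect <- function(u) ifelse(u >= 1, 1, 0.4)
  expect_equal(compute_pac(perfect, 0.1, 0.9), 0)
  # all entries 0.5 -> PAC 1
  half <- function(u) ifelse(u >= 0.5, 1, 0)
  expect_equal(compute_pac(half, 0.1, 0.9), 1)
  expect_error(compute_pac(half, 0.9, 0.1), "u1 < u2")
})

test_that("build_pac_profile and select_k follow the stated selection rule", {
  x <- two_clouds(10, sep = 8, seed = 5)
  prof <- build_pac_profile(x, 2:4, n_resamples = 25, seed = 9)
  expect_length(prof$records, 3)
  expect_equal(prof$pac$K, 2:4)
  prof2 <- build_pac_profile(x, 2:4, n_resamples = 25, seed = 9)
  expect_identical(prof$pac, prof2$pac)

  fake_profile <- structure(list(pac = data.frame(
    K = 2:6, pac = c(0.06, 0.30, 0.25, 0.14, 0.40))), class = "pac_profile")
  expect_equal(select_k(fake_profile), 2)
  expect_equal(select_k(fake_profile, excluded = 2), 5)
  tie <- structure(list(pac = data.frame(K = 2:4, pac = c(0.3, 0.1, 0.1))),
                   class = "pac_profile")
  expect_equal(select_k(tie), 3)
  expect_error(select_k(tie, excluded = 2:4), "excluded")
})

test_that("flag_known_partition uses ARI with the single-category convention", {
  lab <- rep(1:2, each = 25)
  expect_true(flag_known_partition(lab, lab))
  expect_true(flag_known_partition(lab, c("LUSC", "LUAD")[lab]))
  set.seed(6)
  indep <- sample(1:2, 50, replace = TRUE)
  expect_false(flag_known_partition(lab, indep))
  expect_false(flag_known_partition(lab, rep("only", 50)))
})

test_that("final_labels recovers block structure from noisy consensus", {
  set.seed(10)
  truth <- rep(1:3, each = 12)
  cons <- outer(truth, truth, function(a, b) as.numeric(a == b))
  # perfect block consensus
  cm <- structure(list(consensus = cons, cooccur = cons,
                       cosample = matrix(1, 36, 36)),
                  class = "consensus_matrix")
  rownames(cm$consensus) <- sprintf("S%02d", 1:36)
  fl <- final_labels(cm, 3, seed = 1)
  expect_equal(adjusted_rand_index(fl$labels, truth), 1)
  expect_identical(final_labels(cm, 3, seed = 1)$labels, fl$labels)
  # 5% noise
  noisy <- pmin(pmax(cons + matrix(rnorm(36^2, sd = 0.05), 36), 0), 1)
  noisy <- (noisy + t(noisy)) / 2
  cm$consensus <- noisy
  rownames(cm$consensus) <- sprintf("S%02d", 1:36)
  fl2 <- final_labels(cm, 3, seed = 1)
  expect_gte(adjusted_rand_index(fl2$labels, truth), 0.95)
})

test_that("cluster_quality matches direct-formula oracles on a 12-point toy", {
  set.seed(12)
  x <- rbind(matrix(rnorm(12, sd = 0.3), 6, 2),
             matrix(rnorm(12, mean = 5, sd = 0.3), 6, 2))
  lab <- rep(1:2, each = 6)
  got <- cluster_quality(x, lab)

  # silhouette oracle: direct per-point formula
  d <- as.matrix(dist(x))
  sil <- vapply(1:12, function(i) {
    a <- mean(d[i, lab == lab[i] & seq_len(12) != i])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(g)
      mean(d[i, lab == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(got$silhouette, mean(sil), tolerance = 1e-12)

  # CH oracle: between/within mean-square ratio
  cent <- colMeans(x)
  B <- sum(vapply(1:2, function(g)
    sum(lab == g) * sum((colMeans(x[lab == g, ]) - cent)^2), numeric(1)))
  W <- sum(vapply(1:2, function(g)
    sum(sweep(x[lab == g, ], 2, colMeans(x[lab == g, ]))^2), numeric(1)))
  expect_equal(got$calinski_harabasz, (B / 1) / (W / 10), tolerance = 1e-12)

  expect_gte(got$silhouette, 0.9)
  expect_error(cluster_quality(x, rep(1, 12)), "at least 2")
})

test_that("random labels on structureless data give near-zero silhouette", {
  set.seed(13)
  x <- matrix(rnorm(500 * 4), 500, 4)
  lab <- sample(1:5, 500, replace = TRUE)
  q <- cluster_quality(x, lab)
  expect_lte(abs(q$silhouette), 0.1)
})

test_that("PAC is invariant to sample reordering", {
  x <- two_clouds(10, sep = 3, seed = 14)
  cm <- consensus_kmeans(x, 2, n_resamples = 30, seed = 4)
  pac1 <- compute_pac(empirical_cdf(cm))
  perm <- sample(nrow(x))
  cmp <- structure(list(consensus = cm$consensus[perm, perm],
                        cooccur = cm$cooccur[perm, perm],
                        cosample = cm$cosample[perm, perm]),
                   class = "consensus_matrix")
  expect_equal(compute_pac(empirical_cdf(cmp)), pac1)
})

test_that("higher separation never increases PAC at the true K", {
  pacs <- vapply(c(2, 5, 12), function(sep) {
    x <- two_clouds(15, sep = sep, seed = 20)
    compute_pac(empirical_cdf(consensus_kmeans(x, 2, 40, seed = 21)))
  }, numeric(1))
  expect_true(all(diff(pacs) <= 1e-12))
})
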