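# independent product-limit oracle
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, survival = NA_real_)
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out$survival[i] <- s
  }
  out
}

test_that("km_estimate matches hand and oracle product-limit curves", {
  # n = 4, events at 1..4, no censoring -> S = 0.75, 0.5, 0.25, 0
  surv <- survival_table(paste0("S", 1:4), 1:4, rep(1, 4), rep(1, 4))
  est <- km_estimate(surv, group = 1)
  expect_equal(est$curve$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(est$median, 2)

  # all censored -> S = 1 throughout, median not reached
  cens <- survival_table(paste0("S", 1:5), c(3, 8, 12, 20, 30), rep(0, 5),
                         rep(1, 5))
  est <- km_estimate(cens, group = 1)
  expect_true(all(est$curve$survival == 1))
  expect_true(is.na(est$median))

  # random censored cohort vs oracle at every event time
  set.seed(31)
  tt <- round(rexp(20, 0.05), 1)
  ev <- rbinom(20, 1, 0.6)
  surv <- survival_table(paste0("S", 1:20), tt, ev, rep(1, 20))
  est <- km_estimate(surv, group = 1)
  orc <- km_oracle(tt, ev)
  got <- est$curve[est$curve$n_event > 0, c("time", "survival")]
  expect_equal(got$time, orc$time)
  expect_equal(got$survival, orc$survival, tolerance = 1e-12)

  expect_error(survival_table("a", -1, 1, 1), "negative")
})

test_that("logrank_test matches the hypergeometric-variance oracle", {
  # oracle: sum over event times of (O - E) with hypergeometric variance,
  # two-group statistic (O1 - E1)^2 / V
  set.seed(32)
  tt <- c(2, 3, 5, 5, 7, 8, 10, 12, 13, 15, 16, 20)
  ev <- c(1, 0, 1, 1, 0, 1, 1, 0, 1, 1, 0, 1)
  gr <- rep(1:2, 6)
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(tt[ev == 1]))) {
    n_t <- sum(tt >= t)
    n1 <- sum(tt >= t & gr == 1)
    d <- sum(tt == t & ev == 1)
    d1 <- sum(tt == t & ev == 1 & gr == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n_t
    if (n_t > 1)
      v <- v + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
  }
  oracle_stat <- o_minus_e^2 / v
  surv <- survival_table(paste0("S", 1:12), tt, ev, gr)
  got <- logrank_test(surv)
  expect_equal(got$statistic, oracle_stat, tolerance = 1e-10)
  expect_equal(got$df, 1)

  # identical groups -> statistic 0, p = 1
  same <- survival_table(paste0("S", 1:8), rep(c(1, 2, 3, 4), 2),
                         rep(1, 8), rep(1:2, each = 4))
  got <- logrank_test(same)
  expect_equal(got$statistic, 0, tolerance = 1e-12)
  expect_equal(got$p, 1, tolerance = 1e-12)

  five <- survival_table(paste0("S", 1:20), rexp(20, 0.1) + 1,
                         rbinom(20, 1, 0.7), rep(1:5, each = 4))
  expect_equal(logrank_test(five)$df, 4)
  one <- survival_table(paste0("S", 1:4), 1:4, rep(1, 4), rep(1, 4))
  expect_error(logrank_test(one), "2 groups")
})

test_that("anova_tukey_de matches aov/TukeyHSD oracles and selects shifts", {
  # 3-group toy with integer values, F against base-R aov
  v <- c(1, 2, 3, 7, 8, 9, 4, 5, 6)
  g <- rep(1:3, each = 3)
  m <- toy_omic(cbind(v, v * 0 + 2), ids = paste0("S", 1:9),
                feats = c("hit", "flat"))
  res <- anova_tukey_de(m, g, q_threshold = 0.05)
  aov_f <- summary(aov(v ~ factor(g)))[[1]]$`F value`[1]
  expect_equal(res$statistic[res$feature_id == "hit"], aov_f,
               tolerance = 1e-10)
  # constant feature: F = 0, p = 1, never selected
  flat <- res[res$feature_id == "flat", ]
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_false(flat$selected)
  # Tukey p-values against stats::TukeyHSD on the balanced toy
  tk <- TukeyHSD(aov(v ~ factor(g)))$`factor(g)`
  got_pw <- attr(res, "pairwise")[["hit"]]
  expect_equal(sort(got_pw$p_adj), sort(unname(tk[, "p adj"])),
               tolerance = 1e-8)

  # shifted-cluster simulation: one cluster mean-shifted by 10 sd
  set.seed(33)
  n_per <- 20
  lab <- rep(1:5, each = n_per)
  x <- matrix(rnorm(100 * 30), 100, 30)
  x[lab == 3, 1] <- x[lab == 3, 1] + 10
  m <- toy_omic(x, "F4_protein", ids = sprintf("S%03d", 1:100))
  res <- anova_tukey_de(m, lab, q_threshold = 0.05)
  expect_true(res$selected[1])
  expect_lt(res$q[1], 1e-6)
  pw <- attr(res, "pairwise")[["f01"]]
  sig_pairs <- pw[pw$p_adj < 0.01, c("group1", "group2")]
  expect_equal(nrow(sig_pairs), 4)
  expect_true(all(sig_pairs$group1 == 3 | sig_pairs$group2 == 3))
})

test_that("anova_tukey_de controls type I error under the global null", {
  set.seed(34)
  x <- matrix(rnorm(100 * 2000), 100, 2000)
  m <- toy_omic(x, "F4_protein", ids = sprintf("S%03d", 1:100),
                feats = sprintf("f%04d", 1:2000))
  lab <- rep(1:5, each = 20)
  res <- anova_tukey_de(m, lab, q_threshold = 0.05)
  expect_lte(mean(res$selected), 0.05)
})

test_that("methylation_de filters, quantile-normalizes and ranks the shifted probe", {
  # QN needs a probe set wide enough that one shifted probe does not set
  # every sample's extreme quantile — use a few hundred probes, as in
  # down-sampled real arrays
  set.seed(35)
  n <- 50
  lab <- rep(1:5, each = 10)
  z <- matrix(rnorm(n * 200), n, 200)
  z[lab == 2, 1] <- z[lab == 2, 1] + 4
  beta <- plogis(z)
  beta <- cbind(beta, matrix(0.5 + rnorm(n * 3, sd = 0.01), n, 3))  # sd 0.01
  m <- toy_omic(beta, "F3_methylation", ids = sprintf("S%02d", 1:n),
                feats = sprintf("cg%03d", 1:203))
  res <- methylation_de(m, lab, sd_min = 0.2, q_threshold = 0.05)
  expect_false(any(sprintf("cg%03d", 201:203) %in% res$feature_id))
  expect_equal(res$feature_id[which.max(res$statistic)], "cg001")
  expect_true(res$selected[res$feature_id == "cg001"])

  # F for the top probe agrees with an OLS oracle on the transformed data
  xq <- t(limma::normalizeQuantiles(t(m$values[, res$feature_id])))
  xl <- log2(xq + 1e-3)
  ols_f <- summary(aov(xl[, "cg001"] ~ factor(lab)))[[1]]$`F value`[1]
  expect_equal(res$statistic[res$feature_id == "cg001"], ols_f,
               tolerance = 1e-8)

  # quantile normalization: every sample's sorted profile identical
  sorted <- apply(xq, 1, sort)
  expect_lt(max(sorted - rowMeans(sorted)), 1e-12)

  dull <- toy_omic(matrix(0.5 + rnorm(20, sd = 0.01), 5, 4),
                   "F3_methylation")
  expect_warning(res0 <- methylation_de(dull, c(1, 1, 2, 2, 2)), "sd filter")
  expect_equal(nrow(res0), 0)
})

test_that("fisher_enrichment matches hypergeometric enumeration exactly", {
  # oracle: two-sided p = sum of hypergeometric masses <= observed mass
  fisher_oracle <- function(a, b, c_, d) {
    m <- a + c_   # in-cluster total
    n <- b + d
    k <- a + b    # altered total
    lo <- max(0, k - n)
    hi <- min(k, m)
    probs <- dhyper(lo:hi, m, n, k)
    obs <- dhyper(a, m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  # the worked example: all 5 altered in-cluster, all 5 unaltered outside
  bin <- matrix(c(rep(1, 5), rep(0, 5)), 1, 10,
                dimnames = list("G1", paste0("S", 1:10)))
  lab <- rep(1:2, each = 5)
  res <- fisher_enrichment(bin, lab, adjust = FALSE)
  r1 <- res[res$cluster == 1, ]
  expect_equal(r1$p, 2 / 252, tolerance = 1e-10)
  expect_equal(r1$p, fisher_oracle(5, 0, 0, 5), tolerance = 1e-12)

  # identical rates in and out -> p = 1
  bin2 <- matrix(rep(c(1, 0), 5), 1, 10,
                 dimnames = list("G1", paste0("S", 1:10)))
  expect_equal(fisher_enrichment(bin2, lab, adjust = FALSE)$p, c(1, 1))

  # exhaustive agreement on all 2x2 tables with margins <= 12
  for (n in 2:12) {
    for (m in 1:(n - 1)) {       # in-cluster size
      for (k in 0:n) {           # altered total
        for (a in max(0, k - (n - m)):min(k, m)) {
          b <- k - a
          c_ <- m - a
          d <- n - m - b
          p_impl <- fisher.test(matrix(c(a, b, c_, d), 2, 2))$p.value
          expect_equal(p_impl, fisher_oracle(a, b, c_, d),
                       tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("BH q-values follow the step-up formula", {
  # hand-computed set: {0.01, 0.02, 0.03, 0.04}, m = 4 -> all 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  # monotonicity and q in [p, 1] on a random set, via fisher_enrichment
  set.seed(36)
  bin <- matrix(rbinom(20 * 30, 1, 0.3), 20, 30,
                dimnames = list(sprintf("G%02d", 1:20), sprintf("S%02d", 1:30)))
  lab <- rep(1:3, each = 10)
  res <- fisher_enrichment(bin, lab)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(res$q <= 1))
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
})

test_that("cnv_binarize applies the inclusive 0.3 boundary", {
  seg <- matrix(c(0.3,  0,    -0.3,
                  -0.5, 0.29, 1.2), 2, 3, byrow = TRUE,
                dimnames = list(c("c1", "c2"), c("A", "B", "C")))
  bin <- cnv_binarize(seg)
  expect_equal(unname(bin$gain["c1", ]), c(1, 0, 0))   # 0.3 inclusive
  expect_equal(unname(bin$loss["c1", ]), c(0, 0, 1))   # -0.3 inclusive
  expect_equal(unname(bin$gain["c2", ]), c(0, 0, 1))   # 1.2 gain, 0.29 not
  expect_equal(unname(bin$loss["c2", ]), c(1, 0, 0))   # -0.5 loss
  expect_equal(sum(bin$gain[, "B"] + bin$loss[, "B"]), 0)
})

test_that("cnv_enrichment flags designed alterations at raw p <= 0.01", {
  set.seed(37)
  lab <- rep(1:2, each = 30)
  seg <- matrix(rnorm(10 * 60, sd = 0.05), 10, 60,
                dimnames = list(sprintf("cyto%02d", 1:10),
                                sprintf("S%02d", 1:60)))
  seg[1, lab == 1] <- seg[1, lab == 1] + 0.5
  res <- cnv_enrichment(seg, lab)
  hit <- res$gain[res$gain$feature_id == "cyto01" & res$gain$cluster == 1, ]
  expect_true(hit$selected)
  expect_lte(hit$p, 0.01)
})
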