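sep_toy <- function(n_per = 30, k = 2, sep = 8, p = 5, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k) - 1, function(c_)
    matrix(rnorm(n_per * p, mean = c_ * sep), n_per, p)))
  list(x = x, y = rep(seq_len(k), each = n_per))
}

fast_specs <- function(seed) default_base_specs(seed, fast = TRUE)

test_that("split_train_test stratifies with at least one test per class", {
  d <- sep_toy(20, k = 5, seed = 2)
  sp <- split_train_test(d$x, d$y, 0.1, seed = 3)
  expect_length(sp$test, 10)                      # 2 per class at n = 100
  expect_equal(as.vector(table(d$y[sp$test])), rep(2L, 5))
  expect_equal(sort(c(sp$train, sp$test)), seq_along(d$y))
  expect_identical(split_train_test(d$x, d$y, 0.1, seed = 3), sp)
  expect_error(split_train_test(d$x, d$y, 0), "test_fraction")
  expect_error(split_train_test(matrix(0, 3, 2), c(1, 1, 2), 0.5),
               "at least 2 samples")
})

test_that("all three base learners separate an easy 2-class problem", {
  d <- sep_toy(30, sep = 8, seed = 4)
  for (kind in c("svm_rbf", "random_forest", "ffnn")) {
    spec <- fast_specs(5)[[switch(kind, svm_rbf = "svm_rbf",
                                  random_forest = "random_forest",
                                  ffnn = "ffnn")]]
    m <- train_base(d$x, d$y, spec)
    expect_equal(mean(predict(m, d$x) == d$y), 1.0)
    p <- predict_proba(m, d$x)
    expect_true(all(abs(rowSums(p) - 1) < 1e-9))
    expect_true(all(p >= 0))
    # same seed, same grid -> identical hyperparameter selection
    m2 <- train_base(d$x, d$y, spec)
    expect_identical(m$hyperparameters, m2$hyperparameters)
  }
  expect_error(train_base(d$x, rep(1, nrow(d$x)),
                          fast_specs(1)$svm_rbf), "2 classes")
})

test_that("linear_fuse computes the weighted simplex combination", {
  p_svm <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  p_rf <- rbind(c(0, 1), c(1, 0), c(0.5, 0.5))
  p_ffnn <- rbind(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.5))
  w <- fusion_weights(1 / 3, 1 / 3, 1 / 3)
  fused <- linear_fuse(p_svm, p_rf, p_ffnn, w)
  expect_equal(fused, matrix(0.5, 3, 2))
  # identity corner
  expect_identical(linear_fuse(p_svm, p_rf, p_ffnn, fusion_weights(1, 0, 0)),
                   p_svm)
  # invalid inputs
  expect_error(fusion_weights(0.5, 0.5, 0.5), "sum to 1")
  bad <- p_svm
  bad[1, 1] <- -0.2
  expect_error(linear_fuse(bad, p_rf, p_ffnn, fusion_weights(0.5, 0.5, 0)),
               "negative")
})

test_that("fused rows stay on the simplex for random stochastic inputs", {
  set.seed(6)
  for (i in 1:10) {
    p1 <- random_prob_matrix(12, 4)
    p2 <- random_prob_matrix(12, 4)
    p3 <- random_prob_matrix(12, 4)
    w <- rexp(3)
    w <- w / sum(w)
    fused <- linear_fuse(p1, p2, p3, fusion_weights(w[1], w[2], w[3]))
    expect_true(all(abs(rowSums(fused) - 1) < 1e-9))
    expect_true(all(fused >= -1e-12))
  }
})

test_that("weight grid enumeration matches stars-and-bars counts", {
  brute <- function(step) {
    m <- round(1 / step)
    cnt <- 0
    for (a in 0:m) for (b in 0:m) for (c_ in 0:m)
      if (a + b + c_ == m) cnt <- cnt + 1
    cnt
  }
  for (step in c(0.5, 0.25, 0.1, 0.05)) {
    grid <- enumerate_weight_grid(step)
    expect_equal(nrow(grid), brute(step))
    expect_true(all(abs(rowSums(grid) - 1) < 1e-12))
  }
  expect_equal(nrow(enumerate_weight_grid(0.05)), 231)
  expect_error(enumerate_weight_grid(0.3), "divide 1")
})

test_that("grid search lands on the perfect learner's corner and beats corners", {
  set.seed(7)
  y <- sample(1:3, 40, replace = TRUE)
  perfect <- matrix(0, 40, 3)
  perfect[cbind(1:40, y)] <- 1
  r1 <- random_prob_matrix(40, 3)
  r2 <- random_prob_matrix(40, 3)
  gs <- grid_search_weights(perfect, r1, r2, y, classes = 1:3)
  expect_equal(gs$accuracy, 1.0)
  expect_equal(unname(gs$weights[1]), 1)

  # selected accuracy >= every corner accuracy on random fixtures
  acc_of <- function(p) mean(max.col(p, "first") == y)
  for (i in 1:20) {
    p1 <- random_prob_matrix(40, 3)
    p2 <- random_prob_matrix(40, 3)
    p3 <- random_prob_matrix(40, 3)
    gs <- grid_search_weights(p1, p2, p3, y, classes = 1:3)
    expect_gte(gs$accuracy, max(acc_of(p1), acc_of(p2), acc_of(p3)))
  }
})

test_that("concat_probabilities builds the 3K-wide P_C in block order", {
  set.seed(8)
  p1 <- random_prob_matrix(6, 5)
  p2 <- random_prob_matrix(6, 5)
  p3 <- random_prob_matrix(6, 5)
  pc <- concat_probabilities(p1, p2, p3)
  expect_equal(dim(pc), c(6, 15))
  expect_equal(pc[, 1:5], p1)
  expect_equal(pc[, 6:10], p2)
  expect_equal(pc[, 11:15], p3)
  expect_true(all(abs(rowSums(pc[, 1:5]) - 1) < 1e-9))
  p_small <- random_prob_matrix(6, 3)
  expect_error(concat_probabilities(p1, p_small, p3), "not aligned")
})

test_that("stacked fusion works with and without the 60/40 holdout", {
  d <- sep_toy(25, k = 2, sep = 8, seed = 9)
  m_no <- train_stacked(d$x, d$y, "logistic_regression", holdout = FALSE,
                        specs = fast_specs(10), seed = 10)
  m_ho <- train_stacked(d$x, d$y, "logistic_regression", holdout = TRUE,
                        specs = fast_specs(10), seed = 10)
  expect_equal(predict(m_no, d$x)$labels, d$y)
  # with a perfect L0, holdout and no-holdout agree
  expect_equal(predict(m_ho, d$x)$labels, predict(m_no, d$x)$labels)
  # holdout partition sizes: L0 gets 60%
  n_l0 <- nrow(m_ho$l0_models$svm_rbf$model$x)
  expect_equal(n_l0, 30)
  # determinism
  m_no2 <- train_stacked(d$x, d$y, "logistic_regression", holdout = FALSE,
                         specs = fast_specs(10), seed = 10)
  expect_equal(predict(m_no2, d$x)$prob, predict(m_no, d$x)$prob)
})

test_that("feature_level_fuse concatenates blocks over shared samples", {
  a <- toy_omic(matrix(runif(12), 3, 4), ids = c("A", "B", "C"))
  b <- toy_omic(matrix(runif(9), 3, 3), "F4_protein", ids = c("B", "C", "D"))
  fused <- feature_level_fuse(list(a, b))
  expect_equal(dim(fused), c(2, 7))
  expect_equal(attr(fused, "block_widths"), c(4L, 3L))
  single <- feature_level_fuse(list(a))
  expect_equal(unname(single[, 1:4]), unname(a$values))
  bad <- toy_omic(matrix(runif(4), 2, 2), ids = c("X", "Y"))
  expect_error(feature_level_fuse(list(a, bad)), "shared samples")
  # fused widths are additive as in the reported classifier inputs
  expect_equal(719 + 153, 872)
  expect_equal(672 + 719, 1391)
})

test_that("evaluate_accuracy counts exact matches", {
  expect_equal(evaluate_accuracy(1:5, 1:5), 1.0)
  expect_equal(evaluate_accuracy(1:5, 6:10), 0.0)
  expect_equal(evaluate_accuracy(c(1:9, 99), 1:10), 0.9)
  expect_error(evaluate_accuracy(1:3, 1:4), "length mismatch")
})

test_that("predict_new routes by available omics and stored statistics", {
  d <- sep_toy(20, k = 2, sep = 8, p = 6, seed = 11)
  ids <- sprintf("S%02d", seq_len(nrow(d$x)))
  feats <- sprintf("cg%02d", 1:6)
  raw <- d$x + 10                                  # F4-like real values
  dimnames(raw) <- list(ids, feats)
  norm <- minmax_normalize(omic_matrix(raw, "F4_protein"))
  model <- train_fused(norm$values, d$y, mode = "linear",
                       specs = fast_specs(12), seed = 12)
  bundle <- list(list(
    name = "F4_only",
    schema = list(F4_protein = feats),
    stats = list(F4_protein = attr(norm, "minmax_stats")),
    model = model))
  res <- predict_new(bundle, list(F4_protein = omic_matrix(raw, "F4_protein")))
  expect_equal(res$variant, "F4_only")
  expect_equal(res$labels, d$y)                   # training samples re-fed
  # wrong omic kind -> explicit error listing schemas
  wrong <- omic_matrix(matrix(runif(12), 2, 6,
                              dimnames = list(c("N1", "N2"), feats)),
                       "F3_methylation")
  expect_error(predict_new(bundle, list(F3_methylation = wrong)),
               "no trained variant")
})
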