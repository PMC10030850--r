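#' Base learner specification
#'
#' Hyperparameter search spaces and cross-validation controls for the three
#' L0 learners. SVM and random-forest hyperparameters are chosen by
#' stratified k-fold CV (default 5-fold repeated 10 times) on mean accuracy;
#' the FFNN picks its learning rate from the stated grid
#' (0.1 ... 1e-5) by internal validation accuracy.
#'
#' @param kind `"svm_rbf"`, `"random_forest"`, or `"ffnn"`
#' @param grid data.frame of candidate hyperparameters (kind-specific
#'   defaults when `NULL`)
#' @param cv_folds,cv_repeats CV controls for SVM / RF
#' @param ffnn list of FFNN options (dropout 0.1, L2 activity 1e-4, L1
#'   weight 1e-5, learning-rate grid, epochs / patience / batch)
#' @param seed integer seed
#' @return a `base_learner_spec`
#' @export
base_learner_spec <- function(kind = c("svm_rbf", "random_forest", "ffnn"),
                              grid = NULL, cv_folds = 5L, cv_repeats = 10L,
                              ffnn = list(), seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(grid)) {
    grid <- switch(kind,
      svm_rbf = expand.grid(cost = c(0.1, 1, 10, 100),
                            gamma_mult = c(0.1, 1, 10)),
      random_forest = expand.grid(trees = c(200L, 500L),
                                  mtry = c("sqrt", "log2"),
                                  stringsAsFactors = FALSE),
      ffnn = data.frame(lr = c(0.1, 1e-2, 1e-3, 1e-4, 1e-5)))
  }
  stopifnot(nrow(grid) >= 1)
  ffnn <- modifyList(list(dropout = 0.1, l2_activity = 1e-4,
                          l1_weight = 1e-5, max_epochs = 100L,
                          patience = 5L, batch_size = 24L), ffnn)
  structure(list(kind = kind, grid = grid, cv_folds = as.integer(cv_folds),
                 cv_repeats = as.integer(cv_repeats), ffnn = ffnn,
                 seed = as.integer(seed)),
            class = "base_learner_spec")
}

#' Default base-learner specifications for the three L0 kinds
#'
#' `fast = TRUE` shrinks the hyperparameter grids and CV repeats for
#' budgeted runs (smoke tests, small cohorts); the full grids are the
#' package defaults.
#'
#' @param seed integer master seed (per-learner seeds are derived)
#' @param cv_repeats CV repeats for SVM / RF (default 10)
#' @param fast use reduced grids and 2 CV repeats
#' @return named list of [base_learner_spec()] objects
#' @export
default_base_specs <- function(seed = 1L, cv_repeats = 10L, fast = FALSE) {
  if (fast) {
    list(
      svm_rbf = base_learner_spec(
        "svm_rbf", grid = expand.grid(cost = c(1, 10), gamma_mult = c(0.1, 1)),
        cv_repeats = 2L, seed = derive_seed(seed, "svm")),
      random_forest = base_learner_spec(
        "random_forest",
        grid = expand.grid(trees = 100L, mtry = c("sqrt", "log2"),
                           stringsAsFactors = FALSE),
        cv_repeats = 2L, seed = derive_seed(seed, "rf")),
      ffnn = base_learner_spec(
        "ffnn", grid = data.frame(lr = c(1e-2, 1e-3)),
        seed = derive_seed(seed, "ffnn")))
  } else {
    list(
      svm_rbf = base_learner_spec("svm_rbf", cv_repeats = cv_repeats,
                                  seed = derive_seed(seed, "svm")),
      random_forest = base_learner_spec("random_forest",
                                        cv_repeats = cv_repeats,
                                        seed = derive_seed(seed, "rf")),
      ffnn = base_learner_spec("ffnn", seed = derive_seed(seed, "ffnn")))
  }
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (g in unique(y)) {
      idx <- sample(which(y == g))
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
    fold
  })
}

# ---- SVM with RBF kernel ---------------------------------------------------
# Primal kernel SVM: one column of dual coefficients per class (one-vs-rest),
# squared-hinge loss + RKHS-norm penalty, full-batch Adam from a zero start
# (deterministic). Probabilities by per-class Platt sigmoid, renormalized.

rbf_cross <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

svm_rbf_fit <- function(x, y, cost, gamma, iters = 300L, lr = 0.05) {
  classes <- sort(unique(y))
  C <- length(classes)
  n <- nrow(x)
  Y <- matrix(-1, n, C)
  for (j in seq_len(C)) Y[y == classes[j], j] <- 1
  K <- rbf_cross(x, x, gamma)
  A <- matrix(0, n, C)
  b <- numeric(C)
  mA <- vA <- A
  mb <- vb <- b
  for (t in seq_len(iters)) {
    f <- K %*% A
    f <- sweep(f, 2, b, "+")
    m <- pmax(0, 1 - Y * f)
    dF <- -2 * cost * Y * m
    gA <- K %*% (dF + A)
    gb <- colSums(dF)
    mA <- 0.9 * mA + 0.1 * gA
    vA <- 0.999 * vA + 0.001 * gA^2
    mb <- 0.9 * mb + 0.1 * gb
    vb <- 0.999 * vb + 0.001 * gb^2
    bc1 <- 1 - 0.9^t
    bc2 <- 1 - 0.999^t
    A <- A - lr * (mA / bc1) / (sqrt(vA / bc2) + 1e-8)
    b <- b - lr * (mb / bc1) / (sqrt(vb / bc2) + 1e-8)
  }
  f <- sweep(K %*% A, 2, b, "+")
  platt <- lapply(seq_len(C), function(j) {
    yb <- as.integer(Y[, j] > 0)
    fit <- tryCatch(
      suppressWarnings(glm(yb ~ f[, j], family = binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(coef(fit)))) c(0, 1) else coef(fit)
  })
  list(x = x, A = A, b = b, gamma = gamma, platt = platt, classes = classes)
}

svm_rbf_prob <- function(model, x) {
  Kn <- rbf_cross(x, model$x, model$gamma)
  f <- sweep(Kn %*% model$A, 2, model$b, "+")
  p <- vapply(seq_along(model$classes), function(j)
    plogis(model$platt[[j]][1] + model$platt[[j]][2] * f[, j]),
    numeric(nrow(x)))
  p <- matrix(p, nrow = nrow(x))
  rs <- rowSums(p)
  p[rs <= 0, ] <- 1 / ncol(p)
  rs[rs <= 0] <- 1
  p / rowSums(p)
}

# ---- learner-specific fit/predict dispatch ---------------------------------

fit_one <- function(kind, x, y, par, spec) {
  classes <- sort(unique(y))
  switch(kind,
    svm_rbf = {
      gamma0 <- 1 / (ncol(x) * max(mean(matrixStats::colVars(x)), 1e-8))
      svm_rbf_fit(x, y, cost = par$cost, gamma = gamma0 * par$gamma_mult)
    },
    random_forest = {
      mtry <- switch(par$mtry,
                     sqrt = max(1L, floor(sqrt(ncol(x)))),
                     log2 = max(1L, floor(log2(ncol(x)))))
      yi <- match(y, classes) - 1L
      forest <- with_seed(spec$seed,
        rf_fit_cpp(x, yi, length(classes), par$trees, mtry,
                   min_node = 5L, max_depth = 25L))
      list(forest = forest, classes = classes)
    },
    ffnn = {
      hidden <- min(256L, max(16L, ceiling(ncol(x) / 2)))
      Y <- matrix(0, nrow(x), length(classes))
      Y[cbind(seq_len(nrow(x)), match(y, classes))] <- 1
      o <- spec$ffnn
      fit <- mlp_train(x, Y, c(ncol(x), hidden, length(classes)),
                       loss = "ce", lr = par$lr,
                       max_epochs = o$max_epochs, patience = o$patience,
                       batch_size = o$batch_size, dropout = o$dropout,
                       l1_weight = o$l1_weight, l2_activity = o$l2_activity,
                       seed = spec$seed)
      list(fit = fit, classes = classes)
    })
}

prob_one <- function(kind, model, x) {
  p <- switch(kind,
    svm_rbf = svm_rbf_prob(model, x),
    random_forest = {
      pr <- rf_predict_cpp(model$forest, x, length(model$classes))
      rs <- rowSums(pr)
      pr[rs <= 0, ] <- 1 / ncol(pr)
      pr / pmax(rowSums(pr), 1e-12)
    },
    ffnn = mlp_forward(model$fit$params, x, "softmax"))
  colnames(p) <- as.character(model$classes %||% NULL)
  p
}

#' Train one base classifier
#'
#' Fits an L0 learner with hyperparameters chosen per the spec's rule:
#' stratified repeated-CV mean accuracy for SVM / random forest, internal
#' 80/20 validation accuracy over the learning-rate grid for the FFNN (then
#' refit on all training data). Ties go to the first grid row.
#'
#' @param x samples x features numeric matrix
#' @param y class labels (>= 2 classes)
#' @param spec a [base_learner_spec()]
#' @return a `base_learner`; use [predict_proba()] for class probabilities
#' @export
train_base <- function(x, y, spec) {
  stopifnot(inherits(spec, "base_learner_spec"))
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop_omics("non-finite features")
  if (length(unique(y)) < 2) stop_omics("need at least 2 classes")
  grid <- spec$grid
  if (nrow(grid) == 1L) {
    best <- 1L
  } else if (spec$kind == "ffnn") {
    fold <- stratified_folds(y, 5L, derive_seed(spec$seed, "ffnn_val"))
    hold <- fold == 1L
    acc <- vapply(seq_len(nrow(grid)), function(i) {
      fit <- tryCatch(
        fit_one("ffnn", x[!hold, , drop = FALSE], y[!hold],
                as.list(grid[i, , drop = FALSE]), spec),
        error = function(e) NULL)
      if (is.null(fit)) return(-Inf)
      p <- prob_one("ffnn", fit, x[hold, , drop = FALSE])
      mean(fit$classes[max.col(p, "first")] == y[hold])
    }, numeric(1))
    best <- which.max(acc)
  } else {
    scores <- matrix(NA_real_, nrow(grid), spec$cv_repeats * spec$cv_folds)
    col <- 0L
    for (r in seq_len(spec$cv_repeats)) {
      fold <- stratified_folds(y, spec$cv_folds,
                               derive_seed(spec$seed, paste0("cv", r)))
      for (f in seq_len(spec$cv_folds)) {
        col <- col + 1L
        hold <- fold == f
        if (length(unique(y[!hold])) < 2) next
        for (i in seq_len(nrow(grid))) {
          fit <- fit_one(spec$kind, x[!hold, , drop = FALSE], y[!hold],
                         as.list(grid[i, , drop = FALSE]), spec)
          p <- prob_one(spec$kind, fit, x[hold, , drop = FALSE])
          cls <- sort(unique(y[!hold]))
          scores[i, col] <- mean(cls[max.col(p, "first")] == y[hold])
        }
      }
    }
    best <- which.max(rowMeans(scores, na.rm = TRUE))
  }
  model <- fit_one(spec$kind, x, y, as.list(grid[best, , drop = FALSE]), spec)
  structure(list(kind = spec$kind, model = model,
                 classes = sort(unique(y)),
                 hyperparameters = grid[best, , drop = FALSE],
                 spec = spec),
            class = "base_learner")
}

#' Class probabilities from a base learner
#'
#' @param object a [train_base()] result
#' @param x new samples x features matrix (same feature space)
#' @return samples x classes row-stochastic matrix
#' @export
predict_proba <- function(object, x) {
  stopifnot(inherits(object, "base_learner"))
  prob_one(object$kind, object$model, as.matrix(x))
}

#' @export
predict.base_learner <- function(object, newdata, ...) {
  p <- predict_proba(object, newdata)
  object$classes[max.col(p, "first")]
}
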