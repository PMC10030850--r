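#' Stratified train/test split
#'
#' Splits samples by class so that every class contributes at least one test
#' sample; the stated regime is a 90/10 split.
#'
#' @param x samples x features matrix
#' @param y class labels (every class needs >= 2 samples)
#' @param test_fraction held-out proportion (in (0, 1))
#' @param seed integer seed
#' @return list with integer index vectors `train` and `test`
#' @export
split_train_test <- function(x, y, test_fraction = 0.1, seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_omics("test_fraction must lie in (0, 1)")
  if (any(table(y) < 2)) stop_omics("every class needs at least 2 samples")
  test <- with_seed(seed, {
    unlist(lapply(unique(y), function(g) {
      idx <- which(y == g)
      n_test <- max(1L, round(length(idx) * test_fraction))
      sample(idx, min(n_test, length(idx) - 1L))
    }))
  })
  test <- sort(test)
  list(train = setdiff(seq_len(nrow(as.matrix(x))), test), test = test)
}

#' Fusion weights on the probability simplex
#'
#' @param alpha,beta,gamma non-negative weights for the SVM, random-forest
#'   and FFNN probabilities; must sum to 1
#' @return a `fusion_weights` vector
#' @export
fusion_weights <- function(alpha, beta, gamma) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop_omics("weights must be non-negative and sum to 1")
  structure(w, class = "fusion_weights")
}

check_prob_matrix <- function(p, what) {
  p <- as.matrix(p)
  if (any(p < -1e-12)) stop_omics("%s has negative entries", what)
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop_omics("%s rows must sum to 1", what)
  p
}

#' Linear decision-level fusion
#'
#' Weighted elementwise sum of the three base-learner probability matrices:
#' `P_L = alpha P_SVM + beta P_RF + gamma P_FFNN`. Rows remain on the
#' simplex because the weights do.
#'
#' @param p_svm,p_rf,p_ffnn aligned samples x classes probability matrices
#' @param w a [fusion_weights()]
#' @return fused probability matrix (role P_L)
#' @export
linear_fuse <- function(p_svm, p_rf, p_ffnn, w) {
  if (!inherits(w, "fusion_weights")) w <- do.call(fusion_weights, as.list(w))
  p_svm <- check_prob_matrix(p_svm, "P_SVM")
  p_rf <- check_prob_matrix(p_rf, "P_RF")
  p_ffnn <- check_prob_matrix(p_ffnn, "P_FFNN")
  stopifnot(all(dim(p_svm) == dim(p_rf)), all(dim(p_rf) == dim(p_ffnn)))
  w[1] * p_svm + w[2] * p_rf + w[3] * p_ffnn
}

#' Enumerate the fusion weight grid
#'
#' All non-negative multiples of `step` summing to 1, in decreasing
#' lexicographic (alpha, beta, gamma) order — the corner (1, 0, 0) comes
#' first, so accuracy ties favor the SVM corner; step 0.05 yields 231
#' triples.
#'
#' @param step grid step; `1/step` must be an integer
#' @return matrix with columns alpha, beta, gamma
#' @export
enumerate_weight_grid <- function(step = 0.05) {
  m <- round(1 / step)
  if (abs(m * step - 1) > 1e-9) stop_omics("step must divide 1 evenly")
  rows <- list()
  for (a in m:0) for (b in (m - a):0) {
    rows[[length(rows) + 1L]] <- c(a, b, m - a - b) / m
  }
  grid <- do.call(rbind, rows)
  colnames(grid) <- c("alpha", "beta", "gamma")
  grid
}

#' Grid search for fusion weights
#'
#' Evaluates every triple on the weight grid by accuracy of the fused
#' argmax prediction against `y`; ties go to the first triple in
#' lexicographic (alpha, beta, gamma) order. Because the grid contains the
#' corners, the selected accuracy is never below any single learner's.
#'
#' @param p_svm,p_rf,p_ffnn aligned probability matrices
#' @param y true labels (values matching the probability column order)
#' @param step grid step (default 0.05)
#' @param classes class labels in column order (defaults to `sort(unique(y))`)
#' @return list with `weights` ([fusion_weights()]) and `accuracy`
#' @export
grid_search_weights <- function(p_svm, p_rf, p_ffnn, y, step = 0.05,
                                classes = NULL) {
  grid <- enumerate_weight_grid(step)
  classes <- classes %||% sort(unique(y))
  best_acc <- -1
  best_w <- NULL
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, 1] * p_svm + grid[i, 2] * p_rf + grid[i, 3] * p_ffnn
    acc <- mean(classes[max.col(p, "first")] == y)
    if (acc > best_acc) {
      best_acc <- acc
      best_w <- grid[i, ]
    }
  }
  list(weights = fusion_weights(best_w[1], best_w[2], best_w[3]),
       accuracy = best_acc)
}

#' Concatenate base-learner probabilities (P_C)
#'
#' Column-binds the three probability matrices in (SVM, RF, FFNN) block
#' order: the meta-feature representation for stacked fusion.
#'
#' @param p_svm,p_rf,p_ffnn aligned samples x K probability matrices
#' @return samples x 3K matrix
#' @export
concat_probabilities <- function(p_svm, p_rf, p_ffnn) {
  p_svm <- check_prob_matrix(p_svm, "P_SVM")
  p_rf <- check_prob_matrix(p_rf, "P_RF")
  p_ffnn <- check_prob_matrix(p_ffnn, "P_FFNN")
  if (!all(dim(p_svm) == dim(p_rf)) || !all(dim(p_rf) == dim(p_ffnn)))
    stop_omics("probability matrices are not aligned")
  cbind(p_svm, p_rf, p_ffnn)
}

# Meta-learner on P_C: multinomial logistic regression is a zero-hidden-layer
# softmax network; the FFNN variant adds one small hidden layer.
train_meta <- function(p_c, y, learner = c("logistic_regression", "ffnn"),
                       seed = 1L) {
  learner <- match.arg(learner)
  classes <- sort(unique(y))
  Y <- matrix(0, nrow(p_c), length(classes))
  Y[cbind(seq_len(nrow(p_c)), match(y, classes))] <- 1
  widths <- if (learner == "logistic_regression") {
    c(ncol(p_c), length(classes))
  } else {
    c(ncol(p_c), max(16L, ncol(p_c)), length(classes))
  }
  fit <- mlp_train(p_c, Y, widths, loss = "ce", lr = 1e-2,
                   max_epochs = 200L, patience = 20L, batch_size = 24L,
                   seed = seed)
  list(fit = fit, classes = classes, learner = learner)
}

#' Train a decision-level fused model
#'
#' Trains the three L0 learners and an L1 fusion on top of their class
#' probabilities. `mode = "linear"` selects Eq.-style simplex weights by
#' grid search; `"stacked_lr"` / `"stacked_ffnn"` train a meta-learner on
#' the concatenated probabilities P_C. Without holdout, L0 and L1 both use
#' the full training set; with holdout, L0 uses a stratified 60% and L1 the
#' probabilities L0 assigns to the remaining 40%.
#'
#' @param x samples x features training matrix
#' @param y training labels
#' @param mode `"linear"`, `"stacked_lr"`, or `"stacked_ffnn"`
#' @param holdout use the 60/40 L0/L1 partition (stacked modes)
#' @param specs named list of [base_learner_spec()] for `svm_rbf`,
#'   `random_forest`, `ffnn` (defaults built from `seed`)
#' @param step weight grid step for linear mode
#' @param seed integer seed
#' @return a `fused_model`
#' @export
train_fused <- function(x, y, mode = c("linear", "stacked_lr", "stacked_ffnn"),
                        holdout = FALSE, specs = NULL, step = 0.05,
                        seed = 1L) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  specs <- specs %||% default_base_specs(seed)
  if (holdout && mode == "linear")
    stop_omics("holdout applies to stacked modes")
  if (holdout) {
    sp <- split_train_test(x, y, 0.4, derive_seed(seed, "holdout"))
    if (length(unique(y[sp$train])) != length(unique(y)) ||
        length(unique(y[sp$test])) != length(unique(y)))
      stop_omics("a class is missing from a holdout partition")
    l0_idx <- sp$train
    l1_idx <- sp$test
  } else {
    l0_idx <- l1_idx <- seq_len(nrow(x))
  }
  l0 <- lapply(specs, function(s)
    train_base(x[l0_idx, , drop = FALSE], y[l0_idx], s))
  probs <- lapply(l0, predict_proba, x = x[l1_idx, , drop = FALSE])
  y1 <- y[l1_idx]
  classes <- l0[[1]]$classes
  fused <- if (mode == "linear") {
    gs <- grid_search_weights(probs$svm_rbf, probs$random_forest,
                              probs$ffnn, y1, step = step,
                              classes = classes)
    list(weights = gs$weights, selection_accuracy = gs$accuracy)
  } else {
    p_c <- concat_probabilities(probs$svm_rbf, probs$random_forest,
                                probs$ffnn)
    meta <- train_meta(p_c, y1,
                       if (mode == "stacked_lr") "logistic_regression"
                       else "ffnn",
                       seed = derive_seed(seed, "meta"))
    list(meta = meta)
  }
  structure(c(list(mode = mode, holdout = holdout, l0_models = l0,
                   classes = classes,
                   feature_ids = colnames(x)), fused),
            class = "fused_model")
}

#' Train a stacked (non-linear decision-level fused) model
#'
#' Convenience surface over [train_fused()] for the stacked modes: an L1
#' logistic-regression or FFNN meta-learner trained on the concatenated L0
#' probabilities, with or without the 60/40 L0/L1 holdout.
#'
#' @param x,y training matrix and labels
#' @param learner `"logistic_regression"` or `"ffnn"`
#' @param holdout use the 60/40 partition
#' @param specs,seed see [train_fused()]
#' @return a `fused_model`
#' @export
train_stacked <- function(x, y,
                          learner = c("logistic_regression", "ffnn"),
                          holdout = FALSE, specs = NULL, seed = 1L) {
  learner <- match.arg(learner)
  train_fused(x, y,
              mode = if (learner == "logistic_regression") "stacked_lr"
                     else "stacked_ffnn",
              holdout = holdout, specs = specs, seed = seed)
}

#' Predict with a fused model
#'
#' Runs the L0 learners on the new samples and combines their probabilities
#' with the trained fusion (weighted sum or meta-learner). Ties at the
#' argmax resolve to the lowest class index.
#'
#' @param object a [train_fused()] result
#' @param newdata samples x features matrix in the training feature space
#' @param ... unused
#' @return list with `labels` and `prob`
#' @export
predict.fused_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$feature_ids) && !is.null(colnames(x))) {
    if (!identical(colnames(x), object$feature_ids)) {
      missing <- setdiff(object$feature_ids, colnames(x))
      if (length(missing))
        stop_omics("schema mismatch; missing features: %s",
                   paste(head(missing, 5), collapse = ", "))
      x <- x[, object$feature_ids, drop = FALSE]
    }
  }
  probs <- lapply(object$l0_models, predict_proba, x = x)
  p <- if (object$mode == "linear") {
    linear_fuse(probs$svm_rbf, probs$random_forest, probs$ffnn,
                object$weights)
  } else {
    p_c <- concat_probabilities(probs$svm_rbf, probs$random_forest,
                                probs$ffnn)
    mlp_forward(object$meta$fit$params, p_c, "softmax")
  }
  list(labels = object$classes[max.col(p, "first")], prob = p)
}

#' Feature-level fusion
#'
#' Column-wise concatenation of per-omic feature blocks over shared samples
#' (the classifier-side analogue of [stack_omics()], applied to the selected
#' feature sets).
#'
#' @param blocks list of [omic_matrix()] objects or plain matrices
#' @return matrix over the sample intersection with a `block_widths`
#'   attribute
#' @export
feature_level_fuse <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  mats <- lapply(blocks, function(b)
    if (inherits(b, "omic_matrix")) b$values else as.matrix(b))
  common <- Reduce(intersect, lapply(mats, rownames))
  if (length(common) == 0) stop_omics("no shared samples across blocks")
  out <- do.call(cbind, lapply(mats, function(m) m[common, , drop = FALSE]))
  attr(out, "block_widths") <- vapply(mats, ncol, integer(1))
  out
}

#' Classification accuracy
#'
#' @param pred,truth equal-length label vectors
#' @return fraction of exact matches
#' @export
evaluate_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop_omics("length mismatch")
  mean(pred == truth)
}

#' Predict subgroups for new, possibly single-omic, samples
#'
#' A model bundle is a list of trained variants, each declaring the omic
#' kinds and per-kind feature schema it needs (plus stored min-max
#' statistics to replay training-time scaling). The first variant whose
#' schema is covered by the provided omics is applied — so a
#' methylation-only sample routes to the F3-trained variant while the
#' multi-omics variant is skipped.
#'
#' @param bundle list of variants, each a list with `name`, `schema` (named
#'   list: kind -> feature ids), `stats` (named list: kind -> min-max stats
#'   or NULL), `model` (a `fused_model`)
#' @param omics named list of [omic_matrix()] objects keyed by kind
#' @return list with `variant`, `labels`, `prob`
#' @export
predict_new <- function(bundle, omics) {
  kinds_have <- names(omics)
  for (variant in bundle) {
    need <- names(variant$schema)
    if (!all(need %in% kinds_have)) next
    ok <- all(vapply(need, function(k)
      all(variant$schema[[k]] %in% feature_ids(omics[[k]])), logical(1)))
    if (!ok) next
    blocks <- lapply(need, function(k) {
      m <- omics[[k]]
      vals <- m$values[, variant$schema[[k]], drop = FALSE]
      if (anyNA(vals)) {
        m2 <- knn_impute(omic_matrix(m$values, m$kind), 5L)
        vals <- m2$values[, variant$schema[[k]], drop = FALSE]
      }
      st <- variant$stats[[k]]
      if (!is.null(st)) {
        mm <- minmax_normalize(omic_matrix(vals, m$kind), stats = st)
        vals <- mm$values
      }
      vals
    })
    x <- do.call(cbind, blocks)
    colnames(x) <- variant$model$feature_ids
    pred <- predict(variant$model, x)
    return(list(variant = variant$name, labels = pred$labels,
                prob = pred$prob))
  }
  schemas <- vapply(bundle, function(v)
    paste(names(v$schema), collapse = "+"), character(1))
  stop_omics("no trained variant matches the provided omics; trained: %s",
             paste(schemas, collapse = ", "))
}
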