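#' Autoencoder architecture
#'
#' Under-complete symmetric autoencoder: encoder hidden widths, a bottleneck,
#' and a mirrored decoder. The default is the pipeline's selected
#' architecture (2000, 1000, 500 hidden nodes, 100-node bottleneck).
#'
#' @param encoder_widths hidden-layer widths, outermost first
#' @param latent_width bottleneck width; must stay below the input width
#' @return an `ae_architecture`
#' @export
ae_architecture <- function(encoder_widths = c(2000L, 1000L, 500L),
                            latent_width = 100L) {
  stopifnot(all(encoder_widths >= 1), latent_width >= 1)
  structure(list(encoder_widths = as.integer(encoder_widths),
                 latent_width = as.integer(latent_width)),
            class = "ae_architecture")
}

#' Autoencoder training configuration
#'
#' Defaults match the stated training regime: at most 100 epochs, early
#' stopping after 5 epochs without validation improvement, minibatches of 24,
#' a 90/10 train-validation split, ReLU activations, MSE loss, Adam. The
#' learning rate is not pinned by the source method; 1e-3 is the recorded
#' default.
#'
#' @param max_epochs,patience,batch_size,val_fraction,learning_rate,seed
#'   training controls
#' @return an `ae_train_config`
#' @export
ae_train_config <- function(max_epochs = 100L, patience = 5L,
                            batch_size = 24L, val_fraction = 0.10,
                            learning_rate = 1e-3, seed = 1L) {
  stopifnot(patience < max_epochs, val_fraction > 0, val_fraction < 1,
            batch_size >= 1, learning_rate > 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction,
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "ae_train_config")
}

#' Split samples into training and validation rows
#'
#' Validation size is `round(n * val_fraction)`, floored at 1; the partition
#' is disjoint, exhaustive, and reproducible under the seed.
#'
#' @param stack a [stack_omics()] result (or any matrix-bearing object)
#' @param val_fraction validation proportion
#' @param seed integer seed
#' @return list with integer vectors `train` and `val`
#' @export
split_train_val <- function(stack, val_fraction = 0.10, seed = 1L) {
  n <- nrow(if (inherits(stack, "multi_omics_stack")) stack$values else stack)
  if (n < 2) stop_omics("need at least 2 samples to split")
  n_val <- max(1L, round(n * val_fraction))
  if (n_val >= n) n_val <- n - 1L
  val <- with_seed(seed, sort(sample.int(n, n_val)))
  list(train = setdiff(seq_len(n), val), val = val)
}

#' Train the under-complete autoencoder
#'
#' Trains encoder + mirrored decoder on the multi-omics stack with MSE
#' reconstruction loss and early stopping on validation loss; the weights of
#' the best validation epoch are restored.
#'
#' @param stack a [stack_omics()] result
#' @param arch an [ae_architecture()]
#' @param cfg an [ae_train_config()]
#' @return a `trained_encoder` with `loss_history` (per-epoch train/val MSE)
#' @export
train_autoencoder <- function(stack, arch = ae_architecture(),
                              cfg = ae_train_config()) {
  stopifnot(inherits(stack, "multi_omics_stack"),
            inherits(arch, "ae_architecture"),
            inherits(cfg, "ae_train_config"))
  x <- stack$values
  if (anyNA(x)) stop_omics("stack contains missing values")
  p <- ncol(x)
  if (arch$latent_width >= p)
    stop_omics("latent width %d is not under-complete for %d inputs",
               arch$latent_width, p)
  widths <- c(p, arch$encoder_widths, arch$latent_width,
              rev(arch$encoder_widths), p)
  sp <- split_train_val(stack, cfg$val_fraction, derive_seed(cfg$seed, "split"))
  fit <- mlp_train(x[sp$train, , drop = FALSE], x[sp$train, , drop = FALSE],
                   widths, loss = "mse", lr = cfg$learning_rate,
                   max_epochs = cfg$max_epochs, patience = cfg$patience,
                   batch_size = cfg$batch_size,
                   x_val = x[sp$val, , drop = FALSE],
                   y_val = x[sp$val, , drop = FALSE],
                   seed = derive_seed(cfg$seed, "train"))
  structure(list(architecture = arch,
                 params = fit$params,
                 n_encoder_layers = length(arch$encoder_widths) + 1L,
                 loss_history = fit$loss_history,
                 best_epoch = fit$best_epoch,
                 input_feature_ids = colnames(x)),
            class = "trained_encoder")
}

#' Pick the architecture with the smallest train/validation loss gap
#'
#' Given candidate architectures and their loss histories, returns the one
#' minimizing the absolute difference between final training and validation
#' loss; ties go to the first listed.
#'
#' @param candidates list of lists with elements `arch` and `loss_history`
#' @return the selected `ae_architecture`
#' @export
select_architecture <- function(candidates) {
  if (length(candidates) == 0) stop_omics("no candidate architectures")
  gaps <- vapply(candidates, function(cand) {
    h <- cand$loss_history
    if (nrow(h) == 0) stop_omics("empty loss history")
    abs(h$train[nrow(h)] - h$val[nrow(h)])
  }, numeric(1))
  candidates[[which.min(gaps)]]$arch
}

#' Encode samples into the bottleneck representation
#'
#' @param enc a [train_autoencoder()] result
#' @param stack a stack whose columns match the encoder's training features
#' @return samples x latent_width matrix (F_AE)
#' @export
encode <- function(enc, stack) {
  stopifnot(inherits(enc, "trained_encoder"))
  x <- if (inherits(stack, "multi_omics_stack")) stack$values else stack
  if (!identical(colnames(x), enc$input_feature_ids)) {
    bad <- c(setdiff(colnames(x), enc$input_feature_ids),
             setdiff(enc$input_feature_ids, colnames(x)))
    stop_omics("feature mismatch with trained encoder: %s",
               paste(head(bad, 5), collapse = ", "))
  }
  a <- x
  for (l in seq_len(enc$n_encoder_layers)) {
    z <- sweep(a %*% enc$params[[l]]$W, 2, enc$params[[l]]$b, "+")
    a <- relu(z)
  }
  rownames(a) <- rownames(x)
  colnames(a) <- paste0("L", seq_len(ncol(a)))
  a
}

#' PCA baseline reduction
#'
#' Standardizes each feature (zero-variance features become all-zero) and
#' returns the top principal-component scores, ordered by decreasing
#' explained variance.
#'
#' @param stack a [stack_omics()] result or plain matrix
#' @param n_components number of components
#' @return samples x n_components score matrix
#' @export
pca_reduce <- function(stack, n_components = 100L) {
  x <- if (inherits(stack, "multi_omics_stack")) stack$values else stack
  if (n_components > min(nrow(x) - 1L, ncol(x)))
    stop_omics("n_components exceeds min(n - 1, p)")
  sds <- matrixStats::colSds(x)
  mus <- colMeans(x)
  z <- sweep(x, 2, mus, "-")
  z <- sweep(z, 2, ifelse(sds > 0, sds, 1), "/")
  z[, sds == 0] <- 0
  pc <- prcomp(z, center = FALSE, scale. = FALSE, rank. = n_components)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- rownames(x)
  scores
}
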