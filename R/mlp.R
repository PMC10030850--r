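# Dense feed-forward network core: ReLU hidden layers, linear or softmax
# output, MSE or cross-entropy loss, Adam updates, inverted dropout, L1
# weight / L2 activity penalties. Shared by the autoencoder and the FFNN
# base/meta learners. Pure matrix ops so BLAS does the work.

relu <- function(z) z * (z > 0)

softmax_rows <- function(z) {
  z <- z - matrixStats::rowMaxs(z)
  e <- exp(z)
  e / rowSums(e)
}

mlp_init <- function(widths) {
  # uniform fan-in initialization: U(-sqrt(6 / fan_in), +sqrt(6 / fan_in))
  lapply(seq_len(length(widths) - 1L), function(l) {
    fan_in <- widths[l]
    s <- sqrt(6 / fan_in)
    list(W = matrix(runif(fan_in * widths[l + 1L], -s, s),
                    fan_in, widths[l + 1L]),
         b = numeric(widths[l + 1L]))
  })
}

mlp_forward <- function(params, x, out_activation = "linear",
                        dropout = 0, training = FALSE, keep_hidden = FALSE) {
  L <- length(params)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- x
  masks <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    z <- a %*% params[[l]]$W
    z <- sweep(z, 2, params[[l]]$b, "+")
    if (l < L) {
      a <- relu(z)
      if (training && dropout > 0) {
        mask <- matrix(runif(length(a)) >= dropout, nrow(a), ncol(a))
        a <- a * mask / (1 - dropout)
        masks[[l]] <- mask
      }
    } else {
      a <- if (out_activation == "softmax") softmax_rows(z) else z
    }
    acts[[l + 1L]] <- a
  }
  if (keep_hidden) list(out = a, acts = acts, masks = masks) else a
}

mlp_loss <- function(out, y, loss) {
  if (loss == "mse") mean((out - y)^2)
  else -mean(rowSums(y * log(pmax(out, 1e-12))))
}

mlp_backward <- function(params, fwd, y, loss, dropout = 0,
                         l1_weight = 0, l2_activity = 0) {
  L <- length(params)
  acts <- fwd$acts
  n <- nrow(y)
  out <- acts[[L + 1L]]
  # both (softmax, cross-entropy) and (linear, mse) reduce to out - y at z
  delta <- if (loss == "mse") 2 * (out - y) / (n * ncol(y)) else (out - y) / n
  grads <- vector("list", L)
  for (l in L:1) {
    a_prev <- acts[[l]]
    gW <- crossprod(a_prev, delta)
    if (l1_weight > 0) gW <- gW + l1_weight * sign(params[[l]]$W)
    grads[[l]] <- list(W = gW, b = colSums(delta))
    if (l > 1) {
      da <- delta %*% t(params[[l]]$W)
      a_hid <- acts[[l]]
      if (l2_activity > 0) da <- da + 2 * l2_activity * a_hid / n
      if (dropout > 0 && !is.null(fwd$masks[[l - 1L]]))
        da <- da * fwd$masks[[l - 1L]] / (1 - dropout)
      delta <- da * (a_hid > 0)
    }
  }
  grads
}

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)),
       v = lapply(params, function(p) list(W = p$W * 0, b = p$b * 0)))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(params)) {
    for (nm in c("W", "b")) {
      g <- grads[[l]][[nm]]
      state$m[[l]][[nm]] <- beta1 * state$m[[l]][[nm]] + (1 - beta1) * g
      state$v[[l]][[nm]] <- beta2 * state$v[[l]][[nm]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[nm]] / bc1
      vhat <- state$v[[l]][[nm]] / bc2
      params[[l]][[nm]] <- params[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

# Early-stopping rule: given the per-epoch validation losses seen so far,
# training stops after the first epoch at which the loss has failed to
# strictly improve on the running best for `patience` consecutive epochs.
# Returns the stopping epoch (length(val_losses) if never triggered).
early_stop_epoch <- function(val_losses, patience) {
  best <- Inf
  bad <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) return(e)
    }
  }
  length(val_losses)
}

# Generic training loop with early stopping on validation loss. x_val/y_val
# may be NULL, in which case early stopping monitors training loss.
mlp_train <- function(x, y, widths, loss = c("mse", "ce"),
                      out_activation = NULL, lr = 1e-3,
                      max_epochs = 100L, patience = 5L, batch_size = 24L,
                      dropout = 0, l1_weight = 0, l2_activity = 0,
                      x_val = NULL, y_val = NULL, seed = 1L) {
  loss <- match.arg(loss)
  if (is.null(out_activation))
    out_activation <- if (loss == "ce") "softmax" else "linear"
  stopifnot(widths[1] == ncol(x), widths[length(widths)] == ncol(y))
  with_seed(seed, {
    params <- mlp_init(widths)
    state <- adam_init(params)
    n <- nrow(x)
    best <- list(val = Inf, params = params, epoch = 0L)
    bad <- 0L
    hist <- data.frame(epoch = integer(), train = numeric(), val = numeric())
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        fwd <- mlp_forward(params, x[idx, , drop = FALSE], out_activation,
                           dropout = dropout, training = TRUE,
                           keep_hidden = TRUE)
        grads <- mlp_backward(params, fwd, y[idx, , drop = FALSE], loss,
                              dropout = dropout, l1_weight = l1_weight,
                              l2_activity = l2_activity)
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
      }
      tr_loss <- mlp_loss(mlp_forward(params, x, out_activation), y, loss)
      va_loss <- if (is.null(x_val)) tr_loss else
        mlp_loss(mlp_forward(params, x_val, out_activation), y_val, loss)
      if (!is.finite(tr_loss) || !is.finite(va_loss))
        stop_omics("non-finite loss at epoch %d (learning rate too high?)",
                   epoch)
      hist <- rbind(hist, data.frame(epoch = epoch, train = tr_loss,
                                     val = va_loss))
      if (va_loss < best$val) {
        best <- list(val = va_loss, params = params, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) break
      }
    }
    list(params = best$params, loss_history = hist, best_epoch = best$epoch,
         widths = widths, out_activation = out_activation)
  })
}
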