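# AdamW training loop with seeded batching, an internal validation split for
# early stopping, and best-parameter restoration. Everything is driven by
# base-R RNG, so a fixed seed gives bit-identical runs on a fixed platform.

.adamw_init <- function(net) {
  # moments are mutated in place by the C++ step: m and v must not alias
  for (l in net$prims) {
    l$opt_m <- lapply(l$par, function(p) array(0, dim = dim(p) %||% length(p)))
    l$opt_v <- lapply(l$par, function(p) array(0, dim = dim(p) %||% length(p)))
  }
  invisible(net)
}

# One optimizer step over every parameter, in place (C++). `lam` carries the
# loss-side L2 gradient for weight parameters (Eq.-style penalty in the
# loss); `wd` is AdamW's decoupled decay (0 by default).
.adamw_step <- function(net, lr, lam, wd, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  b1t <- 1 - beta1^t; b2t <- 1 - beta2^t
  for (l in net$prims) {
    for (nm in names(l$par)) {
      is_w <- nm %in% l$decay
      adamw_update_cpp(l$par[[nm]], l$grad[[nm]],
                       l$opt_m[[nm]], l$opt_v[[nm]],
                       lr, if (is_w) lam else 0, if (is_w) wd else 0,
                       beta1, beta2, eps, b1t, b2t)
    }
  }
}

# checkpoints carry the parameters AND the batch-norm running buffers --
# restoring weights without their matching statistics breaks inference.
# Parameters are updated in place by the C++ optimizer, so snapshots (and
# restores) take explicit copies.
.copy_arrays <- function(lst) lapply(lst, function(p) p * 1)

.snapshot_params <- function(net) {
  lapply(net$prims, function(l) {
    s <- list(par = .copy_arrays(l$par))
    if (inherits(l, "batchnorm"))
      s$buf <- list(run_mean = l$run_mean, run_var = l$run_var)
    s
  })
}

.restore_params <- function(net, snap) {
  for (i in seq_along(net$prims)) {
    l <- net$prims[[i]]
    l$par <- .copy_arrays(snap[[i]]$par)
    if (!is.null(snap[[i]]$buf)) {
      l$run_mean <- snap[[i]]$buf$run_mean
      l$run_var <- snap[[i]]$buf$run_var
    }
  }
  invisible(net)
}

#' Train a spectral network
#'
#' Minimises [net_loss()] (MSE + lambda * ||w||^2) with AdamW at the
#' configured learning rate and batch size. A seeded internal validation
#' split (`val_fraction` of the calibration rows) drives early stopping: when
#' the validation MSE has not improved for `patience` epochs training stops
#' and the best-validation parameters are restored. Inputs are expected
#' already normalised (see [minmax_fit()]).
#'
#' @param network a `SpectralNet` from [build_network()], or `NULL` to build
#'   one from `config`.
#' @param calibration a `SpectraSet` (normalised absorbance).
#' @param config a [net_config()]; defaults to `network$config`.
#' @return object of class `TrainedNet`: fields `config`, `net`, `history`
#'   (data.frame epoch/train_loss/val_loss), `best_epoch`.
#' @export
train_net <- function(network, calibration, config = network$config) {
  if (is.null(network)) network <- build_network(config)
  stopifnot(inherits(network, "SpectralNet"), inherits(calibration, "SpectraSet"))
  X <- calibration$absorbance
  y <- calibration$target
  n <- nrow(X)
  set.seed(config$seed + 1L)
  .adamw_init(network)
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xtr3 <- array(Xtr, c(nrow(Xtr), 1L, ncol(X)))
  Xv <- array(X[val_idx, , drop = FALSE],
              c(n_val, 1L, ncol(X)))
  yv <- y[val_idx]
  lam <- config$l2_lambda
  best <- list(val = Inf, snap = .snapshot_params(network), epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), lr = numeric(0))
  t_step <- 0L
  lr <- config$learning_rate
  lr_factor <- config$lr_factor %||% 1
  lr_patience <- config$lr_patience %||% 20L
  min_lr <- config$min_lr %||% 1e-5
  last_drop <- 0L
  val_every <- config$val_every %||% 2L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(tr_idx))
    nb <- ceiling(length(ord) / config$batch_size)
    ep_loss <- 0; ep_n <- 0L
    for (b in seq_len(nb)) {
      rows <- ord[((b - 1L) * config$batch_size + 1L):
                    min(b * config$batch_size, length(ord))]
      if (length(rows) < 2L) next               # BN needs batch statistics
      xb <- array(Xtr[rows, , drop = FALSE], c(length(rows), 1L, ncol(X)))
      yb <- ytr[rows]
      for (l in network$prims) .zero_grads(l)
      pred <- net_forward(network, xb, train = TRUE)
      if (any(!is.finite(pred)))
        stop("non-finite activations at epoch ", epoch, ", batch ", b)
      lv <- net_loss(pred, yb)
      if (!is.finite(lv))
        stop("non-finite loss at epoch ", epoch, ", batch ", b)
      net_backward(network, 2 * (pred - yb) / length(yb))
      t_step <- t_step + 1L
      .adamw_step(network, lr, lam, config$weight_decay, t_step)
      ep_loss <- ep_loss + lv * length(rows); ep_n <- ep_n + length(rows)
    }
    # evaluate every `val_every` epochs: recalibrate the batch-norm running
    # buffers with population statistics of the training set (EMA buffers
    # at batch 32 are noisy, especially for the wide flatten layer, and a
    # noisy validation signal corrupts early stopping), then score the
    # validation split in inference mode
    if (epoch %% val_every == 0L || epoch == config$max_epochs) {
      invisible(net_forward(network, Xtr3, train = "stats"))
      val_pred <- net_forward(network, Xv, train = FALSE)
      val_mse <- mean((yv - val_pred)^2)
      # history reports the full Eq.-style loss: epoch-mean MSE + L2 at the
      # epoch-end weights
      pen <- if (lam > 0) lam * .net_l2(network) else 0
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = ep_loss / max(ep_n, 1L) + pen,
                                     val_loss = val_mse, lr = lr))
      if (val_mse < best$val - 1e-12) {
        best <- list(val = val_mse, snap = .snapshot_params(network),
                     epoch = epoch)
      } else if (epoch - best$epoch >= config$patience) {
        break
      }
      # reduce-on-plateau learning-rate schedule
      if (lr_factor < 1 && lr > min_lr &&
          epoch - max(best$epoch, last_drop) >= lr_patience) {
        lr <- max(lr * lr_factor, min_lr)
        last_drop <- epoch
      }
    }
  }
  .restore_params(network, best$snap)
  structure(list(config = config, net = network, history = hist,
                 best_epoch = best$epoch),
            class = "TrainedNet")
}

#' Predict with a trained network
#'
#' Deterministic inference: dropout disabled, batch norm using running
#' statistics. Repeated calls give identical outputs.
#'
#' @param model a `TrainedNet`.
#' @param data a `SpectraSet` normalised with the calibration-fitted
#'   transform, or a numeric matrix.
#' @return numeric vector, one predicted mass fraction per row (unclipped).
#' @export
predict_net <- function(model, data) {
  stopifnot(inherits(model, "TrainedNet"))
  X <- .as_matrix(data)
  if (ncol(X) != model$config$input_length)
    stop("data has ", ncol(X), " variables; network expects ",
         model$config$input_length)
  preds <- net_forward(model$net, X, train = FALSE)
  as.numeric(preds)
}

#' @export
print.TrainedNet <- function(x, ...) {
  cat(sprintf("TrainedNet [%s/%s]: %d parameters, best epoch %d (val MSE %.4g)\n",
              x$config$architecture, x$config$variant,
              n_parameters(x$net), x$best_epoch,
              min(x$history$val_loss)))
  invisible(x)
}
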