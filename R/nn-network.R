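# Network configurations and the three architectures: the Inception+CBAM
# +residual spectral regressor, the DeepSpectra baseline and a plain
# sequential 1D-CNN. Forward and backward passes are hand-coded per
# architecture (the graphs are small and fixed); parameters live in the flat
# list `net$prims` walked by the optimizer.

#' Network configuration
#'
#' @param architecture one of `"incepspect_cbam"`, `"deepspectra"`, `"cnn1d"`.
#' @param variant ablation variant for `incepspect_cbam`: `"full"`,
#'   `"no_cbam"`, `"no_inception"` (Inception blocks replaced by single
#'   3-wide convolutions of matched output channels), `"no_residual"`.
#' @param input_length spectral length p (default 213).
#' @param branch_ch1,branch_ch2 per-branch channel counts of the two
#'   Inception blocks (defaults 8 and 16, giving 32 and 64 output channels).
#' @param cbam a [cbam_spec()].
#' @param fc_units width of the penultimate fully connected layer.
#' @param dropout_rate dropout rate before the output node; `NULL` picks the
#'   architecture default (0.1 for `deepspectra`, 0.2 otherwise).
#' @param l2_lambda L2 penalty coefficient in the loss.
#' @param learning_rate initial AdamW learning rate.
#' @param lr_factor,lr_patience,min_lr reduce-on-plateau schedule: when the
#'   validation loss has not improved for `lr_patience` epochs the learning
#'   rate is multiplied by `lr_factor`, never below `min_lr`. Set
#'   `lr_factor = 1` for a constant rate.
#' @param batch_size minibatch size.
#' @param max_epochs,patience epoch budget and early-stopping patience on the
#'   internal validation split.
#' @param val_fraction fraction of calibration rows held out for early
#'   stopping.
#' @param val_every evaluate the validation split (and recalibrate batch
#'   norm) every this many epochs (default 2; 1 = every epoch).
#' @param weight_decay decoupled AdamW weight decay (default 0: the L2 term
#'   is carried by the loss itself).
#' @param seed RNG seed controlling initialisation, batching and dropout.
#' @return object of class `NetConfig`.
#' @export
net_config <- function(architecture = c("incepspect_cbam", "deepspectra", "cnn1d"),
                       variant = c("full", "no_cbam", "no_inception", "no_residual"),
                       input_length = 213L,
                       branch_ch1 = 8L, branch_ch2 = 16L,
                       cbam = cbam_spec(),
                       fc_units = 64L,
                       dropout_rate = NULL,
                       l2_lambda = 0.001,
                       learning_rate = 0.001,
                       lr_factor = 0.5,
                       lr_patience = 20L,
                       min_lr = 1e-5,
                       batch_size = 32L,
                       max_epochs = 500L,
                       patience = 50L,
                       val_fraction = 0.1,
                       val_every = 2L,
                       weight_decay = 0,
                       seed = 1L) {
  architecture <- match.arg(architecture)
  variant <- match.arg(variant)
  if (is.null(dropout_rate))
    dropout_rate <- if (architecture == "deepspectra") 0.1 else 0.2
  stopifnot(dropout_rate >= 0, dropout_rate < 1, l2_lambda >= 0,
            batch_size >= 1)
  structure(list(architecture = architecture, variant = variant,
                 input_length = as.integer(input_length),
                 branch_ch1 = branch_ch1, branch_ch2 = branch_ch2,
                 cbam = cbam, fc_units = fc_units,
                 dropout_rate = dropout_rate, l2_lambda = l2_lambda,
                 learning_rate = learning_rate,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 min_lr = min_lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 val_every = as.integer(val_every),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "NetConfig")
}

.cbm <- function(in_ch, out_ch, k, stride = 1L, pad = "valid") {
  list(conv = conv1d_layer(in_ch, out_ch, k, stride, pad),
       bn = batchnorm_layer(out_ch), act = mish_layer())
}

# dense -> BN -> Mish, matching the conv-block ordering
.fc_block <- function(in_d, out_d) {
  list(fc = dense_layer(in_d, out_d), bn = batchnorm_layer(out_d),
       act = mish_layer())
}

# Inception block: 1x1 / 1x1->3 / 1x1->5 / maxpool3->1x1 branches, each with
# `ch` output channels, concatenated to 4*ch channels; length preserved.
.incep_block <- function(in_ch, ch) {
  list(b1 = .cbm(in_ch, ch, 1L, pad = "same"),
       b2r = .cbm(in_ch, ch, 1L, pad = "same"),
       b2 = .cbm(ch, ch, 3L, pad = "same"),
       b3r = .cbm(in_ch, ch, 1L, pad = "same"),
       b3 = .cbm(ch, ch, 5L, pad = "same"),
       b4p = maxpool_same_layer(3L),
       b4 = .cbm(in_ch, ch, 1L, pad = "same"),
       ch = ch)
}

.incep_fw <- function(blk, x, train) {
  o1 <- .seq_fw(blk$b1, x, train)
  o2 <- .seq_fw(blk$b2, .seq_fw(blk$b2r, x, train), train)
  o3 <- .seq_fw(blk$b3, .seq_fw(blk$b3r, x, train), train)
  o4 <- .seq_fw(blk$b4, nn_fw(blk$b4p, x, train), train)
  d <- dim(o1); N <- d[1]; L <- d[3]; ch <- blk$ch
  y <- array(0, c(N, 4L * ch, L))
  y[, 1:ch, ] <- o1
  y[, ch + 1:ch, ] <- o2
  y[, 2L * ch + 1:ch, ] <- o3
  y[, 3L * ch + 1:ch, ] <- o4
  y
}

.incep_bw <- function(blk, dy) {
  ch <- blk$ch
  d1 <- .seq_bw(blk$b1, dy[, 1:ch, , drop = FALSE])
  d2 <- .seq_bw(blk$b2r, .seq_bw(blk$b2, dy[, ch + 1:ch, , drop = FALSE]))
  d3 <- .seq_bw(blk$b3r, .seq_bw(blk$b3, dy[, 2L * ch + 1:ch, , drop = FALSE]))
  d4 <- nn_bw(blk$b4p, .seq_bw(blk$b4, dy[, 3L * ch + 1:ch, , drop = FALSE]))
  d1 + d2 + d3 + d4
}

.flatten_prims <- function(x) {
  if (inherits(x, "nn_layer")) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, .flatten_prims)))
  list()
}

#' Build an untrained network
#'
#' Constructs the layer graph for the configured architecture and variant.
#' Initialisation is seeded by `config$seed`, so two builds with the same
#' config have identical initial parameters.
#'
#' @param config a [net_config()].
#' @return object of class `SpectralNet`.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "NetConfig"))
  set.seed(config$seed)
  p <- config$input_length
  L <- list()
  if (config$architecture == "incepspect_cbam") {
    Lo <- (p - 7L) %/% 3L + 1L
    if (Lo < 1L) stop("input_length ", p, " too short for the k=7/s=3 stem")
    c1 <- 4L * config$branch_ch1
    c2 <- 4L * config$branch_ch2
    L$stem <- .cbm(1L, 32L, 7L, stride = 3L)
    if (config$variant == "no_inception") {
      L$incep1 <- .cbm(32L, c1, 3L, pad = "same")
      L$incep2 <- .cbm(c1, c2, 3L, pad = "same")
    } else {
      L$incep1 <- .incep_block(32L, config$branch_ch1)
      L$incep2 <- .incep_block(c1, config$branch_ch2)
    }
    if (config$variant != "no_cbam")
      L$cbam <- cbam_layer(c2, config$cbam)
    if (config$variant != "no_residual") {
      # shortcut from Inception-block-1 output: 1x1 conv adapter to match
      # channels (lengths already match -- both blocks preserve length)
      L$res <- list(conv = conv1d_layer(c1, c2, 1L, pad = "same"),
                    bn = batchnorm_layer(c2))
    }
    L$post_act <- mish_layer()
    L$flat <- flatten_layer()
    flat_d <- c2 * Lo
    L$flat_bn <- batchnorm_layer(flat_d)
    L$fc1 <- .fc_block(flat_d, config$fc_units)
    L$drop <- dropout_layer(config$dropout_rate)
    L$out <- dense_layer(config$fc_units, 1L)
  } else if (config$architecture == "deepspectra") {
    Lo <- (p - 5L) %/% 3L + 1L
    L$stem <- .cbm(1L, 4L, 5L, stride = 3L)
    L$br1 <- c(.cbm(4L, 8L, 1L, pad = "same"), .cbm(8L, 8L, 3L, pad = "same"))
    L$br2 <- c(.cbm(4L, 8L, 1L, pad = "same"), .cbm(8L, 8L, 5L, pad = "same"))
    L$br3 <- c(.cbm(4L, 8L, 3L, pad = "same"), .cbm(8L, 8L, 3L, pad = "same"))
    L$flat <- flatten_layer()
    flat_d <- 24L * Lo
    L$flat_bn <- batchnorm_layer(flat_d)
    L$fc1 <- .fc_block(flat_d, 100L)
    L$drop <- dropout_layer(config$dropout_rate)
    L$out <- dense_layer(100L, 1L)
  } else {                                             # cnn1d
    L$c1 <- .cbm(1L, 16L, 7L, pad = "same")
    L$c2 <- .cbm(16L, 32L, 5L, pad = "same")
    L$c3 <- .cbm(32L, 64L, 3L, pad = "same")
    L$pool <- adaptive_maxpool_layer(min(128L, p))
    L$flat <- flatten_layer()
    flat_d <- 64L * min(128L, p)
    L$flat_bn <- batchnorm_layer(flat_d)
    L$fc1 <- .fc_block(flat_d, 128L)
    L$fc2 <- .fc_block(128L, 64L)
    L$drop <- dropout_layer(config$dropout_rate)
    L$out <- dense_layer(64L, 1L)
  }
  structure(list(config = config, L = L,
                 prims = .flatten_prims(L)),
            class = "SpectralNet")
}

#' Forward pass through a network
#'
#' @param net a `SpectralNet` from [build_network()].
#' @param x input array (N x 1 x p) or matrix (N x p).
#' @param train logical; training mode (batch statistics, dropout).
#' @return numeric vector of N predictions.
#' @export
net_forward <- function(net, x, train = FALSE) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), 1L, ncol(x)))
  if (dim(x)[3] != net$config$input_length)
    stop("input length ", dim(x)[3], " does not match the configured ",
         net$config$input_length)
  L <- net$L
  cfg <- net$config
  if (cfg$architecture == "incepspect_cbam") {
    s <- .seq_fw(L$stem, x, train)
    i1 <- if (cfg$variant == "no_inception") .seq_fw(L$incep1, s, train)
          else .incep_fw(L$incep1, s, train)
    i2 <- if (cfg$variant == "no_inception") .seq_fw(L$incep2, i1, train)
          else .incep_fw(L$incep2, i1, train)
    z <- if (is.null(L$cbam)) i2 else nn_fw(L$cbam, i2, train)
    if (!is.null(L$res))
      z <- z + .seq_fw(L$res, i1, train)
    a <- nn_fw(L$post_act, z, train)
    h <- nn_fw(L$flat_bn, nn_fw(L$flat, a, train), train)
    h <- .seq_fw(L$fc1, h, train)
    h <- nn_fw(L$drop, h, train)
  } else if (cfg$architecture == "deepspectra") {
    s <- .seq_fw(L$stem, x, train)
    o1 <- .seq_fw(L$br1, s, train)
    o2 <- .seq_fw(L$br2, s, train)
    o3 <- .seq_fw(L$br3, s, train)
    d <- dim(o1)
    y <- array(0, c(d[1], 24L, d[3]))
    y[, 1:8, ] <- o1; y[, 9:16, ] <- o2; y[, 17:24, ] <- o3
    h <- nn_fw(L$flat_bn, nn_fw(L$flat, y, train), train)
    h <- .seq_fw(L$fc1, h, train)
    h <- nn_fw(L$drop, h, train)
  } else {
    h <- .seq_fw(L$c1, x, train)
    h <- .seq_fw(L$c2, h, train)
    h <- .seq_fw(L$c3, h, train)
    h <- nn_fw(L$pool, h, train)
    h <- nn_fw(L$flat_bn, nn_fw(L$flat, h, train), train)
    h <- .seq_fw(L$fc1, h, train)
    h <- .seq_fw(L$fc2, h, train)
    h <- nn_fw(L$drop, h, train)
  }
  drop(nn_fw(L$out, h, train))
}

# Backward pass; dy is the gradient w.r.t. the (N-vector) output.
net_backward <- function(net, dy) {
  L <- net$L
  cfg <- net$config
  g <- nn_bw(L$out, matrix(dy, ncol = 1L))
  if (cfg$architecture == "incepspect_cbam") {
    g <- nn_bw(L$drop, g)
    g <- .seq_bw(L$fc1, g)
    g <- nn_bw(L$flat, nn_bw(L$flat_bn, g))
    g <- nn_bw(L$post_act, g)
    d_i1_res <- NULL
    if (!is.null(L$res)) d_i1_res <- .seq_bw(L$res, g)
    if (!is.null(L$cbam)) g <- nn_bw(L$cbam, g)
    d_i1 <- if (cfg$variant == "no_inception") .seq_bw(L$incep2, g)
            else .incep_bw(L$incep2, g)
    if (!is.null(d_i1_res)) d_i1 <- d_i1 + d_i1_res
    ds <- if (cfg$variant == "no_inception") .seq_bw(L$incep1, d_i1)
          else .incep_bw(L$incep1, d_i1)
    invisible(.seq_bw(L$stem, ds))
  } else if (cfg$architecture == "deepspectra") {
    g <- nn_bw(L$drop, g)
    g <- .seq_bw(L$fc1, g)
    g <- nn_bw(L$flat, nn_bw(L$flat_bn, g))
    ds <- .seq_bw(L$br1, g[, 1:8, , drop = FALSE]) +
          .seq_bw(L$br2, g[, 9:16, , drop = FALSE]) +
          .seq_bw(L$br3, g[, 17:24, , drop = FALSE])
    invisible(.seq_bw(L$stem, ds))
  } else {
    g <- nn_bw(L$drop, g)
    g <- .seq_bw(L$fc2, g)
    g <- .seq_bw(L$fc1, g)
    g <- nn_bw(L$flat, nn_bw(L$flat_bn, g))
    g <- nn_bw(L$pool, g)
    g <- .seq_bw(L$c3, g)
    g <- .seq_bw(L$c2, g)
    invisible(.seq_bw(L$c1, g))
  }
}

#' Number of trainable parameters
#' @param net a `SpectralNet`.
#' @return integer parameter count.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$prims, function(l) sum(vapply(l$par, length, 0L)), 0L))
}

# sum of squared weight parameters (conv/dense/attention weights; biases and
# BN parameters excluded)
.net_l2 <- function(net) {
  s <- 0
  for (l in net$prims)
    for (nm in l$decay) s <- s + sum(l$par[[nm]]^2)
  s
}

#' Training loss: mean squared error plus L2 weight penalty
#'
#' `loss = mean((y - yhat)^2) + lambda * sum(w^2)` where the weight norm runs
#' over convolutional, dense and attention weights only (no biases, no batch
#' norm parameters).
#'
#' @param predictions,targets numeric vectors of equal positive length.
#' @param network optional `SpectralNet` supplying the weights; with
#'   `l2_lambda = 0` (or no network) the loss is exactly the MSE.
#' @param l2_lambda penalty coefficient.
#' @return scalar loss.
#' @export
net_loss <- function(predictions, targets, network = NULL, l2_lambda = 0) {
  if (!length(predictions)) stop("empty batch")
  if (length(predictions) != length(targets))
    stop("predictions and targets differ in length")
  mse <- mean((targets - predictions)^2)
  if (l2_lambda > 0 && !is.null(network))
    mse + l2_lambda * .net_l2(network)
  else mse
}
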