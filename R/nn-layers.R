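# Neural-network primitives with hand-written forward/backward passes.
#
# Feature maps are 3D arrays (batch N, channels C, length L); dense
# activations are (N, D) matrices. Layers are environments carrying `par`
# (parameters), `grad` (accumulated gradients, same shapes) and `decay`
# (which parameters count as weights for the L2 penalty). Every backward pass
# is verified against central finite differences in the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

.new_layer <- function(type, par = list(), decay = character(0)) {
  e <- new.env(parent = emptyenv())
  e$par <- par
  e$grad <- lapply(par, function(p) array(0, dim = dim(p) %||% length(p)))
  e$decay <- decay
  class(e) <- c(type, "nn_layer")
  e
}

#' Forward / backward pass through one layer
#'
#' Low-level generics of the network engine. `nn_fw` stores whatever the
#' matching `nn_bw` needs inside the layer environment, so a backward call
#' must follow its forward call.
#'
#' @param layer a layer environment created by one of the layer constructors.
#' @param x input array (N x C x L) or matrix (N x D).
#' @param train logical; `TRUE` enables batch statistics and dropout.
#' @param dy gradient of the loss w.r.t. the layer output.
#' @return `nn_fw`: the layer output; `nn_bw`: the gradient w.r.t. the input.
#' @keywords internal
#' @export
nn_fw <- function(layer, x, train = FALSE) UseMethod("nn_fw")

#' @rdname nn_fw
#' @export
nn_bw <- function(layer, dy) UseMethod("nn_bw")

.zero_grads <- function(layer) {
  for (nm in names(layer$grad)) layer$grad[[nm]][] <- 0
  invisible(layer)
}

# ---- 1D convolution --------------------------------------------------------

# pad: "valid" (none) or "same" (stride-1 length-preserving, odd k).
conv1d_layer <- function(in_ch, out_ch, k, stride = 1L, pad = "valid",
                         init = c("he", "zero")) {
  init <- match.arg(init)
  sd <- sqrt(2 / (in_ch * k))
  W <- if (init == "zero") matrix(0, in_ch * k, out_ch)
       else matrix(rnorm(in_ch * k * out_ch, 0, sd), in_ch * k, out_ch)
  l <- .new_layer("conv1d", list(W = W, b = numeric(out_ch)), decay = "W")
  l$in_ch <- in_ch; l$out_ch <- out_ch; l$k <- as.integer(k)
  l$stride <- as.integer(stride)
  if (identical(pad, "same")) {
    if (stride != 1L) stop("'same' padding implemented for stride 1 only")
    l$pl <- (k - 1L) %/% 2L; l$pr <- k - 1L - l$pl
  } else { l$pl <- 0L; l$pr <- 0L }
  l
}

#' @export
nn_fw.conv1d <- function(layer, x, train = FALSE) {
  d <- dim(x); N <- d[1]; Cin <- d[2]; L <- d[3]
  if (Cin != layer$in_ch)
    stop("conv1d: expected ", layer$in_ch, " input channels, got ", Cin)
  if (L + layer$pl + layer$pr < layer$k)
    stop("conv1d: input length ", L, " too short for kernel ", layer$k)
  res <- conv1d_fw_cpp(x, layer$par$W, layer$par$b, layer$k, layer$stride,
                       layer$pl, layer$pr)
  layer$cache <- list(xc = res$xc, N = N, L = L)
  res$y
}

#' @export
nn_bw.conv1d <- function(layer, dy) {
  cc <- layer$cache
  res <- conv1d_bw_cpp(dy, cc$xc, layer$par$W, cc$N, layer$in_ch, cc$L,
                       layer$k, layer$stride, layer$pl)
  layer$grad$W <- layer$grad$W + res$dW
  layer$grad$b <- layer$grad$b + drop(res$db)
  res$dx
}

# ---- batch normalisation ---------------------------------------------------

# Works on (N, C, L) arrays (per channel over N*L) and (N, D) matrices (per
# column). Running statistics use momentum 0.1; eps 1e-5.
batchnorm_layer <- function(channels, momentum = 0.1, eps = 1e-5) {
  l <- .new_layer("batchnorm",
                  list(gamma = rep(1, channels), beta = numeric(channels)))
  l$channels <- channels; l$momentum <- momentum; l$eps <- eps
  l$run_mean <- numeric(channels); l$run_var <- rep(1, channels)
  l
}

# promote (N, D) matrices to (N, D, 1) so one kernel covers both cases
.bn_as3d <- function(x) {
  if (length(dim(x)) == 3L) list(x = x, two_d = FALSE)
  else { dim(x) <- c(dim(x), 1L); list(x = x, two_d = TRUE) }
}

#' @export
nn_fw.batchnorm <- function(layer, x, train = FALSE) {
  # train = TRUE: batch statistics + EMA update of the running buffers;
  # train = "stats": batch statistics, running buffers REPLACED (population
  # recalibration pass); train = FALSE: running buffers.
  t3 <- .bn_as3d(x)
  use_batch <- !isFALSE(train)
  res <- bn_fw_cpp(t3$x, layer$par$gamma, layer$par$beta,
                   layer$run_mean, layer$run_var, use_batch, layer$eps)
  if (isTRUE(train)) {
    mom <- layer$momentum
    layer$run_mean <- (1 - mom) * layer$run_mean + mom * drop(res$mu)
    layer$run_var  <- (1 - mom) * layer$run_var + mom * drop(res$var)
  } else if (identical(train, "stats")) {
    layer$run_mean <- drop(res$mu)
    layer$run_var <- drop(res$var)
  }
  layer$cache <- list(x = t3$x, mu = res$mu, istd = res$istd,
                      two_d = t3$two_d, train = use_batch)
  y <- res$y
  if (t3$two_d) dim(y) <- dim(y)[1:2]
  y
}

#' @export
nn_bw.batchnorm <- function(layer, dy) {
  cc <- layer$cache
  if (cc$two_d) dim(dy) <- c(dim(dy), 1L)
  res <- bn_bw_cpp(dy, cc$x, cc$mu, cc$istd, layer$par$gamma, cc$train)
  layer$grad$gamma <- layer$grad$gamma + drop(res$dgamma)
  layer$grad$beta <- layer$grad$beta + drop(res$dbeta)
  dx <- res$dx
  if (cc$two_d) dim(dx) <- dim(dx)[1:2]
  dx
}

# ---- Mish activation -------------------------------------------------------

#' Mish activation
#'
#' `mish(x) = x * tanh(log(1 + exp(x)))`, evaluated with an
#' overflow-safe softplus so it is numerically stable for `|x|` well beyond
#' 50 (for large x, softplus(x) = x to machine precision).
#'
#' @param x numeric vector/array.
#' @return same shape as `x`.
#' @export
mish <- function(x) {
  sp <- .softplus(x)
  x * tanh(sp)
}

.softplus <- function(x) {
  out <- x
  small <- x < 20
  out[small] <- log1p(exp(x[small]))
  out
}

.mish_grad <- function(x) {
  t <- tanh(.softplus(x))
  s <- 1 / (1 + exp(-x))
  t + x * (1 - t^2) * s
}

mish_layer <- function() .new_layer("mish")

#' @export
nn_fw.mish <- function(layer, x, train = FALSE) {
  res <- mish_fw_cpp(x)
  layer$cache <- list(x = x, t = res$t, s = res$s)
  res$y
}

#' @export
nn_bw.mish <- function(layer, dy) {
  mish_bw_cpp(layer$cache$x, layer$cache$t, layer$cache$s, dy)
}

# ---- pooling ---------------------------------------------------------------

# stride-1 "same" max pooling with odd window k (pads with -Inf)
maxpool_same_layer <- function(k = 3L) {
  l <- .new_layer("maxpool_same")
  l$k <- as.integer(k)
  l
}

#' @export
nn_fw.maxpool_same <- function(layer, x, train = FALSE) {
  res <- maxpool_same_fw_cpp(x, layer$k)
  layer$cache <- res$arg
  res$y
}

#' @export
nn_bw.maxpool_same <- function(layer, dy) {
  maxpool_same_bw_cpp(dy, layer$cache, layer$k)
}

# adaptive max pooling to a fixed output length (torch bin convention)
adaptive_maxpool_layer <- function(out_len) {
  l <- .new_layer("adaptive_maxpool")
  l$out_len <- as.integer(out_len)
  l
}

.adaptive_bins <- function(L, out_len) {
  i <- seq_len(out_len)
  start <- floor((i - 1) * L / out_len) + 1L
  end <- ceiling(i * L / out_len)
  cbind(start, end)
}

#' @export
nn_fw.adaptive_maxpool <- function(layer, x, train = FALSE) {
  d <- dim(x); N <- d[1]; C <- d[2]; L <- d[3]
  O <- layer$out_len
  bins <- .adaptive_bins(L, O)
  y <- array(0, c(N, C, O))
  arg <- array(0L, c(N, C, O))           # absolute position of the max
  for (i in seq_len(O)) {
    rng <- bins[i, 1]:bins[i, 2]
    best <- x[, , rng[1], drop = FALSE]
    a <- array(rng[1], c(N, C, 1L))
    for (pz in rng[-1]) {
      cand <- x[, , pz, drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      a[upd] <- pz
    }
    y[, , i] <- best
    arg[, , i] <- a
  }
  layer$cache <- list(arg = arg, d = d)
  y
}

#' @export
nn_bw.adaptive_maxpool <- function(layer, dy) {
  cc <- layer$cache
  d <- cc$d
  dx <- array(0, d)
  O <- layer$out_len
  for (i in seq_len(O)) {
    a <- cc$arg[, , i]
    g <- dy[, , i]
    for (pz in unique(as.vector(a))) {
      mask <- (a == pz) * g
      dx[, , pz] <- dx[, , pz] + mask
    }
  }
  dx
}

# ---- dense / dropout / flatten --------------------------------------------

dense_layer <- function(in_d, out_d, init = c("he", "zero")) {
  init <- match.arg(init)
  sd <- sqrt(2 / in_d)
  W <- if (init == "zero") matrix(0, in_d, out_d)
       else matrix(rnorm(in_d * out_d, 0, sd), in_d, out_d)
  l <- .new_layer("dense", list(W = W, b = numeric(out_d)), decay = "W")
  l$in_d <- in_d; l$out_d <- out_d
  l
}

#' @export
nn_fw.dense <- function(layer, x, train = FALSE) {
  if (ncol(x) != layer$in_d)
    stop("dense: expected ", layer$in_d, " inputs, got ", ncol(x))
  layer$cache <- x
  sweep(x %*% layer$par$W, 2L, layer$par$b, "+")
}

#' @export
nn_bw.dense <- function(layer, dy) {
  layer$grad$W <- layer$grad$W + crossprod(layer$cache, dy)
  layer$grad$b <- layer$grad$b + colSums(dy)
  dy %*% t(layer$par$W)
}

dropout_layer <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  l <- .new_layer("dropout")
  l$rate <- rate
  l
}

#' @export
nn_fw.dropout <- function(layer, x, train = FALSE) {
  if (!isTRUE(train) || layer$rate == 0) {
    layer$cache <- NULL
    return(x)
  }
  keep <- 1 - layer$rate
  mask <- (array(runif(length(x)), dim = dim(x) %||% length(x)) < keep) / keep
  layer$cache <- mask
  x * mask
}

#' @export
nn_bw.dropout <- function(layer, dy) {
  if (is.null(layer$cache)) dy else dy * layer$cache
}

flatten_layer <- function() .new_layer("flatten")

#' @export
nn_fw.flatten <- function(layer, x, train = FALSE) {
  d <- dim(x)
  layer$cache <- d
  dim(x) <- c(d[1], d[2] * d[3])
  x
}

#' @export
nn_bw.flatten <- function(layer, dy) {
  dim(dy) <- layer$cache
  dy
}

# ---- sequential helpers ----------------------------------------------------

.seq_fw <- function(layers, x, train = FALSE) {
  for (l in layers) x <- nn_fw(l, x, train)
  x
}

.seq_bw <- function(layers, dy) {
  for (l in rev(layers)) dy <- nn_bw(l, dy)
  dy
}
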