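# Convolutional block attention module (CBAM) for 1D feature maps: channel
# attention (global avg + max pooling over positions, one shared two-layer
# MLP, sigmoid gate) followed by spatial attention (channel-wise mean + max
# maps, one convolution, sigmoid gate).

#' CBAM hyperparameters
#'
#' @param reduction_ratio bottleneck ratio of the shared channel-attention
#'   MLP (hidden width = `max(1, floor(channels / reduction_ratio))`).
#' @param spatial_kernel odd kernel size of the spatial-attention convolution.
#' @return object of class `CbamSpec`.
#' @export
cbam_spec <- function(reduction_ratio = 8L, spatial_kernel = 7L) {
  if (spatial_kernel %% 2L != 1L) stop("spatial_kernel must be odd")
  if (reduction_ratio < 1L) stop("reduction_ratio must be >= 1")
  structure(list(reduction_ratio = as.integer(reduction_ratio),
                 spatial_kernel = as.integer(spatial_kernel)),
            class = "CbamSpec")
}

#' Create a CBAM layer
#'
#' @param channels number of input channels.
#' @param spec a [cbam_spec()].
#' @param init `"he"` for random initialisation (current RNG state) or
#'   `"zero"`; with all-zero parameters both gates are exactly sigmoid(0) =
#'   0.5, so the module scales its input by 0.25.
#' @return a layer environment usable with [channel_attention()],
#'   [spatial_attention()], [cbam()] and the network engine.
#' @export
cbam_layer <- function(channels, spec = cbam_spec(), init = c("he", "zero")) {
  init <- match.arg(init)
  C <- as.integer(channels)
  H <- max(1L, C %/% spec$reduction_ratio)
  k <- spec$spatial_kernel
  rnd <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc)
    else matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  }
  l <- .new_layer("cbam",
                  list(W1 = rnd(C, H), b1 = numeric(H),
                       W2 = rnd(H, C), b2 = numeric(C),
                       Ws = rnd(2L * k, 1L), bs = numeric(1L)),
                  decay = c("W1", "W2", "Ws"))
  l$channels <- C; l$hidden <- H; l$k <- k
  l
}

.as_fmap <- function(x) {
  if (length(dim(x)) == 2L) array(x, c(1L, nrow(x), ncol(x)))
  else x
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# channel attention forward; returns list(Mc, cache)
.cbam_channel_fw <- function(layer, x) {
  d <- dim(x); N <- d[1]; C <- d[2]; L <- d[3]
  pools <- cbam_chan_pool_fw_cpp(x)
  avgc <- pools$avg; maxc <- pools$max; argc <- pools$arg
  mlp <- function(z) {
    n <- nrow(z)
    h <- pmax(z %*% layer$par$W1 + rep(layer$par$b1, each = n), 0)
    list(h = h, o = h %*% layer$par$W2 + rep(layer$par$b2, each = n))
  }
  ma <- mlp(avgc); mm <- mlp(maxc)
  Mc <- .sigmoid(ma$o + mm$o)
  list(Mc = Mc,
       cache = list(avgc = avgc, maxc = maxc, argc = argc,
                    ha = ma$h, hm = mm$h, N = N, C = C, L = L))
}

# spatial attention forward on the (already channel-gated) map
.cbam_spatial_fw <- function(layer, x) {
  d <- dim(x); N <- d[1]; C <- d[2]; L <- d[3]
  pools <- cbam_spat_pool_fw_cpp(x)
  savg <- pools$avg; smax <- pools$max; argS <- pools$arg
  s2 <- array(0, c(N, 2L, L))
  s2[, 1L, ] <- savg
  s2[, 2L, ] <- smax
  # conv: 2 channels -> 1, kernel k, same padding
  k <- layer$k; pl <- (k - 1L) %/% 2L; pr <- k - 1L - pl
  sp <- array(0, c(N, 2L, L + pl + pr))
  sp[, , (pl + 1L):(pl + L)] <- s2
  idx <- outer(seq_len(k), seq_len(L) - 1L, "+")
  sc <- sp[, , as.vector(idx), drop = FALSE]
  dim(sc) <- c(N, 2L, k, L)
  sc <- aperm(sc, c(1, 4, 2, 3))
  dim(sc) <- c(N * L, 2L * k)
  z <- drop(sc %*% layer$par$Ws) + as.numeric(layer$par$bs)
  Ms <- matrix(.sigmoid(z), N, L)
  list(Ms = Ms,
       cache = list(sc = sc, idx = idx, argS = argS, pl = pl, pr = pr,
                    N = N, C = C, L = L))
}

#' Channel attention map
#'
#' `Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))` with one shared
#' two-layer MLP; pooling is over spatial positions, so the result is
#' invariant to spatial permutations of `F`.
#'
#' @param F feature map, array (N x C x L) or matrix (C x L).
#' @param layer a [cbam_layer()].
#' @return N x C matrix of weights, each strictly in (0, 1).
#' @export
channel_attention <- function(F, layer) {
  .cbam_channel_fw(layer, .as_fmap(F))$Mc
}

#' Spatial attention map
#'
#' Channel-wise mean and max maps are concatenated and convolved with one
#' `spatial_kernel`-wide kernel ("same" padding), then gated by a sigmoid;
#' invariant to channel permutations of `F`.
#'
#' @inheritParams channel_attention
#' @return N x L matrix of weights, each strictly in (0, 1).
#' @export
spatial_attention <- function(F, layer) {
  .cbam_spatial_fw(layer, .as_fmap(F))$Ms
}

#' Apply CBAM gating
#'
#' `F' = F (.) Mc` broadcast over positions, then `F'' = F' (.) Ms` broadcast
#' over channels. Shape is preserved and `|F''| <= |F|` elementwise because
#' both gates lie in (0, 1).
#'
#' @inheritParams channel_attention
#' @return gated feature map, same shape as `F` (promoted to N x C x L).
#' @export
cbam <- function(F, layer) {
  nn_fw(layer, .as_fmap(F), train = FALSE)
}

#' @export
nn_fw.cbam <- function(layer, x, train = FALSE) {
  x <- .as_fmap(x)
  ch <- .cbam_channel_fw(layer, x)
  F1 <- bcast_mul_nc_cpp(x, ch$Mc)                 # gate over channels
  sp <- .cbam_spatial_fw(layer, F1)
  F2 <- bcast_mul_nl_cpp(F1, sp$Ms)                # gate over positions
  layer$cache <- list(x = x, F1 = F1, Mc = ch$Mc, Ms = sp$Ms,
                      ch = ch$cache, sp = sp$cache)
  F2
}

#' @export
nn_bw.cbam <- function(layer, dy) {
  cc <- layer$cache
  N <- cc$ch$N; C <- cc$ch$C; L <- cc$ch$L
  k <- layer$k
  # ---- spatial gate ----
  dF1 <- bcast_mul_nl_cpp(dy, cc$Ms)
  dMs <- sum_prod_nl_cpp(dy, cc$F1)                          # N x L
  dz <- dMs * cc$Ms * (1 - cc$Ms)                            # sigmoid'
  dzv <- as.vector(dz)                                       # N*L
  layer$grad$Ws <- layer$grad$Ws + crossprod(cc$sp$sc, dzv)
  layer$grad$bs <- layer$grad$bs + sum(dzv)
  dsc <- outer(dzv, drop(layer$par$Ws))                      # (N*L) x (2k)
  dim(dsc) <- c(N, L, 2L, k)
  dsc <- aperm(dsc, c(1, 3, 4, 2))                           # N x 2 x k x L
  dsp <- array(0, c(N, 2L, L + cc$sp$pl + cc$sp$pr))
  for (j in seq_len(k)) {
    pos <- cc$sp$idx[j, ]
    contrib <- dsc[, , j, , drop = FALSE]
    dim(contrib) <- c(N, 2L, L)
    acc <- dsp[, , pos, drop = FALSE] + contrib
    dsp[, , pos] <- acc
  }
  ds2 <- dsp[, , (cc$sp$pl + 1L):(cc$sp$pl + L), drop = FALSE]
  dsavg <- ds2[, 1L, , drop = FALSE]; dim(dsavg) <- c(N, L)
  dsmax <- ds2[, 2L, , drop = FALSE]; dim(dsmax) <- c(N, L)
  # mean over channels -> spread equally; max -> scatter to argmax channel
  dF1 <- dF1 + cbam_spat_pool_bw_cpp(dsavg, dsmax, cc$sp$argS, C)
  # ---- channel gate ----
  dx <- bcast_mul_nc_cpp(dF1, cc$Mc)
  dMc <- sum_prod_nc_cpp(dF1, cc$x)                           # N x C
  dzc <- dMc * cc$Mc * (1 - cc$Mc)
  # shared MLP, two branches (avg / max descriptors)
  bw_mlp <- function(z_in, h, dout) {
    layer$grad$W2 <- layer$grad$W2 + crossprod(h, dout)
    layer$grad$b2 <- layer$grad$b2 + colSums(dout)
    dh <- (dout %*% t(layer$par$W2)) * (h > 0)
    layer$grad$W1 <- layer$grad$W1 + crossprod(z_in, dh)
    layer$grad$b1 <- layer$grad$b1 + colSums(dh)
    dh %*% t(layer$par$W1)
  }
  davgc <- bw_mlp(cc$ch$avgc, cc$ch$ha, dzc)
  dmaxc <- bw_mlp(cc$ch$maxc, cc$ch$hm, dzc)
  # avg pool over L -> spread; max pool -> scatter to argmax position
  dx + cbam_chan_pool_bw_cpp(davgc, dmaxc, cc$ch$argc, L)
}
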