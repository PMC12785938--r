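test_that("mish matches its closed form to 1e-9 and is stable at extremes", {
  x <- seq(-20, 20, length.out = 1000)
  ref <- x * tanh(log(1 + exp(x)))          # naive form, safe on [-20, 20]
  expect_equal(mish(x), ref, tolerance = 1e-9)
  expect_identical(mish(0), 0)
  expect_equal(mish(50), 50, tolerance = 1e-9)
  expect_equal(mish(1), 0.865098, tolerance = 1e-6)   # independent value
  expect_equal(mish(-50), 0, tolerance = 1e-9)
})

test_that("channel attention is invariant to spatial permutation", {
  set.seed(21)
  l <- cbam_layer(8L, cbam_spec(reduction_ratio = 4L))
  F <- array(rnorm(2 * 8 * 12), c(2, 8, 12))
  Mc <- channel_attention(F, l)
  expect_true(all(Mc > 0 & Mc < 1))
  perm <- sample(12)
  expect_equal(channel_attention(F[, , perm, drop = FALSE], l), Mc)
  # with zero-initialised MLP weights the map is channel-symmetric, so
  # duplicate channels receive identical (0.5) weights
  lz <- cbam_layer(8L, cbam_spec(reduction_ratio = 4L), init = "zero")
  F2 <- F; F2[, 5, ] <- F2[, 3, ]
  Mc2 <- channel_attention(F2, lz)
  expect_equal(Mc2[, 5], Mc2[, 3])
})

test_that("spatial attention is invariant to channel permutation", {
  set.seed(22)
  l <- cbam_layer(8L)
  F <- array(rnorm(3 * 8 * 15), c(3, 8, 15))
  Ms <- spatial_attention(F, l)
  expect_true(all(Ms > 0 & Ms < 1))
  perm <- sample(8)
  expect_equal(spatial_attention(F[, perm, , drop = FALSE], l), Ms)
  expect_equal(dim(Ms), c(3L, 15L))       # same length for any kernel
  l2 <- cbam_layer(8L, cbam_spec(spatial_kernel = 3L))
  expect_equal(dim(spatial_attention(F, l2)), c(3L, 15L))
})

test_that("zero-initialised CBAM gates are exactly 0.5 and cbam(F) = F/4", {
  l <- cbam_layer(6L, init = "zero")
  set.seed(23)
  F <- array(rnorm(2 * 6 * 9), c(2, 6, 9))
  expect_equal(channel_attention(F, l),
               matrix(0.5, 2, 6), ignore_attr = TRUE)
  out <- cbam(F, l)
  expect_equal(out, 0.25 * F, ignore_attr = TRUE)
  # gates < 1 bound the output by the input elementwise
  set.seed(24)
  lr <- cbam_layer(6L)
  expect_true(all(abs(cbam(F, lr)) <= abs(F)))
  # matrix input is promoted to a single-sample map
  expect_equal(dim(cbam(F[1, , ], lr)), c(1L, 6L, 9L))
})

test_that("build_network produces the right shapes and seeded initialisation", {
  cfg <- net_config("incepspect_cbam", input_length = 213L, seed = 5L)
  net <- build_network(cfg)
  set.seed(1)
  x <- matrix(runif(32 * 213), 32, 213)
  out <- net_forward(net, x)
  expect_length(out, 32L)
  # same seed -> identical initial parameters
  net2 <- build_network(cfg)
  expect_identical(lapply(net$prims, function(l) l$par),
                   lapply(net2$prims, function(l) l$par))
  # no_cbam has strictly fewer parameters
  for (v in c("no_cbam", "no_inception", "no_residual")) {
    nv <- build_network(net_config("incepspect_cbam", variant = v,
                                   input_length = 213L, seed = 5L))
    expect_length(net_forward(nv, x[1:2, ]), 2L)
    if (v == "no_cbam") expect_lt(n_parameters(nv), n_parameters(net))
  }
  for (arch in c("deepspectra", "cnn1d")) {
    na <- build_network(net_config(arch, input_length = 213L, seed = 5L))
    expect_length(net_forward(na, x[1:3, ]), 3L)
  }
  expect_error(build_network(net_config("incepspect_cbam", input_length = 5L)),
               "too short")
})

test_that("the loss is MSE plus the weight-only L2 term", {
  expect_equal(net_loss(c(0, 0), c(1, 3)), 5)          # (1 + 9) / 2
  expect_equal(net_loss(c(1, 2), c(1, 2)), 0)
  expect_error(net_loss(numeric(0), numeric(0)), "empty")
  expect_error(net_loss(1, c(1, 2)), "length")
  cfg <- net_config("incepspect_cbam", input_length = 30L, branch_ch1 = 2L,
                    branch_ch2 = 2L, fc_units = 4L, seed = 1L)
  net <- build_network(cfg)
  l2 <- incepspect:::.net_l2(net)
  expect_gt(l2, 0)
  expect_equal(net_loss(c(0, 0), c(1, 3), net, 0.01), 5 + 0.01 * l2)
  # lambda = 0 reduces exactly to MSE
  expect_equal(net_loss(c(0, 0), c(1, 3), net, 0), 5)
  # biases and BN parameters are excluded: perturbing them leaves l2 unchanged
  for (l in net$prims) {
    if (inherits(l, "batchnorm")) { l$par$gamma <- l$par$gamma * 2; break }
  }
  expect_equal(incepspect:::.net_l2(net), l2)
})

test_that("backpropagation matches finite differences on all architectures", {
  check_arch <- function(arch, variant = "full", p = 25L, tol = 5e-3) {
    cfg <- net_config(arch, variant = variant, input_length = p,
                      branch_ch1 = 2L, branch_ch2 = 3L, fc_units = 4L,
                      dropout_rate = 0, seed = 3L)
    net <- build_network(cfg)
    set.seed(9)
    x <- array(rnorm(4 * p), c(4, 1, p)); y <- runif(4)
    loss_at <- function() net_loss(net_forward(net, x, train = TRUE), y)
    for (l in net$prims) incepspect:::.zero_grads(l)
    pr <- net_forward(net, x, train = TRUE)
    incepspect:::net_backward(net, 2 * (pr - y) / length(y))
    set.seed(42)
    worst <- 0
    for (l in net$prims) for (nm in names(l$par)) {
      k <- length(l$par[[nm]])
      for (idx in sample(k, min(2L, k))) {
        eps <- 1e-5; orig <- l$par[[nm]][idx]
        l$par[[nm]][idx] <- orig + eps; lp <- loss_at()
        l$par[[nm]][idx] <- orig - eps; lm_ <- loss_at()
        l$par[[nm]][idx] <- orig
        g_num <- (lp - lm_) / (2 * eps)
        worst <- max(worst, abs(g_num - l$grad[[nm]][idx]) /
                       max(1e-6, abs(g_num) + abs(l$grad[[nm]][idx])))
      }
    }
    expect_lt(worst, tol)
  }
  check_arch("incepspect_cbam")
  check_arch("incepspect_cbam", "no_cbam")
  check_arch("incepspect_cbam", "no_inception")
  check_arch("incepspect_cbam", "no_residual")
  check_arch("deepspectra")
  check_arch("cnn1d", p = 30L)
})

test_that("training is seed-reproducible and decreases the loss", {
  d <- simulate_dataset(mixture_design(levels = seq(0, 1, 0.25),
                                       adulterants = "corn_flour",
                                       replicates_per_level = 4L),
                        noise_model(seed = 2L), default_grid(40L))
  tf <- minmax_fit(d)
  dn <- minmax_apply(tf, d)
  cfg <- net_config("incepspect_cbam", input_length = 40L, branch_ch1 = 2L,
                    branch_ch2 = 3L, fc_units = 8L, batch_size = 8L,
                    max_epochs = 15L, patience = 15L, seed = 7L)
  t1 <- train_net(build_network(cfg), dn, cfg)
  t2 <- train_net(build_network(cfg), dn, cfg)
  expect_identical(t1$history, t2$history)
  expect_lt(t1$history$train_loss[t1$best_epoch],
            t1$history$train_loss[1])
  # prediction is deterministic, works on a batch of 1, one value per row
  p1 <- predict_net(t1, dn)
  expect_identical(p1, predict_net(t1, dn))
  expect_length(p1, n_samples(dn))
  expect_length(predict_net(t1, dn[1, ]), 1L)
  expect_error(predict_net(t1, tiny_set(p = 5L)), "variables")
})
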