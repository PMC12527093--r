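test_that("network configs validate and parameter bookkeeping is exact", {
  expect_error(model_config(dilations = c(2, 1)), "increasing")
  expect_error(model_config(cbam_reduction = 7), "divide")
  expect_error(model_config(spatial_kernel = 4), "odd")
  net <- build_network(model_config(), seed = 1)
  # total equals the sum of the per-layer table and the live parameters
  expect_equal(net$total_parameters, sum(net$layers$n_params))
  expect_equal(count_parameters(net), net$total_parameters)
  # worked examples: FC head and a single batch norm
  expect_equal(net$layers$n_params[net$layers$name == "head.fc"], 512 * 5 + 5)
  expect_equal(net$layers$n_params[net$layers$name == "stem.b1.bn"], 128)
  # component decomposition sums to the total
  bd <- parameter_breakdown(net)
  expect_equal(sum(bd$n_params), net$total_parameters)
  # toggling one flag only changes the expected component
  net2 <- build_network(model_config(use_cbam = FALSE), seed = 1)
  bd2 <- parameter_breakdown(net2)
  expect_equal(bd$n_params[bd$component == "body"],
               bd2$n_params[bd2$component == "body"])
  expect_equal(bd$n_params[bd$component == "stem"],
               bd2$n_params[bd2$component == "stem"])
  expect_false("cbam" %in% bd2$component)
})

test_that("depthwise separable convs cost a fraction of standard convs", {
  # 64 -> 64: 3x3 depthwise + 1x1 pointwise = 9*64 + 64*64 weights
  net <- build_network(model_config(), seed = 1)
  dw <- net$params[["stage1.block1.u1.dw.weight"]]
  pw <- net$params[["stage1.block1.u1.pw.weight"]]
  expect_equal(length(dw) + length(pw), 9 * 64 + 64 * 64)  # 4,672
  # vs 36,864 for the standard 3x3 conv at the same width
  net_std <- build_network(model_config(use_dsc = FALSE), seed = 1)
  expect_equal(length(net_std$params[["stage1.block1.u1.conv.weight"]]),
               36864)
})

tiny_cfg <- model_config(stage_widths = c(4, 4, 8, 8), cbam_reduction = 4,
                         stem_branch_channels = 4, stem_fused_channels = 4,
                         dropout_p = 0)

test_that("forward operators match naive nested-loop oracles on small tensors", {
  set.seed(11)
  to_b <- lmcsleep:::chw_to_batch
  from_b <- lmcsleep:::batch_to_chw
  # plain, strided, dilated, padded convolution
  cases <- list(list(s = 1, d = 1, p = 0), list(s = 2, d = 1, p = 1),
                list(s = 1, d = 2, p = 2), list(s = 2, d = 3, p = 3))
  for (cs in cases) {
    x <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
    w <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
    got <- from_b(lmcsleep:::conv_fw_impl(to_b(x), w, stride = cs$s,
                                          dil = cs$d, pad = cs$p)$out)
    expect_equal(got, naive_conv2d(x, w, cs$s, cs$d, cs$p),
                 tolerance = 1e-10)
  }
  # grouped (depthwise) convolution
  x <- array(rnorm(4 * 8 * 8), c(4, 8, 8))
  wd <- array(rnorm(3 * 3 * 1 * 4), c(3, 3, 1, 4))
  got <- from_b(lmcsleep:::conv_fw_impl(to_b(x), wd, stride = 1, pad = 1,
                                        groups = 4)$out)
  expect_equal(got, naive_conv2d(x, wd, 1, 1, 1, groups = 4),
               tolerance = 1e-10)
  # max pooling
  got <- from_b(lmcsleep:::maxpool_fw_impl(to_b(x))$out)
  expect_equal(got, naive_maxpool(x), tolerance = 1e-12)
  # channel attention
  w1 <- matrix(rnorm(2 * 4), 2, 4)
  w2 <- matrix(rnorm(4 * 2), 4, 2)
  expect_equal(channel_attention(x, w1, w2),
               naive_channel_attention(x, w1, w2), tolerance = 1e-10)
  # spatial attention and the sequential CBAM composition
  wsa <- array(rnorm(7 * 7 * 2), c(7, 7, 2, 1))
  expect_equal(spatial_attention(x, wsa, 0.3),
               naive_spatial_attention(x, wsa, 0.3), tolerance = 1e-10)
  expect_equal(cbam(x, w1, w2, wsa, 0.3),
               naive_spatial_attention(
                 naive_channel_attention(x, w1, w2), wsa, 0.3),
               tolerance = 1e-10)
})

test_that("channel attention follows its closed forms on degenerate input", {
  w1 <- matrix(rnorm(2 * 4), 2, 4)
  w2 <- matrix(rnorm(4 * 2), 4, 2)
  # zeros: sigmoid(0) = 0.5 weights, but 0 * 0.5 = 0
  z <- array(0, c(4, 5, 5))
  expect_true(all(channel_attention(z, w1, w2) == 0))
  # constant per channel: avg pool == max pool -> weights sigmoid(2*MLP(p))
  xc <- array(rep(c(1, -2, 0.5, 3), 25), c(4, 5, 5))
  p <- c(1, -2, 0.5, 3)
  s <- 1 / (1 + exp(-2 * as.vector(w2 %*% pmax(w1 %*% p, 0))))
  expect_equal(channel_attention(xc, w1, w2)[, 1, 1], p * s,
               tolerance = 1e-10)
  # single-channel spatial attention: mean map == max map == x
  x1 <- array(rnorm(36), c(1, 6, 6))
  wsa <- array(rnorm(7 * 7 * 2), c(7, 7, 2, 1))
  cat_self <- array(0, c(2, 6, 6))
  cat_self[1, , ] <- x1[1, , ]; cat_self[2, , ] <- x1[1, , ]
  lg <- naive_conv2d(cat_self, wsa, pad = 3, bias = 0)
  expect_equal(spatial_attention(x1, wsa, 0),
               x1 * array(1 / (1 + exp(-lg)), dim(x1)), tolerance = 1e-10)
})

test_that("the MSDC stem halves space, concatenates 192 channels, and checks size", {
  net <- build_network(model_config(), seed = 2)
  x <- array(rnorm(3 * 200 * 32), c(3, 200, 32))
  y <- msdc_forward(net, x)
  expect_equal(dim(y), c(64, 100, 16))
  # fusion conv consumes 3 x 64 = 192 concatenated channels
  expect_match(net$layers$detail[net$layers$name == "stem.fuse.conv"],
               "192->64")
  # all-zero input stays zero through the bias-free, zero-shifted stem
  expect_true(all(msdc_forward(net, array(0, c(3, 200, 32))) == 0))
  expect_error(msdc_forward(net, array(0, c(3, 5, 5))), "spatial dims")
  expect_error(msdc_forward(build_network(model_config(use_msdc = FALSE),
                                          seed = 1), x), "without")
})

test_that("depthwise/pointwise factorization isolates then mixes channels", {
  set.seed(13)
  x <- array(rnorm(4 * 6 * 6), c(4, 6, 6))
  # identity factorization: centered delta depthwise, identity pointwise
  wd <- array(0, c(3, 3, 4)); wd[2, 2, ] <- 1
  expect_equal(dsc_conv_forward(x, wd, diag(4)), x, tolerance = 1e-12)
  # matches the two-step naive oracle
  wd2 <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  wp <- matrix(rnorm(3 * 4), 3, 4)
  step1 <- naive_conv2d(x, array(wd2, c(3, 3, 1, 4)), stride = 1, pad = 1,
                        groups = 4)
  wp4 <- array(t(wp), c(1, 1, 4, 3))
  expect_equal(dsc_conv_forward(x, wd2, wp),
               naive_conv2d(step1, wp4), tolerance = 1e-10)
  # depthwise stage: perturbing channel 1 leaves other channels untouched
  x2 <- x; x2[1, , ] <- x2[1, , ] + rnorm(36)
  y1 <- dsc_conv_forward(x, wd2, diag(4))
  y2 <- dsc_conv_forward(x2, wd2, diag(4))
  expect_equal(y1[2:4, , ], y2[2:4, , ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(y1[1, , ], y2[1, , ])))
  expect_error(dsc_conv_forward(x, wd2[, , 1:2], diag(4)), "one kernel")
  expect_error(dsc_conv_forward(x, wd2, diag(3)), "Cin mismatch")
})

test_that("residual blocks pass identity when the branch is silenced", {
  net <- build_network(tiny_cfg, seed = 3)
  # zero every branch weight of stage1.block1 (stride 1, identity shortcut)
  for (k in grep("^stage1\\.block1\\.", ls(net$params), value = TRUE))
    net$params[[k]] <- net$params[[k]] * 0
  # batch norm gammas zeroed too => branch output is exactly 0
  x <- array(abs(rnorm(10 * 8 * 4 * 2)), c(10, 8, 4, 2))  # non-negative
  ctx <- list(params = net$params, buffers = net$buffers, training = FALSE)
  blk <- net$spec$children[[3]]  # first body block
  out <- lmcsleep:::net_fw_node(blk, x, ctx)$out
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("stride-2 blocks and the global pool give the pinned shape ladder", {
  net <- build_network(model_config(), seed = 4)
  x <- array(rnorm(200 * 32 * 3 * 2), c(200, 32, 3, 2))
  ctx <- list(params = net$params, buffers = net$buffers, training = FALSE)
  h <- lmcsleep:::net_fw_node(net$spec$children[[1]], x, ctx)$out  # stem
  expect_equal(dim(h), c(100, 16, 64, 2))
  h <- lmcsleep:::net_fw_node(net$spec$children[[2]], h, ctx)$out  # maxpool
  expect_equal(dim(h), c(50, 8, 64, 2))
  h <- lmcsleep:::net_fw_node(net$spec$children[[3]], h, ctx)$out
  h <- lmcsleep:::net_fw_node(net$spec$children[[4]], h, ctx)$out
  expect_equal(dim(h), c(50, 8, 64, 2))                            # stage 1
  h <- lmcsleep:::net_fw_node(net$spec$children[[5]], h, ctx)$out
  expect_equal(dim(h), c(25, 4, 128, 2))                           # stage 2/1
  # full forward flows to 5 softmax classes from varying input sizes
  for (dims in list(c(200, 32), c(48, 37), c(32, 32))) {
    xi <- array(rnorm(dims[1] * dims[2] * 3 * 2), c(dims, 3, 2))
    p <- network_forward(net, xi)$probabilities
    expect_equal(dim(p), c(5, 2))
    expect_equal(colSums(p), c(1, 1), tolerance = 1e-6)
  }
})

test_that("softmax classification yields calibrated probabilities", {
  p <- classify(rep(0, 4), matrix(0, 5, 4), rep(0, 5))
  expect_equal(p$probabilities, rep(0.2, 5), tolerance = 1e-12)
  # z = (1,0,0,0,0)
  w <- matrix(0, 5, 4); b <- c(1, 0, 0, 0, 0)
  p2 <- classify(rep(0, 4), w, b)
  expect_equal(p2$probabilities,
               c(0.4046, 0.1488, 0.1488, 0.1488, 0.1488), tolerance = 1e-3)
  expect_equal(as.character(p2$stage), "W")
  set.seed(6)
  z <- matrix(rnorm(50), 5, 10)
  expect_equal(colSums(softmax(z)), rep(1, 10), tolerance = 1e-6)
})

test_that("training-mode batch norm and dropout are seed-reproducible", {
  net <- build_network(tiny_cfg, seed = 5)
  x <- array(rnorm(40 * 32 * 3 * 4), c(40, 32, 3, 4))
  set.seed(99)
  a <- network_forward(net, x, training = TRUE)$logits
  set.seed(99)
  b <- network_forward(net, x, training = TRUE)$logits
  expect_identical(a, b)
})

test_that("checkpoints restore weights, buffers and the exact forward pass", {
  net <- build_network(tiny_cfg, seed = 17)
  x <- array(rnorm(40 * 32 * 3 * 2), c(40, 32, 3, 2))
  # run one training-mode pass so running stats differ from their init
  set.seed(17)
  invisible(network_forward(net, x, training = TRUE))
  path <- withr::local_tempfile(fileext = ".rds")
  save_network(net, path)
  net2 <- load_network(path)
  expect_identical(network_forward(net, x)$logits,
                   network_forward(net2, x)$logits)
  saveRDS(1:3, path)
  expect_error(load_network(path), "not a network checkpoint")
})
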