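#' Network configuration
#'
#' Architecture knobs of the lightweight sleep-staging network. The default
#' is the fully pinned model: a multi-scale dilated-convolution (MSDC) stem
#' with dilation rates 1/2/3 and concat fusion, a depthwise-separable
#' ResNet18-style body (widths 64/128/256/512, two basic blocks per stage),
#' CBAM attention (reduction 16, 7x7 spatial kernel) after stage 4, and a
#' 5-class softmax head. The three `use_*` flags reproduce the ablation grid:
#' all `FALSE` is the standard residual baseline, `use_cbam` adds attention,
#' `use_dsc` swaps every 3x3 body conv for depthwise + pointwise stages (each
#' followed by batch norm), `use_msdc` replaces the 7x7 stem.
#'
#' @param in_channels Input channels (3: two EEG + one EOG scalogram).
#' @param dilations Strictly increasing positive dilation rates of the stem
#'   branches.
#' @param stage_widths Channel widths of the four residual stages.
#' @param blocks_per_stage Residual blocks per stage.
#' @param stem_branch_channels Channels of each dilated stem branch.
#' @param stem_fused_channels Stem output channels (after 1x1 fusion).
#' @param use_dsc,use_cbam,use_msdc Ablation flags.
#' @param cbam_reduction Channel-attention bottleneck ratio; must divide the
#'   last stage width.
#' @param spatial_kernel Spatial-attention kernel size (odd).
#' @param num_classes Output classes (5 sleep stages; 1000 reproduces the
#'   ImageNet-configured baseline).
#' @param dropout_p Dropout probability before the fully connected head.
#' @param msdc_fusion "concat" (channel concatenation + 1x1 fusion conv,
#'   default) or "add" (branch summation, no fusion conv).
#' @return Object of class `lmc_model_config`.
#' @export
model_config <- function(in_channels = 3, dilations = c(1, 2, 3),
                         stage_widths = c(64, 128, 256, 512),
                         blocks_per_stage = 2,
                         stem_branch_channels = stage_widths[1],
                         stem_fused_channels = stage_widths[1],
                         use_dsc = TRUE, use_cbam = TRUE, use_msdc = TRUE,
                         cbam_reduction = 16, spatial_kernel = 7,
                         num_classes = 5, dropout_p = 0.5,
                         msdc_fusion = c("concat", "add")) {
  msdc_fusion <- match.arg(msdc_fusion)
  if (any(dilations <= 0) || any(dilations != floor(dilations)) ||
      any(diff(dilations) <= 0))
    stop("dilations must be strictly increasing positive integers")
  last_w <- stage_widths[length(stage_widths)]
  if (last_w %% cbam_reduction != 0)
    stop("cbam_reduction (", cbam_reduction, ") must divide the last stage ",
         "width (", last_w, ")")
  if (spatial_kernel %% 2 != 1) stop("spatial_kernel must be odd")
  if (msdc_fusion == "add" && stem_branch_channels != stem_fused_channels)
    stop("'add' fusion requires stem_branch_channels == stem_fused_channels")
  structure(list(in_channels = in_channels, dilations = as.integer(dilations),
                 stage_widths = as.integer(stage_widths),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 stem_branch_channels = as.integer(stem_branch_channels),
                 stem_fused_channels = as.integer(stem_fused_channels),
                 use_dsc = use_dsc, use_cbam = use_cbam, use_msdc = use_msdc,
                 cbam_reduction = as.integer(cbam_reduction),
                 spatial_kernel = as.integer(spatial_kernel),
                 num_classes = as.integer(num_classes),
                 dropout_p = dropout_p, msdc_fusion = msdc_fusion),
            class = "lmc_model_config")
}

# --- node constructors (internal graph description) -------------------------

nd_conv <- function(name, kh, kw, cin, cout, stride = 1, dil = 1, pad = 0,
                    groups = 1, bias = FALSE)
  list(kind = "conv", name = name, kh = kh, kw = kw, cin = cin, cout = cout,
       stride = stride, dil = dil, pad = pad, groups = groups, bias = bias)

nd_bn <- function(name, c) list(kind = "bn", name = name, c = c)
nd_relu <- function() list(kind = "relu")
nd_maxpool <- function(k = 3, stride = 2, pad = 1)
  list(kind = "maxpool", k = k, stride = stride, pad = pad)
nd_gap <- function() list(kind = "gap")
nd_dropout <- function(p) list(kind = "dropout", p = p)
nd_fc <- function(name, cin, cout)
  list(kind = "fc", name = name, cin = cin, cout = cout)
nd_seq <- function(...) list(kind = "seq", children = list(...))
nd_ca <- function(name, c, r) list(kind = "ca", name = name, c = c, r = r)
nd_sa <- function(name, k) list(kind = "sa", name = name, k = k)

# one conv "unit" (conv + bn, or dw + bn + pw + bn when depthwise-separable)
unit_nodes <- function(prefix, cin, cout, stride, dsc) {
  if (dsc) {
    list(nd_conv(paste0(prefix, ".dw"), 3, 3, cin, cin, stride = stride,
                 pad = 1, groups = cin),
         nd_bn(paste0(prefix, ".bn_dw"), cin),
         nd_conv(paste0(prefix, ".pw"), 1, 1, cin, cout),
         nd_bn(paste0(prefix, ".bn_pw"), cout))
  } else {
    list(nd_conv(paste0(prefix, ".conv"), 3, 3, cin, cout, stride = stride,
                 pad = 1),
         nd_bn(paste0(prefix, ".bn"), cout))
  }
}

nd_block <- function(prefix, cin, cout, stride, dsc) {
  branch <- nd_seq()
  branch$children <- c(unit_nodes(paste0(prefix, ".u1"), cin, cout, stride,
                                  dsc),
                       list(nd_relu()),
                       unit_nodes(paste0(prefix, ".u2"), cout, cout, 1, dsc))
  shortcut <- NULL
  if (stride != 1 || cin != cout)
    shortcut <- nd_seq(nd_conv(paste0(prefix, ".down.conv"), 1, 1, cin, cout,
                               stride = stride),
                       nd_bn(paste0(prefix, ".down.bn"), cout))
  list(kind = "block", branch = branch, shortcut = shortcut)
}

nd_msdc <- function(cfg) {
  branches <- lapply(cfg$dilations, function(d)
    list(conv = nd_conv(sprintf("stem.b%d.conv", d), 3, 3, cfg$in_channels,
                        cfg$stem_branch_channels, stride = 2, dil = d,
                        pad = d),
         bn = nd_bn(sprintf("stem.b%d.bn", d), cfg$stem_branch_channels)))
  node <- list(kind = "msdc", fusion = cfg$msdc_fusion, branches = branches,
               dilations = cfg$dilations)
  if (cfg$msdc_fusion == "concat") {
    cat_ch <- length(cfg$dilations) * cfg$stem_branch_channels
    node$fuse_conv <- nd_conv("stem.fuse.conv", 1, 1, cat_ch,
                              cfg$stem_fused_channels)
    node$fuse_bn <- nd_bn("stem.fuse.bn", cfg$stem_fused_channels)
  }
  node
}

# --- parameter initialization and bookkeeping -------------------------------

node_param_shapes <- function(node) {
  switch(node$kind,
    conv = {
      sh <- list(weight = c(node$kh, node$kw, node$cin / node$groups,
                            node$cout))
      if (node$bias) sh$bias <- node$cout
      sh
    },
    bn = list(gamma = node$c, beta = node$c),
    fc = list(weight = c(node$cout, node$cin), bias = node$cout),
    ca = list(w1 = c(node$c / node$r, node$c), w2 = c(node$c, node$c / node$r)),
    sa = list(weight = c(node$k, node$k, 2, 1), bias = 1),
    NULL)
}

init_param <- function(node, pname, shape) {
  n <- prod(shape)
  v <- switch(node$kind,
    conv = if (pname == "weight")
      rnorm(n, sd = sqrt(2 / (node$kh * node$kw * node$cin / node$groups)))
      else rep(0, n),
    bn = if (pname == "gamma") rep(1, n) else rep(0, n),
    fc = if (pname == "weight") rnorm(n, sd = sqrt(2 / node$cin))
      else rep(0, n),
    ca = if (pname == "w1") rnorm(n, sd = sqrt(2 / node$c))
      else rnorm(n, sd = sqrt(2 / (node$c / node$r))),
    sa = if (pname == "weight") rnorm(n, sd = sqrt(2 / (node$k * node$k * 2)))
      else rep(0, n))
  if (length(shape) > 1) array(v, shape) else v
}

walk_nodes <- function(node, fn) {
  if (is.null(node)) return(invisible())
  fn(node)
  switch(node$kind,
    seq = for (ch in node$children) walk_nodes(ch, fn),
    msdc = {
      for (b in node$branches) { walk_nodes(b$conv, fn); walk_nodes(b$bn, fn) }
      walk_nodes(node$fuse_conv, fn)
      walk_nodes(node$fuse_bn, fn)
    },
    block = { walk_nodes(node$branch, fn); walk_nodes(node$shortcut, fn) })
  invisible()
}

#' Build the sleep-staging network
#'
#' Materializes the layer graph described by a [model_config()]: the
#' ordered layer table, all trainable parameters (He-initialized
#' convolutions, unit-gain batch norms, zero biases) and the batch-norm
#' running statistics. All convolutions are bias-free except the spatial
#' attention conv; the fully connected head has a bias.
#'
#' @param config A [model_config()].
#' @param seed Optional RNG seed for the initialization.
#' @return Object of class `lmc_network`: list with `spec` (layer graph),
#'   `params`/`buffers` (environments), `layers` (tibble description),
#'   `total_parameters`, `config`.
#' @export
build_network <- function(config = model_config(), seed = NULL) {
  stopifnot(inherits(config, "lmc_model_config"))
  if (!is.null(seed)) set.seed(seed)
  w <- config$stage_widths
  stem <- if (config$use_msdc) {
    s <- nd_seq(nd_msdc(config))
    s$children <- c(s$children, list(nd_relu()))
    s
  } else {
    nd_seq(nd_conv("stem.conv", 7, 7, config$in_channels,
                   config$stem_fused_channels, stride = 2, pad = 3),
           nd_bn("stem.bn", config$stem_fused_channels),
           nd_relu())
  }
  body <- list()
  cin <- config$stem_fused_channels
  for (s in seq_along(w)) {
    for (b in seq_len(config$blocks_per_stage)) {
      stride <- if (s > 1 && b == 1) 2 else 1
      body[[length(body) + 1]] <-
        nd_block(sprintf("stage%d.block%d", s, b), cin, w[s], stride,
                 config$use_dsc)
      cin <- w[s]
    }
  }
  children <- c(list(stem, nd_maxpool()), body)
  if (config$use_cbam)
    children <- c(children,
                  list(nd_ca("cbam.ca", w[length(w)], config$cbam_reduction),
                       nd_sa("cbam.sa", config$spatial_kernel)))
  children <- c(children, list(nd_gap(), nd_dropout(config$dropout_p),
                               nd_fc("head.fc", w[length(w)],
                                     config$num_classes)))
  spec <- list(kind = "seq", children = children)
  params <- new.env(parent = emptyenv())
  buffers <- new.env(parent = emptyenv())
  rows <- list()
  walk_nodes(spec, function(node) {
    shapes <- node_param_shapes(node)
    if (is.null(shapes)) return()
    n_par <- 0
    for (pname in names(shapes)) {
      key <- paste0(node$name, ".", pname)
      params[[key]] <- init_param(node, pname, shapes[[pname]])
      n_par <- n_par + prod(shapes[[pname]])
    }
    if (node$kind == "bn") {
      buffers[[paste0(node$name, ".run_mean")]] <- rep(0, node$c)
      buffers[[paste0(node$name, ".run_var")]] <- rep(1, node$c)
    }
    detail <- switch(node$kind,
      conv = sprintf("%dx%d s%d d%d g%d %d->%d", node$kh, node$kw,
                     node$stride, node$dil, node$groups, node$cin, node$cout),
      bn = sprintf("batchnorm %d", node$c),
      fc = sprintf("fc %d->%d", node$cin, node$cout),
      ca = sprintf("channel attention C=%d r=%d", node$c, node$r),
      sa = sprintf("spatial attention k=%d", node$k))
    rows[[length(rows) + 1]] <<- tibble::tibble(
      name = node$name, kind = node$kind, detail = detail,
      shapes = paste(vapply(shapes, function(s)
        paste(s, collapse = "x"), ""), collapse = " + "),
      n_params = n_par)
  })
  layers <- dplyr::bind_rows(rows)
  structure(list(spec = spec, params = params, buffers = buffers,
                 layers = layers,
                 total_parameters = sum(layers$n_params), config = config),
            class = "lmc_network")
}

#' @export
print.lmc_network <- function(x, ...) {
  cat("<lmc_network> ", nrow(x$layers), " parameterized layers, ",
      format(x$total_parameters, big.mark = ","), " trainable parameters (",
      sprintf("%.2f M", x$total_parameters / 1e6), ")\n", sep = "")
  cat("  msdc=", x$config$use_msdc, " dsc=", x$config$use_dsc,
      " cbam=", x$config$use_cbam, " classes=", x$config$num_classes, "\n",
      sep = "")
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution weights, batch-norm affine
#' pairs, attention weights, fully connected weight and bias). Verified to
#' equal the sum of the per-layer description table.
#'
#' @param net An `lmc_network`.
#' @return Integer scalar.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "lmc_network"))
  sum(vapply(ls(net$params), function(k) length(net$params[[k]]), 1))
}

#' Per-component parameter breakdown
#'
#' @param net An `lmc_network`.
#' @return Tibble with columns `component` (stem/body/cbam/head) and
#'   `n_params`.
#' @export
parameter_breakdown <- function(net) {
  comp <- dplyr::case_when(
    grepl("^stem", net$layers$name) ~ "stem",
    grepl("^stage", net$layers$name) ~ "body",
    grepl("^cbam", net$layers$name) ~ "cbam",
    TRUE ~ "head")
  net$layers |>
    dplyr::mutate(component = comp) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(n_params = sum(.data$n_params), .groups = "drop")
}

#' @rdname count_parameters
#' @param x Network to describe.
#' @param ... Unused.
#' @export
tidy.lmc_network <- function(x, ...) x$layers

#' @rdname count_parameters
#' @export
glance.lmc_network <- function(x, ...) {
  tibble::tibble(total_parameters = x$total_parameters,
                 params_m = round(x$total_parameters / 1e6, 2),
                 use_msdc = x$config$use_msdc, use_dsc = x$config$use_dsc,
                 use_cbam = x$config$use_cbam,
                 num_classes = x$config$num_classes)
}

# --- forward / backward interpreter -----------------------------------------

pget <- function(ctx, key) {
  v <- ctx$params[[key]]
  if (is.null(v)) stop("missing parameter: ", key)
  v
}

net_fw_node <- function(node, x, ctx) {
  switch(node$kind,
    conv = {
      b <- if (node$bias) pget(ctx, paste0(node$name, ".bias")) else NULL
      r <- conv_fw_impl(x, pget(ctx, paste0(node$name, ".weight")),
                        node$stride, node$dil, node$pad, node$groups, b,
                        keep_col = isTRUE(ctx$training))
      list(out = r$out, cache = r$cache)
    },
    bn = {
      nm <- node$name
      r <- bn_fw_impl(x, pget(ctx, paste0(nm, ".gamma")),
                      pget(ctx, paste0(nm, ".beta")),
                      ctx$buffers[[paste0(nm, ".run_mean")]],
                      ctx$buffers[[paste0(nm, ".run_var")]], ctx$training)
      if (ctx$training) {
        ctx$buffers[[paste0(nm, ".run_mean")]] <- r$run_mean
        ctx$buffers[[paste0(nm, ".run_var")]] <- r$run_var
      }
      list(out = r$out, cache = r$cache)
    },
    relu = relu_fw_impl(x),
    maxpool = maxpool_fw_impl(x, node$k, node$stride, node$pad),
    gap = gap_fw_impl(x),
    dropout = dropout_fw_impl(x, node$p, ctx$training),
    fc = {
      r <- fc_fw_impl(x, pget(ctx, paste0(node$name, ".weight")),
                      pget(ctx, paste0(node$name, ".bias")))
      list(out = r$out, cache = r$cache)
    },
    seq = {
      caches <- vector("list", length(node$children))
      for (i in seq_along(node$children)) {
        r <- net_fw_node(node$children[[i]], x, ctx)
        x <- r$out
        caches[[i]] <- r$cache
      }
      list(out = x, cache = caches)
    },
    msdc = msdc_fw(node, x, ctx),
    block = {
      br <- net_fw_node(node$branch, x, ctx)
      if (is.null(node$shortcut)) {
        sc_out <- x
        sc_cache <- NULL
      } else {
        sc <- net_fw_node(node$shortcut, x, ctx)
        sc_out <- sc$out
        sc_cache <- sc$cache
      }
      z <- br$out + sc_out
      r <- relu_fw_impl(z)
      list(out = r$out, cache = list(branch = br$cache, shortcut = sc_cache,
                                     relu = r$cache))
    },
    ca = {
      r <- ca_fw_impl(x, pget(ctx, paste0(node$name, ".w1")),
                      pget(ctx, paste0(node$name, ".w2")))
      list(out = r$out, cache = r$cache)
    },
    sa = {
      r <- sa_fw_impl(x, pget(ctx, paste0(node$name, ".weight")),
                      pget(ctx, paste0(node$name, ".bias")))
      list(out = r$out, cache = r$cache)
    },
    stop("unknown node kind: ", node$kind))
}

msdc_fw <- function(node, x, ctx) {
  d <- dim(x)
  span <- 2 * max(node$dilations) + 1
  if (d[1] < span || d[2] < span)
    stop("MSDC stem needs input spatial dims >= ", span, "; got ",
         d[1], "x", d[2])
  bouts <- lapply(node$branches, function(b) {
    r1 <- net_fw_node(b$conv, x, ctx)
    r2 <- net_fw_node(b$bn, r1$out, ctx)
    list(out = r2$out, conv = r1$cache, bn = r2$cache)
  })
  if (node$fusion == "add") {
    z <- bouts[[1]]$out
    for (i in seq_along(bouts)[-1]) z <- z + bouts[[i]]$out
    r <- relu_fw_impl(z)
    return(list(out = r$out,
                cache = list(branches = bouts, relu = r$cache,
                             cat_dims = NULL)))
  }
  db <- dim(bouts[[1]]$out)
  cat_x <- cat_channels_cpp(lapply(bouts, function(b) b$out))
  rf <- net_fw_node(node$fuse_conv, cat_x, ctx)
  rb <- net_fw_node(node$fuse_bn, rf$out, ctx)
  list(out = rb$out,
       cache = list(branches = bouts, fuse_conv = rf$cache,
                    fuse_bn = rb$cache, cat_dims = dim(cat_x), bdim = db))
}

acc_grad <- function(ctx, key, g) {
  cur <- ctx$grads[[key]]
  ctx$grads[[key]] <- if (is.null(cur)) g else cur + g
}

net_bw_node <- function(node, cache, dout, ctx) {
  switch(node$kind,
    conv = {
      need_dx <- !(node$name %in% ctx$input_convs)
      r <- conv_bw_impl(cache, dout, need_dx)
      acc_grad(ctx, paste0(node$name, ".weight"), r$dw)
      if (node$bias) acc_grad(ctx, paste0(node$name, ".bias"), r$db)
      r$dx
    },
    bn = {
      r <- bn_bw_impl(cache, dout)
      acc_grad(ctx, paste0(node$name, ".gamma"), r$dgamma)
      acc_grad(ctx, paste0(node$name, ".beta"), r$dbeta)
      r$dx
    },
    relu = relu_bw_impl(cache, dout),
    maxpool = maxpool_bw_impl(cache, dout),
    gap = gap_bw_impl(cache, dout),
    dropout = dropout_bw_impl(cache, dout),
    fc = {
      r <- fc_bw_impl(cache, dout)
      acc_grad(ctx, paste0(node$name, ".weight"), r$dw)
      acc_grad(ctx, paste0(node$name, ".bias"), r$db)
      r$dx
    },
    seq = {
      for (i in rev(seq_along(node$children)))
        dout <- net_bw_node(node$children[[i]], cache[[i]], dout, ctx)
      dout
    },
    msdc = msdc_bw(node, cache, dout, ctx),
    block = {
      dz <- relu_bw_impl(cache$relu, dout)
      dx <- net_bw_node(node$branch, cache$branch, dz, ctx)
      if (is.null(node$shortcut)) dx + dz
      else dx + net_bw_node(node$shortcut, cache$shortcut, dz, ctx)
    },
    ca = {
      r <- ca_bw_impl(cache, dout)
      acc_grad(ctx, paste0(node$name, ".w1"), r$dw1)
      acc_grad(ctx, paste0(node$name, ".w2"), r$dw2)
      r$dx
    },
    sa = {
      r <- sa_bw_impl(cache, dout)
      acc_grad(ctx, paste0(node$name, ".weight"), r$dw)
      acc_grad(ctx, paste0(node$name, ".bias"), r$db)
      r$dx
    },
    stop("unknown node kind: ", node$kind))
}

msdc_bw <- function(node, cache, dout, ctx) {
  back_branch <- function(b, cache_b, d) {
    d1 <- net_bw_node(b$bn, cache_b$bn, d, ctx)
    net_bw_node(b$conv, cache_b$conv, d1, ctx)
  }
  if (node$fusion == "add") {
    dz <- relu_bw_impl(cache$relu, dout)
    dx <- NULL
    for (i in seq_along(node$branches)) {
      g <- back_branch(node$branches[[i]], cache$branches[[i]], dz)
      dx <- if (is.null(dx)) g else dx + g
    }
    return(dx)
  }
  dfuse <- net_bw_node(node$fuse_bn, cache$fuse_bn, dout, ctx)
  dcat <- net_bw_node(node$fuse_conv, cache$fuse_conv, dfuse, ctx)
  db <- cache$bdim
  dx <- NULL
  for (i in seq_along(node$branches)) {
    dslice <- slice_channels_cpp(dcat, (i - 1) * db[3] + 1, i * db[3])
    g <- back_branch(node$branches[[i]], cache$branches[[i]], dslice)
    dx <- if (is.null(dx)) g else dx + g
  }
  dx
}

#' Softmax over the rows of a logit matrix
#'
#' @param z Logit matrix `[num_classes x N]` (or vector).
#' @return Matrix of column-wise probabilities summing to 1.
#' @export
softmax <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(z))
}

#' Run the network forward
#'
#' @param net An `lmc_network`.
#' @param x Input batch: array `[H, W, C, N]` (internal layout) or
#'   `[N, C, H, W]` epoch-bundle layout (auto-detected via the channel
#'   dimension of the model config when `layout` is given).
#' @param training Logical; enables batch statistics, dropout, and
#'   running-stat updates.
#' @return List with `logits` `[num_classes x N]`, `probabilities`, and the
#'   backward `cache` (when `keep_cache`).
#' @param keep_cache Keep the layer caches for a backward pass.
#' @param layout `"hwcn"` (default) or `"nchw"`.
#' @export
network_forward <- function(net, x, training = FALSE, keep_cache = FALSE,
                            layout = c("hwcn", "nchw")) {
  layout <- match.arg(layout)
  if (layout == "nchw") x <- aperm(x, c(3, 4, 2, 1))
  ctx <- list(params = net$params, buffers = net$buffers,
              training = training)
  r <- net_fw_node(net$spec, x, ctx)
  out <- list(logits = r$out, probabilities = softmax(r$out))
  if (keep_cache) out$cache <- r$cache
  out
}

# one forward+backward pass; returns grads env and the loss pieces
network_backward <- function(net, cache, dlogits) {
  input_convs <- if (net$config$use_msdc)
    sprintf("stem.b%d.conv", net$config$dilations) else "stem.conv"
  ctx <- list(params = net$params, buffers = net$buffers, training = TRUE,
              grads = new.env(parent = emptyenv()),
              input_convs = input_convs)
  net_bw_node(net$spec, cache, dlogits, ctx)
  ctx$grads
}

#' Predict stages for an epoch bundle
#'
#' @param net A trained `lmc_network`.
#' @param bundle An `lmc_epoch_bundle` (or an `[N, C, H, W]` array).
#' @param batch_size Evaluation minibatch size.
#' @return Tibble with `predicted` (factor), per-class probability columns,
#'   and `truth` when the bundle carries labels.
#' @export
predict_stages <- function(net, bundle, batch_size = 128) {
  x <- if (inherits(bundle, "lmc_epoch_bundle")) bundle$tfr else bundle
  n <- dim(x)[1]
  probs <- matrix(0, n, net$config$num_classes)
  for (i0 in seq(1, n, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1, n)
    xb <- aperm(x[idx, , , , drop = FALSE], c(3, 4, 2, 1))
    probs[idx, ] <- t(network_forward(net, xb)$probabilities)
  }
  out <- tibble::tibble(
    predicted = stage_factor(max.col(probs, ties.method = "first") - 1L))
  colnames(probs) <- paste0("p_", STAGE_LEVELS[seq_len(ncol(probs))])
  out <- dplyr::bind_cols(out, tibble::as_tibble(probs))
  if (inherits(bundle, "lmc_epoch_bundle")) out$truth <- bundle$label
  out
}

# --- single-sample functional operator surface ------------------------------

chw_to_batch <- function(x) {
  d <- dim(x)
  array(aperm(x, c(2, 3, 1)), c(d[2], d[3], d[1], 1))
}

batch_to_chw <- function(y) {
  d <- dim(y)
  aperm(array(y, d[1:3]), c(3, 1, 2))
}

#' Multi-scale dilated stem forward pass
#'
#' Applies a built network's stem (three parallel dilated 3x3 stride-2
#' convolutions with batch norm, channel concatenation, 1x1 fusion, ReLU) to
#' a single `[C, H, W]` input.
#'
#' @param net An `lmc_network` built with `use_msdc = TRUE`.
#' @param x Array `[C, H, W]` with spatial dims at least `2 * max(dilation)
#'   + 1`.
#' @return Array `[stem_channels, ceil(H/2), ceil(W/2)]`.
#' @export
msdc_forward <- function(net, x) {
  if (!net$config$use_msdc) stop("network was built without the MSDC stem")
  ctx <- list(params = net$params, buffers = net$buffers, training = FALSE)
  r <- net_fw_node(net$spec$children[[1]], chw_to_batch(x), ctx)
  batch_to_chw(r$out)
}

#' Depthwise separable convolution (functional form)
#'
#' Depthwise stage: one `[kh, kw]` kernel per input channel, no channel
#' mixing. Pointwise stage: 1x1 convolution mixing channels only. No
#' normalization or nonlinearity (the network inserts batch norm after each
#' stage).
#'
#' @param x Array `[Cin, H, W]`.
#' @param wd Depthwise kernels `[kh, kw, Cin]`.
#' @param wp Pointwise weights `[Cout, Cin]`.
#' @param stride Depthwise stride.
#' @return Array `[Cout, H', W']`.
#' @export
dsc_conv_forward <- function(x, wd, wp, stride = 1) {
  d <- dim(x)
  dwd <- dim(wd)
  if (length(dwd) != 3 || dwd[3] != d[1])
    stop("wd must be [kh, kw, Cin] with one kernel per input channel")
  if (ncol(wp) != d[1]) stop("wp must be [Cout, Cin]; Cin mismatch")
  xb <- chw_to_batch(x)
  w4 <- array(wd, c(dwd[1], dwd[2], 1, dwd[3]))
  r1 <- conv_fw_impl(xb, w4, stride = stride, pad = (dwd[1] - 1) / 2,
                     groups = d[1])
  wp4 <- array(t(wp), c(1, 1, d[1], nrow(wp)))
  r2 <- conv_fw_impl(r1$out, wp4)
  batch_to_chw(r2$out)
}

#' CBAM channel attention (functional form)
#'
#' `x * sigmoid(MLP(avgpool(x)) + MLP(maxpool(x)))` with a shared bias-free
#' bottleneck MLP (C -> C/r -> C, ReLU in between); per-channel weights in
#' (0, 1) broadcast over space; shape preserved.
#'
#' @param x Array `[C, H, W]`.
#' @param w1 Bottleneck weight `[C/r, C]`.
#' @param w2 Expansion weight `[C, C/r]`.
#' @return Array of the same shape as `x`.
#' @export
channel_attention <- function(x, w1, w2) {
  batch_to_chw(ca_fw_impl(chw_to_batch(x), w1, w2)$out)
}

#' CBAM spatial attention (functional form)
#'
#' Channel-wise mean and max maps, concatenated, convolved with a `k x k`
#' 2-in/1-out kernel (padding `(k-1)/2`, bias), sigmoid, broadcast over
#' channels; shape preserved.
#'
#' @param x Array `[C, H, W]`.
#' @param w Conv kernel `[k, k, 2, 1]`.
#' @param b Scalar bias.
#' @return Array of the same shape as `x`.
#' @export
spatial_attention <- function(x, w, b = 0) {
  batch_to_chw(sa_fw_impl(chw_to_batch(x), w, b)$out)
}

#' Sequential CBAM (channel then spatial attention)
#'
#' @inheritParams channel_attention
#' @param w_sa,b_sa Spatial-attention conv kernel and bias.
#' @return Array of the same shape as `x`.
#' @export
cbam <- function(x, w1, w2, w_sa, b_sa = 0) {
  spatial_attention(channel_attention(x, w1, w2), w_sa, b_sa)
}

#' Softmax classifier head (functional form)
#'
#' `z = W f + b`, probabilities by softmax; the predicted stage is the
#' argmax.
#'
#' @param features Feature vector (length matching `ncol(weight)`).
#' @param weight FC weight `[num_classes, n_features]`.
#' @param bias FC bias (length `num_classes`).
#' @return Object of class `lmc_prediction`: list with `logits`,
#'   `probabilities`, `stage`.
#' @export
classify <- function(features, weight, bias) {
  z <- as.vector(weight %*% features + bias)
  p <- as.vector(softmax(z))
  stage <- if (length(p) == 5) stage_factor(which.max(p) - 1L)
           else which.max(p)
  structure(list(logits = z, probabilities = p, stage = stage),
            class = "lmc_prediction")
}

#' Save / load network weights
#'
#' Serializes the trainable parameters, batch-norm running statistics and
#' the embedded model configuration to an RDS checkpoint; loading rebuilds
#' the layer graph from the stored configuration and restores the weights.
#'
#' @param net An `lmc_network`.
#' @param path Checkpoint file path.
#' @return `save_network()` the path, invisibly; `load_network()` the
#'   restored `lmc_network`.
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "lmc_network"))
  saveRDS(list(config = net$config, params = as.list(net$params),
               buffers = as.list(net$buffers)), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  ck <- readRDS(path)
  if (!is.list(ck) || !inherits(ck$config, "lmc_model_config"))
    stop("file is not a network checkpoint: ", path)
  net <- build_network(ck$config)
  for (k in names(ck$params)) net$params[[k]] <- ck$params[[k]]
  for (k in names(ck$buffers)) net$buffers[[k]] <- ck$buffers[[k]]
  net
}
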