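# Layer-level forward/backward primitives. Batch tensor layout is the
# column-major array (H, W, C, N); convolution weights are (kh, kw,
# Cin/groups, Cout). Each *_fw returns list(out, cache); each *_bw consumes
# the cache and the upstream gradient.

# keep_col caches the im2col matrix for the backward pass; worthwhile for
# mid-sized groups==1 convolutions (the stem), skipped for 1x1 (fast path)
# and for huge unpacked matrices.
conv_fw_impl <- function(x, w, stride = 1, dil = 1, pad = 0, groups = 1,
                         bias = NULL, keep_col = FALSE) {
  dw <- dim(w)
  col <- NULL
  dx <- dim(x)
  use_col <- keep_col && groups == 1 && !(dw[1] == 1 && dw[2] == 1) &&
    prod(dw[1:3]) * (dx[1] * dx[2] / stride^2) * dx[4] < 5e6
  depthwise <- groups > 1 && groups == dx[3] && dw[4] == dx[3] &&
    dw[3] == 1 && dil == 1
  if (use_col) {
    r <- conv2d_fwcol_cpp(x, dim(x), w, dw, stride, dil, pad)
    out <- r$out
    col <- r$col
  } else if (depthwise) {
    out <- depthwise_fw_cpp(x, dim(x), w, dw, stride, pad)
  } else {
    out <- conv2d_fw_cpp(x, dim(x), w, dw, stride, dil, pad, groups)
  }
  if (!is.null(bias)) {
    d <- dim(out)
    out <- out + rep(rep(bias, each = d[1] * d[2]), times = d[4])
    dim(out) <- d
  }
  list(out = out,
       cache = list(x = if (is.null(col)) x else dim(x), w = w, col = col,
                    stride = stride, dil = dil, pad = pad,
                    groups = groups, depthwise = depthwise,
                    has_bias = !is.null(bias)))
}

conv_bw_impl <- function(cache, dout, need_dx = TRUE) {
  g <- if (!is.null(cache$col))
    conv2d_bwcol_cpp(cache$col, cache$x, cache$w, dim(cache$w), dout,
                     cache$stride, cache$dil, cache$pad, need_dx)
  else if (isTRUE(cache$depthwise))
    depthwise_bw_cpp(cache$x, dim(cache$x), cache$w, dim(cache$w), dout,
                     cache$stride, cache$pad, need_dx)
  else
    conv2d_bw_cpp(cache$x, dim(cache$x), cache$w, dim(cache$w), dout,
                  cache$stride, cache$dil, cache$pad, cache$groups,
                  need_dx)
  db <- NULL
  if (cache$has_bias) {
    d <- dim(dout)
    db <- rowSums(matrix(colSums(matrix(dout, d[1] * d[2])),
                         d[3], d[4]))
  }
  list(dx = g$dx, dw = g$dw, db = db)
}

# batch norm over (H, W, N) per channel
bn_fw_impl <- function(x, gamma, beta, run_mean, run_var, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  if (training) {
    st <- bn_stats_cpp(x, d)
    mu <- st$mean
    v <- st$var
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  inv_std <- 1 / sqrt(v + eps)
  out <- bn_norm_cpp(x, d, mu, inv_std, gamma, beta)
  list(out = out, run_mean = run_mean, run_var = run_var,
       cache = list(x = x, mu = mu, inv_std = inv_std, gamma = gamma,
                    d = d, batch_stats = training))
}

bn_bw_impl <- function(cache, dout) {
  r <- bn_bw_cpp(cache$x, cache$d, cache$mu, cache$inv_std, cache$gamma,
                 dout, cache$batch_stats)
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

relu_fw_impl <- function(x) {
  out <- relu_fw_cpp(x)
  list(out = out, cache = list(out = out))
}

relu_bw_impl <- function(cache, dout) relu_bw_cpp(dout, cache$out)

maxpool_fw_impl <- function(x, k = 3, stride = 2, pad = 1) {
  r <- maxpool_fw_cpp(x, dim(x), k, stride, pad)
  list(out = r$out,
       cache = list(arg = r$arg, xdim = dim(x), odim = dim(r$out)))
}

maxpool_bw_impl <- function(cache, dout)
  maxpool_bw_cpp(dout, cache$arg, cache$xdim, cache$odim)

# global average pool: (H,W,C,N) -> features (C,N)
gap_fw_impl <- function(x) {
  d <- dim(x)
  hw <- d[1] * d[2]
  feat <- matrix(colMeans(matrix(x, hw)), d[3], d[4])
  list(out = feat, cache = list(d = d))
}

gap_bw_impl <- function(cache, dout) {
  d <- cache$d
  hw <- d[1] * d[2]
  dx <- rep(as.vector(dout), each = hw) / hw
  dim(dx) <- d
  dx
}

dropout_fw_impl <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = list(mask = NULL)))
  mask <- (runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_bw_impl <- function(cache, dout)
  if (is.null(cache$mask)) dout else dout * cache$mask

fc_fw_impl <- function(x, w, b) {
  list(out = w %*% x + b, cache = list(x = x, w = w))
}

fc_bw_impl <- function(cache, dout) {
  list(dx = t(cache$w) %*% dout, dw = dout %*% t(cache$x),
       db = rowSums(dout))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# column-wise max and argmax over the rows of a (R x M) matrix, vectorized
# over rows (R is small in every use here)
rowwise_max <- function(m) {
  best <- m[1, ]
  arg <- rep.int(1L, ncol(m))
  nr <- nrow(m)
  if (nr > 1) {
    for (r in 2:nr) {
      upd <- m[r, ] > best
      best[upd] <- m[r, upd]
      arg[upd] <- r
    }
  }
  list(max = best, arg = arg)
}

# CBAM channel attention: shared bottleneck MLP (C -> C/r -> C, bias-free)
# on global average- and max-pooled descriptors, summed, sigmoid, broadcast.
ca_fw_impl <- function(x, w1, w2) {
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- matrix(x, hw)
  avg <- matrix(colMeans(xm), d[3], d[4])
  mm <- rowwise_max(xm)
  mx <- matrix(mm$max, d[3], d[4])
  mlp <- function(p) {
    h <- w1 %*% p
    hr <- pmax(h, 0)
    list(a = w2 %*% hr, h = h, hr = hr)
  }
  ma <- mlp(avg)
  mb <- mlp(mx)
  s <- sigmoid(ma$a + mb$a)
  sfull <- rep(as.vector(s), each = hw)
  out <- x * sfull
  dim(out) <- d
  list(out = out,
       cache = list(x = x, d = d, s = s, avg = avg, mx = mx, arg = mm$arg,
                    ma = ma, mb = mb, w1 = w1, w2 = w2))
}

ca_bw_impl <- function(cache, dout) {
  d <- cache$d
  hw <- d[1] * d[2]
  s <- cache$s
  dx <- dout * rep(as.vector(s), each = hw)
  dim(dx) <- d
  ds <- matrix(colSums(matrix(dout * cache$x, hw)), d[3], d[4])
  da <- ds * s * (1 - s)
  dw1 <- matrix(0, nrow(cache$w1), ncol(cache$w1))
  dw2 <- matrix(0, nrow(cache$w2), ncol(cache$w2))
  back_mlp <- function(m, p) {
    dhr <- t(cache$w2) %*% da
    dh <- dhr * (m$h > 0)
    dw2 <<- dw2 + da %*% t(m$hr)
    dw1 <<- dw1 + dh %*% t(p)
    t(cache$w1) %*% dh
  }
  dp_avg <- back_mlp(cache$ma, cache$avg)
  dp_max <- back_mlp(cache$mb, cache$mx)
  # average-pool path
  dx <- dx + rep(as.vector(dp_avg), each = hw) / hw
  dim(dx) <- d
  # max-pool path: scatter to the argmax spatial position of each column
  dxm <- matrix(0, hw, d[3] * d[4])
  dxm[cbind(cache$arg, seq_len(ncol(dxm)))] <- as.vector(dp_max)
  dx <- dx + array(dxm, d)
  list(dx = dx, dw1 = dw1, dw2 = dw2)
}

# CBAM spatial attention: channel-wise mean and max maps -> k x k conv
# (2 -> 1, bias) -> sigmoid -> broadcast over channels.
sa_fw_impl <- function(x, w, b) {
  d <- dim(x)
  hw <- d[1] * d[2]
  y <- array(x, c(hw, d[3], d[4]))
  yp <- aperm(y, c(1, 3, 2))                       # (hw, N, C)
  mu <- rowMeans(yp, dims = 2)                     # (hw, N)
  mx <- y[, 1, , drop = FALSE]
  dim(mx) <- c(hw, d[4])
  argc <- array(1L, c(hw, d[4]))
  if (d[3] > 1) {
    for (cc in 2:d[3]) {
      slice <- y[, cc, ]
      dim(slice) <- c(hw, d[4])
      upd <- slice > mx
      mx[upd] <- slice[upd]
      argc[upd] <- cc
    }
  }
  cat2 <- array(0, c(d[1], d[2], 2, d[4]))
  cat2[, , 1, ] <- mu
  cat2[, , 2, ] <- mx
  k <- dim(w)[1]
  cv <- conv_fw_impl(cat2, w, stride = 1, dil = 1, pad = (k - 1) / 2,
                     groups = 1, bias = b)
  s <- sigmoid(cv$out)                             # (H, W, 1, N)
  sm <- matrix(s, hw, d[4])
  sfull <- aperm(array(sm, c(hw, d[4], d[3])), c(1, 3, 2))
  out <- x * array(sfull, d)
  list(out = out,
       cache = list(x = x, d = d, s = s, sfull = sfull, conv = cv$cache,
                    argc = argc))
}

sa_bw_impl <- function(cache, dout) {
  d <- cache$d
  hw <- d[1] * d[2]
  dx <- dout * array(cache$sfull, d)
  dsf <- dout * cache$x
  z <- array(dsf, c(hw, d[3], d[4]))
  ds <- rowSums(aperm(z, c(1, 3, 2)), dims = 2)    # (hw, N), sum over C
  s <- cache$s
  dlogit <- array(as.vector(ds) * as.vector(s) * (1 - as.vector(s)),
                  dim(s))
  cb <- conv_bw_impl(cache$conv, dlogit)
  dmu <- cb$dx[, , 1, , drop = FALSE]
  dmx <- cb$dx[, , 2, , drop = FALSE]
  # mean path: spread over channels
  dmu_m <- matrix(dmu, hw, d[4])
  dx <- dx + array(aperm(array(dmu_m / d[3], c(hw, d[4], d[3])),
                         c(1, 3, 2)), d)
  # max path: scatter to argmax channel
  dmx_m <- matrix(dmx, hw, d[4])
  dxm <- array(0, c(hw, d[3], d[4]))
  idx <- cbind(rep(seq_len(hw), d[4]), as.vector(cache$argc),
               rep(seq_len(d[4]), each = hw))
  dxm[idx] <- as.vector(dmx_m)
  dx <- dx + array(dxm, d)
  list(dx = dx, dw = cb$dw, db = cb$db)
}
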