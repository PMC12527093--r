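# Naive nested-loop reference implementations used as independent oracles
# for the vectorized/C++ forward operators. Single-sample layout [C, H, W]
# matches the functional operator surface.

naive_conv2d <- function(x_chw, w, stride = 1, dil = 1, pad = 0,
                         groups = 1, bias = NULL) {
  d <- dim(x_chw)
  cin <- d[1]; h <- d[2]; wd <- d[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  cg <- cin / groups
  coutg <- cout / groups
  ho <- (h + 2 * pad - dil * (kh - 1) - 1) %/% stride + 1
  wo <- (wd + 2 * pad - dil * (kw - 1) - 1) %/% stride + 1
  out <- array(0, c(cout, ho, wo))
  for (co in seq_len(cout)) {
    g <- (co - 1) %/% coutg
    for (i in seq_len(ho)) {
      for (j in seq_len(wo)) {
        acc <- 0
        for (ki in seq_len(kh)) {
          for (kj in seq_len(kw)) {
            hi <- (i - 1) * stride - pad + dil * (ki - 1) + 1
            wi <- (j - 1) * stride - pad + dil * (kj - 1) + 1
            if (hi < 1 || hi > h || wi < 1 || wi > wd) next
            for (cc in seq_len(cg)) {
              acc <- acc + x_chw[g * cg + cc, hi, wi] * w[ki, kj, cc, co]
            }
          }
        }
        out[co, i, j] <- acc + if (is.null(bias)) 0 else bias[co]
      }
    }
  }
  out
}

naive_maxpool <- function(x_chw, k = 3, stride = 2, pad = 1) {
  d <- dim(x_chw)
  ho <- (d[2] + 2 * pad - k) %/% stride + 1
  wo <- (d[3] + 2 * pad - k) %/% stride + 1
  out <- array(0, c(d[1], ho, wo))
  for (cc in seq_len(d[1])) {
    for (i in seq_len(ho)) {
      for (j in seq_len(wo)) {
        vals <- c()
        for (ki in seq_len(k)) {
          for (kj in seq_len(k)) {
            hi <- (i - 1) * stride - pad + ki
            wi <- (j - 1) * stride - pad + kj
            if (hi >= 1 && hi <= d[2] && wi >= 1 && wi <= d[3])
              vals <- c(vals, x_chw[cc, hi, wi])
          }
        }
        out[cc, i, j] <- max(vals)
      }
    }
  }
  out
}

# channel attention per its defining formula, elementwise
naive_channel_attention <- function(x_chw, w1, w2) {
  d <- dim(x_chw)
  avg <- apply(x_chw, 1, mean)
  mx <- apply(x_chw, 1, max)
  mlp <- function(p) as.vector(w2 %*% pmax(w1 %*% p, 0))
  s <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  out <- x_chw
  for (cc in seq_len(d[1])) out[cc, , ] <- x_chw[cc, , ] * s[cc]
  out
}

naive_spatial_attention <- function(x_chw, w, b = 0) {
  d <- dim(x_chw)
  mu <- apply(x_chw, c(2, 3), mean)
  mx <- apply(x_chw, c(2, 3), max)
  cat2 <- array(0, c(2, d[2], d[3]))
  cat2[1, , ] <- mu
  cat2[2, , ] <- mx
  k <- dim(w)[1]
  logit <- naive_conv2d(cat2, w, stride = 1, dil = 1, pad = (k - 1) / 2,
                        bias = b)
  s <- 1 / (1 + exp(-logit[1, , ]))
  out <- x_chw
  for (cc in seq_len(d[1])) out[cc, , ] <- x_chw[cc, , ] * s
  out
}

# brute-force per-sample confusion counting
naive_confusion <- function(y_true, y_pred) {
  m <- matrix(0L, 5, 5)
  for (k in seq_along(y_true))
    m[y_true[k] + 1, y_pred[k] + 1] <- m[y_true[k] + 1, y_pred[k] + 1] + 1L
  m
}

# tiny deterministic recording for io tests
make_test_recording <- function(n_epochs = 3, fs = 100, seed = 7) {
  set.seed(seed)
  ds <- synth_dataset(1, n_epochs, seed = seed, artifact_rate = 0)
  ds$recordings[[1]]
}
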