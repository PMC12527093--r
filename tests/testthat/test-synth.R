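test_that("synthetic datasets are bit-reproducible and correctly sized", {
  d1 <- synth_dataset(3, 20, seed = 42)
  d2 <- synth_dataset(3, 20, seed = 42)
  expect_identical(d1$recordings[[2]]$channels[[1]],
                   d2$recordings[[2]]$channels[[1]])
  expect_identical(d1$recordings[[3]]$stages, d2$recordings[[3]]$stages)
  d3 <- synth_dataset(3, 20, seed = 43)
  expect_false(identical(d1$recordings[[1]]$channels[[1]],
                         d3$recordings[[1]]$channels[[1]]))
  # counting: subjects x epochs
  expect_length(d1$recordings, 3)
  expect_equal(nrow(tidy(d1)), 60)
  expect_equal(length(d1$recordings[[1]]$channels[[1]]), 20 * 3000)
})

test_that("one synthesized epoch is 3000 samples with stage-typical spectra", {
  set.seed(1)
  ep <- synth_epoch("N3", fs = 100)
  expect_equal(dim(ep), c(3000, 3))
  # component frequencies above Nyquist are rejected
  bad <- stage_profiles()
  bad$W$components[[1]]$freq_hi <- 60
  expect_error(synth_epoch("W", profiles = bad), "Nyquist")
  # determinism of a single epoch under an equal RNG state
  set.seed(3); a <- synth_epoch("N2")
  set.seed(3); b <- synth_epoch("N2")
  expect_identical(a, b)
})

test_that("periodogram peaks land in each stage's defining band", {
  set.seed(7)
  n_try <- 300
  hit_n3 <- 0
  hit_w <- 0
  for (i in seq_len(n_try)) {
    pk_n3 <- {
      x <- synth_epoch("N3")[, 1]
      which.max(vapply(seq(0.25, 20, by = 0.25), function(f)
        band_power(x, 100, f - 0.125, f + 0.125), 1)) * 0.25
    }
    if (pk_n3 >= 0.5 && pk_n3 <= 2) hit_n3 <- hit_n3 + 1
    pk_w <- {
      x <- synth_epoch("W")[, 1]
      which.max(vapply(seq(0.25, 20, by = 0.25), function(f)
        band_power(x, 100, f - 0.125, f + 0.125), 1)) * 0.25
    }
    if (pk_w >= 8 && pk_w <= 12) hit_w <- hit_w + 1
  }
  expect_gte(hit_n3 / n_try, 0.95)
  expect_gte(hit_w / n_try, 0.95)
})

test_that("realized stage proportions track the request in persistent runs", {
  props <- c(0.211, 0.065, 0.413, 0.132, 0.179)
  ds <- synth_dataset(3, 400, proportions = props, seed = 9,
                      artifact_rate = 0)
  for (rec in ds$recordings) {
    m <- map_stages_rk_to_aasm(rec$stages)
    realized <- as.vector(table(m$stage)) / length(rec$stages)
    expect_true(all(abs(realized - props) <= 0.02))
  }
  # and stages occur in multi-epoch runs, not i.i.d. shuffles
  codes <- map_stages_rk_to_aasm(ds$recordings[[1]]$stages)$code
  runs <- rle(codes)
  expect_gt(mean(runs$lengths), 2)
})

test_that("stages are linearly separable in band-power space", {
  # nearest-centroid on log band powers must clear 80% on held-out epochs;
  # this guarantees the network smoke test is achievable
  set.seed(15)
  n_per <- 40
  feats <- function(ep) {
    log(c(band_power(ep[, 1], 100, 0.5, 4), band_power(ep[, 1], 100, 4, 8),
          band_power(ep[, 1], 100, 8, 12), band_power(ep[, 1], 100, 12, 15),
          band_power(ep[, 3], 100, 0.3, 3)) + 1e-12)
  }
  xs <- list()
  ys <- integer(0)
  for (s in 0:4) {
    for (i in seq_len(n_per)) {
      xs[[length(xs) + 1]] <- feats(synth_epoch(s))
      ys <- c(ys, s)
    }
  }
  X <- do.call(rbind, xs)
  train <- rep(c(TRUE, FALSE), length.out = nrow(X))
  centroids <- vapply(0:4, function(s)
    colMeans(X[train & ys == s, , drop = FALSE]), numeric(ncol(X)))
  pred <- apply(X[!train, ], 1, function(f)
    which.min(colSums((centroids - f)^2)) - 1L)
  expect_gte(mean(pred == ys[!train]), 0.80)
})

test_that("scalograms of N2 epochs carry spindle-band energy in bursts", {
  set.seed(30)
  cfg <- scalogram_config()
  # spindle band 12-14 Hz maps to scales ~ 6.8-8.0 under f(a) = w0*fs/(2*pi*a)
  spindle_scales <- 7:8
  n2 <- replicate(6, {
    sc <- cwt_scalogram(synth_epoch("N2")[, 1], cfg)
    prof <- rowMeans(sc[, spindle_scales])  # time profile in the band
    max(prof) / (median(prof) + 1e-9)      # bursts: peak >> median
  })
  n1 <- replicate(6, {
    sc <- cwt_scalogram(synth_epoch("N1")[, 1], cfg)
    prof <- rowMeans(sc[, spindle_scales])
    max(prof) / (median(prof) + 1e-9)
  })
  expect_gt(median(n2), median(n1))
  expect_gt(median(n2), 3)
})
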