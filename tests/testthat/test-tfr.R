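cfg <- scalogram_config()

test_that("epoch segmentation discards the trailing remainder and artifacts", {
  fs <- 100
  mk_rec <- function(n_samples, stages) {
    set.seed(2)
    new_recording("T01", list(a = rnorm(n_samples), b = rnorm(n_samples),
                              c = rnorm(n_samples)), fs, stages)
  }
  segs <- segment_epochs(mk_rec(9000, rep("Sleep stage W", 3)))
  expect_length(segs, 3)
  expect_equal(nrow(segs[[1]]$samples), 3000)  # 30 s x 100 Hz
  expect_length(segment_epochs(mk_rec(6000, rep("Sleep stage 2", 2))), 2)
  # 95 s -> floor(9500/3000) = 3 epochs, 500 samples dropped
  expect_length(segment_epochs(mk_rec(9500, rep("Sleep stage 1", 4))), 3)
  # shorter than one epoch -> empty, not an error
  expect_length(segment_epochs(mk_rec(2000, "Sleep stage W")), 0)
  # MOVEMENT epochs excluded
  segs <- segment_epochs(mk_rec(9000, c("Sleep stage W", "Movement time",
                                        "Sleep stage R")))
  expect_length(segs, 2)
  expect_equal(as.character(vapply(segs, function(s)
    as.character(s$stage), "")), c("W", "REM"))
})

test_that("the Morlet bank is centered, scale-covariant, and L2-finite", {
  bank <- morlet_bank(cfg)
  expect_length(bank, 32)
  expect_true(all(vapply(bank, function(p) length(p) %% 2 == 1, TRUE)))
  # center sample is phi(0) = 1 (scaled by 1/sqrt(a))
  for (a in c(1, 8, 32)) {
    p <- bank[[a]]
    expect_equal(p[(length(p) + 1) / 2], complex(real = 1 / sqrt(a)),
                 tolerance = 1e-12)
    # envelope decays below 1e-8 at the grid edges
    expect_lt(Mod(p[1]) * sqrt(a), 1e-7)
  }
  # doubling the scale doubles the time support (|psi| > 1e-3)
  support <- vapply(bank, function(p) sum(Mod(p) > 1e-3), 1)
  for (a in c(2, 4, 8, 16))
    expect_lt(abs(support[2 * a] - 2 * support[a]), 16)
  # discrete L1 mass grows as sqrt(a) (quadrature oracle); L2 norm is
  # scale-invariant under the 1/sqrt(a) convention, and finite
  l1 <- vapply(bank, function(p) sum(Mod(p)), 1)
  l2 <- vapply(bank, function(p) sqrt(sum(Mod(p)^2)), 1)
  expect_true(all(is.finite(l2)))
  ratio <- l1 / sqrt(cfg$scales)
  expect_lt(max(abs(ratio / ratio[16] - 1)[4:32]), 0.02)
  expect_lt(max(abs(l2 / l2[16] - 1)[4:32]), 0.02)
})

test_that("the scalogram is linear before magnitude and finds tone scales", {
  t <- seq_len(3000)
  x <- sin(2 * pi * 10 * t / 100)
  sc <- cwt_scalogram(x, cfg)
  expect_equal(dim(sc), c(3000, 32))
  expect_true(all(sc >= 0))
  # argmax of the time-averaged map brackets omega0*fs/(2*pi*f) ~ 9.55
  expect_true(which.max(colMeans(sc)) %in% c(9, 10))
  # zero in, zero out
  expect_true(all(cwt_scalogram(rep(0, 3000), cfg) == 0))
  # complex-coefficient linearity
  y <- cos(2 * pi * 3 * t / 100)
  cx <- lmcsleep:::cwt_complex(x, cfg)
  cy <- lmcsleep:::cwt_complex(y, cfg)
  cxy <- lmcsleep:::cwt_complex(x + y, cfg)
  expect_equal(cxy, cx + cy, tolerance = 1e-9)
  expect_error(cwt_scalogram(c(rep(0, 2999), NaN), cfg), "NaN")
  expect_error(cwt_scalogram(rep(0, 100), cfg), "expected")
})

test_that("median downsampling is robust, window-local, and shape-checked", {
  # 3000 -> 200 uses the 15-sample window
  m <- matrix(rnorm(3000 * 4), 3000, 4)
  d <- median_downsample(m, 200)
  expect_equal(dim(d), c(200, 4))
  # window medians equal the sort-based oracle
  oracle <- apply(matrix(m[, 1], nrow = 15), 2, median)
  expect_equal(d[, 1], oracle, tolerance = 1e-12)
  # constant map unchanged
  expect_true(all(median_downsample(matrix(3, 30, 2), 2) == 3))
  # single outlier per window cannot move the median of 15
  w <- matrix(1:15, 15, 1)
  expect_equal(as.vector(median_downsample(w, 1)), 8)
  for (pos in c(1, 8, 15)) {
    w2 <- w; w2[pos] <- 1e6
    w3 <- w; w3[pos] <- -1e6
    expect_true(median_downsample(w2, 1) %in% 7:9)
    expect_true(median_downsample(w3, 1) %in% 7:9)
  }
  # permutation within a window leaves the output unchanged
  set.seed(9)
  mm <- matrix(rnorm(30), 30, 1)
  perm <- as.vector(vapply(0:1, function(b) 15 * b + sample(15), numeric(15)))
  expect_equal(median_downsample(mm, 2),
               median_downsample(mm[perm, , drop = FALSE], 2))
  # even window: mean of the two central order statistics
  expect_equal(as.vector(median_downsample(matrix(c(1, 2, 3, 10), 4, 1), 1)),
               2.5)
  expect_error(median_downsample(matrix(0, 10, 1), 3), "divisible")
})

test_that("z-score normalization centers, scales, and is idempotent", {
  x <- c(0, 1, 2, 3)
  expect_equal(normalize_tfr(x), c(-1.342, -0.447, 0.447, 1.342),
               tolerance = 1e-3)
  expect_true(all(normalize_tfr(matrix(5, 3, 3)) == 0))
  set.seed(4)
  m <- matrix(rnorm(100, 3, 10), 10)
  expect_equal(mean(normalize_tfr(m)), 0, tolerance = 1e-9)
  expect_equal(normalize_tfr(normalize_tfr(m)), normalize_tfr(m),
               tolerance = 1e-6)
})

test_that("record preprocessing stacks [3, 200, 32] epochs deterministically", {
  ds <- synth_dataset(1, 5, seed = 55, artifact_rate = 0)
  b <- preprocess_record(ds$recordings[[1]], cfg)
  expect_equal(dim(b$tfr), c(5, 3, 200, 32))
  expect_false(anyNA(b$label))
  # movement epochs vanish from the output
  rec <- ds$recordings[[1]]
  rec$stages[2] <- "Movement time"
  b2 <- preprocess_record(rec, cfg)
  expect_equal(dim(b2$tfr)[1], 4)
  # bit-identical on re-run: no randomness anywhere in the pipeline
  b3 <- preprocess_record(ds$recordings[[1]], cfg)
  expect_identical(b$tfr, b3$tfr)
  expect_error(preprocess_record(
    new_recording("x", list(a = rnorm(3000)), 100, "Sleep stage W"), cfg),
    "3 channels")
})

test_that("scalogram config validates its geometry", {
  expect_error(scalogram_config(target_t = 199), "divide")
  expect_error(scalogram_config(scales = c(3, 2, 1)), "increasing")
  expect_equal(scalogram_config(target_t = 100)$target_t, 100L)
  # m = 15 under the default geometry
  c0 <- scalogram_config()
  expect_equal(c0$epoch_seconds * c0$fs / c0$target_t, 15)
})
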