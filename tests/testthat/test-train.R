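test_that("inverse-frequency class weights follow w = N / (K * n)", {
  expect_equal(compute_class_weights(c(5, 5, 5, 5, 5)), rep(1, 5))
  expect_equal(compute_class_weights(c(10, 30)), c(2, 2 / 3),
               tolerance = 1e-12)
  # SleepEDF-20 stage counts: the N1 weight is the largest
  counts <- c(9118, 2804, 17799, 5703, 7717)
  w <- compute_class_weights(counts)
  expect_equal(w[2], 43141 / (5 * 2804), tolerance = 1e-12)
  expect_equal(w[2], 3.077, tolerance = 1e-3)
  expect_equal(which.max(w), 2L)
  # frequency-weighted mean is exactly 1; invariant to count rescaling
  expect_equal(sum(w * counts / sum(counts)), 1, tolerance = 1e-12)
  expect_equal(compute_class_weights(counts * 7L), w, tolerance = 1e-12)
  expect_error(compute_class_weights(c(3, 0, 1, 1, 1)), "positive")
})

test_that("weighted cross-entropy is exact on closed-form cases", {
  # perfect prediction -> zero loss
  p <- matrix(1e-12, 5, 4)
  p[cbind(c(1, 2, 3, 4), 1:4)] <- 1
  expect_lt(weighted_cross_entropy(p, c(0, 1, 2, 3)), 1e-9)
  # uniform prediction, unit weights -> ln 5
  pu <- matrix(0.2, 5, 3)
  expect_equal(weighted_cross_entropy(pu, c(0, 2, 4)), log(5),
               tolerance = 1e-12)
  # linear in the per-class weight
  w1 <- c(1, 1, 1, 1, 1)
  w2 <- c(2, 1, 1, 1, 1)
  l1 <- weighted_cross_entropy(pu, c(0, 2, 4), w1)
  l2 <- weighted_cross_entropy(pu, c(0, 2, 4), w2)
  expect_equal(l2 - l1, log(5) / 3, tolerance = 1e-12)
})

test_that("early stopping halts after `patience` flat epochs and keeps the best", {
  # best at epoch 2, then 20 non-improving epochs -> stop at epoch 22
  accs <- c(0.50, 0.60, rep(0.55, 25))
  tr <- early_stopping_trace(accs, patience = 20)
  expect_equal(tr$best_epoch, 2)
  expect_equal(tr$stop_epoch, 22)
  expect_equal(tr$best_accuracy, 0.60)
  # ties never reset patience
  tr2 <- early_stopping_trace(c(0.5, rep(0.5, 10)), patience = 3)
  expect_equal(tr2$stop_epoch, 4)
  expect_equal(tr2$best_epoch, 1)
  # patience 0 stops at the first non-improving epoch
  tr3 <- early_stopping_trace(c(0.4, 0.6, 0.5, 0.9), patience = 0)
  expect_equal(tr3$stop_epoch, 3)
  expect_equal(tr3$best_epoch, 2)
  # monotone improvement runs the full budget
  tr4 <- early_stopping_trace(seq(0.1, 0.9, length.out = 9), patience = 3)
  expect_equal(tr4$stop_epoch, 9)
  expect_equal(tr4$best_epoch, 9)
})

test_that("training config enforces the protocol invariants", {
  tc <- train_config()
  expect_equal(tc$lr, 5e-6)
  expect_equal(tc$batch_size, 64L)
  expect_equal(tc$weight_decay, 1e-3)
  expect_equal(tc$patience, 20L)
  expect_equal(tc$folds, 10L)
  expect_error(train_config(patience = 10, max_epochs = 10), "smaller")
  expect_error(train_config(lr = 0))
})

# a tiny directly-constructed separable problem: class k raises a distinct
# block of the "scalogram", so a reduced network can learn it in seconds
make_toy_bundle <- function(n_per_class = 12, subjects = 4, seed = 21) {
  set.seed(seed)
  n <- n_per_class * 5
  tfr <- array(rnorm(n * 3 * 40 * 32, sd = 0.5), c(n, 3, 40, 32))
  lab <- rep(0:4, each = n_per_class)
  for (i in seq_len(n)) {
    s <- lab[i] * 6
    tfr[i, , , (s + 1):(s + 6)] <- tfr[i, , , (s + 1):(s + 6)] + 2
  }
  subj <- sprintf("T%02d", rep_len(seq_len(subjects), n))
  ord <- sample(n)
  structure(list(tfr = tfr[ord, , , , drop = FALSE],
                 label = stage_factor(lab[ord]),
                 subject = subj[ord],
                 config = NULL),
            class = "lmc_epoch_bundle")
}

toy_cfg <- model_config(stage_widths = c(8, 8, 16, 16), cbam_reduction = 4,
                        stem_branch_channels = 8, stem_fused_channels = 8)

test_that("the loss falls over the first epochs on a learnable problem", {
  b <- make_toy_bundle()
  tr_idx <- which(b$subject %in% c("T01", "T02", "T03"))
  va_idx <- which(b$subject == "T04")
  net <- build_network(toy_cfg, seed = 8)
  set.seed(80)
  res <- train_network(net, lmcsleep:::subset_bundle(b, tr_idx),
                       lmcsleep:::subset_bundle(b, va_idx),
                       train_config(lr = 3e-3, batch_size = 16,
                                    max_epochs = 5, patience = 4, seed = 8))
  h <- res$history
  expect_equal(nrow(h), 5)
  # monotone trend: later losses below the starting loss
  expect_lt(mean(h$train_loss[4:5]), h$train_loss[1])
  # invariant: reported best equals the max of the history
  expect_equal(res$best_val_accuracy, max(h$val_accuracy))
  expect_equal(sum(res$confusion), length(va_idx))
})

test_that("training is bit-reproducible under a fixed seed", {
  b <- make_toy_bundle()
  tr_idx <- which(b$subject != "T04")
  va_idx <- which(b$subject == "T04")
  run <- function() {
    net <- build_network(toy_cfg, seed = 9)
    set.seed(90)
    train_network(net, lmcsleep:::subset_bundle(b, tr_idx),
                  lmcsleep:::subset_bundle(b, va_idx),
                  train_config(lr = 1e-3, batch_size = 16, max_epochs = 2,
                               patience = 1, seed = 9))$history
  }
  expect_identical(run(), run())
})

test_that("fold assignment partitions subjects without leakage", {
  subjects <- rep(sprintf("S%02d", 1:20), each = 10)
  fm <- make_folds(subjects, folds = 10, seed = 3)
  expect_equal(nrow(fm), 20)
  expect_equal(unname(table(fm$fold)), rep(2L, 10), ignore_attr = TRUE)
  # disjoint and covering
  expect_equal(sort(fm$unit), sprintf("S%02d", 1:20))
  expect_error(make_folds(rep("A", 5), folds = 10), "at least")
  # record-wise mode deals epochs
  fr <- make_folds(subjects, folds = 4, seed = 3, by = "record")
  expect_equal(nrow(fr), 200)
})

test_that("cross-validation pools fold confusions conservatively", {
  b <- make_toy_bundle(n_per_class = 8, subjects = 4, seed = 22)
  cv <- cross_validate(b, toy_cfg,
                       train_config(lr = 3e-3, batch_size = 16,
                                    max_epochs = 2, patience = 1,
                                    folds = 4, seed = 5))
  expect_length(cv$fold_results, 4)
  # every epoch is validated exactly once
  expect_equal(sum(cv$pooled_confusion), dim(b$tfr)[1])
  expect_equal(nrow(cv$fold_metrics), 4)
  expect_true(all(c("pooled", "fold_mean", "fold_sd") %in%
                    names(cv$summary)))
  # fold val subjects are pairwise disjoint: total of per-fold N equals N
  expect_equal(sum(vapply(cv$fold_results,
                          function(r) sum(r$confusion), 1)),
               dim(b$tfr)[1])
})
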