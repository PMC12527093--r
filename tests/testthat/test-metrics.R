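test_that("confusion_matrix matches a naive per-sample counting oracle", {
  set.seed(31)
  for (n in c(10, 200, 1000)) {
    yt <- sample(0:4, n, replace = TRUE)
    yp <- sample(0:4, n, replace = TRUE)
    cm <- confusion_matrix(yt, yp)
    expect_equal(unclass(cm), naive_confusion(yt, yp),
                 ignore_attr = TRUE)
    expect_equal(sum(cm), n)
  }
  yt <- c(0, 1, 1)
  cm <- confusion_matrix(yt, c(0, 2, 1))
  expect_equal(cm["N1", "N2"], 1L)
  expect_equal(cm["N1", "N1"], 1L)
  expect_equal(cm["W", "W"], 1L)
  expect_true(all(diag(confusion_matrix(yt, yt)) == c(1, 2, 0, 0, 0)))
  expect_error(confusion_matrix(c(0, 7), c(0, 1)), "stage codes")
  expect_error(confusion_matrix(0:2, 0:1), "equal length")
})

test_that("per-class precision/recall/F1 follow their defining formulas", {
  # two informative classes embedded in the 5-class layout
  m <- matrix(0L, 5, 5)
  m[1, 1] <- 8; m[1, 2] <- 2; m[2, 1] <- 1; m[2, 2] <- 9
  pc <- per_class_metrics(as_confusion(m))
  expect_equal(pc$precision[1], 8 / 9, tolerance = 1e-12)
  expect_equal(pc$recall[1], 0.8, tolerance = 1e-12)
  expect_equal(pc$f1[1], 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8),
               tolerance = 1e-12)
  expect_true(all(pc$degenerate[3:5]))
  expect_true(all(pc$f1[3:5] == 0))
  # perfect diagonal
  pc2 <- per_class_metrics(as_confusion(diag(c(5, 4, 3, 2, 1))))
  expect_true(all(pc2$precision == 1 & pc2$recall == 1 & pc2$f1 == 1))
})

test_that("accuracy, macro-F1 and kappa match independent references", {
  skip_if_not_installed("e1071")
  set.seed(77)
  for (i in 1:5) {
    m <- matrix(rpois(25, 40), 5, 5)
    sm <- summary_metrics(as_confusion(m))
    ca <- e1071::classAgreement(m)
    expect_equal(sm$accuracy, ca$diag, tolerance = 1e-12)
    expect_equal(sm$kappa, ca$kappa, tolerance = 1e-12)
    expect_equal(sm$macro_f1, mean(per_class_metrics(as_confusion(m))$f1),
                 tolerance = 1e-12)
  }
  # closed-form cases
  expect_equal(summary_metrics(as_confusion(diag(5) * 10L))$accuracy, 1)
  expect_equal(summary_metrics(as_confusion(diag(5) * 10L))$kappa, 1)
  u <- summary_metrics(as_confusion(matrix(4L, 5, 5)))
  expect_equal(u$accuracy, 0.2)
  expect_equal(u$kappa, 0, tolerance = 1e-12)
  # single-class degenerate: kappa undefined
  d <- matrix(0L, 5, 5); d[1, 1] <- 10L
  expect_true(is.na(summary_metrics(as_confusion(d))$kappa))
})

test_that("metrics are invariant to a simultaneous class permutation", {
  set.seed(5)
  m <- matrix(rpois(25, 30), 5, 5)
  perm <- sample(5)
  sm1 <- summary_metrics(as_confusion(m))
  sm2 <- summary_metrics(as_confusion(m[perm, perm]))
  expect_equal(sm1$accuracy, sm2$accuracy, tolerance = 1e-12)
  expect_equal(sm1$kappa, sm2$kappa, tolerance = 1e-12)
  expect_equal(sm1$macro_f1, sm2$macro_f1, tolerance = 1e-12)
  pc1 <- per_class_metrics(as_confusion(m))
  pc2 <- per_class_metrics(as_confusion(m[perm, perm]))
  expect_equal(pc2$f1, pc1$f1[perm], tolerance = 1e-12)
})

test_that("the published confusion-matrix fixture loads and is coherent", {
  cm <- sleepedf20_reference_confusion()
  expect_s3_class(cm, "lmc_confusion")
  expect_equal(sum(cm), 39219)
  expect_equal(sum(diag(cm)), 34607)
  v <- verify_reference_metrics()
  expect_equal(v$per_class$f1[v$per_class$stage == "N2"], 90.6)
  # long/tidy form round-trips the counts
  expect_equal(sum(tidy(cm)$n), 39219)
})
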