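#' Build a 5x5 sleep-stage confusion matrix
#'
#' Rows are the true stage, columns the predicted stage, both in the fixed
#' W, N1, N2, N3, REM order.
#'
#' @param y_true,y_pred Equal-length label vectors (codes 0-4, names, or
#'   factors).
#' @return Object of class `lmc_confusion`: an integer matrix with stage
#'   dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred) {
  t <- stage_factor(y_true)
  p <- stage_factor(y_pred)
  if (length(t) != length(p))
    stop("y_true and y_pred must have equal length")
  if (anyNA(t) || anyNA(p)) stop("labels contain NA")
  m <- table(true = t, predicted = p)
  m <- matrix(as.integer(m), 5, 5,
              dimnames = list(true = STAGE_LEVELS, predicted = STAGE_LEVELS))
  structure(m, class = c("lmc_confusion", "matrix", "array"))
}

#' Coerce a plain counts matrix to a confusion object
#'
#' @param m 5x5 non-negative counts matrix (rows = true stage).
#' @return `lmc_confusion`.
#' @export
as_confusion <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(5, 5))) stop("expected a 5x5 matrix")
  if (any(m < 0)) stop("confusion counts must be non-negative")
  storage.mode(m) <- "integer"
  dimnames(m) <- list(true = STAGE_LEVELS, predicted = STAGE_LEVELS)
  structure(m, class = c("lmc_confusion", "matrix", "array"))
}

#' @export
print.lmc_confusion <- function(x, ...) {
  cat("<confusion matrix> N =", sum(x), "(rows = true stage)\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class precision, recall and F1
#'
#' For class c: `TP = m[c, c]`, `FP` = column sum minus TP, `FN` = row sum
#' minus TP; `PR = TP / (TP + FP)`, `RE = TP / (TP + FN)`, `F1` the harmonic
#' mean of the unrounded PR and RE. Degenerate denominators yield 0 and are
#' flagged rather than NaN, so macro averages stay defined on sparse
#' validation folds.
#'
#' @param cm An [confusion_matrix()] / [as_confusion()] object.
#' @return Tibble with columns `stage`, `support`, `precision`, `recall`,
#'   `f1`, `degenerate`.
#' @export
per_class_metrics <- function(cm) {
  cm <- as_confusion(unclass(cm))
  if (sum(cm) == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  pr <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  re <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(pr + re > 0, 2 * pr * re / (pr + re), 0)
  tibble::tibble(stage = factor(STAGE_LEVELS, levels = STAGE_LEVELS),
                 support = as.integer(rowSums(cm)),
                 precision = unname(pr), recall = unname(re),
                 f1 = unname(f1),
                 degenerate = unname(tp + fp == 0 | tp + fn == 0))
}

#' Overall agreement statistics
#'
#' Accuracy (`trace / N`), macro-F1 (unweighted mean of the five unrounded
#' per-class F1 values) and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` with `p_e = sum_i row_i * col_i / N^2`. For the
#' single-class degenerate case (`p_e = 1`) kappa is reported as `NA`.
#'
#' @param cm A confusion matrix object.
#' @return Tibble (one row) with `n`, `accuracy`, `macro_f1`, `kappa`.
#' @export
summary_metrics <- function(cm) {
  cm <- as_confusion(unclass(cm))
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  acc <- sum(diag(cm)) / n
  mf1 <- mean(per_class_metrics(cm)$f1)
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) NA_real_
           else (acc - pe) / (1 - pe)
  tibble::tibble(n = n, accuracy = acc, macro_f1 = mf1, kappa = kappa)
}

#' @rdname confusion_matrix
#' @param x Confusion matrix to tabulate (long form).
#' @param ... Unused.
#' @export
tidy.lmc_confusion <- function(x, ...) {
  tibble::tibble(
    true = factor(rep(STAGE_LEVELS, times = 5), levels = STAGE_LEVELS),
    predicted = factor(rep(STAGE_LEVELS, each = 5), levels = STAGE_LEVELS),
    n = as.integer(x))
}

#' @rdname confusion_matrix
#' @export
glance.lmc_confusion <- function(x, ...) summary_metrics(x)

#' @rdname confusion_matrix
#' @param object Confusion matrix to plot.
#' @export
autoplot.lmc_confusion <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$true) |>
    dplyr::mutate(frac = .data$n / pmax(sum(.data$n), 1)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$frac)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(STAGE_LEVELS)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 name = "row frac") +
    ggplot2::labs(x = "predicted stage", y = "true stage")
}

#' Published SleepEDF-20 confusion matrix
#'
#' The pooled 10-fold 5x5 confusion matrix reported for this architecture on
#' SleepEDF-20, shipped as a plain-text fixture. All matrix-derived
#' statistics (accuracy 88.2%, kappa 0.84, macro-F1 82.4%, per-class
#' precision/recall/F1) can be recomputed from it with
#' [per_class_metrics()] and [summary_metrics()].
#'
#' @return `lmc_confusion` matrix.
#' @export
sleepedf20_reference_confusion <- function() {
  path <- system.file("extdata", "sleepedf20_confusion.tsv",
                      package = "lmcsleep")
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                   sep = "\t", check.names = FALSE))
  as_confusion(m)
}

#' Recompute the published evaluation table from the reference matrix
#'
#' @return Tibble with per-class precision/recall/F1 (percent, 1 decimal)
#'   plus the overall accuracy, macro-F1 and kappa, all derived from the
#'   shipped confusion matrix.
#' @export
verify_reference_metrics <- function() {
  cm <- sleepedf20_reference_confusion()
  pc <- per_class_metrics(cm) |>
    dplyr::mutate(precision = round(100 * .data$precision, 1),
                  recall = round(100 * .data$recall, 1),
                  f1 = round(100 * .data$f1, 1))
  sm <- summary_metrics(cm)
  list(per_class = pc,
       overall = tibble::tibble(accuracy = round(100 * sm$accuracy, 1),
                                kappa = round(sm$kappa, 2),
                                macro_f1 = round(100 * sm$macro_f1, 1)))
}
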