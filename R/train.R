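#' Training configuration
#'
#' Optimization protocol: Adam (beta1 = 0.9, beta2 = 0.999) with learning
#' rate 5e-6, minibatches of 64, weighted cross-entropy, L2 weight decay
#' 1e-3 on convolution/FC weights (not batch-norm parameters or biases),
#' early stopping on validation accuracy with patience 20 epochs, and
#' 10-fold cross-validation.
#'
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam moment decays.
#' @param batch_size Minibatch size.
#' @param weight_decay L2 coefficient applied to conv/FC/attention weights.
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs Epoch budget.
#' @param folds Cross-validation folds.
#' @param seed RNG seed covering initialization, shuffling and dropout.
#' @return Object of class `lmc_train_config`.
#' @export
train_config <- function(lr = 5e-6, beta1 = 0.9, beta2 = 0.999,
                         batch_size = 64, weight_decay = 1e-3,
                         patience = 20, max_epochs = 200, folds = 10,
                         seed = 1) {
  stopifnot(lr > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            batch_size >= 1, weight_decay >= 0, patience >= 0,
            max_epochs >= 1, folds >= 2)
  if (patience >= max_epochs)
    stop("patience must be smaller than max_epochs")
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "lmc_train_config")
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * n_c)` with `N` the total count and `K` the number of
#' classes: weights inversely proportional to class counts, scaled so the
#' class-frequency-weighted mean of the weights is exactly 1. Invariant to
#' rescaling all counts.
#'
#' @param counts Positive integer vector of per-class epoch counts.
#' @return Numeric weight vector of the same length.
#' @export
compute_class_weights <- function(counts) {
  if (any(counts <= 0))
    stop("all class counts must be positive; drop or merge empty classes ",
         "before computing weights")
  n <- sum(counts)
  k <- length(counts)
  unname(n / (k * counts))
}

#' Weighted cross-entropy loss
#'
#' Mean over the batch of `-w[y] * log(P[y])`, with the log clamped at
#' 1e-12. The L2 penalty is applied by the optimizer, not here.
#'
#' @param probabilities Matrix `[num_classes x N]` of column-wise
#'   probabilities (or a single probability vector).
#' @param labels Length-N stage labels (codes 0-4, names, or factor).
#' @param weights Per-class weights (default: unweighted).
#' @return Scalar loss.
#' @export
weighted_cross_entropy <- function(probabilities, labels,
                                   weights = rep(1, 5)) {
  if (is.null(dim(probabilities)))
    probabilities <- matrix(probabilities, ncol = 1)
  y <- as.integer(stage_factor(labels))
  stopifnot(length(y) == ncol(probabilities))
  py <- probabilities[cbind(y, seq_along(y))]
  mean(-weights[y] * log(pmax(py, 1e-12)))
}

# Early-stopping rule: training halts once validation accuracy has failed
# to exceed the best seen for `patience` consecutive epochs ("improvement"
# is strictly greater; ties do not reset patience). patience = 0 stops at
# the first non-improving epoch.
early_stop_monitor <- function(patience) {
  env <- new.env(parent = emptyenv())
  env$best <- -Inf
  env$best_epoch <- 0L
  env$bad <- 0L
  env$update <- function(epoch, acc) {
    if (acc > env$best) {
      env$best <- acc
      env$best_epoch <- as.integer(epoch)
      env$bad <- 0L
      return(FALSE)
    }
    env$bad <- env$bad + 1L
    env$bad >= patience && env$bad >= 1L
  }
  env
}

#' Simulate the early-stopping rule on a scripted accuracy sequence
#'
#' Feeds a fixed sequence of per-epoch validation accuracies through the
#' same monitor the trainer uses and reports where training would stop and
#' which epoch's weights would be restored.
#'
#' @param accuracies Numeric vector of per-epoch validation accuracies.
#' @param patience Early-stopping patience.
#' @return List with `best_epoch`, `best_accuracy`, `stop_epoch` (number of
#'   epochs actually run; `length(accuracies)` if never triggered).
#' @export
early_stopping_trace <- function(accuracies, patience) {
  mon <- early_stop_monitor(patience)
  stop_epoch <- length(accuracies)
  for (e in seq_along(accuracies)) {
    if (mon$update(e, accuracies[e])) {
      stop_epoch <- e
      break
    }
  }
  list(best_epoch = mon$best_epoch, best_accuracy = mon$best,
       stop_epoch = stop_epoch)
}

adam_state <- function() new.env(parent = emptyenv())

adam_step <- function(net, grads, st, cfg, t) {
  keys <- ls(grads)
  b1t <- 1 - cfg$beta1^t
  b2t <- 1 - cfg$beta2^t
  for (k in keys) {
    g <- grads[[k]]
    if (cfg$weight_decay > 0 && grepl("\\.(weight|w1|w2)$", k))
      g <- g + cfg$weight_decay * net$params[[k]]
    m <- st[[paste0(k, ".m")]]
    v <- st[[paste0(k, ".v")]]
    if (is.null(m)) { m <- 0 * g; v <- 0 * g }
    m <- cfg$beta1 * m + (1 - cfg$beta1) * g
    v <- cfg$beta2 * v + (1 - cfg$beta2) * g * g
    st[[paste0(k, ".m")]] <- m
    st[[paste0(k, ".v")]] <- v
    net$params[[k]] <- net$params[[k]] -
      cfg$lr * (m / b1t) / (sqrt(v / b2t) + 1e-8)
  }
}

bundle_counts <- function(labels) as.vector(table(labels))

eval_accuracy <- function(net, x, y, batch_size = 128) {
  n <- dim(x)[4]
  correct <- 0
  for (i0 in seq(1, n, by = batch_size)) {
    idx <- i0:min(i0 + batch_size - 1, n)
    p <- network_forward(net, x[, , , idx, drop = FALSE])$probabilities
    correct <- correct + sum(max.col(t(p), ties.method = "first") == y[idx])
  }
  correct / n
}

# bundle [N,C,H,W] -> internal (H,W,C,N)
bundle_tensor <- function(bundle) aperm(bundle$tfr, c(3, 4, 2, 1))

#' Train a network on labeled scalogram epochs
#'
#' Adam steps on shuffled minibatches with weighted cross-entropy (class
#' weights from the training-set stage counts), validation accuracy after
#' every epoch, early stopping with best-checkpoint restoration.
#'
#' @param net An `lmc_network` (modified in place and returned).
#' @param train_bundle,val_bundle `lmc_epoch_bundle`s with disjoint
#'   subjects.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return Object of class `lmc_train_result`: `history` (tibble epoch /
#'   train_loss / val_accuracy), `best_epoch`, `best_val_accuracy`,
#'   `confusion` (validation confusion at the restored best weights), and
#'   the trained `net`.
#' @export
train_network <- function(net, train_bundle, val_bundle, config,
                          verbose = FALSE) {
  if (dim(train_bundle$tfr)[1] == 0 || dim(val_bundle$tfr)[1] == 0)
    stop("empty training or validation split")
  overlap <- intersect(unique(train_bundle$subject),
                       unique(val_bundle$subject))
  if (length(overlap) > 0)
    warning("subjects appear in both splits: ",
            paste(overlap, collapse = ", "))
  xtr <- bundle_tensor(train_bundle)
  ytr <- as.integer(train_bundle$label)
  xva <- bundle_tensor(val_bundle)
  yva <- as.integer(val_bundle$label)
  cw <- compute_class_weights(bundle_counts(train_bundle$label))
  st <- adam_state()
  mon <- early_stop_monitor(config$patience)
  n <- length(ytr)
  hist <- list()
  best_params <- NULL
  best_buffers <- NULL
  t_step <- 0
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(n)
    loss_sum <- 0
    loss_n <- 0
    for (i0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[i0:min(i0 + config$batch_size - 1, n)]
      if (length(idx) < 2) next  # batch norm needs >= 2 samples
      xb <- xtr[, , , idx, drop = FALSE]
      yb <- ytr[idx]
      fw <- network_forward(net, xb, training = TRUE, keep_cache = TRUE)
      p <- fw$probabilities
      bsz <- length(idx)
      loss <- mean(-cw[yb] * log(pmax(p[cbind(yb, seq_len(bsz))], 1e-12)))
      onehot <- matrix(0, nrow(p), bsz)
      onehot[cbind(yb, seq_len(bsz))] <- 1
      dlogits <- (p - onehot) * rep(cw[yb], each = nrow(p)) / bsz
      grads <- network_backward(net, fw$cache, dlogits)
      t_step <- t_step + 1
      adam_step(net, grads, st, config, t_step)
      loss_sum <- loss_sum + loss * bsz
      loss_n <- loss_n + bsz
    }
    val_acc <- eval_accuracy(net, xva, yva)
    hist[[epoch]] <- tibble::tibble(epoch = epoch,
                                    train_loss = loss_sum / loss_n,
                                    val_accuracy = val_acc)
    improved_stop <- mon$update(epoch, val_acc)
    if (mon$best_epoch == epoch) {
      best_params <- as.list(net$params)
      best_buffers <- as.list(net$buffers)
    }
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %.4f%s", epoch,
                      loss_sum / loss_n, val_acc,
                      if (mon$best_epoch == epoch) " *" else ""))
    if (improved_stop) break
  }
  # restore the best checkpoint
  if (!is.null(best_params)) {
    for (k in names(best_params)) net$params[[k]] <- best_params[[k]]
    for (k in names(best_buffers)) net$buffers[[k]] <- best_buffers[[k]]
  }
  pred <- predict_stages(net, val_bundle)
  structure(list(history = dplyr::bind_rows(hist),
                 best_epoch = mon$best_epoch,
                 best_val_accuracy = mon$best,
                 confusion = confusion_matrix(val_bundle$label,
                                              pred$predicted),
                 net = net),
            class = "lmc_train_result")
}

#' @export
print.lmc_train_result <- function(x, ...) {
  cat("<lmc_train_result> ", nrow(x$history), " epochs; best epoch ",
      x$best_epoch, " (val acc ", sprintf("%.3f", x$best_val_accuracy),
      ")\n", sep = "")
  invisible(x)
}

#' @rdname train_network
#' @param x Result to tabulate.
#' @param ... Unused.
#' @export
tidy.lmc_train_result <- function(x, ...) x$history

#' @rdname train_network
#' @export
glance.lmc_train_result <- function(x, ...) {
  tibble::tibble(epochs_run = nrow(x$history), best_epoch = x$best_epoch,
                 best_val_accuracy = x$best_val_accuracy)
}

#' @rdname train_network
#' @param object Result to plot.
#' @export
autoplot.lmc_train_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' Subject-wise (or record-wise) fold assignment
#'
#' Subjects are shuffled with the given seed and dealt round-robin into
#' `folds` groups; fold validation sets are pairwise disjoint and cover all
#' subjects. Record-wise mode deals individual epochs instead (provided for
#' comparability; it leaks subject identity across splits).
#'
#' @param subjects Character vector, one entry per epoch.
#' @param folds Number of folds.
#' @param seed Shuffle seed.
#' @param by "subject" (default) or "record".
#' @return Tibble with `fold`, `unit` (subject id or epoch index).
#' @export
make_folds <- function(subjects, folds, seed = 1, by = c("subject",
                                                         "record")) {
  by <- match.arg(by)
  units <- if (by == "subject") unique(subjects)
           else as.character(seq_along(subjects))
  if (length(units) < folds)
    stop("need at least ", folds, " ", by, "s for ", folds,
         "-fold cross-validation; have ", length(units))
  set.seed(seed)
  shuffled <- sample(units)
  tibble::tibble(fold = rep_len(seq_len(folds), length(shuffled)),
                 unit = shuffled)
}

subset_bundle <- function(bundle, idx) {
  structure(list(tfr = bundle$tfr[idx, , , , drop = FALSE],
                 label = bundle$label[idx],
                 subject = bundle$subject[idx],
                 config = bundle$config),
            class = "lmc_epoch_bundle")
}

#' k-fold cross-validation
#'
#' Partitions subjects into folds, trains one network per fold (9 parts
#' train / 1 part validation for the default 10 folds), and pools the
#' per-fold validation confusion matrices by element-wise summation.
#' Summary statistics are reported both pooled and fold-averaged
#' (mean and SD across folds).
#'
#' @param bundle A labeled `lmc_epoch_bundle`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param by Split unit: "subject" (default, prevents subject leakage) or
#'   "record".
#' @param verbose Print per-epoch progress.
#' @return Object of class `lmc_cv`: `fold_results` (list of
#'   `lmc_train_result`), `pooled_confusion`, `fold_metrics` (per-fold
#'   tibble), `summary` (pooled and fold-averaged accuracy / macro-F1 /
#'   kappa).
#' @export
cross_validate <- function(bundle, model_cfg = model_config(),
                           train_cfg = train_config(),
                           by = c("subject", "record"), verbose = FALSE) {
  by <- match.arg(by)
  fold_map <- make_folds(bundle$subject, train_cfg$folds,
                         seed = train_cfg$seed, by = by)
  results <- vector("list", train_cfg$folds)
  for (f in seq_len(train_cfg$folds)) {
    val_units <- fold_map$unit[fold_map$fold == f]
    val_idx <- if (by == "subject") which(bundle$subject %in% val_units)
               else as.integer(val_units)
    tr_idx <- setdiff(seq_along(bundle$subject), val_idx)
    net <- build_network(model_cfg, seed = train_cfg$seed + f)
    set.seed(train_cfg$seed * 1000L + f)
    results[[f]] <- train_network(net, subset_bundle(bundle, tr_idx),
                                  subset_bundle(bundle, val_idx),
                                  train_cfg, verbose = verbose)
  }
  pooled <- as_confusion(Reduce(`+`, lapply(results, function(r)
    unclass(r$confusion))))
  fold_metrics <- purrr::imap_dfr(results, function(r, f)
    dplyr::bind_cols(tibble::tibble(fold = f), summary_metrics(r$confusion)))
  pooled_sm <- summary_metrics(pooled)
  summary <- tibble::tibble(
    metric = c("accuracy", "macro_f1", "kappa"),
    pooled = c(pooled_sm$accuracy, pooled_sm$macro_f1, pooled_sm$kappa),
    fold_mean = c(mean(fold_metrics$accuracy), mean(fold_metrics$macro_f1),
                  mean(fold_metrics$kappa, na.rm = TRUE)),
    fold_sd = c(sd(fold_metrics$accuracy), sd(fold_metrics$macro_f1),
                sd(fold_metrics$kappa, na.rm = TRUE)))
  structure(list(fold_results = results, pooled_confusion = pooled,
                 fold_metrics = fold_metrics, summary = summary),
            class = "lmc_cv")
}

#' @export
print.lmc_cv <- function(x, ...) {
  cat("<lmc_cv> ", length(x$fold_results), " folds, pooled N = ",
      sum(x$pooled_confusion), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname cross_validate
#' @param x Cross-validation object.
#' @param ... Unused.
#' @export
tidy.lmc_cv <- function(x, ...) x$fold_metrics

#' @rdname cross_validate
#' @export
glance.lmc_cv <- function(x, ...) {
  tidyr::pivot_wider(x$summary[, c("metric", "pooled")],
                     names_from = "metric", values_from = "pooled")
}
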