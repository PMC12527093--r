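#' Scalogram configuration
#'
#' Parameters of the Morlet continuous-wavelet-transform preprocessing:
#' mother-wavelet center angular frequency `omega0` (dimensionless,
#' rad per unit of the wavelet's time argument; 6.0 is the standard
#' admissibility-safe choice), the integer scale set (default 1..32), the
#' downsampled time-axis length `target_t` (default 200, giving a
#' median window of `epoch_seconds * fs / target_t` = 15 samples), and the
#' epoch geometry. The implied pseudo-frequency of scale `a` is
#' `omega0 / (2 * pi) * fs / a` Hz.
#'
#' @param omega0 Morlet center angular frequency.
#' @param scales Strictly increasing positive integer scales.
#' @param target_t Downsampled number of time points; must divide
#'   `epoch_seconds * fs`.
#' @param epoch_seconds Epoch length in seconds.
#' @param fs Sampling rate in Hz.
#' @param downsample One of "median" (default), "mean", "max" — the latter
#'   two exist for the downsampling comparison harness only.
#' @return Object of class `lmc_scalogram_config`.
#' @export
scalogram_config <- function(omega0 = 6, scales = 1:32, target_t = 200,
                             epoch_seconds = 30, fs = 100,
                             downsample = c("median", "mean", "max")) {
  downsample <- match.arg(downsample)
  if (any(scales <= 0) || any(diff(scales) <= 0))
    stop("scales must be positive and strictly increasing")
  n <- epoch_seconds * fs
  if (n %% target_t != 0)
    stop("target_t (", target_t, ") must divide epoch_seconds * fs (", n, ")")
  structure(list(omega0 = omega0, scales = as.integer(scales),
                 target_t = as.integer(target_t),
                 epoch_seconds = epoch_seconds, fs = fs,
                 downsample = downsample),
            class = "lmc_scalogram_config")
}

#' Discretized complex Morlet wavelet bank
#'
#' One wavelet per scale: `psi_a[k] = a^(-1/2) * exp(-(k/a)^2 / 2) *
#' exp(1i * omega0 * k / a)` sampled on a symmetric integer grid wide enough
#' that the Gaussian envelope falls below 1e-8 at the edges (odd length,
#' centered at k = 0). The `1/sqrt(a)` prefactor is the standard L2
#' convention, under which the discrete L2 norm grows like `a^(1/2)`.
#'
#' @param config A [scalogram_config()].
#' @return List of complex vectors, one per scale, with attributes `scales`
#'   and `halfwidth`.
#' @export
morlet_bank <- function(config) {
  stopifnot(inherits(config, "lmc_scalogram_config"))
  half <- ceiling(config$scales * sqrt(2 * log(1e8)))
  bank <- lapply(seq_along(config$scales), function(i) {
    a <- config$scales[i]
    k <- seq(-half[i], half[i])
    (1 / sqrt(a)) * exp(-(k / a)^2 / 2) * exp(1i * config$omega0 * k / a)
  })
  attr(bank, "scales") <- config$scales
  attr(bank, "halfwidth") <- half
  bank
}

# FFTs of the conjugated, time-reversed bank members at a common length,
# cached so whole-record preprocessing pays the wavelet FFTs once.
bank_fft <- function(bank, n_signal) {
  half <- attr(bank, "halfwidth")
  lmax <- 2 * max(half) + 1
  nfft <- 2^ceiling(log2(n_signal + lmax - 1))
  ffts <- lapply(bank, function(p) {
    g <- Conj(rev(p))
    fft(c(g, complex(real = rep(0, nfft - length(g)))))
  })
  list(ffts = ffts, nfft = nfft, half = half)
}

#' Morlet CWT scalogram of one epoch channel
#'
#' Computes, for every scale, the magnitude of the complex coefficient
#' obtained by discrete convolution of the epoch with the conjugated,
#' time-reversed wavelet (same-length output, zero-padded boundaries), i.e.
#' the discretization of `CWT(a; tau) = 1/sqrt(a) * integral f(t)
#' psi*((t - tau)/a) dt`.
#'
#' @param epoch_channel Numeric vector of exactly `epoch_seconds * fs`
#'   samples.
#' @param config A [scalogram_config()].
#' @param bank Optional precomputed [morlet_bank()]; rebuilt when `NULL`.
#' @return Non-negative numeric matrix `[T_raw x n_scales]`.
#' @export
cwt_scalogram <- function(epoch_channel, config, bank = NULL) {
  n <- config$epoch_seconds * config$fs
  if (length(epoch_channel) != n)
    stop("epoch has ", length(epoch_channel), " samples; expected ", n)
  if (any(!is.finite(epoch_channel)))
    stop("epoch contains NaN/Inf samples")
  if (is.null(bank)) bank <- morlet_bank(config)
  bf <- bank_fft(bank, n)
  Mod(cwt_complex(epoch_channel, config, bank, bf))
}

# Complex CWT coefficients (pre-magnitude); exposed internally so linearity
# can be tested on the complex intermediate.
cwt_complex <- function(epoch_channel, config, bank = NULL, bf = NULL) {
  n <- length(epoch_channel)
  if (is.null(bank)) bank <- morlet_bank(config)
  if (is.null(bf)) bf <- bank_fft(bank, n)
  fpad <- fft(c(epoch_channel, rep(0, bf$nfft - n)))
  out <- matrix(0i, nrow = n, ncol = length(bank))
  for (j in seq_along(bank)) {
    full <- fft(fpad * bf$ffts[[j]], inverse = TRUE) / bf$nfft
    out[, j] <- full[(bf$half[j] + 1):(bf$half[j] + n)]
  }
  out
}

#' Median-downsample the time axis of a time-frequency map
#'
#' Partitions the rows (time samples) into non-overlapping windows of
#' `m = T_raw / target_t` samples and replaces each window by its median
#' (mean of the two central order statistics for even `m`), column by
#' column. Medians make the compression robust to single-sample outliers.
#'
#' @param map Numeric matrix `[T_raw x S]`.
#' @param target_t Output time length; must divide `T_raw`.
#' @param kind "median" (default), or "mean"/"max" for the comparison
#'   harness.
#' @return Numeric matrix `[target_t x S]`.
#' @export
median_downsample <- function(map, target_t, kind = "median") {
  t_raw <- nrow(map)
  if (target_t < 1 || t_raw %% target_t != 0)
    stop("T_raw (", t_raw, ") is not divisible by target_t (", target_t, ")")
  m <- t_raw %/% target_t
  if (kind == "median") return(median_pool_cpp(map, m))
  grp <- rep(seq_len(target_t), each = m)
  fun <- if (kind == "mean") colMeans else function(x) apply(x, 2, max)
  out <- matrix(0, target_t, ncol(map))
  for (t in seq_len(target_t)) out[t, ] <- fun(map[grp == t, , drop = FALSE])
  out
}

#' Per-map z-score normalization
#'
#' `(x - mean(x)) / (sd(x) + 1e-8)` with the population (1/n) standard
#' deviation, applied per channel and per epoch so absolute amplitude units
#' cancel before the network sees the data. Constant maps normalize to zero.
#'
#' @param map Numeric array (any shape).
#' @return Array of the same shape with mean ~0 and SD ~1 (non-constant
#'   input).
#' @export
normalize_tfr <- function(map) {
  mu <- mean(map)
  sdev <- sqrt(mean((map - mu)^2))
  (map - mu) / (sdev + 1e-8)
}

#' Segment a recording into labeled 30 s epochs
#'
#' Splits each channel into consecutive `epoch_seconds * fs`-sample
#' segments; the trailing remainder and any epochs beyond the annotated span
#' are discarded, as are MOVEMENT/UNKNOWN epochs.
#'
#' @param record An [new_recording()].
#' @param epoch_seconds Epoch length in seconds.
#' @return List of `list(samples = [n x 3] matrix, stage = factor)` for each
#'   kept epoch; empty list for a recording shorter than one epoch.
#' @export
segment_epochs <- function(record, epoch_seconds = 30) {
  n <- as.integer(epoch_seconds * record$fs)
  n_seg <- floor(length(record$channels[[1]]) / n)
  mapped <- map_stages_rk_to_aasm(record$stages)
  n_seg <- min(n_seg, nrow(mapped))
  if (n_seg < 1) return(list())
  out <- vector("list", n_seg)
  keep <- logical(n_seg)
  for (i in seq_len(n_seg)) {
    keep[i] <- mapped$keep[i]
    if (!keep[i]) next
    rows <- ((i - 1) * n + 1):(i * n)
    out[[i]] <- list(
      samples = vapply(record$channels, function(ch) ch[rows], numeric(n)),
      stage = mapped$stage[i])
  }
  out[keep]
}

#' Preprocess a recording into scalogram epochs
#'
#' The full per-epoch pipeline, applied to each channel independently:
#' segment -> complex Morlet CWT -> magnitude -> median downsampling of the
#' time axis -> per-channel z-score. Channels are stacked as a
#' `[3, target_t, n_scales]` tensor per epoch. Deterministic: no randomness
#' anywhere in the pipeline.
#'
#' @param record An [new_recording()] with exactly 3 channels.
#' @param config A [scalogram_config()].
#' @param trim_wake Optionally trim leading/trailing wake: keep at most
#'   `trim_wake_margin` W epochs on each side of the sleep period. Off by
#'   default.
#' @param trim_wake_margin Number of W epochs retained on each side when
#'   trimming.
#' @return An `lmc_epoch_bundle`: list with `tfr` `[N, 3, target_t, S]`,
#'   `label` (factor), `subject` (character), `config`.
#' @export
preprocess_record <- function(record, config = scalogram_config(),
                              trim_wake = FALSE, trim_wake_margin = 60) {
  if (length(record$channels) != 3)
    stop("expected exactly 3 channels, got ", length(record$channels))
  if (record$fs != config$fs)
    stop("recording fs (", record$fs, ") != config fs (", config$fs, ")")
  epochs <- segment_epochs(record, config$epoch_seconds)
  if (trim_wake && length(epochs) > 0) {
    stg <- vapply(epochs, function(e) as.character(e$stage), "")
    sleep_idx <- which(stg != "W")
    if (length(sleep_idx) > 0) {
      lo <- max(1, min(sleep_idx) - trim_wake_margin)
      hi <- min(length(epochs), max(sleep_idx) + trim_wake_margin)
      epochs <- epochs[lo:hi]
    }
  }
  n_ep <- length(epochs)
  S <- length(config$scales)
  tfr <- array(0, dim = c(n_ep, 3, config$target_t, S))
  label <- character(n_ep)
  if (n_ep > 0) {
    bank <- morlet_bank(config)
    bf <- bank_fft(bank, config$epoch_seconds * config$fs)
    for (i in seq_len(n_ep)) {
      for (ch in 1:3) {
        x <- epochs[[i]]$samples[, ch]
        if (any(!is.finite(x))) stop("NaN/Inf in epoch ", i, " channel ", ch)
        mag <- Mod(cwt_complex(x, config, bank, bf))
        ds <- median_downsample(mag, config$target_t, config$downsample)
        tfr[i, ch, , ] <- normalize_tfr(ds)
      }
      label[i] <- as.character(epochs[[i]]$stage)
    }
  }
  structure(list(tfr = tfr, label = factor(label, levels = STAGE_LEVELS),
                 subject = rep(record$subject_id, n_ep), config = config),
            class = "lmc_epoch_bundle")
}

#' Preprocess every recording of a synthetic dataset
#'
#' @param dataset An `lmc_synth_dataset` (or list of recordings).
#' @param config A [scalogram_config()].
#' @param ... Passed to [preprocess_record()].
#' @return A single combined `lmc_epoch_bundle`.
#' @export
preprocess_dataset <- function(dataset, config = scalogram_config(), ...) {
  recs <- if (inherits(dataset, "lmc_synth_dataset")) dataset$recordings
          else dataset
  bundles <- lapply(recs, preprocess_record, config = config, ...)
  bind_bundles(bundles)
}

bind_bundles <- function(bundles) {
  stopifnot(length(bundles) > 0)
  ns <- vapply(bundles, function(b) dim(b$tfr)[1], 1L)
  d <- dim(bundles[[1]]$tfr)[-1]
  tfr <- array(0, dim = c(sum(ns), d))
  at <- 0
  for (b in bundles) {
    n <- dim(b$tfr)[1]
    if (n > 0) tfr[(at + 1):(at + n), , , ] <- b$tfr
    at <- at + n
  }
  structure(list(
    tfr = tfr,
    label = factor(unlist(lapply(bundles, function(b) as.character(b$label))),
                   levels = STAGE_LEVELS),
    subject = unlist(lapply(bundles, function(b) b$subject)),
    config = bundles[[1]]$config), class = "lmc_epoch_bundle")
}

#' @export
print.lmc_epoch_bundle <- function(x, ...) {
  d <- dim(x$tfr)
  cat("<lmc_epoch_bundle> ", d[1], " epochs [", d[2], " ch x ", d[3],
      " t x ", d[4], " scales], ", length(unique(x$subject)),
      " subject(s)\n", sep = "")
  if (d[1] > 0) print(table(x$label))
  invisible(x)
}

#' Extract one epoch from a bundle
#'
#' @param bundle An `lmc_epoch_bundle`.
#' @param i Epoch index.
#' @return `lmc_tfr_epoch`: list with `data` `[3, T, S]`, `label`,
#'   `subject`.
#' @export
bundle_epoch <- function(bundle, i) {
  structure(list(data = array(bundle$tfr[i, , , ], dim = dim(bundle$tfr)[-1]),
                 label = bundle$label[i], subject = bundle$subject[i]),
            class = "lmc_tfr_epoch")
}

#' @rdname bundle_epoch
#' @param x Epoch to tabulate (long form: channel, time, scale, value).
#' @param ... Unused.
#' @export
tidy.lmc_tfr_epoch <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    channel = rep(seq_len(d[1]), times = d[2] * d[3]),
    time = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    scale = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = as.vector(x$data))
}

#' @rdname bundle_epoch
#' @param object Epoch to plot.
#' @export
autoplot.lmc_tfr_epoch <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$scale,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "z") +
    ggplot2::labs(title = paste("Scalogram, stage", object$label),
                  x = "downsampled time", y = "scale (small = high freq)")
}
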