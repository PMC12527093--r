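#' Stage-dependent spectral profiles for synthetic PSG
#'
#' Default oscillatory signatures used by the synthetic generator, one per
#' AASM stage. Each profile lists oscillatory components (uniform frequency
#' range in Hz, amplitude in arbitrary microvolt-like units, burst duty cycle
#' and burst-duration range in seconds), a broadband Gaussian noise SD, and an
#' EOG event model (rate per second, amplitude, duration). The defaults encode
#' the textbook signatures: continuous alpha (8-12 Hz) with frequent blinks
#' for W, low-amplitude theta (4-7 Hz) for N1, theta background plus 12-14 Hz
#' spindle bursts of 0.5-1 s for N2, high-amplitude delta (0.5-2 Hz) for N3,
#' and mixed theta (4-8 Hz) with large slow EOG deflections for REM.
#'
#' @param fs Sampling rate in Hz (component frequencies must stay below
#'   `fs / 2`).
#' @return Named list (W, N1, N2, N3, REM) of profile lists.
#' @export
stage_profiles <- function(fs = 100) {
  comp <- function(lo, hi, amp, duty = 1, burst_lo = 0.5, burst_hi = 1) {
    list(freq_lo = lo, freq_hi = hi, amplitude = amp, duty = duty,
         burst_lo = burst_lo, burst_hi = burst_hi)
  }
  eog <- function(rate, amp, dur) list(rate = rate, amplitude = amp, duration = dur)
  profiles <- list(
    W   = list(components = list(comp(8, 12, 30)),
               noise_sd = 8, eog = eog(0.25, 80, 0.3)),
    N1  = list(components = list(comp(4, 7, 18)),
               noise_sd = 8, eog = eog(0.02, 40, 0.5)),
    N2  = list(components = list(comp(4, 7, 16),
                                 comp(12, 14, 28, duty = 0.12)),
               noise_sd = 8, eog = eog(0, 0, 0.5)),
    N3  = list(components = list(comp(0.5, 2, 75)),
               noise_sd = 10, eog = eog(0, 0, 0.5)),
    REM = list(components = list(comp(4, 8, 20)),
               noise_sd = 8, eog = eog(0.15, 120, 1.5))
  )
  for (p in profiles)
    for (cc in p$components)
      if (cc$freq_hi >= fs / 2)
        stop("component frequency ", cc$freq_hi, " Hz >= Nyquist (fs/2 = ",
             fs / 2, " Hz)")
  profiles
}

hann_win <- function(n) {
  if (n <= 1) return(rep(1, max(n, 1)))
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
}

# one oscillatory component realization over n samples
synth_component <- function(cc, n, fs) {
  f <- runif(1, cc$freq_lo, cc$freq_hi)
  phase <- runif(1, 0, 2 * pi)
  carrier <- cc$amplitude * sin(2 * pi * f * seq_len(n) / fs + phase)
  if (cc$duty >= 1) return(carrier)
  # burst gating: windows totalling ~duty of the epoch
  env <- numeric(n)
  target <- cc$duty * n
  covered <- 0
  while (covered < target) {
    dur <- round(runif(1, cc$burst_lo, cc$burst_hi) * fs)
    start <- sample.int(max(n - dur, 1), 1)
    idx <- start:min(start + dur - 1, n)
    env[idx] <- pmax(env[idx], hann_win(length(idx)))
    covered <- covered + dur
  }
  carrier * env
}

synth_eog_events <- function(ev, n, fs) {
  out <- numeric(n)
  if (ev$rate <= 0 || ev$amplitude <= 0) return(out)
  k <- stats::rpois(1, ev$rate * n / fs)
  if (k == 0) return(out)
  dur <- max(round(ev$duration * fs), 2)
  for (i in seq_len(k)) {
    start <- sample.int(max(n - dur, 1), 1)
    idx <- start:min(start + dur - 1, n)
    out[idx] <- out[idx] + sample(c(-1, 1), 1) * ev$amplitude *
      hann_win(length(idx))
  }
  out
}

#' Synthesize one 30 s PSG epoch for a given sleep stage
#'
#' Generates three synchronized channels (two EEG, one EOG) whose spectral
#' content follows the stage's profile: each oscillatory component is a
#' sinusoid with jittered frequency and phase, burst-gated where the duty
#' cycle is below 1, plus broadband Gaussian noise. The EOG channel carries an
#' attenuated copy of the EEG plus stage-specific event deflections. Uses the
#' current R RNG state; seed upstream for reproducibility.
#'
#' @param stage Stage label (code 0-4 or name).
#' @param profiles Profile list as from [stage_profiles()].
#' @param fs Sampling rate in Hz.
#' @param epoch_seconds Epoch length in seconds.
#' @return Numeric matrix `[epoch_seconds * fs, 3]` with columns
#'   `eeg_fpz_cz`, `eeg_pz_oz`, `eog`.
#' @export
synth_epoch <- function(stage, profiles = stage_profiles(fs), fs = 100,
                        epoch_seconds = 30) {
  stage <- as.character(stage_factor(stage))
  p <- profiles[[stage]]
  for (cc in p$components)
    if (cc$freq_hi >= fs / 2)
      stop("component frequency ", cc$freq_hi, " Hz >= Nyquist (fs/2 = ",
           fs / 2, " Hz)")
  n <- as.integer(epoch_seconds * fs)
  mk_eeg <- function(scale) {
    sig <- numeric(n)
    for (cc in p$components) sig <- sig + scale * synth_component(cc, n, fs)
    sig + rnorm(n, sd = p$noise_sd)
  }
  ch1 <- mk_eeg(1)
  ch2 <- mk_eeg(0.8)
  eog <- 0.3 * ch1 + synth_eog_events(p$eog, n, fs) + rnorm(n, sd = p$noise_sd)
  out <- cbind(eeg_fpz_cz = ch1, eeg_pz_oz = ch2, eog = eog)
  out
}

# Stage sequence with exact per-stage quotas arranged in geometric runs, so
# realized proportions match the request while stages still occur in
# hypnogram-like bouts (mean run length 1 / (1 - persistence)).
markov_stage_sequence <- function(n, proportions, persistence = 0.85) {
  stopifnot(length(proportions) == 5, abs(sum(proportions) - 1) < 1e-6)
  # largest-remainder quota
  raw <- proportions * n
  quota <- floor(raw)
  rem <- n - sum(quota)
  if (rem > 0) {
    add <- order(raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[add] <- quota[add] + 1
  }
  left <- quota
  seq_out <- integer(0)
  current <- NA_integer_
  while (sum(left) > 0) {
    avail <- which(left > 0)
    pick <- if (length(avail) == 1) avail else {
      w <- left[avail]
      if (!is.na(current) && current %in% avail && length(avail) > 1)
        w[avail == current] <- 0  # force a stage change between runs
      avail[sample.int(length(avail), 1, prob = w)]
    }
    run <- min(1 + stats::rgeom(1, 1 - persistence), left[pick])
    seq_out <- c(seq_out, rep(pick, run))
    left[pick] <- left[pick] - run
    current <- pick
  }
  seq_out - 1L  # 0-based stage codes
}

# Sleep-EDF R&K spelling for a stage code; N3 epochs are randomly annotated
# as stage 3 or 4 so the R&K -> AASM merge is exercised.
rk_annotation <- function(code) {
  switch(code + 1L,
         "Sleep stage W",
         "Sleep stage 1",
         "Sleep stage 2",
         if (runif(1) < 0.5) "Sleep stage 3" else "Sleep stage 4",
         "Sleep stage R")
}

#' Generate a synthetic multi-subject PSG dataset
#'
#' Draws, per subject, a stage sequence with exact stage quotas arranged in
#' persistent runs (emulating hypnogram bout structure), then synthesizes
#' each 30 s epoch with [synth_epoch()] and concatenates them into one
#' continuous 3-channel recording with R&K-style annotations ("Sleep stage
#' W/1/2/3/4/R"). A small fraction of epochs is replaced by "Movement time"
#' artifacts to exercise annotation filtering. Output is bit-reproducible for
#' a given seed and parameter set.
#'
#' @param n_subjects Number of subject-nights.
#' @param epochs_per_subject 30 s epochs per subject.
#' @param proportions Length-5 stage proportions (W, N1, N2, N3, REM); the
#'   default follows the SleepEDF-20 class distribution (21.1, 6.5, 41.3,
#'   13.2, 17.9 percent).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param persistence Stage self-persistence in (0, 1); mean bout length is
#'   `1 / (1 - persistence)` epochs.
#' @param artifact_rate Fraction of epochs replaced by MOVEMENT artifacts.
#' @param fs Sampling rate in Hz.
#' @param profiles Spectral profiles, see [stage_profiles()].
#' @return An object of class `lmc_synth_dataset`: list with `recordings`
#'   (list of `lmc_recording`), `proportions`, `seed`.
#' @export
synth_dataset <- function(n_subjects, epochs_per_subject,
                          proportions = c(0.211, 0.065, 0.413, 0.132, 0.179),
                          seed = NULL, persistence = 0.85,
                          artifact_rate = 0.02, fs = 100,
                          profiles = stage_profiles(fs)) {
  proportions <- proportions / sum(proportions)
  if (!is.null(seed)) set.seed(seed)
  recs <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    codes <- markov_stage_sequence(epochs_per_subject, proportions, persistence)
    is_artifact <- runif(epochs_per_subject) < artifact_rate
    n <- 30 * fs
    chans <- matrix(0, nrow = epochs_per_subject * n, ncol = 3)
    stages <- character(epochs_per_subject)
    for (i in seq_along(codes)) {
      rows <- ((i - 1) * n + 1):(i * n)
      if (is_artifact[i]) {
        chans[rows, ] <- matrix(rnorm(3 * n, sd = 60), ncol = 3)
        stages[i] <- if (runif(1) < 0.5) "Movement time" else "Sleep stage ?"
      } else {
        chans[rows, ] <- synth_epoch(codes[i], profiles, fs)
        stages[i] <- rk_annotation(codes[i])
      }
    }
    recs[[s]] <- new_recording(
      subject_id = sprintf("S%02d", s),
      channels = list(`EEG Fpz-Cz` = chans[, 1], `EEG Pz-Oz` = chans[, 2],
                      `EOG horizontal` = chans[, 3]),
      fs = fs, stages = stages)
  }
  structure(list(recordings = recs, proportions = proportions, seed = seed),
            class = "lmc_synth_dataset")
}

#' @export
print.lmc_synth_dataset <- function(x, ...) {
  n_ep <- sum(vapply(x$recordings, function(r) length(r$stages), 1L))
  cat("<lmc_synth_dataset> ", length(x$recordings), " subjects, ",
      n_ep, " epochs (fs = ", x$recordings[[1]]$fs, " Hz)\n", sep = "")
  invisible(x)
}

#' @rdname synth_dataset
#' @param x Dataset to tabulate.
#' @param ... Unused.
#' @export
tidy.lmc_synth_dataset <- function(x, ...) {
  purrr::map_dfr(x$recordings, function(r) {
    tibble::tibble(subject = r$subject_id,
                   epoch = seq_along(r$stages),
                   annotation = r$stages)
  })
}

#' Band power of a signal in a frequency band
#'
#' Mean periodogram power of `x` over `[f_lo, f_hi)` Hz, computed from the
#' FFT. Used by the synthetic-data separability checks and handy for quick
#' sanity plots.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param f_lo,f_hi Band edges in Hz.
#' @return Scalar mean power in the band.
#' @export
band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- freqs >= f_lo & freqs < f_hi & freqs <= fs / 2
  if (!any(sel)) return(0)
  mean(sp[sel])
}
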