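#' Construct a raw PSG recording
#'
#' Container for one subject-night: synchronized channels at a common
#' sampling rate plus one raw annotation string per 30 s interval. All
#' channel vectors must have equal length; if more labels are supplied than
#' `floor(length / (30 * fs))` whole epochs, the excess labels are dropped.
#'
#' @param subject_id Subject identifier string.
#' @param channels Named list of equal-length numeric vectors (microvolts).
#' @param fs Sampling rate in Hz (> 0).
#' @param stages Character vector of raw 30 s stage annotations.
#' @return Object of class `lmc_recording`.
#' @export
new_recording <- function(subject_id, channels, fs, stages = character()) {
  stopifnot(is.list(channels), length(channels) >= 1, fs > 0)
  lens <- vapply(channels, length, 1L)
  if (length(unique(lens)) != 1)
    stop("all channels must have equal length; got ",
         paste(lens, collapse = ", "))
  max_epochs <- floor(lens[[1]] / (30 * fs))
  if (length(stages) > max_epochs) stages <- stages[seq_len(max_epochs)]
  structure(list(subject_id = subject_id, channels = channels, fs = fs,
                 stages = stages),
            class = "lmc_recording")
}

#' @export
print.lmc_recording <- function(x, ...) {
  cat("<lmc_recording> ", x$subject_id, ": ",
      length(x$channels), " channels x ", length(x$channels[[1]]),
      " samples @ ", x$fs, " Hz, ", length(x$stages), " stage labels\n",
      sep = "")
  invisible(x)
}

pad_ascii <- function(s, width) {
  s <- substr(s, 1, width)
  sprintf("%-*s", width, s)
}

#' Write a recording to EDF with a companion EDF+ hypnogram
#'
#' Writes the signals as a plain EDF file (30 s data records, 16-bit samples
#' with per-signal physical scaling) and the stage annotations as a separate
#' EDF+ annotation file in Sleep-EDF hypnogram style (one timestamped
#' annotation per stage bout, consecutive identical stages merged). The
#' signal is truncated to a whole number of 30 s records.
#'
#' @param record An [new_recording()] object.
#' @param psg_path Output path for the signal EDF.
#' @param hyp_path Output path for the hypnogram EDF+ file (optional; skipped
#'   when `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_edf <- function(record, psg_path, hyp_path = NULL) {
  fs <- record$fs
  spr <- as.integer(30 * fs)              # samples per 30 s record per signal
  nrec <- floor(length(record$channels[[1]]) / spr)
  ns <- length(record$channels)
  con <- file(psg_path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(paste0(
    pad_ascii("0", 8),
    pad_ascii(record$subject_id, 80),
    pad_ascii("Startdate 01-JAN-2000 synthetic", 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii(as.character(256 * (ns + 1)), 8),
    pad_ascii("", 44),
    pad_ascii(as.character(nrec), 8),
    pad_ascii("30", 8),
    pad_ascii(as.character(ns), 4)), con, eos = NULL)
  phys_max <- vapply(record$channels, function(x) {
    m <- max(abs(x[seq_len(nrec * spr)]), 1e-6)
    ceiling(m)
  }, 1)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, pad_ascii, "", width = width),
                    collapse = ""), con, eos = NULL)
  field(names(record$channels), 16)
  field(rep("synthetic", ns), 80)
  field(rep("uV", ns), 8)
  field(as.character(-phys_max), 8)
  field(as.character(phys_max), 8)
  field(rep("-32768", ns), 8)
  field(rep("32767", ns), 8)
  field(rep("", ns), 80)
  field(rep(as.character(spr), ns), 8)
  field(rep("", ns), 32)
  dig <- lapply(seq_len(ns), function(i) {
    x <- record$channels[[i]][seq_len(nrec * spr)]
    as.integer(pmin(pmax(round(
      (x + phys_max[i]) / (2 * phys_max[i]) * 65535 - 32768), -32768), 32767))
  })
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (i in seq_len(ns)) writeBin(dig[[i]][idx], con, size = 2,
                                    endian = "little")
  }
  if (!is.null(hyp_path)) write_hypnogram_edf(record$stages, hyp_path)
  invisible(c(psg_path, hyp_path))
}

# EDF+ annotation-only file: a single data record holding all stage TALs.
write_hypnogram_edf <- function(stages, path) {
  onset <- (seq_along(stages) - 1) * 30
  keep <- c(TRUE, stages[-1] != stages[-length(stages)])
  bout_start <- onset[keep]
  bout_stage <- stages[keep]
  bout_end <- c(bout_start[-1], length(stages) * 30)
  tal <- paste0("+0\x14\x14",
                paste0("+", bout_start, "\x15", bout_end - bout_start,
                       "\x14", bout_stage, "\x14", collapse = ""))
  payload <- c(charToRaw(tal), as.raw(0))
  if (length(payload) %% 2 == 1) payload <- c(payload, as.raw(0))
  spr <- length(payload) / 2
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(paste0(
    pad_ascii("0", 8), pad_ascii("hypnogram", 80),
    pad_ascii("Startdate 01-JAN-2000 synthetic", 80),
    pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
    pad_ascii("512", 8), pad_ascii("EDF+C", 44),
    pad_ascii("1", 8), pad_ascii("0", 8), pad_ascii("1", 4)), con, eos = NULL)
  writeChar(paste0(
    pad_ascii("EDF Annotations", 16), pad_ascii("", 80), pad_ascii("", 8),
    pad_ascii("-1", 8), pad_ascii("1", 8), pad_ascii("-32768", 8),
    pad_ascii("32767", 8), pad_ascii("", 80),
    pad_ascii(as.character(spr), 8), pad_ascii("", 32)), con, eos = NULL)
  writeBin(payload, con)
  invisible(path)
}

read_header_field <- function(raw, at, width) {
  trimws(rawToChar(raw[(at + 1):(at + width)]))
}

#' Read an EDF/EDF+ file
#'
#' Minimal EDF reader: parses the fixed-layout header, decodes ordinary
#' signals to physical units, and parses any "EDF Annotations" signal into a
#' table of (onset, duration, text) annotations.
#'
#' @param path EDF file path.
#' @return List with `signals` (named list of numeric vectors), `fs` (named
#'   numeric, Hz per signal), `annotations` (tibble with columns onset,
#'   duration, text), `patient`, `n_records`, `record_seconds`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such EDF file: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 256) stop("not an EDF file (truncated header): ", path)
  patient <- read_header_field(raw, 8, 80)
  nrec <- as.integer(read_header_field(raw, 236, 8))
  rec_sec <- as.numeric(read_header_field(raw, 244, 8))
  ns <- as.integer(read_header_field(raw, 252, 4))
  sig_field <- function(off, width, i)
    read_header_field(raw, 256 + off * ns + (i - 1) * width, width)
  labels <- vapply(seq_len(ns), function(i) sig_field(0, 16, i), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) sig_field(104, 8, i), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) sig_field(112, 8, i), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) sig_field(120, 8, i), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) sig_field(128, 8, i), ""))
  spr <- as.integer(vapply(seq_len(ns), function(i) sig_field(216, 8, i), ""))
  hdr_bytes <- 256 * (ns + 1)
  rec_bytes <- sum(spr) * 2
  is_ann <- labels == "EDF Annotations"
  sig_raw <- vector("list", ns)
  for (i in seq_len(ns)) sig_raw[[i]] <-
    if (is_ann[i]) raw(0) else integer(0)
  # pre-allocate numeric storage
  signals <- lapply(seq_len(ns), function(i)
    if (is_ann[i]) NULL else numeric(nrec * spr[i]))
  ann_raw <- raw(0)
  off0 <- hdr_bytes
  for (r in seq_len(nrec)) {
    off <- off0 + (r - 1) * rec_bytes
    for (i in seq_len(ns)) {
      nbytes <- spr[i] * 2
      chunk <- raw[(off + 1):(off + nbytes)]
      if (is_ann[i]) {
        ann_raw <- c(ann_raw, chunk)
      } else {
        d <- readBin(chunk, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
        phys <- pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) /
          (dmax[i] - dmin[i])
        signals[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
      }
      off <- off + nbytes
    }
  }
  annotations <- parse_tals(ann_raw)
  keep <- !is_ann
  list(signals = setNames(signals[keep], labels[keep]),
       fs = setNames(spr[keep] / rec_sec, labels[keep]),
       annotations = annotations,
       patient = patient, n_records = nrec, record_seconds = rec_sec)
}

# Parse EDF+ time-stamped annotation lists (TALs) from a raw byte stream.
parse_tals <- function(ann_raw) {
  empty <- tibble::tibble(onset = numeric(), duration = numeric(),
                          text = character())
  if (length(ann_raw) == 0) return(empty)
  nz <- ann_raw[ann_raw != as.raw(0)]
  # split the stream into TALs; a TAL is [+-]onset(\x15duration)?\x14text\x14
  chunks <- strsplit(rawToChar(nz), "\x14\\+", perl = TRUE)[[1]]
  if (length(chunks) == 0) return(empty)
  chunks[-1] <- paste0("+", chunks[-1])
  out <- list()
  for (tal in chunks) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2) next  # timestamp-only TAL
    head_part <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head_part[1]))
    if (is.na(onset)) stop("unparsable annotation onset: ", parts[1])
    duration <- if (length(head_part) > 1)
      suppressWarnings(as.numeric(head_part[2])) else NA_real_
    for (text in parts[-1]) {
      if (nzchar(text))
        out[[length(out) + 1]] <- tibble::tibble(onset = onset,
                                                 duration = duration,
                                                 text = text)
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

#' Read a Sleep-EDF-style PSG / hypnogram pair
#'
#' Reads the named channels from the signal EDF and the stage annotations
#' from the hypnogram EDF+, expands each annotated bout into one label per
#' 30 s interval, and returns a recording. Labels are truncated to the
#' annotated span and never exceed the number of whole 30 s epochs in the
#' signal.
#'
#' @param psg_path Path to the signal EDF.
#' @param hyp_path Path to the hypnogram EDF(+).
#' @param channel_names Channel labels to extract, in the desired order
#'   (default: the Sleep-EDF montage Fpz-Cz, Pz-Oz, horizontal EOG).
#' @return An `lmc_recording`.
#' @export
read_sleepedf_pair <- function(psg_path, hyp_path,
                               channel_names = c("EEG Fpz-Cz", "EEG Pz-Oz",
                                                 "EOG horizontal")) {
  psg <- read_edf(psg_path)
  missing_ch <- setdiff(channel_names, names(psg$signals))
  if (length(missing_ch) > 0)
    stop("channel(s) not in EDF: ", paste(missing_ch, collapse = ", "),
         "; available: ", paste(names(psg$signals), collapse = ", "))
  fs <- unname(psg$fs[channel_names])
  if (length(unique(fs)) != 1)
    stop("requested channels have different sampling rates: ",
         paste(fs, collapse = ", "))
  hyp <- read_edf(hyp_path)
  ann <- hyp$annotations
  ann <- ann[grepl("^(Sleep stage|Movement|MOVEMENT|Sleep_stage)", ann$text), ]
  labels <- character(0)
  if (nrow(ann) > 0) {
    ann <- ann[order(ann$onset), ]
    for (k in seq_len(nrow(ann))) {
      dur <- ann$duration[k]
      if (is.na(dur) || dur <= 0) dur <- 30
      n_lab <- floor(dur / 30)
      i0 <- round(ann$onset[k] / 30)
      if (n_lab > 0) labels[(i0 + 1):(i0 + n_lab)] <- ann$text[k]
    }
  }
  labels[is.na(labels)] <- "Sleep stage ?"
  new_recording(subject_id = psg$patient,
                channels = psg$signals[channel_names],
                fs = fs[1], stages = labels)
}

#' Map R&K stage annotations to the 5-class AASM scheme
#'
#' R&K stages 3 and 4 merge into N3; MOVEMENT and UNKNOWN epochs are flagged
#' for removal (`keep = FALSE`) rather than silently dropped. Any annotation
#' outside the declared vocabulary is an error naming the offending string.
#'
#' @param raw_stages Character vector of annotations (Sleep-EDF spellings
#'   like "Sleep stage W" / "Sleep stage 4" / "Movement time", or the bare
#'   tokens W/1/2/3/4/R/MOVEMENT/UNKNOWN).
#' @return Tibble with columns `annotation`, `stage` (factor W..REM, `NA`
#'   for removed epochs), `code` (0-4 integer, `NA` for removed), `keep`.
#' @export
map_stages_rk_to_aasm <- function(raw_stages) {
  vocab <- c(
    "Sleep stage W" = "W", "W" = "W",
    "Sleep stage 1" = "N1", "1" = "N1",
    "Sleep stage 2" = "N2", "2" = "N2",
    "Sleep stage 3" = "N3", "3" = "N3",
    "Sleep stage 4" = "N3", "4" = "N3",
    "Sleep stage R" = "REM", "R" = "REM", "REM" = "REM",
    "Movement time" = "DROP", "MOVEMENT" = "DROP", "M" = "DROP",
    "Sleep stage ?" = "DROP", "UNKNOWN" = "DROP", "?" = "DROP")
  unknown <- setdiff(unique(raw_stages), names(vocab))
  if (length(unknown) > 0)
    stop("unknown stage annotation(s): ",
         paste(sprintf('"%s"', unknown), collapse = ", "))
  mapped <- unname(vocab[raw_stages])
  keep <- mapped != "DROP"
  stage <- rep(NA_character_, length(mapped))
  stage[keep] <- mapped[keep]
  stage <- factor(stage, levels = STAGE_LEVELS)
  tibble::tibble(annotation = raw_stages, stage = stage,
                 code = as.integer(stage) - 1L, keep = keep)
}

#' Save / load a preprocessed epoch bundle
#'
#' A keyed on-disk container for preprocessed scalogram epochs: arrays
#' `tfr` `[N, 3, T, S]`, `label` (factor), `subject` (character), and the
#' `config` used to produce them.
#'
#' @param bundle An `lmc_epoch_bundle` (see [preprocess_record()]).
#' @param path Output file path.
#' @return `save_tfr_bundle()` returns the path invisibly;
#'   `load_tfr_bundle()` the bundle.
#' @export
save_tfr_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "lmc_epoch_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_tfr_bundle
#' @export
load_tfr_bundle <- function(path) {
  bundle <- readRDS(path)
  if (!inherits(bundle, "lmc_epoch_bundle"))
    stop("file is not an epoch bundle: ", path)
  bundle
}
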