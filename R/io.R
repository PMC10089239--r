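# File formats and configuration: minimal EDF reader/writer, delimited
# array I/O, and lossless JSON round-tripping of pipeline configurations.

fmt_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

#' Write an EEG recording as an EDF file
#'
#' Minimal European-Data-Format writer: a single data record holding the
#' whole recording, 16-bit samples scaled per channel to the data range.
#' Round-trip accuracy is therefore limited by the 16-bit quantisation step
#' (data range / 65534 per channel).
#'
#' @param rec An [eeg_recording()].
#' @param path Output file.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data); n_samp <- ncol(rec$data)
  phys_max <- pmax(apply(abs(rec$data), 1, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    fmt_field("0", 8), fmt_field("synthetic", 80), fmt_field("rhythmtag", 80),
    fmt_field("01.01.00", 8), fmt_field("00.00.00", 8),
    fmt_field(hdr_bytes, 8), fmt_field("", 44), fmt_field(1, 8),
    fmt_field(format(n_samp / rec$fs_hz, digits = 7), 8), fmt_field(ns, 4)),
    con, eos = NULL)
  fields <- c(
    vapply(rec$channel_labels, fmt_field, "", width = 16),
    rep(fmt_field("", 80), ns),
    rep(fmt_field("uV", 8), ns),
    vapply(-phys_max, function(v) fmt_field(format(v, digits = 7), 8), ""),
    vapply(phys_max, function(v) fmt_field(format(v, digits = 7), 8), ""),
    rep(fmt_field(-32767, 8), ns),
    rep(fmt_field(32767, 8), ns),
    rep(fmt_field("", 80), ns),
    rep(fmt_field(n_samp, 8), ns),
    rep(fmt_field("", 32), ns))
  writeChar(paste(fields, collapse = ""), con, eos = NULL)
  for (ch in seq_len(ns)) {
    dig <- as.integer(round(rec$data[ch, ] / phys_max[ch] * 32767))
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEG recording
#'
#' Reads continuous EDF (16-bit) files such as those produced by
#' [write_edf()], concatenating data records.
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (length(ns) != 1L || is.na(ns) || ns < 1)
    stop("corrupt or truncated EDF header")
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(spr) != ns || anyNA(spr) || any(spr < 1))
    stop("corrupt or truncated EDF header")
  if (!all(spr == spr[1])) stop("EDF files with mixed sampling rates are not supported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, ns, spr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      if (length(dig) < spr[ch]) stop("truncated EDF data section")
      scale <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
      data[ch, (r - 1) * spr[1] + seq_len(spr[ch])] <-
        phys_min[ch] + (dig - dig_min[ch]) * scale
    }
  }
  eeg_recording(data, fs, labels, "unknown")
}

#' Write a recording as a TSV matrix (+ JSON sidecar with the sampling rate)
#' @param rec An [eeg_recording()].
#' @param path Output TSV path; a `.json` sidecar is written alongside.
#' @export
write_eeg_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- t(rec$data)
  colnames(m) <- rec$channel_labels
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(fs_hz = rec$fs_hz, reference = rec$reference,
                            channel_labels = rec$channel_labels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EEG recording from EDF or TSV
#'
#' Dispatches on the file extension: `.edf` files go through [read_edf()],
#' anything else is read as a delimited matrix (columns = channels, header =
#' labels) with the sampling rate taken from a `.json` sidecar or the
#' `fs_hz` argument. Errors when the sidecar and `fs_hz` disagree or when
#' labels do not match the data.
#'
#' @param path Input file.
#' @param fs_hz Sampling rate for delimited input (optional when a sidecar
#'   exists).
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, fs_hz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    rec <- read_edf(path)
    if (!is.null(fs_hz) && abs(rec$fs_hz - fs_hz) > 1e-9)
      stop(sprintf("sampling-rate mismatch: file says %g Hz, caller says %g Hz",
                   rec$fs_hz, fs_hz))
    return(rec)
  }
  m <- utils::read.delim(path, check.names = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE)
  else NULL
  if (is.null(fs_hz)) {
    if (is.null(meta$fs_hz)) stop("no sampling rate: supply fs_hz or a .json sidecar")
    fs_hz <- meta$fs_hz
  } else if (!is.null(meta$fs_hz) && abs(meta$fs_hz - fs_hz) > 1e-9)
    stop("sampling-rate mismatch between sidecar and fs_hz argument")
  if (!is.null(meta$channel_labels) &&
      !identical(as.character(meta$channel_labels), colnames(m)))
    stop("channel-label mismatch between sidecar and file header")
  eeg_recording(t(as.matrix(m)), fs_hz, colnames(m),
                if (is.null(meta$reference)) "unknown" else meta$reference)
}

#' Pipeline configuration
#'
#' One flat configuration object covering every stage parameter, designed to
#' round-trip losslessly through JSON. See [run_pipeline()].
#'
#' @param rhythms Which rhythms to analyse.
#' @param n_channels,fs_hz,n_trials,n_participants Synthetic-cohort geometry.
#' @param n_repetitions Named list of pattern repeats per trial per rhythm.
#' @param noise_exponent,noise_rms_uv,kappa Synthetic noise / phase model.
#' @param window_bins Neighbour window for [noise_subtract()].
#' @param n_cycles,step_ms Morlet parameters.
#' @param trim_s Named list of per-rhythm edge trims (seconds).
#' @param sync_freqs_hz Named list of per-rhythm SI frequencies.
#' @param preprocess Run the filtering/rejection chain before analysis
#'   (`TRUE`) or segment the raw synthetic recording directly (`FALSE`).
#' @param lo_hz,hi_hz,line_hz,reject_uv,block_uv Preprocessing parameters.
#' @param seed Master seed.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(rhythms = c("duple_triple", "quadruple"),
                            n_channels = 98, fs_hz = 1000, n_trials = 50,
                            n_participants = 17,
                            n_repetitions = list(duple_triple = 19, quadruple = 9),
                            noise_exponent = 1, noise_rms_uv = 10, kappa = 5,
                            window_bins = c(3, 5), n_cycles = 7, step_ms = 2,
                            trim_s = list(duple_triple = 2, quadruple = 4),
                            sync_freqs_hz = list(duple_triple = c(1, 1.5, 3),
                                                 quadruple = c(0.75, 3)),
                            preprocess = FALSE, lo_hz = 0.5, hi_hz = 45,
                            line_hz = 50, reject_uv = 30, block_uv = 100,
                            seed = 1) {
  structure(list(rhythms = rhythms, n_channels = n_channels, fs_hz = fs_hz,
                 n_trials = n_trials, n_participants = n_participants,
                 n_repetitions = n_repetitions, noise_exponent = noise_exponent,
                 noise_rms_uv = noise_rms_uv, kappa = kappa,
                 window_bins = window_bins, n_cycles = n_cycles,
                 step_ms = step_ms, trim_s = trim_s,
                 sync_freqs_hz = sync_freqs_hz, preprocess = preprocess,
                 lo_hz = lo_hz, hi_hz = hi_hz, line_hz = line_hz,
                 reject_uv = reject_uv, block_uv = block_uv,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Reduced-size study configuration
#'
#' The scaled-down cohort used by the analysis drivers and the validation
#' suite: the published cohort structure (17 participants, 50 trials per
#' rhythm, von Mises kappa = 5, 10 uV RMS pink noise) with shorter trials
#' (10 six-beat / 5 twelve-beat pattern repeats, about 20 s), 48 channels
#' and a 250 Hz sampling rate, sized so group-level recovery of the injected
#' amplitudes and lags is statistically comfortable while a full run stays
#' in the minutes range. At the coarser 0.05 Hz resolution of the shorter
#' trials the noise-subtraction window is +/-2..3 bins (+/-0.10-0.15 Hz),
#' which keeps the window's physical span inside the one used at 0.028 Hz
#' resolution and keeps stimulus harmonics 0.25 Hz apart out of each
#' other's noise estimates.
#'
#' @param seed Master seed.
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
scaled_study_config <- function(seed = 1, ...) {
  pipeline_config(n_channels = 48, fs_hz = 250, n_trials = 50,
                  n_participants = 17,
                  n_repetitions = list(duple_triple = 10, quadruple = 5),
                  trim_s = list(duple_triple = 2, quadruple = 4),
                  window_bins = c(2, 3),
                  seed = seed, ...)
}

#' Write / read a pipeline configuration as JSON
#' @param cfg A `pipeline_config`.
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$window_bins <- as.numeric(raw$window_bins)
  raw$rhythms <- as.character(raw$rhythms)
  cfg <- do.call(pipeline_config, raw)
  cfg
}
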