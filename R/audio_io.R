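#' Construct an audio signal
#'
#' The basic unit every pipeline stage consumes: a waveform with its sample
#' rate. Samples are dimensionless amplitudes, nominally in `[-1, 1]`.
#' Multi-channel audio is represented as a matrix with one column per channel
#' until [preprocess()] collapses it to mono.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#' @param sample_rate Sampling rate in Hz (positive).
#' @return An object of class `audio_signal` with elements `samples` and
#'   `sample_rate`.
#' @export
audio_signal <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("'samples' must be a non-empty numeric vector or matrix")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0)
    stop("'sample_rate' must be a single positive number")
  structure(list(samples = samples, sample_rate = as.integer(round(sample_rate))),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  ch <- if (is.matrix(x$samples)) ncol(x$samples) else 1L
  n <- if (is.matrix(x$samples)) nrow(x$samples) else length(x$samples)
  cat(sprintf("<audio_signal> %d channel(s), %d samples @ %d Hz (%.3f s)\n",
              ch, n, x$sample_rate, n / x$sample_rate))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param signal An `audio_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(signal) {
  stopifnot(inherits(signal, "audio_signal"))
  n <- if (is.matrix(signal$samples)) nrow(signal$samples) else length(signal$samples)
  n / signal$sample_rate
}

# -- WAV I/O ------------------------------------------------------------------
# Minimal RIFF/WAVE codec. Readers accept PCM 8/16/24/32-bit and IEEE float;
# the writer always emits mono/stereo 16-bit PCM. Samples are normalized to
# [-1, 1] on read regardless of bit depth, so downstream energy thresholds
# are depth-independent.

#' Read a WAV file
#'
#' Supports PCM (8, 16, 24, 32 bit) and 32-bit IEEE float data. Samples are
#' scaled to `[-1, 1]`. Multi-channel files return a matrix with one column
#' per channel; use [preprocess()] to downmix and resample.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("audio file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4L, useBytes = TRUE), "RIFF"))
    stop("cannot decode '", path, "': not a RIFF file")
  readBin(con, "integer", 1L, 4L, endian = "little")
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    stop("cannot decode '", path, "': not a WAVE file")
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        format   = readBin(con, "integer", 1L, 2L, signed = FALSE, endian = "little"),
        channels = readBin(con, "integer", 1L, 2L, signed = FALSE, endian = "little"),
        rate     = readBin(con, "integer", 1L, 4L, endian = "little"),
        byterate = readBin(con, "integer", 1L, 4L, endian = "little"),
        align    = readBin(con, "integer", 1L, 2L, signed = FALSE, endian = "little"),
        bits     = readBin(con, "integer", 1L, 2L, signed = FALSE, endian = "little"))
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) readBin(con, "raw", 1L)
    } else {
      readBin(con, "raw", size + size %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("cannot decode '", path, "': missing fmt chunk")
  if (is.null(data_raw) || length(data_raw) == 0L)
    stop("cannot decode '", path, "': empty or missing data chunk")
  x <- decode_pcm(data_raw, fmt$format, fmt$bits)
  if (length(x) < 1L) stop("cannot decode '", path, "': no samples")
  if (fmt$channels > 1L) {
    n <- (length(x) %/% fmt$channels) * fmt$channels
    x <- matrix(x[seq_len(n)], ncol = fmt$channels, byrow = TRUE)
  }
  audio_signal(x, fmt$rate)
}

decode_pcm <- function(raw, format, bits) {
  if (format == 3L) {
    if (bits == 32L) return(readBin(raw, "double", length(raw) %/% 4L, 4L, endian = "little"))
    if (bits == 64L) return(readBin(raw, "double", length(raw) %/% 8L, 8L, endian = "little"))
    stop("unsupported float bit depth: ", bits)
  }
  if (format != 1L) stop("unsupported WAV encoding (format tag ", format, ")")
  switch(as.character(bits),
    "8"  = (as.integer(raw) - 128) / 128,
    "16" = readBin(raw, "integer", length(raw) %/% 2L, 2L, endian = "little") / 32768,
    "24" = {
      n <- length(raw) %/% 3L
      b <- matrix(as.integer(raw[seq_len(3L * n)]), nrow = 3L)
      v <- b[1L, ] + 256L * b[2L, ] + 65536L * b[3L, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = readBin(raw, "integer", length(raw) %/% 4L, 4L, endian = "little") / 2147483648,
    stop("unsupported PCM bit depth: ", bits))
}

#' Write an audio signal as 16-bit PCM WAV
#'
#' Samples are clipped to `[-1, 1]` and quantized to 16 bits.
#'
#' @param signal An [audio_signal()] (mono vector or channel-column matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  ch <- ncol(x)
  pcm <- as.integer(round(pmax(pmin(t(x), 1), -1) * 32767))
  data_size <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")
  writeBin(ch, con, 2L, endian = "little")
  writeBin(signal$sample_rate, con, 4L, endian = "little")
  writeBin(signal$sample_rate * ch * 2L, con, 4L, endian = "little")
  writeBin(ch * 2L, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}

# -- Normalization ------------------------------------------------------------

#' Normalize audio to mono 44,100 Hz
#'
#' Standardizes a recording for the pause pipeline: multi-channel audio is
#' downmixed by the arithmetic mean of its channels, then band-limited
#' polyphase resampling brings the waveform to the target rate. Already
#' conformant input is returned unchanged, which makes the operation
#' idempotent.
#'
#' @param raw An [audio_signal()] with any number of channels and any rate.
#' @param target_rate Target sampling rate in Hz (default 44100).
#' @return A mono [audio_signal()] at `target_rate`.
#' @export
preprocess <- function(raw, target_rate = 44100L) {
  stopifnot(inherits(raw, "audio_signal"))
  x <- raw$samples
  if (is.matrix(x)) x <- rowMeans(x)
  if (length(x) < 1L) stop("cannot preprocess an empty signal")
  if (raw$sample_rate != target_rate) {
    g <- int_gcd(as.integer(target_rate), raw$sample_rate)
    x <- as.numeric(signal::resample(x, target_rate %/% g, raw$sample_rate %/% g))
  }
  audio_signal(x, target_rate)
}

int_gcd <- function(a, b) if (b == 0L) a else int_gcd(b, a %% b)

#' Cut a signal into non-overlapping frames
#'
#' Frames are contiguous blocks of `floor(frame_duration * sample_rate)`
#' samples; a trailing remainder shorter than one frame is dropped, so the
#' frame count is `floor(duration / frame_duration)`.
#'
#' @param signal A mono [audio_signal()].
#' @param frame_duration Frame length in seconds (default 0.03, the pause
#'   feature resolution).
#' @return A numeric matrix with one column per frame (`frame_length` rows),
#'   with attributes `frame_duration` and `dropped_samples`.
#' @export
frame_audio <- function(signal, frame_duration = 0.03) {
  stopifnot(inherits(signal, "audio_signal"))
  if (is.matrix(signal$samples))
    stop("frame_audio() expects mono audio; run preprocess() first")
  if (!is.numeric(frame_duration) || frame_duration <= 0)
    stop("'frame_duration' must be positive")
  nf <- floor(frame_duration * signal$sample_rate)
  if (nf < 1L) stop("'frame_duration' is shorter than one sample")
  n_frames <- length(signal$samples) %/% nf
  if (n_frames < 1L)
    stop(sprintf("signal (%.4f s) is shorter than one frame (%.4f s)",
                 signal_duration(signal), frame_duration))
  frames <- matrix(signal$samples[seq_len(nf * n_frames)], nrow = nf)
  attr(frames, "frame_duration") <- frame_duration
  attr(frames, "dropped_samples") <- length(signal$samples) - nf * n_frames
  frames
}

#' Cut a signal into fixed-duration segments
#'
#' Used to produce the 4-second clips that segment-level classifiers consume.
#' The trailing remainder shorter than one segment is dropped.
#'
#' @param signal A mono [audio_signal()].
#' @param segment_duration Segment length in seconds (default 4).
#' @return A list of [audio_signal()] segments.
#' @export
segment_signal <- function(signal, segment_duration = 4) {
  stopifnot(inherits(signal, "audio_signal"))
  ns <- floor(segment_duration * signal$sample_rate)
  n_seg <- length(signal$samples) %/% ns
  if (n_seg < 1L)
    stop("signal is shorter than one segment (", segment_duration, " s)")
  lapply(seq_len(n_seg), function(i)
    audio_signal(signal$samples[((i - 1L) * ns + 1L):(i * ns)], signal$sample_rate))
}

# -- Corpus manifests ---------------------------------------------------------

#' Read a corpus manifest
#'
#' A manifest is a CSV with header `subject_id,audio_path,label` mapping each
#' recording to a subject and (optionally) a binary diagnosis label
#' (0 = control, 1 = AD). Subject ids must be unique.
#'
#' @param path CSV path.
#' @return A data.frame with columns `subject_id`, `audio_path`, `label`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       audio_path = "character"))
  validate_manifest(df)
}

#' Write a corpus manifest
#' @param manifest Data.frame with columns `subject_id`, `audio_path`, `label`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

validate_manifest <- function(df) {
  need <- c("subject_id", "audio_path", "label")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("manifest subject_ids must be unique")
  lab <- df$label[!is.na(df$label)]
  if (length(lab) && !all(lab %in% c(0, 1)))
    stop("manifest labels must be 0 (non-AD) or 1 (AD)")
  df
}
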