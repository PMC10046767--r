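# Synthetic two-group speech corpora.
#
# Recordings alternate voiced and pause intervals with exponentially
# distributed durations; the two groups differ in their pause-duration mean
# (the AD-like group pauses longer/more), which is the contrast the pause
# pipeline is meant to detect. Voiced intervals are equal-amplitude harmonic
# complexes (f0 drawn per interval, partials up to 4 kHz) over a band-limited
# noise floor; pauses carry the noise floor only. Ground-truth frame labels
# on the 0.03 s grid are returned alongside, so detector accuracy is exactly
# scorable. This is a test harness emulating pause structure, not a model of
# speech.

#' Configuration for the synthetic speech generator
#'
#' Defaults emulate a two-group contrast in pause structure: both groups
#' share the voiced-interval mean while the AD-like group's pauses are three
#' times longer on average (0.5 s vs 1.5 s), mirroring the qualitative
#' AD-vs-control difference the pipeline targets.
#'
#' @param n_subjects_per_group Subjects per group (default 5).
#' @param duration Recording length in seconds (default 60).
#' @param voiced_dur_mean Mean voiced-interval duration in seconds, length-2
#'   vector `c(control, ad)` (default both 1.5).
#' @param pause_dur_mean Mean pause duration in seconds, `c(control, ad)`
#'   (default `c(0.5, 1.5)`); `Inf` produces pure pause.
#' @param voiced_amplitude Peak amplitude of voiced intervals, in (0, 1]
#'   (default 0.5).
#' @param noise_floor Peak amplitude of the noise floor, in [0, 1)
#'   (default 0.001, i.e. -54 dB below the voiced peak).
#' @param f0_range Fundamental-frequency range in Hz (default 100-220).
#' @param sample_rate Output sampling rate in Hz (default 44100).
#' @param seed Corpus master seed; per-recording seeds derive from it.
#' @return Object of class `speech_gen_config`.
#' @export
speech_gen_config <- function(n_subjects_per_group = 5L, duration = 60,
                              voiced_dur_mean = c(1.5, 1.5),
                              pause_dur_mean = c(0.5, 1.5),
                              voiced_amplitude = 0.5, noise_floor = 0.001,
                              f0_range = c(100, 220), sample_rate = 44100L,
                              seed = 1L) {
  if (length(voiced_dur_mean) == 1L) voiced_dur_mean <- rep(voiced_dur_mean, 2L)
  if (length(pause_dur_mean) == 1L) pause_dur_mean <- rep(pause_dur_mean, 2L)
  stopifnot(n_subjects_per_group >= 1L, duration > 0,
            all(voiced_dur_mean > 0), all(pause_dur_mean > 0),
            voiced_amplitude > 0, voiced_amplitude <= 1,
            noise_floor >= 0, noise_floor < 1,
            length(f0_range) == 2L, f0_range[1L] > 0,
            f0_range[2L] >= f0_range[1L])
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 duration = duration,
                 voiced_dur_mean = stats::setNames(voiced_dur_mean, c("cn", "ad")),
                 pause_dur_mean = stats::setNames(pause_dur_mean, c("cn", "ad")),
                 voiced_amplitude = voiced_amplitude,
                 noise_floor = noise_floor, f0_range = f0_range,
                 sample_rate = as.integer(sample_rate),
                 seed = as.integer(seed)),
            class = "speech_gen_config")
}

#' Generate one synthetic recording with ground-truth frame labels
#'
#' @param config A [speech_gen_config()].
#' @param group 0 (control) or 1 (AD-like).
#' @param seed Integer seed for this recording.
#' @param frame_duration Frame grid for the ground-truth labels (default
#'   0.03 s); a frame is voiced when voiced intervals cover more than half
#'   of it.
#' @return List with `signal` (an [audio_signal()]), `truth` (integer 0/1
#'   frame labels) and `group`.
#' @export
generate_recording <- function(config, group, seed,
                               frame_duration = 0.03) {
  stopifnot(inherits(config, "speech_gen_config"), group %in% c(0L, 1L))
  set.seed(as.integer(seed))
  sr <- config$sample_rate
  n <- round(config$duration * sr)
  g <- if (group == 1L) "ad" else "cn"
  vm <- config$voiced_dur_mean[[g]]
  pm <- config$pause_dur_mean[[g]]

  # alternating state intervals; stationary start probability
  p_voiced_start <- if (is.infinite(pm)) 0 else vm / (vm + pm)
  state <- stats::runif(1L) < p_voiced_start
  t_cur <- 0
  onsets <- numeric(0); offsets <- numeric(0)
  while (t_cur < config$duration) {
    mean_d <- if (state) vm else pm
    d <- if (is.infinite(mean_d)) Inf else stats::rexp(1L, 1 / mean_d)
    t_next <- min(t_cur + d, config$duration)
    if (state) { onsets <- c(onsets, t_cur); offsets <- c(offsets, t_next) }
    t_cur <- t_next
    state <- !state
  }

  x <- synth_noise_floor(n, sr, config$noise_floor)
  voiced_mask <- logical(n)
  for (k in seq_along(onsets)) {
    i0 <- floor(onsets[k] * sr) + 1L
    i1 <- min(ceiling(offsets[k] * sr), n)
    if (i1 < i0) next
    idx <- i0:i1
    f0 <- stats::runif(1L, config$f0_range[1L], config$f0_range[2L])
    phase <- stats::runif(1L, 0, 2 * pi)
    x[idx] <- x[idx] + harmonic_complex(length(idx), sr, f0, phase,
                                        config$voiced_amplitude)
    voiced_mask[idx] <- TRUE
  }

  n_frames <- floor(config$duration / frame_duration)
  nf <- floor(frame_duration * sr)
  truth <- integer(n_frames)
  if (n_frames >= 1L) {
    fm <- matrix(voiced_mask[seq_len(nf * n_frames)], nrow = nf)
    truth <- as.integer(colMeans(fm) > 0.5)
  }
  list(signal = audio_signal(x, sr), truth = truth, group = as.integer(group))
}

# Equal-amplitude harmonic complex with partials k*f0 up to 4 kHz, via the
# Dirichlet-kernel closed form sum_{k=1..K} sin(k*theta); peak-normalized.
harmonic_complex <- function(len, sr, f0, phase, amplitude) {
  K <- max(1L, floor(4000 / f0))
  theta <- 2 * pi * f0 * (0:(len - 1L)) / sr + phase
  s <- sin(theta / 2)
  deg <- abs(s) < 1e-9
  s[deg] <- 1
  y <- sin(K * theta / 2) * sin((K + 1) * theta / 2) / s
  y[deg] <- 0
  m <- max(abs(y))
  if (m < 1e-12) return(numeric(len))
  y * (amplitude / m)
}

# Noise floor band-limited below ~4 kHz: white noise drawn at 8 kHz and
# linearly interpolated up to the output rate, then peak-normalized.
synth_noise_floor <- function(n, sr, amplitude) {
  if (amplitude <= 0) return(numeric(n))
  n_low <- max(2L, ceiling(n * 8000 / sr))
  z <- stats::rnorm(n_low)
  y <- stats::approx(seq_len(n_low), z, xout = seq(1, n_low, length.out = n))$y
  y * (amplitude / max(abs(y)))
}

#' Generate a balanced two-group synthetic corpus
#'
#' Produces `2 * n_subjects_per_group` recordings (subjects `cn01...`,
#' `ad01...`) with per-recording seeds derived deterministically from the
#' corpus seed. When `out_dir` is given, the WAV files, `manifest.csv`,
#' per-subject ground-truth frame labels under `truth/`, and a
#' `gen_config.json` provenance record are written there; the directory must
#' not already exist.
#'
#' @param config A [speech_gen_config()].
#' @param out_dir Optional output directory (must not exist).
#' @param frame_duration Ground-truth frame grid in seconds (default 0.03).
#' @return Object of class `speech_corpus`: list with `signals` (named list
#'   of [audio_signal()]), `truth` (named list of 0/1 frame labels),
#'   `manifest` (data.frame), `config`.
#' @export
generate_corpus <- function(config, out_dir = NULL, frame_duration = 0.03) {
  stopifnot(inherits(config, "speech_gen_config"))
  npg <- config$n_subjects_per_group
  ids <- c(sprintf("cn%02d", seq_len(npg)), sprintf("ad%02d", seq_len(npg)))
  groups <- rep(c(0L, 1L), each = npg)
  set.seed(config$seed)
  rec_seeds <- sample.int(2147483646L, 2L * npg)

  if (!is.null(out_dir)) {
    if (file.exists(out_dir))
      stop("output directory already exists: ", out_dir)
    dir.create(out_dir, recursive = TRUE)
    dir.create(file.path(out_dir, "truth"))
  }

  signals <- vector("list", 2L * npg)
  truth <- vector("list", 2L * npg)
  paths <- rep(NA_character_, 2L * npg)
  for (i in seq_along(ids)) {
    rec <- generate_recording(config, groups[i], rec_seeds[i], frame_duration)
    signals[[i]] <- rec$signal
    truth[[i]] <- rec$truth
    if (!is.null(out_dir)) {
      paths[i] <- file.path(out_dir, paste0(ids[i], ".wav"))
      write_wav(rec$signal, paths[i])
      utils::write.csv(
        data.frame(frame_index = seq_along(rec$truth),
                   t_start = (seq_along(rec$truth) - 1L) * frame_duration,
                   label = rec$truth),
        file.path(out_dir, "truth", paste0(ids[i], ".csv")),
        row.names = FALSE)
    }
  }
  names(signals) <- ids
  names(truth) <- ids
  manifest <- data.frame(subject_id = ids, audio_path = paths,
                         label = groups, stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "gen_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(signals = signals, truth = truth, manifest = manifest,
                 config = config),
            class = "speech_corpus")
}

#' @export
print.speech_corpus <- function(x, ...) {
  cat(sprintf("<speech_corpus> %d recordings (%d per group), %.0f s each @ %d Hz\n",
              nrow(x$manifest), x$config$n_subjects_per_group,
              x$config$duration, x$config$sample_rate))
  invisible(x)
}
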