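# Six-sub-band GMM voice activity detection.
#
# Each 0.03 s frame is Hann-windowed, its power spectrum split into the six
# speech sub-bands (80-250, 250-500, 500-1000, 1000-2000, 2000-3000,
# 3000-4000 Hz), and the log-energy of each band is scored under a
# two-component Gaussian mixture for the silent state (H0) and one for the
# voiced state (H1). A frame is voiced when any per-band base-2 log-likelihood
# ratio exceeds T_tau or the K-weighted total ratio exceeds T_a, provided the
# total 80-4000 Hz energy passes the gate Tm.

VAD_BANDS <- cbind(low = c(80, 250, 500, 1000, 2000, 3000),
                   high = c(250, 500, 1000, 2000, 3000, 4000))
VAD_EPS <- 1e-12

#' Sub-band log-energies of one audio frame
#'
#' Applies a Hann window, takes the magnitude-squared FFT, and sums power over
#' the half-open frequency intervals `[low, high)` of the six sub-bands.
#' Energies are reported in dB: `E_i = 10*log10(sum(|X(f)|^2) + 1e-12)`, so an
#' all-zero frame hits the floor `10*log10(1e-12) = -120` dB in every band.
#' The total energy `E_t` spans 80-4000 Hz.
#'
#' @param frame Numeric vector of amplitudes (length >= 2).
#' @param sample_rate Sampling rate in Hz (>= 8000 so all bands exist).
#' @return An object of class `subband_energies`: list with `E` (six band
#'   energies, dB) and `E_t` (total energy, dB).
#' @export
compute_subband_energies <- function(frame, sample_rate) {
  if (length(frame) < 2L) stop("frame must contain at least 2 samples")
  if (sample_rate < 8000) stop("sample_rate must be >= 8000 Hz")
  em <- energies_of_frames(matrix(frame, ncol = 1L), sample_rate)
  structure(list(E = em$E[1L, ], E_t = em$E_t[1L]), class = "subband_energies")
}

# Vectorized band-energy computation for a frame matrix (one column per
# frame). Pairs of real frames are packed into one complex FFT, which halves
# the transform count on long recordings.
energies_of_frames <- function(frames, sample_rate) {
  n <- nrow(frames)
  nc <- ncol(frames)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))  # Hann
  fw <- frames * w
  pow <- matrix(0, n, nc)
  odd <- seq(1L, nc, by = 2L)
  if (nc >= 2L) {
    even <- seq(2L, nc, by = 2L)
    npair <- length(even)
    z <- fw[, odd[seq_len(npair)], drop = FALSE] +
      1i * fw[, even, drop = FALSE]
    Z <- stats::mvfft(z)
    Zc <- Conj(Z[c(1L, n:2L), , drop = FALSE])
    A <- (Z + Zc) / 2
    B <- (Z - Zc) / (2i)
    pow[, odd[seq_len(npair)]] <- Mod(A)^2
    pow[, even] <- Mod(B)^2
  }
  if (nc %% 2L == 1L) {
    pow[, nc] <- Mod(stats::fft(fw[, nc]))^2
  }
  freqs <- (0:(n - 1L)) * sample_rate / n
  half <- freqs <= sample_rate / 2
  E <- matrix(0, nc, 6L)
  for (b in seq_len(6L)) {
    idx <- which(half & freqs >= VAD_BANDS[b, "low"] & freqs < VAD_BANDS[b, "high"])
    E[, b] <- 10 * log10(colSums(pow[idx, , drop = FALSE]) + VAD_EPS)
  }
  idx_t <- which(half & freqs >= 80 & freqs < 4000)
  E_t <- 10 * log10(colSums(pow[idx_t, , drop = FALSE]) + VAD_EPS)
  list(E = E, E_t = E_t)
}

# -- Mixture model ------------------------------------------------------------

#' Two-component univariate Gaussian mixture
#'
#' One mixture models the energy of one sub-band in one state (silent or
#' voiced). Weights must sum to 1 and standard deviations must be positive.
#'
#' @param weights Two nonnegative mixture weights summing to 1.
#' @param means Two component means (dB).
#' @param sds Two positive component standard deviations (dB).
#' @return An object of class `gmm1d`.
#' @export
gmm1d <- function(weights, means, sds) {
  stopifnot(length(weights) == 2L, length(means) == 2L, length(sds) == 2L)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("mixture weights must be nonnegative and sum to 1")
  if (any(sds <= 0)) stop("mixture standard deviations must be positive")
  structure(list(weights = as.numeric(weights), means = as.numeric(means),
                 sds = as.numeric(sds)), class = "gmm1d")
}

#' Mixture density
#'
#' Evaluates `w1*N(e; mu1, sigma1) + w2*N(e; mu2, sigma2)`.
#'
#' @param mix A [gmm1d()].
#' @param e Energy value(s), dB.
#' @return Density value(s), strictly positive.
#' @export
gmm_density <- function(mix, e) {
  stopifnot(inherits(mix, "gmm1d"))
  mix$weights[1L] * stats::dnorm(e, mix$means[1L], mix$sds[1L]) +
    mix$weights[2L] * stats::dnorm(e, mix$means[2L], mix$sds[2L])
}

#' Voice-activity detector model
#'
#' Holds the per-band silent (H0) and voiced (H1) mixtures, the sub-band
#' weights `K` (nonnegative, summing to 1), the total-energy gate `Tm` (dB),
#' the per-band log-likelihood-ratio threshold `T_tau` and the total-ratio
#' threshold `T_a`.
#'
#' @param silent,voiced Lists of six [gmm1d()] mixtures (bands 1..6).
#' @param K Six nonnegative sub-band weights summing to 1 (default uniform).
#' @param Tm Total-energy gate in dB; frames at or below it are non-voiced.
#' @param T_tau Per-band ratio threshold (default 1.0).
#' @param T_a Total ratio threshold (default 0.5).
#' @return An object of class `vad_model`.
#' @export
vad_model <- function(silent, voiced, K = rep(1 / 6, 6), Tm = -60,
                      T_tau = 1.0, T_a = 0.5) {
  check_mixes <- function(m, what) {
    if (length(m) != 6L || !all(vapply(m, inherits, logical(1), "gmm1d")))
      stop("'", what, "' must be a list of six gmm1d mixtures")
  }
  check_mixes(silent, "silent")
  check_mixes(voiced, "voiced")
  if (length(K) != 6L || any(K < 0) || abs(sum(K) - 1) > 1e-12)
    stop("'K' must be six nonnegative weights summing to 1")
  structure(list(silent = silent, voiced = voiced, K = as.numeric(K),
                 Tm = Tm, T_tau = T_tau, T_a = T_a), class = "vad_model")
}

#' @export
print.vad_model <- function(x, ...) {
  cat("<vad_model> 6 sub-bands, 2-component GMMs per state\n")
  cat(sprintf("  Tm = %.2f dB, T_tau = %.3g, T_a = %.3g\n", x$Tm, x$T_tau, x$T_a))
  cat("  K =", paste(signif(x$K, 3), collapse = " "), "\n")
  invisible(x)
}

#' Per-band and total log-likelihood ratios of one frame
#'
#' `L_i = log2(P(E_i|H1) / P(E_i|H0))` for each band, with both densities
#' floored at 1e-12 so the ratio stays bounded, and `L_t = sum(K_i * L_i)`.
#'
#' @param model A [vad_model()].
#' @param energies A `subband_energies` object.
#' @return List with `L` (six ratios) and `L_t`.
#' @export
frame_loglik_ratios <- function(model, energies) {
  stopifnot(inherits(model, "vad_model"), inherits(energies, "subband_energies"))
  L <- vapply(seq_len(6L), function(i) {
    p1 <- gmm_density(model$voiced[[i]], energies$E[i])
    p0 <- gmm_density(model$silent[[i]], energies$E[i])
    log2((p1 + VAD_EPS) / (p0 + VAD_EPS))
  }, numeric(1))
  list(L = L, L_t = sum(model$K * L))
}

#' Classify one frame as voiced or non-voiced
#'
#' The total energy must first pass the gate: if `E_t <= Tm` the frame is
#' non-voiced and the ratios are reported as zero. Otherwise the frame is
#' voiced when any `L_i > T_tau` or `L_t > T_a`.
#'
#' @param model A [vad_model()].
#' @param energies A `subband_energies` object.
#' @return An object of class `frame_decision`: list with `label` (0/1), `L`,
#'   `L_t`.
#' @export
classify_frame <- function(model, energies) {
  stopifnot(inherits(model, "vad_model"), inherits(energies, "subband_energies"))
  if (energies$E_t <= model$Tm) {
    return(structure(list(label = 0L, L = rep(0, 6L), L_t = 0),
                     class = "frame_decision"))
  }
  r <- frame_loglik_ratios(model, energies)
  lab <- if (any(r$L > model$T_tau) || r$L_t > model$T_a) 1L else 0L
  structure(list(label = lab, L = r$L, L_t = r$L_t), class = "frame_decision")
}

# any() by row without extra dependencies
row_any <- function(m) rowSums(m) > 0

#' Run voice activity detection over a recording
#'
#' Frames the signal at `frame_duration`, computes sub-band energies per
#' frame, and applies [classify_frame()] logic to every frame, producing the
#' binary pause sequence (1 = voiced, 0 = non-voiced).
#'
#' @param signal A preprocessed mono [audio_signal()].
#' @param model A [vad_model()].
#' @param frame_duration Frame length in seconds (default 0.03).
#' @param subject_id Optional subject id carried on the result.
#' @return A [pause_sequence()].
#' @export
run_vad <- function(signal, model, frame_duration = 0.03,
                    subject_id = NA_character_) {
  frames <- frame_audio(signal, frame_duration)
  em <- energies_of_frames(frames, signal$sample_rate)
  labels <- vad_labels_from_energies(model, em$E, em$E_t)
  pause_sequence(labels, frame_duration, subject_id)
}

vad_labels_from_energies <- function(model, E, E_t) {
  n <- nrow(E)
  L <- matrix(0, n, 6L)
  for (i in seq_len(6L)) {
    s <- model$silent[[i]]; v <- model$voiced[[i]]
    p0 <- s$weights[1L] * stats::dnorm(E[, i], s$means[1L], s$sds[1L]) +
      s$weights[2L] * stats::dnorm(E[, i], s$means[2L], s$sds[2L])
    p1 <- v$weights[1L] * stats::dnorm(E[, i], v$means[1L], v$sds[1L]) +
      v$weights[2L] * stats::dnorm(E[, i], v$means[2L], v$sds[2L])
    L[, i] <- log2((p1 + VAD_EPS) / (p0 + VAD_EPS))
  }
  L_t <- as.numeric(L %*% model$K)
  as.integer(E_t > model$Tm & (row_any(L > model$T_tau) | L_t > model$T_a))
}

# -- Model fitting ------------------------------------------------------------

#' Fit a voice-activity model from calibration audio
#'
#' Pools the per-band frame log-energies of the calibration recordings and
#' fits, for each band, a four-component Gaussian mixture by
#' expectation-maximization, with means initialized at the 10th/30th/70th/90th
#' energy percentiles. Components are ordered by mean: the lower two form the
#' silent-state mixture and the upper two the voiced-state mixture (the
#' state assignment is fixed by energy ordering). Sub-band weights default to
#' uniform (`K_i = 1/6`) and the energy gate to the 5th percentile of `E_t`
#' plus 6 dB. The fit is deterministic: no random initialization is used.
#'
#' @param calibration An [audio_signal()] or list of them, totaling >= 10 s.
#' @param frame_duration Frame length in seconds (default 0.03).
#' @param K Sub-band weights (default uniform).
#' @param T_tau,T_a Decision thresholds (defaults 1.0 and 0.5).
#' @param Tm Energy gate in dB; `NULL` (default) sets the 5th percentile of
#'   `E_t` + 6 dB.
#' @param em_iter Maximum EM iterations per band (default 100).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_frames Cap on pooled calibration frames; above it an evenly
#'   spaced deterministic subsample is used (default 20000).
#' @return A [vad_model()].
#' @export
fit_vad_model <- function(calibration, frame_duration = 0.03,
                          K = rep(1 / 6, 6), T_tau = 1.0, T_a = 0.5,
                          Tm = NULL, em_iter = 100L, tol = 1e-8,
                          max_frames = 20000L) {
  if (inherits(calibration, "audio_signal")) calibration <- list(calibration)
  stopifnot(length(calibration) >= 1L,
            all(vapply(calibration, inherits, logical(1), "audio_signal")))
  total <- sum(vapply(calibration, signal_duration, numeric(1)))
  if (total < 10) stop("calibration audio must total at least 10 s (got ",
                       round(total, 2), " s)")
  ems <- lapply(calibration, function(s)
    energies_of_frames(frame_audio(s, frame_duration), s$sample_rate))
  fit_vad_model_from_energies(ems, K = K, T_tau = T_tau, T_a = T_a, Tm = Tm,
                              em_iter = em_iter, tol = tol,
                              max_frames = max_frames)
}

# Core of fit_vad_model() working on precomputed per-recording energy lists,
# so pipeline drivers can share one energy pass between calibration and
# frame labeling.
fit_vad_model_from_energies <- function(ems, K = rep(1 / 6, 6), T_tau = 1.0,
                                        T_a = 0.5, Tm = NULL, em_iter = 100L,
                                        tol = 1e-8, max_frames = 20000L) {
  E <- do.call(rbind, lapply(ems, `[[`, "E"))
  E_t <- unlist(lapply(ems, `[[`, "E_t"))
  if (nrow(E) > max_frames) {
    keep <- unique(round(seq(1L, nrow(E), length.out = max_frames)))
    E <- E[keep, , drop = FALSE]
    E_t <- E_t[keep]
  }
  silent <- vector("list", 6L)
  voiced <- vector("list", 6L)
  for (b in seq_len(6L)) {
    fit <- em_four_component(E[, b], max_iter = em_iter, tol = tol)
    silent[[b]] <- gmm1d(fit$w[1:2] / sum(fit$w[1:2]), fit$mu[1:2], fit$sd[1:2])
    voiced[[b]] <- gmm1d(fit$w[3:4] / sum(fit$w[3:4]), fit$mu[3:4], fit$sd[3:4])
  }
  if (is.null(Tm)) Tm <- as.numeric(stats::quantile(E_t, 0.05)) + 6
  vad_model(silent, voiced, K = K, Tm = Tm, T_tau = T_tau, T_a = T_a)
}

# Deterministic 4-component EM on a 1-D energy sample. Means start at the
# 10/30/70/90th percentiles; component order (and hence the silent/voiced
# split) is re-imposed by sorting on the fitted means.
em_four_component <- function(e, max_iter = 100L, tol = 1e-8,
                              sd_floor = 1e-3) {
  if (stats::sd(e) < 1e-8)
    stop("degenerate calibration: frame energies are (near-)constant")
  mu <- as.numeric(stats::quantile(e, c(0.1, 0.3, 0.7, 0.9)))
  sdv <- rep(max(stats::sd(e) / 4, sd_floor), 4L)
  w <- rep(0.25, 4L)
  n <- length(e)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:4, function(k) w[k] * stats::dnorm(e, mu[k], sdv[k]),
                   numeric(n))
    tot <- rowSums(dens) + 1e-300
    resp <- dens / tot
    Nk <- colSums(resp) + 1e-12
    w <- Nk / sum(Nk)
    mu <- colSums(resp * e) / Nk
    sdv <- sqrt(colSums(resp * (e - rep(mu, each = n))^2) / Nk)
    sdv <- pmax(sdv, sd_floor)
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(w = w[ord], mu = mu[ord], sd = sdv[ord])
}

# -- Serialization ------------------------------------------------------------

#' Write a VAD model to JSON
#' @param model A [vad_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vad_model <- function(model, path) {
  stopifnot(inherits(model, "vad_model"))
  doc <- list(
    format = "pausekit-vad-model",
    version = 1L,
    K = model$K, Tm = model$Tm, T_tau = model$T_tau, T_a = model$T_a,
    silent = lapply(model$silent, unclass),
    voiced = lapply(model$voiced, unclass))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a VAD model from JSON
#' @param path Path written by [write_vad_model()].
#' @return A [vad_model()].
#' @export
read_vad_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "pausekit-vad-model"))
    stop("not a pausekit VAD model file: ", path)
  mk <- function(df) lapply(seq_len(nrow(df)), function(i)
    gmm1d(unlist(df$weights[i]), unlist(df$means[i]), unlist(df$sds[i])))
  vad_model(mk(doc$silent), mk(doc$voiced), K = doc$K, Tm = doc$Tm,
            T_tau = doc$T_tau, T_a = doc$T_a)
}
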