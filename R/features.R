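# Functional acoustic feature profiles.
#
# Each 4 s segment is summarized by one fixed-length vector: short-time
# low-level descriptors (LLDs) are computed on 25 ms frames with a 10 ms hop,
# then statistical functionals collapse every LLD contour (and, for the large
# profile, its first-order delta) to scalars. Two profiles are provided,
# sized exactly to the published standard sets:
#   * "compare2013": 65 LLDs x 2 (contour + delta) x 49 functionals + 3
#     global descriptors = 6373 features.
#   * "egemaps": 20 LLDs x 4 functionals + 8 temporal descriptors = 88
#     features.
# The extractor is deterministic for fixed audio and configuration.

FEATURE_SET_SIZES <- c(compare2013 = 6373L, egemaps = 88L)

#' Feature set sizes
#'
#' Number of features per segment for each supported profile.
#' @return Named integer vector.
#' @export
feature_set_sizes <- function() FEATURE_SET_SIZES

# -- Short-time analysis ------------------------------------------------------

# Returns windowed frames, power spectra (half spectrum), bin frequencies,
# and time-domain frames for a mono signal.
stft_analysis <- function(x, sr, win_s = 0.025, hop_s = 0.010) {
  nw <- floor(win_s * sr)
  hop <- floor(hop_s * sr)
  n <- length(x)
  if (n < nw) stop("segment too short for short-time analysis")
  starts <- seq(1L, n - nw + 1L, by = hop)
  idx <- outer(seq_len(nw) - 1L, starts, `+`)
  frames <- matrix(x[idx], nrow = nw)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1L)) / (nw - 1L))
  fw <- frames * w
  pow <- packed_power_fft(fw)
  nb <- nrow(pow)
  half <- seq_len(floor(nb / 2) + 1L)
  list(frames = frames, windowed = fw,
       pow = pow[half, , drop = FALSE],
       freqs = (half - 1L) * sr / nb,
       sr = sr, hop_s = hop_s, n_frames = ncol(frames))
}

# |FFT|^2 of the columns of a real matrix, packing column pairs into complex
# transforms.
packed_power_fft <- function(m) {
  n <- nrow(m); nc <- ncol(m)
  pow <- matrix(0, n, nc)
  if (nc >= 2L) {
    odd <- seq(1L, nc - 1L, by = 2L)
    even <- odd + 1L
    Z <- stats::mvfft(m[, odd, drop = FALSE] + 1i * m[, even, drop = FALSE])
    Zc <- Conj(Z[c(1L, n:2L), , drop = FALSE])
    pow[, odd] <- Mod((Z + Zc) / 2)^2
    pow[, even] <- Mod((Z - Zc) / (2i))^2
  }
  if (nc %% 2L == 1L) pow[, nc] <- Mod(stats::fft(m[, nc]))^2
  pow
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(freqs, n_filters = 26L, f_lo = 20, f_hi = 8000) {
  edges <- mel_to_hz(seq(hz_to_mel(f_lo), hz_to_mel(f_hi),
                         length.out = n_filters + 2L))
  fb <- matrix(0, length(freqs), n_filters)
  for (k in seq_len(n_filters)) {
    lo <- edges[k]; mid <- edges[k + 1L]; hi <- edges[k + 2L]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[, k] <- pmax(0, pmin(up, down))
  }
  fb
}

dct_matrix <- function(n_in, n_out) {
  m <- outer(seq_len(n_out), seq_len(n_in) - 0.5,
             function(k, j) cos(pi * k * j / n_in))
  m * sqrt(2 / n_in)
}

# F0 and voicing via short-time autocorrelation (FFT-based), search range
# 70-400 Hz.
f0_contour <- function(st, f_min = 70, f_max = 400, voicing_thresh = 0.45) {
  nw <- nrow(st$windowed)
  nfft <- 2^ceiling(log2(2L * nw))
  padded <- rbind(st$windowed, matrix(0, nfft - nw, st$n_frames))
  spec <- packed_power_fft(padded)
  ac <- Re(stats::mvfft(spec, inverse = TRUE)) / nfft
  lag_lo <- max(2L, floor(st$sr / f_max))
  lag_hi <- min(nw - 1L, ceiling(st$sr / f_min))
  seg <- ac[(lag_lo + 1L):(lag_hi + 1L), , drop = FALSE]
  best <- apply(seg, 2L, which.max)
  r0 <- pmax(ac[1L, ], 1e-12)
  peak <- seg[cbind(best, seq_len(ncol(seg)))] / r0
  lag <- lag_lo + best - 1L
  f0 <- st$sr / lag
  voiced <- peak > voicing_thresh & r0 > 1e-10
  list(f0 = ifelse(voiced, f0, 0), voicing = pmax(pmin(peak, 1), 0),
       voiced = voiced)
}

weighted_centroid <- function(pow, wgt) {
  colSums(pow * wgt) / (colSums(pow) + 1e-12)
}

band_power_db <- function(pow, freqs, lo, hi) {
  sel <- freqs >= lo & freqs < hi
  10 * log10(colSums(pow[sel, , drop = FALSE]) + 1e-12)
}

spectral_slope <- function(pow, freqs, lo, hi) {
  sel <- which(freqs >= lo & freqs < hi)
  f <- freqs[sel]
  db <- 10 * log10(pow[sel, , drop = FALSE] + 1e-12)
  fc <- f - mean(f)
  as.numeric(crossprod(fc, db)) / sum(fc^2)
}

rolloff_freq <- function(pow, freqs, q) {
  cs <- apply(pow, 2L, cumsum)
  tot <- cs[nrow(cs), ]
  idx <- vapply(seq_len(ncol(cs)), function(j) {
    if (tot[j] <= 0) return(1L)
    which(cs[, j] >= q * tot[j])[1L]
  }, integer(1))
  freqs[idx]
}

# -- LLD contours -------------------------------------------------------------

# Core low-level descriptor matrix (frames x LLDs) shared by both profiles.
compute_llds <- function(st) {
  pow <- st$pow
  freqs <- st$freqs
  frames <- st$frames
  n <- st$n_frames

  fb <- mel_filterbank(freqs)
  melE <- t(fb) %*% pow                       # 26 x n
  log_mel <- t(log(melE + 1e-12))             # n x 26
  mfcc <- t(dct_matrix(26L, 14L) %*% t(log_mel))  # n x 14

  rms <- sqrt(colMeans(frames^2))
  rms_db <- 20 * log10(rms + 1e-12)
  zcr <- colMeans(abs(diff(sign(frames))) > 0)

  f0r <- f0_contour(st)
  period <- ifelse(f0r$f0 > 0, 1 / f0r$f0, 0)
  jitter <- c(0, abs(diff(period)) / pmax(period[-1], 1e-9))
  jitter[!(f0r$voiced & c(FALSE, f0r$voiced[-n]))] <- 0
  shimmer <- c(0, abs(diff(rms_db)))
  vr <- pmin(pmax(f0r$voicing, 1e-6), 1 - 1e-6)
  hnr <- 10 * log10(vr / (1 - vr))

  psum <- colSums(pow) + 1e-12
  centroid <- weighted_centroid(pow, freqs)
  pn <- sweep(pow, 2L, psum, "/")
  entropy <- -colSums(pn * log(pn + 1e-12))
  dev <- outer(freqs, centroid, "-")
  spread <- sqrt(colSums(pow * dev^2) / psum)
  skewness_sp <- (colSums(pow * dev^3) / psum) / (spread^3 + 1e-12)
  kurtosis_sp <- (colSums(pow * dev^4) / psum) / (spread^4 + 1e-12)
  flux <- c(0, sqrt(colSums((sqrt(pn[, -1L, drop = FALSE]) -
                               sqrt(pn[, -n, drop = FALSE]))^2)))
  slope_full <- spectral_slope(pow, freqs, 0, 8000)
  roll25 <- rolloff_freq(pow, freqs, 0.25)
  roll50 <- rolloff_freq(pow, freqs, 0.50)
  roll75 <- rolloff_freq(pow, freqs, 0.75)
  roll90 <- rolloff_freq(pow, freqs, 0.90)
  harmonicity <- 10 * log10((apply(pow, 2L, max) + 1e-12) / (colMeans(pow) + 1e-12))
  flatness <- exp(colMeans(log(pow + 1e-12))) / (colMeans(pow) + 1e-12)
  crest <- apply(abs(frames), 2L, max) / (rms + 1e-12)
  sharpness <- weighted_centroid(pow, freqs * sqrt(freqs / 1000 + 1))
  band_low <- band_power_db(pow, freqs, 250, 650)
  band_high <- band_power_db(pow, freqs, 1000, 4000)

  alpha_ratio <- band_power_db(pow, freqs, 50, 1000) -
    band_power_db(pow, freqs, 1000, 5000)
  sel_lo <- freqs < 2000
  sel_hi <- freqs >= 2000 & freqs < 5000
  hammarberg <- 10 * log10((apply(pow[sel_lo, , drop = FALSE], 2L, max) + 1e-12) /
                             (apply(pow[sel_hi, , drop = FALSE], 2L, max) + 1e-12))
  slope_0_500 <- spectral_slope(pow, freqs, 0, 500)
  slope_500_1500 <- spectral_slope(pow, freqs, 500, 1500)
  f0_semitone <- ifelse(f0r$f0 > 0, 12 * log2(f0r$f0 / 27.5), 0)

  list(
    log_mel = log_mel, mfcc = mfcc, rms = rms, rms_db = rms_db, zcr = zcr,
    f0 = f0r$f0, f0_semitone = f0_semitone, voicing = f0r$voicing,
    voiced = f0r$voiced, jitter = jitter, shimmer = shimmer, hnr = hnr,
    centroid = centroid, flux = flux, entropy = entropy, spread = spread,
    skewness_sp = skewness_sp, kurtosis_sp = kurtosis_sp,
    slope_full = slope_full, roll25 = roll25, roll50 = roll50,
    roll75 = roll75, roll90 = roll90, harmonicity = harmonicity,
    flatness = flatness, crest = crest, sharpness = sharpness,
    band_low = band_low, band_high = band_high, alpha_ratio = alpha_ratio,
    hammarberg = hammarberg, slope_0_500 = slope_0_500,
    slope_500_1500 = slope_500_1500)
}

compare_lld_matrix <- function(ll) {
  m <- cbind(ll$log_mel, ll$mfcc, ll$rms, ll$rms_db, ll$zcr, ll$f0,
             ll$voicing, ll$jitter, ll$shimmer, ll$hnr, ll$centroid, ll$flux,
             ll$entropy, ll$spread, ll$skewness_sp, ll$kurtosis_sp,
             ll$slope_full, ll$roll25, ll$roll50, ll$roll75, ll$roll90,
             ll$harmonicity, ll$flatness, ll$crest, ll$sharpness,
             ll$band_low, ll$band_high)
  colnames(m) <- c(paste0("melband", 1:26), paste0("mfcc", 1:14),
                   "rms", "rms_db", "zcr", "f0", "voicing_prob", "jitter",
                   "shimmer", "hnr", "spectral_centroid", "spectral_flux",
                   "spectral_entropy", "spectral_spread", "spectral_skewness",
                   "spectral_kurtosis", "spectral_slope", "rolloff25",
                   "rolloff50", "rolloff75", "rolloff90", "harmonicity",
                   "spectral_flatness", "crest_factor", "sharpness",
                   "bandenergy_250_650", "bandenergy_1000_4000")
  stopifnot(ncol(m) == 65L)
  m
}

egemaps_lld_matrix <- function(ll) {
  m <- cbind(ll$rms_db, ll$f0_semitone, ll$jitter, ll$shimmer, ll$hnr,
             ll$alpha_ratio, ll$hammarberg, ll$slope_0_500, ll$slope_500_1500,
             ll$flux, ll$centroid, ll$mfcc[, 1:4, drop = FALSE], ll$entropy,
             ll$roll90, ll$zcr, ll$spread, ll$skewness_sp)
  colnames(m) <- c("loudness_db", "f0_semitone", "jitter", "shimmer", "hnr",
                   "alpha_ratio", "hammarberg_index", "slope_0_500",
                   "slope_500_1500", "spectral_flux", "spectral_centroid",
                   paste0("mfcc", 1:4), "spectral_entropy", "rolloff90",
                   "zcr", "spectral_spread", "spectral_skewness")
  stopifnot(ncol(m) == 20L)
  m
}

# -- Statistical functionals --------------------------------------------------

# 49 functionals collapsing one contour to scalars. Constant or degenerate
# contours yield well-defined values (0 where a moment is undefined).
apply_functionals <- function(x) {
  n <- length(x)
  x[!is.finite(x)] <- 0
  mu <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s)) s <- 0
  ctr <- x - mu
  skew <- if (s > 1e-12) mean(ctr^3) / s^3 else 0
  kurt <- if (s > 1e-12) mean(ctr^4) / s^4 - 3 else 0
  qs <- stats::quantile(x, c(0.01, 0.05, 0.25, 0.5, 0.75, 0.99), names = FALSE)
  rng <- max(x) - min(x)
  t01 <- if (n > 1L) (seq_len(n) - 1L) / (n - 1L) else 0
  # linear fit
  if (n > 1L) {
    tc <- t01 - mean(t01)
    slope <- sum(tc * x) / sum(tc^2)
    offset <- mu - slope * mean(t01)
    res_l <- x - (offset + slope * t01)
  } else {
    slope <- 0; offset <- mu; res_l <- 0
  }
  # quadratic fit
  if (n > 2L) {
    qf <- stats::lm.fit(cbind(1, t01, t01^2), x)
    qc <- qf$coefficients
    qc[!is.finite(qc)] <- 0
    res_q <- x - cbind(1, t01, t01^2) %*% qc
  } else {
    qc <- c(mu, 0, 0); res_q <- 0
  }
  ax <- abs(x)
  tcent <- if (sum(ax) > 1e-12) sum(t01 * ax) / sum(ax) else 0
  lev <- function(q) mean(x > min(x) + q * rng)
  dn <- diff(x)
  if (length(dn) == 0L) dn <- 0
  # simple interior peaks
  peaks <- if (n >= 3L) which(x[2:(n - 1L)] > x[1:(n - 2L)] &
                                x[2:(n - 1L)] > x[3:n]) + 1L else integer(0)
  pk_vals <- if (length(peaks)) x[peaks] else mu
  pk_dist <- if (length(peaks) >= 2L) mean(diff(peaks)) / n else 0
  above <- x > mu
  r <- rle(above)
  seg_len <- r$lengths[r$values]
  if (!length(seg_len)) seg_len <- 0L
  out <- c(
    mean = mu, sd = s, skewness = skew, kurtosis = kurt,
    min = min(x), min_pos = which.min(x) / n,
    max = max(x), max_pos = which.max(x) / n, range = rng,
    q1 = qs[3], median = qs[4], q3 = qs[5],
    iqr12 = qs[4] - qs[3], iqr23 = qs[5] - qs[4], iqr13 = qs[5] - qs[3],
    p1 = qs[1], p5 = qs[2], p99 = qs[6], range_p1_p99 = qs[6] - qs[1],
    rqmean = sqrt(mean(x^2)),
    lin_slope = slope, lin_offset = offset,
    lin_err_abs = mean(abs(res_l)), lin_err_sq = mean(res_l^2),
    quad_a = qc[3], quad_b = qc[2], quad_c = qc[1],
    quad_err_abs = mean(abs(res_q)), quad_err_sq = mean(res_q^2),
    t_centroid = tcent,
    uplevel25 = lev(0.25), uplevel50 = lev(0.50),
    uplevel75 = lev(0.75), uplevel90 = lev(0.90),
    downlevel25 = 1 - lev(0.25), downlevel50 = 1 - lev(0.50),
    downlevel75 = 1 - lev(0.75),
    rise_frac = mean(dn > 0), fall_frac = mean(dn < 0),
    mean_abs_diff = mean(abs(dn)), mean_diff = mean(dn),
    sd_diff = if (length(dn) > 1L) stats::sd(dn) else 0,
    n_peaks_rel = length(peaks) / n,
    peak_mean = mean(pk_vals), peak_range = max(pk_vals) - min(pk_vals),
    peak_dist_rel = pk_dist,
    seg_mean_len = mean(seg_len) / n, seg_max_len = max(seg_len) / n,
    n_seg_rel = length(seg_len) / n)
  stopifnot(length(out) == 49L)
  out
}

FUNCTIONAL_NAMES <- names(apply_functionals(c(0, 1, 0.5)))

voiced_run_stats <- function(voiced, hop_s) {
  r <- rle(as.logical(voiced))
  vl <- r$lengths[r$values] * hop_s
  ul <- r$lengths[!r$values] * hop_s
  c(voiced_fraction = mean(voiced),
    voiced_segs_per_sec = sum(r$values) / (length(voiced) * hop_s),
    voiced_len_mean = if (length(vl)) mean(vl) else 0,
    voiced_len_sd = if (length(vl) > 1L) stats::sd(vl) else 0,
    unvoiced_len_mean = if (length(ul)) mean(ul) else 0,
    unvoiced_len_sd = if (length(ul) > 1L) stats::sd(ul) else 0)
}

# -- Public interface ---------------------------------------------------------

#' Extract a functional acoustic feature vector from a segment
#'
#' Computes short-time low-level descriptors on 25 ms / 10 ms frames and
#' collapses them with statistical functionals into one fixed-length vector
#' per segment. The `"compare2013"` profile has exactly 6373 features and the
#' `"egemaps"` profile exactly 88, matching the published set sizes.
#' Non-finite values are imputed to 0 with a warning.
#'
#' @param segment_audio A mono [audio_signal()] of at least 0.1 s.
#' @param feature_set `"compare2013"` or `"egemaps"`.
#' @return Named numeric vector with attribute `feature_set`.
#' @export
extract_features <- function(segment_audio,
                             feature_set = c("compare2013", "egemaps")) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(segment_audio, "audio_signal"))
  if (is.matrix(segment_audio$samples))
    stop("extract_features() expects mono audio; run preprocess() first")
  if (signal_duration(segment_audio) < 0.1)
    stop("segment must be at least 0.1 s long")
  st <- stft_analysis(segment_audio$samples, segment_audio$sample_rate)
  ll <- compute_llds(st)
  v <- if (feature_set == "compare2013") {
    m <- compare_lld_matrix(ll)
    dm <- rbind(0, diff(m))
    colnames(dm) <- paste0(colnames(m), "_de")
    both <- cbind(m, dm)
    fx <- unlist(lapply(seq_len(ncol(both)), function(j) {
      f <- apply_functionals(both[, j])
      names(f) <- paste0(colnames(both)[j], "_", FUNCTIONAL_NAMES)
      f
    }))
    vs <- voiced_run_stats(ll$voiced, st$hop_s)
    c(fx,
      duration_s = signal_duration(segment_audio),
      voiced_fraction = unname(vs["voiced_fraction"]),
      voiced_run_mean_s = unname(vs["voiced_len_mean"]))
  } else {
    m <- egemaps_lld_matrix(ll)
    fx <- unlist(lapply(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      x[!is.finite(x)] <- 0
      f <- c(mean = mean(x), sd = stats::sd(x),
             p20 = unname(stats::quantile(x, 0.20)),
             p80 = unname(stats::quantile(x, 0.80)))
      names(f) <- paste0(colnames(m)[j], "_", c("mean", "sd", "p20", "p80"))
      f
    }))
    vs <- voiced_run_stats(ll$voiced, st$hop_s)
    peaks_per_sec <- {
      x <- ll$rms_db
      n <- length(x)
      np <- if (n >= 3L) sum(x[2:(n - 1L)] > x[1:(n - 2L)] &
                               x[2:(n - 1L)] > x[3:n]) else 0L
      np / (n * st$hop_s)
    }
    c(fx, vs, duration_s = signal_duration(segment_audio),
      loudness_peaks_per_sec = peaks_per_sec)
  }
  if (any(!is.finite(v))) {
    warning(sum(!is.finite(v)), " non-finite feature value(s) imputed to 0")
    v[!is.finite(v)] <- 0
  }
  stopifnot(length(v) == FEATURE_SET_SIZES[[feature_set]])
  attr(v, "feature_set") <- feature_set
  v
}

#' Extract the feature matrix for all segments of a recording
#'
#' Cuts the recording into fixed-length segments ([segment_signal()]) and
#' extracts one feature vector per segment.
#'
#' @param signal A preprocessed mono [audio_signal()].
#' @param feature_set `"compare2013"` or `"egemaps"`.
#' @param segment_duration Segment length in seconds (default 4).
#' @return Numeric matrix, one row per segment.
#' @export
extract_feature_matrix <- function(signal,
                                   feature_set = c("compare2013", "egemaps"),
                                   segment_duration = 4) {
  feature_set <- match.arg(feature_set)
  segs <- segment_signal(signal, segment_duration)
  do.call(rbind, lapply(segs, extract_features, feature_set = feature_set))
}

#' Standardize features with training-set statistics
#'
#' Z-scores every column using the mean and standard deviation of the
#' training matrix only; constant features (sd below 1e-12) map to 0.
#'
#' @param train Numeric training matrix (rows = segments).
#' @param newdata Optional matrix to transform with the training statistics;
#'   defaults to `train` itself.
#' @return List with `scaled` (transformed `newdata`), `train` (transformed
#'   training matrix), `center`, `scale`.
#' @export
scale_features <- function(train, newdata = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 1L) stop("training matrix must be non-empty")
  center <- colMeans(train)
  sds <- apply(train, 2L, stats::sd)
  if (nrow(train) == 1L) sds[] <- 0
  ok <- is.finite(sds) & sds > 1e-12
  tr <- function(m) {
    m <- as.matrix(m)
    out <- sweep(m, 2L, center, "-")
    out[, ok] <- sweep(out[, ok, drop = FALSE], 2L, sds[ok], "/")
    out[, !ok] <- 0
    out
  }
  scaled_train <- tr(train)
  list(scaled = if (is.null(newdata)) scaled_train else tr(newdata),
       train = scaled_train, center = center, scale = ifelse(ok, sds, 1))
}
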