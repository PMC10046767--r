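# Shared fixtures, built in code.

# Pure tone as an audio_signal.
tone_signal <- function(freq, duration, sr = 44100, amplitude = 0.5) {
  t <- seq(0, by = 1 / sr, length.out = round(duration * sr))
  audio_signal(amplitude * sin(2 * pi * freq * t), sr)
}

silence_signal <- function(duration, sr = 44100) {
  audio_signal(numeric(round(duration * sr)), sr)
}

# A hand-built VAD model: every band's silent state is centred at
# `silent_mean` dB and the voiced state at `voiced_mean` dB.
toy_vad_model <- function(silent_mean = -80, voiced_mean = -20, sd = 8,
                          Tm = -110, T_tau = 1.0, T_a = 0.5,
                          K = rep(1 / 6, 6)) {
  mk <- function(mu) gmm1d(c(0.5, 0.5), c(mu - 2, mu + 2), c(sd, sd))
  vad_model(silent = replicate(6, mk(silent_mean), simplify = FALSE),
            voiced = replicate(6, mk(voiced_mean), simplify = FALSE),
            K = K, Tm = Tm, T_tau = T_tau, T_a = T_a)
}

# Random-but-valid model and band energies for oracle comparisons.
random_vad_model <- function() {
  rmix <- function() {
    w <- stats::runif(2); w <- w / sum(w)
    gmm1d(w, stats::runif(2, -100, 0), stats::runif(2, 0.5, 10))
  }
  K <- stats::runif(6); K <- K / sum(K)
  vad_model(silent = replicate(6, rmix(), simplify = FALSE),
            voiced = replicate(6, rmix(), simplify = FALSE),
            K = K, Tm = stats::runif(1, -120, -20),
            T_tau = stats::runif(1, -2, 2), T_a = stats::runif(1, -2, 2))
}

random_energies <- function() {
  structure(list(E = stats::runif(6, -110, 0), E_t = stats::runif(1, -120, 0)),
            class = "subband_energies")
}

# Term-by-term evaluation of the frame decision, written independently of
# the package internals: explicit normal densities, explicit base-2 logs.
oracle_classify <- function(model, energies) {
  if (energies$E_t <= model$Tm) return(0L)
  dens <- function(mix, e) {
    g1 <- exp(-(e - mix$means[1])^2 / (2 * mix$sds[1]^2)) /
      (sqrt(2 * pi) * mix$sds[1])
    g2 <- exp(-(e - mix$means[2])^2 / (2 * mix$sds[2]^2)) /
      (sqrt(2 * pi) * mix$sds[2])
    mix$weights[1] * g1 + mix$weights[2] * g2
  }
  L <- numeric(6)
  for (i in 1:6) {
    p1 <- dens(model$voiced[[i]], energies$E[i])
    p0 <- dens(model$silent[[i]], energies$E[i])
    L[i] <- log((p1 + 1e-12) / (p0 + 1e-12)) / log(2)
  }
  Lt <- sum(model$K * L)
  if (any(L > model$T_tau) || Lt > model$T_a) 1L else 0L
}

# Small synthetic corpus for pipeline tests.
tiny_corpus <- function(n = 3, duration = 20, seed = 5,
                        pause_means = c(0.5, 1.5)) {
  generate_corpus(speech_gen_config(
    n_subjects_per_group = n, duration = duration,
    pause_dur_mean = pause_means, seed = seed))
}
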