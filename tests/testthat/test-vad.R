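test_that("an all-zero frame hits the epsilon energy floor in every band", {
  e <- compute_subband_energies(numeric(1323), 44100)
  expect_equal(e$E, rep(10 * log10(1e-12), 6))
  expect_equal(e$E_t, 10 * log10(1e-12))
})

test_that("a pure 1500 Hz tone concentrates energy in the 1-2 kHz band", {
  frame <- 0.5 * sin(2 * pi * 1500 * (0:1322) / 44100)
  e <- compute_subband_energies(frame, 44100)
  expect_gte(e$E[4] - max(e$E[-4]), 20)
  # cross-check the dominant band against a plain periodogram oracle
  pw <- Mod(stats::fft(frame * (0.5 - 0.5 * cos(2 * pi * (0:1322) / 1322))))^2
  freqs <- (0:1322) * 44100 / 1323
  oracle <- sapply(1:6, function(b) {
    lo <- c(80, 250, 500, 1000, 2000, 3000)[b]
    hi <- c(250, 500, 1000, 2000, 3000, 4000)[b]
    10 * log10(sum(pw[freqs >= lo & freqs < hi & freqs <= 22050]) + 1e-12)
  })
  expect_equal(e$E, oracle, tolerance = 1e-10)
})

test_that("scaling a frame by 10 raises every band energy by 20 dB", {
  frame <- stats::rnorm(1323, sd = 0.05)
  e1 <- compute_subband_energies(frame, 44100)
  e2 <- compute_subband_energies(10 * frame, 44100)
  expect_equal(e2$E - e1$E, rep(20, 6), tolerance = 0.01)
})

test_that("energies_of_frames matches the single-frame path for every column", {
  set.seed(42)
  frames <- matrix(stats::rnorm(1323 * 7, sd = 0.1), 1323)
  em <- pausekit:::energies_of_frames(frames, 44100)
  for (j in 1:7) {
    single <- compute_subband_energies(frames[, j], 44100)
    expect_equal(em$E[j, ], single$E, tolerance = 1e-9)
    expect_equal(em$E_t[j], single$E_t, tolerance = 1e-9)
  }
})

test_that("gmm_density follows the two-component mixture formula", {
  g <- gmm1d(c(1, 0), c(-40, 0), c(3, 1))
  expect_equal(gmm_density(g, -40), 1 / (3 * sqrt(2 * pi)))
  expect_equal(gmm_density(g, -40 + 2.5), gmm_density(g, -40 - 2.5))
  h <- gmm1d(c(0.5, 0.5), c(0, 10), c(1, 1))
  manual <- 0.5 * exp(0) / sqrt(2 * pi) + 0.5 * exp(-50) / sqrt(2 * pi)
  expect_equal(gmm_density(h, 0), manual)
  expect_error(gmm1d(c(0.7, 0.7), c(0, 1), c(1, 1)), "sum to 1")
  expect_error(gmm1d(c(0.5, 0.5), c(0, 1), c(1, 0)), "positive")
})

test_that("identical silent and voiced mixtures give zero log-likelihood ratios", {
  m <- toy_vad_model(silent_mean = -40, voiced_mean = -40)
  e <- structure(list(E = rep(-45, 6), E_t = -30), class = "subband_energies")
  r <- frame_loglik_ratios(m, e)
  expect_equal(r$L, rep(0, 6))
  expect_equal(r$L_t, 0)
})

test_that("degenerate band weights reduce the total ratio to one band", {
  m <- toy_vad_model(K = c(1, 0, 0, 0, 0, 0))
  e <- random_energies()
  r <- frame_loglik_ratios(m, e)
  expect_equal(r$L_t, r$L[1])
  expect_equal(r$L_t, sum(m$K * r$L), tolerance = 1e-9)
})

test_that("the energy gate forces a non-voiced label regardless of mixtures", {
  m <- toy_vad_model(Tm = 0)  # gate above any plausible E_t
  e <- structure(list(E = rep(-20, 6), E_t = -10), class = "subband_energies")
  d <- classify_frame(m, e)
  expect_equal(d$label, 0L)
  expect_equal(d$L, rep(0, 6))
})

test_that("either decision branch of the threshold rule can fire alone", {
  # all ratios zero, positive thresholds -> non-voiced
  m0 <- toy_vad_model(silent_mean = -40, voiced_mean = -40,
                      T_tau = 0.5, T_a = 0.5)
  e <- structure(list(E = rep(-40, 6), E_t = -20), class = "subband_energies")
  expect_equal(classify_frame(m0, e)$label, 0L)
  # one band ratio above T_tau while the total stays below T_a -> voiced
  silent <- replicate(6, gmm1d(c(0.5, 0.5), c(-42, -38), c(5, 5)),
                      simplify = FALSE)
  voiced <- replicate(6, gmm1d(c(0.5, 0.5), c(-42, -38), c(5, 5)),
                      simplify = FALSE)
  voiced[[3]] <- gmm1d(c(0.5, 0.5), c(-22, -18), c(5, 5))
  m1 <- vad_model(silent, voiced, Tm = -120, T_tau = 0.5, T_a = 10)
  e$E[3] <- -20  # band 3 energy sits on its voiced state
  d <- classify_frame(m1, e)
  expect_gt(d$L[3], m1$T_tau)
  expect_lt(d$L_t, m1$T_a)
  expect_equal(d$label, 1L)
})

test_that("classify_frame agrees with a term-by-term oracle on random inputs", {
  set.seed(123)
  agree <- vapply(seq_len(400), function(i) {
    m <- random_vad_model()
    e <- random_energies()
    classify_frame(m, e)$label == oracle_classify(m, e)
  }, logical(1))
  expect_true(all(agree))
})

test_that("run_vad labels an all-zero second as fully non-voiced", {
  ps <- run_vad(silence_signal(1), toy_vad_model())
  expect_equal(length(ps$labels), 33L)
  expect_true(all(ps$labels == 0L))
})

test_that("run_vad on 0.12 s yields exactly four frame labels", {
  ps <- run_vad(tone_signal(200, 0.12), toy_vad_model())
  expect_length(ps$labels, 4L)
})

test_that("a loud tone followed by silence splits into voiced then non-voiced", {
  sig <- audio_signal(c(tone_signal(1000, 0.5)$samples,
                        numeric(round(0.5 * 44100))), 44100)
  m <- toy_vad_model(silent_mean = -120, voiced_mean = -20, Tm = -115)
  ps <- run_vad(sig, m)
  # per-frame oracle over the same energies
  frames <- frame_audio(sig, 0.03)
  expected <- vapply(seq_len(ncol(frames)), function(j)
    oracle_classify(m, compute_subband_energies(frames[, j], 44100)),
    integer(1))
  expect_equal(ps$labels, expected)
  expect_true(all(ps$labels[1:15] == 1L))
  expect_true(all(ps$labels[18:33] == 0L))
})

test_that("raising the thresholds never increases the voiced count", {
  corp <- tiny_corpus(n = 1, duration = 15, seed = 9)
  sig <- corp$signals[[1]]
  base <- fit_vad_model(sig)
  n_voiced <- function(T_tau, T_a) {
    m <- vad_model(base$silent, base$voiced, K = base$K, Tm = base$Tm,
                   T_tau = T_tau, T_a = T_a)
    sum(run_vad(sig, m)$labels)
  }
  counts <- mapply(n_voiced, T_tau = c(-1, 0, 1, 2, 4), T_a = c(-1.5, 0, 0.5, 2, 4))
  expect_true(all(diff(counts) <= 0))
})

test_that("a gate above the maximum frame energy silences any model", {
  corp <- tiny_corpus(n = 1, duration = 12, seed = 2)
  sig <- corp$signals[[1]]
  max_et <- max(pausekit:::energies_of_frames(frame_audio(sig, 0.03),
                                              sig$sample_rate)$E_t)
  for (m in list(toy_vad_model(), random_vad_model())) {
    m$Tm <- max_et + 1
    expect_true(all(run_vad(sig, m)$labels == 0L))
  }
})

test_that("fit_vad_model orders silent below voiced states and is deterministic", {
  calib <- list(silence_signal(6), tone_signal(1500, 6))
  m1 <- fit_vad_model(calib)
  m2 <- fit_vad_model(calib)
  expect_identical(m1, m2)
  mean_of <- function(g) sum(g$weights * g$means)
  expect_lt(mean_of(m1$silent[[4]]), mean_of(m1$voiced[[4]]))
})

test_that("fit_vad_model recovers two well-separated energy clusters", {
  # loud and faint tones 40 dB apart -> energies form two disjoint clusters
  loud <- tone_signal(1500, 6, amplitude = 0.3)
  faint <- tone_signal(1500, 6, amplitude = 0.003)
  m <- fit_vad_model(list(loud, faint))
  e_loud <- compute_subband_energies(frame_audio(loud, 0.03)[, 5], 44100)$E[4]
  e_faint <- compute_subband_energies(frame_audio(faint, 0.03)[, 5], 44100)$E[4]
  mean_of <- function(g) sum(g$weights * g$means)
  expect_lt(abs(mean_of(m$silent[[4]]) - e_faint), 1)
  expect_lt(abs(mean_of(m$voiced[[4]]) - e_loud), 1)
})

test_that("fit_vad_model rejects degenerate and too-short calibration", {
  expect_error(fit_vad_model(silence_signal(12)), "degenerate|constant")
  expect_error(fit_vad_model(tone_signal(500, 2)), "at least 10 s")
})

test_that("VAD models survive a JSON round trip", {
  m <- toy_vad_model(Tm = -42.5, T_tau = 1.25, T_a = 0.75)
  path <- withr::local_tempfile(fileext = ".json")
  write_vad_model(m, path)
  back <- read_vad_model(path)
  expect_equal(back, m)
})

test_that("identical signal, model and frame duration give identical sequences", {
  corp <- tiny_corpus(n = 1, duration = 12, seed = 8)
  m <- fit_vad_model(corp$signals[[1]])
  a <- run_vad(corp$signals[[1]], m)
  b <- run_vad(corp$signals[[1]], m)
  expect_identical(a$labels, b$labels)
})
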