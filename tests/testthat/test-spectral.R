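make_tone_trials <- function(f0 = 40, fs = 250, n_trials = 3, dur = 2,
                             amp = 1, noise = 0) {
  n <- round(dur * fs)
  t_axis <- (seq_len(n) - 1) / fs
  dat <- array(0, dim = c(n_trials, 1, n))
  for (k in seq_len(n_trials)) {
    dat[k, 1, ] <- amp * sin(2 * pi * f0 * t_axis + k) +
      noise * rnorm(n)
  }
  trial_tensor(dat, fs = fs, window = c(dur / 2, dur / 2))
}

test_that("wavelet response is maximal at the tone frequency and linear", {
  tt <- make_tone_trials(f0 = 40)
  freqs <- default_freq_grid(5, 80, 20)
  tf <- wavelet_transform(tt, 1, freqs)
  pow <- apply(Mod(tf$coef)^2, 2, mean)
  expect_equal(freqs[which.max(pow)], freqs[which.min(abs(freqs - 40))])
  # zero signal -> zero coefficients
  tt0 <- trial_tensor(array(0, dim = c(2, 1, 500)), fs = 250, window = c(1, 1))
  expect_equal(max(Mod(wavelet_transform(tt0, 1, freqs)$coef)), 0)
  # doubling the signal doubles |X| everywhere
  tt2 <- tt
  tt2$data <- tt$data * 2
  tf2 <- wavelet_transform(tt2, 1, freqs)
  expect_equal(Mod(tf2$coef), 2 * Mod(tf$coef), tolerance = 1e-10)
})

test_that("wavelet transform rejects frequencies at or above Nyquist", {
  tt <- make_tone_trials()
  expect_error(wavelet_transform(tt, 1, c(10, 125)), "Nyquist")
})

test_that("Welch spectrum satisfies Parseval and localizes a tone", {
  set.seed(21)
  x <- rnorm(20000)
  ps <- power_spectrum(x, fs = 500, segment_length = 512)
  df <- diff(ps$f[1:2])
  expect_lt(abs(sum(ps$P) * df - var(x)) / var(x), 0.05)
  tone <- sin(2 * pi * 37 * seq(0, 40, by = 1 / 500))
  pst <- power_spectrum(tone, fs = 500, segment_length = 1024)
  expect_equal(pst$f[which.max(pst$P)], pst$f[which.min(abs(pst$f - 37))])
  expect_error(power_spectrum(rnorm(100), fs = 100, segment_length = 256),
               "exceeds signal length")
})

test_that("Welch spectrum matches the analytic AR(2) spectrum", {
  set.seed(22)
  fs <- 250
  f0 <- 30
  r <- 0.95
  a1 <- 2 * r * cos(2 * pi * f0 / fs)
  a2 <- -r^2
  x <- as.numeric(stats::filter(rnorm(2^16), c(a1, a2), method = "recursive"))
  ps <- power_spectrum(x, fs = fs, segment_length = 1024)
  # analytic one-sided AR(2) density with unit innovation variance
  omega <- 2 * pi * ps$f / fs
  denom <- Mod(1 - a1 * exp(-1i * omega) - a2 * exp(-2i * omega))^2
  analytic <- 2 / (fs * denom)
  band <- ps$f > 10 & ps$f < 60
  rel <- ps$P[band] / analytic[band]
  expect_lt(abs(median(rel) - 1), 0.15)
  expect_equal(ps$f[which.max(ps$P)], ps$f[which.min(abs(ps$f - f0))],
               tolerance = 2)
})

test_that("self-coherence is exactly 1 and coherence is scale invariant", {
  tt <- make_surrogate_trials(n_trials = 20, seed = 6, background_sd = 0.5)
  freqs <- test_freqs()
  tfx <- wavelet_transform(tt, 1, freqs)
  tfy <- wavelet_transform(tt, 2, freqs)
  self <- event_coherence(tfx, tfx)
  expect_equal(self$coherence, rep(1, length(freqs)), tolerance = 1e-10)
  coh <- event_coherence(tfx, tfy)
  tfy_scaled <- tfy
  tfy_scaled$coef <- tfy$coef * 13.7
  coh2 <- event_coherence(tfx, tfy_scaled)
  expect_equal(coh2$coherence, coh$coherence, tolerance = 1e-10)
  expect_true(all(coh$coherence >= 0 & coh$coherence <= 1))
  expect_error(event_coherence(tfx, structure(tfy, class = "list")),
               "tf_decomp")
})

test_that("common-signal surrogate recovers the analytic coherence 0.5", {
  # x = sqrt(.5) s + sqrt(.5) n with n drawn from the same narrowband law:
  # the analytic coherence is 0.5 at every frequency, so the grid mean is
  # an estimate of 0.5 and the band centre a noisier one
  tt <- make_surrogate_trials(n_trials = 200, shared_fraction = 0.5,
                              band = c(20, 60), background_sd = 0, seed = 7)
  freqs <- default_freq_grid(10, 70, 15)
  coh <- event_coherence(wavelet_transform(tt, 1, freqs),
                         wavelet_transform(tt, 2, freqs))
  expect_lt(abs(mean(coh$coherence) - 0.5), 0.03)
  fc <- which.min(abs(freqs - 40))
  expect_lt(abs(coh$coherence[fc] - 0.5), 0.1)
})

test_that("line-noise normalization flattens a 50 Hz line and is idempotent", {
  set.seed(30)
  fs <- 500
  t_axis <- seq(0, 60, by = 1 / fs)
  clean <- rnorm(length(t_axis))
  dirty <- clean + 3 * sin(2 * pi * 50 * t_axis)
  ps_dirty <- power_spectrum(dirty, fs = fs, segment_length = 1024)
  ps_clean <- remove_line_noise(ps_dirty)
  flank <- (ps_clean$f >= 45 & ps_clean$f <= 48) |
    (ps_clean$f >= 52 & ps_clean$f <= 55)
  at_line <- which.min(abs(ps_clean$f - 50))
  expect_lte(ps_clean$P[at_line] / mean(ps_clean$P[flank]), 1.5)
  # idempotence
  ps_twice <- remove_line_noise(ps_clean)
  expect_equal(ps_twice$P, ps_clean$P, tolerance = 1e-8)
  # no-op on clean input
  ps0 <- power_spectrum(clean, fs = fs, segment_length = 1024)
  ps0_cleaned <- remove_line_noise(ps0)
  expect_lt(max(abs(ps0_cleaned$P - ps0$P) / ps0$P), 0.35)
  expect_equal(mean(ps0_cleaned$P != ps0$P), 0, tolerance = 0.05)
})

test_that("line-noise normalization on wavelet coefficients keeps phases", {
  spec <- surrogate_spec(n_channels_per_area = 1, sampling_rate = 250,
                         n_trials = 20, trial_length = 2,
                         line_noise_amp = 2, background_sd = 0.5, seed = 8)
  out <- gen_coupled_lfp(spec)
  tt <- segment_trials(out$recording, out$events, window = c(1, 1))
  freqs <- seq(35, 65, by = 2.5)
  tf <- wavelet_transform(tt, 1, freqs)
  tf_clean <- remove_line_noise(tf)
  expect_equal(Arg(tf_clean$coef), Arg(tf$coef), tolerance = 1e-10)
  pow <- function(x, j) mean(Mod(x$coef[, j, ])^2)
  at50 <- which(freqs == 50)
  expect_lt(pow(tf_clean, at50), pow(tf, at50))
  # line frequency at the grid edge is rejected (no lower flanking band)
  tf_edge <- wavelet_transform(tt, 1, seq(49, 60, by = 1))
  expect_error(remove_line_noise(tf_edge), "grid edge")
})

test_that("phase difference obeys the delay identity and antisymmetry", {
  # broadband shared component so the wavelet passband is well covered and
  # the phase slope is clean; 3-sample delay at 500 Hz = 6 ms exactly
  tau <- 0.006
  tt <- make_surrogate_trials(n_trials = 100, shared_fraction = 1,
                              band = c(10, 60), fs = 500,
                              background_sd = 0, seed = 9,
                              directed_lag = tau)
  freqs <- default_freq_grid(12, 55, 10)
  tfx <- wavelet_transform(tt, 1, freqs)
  tfy <- wavelet_transform(tt, 2, freqs)
  pd <- phase_difference(tfx, tfy)
  expected <- (2 * pi * freqs * tau + pi) %% (2 * pi) - pi  # wrapped
  ok <- pd$reliable
  # compare on the circle
  err <- Arg(exp(1i * (pd$phase[ok] - expected[ok])))
  expect_lt(max(abs(err)), 0.25)
  # y = x gives zero phase everywhere
  pd0 <- phase_difference(tfx, tfx)
  expect_equal(max(abs(pd0$phase)), 0, tolerance = 1e-10)
  # swapping arguments flips the sign (on the circle)
  pd_rev <- phase_difference(tfy, tfx)
  flip <- Arg(exp(1i * (pd$phase + pd_rev$phase)))
  expect_lt(max(abs(flip[ok & pd_rev$reliable])), 1e-8)
})
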