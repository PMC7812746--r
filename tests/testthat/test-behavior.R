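test_that("protraction amplitude: flat, ramp, and window errors", {
  t_axis <- seq(-1, 1, by = 0.01)
  expect_equal(protraction_amplitude(rep(2, length(t_axis)),
                                     t_axis)$amplitude_deg, 0)
  ramp <- ifelse(t_axis > 0, 12 * pmin(t_axis / 0.4, 1), 0)
  pa <- protraction_amplitude(ramp, t_axis)
  expect_equal(pa$amplitude_deg, 12, tolerance = 1e-9)
  expect_gt(pa$movement_power, 0)
  expect_error(protraction_amplitude(ramp, t_axis,
                                     baseline_window = c(5, 6)), "empty")
})

test_that("median split halves the trials; octile groups overlap and rise", {
  amps <- c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10)
  grp <- split_trials(amps, "median")
  expect_equal(sum(grp == "small"), 5)
  expect_equal(sum(grp == "large"), 5)
  expect_true(all(amps[grp == "small"] < amps[grp == "large"]))
  expect_equal(length(grp), length(amps))  # total conserved

  set.seed(50)
  amps2 <- runif(100)
  groups <- split_trials(amps2, "overlapping8")
  expect_length(groups, 8)
  means <- vapply(groups, function(i) mean(amps2[i]), numeric(1))
  expect_true(all(diff(means) > 0))
  # neighbouring groups share trials (the windows overlap)
  overlap <- vapply(1:7, function(g) {
    length(intersect(groups[[g]], groups[[g + 1]]))
  }, numeric(1))
  expect_true(all(overlap > 0))
  expect_error(split_trials(1:5, "overlapping8"), ">= 8")
})

test_that("overlapping8 on amplitudes 1..8 gives strictly increasing means", {
  groups <- split_trials(1:8, "overlapping8")
  means <- vapply(groups, function(i) mean((1:8)[i]), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("predictor recovers a strong synthetic coherence-amplitude link", {
  spec <- surrogate_spec(n_channels_per_area = 1, sampling_rate = 250,
                         n_trials = 120, trial_length = 4,
                         shared_fraction = 0.5, background_sd = 0.3,
                         seed = 60)
  link <- behavior_link_spec(amplitude_mean = 10, amplitude_sd = 2.5,
                             link_band = c(30, 45), link_slope = 0.12,
                             noise_sd = 0.1)
  out <- gen_behavior_dataset(spec, link)
  freqs <- seq(28, 48, by = 2.5)
  tfx <- wavelet_transform(out$trials, 1, freqs)
  tfy <- wavelet_transform(out$trials, 2, freqs)
  feats <- trial_coherence_features(tfx, tfy, n_cycles = 40)
  amps <- out$behavior$amplitude_deg
  model <- fit_coherence_predictor(feats, amps)
  expect_gt(model$r2_cv, 0.8)
  expect_gte(model$r2_train, model$r2_cv)
  # shuffled labels destroy the association
  set.seed(61)
  shuf <- fit_coherence_predictor(feats, sample(amps))
  expect_lt(shuf$r2_cv, 0.1)
  # transfer to an identically generated condition works comparably
  spec2 <- spec
  spec2$seed <- 600L
  out2 <- gen_behavior_dataset(spec2, link)
  feats2 <- trial_coherence_features(
    wavelet_transform(out2$trials, 1, freqs),
    wavelet_transform(out2$trials, 2, freqs), n_cycles = 40
  )
  tr <- apply_predictor(model, feats2, out2$behavior$amplitude_deg)
  expect_gt(tr$r2, model$r2_cv - 0.15)
})

test_that("under-determined designs demand ridge; ridge fit then works", {
  set.seed(62)
  feats <- matrix(rnorm(20 * 15), 20, 15)
  amps <- rnorm(20)
  expect_error(fit_coherence_predictor(feats, amps), "ridge")
  m <- fit_coherence_predictor(feats, amps, ridge = 1)
  expect_true(is.finite(m$r2_cv))
})

test_that("predictor models serialize to JSON and back", {
  set.seed(63)
  feats <- matrix(rnorm(60 * 5), 60, 5)
  attr(feats, "freqs") <- c(4, 8, 16, 32, 64)
  amps <- feats %*% c(1, -2, 0, 3, 0.5) + rnorm(60, sd = 0.1)
  m <- fit_coherence_predictor(feats, as.numeric(amps))
  path <- tempfile(fileext = ".json")
  write_predictor(m, path)
  m2 <- read_predictor(path)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$intercept, m$intercept)
  expect_equal(m2$freqs, m$freqs)
  pred <- apply_predictor(m2, feats, as.numeric(amps))
  expect_gt(pred$r2, 0.95)
  unlink(path)
})

test_that("LFP-behavior coherence: identical signals cohere, independent do not", {
  tt <- make_surrogate_trials(n_trials = 30, seed = 64, background_sd = 0.5)
  freqs <- test_freqs()
  tf <- wavelet_transform(tt, 1, freqs)
  mov_same <- tt$data[, 1, ]
  c_same <- lfp_behavior_coherence(tf, mov_same)
  expect_equal(c_same$coherence, rep(1, length(freqs)), tolerance = 1e-8)
  set.seed(65)
  mov_ind <- matrix(rnorm(length(mov_same)), nrow = nrow(mov_same))
  c_ind <- lfp_behavior_coherence(tf, mov_ind)
  expect_lt(mean(c_ind$coherence), sqrt(pi / (4 * 30)) + 0.1)
})

test_that("delta-band coupled whisker traces cohere with the LFP below 4 Hz", {
  spec <- surrogate_spec(n_channels_per_area = 1, sampling_rate = 100,
                         n_trials = 60, trial_length = 6,
                         shared_fraction = 0.3, background_sd = 0.4,
                         seed = 66)
  link <- behavior_link_spec(link_slope = 0, noise_sd = 0.3,
                             movement_coupling = 4)
  out <- gen_behavior_dataset(spec, link)
  freqs <- default_freq_grid(1.5, 40, 14)
  tf <- wavelet_transform(out$trials, 1, freqs)
  coh <- lfp_behavior_coherence(tf, out$whisker, n_cycles = 4)
  expect_lt(freqs[which.max(coh$coherence)], 4)
})
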