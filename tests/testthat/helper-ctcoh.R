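# Small fixture builders shared across test files.

# Two-area single-channel surrogate segmented into trials.
make_surrogate_trials <- function(n_trials = 50, fs = 250, trial_length = 2,
                                  shared_fraction = 0.5, band = c(30, 45),
                                  background_sd = 0, seed = 1L, ...) {
  spec <- surrogate_spec(
    n_channels_per_area = 1, sampling_rate = fs, n_trials = n_trials,
    trial_length = trial_length, shared_band = band,
    shared_fraction = shared_fraction, background_sd = background_sd,
    seed = seed, ...
  )
  out <- gen_coupled_lfp(spec)
  segment_trials(out$recording, out$events,
                 window = c(trial_length / 2, trial_length / 2))
}

# Coarse grid used when test speed matters more than resolution.
test_freqs <- function() default_freq_grid(5, 80, 15)

# A noise-free network (shared across model tests).
make_quiet_network <- function(...) {
  pops <- default_populations()
  pops$noise_sd <- 0
  build_network(populations = pops, ...)
}

# Simulated bivariate VAR(1) trials: x drives y with coefficient b.
# Returns list(x, y) trial x time matrices.
make_var1_trials <- function(n_trials = 30, nt = 400, a = 0.5, b = 0.4,
                             seed = 1) {
  set.seed(seed)
  x <- matrix(0, n_trials, nt)
  y <- matrix(0, n_trials, nt)
  burn <- 50
  for (k in seq_len(n_trials)) {
    e <- rnorm(nt + burn)
    h <- rnorm(nt + burn)
    xs <- numeric(nt + burn)
    ys <- numeric(nt + burn)
    for (t in 2:(nt + burn)) {
      xs[t] <- a * xs[t - 1] + e[t]
      ys[t] <- a * ys[t - 1] + b * xs[t - 1] + h[t]
    }
    x[k, ] <- xs[burn + seq_len(nt)]
    y[k, ] <- ys[burn + seq_len(nt)]
  }
  list(x = x, y = y)
}

# Closed-form Geweke causality spectra for the VAR(1)
#   x_t = a x_{t-1} + e_t,  y_t = a y_{t-1} + b x_{t-1} + h_t,
# unit innovation variances, no instantaneous correlation. Derived directly
# from the true transfer function H = (I - A z)^{-1}, z = exp(-i 2 pi f/fs):
# independent oracle for granger_spectrum.
geweke_var1_oracle <- function(freqs, fs, a = 0.5, b = 0.4) {
  z <- exp(-2i * pi * freqs / fs)
  det <- (1 - a * z)^2
  H11 <- (1 - a * z) / det
  H21 <- b * z / det
  H22 <- (1 - a * z) / det
  Syy <- Mod(H21)^2 + Mod(H22)^2   # unit innovations
  gxy <- log(Syy / Mod(H22)^2)
  list(gxy = gxy, gyx = rep(0, length(freqs)))
}
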