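#' Surrogate recording specification
#'
#' Describes a two-area multichannel surrogate with a band-limited shared
#' component of known strength and directed lag. Each channel is built as
#'
#'   x = sqrt(shared_fraction) * s_area + sqrt(1 - shared_fraction) * m +
#'       background_sd * b + evoked + line noise
#'
#' where `s_area` is a stochastically driven damped harmonic oscillator
#' (AR(2)) centred in `shared_band`, common to all channels of an area and
#' fed to area 2 with a pure sample delay of `directed_lag`; `m` is an
#' independent oscillator with the identical spectrum, private to each
#' channel; and `b` is broadband background noise (1/f by default). With
#' `background_sd = 0` the inter-area coherence at the band centre equals
#' `shared_fraction` exactly in expectation, which is what makes the
#' generator usable as a parameter-recovery oracle.
#'
#' @param n_channels_per_area Channels per probe (default 14, the laminar
#'   probe geometry the package emulates).
#' @param sampling_rate Hz.
#' @param n_trials Number of trials (>= 1).
#' @param trial_length Trial duration in seconds; the stimulus onset sits at
#'   the trial midpoint, so a 10 s trial gives 5 s pre- and 5 s
#'   post-stimulus.
#' @param shared_band `c(f_lo, f_hi)` in Hz, `f_lo < f_hi <` Nyquist.
#' @param shared_fraction Variance fraction of the shared component, in
#'   `[0, 1]`; equals the target coherence at band centre.
#' @param directed_lag Delay (s) of the shared component into area 2;
#'   positive means area 1 leads.
#' @param line_noise_amp Amplitude of a 50 Hz sinusoid with random per-trial
#'   phase, common to all channels.
#' @param evoked_template Biphasic evoked-deflection descriptor, see
#'   [evoked_template()]; `NULL` disables the evoked response.
#' @param background_sd Standard deviation of the broadband background.
#' @param background_color `"pink"` (1/f, default) or `"white"`.
#' @param seed Integer seed; identical spec + seed gives bit-identical data.
#'
#' @return A `surrogate_spec` list.
#' @export
surrogate_spec <- function(n_channels_per_area = 14, sampling_rate = 1000,
                           n_trials = 100, trial_length = 10,
                           shared_band = c(30, 45), shared_fraction = 0.5,
                           directed_lag = 0, line_noise_amp = 0,
                           evoked_template = NULL, background_sd = 0.5,
                           background_color = c("pink", "white"),
                           seed = 1L) {
  ct_assert(is_count(n_channels_per_area), "n_channels_per_area must be a count")
  ct_assert(is_count(n_trials), "n_trials must be >= 1")
  ct_assert(is_scalar_num(trial_length) && trial_length > 0,
            "trial_length must be positive")
  ct_assert(length(shared_band) == 2 && shared_band[1] < shared_band[2],
            "shared_band must be c(f_lo, f_hi) with f_lo < f_hi")
  if (shared_band[2] >= sampling_rate / 2) {
    ct_stop("shared_band upper edge %g Hz is not below the Nyquist frequency %g Hz",
            shared_band[2], sampling_rate / 2)
  }
  ct_assert(is_scalar_num(shared_fraction) &&
              shared_fraction >= 0 && shared_fraction <= 1,
            "shared_fraction must lie in [0, 1]")
  ct_assert(is_scalar_num(directed_lag), "directed_lag must be a number")
  ct_assert(is_scalar_num(background_sd) && background_sd >= 0,
            "background_sd must be >= 0")
  structure(
    list(
      n_channels_per_area = as.integer(n_channels_per_area),
      sampling_rate = sampling_rate,
      n_trials = as.integer(n_trials),
      trial_length = trial_length,
      shared_band = shared_band,
      shared_fraction = shared_fraction,
      directed_lag = directed_lag,
      line_noise_amp = line_noise_amp,
      evoked_template = evoked_template,
      background_sd = background_sd,
      background_color = match.arg(background_color),
      seed = as.integer(seed)
    ),
    class = "surrogate_spec"
  )
}

#' Biphasic evoked-response template
#'
#' A negative-then-positive transient mimicking the stimulus-evoked LFP
#' deflection: a negative Gaussian trough followed by a positive Gaussian
#' peak, decayed back to baseline within roughly 200 ms.
#'
#' @param amplitude Peak-to-baseline amplitude of the negative trough
#'   (positive number; the trough is `-amplitude`). May be a vector with one
#'   entry per channel to emulate laminar amplitude gradients.
#' @param neg_latency,pos_latency Trough/peak latencies (s) after onset.
#' @param neg_sd,pos_sd Gaussian widths (s).
#' @param pos_gain Positive-peak amplitude as a fraction of `amplitude`.
#' @return An `evoked_template` list.
#' @export
evoked_template <- function(amplitude = 2, neg_latency = 0.025,
                            neg_sd = 0.008, pos_latency = 0.06,
                            pos_sd = 0.015, pos_gain = 0.6) {
  structure(
    list(amplitude = amplitude, neg_latency = neg_latency, neg_sd = neg_sd,
         pos_latency = pos_latency, pos_sd = pos_sd, pos_gain = pos_gain),
    class = "evoked_template"
  )
}

# Evaluate the template on a time axis (t = 0 at onset) for one channel.
eval_template <- function(tpl, t, amplitude) {
  -amplitude * exp(-(t - tpl$neg_latency)^2 / (2 * tpl$neg_sd^2)) +
    amplitude * tpl$pos_gain * exp(-(t - tpl$pos_latency)^2 / (2 * tpl$pos_sd^2))
}

# AR(2) pole modulus giving approximately the requested -3 dB bandwidth.
ar2_damping <- function(band, fs) {
  bw <- band[2] - band[1]
  min(max(1 - pi * bw / (2 * fs), 0.8), 0.995)
}

#' Generate a coupled two-area surrogate recording
#'
#' Produces a continuous multichannel recording holding `n_trials`
#' back-to-back trials, with a stimulus event at the midpoint of each trial,
#' and the band-limited inter-area coupling requested by the spec.
#'
#' @param spec A [surrogate_spec()].
#' @param condition Condition label written into the event table.
#' @param shared_fraction_by_trial Optional vector (length `n_trials`)
#'   overriding `spec$shared_fraction` per trial; used by the behavioral
#'   generator to tie coupling strength to protraction amplitude.
#' @return List with elements `recording` ([mc_recording]) and `events`
#'   ([event_table]).
#' @export
#' @examples
#' out <- gen_coupled_lfp(surrogate_spec(n_channels_per_area = 2,
#'   sampling_rate = 250, n_trials = 4, trial_length = 2, seed = 7))
#' nrow(out$events)
gen_coupled_lfp <- function(spec, condition = "stim",
                            shared_fraction_by_trial = NULL) {
  ct_assert(inherits(spec, "surrogate_spec"), "spec must be a surrogate_spec")
  fs <- spec$sampling_rate
  n_per <- round(spec$trial_length * fs)
  nch <- spec$n_channels_per_area
  lag_samp <- round(spec$directed_lag * fs)
  frac <- if (is.null(shared_fraction_by_trial)) {
    rep(spec$shared_fraction, spec$n_trials)
  } else {
    ct_assert(length(shared_fraction_by_trial) == spec$n_trials,
              "need one shared fraction per trial")
    pmin(pmax(shared_fraction_by_trial, 0), 1)
  }
  r <- ar2_damping(spec$shared_band, fs)
  f0 <- mean(spec$shared_band)
  onset_in_trial <- spec$trial_length / 2
  t_trial <- (seq_len(n_per) - 1) / fs - onset_in_trial

  sig <- with_seed(spec$seed, {
    out <- matrix(0, nrow = n_per * spec$n_trials, ncol = 2L * nch)
    for (k in seq_len(spec$n_trials)) {
      rows <- (k - 1L) * n_per + seq_len(n_per)
      # shared component, generated with headroom for the delay
      s <- ar2_oscillation(n_per + abs(lag_samp), f0, fs, r)
      s1 <- s[seq_len(n_per) + max(lag_samp, 0)]
      s2 <- s[seq_len(n_per) + max(-lag_samp, 0)]
      a <- sqrt(frac[k])
      b <- sqrt(1 - frac[k])
      line <- if (spec$line_noise_amp > 0) {
        spec$line_noise_amp * sin(2 * pi * 50 * t_trial + runif(1, 0, 2 * pi))
      } else {
        0
      }
      for (area in 1:2) {
        s_area <- if (area == 1) s1 else s2
        for (ch in seq_len(nch)) {
          col <- (area - 1L) * nch + ch
          x <- a * s_area + b * ar2_oscillation(n_per, f0, fs, r)
          if (spec$background_sd > 0) {
            bgn <- if (spec$background_color == "pink") {
              pink_noise(n_per)
            } else {
              rnorm(n_per)
            }
            x <- x + spec$background_sd * bgn
          }
          if (!is.null(spec$evoked_template)) {
            amp <- rep_len(spec$evoked_template$amplitude, nch)[ch]
            x <- x + eval_template(spec$evoked_template, t_trial, amp)
          }
          out[rows, col] <- x + line
        }
      }
    }
    out
  })

  depth <- rep(seq_len(nch) * 100, 2)
  area <- rep(c("area1", "area2"), each = nch)
  rec <- mc_recording(sig, fs = fs, depth_um = depth, area = area)
  ev <- event_table(
    (seq_len(spec$n_trials) - 1) * spec$trial_length + onset_in_trial,
    condition
  )
  list(recording = rec, events = ev)
}

#' Generate a laminar volley with a known sink location
#'
#' Builds a depth profile whose current source density has its extremum at a
#' requested channel: a negative-Gaussian depth envelope (the voltage
#' signature of a current sink) multiplied by a smooth temporal pulse.
#'
#' @param n_channels Number of equally spaced channels (>= 3).
#' @param sink_channel Channel index of the sink (1-based).
#' @param spacing Electrode spacing in micrometres.
#' @param fs Sampling rate (Hz).
#' @param duration Signal duration (s).
#' @param depth_sd Width of the Gaussian depth envelope, in channel units.
#' @return An [mc_recording] of the volley.
#' @export
gen_laminar_volley <- function(n_channels = 14, sink_channel = 7,
                               spacing = 100, fs = 1000, duration = 0.3,
                               depth_sd = 1.5) {
  if (n_channels < 3) {
    ct_stop("CSD is undefined for fewer than 3 channels (got %d)", n_channels)
  }
  ct_assert(sink_channel >= 1 && sink_channel <= n_channels,
            "sink_channel must lie in 1..n_channels")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  pulse <- exp(-(t - duration / 3)^2 / (2 * (duration / 12)^2))
  depth_env <- -exp(-((seq_len(n_channels) - sink_channel)^2) /
                      (2 * depth_sd^2))
  sig <- outer(pulse, depth_env)
  mc_recording(sig, fs = fs, depth_um = seq_len(n_channels) * spacing,
               area = rep("probe", n_channels))
}

#' Behavior-link specification
#'
#' Trial-to-trial protraction amplitudes are normally distributed; the
#' surrogate's inter-area coupling strength within `link_band` varies
#' linearly with the amplitude, which is the ground-truth association the
#' behavioral analyses must recover.
#'
#' @param amplitude_mean,amplitude_sd Protraction amplitude law (degrees).
#' @param link_band `c(f_lo, f_hi)` Hz in which coupling tracks amplitude.
#' @param link_slope Coherence units per degree.
#' @param noise_sd Measurement noise on the whisker trace (degrees).
#' @param movement_coupling Variance fraction of a slow (delta-band) shared
#'   component injected into both the whisker trace and the area-1 LFP;
#'   0 disables LFP-movement coupling.
#' @return A `behavior_link_spec` list.
#' @export
behavior_link_spec <- function(amplitude_mean = 10, amplitude_sd = 2,
                               link_band = c(30, 45), link_slope = 0.1,
                               noise_sd = 0.5, movement_coupling = 0) {
  ct_assert(is_scalar_num(amplitude_sd) && amplitude_sd >= 0,
            "amplitude_sd must be >= 0")
  ct_assert(is_scalar_num(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  ct_assert(length(link_band) == 2 && link_band[1] < link_band[2],
            "link_band must be c(f_lo, f_hi)")
  structure(
    list(amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
         link_band = link_band, link_slope = link_slope, noise_sd = noise_sd,
         movement_coupling = movement_coupling),
    class = "behavior_link_spec"
  )
}

#' Generate a behavioral surrogate dataset
#'
#' Draws per-trial protraction amplitudes from the normal law in `link`,
#' couples the surrogate's inter-area coupling strength in `link_band` to
#' the amplitude through `link_slope`, and synthesizes whisker-angle traces
#' (a raised-cosine protraction of the drawn amplitude in the response
#' window, plus measurement noise).
#'
#' @param spec A [surrogate_spec()]; its `shared_band` is overridden by
#'   `link$link_band` and its `shared_fraction` is used as the coupling at
#'   the mean amplitude.
#' @param link A [behavior_link_spec()].
#' @return List with `trials` (a [trial_tensor]), `behavior` (data.frame:
#'   trial, amplitude_deg, movement_power), `whisker` (trial x time matrix of
#'   whisker angle, degrees), and `truth` (amplitudes and per-trial coupling
#'   fractions actually used).
#' @export
gen_behavior_dataset <- function(spec, link) {
  ct_assert(inherits(spec, "surrogate_spec"), "spec must be a surrogate_spec")
  ct_assert(inherits(link, "behavior_link_spec"),
            "link must be a behavior_link_spec")
  spec$shared_band <- link$link_band
  fs <- spec$sampling_rate
  n_per <- round(spec$trial_length * fs)
  onset_in_trial <- spec$trial_length / 2
  t_trial <- (seq_len(n_per) - 1) / fs - onset_in_trial

  amplitudes <- with_seed(child_seed(spec$seed, 101), {
    rnorm(spec$n_trials, link$amplitude_mean, link$amplitude_sd)
  })
  frac <- pmin(pmax(
    spec$shared_fraction +
      link$link_slope * (amplitudes - link$amplitude_mean),
    0.02), 0.98)

  out <- gen_coupled_lfp(spec, condition = "behavior",
                         shared_fraction_by_trial = frac)
  trials <- segment_trials(out$recording, out$events,
                           window = c(onset_in_trial, onset_in_trial))

  # whisker trace: raised-cosine protraction over [0, 0.5] s post-onset
  resp <- t_trial >= 0 & t_trial <= 0.5
  bump <- numeric(n_per)
  bump[resp] <- 0.5 * (1 - cos(2 * pi * (t_trial[resp]) / 0.5))
  whisker <- with_seed(child_seed(spec$seed, 202), {
    w <- matrix(0, spec$n_trials, n_per)
    for (k in seq_len(spec$n_trials)) {
      w[k, ] <- amplitudes[k] * bump + link$noise_sd * rnorm(n_per)
      if (link$movement_coupling > 0) {
        slow <- ar2_oscillation(n_per, 2, fs, r = 0.995)
        w[k, ] <- w[k, ] + sqrt(link$movement_coupling) * slow
        # inject the same slow component into all area-1 channels
        nch <- spec$n_channels_per_area
        trials$data[k, seq_len(nch), ] <-
          trials$data[k, seq_len(nch), , drop = FALSE] +
          rep(sqrt(link$movement_coupling) * slow,
              each = nch)
      }
    }
    w
  })

  base_idx <- which(t_trial < 0)
  behavior <- data.frame(
    trial = seq_len(spec$n_trials),
    amplitude_deg = apply(whisker, 1, function(tr) {
      max(tr[resp]) - mean(tr[base_idx])
    }),
    movement_power = apply(whisker, 1, function(tr) {
      mean((tr[resp] - mean(tr[base_idx]))^2)
    })
  )
  list(trials = trials, behavior = behavior, whisker = whisker,
       truth = list(amplitudes = amplitudes, shared_fraction = frac))
}
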