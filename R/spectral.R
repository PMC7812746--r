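#' Default logarithmic frequency grid
#'
#' @param f_lo,f_hi Grid limits in Hz.
#' @param n Number of points.
#' @return Strictly increasing frequency vector (Hz).
#' @export
default_freq_grid <- function(f_lo = 2, f_hi = 100, n = 40) {
  exp(seq(log(f_lo), log(f_hi), length.out = n))
}

#' Morlet time-frequency decomposition
#'
#' Convolves every trial of one channel with complex Morlet wavelets
#' (Gaussian-windowed complex exponentials with a fixed number of cycles),
#' giving complex coefficients per trial, frequency and time. Kernels are
#' L2-normalized; linearity holds exactly.
#'
#' @param trials A [trial_tensor].
#' @param channel Channel index to decompose.
#' @param freqs Frequency grid (Hz), strictly increasing, all below Nyquist.
#' @param cycles Cycles per wavelet (>= 2, default 7).
#' @return A `tf_decomp` object: complex array `coef` (trial x freq x time),
#'   `freqs`, `time`, `fs`, `cycles`, `channel`.
#' @export
#' @examples
#' tt <- trial_tensor(array(rnorm(2 * 1 * 256), c(2, 1, 256)), fs = 256,
#'                    window = c(0.5, 0.5))
#' tf <- wavelet_transform(tt, channel = 1, freqs = c(10, 20, 40))
#' dim(tf$coef)
wavelet_transform <- function(trials, channel, freqs = default_freq_grid(),
                              cycles = 7) {
  ct_assert(inherits(trials, "trial_tensor"), "trials must be a trial_tensor")
  ct_assert(is_count(channel) && channel <= dim(trials$data)[2],
            "channel out of range")
  ct_assert(all(diff(freqs) > 0), "freqs must be strictly increasing")
  ct_assert(cycles >= 2, "cycles must be >= 2")
  fs <- trials$fs
  if (max(freqs) >= fs / 2) {
    ct_stop("maximum frequency %g Hz is not below the Nyquist frequency %g Hz",
            max(freqs), fs / 2)
  }
  x <- trials$data[, channel, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n_trials <- nrow(x)
  n_time <- ncol(x)

  # longest kernel sets the FFT size
  sigma_max <- cycles / (2 * pi * min(freqs))
  half_max <- ceiling(3.5 * sigma_max * fs)
  nfft <- nextn(n_time + 2 * half_max + 1, 2)
  sig_f <- mvfft(rbind(t(x), matrix(0, nfft - n_time, n_trials)))

  coef <- array(complex(real = 0), dim = c(n_trials, length(freqs), n_time))
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sigma <- cycles / (2 * pi * f)
    half <- ceiling(3.5 * sigma * fs)
    tk <- (-half:half) / fs
    w <- exp(2i * pi * f * tk) * exp(-tk^2 / (2 * sigma^2))
    w <- w / sqrt(sum(Mod(w)^2))
    wf <- fft(c(w, complex(real = numeric(nfft - length(w)))))
    conv <- mvfft(sig_f * matrix(wf, nfft, n_trials), inverse = TRUE) / nfft
    # kernel is centred at index half+1: take the aligned segment
    coef[, j, ] <- t(conv[half + seq_len(n_time), , drop = FALSE])
  }
  structure(
    list(coef = coef, freqs = freqs, time = trials$time, fs = fs,
         cycles = cycles, channel = channel,
         condition = trials$condition),
    class = "tf_decomp"
  )
}

#' Welch-averaged power spectrum
#'
#' Hann-windowed overlapping segments, averaged periodograms, one-sided
#' spectral density (so the integral over frequency approximates the signal
#' variance).
#'
#' @param signal Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param segment_length Segment length in samples.
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @param demean Subtract the signal mean first (default TRUE).
#' @return List with `f` (Hz) and `P` (density, units^2/Hz), class
#'   `power_spectrum`.
#' @export
power_spectrum <- function(signal, fs, segment_length = 256, overlap = 0.5,
                           demean = TRUE) {
  n <- length(signal)
  ct_assert(segment_length >= 8, "segment_length must be >= 8")
  if (segment_length > n) {
    ct_stop("segment_length %d exceeds signal length %d", segment_length, n)
  }
  ct_assert(overlap >= 0 && overlap < 1, "overlap must be in [0, 1)")
  if (demean) signal <- signal - mean(signal)
  step <- max(1L, floor(segment_length * (1 - overlap)))
  starts <- seq(1L, n - segment_length + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segment_length) / (segment_length + 1))
  u <- sum(w^2)
  nfreq <- floor(segment_length / 2)
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- signal[s + seq_len(segment_length) - 1L]
    seg <- (seg - mean(seg)) * w
    xf <- fft(seg)
    acc <- acc + Mod(xf[2:(nfreq + 1)])^2
  }
  P <- 2 * acc / (length(starts) * fs * u)
  f <- (seq_len(nfreq)) * fs / segment_length
  structure(list(f = f, P = P, fs = fs, n_segments = length(starts)),
            class = "power_spectrum")
}

# Window indices for the frequency-dependent two-cycle averaging window.
cycle_window_idx <- function(time, f, onset, n_cycles = 2,
                             side = c("post", "pre")) {
  side <- match.arg(side)
  if (side == "post") {
    which(time >= onset & time < onset + n_cycles / f)
  } else {
    which(time >= onset - n_cycles / f & time < onset)
  }
}

#' Trial coherence with frequency-dependent windows
#'
#' Coherence across trials: at each frequency and time point,
#' `C(f,t) = |sum_k X_k Y_k*| / sqrt(sum_k |X_k|^2 sum_k |Y_k|^2)`, then for
#' each frequency `C(f,t)` is averaged over a window spanning two
#' oscillation cycles (`2/f` seconds) after stimulus onset. Mode
#' `"baseline"` instead averages over the two cycles preceding onset,
#' providing the intertrial reference.
#'
#' @param tf_x,tf_y `tf_decomp` objects with equal trial counts, grids and
#'   time axes.
#' @param onset Onset time (s) on the trial time axis (default 0).
#' @param mode `"evoked"` (post-onset window) or `"baseline"` (pre-onset).
#' @param n_cycles Cycles in the averaging window (default 2).
#' @return A `coherence_result`: `coherence` (per frequency), `freqs`, `K`
#'   (trial count), `Cft` (frequency x time coherence), `mode`, `pair`.
#' @export
event_coherence <- function(tf_x, tf_y, onset = 0,
                            mode = c("evoked", "baseline"), n_cycles = 2) {
  mode <- match.arg(mode)
  check_tf_pair(tf_x, tf_y)
  K <- dim(tf_x$coef)[1]
  ct_assert(K >= 2, "coherence across trials is undefined for K < 2 trials")
  sxy <- apply(tf_x$coef * Conj(tf_y$coef), c(2, 3), sum)
  sxx <- apply(Mod(tf_x$coef)^2, c(2, 3), sum)
  syy <- apply(Mod(tf_y$coef)^2, c(2, 3), sum)
  cft <- Mod(sxy) / sqrt(sxx * syy)
  freqs <- tf_x$freqs
  side <- if (mode == "evoked") "post" else "pre"
  coh <- vapply(seq_along(freqs), function(j) {
    idx <- cycle_window_idx(tf_x$time, freqs[j], onset, n_cycles, side)
    ct_assert(length(idx) >= 1,
              "no samples in the %d-cycle window at %g Hz; widen the trial window",
              n_cycles, freqs[j])
    mean(cft[j, idx])
  }, numeric(1))
  structure(
    list(coherence = coh, freqs = freqs, K = K, Cft = cft,
         time = tf_x$time, mode = mode, onset = onset, n_cycles = n_cycles,
         pair = c(x = tf_x$channel, y = tf_y$channel)),
    class = "coherence_result"
  )
}

check_tf_pair <- function(tf_x, tf_y) {
  ct_assert(inherits(tf_x, "tf_decomp") && inherits(tf_y, "tf_decomp"),
            "inputs must be tf_decomp objects")
  ct_assert(identical(dim(tf_x$coef), dim(tf_y$coef)),
            "tf decompositions must have identical dimensions")
  ct_assert(isTRUE(all.equal(tf_x$freqs, tf_y$freqs)),
            "tf decompositions must share one frequency grid")
  ct_assert(isTRUE(all.equal(tf_x$time, tf_y$time)),
            "tf decompositions must share one time axis")
  invisible(TRUE)
}

#' Band-averaged coherence
#'
#' @param coh A `coherence_result`.
#' @param band `c(lo, hi)` Hz or a band name from [ct_bands()].
#' @return Mean coherence over grid frequencies inside the band.
#' @export
band_coherence <- function(coh, band) {
  if (is.character(band)) band <- ct_bands()[[band]]
  ct_assert(!is.null(band) && length(band) == 2, "unknown band")
  idx <- band_index(coh$freqs, band)
  ct_assert(length(idx) > 0, "no grid frequencies inside the band")
  mean(coh$coherence[idx])
}

#' Line-noise normalization
#'
#' Rescales power in a narrow band around the line frequency to the level
#' interpolated from flanking bands, leaving phases untouched. Works on
#' `power_spectrum` objects and on `tf_decomp` objects (where the
#' trial-and-time-averaged power per frequency defines the rescaling).
#'
#' @param x A `power_spectrum` or `tf_decomp`.
#' @param line_freq Line frequency (default 50 Hz).
#' @param halfwidth Half-width (Hz) of the contaminated band (default 1).
#' @param flank Width (Hz) of the flanking reference bands (default 3.5,
#'   starting 0.5 Hz outside the contaminated band).
#' @return Object of the same class with normalized power.
#' @export
remove_line_noise <- function(x, line_freq = 50, halfwidth = 1, flank = 3.5) {
  UseMethod("remove_line_noise")
}

line_noise_gain <- function(f, P, line_freq, halfwidth, flank) {
  lo_band <- f >= line_freq - halfwidth - 0.5 - flank &
    f < line_freq - halfwidth - 0.5
  hi_band <- f > line_freq + halfwidth + 0.5 &
    f <= line_freq + halfwidth + 0.5 + flank
  hit <- f >= line_freq - halfwidth & f <= line_freq + halfwidth
  if (!any(lo_band) || !any(hi_band)) {
    ct_stop("line frequency %g Hz is too close to the grid edge for flanking bands",
            line_freq)
  }
  if (!any(hit)) return(NULL)
  target <- numeric(sum(hit))
  m_lo <- mean(P[lo_band])
  m_hi <- mean(P[hi_band])
  f_lo <- mean(f[lo_band])
  f_hi <- mean(f[hi_band])
  fh <- f[hit]
  target <- m_lo + (m_hi - m_lo) * (fh - f_lo) / (f_hi - f_lo)
  target <- pmax(target, .Machine$double.eps)
  current <- pmax(P[hit], .Machine$double.eps)
  # only normalize down, and only when power clearly exceeds the
  # interpolated level: leaves clean spectra untouched and is idempotent
  gain <- ifelse(current > 1.05 * target, sqrt(target / current), 1)
  list(hit = which(hit), gain = gain)
}

#' @export
remove_line_noise.power_spectrum <- function(x, line_freq = 50, halfwidth = 1,
                                             flank = 3.5) {
  g <- line_noise_gain(x$f, x$P, line_freq, halfwidth, flank)
  if (!is.null(g)) x$P[g$hit] <- x$P[g$hit] * g$gain^2
  x
}

#' @export
remove_line_noise.tf_decomp <- function(x, line_freq = 50, halfwidth = 1,
                                        flank = 3.5) {
  pow <- apply(Mod(x$coef)^2, 2, mean)
  g <- line_noise_gain(x$freqs, pow, line_freq, halfwidth, flank)
  if (!is.null(g)) {
    for (i in seq_along(g$hit)) {
      x$coef[, g$hit[i], ] <- x$coef[, g$hit[i], ] * g$gain[i]
    }
  }
  x
}

#' Phase-difference spectrum
#'
#' Average phase lag between two channels over the two-cycle post-onset
#' window: `dphi(f) = arg(sum_k sum_t X_k Y_k*)`, wrapped to `(-pi, pi]`.
#' Positive values mean `x` leads `y`. Frequencies whose cross-spectral
#' phase consistency is near zero are flagged unreliable.
#'
#' @inheritParams event_coherence
#' @param min_plv Minimum phase-locking of the cross-spectrum below which
#'   the phase estimate is flagged unreliable (default 0.1).
#' @return A `phase_diff_result`: `phase` (radians per frequency), `freqs`,
#'   `reliable` (logical), `bands` (circular band means).
#' @export
phase_difference <- function(tf_x, tf_y, onset = 0, n_cycles = 2,
                             min_plv = 0.1) {
  check_tf_pair(tf_x, tf_y)
  freqs <- tf_x$freqs
  cross <- tf_x$coef * Conj(tf_y$coef)
  phase <- numeric(length(freqs))
  reliable <- logical(length(freqs))
  for (j in seq_along(freqs)) {
    idx <- cycle_window_idx(tf_x$time, freqs[j], onset, n_cycles, "post")
    z <- sum(cross[, j, idx])
    denom <- sum(Mod(cross[, j, idx]))
    plv <- if (denom > 0) Mod(z) / denom else 0
    phase[j] <- Arg(z)
    reliable[j] <- plv >= min_plv
  }
  bands <- lapply(ct_bands(), function(b) {
    idx <- band_index(freqs, b)
    idx <- idx[reliable[idx]]
    if (length(idx) == 0) return(NA_real_)
    Arg(sum(exp(1i * phase[idx])))
  })
  structure(
    list(phase = phase, freqs = freqs, reliable = reliable, bands = bands,
         convention = "positive phase means x leads y"),
    class = "phase_diff_result"
  )
}
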