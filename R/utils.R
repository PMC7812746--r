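#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft mvfft rnorm runif median quantile sd var
#'   pchisq qchisq p.adjust filter nextn approx
#' @importFrom utils head tail
NULL

# Stop with a consistent error prefix so callers can match on it.
ct_stop <- function(...) stop(sprintf(...), call. = FALSE)

ct_assert <- function(cond, ...) {
  if (!isTRUE(cond)) ct_stop(...)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

#' Frequency band conventions
#'
#' Band partition used throughout the package: theta 4--8 Hz, alpha 8--12 Hz
#' and gamma 30--100 Hz follow the common electrophysiology convention for
#' sensorimotor coherence work; delta (1--4 Hz) and beta (12--30 Hz) edges,
#' and the split of gamma into a lower (30--55 Hz) and higher (65--100 Hz)
#' part that skirts 50/60 Hz line noise, are package conventions.
#'
#' @return Named list of `c(lo, hi)` band edges in Hz.
#' @export
#' @examples
#' ct_bands()$theta
ct_bands <- function() {
  list(
    delta = c(1, 4),
    theta = c(4, 8),
    alpha = c(8, 12),
    beta = c(12, 30),
    gamma = c(30, 100),
    gamma_low = c(30, 55),
    gamma_high = c(65, 100)
  )
}

# Indices of frequencies falling inside a closed band.
band_index <- function(freqs, band) {
  which(freqs >= band[1] & freqs <= band[2])
}

# Seed handling: every stochastic entry point takes an integer seed and uses
# a local RNG state so callers' streams are not disturbed.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  ct_assert(is_count(abs(seed) + 1), "seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed (kept below 2^31).
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

# 1/f ("pink") noise by spectral shaping of white noise; unit variance.
pink_noise <- function(n) {
  white <- rnorm(n)
  nf <- nextn(n, 2)
  xf <- fft(c(white, numeric(nf - n)))
  f <- c(1, seq_len(nf - 1))
  f <- pmin(f, nf - (f - 1))     # symmetric frequency index
  xf <- xf / sqrt(f)
  x <- Re(fft(xf, inverse = TRUE))[seq_len(n)]
  as.numeric(scale(x))
}

# Damped-harmonic-oscillator (AR(2)) narrowband process, unit variance in
# expectation (normalized by the analytic stationary sd, so mixing
# fractions stay exact and coherence targets unbiased). Peak frequency f0
# (Hz); damping `r` (pole modulus) sets the bandwidth, r close to 1 means
# narrow.
ar2_oscillation <- function(n, f0, fs, r = 0.97, burn = 300L) {
  ct_assert(f0 < fs / 2, "oscillator frequency %g Hz is not below Nyquist", f0)
  a1 <- 2 * r * cos(2 * pi * f0 / fs)
  a2 <- -r^2
  e <- rnorm(n + burn)
  x <- as.numeric(filter(e, c(a1, a2), method = "recursive"))
  x <- x[(burn + 1L):(burn + n)]
  v <- (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
  x / sqrt(v)
}
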