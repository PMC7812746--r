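#' Trial tensor
#'
#' Per-trial segmented signals: a trial x channel x time array with the
#' segmentation window, condition labels and sampling rate attached. The
#' trial window is half-open, `[-pre, post)` relative to the event onset.
#'
#' @param data 3-d numeric array, trial x channel x time.
#' @param fs Sampling rate (Hz).
#' @param window `c(pre, post)` in seconds (both positive).
#' @param condition Character vector of per-trial condition labels.
#' @param channels Optional channel metadata data.frame.
#' @return A `trial_tensor` object.
#' @export
trial_tensor <- function(data, fs, window, condition = NULL,
                         channels = NULL) {
  ct_assert(is.array(data) && length(dim(data)) == 3,
            "data must be a trial x channel x time array")
  ct_assert(length(window) == 2 && all(window >= 0),
            "window must be c(pre, post) with non-negative entries")
  n_trials <- dim(data)[1]
  if (is.null(condition)) condition <- rep("trial", n_trials)
  ct_assert(length(condition) == n_trials,
            "one condition label per trial required")
  structure(
    list(
      data = data,
      fs = fs,
      window = window,
      condition = as.character(condition),
      channels = channels,
      time = seq_len(dim(data)[3]) / fs - window[1] - 1 / fs
    ),
    class = "trial_tensor"
  )
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<trial_tensor> %d trials x %d channels x %d samples @ %g Hz, window [-%g, %g) s\n",
    d[1], d[2], d[3], x$fs, x$window[1], x$window[2]
  ))
  tab <- table(x$condition)
  cat("  conditions:", paste(sprintf("%s (%d)", names(tab), tab),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Segment a recording into trials
#'
#' Cuts half-open `[-pre, post)` windows around each event onset. Events
#' whose window does not fit inside the recording are dropped with a
#' warning naming them, never silently truncated.
#'
#' @param rec An [mc_recording].
#' @param events An [event_table()] data.frame.
#' @param window `c(pre, post)` seconds around each onset.
#' @return A [trial_tensor]; dropped onsets are recorded in
#'   `attr(x, "dropped")`.
#' @export
#' @examples
#' rec <- mc_recording(matrix(rnorm(3000), ncol = 3), fs = 100)
#' ev <- event_table(c(1, 5, 9.9))
#' tt <- segment_trials(rec, ev, window = c(0.5, 0.5))  # last event dropped
#' dim(tt$data)
segment_trials <- function(rec, events, window) {
  ct_assert(inherits(rec, "mc_recording"), "rec must be an mc_recording")
  ct_assert(length(window) == 2 && all(window >= 0),
            "window must be c(pre, post)")
  fs <- rec$fs
  n <- nrow(rec$signal)
  n_pre <- round(window[1] * fs)
  n_post <- round(window[2] * fs)
  n_len <- n_pre + n_post
  ct_assert(n_len >= 1, "window is empty at this sampling rate")
  onset_idx <- round(events$onset_s * fs) + 1L
  start <- onset_idx - n_pre
  keep <- start >= 1L & (start + n_len - 1L) <= n
  if (any(!keep)) {
    warning(sprintf(
      "dropped %d/%d events whose window does not fit the recording (onsets: %s s)",
      sum(!keep), length(keep),
      paste(signif(events$onset_s[!keep], 4), collapse = ", ")
    ), call. = FALSE)
  }
  idx <- which(keep)
  out <- array(0, dim = c(length(idx), ncol(rec$signal), n_len))
  for (j in seq_along(idx)) {
    rows <- start[idx[j]] + seq_len(n_len) - 1L
    out[j, , ] <- t(rec$signal[rows, , drop = FALSE])
  }
  tt <- trial_tensor(out, fs = fs, window = window,
                     condition = events$condition[idx],
                     channels = rec$channels)
  attr(tt, "dropped") <- events[!keep, , drop = FALSE]
  tt
}

#' Event-related average with baseline Z-scoring
#'
#' Averages trials per channel and Z-scores the mean trace against the
#' baseline window (per-channel baseline mean and standard deviation of the
#' trial-averaged trace). A channel with zero baseline variance is reported
#' and its Z-scored trace set to `NA` rather than divided by zero.
#'
#' @param trials A [trial_tensor].
#' @param baseline_window `c(from, to)` in seconds relative to onset
#'   (negative = pre-stimulus). Default -1.0 to -0.1 s, ending before onset
#'   to avoid stimulus bleed.
#' @return An `erp_result` list: `mean` and `zscored` (channel x time
#'   matrices), `time`, `n_trials`, `baseline_window`, `baseline_mean`,
#'   `baseline_sd`.
#' @export
event_related_average <- function(trials, baseline_window = c(-1.0, -0.1)) {
  ct_assert(inherits(trials, "trial_tensor"), "trials must be a trial_tensor")
  n_trials <- dim(trials$data)[1]
  ct_assert(n_trials >= 2, "need at least 2 trials to average")
  m <- apply(trials$data, c(2, 3), mean)
  bidx <- which(trials$time >= baseline_window[1] &
                  trials$time <= baseline_window[2])
  ct_assert(length(bidx) >= 2,
            "baseline window [%g, %g] s contains fewer than 2 samples",
            baseline_window[1], baseline_window[2])
  bmean <- rowMeans(m[, bidx, drop = FALSE])
  bsd <- apply(m[, bidx, drop = FALSE], 1, sd)
  z <- (m - bmean) / bsd
  bad <- bsd == 0
  if (any(bad)) {
    warning(sprintf(
      "zero baseline variance on channel(s) %s; Z-scoring refused there",
      paste(which(bad), collapse = ", ")
    ), call. = FALSE)
    z[bad, ] <- NA_real_
  }
  structure(
    list(mean = m, zscored = z, time = trials$time, fs = trials$fs,
         n_trials = n_trials, baseline_window = baseline_window,
         baseline_mean = bmean, baseline_sd = bsd,
         channels = trials$channels),
    class = "erp_result"
  )
}

#' First negative / positive peak metrics of an evoked response
#'
#' Finds, within the search window, the first local minimum below the
#' baseline mean (the negative deflection) and the first subsequent local
#' maximum above it (the positive peak). Amplitudes are reported relative
#' to the baseline mean. When no qualifying extremum exists the peak is
#' explicitly `absent` (amplitude and latency `NA`), never silently zero.
#'
#' @param erp An `erp_result` from [event_related_average()].
#' @param channel Channel index.
#' @param search_window `c(from, to)` seconds post-onset; default 0 to
#'   0.2 s, the period over which the evoked deflection returns to
#'   baseline.
#' @param use_zscored Use the Z-scored trace instead of the raw mean.
#' @return A `peak_metrics` list with `negative` and `positive` components
#'   (`amplitude`, `latency_s`, `absent`) and the search window.
#' @export
peak_metrics <- function(erp, channel, search_window = c(0, 0.2),
                         use_zscored = FALSE) {
  ct_assert(inherits(erp, "erp_result"), "erp must be an erp_result")
  trace_full <- if (use_zscored) erp$zscored[channel, ] else erp$mean[channel, ]
  base <- if (use_zscored) 0 else erp$baseline_mean[channel]
  idx <- which(erp$time >= search_window[1] & erp$time <= search_window[2])
  ct_assert(length(idx) >= 3, "search window too short")
  x <- trace_full[idx] - base
  t <- erp$time[idx]
  n <- length(x)
  interior <- 2:(n - 1)
  is_min <- x[interior] <= x[interior - 1] & x[interior] <= x[interior + 1] &
    x[interior] < 0
  is_max <- x[interior] >= x[interior - 1] & x[interior] >= x[interior + 1] &
    x[interior] > 0
  absent <- list(amplitude = NA_real_, latency_s = NA_real_, absent = TRUE)
  neg <- absent
  pos <- absent
  imin <- interior[is_min]
  if (length(imin) > 0) {
    i0 <- imin[1]
    neg <- list(amplitude = x[i0], latency_s = t[i0], absent = FALSE)
    imax <- interior[is_max]
    imax <- imax[imax > i0]
    if (length(imax) > 0) {
      i1 <- imax[1]
      pos <- list(amplitude = x[i1], latency_s = t[i1], absent = FALSE)
    }
  } else {
    # no negative deflection: still report the first positive peak, if any
    imax <- interior[is_max]
    if (length(imax) > 0) {
      i1 <- imax[1]
      pos <- list(amplitude = x[i1], latency_s = t[i1], absent = FALSE)
    }
  }
  structure(
    list(negative = neg, positive = pos, search_window = search_window,
         channel = channel),
    class = "peak_metrics"
  )
}

#' Current source density of a laminar profile
#'
#' Standard second spatial difference across equally spaced channels:
#' `csd_i = -(phi[i-1] - 2 phi[i] + phi[i+1]) / h^2` for interior channels,
#' with the convention that current sinks are negative. No spatial
#' smoothing is applied unless requested.
#'
#' @param erp An `erp_result` (its per-channel mean traces are used), or a
#'   plain channel x time numeric matrix.
#' @param spacing Electrode spacing `h` in micrometres; channels must be
#'   uniformly spaced (checked against metadata when available).
#' @param smooth Optional odd integer width of a spatial boxcar applied
#'   before differencing (default 0 = none).
#' @return A `csd_profile` list: `csd` ((n_channels - 2) x time matrix),
#'   `channels` (interior channel indices), `spacing_um`, `time`.
#' @export
csd_profile <- function(erp, spacing, smooth = 0) {
  if (inherits(erp, "erp_result")) {
    m <- erp$mean
    time <- erp$time
    if (!is.null(erp$channels)) {
      d <- diff(erp$channels$depth_um)
      if (length(unique(erp$channels$area)) == 1 &&
          any(abs(d - d[1]) > 1e-9 * max(abs(d)))) {
        ct_stop("channel spacing is non-uniform; CSD requires uniform spacing")
      }
    }
  } else {
    m <- as.matrix(erp)
    time <- seq_len(ncol(m))
  }
  nch <- nrow(m)
  ct_assert(nch >= 3, "CSD needs at least 3 channels")
  ct_assert(is_scalar_num(spacing) && spacing > 0, "spacing must be positive")
  if (smooth > 1) {
    ct_assert(smooth %% 2 == 1, "smooth width must be odd")
    kernel <- rep(1 / smooth, smooth)
    pad <- (smooth - 1) / 2
    mp <- rbind(m[rep(1, pad), , drop = FALSE], m,
                m[rep(nch, pad), , drop = FALSE])
    m <- apply(mp, 2, function(col) {
      as.numeric(stats::filter(col, kernel, sides = 2))[pad + seq_len(nch)]
    })
  }
  interior <- 2:(nch - 1)
  csd <- -(m[interior - 1, , drop = FALSE] - 2 * m[interior, , drop = FALSE] +
             m[interior + 1, , drop = FALSE]) / spacing^2
  structure(
    list(csd = csd, channels = interior, spacing_um = spacing, time = time),
    class = "csd_profile"
  )
}
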