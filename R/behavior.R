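#' Protraction amplitude and movement power of a whisker trace
#'
#' Amplitude is the maximum of the trace in the response window relative to
#' the baseline-window mean; movement power is the mean squared
#' baseline-subtracted angle in the response window.
#'
#' @param trace Whisker angle (degrees) over time.
#' @param time Time axis (s), onset at 0.
#' @param baseline_window,response_window `c(from, to)` in seconds.
#' @return List with `amplitude_deg` and `movement_power`.
#' @export
#' @examples
#' t <- seq(-1, 1, by = 0.01)
#' tr <- ifelse(t > 0 & t < 0.5, 12 * sin(pi * t / 0.5), 0)
#' protraction_amplitude(tr, t)$amplitude_deg
protraction_amplitude <- function(trace, time,
                                  baseline_window = c(-1, 0),
                                  response_window = c(0, 0.5)) {
  ct_assert(length(trace) == length(time), "trace and time must align")
  bidx <- which(time >= baseline_window[1] & time < baseline_window[2])
  ridx <- which(time >= response_window[1] & time < response_window[2])
  ct_assert(length(bidx) > 0, "baseline window is empty")
  ct_assert(length(ridx) > 0, "response window is empty")
  base <- mean(trace[bidx])
  list(
    amplitude_deg = max(trace[ridx]) - base,
    movement_power = mean((trace[ridx] - base)^2)
  )
}

#' Split trials by protraction amplitude
#'
#' Mode `"median"` divides trials into the 50% with the smallest and the
#' 50% with the largest protractions (odd counts put the extra trial in the
#' small group; ties are broken by trial order). Mode `"overlapping8"`
#' forms eight overlapping groups from a sliding rank window of width 25%
#' of the trials, stepped by (100 - 25)/7 = 10.7% so the group centres span
#' the full amplitude range.
#'
#' @param amplitudes Per-trial protraction amplitudes.
#' @param mode `"median"` or `"overlapping8"`.
#' @return For `"median"`, a factor with levels `small`/`large`; for
#'   `"overlapping8"`, a list of eight integer index vectors (a trial may
#'   appear in neighbouring groups).
#' @export
split_trials <- function(amplitudes, mode = c("median", "overlapping8")) {
  mode <- match.arg(mode)
  n <- length(amplitudes)
  ord <- order(amplitudes, seq_len(n))  # tie-break by trial order
  if (mode == "median") {
    ct_assert(n >= 2, "median split needs >= 2 trials")
    n_small <- ceiling(n / 2)
    grp <- rep("large", n)
    grp[ord[seq_len(n_small)]] <- "small"
    return(factor(grp, levels = c("small", "large")))
  }
  ct_assert(n >= 8, "overlapping8 split needs >= 8 trials")
  w <- 0.25 * n
  starts <- seq(0, n - w, length.out = 8)
  lapply(seq_len(8), function(g) {
    lo <- floor(starts[g]) + 1L
    hi <- min(n, ceiling(starts[g] + w))
    sort(ord[lo:hi])
  })
}

#' Per-trial coherence features (jackknife pseudo-values)
#'
#' Coherence is only defined across trials, so the per-trial "coherence
#' level" is operationalized as the leave-one-out jackknife pseudo-value:
#' `K * C_all(f) - (K - 1) * C_without_k(f)`, i.e. trial k's contribution
#' to the trial-ensemble coherence, computed over the two-cycle post-onset
#' window per frequency.
#'
#' @inheritParams event_coherence
#' @return Matrix trial x frequency of pseudo-values, with the frequency
#'   grid in `attr(x, "freqs")`.
#' @export
trial_coherence_features <- function(tf_x, tf_y, onset = 0, n_cycles = 2) {
  check_tf_pair(tf_x, tf_y)
  K <- dim(tf_x$coef)[1]
  ct_assert(K >= 3, "jackknife features need K >= 3 trials")
  freqs <- tf_x$freqs
  out <- matrix(0, K, length(freqs))
  for (j in seq_along(freqs)) {
    idx <- cycle_window_idx(tf_x$time, freqs[j], onset, n_cycles, "post")
    X <- tf_x$coef[, j, idx, drop = TRUE]
    Y <- tf_y$coef[, j, idx, drop = TRUE]
    if (length(idx) == 1L) {
      X <- matrix(X, ncol = 1)
      Y <- matrix(Y, ncol = 1)
    }
    xy <- X * Conj(Y)
    xx <- Mod(X)^2
    yy <- Mod(Y)^2
    sxy <- colSums(xy)
    sxx <- colSums(xx)
    syy <- colSums(yy)
    c_all <- mean(Mod(sxy) / sqrt(sxx * syy))
    T <- length(idx)
    sxy_m <- matrix(sxy, K, T, byrow = TRUE) - xy
    sxx_m <- matrix(sxx, K, T, byrow = TRUE) - xx
    syy_m <- matrix(syy, K, T, byrow = TRUE) - yy
    c_loo <- rowMeans(Mod(sxy_m) / sqrt(sxx_m * syy_m))
    out[, j] <- K * c_all - (K - 1) * c_loo
  }
  attr(out, "freqs") <- freqs
  out
}

#' LFP-behavior coherence
#'
#' Applies the trial-coherence estimator to an LFP channel and a per-trial
#' behavioral signal (whisker angle or movement-power trace) resampled to
#' the LFP rate.
#'
#' @param tf_lfp `tf_decomp` of the LFP channel.
#' @param movement Trial x time matrix of the behavioral signal, on the
#'   same time axis as the LFP trials.
#' @inheritParams event_coherence
#' @return A `coherence_result`.
#' @export
lfp_behavior_coherence <- function(tf_lfp, movement, onset = 0,
                                   mode = "evoked", n_cycles = 2) {
  ct_assert(inherits(tf_lfp, "tf_decomp"), "tf_lfp must be a tf_decomp")
  ct_assert(is.matrix(movement), "movement must be a trial x time matrix")
  d <- dim(tf_lfp$coef)
  ct_assert(nrow(movement) == d[1] && ncol(movement) == d[3],
            "movement must match the LFP trials (%d x %d, got %d x %d)",
            d[1], d[3], nrow(movement), ncol(movement))
  tt <- trial_tensor(array(movement, dim = c(d[1], 1, d[3])),
                     fs = tf_lfp$fs,
                     window = c(-tf_lfp$time[1], max(tf_lfp$time) + 1 / tf_lfp$fs))
  tt$time <- tf_lfp$time
  tf_mov <- wavelet_transform(tt, channel = 1, freqs = tf_lfp$freqs,
                              cycles = tf_lfp$cycles)
  event_coherence(tf_lfp, tf_mov, onset = onset, mode = mode,
                  n_cycles = n_cycles)
}

#' Coherence-based linear predictor of protraction amplitude
#'
#' Least-squares regression of per-trial protraction amplitudes on
#' per-trial coherence features over the frequency grid, with optional
#' ridge regularization and leave-one-out cross-validation.
#'
#' @param features Trial x frequency feature matrix (see
#'   [trial_coherence_features()]).
#' @param amplitudes Per-trial protraction amplitudes (degrees).
#' @param ridge Ridge penalty `lambda` (0 = ordinary least squares;
#'   required positive when trials < 2 x features).
#' @param cv `"loo"` (leave-one-trial-out, default) or `"none"`.
#' @return A `predictor_model`: `weights` (per frequency), `intercept`,
#'   `r2_train`, `r2_cv`, `freqs`, `fitted`, `cv_predictions`.
#' @export
fit_coherence_predictor <- function(features, amplitudes, ridge = 0,
                                    cv = c("loo", "none")) {
  cv <- match.arg(cv)
  features <- as.matrix(features)
  K <- nrow(features)
  F <- ncol(features)
  ct_assert(length(amplitudes) == K, "one amplitude per trial required")
  if (K < 2 * F && ridge <= 0) {
    ct_stop(paste0(
      "under-determined design (%d trials for %d frequency features): ",
      "enable ridge regularization (ridge > 0)"), K, F)
  }
  fit_once <- function(X, y) {
    mx <- colMeans(X)
    my <- mean(y)
    Xc <- sweep(X, 2, mx)
    G <- crossprod(Xc) + diag(ridge, F)
    beta <- tryCatch(solve(G, crossprod(Xc, y - my)),
                     error = function(e) {
                       ct_stop(paste0(
                         "singular design without regularization: ",
                         "enable ridge (ridge > 0)"))
                     })
    list(beta = as.numeric(beta), intercept = my - sum(mx * beta))
  }
  full <- fit_once(features, amplitudes)
  fitted <- as.numeric(features %*% full$beta) + full$intercept
  sst <- sum((amplitudes - mean(amplitudes))^2)
  r2_train <- 1 - sum((amplitudes - fitted)^2) / sst
  cv_pred <- rep(NA_real_, K)
  r2_cv <- NA_real_
  if (cv == "loo") {
    for (k in seq_len(K)) {
      fk <- fit_once(features[-k, , drop = FALSE], amplitudes[-k])
      cv_pred[k] <- sum(features[k, ] * fk$beta) + fk$intercept
    }
    r2_cv <- 1 - sum((amplitudes - cv_pred)^2) / sst
  }
  structure(
    list(weights = full$beta, intercept = full$intercept,
         r2_train = r2_train, r2_cv = r2_cv,
         freqs = attr(features, "freqs"), ridge = ridge,
         fitted = fitted, cv_predictions = cv_pred, n_trials = K),
    class = "predictor_model"
  )
}

#' Apply a fitted predictor to new trials
#'
#' Supports cross-condition transfer: a model trained on one condition's
#' features evaluated on another condition's trials.
#'
#' @param model A `predictor_model`.
#' @param features Trial x frequency matrix (same grid as training).
#' @param amplitudes Optional true amplitudes; when given, transfer R^2 is
#'   reported.
#' @return List with `predictions` and (optionally) `r2`.
#' @export
apply_predictor <- function(model, features, amplitudes = NULL) {
  ct_assert(inherits(model, "predictor_model"), "model must be a predictor_model")
  features <- as.matrix(features)
  ct_assert(ncol(features) == length(model$weights),
            "feature grid mismatch: model has %d weights, features %d columns",
            length(model$weights), ncol(features))
  pred <- as.numeric(features %*% model$weights) + model$intercept
  out <- list(predictions = pred)
  if (!is.null(amplitudes)) {
    sst <- sum((amplitudes - mean(amplitudes))^2)
    out$r2 <- 1 - sum((amplitudes - pred)^2) / sst
  }
  out
}

#' Serialize / load a predictor model as JSON
#'
#' @param model A `predictor_model`.
#' @param path JSON file path.
#' @return `read_predictor()` returns the `predictor_model`.
#' @export
write_predictor <- function(model, path) {
  obj <- list(
    freqs = model$freqs, weights = model$weights,
    intercept = model$intercept, ridge = model$ridge,
    r2_train = model$r2_train, r2_cv = model$r2_cv,
    n_trials = model$n_trials
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(weights = obj$weights, intercept = obj$intercept,
         r2_train = obj$r2_train, r2_cv = obj$r2_cv, freqs = obj$freqs,
         ridge = obj$ridge, fitted = NULL, cv_predictions = NULL,
         n_trials = obj$n_trials),
    class = "predictor_model"
  )
}
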