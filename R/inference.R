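#' Difference-of-coherence (DoC) test
#'
#' Compares two coherence spectra per frequency. Coherences are Fisher
#' z-transformed (`atanh`); the difference is standardized by
#' `sqrt(1/(2 K_A - 2) + 1/(2 K_B - 2))` and squared, giving a chi-squared
#' statistic with one degree of freedom. Two-tailed testing is realized
#' through the squared statistic; at `alpha = 0.05` the critical value is
#' `qchisq(0.95, 1) = 3.84`.
#'
#' @param coh_a,coh_b `coherence_result` objects on the same frequency grid
#'   with recorded trial counts.
#' @param alpha Significance level (default 0.05).
#' @return A `doc_result` data.frame-like list: `freqs`, `delta`
#'   (`C_A - C_B`), `chi2`, `p`, `significant`, trial counts and the
#'   critical value used.
#' @export
#' @examples
#' # identical coherences: delta 0, p 1 everywhere
#' ca <- structure(list(coherence = c(0.4, 0.5), freqs = c(10, 20), K = 50),
#'                 class = "coherence_result")
#' doc_test(ca, ca)$p
doc_test <- function(coh_a, coh_b, alpha = 0.05) {
  ct_assert(inherits(coh_a, "coherence_result") &&
              inherits(coh_b, "coherence_result"),
            "inputs must be coherence_result objects")
  ct_assert(isTRUE(all.equal(coh_a$freqs, coh_b$freqs)),
            "coherence results must share one frequency grid")
  ka <- coh_a$K
  kb <- coh_b$K
  ct_assert(!is.null(ka) && !is.null(kb) && ka >= 2 && kb >= 2,
            "both conditions must record trial counts K >= 2")
  eps <- 1e-12
  za <- atanh(pmin(pmax(coh_a$coherence, 0), 1 - eps))
  zb <- atanh(pmin(pmax(coh_b$coherence, 0), 1 - eps))
  se <- sqrt(1 / (2 * ka - 2) + 1 / (2 * kb - 2))
  z <- (za - zb) / se
  chi2 <- z^2
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  crit <- qchisq(1 - alpha, df = 1)
  structure(
    list(
      freqs = coh_a$freqs,
      delta = coh_a$coherence - coh_b$coherence,
      chi2 = chi2,
      p = p,
      significant = chi2 > crit,
      K_A = ka, K_B = kb, alpha = alpha, critical = crit
    ),
    class = "doc_result"
  )
}

#' @export
print.doc_result <- function(x, ...) {
  cat(sprintf(
    "<doc_result> %d frequencies, K_A=%d K_B=%d, %d significant at alpha=%g (chi2 > %.2f)\n",
    length(x$freqs), x$K_A, x$K_B, sum(x$significant), x$alpha, x$critical
  ))
  invisible(x)
}

#' Convert a DoC result to a table
#'
#' @param x A `doc_result`.
#' @param q FDR level for the Benjamini-Hochberg column.
#' @return data.frame with `f`, `delta`, `chi2`, `p`, `p_adj`, `significant`.
#' @export
doc_table <- function(x, q = 0.05) {
  bh <- bh_correct(x$p, q)
  data.frame(
    f = x$freqs, delta = x$delta, chi2 = x$chi2, p = x$p,
    p_adj = bh$p_adj, significant = x$significant,
    significant_fdr = bh$mask
  )
}

#' Label-permutation DoC test
#'
#' Nonparametric check on [doc_test()]: trials of the two conditions are
#' pooled and condition labels permuted; the null distribution of
#' `|C_A - C_B|` per frequency yields permutation p-values.
#'
#' @param tf_ax,tf_ay Condition A `tf_decomp` pair.
#' @param tf_bx,tf_by Condition B pair (same grid/time axis).
#' @param onset Onset (s) for the two-cycle averaging window.
#' @param n_perm Number of permutations (default 200).
#' @param n_cycles Cycles in the averaging window.
#' @param seed Integer seed for the permutations.
#' @return List with `p` (per frequency), `delta` (observed), `freqs`.
#' @export
doc_permutation <- function(tf_ax, tf_ay, tf_bx, tf_by, onset = 0,
                            n_perm = 200, n_cycles = 2, seed = 1L) {
  check_tf_pair(tf_ax, tf_ay)
  check_tf_pair(tf_bx, tf_by)
  ct_assert(isTRUE(all.equal(tf_ax$freqs, tf_bx$freqs)),
            "conditions must share one frequency grid")
  ka <- dim(tf_ax$coef)[1]
  kb <- dim(tf_bx$coef)[1]
  freqs <- tf_ax$freqs
  nf <- length(freqs)
  p <- numeric(nf)
  delta <- numeric(nf)
  with_seed(seed, {
    for (j in seq_len(nf)) {
      idx <- cycle_window_idx(tf_ax$time, freqs[j], onset, n_cycles, "post")
      xy <- rbind(tf_ax$coef[, j, idx, drop = TRUE] *
                    Conj(tf_ay$coef[, j, idx, drop = TRUE]),
                  tf_bx$coef[, j, idx, drop = TRUE] *
                    Conj(tf_by$coef[, j, idx, drop = TRUE]))
      xx <- rbind(Mod(tf_ax$coef[, j, idx, drop = TRUE])^2,
                  Mod(tf_bx$coef[, j, idx, drop = TRUE])^2)
      yy <- rbind(Mod(tf_ay$coef[, j, idx, drop = TRUE])^2,
                  Mod(tf_by$coef[, j, idx, drop = TRUE])^2)
      if (length(idx) == 1L) {
        xy <- matrix(xy, ncol = 1)
        xx <- matrix(xx, ncol = 1)
        yy <- matrix(yy, ncol = 1)
      }
      coh_split <- function(ia) {
        ib <- setdiff(seq_len(ka + kb), ia)
        ca <- mean(Mod(colSums(xy[ia, , drop = FALSE])) /
                     sqrt(colSums(xx[ia, , drop = FALSE]) *
                            colSums(yy[ia, , drop = FALSE])))
        cb <- mean(Mod(colSums(xy[ib, , drop = FALSE])) /
                     sqrt(colSums(xx[ib, , drop = FALSE]) *
                            colSums(yy[ib, , drop = FALSE])))
        ca - cb
      }
      obs <- coh_split(seq_len(ka))
      null <- vapply(seq_len(n_perm), function(i) {
        coh_split(sample.int(ka + kb, ka))
      }, numeric(1))
      delta[j] <- obs
      p[j] <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
    }
  })
  list(p = p, delta = delta, freqs = freqs, n_perm = n_perm)
}

#' Benjamini-Hochberg correction
#'
#' Step-up false-discovery-rate control. Thin wrapper over
#' `stats::p.adjust(method = "BH")` returning both the rejection mask and
#' the adjusted p-values.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `mask` (logical) and `p_adj`.
#' @export
#' @examples
#' bh_correct(c(0.01, 0.02, 0.03, 0.04, 0.05))$mask
bh_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0) {
    return(list(mask = logical(0), p_adj = numeric(0)))
  }
  ct_assert(all(p_values > 0 & p_values <= 1), "p-values must lie in (0, 1]")
  p_adj <- p.adjust(p_values, method = "BH")
  list(mask = p_adj <= q, p_adj = p_adj)
}

# ---- spectral Granger causality -------------------------------------------

# Fit a bivariate VAR(p) by per-equation OLS over stacked trials.
# x, y: trial x time matrices (demeaned per trial). Returns A (2 x 2 x p)
# and Sigma (2 x 2 innovation covariance).
fit_var <- function(x, y, p) {
  n_trials <- nrow(x)
  nt <- ncol(x)
  ct_assert(nt > 10 * p, "trials too short for VAR order %d", p)
  rows <- (nt - p) * n_trials
  X <- matrix(0, rows, 2 * p)
  Y <- matrix(0, rows, 2)
  r0 <- 0L
  for (k in seq_len(n_trials)) {
    xs <- x[k, ] - mean(x[k, ])
    ys <- y[k, ] - mean(y[k, ])
    tt <- (p + 1):nt
    for (l in seq_len(p)) {
      X[r0 + seq_along(tt), 2 * l - 1] <- xs[tt - l]
      X[r0 + seq_along(tt), 2 * l] <- ys[tt - l]
    }
    Y[r0 + seq_along(tt), 1] <- xs[tt]
    Y[r0 + seq_along(tt), 2] <- ys[tt]
    r0 <- r0 + length(tt)
  }
  B <- tryCatch(qr.solve(X, Y), error = function(e) {
    ct_stop("VAR fit failed (rank-deficient design): %s", conditionMessage(e))
  })
  E <- Y - X %*% B
  Sigma <- crossprod(E) / (rows - 2 * p)
  A <- array(0, dim = c(2, 2, p))
  for (l in seq_len(p)) {
    # row i of B maps predictor i; predictors ordered (x_{t-l}, y_{t-l})
    A[1, 1, l] <- B[2 * l - 1, 1]
    A[1, 2, l] <- B[2 * l, 1]
    A[2, 1, l] <- B[2 * l - 1, 2]
    A[2, 2, l] <- B[2 * l, 2]
  }
  list(A = A, Sigma = Sigma, nobs = rows)
}

var_bic <- function(fit) {
  d <- det(fit$Sigma)
  p <- dim(fit$A)[3]
  log(max(d, .Machine$double.xmin)) + (log(fit$nobs) / fit$nobs) * 4 * p
}

# Check VAR stability via the companion matrix spectral radius.
var_stable <- function(A) {
  p <- dim(A)[3]
  comp <- matrix(0, 2 * p, 2 * p)
  for (l in seq_len(p)) comp[1:2, (2 * l - 1):(2 * l)] <- A[, , l]
  if (p > 1) comp[3:(2 * p), 1:(2 * p - 2)] <- diag(2 * p - 2)
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

# Geweke frequency-domain causality from transfer matrix H(f) and Sigma.
# Returns c(G_xy, G_yx) for one frequency; H indexed [target, source].
geweke_from_H <- function(H, Sigma) {
  Syy <- Re(H[2, , drop = FALSE] %*% Sigma %*% Conj(t(H[2, , drop = FALSE])))
  Sxx <- Re(H[1, , drop = FALSE] %*% Sigma %*% Conj(t(H[1, , drop = FALSE])))
  s2_x_given_y <- Sigma[1, 1] - Sigma[1, 2]^2 / Sigma[2, 2]
  s2_y_given_x <- Sigma[2, 2] - Sigma[1, 2]^2 / Sigma[1, 1]
  g_xy <- log(Syy / pmax(Syy - s2_x_given_y * Mod(H[2, 1])^2,
                         .Machine$double.eps))
  g_yx <- log(Sxx / pmax(Sxx - s2_y_given_x * Mod(H[1, 2])^2,
                         .Machine$double.eps))
  c(max(g_xy, 0), max(g_yx, 0))
}

granger_from_var <- function(A, Sigma, freqs, fs) {
  p <- dim(A)[3]
  gxy <- numeric(length(freqs))
  gyx <- numeric(length(freqs))
  for (i in seq_along(freqs)) {
    Af <- diag(2) + 0i
    for (l in seq_len(p)) {
      Af <- Af - A[, , l] * exp(-2i * pi * freqs[i] * l / fs)
    }
    H <- solve(Af)
    g <- geweke_from_H(H, Sigma)
    gxy[i] <- g[1]
    gyx[i] <- g[2]
  }
  list(gxy = gxy, gyx = gyx)
}

# Trial-averaged cross-spectral density on a uniform grid of nfft points
# (full circle). Hann taper per trial, then light Daniell smoothing across
# frequency (stabilizes the factorization).
csd_matrix <- function(x, y, nfft, smooth = 5L) {
  n_trials <- nrow(x)
  nt <- ncol(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nt) / (nt + 1))
  u <- sum(w^2)
  S <- array(0i, dim = c(2, 2, nfft))
  for (k in seq_len(n_trials)) {
    xs <- (x[k, ] - mean(x[k, ])) * w
    ys <- (y[k, ] - mean(y[k, ])) * w
    xf <- fft(c(xs, numeric(nfft - nt)))
    yf <- fft(c(ys, numeric(nfft - nt)))
    S[1, 1, ] <- S[1, 1, ] + xf * Conj(xf)
    S[1, 2, ] <- S[1, 2, ] + xf * Conj(yf)
    S[2, 1, ] <- S[2, 1, ] + yf * Conj(xf)
    S[2, 2, ] <- S[2, 2, ] + yf * Conj(yf)
  }
  S <- S / (n_trials * u)
  if (smooth > 1) {
    kernel <- rep(1 / smooth, smooth)
    circ_ma <- function(v) {
      ext <- c(tail(v, smooth), v, head(v, smooth))
      sm <- as.numeric(stats::filter(ext, kernel, sides = 2))
      sm[smooth + seq_len(nfft)]
    }
    for (a in 1:2) for (b in 1:2) {
      # moving average across the frequency circle (filter() is real-only,
      # so smooth the real and imaginary parts separately)
      v <- S[a, b, ]
      S[a, b, ] <- complex(real = circ_ma(Re(v)), imaginary = circ_ma(Im(v)))
    }
  }
  S
}

# Wilson's spectral matrix factorization: S(f) = H(f) Sigma H(f)^H with H
# minimum-phase, H(0-lag) = I. S is 2 x 2 x nfft on the full frequency
# circle. Iterative algorithm; returns psi (2 x 2 x nfft), H, Sigma.
wilson_factorize <- function(S, max_iter = 100, tol = 1e-9) {
  nfft <- dim(S)[3]
  # regularize: guarantee positive definiteness at every frequency
  avg_pow <- mean(Re(S[1, 1, ]) + Re(S[2, 2, ])) / 2
  for (j in seq_len(nfft)) {
    S[, , j] <- S[, , j] + diag(2) * avg_pow * 1e-8
  }
  Sm <- matrix(0, 2, 2)
  for (j in seq_len(nfft)) Sm <- Sm + Re(S[, , j])
  Sm <- Sm / nfft
  psi0 <- chol(Sm)  # upper triangular, matching the plus-operator convention
  psi <- array(0i, dim = c(2, 2, nfft))
  for (j in seq_len(nfft)) psi[, , j] <- psi0

  half <- floor(nfft / 2)
  plus_op <- function(g) {
    # causal part across the frequency circle: positive lags kept, negative
    # lags zeroed, and the zero lag replaced by the upper-triangular half
    # (Wilson's boundary condition, keeping the factor minimum-phase)
    gc <- array(0i, dim = dim(g))
    for (a in 1:2) for (b in 1:2) {
      gc[a, b, ] <- fft(g[a, b, ], inverse = TRUE) / nfft
    }
    c0 <- gc[, , 1] / 2
    c0[2, 1] <- 0            # keep triu(c0), 2x2 case
    gc[, , 1] <- c0
    if (half + 2 <= nfft) gc[, , (half + 2):nfft] <- 0i
    out <- array(0i, dim = dim(g))
    for (a in 1:2) for (b in 1:2) {
      out[a, b, ] <- fft(gc[a, b, ])
    }
    out
  }

  err_prev <- Inf
  for (iter in seq_len(max_iter)) {
    g <- array(0i, dim = c(2, 2, nfft))
    for (j in seq_len(nfft)) {
      pj <- psi[, , j]
      pinv <- tryCatch(solve(pj), error = function(e) NULL)
      if (is.null(pinv)) {
        ct_stop("spectral factorization failed: singular factor at frequency bin %d", j)
      }
      g[, , j] <- pinv %*% S[, , j] %*% Conj(t(pinv)) + diag(2)
    }
    gp <- plus_op(g)
    psi_new <- array(0i, dim = c(2, 2, nfft))
    err <- 0
    for (j in seq_len(nfft)) {
      psi_new[, , j] <- psi[, , j] %*% gp[, , j]
      err <- max(err, max(Mod(psi_new[, , j] - psi[, , j])))
    }
    psi <- psi_new
    if (err < tol || abs(err_prev - err) < tol * 1e-2) break
    err_prev <- err
  }
  # psi0 = causal lag-0 coefficient
  p0 <- matrix(0i, 2, 2)
  for (j in seq_len(nfft)) p0 <- p0 + psi[, , j]
  p0 <- p0 / nfft
  p0 <- Re(p0)
  Sigma <- p0 %*% t(p0)
  H <- array(0i, dim = c(2, 2, nfft))
  p0inv <- solve(p0)
  for (j in seq_len(nfft)) H[, , j] <- psi[, , j] %*% p0inv
  list(psi = psi, H = H, Sigma = Sigma, n_iter = iter, err = err)
}

#' Spectral Granger causality
#'
#' Frequency-resolved Geweke causality between two sets of paired trials.
#' The `"var"` backend fits a bivariate vector autoregression by
#' least-squares over stacked trials (order selected by BIC, capped at
#' `max_order`) and decomposes its spectrum; the `"nonparametric"` backend
#' factorizes the trial-averaged cross-spectral density with Wilson's
#' algorithm, avoiding any model-order choice.
#'
#' @param trials_x,trials_y Trial x time numeric matrices (equal shapes), or
#'   vectors for a single trial.
#' @param fs Sampling rate (Hz).
#' @param freqs Frequency grid (Hz) on which to report causality.
#' @param method `"var"` (default) or `"nonparametric"`.
#' @param order VAR order; `NULL` selects by BIC.
#' @param max_order BIC search cap (default 20).
#' @param nfft FFT grid size for the nonparametric backend.
#' @return A `granger_result`: `gxy` (`x -> y`), `gyx`, `freqs`, `method`,
#'   plus backend diagnostics (`order`, `Sigma`, spectral radius or
#'   factorization error).
#' @export
granger_spectrum <- function(trials_x, trials_y, fs,
                             freqs = default_freq_grid(),
                             method = c("var", "nonparametric"),
                             order = NULL, max_order = 20, nfft = 512) {
  method <- match.arg(method)
  if (is.vector(trials_x)) trials_x <- matrix(trials_x, nrow = 1)
  if (is.vector(trials_y)) trials_y <- matrix(trials_y, nrow = 1)
  ct_assert(identical(dim(trials_x), dim(trials_y)),
            "paired trials must have identical shapes")
  ct_assert(max(freqs) <= fs / 2, "frequency grid exceeds Nyquist")

  if (method == "var") {
    p_use <- order
    if (is.null(p_use)) {
      best <- Inf
      p_use <- 1L
      for (p in seq_len(max_order)) {
        if (ncol(trials_x) <= 10 * p) break
        fit <- fit_var(trials_x, trials_y, p)
        b <- var_bic(fit)
        if (b < best - 1e-10) {
          best <- b
          p_use <- p
        }
      }
    }
    fit <- fit_var(trials_x, trials_y, p_use)
    rho <- var_stable(fit$A)
    if (rho >= 1) {
      ct_stop("estimated VAR(%d) is unstable (spectral radius %.3f)", p_use, rho)
    }
    g <- granger_from_var(fit$A, fit$Sigma, freqs, fs)
    res <- list(gxy = g$gxy, gyx = g$gyx, freqs = freqs, method = "var",
                order = p_use, Sigma = fit$Sigma, spectral_radius = rho)
  } else {
    S <- csd_matrix(trials_x, trials_y, nfft)
    fac <- wilson_factorize(S)
    f_grid <- (seq_len(nfft) - 1) * fs / nfft
    gxy_grid <- numeric(nfft)
    gyx_grid <- numeric(nfft)
    half <- floor(nfft / 2) + 1L
    for (j in seq_len(half)) {
      g <- geweke_from_H(fac$H[, , j], fac$Sigma)
      gxy_grid[j] <- g[1]
      gyx_grid[j] <- g[2]
    }
    idx <- seq_len(half)
    gxy <- approx(f_grid[idx], gxy_grid[idx], xout = freqs, rule = 2)$y
    gyx <- approx(f_grid[idx], gyx_grid[idx], xout = freqs, rule = 2)$y
    res <- list(gxy = gxy, gyx = gyx, freqs = freqs,
                method = "nonparametric", Sigma = fac$Sigma,
                factorization = list(n_iter = fac$n_iter, err = fac$err))
  }
  structure(res, class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf(
    "<granger_result> method=%s, %d frequencies; mean G_xy=%.4f, mean G_yx=%.4f\n",
    x$method, length(x$freqs), mean(x$gxy), mean(x$gyx)
  ))
  invisible(x)
}

#' Trial-shuffle null for Granger causality
#'
#' Breaks the x-y pairing by circularly shifting the trial order of `y`,
#' recomputing the causality spectrum for each shift. Used as the null
#' reference: observed causality below the null's upper quantile is
#' indistinguishable from chance.
#'
#' @inheritParams granger_spectrum
#' @param n_shuffle Number of trial shuffles (default 20; needs more trials
#'   than shuffles).
#' @param probs Null quantile(s) to report (default 0.95).
#' @return List with `gxy_null`/`gyx_null` quantiles per frequency.
#' @export
granger_null <- function(trials_x, trials_y, fs,
                         freqs = default_freq_grid(),
                         method = "var", n_shuffle = 20, probs = 0.95, ...) {
  n_trials <- nrow(trials_x)
  ct_assert(n_trials >= 3, "need >= 3 trials for a shuffle null")
  n_shuffle <- min(n_shuffle, n_trials - 1)
  gxy <- matrix(0, n_shuffle, length(freqs))
  gyx <- matrix(0, n_shuffle, length(freqs))
  for (s in seq_len(n_shuffle)) {
    sh <- granger_spectrum(trials_x,
                           trials_y[c((s + 1):n_trials, 1:s), , drop = FALSE],
                           fs, freqs, method = method, ...)
    gxy[s, ] <- sh$gxy
    gyx[s, ] <- sh$gyx
  }
  list(
    gxy_null = apply(gxy, 2, quantile, probs = probs),
    gyx_null = apply(gyx, 2, quantile, probs = probs),
    freqs = freqs, n_shuffle = n_shuffle
  )
}
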