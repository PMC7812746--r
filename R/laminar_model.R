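# Firing-rate model of the cortico-thalamo-cerebellar loop.
#
# Populations (15): trigeminal nuclei (TN); thalamic relays VPM, Pom, VL;
# zona incerta (ZI); cerebellar Purkinje cells (PC) and nuclei (CN); and,
# per cortical area (S1, M1), supragranular and infragranular
# excitatory-inhibitory pairs (S1sE/S1sI/S1iE/S1iI, same for M1).
# Dynamics: tau dr/dt = -r + phi(W r + I_ext - g_a a + sigma xi(t)),
# with rate-tracking adaptation tau_a da/dt = r - a (cerebellar nuclei
# only, producing post-inhibitory rebound), and transfer function
# phi(x) = x / (1 - exp(-x)).

CT_POPULATIONS <- c("TN", "VPM", "Pom", "VL", "ZI", "PC", "CN",
                    "S1sE", "S1sI", "S1iE", "S1iI",
                    "M1sE", "M1sI", "M1iE", "M1iI")

CT_INHIBITORY <- c("PC", "ZI", "S1sI", "S1iI", "M1sI", "M1iI")

#' Transfer function of the rate model
#'
#' `phi(x) = x / (1 - exp(-x))`: smooth, strictly positive, with
#' `phi(0) = 1`, slope 1/2 at the origin and asymptotically linear for
#' large drive.
#'
#' @param x Numeric input (net drive).
#' @return `phi(x)`, elementwise.
#' @export
rate_phi <- function(x) {
  out <- x / (1 - exp(-x))
  small <- abs(x) < 1e-8
  if (any(small)) out[small] <- 1 + x[small] / 2
  # exp overflow for very negative x yields 0/Inf = NaN; the limit is 0
  out[is.nan(out) & x < 0] <- 0
  out
}

# Derivative of phi (used by documentation/diagnostics, not the solver).
rate_phi_prime <- function(x, h = 1e-6) {
  (rate_phi(x + h) - rate_phi(x - h)) / (2 * h)
}

# Default per-population parameters. Time constants follow the laminar
# convention that superficial E-I pairs resonate in the gamma band
# (tauE 6 ms, tauI 8 ms) and deep pairs at theta/alpha (tauE 30 ms,
# tauI 75 ms); subcortical relays use 10 ms.
default_populations <- function() {
  pops <- data.frame(
    name = CT_POPULATIONS,
    tau = c(rep(0.010, 7),
            0.006, 0.008, 0.030, 0.075,
            0.006, 0.008, 0.030, 0.075),
    noise_sd = c(0.08, 0.08, 0.40, 0.026, 0.08, 0.08, 0.20,
                 0.08, 0.08, 0.08, 0.08,
                 0.08, 0.08, 0.08, 0.08),
    baseline_drive = c(0.5, 0.3, 0.3, 0.3, 0.89, 0.5, 1.67,
                       0.5, 0.0, 1.2, 0.0,
                       0.5, 0.0, 1.2, 0.0),
    g_a = c(rep(0, 6), 1.0, rep(0, 8)),
    tau_a = c(rep(0.08, 15)),
    stringsAsFactors = FALSE
  )
  pops$inhibitory <- pops$name %in% CT_INHIBITORY
  pops
}

# Default signed connection weights as an edge list (source -> target).
# Intra-module cortical weights give underdamped E-I resonance; the
# cross-structure weights implement the anatomical loop: trigeminal input
# to thalamus and cerebellum, Purkinje inhibition of the nuclei, nuclear
# excitation of VL/ZI/Pom, incertal inhibition of Pom, thalamocortical
# projections (VPM to superficial S1; Pom to superficial+deep S1 and
# superficial M1; VL to M1), and cortico-cortical links (deep S1 to
# superficial M1, deep M1 to superficial S1, optional reciprocal
# superficial S1-M1 loop).
default_edges <- function(s1_m1_superficial_loop = TRUE,
                          m1_to_zi = FALSE) {
  e <- list(
    # cortical modules (per area, per layer): E-I pairs
    c("S1sE", "S1sE", 2.0), c("S1sI", "S1sE", -4.42),
    c("S1sE", "S1sI", 3.27), c("S1sI", "S1sI", -1.0),
    c("S1iE", "S1iE", 1.5), c("S1iI", "S1iE", -3.0),
    c("S1iE", "S1iI", 2.0), c("S1iI", "S1iI", -1.5),
    c("M1sE", "M1sE", 2.0), c("M1sI", "M1sE", -4.42),
    c("M1sE", "M1sI", 3.27), c("M1sI", "M1sI", -1.0),
    c("M1iE", "M1iE", 1.5), c("M1iI", "M1iE", -3.0),
    c("M1iE", "M1iI", 2.0), c("M1iI", "M1iI", -1.5),
    # intra-areal laminar coupling
    c("S1sE", "S1iE", 0.5), c("M1sE", "M1iE", 0.5),
    # trigeminal fan-out (incl. mossy-fiber collaterals to CN and the
    # mossy -> granule -> PC pathway)
    c("TN", "VPM", 0.51), c("TN", "Pom", 0.50),
    c("TN", "PC", 0.10), c("TN", "CN", 0.64),
    # cerebellar core
    c("PC", "CN", -1.64),
    c("CN", "VL", 3.0), c("CN", "ZI", 1.20), c("CN", "Pom", 0.45),
    # incertal inhibition of the paralemniscal relay
    c("ZI", "Pom", -0.66),
    # thalamocortical (Pom terminals reach both the supragranular E and I
    # populations and the deep E population)
    c("VPM", "S1sE", 0.80), c("VPM", "S1sI", 0.07),
    c("Pom", "S1sE", 1.18), c("Pom", "S1sI", 0.10), c("Pom", "S1iE", 0.26),
    c("Pom", "M1sE", 1.31), c("Pom", "M1sI", 0.08),
    c("VL", "M1sE", 2.61), c("VL", "M1iE", 0.10),
    # cortico-cortical
    c("S1iE", "M1sE", 0.10), c("M1iE", "S1sE", 0.05)
  )
  if (s1_m1_superficial_loop) {
    e <- c(e, list(c("S1sE", "M1sE", 1.2), c("M1sE", "S1sE", 1.2)))
  }
  if (m1_to_zi) {
    e <- c(e, list(c("M1sE", "ZI", 0.3)))
  }
  e
}

#' Build the cortico-thalamo-cerebellar network
#'
#' Assembles a `network_spec`: population parameters and the signed
#' connection-weight matrix `W` (indexed `W[target, source]`). Inhibitory
#' sources (Purkinje cells, zona incerta, cortical I populations) may only
#' carry non-positive outgoing weights; excitatory sources only
#' non-negative ones -- violations are rejected.
#'
#' @param edges Optional edge list replacing the defaults; each element
#'   `c(source, target, weight)`. Use [default_edges()] as a starting
#'   point for ablations.
#' @param populations Optional data.frame overriding
#'   `default_populations()` (same columns).
#' @param s1_m1_superficial_loop Include the reciprocal superficial
#'   S1-M1 connection (default TRUE).
#' @param m1_to_zi Include a motor-cortical projection to the zona incerta
#'   (default FALSE).
#' @param dt Integration step (s), default 0.2 ms.
#' @param seed Default integer seed for simulations.
#' @return A `network_spec` list: `populations`, `W`, `dt`, `seed`.
#' @export
#' @examples
#' net <- build_network()
#' net$W["Pom", "ZI"] < 0  # incertal projection is GABAergic
build_network <- function(edges = NULL, populations = NULL,
                          s1_m1_superficial_loop = TRUE, m1_to_zi = FALSE,
                          dt = 2e-4, seed = 1L) {
  pops <- if (is.null(populations)) default_populations() else populations
  ct_assert(all(c("name", "tau", "noise_sd", "baseline_drive", "g_a",
                  "tau_a", "inhibitory") %in% names(pops)),
            "populations must carry name/tau/noise_sd/baseline_drive/g_a/tau_a/inhibitory")
  ct_assert(all(pops$tau > 0), "all time constants must be positive")
  ct_assert(all(pops$noise_sd >= 0), "noise_sd must be non-negative")
  ct_assert(all(pops$tau_a[pops$g_a != 0] > 0),
            "adapting populations need tau_a > 0")
  if (is.null(edges)) {
    edges <- default_edges(s1_m1_superficial_loop, m1_to_zi)
  }
  n <- nrow(pops)
  W <- matrix(0, n, n, dimnames = list(pops$name, pops$name))
  for (e in edges) {
    ct_assert(length(e) == 3, "each edge must be c(source, target, weight)")
    src <- as.character(e[1])
    tgt <- as.character(e[2])
    w <- as.numeric(e[3])
    ct_assert(src %in% pops$name, "unknown source population '%s'", src)
    ct_assert(tgt %in% pops$name, "unknown target population '%s'", tgt)
    inh <- pops$inhibitory[pops$name == src]
    if (inh && w > 0) {
      ct_stop("sign violation: inhibitory source %s cannot have positive weight to %s",
              src, tgt)
    }
    if (!inh && w < 0) {
      ct_stop("sign violation: excitatory source %s cannot have negative weight to %s",
              src, tgt)
    }
    W[tgt, src] <- w
  }
  structure(
    list(populations = pops, W = W, dt = dt, seed = as.integer(seed)),
    class = "network_spec"
  )
}

#' Stimulation protocol
#'
#' Air-puff input drives the trigeminal nuclei; optogenetic-like Purkinje
#' stimulation drives PC. `delay` postpones the PC stimulus relative to the
#' air puff (0 or 0.02 s in the experimental conditions). In
#' `"steady_state"` mode both drives are constant over the whole
#' simulation.
#'
#' @param air_amp,pc_amp Drive amplitudes (0 disables a stimulus).
#' @param air_onset,air_duration Air-puff timing (s), pulse mode.
#' @param pc_onset,pc_duration PC stimulus timing (s); default duration
#'   0.1 s, the standard optogenetic burst length.
#' @param delay Extra delay (s) added to `pc_onset`.
#' @param mode `"pulse"` or `"steady_state"`.
#' @return A `stimulus_protocol` list.
#' @export
stimulus_protocol <- function(air_amp = 0, air_onset = 0.5,
                              air_duration = 0.05, pc_amp = 0,
                              pc_onset = 0.5, pc_duration = 0.1,
                              delay = 0, mode = c("pulse", "steady_state")) {
  mode <- match.arg(mode)
  ct_assert(air_duration > 0 && pc_duration > 0, "durations must be positive")
  ct_assert(delay >= 0, "delay must be >= 0")
  structure(
    list(air_amp = air_amp, air_onset = air_onset,
         air_duration = air_duration, pc_amp = pc_amp,
         pc_onset = pc_onset + delay, pc_duration = pc_duration,
         delay = delay, mode = mode),
    class = "stimulus_protocol"
  )
}

# External drive matrix (time step x population) for a protocol.
protocol_drive <- function(network, protocol, n_steps) {
  pops <- network$populations
  dt <- network$dt
  drive <- matrix(rep(pops$baseline_drive, each = n_steps), n_steps,
                  nrow(pops))
  colnames(drive) <- pops$name
  t_axis <- (seq_len(n_steps) - 1) * dt
  if (protocol$mode == "steady_state") {
    drive[, "TN"] <- drive[, "TN"] + protocol$air_amp
    drive[, "PC"] <- drive[, "PC"] + protocol$pc_amp
  } else {
    if (protocol$air_amp != 0) {
      on <- t_axis >= protocol$air_onset &
        t_axis < protocol$air_onset + protocol$air_duration
      drive[on, "TN"] <- drive[on, "TN"] + protocol$air_amp
    }
    if (protocol$pc_amp != 0) {
      on <- t_axis >= protocol$pc_onset &
        t_axis < protocol$pc_onset + protocol$pc_duration
      drive[on, "PC"] <- drive[on, "PC"] + protocol$pc_amp
    }
  }
  drive
}

#' Simulate the network
#'
#' Euler-Maruyama integration of
#' `tau dr/dt = -r + phi(W r + I_ext(t) - g_a a + sigma xi)`, with white
#' noise `xi` inside the transfer-function argument. The noise is
#' discretized as `N(0, 1) * sqrt(2e-4 / dt)`, i.e. its spectral density
#' is referenced to the default 0.2 ms step, so halving `dt` leaves the
#' physical noise spectrum (and hence rate fluctuations) unchanged while
#' keeping the argument excursions small enough that the transfer
#' function operates near its local slope. Includes rate-tracking
#' adaptation `tau_a da/dt = r - a` for adapting populations. Rates are
#' clipped at zero; NaN or runaway trajectories abort with the name of the
#' first diverging population.
#'
#' @param network A `network_spec` from [build_network()].
#' @param protocol A [stimulus_protocol()].
#' @param duration Simulated time (s).
#' @param seed Integer seed (default from the network spec).
#' @param r0 Initial rates (default: the noise-free fixed point under
#'   baseline drive, so simulations start equilibrated).
#' @return A `sim_result`: `rates` (time x population), `time`, `dt`,
#'   `protocol`, `seed`.
#' @export
simulate_network <- function(network, protocol, duration = 2,
                             seed = network$seed, r0 = NULL) {
  ct_assert(inherits(network, "network_spec"), "network must be a network_spec")
  ct_assert(inherits(protocol, "stimulus_protocol"),
            "protocol must be a stimulus_protocol")
  pops <- network$populations
  dt <- network$dt
  ct_assert(dt < min(pops$tau) / 5,
            "dt = %g s is too coarse: must be below min(tau)/5 = %g s",
            dt, min(pops$tau) / 5)
  n_steps <- round(duration / dt)
  n_pop <- nrow(pops)
  drive <- protocol_drive(network, protocol, n_steps)
  if (is.null(r0)) {
    ss <- steady_state_rates(network)
    r0 <- ss$rates
  }
  tau <- pops$tau
  g_a <- pops$g_a
  tau_a <- pops$tau_a
  # white argument noise with spectral density referenced to the default
  # 0.2 ms step: at dt = 2e-4 the per-step sd equals noise_sd, and refining
  # dt preserves the physical noise spectrum
  sig <- pops$noise_sd * sqrt(2e-4 / dt)
  adapting <- which(g_a != 0)
  W <- network$W

  rates <- matrix(0, n_steps, n_pop, dimnames = list(NULL, pops$name))
  r <- r0
  a <- r0
  noise <- with_seed(seed, {
    if (any(sig > 0)) {
      matrix(rnorm(n_steps * n_pop), n_steps, n_pop) *
        rep(sig, each = n_steps)
    } else {
      matrix(0, n_steps, n_pop)
    }
  })
  dt_tau <- dt / tau
  for (i in seq_len(n_steps)) {
    u <- as.numeric(W %*% r) + drive[i, ] + noise[i, ]
    if (length(adapting)) u[adapting] <- u[adapting] - g_a[adapting] * a[adapting]
    r <- r + dt_tau * (-r + rate_phi(u))
    if (any(!is.finite(r)) || any(r > 1e6)) {
      bad <- which(!is.finite(r) | r > 1e6)[1]
      ct_stop("simulation diverged at t = %.4f s in population %s",
              i * dt, pops$name[bad])
    }
    r[r < 0] <- 0
    if (length(adapting)) {
      a[adapting] <- a[adapting] +
        (dt / tau_a[adapting]) * (r[adapting] - a[adapting])
    }
    rates[i, ] <- r
  }
  structure(
    list(rates = rates, time = (seq_len(n_steps) - 1) * dt, dt = dt,
         protocol = protocol, seed = seed),
    class = "sim_result"
  )
}

#' Noise-free steady-state rates
#'
#' Finds the fixed point of `r = phi(W r + I - g_a r)` (adaptation at its
#' own fixed point `a = r`) by damped iteration.
#'
#' @param network A `network_spec`.
#' @param constant_inputs Optional named vector of external drives
#'   (defaults to the populations' `baseline_drive`); names are population
#'   names, missing entries keep their baseline.
#' @param eta Damping factor of the iteration (default 0.2).
#' @param tol Convergence tolerance on `max |r_new - r|` (default 1e-12).
#' @param max_iter Iteration cap (default 50000).
#' @return List with `rates` (named vector), `converged`, `n_iter`.
#' @export
steady_state_rates <- function(network, constant_inputs = NULL, eta = 0.2,
                               tol = 1e-12, max_iter = 50000) {
  pops <- network$populations
  I <- pops$baseline_drive
  names(I) <- pops$name
  if (!is.null(constant_inputs)) {
    ct_assert(!is.null(names(constant_inputs)),
              "constant_inputs must be a named vector")
    ct_assert(all(names(constant_inputs) %in% pops$name),
              "constant_inputs names must be population names")
    I[names(constant_inputs)] <- constant_inputs
  }
  r <- rep(1, nrow(pops))
  g_a <- pops$g_a
  W <- network$W
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    r_new <- (1 - eta) * r + eta * rate_phi(as.numeric(W %*% r) + I - g_a * r)
    if (max(abs(r_new - r)) < tol) {
      r <- r_new
      converged <- TRUE
      break
    }
    r <- r_new
  }
  if (!converged) {
    warning("steady-state iteration did not converge within max_iter",
            call. = FALSE)
  }
  names(r) <- pops$name
  list(rates = r, converged = converged, n_iter = i)
}

#' LFP proxy of a laminar module
#'
#' Returns the mean-subtracted excitatory-population rate of one laminar
#' module, the model-side stand-in for that module's LFP.
#'
#' @param sim A `sim_result`.
#' @param area `"S1"` or `"M1"` (or a full population name in `layer`'s
#'   place).
#' @param layer `"supra"` or `"infra"`.
#' @return Numeric vector (mean-subtracted rate trace).
#' @export
lfp_proxy <- function(sim, area, layer = NULL) {
  ct_assert(inherits(sim, "sim_result"), "sim must be a sim_result")
  pop <- if (is.null(layer)) {
    area
  } else {
    ct_assert(area %in% c("S1", "M1"), "unknown area '%s'", area)
    ct_assert(layer %in% c("supra", "infra"), "unknown layer '%s'", layer)
    paste0(area, substr(layer, 1, 1), "E")
  }
  if (!pop %in% colnames(sim$rates)) {
    ct_stop("unknown population/area-layer '%s'", pop)
  }
  x <- sim$rates[, pop]
  x - mean(x)
}

#' Simulate repeated stimulated trials
#'
#' Runs `n_trials` independent noise realizations of a fixed-duration
#' stimulated epoch and collects the requested LFP proxies into a
#' [trial_tensor]. Each trial gets a seed derived from `seed` and starts at
#' the noise-free fixed point; an initial `burn` period is discarded so
#' trials are stationary.
#'
#' @param network A `network_spec`.
#' @param protocol A [stimulus_protocol()].
#' @param n_trials Number of trials.
#' @param duration Analyzed epoch length (s) per trial.
#' @param proxies List of `c(area, layer)` pairs defining the channels.
#' @param burn Discarded initialization time (s, default 0.5).
#' @param downsample Keep every k-th sample via block averaging (default
#'   10, i.e. 500 Hz at the default dt).
#' @param seed Integer seed.
#' @param condition Condition label for the tensor.
#' @return A [trial_tensor], channels ordered as `proxies`.
#' @export
model_trials <- function(network, protocol, n_trials = 100, duration = 2,
                         proxies = list(c("S1", "infra"), c("M1", "supra")),
                         burn = 0.5, downsample = 10L,
                         seed = network$seed, condition = "model") {
  dt <- network$dt
  n_keep <- round(duration / (dt * downsample))
  ss <- steady_state_rates(network)
  out <- array(0, dim = c(n_trials, length(proxies), n_keep))
  for (k in seq_len(n_trials)) {
    sim <- simulate_network(network, protocol, duration = duration + burn,
                            seed = child_seed(seed, k), r0 = ss$rates)
    keep <- sim$time >= burn
    for (j in seq_along(proxies)) {
      x <- lfp_proxy(sim, proxies[[j]][1], proxies[[j]][2])[keep]
      n_full <- n_keep * downsample
      x <- x[seq_len(n_full)]
      out[k, j, ] <- colMeans(matrix(x, nrow = downsample))
    }
  }
  fs <- 1 / (dt * downsample)
  trial_tensor(out, fs = fs, window = c(0, n_keep / fs),
               condition = rep(condition, n_trials),
               channels = data.frame(
                 channel = seq_along(proxies),
                 depth_um = seq_along(proxies) * 100,
                 area = vapply(proxies, `[`, "", 1)
               ))
}
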