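test_that("network construction enforces anatomy and sign constraints", {
  net <- build_network()
  expect_lt(net$W["Pom", "ZI"], 0)   # GABAergic incertal projection
  expect_lt(net$W["CN", "PC"], 0)    # Purkinje inhibition of the nuclei
  expect_gt(net$W["VL", "CN"], 0)
  expect_gt(net$W["S1sE", "VPM"], 0)
  expect_error(build_network(edges = list(c("PC", "CN", 1))),
               "sign violation")
  expect_error(build_network(edges = list(c("TN", "VPM", -1))),
               "sign violation")
  expect_error(build_network(edges = list(c("XX", "VPM", 1))),
               "unknown source")
})

test_that("zeroing inter-population weights isolates the E-I modules", {
  ed <- Filter(function(e) {
    # keep only intra-module E-I edges
    src <- substr(e[1], 1, 3)
    tgt <- substr(e[2], 1, 3)
    src == tgt && nchar(e[1]) == 4 && nchar(e[2]) == 4
  }, default_edges())
  net <- build_network(edges = ed)
  W <- net$W
  blocks <- list(c("S1sE", "S1sI"), c("S1iE", "S1iI"),
                 c("M1sE", "M1sI"), c("M1iE", "M1iI"))
  for (b in blocks) {
    others <- setdiff(colnames(W), b)
    expect_true(all(W[b, others] == 0))
    expect_true(all(W[others, b] == 0))
  }
})

test_that("targeted ablation zeroes only the requested edge", {
  full <- build_network()
  ablated <- build_network(s1_m1_superficial_loop = FALSE)
  expect_gt(full$W["M1sE", "S1sE"], 0)
  expect_equal(ablated$W["M1sE", "S1sE"], 0)
  expect_equal(ablated$W["S1sE", "M1sE"], 0)
  keep <- !(rownames(full$W) == "M1sE" & FALSE)
  diff_mask <- full$W != ablated$W
  expect_equal(sum(diff_mask), 2)
})

test_that("uniform fixed point: zero coupling and drive gives rates phi(0)", {
  pops <- default_populations()
  pops$noise_sd <- 0
  pops$baseline_drive <- 0
  pops$g_a <- 0
  net <- build_network(edges = list(), populations = pops)
  ss <- steady_state_rates(net)
  expect_true(ss$converged)
  expect_equal(unname(ss$rates), rep(rate_phi(0), 15), tolerance = 1e-9)
  expect_equal(rate_phi(0), 1)
})

test_that("noise-free simulation settles at the fixed point", {
  net <- make_quiet_network()
  ss <- steady_state_rates(net)
  sim <- simulate_network(net, stimulus_protocol(), duration = 1)
  expect_lt(max(abs(sim$rates[nrow(sim$rates), ] - ss$rates)), 1e-6)
  # max |dr/dt| ~ 0 after the transient
  late <- sim$rates[(nrow(sim$rates) - 100):nrow(sim$rates), ]
  expect_lt(max(abs(apply(late, 2, diff))) / net$dt, 1e-3)
})

test_that("fixed point agrees with the long-run noise-free simulation mean", {
  net <- make_quiet_network()
  ss <- steady_state_rates(net, c(TN = 1.5))
  prot <- stimulus_protocol(air_amp = 1.0, mode = "steady_state")
  sim <- simulate_network(net, prot, duration = 3)
  run_mean <- colMeans(sim$rates[sim$time > 1.5, ])
  expect_lt(max(abs(run_mean - ss$rates) / pmax(ss$rates, 1e-6)), 1e-5)
})

test_that("rates stay non-negative and seeded runs reproduce exactly", {
  net <- build_network(seed = 5L)
  prot <- stimulus_protocol(air_amp = 2, mode = "steady_state")
  a <- simulate_network(net, prot, duration = 0.5)
  b <- simulate_network(net, prot, duration = 0.5)
  expect_identical(a$rates, b$rates)
  expect_true(all(a$rates >= 0))
  c2 <- simulate_network(net, prot, duration = 0.5, seed = 6L)
  expect_false(identical(a$rates, c2$rates))
})

test_that("halving dt barely moves the noise-free trajectory endpoint", {
  net1 <- make_quiet_network()
  pops <- default_populations()
  pops$noise_sd <- 0
  net2 <- build_network(populations = pops, dt = 1e-4)
  prot <- stimulus_protocol(air_amp = 1, mode = "steady_state")
  s1 <- simulate_network(net1, prot, duration = 1)
  s2 <- simulate_network(net2, prot, duration = 1)
  r1 <- s1$rates[nrow(s1$rates), ]
  r2 <- s2$rates[nrow(s2$rates), ]
  expect_lt(max(abs(r1 - r2) / pmax(r2, 1e-9)), 1e-3)
})

test_that("a brief trigeminal impulse evokes a decaying cortical oscillation", {
  net <- make_quiet_network()
  prot <- stimulus_protocol(air_amp = 4, air_onset = 0.3,
                            air_duration = 0.01)
  sim <- simulate_network(net, prot, duration = 1.2)
  ss <- steady_state_rates(net)
  x <- sim$rates[, "S1sE"] - ss$rates["S1sE"]
  post <- x[sim$time > 0.3 & sim$time < 0.7]
  d <- diff(post)
  ext <- which(diff(sign(d)) != 0) + 1L
  ext <- ext[abs(post[ext]) > 1e-10]
  expect_gte(length(ext), 2)  # oscillatory: more than one extremum
  # the oscillation is damped: the envelope decays across successive
  # 100 ms windows back to (near) the fixed point
  fs <- 1 / net$dt
  post <- x[sim$time >= 0.3][seq_len(4 * round(0.1 * fs))]
  win <- matrix(post, ncol = 4)
  env <- apply(abs(win), 2, max)
  expect_true(all(diff(env) < 0))
  expect_lt(env[4], 0.05 * env[1])
})

test_that("cerebellar nuclei are suppressed by a PC pulse and rebound", {
  net <- make_quiet_network()
  ss <- steady_state_rates(net)
  prot <- stimulus_protocol(pc_amp = 3, pc_onset = 0.5, pc_duration = 0.1)
  sim <- simulate_network(net, prot, duration = 1.2)
  cn <- sim$rates[, "CN"]
  base <- ss$rates["CN"]
  during <- cn[sim$time >= 0.5 & sim$time < 0.6]
  after <- cn[sim$time >= 0.6 & sim$time < 0.65]
  expect_lt(min(during), 0.5 * base)        # suppression during the pulse
  expect_gt(max(after), base * 1.05)        # rebound within 50 ms of offset
})

test_that("sustained PC drive monotonically reduces the CN stationary rate", {
  net <- make_quiet_network()
  pc_base <- net$populations$baseline_drive[net$populations$name == "PC"]
  grid <- seq(0, 3, by = 0.5)
  cn <- vapply(grid, function(a) {
    steady_state_rates(net, c(PC = pc_base + a))$rates[["CN"]]
  }, numeric(1))
  expect_true(all(diff(cn) <= 1e-9))
  expect_lt(cn[length(cn)], cn[1])
})

test_that("lfp proxy subtracts the mean and rejects unknown modules", {
  net <- build_network()
  prot <- stimulus_protocol(mode = "steady_state")
  sim <- simulate_network(net, prot, duration = 0.3)
  x <- lfp_proxy(sim, "S1", "supra")
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(x, sim$rates[, "S1sE"] - mean(sim$rates[, "S1sE"]))
  expect_error(lfp_proxy(sim, "S1", "granular"), "unknown layer")
  expect_error(lfp_proxy(sim, "V1", "supra"), "unknown area")
  # constant-rate simulation -> all-zero proxy
  quiet <- make_quiet_network()
  sim0 <- simulate_network(quiet, stimulus_protocol(), duration = 0.5)
  late <- which(sim0$time > 0.4)
  x0 <- sim0$rates[late, "S1sE"] - mean(sim0$rates[late, "S1sE"])
  expect_lt(max(abs(x0)), 1e-6)
})

test_that("isolated laminar modules resonate: superficial gamma, deep slower", {
  ed <- Filter(function(e) substr(e[1], 1, 3) == substr(e[2], 1, 3) &&
                 nchar(e[1]) == 4, default_edges())
  pops <- default_populations()
  pops$baseline_drive[pops$name %in% c("S1sE", "S1iE")] <- 6
  net <- build_network(edges = ed, populations = pops)
  prot <- stimulus_protocol(mode = "steady_state")
  sim <- simulate_network(net, prot, duration = 8, seed = 77)
  fs <- 1 / net$dt
  keep <- sim$time > 0.5
  ps_s <- power_spectrum(sim$rates[keep, "S1sE"] -
                           mean(sim$rates[keep, "S1sE"]),
                         fs = fs, segment_length = 2^13)
  ps_i <- power_spectrum(sim$rates[keep, "S1iE"] -
                           mean(sim$rates[keep, "S1iE"]),
                         fs = fs, segment_length = 2^13)
  in_range <- function(ps) ps$f >= 2 & ps$f <= 150
  f_s <- ps_s$f[in_range(ps_s)][which.max(ps_s$P[in_range(ps_s)])]
  f_i <- ps_i$f[in_range(ps_i)][which.max(ps_i$P[in_range(ps_i)])]
  expect_gte(f_s, 30)
  expect_lte(f_s, 100)
  expect_lt(f_i, f_s)
  expect_lt(f_i, 30)
})

test_that("too-coarse integration steps are rejected", {
  net <- build_network(dt = 0.005)
  expect_error(simulate_network(net, stimulus_protocol(), duration = 0.1),
               "too coarse")
})
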