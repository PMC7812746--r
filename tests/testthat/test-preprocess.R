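test_that("segmentation conserves trials and drops edge events loudly", {
  rec <- mc_recording(matrix(rnorm(20000), ncol = 2), fs = 100)
  ev <- event_table(seq(5, 95, by = 1))
  tt <- segment_trials(rec, ev, window = c(2, 2))
  expect_equal(dim(tt$data)[1], nrow(ev))
  # event too close to the start: dropped with a warning, not truncated
  ev2 <- event_table(c(1, 50))
  expect_warning(tt2 <- segment_trials(rec, ev2, window = c(5, 5)),
                 "dropped 1/2")
  expect_equal(dim(tt2$data)[1], 1)
  expect_equal(attr(tt2, "dropped")$onset_s, 1)
})

test_that("segmentation of a constant signal is shift invariant", {
  rec <- mc_recording(matrix(7, 5000, 1), fs = 100)
  tt <- segment_trials(rec, event_table(c(10, 20, 30)), window = c(1, 1))
  expect_true(all(tt$data == 7))
  expect_identical(tt$data[1, , ], tt$data[3, , ])
})

test_that("event-related average recovers a template and Z-scores baseline", {
  set.seed(8)
  n_trials <- 200
  fs <- 100
  t_axis <- seq(-1.5, 1.5 - 1 / fs, by = 1 / fs)
  template <- -exp(-(t_axis - 0.03)^2 / (2 * 0.01^2))
  dat <- array(0, dim = c(n_trials, 1, length(t_axis)))
  for (k in seq_len(n_trials)) dat[k, 1, ] <- 3 + template + 2 * rnorm(length(t_axis))
  tt <- trial_tensor(dat, fs = fs, window = c(1.5, 1.5))
  erp <- event_related_average(tt)
  # mean converges to offset + template at ~ sd/sqrt(n)
  expect_lt(max(abs(erp$mean[1, ] - (3 + template))), 5 * 2 / sqrt(n_trials))
  bidx <- tt$time >= -1 & tt$time <= -0.1
  expect_lt(abs(mean(erp$zscored[1, bidx])), 0.1)
  expect_lt(abs(sd(erp$zscored[1, bidx]) - 1), 0.1)
})

test_that("identical trials average to any single trial; zero variance refused", {
  dat <- array(rep(sin(seq_len(300) / 10), each = 4), dim = c(4, 1, 300))
  tt <- trial_tensor(dat, fs = 100, window = c(1.5, 1.5))
  erp <- event_related_average(tt)
  expect_equal(erp$mean[1, ], dat[1, 1, ])
  flat <- trial_tensor(array(1, dim = c(4, 1, 300)), fs = 100,
                       window = c(1.5, 1.5))
  expect_warning(erp2 <- event_related_average(flat), "zero baseline variance")
  expect_true(all(is.na(erp2$zscored[1, ])))
})

test_that("peak metrics match the closed form for a sine deflection", {
  fs <- 1000
  time <- seq(0, 0.1 - 1 / fs, by = 1 / fs)
  erp <- structure(
    list(mean = matrix(-sin(2 * pi * time / 0.1), 1), time = time,
         baseline_mean = 0, channels = NULL),
    class = "erp_result"
  )
  pm <- peak_metrics(erp, 1, search_window = c(0, 0.1))
  expect_false(pm$negative$absent)
  expect_equal(pm$negative$latency_s, 0.025, tolerance = 1e-6)
  expect_equal(pm$negative$amplitude, -1, tolerance = 1e-4)
  expect_equal(pm$positive$latency_s, 0.075, tolerance = 1e-6)
  expect_equal(pm$positive$amplitude, 1, tolerance = 1e-4)
  # linearity: doubling scales amplitudes, not latencies
  erp2 <- erp
  erp2$mean <- 2 * erp$mean
  pm2 <- peak_metrics(erp2, 1, search_window = c(0, 0.1))
  expect_equal(pm2$negative$amplitude, 2 * pm$negative$amplitude)
  expect_equal(pm2$negative$latency_s, pm$negative$latency_s)
})

test_that("flat traces yield explicitly absent peaks", {
  erp <- structure(
    list(mean = matrix(0, 1, 100), time = seq(0, 0.99, by = 0.01),
         baseline_mean = 0, channels = NULL),
    class = "erp_result"
  )
  pm <- peak_metrics(erp, 1, search_window = c(0, 0.9))
  expect_true(pm$negative$absent)
  expect_true(pm$positive$absent)
  expect_true(is.na(pm$negative$amplitude))
})

test_that("CSD: affine profiles vanish, quadratic gives the exact constant", {
  depth <- 1:10
  affine <- outer(3 + 2 * depth, rep(1, 5))
  expect_equal(max(abs(csd_profile(affine, spacing = 1)$csd)), 0)
  quad <- outer(depth^2, rep(1, 5))
  expect_equal(unique(as.numeric(csd_profile(quad, spacing = 1)$csd)), -2)
})

test_that("CSD is linear and the sign convention marks sinks negative", {
  set.seed(3)
  a <- matrix(rnorm(40), 8, 5)
  b <- matrix(rnorm(40), 8, 5)
  lhs <- csd_profile(2 * a + 3 * b, spacing = 50)$csd
  rhs <- 2 * csd_profile(a, spacing = 50)$csd +
    3 * csd_profile(b, spacing = 50)$csd
  expect_equal(lhs, rhs)
  # negative-Gaussian depth profile (a sink) gives negative CSD at centre
  prof <- matrix(-exp(-((1:9 - 5)^2) / 2), 9, 1)
  csd <- csd_profile(prof, spacing = 1)
  expect_lt(csd$csd[which(csd$channels == 5), 1], 0)
})

test_that("averaging commutes with channel reordering", {
  set.seed(5)
  dat <- array(rnorm(10 * 3 * 50), dim = c(10, 3, 50))
  tt <- trial_tensor(dat, fs = 100, window = c(0.25, 0.25))
  erp <- event_related_average(tt, baseline_window = c(-0.25, -0.05))
  perm <- c(3, 1, 2)
  tt2 <- trial_tensor(dat[, perm, , drop = FALSE], fs = 100,
                      window = c(0.25, 0.25))
  erp2 <- event_related_average(tt2, baseline_window = c(-0.25, -0.05))
  expect_equal(erp2$mean, erp$mean[perm, ])
  expect_equal(erp2$zscored, erp$zscored[perm, ])
})
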