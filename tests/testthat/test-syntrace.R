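test_that("config validation rejects invalid parameter sets", {
  expect_error(channel_sim_config(10, 2, 50, 50, 1, 2000, 10),
               class = "glyrfluct_config_error") # missing seed
  expect_error(channel_sim_config(10, -2, 50, 50, 1, 2000, 10, seed = 1),
               class = "glyrfluct_config_error")
  expect_error(channel_sim_config(10, 2, -1, 50, 1, 2000, 10, seed = 1),
               class = "glyrfluct_config_error")
  expect_error(channel_sim_config(10, 2, NaN, 50, 1, 2000, 10, seed = 1),
               class = "glyrfluct_config_error")
  # gating must be resolvable: fs >= 10 * (k_open + k_close)
  expect_error(channel_sim_config(10, 2, 500, 500, 1, 2000, 10, seed = 1),
               class = "glyrfluct_config_error")
  expect_error(mipsc_train_config(1, 50, tau_rise = 5, tau_decay = 2,
                                  seed = 1),
               class = "glyrfluct_config_error")
  expect_error(simulate_dose_response(300, 1.5, 1, numeric(), seed = 1),
               class = "glyrfluct_config_error")
})

test_that("degenerate rate limits behave as closed-form edge cases", {
  # k_open = 0: all channels stay closed, trace is pure baseline noise
  cfg <- channel_sim_config(50, 2, 0, 100, 1.5, 2000, 20, seed = 11)
  sim <- simulate_two_state_ensemble(cfg)
  expect_true(all(sim$ground_truth$open_counts == 0L))
  expect_equal(sd(sim$trace$samples), 1.5, tolerance = 0.05)
  # k_close = 0, no noise: constant trace at full-open magnitude
  cfg2 <- channel_sim_config(50, 2, 100, 0, 0, 2000, 5, seed = 12)
  sim2 <- simulate_two_state_ensemble(cfg2)
  expect_true(all(sim2$trace$samples == -100))
})

test_that("stationary ensemble matches analytic binomial moments", {
  # oracle: mean = n i p, channel variance = i^2 n p (1-p)
  cfg <- channel_sim_config(200, 2, 50, 50, 0, 2000, 60, seed = 21)
  sim <- simulate_two_state_ensemble(cfg)
  expect_equal(mean(-sim$trace$samples), 200, tolerance = 0.02)
  expect_equal(var(sim$trace$samples), 200, tolerance = 0.10)
  expect_equal(sim$ground_truth$p_open, 0.5)
})

test_that("ensemble autocovariance decays with the relaxation time", {
  # two-state relaxation: acf lag tau decays as exp(-(k_open+k_close) t)
  cfg <- channel_sim_config(100, 2, 100, 100, 0, 4000, 40, seed = 22)
  sim <- simulate_two_state_ensemble(cfg)
  a <- stats::acf(sim$trace$samples, lag.max = 40, plot = FALSE)$acf[, 1, 1]
  lags <- (0:40) / 4000
  fit <- lm(log(a[a > 0.05]) ~ lags[a > 0.05])
  tau_fit <- -1 / coef(fit)[2]
  expect_equal(unname(tau_fit), 1 / 200, tolerance = 0.15)
})

test_that("fixed seeds give bit-identical traces", {
  cfg <- channel_sim_config(20, 2, 50, 50, 1, 2000, 5, seed = 33)
  s1 <- simulate_two_state_ensemble(cfg)
  s2 <- simulate_two_state_ensemble(cfg)
  expect_identical(s1$trace$samples, s2$trace$samples)
  mc <- mipsc_train_config(2, 50, seed = 33, duration = 5,
                           sampling_rate = 2000)
  expect_identical(simulate_mipsc_train(mc)$trace$samples,
                   simulate_mipsc_train(mc)$trace$samples)
})

test_that("glycine application with a constant profile is stationary", {
  # p = 0: baseline only
  cfg <- channel_sim_config(100, 2, 0, 100, 1, 2000, 10, seed = 41)
  sim0 <- simulate_glycine_application(cfg, function(t) rep(0, length(t)))
  expect_true(all(sim0$ground_truth$open_counts == 0L))
  # constant p equal to the stationary P_o: first two moments match the
  # plain stationary simulator across seeds (Monte-Carlo tolerance)
  moments <- sapply(1:8, function(s) {
    cfgs <- channel_sim_config(100, 2, 100, 100, 0, 2000, 20, seed = 100 + s)
    a <- simulate_two_state_ensemble(cfgs)
    b <- simulate_glycine_application(cfgs, function(t) rep(0.5, length(t)))
    c(mean(a$trace$samples), mean(b$trace$samples),
      var(a$trace$samples), var(b$trace$samples))
  })
  expect_equal(mean(moments[1, ]), mean(moments[2, ]), tolerance = 0.02)
  expect_equal(mean(moments[3, ]), mean(moments[4, ]), tolerance = 0.15)
})

test_that("profile validation rejects out-of-range open probabilities", {
  cfg <- channel_sim_config(10, 2, 0, 100, 1, 2000, 5, seed = 5)
  expect_error(simulate_glycine_application(cfg, function(t) t * 0 + 1.2),
               class = "glyrfluct_config_error")
})

test_that("mipsc train matches its ground truth and Poisson statistics", {
  # zero rate: pure noise
  mc0 <- mipsc_train_config(0, 50, seed = 51, duration = 10,
                            sampling_rate = 2000)
  s0 <- simulate_mipsc_train(mc0)
  expect_length(s0$ground_truth$event_onsets, 0)
  expect_equal(sd(s0$trace$samples), mc0$baseline_noise_sd, tolerance = 0.1)
  # Poisson count within 3 sigma of rate * duration
  mc1 <- mipsc_train_config(1, 50, seed = 52, duration = 300,
                            sampling_rate = 2000, baseline_noise_sd = 0)
  s1 <- simulate_mipsc_train(mc1)
  expect_lt(abs(length(s1$ground_truth$event_onsets) - 300), 3 * sqrt(300))
  # ground-truth consistency: clean + stored noise reproduces the trace
  mc2 <- mipsc_train_config(2, 50, seed = 53, duration = 10,
                            sampling_rate = 2000)
  s2 <- simulate_mipsc_train(mc2, store_noise = TRUE)
  expect_identical(s2$trace$samples,
                   s2$ground_truth$clean + s2$ground_truth$noise)
  expect_equal(length(s2$ground_truth$event_onsets),
               length(s2$ground_truth$event_amplitudes))
  expect_false(is.unsorted(s2$ground_truth$event_onsets))
})

test_that("noiseless biexponential event peaks at the analytic time", {
  # analytic peak time t* = tr*td/(td-tr) * log(td/tr)
  fs <- 20000
  mc <- mipsc_train_config(1 / 60, 50, amp_cv = 0, tau_rise = 0.5,
                           tau_decay = 5, baseline_noise_sd = 0,
                           sampling_rate = fs, duration = 60, seed = 50)
  sim <- simulate_mipsc_train(mc)
  expect_length(sim$ground_truth$event_onsets, 1L) # seed chosen for this
  tstar <- biexp_peak_time(0.5, 5) # ms
  expect_equal(tstar, 0.5 * 5 / 4.5 * log(10))
  extremum <- min(sim$trace$samples)
  expect_equal(extremum, -50, tolerance = 1e-3)
  t_ext <- (which.min(sim$trace$samples) - 1) / fs
  expect_lt(abs(t_ext - sim$ground_truth$event_onsets[1] - tstar / 1000),
            2 / fs)
})

test_that("dose-response generator honours the Hill closed form", {
  tab <- simulate_dose_response(300, 1.5, 1000, c(300), noise_cv = 0,
                                n_cells = 2, seed = 61)
  expect_equal(unique(tab$peak_current), 500) # C = EC50 -> Imax/2
  tab2 <- simulate_dose_response(300, 1, 1000, 1e6 * 300, noise_cv = 0,
                                 n_cells = 1, seed = 62)
  expect_equal(tab2$peak_current, 1000, tolerance = 1e-4) # saturation
})

test_that("tonic block leaves only baseline noise after the step", {
  cfg <- channel_sim_config(50, 2, 100, 100, 1, 2000, 40, seed = 71)
  sim <- simulate_tonic_block(cfg, 20)
  post <- sim$trace$samples[(20 * 2000 + 1):(40 * 2000)]
  expect_equal(mean(post), 0, tolerance = 0.1)
  expect_equal(sd(post), 1, tolerance = 0.05)
  expect_identical(sim$trace$annotations$label, "strychnine")
  # zero channels: nothing changes at the block onset
  cfg0 <- channel_sim_config(0, 2, 100, 100, 1, 2000, 40, seed = 72)
  sim0 <- simulate_tonic_block(cfg0, 20)
  expect_equal(mean(sim0$trace$samples[1:(20 * 2000)]),
               mean(sim0$trace$samples[(20 * 2000 + 1):(40 * 2000)]),
               tolerance = 0.1)
  # silent degenerate config: all closed, no rates, no noise
  cfgz <- channel_sim_config(10, 2, 0, 0, 0, 2000, 10, seed = 73)
  simz <- simulate_tonic_block(cfgz, 5)
  expect_true(all(simz$trace$samples == 0))
  expect_error(simulate_tonic_block(cfg, 45),
               class = "glyrfluct_config_error")
})
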