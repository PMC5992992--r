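test_that("noise SD estimation is accurate and event-robust", {
  fs <- 10000
  tr0 <- trace(rep(1.5, fs), fs)
  expect_equal(estimate_noise_sd(tr0), 0) # constant trace
  set.seed(1)
  trn <- trace(rnorm(60 * fs, sd = 3), fs)
  expect_equal(estimate_noise_sd(trn), 3, tolerance = 0.05)
  # dense large events, automatic window: still within 15%
  mc <- mipsc_train_config(5, 80, amp_cv = 0.2, baseline_noise_sd = 3,
                           sampling_rate = fs, duration = 60, seed = 2)
  trd <- simulate_mipsc_train(mc)$trace
  expect_equal(estimate_noise_sd(trd), 3, tolerance = 0.15)
  # configured window
  cfg <- detection_config(noise_window = c(0, 5))
  expect_equal(estimate_noise_sd(trn, cfg), 3, tolerance = 0.05)
})

test_that("pure noise yields (almost) no detections at 6 sigma", {
  # false-positive property of the scaled-template criterion: over 8 seeds
  # of 30 s noise, at most one seed may produce any event
  fs <- 10000
  cfg <- detection_config(threshold_sigma = 6)
  n_events <- vapply(1:8, function(s) {
    set.seed(s)
    tr <- trace(rnorm(30 * fs, sd = 3), fs)
    nrow(detect_events(tr, cfg, noise_sd = 3))
  }, 0L)
  expect_lte(sum(n_events > 0), 1)
})

test_that("threshold boundary is inclusive for a noiseless event", {
  fs <- 10000
  sigma <- 2 # externally fixed noise scale
  cfg <- detection_config(threshold_sigma = 5.5)
  kern <- biexp_waveform((0:(0.05 * fs)) / fs * 1000, 0.5, 5)
  x <- numeric(2 * fs)
  x[fs:(fs + length(kern) - 1)] <- -sigma * 5.5 * kern
  ev <- detect_events(trace(x, fs), cfg, noise_sd = sigma)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_time, (fs - 1) / fs, tolerance = 2 / fs)
})

test_that("detection recovers a 10-sigma synthetic train", {
  fs <- 10000
  mc <- mipsc_train_config(1, 30, amp_cv = 0.2, baseline_noise_sd = 3,
                           sampling_rate = fs, duration = 60,
                           lowpass_hz = 2000, seed = 7)
  sim <- simulate_mipsc_train(mc)
  ev <- detect_events(sim$trace)
  m <- match_events(ev$onset_time, sim$ground_truth$event_onsets)
  expect_gte(m$sensitivity, 0.95)
  expect_gte(m$precision, 0.95)
})

test_that("detection is translation-equivariant in time", {
  fs <- 10000
  mc <- mipsc_train_config(1, 40, baseline_noise_sd = 3,
                           sampling_rate = fs, duration = 20, seed = 8)
  sim <- simulate_mipsc_train(mc)
  ev1 <- detect_events(sim$trace)
  shifted <- trace(sim$trace$samples, fs, start_time = 3.25)
  ev2 <- detect_events(shifted, noise_sd = attr(ev1, "noise_sd"))
  expect_equal(ev2$onset_time, ev1$onset_time + 3.25, tolerance = 1e-9)
})

test_that("kinetics match a dense-grid oracle on noiseless events", {
  fs <- 20000
  kern_t <- (0:(0.06 * fs)) / fs * 1000
  kern <- biexp_waveform(kern_t, 0.5, 5)
  x <- numeric(3 * fs)
  i0 <- fs + 1L
  x[i0:(i0 + length(kern) - 1)] <- -50 * kern
  tr <- trace(x, fs)
  ev <- make_events(onset = 1)
  ev <- measure_kinetics(tr, ev, detection_config())
  orc <- dense_kinetics(50 * kern, fs)
  expect_equal(ev$peak_amplitude, orc$peak, tolerance = 0.01)
  expect_equal(ev$rise_10_90, orc$rise, tolerance = 1000 / fs)
  expect_equal(ev$decay_90_10, orc$decay, tolerance = 1000 / fs)
  # amplitude invariance of kinetics: x2 scaling leaves rise/decay unchanged
  tr2 <- trace(2 * x, fs)
  ev2 <- measure_kinetics(tr2, make_events(onset = 1), detection_config())
  expect_equal(ev2$peak_amplitude, 2 * ev$peak_amplitude, tolerance = 1e-6)
  expect_equal(ev2$rise_10_90, ev$rise_10_90, tolerance = 1e-9)
  expect_equal(ev2$decay_90_10, ev$decay_90_10, tolerance = 1e-9)
})

test_that("a pure step has rise time below one sample interval", {
  fs <- 10000
  x <- numeric(2 * fs)
  x[(fs + 1):(2 * fs)] <- -40
  ev <- measure_kinetics(trace(x, fs), make_events(onset = 1),
                         detection_config())
  expect_lte(ev$rise_10_90, 1000 / fs)
})

test_that("acceptance filters implement the overlap/rise/decay rules", {
  fs <- 20000
  x <- numeric(3 * fs)
  tr <- trace(x, fs)
  # two events 1 ms apart: both rejected as overlapping
  ev <- make_events(onset = c(1.000, 1.001))
  ev <- filter_events(ev, tr)
  expect_equal(ev$rejection_reason, c("overlap", "overlap"))
  expect_false(any(ev$accepted))
  # isolated event with 2.5 ms rise: slow_rise; 1 ms rise: accepted
  ev2 <- make_events(onset = c(1, 2), rise = c(1, 2.5))
  ev2$measured <- TRUE
  ev2 <- filter_events(ev2, tr)
  expect_equal(ev2$rejection_reason, c("none", "slow_rise"))
  expect_equal(ev2$accepted, c(TRUE, FALSE))
  # boundary: rise exactly 2 ms is rejected (< 2 ms criterion)
  ev3 <- filter_events(make_events(onset = 1, rise = 2), tr)
  expect_equal(ev3$rejection_reason, "slow_rise")
})

test_that("rough decays are rejected, clean decays accepted", {
  fs <- 20000
  kern_t <- (0:(0.06 * fs)) / fs * 1000
  kern <- biexp_waveform(kern_t, 0.5, 5)
  clean <- numeric(3 * fs)
  i0 <- fs + 1L
  clean[i0:(i0 + length(kern) - 1)] <- -50 * kern
  cfg0 <- detection_config()
  tr_c <- trace(clean, fs)
  ev_c <- detect_events(tr_c, cfg0, noise_sd = 1) # sigma fixed externally
  ev_c <- filter_events(measure_kinetics(tr_c, ev_c, cfg0), tr_c, cfg0)
  expect_equal(nrow(ev_c), 1L)
  expect_true(all(ev_c$accepted))
  # a second event riding on the decay: both members flagged as overlap
  dirty <- clean
  j0 <- i0 + round(0.008 * fs)
  dirty[j0:(j0 + length(kern) - 1)] <-
    dirty[j0:(j0 + length(kern) - 1)] - 60 * kern
  cfgd <- detection_config(refractory = 0.5)
  evd <- detect_events(trace(dirty, fs), cfgd, noise_sd = 1)
  evd <- measure_kinetics(trace(dirty, fs), evd, cfgd)
  evd <- filter_events(evd, trace(dirty, fs), cfgd)
  expect_false(any(evd$accepted))
})

test_that("summaries follow the frequency and minimum-event rules", {
  ev <- make_events(onset = seq(1, 30, length.out = 30))
  ev$accepted <- c(rep(TRUE, 19), rep(FALSE, 11))
  ev$rejection_reason <- ifelse(ev$accepted, "none", "overlap")
  s <- summarize_minis(ev, analyzed_duration = 60)
  expect_equal(s$frequency, 0.5) # 30 events in 60 s
  expect_equal(s$n_accepted, 19)
  expect_false(s$kinetics_valid) # 19 < 20
  ev$accepted[20] <- TRUE
  expect_true(summarize_minis(ev, 60)$kinetics_valid)
  # empty list: zero frequency, undefined kinetics
  s0 <- summarize_minis(make_events(numeric(0)), 60)
  expect_equal(s0$frequency, 0)
  expect_true(is.na(s0$mean_amplitude))
  expect_error(summarize_minis(ev, 0), class = "glyrfluct_config_error")
})

test_that("summary kinetics recover generating values at SNR 10", {
  # acquisition chain: 20 kHz sampling, 2 kHz low-pass; the oracle is the
  # dense-grid kinetics of the filtered kernel (SNR = amp_mean / noise_sd)
  fs <- 20000
  kern <- biexp_waveform((0:(0.05 * fs)) / fs * 1000, 0.5, 5)
  kf <- lowpass_filter(c(kern, numeric(length(kern))), fs, 2000)
  orc <- dense_kinetics(kf, fs)
  mc <- mipsc_train_config(1, 50, amp_cv = 0.2, baseline_noise_sd = 5,
                           sampling_rate = fs, duration = 60,
                           lowpass_hz = 2000, seed = 3)
  res <- analyze_minis(simulate_mipsc_train(mc)$trace)
  expect_equal(res$summary$mean_amplitude, 50 * orc$peak, tolerance = 0.1)
  expect_equal(res$summary$mean_rise, orc$rise, tolerance = 0.1)
  expect_equal(res$summary$mean_decay, orc$decay, tolerance = 0.1)
})

test_that("weaker/faster generating events give smaller summaries", {
  # paired-seed monotonicity, mirroring a wild-type vs mutant contrast
  fs <- 10000
  res <- lapply(1:3, function(s) {
    wt <- mipsc_train_config(2, 60, tau_decay = 6, baseline_noise_sd = 3,
                             sampling_rate = fs, duration = 40,
                             lowpass_hz = 2000, seed = s)
    mu <- mipsc_train_config(0.5, 35, tau_decay = 3, baseline_noise_sd = 3,
                             sampling_rate = fs, duration = 40,
                             lowpass_hz = 2000, seed = s)
    cw <- detection_config(template_tau_decay = 6)
    cm <- detection_config(template_tau_decay = 3)
    list(wt = analyze_minis(simulate_mipsc_train(wt)$trace, cw)$summary,
         mu = analyze_minis(simulate_mipsc_train(mu)$trace, cm)$summary)
  })
  for (r in res) {
    expect_lt(r$mu$frequency, r$wt$frequency)
    expect_lt(r$mu$mean_amplitude, r$wt$mean_amplitude)
    expect_lt(r$mu$mean_decay, r$wt$mean_decay)
  }
})
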