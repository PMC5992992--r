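# shared independent oracles and fixture builders (built in code, no files)

# dense-grid kinetics oracle: peak, 10-90% rise and 90-10% decay of an
# arbitrary sampled waveform, evaluated on a 1 MHz interpolation grid
dense_kinetics <- function(w, fs) {
  t_ms <- (seq_along(w) - 1) / fs * 1000
  td <- seq(0, max(t_ms), by = 1e-3)
  wd <- stats::approx(t_ms, w, td)$y
  pk <- which.max(wd)
  peak <- wd[pk]
  r10 <- td[which(wd[1:pk] >= 0.1 * peak)[1]]
  r90 <- td[which(wd[1:pk] >= 0.9 * peak)[1]]
  dseg <- wd[pk:length(wd)]
  d90 <- td[pk + which(dseg <= 0.9 * peak)[1] - 1]
  d10 <- td[pk + which(dseg <= 0.1 * peak)[1] - 1]
  list(peak = peak, rise = r90 - r10, decay = d10 - d90,
       peak_time = td[pk])
}

# sensitivity/precision of detected onsets vs ground truth (2 ms matching)
match_events <- function(detected_onsets, true_onsets, tol = 0.002) {
  sens <- if (length(true_onsets))
    mean(vapply(true_onsets, function(o)
      any(abs(detected_onsets - o) < tol), TRUE)) else NA_real_
  prec <- if (length(detected_onsets))
    mean(vapply(detected_onsets, function(o)
      any(abs(true_onsets - o) < tol), TRUE)) else NA_real_
  list(sensitivity = sens, precision = prec)
}

# power_spectrum object from closed-form PSD values (noiseless fixtures)
make_spectrum <- function(frequencies, psd, df = diff(frequencies[1:2])) {
  structure(list(frequencies = frequencies, psd = psd, is_net = TRUE,
                 fmax_used = max(frequencies) + df, df = df,
                 parseval_ratio = 1, n_negative = sum(psd < 0)),
            class = "power_spectrum")
}

# minimal detected_events frame for filter/summary unit tests
make_events <- function(onset, rise = 1, decay = 8, amp = 50,
                        decay10 = onset + 0.012) {
  n <- length(onset)
  out <- data.frame(onset_time = onset, peak_time = onset + 0.0013,
                    peak_amplitude = rep_len(amp, max(n, 0)),
                    rise_10_90 = rep_len(rise, n),
                    decay_90_10 = rep_len(decay, n),
                    accepted = rep(NA, n),
                    rejection_reason = rep("none", n),
                    measured = rep(TRUE, n),
                    decay10_time = rep_len(decay10, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("detected_events", "data.frame")
  attr(out, "noise_sd") <- 0
  out
}

# reference ramp simulation used by the noise-analysis recovery checks:
# 10 s control then a triangular open-probability ramp 0 -> 0.9 -> 0
ramp_simulation <- function(seed, n_channels = 100, unitary = 2,
                            k_close = 200, duration = 70, fs = 20000) {
  cfg <- channel_sim_config(n_channels, unitary, 0, k_close,
                            baseline_noise_sd = 2, sampling_rate = fs,
                            duration = duration, seed = seed)
  ramp <- duration - 10
  prof <- function(t) ifelse(t < 10, 0,
                             0.9 * (1 - abs(2 * (t - 10) / ramp - 1)))
  simulate_glycine_application(cfg, prof)
}
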