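#' Configuration for a two-state channel ensemble simulation
#'
#' Describes an ensemble of `n_channels` independent two-state
#' (closed <-> open) channels with opening rate `k_open`, closing rate
#' `k_close` and unitary current `unitary_current` (magnitude; contributions
#' are stored negative, i.e. inward). The stationary open probability is
#' `k_open / (k_open + k_close)` and the stationary ensemble moments are
#' the binomial ones: mean magnitude `n * i_u * P_o`, channel variance
#' `i_u^2 * n * P_o * (1 - P_o)`.
#'
#' @param n_channels number of channels (>= 0).
#' @param unitary_current unitary current magnitude in pA (> 0).
#' @param k_open,k_close opening/closing rates in 1/s (>= 0).
#' @param baseline_noise_sd Gaussian baseline noise SD in pA (>= 0).
#' @param sampling_rate sampling rate in Hz; must be at least
#'   `10 * (k_open + k_close)` so gating is resolvable.
#' @param duration trace duration in seconds (> 0).
#' @param seed integer RNG seed; mandatory (no implicit default).
#' @return a `channel_sim_config` list.
#' @export
channel_sim_config <- function(n_channels, unitary_current, k_open, k_close,
                               baseline_noise_sd, sampling_rate = 20000,
                               duration = 60, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop_config("seed is mandatory in simulation configs")
  assert_number(n_channels, "n_channels", 0)
  assert_number(unitary_current, "unitary_current", 0, strict = TRUE)
  assert_number(k_open, "k_open", 0)
  assert_number(k_close, "k_close", 0)
  assert_number(baseline_noise_sd, "baseline_noise_sd", 0)
  assert_number(sampling_rate, "sampling_rate", 0, strict = TRUE)
  assert_number(duration, "duration", 0, strict = TRUE)
  if (sampling_rate < 10 * (k_open + k_close))
    stop_config("sampling_rate must be >= 10 * (k_open + k_close); got ",
                sampling_rate, " vs rates summing to ", k_open + k_close)
  structure(list(n_channels = as.integer(n_channels),
                 unitary_current = unitary_current,
                 k_open = k_open, k_close = k_close,
                 baseline_noise_sd = baseline_noise_sd,
                 sampling_rate = sampling_rate, duration = duration,
                 seed = as.integer(seed)),
            class = "channel_sim_config")
}

#' Stationary open probability implied by a config
#' @param cfg a `channel_sim_config`.
#' @return `k_open / (k_open + k_close)`, or 0 when both rates are zero.
#' @export
stationary_popen <- function(cfg) {
  ksum <- cfg$k_open + cfg$k_close
  if (ksum <= 0) 0 else cfg$k_open / ksum
}

#' Simulate a stationary two-state channel ensemble
#'
#' Each channel evolves as an independent continuous-time two-state Markov
#' chain (exact jump simulation); an open channel contributes
#' `-unitary_current` pA. Gaussian baseline noise is added. The initial open
#' count is drawn from the stationary binomial distribution so the whole
#' record is stationary.
#'
#' @param cfg a [channel_sim_config()].
#' @param store_noise keep the noise realization in the ground truth so the
#'   trace can be reconstructed exactly from its components.
#' @return a list with elements `trace` (a [trace()]) and `ground_truth`
#'   (generating parameters, stationary moments, open-count vector).
#' @export
simulate_two_state_ensemble <- function(cfg, store_noise = FALSE) {
  stopifnot(inherits(cfg, "channel_sim_config"))
  set.seed(cfg$seed)
  n_samples <- round(cfg$duration * cfg$sampling_rate)
  dt <- 1 / cfg$sampling_rate
  counts <- sim_ensemble_counts(cfg$n_channels, cfg$k_open, cfg$k_close,
                                n_samples, dt)
  noise <- if (cfg$baseline_noise_sd > 0)
    rnorm(n_samples, 0, cfg$baseline_noise_sd) else numeric(n_samples)
  samples <- -cfg$unitary_current * counts + noise
  p <- stationary_popen(cfg)
  gt <- list(config = cfg, p_open = p,
             mean_current = cfg$n_channels * cfg$unitary_current * p,
             channel_variance = cfg$unitary_current^2 * cfg$n_channels *
               p * (1 - p),
             open_counts = counts)
  if (store_noise) gt$noise <- noise
  list(trace = trace(samples, cfg$sampling_rate), ground_truth = gt)
}

#' Simulate a slowly changing glycine application
#'
#' As [simulate_two_state_ensemble()] but with `k_open` rescaled over time so
#' the instantaneous open probability tracks `popen_profile` while `k_close`
#' stays fixed: `k_open(t) = k_close * p(t) / (1 - p(t))`. The profile must
#' change slowly relative to the channel relaxation time.
#'
#' @param cfg a [channel_sim_config()]; its `k_open` is ignored except for
#'   validation, the profile drives the opening rate.
#' @param popen_profile function of time (s) returning open probabilities in
#'   `[0, 1]`, or a numeric vector on the sample grid.
#' @param p_max cap on profile values (rate divergence guard), default 0.95.
#' @return list with `trace` and `ground_truth` (includes the evaluated
#'   profile).
#' @export
simulate_glycine_application <- function(cfg, popen_profile, p_max = 0.95) {
  stopifnot(inherits(cfg, "channel_sim_config"))
  set.seed(cfg$seed)
  n_samples <- round(cfg$duration * cfg$sampling_rate)
  dt <- 1 / cfg$sampling_rate
  tt <- (seq_len(n_samples) - 1) * dt
  p <- if (is.function(popen_profile)) popen_profile(tt)
       else rep_len(as.numeric(popen_profile), n_samples)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_config("popen_profile must take values in [0, 1]")
  p <- pmin(p, p_max)
  if (cfg$k_close <= 0)
    stop_config("k_close must be > 0 to drive a popen profile")
  k_open_t <- cfg$k_close * p / (1 - p)
  if (cfg$sampling_rate * (1 + 1e-9) < 10 * (max(k_open_t) + cfg$k_close))
    stop_config("profile implies gating faster than the sampling rate ",
                "can resolve (need fs >= 10 * max rate sum)")
  init <- rbinom(1, cfg$n_channels, p[1])
  counts <- sim_ensemble_counts_tv(cfg$n_channels, k_open_t, cfg$k_close,
                                   dt, init)
  noise <- if (cfg$baseline_noise_sd > 0)
    rnorm(n_samples, 0, cfg$baseline_noise_sd) else numeric(n_samples)
  samples <- -cfg$unitary_current * counts + noise
  gt <- list(config = cfg, popen = p,
             mean_current_t = cfg$n_channels * cfg$unitary_current * p,
             open_counts = counts)
  list(trace = trace(samples, cfg$sampling_rate), ground_truth = gt)
}

#' Configuration for a miniature-IPSC train simulation
#'
#' @param event_rate Poisson event rate in Hz (>= 0).
#' @param amp_mean mean peak amplitude in pA (> 0, magnitude).
#' @param amp_cv amplitude coefficient of variation (log-normal jitter).
#' @param tau_rise,tau_decay biexponential time constants in ms;
#'   `tau_decay > tau_rise > 0`.
#' @param baseline_noise_sd Gaussian noise SD in pA.
#' @param sampling_rate Hz.
#' @param duration seconds.
#' @param lowpass_hz optional acquisition-chain low-pass cutoff applied to
#'   the final trace (e.g. 2000 Hz to mirror a 2 kHz Bessel filter before a
#'   20 kHz digitizer); `NULL` disables it.
#' @param seed mandatory integer seed.
#' @return a `mipsc_train_config` list.
#' @export
mipsc_train_config <- function(event_rate, amp_mean, amp_cv = 0.2,
                               tau_rise = 0.5, tau_decay = 5,
                               baseline_noise_sd = 3, sampling_rate = 20000,
                               duration = 60, lowpass_hz = NULL, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop_config("seed is mandatory in simulation configs")
  assert_number(event_rate, "event_rate", 0)
  assert_number(amp_mean, "amp_mean", 0, strict = TRUE)
  assert_number(amp_cv, "amp_cv", 0)
  assert_number(tau_rise, "tau_rise", 0, strict = TRUE)
  assert_number(tau_decay, "tau_decay", 0, strict = TRUE)
  if (tau_decay <= tau_rise)
    stop_config("tau_decay must exceed tau_rise")
  assert_number(baseline_noise_sd, "baseline_noise_sd", 0)
  assert_number(sampling_rate, "sampling_rate", 0, strict = TRUE)
  assert_number(duration, "duration", 0, strict = TRUE)
  structure(list(event_rate = event_rate, amp_mean = amp_mean,
                 amp_cv = amp_cv, tau_rise = tau_rise, tau_decay = tau_decay,
                 baseline_noise_sd = baseline_noise_sd,
                 sampling_rate = sampling_rate, duration = duration,
                 lowpass_hz = lowpass_hz, seed = as.integer(seed)),
            class = "mipsc_train_config")
}

#' Peak-normalized biexponential synaptic waveform
#'
#' `w(t) = (exp(-t/tau_decay) - exp(-t/tau_rise)) / w(t_peak)` with
#' `t_peak = tau_rise*tau_decay/(tau_decay - tau_rise) * log(tau_decay/tau_rise)`,
#' so the peak equals 1.
#'
#' @param t times (same unit as the taus).
#' @param tau_rise,tau_decay time constants.
#' @return waveform values; 0 for `t < 0`.
#' @export
biexp_waveform <- function(t, tau_rise, tau_decay) {
  tp <- biexp_peak_time(tau_rise, tau_decay)
  peak <- exp(-tp / tau_decay) - exp(-tp / tau_rise)
  out <- (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak
  out[t < 0] <- 0
  out
}

#' @rdname biexp_waveform
#' @export
biexp_peak_time <- function(tau_rise, tau_decay)
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)

#' Simulate a Poisson train of miniature IPSCs
#'
#' Event onsets are a homogeneous Poisson process; each event adds a
#' peak-normalized biexponential waveform of log-normal amplitude (mean
#' `amp_mean`, CV `amp_cv`), inward (negative). Gaussian baseline noise is
#' added. Ground truth (onsets, amplitudes, optionally the noise realization)
#' is returned for parameter-recovery testing.
#'
#' @param cfg a [mipsc_train_config()].
#' @param store_noise keep the noise vector in the ground truth.
#' @return list with `trace` and `ground_truth` (`event_onsets` s,
#'   `event_amplitudes` pA magnitudes, `config`).
#' @export
simulate_mipsc_train <- function(cfg, store_noise = FALSE) {
  stopifnot(inherits(cfg, "mipsc_train_config"))
  set.seed(cfg$seed)
  n_samples <- round(cfg$duration * cfg$sampling_rate)
  n_ev <- rpois(1, cfg$event_rate * cfg$duration)
  onsets <- sort(runif(n_ev, 0, cfg$duration))
  amps <- if (n_ev > 0) {
    if (cfg$amp_cv > 0) {
      sdlog <- sqrt(log(1 + cfg$amp_cv^2))
      rlnorm(n_ev, log(cfg$amp_mean) - sdlog^2 / 2, sdlog)
    } else rep(cfg$amp_mean, n_ev)
  } else numeric()
  clean <- numeric(n_samples)
  kern_len <- ceiling(10 * cfg$tau_decay / 1000 * cfg$sampling_rate)
  kt <- (seq_len(kern_len) - 1) / cfg$sampling_rate * 1000 # ms
  kern <- biexp_waveform(kt, cfg$tau_rise, cfg$tau_decay)
  for (i in seq_len(n_ev)) {
    i0 <- floor(onsets[i] * cfg$sampling_rate) + 1L
    idx <- i0:min(n_samples, i0 + kern_len - 1L)
    if (i0 > n_samples) next
    clean[idx] <- clean[idx] - amps[i] * kern[seq_along(idx)]
  }
  noise <- if (cfg$baseline_noise_sd > 0)
    rnorm(n_samples, 0, cfg$baseline_noise_sd) else numeric(n_samples)
  gt <- list(config = cfg, event_onsets = onsets, event_amplitudes = amps)
  if (store_noise) { gt$noise <- noise; gt$clean <- clean }
  samples <- clean + noise
  if (!is.null(cfg$lowpass_hz))
    samples <- lowpass_filter(samples, cfg$sampling_rate, cfg$lowpass_hz)
  list(trace = trace(samples, cfg$sampling_rate), ground_truth = gt)
}

#' Simulate a Hill dose-response table
#'
#' Per cell and concentration `C`, peak current
#' `imax * C^hill / (C^hill + ec50^hill)` times multiplicative log-normal
#' noise of coefficient of variation `noise_cv`.
#'
#' @param ec50 half-maximal concentration (uM, > 0).
#' @param hill Hill coefficient (> 0).
#' @param imax maximal current magnitude (pA, > 0).
#' @param concentrations non-empty numeric vector of concentrations (uM).
#' @param noise_cv multiplicative noise CV (>= 0).
#' @param n_cells number of cells.
#' @param seed mandatory integer seed.
#' @return `data.frame` with columns `cell_id`, `concentration`,
#'   `peak_current`; generating parameters attached as attribute
#'   `"ground_truth"`.
#' @export
simulate_dose_response <- function(ec50, hill, imax, concentrations,
                                   noise_cv = 0.08, n_cells = 10, seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop_config("seed is mandatory in simulation configs")
  assert_number(ec50, "ec50", 0, strict = TRUE)
  assert_number(hill, "hill", 0, strict = TRUE)
  assert_number(imax, "imax", 0, strict = TRUE)
  assert_number(noise_cv, "noise_cv", 0)
  if (!length(concentrations))
    stop_config("concentrations must be non-empty")
  set.seed(seed)
  grid <- expand.grid(cell_id = seq_len(n_cells),
                      concentration = as.numeric(concentrations))
  mu <- imax * grid$concentration^hill /
    (grid$concentration^hill + ec50^hill)
  fac <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    rlnorm(nrow(grid), -sdlog^2 / 2, sdlog)
  } else 1
  out <- data.frame(cell_id = grid$cell_id,
                    concentration = grid$concentration,
                    peak_current = mu * fac)
  attr(out, "ground_truth") <- list(ec50 = ec50, hill = hill, imax = imax,
                                    noise_cv = noise_cv, n_cells = n_cells,
                                    seed = seed)
  out
}

#' Simulate a tonic current abolished by an antagonist step
#'
#' A stationary two-state ensemble runs until `block_onset`; afterwards all
#' channels are forced closed (full block, e.g. 2 uM strychnine) and only
#' baseline noise remains. The block is recorded as a `"strychnine"`
#' annotation.
#'
#' @param cfg a [channel_sim_config()].
#' @param block_onset block time in seconds, strictly inside the trace.
#' @param drug_label annotation label, default `"strychnine"`.
#' @return list with `trace` and `ground_truth` (stationary moments of the
#'   blocked component).
#' @export
simulate_tonic_block <- function(cfg, block_onset,
                                 drug_label = "strychnine") {
  stopifnot(inherits(cfg, "channel_sim_config"))
  if (!is.finite(block_onset) || block_onset <= 0 ||
      block_onset >= cfg$duration)
    stop_config("block_onset must lie strictly inside the trace")
  set.seed(cfg$seed)
  n_samples <- round(cfg$duration * cfg$sampling_rate)
  dt <- 1 / cfg$sampling_rate
  n_pre <- round(block_onset * cfg$sampling_rate)
  counts <- integer(n_samples)
  counts[seq_len(n_pre)] <-
    sim_ensemble_counts(cfg$n_channels, cfg$k_open, cfg$k_close, n_pre, dt)
  noise <- if (cfg$baseline_noise_sd > 0)
    rnorm(n_samples, 0, cfg$baseline_noise_sd) else numeric(n_samples)
  samples <- -cfg$unitary_current * counts + noise
  p <- stationary_popen(cfg)
  ann <- data.frame(label = drug_label, onset = block_onset,
                    offset = cfg$duration, stringsAsFactors = FALSE)
  gt <- list(config = cfg, p_open = p,
             mean_current = cfg$n_channels * cfg$unitary_current * p,
             channel_variance = cfg$unitary_current^2 * cfg$n_channels *
               p * (1 - p),
             block_onset = block_onset)
  list(trace = trace(samples, cfg$sampling_rate, annotations = ann),
       ground_truth = gt)
}

#' Write ground truth as a JSON sidecar file
#' @param ground_truth list as returned by the simulators.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  gt$open_counts <- NULL # bulky; regenerable from config + seed
  gt$noise <- NULL
  gt$clean <- NULL
  if (!is.null(gt$popen) && length(gt$popen) > 1000)
    gt$popen <- NULL
  if (!is.null(gt$mean_current_t) && length(gt$mean_current_t) > 1000)
    gt$mean_current_t <- NULL
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
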