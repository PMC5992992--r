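#' Peak current of an agonist application
#'
#' Magnitude of the extremum of the 50 Hz low-passed, baseline-subtracted
#' current within the application window. The baseline is the mean over the
#' 5 s preceding the application (clipped to the trace start).
#'
#' @param trace a [trace()].
#' @param application_window `(from, to)` seconds.
#' @param lowpass_hz smoothing cutoff, default 50 Hz.
#' @param baseline_s baseline length before the window, default 5 s.
#' @return peak current magnitude in pA.
#' @export
measure_peak_current <- function(trace, application_window, lowpass_hz = 50,
                                 baseline_s = 5) {
  fs <- trace$sampling_rate
  idx <- window_idx(trace, application_window[1], application_window[2])
  lp <- lowpass_filter(trace$samples, fs, lowpass_hz)
  b1 <- application_window[1]
  b0 <- max(trace$start_time, b1 - baseline_s)
  if (b1 <= trace$start_time) {
    baseline <- lp[1]
  } else {
    baseline <- mean(lp[window_idx(trace, b0, b1)])
  }
  max(abs(lp[idx] - baseline))
}

hill_current <- function(conc, imax, ec50, hill)
  imax * conc^hill / (conc^hill + ec50^hill)

#' Fit a Hill dose-response curve
#'
#' Peak currents are averaged per concentration across cells (as in standard
#' practice) and the Hill sigmoid
#' `I(C) = I_max * C^n / (C^n + EC50^n)` is fitted by least squares with
#' free slope and free maximum. `I(EC50) = I_max / 2` by construction.
#'
#' @param table `data.frame` with columns `cell_id`, `concentration` (uM)
#'   and `peak_current` (pA magnitude); at least 4 distinct concentrations.
#' @param per_cell fit on all per-cell points instead of per-concentration
#'   means (exposed alternative; default `FALSE`).
#' @return object of class `dose_response_fit`: `ec50`, `hill`, `imax`,
#'   standard errors (`se_ec50`, `se_hill`, `se_imax`), `n_cells` per
#'   concentration, `flagged` (non-convergence handled by a fallback
#'   optimizer, or EC50 outside the tested range x10).
#' @export
fit_dose_response <- function(table, per_cell = FALSE) {
  stopifnot(all(c("concentration", "peak_current") %in% names(table)))
  concs <- sort(unique(table$concentration))
  if (length(concs) < 4L)
    stop_config("need >= 4 distinct concentrations")
  means <- vapply(concs, function(cc)
    mean(table$peak_current[table$concentration == cc]), 0)
  ncells <- vapply(concs, function(cc)
    length(unique(table$cell_id[table$concentration == cc])), 0L)
  dat <- if (per_cell)
    data.frame(conc = table$concentration, I = table$peak_current)
  else data.frame(conc = concs, I = means)
  imax0 <- max(dat$I)
  ec0 <- dat$conc[which.min(abs(dat$I - imax0 / 2))]
  flagged <- FALSE
  fit <- tryCatch(
    nls(I ~ hill_current(conc, imax, ec50, hill), data = dat,
        start = list(imax = imax0, ec50 = ec0, hill = 1),
        control = stats::nls.control(maxiter = 200, warnOnly = FALSE),
        algorithm = "port",
        lower = c(imax = imax0 * 0.1, ec50 = min(concs) / 100,
                  hill = 0.1),
        upper = c(imax = imax0 * 100, ec50 = max(concs) * 100, hill = 10)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))),
                   error = function(e) rep(NA_real_, 3))
    names(se) <- names(cf)
  } else {
    # fallback: Nelder-Mead on log parameters
    flagged <- TRUE
    obj <- function(par) {
      p <- exp(par)
      sum((dat$I - hill_current(dat$conc, p[1], p[2], p[3]))^2)
    }
    op <- optim(log(c(imax0, ec0, 1.5)), obj,
                control = list(maxit = 2000, reltol = 1e-12))
    cf <- setNames(exp(op$par), c("imax", "ec50", "hill"))
    se <- setNames(rep(NA_real_, 3), c("imax", "ec50", "hill"))
  }
  if (cf[["ec50"]] > max(concs) * 10 || cf[["ec50"]] < min(concs) / 10)
    flagged <- TRUE
  out <- list(ec50 = unname(cf[["ec50"]]), hill = unname(cf[["hill"]]),
              imax = unname(cf[["imax"]]),
              se_ec50 = unname(se[["ec50"]]), se_hill = unname(se[["hill"]]),
              se_imax = unname(se[["imax"]]),
              concentrations = concs, mean_currents = means,
              n_cells = ncells, per_cell = per_cell, flagged = flagged)
  class(out) <- "dose_response_fit"
  out
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(
    "<dose_response_fit> EC50 = %.3g uM (se %.2g), hill = %.3g, Imax = %.3g pA%s\n",
    x$ec50, x$se_ec50, x$hill, x$imax,
    if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Tonic-inhibition shift at an antagonist step
#'
#' Quantifies tonic (standing) current blocked by an antagonist: the change
#' in holding current and in current variance between a pre-drug window and
#' a post-drug window separated by an equilibration gap.
#'
#' `delta_holding` is reported as the magnitude of the blocked inward
#' current, `mean(post) - mean(pre)` under the inward-negative convention;
#' `delta_variance = var(pre) - var(post)` on the band-passed (AC) signal.
#'
#' @param trace a [trace()] carrying an annotation whose label matches
#'   `drug_label`.
#' @param drug_label annotation label (e.g. `"strychnine"`).
#' @param pre_s,post_s window lengths in seconds (default 10 each).
#' @param equilibration_s gap after drug onset before the post window
#'   (default 5 s).
#' @param bandpass AC band for the variance (Hz), default `c(1, 2000)`.
#' @return object of class `tonic_shift`: `delta_holding` (pA),
#'   `delta_variance` (pA^2), `pre_window`, `post_window`.
#' @export
measure_tonic_shift <- function(trace, drug_label = "strychnine",
                                pre_s = 10, post_s = 10,
                                equilibration_s = 5,
                                bandpass = c(1, 2000)) {
  hit <- which(trace$annotations$label == drug_label)
  if (!length(hit))
    stop_config("no annotation labelled '", drug_label, "' on the trace")
  onset <- trace$annotations$onset[hit[1]]
  fs <- trace$sampling_rate
  t_end <- trace$start_time + trace_duration(trace)
  pre <- c(max(trace$start_time, onset - pre_s), onset)
  post <- c(onset + equilibration_s,
            min(t_end, onset + equilibration_s + post_s))
  if (post[2] <= post[1])
    stop_config("trace too short after the drug onset for a post window")
  hi <- min(bandpass[2], 0.45 * fs)
  ip <- window_idx(trace, pre[1], pre[2])
  iq <- window_idx(trace, post[1], post[2])
  # band-pass each window separately so the holding-current step at the
  # drug onset cannot leak high-passed transients into the variances
  ac_pre <- bandpass_filter(trace$samples[ip], fs, lo = bandpass[1], hi = hi)
  ac_post <- bandpass_filter(trace$samples[iq], fs, lo = bandpass[1], hi = hi)
  out <- list(delta_holding = mean(trace$samples[iq]) -
                mean(trace$samples[ip]),
              delta_variance = var(ac_pre) - var(ac_post),
              pre_window = pre, post_window = post,
              drug_label = drug_label)
  class(out) <- "tonic_shift"
  out
}

#' @export
print.tonic_shift <- function(x, ...) {
  cat(sprintf(
    "<tonic_shift:%s> delta holding = %.3g pA, delta variance = %.3g pA^2\n",
    x$drug_label, x$delta_holding, x$delta_variance))
  invisible(x)
}

#' Read/write dose-response tables
#'
#' CSV with columns `cell_id`, `concentration_um`, `peak_pa` (external
#' interface) mapped to the internal `concentration` / `peak_current` names.
#'
#' @param path CSV path.
#' @param table internal dose table.
#' @return a `data.frame` (read) or `path` (write).
#' @export
read_dose_table <- function(path) {
  dt <- data.table::fread(path)
  out <- data.frame(cell_id = dt$cell_id,
                    concentration = dt[["concentration_um"]] %||%
                      dt[["concentration"]],
                    peak_current = dt[["peak_pa"]] %||% dt[["peak_current"]])
  out
}

#' @rdname read_dose_table
#' @export
write_dose_table <- function(table, path) {
  data.table::fwrite(data.table::data.table(
    cell_id = table$cell_id, concentration_um = table$concentration,
    peak_pa = table$peak_current), path)
  invisible(path)
}
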