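#' Windowed variance-mean data from a slowly changing agonist response
#'
#' Implements stationary noise analysis bookkeeping: the trace is split into
#' consecutive non-overlapping windows; per window the mean current `I_m`
#' (magnitude, relative to the control holding current measured on the DC
#' trace) and the variance of a band-pass filtered AC-coupled copy of the
#' signal are computed. The control background variance (AC variance over
#' `control_window`) is subtracted from every window's variance; windows
#' whose net variance goes negative are flagged, not dropped.
#'
#' @param trace a [trace()] recorded during a slowly changing agonist
#'   application.
#' @param control_window `(from, to)` seconds of agonist-free control; must
#'   precede any drug annotation on the trace.
#' @param window_length analysis window length in seconds (>= 0.05),
#'   default 0.1.
#' @param bandpass AC band edges in Hz, default `c(1, 2000)` (removes slow
#'   drift, keeps the gating band).
#' @param detrend linearly detrend each window's AC signal before taking the
#'   variance. Default `FALSE`: the zero-phase high-pass already removes
#'   drift, and window-local detrending of autocorrelated gating noise
#'   shrinks the variance by roughly `2 tau / T` per removed degree of
#'   freedom, biasing the unitary current downward.
#' @return object of class `variance_mean` with `points`
#'   (`data.frame(I_m, variance, flagged)` where `variance` is net of
#'   background), `background_variance`, `window_length`, `n_windows`.
#' @export
compute_variance_mean <- function(trace, control_window,
                                  window_length = 0.1,
                                  bandpass = c(1, 2000), detrend = FALSE) {
  fs <- trace$sampling_rate
  if (window_length < 0.05)
    stop_config("window_length must be >= 0.05 s")
  if (nrow(trace$annotations) &&
      control_window[2] > min(trace$annotations$onset))
    stop_config("control window overlaps a drug annotation")
  hi <- min(bandpass[2], 0.45 * fs)
  ac <- bandpass_filter(trace$samples, fs, lo = bandpass[1], hi = hi)
  ctrl <- window_idx(trace, control_window[1], control_window[2])
  ctrl_hold <- mean(trace$samples[ctrl])
  # the AC signal is zero-mean by construction (high-passed), so variances
  # are mean squares: no window-local mean subtraction, no 2*tau/T shrinkage.
  # The background comes from the control segment filtered in isolation, so
  # any sharp transition at the control/drug boundary cannot leak into it.
  ac_ctrl <- bandpass_filter(trace$samples[ctrl], fs, lo = bandpass[1],
                             hi = hi)
  background <- mean(ac_ctrl^2)
  wlen <- round(window_length * fs)
  n_win <- floor(length(trace$samples) / wlen)
  Im <- vr <- numeric(0)
  tt0 <- seq_len(wlen)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * wlen + 1L):(w * wlen)
    if (idx[1] <= max(ctrl) && idx[wlen] >= min(ctrl)) next # skip control
    dc_mean <- mean(trace$samples[idx])
    seg <- ac[idx]
    if (detrend) seg <- stats::residuals(stats::lm.fit(cbind(1, tt0), seg))
    Im <- c(Im, abs(dc_mean - ctrl_hold))
    vr <- c(vr, mean(seg^2))
  }
  net <- vr - background
  out <- list(points = data.frame(I_m = Im, variance = net,
                                  flagged = net < 0),
              background_variance = background,
              window_length = window_length, n_windows = length(Im))
  class(out) <- "variance_mean"
  out
}

#' Construct variance-mean data directly from points
#'
#' Useful for testing and for importing externally computed variance-mean
#' pairs.
#'
#' @param I_m mean current magnitudes (pA).
#' @param variance net variances (pA^2).
#' @param background_variance background variance (pA^2).
#' @param window_length window length (s).
#' @return a `variance_mean` object.
#' @export
variance_mean_data <- function(I_m, variance, background_variance = 0,
                               window_length = 0.1) {
  if (any(I_m < 0)) stop_config("I_m values must be >= 0 (magnitudes)")
  out <- list(points = data.frame(I_m = I_m, variance = variance,
                                  flagged = variance < 0),
              background_variance = background_variance,
              window_length = window_length, n_windows = length(I_m))
  class(out) <- "variance_mean"
  out
}

#' @export
print.variance_mean <- function(x, ...) {
  cat(sprintf("<variance_mean> %d windows of %g s, background %.3g pA^2\n",
              x$n_windows, x$window_length, x$background_variance))
  cat(sprintf("  I_m range [%.3g, %.3g] pA, %d flagged negative\n",
              min(x$points$I_m), max(x$points$I_m), sum(x$points$flagged)))
  invisible(x)
}

#' Parabolic fit of the variance-mean relationship
#'
#' Weighted least squares of `var(I_m) = I_u * I_m - I_m^2 / N_c` through the
#' origin (binomial channel noise for identical independent two-state
#' channels), giving the unitary current `I_u` and channel number `N_c`. The
#' fit is rejected (condition of class `glyrfluct_fit_error`) when the
#' curvature term is non-negative or statistically indistinguishable from
#' zero, prompting the linear fallback of [fit_linear_initial()].
#'
#' @param data a `variance_mean` object with at least 8 points spanning at
#'   least 50% of the peak current.
#' @param weights `"variance"` (default; weights proportional to
#'   `1 / total-variance^2`, i.e. inverse expected variance-of-variance) or
#'   `"none"` for plain least squares.
#' @return object of class `noise_fit` with `I_u`, `N_c`, `se_I_u`, `se_N_c`,
#'   `fit_kind = "parabolic"`, `r_squared`; `P_o` is `NA` until
#'   [open_probability()] is applied.
#' @export
fit_parabolic <- function(data, weights = c("variance", "none")) {
  weights <- match.arg(weights)
  pts <- data$points
  if (nrow(pts) < 8L)
    stop_fit("parabolic fit needs >= 8 variance-mean points")
  imax <- max(pts$I_m)
  if (imax <= 0 || (imax - min(pts$I_m)) < 0.5 * imax)
    stop_fit("points must span >= 50% of the peak current")
  X <- cbind(I = pts$I_m, I2 = pts$I_m^2)
  y <- pts$variance
  wls <- function(w) {
    fit <- lm(y ~ X - 1, weights = w)
    # suppressed: summary.lm warns about "essentially perfect fit" on exact
    # synthetic data, where a zero residual is the point of the test
    list(b = coef(fit), V = suppressWarnings(vcov(fit)), fit = fit)
  }
  f <- wls(NULL)
  if (weights == "variance") {
    pred <- pmax(X %*% f$b, 0) + data$background_variance
    floorv <- max(data$background_variance, 1e-12)
    w <- 1 / pmax(pred, 0.05 * max(pred))^2
    f <- wls(as.numeric(w))
  }
  b1 <- unname(f$b[1]); b2 <- unname(f$b[2])
  se <- sqrt(diag(f$V))
  # degenerate (straight-line) data: curvature numerically zero
  degenerate <- abs(b2) * imax <= 1e-8 * abs(b1)
  if (b2 >= 0 || degenerate || b2 + 1.96 * se[2] >= 0)
    stop_fit("no downward curvature in the variance-mean relationship; ",
             "use fit_linear_initial()")
  N_c <- -1 / b2
  out <- list(I_u = b1, N_c = N_c, P_o = NA_real_,
              se_I_u = unname(se[1]),
              se_N_c = unname(se[2]) / b2^2,
              fit_kind = "parabolic",
              r_squared = 1 - sum(stats::residuals(f$fit)^2 *
                                    (f$fit$weights %||% 1)) /
                sum((y - mean(y))^2 * (f$fit$weights %||% 1)))
  class(out) <- "noise_fit"
  out
}

#' Linear fit of the initial variance-mean relationship
#'
#' Fallback when no satisfactory parabola exists: the initial (low open
#' probability) portion of the variance-mean plot follows
#' `variance = I_u * I_m`, so the origin-constrained slope estimates `I_u`.
#' `N_c` is undefined for this fit kind.
#'
#' @param data a `variance_mean` object.
#' @param initial_fraction use points with `I_m` at or below this fraction of
#'   the maximum `I_m` (default 0.3); at least 4 such points are required
#'   (a single-point dataset is allowed and handled by the direct ratio
#'   `I_u = variance / I_m`).
#' @return a `noise_fit` with `fit_kind = "linear"`, `N_c = NA`; a
#'   `nonphysical` flag is set when the fitted slope is not positive.
#' @export
fit_linear_initial <- function(data, initial_fraction = 0.3) {
  pts <- data$points
  if (nrow(pts) == 1L) {
    if (pts$I_m <= 0) stop_fit("single point must have I_m > 0")
    iu <- pts$variance / pts$I_m
    out <- list(I_u = iu, N_c = NA_real_, P_o = NA_real_,
                se_I_u = NA_real_, se_N_c = NA_real_, fit_kind = "linear",
                r_squared = NA_real_, nonphysical = iu <= 0)
    class(out) <- "noise_fit"
    if (out$nonphysical)
      warning("fitted unitary current is not positive (nonphysical)")
    return(out)
  }
  keep <- pts$I_m <= initial_fraction * max(pts$I_m)
  if (sum(keep) < 4L)
    stop_fit("need >= 4 points in the initial ", initial_fraction,
             " fraction of peak current")
  sub <- pts[keep, , drop = FALSE]
  fit <- lm(variance ~ I_m - 1, data = sub)
  iu <- unname(coef(fit)[1])
  smry <- suppressWarnings(summary(fit)) # perfect exact fits warn
  out <- list(I_u = iu, N_c = NA_real_, P_o = NA_real_,
              se_I_u = unname(sqrt(diag(smry$cov.unscaled)) *
                                smry$sigma)[1],
              se_N_c = NA_real_, fit_kind = "linear",
              r_squared = smry$r.squared,
              nonphysical = iu <= 0)
  class(out) <- "noise_fit"
  if (out$nonphysical)
    warning("fitted unitary current is not positive (nonphysical)")
  out
}

#' Fit noise data with parabolic-then-linear fallback
#'
#' Attempts [fit_parabolic()]; on rejection (no satisfactory parabola)
#' returns [fit_linear_initial()], mirroring the practice of fitting only the
#' initial portion linearly when the parabola fails.
#'
#' @param data a `variance_mean` object.
#' @param peak_current optional peak current (pA magnitude) to derive `P_o`
#'   via [open_probability()] when the parabolic fit succeeds.
#' @inheritParams fit_parabolic
#' @return a `noise_fit`.
#' @export
fit_noise <- function(data, peak_current = NULL,
                      weights = c("variance", "none")) {
  fit <- tryCatch(fit_parabolic(data, weights = weights),
                  glyrfluct_fit_error = function(e) NULL)
  if (is.null(fit)) return(fit_linear_initial(data))
  if (!is.null(peak_current))
    fit$P_o <- open_probability(peak_current, fit)
  fit
}

#' Open probability from the peak current and a parabolic fit
#'
#' `P_o = I_peak / (I_u * N_c)`. Values in `(1, 1.05]` are clamped to 1 with
#' a warning; values outside `(0, 1.05]` are an error.
#'
#' @param peak_current peak current magnitude (pA, > 0).
#' @param fit a parabolic `noise_fit`.
#' @return open probability in `(0, 1]`.
#' @export
open_probability <- function(peak_current, fit) {
  if (!identical(fit$fit_kind, "parabolic"))
    stop_fit("open probability needs a parabolic fit (N_c unknown)")
  assert_number(peak_current, "peak_current", 0, strict = TRUE)
  po <- peak_current / (fit$I_u * fit$N_c)
  if (po <= 0 || po > 1.05)
    stop_fit("derived open probability ", signif(po, 3),
             " outside (0, 1.05]")
  if (po > 1 + 1e-9) {
    warning("open probability ", signif(po, 3), " clamped to 1")
    po <- 1
  } else if (po > 1) po <- 1 # numerical round-off, not worth a warning
  po
}

#' @export
print.noise_fit <- function(x, ...) {
  cat(sprintf("<noise_fit:%s> I_u = %.3g pA (se %.2g)", x$fit_kind, x$I_u,
              x$se_I_u))
  if (identical(x$fit_kind, "parabolic"))
    cat(sprintf(", N_c = %.3g (se %.2g)", x$N_c, x$se_N_c))
  if (is.finite(x$P_o)) cat(sprintf(", P_o = %.3g", x$P_o))
  cat(sprintf(", r2 = %.3f\n", x$r_squared))
  invisible(x)
}
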