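## Welch power spectral density: averaged modified periodograms, Hann
## window, 50% overlap. One-sided, normalized so that sum(psd) * df equals
## the signal variance (Parseval).
welch_psd <- function(x, fs, seg_seconds = 8, overlap = 0.5) {
  nseg <- min(length(x), max(16L, round(seg_seconds * fs)))
  if (nseg %% 2L == 1L) nseg <- nseg - 1L
  hop <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1)))
  U <- sum(w^2)
  nf <- nseg %/% 2L
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / (fs * U)
    half <- P[1:(nf + 1L)]
    half[2:nf] <- 2 * half[2:nf] # one-sided doubling (not DC/Nyquist)
    acc <- acc + half
  }
  psd <- acc / length(starts)
  freq <- (0:nf) * fs / nseg
  list(frequencies = freq[-1L], psd = psd[-1L], df = fs / nseg,
       n_segments = length(starts))
}

#' One-sided (net) power spectral density of a current segment
#'
#' Averaged modified periodograms (Hann window, 50% overlap, segment mean
#' removed). With a control segment, the net spectrum drug minus control is
#' returned, truncated to frequencies below `fmax` (200 Hz by default, the
#' band carrying channel-gating information). The full-band integral of each
#' one-sided spectrum matches the segment variance (Parseval), recorded in
#' the `parseval_ratio` field.
#'
#' @param trace_segment a [trace()] of the steady-state drug response
#'   (>= 10 s recommended).
#' @param control_segment optional control [trace()] at the same sampling
#'   rate; `NULL` returns the raw spectrum.
#' @param fmax upper frequency bound for the returned spectrum (Hz).
#' @param seg_seconds Welch segment length in seconds (default 8, i.e.
#'   resolution well below 0.5 Hz).
#' @return object of class `power_spectrum`: `frequencies`, `psd`, `is_net`,
#'   `fmax_used`, `df`, `parseval_ratio` (integral / variance for the drug
#'   segment), `n_negative` (net points below zero, excluded from fitting).
#' @export
compute_psd <- function(trace_segment, control_segment = NULL, fmax = 200,
                        seg_seconds = 8) {
  fs <- trace_segment$sampling_rate
  p1 <- welch_psd(trace_segment$samples, fs, seg_seconds)
  pr <- sum(p1$psd) * p1$df / var(trace_segment$samples)
  psd <- p1$psd
  is_net <- FALSE
  if (!is.null(control_segment)) {
    if (!isTRUE(all.equal(control_segment$sampling_rate, fs)))
      stop_config("drug and control segments must share a sampling rate")
    p0 <- welch_psd(control_segment$samples, fs, seg_seconds)
    psd <- psd - p0$psd
    is_net <- TRUE
  }
  keep <- p1$frequencies < fmax
  out <- list(frequencies = p1$frequencies[keep], psd = psd[keep],
              is_net = is_net, fmax_used = fmax, df = p1$df,
              parseval_ratio = pr, n_negative = sum(psd[keep] < 0))
  class(out) <- "power_spectrum"
  out
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf(
    "<power_spectrum>%s %d points, %.3g-%.3g Hz (df %.3g), %d negative\n",
    if (x$is_net) " net," else "", length(x$frequencies),
    min(x$frequencies), max(x$frequencies), x$df, x$n_negative))
  invisible(x)
}

## log-space least squares on net-positive points
spectrum_fit_points <- function(spectrum) {
  keep <- spectrum$psd > 0
  if (sum(keep) < 10L)
    stop_fit("need >= 10 net-positive spectral points")
  list(f = spectrum$frequencies[keep], s = spectrum$psd[keep])
}

lorentz1 <- function(f, s0, fc) s0 / (1 + (f / fc)^2)

#' Fit a single Lorentzian to a power spectrum
#'
#' Least squares in log-power space (periodogram errors are multiplicative)
#' of `S(f) = S_o / (1 + (f/f_c)^2)`. The gating time constant is
#' `tau = 1 / (2 * pi * f_c)`.
#'
#' @param spectrum a `power_spectrum`; negative net points are excluded.
#' @return object of class `lorentzian_fit`: `s0` (pA^2/Hz), `fc` (Hz),
#'   `tau` (s), `components = 1`, `rss` (log-space residual sum of squares),
#'   `n_points`.
#' @export
fit_single_lorentzian <- function(spectrum) {
  pts <- spectrum_fit_points(spectrum)
  logs <- log(pts$s)
  obj <- function(par) {
    sum((logs - log(lorentz1(pts$f, exp(par[1]), exp(par[2]))))^2)
  }
  s0_init <- exp(mean(logs[pts$f <= quantile(pts$f, 0.1)]))
  half <- pts$f[which(pts$s < s0_init / 2)[1]]
  fc_init <- if (is.finite(half) && length(half)) half else median(pts$f)
  fit <- optim(c(log(s0_init), log(max(fc_init, min(pts$f)))), obj,
               method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  if (fit$convergence != 0)
    stop_fit("single-Lorentzian fit did not converge")
  s0 <- exp(fit$par[1]); fc <- exp(fit$par[2])
  out <- list(s0 = s0, fc = fc, tau = 1 / (2 * pi * fc), components = 1L,
              rss = fit$value, n_points = length(pts$f))
  class(out) <- "lorentzian_fit"
  out
}

#' Fit a sum of two Lorentzians to a power spectrum
#'
#' `S(f) = S_o1/(1+(f/f_c1)^2) + S_o2/(1+(f/f_c2)^2)` fitted in log-power
#' space; components are ordered `fc1 < fc2` and a single weighted time
#' constant is formed from the zero-frequency powers:
#' `tau_w = tau1 * S_o1/(S_o1+S_o2) + tau2 * S_o2/(S_o1+S_o2)`.
#'
#' Degenerate solutions (corner frequencies within 5% of each other) signal
#' a fit error so callers fall back to the single-Lorentzian description.
#'
#' @param spectrum a `power_spectrum`.
#' @return a `lorentzian_fit` with `components = 2` and fields `s01`, `s02`,
#'   `fc1`, `fc2`, `tau1`, `tau2`, `tau_w`; `s0`, `fc`, `tau` mirror the
#'   dominant (slower) component for printing.
#' @export
fit_double_lorentzian <- function(spectrum) {
  pts <- spectrum_fit_points(spectrum)
  logs <- log(pts$s)
  model <- function(par) {
    lorentz1(pts$f, exp(par[1]), exp(par[2])) +
      lorentz1(pts$f, exp(par[3]), exp(par[4]))
  }
  obj <- function(par) sum((logs - log(model(par)))^2)
  single <- fit_single_lorentzian(spectrum)
  starts <- list(
    c(log(single$s0), log(single$fc / 5), log(single$s0 / 4),
      log(single$fc * 5)),
    c(log(single$s0), log(single$fc / 2), log(single$s0 / 10),
      log(single$fc * 10)),
    c(log(single$s0 / 2), log(single$fc / 10), log(single$s0 / 2),
      log(single$fc * 2)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(optim(st, obj, method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-14)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best) || best$convergence != 0)
    stop_fit("double-Lorentzian fit did not converge")
  s <- exp(best$par[c(1, 3)]); fc <- exp(best$par[c(2, 4)])
  ord <- order(fc)
  s <- s[ord]; fc <- fc[ord]
  if (abs(fc[2] - fc[1]) / fc[2] < 0.05)
    stop_fit("degenerate double-Lorentzian (corner frequencies within 5%)")
  tau <- 1 / (2 * pi * fc)
  wsum <- s[1] + s[2]
  tau_w <- tau[1] * s[1] / wsum + tau[2] * s[2] / wsum
  out <- list(s0 = s[1], fc = fc[1], tau = tau[1], components = 2L,
              s01 = s[1], s02 = s[2], fc1 = fc[1], fc2 = fc[2],
              tau1 = tau[1], tau2 = tau[2], tau_w = tau_w,
              rss = best$value, n_points = length(pts$f))
  class(out) <- "lorentzian_fit"
  out
}

#' Weighted time constant from two-Lorentzian parameters
#'
#' `tau_w = tau1 * S_o1/(S_o1+S_o2) + tau2 * S_o2/(S_o1+S_o2)`.
#'
#' @param tau1,tau2 component time constants.
#' @param s01,s02 zero-frequency spectral powers.
#' @return the weighted time constant.
#' @export
weighted_tau <- function(tau1, tau2, s01, s02)
  tau1 * s01 / (s01 + s02) + tau2 * s02 / (s01 + s02)

#' Choose between single- and double-Lorentzian fits
#'
#' Extra-sum-of-squares F-test on the log-space residuals at `alpha`; the
#' two-component description is retained only when it improves the fit
#' significantly (and, with equal residuals, parsimony keeps the single
#' Lorentzian).
#'
#' @param single a single-component `lorentzian_fit`.
#' @param double a two-component `lorentzian_fit`, or `NULL` (single wins).
#' @param spectrum the fitted `power_spectrum` (for bookkeeping).
#' @param alpha significance level, default 0.05.
#' @return the selected `lorentzian_fit` with fields `selected` ("single" or
#'   "double"), `f_statistic`, `p_value`.
#' @export
select_model <- function(single, double, spectrum, alpha = 0.05) {
  if (is.null(double)) {
    single$selected <- "single"
    single$f_statistic <- NA_real_
    single$p_value <- NA_real_
    return(single)
  }
  n <- single$n_points
  df2 <- n - 4L
  improved <- single$rss - double$rss
  if (improved <= 0 || df2 <= 0) {
    single$selected <- "single"
    single$f_statistic <- 0
    single$p_value <- 1
    return(single)
  }
  fstat <- (improved / 2) / (double$rss / df2)
  p <- pf(fstat, 2, df2, lower.tail = FALSE)
  pick <- if (p < alpha) double else single
  pick$selected <- if (p < alpha) "double" else "single"
  pick$f_statistic <- fstat
  pick$p_value <- p
  pick
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  if (x$components == 1L) {
    cat(sprintf("<lorentzian_fit> S_o = %.3g pA^2/Hz, f_c = %.3g Hz, tau = %.3g ms\n",
                x$s0, x$fc, 1000 * x$tau))
  } else {
    cat(sprintf("<lorentzian_fit, 2 components> tau_w = %.3g ms\n",
                1000 * x$tau_w))
    cat(sprintf("  1: S_o = %.3g, f_c = %.3g Hz, tau = %.3g ms\n",
                x$s01, x$fc1, 1000 * x$tau1))
    cat(sprintf("  2: S_o = %.3g, f_c = %.3g Hz, tau = %.3g ms\n",
                x$s02, x$fc2, 1000 * x$tau2))
  }
  invisible(x)
}
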