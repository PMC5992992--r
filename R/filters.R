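#' Zero-phase FFT filters
#'
#' Band-, low- and high-pass filtering by masking Fourier coefficients, which
#' is zero-phase by construction. Appropriate for the long (tens of seconds)
#' records this package works on; edge effects are confined to roughly one
#' period of the cutoff frequency at each end.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param lo,hi band edges in Hz; `NULL` disables that edge.
#' @return filtered numeric vector of the same length.
#' @export
bandpass_filter <- function(x, fs, lo = NULL, hi = NULL) {
  n <- length(x)
  if (n < 2L) return(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f) # fold to two-sided magnitude
  keep <- rep(TRUE, n)
  if (!is.null(lo) && lo > 0) keep <- keep & (f >= lo)
  if (!is.null(hi) && hi < fs / 2) keep <- keep & (f <= hi)
  if (all(keep)) return(x)
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

#' @rdname bandpass_filter
#' @param cutoff cutoff frequency in Hz.
#' @export
lowpass_filter <- function(x, fs, cutoff) bandpass_filter(x, fs, hi = cutoff)

#' @rdname bandpass_filter
#' @export
highpass_filter <- function(x, fs, cutoff) bandpass_filter(x, fs, lo = cutoff)
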