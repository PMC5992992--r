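#' Whole-cell current trace container
#'
#' A `glyr_trace` is the universal signal container of the package: a
#' uniformly sampled whole-cell current in pA with its sampling rate, start
#' time and drug-application annotations. Inward current is negative.
#'
#' @param samples numeric vector of current samples (pA, inward negative).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param start_time time of the first sample in seconds.
#' @param annotations `data.frame` with columns `label`, `onset`, `offset`
#'   (seconds) marking drug applications, or `NULL`.
#' @param units character, currently always `"pA"`.
#' @return An object of class `glyr_trace`.
#' @export
trace <- function(samples, sampling_rate, start_time = 0,
                  annotations = NULL, units = "pA") {
  assert_number(sampling_rate, "sampling_rate", 0, strict = TRUE)
  if (!is.numeric(samples) || length(samples) < 1L)
    stop_config("samples must be a non-empty numeric vector")
  if (any(!is.finite(samples)))
    stop_config("all trace samples must be finite")
  if (is.null(annotations)) {
    annotations <- data.frame(label = character(), onset = numeric(),
                              offset = numeric(), stringsAsFactors = FALSE)
  } else {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    stopifnot(all(c("label", "onset", "offset") %in% names(annotations)))
    end <- start_time + length(samples) / sampling_rate
    if (nrow(annotations) &&
        (any(annotations$onset < start_time - 1e-9) ||
         any(annotations$offset > end + 1e-9)))
      stop_config("annotations must lie within the trace time span")
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 start_time = start_time,
                 annotations = annotations,
                 units = units),
            class = "glyr_trace")
}

#' @export
print.glyr_trace <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<glyr_trace> %d samples @ %g Hz (%.3f s), units %s\n",
              length(x$samples), x$sampling_rate, dur, x$units))
  cat(sprintf("  mean %.2f pA, sd %.2f pA\n",
              mean(x$samples), stats::sd(x$samples)))
  if (nrow(x$annotations))
    for (i in seq_len(nrow(x$annotations)))
      cat(sprintf("  annotation: %s [%g, %g] s\n", x$annotations$label[i],
                  x$annotations$onset[i], x$annotations$offset[i]))
  invisible(x)
}

#' @export
length.glyr_trace <- function(x) length(x$samples)

#' Trace duration in seconds
#' @param x a `glyr_trace`.
#' @return duration in seconds.
#' @export
trace_duration <- function(x) length(x$samples) / x$sampling_rate

#' Time axis of a trace
#' @param x a `glyr_trace`.
#' @return numeric vector of sample times (s).
#' @export
trace_times <- function(x)
  x$start_time + (seq_along(x$samples) - 1L) / x$sampling_rate

## index range for a [from, to) time window, clipped to the trace
window_idx <- function(tr, from, to) {
  n <- length(tr$samples)
  i0 <- floor((from - tr$start_time) * tr$sampling_rate) + 1L
  i1 <- ceiling((to - tr$start_time) * tr$sampling_rate)
  if (i1 < 1L || i0 > n) stop_range("window [", from, ", ", to,
                                    "] s lies outside the trace")
  seq.int(max(1L, i0), min(n, i1))
}

#' Extract a time window of a trace as a new trace
#' @param x a `glyr_trace`.
#' @param from,to window bounds in seconds.
#' @return a `glyr_trace` covering `[from, to)`.
#' @export
trace_window <- function(x, from, to) {
  idx <- window_idx(x, from, to)
  keep <- x$annotations[x$annotations$onset < to &
                          x$annotations$offset > from, , drop = FALSE]
  if (nrow(keep)) {
    keep$onset <- pmax(keep$onset, from)
    keep$offset <- pmin(keep$offset, to)
  }
  trace(x$samples[idx], x$sampling_rate,
        start_time = x$start_time + (idx[1] - 1L) / x$sampling_rate,
        annotations = keep, units = x$units)
}

## ---------------------------------------------------------------------------
## CSV trace format: '#'-prefixed header lines then one sample per line.
##   # sampling_rate_hz=20000
##   # units=pA
##   # start_time_s=0
##   # annotation=strychnine,30.0,60.0

#' Write a trace to the package CSV format
#'
#' @param x a `glyr_trace`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  hdr <- c(sprintf("# sampling_rate_hz=%.10g", x$sampling_rate),
           sprintf("# units=%s", x$units),
           sprintf("# start_time_s=%.10g", x$start_time))
  if (nrow(x$annotations))
    hdr <- c(hdr, sprintf("# annotation=%s,%.10g,%.10g",
                          x$annotations$label, x$annotations$onset,
                          x$annotations$offset))
  con <- file(path, "w")
  writeLines(hdr, con)
  close(con)
  data.table::fwrite(data.table::data.table(x$samples), path,
                     append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read a trace from the package CSV format
#' @param path file written by [write_trace_csv()].
#' @return a `glyr_trace`.
#' @export
read_trace_csv <- function(path) {
  head_lines <- readLines(path, n = 200L)
  hdr <- grep("^#", head_lines, value = TRUE)
  n_hdr <- length(hdr)
  kv <- sub("^#\\s*", "", hdr)
  get1 <- function(key) {
    hit <- grep(paste0("^", key, "="), kv, value = TRUE)
    if (!length(hit)) NULL else sub(paste0("^", key, "="), "", hit[1])
  }
  fs <- as.numeric(get1("sampling_rate_hz"))
  if (!length(fs) || is.na(fs)) stop_config("missing sampling_rate_hz header")
  st <- as.numeric(get1("start_time_s") %||% "0")
  units <- get1("units") %||% "pA"
  anns <- grep("^annotation=", kv, value = TRUE)
  ann_df <- NULL
  if (length(anns)) {
    parts <- strsplit(sub("^annotation=", "", anns), ",")
    ann_df <- data.frame(label = vapply(parts, `[`, "", 1),
                         onset = as.numeric(vapply(parts, `[`, "", 2)),
                         offset = as.numeric(vapply(parts, `[`, "", 3)),
                         stringsAsFactors = FALSE)
  }
  samples <- data.table::fread(path, skip = n_hdr, header = FALSE)[[1]]
  trace(samples, fs, start_time = st, annotations = ann_df, units = units)
}

## ---------------------------------------------------------------------------
## HDF5 layout: /trace/samples with attributes sampling_rate_hz, start_time_s,
## units, and /trace/annotations as a compound-free trio of vectors.

#' Write/read a trace in HDF5 (requires the rhdf5 package)
#'
#' Layout: dataset `/trace/samples` plus datasets
#' `/trace/annotation_{label,onset,offset}` and scalar datasets for the
#' sampling rate, start time and units.
#'
#' @param x a `glyr_trace`.
#' @param path HDF5 file path.
#' @return `path` (write) or a `glyr_trace` (read).
#' @export
write_trace_h5 <- function(x, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop_config("HDF5 trace I/O needs the 'rhdf5' package")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "trace")
  rhdf5::h5write(x$samples, path, "trace/samples")
  rhdf5::h5write(x$sampling_rate, path, "trace/sampling_rate_hz")
  rhdf5::h5write(x$start_time, path, "trace/start_time_s")
  rhdf5::h5write(x$units, path, "trace/units")
  rhdf5::h5write(as.character(x$annotations$label), path,
                 "trace/annotation_label")
  rhdf5::h5write(as.numeric(x$annotations$onset), path,
                 "trace/annotation_onset")
  rhdf5::h5write(as.numeric(x$annotations$offset), path,
                 "trace/annotation_offset")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_trace_h5
#' @export
read_trace_h5 <- function(path) {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop_config("HDF5 trace I/O needs the 'rhdf5' package")
  samples <- as.numeric(rhdf5::h5read(path, "trace/samples"))
  fs <- as.numeric(rhdf5::h5read(path, "trace/sampling_rate_hz"))
  st <- as.numeric(rhdf5::h5read(path, "trace/start_time_s"))
  units <- as.character(rhdf5::h5read(path, "trace/units"))
  lab <- as.character(rhdf5::h5read(path, "trace/annotation_label"))
  ann <- NULL
  if (length(lab))
    ann <- data.frame(label = lab,
                      onset = as.numeric(rhdf5::h5read(path, "trace/annotation_onset")),
                      offset = as.numeric(rhdf5::h5read(path, "trace/annotation_offset")),
                      stringsAsFactors = FALSE)
  rhdf5::h5closeAll()
  trace(samples, fs, start_time = st, annotations = ann, units = units)
}
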