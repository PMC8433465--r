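#' Uniformly sampled impedance trace
#'
#' The mechanical beating signal: impedance magnitude (arbitrary units)
#' sampled at a fixed interval, as produced by FFT amplitude demodulation of
#' the carrier (nominally every 12.8 ms).
#'
#' @param values Numeric vector of impedance magnitudes (a.u.), all finite.
#' @param sample_interval Sampling interval in seconds (> 0).
#' @param start_time Time of the first sample in seconds.
#'
#' @return An object of class `impedance_trace`: a list with elements
#'   `values`, `sample_interval` and `start_time`.
#' @export
#' @examples
#' tr <- impedance_trace(sin(seq(0, 10, by = 0.1)), sample_interval = 0.0128)
#' print(tr)
impedance_trace <- function(values, sample_interval, start_time = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("impedance_trace: need at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("impedance_trace: values must all be finite", call. = FALSE)
  }
  if (!is.numeric(sample_interval) || length(sample_interval) != 1L ||
      !is.finite(sample_interval) || sample_interval <= 0) {
    stop("impedance_trace: sample_interval must be a positive number",
         call. = FALSE)
  }
  structure(
    list(values = values,
         sample_interval = as.numeric(sample_interval),
         start_time = as.numeric(start_time)),
    class = "impedance_trace"
  )
}

#' @export
print.impedance_trace <- function(x, ...) {
  dur <- (length(x$values) - 1L) * x$sample_interval
  cat(sprintf(
    "<impedance_trace> %d samples @ %.4g ms, %.3f s, range [%.4g, %.4g] a.u.\n",
    length(x$values), 1000 * x$sample_interval, dur,
    min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.impedance_trace <- function(x) length(x$values)

#' Sample times of a trace
#'
#' @param trace An [impedance_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "impedance_trace"))
  trace$start_time + (seq_along(trace$values) - 1L) * trace$sample_interval
}

#' @export
as.data.frame.impedance_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), impedance = x$values)
}

#' Read / write impedance traces as CSV
#'
#' Traces are stored with header `time_s,impedance`, UTF-8, '.' decimal
#' separator. Comment lines starting with `#` (provenance headers written by
#' the pipeline) are skipped on read. The time column must be uniformly
#' spaced; the sampling interval is recovered as the median time step.
#'
#' @param trace An [impedance_trace()].
#' @param path File path.
#' @param header Optional character vector of provenance lines to prepend
#'   (each written prefixed with `# `).
#' @return `read_trace_csv()` returns an [impedance_trace()];
#'   `write_trace_csv()` returns `path` invisibly.
#' @export
write_trace_csv <- function(trace, path, header = NULL) {
  stopifnot(inherits(trace, "impedance_trace"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("time_s,impedance", con)
  df <- as.data.frame(trace)
  writeLines(paste(format(df$time_s, trim = TRUE, digits = 15),
                   format(df$impedance, trim = TRUE, digits = 15), sep = ","),
             con)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "impedance") %in% names(df))) {
    stop("trace CSV must have columns time_s,impedance", call. = FALSE)
  }
  dt <- diff(df$time_s)
  interval <- stats::median(dt)
  if (any(abs(dt - interval) > 1e-6 * interval)) {
    stop("trace CSV is not uniformly sampled", call. = FALSE)
  }
  impedance_trace(df$impedance, interval, start_time = df$time_s[1L])
}
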