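#' FFT amplitude demodulation of a carrier recording
#'
#' Converts a raw carrier recording into an impedance trace by taking the
#' DFT of consecutive non-overlapping rectangular windows and reading the
#' magnitude of the bin at the carrier frequency, scaled so a pure sinusoid
#' of amplitude A yields A. With the nominal 12.8 ms window the output
#' interval is 12.8 ms.
#'
#' The carrier frequency must fall exactly on a DFT bin of the window
#' (`carrier_freq * window_duration` integral); otherwise spectral leakage
#' would bias the magnitude, and the function refuses.
#'
#' @param raw A [carrier_recording()].
#' @param window_duration Window length in seconds (default 0.0128).
#' @return An [impedance_trace()] with `sample_interval = window_duration`;
#'   sample times refer to window centres.
#' @export
demodulate <- function(raw, window_duration = 0.0128) {
  stopifnot(inherits(raw, "carrier_recording"))
  nwin_exact <- window_duration * raw$sample_rate
  nwin <- round(nwin_exact)
  if (abs(nwin_exact - nwin) > 1e-9 * nwin || nwin < 8L) {
    stop("demodulate: window_duration must span a whole number (>= 8) of samples",
         call. = FALSE)
  }
  k_exact <- raw$carrier_freq * window_duration
  k <- round(k_exact)
  if (abs(k_exact - k) > 1e-9 || k < 1L || k >= nwin / 2) {
    stop("demodulate: carrier_freq is not aligned to a DFT bin of the window",
         call. = FALSE)
  }
  nw <- length(raw$samples) %/% nwin
  if (nw < 2L) {
    stop("demodulate: recording shorter than two demodulation windows",
         call. = FALSE)
  }
  m <- matrix(raw$samples[seq_len(nw * nwin)], nrow = nwin)
  spec <- stats::mvfft(m)[k + 1L, ]
  impedance_trace(2 * Mod(spec) / nwin, window_duration,
                  start_time = window_duration / 2)
}

#' 5-point smoothing filter
#'
#' Centered 5-point moving average; the two samples at each edge are
#' averaged over the available shrunken window, so the output has the same
#' length and no invented boundary values.
#'
#' @param trace An [impedance_trace()] with at least 5 samples.
#' @return The smoothed [impedance_trace()].
#' @export
smooth5 <- function(trace) {
  stopifnot(inherits(trace, "impedance_trace"))
  v <- trace$values
  n <- length(v)
  if (n < 5L) stop("smooth5: trace must have at least 5 samples", call. = FALSE)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - 2L, 1L)
  hi <- pmin(seq_len(n) + 2L, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  impedance_trace(out, trace$sample_interval, trace$start_time)
}

#' Cubic-spline upsampling
#'
#' Interpolates `factor - 1` extra points between each pair of neighbouring
#' samples with a cubic spline (FMM end conditions, which reproduce cubic
#' polynomials exactly), improving the temporal resolution by `factor`
#' (nominally from 12.8 ms to 1.28 ms at `factor = 10`). Original samples
#' are reproduced exactly at their knot positions.
#'
#' @param trace An [impedance_trace()] with at least 4 samples.
#' @param factor Integer upsampling factor >= 2.
#' @return An [impedance_trace()] of length `factor * (n - 1) + 1` and
#'   sample interval `trace$sample_interval / factor`.
#' @export
upsample <- function(trace, factor = 10L) {
  stopifnot(inherits(trace, "impedance_trace"))
  factor <- as.integer(factor)
  n <- length(trace$values)
  if (is.na(factor) || factor < 2L) {
    stop("upsample: factor must be an integer >= 2", call. = FALSE)
  }
  if (n < 4L) {
    stop("upsample: trace must have at least 4 samples for a cubic spline",
         call. = FALSE)
  }
  f <- stats::splinefun(seq_len(n), trace$values, method = "fmm")
  xout <- seq(1, n, by = 1 / factor)
  impedance_trace(f(xout), trace$sample_interval / factor, trace$start_time)
}
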