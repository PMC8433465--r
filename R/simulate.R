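#' @title Synthetic cardiomyocyte beating-signal simulator
#' @description Generates impedance beating traces with per-beat ground truth
#'   emulating rhythmic and EAD-like multi-peak arrhythmic morphologies, plus
#'   the raw amplitude-modulated carrier recordings they would arise from.
#' @name simulate
NULL

# Fixed waveform shape constants (dimensionless fractions of the beat).
# One beat = deep narrow raised-cosine diastolic notch anchoring the valley
# + low sinusoidal systolic dome + raised-cosine contraction bump(s) that
# carry the morphology, renormalised to span [valley_level, peak_level].
.atm_shape <- list(
  dome            = 0.15, # weight of the sinusoidal systolic dome
  notch_depth     = 0.35, # weight (depth) of the diastolic notch
  notch_width     = 0.06, # full width of the notch, fraction of the period
  bump_width      = 0.35, # width of the primary contraction bump
  secondary_width = 0.20  # width of EAD-like secondary bumps
)

.morph_kinds <- c("rhythmic", "arrhythmic_2peak", "arrhythmic_3peak")

#' Beat morphology specification
#'
#' Describes one beat class: the impedance levels it spans and the phase
#' positions/relative amplitudes of EAD-like secondary peaks (extra
#' contractions within the beat caused by delayed repolarization under hERG
#' blockade).
#'
#' @param kind One of `"rhythmic"`, `"arrhythmic_2peak"`,
#'   `"arrhythmic_3peak"`.
#' @param peak_level,valley_level Impedance levels (a.u.) of the systolic
#'   peak and diastolic valley; `peak_level > valley_level`.
#' @param rise_fraction Beat-phase position of the primary contraction peak,
#'   in (0, 1).
#' @param secondary_peak_delays Strictly increasing beat-phase offsets in
#'   (0, 1) of the secondary peaks: empty for rhythmic, length 1 for 2-peak,
#'   length 2 for 3-peak morphologies.
#' @param secondary_peak_relative_amplitudes Relative amplitudes in (0, 1]
#'   of the secondary peaks, same length as the delays.
#'
#' @return An object of class `beat_morphology`.
#' @export
#' @examples
#' beat_morphology("arrhythmic_2peak",
#'                 secondary_peak_delays = 0.72,
#'                 secondary_peak_relative_amplitudes = 0.8)
beat_morphology <- function(kind,
                            peak_level = 6.758,
                            valley_level = 6.687,
                            rise_fraction = 0.40,
                            secondary_peak_delays = numeric(),
                            secondary_peak_relative_amplitudes = numeric()) {
  kind <- match.arg(kind, .morph_kinds)
  if (!is.finite(peak_level) || !is.finite(valley_level) ||
      peak_level <= valley_level) {
    stop("beat_morphology: peak_level must exceed valley_level", call. = FALSE)
  }
  if (rise_fraction <= 0 || rise_fraction >= 1) {
    stop("beat_morphology: rise_fraction must lie in (0,1)", call. = FALSE)
  }
  d <- as.numeric(secondary_peak_delays)
  a <- as.numeric(secondary_peak_relative_amplitudes)
  if (length(d) != length(a)) {
    stop("beat_morphology: delays and relative amplitudes must have equal length",
         call. = FALSE)
  }
  n_sec <- switch(kind, rhythmic = 0L, arrhythmic_2peak = 1L,
                  arrhythmic_3peak = 2L)
  if (length(d) != n_sec) {
    stop(sprintf("beat_morphology: kind '%s' requires %d secondary peak(s), got %d",
                 kind, n_sec, length(d)), call. = FALSE)
  }
  if (n_sec > 0L) {
    if (any(d <= 0 | d >= 1) || is.unsorted(d, strictly = TRUE)) {
      stop("beat_morphology: delays must be strictly increasing within (0,1)",
           call. = FALSE)
    }
    if (any(a <= 0 | a > 1)) {
      stop("beat_morphology: relative amplitudes must lie in (0,1]",
           call. = FALSE)
    }
  }
  structure(
    list(kind = kind, peak_level = peak_level, valley_level = valley_level,
         rise_fraction = rise_fraction,
         secondary_peak_delays = d,
         secondary_peak_relative_amplitudes = a),
    class = "beat_morphology"
  )
}

#' Stock beat morphologies
#'
#' The default morphology set used throughout: a rhythmic single-peak class,
#' canonical two-peak and three-peak arrhythmic classes, and "shifted"
#' variants of each whose secondary peaks sit at different phase positions.
#' The shifted variants emulate the peak-offset variability of arrhythmic
#' beats across recording segments that defeats arrhythmic multitemplate
#' matching while leaving rhythmic-template matching intact.
#'
#' @param peak_level,valley_level Impedance levels (a.u.) shared by all
#'   classes; defaults follow the bundled recording statistics
#'   (peak 6.758, valley 6.687).
#' @return Named list of [beat_morphology()] objects: `rhythmic`,
#'   `arrhythmic_2peak`, `arrhythmic_3peak`, `arrhythmic_2peak_shifted`,
#'   `arrhythmic_3peak_shifted`.
#' @export
atm_morphologies <- function(peak_level = 6.758, valley_level = 6.687) {
  m <- function(kind, d = numeric(), a = numeric()) {
    beat_morphology(kind, peak_level, valley_level,
                    secondary_peak_delays = d,
                    secondary_peak_relative_amplitudes = a)
  }
  list(
    rhythmic                 = m("rhythmic"),
    arrhythmic_2peak         = m("arrhythmic_2peak", 0.72, 0.80),
    arrhythmic_3peak         = m("arrhythmic_3peak", c(0.60, 0.80), c(0.75, 0.60)),
    arrhythmic_2peak_shifted = m("arrhythmic_2peak", 0.65, 0.85),
    arrhythmic_3peak_shifted = m("arrhythmic_3peak", c(0.55, 0.76), c(0.70, 0.55))
  )
}

# raised-cosine bump of full width w centred at c, zero outside
.bump <- function(phi, centre, width) {
  v <- numeric(length(phi))
  k <- abs(phi - centre) < width / 2
  v[k] <- 0.5 * (1 + cos(2 * pi * (phi[k] - centre) / width))
  v
}

# diastolic notch profile: 0 at phi = 0 and 1, plateau 1 in the interior
.notch_plateau <- function(phi, lam) {
  v <- rep(1, length(phi))
  a <- phi < lam / 2
  b <- phi > 1 - lam / 2
  v[a] <- 0.5 * (1 - cos(2 * pi * phi[a] / lam))
  v[b] <- 0.5 * (1 - cos(2 * pi * (1 - phi[b]) / lam))
  v
}

# normalized beat shape on phase phi in [0,1]: 0 at both ends, max 1
.beat_shape <- function(phi, morphology) {
  sh <- .atm_shape
  wsum <- function(p) {
    s <- sh$notch_depth * .notch_plateau(p, sh$notch_width) +
      sh$dome * pmax(sin(pi * p), 0) +
      (1 - sh$dome - sh$notch_depth) *
        .bump(p, morphology$rise_fraction, sh$bump_width)
    d <- morphology$secondary_peak_delays
    a <- morphology$secondary_peak_relative_amplitudes
    for (j in seq_along(d)) {
      s <- s + (1 - sh$dome - sh$notch_depth) * a[j] *
        .bump(p, d[j], sh$secondary_width)
    }
    s
  }
  # grid-independent normalisation: analytic maximum from a dense phase grid
  smax <- max(wsum(seq(0, 1, length.out = 4096L)))
  wsum(phi) / smax
}

#' Generate one beat waveform
#'
#' Samples a single valley-to-valley beat of the given morphology. The first
#' and last samples sit at `valley_level`; the global maximum reaches
#' `peak_level`; the number of dominant local maxima (above the valley plus
#' 25% of the amplitude) equals one plus the number of secondary peaks.
#'
#' @param morphology A [beat_morphology()].
#' @param period Beat duration in seconds (at least 10 sample intervals).
#' @param sample_interval Sampling interval in seconds.
#' @return Numeric vector of `round(period / sample_interval)` samples.
#' @export
#' @examples
#' w <- make_beat_waveform(atm_morphologies()$rhythmic, 1.563, 0.0128)
#' length(w)  # 122
make_beat_waveform <- function(morphology, period, sample_interval) {
  stopifnot(inherits(morphology, "beat_morphology"))
  if (!is.finite(period) || !is.finite(sample_interval) ||
      period <= 0 || sample_interval <= 0 ||
      period < 10 * sample_interval) {
    stop("make_beat_waveform: period must be at least 10 sample intervals",
         call. = FALSE)
  }
  n <- round(period / sample_interval)
  phi <- seq(0, 1, length.out = n)
  amp <- morphology$peak_level - morphology$valley_level
  morphology$valley_level + amp * .beat_shape(phi, morphology)
}

#' Simulation configuration
#'
#' @param n_beats Number of beats (>= 1).
#' @param beat_period_mean Mean beat period in seconds (default 1.563).
#' @param beat_period_cv Coefficient of variation of the per-beat period
#'   (truncated-normal jitter, cut at 3 SD).
#' @param morphology_schedule Per-beat morphology assignment: a single
#'   [beat_morphology()] (recycled), a list of `n_beats` morphologies, or a
#'   character vector of names resolved against [atm_morphologies()]
#'   (recycled to `n_beats` if shorter).
#' @param noise_sd Additive white-noise SD in impedance a.u.; default 0.5%
#'   of the beat amplitude of the first scheduled morphology. Noise draws
#'   are truncated at 5 SD so trace excursions stay bounded.
#' @param drift_amplitude,drift_period Amplitude (a.u.) and period (s) of a
#'   sinusoidal baseline drift.
#' @param sample_interval Sampling interval in seconds (default 0.0128, the
#'   demodulator output interval).
#' @param rng_seed Integer seed; identical configurations with the same seed
#'   produce bit-identical traces.
#' @param pad_fraction Fraction of a mean beat period of partial-beat signal
#'   prepended before the first valley and appended after the last, so a
#'   recording starts and ends mid-beat as real acquisitions do (default
#'   0.5).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_beats,
                       beat_period_mean = 1.563,
                       beat_period_cv = 0.01,
                       morphology_schedule = atm_morphologies()$rhythmic,
                       noise_sd = NULL,
                       drift_amplitude = 0.002,
                       drift_period = 60,
                       sample_interval = 0.0128,
                       rng_seed = 1L,
                       pad_fraction = 0.5) {
  n_beats <- as.integer(n_beats)
  if (is.na(n_beats) || n_beats < 1L) {
    stop("sim_config: n_beats must be >= 1", call. = FALSE)
  }
  if (beat_period_mean <= 0 || sample_interval <= 0) {
    stop("sim_config: beat_period_mean and sample_interval must be positive",
         call. = FALSE)
  }
  if (beat_period_cv < 0 || beat_period_cv >= 1 / 3) {
    stop("sim_config: beat_period_cv must lie in [0, 1/3)", call. = FALSE)
  }
  sched <- morphology_schedule
  if (is.character(sched)) {
    stock <- atm_morphologies()
    bad <- setdiff(unique(sched), names(stock))
    if (length(bad)) {
      stop("sim_config: unknown morphology name(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    sched <- stock[rep_len(sched, n_beats)]
  } else if (inherits(sched, "beat_morphology")) {
    sched <- rep(list(sched), n_beats)
  }
  if (!is.list(sched) || length(sched) != n_beats ||
      !all(vapply(sched, inherits, logical(1), "beat_morphology"))) {
    stop("sim_config: morphology_schedule must assign one beat_morphology per beat",
         call. = FALSE)
  }
  if (is.null(noise_sd)) {
    noise_sd <- 0.005 * (sched[[1L]]$peak_level - sched[[1L]]$valley_level)
  }
  if (noise_sd < 0 || drift_amplitude < 0 || drift_period <= 0) {
    stop("sim_config: noise_sd/drift_amplitude must be >= 0, drift_period > 0",
         call. = FALSE)
  }
  if (pad_fraction < 0 || pad_fraction >= 1) {
    stop("sim_config: pad_fraction must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_beats = n_beats, beat_period_mean = beat_period_mean,
         beat_period_cv = beat_period_cv, morphology_schedule = sched,
         noise_sd = noise_sd, drift_amplitude = drift_amplitude,
         drift_period = drift_period, sample_interval = sample_interval,
         rng_seed = as.integer(rng_seed), pad_fraction = pad_fraction),
    class = "sim_config"
  )
}

# evaluate code under a local RNG state seeded by `seed`
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Synthesize a labeled beating trace
#'
#' Draws per-beat periods from a truncated normal (cut at 3 SD), renders
#' each beat's morphology on the shared uniform time grid, and adds
#' sinusoidal baseline drift and truncated white noise. Beats share their
#' boundary valleys; the recorded ground truth is the exact boundary times
#' plus per-beat labels.
#'
#' @param config A [sim_config()].
#' @return An object of class `labeled_trace`: list with `trace`
#'   ([impedance_trace()]), `truth_valley_times` (seconds, length
#'   `n_beats + 1`), `truth_labels` (`"rhythmic"`/`"arrhythmic"` per beat),
#'   `truth_morphologies` (kind strings) and `config`.
#' @export
synth_trace <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_beats
  mean_p <- config$beat_period_mean
  sd_p <- config$beat_period_cv * mean_p
  with_seed(config$rng_seed, {
    periods <- rep(NA_real_, n)
    todo <- rep(TRUE, n)
    while (any(todo)) { # truncated normal via redraw
      periods[todo] <- stats::rnorm(sum(todo), mean_p, sd_p)
      todo <- abs(periods - mean_p) > 3 * sd_p
      if (sd_p == 0) break
    }
    pad <- config$pad_fraction * mean_p
    valley_times <- pad + c(0, cumsum(periods))
    total <- valley_times[n + 1L] + pad
    dt <- config$sample_interval
    nt <- floor(total / dt) + 1L
    tt <- (seq_len(nt) - 1L) * dt
    values <- numeric(nt)
    beat_of <- pmin(findInterval(tt, valley_times), n)
    for (i in seq_len(n)) {
      k <- beat_of == i & tt >= valley_times[1L]
      m <- config$morphology_schedule[[i]]
      phi <- (tt[k] - valley_times[i]) / periods[i]
      values[k] <- m$valley_level +
        (m$peak_level - m$valley_level) * .beat_shape(phi, m)
    }
    if (pad > 0) {
      # partial beats before the first and after the last valley
      m1 <- config$morphology_schedule[[1L]]
      k <- tt < valley_times[1L]
      phi <- (tt[k] - valley_times[1L] + mean_p) / mean_p
      values[k] <- m1$valley_level +
        (m1$peak_level - m1$valley_level) * .beat_shape(phi, m1)
      mn <- config$morphology_schedule[[n]]
      k <- tt > valley_times[n + 1L]
      phi <- (tt[k] - valley_times[n + 1L]) / mean_p
      values[k] <- mn$valley_level +
        (mn$peak_level - mn$valley_level) * .beat_shape(phi, mn)
    }
    if (config$drift_amplitude > 0) {
      values <- values +
        config$drift_amplitude * sin(2 * pi * tt / config$drift_period)
    }
    if (config$noise_sd > 0) {
      eps <- stats::rnorm(nt, 0, config$noise_sd)
      eps <- pmin(pmax(eps, -5 * config$noise_sd), 5 * config$noise_sd)
      values <- values + eps
    }
    kinds <- unname(vapply(config$morphology_schedule, `[[`, "", "kind"))
    structure(
      list(trace = impedance_trace(values, dt, start_time = 0),
           truth_valley_times = valley_times,
           truth_labels = ifelse(kinds == "rhythmic", "rhythmic", "arrhythmic"),
           truth_morphologies = kinds,
           config = config),
      class = "labeled_trace"
    )
  })
}

#' @export
print.labeled_trace <- function(x, ...) {
  cat(sprintf("<labeled_trace> %d beats (%d rhythmic / %d arrhythmic), ",
              length(x$truth_labels),
              sum(x$truth_labels == "rhythmic"),
              sum(x$truth_labels == "arrhythmic")))
  print(x$trace)
  invisible(x)
}

#' Raw carrier recording
#'
#' @param samples Voltage samples (V).
#' @param sample_rate Sampling rate in Hz (>= 4 x carrier frequency).
#' @param carrier_freq Carrier frequency in Hz (default 10 kHz).
#' @param drive_amplitude Nominal drive amplitude in V (default 30 mV).
#' @return An object of class `carrier_recording`.
#' @export
carrier_recording <- function(samples, sample_rate, carrier_freq = 10000,
                              drive_amplitude = 0.030) {
  if (sample_rate < 4 * carrier_freq) {
    stop("carrier_recording: sample_rate must be at least 4 x carrier_freq",
         call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         carrier_freq = carrier_freq, drive_amplitude = drive_amplitude),
    class = "carrier_recording"
  )
}

#' @export
print.carrier_recording <- function(x, ...) {
  cat(sprintf("<carrier_recording> %d samples @ %g Hz, carrier %g Hz\n",
              length(x$samples), x$sample_rate, x$carrier_freq))
  invisible(x)
}

#' Synthesize a raw carrier recording from a beating trace
#'
#' Models the impedance pathway of the sensing chain: the instantaneous
#' carrier amplitude follows the impedance trace (piecewise-linear
#' interpolation between trace samples), so that amplitude demodulation
#' recovers the trace.
#'
#' @param labeled A `labeled_trace` (from [synth_trace()]) or an
#'   [impedance_trace()].
#' @param sample_rate Carrier sampling rate in Hz (default 100 kHz, 10
#'   samples per cycle of the 10 kHz carrier).
#' @param carrier_freq Carrier frequency in Hz.
#' @param drive_amplitude Nominal drive amplitude in V, stored as metadata.
#' @return A [carrier_recording()].
#' @export
synth_carrier <- function(labeled, sample_rate = 1e5, carrier_freq = 10000,
                          drive_amplitude = 0.030) {
  trace <- if (inherits(labeled, "labeled_trace")) labeled$trace else labeled
  stopifnot(inherits(trace, "impedance_trace"))
  if (sample_rate < 4 * carrier_freq) {
    stop("synth_carrier: sample_rate must be at least 4 x carrier_freq",
         call. = FALSE)
  }
  total <- (length(trace$values) - 1L) * trace$sample_interval
  tt <- seq(0, total, by = 1 / sample_rate)
  envelope <- stats::approx(trace_times(trace) - trace$start_time,
                            trace$values, xout = tt, rule = 2)$y
  carrier_recording(envelope * sin(2 * pi * carrier_freq * tt),
                    sample_rate, carrier_freq, drive_amplitude)
}

#' Read a simulation configuration from YAML
#'
#' Recognized keys mirror the [sim_config()] arguments (`n_beats`,
#' `beat_period_mean`, `beat_period_cv`, `morphology_schedule` — a list of
#' morphology names —, `noise_sd`, `drift_amplitude`, `drift_period`,
#' `sample_interval`, `rng_seed`, `pad_fraction`); omitted keys use the
#' defaults.
#'
#' @param path Path to a YAML file.
#' @param rng_seed Optional seed overriding the file's `rng_seed`.
#' @return A [sim_config()].
#' @export
read_sim_yaml <- function(path, rng_seed = NULL) {
  y <- yaml::read_yaml(path)
  known <- c("n_beats", "beat_period_mean", "beat_period_cv",
             "morphology_schedule", "noise_sd", "drift_amplitude",
             "drift_period", "sample_interval", "rng_seed", "pad_fraction")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop("read_sim_yaml: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(y$n_beats)) {
    stop("read_sim_yaml: n_beats is required", call. = FALSE)
  }
  if (!is.null(y$morphology_schedule)) {
    y$morphology_schedule <- unlist(y$morphology_schedule)
  }
  if (!is.null(rng_seed)) y$rng_seed <- rng_seed
  do.call(sim_config, y)
}

#' Read / write per-beat ground-truth labels as CSV
#'
#' Columns: `beat_index` (0-based), `start_s`, `end_s`, `label`
#' (`rhythmic`/`arrhythmic`), `morphology` (kind string).
#'
#' @param labeled A `labeled_trace`.
#' @param path File path.
#' @param header Optional provenance lines (written prefixed `# `).
#' @return `read_labels_csv()` returns a data.frame; `write_labels_csv()`
#'   returns `path` invisibly.
#' @export
write_labels_csv <- function(labeled, path, header = NULL) {
  stopifnot(inherits(labeled, "labeled_trace"))
  n <- length(labeled$truth_labels)
  df <- data.frame(
    beat_index = seq_len(n) - 1L,
    start_s = labeled$truth_valley_times[seq_len(n)],
    end_s = labeled$truth_valley_times[seq_len(n) + 1L],
    label = labeled$truth_labels,
    morphology = labeled$truth_morphologies
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels_csv
#' @export
read_labels_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
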