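#' Pearson correlation coefficient
#'
#' The matching statistic: r(X, Y) = Cov(X, Y) / sqrt(Var(X) Var(Y)),
#' computed by direct covariance/variance accumulation. Inputs must have
#' equal length (length-match templates first, see
#' [fit_template_length()]) and non-zero variance.
#'
#' @param x,y Equal-length numeric vectors (length >= 2), each non-constant.
#' @return Correlation in \[-1, 1\].
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
pearson_r <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) {
    stop("pearson_r: length mismatch (", n, " vs ", length(y),
         "); length-match the inputs first", call. = FALSE)
  }
  if (n < 2L) stop("pearson_r: need at least 2 samples", call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  vx <- sum(dx * dx)
  vy <- sum(dy * dy)
  if (vx == 0 || vy == 0) {
    stop("pearson_r: zero variance in input (degenerate signal)",
         call. = FALSE)
  }
  sum(dx * dy) / sqrt(vx * vy)
}

.template_labels <- c("rhythmic", "arrhythmic_2peak", "arrhythmic_3peak")

#' Beat template
#'
#' A stored reference beat, resampled on demand to any target length before
#' correlation.
#'
#' @param values Numeric beat samples (length >= 4, finite, non-constant).
#' @param sample_interval Sampling interval in seconds.
#' @param label Template class: `"rhythmic"`, `"arrhythmic_2peak"` or
#'   `"arrhythmic_3peak"`.
#' @param source Free-text provenance (segment id, beat index, seed ...).
#' @return An object of class `atm_template`.
#' @export
atm_template <- function(values, sample_interval, label, source = "") {
  values <- as.numeric(values)
  label <- match.arg(label, .template_labels)
  if (length(values) < 4L || !all(is.finite(values))) {
    stop("atm_template: need >= 4 finite samples", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    stop("atm_template: template must be non-constant", call. = FALSE)
  }
  structure(
    list(values = values, sample_interval = sample_interval,
         label = label, source = as.character(source)),
    class = "atm_template"
  )
}

#' @export
print.atm_template <- function(x, ...) {
  cat(sprintf("<atm_template> '%s', %d samples @ %.4g ms (%s)\n",
              x$label, length(x$values), 1000 * x$sample_interval, x$source))
  invisible(x)
}

#' Extract a beat template from a segmented trace
#'
#' @param trace An [impedance_trace()].
#' @param valleys Valley indices from [detect_valleys()].
#' @param beat_choice 1-based beat number, or `"random"`. The first complete
#'   beat (`beat_choice = 1`) is the conventional rhythmic template.
#' @param label Template class label (see [atm_template()]).
#' @param params [segmentation_params()] used for beat extraction.
#' @param rng_seed Seed used when `beat_choice = "random"`; recorded in the
#'   template provenance.
#' @return An [atm_template()].
#' @export
extract_template <- function(trace, valleys, beat_choice = 1L,
                             label = "rhythmic",
                             params = segmentation_params(),
                             rng_seed = 1L) {
  beats <- extract_beats(trace, valleys, params)
  if (!length(beats)) {
    stop("extract_template: no complete beats in segmentation", call. = FALSE)
  }
  if (identical(beat_choice, "random")) {
    idx <- with_seed(rng_seed, sample.int(length(beats), 1L))
    src <- sprintf("random beat %d of %d (seed %d)", idx, length(beats),
                   as.integer(rng_seed))
  } else {
    idx <- as.integer(beat_choice)
    if (is.na(idx) || idx < 1L || idx > length(beats)) {
      stop(sprintf("extract_template: beat %s does not exist (%d beats)",
                   as.character(beat_choice), length(beats)), call. = FALSE)
    }
    src <- sprintf("beat %d of %d", idx, length(beats))
  }
  b <- beats[[idx]]
  atm_template(b$values, b$sample_interval, label, src)
}

#' Length-match a template to a target beat
#'
#' Implements the dynamic length adjustment: the template is prolonged by
#' cubic-spline interpolation to (the smallest integer) `m` times the target
#' data length and then resampled by taking every `m`-th point, which is
#' equivalent to evaluating the spline at `target_length` uniform points
#' across the template support. Endpoints are preserved; equal lengths
#' return the template unchanged.
#'
#' @param template An [atm_template()] (or bare numeric vector).
#' @param target_length Desired length (>= 4).
#' @return Numeric vector of length `target_length`.
#' @export
fit_template_length <- function(template, target_length) {
  v <- if (inherits(template, "atm_template")) template$values else
    as.numeric(template)
  target_length <- as.integer(target_length)
  if (is.na(target_length) || target_length < 4L) {
    stop("fit_template_length: target_length must be >= 4", call. = FALSE)
  }
  if (stats::var(v) == 0) {
    stop("fit_template_length: constant template is degenerate",
         call. = FALSE)
  }
  n <- length(v)
  if (target_length == n) return(v)
  f <- stats::splinefun(seq_len(n), v, method = "fmm")
  f(seq(1, n, length.out = target_length))
}

#' Matching configuration
#'
#' @param mode `"rhythmic_template"` (a beat is arrhythmic when its
#'   correlation with the single rhythmic template drops below
#'   `rhythmic_threshold`) or `"arrhythmic_multitemplate"` (a beat is
#'   arrhythmic when its best correlation over the arrhythmic templates
#'   exceeds `arrhythmic_threshold`).
#' @param rhythmic_threshold Correlation threshold for the rhythmic
#'   template (default 0.94).
#' @param arrhythmic_threshold Correlation threshold for arrhythmic
#'   multitemplates (default 0.90).
#' @return An object of class `match_config`.
#' @export
match_config <- function(mode = c("rhythmic_template",
                                  "arrhythmic_multitemplate"),
                         rhythmic_threshold = 0.94,
                         arrhythmic_threshold = 0.90) {
  mode <- match.arg(mode)
  for (th in c(rhythmic_threshold, arrhythmic_threshold)) {
    if (!is.finite(th) || th <= -1 || th >= 1) {
      stop("match_config: thresholds must lie in (-1, 1)", call. = FALSE)
    }
  }
  structure(
    list(mode = mode, rhythmic_threshold = rhythmic_threshold,
         arrhythmic_threshold = arrhythmic_threshold),
    class = "match_config"
  )
}

#' Classify one beat against templates
#'
#' Each template is length-matched to the beat and scored by [pearson_r()].
#' In `rhythmic_template` mode the beat is rhythmic iff its correlation with
#' the single rhythmic template is at least the threshold (equality counts
#' as rhythmic). In `arrhythmic_multitemplate` mode the highest correlation
#' over the arrhythmic templates is the output score; the beat is
#' arrhythmic iff it strictly exceeds the threshold, and the winning
#' template is recorded.
#'
#' @param beat An `atm_beat` (or bare numeric vector).
#' @param templates List of [atm_template()] (a single template is
#'   accepted). Rhythmic mode requires exactly one rhythmic template;
#'   multitemplate mode requires >= 1 arrhythmic templates.
#' @param config A [match_config()].
#' @param beat_index Optional index recorded in the result.
#' @return An object of class `match_result`: list with `beat_index`,
#'   `correlations` (named per template), `predicted_label` (`"rhythmic"`,
#'   `"arrhythmic"` or `"unclassifiable"` for zero-variance beats) and
#'   `winning_template`.
#' @export
match_beat <- function(beat, templates, config = match_config(),
                       beat_index = NA_integer_) {
  values <- if (inherits(beat, "atm_beat")) beat$values else as.numeric(beat)
  if (inherits(templates, "atm_template")) templates <- list(templates)
  if (!length(templates)) stop("match_beat: no templates", call. = FALSE)
  labs <- vapply(templates, `[[`, "", "label")
  ids <- names(templates)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- make.unique(labs)
  }
  if (config$mode == "rhythmic_template") {
    if (length(templates) != 1L || labs[1L] != "rhythmic") {
      stop("match_beat: rhythmic_template mode requires exactly one rhythmic template",
           call. = FALSE)
    }
  } else if (!all(labs %in% c("arrhythmic_2peak", "arrhythmic_3peak"))) {
    stop("match_beat: arrhythmic_multitemplate mode requires arrhythmic templates only",
         call. = FALSE)
  }
  res <- structure(
    list(beat_index = beat_index,
         correlations = stats::setNames(rep(NA_real_, length(templates)), ids),
         predicted_label = NA_character_,
         winning_template = NA_character_),
    class = "match_result"
  )
  if (stats::var(values) == 0) {
    res$predicted_label <- "unclassifiable"
    return(res)
  }
  r <- vapply(templates, function(tpl) {
    pearson_r(values, fit_template_length(tpl, length(values)))
  }, numeric(1))
  res$correlations[] <- r
  if (config$mode == "rhythmic_template") {
    res$predicted_label <-
      if (r[1L] >= config$rhythmic_threshold) "rhythmic" else "arrhythmic"
    res$winning_template <- ids[1L]
  } else {
    best <- which.max(r) # ties resolve to the first template
    res$winning_template <- ids[best]
    res$predicted_label <-
      if (r[best] > config$arrhythmic_threshold) "arrhythmic" else "rhythmic"
  }
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> beat %s -> %s (r: %s)\n",
              as.character(x$beat_index), x$predicted_label,
              paste(sprintf("%s=%.4f", names(x$correlations),
                            x$correlations), collapse = ", ")))
  invisible(x)
}

#' Classify every beat of a segmented trace
#'
#' @param beats List of beats from [extract_beats()].
#' @param templates,config As in [match_beat()].
#' @return List of `match_result`, one per beat (indices 1-based).
#' @export
match_beats <- function(beats, templates, config = match_config()) {
  lapply(seq_along(beats), function(j) {
    match_beat(beats[[j]], templates, config, beat_index = j)
  })
}

#' Pairwise self-similarity of a beat set
#'
#' Every beat serves as a template for every other: entry (i, j) is the
#' correlation between beat i and beat j length-matched to beat i. The
#' matrix is symmetrized by averaging the two match directions (they differ
#' only by which beat is resampled); the diagonal is exactly 1. Degenerate
#' (zero-variance) beats yield NA rows/columns.
#'
#' @param beats List of beats (or numeric vectors), length >= 2.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_self_similarity <- function(beats) {
  if (length(beats) < 2L) {
    stop("pairwise_self_similarity: need at least 2 beats", call. = FALSE)
  }
  vals <- lapply(beats, function(b) {
    if (inherits(b, "atm_beat")) b$values else as.numeric(b)
  })
  nb <- length(vals)
  r <- diag(1, nb)
  ok <- vapply(vals, function(v) stats::var(v) > 0, logical(1))
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):nb) {
      if (ok[i] && ok[j]) {
        rij <- pearson_r(vals[[i]],
                         fit_template_length(vals[[j]], length(vals[[i]])))
        rji <- pearson_r(vals[[j]],
                         fit_template_length(vals[[i]], length(vals[[j]])))
        r[i, j] <- r[j, i] <- (rij + rji) / 2
      } else {
        r[i, j] <- r[j, i] <- NA_real_
      }
    }
  }
  if (any(!ok)) r[cbind(which(!ok), which(!ok))] <- NA_real_
  r
}

#' Calibrate a correlation threshold from class-wise correlations
#'
#' The threshold is the maximum correlation observed between the template
#' and the *other* class, rounded up to two decimals (the resolution at
#' which thresholds are conventionally reported). Same-class correlations
#' that fall below the resulting threshold are flagged as outliers in the
#' returned record. If the other-class maximum reaches 0.99 the classes are
#' not separable at two-decimal resolution and calibration fails.
#'
#' @param same_class_r Correlations between the template and beats of its
#'   own class (non-empty).
#' @param other_class_r Correlations with beats of the other class
#'   (non-empty).
#' @return An object of class `atm_calibration`: list with `threshold`,
#'   `other_class_max`, and `flagged` (same-class correlations below the
#'   threshold, possibly empty).
#' @export
#' @examples
#' calibrate_threshold(c(0.995, 0.990), c(0.935967, 0.82))$threshold  # 0.94
calibrate_threshold <- function(same_class_r, other_class_r) {
  if (!length(same_class_r) || !length(other_class_r)) {
    stop("calibrate_threshold: both correlation lists must be non-empty",
         call. = FALSE)
  }
  mx <- max(other_class_r)
  if (mx >= 0.99) {
    stop("calibrate_threshold: classes not separable at 2-decimal resolution (other-class max ",
         format(mx), " >= 0.99)", call. = FALSE)
  }
  # ceiling to 2 decimals, guarding against binary representation of x*100
  threshold <- ceiling(round(mx * 100, 9)) / 100
  flagged <- same_class_r[same_class_r < threshold]
  if (length(flagged)) {
    warning(sprintf(
      "calibrate_threshold: %d same-class correlation(s) below threshold %.2f (min %.6f)",
      length(flagged), threshold, min(flagged)), call. = FALSE)
  }
  structure(
    list(threshold = threshold, other_class_max = mx, flagged = flagged),
    class = "atm_calibration"
  )
}

#' @export
print.atm_calibration <- function(x, ...) {
  cat(sprintf(
    "<atm_calibration> threshold %.2f (other-class max %.6f, %d flagged same-class outlier(s))\n",
    x$threshold, x$other_class_max, length(x$flagged)))
  invisible(x)
}

#' Read / write templates as JSON
#'
#' Format: `{"label": ..., "sample_interval_s": ..., "values": [...],
#' "source": ...}`.
#'
#' @param template An [atm_template()].
#' @param path File path.
#' @return `read_template_json()` returns an [atm_template()];
#'   `write_template_json()` returns `path` invisibly.
#' @export
write_template_json <- function(template, path) {
  stopifnot(inherits(template, "atm_template"))
  jsonlite::write_json(
    list(label = template$label,
         sample_interval_s = template$sample_interval,
         values = template$values,
         source = template$source),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template_json
#' @export
read_template_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  atm_template(x$values, x$sample_interval_s, x$label,
               if (is.null(x$source)) "" else x$source)
}
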