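#' Recognition accuracy from match/mismatch counts
#'
#' @param n_total Total number of classified beats (>= 1).
#' @param n_mismatch Number of mismatched beats, in \[0, n_total\].
#' @return Accuracy in percent at full precision,
#'   `100 * (n_total - n_mismatch) / n_total`.
#' @export
#' @examples
#' accuracy_from_counts(242, 43)  # 82.23...% -> prints as 82.2%
accuracy_from_counts <- function(n_total, n_mismatch) {
  if (!is.finite(n_total) || n_total < 1) {
    stop("accuracy_from_counts: n_total must be >= 1", call. = FALSE)
  }
  if (!is.finite(n_mismatch) || n_mismatch < 0 || n_mismatch > n_total) {
    stop("accuracy_from_counts: n_mismatch must lie in [0, n_total]",
         call. = FALSE)
  }
  100 * (n_total - n_mismatch) / n_total
}

#' Round half away from zero
#'
#' Reporting convention for printed accuracies (so 74.2489...% prints as
#' 74.25%), unlike base `round()`'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Score predictions against ground truth
#'
#' A beat is mismatched when its predicted label differs from the truth
#' label; unclassifiable beats always count as mismatches. When segment ids
#' are supplied a per-segment breakdown is included.
#'
#' @param results List of `match_result` (from [match_beats()]) or a
#'   character vector of predicted labels.
#' @param truth_labels Character vector of per-beat truth labels
#'   (`"rhythmic"`/`"arrhythmic"`), aligned by index with `results`.
#' @param segment_ids Optional per-beat segment identifiers.
#' @param mode Optional mode string recorded in the report.
#' @return An object of class `atm_eval_report`: list with `n_total`,
#'   `n_mismatch`, `accuracy_percent`, `per_segment` (data.frame or NULL)
#'   and `mode`.
#' @export
evaluate_predictions <- function(results, truth_labels, segment_ids = NULL,
                                 mode = NA_character_) {
  predicted <- if (is.character(results)) results else
    vapply(results, `[[`, "", "predicted_label")
  if (length(predicted) != length(truth_labels)) {
    stop("evaluate_predictions: predictions and truth labels differ in length (",
         length(predicted), " vs ", length(truth_labels), ")", call. = FALSE)
  }
  if (!is.null(segment_ids) && length(segment_ids) != length(predicted)) {
    stop("evaluate_predictions: segment_ids length mismatch", call. = FALSE)
  }
  mismatch <- predicted != truth_labels # unclassifiable never equals a label
  n <- length(predicted)
  per_segment <- NULL
  if (!is.null(segment_ids)) {
    agg <- tapply(mismatch, segment_ids, sum)
    cnt <- tapply(mismatch, segment_ids, length)
    per_segment <- data.frame(
      segment = names(agg),
      n = as.integer(cnt),
      n_mismatch = as.integer(agg),
      accuracy_percent = 100 * (as.integer(cnt) - as.integer(agg)) /
        as.integer(cnt),
      row.names = NULL
    )
  }
  structure(
    list(n_total = n, n_mismatch = sum(mismatch),
         accuracy_percent = accuracy_from_counts(n, sum(mismatch)),
         per_segment = per_segment, mode = mode),
    class = "atm_eval_report"
  )
}

#' @export
print.atm_eval_report <- function(x, ...) {
  cat(sprintf("<atm_eval_report>%s %d/%d matched, accuracy %.2f%%\n",
              if (is.na(x$mode)) "" else paste0(" [", x$mode, "]"),
              x$n_total - x$n_mismatch, x$n_total,
              round_half_away(x$accuracy_percent, 2)))
  if (!is.null(x$per_segment)) {
    for (i in seq_len(nrow(x$per_segment))) {
      cat(sprintf("  segment %s: %d/%d (%.2f%%)\n",
                  x$per_segment$segment[i],
                  x$per_segment$n[i] - x$per_segment$n_mismatch[i],
                  x$per_segment$n[i],
                  round_half_away(x$per_segment$accuracy_percent[i], 2)))
    }
  }
  invisible(x)
}

#' Mean and standard deviation of a group of accuracies
#'
#' Sample SD (n - 1 denominator), the convention for small segment
#' replicates; a single value has SD 0.
#'
#' @param values Numeric vector of percentages (length >= 1).
#' @return Named numeric vector `c(mean = ..., sd = ...)`.
#' @export
summarize_group <- function(values) {
  if (!length(values)) {
    stop("summarize_group: need at least one value", call. = FALSE)
  }
  c(mean = mean(values),
    sd = if (length(values) > 1L) stats::sd(values) else 0)
}
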