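#' Segmentation parameters for adaptive valley detection
#'
#' The detector accepts strict local minima that fall into the bottom
#' `depth_fraction` of the locally observed signal range (rolling
#' minimum/maximum over `baseline_window`), then enforces a refractory
#' spacing proportional to the running median inter-valley interval. All
#' thresholds are relative to local baseline and amplitude, so detection is
#' invariant under positive affine transforms of the trace and tolerant of
#' slow baseline drift.
#'
#' @param baseline_window Width in seconds of the rolling window used for
#'   the local baseline and amplitude (recommended >= 2 beat periods).
#' @param depth_fraction Fraction of the local amplitude above the local
#'   minimum below which a candidate valley must lie, in (0,1).
#' @param refractory_fraction Minimum spacing between accepted valleys as a
#'   fraction of the running median inter-valley interval, in (0,1).
#' @param min_beat_samples Minimum number of samples for an extracted beat.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(baseline_window = 5,
                                depth_fraction = 0.25,
                                refractory_fraction = 0.4,
                                min_beat_samples = 100L) {
  if (baseline_window <= 0 || min_beat_samples < 1 ||
      depth_fraction <= 0 || depth_fraction >= 1 ||
      refractory_fraction <= 0 || refractory_fraction >= 1) {
    stop("segmentation_params: fields must be positive; fractions in (0,1)",
         call. = FALSE)
  }
  structure(
    list(baseline_window = baseline_window,
         depth_fraction = depth_fraction,
         refractory_fraction = refractory_fraction,
         min_beat_samples = as.integer(min_beat_samples)),
    class = "segmentation_params"
  )
}

# exact rolling min/max over centred windows of half-width `half`
# (two-block prefix/suffix decomposition; windows clipped at the edges are
# evaluated over a slightly enlarged span, which only affects the first and
# last half-window of the trace)
.rolling_extremes <- function(v, half) {
  n <- length(v)
  w <- 2L * half + 1L
  if (w >= n) {
    return(list(min = rep(min(v), n), max = rep(max(v), n)))
  }
  nb <- ceiling(n / w)
  roll1 <- function(vp, comb) {
    m <- matrix(vp, nrow = w)
    pref <- apply(m, 2L, comb)
    suff <- apply(m[rev(seq_len(w)), , drop = FALSE], 2L, comb)
    suff <- suff[rev(seq_len(w)), , drop = FALSE]
    list(pref = as.vector(pref), suff = as.vector(suff))
  }
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  mn <- roll1(c(v, rep(Inf, nb * w - n)), cummin)
  mx <- roll1(c(v, rep(-Inf, nb * w - n)), cummax)
  list(min = pmin(mn$suff[lo], mn$pref[hi]),
       max = pmax(mx$suff[lo], mx$pref[hi]))
}

# strict local minima, plateau-aware: the earliest index of any equal-valued
# run that is lower than both neighbouring runs
.strict_local_minima <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  if (k < 3L) return(integer())
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  interior <- 2:(k - 1L)
  ismin <- r$values[interior] < r$values[interior - 1L] &
    r$values[interior] < r$values[interior + 1L]
  starts[interior][ismin]
}

#' Detect beat-boundary valleys by the adaptive threshold algorithm
#'
#' @param trace An [impedance_trace()] (normally smoothed and upsampled).
#' @param params A [segmentation_params()].
#' @return Strictly increasing integer vector of valley sample indices
#'   (1-based); possibly empty.
#' @export
#' @examples
#' lt <- synth_trace(sim_config(5, rng_seed = 1))
#' tr <- upsample(smooth5(lt$trace), 10)
#' detect_valleys(tr, segmentation_params())
detect_valleys <- function(trace, params = segmentation_params()) {
  stopifnot(inherits(trace, "impedance_trace"),
            inherits(params, "segmentation_params"))
  v <- trace$values
  n <- length(v)
  if (n <= params$min_beat_samples) return(integer())
  cand <- .strict_local_minima(v)
  if (!length(cand)) return(integer())
  half <- max(1L, round(params$baseline_window / trace$sample_interval / 2))
  ex <- .rolling_extremes(v, half)
  thr <- ex$min + params$depth_fraction * (ex$max - ex$min)
  cand <- cand[v[cand] <= thr[cand]]
  if (length(cand) < 2L) return(cand)
  # refractory pruning against the running median inter-valley interval
  est <- stats::median(diff(cand))
  acc <- cand[1L]
  for (i in cand[-1L]) {
    gap <- i - acc[length(acc)]
    if (gap >= params$refractory_fraction * est) {
      acc <- c(acc, i)
      if (length(acc) > 2L) est <- stats::median(diff(acc))
    } else if (v[i] < v[acc[length(acc)]]) {
      acc[length(acc)] <- i # keep the deeper of two conflicting minima
      if (length(acc) > 2L) est <- stats::median(diff(acc))
    } # ties keep the earlier index
  }
  acc
}

# dominant local maxima of one beat: strict maxima above valley + 25% amp
.dominant_peaks <- function(values) {
  n <- length(values)
  if (n < 3L) return(integer())
  thr <- min(values) + 0.25 * (max(values) - min(values))
  i <- 2:(n - 1L)
  i[values[i] > values[i - 1L] & values[i] > values[i + 1L] & values[i] > thr]
}

#' Extract valley-to-valley beat units
#'
#' One beat per consecutive valley pair, sharing boundary samples with its
#' neighbours (closed intervals). Beats shorter than `min_beat_samples` are
#' discarded, as is any partial data before the first or after the last
#' valley.
#'
#' @param trace An [impedance_trace()].
#' @param valleys Valley indices from [detect_valleys()].
#' @param params A [segmentation_params()] (supplies `min_beat_samples`).
#' @return List of `atm_beat` objects: each has `values`, `sample_interval`,
#'   `start_time`, `peak_indices` (dominant maxima, 1-based within the
#'   beat), and `truth_label` (NA until assigned).
#' @export
extract_beats <- function(trace, valleys, params = segmentation_params()) {
  stopifnot(inherits(trace, "impedance_trace"))
  if (length(valleys) < 2L) return(list())
  beats <- list()
  for (j in seq_len(length(valleys) - 1L)) {
    i0 <- valleys[j]
    i1 <- valleys[j + 1L]
    if (i1 - i0 + 1L < params$min_beat_samples) next
    vals <- trace$values[i0:i1]
    beats[[length(beats) + 1L]] <- structure(
      list(values = vals,
           sample_interval = trace$sample_interval,
           start_time = trace$start_time + (i0 - 1L) * trace$sample_interval,
           peak_indices = .dominant_peaks(vals),
           truth_label = NA_character_),
      class = "atm_beat"
    )
  }
  beats
}

#' @export
print.atm_beat <- function(x, ...) {
  cat(sprintf("<atm_beat> %d samples from t=%.3f s, %d dominant peak(s)%s\n",
              length(x$values), x$start_time, length(x$peak_indices),
              if (is.na(x$truth_label)) "" else paste0(", truth=", x$truth_label)))
  invisible(x)
}

#' Attach ground-truth labels to extracted beats by interval overlap
#'
#' Each beat inherits the label of the ground-truth beat interval it
#' overlaps most (as read by [read_labels_csv()] or taken from a
#' `labeled_trace`).
#'
#' @param beats List of beats from [extract_beats()].
#' @param truth A `labeled_trace` or a labels data.frame with columns
#'   `start_s`, `end_s`, `label`.
#' @return The beat list with `truth_label` filled in.
#' @export
assign_truth_labels <- function(beats, truth) {
  if (inherits(truth, "labeled_trace")) {
    n <- length(truth$truth_labels)
    truth <- data.frame(start_s = truth$truth_valley_times[seq_len(n)],
                        end_s = truth$truth_valley_times[seq_len(n) + 1L],
                        label = truth$truth_labels)
  }
  for (j in seq_along(beats)) {
    b <- beats[[j]]
    b_end <- b$start_time + (length(b$values) - 1L) * b$sample_interval
    ov <- pmin(b_end, truth$end_s) - pmax(b$start_time, truth$start_s)
    if (any(ov > 0)) beats[[j]]$truth_label <- truth$label[which.max(ov)]
  }
  beats
}

#' Mean beat features of a segmented trace
#'
#' @param trace An [impedance_trace()].
#' @param valleys Valley indices from [detect_valleys()] (>= 2).
#' @return An object of class `beat_features`: list with `peak_value` and
#'   `valley_value` (mean per-beat maximum / mean valley sample, a.u.),
#'   `peak_interval` and `valley_interval` (mean spacing in seconds), and
#'   `amplitude` (= `peak_value - valley_value`).
#' @export
beat_features <- function(trace, valleys) {
  stopifnot(inherits(trace, "impedance_trace"))
  if (length(valleys) < 2L) {
    stop("beat_features: need at least 2 valleys", call. = FALSE)
  }
  dt <- trace$sample_interval
  nb <- length(valleys) - 1L
  peak_idx <- integer(nb)
  peak_val <- numeric(nb)
  for (j in seq_len(nb)) {
    seg <- valleys[j]:valleys[j + 1L]
    peak_idx[j] <- seg[which.max(trace$values[seg])]
    peak_val[j] <- trace$values[peak_idx[j]]
  }
  pv <- mean(peak_val)
  vv <- mean(trace$values[valleys])
  structure(
    list(peak_value = pv,
         valley_value = vv,
         peak_interval = if (nb > 1L) mean(diff(peak_idx)) * dt else
           (valleys[2L] - valleys[1L]) * dt,
         valley_interval = mean(diff(valleys)) * dt,
         amplitude = pv - vv),
    class = "beat_features"
  )
}

#' @export
print.beat_features <- function(x, ...) {
  cat(sprintf(
    "<beat_features> peak %.4g / valley %.4g a.u. (amplitude %.4g); peak interval %.4g s / valley interval %.4g s\n",
    x$peak_value, x$valley_value, x$amplitude,
    x$peak_interval, x$valley_interval))
  invisible(x)
}
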