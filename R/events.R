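#' Detect breathing events in a smoothed trace
#'
#' End-inspiration peaks are local maxima whose topographic prominence
#' exceeds a stated fraction of the trace's 5th-to-95th percentile span,
#' separated by at least `min_sep`. For each peak, the begin-of-inspiration
#' point is found by walking backwards to the last sample at which the
#' signal still sat at baseline (below `baseline + k * noise_sd`). An event
#' is complete iff both its start and the following start lie inside the
#' record.
#'
#' @param trace A smoothed or baseline-corrected [breathing_trace()].
#' @param prominence Required prominence as a fraction of the 5-95
#'   percentile span (default 0.3).
#' @param min_sep Minimum peak separation in s; default 0.5 x
#'   `expected_period`.
#' @param expected_period Expected breath period in s; estimated from the
#'   trace autocorrelation when `NULL`.
#' @param k_noise Baseline-crossing threshold in units of the baseline noise
#'   SD (default 1).
#' @return A list with `peaks` and `starts` (times in s), `peak_idx`,
#'   `start_idx`, `complete` (one flag per peak) and the `threshold` used.
#'   Zero peaks yields empty vectors with a warning.
#' @export
detect_events <- function(trace, prominence = 0.3, min_sep = NULL,
                          expected_period = NULL, k_noise = 1) {
  v <- trace$v
  n <- length(v)
  span <- diff(stats::quantile(v, c(0.05, 0.95), names = FALSE))
  if (span <= 0) {
    warning("detect_events: flat trace, no peaks found")
    return(empty_events())
  }
  if (is.null(min_sep)) {
    if (is.null(expected_period)) expected_period <- estimate_period(trace)
    min_sep <- 0.5 * expected_period
  }
  prom <- peak_prominences(v)
  cand <- which(prom > 0)
  cand <- cand[prom[cand] >= prominence * span]
  # greedy separation enforcement, highest peaks first
  cand <- cand[order(v[cand], decreasing = TRUE)]
  sep <- max(1L, round(min_sep * trace$frame_rate))
  keep <- integer(0)
  for (i in cand) {
    if (all(abs(i - keep) >= sep)) keep <- c(keep, i)
  }
  peak_idx <- sort(keep)
  if (length(peak_idx) == 0) {
    warning("detect_events: no peaks found")
    return(empty_events())
  }

  baseline <- stats::median(v)
  noise_sd <- stats::mad(v[v <= baseline])
  if (!is.finite(noise_sd) || noise_sd == 0) noise_sd <- stats::sd(v) / 10
  thr <- baseline + k_noise * noise_sd
  start_idx <- vapply(seq_along(peak_idx), function(j) {
    lo <- if (j == 1) 1L else peak_idx[j - 1]
    i <- peak_idx[j]
    below <- which(v[lo:i] <= thr)
    if (length(below) == 0) NA_integer_ else lo + max(below) - 1L
  }, integer(1))

  complete <- !is.na(start_idx) &
    c(!is.na(start_idx[-1]), FALSE)   # needs the next start inside the record
  list(peaks = trace$t[peak_idx], starts = trace$t[start_idx],
       peak_idx = peak_idx, start_idx = start_idx,
       complete = complete, threshold = thr)
}

empty_events <- function() {
  list(peaks = numeric(0), starts = numeric(0), peak_idx = integer(0),
       start_idx = integer(0), complete = logical(0), threshold = NA_real_)
}

# topographic prominence of every local maximum (0 elsewhere)
peak_prominences <- function(v) {
  n <- length(v)
  prom <- numeric(n)
  if (n < 3) return(prom)
  is_max <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE)
  for (i in which(is_max)) {
    p <- v[i]
    left <- v[seq_len(i - 1)]
    higher <- which(left > p)
    lmin <- min(left[seq.int(if (length(higher)) max(higher) else 1L, i - 1L)])
    right <- v[seq.int(i + 1L, n)]
    higher <- which(right > p)
    rmin <- min(right[seq_len(if (length(higher)) min(higher) else length(right))])
    prom[i] <- p - max(lmin, rmin)
  }
  prom
}

# dominant breath period from the autocorrelation of the detrended trace
estimate_period <- function(trace, min_period = 0.3) {
  v <- trace$v - mean(trace$v)
  n <- length(v)
  max_lag <- min(n - 2L, floor(n / 2))
  ac <- stats::acf(v, lag.max = max_lag, plot = FALSE)$acf[-1]
  lo <- max(2L, round(min_period * trace$frame_rate))
  if (lo >= max_lag) return(max_lag / trace$frame_rate)
  (lo + which.max(ac[lo:max_lag]) - 1L) / trace$frame_rate
}

#' Overlay breathing events at their end-inspiration peak
#'
#' Cuts the trace at successive begin-of-inspiration points and re-times
#' each complete event so its peak sits at `t_rel = 0` (negative times:
#' inspiration; positive: expiration). Incomplete boundary events are
#' retained with `complete = FALSE` and excluded from fitting.
#'
#' @param trace The [breathing_trace()] the events were detected on.
#' @param events Output of [detect_events()].
#' @return A list of `breathing_event` objects (fields `t_rel`, `v`,
#'   `complete`, `frame_rate`).
#' @export
overlay_events <- function(trace, events) {
  lapply(seq_along(events$peak_idx), function(j) {
    i0 <- events$start_idx[j]
    i1 <- if (j < length(events$peak_idx)) events$start_idx[j + 1] else NA_integer_
    complete <- isTRUE(events$complete[j])
    if (is.na(i0)) i0 <- if (j == 1) 1L else events$peak_idx[j - 1]
    if (is.na(i1)) i1 <- length(trace$v)
    idx <- i0:i1
    structure(list(t_rel = trace$t[idx] - trace$t[events$peak_idx[j]],
                   v = trace$v[idx], complete = complete,
                   frame_rate = trace$frame_rate),
              class = "breathing_event")
  })
}

#' Area under one breathing event
#'
#' Trapezoidal integral of the positive part of the baseline-referenced
#' event waveform, start to end.
#'
#' @param event A complete `breathing_event` from [overlay_events()].
#' @return AUC in value x s.
#' @export
compute_auc <- function(event) {
  stopifnot(inherits(event, "breathing_event"))
  if (!isTRUE(event$complete)) {
    stop("compute_auc: event is not fully recorded")
  }
  trapz_integral(event$t_rel, pmax(event$v, 0))
}

#' Breathing frequency from peak times
#'
#' @param peaks End-inspiration peak times in s (>= 2).
#' @return A list with `frequency` (Hz) and `mean_interval` (ms);
#'   `frequency * mean_interval == 1000` by definition.
#' @export
breathing_frequency <- function(peaks) {
  if (length(peaks) < 2) stop("breathing_frequency: need at least 2 peaks")
  mi <- mean(diff(peaks))
  list(frequency = 1 / mi, mean_interval = 1000 * mi)
}
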