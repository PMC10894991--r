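#' Extract a breathing trace from a radiograph sequence
#'
#' Per frame, the mean intensity over a lung ROI; with a reference ROI
#' (placed beside the animal, containing only air) its per-frame mean is
#' subtracted to normalize beam fluctuations. Without a reference ROI (small
#' field of view, no air region available) the raw ROI mean is returned and
#' [correct_baseline()] should be applied downstream.
#'
#' @param seq A [radiograph_sequence()].
#' @param roi Lung [roi_box()].
#' @param ref_roi Optional air-reference [roi_box()]; must not overlap `roi`.
#' @return A [breathing_trace()].
#' @export
extract_trace <- function(seq, roi, ref_roi = NULL) {
  stopifnot(inherits(seq, "radiograph_sequence"))
  d <- dim(seq$frames)
  check_roi_bounds(roi, d)
  if (!is.null(ref_roi)) {
    check_roi_bounds(ref_roi, d)
    if (rois_overlap(roi, ref_roi)) {
      stop("extract_trace: roi and ref_roi overlap")
    }
  }
  nf <- d[3]
  v <- vapply(seq_len(nf), function(i) {
    m <- mean(roi_pixels(seq$frames[, , i], roi))
    if (!is.null(ref_roi)) m <- m - mean(roi_pixels(seq$frames[, , i], ref_roi))
    m
  }, numeric(1))
  breathing_trace((seq_len(nf) - 1) / seq$frame_rate, v, seq$frame_rate)
}

# centred moving average; edges use shrinking (truncated) windows so the
# output has the input length. w must be odd.
moving_average <- function(v, w) {
  n <- length(v)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

window_samples <- function(window, frame_rate, n) {
  w <- round(window * frame_rate)
  w <- w + (1L - w %% 2L)          # nearest odd count
  if (window < 2 / frame_rate) stop("window must be at least 2 samples long")
  if (w > n) stop("window longer than the trace")
  as.integer(w)
}

#' Rolling-average smoothing of a breathing trace
#'
#' Centred moving average with the window rounded to the nearest odd sample
#' count; edges use shrinking windows, so the output length equals the
#' input length.
#'
#' @param trace A [breathing_trace()].
#' @param window Window length in s (>= 2 frame periods, <= trace length).
#' @return The smoothed [breathing_trace()].
#' @export
smooth_trace <- function(trace, window) {
  w <- window_samples(window, trace$frame_rate, length(trace$v))
  breathing_trace(trace$t, moving_average(trace$v, w), trace$frame_rate,
                  truth = trace$truth)
}

#' Rolling-average baseline correction
#'
#' Subtracts the trace's own rolling average (window as in
#' [smooth_trace()], but much longer than a breath), removing slow baseline
#' build-up and drift; the interior of the corrected trace has mean ~ 0.
#'
#' @param trace A [breathing_trace()].
#' @param window Window length in s; should be at least twice the expected
#'   breathing period.
#' @return The baseline-corrected [breathing_trace()].
#' @export
correct_baseline <- function(trace, window) {
  w <- window_samples(window, trace$frame_rate, length(trace$v))
  breathing_trace(trace$t, trace$v - moving_average(trace$v, w),
                  trace$frame_rate, truth = trace$truth)
}
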