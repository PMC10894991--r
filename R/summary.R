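#' Functional-analysis configuration
#'
#' Collects the tunable settings of [summarize_function()]. Window lengths
#' default to fractions of the median breath interval measured on the trace
#' itself: smoothing 0.25x, baseline 2x.
#'
#' @param mode `"reference"` (trace already beam-normalized by a reference
#'   ROI; smoothing only) or `"baseline"` (no air reference available;
#'   rolling-average baseline correction first).
#' @param fit `"hyperbolic"`, `"double_gaussian"`, or `"both"`.
#' @param smooth_window,baseline_window Window lengths in s (NULL =
#'   period-derived defaults).
#' @param prominence Peak prominence threshold (fraction of the 5-95
#'   percentile span).
#' @param min_sep Minimum peak separation in s (NULL = 0.5 x estimated
#'   period).
#' @param expected_period Expected breath period in s (NULL = estimated
#'   from the trace autocorrelation).
#' @param onset_t_max Upper bound for the dampening-onset search in s
#'   (NULL = 0.5 x period).
#' @return A list of class `functional_config`.
#' @export
functional_config <- function(mode = c("reference", "baseline"),
                              fit = c("both", "hyperbolic", "double_gaussian"),
                              smooth_window = NULL, baseline_window = NULL,
                              prominence = 0.3, min_sep = NULL,
                              expected_period = NULL, onset_t_max = NULL) {
  structure(list(mode = match.arg(mode), fit = match.arg(fit),
                 smooth_window = smooth_window,
                 baseline_window = baseline_window, prominence = prominence,
                 min_sep = min_sep, expected_period = expected_period,
                 onset_t_max = onset_t_max),
            class = "functional_config")
}

#' Full functional analysis of a breathing trace
#'
#' Composes the planar pipeline: (baseline correction for the no-reference
#' mode) - rolling-average smoothing - peak/start detection - event overlay
#' at the peak - model fits - summary parameters. The raise and fall
#' constants are the `c1` coefficients of the inspiration and expiration
#' hyperbolic fits; the dampening onset is the third-derivative minimum of
#' the double-Gaussian expiration fit.
#'
#' @param trace A [breathing_trace()].
#' @param config A [functional_config()].
#' @return An object of class `functional_summary` with fields `frequency`
#'   (Hz), `mean_interval` (ms), `auc` (mean per-event value x s),
#'   `raise_const`, `fall_const`, `dampening_onset` (ms or NA), `n_events`,
#'   and a `detail` list (events, fits, branch used).
#' @export
summarize_function <- function(trace, config = functional_config()) {
  cfg <- config
  period <- if (!is.null(cfg$expected_period)) cfg$expected_period else
    estimate_period(trace)

  stage <- "preprocess"
  out <- tryCatch({
    work <- trace
    if (cfg$mode == "baseline") {
      bw <- if (!is.null(cfg$baseline_window)) cfg$baseline_window else
        min(2 * period, (length(trace$v) - 1) / trace$frame_rate)
      work <- correct_baseline(work, bw)
    }
    # reference events to the resting level so AUC integrates the breath
    # excursion, not an arbitrary intensity offset
    work$v <- work$v - stats::median(work$v)
    sw <- if (!is.null(cfg$smooth_window)) cfg$smooth_window else
      max(0.25 * period, 2 / trace$frame_rate)
    smoothed <- smooth_trace(work, sw)

    stage <- "detect"
    # the rolling average is used to *locate* peaks and starts; events are
    # overlaid and fitted on the unsmoothed (corrected) curve
    ev <- detect_events(smoothed, prominence = cfg$prominence,
                        min_sep = cfg$min_sep, expected_period = period)
    if (length(ev$peaks) < 2) stop("fewer than 2 breathing events detected")
    events <- overlay_events(work, ev)
    complete <- Filter(function(e) isTRUE(e$complete), events)
    if (length(complete) < 1) stop("no fully recorded breathing events")

    stage <- "frequency"
    freq <- breathing_frequency(ev$peaks)
    auc <- mean(vapply(complete, compute_auc, numeric(1)))

    raise_const <- fall_const <- NA_real_
    onset_ms <- NA_real_
    hyp <- dg <- NULL
    if (cfg$fit %in% c("both", "hyperbolic")) {
      stage <- "hyperbolic fit"
      hyp <- list(inspiration = fit_hyperbolic(events, "inspiration"),
                  expiration = fit_hyperbolic(events, "expiration"))
      raise_const <- hyp$inspiration$c1
      fall_const <- hyp$expiration$c1
    }
    if (cfg$fit %in% c("both", "double_gaussian")) {
      stage <- "double-Gaussian fit"
      dg <- fit_double_gaussian(events)
      if (isTRUE(dg$converged)) {
        t_max <- if (!is.null(cfg$onset_t_max)) cfg$onset_t_max else 0.5 * period
        onset_ms <- 1000 * as.numeric(dampening_onset(dg, t_max))
      }
    }

    structure(list(frequency = freq$frequency,
                   mean_interval = freq$mean_interval,
                   auc = auc, raise_const = raise_const,
                   fall_const = fall_const, dampening_onset = onset_ms,
                   n_events = length(ev$peaks),
                   detail = list(events = events, detection = ev,
                                 hyperbolic = hyp, double_gaussian = dg,
                                 smoothed = smoothed, mode = cfg$mode,
                                 period_used = period)),
              class = "functional_summary")
  }, error = function(e) {
    stop(sprintf("summarize_function [%s]: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  out
}

#' @export
print.functional_summary <- function(x, ...) {
  cat(sprintf(paste0("functional summary: %d events, %.3g Hz ",
                     "(interval %.0f ms)\n  AUC %.4g, raise %.4g, ",
                     "fall %.4g, dampening onset %.1f ms\n"),
              x$n_events, x$frequency, x$mean_interval, x$auc,
              x$raise_const, x$fall_const, x$dampening_onset))
  invisible(x)
}

#' Per-animal functional summary table
#'
#' @param summaries Named list of `functional_summary` objects (one per
#'   animal).
#' @param group Optional group label per animal (e.g. "CN"/"SAA").
#' @return A data.frame with one row per animal.
#' @export
summary_table <- function(summaries, group = NULL) {
  rows <- lapply(summaries, function(s) {
    data.frame(frequency_hz = s$frequency, mean_interval_ms = s$mean_interval,
               auc = s$auc, raise_const = s$raise_const,
               fall_const = s$fall_const, dampening_onset_ms = s$dampening_onset,
               n_events = s$n_events)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(animal = names(summaries) %||% seq_along(summaries)),
               out)
  if (!is.null(group)) out$group <- group
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
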