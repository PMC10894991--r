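#' Breathing-model parameters
#'
#' Parameterizes the synthetic breathing waveform: each breath is a linear
#' inspiration ramp of `rise_time` up to `amplitude`, followed by a
#' two-phase expiration — fast elastic recoil `amplitude * exp(-recoil_rate * t^2)`
#' up to `onset` seconds after the peak, then a slower diaphragm-dampened
#' Gaussian decay with rate `damped_rate`, joined so that the waveform and
#' its first derivative are continuous at `onset` — and a resting phase at
#' baseline until the next breath. Cardiac modulation, slow baseline drift
#' and Gaussian noise are superimposed.
#'
#' @param period Breath-to-breath interval in s.
#' @param rise_time Inspiration duration in s (`< period`).
#' @param amplitude Peak excursion above baseline (dimensionless
#'   transmission units).
#' @param recoil_rate Fast-expiration Gaussian decay rate in 1/s^2.
#' @param damped_rate Slow-expiration Gaussian decay rate in 1/s^2
#'   (`< recoil_rate`).
#' @param onset Time after the peak, in s, at which dampening takes over.
#' @param cardiac_amp,cardiac_freq Amplitude (same units as `amplitude`) and
#'   frequency (Hz) of the heart-motion sinusoid.
#' @param drift_amp,drift_freq Amplitude and frequency (Hz) of the slow
#'   baseline (beam-flicker) sinusoid.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed RNG seed used by the generator.
#' @return An object of class `breathing_model_params`.
#' @seealso [breathing_preset()] for the healthy-control and severe-asthma
#'   presets, [generate_breathing_trace()].
#' @export
breathing_model_params <- function(period = 1.4, rise_time = 0.15,
                                   amplitude = 1, recoil_rate = 300,
                                   damped_rate = 15, onset = 0.05,
                                   cardiac_amp = 0.03, cardiac_freq = 5,
                                   drift_amp = 0.05, drift_freq = 0.05,
                                   noise_sd = 0.02, seed = 1L) {
  if (!(period > rise_time && rise_time > 0)) {
    stop("breathing_model_params: need period > rise_time > 0")
  }
  if (!(recoil_rate > damped_rate && damped_rate > 0)) {
    stop("breathing_model_params: need recoil_rate > damped_rate > 0")
  }
  if (onset < 0) stop("breathing_model_params: onset must be >= 0")
  amps <- c(amplitude = amplitude, cardiac_amp = cardiac_amp,
            drift_amp = drift_amp, noise_sd = noise_sd)
  if (any(amps < 0)) {
    stop(sprintf("breathing_model_params: '%s' must be >= 0",
                 names(amps)[which(amps < 0)[1]]))
  }
  structure(list(period = period, rise_time = rise_time, amplitude = amplitude,
                 recoil_rate = recoil_rate, damped_rate = damped_rate,
                 onset = onset, cardiac_amp = cardiac_amp,
                 cardiac_freq = cardiac_freq, drift_amp = drift_amp,
                 drift_freq = drift_freq, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "breathing_model_params")
}

#' Breathing presets for the healthy-control and severe-asthma groups
#'
#' `"CN"` is the healthy control; `"SAA"` models severe allergic asthma as a
#' loss of elastic recoil: slower recoil and dampened decay rates and a later
#' dampening onset at equal amplitude, which enlarges the per-breath area
#' under the curve and flattens the expiration.
#'
#' @param group `"CN"` or `"SAA"`.
#' @param ... Overrides passed to [breathing_model_params()].
#' @return A [breathing_model_params()] object.
#' @export
breathing_preset <- function(group = c("CN", "SAA"), ...) {
  group <- match.arg(group)
  base <- switch(group,
    CN  = list(recoil_rate = 300, damped_rate = 15, onset = 0.05),
    SAA = list(recoil_rate = 110, damped_rate = 5, onset = 0.18))
  do.call(breathing_model_params, utils::modifyList(base, list(...)))
}

# Slow-phase Gaussian continuation: value and slope matched to the recoil
# Gaussian at `onset` (centre t0 < 0, peak B follow from the matching).
damped_branch_constants <- function(p) {
  r <- p$recoil_rate; d <- p$damped_rate; o <- p$onset
  t0 <- o * (1 - r / d)
  B <- p$amplitude * exp(r * o^2 * (r / d - 1))
  list(t0 = t0, B = B)
}

#' Noise-free breathing waveform (closed form)
#'
#' Evaluates the deterministic breath waveform at arbitrary times; `t = 0`
#' is begin-inspiration of the first breath and breaths repeat every
#' `period`.
#'
#' @param t Times in s (vector).
#' @param params A [breathing_model_params()].
#' @return Waveform values (baseline 0).
#' @export
breathing_waveform <- function(t, params) {
  p <- params
  tau <- t %% p$period
  v <- numeric(length(t))
  insp <- tau < p$rise_time
  v[insp] <- p$amplitude * tau[insp] / p$rise_time
  te <- tau - p$rise_time            # time since end-inspiration peak
  fast <- !insp & te < p$onset
  v[fast] <- p$amplitude * exp(-p$recoil_rate * te[fast]^2)
  slow <- !insp & !fast
  k <- damped_branch_constants(p)
  v[slow] <- k$B * exp(-p$damped_rate * (te[slow] - k$t0)^2)
  v
}

#' Time-stamped breathing trace
#'
#' @param t Sample times in s, strictly increasing at uniform spacing
#'   `1/frame_rate`.
#' @param v Mean-transmission values (same length as `t`).
#' @param frame_rate Sampling rate in fps.
#' @param truth Optional ground-truth list attached by the generator.
#' @return An object of class `breathing_trace`.
#' @export
breathing_trace <- function(t, v, frame_rate, truth = NULL) {
  if (length(t) != length(v)) stop("breathing_trace: t and v lengths differ")
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("breathing_trace: t must be strictly increasing")
    if (max(abs(dt - 1 / frame_rate)) > 1e-6 / frame_rate) {
      stop("breathing_trace: t spacing must equal 1/frame_rate")
    }
  }
  structure(list(t = t, v = v, frame_rate = frame_rate, truth = truth),
            class = "breathing_trace")
}

#' @export
print.breathing_trace <- function(x, ...) {
  cat(sprintf("breathing trace: %d samples at %.4g fps (%.3g s)%s\n",
              length(x$t), x$frame_rate, length(x$t) / x$frame_rate,
              if (!is.null(x$truth)) sprintf(", %d ground-truth breaths",
                                             length(x$truth$peaks)) else ""))
  invisible(x)
}

#' Generate a synthetic breathing trace with ground truth
#'
#' Samples the closed-form breath waveform at `frame_rate`, adds cardiac and
#' drift sinusoids and seeded Gaussian noise, and attaches ground truth:
#' begin-inspiration times, end-inspiration peak times, and the per-breath
#' area under the noise-free waveform (trapezoid at 10x oversampling).
#'
#' @param params A [breathing_model_params()].
#' @param duration Trace duration in s (`>= period`).
#' @param frame_rate Sampling rate in fps; must resolve each breath with at
#'   least 10 samples.
#' @return A [breathing_trace()] whose `truth` element has `starts`, `peaks`
#'   and `auc` (one per fully contained breath).
#' @export
generate_breathing_trace <- function(params, duration, frame_rate) {
  p <- params
  if (duration < p$period) stop("generate_breathing_trace: duration < period")
  if (frame_rate * p$period < 10) {
    stop("generate_breathing_trace: frame_rate too low to resolve breaths (need frame_rate * period >= 10)")
  }
  n <- floor(duration * frame_rate)
  t <- (seq_len(n) - 1) / frame_rate
  clean <- breathing_waveform(t, p)

  # breaths whose end-inspiration peak falls inside the record
  n_breaths <- floor((duration - p$rise_time) / p$period - 1e-12) + 1L
  starts <- (seq_len(n_breaths) - 1) * p$period
  peaks <- starts + p$rise_time
  auc <- vapply(starts, function(s0) {
    tt <- seq(s0, min(s0 + p$period, duration), by = 1 / (10 * frame_rate))
    trapz_integral(tt, pmax(breathing_waveform(tt, p), 0))
  }, numeric(1))

  v <- clean +
    p$cardiac_amp * sin(2 * pi * p$cardiac_freq * t) +
    p$drift_amp * sin(2 * pi * p$drift_freq * t)
  if (p$noise_sd > 0) {
    v <- v + with_seed(p$seed, stats::rnorm(n, sd = p$noise_sd))
  }
  breathing_trace(t, v, frame_rate,
                  truth = list(starts = starts, peaks = peaks, auc = auc,
                               clean = clean, params = p))
}

# trapezoidal rule on a sampled curve
trapz_integral <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# evaluate expr with a local, restored RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
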