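test_that("trace extraction subtracts the air reference and validates ROIs", {
  frames <- array(0, dim = c(6, 12, 4))
  frames[, 1:6, ] <- 5      # lung region
  frames[, 7:12, ] <- 2     # air reference
  s <- radiograph_sequence(frames, 10, 30)
  lung <- roi_box(0, 0, 6, 6); ref <- roi_box(0, 6, 6, 12)
  tr <- extract_trace(s, lung, ref)
  expect_equal(tr$v, rep(3, 4))
  expect_equal(extract_trace(s, lung)$v, rep(5, 4))   # no-reference mode
  expect_error(extract_trace(s, lung, roi_box(0, 5, 6, 12)), "overlap")
  expect_error(extract_trace(s, roi_box(0, 0, 7, 6), ref), "exceeds")
})

test_that("reference subtraction on log frames removes multiplicative flicker", {
  set.seed(4)
  nf <- 200
  flicker <- 1 + 0.05 * sin(2 * pi * 0.3 * (1:nf) / 10)
  base <- array(rep(c(rep(400, 6 * 6), rep(900, 6 * 6)), nf), c(6, 12, nf))
  frames <- sweep(base, 3, flicker, `*`)
  s_log <- radiograph_sequence(log(frames), 10, 30)
  lung <- roi_box(0, 0, 6, 6); ref <- roi_box(0, 6, 6, 12)
  with_ref <- extract_trace(s_log, lung, ref)
  without <- extract_trace(s_log, lung)
  expect_lt(var(with_ref$v), 1e-3 * var(without$v))
})

test_that("rolling-average smoothing: identity, gain, impulse response, errors", {
  n <- 200
  tr <- breathing_trace((0:(n - 1)) / 20, rep(2.5, n), 20)
  expect_equal(smooth_trace(tr, 0.5)$v, tr$v)

  # sine of period P with window P: attenuated below 5 %
  P <- 1
  t <- (0:(20 * 20 - 1)) / 20
  sine <- breathing_trace(t, sin(2 * pi * t / P), 20)
  sm <- smooth_trace(sine, P)
  interior <- seq(41, length(t) - 40)
  expect_lt(max(abs(sm$v[interior])), 0.05)

  # impulse -> plateau of h / w
  imp <- breathing_trace((0:99) / 10, c(rep(0, 50), 8, rep(0, 49)), 10)
  smi <- smooth_trace(imp, 0.5)     # 5 samples
  expect_equal(max(smi$v), 8 / 5)
  expect_equal(sum(smi$v > 1e-12), 5)

  expect_error(smooth_trace(tr, 25), "longer")
  expect_error(smooth_trace(tr, 0.01), "at least 2 samples")
  expect_length(smooth_trace(tr, 0.45)$v, n)   # length preserved
})

test_that("baseline correction removes drift and build-up", {
  p <- quiet_preset(period = 1)
  base <- generate_breathing_trace(p, 20, 50)
  corr0 <- correct_baseline(base, 4)
  expect_lt(abs(mean(corr0$v[101:900])), 0.02)

  # constant trace -> ~0 everywhere
  flat <- breathing_trace(base$t, rep(3, length(base$t)), 50)
  expect_equal(correct_baseline(flat, 4)$v, rep(0, length(base$t)))

  # added linear drift: corrected output matches the drift-free correction
  drift <- breathing_trace(base$t, base$v + 0.3 * base$t, 50)
  corr1 <- correct_baseline(drift, 4)
  interior <- 101:900
  rms <- sqrt(mean((corr1$v[interior] - corr0$v[interior])^2))
  expect_lt(rms / sd(corr0$v[interior]), 0.02)

  # slow exponential build-up: peak heights become uniform within 5 %
  build <- breathing_trace(base$t, base$v + 0.8 * (1 - exp(-base$t / 8)), 50)
  corr2 <- correct_baseline(build, 3)
  ev <- detect_events(smooth_trace(corr2, 0.08), expected_period = 1)
  heights <- corr2$v[ev$peak_idx]
  heights <- heights[ev$peak_idx > 100 & ev$peak_idx < 900]
  expect_lt(diff(range(heights)) / mean(heights), 0.05)
})

test_that("event detection finds every breath and no spurious peaks", {
  p <- quiet_preset(period = 1)
  tr <- generate_breathing_trace(p, 10, 100)
  ev <- detect_events(smooth_trace(tr, 0.05), expected_period = 1)
  expect_length(ev$peaks, 10)
  expect_true(all(diff(ev$peak_idx) > 0))

  flat <- breathing_trace(tr$t, rep(1, length(tr$t)), 100)
  expect_warning(ev0 <- detect_events(flat), "no peaks|flat")
  expect_length(ev0$peaks, 0)

  # Monte-Carlo: 5 % amplitude noise, peaks within +-1 frame, in >=95/100 seeds
  hits <- 0
  for (s in 1:100) {
    pn <- breathing_preset("CN", period = 1, noise_sd = 0.05, cardiac_amp = 0,
                           drift_amp = 0, seed = s)
    trn <- generate_breathing_trace(pn, 10, 100)
    evn <- detect_events(smooth_trace(trn, 0.05), expected_period = 1)
    ok <- length(evn$peaks) == length(trn$truth$peaks) &&
      all(abs(evn$peaks - trn$truth$peaks) <= 0.01 + 1e-9)
    hits <- hits + ok
  }
  expect_gte(hits, 95)
})

test_that("event overlay re-times peaks to zero and flags boundary events", {
  p <- quiet_preset(period = 1)
  tr <- generate_breathing_trace(p, 10, 100)
  sm <- smooth_trace(tr, 0.05)
  ev <- detect_events(sm, expected_period = 1)
  events <- overlay_events(sm, ev)
  expect_length(events, length(ev$peaks))
  expect_equal(sum(vapply(events, `[[`, logical(1), "complete")),
               sum(ev$complete))
  for (e in events) {
    if (!e$complete) next
    expect_equal(e$t_rel[which.max(e$v)], 0)
  }
  # noise-free periodic trace: overlaid waveforms identical
  comp <- Filter(function(e) e$complete, events)
  ref <- comp[[1]]
  for (e in comp[-1]) {
    m <- min(length(ref$v), length(e$v))
    expect_lt(sqrt(mean((ref$v[seq_len(m)] - e$v[seq_len(m)])^2)), 1e-9)
  }
})

test_that("per-event AUC matches geometry and generator ground truth", {
  tri <- structure(list(t_rel = seq(-0.5, 0.5, by = 0.01),
                        v = 2 * (1 - abs(seq(-0.5, 0.5, by = 0.01)) / 0.5),
                        complete = TRUE, frame_rate = 100),
                   class = "breathing_event")
  expect_equal(compute_auc(tri), 1, tolerance = 1e-12)

  rect <- structure(list(t_rel = seq(0, 0.5, by = 0.01),
                         v = rep(1, 51), complete = TRUE, frame_rate = 100),
                    class = "breathing_event")
  expect_equal(compute_auc(rect), 0.5)

  bad <- tri; bad$complete <- FALSE
  expect_error(compute_auc(bad), "fully recorded")

  # generator events at 100 fps match the oversampled ground truth within 1 %
  p <- quiet_preset(period = 1)
  tr <- generate_breathing_trace(p, 10, 100)
  ev <- detect_events(smooth_trace(tr, 0.05), expected_period = 1)
  events <- overlay_events(tr, ev)
  comp <- which(ev$complete)
  aucs <- vapply(events[comp], compute_auc, numeric(1))
  expect_equal(aucs, tr$truth$auc[comp], tolerance = 0.01)
})

test_that("breathing frequency is the reciprocal mean interval", {
  f <- breathing_frequency(0:9)
  expect_equal(f$frequency, 1)
  expect_equal(f$mean_interval, 1000)
  f2 <- breathing_frequency(c(0, 1.4, 2.8))
  expect_equal(f2$frequency, 1 / 1.4)
  expect_equal(f2$mean_interval, 1400)
  set.seed(2)
  jit <- cumsum(runif(8, 0.8, 1.6))
  fj <- breathing_frequency(jit)
  expect_equal(fj$frequency * fj$mean_interval, 1000)
  expect_error(breathing_frequency(1), "2 peaks")
})

test_that("pipeline invariances: time shift and amplitude scaling", {
  p <- quiet_preset(period = 1)
  tr <- generate_breathing_trace(p, 12, 100)
  cfg <- functional_config(mode = "reference", expected_period = 1,
                           smooth_window = 0.05)
  s0 <- summarize_function(tr, cfg)

  # shift by k frames: peak times shift by exactly k frames, parameters fixed
  k <- 37
  shifted <- breathing_trace(tr$t, c(rep(0, k), tr$v[seq_len(length(tr$v) - k)]),
                             100)
  s1 <- summarize_function(shifted, cfg)
  # every detected peak of the shifted trace sits exactly k frames after
  # a peak of the original
  back <- s1$detail$detection$peaks - k / 100
  offs <- vapply(back, function(b) min(abs(b - s0$detail$detection$peaks)),
                 numeric(1))
  expect_true(all(offs < 1e-9))
  expect_equal(s1$fall_const, s0$fall_const, tolerance = 0.02 * abs(s0$fall_const))

  # amplitude scaling: AUC and linear double-Gaussian coefficients scale,
  # frequency, onset and the Gaussian rates are unchanged
  sc <- 3
  scaled <- breathing_trace(tr$t, sc * tr$v, 100)
  s2 <- summarize_function(scaled, cfg)
  expect_equal(s2$auc, sc * s0$auc, tolerance = 1e-6)
  expect_equal(s2$frequency, s0$frequency)
  dg0 <- s0$detail$double_gaussian; dg2 <- s2$detail$double_gaussian
  expect_equal(dg2$c1, dg0$c1, tolerance = 1e-3)
  expect_equal(dg2$c3, dg0$c3, tolerance = 1e-3)
  expect_equal(dg2$c2, sc * dg0$c2, tolerance = 1e-3)
  expect_equal(dg2$c4, sc * dg0$c4, tolerance = 1e-3)
  expect_equal(dg2$c0, sc * dg0$c0, tolerance = 1e-3 * max(1, abs(dg0$c0)))
  expect_equal(s2$dampening_onset, s0$dampening_onset, tolerance = 1e-6)
})

test_that("summarize_function composes the stages and reports provenance", {
  p <- breathing_preset("CN", seed = 9)
  tr <- generate_breathing_trace(p, 30, 40)
  s <- summarize_function(tr, functional_config(mode = "reference",
                                                expected_period = p$period,
                                                smooth_window = 0.07))
  expect_true(all(is.finite(c(s$frequency, s$auc, s$raise_const,
                              s$fall_const))))
  expect_gte(s$n_events, 30 / 1.4 - 2)
  expect_equal(s$frequency * s$mean_interval, 1000)
  expect_identical(s$detail$mode, "reference")
  # deterministic given the seed
  s2 <- summarize_function(generate_breathing_trace(breathing_preset("CN", seed = 9), 30, 40),
                           functional_config(mode = "reference",
                                             expected_period = p$period,
                                             smooth_window = 0.07))
  expect_identical(s$auc, s2$auc)
  # errors carry the failing stage
  flat <- breathing_trace(tr$t, rep(0, length(tr$t)), 40)
  expect_error(suppressWarnings(summarize_function(flat)), "\\[detect\\]")
})
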