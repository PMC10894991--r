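test_that("breathing trace generator: peak count, determinism, AUC ground truth", {
  p <- quiet_preset(period = 1, rise_time = 0.15)
  tr <- generate_breathing_trace(p, 10, 100)
  expect_length(tr$truth$peaks, 10)
  expect_equal(tr$truth$peaks, 0:9 + 0.15)

  # identical seed, identical trace; different seed, same ground truth
  pn <- breathing_preset("CN", seed = 11)
  t1 <- generate_breathing_trace(pn, 10, 100)
  t2 <- generate_breathing_trace(pn, 10, 100)
  expect_identical(t1$v, t2$v)
  t3 <- generate_breathing_trace(breathing_preset("CN", seed = 12), 10, 100)
  expect_false(identical(t1$v, t3$v))
  expect_identical(t1$truth$peaks, t3$truth$peaks)
  expect_identical(t1$truth$auc, t3$truth$auc)

  # per-event ground-truth AUC against an independent trapezoid oracle at
  # the generator's own oversampled grid
  for (k in 1:3) {
    s0 <- (k - 1) * p$period
    tt <- seq(s0, s0 + p$period, by = 1 / 1000)
    expect_equal(tr$truth$auc[k],
                 oracle_trapz(tt, pmax(breathing_waveform(tt, p), 0)),
                 tolerance = 1e-9)
  }

  expect_error(generate_breathing_trace(p, 0.5, 100), "duration")
  expect_error(generate_breathing_trace(p, 10, 5), "frame_rate")
})

test_that("expiration waveform is C1 at the dampening onset and SAA enlarges the AUC", {
  for (g in c("CN", "SAA")) {
    p <- quiet_preset(g)
    te <- p$rise_time + p$onset
    eps <- 1e-7
    v <- breathing_waveform(te + c(-eps, 0, eps), p)
    expect_lt(abs(v[3] - v[1]), 1e-5)                     # value continuity
    d_left <- (v[2] - breathing_waveform(te - 1e-4, p)) / 1e-4
    d_right <- (breathing_waveform(te + 1e-4, p) - v[2]) / 1e-4
    expect_equal(d_left, d_right, tolerance = 1e-2 * max(1, abs(d_left)))
  }
  cn <- generate_breathing_trace(quiet_preset("CN"), 10, 100)
  saa <- generate_breathing_trace(quiet_preset("SAA"), 10, 100)
  expect_true(all(saa$truth$auc > cn$truth$auc))
})

test_that("two-region image matches its stated moments and closed-form CNR", {
  img <- generate_two_region_image(10, 6, 0, 0, shape = c(5, 5))
  expect_true(all(img[, 1:5] == 10) && all(img[, 6:10] == 6))

  img <- generate_two_region_image(10, 6, 2, 2, shape = c(200, 200), seed = 3)
  expect_identical(img, generate_two_region_image(10, 6, 2, 2,
                                                  shape = c(200, 200), seed = 3))
  cnr <- compute_cnr(img, attr(img, "roi1"), attr(img, "roi2"))
  expect_equal(cnr, 2, tolerance = 0.05)
})

test_that("edge phantom is a step at sigma 0 and contrast-sign symmetric", {
  step <- generate_edge_phantom(0, 31.2, shape = c(4, 20))
  expect_setequal(unique(as.numeric(step)), c(0, 1))
  up <- generate_edge_phantom(2, 31.2, shape = c(4, 40), low = 0, high = 1)
  dn <- generate_edge_phantom(2, 31.2, shape = c(4, 40), low = 1, high = 0)
  expect_equal(edge_fwhm(up, 2, 31.2), edge_fwhm(dn, 2, 31.2))
  expect_error(generate_edge_phantom(-1, 31.2), "sigma")
})

test_that("photon wavelength is derived from energy", {
  expect_equal(xray_wavelength(22), 5.636e-11, tolerance = 1e-3)
  g <- default_geom()
  expect_equal(g$wavelength, xray_wavelength(22))
})

test_that("phase-contrast projections: contact limit, unitarity, fringes, truncation", {
  geom <- default_geom(frame_rate = 40, fov = 63.9)
  prot <- scan_protocol(arc = 9, speed = 18)    # 20 angles, cheap
  ph <- thorax_phantom(nx = 96, seed = 2)

  # distance 0: pure attenuation exp(-2k integral beta)
  g0 <- acquisition_geometry(22, 1e-12, 31.2, 63.9, 40, 2.8)
  g0$distance <- 0
  ps0 <- generate_pbi_projections(ph, g0, prot, poisson_noise = FALSE)
  k <- 2 * pi / g0$wavelength
  sb <- phantom_sinogram(ph, ps0$angles, 96, "beta") * 31.2e-6
  expect_equal(ps0$projections / 1e4, exp(-2 * k * sb), tolerance = 1e-10)

  # beta = 0: Fresnel propagation conserves total intensity to 0.1 %
  ph_phase <- ph
  ph_phase$shapes$dbeta <- 0
  ps <- generate_pbi_projections(ph_phase, geom, prot, poisson_noise = FALSE)
  totals <- rowSums(ps$projections) / (96 * 1e4)
  expect_true(all(abs(totals - 1) < 1e-3))

  # edge fringes: signed overshoot/undershoot pair at a homogeneous disk edge
  disk <- structure(list(nx = 256, shapes = data.frame(
    cx = 0, cy = 0, a = 50, b = 50, ddelta = 4e-7, dbeta = 4e-10)),
    class = "thorax_phantom")
  psd <- generate_pbi_projections(disk, default_geom(fov = 63.9), prot,
                                  poisson_noise = FALSE)
  prof <- psd$projections[1, ] / 1e4
  contact <- exp(-2 * k * phantom_sinogram(disk, 0, 256, "beta")[1, ] * 31.2e-6)
  edge <- 128 - 50           # left edge detector index (approx)
  win <- (edge - 6):(edge + 6)
  diffp <- prof[win] - contact[win]
  expect_gt(max(diffp), 3e-3)    # bright fringe outside the edge
  expect_lt(min(diffp), -3e-3)   # dark fringe inside: signed pair

  # phantom wider than the FOV warns about local tomography
  expect_warning(
    generate_pbi_projections(thorax_phantom(nx = 96, seed = 1),
                             default_geom(fov = 2), prot,
                             poisson_noise = FALSE),
    "local tomography")
})

test_that("spectral Fresnel propagation agrees with a direct convolution oracle", {
  lam <- xray_wavelength(22)
  dx <- 1e-5; n <- 512; z <- 2000   # regime where the quadrature converges
  xs <- (seq_len(n) - (n + 1) / 2) * dx
  r <- 60 * dx
  chord <- ifelse(abs(xs) < r, 2 * sqrt(pmax(r^2 - xs^2, 0)), 0)
  k <- 2 * pi / lam
  u <- exp(-k * 4e-10 * chord * 3e3 - 1i * k * 4e-7 * chord * 3e3)
  spectral <- fresnel_propagate(u, dx, lam, z)
  idx <- seq(n / 2 - 60, n / 2 + 60)
  direct <- oracle_fresnel_direct(u, dx, lam, z, idx)
  expect_lt(max(abs(direct - spectral[idx])) / max(abs(spectral[idx])), 1e-3)
  # distance 0 is the identity
  expect_identical(fresnel_propagate(u, dx, lam, 0), u)

  # closed-form check at the real geometry: a Gaussian amplitude propagates
  # to another Gaussian with complex width a = 2 pi^2 sigma^2 + i pi lambda z
  dx2 <- 2e-6; n2 <- 4096; z2 <- 1.5; sig <- 30e-6
  xs <- (seq_len(n2) - (n2 + 1) / 2) * dx2
  u0 <- exp(-xs^2 / (2 * sig^2))
  up <- fresnel_propagate(u0, dx2, lam, z2)
  a <- 2 * pi^2 * sig^2 + 1i * pi * lam * z2
  ana <- sig * sqrt(2 * pi) * sqrt(pi / a) * exp(-pi^2 * xs^2 / a)
  expect_lt(max(abs(up - ana)) / max(abs(ana)), 1e-10)
})

test_that("thorax phantom: calibrated aeration, material sanity, consolidation", {
  ph <- thorax_phantom(nx = 140, seed = 5)
  expect_equal(ph$aerated_fraction_truth, 0.30, tolerance = 0.01)
  # truth is recomputable by voxel counting
  expect_equal(ph$aerated_fraction_truth,
               sum(ph$air_mask) / sum(ph$lung_mask))
  expect_true(all(ph$shapes$a > 0))
  with(ph$materials, {
    expect_true(delta_tissue / beta_tissue >= 100 &&
                delta_tissue / beta_tissue <= 3000)
  })
  expect_error(thorax_phantom(nx = 140, delta_tissue = 1e-7,
                              beta_tissue = 1e-12), "delta/beta")

  saa <- thorax_phantom(nx = 140, n_consolidation = 3, seed = 5)
  expect_lt(saa$aerated_fraction_truth, ph$aerated_fraction_truth)
  # same seed reproduces the phantom exactly
  expect_identical(thorax_phantom(nx = 140, seed = 5)$delta_map, ph$delta_map)
})

test_that("radiograph sequences track the driving trace through extraction", {
  geom <- default_geom(frame_rate = 20, pixel_size = 31.2, fov = 63.9)
  p <- quiet_preset(amplitude = 0.08, period = 1)
  tr <- generate_breathing_trace(p, 5, 20)
  ph <- thorax_phantom(nx = 120, seed = 3)

  # constant trace, no noise: all frames identical
  flat_tr <- breathing_trace(tr$t, rep(0.04, length(tr$t)), 20)
  sq <- generate_radiograph_sequence(ph, flat_tr, geom, poisson_noise = FALSE)
  expect_equal(sq$frames[, , 1], sq$frames[, , dim(sq$frames)[3]])

  # noise-free: extracted trace correlates with the driving trace
  sq <- generate_radiograph_sequence(ph, tr, geom, poisson_noise = FALSE)
  rois <- attr(sq, "rois")
  ext <- extract_trace(sq, rois$lung, rois$reference)
  expect_gt(cor(ext$v, tr$v), 0.99)

  # seeded Poisson noise at 1e4 counts: peaks recovered within one frame
  sqn <- generate_radiograph_sequence(ph, tr, geom, flat_counts = 1e4,
                                      seed = 21)
  extn <- extract_trace(sqn, rois$lung, rois$reference)
  sm <- smooth_trace(extn, 0.1)
  ev <- detect_events(sm, expected_period = 1)
  expect_equal(length(ev$peaks), length(tr$truth$peaks))
  expect_true(all(abs(ev$peaks - tr$truth$peaks) <= 1 / 20 + 1e-9))

  # doubling the amplitude doubles the extracted excursion within 5 %
  p2 <- quiet_preset(amplitude = 0.16, period = 1)
  tr2 <- generate_breathing_trace(p2, 5, 20)
  ext2 <- extract_trace(generate_radiograph_sequence(ph, tr2, geom,
                                                     poisson_noise = FALSE),
                        rois$lung, rois$reference)
  exc1 <- diff(range(ext$v)); exc2 <- diff(range(ext2$v))
  expect_equal(exc2 / exc1, 2, tolerance = 0.05)

  expect_error(generate_radiograph_sequence(ph, tr, default_geom(frame_rate = 40)),
               "frame rates")
})
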