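test_that("CNR follows the pooled-SD definition with a literal variant", {
  # deterministic means/SDs via a constructed image
  v1 <- c(8, 12, 10, 10); v2 <- c(4, 8, 6, 6)   # mean 10/6, sd 2*sqrt(2/3)
  im <- cbind(matrix(v1, 2), matrix(v2, 2))
  sd12 <- sd(v1)
  got <- compute_cnr(im, roi_box(0, 0, 2, 2), roi_box(0, 2, 2, 4))
  expect_equal(got, 4 / sd12)
  lit <- compute_cnr(im, roi_box(0, 0, 2, 2), roi_box(0, 2, 2, 4),
                     convention = "literal")
  expect_equal(lit, 4 / sd12^2)

  # identical regions give 0; zero variance with distinct means flags Inf
  same <- matrix(5, 4, 8)
  expect_equal(compute_cnr(same, roi_box(0, 0, 4, 4), roi_box(0, 4, 4, 8)), 0)
  two <- cbind(matrix(1, 4, 4), matrix(2, 4, 4))
  expect_warning(ci <- compute_cnr(two, roi_box(0, 0, 4, 4), roi_box(0, 4, 4, 8)),
                 "zero variance")
  expect_identical(ci, Inf)

  # sampled two-region fixture within 5 % of closed form |10-6|/2 = 2
  big <- generate_two_region_image(10, 6, 2, 2, shape = c(200, 200), seed = 5)
  expect_equal(compute_cnr(big, attr(big, "roi1"), attr(big, "roi2")), 2,
               tolerance = 0.05)

  # affine remap invariance (standard convention)
  expect_equal(compute_cnr(3 * big - 7, attr(big, "roi1"), attr(big, "roi2")),
               compute_cnr(big, attr(big, "roi1"), attr(big, "roi2")),
               tolerance = 1e-12)
  expect_error(compute_cnr(big, attr(big, "roi1"), attr(big, "roi1")),
               "disjoint")
})

test_that("COV defaults to SD/mean with the printed mean/variance form behind a switch", {
  roi <- roi_box(0, 0, 10, 10)
  const <- matrix(7, 10, 10)
  expect_equal(as.numeric(compute_cov(const, roi)), 0)

  set.seed(12)
  im <- matrix(rnorm(100, 100, 1), 10, 10)
  expect_equal(as.numeric(compute_cov(im, roi)), sd(im) / mean(im))
  expect_equal(as.numeric(compute_cov(im, roi, convention = "literal")),
               mean(im) / var(as.numeric(im)))
  expect_identical(attr(compute_cov(im, roi), "convention"), "standard")

  zero <- matrix(c(-1, 1), 10, 10)
  expect_error(compute_cov(zero, roi), "zero-mean")

  # soft-tissue-scale fixture: mu = 1, sigma = 7e-4 recovered within 10 %
  set.seed(3)
  soft <- matrix(rnorm(300 * 300, 1, 7e-4), 300, 300)
  expect_equal(as.numeric(compute_cov(soft, roi_box(0, 0, 300, 300))), 7e-4,
               tolerance = 0.1)
})

test_that("edge FWHM measures the differentiated profile with sub-pixel width", {
  # ideal step: sampling-limited lower bound of 1 px
  step <- generate_edge_phantom(0, 31.2, shape = c(8, 64))
  expect_equal(edge_fwhm(step, 4, 31.2), 1 * 31.2, tolerance = 0.01)

  # Gaussian edge: 2 sqrt(2 ln 2) sigma px; the discrete line-spread
  # function carries the half-sample box broadening sigma^2 + 1/12
  for (sigma in c(2, 3, 5)) {
    g <- generate_edge_phantom(sigma, 31.2, shape = c(8, 40 * sigma))
    expect_equal(edge_fwhm(g, 4, 31.2),
                 2 * sqrt(2 * log(2)) * sqrt(sigma^2 + 1 / 12) * 31.2,
                 tolerance = 0.01)
  }
  g3 <- generate_edge_phantom(3, 31.2, shape = c(8, 128))
  expect_equal(edge_fwhm(g3, 4, 31.2), 2.3548 * 3 * 31.2, tolerance = 0.02)

  # polarity and affine invariance
  g <- generate_edge_phantom(3, 25, shape = c(8, 128))
  expect_equal(edge_fwhm(1 - g, 4, 25), edge_fwhm(g, 4, 25))
  expect_equal(edge_fwhm(5 * g + 2, 4, 25), edge_fwhm(g, 4, 25),
               tolerance = 1e-12)

  expect_error(edge_fwhm(matrix(1, 8, 64), 4, 25), "no unique")
  expect_error(edge_fwhm(profile = c(1, 2)), "too short")
})

test_that("midpoint threshold is the air/tissue mean and rejects equal inputs", {
  expect_equal(midpoint_threshold(0, 1), 0.5)
  expect_equal(midpoint_threshold(-1, 3), 1)
  expect_equal(midpoint_threshold(3, -1), midpoint_threshold(-1, 3))
  expect_error(midpoint_threshold(2, 2), "equal")
})

test_that("aerated fraction counts sub-threshold voxels per ROI and averages", {
  img <- matrix(1, 20, 20)          # tissue value 1
  img[1:10, 1:10] <- 0              # air block
  roi_half <- roi_box(5, 0, 15, 10) # half air, half tissue
  roi_tissue <- roi_box(10, 10, 20, 20)
  rep6 <- list(roi_half, roi_tissue,
               roi_box(0, 0, 5, 5), roi_box(0, 5, 5, 10),
               roi_box(5, 10, 10, 15), roi_box(15, 0, 20, 5))
  af <- aerated_fraction(img, rep6, 0.5)
  expect_equal(af$per_roi[1], 0.5)
  expect_equal(af$per_roi[2], 0)
  expect_equal(af$mean_fraction, mean(af$per_roi))
  expect_equal(af$n_rois, 6)

  expect_error(aerated_fraction(img, list(roi_half, roi_half), 0.5), "overlap")

  # monotone non-decreasing in the threshold
  set.seed(6)
  noisy <- matrix(runif(400), 20, 20)
  ths <- seq(0.1, 0.9, by = 0.1)
  fr <- vapply(ths, function(th) {
    aerated_fraction(noisy, list(roi_box(0, 0, 20, 20)), th)$mean_fraction
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))

  # invariance under joint affine remap of image and threshold
  af2 <- aerated_fraction(2 * img + 1, rep6, 2 * 0.5 + 1)
  expect_equal(af2$per_roi, af$per_roi)

  # inverted-contrast convention
  af3 <- aerated_fraction(-img, rep6, -0.5, air_below = FALSE)
  expect_equal(af3$per_roi, af$per_roi)
})

test_that("consolidated (SAA) phantoms have lower aerated fraction than controls", {
  rate <- function(n_cons, seed) {
    ph <- thorax_phantom(nx = 140, n_consolidation = n_cons, seed = seed)
    rois <- phantom_lung_rois(ph)
    aerated_fraction(ph$air_mask * 1, rois, 0.5, air_below = FALSE)$mean_fraction
  }
  for (seed in 1:5) {
    expect_lt(rate(3, seed), rate(0, seed))
  }
})

test_that("ROI suggestion stays inside the mask and never overlaps", {
  ph <- thorax_phantom(nx = 120, seed = 4)
  rois <- suggest_lung_rois(ph$lung_mask, n = 6, size = 10)
  expect_lte(length(rois), 6)
  for (i in seq_along(rois)) {
    px <- roi_pixels(ph$lung_mask * 1, rois[[i]])
    expect_gte(mean(px), 0.9)
    for (j in seq_len(i - 1)) {
      expect_false(lungpbi:::rois_overlap(rois[[i]], rois[[j]]))
    }
  }
})

test_that("iq_report bundles CNR, COV and FWHM for a slice", {
  set.seed(9)
  top <- cbind(matrix(rnorm(40 * 50, 10, 1), 40, 50),
               matrix(rnorm(40 * 50, 6, 1), 40, 50))
  # rows 41-80: a single blurred edge, so the profile row crosses one edge
  edge <- generate_edge_phantom(2, 31.2, shape = c(40, 100), low = 6, high = 10)
  im <- rbind(top, edge)
  rep <- iq_report(im, list(roi_box(0, 0, 40, 50), roi_box(0, 50, 40, 100)),
                   cov_roi = roi_box(0, 0, 40, 50), edge_row = 60,
                   pixel_size = 31.2)
  expect_equal(rep$cnr, 4, tolerance = 0.1)
  expect_equal(rep$cov, 0.1, tolerance = 0.1)
  expect_equal(rep$fwhm_um, 2.3548 * 2 * 31.2, tolerance = 0.05)
})
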