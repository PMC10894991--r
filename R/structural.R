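#' Contrast-to-noise ratio between two regions
#'
#' Default convention `|g1 - g2| / sqrt(0.5 (sd1^2 + sd2^2))` with sample
#' means and standard deviations. A variance-denominator variant
#' (`|g1 - g2| / (0.5 (sd1^2 + sd2^2))`, no square root) is available via
#' `convention = "literal"`; it is not dimensionless and is provided only
#' for comparability with reports that use it.
#'
#' @param image Numeric matrix.
#' @param roi1,roi2 Disjoint [roi_box()]es.
#' @param convention `"standard"` (default) or `"literal"`.
#' @return CNR value; 0 for identical constant regions, `Inf` (with a
#'   warning) if both SDs are 0 but the means differ.
#' @export
compute_cnr <- function(image, roi1, roi2,
                        convention = c("standard", "literal")) {
  convention <- match.arg(convention)
  if (rois_overlap(roi1, roi2)) stop("compute_cnr: ROIs must be disjoint")
  p1 <- roi_pixels(image, roi1); p2 <- roi_pixels(image, roi2)
  g1 <- mean(p1); g2 <- mean(p2)
  s1 <- stats::sd(p1); s2 <- stats::sd(p2)
  pooled <- 0.5 * (s1^2 + s2^2)
  if (pooled == 0) {
    if (g1 == g2) return(0)
    warning("compute_cnr: zero variance in both regions with unequal means")
    return(Inf)
  }
  num <- abs(g1 - g2)
  if (convention == "standard") num / sqrt(pooled) else num / pooled
}

#' Coefficient of variation in a region
#'
#' Default convention: sample SD divided by the mean (the dimensionless
#' coefficient of variation). `convention = "literal"` returns
#' mean / variance instead, for comparability with reports using that
#' ratio. The convention used is attached as an attribute.
#'
#' @param image Numeric matrix.
#' @param roi A [roi_box()] over a homogeneous (soft-tissue) region.
#' @param convention `"standard"` (SD/mean, default) or `"literal"`
#'   (mean/variance).
#' @return COV value with attribute `convention`; zero-mean regions are
#'   rejected.
#' @export
compute_cov <- function(image, roi, convention = c("standard", "literal")) {
  convention <- match.arg(convention)
  p <- roi_pixels(image, roi)
  g <- mean(p)
  if (g == 0) stop("compute_cov: zero-mean region, ratio undefined")
  v <- if (convention == "standard") stats::sd(p) / g else g / stats::var(as.numeric(p))
  structure(v, convention = convention)
}

#' Edge sharpness as the FWHM of the differentiated edge profile
#'
#' Extracts a profile across a single monotone edge, differentiates it
#' (first differences, the discrete line-spread function), takes the
#' absolute value, and measures the full width at half maximum of the
#' resulting peak with sub-pixel linear interpolation. A Gaussian-blurred
#' edge of width sigma gives `2 sqrt(2 ln 2) sigma` pixels; an ideal step
#' gives the 1-px sampling-limited bound.
#'
#' @param image Numeric matrix, or NULL if `profile` is given directly.
#' @param profile_row Row index (1-based) along which to read the
#'   horizontal profile; alternatively pass `profile`.
#' @param pixel_size Pixel size in micrometres.
#' @param profile Optional numeric vector: the edge profile itself.
#' @return FWHM in micrometres. Profiles without a unique interior peak in
#'   the derivative are rejected.
#' @export
edge_fwhm <- function(image = NULL, profile_row = NULL, pixel_size = 1,
                      profile = NULL) {
  if (is.null(profile)) {
    if (is.null(image)) stop("edge_fwhm: supply an image or a profile")
    if (is.null(profile_row)) profile_row <- nrow(image) %/% 2L
    profile <- image[profile_row, ]
  }
  n <- length(profile)
  if (n < 5) stop("edge_fwhm: profile too short")
  d <- abs(diff(profile))   # line-spread function at half-sample positions
  pk <- which.max(d)
  if (pk == 1L || pk == length(d) || d[pk] == 0) {
    stop("edge_fwhm: no unique interior peak in the differentiated profile")
  }
  half <- d[pk] / 2
  left <- pk
  while (left > 1 && d[left] > half) left <- left - 1L
  if (d[left] > half) stop("edge_fwhm: peak not resolved on the left")
  xl <- left + (half - d[left]) / (d[left + 1L] - d[left])
  right <- pk
  while (right < length(d) && d[right] > half) right <- right + 1L
  if (d[right] > half) stop("edge_fwhm: peak not resolved on the right")
  xr <- right - (half - d[right]) / (d[right - 1L] - d[right])
  (xr - xl) * pixel_size
}

#' Midpoint threshold between air and soft tissue
#'
#' `(air_value + tissue_value) / 2`, where the two reference values are ROI
#' means over a designated pure-air and pure-tissue region, computed once
#' per study and held constant across ROIs and samples.
#'
#' @param air_value,tissue_value Reference gray values (must differ).
#' @return The threshold.
#' @export
midpoint_threshold <- function(air_value, tissue_value) {
  if (air_value == tissue_value) {
    stop("midpoint_threshold: air and tissue values are equal")
  }
  (air_value + tissue_value) / 2
}

#' Aerated-lung fraction over a set of ROIs
#'
#' Per ROI, the fraction of voxels on the air side of a fixed threshold
#' (below it, in the phase-retrieved attenuation convention where air is
#' darker; set `air_below = FALSE` for inverted-contrast data); the
#' per-ROI fractions are averaged.
#'
#' @param volume Reconstructed slice (matrix) or stack (3-D array; ROIs are
#'   applied to every slice).
#' @param rois List of pairwise-disjoint [roi_box()]es (default count six).
#' @param threshold Gray-value threshold from [midpoint_threshold()].
#' @param air_below Logical: air side is below the threshold (default).
#' @return An object of class `aerated_fraction_report`: `per_roi`,
#'   `mean_fraction`, `threshold`, `n_rois`.
#' @export
aerated_fraction <- function(volume, rois, threshold, air_below = TRUE) {
  if (is.matrix(volume)) volume <- array(volume, dim = c(dim(volume), 1L))
  n <- length(rois)
  for (i in seq_len(n)) {
    check_roi_bounds(rois[[i]], dim(volume))
    for (j in seq_len(i - 1L)) {
      if (rois_overlap(rois[[i]], rois[[j]])) {
        stop(sprintf("aerated_fraction: ROIs %d and %d overlap", j, i))
      }
    }
  }
  per_roi <- vapply(rois, function(r) {
    px <- unlist(lapply(seq_len(dim(volume)[3]),
                        function(s) roi_pixels(volume[, , s], r)))
    if (air_below) mean(px < threshold) else mean(px > threshold)
  }, numeric(1))
  structure(list(per_roi = per_roi, mean_fraction = mean(per_roi),
                 threshold = threshold, n_rois = n),
            class = "aerated_fraction_report")
}

#' @export
print.aerated_fraction_report <- function(x, ...) {
  cat(sprintf("aerated fraction: mean %.3f over %d ROIs (threshold %.4g)\n",
              x$mean_fraction, x$n_rois, x$threshold))
  invisible(x)
}

#' Suggest non-overlapping ROIs inside a lung mask
#'
#' Helper for reproducible ROI placement: tiles the bounding box of a lung
#' mask and returns the `n` boxes of the requested size with the highest
#' in-mask coverage. Placement is a suggestion only; review before use.
#'
#' @param mask Logical matrix (TRUE inside the lung).
#' @param n Number of ROIs (default 6).
#' @param size ROI side length in pixels.
#' @param min_coverage Minimum fraction of ROI pixels inside the mask.
#' @return A list of [roi_box()]es (possibly fewer than `n`, with a
#'   warning).
#' @export
suggest_lung_rois <- function(mask, n = 6L, size = 12L, min_coverage = 0.9) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("suggest_lung_rois: empty mask")
  r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
  c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
  cand <- list(); cov <- numeric(0)
  for (r in seq(r0, max(r0, r1 - size + 1L), by = size)) {
    for (cc in seq(c0, max(c0, c1 - size + 1L), by = size)) {
      if (r + size - 1L > nrow(mask) || cc + size - 1L > ncol(mask)) next
      frac <- mean(mask[r:(r + size - 1L), cc:(cc + size - 1L)])
      if (frac >= min_coverage) {
        cand[[length(cand) + 1L]] <- roi_box(r - 1L, cc - 1L,
                                             r + size - 1L, cc + size - 1L)
        cov <- c(cov, frac)
      }
    }
  }
  if (length(cand) < n) {
    warning(sprintf("suggest_lung_rois: only %d candidate ROIs found", length(cand)))
  }
  cand[order(cov, decreasing = TRUE)][seq_len(min(n, length(cand)))]
}

#' Image-quality report for a reconstructed slice
#'
#' @param image Reconstructed slice.
#' @param cnr_rois List of two [roi_box()]es (contrasting materials).
#' @param cov_roi [roi_box()] over homogeneous soft tissue.
#' @param edge_row Row for the edge profile (1-based), crossing one edge.
#' @param pixel_size Pixel size in micrometres.
#' @return An object of class `iq_report`: `cnr`, `cov`, `fwhm_um`.
#' @export
iq_report <- function(image, cnr_rois, cov_roi, edge_row, pixel_size) {
  structure(list(
    cnr = compute_cnr(image, cnr_rois[[1]], cnr_rois[[2]]),
    cov = as.numeric(compute_cov(image, cov_roi)),
    fwhm_um = edge_fwhm(image, edge_row, pixel_size),
    rois_used = list(cnr = cnr_rois, cov = cov_roi, edge_row = edge_row)),
    class = "iq_report")
}

#' @export
print.iq_report <- function(x, ...) {
  cat(sprintf("image quality: CNR %.3g, COV %.3g, edge FWHM %.3g um\n",
              x$cnr, x$cov, x$fwhm_um))
  invisible(x)
}
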