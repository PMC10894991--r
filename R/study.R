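#' Draw per-animal breathing parameters for a simulated study
#'
#' Animals within a group share the group preset up to log-normal
#' biological variation: amplitude, breath period and decay rates (one
#' common compliance factor for both rates) vary with ~3 % CV, the
#' dampening onset with ~5 % CV.
#'
#' @param group `"CN"` or `"SAA"`.
#' @param seed Animal-level RNG seed (also seeds the trace noise).
#' @return A [breathing_model_params()].
#' @export
draw_animal_params <- function(group, seed) {
  base <- breathing_preset(group)
  with_seed(seed, {
    rate_f <- exp(stats::rnorm(1, 0, 0.03))
    breathing_preset(
      group,
      amplitude = base$amplitude * exp(stats::rnorm(1, 0, 0.03)),
      period = base$period * exp(stats::rnorm(1, 0, 0.03)),
      recoil_rate = base$recoil_rate * rate_f,
      damped_rate = base$damped_rate * rate_f,
      onset = base$onset * exp(stats::rnorm(1, 0, 0.05)),
      seed = seed)
  })
}

#' Simulate the planar (functional) arm of a two-group study
#'
#' Generates one breathing trace per animal (30 s at 40 fps by default,
#' reference-normalized mode) and runs the full functional pipeline,
#' returning the per-animal summary table ready for [compare_groups()].
#'
#' @param n_cn,n_saa Animals per group.
#' @param duration Trace duration in s.
#' @param frame_rate Sampling rate in fps.
#' @param seed Study-level seed; animal seeds are derived from it.
#' @param fit Fit branch passed to [functional_config()].
#' @return A data.frame from [summary_table()] with a `group` column.
#' @export
simulate_functional_study <- function(n_cn = 4, n_saa = 3, duration = 30,
                                      frame_rate = 40, seed = 1L,
                                      fit = "hyperbolic") {
  groups <- rep(c("CN", "SAA"), c(n_cn, n_saa))
  base <- as.integer(seed %% 2000000L)     # keep derived seeds below 2^31
  summaries <- lapply(seq_along(groups), function(i) {
    p <- draw_animal_params(groups[i], base * 1000L + i)
    tr <- generate_breathing_trace(p, duration, frame_rate)
    # smoothing must stay shorter than the inspiration rise (~0.15 s) or the
    # end-inspiration peak is flattened and its position becomes unstable
    summarize_function(tr, functional_config(mode = "reference", fit = fit,
                                             expected_period = p$period,
                                             smooth_window = 0.05 * p$period))
  })
  names(summaries) <- sprintf("%s_%d", groups, seq_along(groups))
  summary_table(summaries, group = groups)
}

#' Simulate the CT (structural) arm of a two-group study
#'
#' One thorax phantom per animal (consolidation blobs in the SAA group),
#' taken through the full structural pipeline: phase-contrast projections
#' over 180 degrees, flat-field normalization, TIE-HOM retrieval, 150 %
#' zero padding, every-2nd-projection subsampling, FBP, and six-ROI
#' midpoint-threshold aeration. The air/tissue threshold is measured once,
#' on the first control animal, and held constant for all ROIs and
#' samples.
#'
#' @param n_cn,n_saa Animals per group.
#' @param nx Phantom/reconstruction grid side in pixels.
#' @param pixel_size Pixel size in micrometres.
#' @param frame_rate Acquisition frame rate (with 18 deg/s rotation this
#'   sets the number of projections over 180 degrees).
#' @param n_consolidation Consolidation blobs per SAA animal.
#' @param flat_counts Flat-field photon count per detector pixel.
#' @param seed Study-level seed.
#' @return A data.frame: animal, group, aerated fraction measured by the
#'   pipeline, voxel-counted truth over the same ROIs, and the phantom's
#'   whole-mask truth.
#' @export
simulate_structural_study <- function(n_cn = 7, n_saa = 6, nx = 140,
                                      pixel_size = 31.2, frame_rate = 28,
                                      n_consolidation = 3,
                                      flat_counts = 1e4, seed = 1L) {
  groups <- rep(c("CN", "SAA"), c(n_cn, n_saa))
  geom <- acquisition_geometry(22, 1.5, pixel_size, nx * pixel_size / 1000,
                               frame_rate, 2.8)
  prot <- scan_protocol(arc = 180, speed = 18, subsample_step = 2L,
                        subset_arc = 180)
  threshold <- NULL
  base <- as.integer(seed %% 2000000L)     # keep derived seeds below 2^31
  rows <- lapply(seq_along(groups), function(i) {
    s <- base * 1000L + i
    ph <- thorax_phantom(nx = nx, pixel_size = pixel_size,
                         n_consolidation = if (groups[i] == "SAA") n_consolidation else 0L,
                         seed = s)
    ps <- generate_pbi_projections(ph, geom, prot, flat_counts = flat_counts,
                                   seed = s + 500L)
    rec <- reconstruct_ct(ps, delta_beta = 1000, pad_factor = 1.5,
                          subsample_step = 2L)
    if (is.null(threshold)) {
      refs <- reference_rois(nx)
      threshold <<- midpoint_threshold(mean(roi_pixels(rec, refs$air)),
                                       mean(roi_pixels(rec, refs$tissue)))
    }
    rois <- phantom_lung_rois(ph)
    meas <- aerated_fraction(rec, rois, threshold)
    truth <- aerated_fraction(ph$air_mask * 1.0, rois, 0.5, air_below = FALSE)
    data.frame(animal = sprintf("%s_%d", groups[i], i), group = groups[i],
               fraction = meas$mean_fraction,
               roi_truth = truth$mean_fraction,
               mask_truth = ph$aerated_fraction_truth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

# fixed air (off-body corner) and soft-tissue (below the lungs) reference
# regions for the study-wide midpoint threshold
reference_rois <- function(nx) {
  m <- max(4L, round(0.02 * nx))
  sz <- max(8L, round(0.08 * nx))
  list(air = roi_box(m, m, m + sz, m + sz),
       tissue = roi_box(round(nx / 2 + 0.30 * nx) - round(sz / 2),
                        round(nx / 2) - round(sz / 2),
                        round(nx / 2 + 0.30 * nx) + round(sz / 2),
                        round(nx / 2) + round(sz / 2)))
}
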