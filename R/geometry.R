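#' Acquisition geometry
#'
#' Bundles the beamline parameters that every downstream stage needs:
#' photon energy, propagation distance, detector pixel pitch, field of view,
#' frame rate and entrance dose rate. The x-ray wavelength is derived from
#' the energy and stored alongside.
#'
#' @param energy Photon energy in keV.
#' @param distance Sample-to-detector propagation distance in m.
#' @param pixel_size Detector pixel pitch in micrometres.
#' @param fov Field-of-view side length in mm.
#' @param frame_rate Frames per second.
#' @param dose_rate Entrance dose rate in mGy/s.
#' @return An object of class `acquisition_geometry`.
#' @examples
#' geom <- acquisition_geometry(energy = 22, distance = 1.5, pixel_size = 31.2,
#'                              fov = 63.9, frame_rate = 40, dose_rate = 2.8)
#' geom$wavelength  # ~5.64e-11 m
#' @export
acquisition_geometry <- function(energy, distance, pixel_size, fov,
                                 frame_rate, dose_rate) {
  args <- list(energy = energy, distance = distance, pixel_size = pixel_size,
               fov = fov, frame_rate = frame_rate, dose_rate = dose_rate)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("acquisition_geometry: field '%s' must be a single positive number", nm))
    }
  }
  g <- c(args, list(wavelength = xray_wavelength(energy)))
  structure(g, class = "acquisition_geometry")
}

#' X-ray wavelength from photon energy
#'
#' lambda = h*c / E with CODATA constants; E in keV, result in metres.
#'
#' @param energy_kev Photon energy in keV.
#' @return Wavelength in m.
#' @export
xray_wavelength <- function(energy_kev) {
  if (any(energy_kev <= 0)) stop("xray_wavelength: energy must be positive")
  h <- 6.62607015e-34   # J s
  c0 <- 299792458       # m / s
  e <- 1.602176634e-19  # J / eV
  h * c0 / (energy_kev * 1e3 * e)
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "acquisition geometry: %.3g keV (lambda %.3e m), z = %.3g m,\n",
    "  pixel %.3g um, FOV %.3g mm, %.4g fps, dose rate %.3g mGy/s\n"),
    x$energy, x$wavelength, x$distance, x$pixel_size, x$fov,
    x$frame_rate, x$dose_rate))
  invisible(x)
}

#' Tomographic scan protocol
#'
#' @param arc Total rotation in degrees.
#' @param speed Rotation speed in degrees/s.
#' @param subsample_step Keep every k-th projection (integer >= 1).
#' @param subset_arc Angular subset actually used for reconstruction, degrees.
#' @return An object of class `scan_protocol`.
#' @export
scan_protocol <- function(arc = 540, speed = 18, subsample_step = 1L,
                          subset_arc = arc) {
  if (speed <= 0) stop("scan_protocol: speed must be > 0")
  if (subset_arc <= 0 || arc < subset_arc) {
    stop("scan_protocol: need arc >= subset_arc > 0")
  }
  if (subsample_step < 1) stop("scan_protocol: subsample_step must be >= 1")
  structure(list(arc = arc, speed = speed,
                 subsample_step = as.integer(subsample_step),
                 subset_arc = subset_arc),
            class = "scan_protocol")
}

#' Radiograph time series
#'
#' A stack of 2-D intensity frames (counts) with uniform timing. Frames are
#' stored as a 3-D array indexed `[row, col, frame]`, 0-based timing
#' `t_i = (i - 1) / frame_rate`.
#'
#' @param frames 3-D numeric array `[row, col, frame]`, non-negative, or a
#'   list of equal-shaped matrices.
#' @param frame_rate Frames per second.
#' @param pixel_size Pixel pitch in micrometres.
#' @return An object of class `radiograph_sequence`.
#' @export
radiograph_sequence <- function(frames, frame_rate, pixel_size) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("radiograph_sequence: frames differ in shape")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3L) stop("radiograph_sequence: frames must be [row, col, frame]")
  if (frame_rate <= 0) stop("radiograph_sequence: frame_rate must be > 0")
  if (pixel_size <= 0) stop("radiograph_sequence: pixel_size must be > 0")
  if (any(frames < 0)) stop("radiograph_sequence: intensities must be >= 0")
  structure(list(frames = frames, frame_rate = frame_rate,
                 pixel_size = pixel_size),
            class = "radiograph_sequence")
}

#' @export
print.radiograph_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("radiograph sequence: %d frames of %d x %d px, %.4g fps (%.3g s), pixel %.3g um\n",
              d[3], d[1], d[2], x$frame_rate, d[3] / x$frame_rate, x$pixel_size))
  invisible(x)
}

n_frames <- function(seq) dim(seq$frames)[3]

#' Rectangular region of interest
#'
#' 0-based, half-open pixel bounds: rows `[row0, row1)`, columns
#' `[col0, col1)`. This convention is used everywhere in the package.
#'
#' @param row0,col0 Inclusive 0-based upper-left corner.
#' @param row1,col1 Exclusive lower-right corner.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(row0, col0, row1, col1) {
  b <- vapply(list(row0, col0, row1, col1), as.integer, integer(1))
  if (b[3] <= b[1] || b[4] <= b[2]) stop("roi_box: need row1 > row0 and col1 > col0")
  if (b[1] < 0 || b[2] < 0) stop("roi_box: bounds must be >= 0")
  structure(list(row0 = b[1], col0 = b[2], row1 = b[3], col1 = b[4]),
            class = "roi_box")
}

#' Extract the pixels of an ROI from a matrix
#'
#' @param image A numeric matrix.
#' @param roi An [roi_box()].
#' @return The sub-matrix covered by the ROI.
#' @export
roi_pixels <- function(image, roi) {
  check_roi_bounds(roi, dim(image))
  image[(roi$row0 + 1L):roi$row1, (roi$col0 + 1L):roi$col1, drop = FALSE]
}

check_roi_bounds <- function(roi, dims) {
  if (roi$row1 > dims[1] || roi$col1 > dims[2]) {
    stop(sprintf("ROI [%d,%d)x[%d,%d) exceeds frame bounds %d x %d",
                 roi$row0, roi$row1, roi$col0, roi$col1, dims[1], dims[2]))
  }
  invisible(TRUE)
}

rois_overlap <- function(a, b) {
  (a$row0 < b$row1 && b$row0 < a$row1) && (a$col0 < b$col1 && b$col0 < a$col1)
}

#' Cumulative entrance dose
#'
#' Dose accumulated at constant dose rate: `dose_rate * duration`.
#'
#' @param dose_rate Entrance dose rate in mGy/s (>= 0).
#' @param duration Exposure time in s (>= 0).
#' @return Dose in mGy.
#' @examples
#' cumulative_dose(2.8, 30)  # 84 mGy, a 30-s planar acquisition
#' @export
cumulative_dose <- function(dose_rate, duration) {
  if (any(dose_rate < 0)) stop("cumulative_dose: dose_rate must be >= 0")
  if (any(duration < 0)) stop("cumulative_dose: duration must be >= 0")
  dose_rate * duration
}

#' Scan duration from arc and rotation speed
#'
#' @param arc Rotation arc in degrees (>= 0).
#' @param speed Rotation speed in degrees/s (> 0).
#' @return Duration in s.
#' @examples
#' scan_duration(540, 18)  # 30 s
#' @export
scan_duration <- function(arc, speed) {
  if (any(speed <= 0)) stop("scan_duration: speed must be > 0")
  if (any(arc < 0)) stop("scan_duration: arc must be >= 0")
  arc / speed
}

#' Temporal frame binning by summation
#'
#' Sums blocks of `n` consecutive frames to trade temporal resolution for
#' photon statistics (e.g. 1000 fps acquired, binned to 100 fps with
#' `n = 10`). A trailing partial block (frame count mod `n`) is dropped.
#'
#' @param seq A [radiograph_sequence()].
#' @param n Block length (integer >= 1, <= number of frames).
#' @return A [radiograph_sequence()] with `frame_rate / n` and summed frames.
#' @export
bin_frames <- function(seq, n) {
  stopifnot(inherits(seq, "radiograph_sequence"))
  n <- as.integer(n)
  nf <- n_frames(seq)
  if (n < 1L) stop("bin_frames: n must be >= 1")
  if (n > nf) stop("bin_frames: n exceeds frame count")
  if (n == 1L) return(seq)
  keep <- (nf %/% n) * n
  d <- dim(seq$frames)
  out <- array(0, dim = c(d[1], d[2], keep %/% n))
  for (b in seq_len(keep %/% n)) {
    idx <- ((b - 1L) * n + 1L):(b * n)
    out[, , b] <- rowSums(seq$frames[, , idx, drop = FALSE], dims = 2)
  }
  radiograph_sequence(out, seq$frame_rate / n, seq$pixel_size)
}

#' Reconstruction matrix side length
#'
#' Number of pixels spanning a field of view: `floor(1000 * fov / pixel_size)`
#' (fov in mm, pixel size in micrometres).
#'
#' @param fov Field of view in mm (> 0).
#' @param pixel_size Pixel size in micrometres (> 0).
#' @return Integer matrix side in pixels.
#' @examples
#' matrix_side(10, 25)      # 400
#' matrix_side(63.9, 31.2)  # 2048
#' @export
matrix_side <- function(fov, pixel_size) {
  if (any(fov <= 0) || any(pixel_size <= 0)) {
    stop("matrix_side: fov and pixel_size must be > 0")
  }
  as.integer(floor(1000 * fov / pixel_size))
}

#' Dose ledger for a scan protocol
#'
#' Accounts rate x time for the full acquisition, the angular subset used,
#' and the subsampled projection set (dose attribution scales by
#' 1/subsample_step). If a separately reported total dose is supplied and
#' disagrees with rate x time by more than 5 %, the entry is flagged rather
#' than reconciled.
#'
#' @param geom An [acquisition_geometry()] (supplies the dose rate).
#' @param protocol A [scan_protocol()].
#' @param reported_total Optional externally reported total dose in mGy.
#' @return A data.frame with one row per accounting stage, plus an attribute
#'   `flag` describing any inconsistency with `reported_total`.
#' @export
dose_ledger <- function(geom, protocol, reported_total = NULL) {
  t_full <- scan_duration(protocol$arc, protocol$speed)
  t_sub <- scan_duration(protocol$subset_arc, protocol$speed)
  full <- cumulative_dose(geom$dose_rate, t_full)
  subset <- cumulative_dose(geom$dose_rate, t_sub)
  used <- subset / protocol$subsample_step
  out <- data.frame(
    stage = c("full_acquisition", "angular_subset", "subsampled"),
    duration_s = c(t_full, t_sub, t_sub),
    dose_mGy = c(full, subset, used),
    stringsAsFactors = FALSE)
  flag <- NA_character_
  if (!is.null(reported_total) && abs(reported_total - full) > 0.05 * full) {
    flag <- sprintf(paste0(
      "reported total %.3g mGy inconsistent with rate x time = %.3g mGy ",
      "(%.3g mGy/s x %.3g s); ledger reports rate x time"),
      reported_total, full, geom$dose_rate, t_full)
    warning(flag)
  }
  attr(out, "flag") <- flag
  out
}
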