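#' Angle-tagged phase-contrast projection set
#'
#' Single-slice parallel-beam container: each row of `projections` is the
#' 1-D detector line for one angle (a sinogram of intensity counts), with
#' averaged-ready flat and dark reference lines and the acquisition
#' geometry.
#'
#' @param angles Projection angles in degrees, strictly increasing.
#' @param projections Matrix `[n_angles, n_det]` of intensity counts.
#' @param flat,dark Reference lines (length `n_det`).
#' @param geom An [acquisition_geometry()].
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(angles, projections, flat, dark, geom) {
  if (length(angles) != nrow(projections)) {
    stop("projection_set: one angle per projection required")
  }
  if (any(diff(angles) <= 0)) stop("projection_set: angles must be strictly increasing")
  if (length(flat) != ncol(projections) || length(dark) != ncol(projections)) {
    stop("projection_set: flat/dark length must match detector width")
  }
  if (any(flat <= dark)) stop("projection_set: flat must exceed dark pixelwise")
  structure(list(angles = angles, projections = projections,
                 flat = flat, dark = dark, geom = geom),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("projection set: %d angles over [%.4g, %.4g] deg, %d detector px\n",
              length(x$angles), min(x$angles), max(x$angles),
              ncol(x$projections)))
  invisible(x)
}

#' Fresnel free-space propagation of a 1-D complex wavefield
#'
#' Spectral (angular-spectrum) propagator with the paraxial transfer
#' function `H(f) = exp(-i pi lambda z f^2)`. The field is zero-padded to
#' twice its width (symmetrically, edge values extended) to suppress
#' wrap-around, then cropped back. The propagator is unitary: total
#' intensity is conserved for a non-absorbing field.
#'
#' @param u Complex field sampled at spacing `dx`.
#' @param dx Sample spacing in m.
#' @param wavelength Wavelength in m.
#' @param distance Propagation distance in m (0 returns `u` unchanged).
#' @return The propagated complex field, same length as `u`.
#' @export
fresnel_propagate <- function(u, dx, wavelength, distance) {
  fresnel_propagate_mat(matrix(u, ncol = 1), dx, wavelength, distance)[, 1]
}

# batched variant: one field per column
fresnel_propagate_mat <- function(U, dx, wavelength, distance) {
  if (distance == 0) return(U)
  n <- nrow(U)
  pad <- n %/% 2
  Up <- rbind(matrix(U[1, ], pad, ncol(U), byrow = TRUE), U,
              matrix(U[n, ], pad, ncol(U), byrow = TRUE))
  np <- nrow(Up)
  H <- exp(-1i * pi * wavelength * distance * fft_freq(np, dx)^2)
  out <- stats::mvfft(stats::mvfft(Up) * H, inverse = TRUE) / np
  out[(pad + 1):(pad + n), , drop = FALSE]
}

# FFT frequency axis in cycles per unit of dx, fftshift-free ordering
fft_freq <- function(n, dx = 1) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k <- c(0:(n / 2 - 1), -(n / 2):-1)
  k / (n * dx)
}

#' Generate propagation-based phase-contrast projections of a phantom
#'
#' For each angle: analytic line integrals of delta and beta through the
#' phantom, contact-plane complex transmission
#' `exp(-k integral(beta) dl) * exp(-i k integral(delta) dl)` with
#' `k = 2 pi / lambda`, Fresnel propagation over the sample-to-detector
#' distance, intensity at a stated flat-field count, and seeded Poisson
#' noise. Flat (no sample) and dark (beam off) reference lines are
#' attached.
#'
#' @param phantom A [thorax_phantom()].
#' @param geom An [acquisition_geometry()]; `frame_rate` and the protocol
#'   rotation speed define the angular sampling.
#' @param protocol A [scan_protocol()]; angles are
#'   `start + i * speed / frame_rate` for `i = 0, 1, ...` over `arc`.
#' @param flat_counts Mean flat-field photon count per detector pixel.
#' @param poisson_noise Apply Poisson noise (`FALSE` gives the noise-free
#'   intensity scaled to `flat_counts`).
#' @param seed RNG seed for the noise.
#' @param motion_trace Optional [breathing_trace()] sampled at the
#'   acquisition frame rate: the air pockets and bronchi breathe during the
#'   scan (their radii scale with the trace), so projections at different
#'   angles see different aeration states.
#' @param motion_scale Fractional radius swing per unit trace amplitude.
#' @return A [projection_set()].
#' @export
generate_pbi_projections <- function(phantom, geom, protocol,
                                     flat_counts = 1e4,
                                     poisson_noise = TRUE, seed = 1L,
                                     motion_trace = NULL,
                                     motion_scale = 0.05) {
  d_angle <- protocol$speed / geom$frame_rate
  angles <- seq(0, protocol$arc - d_angle / 2, by = d_angle)
  dx <- geom$pixel_size * 1e-6
  fov_px <- matrix_side(geom$fov, geom$pixel_size)
  if (phantom$nx > fov_px) {
    warning(sprintf(paste0("phantom (%d px) exceeds the field of view (%d px): ",
                           "projections are truncated (local tomography)"),
                    phantom$nx, fov_px))
  }
  n_det <- min(phantom$nx, fov_px)
  k <- 2 * pi / geom$wavelength

  if (is.null(motion_trace)) {
    sino_d <- phantom_sinogram(phantom, angles, n_det, "delta") * dx
    sino_b <- phantom_sinogram(phantom, angles, n_det, "beta") * dx
  } else {
    amp <- max(abs(motion_trace$v))
    sc <- 1 + motion_scale * stats::approx(motion_trace$t, motion_trace$v,
                                    xout = angles / protocol$speed,
                                    rule = 2)$y / max(amp, 1e-12)
    air <- phantom$shapes$role %in% c("pocket", "bronchus")
    sino_d <- matrix(0, length(angles), n_det)
    sino_b <- matrix(0, length(angles), n_det)
    for (i in seq_along(angles)) {      # aeration state varies with time
      phi <- phantom
      phi$shapes$a[air] <- phantom$shapes$a[air] * sc[i]
      phi$shapes$b[air] <- phantom$shapes$b[air] * sc[i]
      sino_d[i, ] <- phantom_sinogram(phi, angles[i], n_det, "delta") * dx
      sino_b[i, ] <- phantom_sinogram(phi, angles[i], n_det, "beta") * dx
    }
  }

  # complex transmission per angle (columns), propagated in one batch
  U <- t(exp(-k * sino_b) * exp(-1i * k * sino_d))
  inten <- t(Mod(fresnel_propagate_mat(U, dx, geom$wavelength,
                                       geom$distance))^2)

  proj <- inten * flat_counts
  flat <- rep(flat_counts, n_det)
  dark <- rep(0, n_det)
  if (poisson_noise) {
    proj <- with_seed(seed, {
      noisy <- matrix(stats::rpois(length(proj), lambda = pmax(proj, 0)),
                      nrow(proj), ncol(proj))
      storage.mode(noisy) <- "double"
      noisy
    })
    # flat/dark are kept as noise-free means (averaged reference frames)
  }
  projection_set(angles, proj, flat, dark, geom)
}

#' Generate a breathing radiograph sequence from a phantom and trace
#'
#' Forward model behind the planar (cinematic) acquisitions: a fixed
#' projection of the thorax phantom at angle 0, whose lung-region
#' attenuation is modulated frame by frame by the breathing trace via
#' Beer-Lambert (aeration increases transmission), sampled at a stated
#' flat-field count with Poisson noise. The 1-D projection line is
#' replicated over rows to form 2-D frames, so a lung ROI and an off-body
#' air reference ROI behave as in the planar acquisitions.
#'
#' @param phantom A [thorax_phantom()].
#' @param trace A [breathing_trace()] (its values scale the lung-region
#'   optical depth; units of optical-depth excursion).
#' @param geom An [acquisition_geometry()] with `frame_rate` equal to the
#'   trace frame rate.
#' @param flat_counts Mean flat-field count per pixel.
#' @param n_rows Number of detector rows in each frame.
#' @param poisson_noise Apply Poisson noise.
#' @param seed RNG seed.
#' @return A [radiograph_sequence()] with attribute `rois`: `lung` and
#'   `reference` [roi_box()]es placed by the generator.
#' @export
generate_radiograph_sequence <- function(phantom, trace, geom,
                                         flat_counts = 1e4, n_rows = 32L,
                                         poisson_noise = TRUE, seed = 1L) {
  if (abs(trace$frame_rate - geom$frame_rate) > 1e-9) {
    stop("generate_radiograph_sequence: trace and geometry frame rates differ")
  }
  n_det <- phantom$nx
  dx <- geom$pixel_size * 1e-6
  k <- 2 * pi / geom$wavelength
  mu_static <- 2 * k * phantom_sinogram(phantom, 0, n_det, "beta")[1, ] * dx
  # unit lung-attenuation profile: normalized air path through the lungs
  lung_path <- phantom_sinogram(structure(list(shapes = data.frame(
    cx = phantom$lungs[, "cx"], cy = phantom$lungs[, "cy"],
    a = phantom$lungs[, "a"], b = phantom$lungs[, "b"],
    ddelta = 1, dbeta = 1)), class = "thorax_phantom"),
    0, n_det, "beta")[1, ]
  lung_profile <- lung_path / max(lung_path)

  nf <- length(trace$v)
  frames <- array(0, dim = c(n_rows, n_det, nf))
  for (i in seq_len(nf)) {
    # inspiration (positive trace) fills the lung with air: transmission rises
    transmission <- exp(-pmax(mu_static - trace$v[i] * lung_profile, 0))
    frames[, , i] <- matrix(transmission * flat_counts, n_rows, n_det,
                            byrow = TRUE)
  }
  if (poisson_noise) {
    frames <- with_seed(seed, {
      noisy <- array(stats::rpois(length(frames), lambda = frames), dim(frames))
      storage.mode(noisy) <- "double"
      noisy
    })
  }
  seq_out <- radiograph_sequence(frames, geom$frame_rate, geom$pixel_size)
  lung_cols <- which(lung_profile > 0.5)
  body_cols <- which(mu_static > 0)
  air_cols <- setdiff(seq_len(n_det), body_cols)
  ref_run <- split(air_cols, cumsum(c(1, diff(air_cols) != 1)))
  ref_run <- ref_run[[which.max(lengths(ref_run))]]
  attr(seq_out, "rois") <- list(
    lung = roi_box(0, min(lung_cols) - 1, n_rows, max(lung_cols)),
    reference = roi_box(0, min(ref_run) - 1, n_rows, max(ref_run)))
  seq_out
}
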