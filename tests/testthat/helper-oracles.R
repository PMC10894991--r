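# Independent oracles used across tests. These deliberately re-derive
# quantities with separate code paths from the package implementation.

# analytic parallel-beam sinogram of a centred uniform disk (chord lengths)
disk_sinogram <- function(radius, n_det, angles_deg, mu = 1) {
  s <- seq_len(n_det) - (n_det + 1) / 2
  chord <- ifelse(radius^2 - s^2 > 0, 2 * sqrt(pmax(radius^2 - s^2, 0)), 0)
  matrix(rep(chord * mu, length(angles_deg)), length(angles_deg), n_det,
         byrow = TRUE)
}

# trapezoidal rule, written independently of the package helper
oracle_trapz <- function(x, y) {
  idx <- seq_len(length(x) - 1)
  sum(0.5 * (y[idx] + y[idx + 1]) * (x[idx + 1] - x[idx]))
}

# exhaustive two-sample permutation test (mid-p for ties), direction b > a
oracle_permutation_p <- function(a, b) {
  pool <- c(a, b)
  idx <- utils::combn(length(pool), length(a))
  obs <- mean(b) - mean(a)
  stats <- apply(idx, 2, function(ii) mean(pool[-ii]) - mean(pool[ii]))
  (sum(stats > obs + 1e-12) + 0.5 * sum(abs(stats - obs) < 1e-12)) /
    ncol(idx)
}

# direct Fresnel convolution of the scattered field u - 1 (quadrature is
# valid only when the chirp kernel is sampled below Nyquist over the
# aperture: lambda * z / (2 dx) > n * dx)
oracle_fresnel_direct <- function(u, dx, wavelength, z, idx) {
  n <- length(u)
  xs <- (seq_len(n) - (n + 1) / 2) * dx
  vapply(idx, function(j) {
    1 + sum((u - 1) * exp(1i * pi * (xs[j] - xs)^2 / (wavelength * z))) *
      dx / sqrt(1i * wavelength * z)
  }, complex(1))
}

# small uniform radiograph stack builder
const_sequence <- function(value = 1, nf = 5, nr = 8, nc = 10,
                           frame_rate = 10, pixel_size = 30) {
  radiograph_sequence(array(value, dim = c(nr, nc, nf)), frame_rate,
                      pixel_size)
}

default_geom <- function(frame_rate = 40, pixel_size = 31.2, fov = 63.9) {
  acquisition_geometry(energy = 22, distance = 1.5, pixel_size = pixel_size,
                       fov = fov, frame_rate = frame_rate, dose_rate = 2.8)
}

# noise-free breathing parameter sets
quiet_preset <- function(group = "CN", ...) {
  breathing_preset(group, noise_sd = 0, cardiac_amp = 0, drift_amp = 0, ...)
}
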