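#' Synthetic thorax phantom with known aeration
#'
#' A single-slice thorax built from analytic ellipses: a soft-tissue body
#' outline, two lung fields filled with a quasi-regular lattice of circular
#' air pockets (parenchymal aeration) plus one larger air tube per lung
#' (bronchus), and optional soft-tissue consolidation blobs that locally
#' de-aerate the lung. Materials are parameterized directly by the complex
#' refractive-index pair (delta, beta) at the working energy; the defaults
#' give soft tissue delta/beta = 1000 at 22 keV.
#'
#' The air-pocket radius is calibrated (two raster passes) so that the
#' voxel-counted air fraction inside the lung mask matches
#' `aerated_fraction`; consolidation blobs are applied after calibration, so
#' a consolidated phantom has a truth fraction strictly below the nominal
#' one. The voxel-counted value is returned as `aerated_fraction_truth`.
#'
#' @param nx Raster side length in pixels (square grid).
#' @param pixel_size Pixel size in micrometres.
#' @param aerated_fraction Nominal air fraction inside the lung mask.
#' @param n_consolidation Number of consolidation blobs (0 = healthy).
#' @param delta_tissue,beta_tissue Soft-tissue refractive-index decrement
#'   and absorption index.
#' @param delta_air,beta_air Same for air (small but positive).
#' @param seed RNG seed for pocket jitter and blob placement.
#' @return An object of class `thorax_phantom` with the shape table, raster
#'   maps (`delta_map`, `beta_map`, `lung_mask`, `air_mask`) and
#'   `aerated_fraction_truth`.
#' @export
thorax_phantom <- function(nx = 200, pixel_size = 31.2,
                           aerated_fraction = 0.30, n_consolidation = 0L,
                           delta_tissue = 4.0e-7, beta_tissue = 4.0e-10,
                           delta_air = 4.0e-10, beta_air = 4.0e-13,
                           seed = 1L) {
  stopifnot(nx >= 40, pixel_size > 0,
            aerated_fraction >= 0, aerated_fraction <= 1)
  if (delta_tissue <= 0 || beta_tissue <= 0 || delta_air <= 0 || beta_air <= 0) {
    stop("thorax_phantom: delta and beta must be positive for all materials")
  }
  ratios <- c(delta_tissue / beta_tissue, delta_air / beta_air)
  if (any(ratios < 100) || any(ratios > 3000)) {
    stop("thorax_phantom: delta/beta must lie in [100, 3000]")
  }

  half <- nx / 2
  # body and lung ellipses, coordinates in pixels, origin at grid centre
  body <- c(cx = 0, cy = 0, a = 0.46 * nx, b = 0.40 * nx)
  lungs <- rbind(c(cx = -0.20 * nx, cy = -0.02 * nx, a = 0.155 * nx, b = 0.26 * nx),
                 c(cx =  0.20 * nx, cy = -0.02 * nx, a = 0.155 * nx, b = 0.26 * nx))

  with_seed(seed, {
    # candidate pocket centres on a jittered lattice, kept well inside a lung
    spacing <- 0.07 * nx
    jit <- 0.004 * nx
    gx <- seq(-half + spacing, half - spacing, by = spacing)
    cand <- expand.grid(x = gx, y = gx)
    cand$x <- cand$x + stats::runif(nrow(cand), -jit, jit)
    cand$y <- cand$y + stats::runif(nrow(cand), -jit, jit)
    margin <- spacing / 2
    inside <- rep(FALSE, nrow(cand))
    for (i in 1:2) {
      L <- lungs[i, ]
      inside <- inside |
        (((cand$x - L["cx"]) / (L["a"] - margin))^2 +
         ((cand$y - L["cy"]) / (L["b"] - margin))^2 < 1)
    }
    pockets <- cand[inside, , drop = FALSE]

    # one bronchus per lung: a larger air tube near the mediastinal edge
    bronchi <- data.frame(x = lungs[, "cx"] * 0.55, y = lungs[, "cy"] + 0.04 * nx,
                          r = 0.022 * nx)

    # consolidation blobs: random soft-tissue ellipses inside the lungs
    blobs <- NULL
    if (n_consolidation > 0) {
      side <- sample(1:2, n_consolidation, replace = TRUE)
      L <- lungs[side, , drop = FALSE]
      u <- stats::runif(n_consolidation, -0.45, 0.45)
      w <- stats::runif(n_consolidation, -0.55, 0.55)
      blobs <- data.frame(cx = L[, "cx"] + u * L[, "a"],
                          cy = L[, "cy"] + w * L[, "b"],
                          a = 0.055 * nx, b = 0.045 * nx)
    }
    NULL
  })

  grid <- pixel_centres(nx)
  lung_mask <- ellipse_mask(grid, lungs[1, ]) | ellipse_mask(grid, lungs[2, ])
  lung_area <- sum(lung_mask)

  air_needed <- aerated_fraction * lung_area -
    sum(vapply(seq_len(nrow(bronchi)), function(i) {
      sum(disk_mask(grid, bronchi$x[i], bronchi$y[i], bronchi$r[i]) & lung_mask)
    }, numeric(1)))
  r_cap <- spacing / 2 - jit - 0.25   # guarantees pocket non-overlap
  r0 <- min(sqrt(max(air_needed, 0) / (pi * max(nrow(pockets), 1L))), r_cap)
  # second raster pass corrects pixelation of the first estimate
  frac0 <- raster_air_fraction(grid, lung_mask, pockets, r0, bronchi)
  if (frac0 > 0 && aerated_fraction > 0) {
    r0 <- min(r0 * sqrt(aerated_fraction / frac0), r_cap)
  }

  # drop pockets/bronchi swallowed by consolidation
  if (!is.null(blobs)) {
    for (i in seq_len(nrow(blobs))) {
      B <- blobs[i, ]
      hit <- ((pockets$x - B$cx) / (B$a + r0))^2 +
             ((pockets$y - B$cy) / (B$b + r0))^2 < 1
      pockets <- pockets[!hit, , drop = FALSE]
      hitb <- ((bronchi$x - B$cx) / (B$a + bronchi$r))^2 +
              ((bronchi$y - B$cy) / (B$b + bronchi$r))^2 < 1
      bronchi <- bronchi[!hitb, , drop = FALSE]
    }
  }

  air_mask <- matrix(FALSE, nx, nx)
  for (i in seq_len(nrow(pockets))) {
    air_mask <- air_mask | disk_mask(grid, pockets$x[i], pockets$y[i], r0)
  }
  for (i in seq_len(nrow(bronchi))) {
    air_mask <- air_mask | disk_mask(grid, bronchi$x[i], bronchi$y[i], bronchi$r[i])
  }
  air_mask <- air_mask & lung_mask

  body_mask <- ellipse_mask(grid, body)
  delta_map <- matrix(delta_air, nx, nx)
  beta_map <- matrix(beta_air, nx, nx)
  delta_map[body_mask] <- delta_tissue
  beta_map[body_mask] <- beta_tissue
  delta_map[air_mask] <- delta_air
  beta_map[air_mask] <- beta_air

  # shape table for analytic projections: additive (delta, beta) increments
  dd <- delta_tissue - delta_air
  db <- beta_tissue - beta_air
  shapes <- rbind(
    data.frame(cx = body["cx"], cy = body["cy"], a = body["a"], b = body["b"],
               ddelta = dd, dbeta = db, role = "body"),
    data.frame(cx = lungs[, "cx"], cy = lungs[, "cy"], a = lungs[, "a"],
               b = lungs[, "b"], ddelta = 0, dbeta = 0, role = "lung"),
    if (nrow(pockets) > 0)
      data.frame(cx = pockets$x, cy = pockets$y, a = r0, b = r0,
                 ddelta = -dd, dbeta = -db, role = "pocket"),
    if (nrow(bronchi) > 0)
      data.frame(cx = bronchi$x, cy = bronchi$y, a = bronchi$r, b = bronchi$r,
                 ddelta = -dd, dbeta = -db, role = "bronchus"))
  rownames(shapes) <- NULL

  structure(list(
    nx = nx, pixel_size = pixel_size, shapes = shapes,
    lungs = lungs, blobs = blobs,
    delta_map = delta_map, beta_map = beta_map,
    lung_mask = lung_mask, air_mask = air_mask, body_mask = body_mask,
    materials = list(delta_tissue = delta_tissue, beta_tissue = beta_tissue,
                     delta_air = delta_air, beta_air = beta_air),
    aerated_fraction_truth = sum(air_mask) / lung_area),
    class = "thorax_phantom")
}

#' @export
print.thorax_phantom <- function(x, ...) {
  cat(sprintf(paste0("thorax phantom: %d x %d px at %.3g um, ",
                     "%d shapes, aerated fraction %.3f%s\n"),
              x$nx, x$nx, x$pixel_size, nrow(x$shapes),
              x$aerated_fraction_truth,
              if (!is.null(x$blobs)) sprintf(" (%d consolidation blobs)",
                                             nrow(x$blobs)) else ""))
  invisible(x)
}

pixel_centres <- function(nx) {
  s <- seq_len(nx) - (nx + 1) / 2
  list(x = matrix(s, nx, nx, byrow = TRUE),   # column coordinate
       y = matrix(s, nx, nx))                 # row coordinate
}

ellipse_mask <- function(grid, e) {
  ((grid$x - e["cx"]) / e["a"])^2 + ((grid$y - e["cy"]) / e["b"])^2 <= 1
}

disk_mask <- function(grid, cx, cy, r) {
  (grid$x - cx)^2 + (grid$y - cy)^2 <= r^2
}

raster_air_fraction <- function(grid, lung_mask, pockets, r, bronchi) {
  m <- matrix(FALSE, nrow(lung_mask), ncol(lung_mask))
  for (i in seq_len(nrow(pockets))) {
    m <- m | disk_mask(grid, pockets$x[i], pockets$y[i], r)
  }
  for (i in seq_len(nrow(bronchi))) {
    m <- m | disk_mask(grid, bronchi$x[i], bronchi$y[i], bronchi$r[i])
  }
  sum(m & lung_mask) / sum(lung_mask)
}

#' Parallel-beam line integrals through a phantom
#'
#' Analytic ellipse chord lengths (no rasterization): for an ellipse with
#' semi-axes a, b the projection at angle theta and detector offset s is
#' `2ab sqrt(alpha^2 - s'^2) / alpha^2` with
#' `alpha^2 = a^2 cos^2 + b^2 sin^2`. Increments of all shapes are summed.
#'
#' @param phantom A [thorax_phantom()] (or any object with a `shapes` table
#'   in pixel units).
#' @param angles_deg Projection angles in degrees (0 = beam along image
#'   rows, counter-clockwise positive).
#' @param n_det Number of detector pixels (default: phantom grid side).
#' @param what `"delta"` or `"beta"`.
#' @return Matrix `[length(angles), n_det]` of line integrals in
#'   pixel-length units (multiply by the pixel size in metres for physical
#'   path integrals).
#' @export
phantom_sinogram <- function(phantom, angles_deg, n_det = phantom$nx,
                             what = c("delta", "beta")) {
  what <- match.arg(what)
  col <- if (what == "delta") "ddelta" else "dbeta"
  s <- seq_len(n_det) - (n_det + 1) / 2
  th <- angles_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  out <- matrix(0, length(th), n_det)
  sh <- phantom$shapes
  for (j in seq_len(nrow(sh))) {       # vectorized over angles x detector
    w <- sh[[col]][j]
    if (w == 0) next
    alpha2 <- sh$a[j]^2 * ct^2 + sh$b[j]^2 * st^2
    centre <- sh$cx[j] * ct + sh$cy[j] * st
    u2 <- alpha2 - (matrix(s, length(th), n_det, byrow = TRUE) - centre)^2
    u2[u2 < 0] <- 0
    out <- out + (w * 2 * sh$a[j] * sh$b[j] / alpha2) * sqrt(u2)
  }
  out
}

#' Deterministic six-ROI layout inside the phantom lungs
#'
#' Three boxes per lung, inscribed in the lung ellipse and stacked
#' vertically, identical for every phantom of the same grid size: a
#' reproducible placement protocol so that aeration is sampled consistently
#' across animals.
#'
#' @param phantom A [thorax_phantom()].
#' @param n_per_lung Boxes per lung (default 3).
#' @param shrink Fraction of the inscribed width/height actually used.
#' @return A list of `2 * n_per_lung` [roi_box()]es.
#' @export
phantom_lung_rois <- function(phantom, n_per_lung = 3L, shrink = 0.85) {
  nx <- phantom$nx
  off <- (nx + 1) / 2                   # grid-centre -> 1-based pixel index
  edges <- seq(-0.8, 0.8, length.out = n_per_lung + 1)
  rois <- list()
  for (i in 1:2) {
    L <- phantom$lungs[i, ]
    for (j in seq_len(n_per_lung)) {
      y0 <- edges[j] * L["b"]; y1 <- edges[j + 1] * L["b"]
      halfw <- shrink * L["a"] * sqrt(1 - max(abs(y0), abs(y1))^2 / L["b"]^2)
      r0 <- round(L["cy"] + y0 + off + (1 - shrink) / 2 * (y1 - y0))
      r1 <- round(L["cy"] + y1 + off - (1 - shrink) / 2 * (y1 - y0))
      c0 <- round(L["cx"] - halfw + off)
      c1 <- round(L["cx"] + halfw + off)
      rois[[length(rois) + 1L]] <- roi_box(r0 - 1L, c0 - 1L, r1 - 1L, c1 - 1L)
    }
  }
  rois
}

#' Straight-edge phantom with Gaussian blur
#'
#' A vertical edge whose horizontal profile is the integral of a Gaussian of
#' width `sigma` (an error-function ramp); `sigma = 0` gives an ideal step.
#' Used as a fixture for edge-sharpness (FWHM) measurements.
#'
#' @param sigma Edge blur in pixels (>= 0).
#' @param pixel_size Pixel size in micrometres (carried as an attribute).
#' @param shape Image dimensions `c(rows, cols)`.
#' @param low,high Intensity levels either side of the edge.
#' @return A matrix with attributes `pixel_size` and `edge_col` (the edge
#'   position, 0-based column coordinate).
#' @export
generate_edge_phantom <- function(sigma, pixel_size, shape = c(64, 128),
                                  low = 0, high = 1) {
  if (sigma < 0) stop("generate_edge_phantom: sigma must be >= 0")
  edge <- (shape[2] - 1) / 2
  xs <- seq_len(shape[2]) - 1
  profile <- if (sigma == 0) as.numeric(xs > edge) else
    stats::pnorm((xs - edge) / sigma)
  img <- matrix(low + (high - low) * profile, shape[1], shape[2], byrow = TRUE)
  attr(img, "pixel_size") <- pixel_size
  attr(img, "edge_col") <- edge
  img
}

#' Two-region noise image for CNR fixtures
#'
#' Two abutting rectangles of seeded Gaussian noise with stated means and
#' standard deviations, side by side.
#'
#' @param g1,g2 Region means.
#' @param sd1,sd2 Region standard deviations (>= 0).
#' @param shape Per-region dimensions `c(rows, cols)`.
#' @param seed RNG seed.
#' @return A matrix `shape[1] x 2*shape[2]` with attributes `roi1` and
#'   `roi2` ([roi_box()] for the two regions).
#' @export
generate_two_region_image <- function(g1, g2, sd1, sd2, shape = c(200, 200),
                                      seed = 1L) {
  if (sd1 < 0 || sd2 < 0) stop("generate_two_region_image: sd must be >= 0")
  npx <- prod(shape)
  img <- with_seed(seed, cbind(
    matrix(stats::rnorm(npx, g1, sd1), shape[1], shape[2]),
    matrix(stats::rnorm(npx, g2, sd2), shape[1], shape[2])))
  attr(img, "roi1") <- roi_box(0, 0, shape[1], shape[2])
  attr(img, "roi2") <- roi_box(0, shape[2], shape[1], 2 * shape[2])
  img
}
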