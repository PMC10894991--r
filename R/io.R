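#' Write a stack of images as a multi-page TIFF
#'
#' Values are written as 32-bit float so the linear scale of phase-retrieved
#' data survives the round trip.
#'
#' @param x A 3-D array `[row, col, frame]`, a matrix (single page), or a
#'   `radiograph_sequence`.
#' @param path Output file path.
#' @param scale Divide values by this before writing (TIFF float samples
#'   live in `[0, 1]`); e.g. the flat-field count for raw count frames.
#'   With the default 1 the data must already lie in `[0, 1]`.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(x, path, scale = 1) {
  if (inherits(x, "radiograph_sequence")) x <- x$frames
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  x <- x / scale
  if (min(x) < 0 || max(x) > 1) {
    stop(sprintf(paste0("write_tiff_stack: values in [%.3g, %.3g] after ",
                        "scaling; float TIFF samples must lie in [0, 1] - ",
                        "pass an appropriate `scale`"), min(x), max(x)))
  }
  pages <- lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF into an array
#'
#' @param path TIFF file path.
#' @return A 3-D array `[row, col, frame]`.
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  array(unlist(pages, use.names = FALSE), dim = c(d[1], d[2], length(pages)))
}

#' Read a dataset sidecar configuration
#'
#' TIFF carries no acquisition metadata, so each dataset travels with a YAML
#' sidecar holding a `geometry` block (energy, distance, pixel_size, fov,
#' frame_rate, dose_rate), an optional `protocol` block (arc, speed,
#' subsample_step, subset_arc) and optional `rois` (named list of
#' row0/col0/row1/col1).
#'
#' @param path YAML file path.
#' @return A list with elements `geometry` ([acquisition_geometry()]),
#'   `protocol` ([scan_protocol()] or NULL), `rois` (named list of
#'   [roi_box()]), and `extra` (all remaining keys).
#' @export
read_dataset_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$geometry)) stop("config: missing required 'geometry' block")
  geom <- do.call(acquisition_geometry, raw$geometry)
  protocol <- if (!is.null(raw$protocol)) do.call(scan_protocol, raw$protocol)
  rois <- lapply(raw$rois, function(r) do.call(roi_box, r[c("row0", "col0", "row1", "col1")]))
  extra <- raw[setdiff(names(raw), c("geometry", "protocol", "rois"))]
  list(geometry = geom, protocol = protocol, rois = rois, extra = extra)
}

#' Write a dataset sidecar configuration
#'
#' @param geometry An [acquisition_geometry()].
#' @param path Output YAML path.
#' @param protocol Optional [scan_protocol()].
#' @param rois Optional named list of [roi_box()].
#' @param extra Optional named list of additional keys.
#' @return `path`, invisibly.
#' @export
write_dataset_config <- function(geometry, path, protocol = NULL, rois = NULL,
                                 extra = NULL) {
  out <- list(geometry = unclass(geometry)[c("energy", "distance", "pixel_size",
                                             "fov", "frame_rate", "dose_rate")])
  if (!is.null(protocol)) out$protocol <- unclass(protocol)
  if (!is.null(rois)) out$rois <- lapply(rois, unclass)
  if (!is.null(extra)) out <- c(out, extra)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write a breathing trace as CSV
#'
#' Two columns, `time_s` and `value`, with a header row.
#'
#' @param trace A [breathing_trace()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$t, value = trace$v),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a breathing trace from CSV
#'
#' @param path CSV with columns `time_s` and `value` at uniform spacing.
#' @return A [breathing_trace()].
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  dt <- diff(d$time_s)
  breathing_trace(d$time_s, d$value, frame_rate = 1 / stats::median(dt))
}

#' Write provenance parameters as JSON
#'
#' @param params Named list of parameters to record.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(params, path) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
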