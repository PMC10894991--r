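#' Plot a breathing trace with detected events
#'
#' @param trace A [breathing_trace()].
#' @param events Optional [detect_events()] output; peaks are marked with
#'   asterisks and starts with dots.
#' @param file Optional PNG path; NULL draws on the current device.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the file path (or NULL).
#' @export
plot_trace <- function(trace, events = NULL, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 400, res = 120)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(trace$t, trace$v, type = "l", xlab = "time (s)",
                 ylab = "mean transmission", ...)
  if (!is.null(events) && length(events$peak_idx)) {
    graphics::points(events$peaks, trace$v[events$peak_idx],
                     pch = 8, col = "red")
    ok <- !is.na(events$start_idx)
    graphics::points(events$starts[ok], trace$v[events$start_idx[ok]],
                     pch = 16, col = "black")
  }
  invisible(file)
}

#' Annotated strip plot of a group comparison
#'
#' Per-animal values by group with the one-sided Welch annotation above.
#'
#' @param table Per-animal data.frame with a `group` column.
#' @param param Column to plot.
#' @param comparison One row of [compare_groups()] output for `param`.
#' @param file Optional PNG path.
#' @return Invisibly, the file path (or NULL).
#' @export
plot_group_comparison <- function(table, param, comparison = NULL,
                                  file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 500, height = 500, res = 120)
    on.exit(grDevices::dev.off())
  }
  g <- factor(table$group)
  x <- as.integer(g) + stats::runif(nrow(table), -0.08, 0.08)
  graphics::plot(x, table[[param]], xlim = c(0.5, nlevels(g) + 0.5),
                 xaxt = "n", xlab = "", ylab = param, pch = 16)
  graphics::axis(1, at = seq_len(nlevels(g)), labels = levels(g))
  if (!is.null(comparison)) {
    graphics::mtext(sprintf("%s (p = %.3g)", comparison$annotation,
                            comparison$p), side = 3)
  }
  invisible(file)
}
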