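#' One-sided Welch's t-test between two groups
#'
#' Welch's unequal-variance t statistic with Satterthwaite degrees of
#' freedom and a one-sided p-value in a pre-registered direction. The
#' direction must be stated before testing (the headline comparisons here:
#' AUC larger, fall constant smaller, aerated fraction smaller in the
#' asthmatic group).
#'
#' @param a,b Numeric sample vectors (each n >= 2).
#' @param direction `"a_greater"` or `"b_greater"`: which group is
#'   hypothesized to have the larger mean.
#' @return An object of class `group_comparison`: `statistic`, `dof`, `p`,
#'   `direction`, `annotation`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `degenerate`.
#' @export
welch_one_sided <- function(a, b, direction = c("a_greater", "b_greater")) {
  direction <- match.arg(direction)
  if (length(a) < 2 || length(b) < 2) {
    stop("welch_one_sided: each group needs at least 2 values")
  }
  degenerate <- FALSE
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      warning("welch_one_sided: zero variance in both groups with equal means; p = 0.5")
      res <- list(statistic = 0, parameter = length(a) + length(b) - 2,
                  p.value = 0.5)
      degenerate <- TRUE
    } else {
      stop("welch_one_sided: zero variance in both groups")
    }
  } else {
    alt <- if (direction == "a_greater") "greater" else "less"
    ht <- stats::t.test(a, b, alternative = alt, var.equal = FALSE)
    res <- list(statistic = unname(ht$statistic),
                parameter = unname(ht$parameter), p.value = ht$p.value)
  }
  structure(list(statistic = res$statistic, dof = res$parameter,
                 p = res$p.value, direction = direction,
                 annotation = annotate_significance(res$p.value),
                 mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b), degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch one-sided (%s): t = %.3g, dof = %.3g, p = %.4g [%s]\n",
              x$direction, x$statistic, x$dof, x$p, x$annotation))
  invisible(x)
}

#' Significance star annotation
#'
#' `ns` for p > 0.05, then `*` (<= 0.05), `**` (<= 0.01), `***` (<= 0.001)
#' and `****` (<= 0.0001).
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return Character vector of annotations.
#' @export
annotate_significance <- function(p) {
  if (any(p < 0 | p > 1 | !is.finite(p))) {
    stop("annotate_significance: p must lie in [0, 1]")
  }
  vapply(p, function(pp) {
    if (pp > 0.05) "ns"
    else if (pp > 0.01) "*"
    else if (pp > 0.001) "**"
    else if (pp > 0.0001) "***"
    else "****"
  }, character(1))
}

#' Compare functional/structural parameters between groups
#'
#' Runs the pre-registered one-sided Welch comparison for each requested
#' column of a per-animal summary table.
#'
#' @param table A data.frame with a `group` column and numeric parameter
#'   columns (e.g. from [summary_table()]).
#' @param comparisons Named character vector: for each column name, the
#'   group hypothesized larger (e.g. `c(auc = "SAA", fall_const = "CN")`).
#' @param groups Length-2 character vector naming the two groups; the first
#'   is "a" in [welch_one_sided()].
#' @return A data.frame with one row per comparison: parameter, direction,
#'   group means, t, dof, p, annotation.
#' @export
compare_groups <- function(table, comparisons,
                           groups = c("CN", "SAA")) {
  stopifnot(all(names(comparisons) %in% names(table)),
            "group" %in% names(table))
  rows <- lapply(names(comparisons), function(param) {
    a <- table[[param]][table$group == groups[1]]
    b <- table[[param]][table$group == groups[2]]
    dir <- if (comparisons[[param]] == groups[1]) "a_greater" else "b_greater"
    r <- welch_one_sided(a, b, dir)
    data.frame(parameter = param,
               larger = comparisons[[param]],
               mean_a = r$mean_a, mean_b = r$mean_b,
               t = r$statistic, dof = r$dof, p = r$p,
               annotation = r$annotation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", groups[1])
  names(out)[names(out) == "mean_b"] <- paste0("mean_", groups[2])
  out
}
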