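# pooled (t, v) samples for one breath phase across overlaid events
pool_phase_samples <- function(events, phase = c("inspiration", "expiration"),
                               min_t = NULL) {
  phase <- match.arg(phase)
  events <- Filter(function(e) isTRUE(e$complete), events)
  if (length(events) == 0) stop("no complete events to fit")
  if (is.null(min_t)) min_t <- 1 / events[[1]]$frame_rate
  t <- unlist(lapply(events, `[[`, "t_rel"))
  v <- unlist(lapply(events, `[[`, "v"))
  if (phase == "inspiration") {
    sel <- t < 0
    t <- -t[sel]           # time before the peak, > 0
  } else {
    sel <- t > 0
    t <- t[sel]
  }
  v <- v[sel]
  keep <- t >= min_t       # the 1/t model is singular at the overlay peak
  list(t = t[keep], v = v[keep])
}

#' Hyperbolic (1/t) fit of a breath phase
#'
#' Fits `f(t) = c0 / (c1 * t) + c2` to the pooled samples of one phase of
#' all complete overlaid events; `t` is time before the peak for the
#' inspiration phase and time after the peak for the expiration phase, with
#' samples closer to the peak than one frame excluded (the model is
#' singular at t = 0). Only the ratio c0/c1 is identifiable, so the fit is
#' solved as linear least squares in `A = c0/c1` and `c2`, and reported
#' with `c0 = 1`, `c1 = 1/A`. The expiration `c1` is the fall constant and
#' the inspiration `c1` the raise constant.
#'
#' @param events List of events from [overlay_events()].
#' @param phase `"inspiration"` or `"expiration"`.
#' @param min_t Exclusion radius around the peak in s (default one frame).
#' @return An object of class `hyperbolic_fit`: `c0`, `c1`, `c2`, `phase`,
#'   `rss`, `n`.
#' @export
fit_hyperbolic <- function(events, phase = c("inspiration", "expiration"),
                           min_t = NULL) {
  phase <- match.arg(phase)
  s <- pool_phase_samples(events, phase, min_t)
  if (length(s$t) < 3) {
    stop(sprintf("fit_hyperbolic: fewer than 3 %s samples", phase))
  }
  fit <- stats::lm(v ~ I(1 / t), data = s)
  A <- stats::coef(fit)[["I(1/t)"]]
  if (A == 0) stop("fit_hyperbolic: degenerate fit (A = 0)")
  structure(list(c0 = 1, c1 = 1 / A, c2 = stats::coef(fit)[["(Intercept)"]],
                 phase = phase, rss = sum(stats::resid(fit)^2),
                 n = length(s$t)),
            class = "hyperbolic_fit")
}

#' Evaluate a hyperbolic fit
#'
#' @param fit A `hyperbolic_fit`.
#' @param t Times (> 0; the model is singular at 0).
#' @return Fitted values.
#' @export
predict_hyperbolic <- function(fit, t) {
  if (any(t == 0)) stop("predict_hyperbolic: model undefined at t = 0")
  fit$c0 / (fit$c1 * t) + fit$c2
}

#' Double-Gaussian fit of the expiration phase
#'
#' Fits `f(t) = c2 exp(-c1 t^2) + c4 exp(-c3 t^2) + c0` to the pooled
#' expiration samples (t >= 0) of all complete events: the fast term
#' captures the elastic recoil, the slow term the diaphragm-dampened phase.
#' Initialization is a multi-start search on a log-spaced (c1, c3) grid
#' with the linear coefficients solved exactly per start, followed by
#' Levenberg-Marquardt refinement. Parameters are returned with the
#' convention `c1 >= c3` (swap-symmetric starts converge to one ordering).
#'
#' @param events List of events from [overlay_events()], or a list with
#'   numeric `t` (>= 0) and `v` for direct fitting.
#' @param n_starts Number of (c1, c3) grid starts (default 8).
#' @return An object of class `double_gaussian_fit`: `c0 ... c4`, `rss`,
#'   `n`, `converged`.
#' @export
fit_double_gaussian <- function(events, n_starts = 8) {
  s <- if (is.list(events) && !is.null(events$t) && is.numeric(events$t)) {
    list(t = events$t, v = events$v)
  } else {
    pool_phase_samples(events, "expiration", min_t = 0)
  }
  if (length(s$t) < 6) stop("fit_double_gaussian: need at least 6 expiration samples")
  t <- s$t; v <- s$v
  t_scale <- max(stats::quantile(t[t > 0], 0.9, names = FALSE), 1e-6)

  # log-spaced rate grid spanning slow (~trace length) to fast (~one frame)
  rates <- exp(seq(log(0.2 / t_scale^2), log(50 / t_scale^2),
                   length.out = max(4, ceiling(sqrt(2 * n_starts)))))
  pairs <- utils::combn(length(rates), 2)
  pairs <- pairs[, seq_len(min(ncol(pairs), n_starts)), drop = FALSE]

  best <- NULL
  for (j in seq_len(ncol(pairs))) {
    c3 <- rates[pairs[1, j]]; c1 <- rates[pairs[2, j]]   # c1 > c3
    X <- cbind(exp(-c1 * t^2), exp(-c3 * t^2), 1)
    beta <- tryCatch(unname(stats::lm.fit(X, v)$coefficients),
                     error = function(e) NULL)
    if (is.null(beta) || any(!is.finite(beta))) next
    rss <- sum((v - X %*% beta)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(c1 = c1, c2 = beta[1], c3 = c3, c4 = beta[2],
                   c0 = beta[3], rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(c0 = NA, c1 = NA, c2 = NA, c3 = NA, c4 = NA,
                          rss = NA, n = length(t), converged = FALSE,
                          message = "all starts degenerate"),
                     class = "double_gaussian_fit"))
  }

  fitted <- tryCatch({
    fit <- minpack.lm::nlsLM(
      v ~ c2 * exp(-c1 * t^2) + c4 * exp(-c3 * t^2) + c0,
      data = data.frame(t = t, v = v),
      start = best[c("c0", "c1", "c2", "c3", "c4")],
      lower = c(c0 = -Inf, c1 = 1e-12, c2 = -Inf, c3 = 1e-12, c4 = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- as.list(stats::coef(fit))
    p$rss <- sum(stats::resid(fit)^2)
    p$converged <- TRUE
    p
  }, error = function(e) {
    c(best, list(converged = FALSE, message = conditionMessage(e)))
  })

  if (fitted$c1 < fitted$c3) {   # enforce the fast-term-first convention
    fitted[c("c1", "c2", "c3", "c4")] <- fitted[c("c3", "c4", "c1", "c2")]
  }
  structure(c(fitted[c("c0", "c1", "c2", "c3", "c4", "rss", "converged")],
              list(n = length(t),
                   message = if (!isTRUE(fitted$converged)) fitted$message)),
            class = "double_gaussian_fit")
}

#' Evaluate a double-Gaussian fit or its derivatives
#'
#' Derivatives are closed-form: for one term `c exp(-a t^2)` the first
#' three derivatives carry the polynomial factors `-2at`,
#' `4a^2 t^2 - 2a`, and `12 a^2 t - 8 a^3 t^3`.
#'
#' @param fit A `double_gaussian_fit`.
#' @param t Times.
#' @param deriv Derivative order 0-3.
#' @return Values of the requested derivative.
#' @export
predict_double_gaussian <- function(fit, t, deriv = 0L) {
  term <- function(c, a) {
    g <- c * exp(-a * t^2)
    switch(as.character(deriv),
           "0" = g,
           "1" = -2 * a * t * g,
           "2" = (4 * a^2 * t^2 - 2 * a) * g,
           "3" = (12 * a^2 * t - 8 * a^3 * t^3) * g,
           stop("deriv must be 0, 1, 2 or 3"))
  }
  out <- term(fit$c2, fit$c1) + term(fit$c4, fit$c3)
  if (deriv == 0L) out <- out + fit$c0
  out
}

#' Diaphragm-dampening onset from a double-Gaussian fit
#'
#' The time at which the elastic recoil is taken over by the diaphragm,
#' defined as the minimum of the third derivative of the fitted expiration
#' curve on `(0, t_max]`. The third derivative is evaluated analytically on
#' a dense grid (10^4 points) and the global minimum is polished by local
#' optimization. If no interior minimum exists the result is flagged.
#'
#' @param fit A `double_gaussian_fit`.
#' @param t_max Upper bound of the expiration support in s.
#' @param which `"global"` (default) or `"first"` local minimum.
#' @return Onset time in s, with attributes `flag` (NA or a message) and
#'   `f3` (the third-derivative value at the onset).
#' @export
dampening_onset <- function(fit, t_max, which = c("global", "first")) {
  which <- match.arg(which)
  stopifnot(t_max > 0, is.finite(fit$c1), is.finite(fit$c3))
  grid <- seq(t_max / 1e4, t_max, length.out = 1e4)
  f3 <- predict_double_gaussian(fit, grid, deriv = 3L)
  flag <- NA_character_

  d <- diff(f3)
  interior_min <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  idx <- if (which == "first" && length(interior_min) > 0) {
    interior_min[1]
  } else {
    which.min(f3)
  }
  if (length(interior_min) == 0 || idx == 1L || idx == length(grid)) {
    flag <- "no interior minimum of the 3rd derivative on (0, t_max]"
  }
  lo <- grid[max(idx - 1L, 1L)]
  hi <- grid[min(idx + 1L, length(grid))]
  opt <- stats::optimize(function(tt) predict_double_gaussian(fit, tt, 3L),
                         lower = lo, upper = hi)
  structure(opt$minimum, flag = flag, f3 = opt$objective)
}
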