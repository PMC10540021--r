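#' 95% credible band around a score series
#'
#' Per-assessment credible intervals from the normal approximation to
#' each score's posterior: `eap_i +/- z * se_i` with
#' `z = qnorm((1 + level) / 2)` (1.959964 at the default 95% level).
#'
#' @param series data frame with columns `time` (numeric or
#'   `POSIXct`, strictly increasing), `eap`, `se` (positive).
#' @param level credible level in (0, 1).
#' @return the series with columns `lower`, `upper` appended.
#' @export
credible_band <- function(series, level = 0.95) {
  series <- validate_series(series)
  if (!is.numeric(level) || length(level) != 1L ||
      level <= 0 || level >= 1)
    stop("level must lie strictly between 0 and 1")
  z <- if (identical(level, 0.95)) Z95 else stats::qnorm((1 + level) / 2)
  series$lower <- series$eap - z * series$se
  series$upper <- series$eap + z * series$se
  series
}

#' Posterior density surface over time
#'
#' Stacks per-assessment posterior densities (all on one shared theta
#' grid) into a time-by-theta matrix whose dark ridges trace where the
#' patient's true symptom level most plausibly lies. Each time slice
#' is (re)normalized to integrate to 1 under the grid weights.
#'
#' @param densities list of numeric vectors, one gridded density per
#'   assessment, each over `grid$theta`.
#' @param times vector of assessment times (any orderable type), same
#'   length as `densities`.
#' @param grid the shared [quad_grid()].
#' @return object of class `density_surface`: list with `times`,
#'   `theta`, and `density` (matrix, `length(times)` rows by
#'   `length(theta)` columns).
#' @export
density_surface <- function(densities, times, grid) {
  if (length(densities) == 0L) stop("no densities supplied")
  if (length(densities) != length(times))
    stop("densities and times differ in length")
  m <- length(grid$theta)
  if (any(vapply(densities, length, integer(1)) != m))
    stop("all densities must share the quadrature grid (", m, " points)")
  dens <- do.call(rbind, lapply(densities, function(d) {
    if (any(d < 0)) stop("negative density value")
    z <- sum(grid$weights * d)
    if (z <= 0) stop("slice integrates to zero")
    d / z
  }))
  structure(list(times = times, theta = grid$theta, density = dens,
                 weights = grid$weights),
            class = "density_surface")
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf("<density_surface> %d time slice(s) x %d theta points\n",
              nrow(x$density), ncol(x$density)))
  invisible(x)
}

#' LOESS smoothing of a score series with a t-based SE band
#'
#' Locally estimated scatterplot smoothing of the EAP trajectory:
#' tricube-weighted local polynomial least squares over the
#' span-nearest neighbours of each evaluation time (via
#' [stats::loess()] with exact direct fitting), with a symmetric
#' confidence band `fit +/- t * se(fit)` where the multiplier is the
#' two-sided t quantile at the fit's residual (look-up) degrees of
#' freedom. Useful when the patient's symptoms are expected to follow
#' a smoother course than the raw momentary scores.
#'
#' @param series data frame with columns `time`, `eap` (`se` optional
#'   and unused by the fit: LOESS models trajectory-level error).
#' @param span fraction of points in each local neighbourhood
#'   (default 0.75).
#' @param degree local polynomial degree, 0, 1 (default) or 2.
#' @param level band level for the t multiplier (default 0.95).
#' @param eval_times times at which to evaluate the fit; defaults to
#'   the observation times. Must lie within the observed range.
#' @return object of class `smoothed_series`: data frame with columns
#'   `time`, `fit`, `se_fit`, `band_low`, `band_high`, plus attributes
#'   `span`, `degree`, `df`.
#' @export
loess_smooth <- function(series, span = 0.75, degree = 1,
                         level = 0.95, eval_times = NULL) {
  series <- validate_series(series, need_se = FALSE)
  n <- nrow(series)
  if (n < degree + 2L)
    stop("need at least ", degree + 2L, " points for degree ", degree)
  if (floor(span * n) < degree + 1L)
    stop("span too small: span * n must be at least ", degree + 1L)
  x <- as.numeric(series$time)
  if (is.null(eval_times)) eval_times <- series$time
  xe <- as.numeric(eval_times)
  if (any(xe < min(x)) || any(xe > max(x)))
    stop("evaluation times must lie within the observed time range")
  # exact fits (collinear or constant input) and very small
  # neighbourhoods make the local solves singular; loess falls back to
  # a pseudoinverse and warns — expected here, so muffle that family
  muffle_degenerate <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      if (grepl("condition number|pseudoinverse|neighborhood|singular",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  fit <- muffle_degenerate(
    stats::loess(eap ~ x, data.frame(x = x, eap = series$eap),
                 span = span, degree = degree, family = "gaussian",
                 control = stats::loess.control(
                   surface = "direct", statistics = "exact")))
  pr <- muffle_degenerate(
    stats::predict(fit, data.frame(x = xe), se = TRUE))
  tmult <- stats::qt((1 + level) / 2, pr$df)
  out <- data.frame(time = eval_times, fit = pr$fit, se_fit = pr$se.fit,
                    band_low = pr$fit - tmult * pr$se.fit,
                    band_high = pr$fit + tmult * pr$se.fit)
  structure(out, span = span, degree = degree, df = pr$df,
            class = c("smoothed_series", "data.frame"))
}

#' Overlay a target trajectory on a cohort envelope
#'
#' Evaluates every comparison series on a common time grid by linear
#' interpolation (within each series' own observed range only — no
#' extrapolation) and reduces them to a pointwise min / median / max
#' envelope, the backdrop against which an individual's trajectory is
#' displayed.
#'
#' @param target data frame with columns `time`, `eap` (the
#'   highlighted respondent).
#' @param others list of such data frames (the rest of the cohort).
#' @param time_grid numeric or `POSIXct` vector of evaluation times.
#' @return object of class `cohort_overlay`: list with `grid` (data
#'   frame `time, env_min, env_median, env_max, n_series`), `target`,
#'   and `others_interp` (matrix of interpolated cohort values, one
#'   row per series).
#' @export
cohort_overlay <- function(target, others, time_grid) {
  if (length(time_grid) == 0L) stop("empty time grid")
  if (length(others) == 0L) stop("need at least one comparison series")
  target <- validate_series(target, need_se = FALSE)
  tg <- as.numeric(time_grid)
  vals <- do.call(rbind, lapply(others, function(s) {
    s <- validate_series(s, need_se = FALSE)
    x <- as.numeric(s$time)
    y <- stats::approx(x, s$eap, xout = tg, rule = 1)$y  # NA outside range
    y
  }))
  env <- data.frame(
    time = time_grid,
    env_min = apply(vals, 2L, function(v)
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)),
    env_median = apply(vals, 2L, function(v)
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)),
    env_max = apply(vals, 2L, function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)),
    n_series = apply(vals, 2L, function(v) sum(!is.na(v))))
  structure(list(grid = env, target = target, others_interp = vals),
            class = "cohort_overlay")
}

#' Plot a score trajectory with its uncertainty band
#'
#' Line-and-ribbon display of a respondent's score series: points at
#' each EAP estimate, a shaded 95% credible band, optionally a LOESS
#' smooth and a gray cohort backdrop. Requires ggplot2 (suggested).
#'
#' @param series data frame with `time`, `eap`, `se`.
#' @param smooth optional `smoothed_series` from [loess_smooth()].
#' @param overlay optional `cohort_overlay`.
#' @param level credible level for the per-point band.
#' @return a ggplot object.
#' @export
plot_trajectory <- function(series, smooth = NULL, overlay = NULL,
                            level = 0.95) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_trajectory requires the ggplot2 package")
  band <- credible_band(series, level)
  p <- ggplot2::ggplot(band, ggplot2::aes(x = time, y = eap))
  if (!is.null(overlay)) {
    ov <- as.data.frame(t(overlay$others_interp))
    ov$time <- overlay$grid$time
    long <- stats::reshape(ov, direction = "long",
                           varying = seq_len(ncol(ov) - 1L),
                           v.names = "eap", timevar = "series")
    p <- p + ggplot2::geom_line(
      data = long[!is.na(long$eap), ],
      ggplot2::aes(group = series), colour = "gray70")
  }
  p <- p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         alpha = 0.2, fill = "firebrick") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::geom_line(colour = "firebrick", linewidth = 0.3)
  if (!is.null(smooth))
    p <- p + ggplot2::geom_line(
      data = as.data.frame(smooth),
      ggplot2::aes(x = time, y = fit), colour = "black")
  p + ggplot2::labs(x = "time", y = "severity (z score)")
}

# shared series validation: time strictly increasing, se positive
validate_series <- function(series, need_se = TRUE) {
  series <- as.data.frame(series)
  need <- c("time", "eap", if (need_se) "se")
  if (!all(need %in% names(series)))
    stop("series must have columns: ", paste(need, collapse = ", "))
  if (nrow(series) == 0L) stop("empty series")
  if (is.unsorted(as.numeric(series$time), strictly = TRUE))
    stop("series timestamps must be strictly increasing")
  if (need_se && any(series$se <= 0))
    stop("series se values must be positive")
  series
}
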