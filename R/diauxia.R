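# Diauxia detection: analytic second derivative of the active-complex curve,
# sign-change (inflection) counting, classification, threshold-crossing
# activation metrics, and the same analysis for smoothed empirical curves.
#
# An activation curve is called diauxic when it has more than one inflection
# point: the rise pauses and resumes, as in two-phase microbial growth.

#' Analytic second derivative of the active-complex curve
#'
#' Differentiates \eqn{\dot x_a = \alpha_2 x_n y_a} once more along the flow,
#' substituting the model right-hand side for \eqn{\dot x_n} and
#' \eqn{\dot y_a}:
#' \eqn{\ddot x_a = \alpha_2 (\dot x_n y_a + x_n \dot y_a)}. For the reduced
#' system \eqn{x_n = 1-\gamma+z-x_a} so \eqn{\dot x_n = \dot z - \dot x_a}.
#' Because the derivative is evaluated analytically at each recorded state,
#' its zeros reflect the model, not differencing noise.
#'
#' @param traj A `trajectory` from the non-dimensional full or reduced
#'   variant (the dimensional variant is not supported).
#' @return Numeric vector of second-derivative values aligned to
#'   `traj$times`.
#' @export
second_derivative_xa <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  p <- traj$params
  st <- traj$states
  rownames(st) <- NULL
  if (traj$variant == "nondimensional") {
    f <- hill_rate(st[, "xa"], p$hill)
    seq6 <- p$alpha4 * f * st[, "xn"] * st[, "z"] - p$delta * st[, "w"]
    dxn <- p$alpha1 * st[, "x"] * st[, "c"] -
      p$alpha2 * st[, "xn"] * st[, "ya"] - seq6
    dya <- p$alpha3 * st[, "xa"] * st[, "yn"]
    p$alpha2 * (dxn * st[, "ya"] + st[, "xn"] * dya)
  } else if (traj$variant == "reduced") {
    xn <- 1 - p$gamma + st[, "z"] - st[, "xa"]
    f <- hill_rate(st[, "xa"], p$hill)
    dxa <- p$alpha2 * xn * st[, "ya"]
    dya <- p$alpha3 * st[, "xa"] * (1 - st[, "ya"])
    dz <- -p$alpha4 * f * xn * st[, "z"] + p$delta * (p$gamma - st[, "z"])
    dxn <- dz - dxa
    p$alpha2 * (dxn * st[, "ya"] + xn * dya)
  } else {
    stop("second_derivative_xa: unsupported trajectory variant '",
         traj$variant, "'", call. = FALSE)
  }
}

#' Count sign changes (inflection points) of a second-derivative series
#'
#' Values within `deadband` of zero are ignored; a sign change is counted
#' between consecutive runs of opposite sign whose lengths are at least
#' `persistence` grid points, which suppresses round-off chatter near zero.
#' A zero at the start of the series is not counted as a change. The
#' reported `times` interpolate the zero crossing linearly between the
#' samples flanking each change.
#'
#' @param values Second-derivative values.
#' @param times Time grid aligned to `values`.
#' @param deadband Magnitude below which values count as zero; default
#'   `1e-10 * max(abs(values))`.
#' @param persistence Minimum run length (grid points) for a sign run to
#'   count.
#' @return An `inflection_report`: list with `count`, `times`,
#'   `initial_sign` (sign of the first above-deadband run, 0 if none),
#'   `is_diauxic` (`count >= 2`), and the settings used.
#' @export
count_inflections <- function(values, times, deadband = NULL,
                              persistence = 5L) {
  if (length(values) != length(times))
    stop("count_inflections: values and times must have equal length",
         call. = FALSE)
  if (is.null(deadband)) deadband <- 1e-10 * max(abs(values), 0)
  sg <- integer(length(values))
  sg[values > deadband] <- 1L
  sg[values < -deadband] <- -1L
  nz <- which(sg != 0L)
  if (!length(nz)) {
    warning("count_inflections: all values within the deadband ",
            "(degenerate curve)", call. = FALSE)
    return(new_inflection_report(0L, numeric(0), 0L, deadband, persistence))
  }
  r <- rle(sg[nz])
  keep <- r$lengths >= persistence
  signs <- r$values[keep]
  if (!length(signs))
    return(new_inflection_report(0L, numeric(0), 0L, deadband, persistence))
  # indices (into nz) of run boundaries, for locating each crossing
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  kept_start <- run_start[keep]
  kept_end <- run_end[keep]
  cross_times <- numeric(0)
  cnt <- 0L
  for (j in seq_along(signs)[-1L]) {
    if (signs[j] != signs[j - 1L]) {
      cnt <- cnt + 1L
      i_prev <- nz[kept_end[j - 1L]]   # last sample of the previous run
      i_next <- nz[kept_start[j]]      # first sample of the new run
      v0 <- values[i_prev]; v1 <- values[i_next]
      frac <- if (v1 != v0) v0 / (v0 - v1) else 0.5
      cross_times <- c(cross_times,
                       times[i_prev] + frac * (times[i_next] - times[i_prev]))
    }
  }
  new_inflection_report(cnt, cross_times, signs[1L], deadband, persistence)
}

new_inflection_report <- function(count, times, initial_sign, deadband,
                                  persistence) {
  structure(list(count = as.integer(count), times = times,
                 initial_sign = as.integer(initial_sign),
                 is_diauxic = count >= 2L,
                 deadband = deadband, persistence = as.integer(persistence)),
            class = "inflection_report")
}

#' Inflection report for a simulated trajectory
#'
#' Convenience wrapper: [second_derivative_xa()] followed by
#' [count_inflections()].
#'
#' @param traj A non-dimensional or reduced `trajectory`.
#' @param ... Passed to [count_inflections()].
#' @return An `inflection_report`.
#' @export
trajectory_inflections <- function(traj, ...) {
  count_inflections(second_derivative_xa(traj), traj$times, ...)
}

#' Classify an activation curve as diauxic
#'
#' A curve is diauxic when it has more than one inflection point.
#'
#' @param report An `inflection_report`.
#' @return `TRUE` iff `report$count >= 2`.
#' @export
classify_diauxic <- function(report) {
  stopifnot(inherits(report, "inflection_report"))
  report$count >= 2L
}

#' Inflection analysis of an empirical activity curve
#'
#' Smooths the raw readings (centred moving average of width `window`, then
#' a smoothing spline), evaluates the spline's second derivative on a
#' refined grid, and counts sign changes as for simulated curves. Intended
#' for kinase-activity time courses sampled every few minutes.
#'
#' If the smoothed curve's total range does not clearly exceed the estimated
#' measurement noise (residual of the moving average), the curve carries no
#' resolvable activation signal: a degenerate-curve warning is issued and
#' the count is 0.
#'
#' The default deadband is `1e-3` of the peak second-derivative magnitude —
#' wider than for analytic model derivatives, because spline curvature
#' estimates carry boundary and lack-of-fit artifacts at that level. With
#' the default `spline_smoothing = NULL` the spar is chosen by generalised
#' cross-validation, which is reliable for clean or mildly noisy curves;
#' for noisy curves GCV tends to under-smooth (the moving average leaves
#' correlated residuals) and an explicit `spline_smoothing` around 0.6-0.8
#' is advisable.
#'
#' @param curve A `curve_series` (see [curve_series()]) or a data frame with
#'   columns `time` and `activity`.
#' @param window Moving-average width in samples (odd integers behave most
#'   predictably; width 1 disables the pre-smoothing).
#' @param spline_smoothing Smoothing-spline parameter passed to
#'   [stats::smooth.spline()] as `spar` (0 = interpolating end of the range);
#'   `NULL` selects it by generalised cross-validation.
#' @param persistence,deadband Passed to [count_inflections()] (defaults:
#'   persistence 5 on the refined grid, deadband `1e-3` of the peak
#'   magnitude).
#' @param refine Evaluation-grid refinement factor for the spline's second
#'   derivative.
#' @return An `inflection_report` with the smoothed values attached as
#'   attribute `smoothed`.
#' @export
empirical_curve_inflections <- function(curve, window = 5L,
                                        spline_smoothing = NULL,
                                        persistence = 5L, deadband = NULL,
                                        refine = 10L) {
  curve <- as_curve_series(curve)
  n <- length(curve$times)
  if (n < 7L)
    stop("empirical_curve_inflections: at least 7 samples required",
         call. = FALSE)
  window <- max(1L, as.integer(window))
  sm <- moving_average(curve$values, window)
  noise_sd <- stats::sd(curve$values - sm)
  if (diff(range(sm)) <= max(6 * noise_sd, 1e-12)) {
    warning("empirical_curve_inflections: curve range does not exceed the ",
            "noise level (degenerate curve)", call. = FALSE)
    rep <- new_inflection_report(0L, numeric(0), 0L, NA_real_, persistence)
    attr(rep, "smoothed") <- sm
    return(rep)
  }
  fit <- stats::smooth.spline(curve$times, sm, spar = spline_smoothing)
  grid <- seq(min(curve$times), max(curve$times),
              length.out = max(refine * n, 100L))
  d2 <- stats::predict(fit, grid, deriv = 2L)$y
  if (is.null(deadband)) deadband <- 1e-3 * max(abs(d2))
  rep <- count_inflections(d2, grid, deadband = deadband,
                           persistence = persistence)
  attr(rep, "smoothed") <- stats::predict(fit, curve$times)$y
  rep
}

# Centred moving average with shrinking windows at the edges.
moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Activation timing metrics of a trajectory
#'
#' Times at which the active-complex level first crosses 10%, 50% and 90% of
#' its final value, found by linear interpolation on the recorded grid. If
#' the final level is indistinguishable from zero (activation never starts)
#' all crossing times are reported as `NA`. A warning is issued when the
#' curve is not non-decreasing overall.
#'
#' @param traj A non-dimensional, reduced or dimensional `trajectory`.
#' @return List with `t10`, `t50`, `t90`, `final_xa`.
#' @export
activation_metrics <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  xa <- traj$states[, "xa"]
  tt <- traj$times
  final <- xa[length(xa)]
  scale <- max(abs(xa), 1e-300)
  if (min(diff(xa)) < -1e-6 * scale)
    warning("activation_metrics: xa is not non-decreasing overall",
            call. = FALSE)
  crossing <- function(q) {
    thr <- q * final
    if (final <= 1e-9) return(NA_real_)
    i <- which(xa >= thr)[1L]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(tt[1L])
    frac <- (thr - xa[i - 1L]) / (xa[i] - xa[i - 1L])
    tt[i - 1L] + frac * (tt[i] - tt[i - 1L])
  }
  list(t10 = crossing(0.10), t50 = crossing(0.50), t90 = crossing(0.90),
       final_xa = final)
}

#' @export
print.inflection_report <- function(x, ...) {
  cat(sprintf("Inflection report: %d sign change(s)%s\n", x$count,
              if (x$is_diauxic) " -- diauxic" else ""))
  if (x$count > 0)
    cat("  at t =", paste(signif(x$times, 5), collapse = ", "), "\n")
  cat("  initial second-derivative sign:", x$initial_sign, "\n")
  invisible(x)
}

#' Write an inflection report as JSON
#'
#' @param report An `inflection_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inflection_json <- function(report, path) {
  stopifnot(inherits(report, "inflection_report"))
  jsonlite::write_json(
    list(count = report$count, times = as.numeric(report$times),
         initial_sign = report$initial_sign,
         is_diauxic = report$is_diauxic),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Empirical activity curves
#'
#' A light container for (time, activity) series such as kinase-activity
#' readings, with an optional smoothed version.
#'
#' @param times Strictly increasing sampling times.
#' @param values Activity readings (arbitrary units), same length.
#' @param smoothed Optional smoothed values.
#' @return A `curve_series` object.
#' @export
curve_series <- function(times, values, smoothed = NULL) {
  if (length(times) != length(values))
    stop("curve_series: times and values must have equal length",
         call. = FALSE)
  if (any(diff(times) <= 0))
    stop("curve_series: times must be strictly increasing", call. = FALSE)
  if (!is.null(smoothed) && length(smoothed) != length(times))
    stop("curve_series: smoothed must match times in length", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 smoothed = smoothed),
            class = "curve_series")
}

as_curve_series <- function(x) {
  if (inherits(x, "curve_series")) return(x)
  if (is.data.frame(x) && all(c("time", "activity") %in% names(x)))
    return(curve_series(x$time, x$activity))
  stop("expected a curve_series or a data frame with columns time, activity",
       call. = FALSE)
}

#' Read and write empirical curves as two-column CSV
#'
#' The format is a header `time,activity` followed by one row per sample.
#'
#' @param path CSV file path.
#' @return `read_curve_csv()` returns a `curve_series`;
#'   `write_curve_csv()` returns `path` invisibly.
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path))
    stop("curve CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("time", "activity") %in% names(df)))
    stop("curve CSV must have columns 'time' and 'activity'", call. = FALSE)
  curve_series(df$time, df$activity)
}

#' @param curve A `curve_series`.
#' @rdname read_curve_csv
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "curve_series"))
  txt <- sprintf("%.15g,%.15g", curve$times, curve$values)
  writeLines(c("time,activity", txt), path)
  invisible(path)
}
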