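# Fixed-step classical Runge-Kutta (RK4) integration with trajectory
# recording, steady-state stopping, conservation checking and empirical
# global-error estimation.

#' Integration settings
#'
#' @param h Step size in model time units (positive). The default 1/1000 is
#'   the reference step used for all headline analyses.
#' @param t_max Integration horizon (positive, `h <= t_max`).
#' @param steady_state_tol Stop when the max-norm of the right-hand side
#'   falls below this tolerance; set to `0` to always run to `t_max`.
#' @param record_stride Record every `record_stride`-th accepted step
#'   (integer >= 1); the initial and final states are always recorded.
#' @return An object of class `integration_config`.
#' @export
integration_config <- function(h = 1e-3, t_max = 200,
                               steady_state_tol = 1e-8, record_stride = 1L) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("integration_config: h must be a positive scalar", call. = FALSE)
  if (!is.numeric(t_max) || length(t_max) != 1L || !is.finite(t_max) ||
      t_max <= 0 || h > t_max)
    stop("integration_config: t_max must be positive with h <= t_max",
         call. = FALSE)
  if (!is.numeric(steady_state_tol) || steady_state_tol < 0)
    stop("integration_config: steady_state_tol must be >= 0", call. = FALSE)
  record_stride <- as.integer(record_stride)
  if (is.na(record_stride) || record_stride < 1L)
    stop("integration_config: record_stride must be an integer >= 1",
         call. = FALSE)
  structure(list(h = h, t_max = t_max, steady_state_tol = steady_state_tol,
                 record_stride = record_stride),
            class = "integration_config")
}

#' One classical fourth-order Runge-Kutta step
#'
#' Four stage evaluations combined with Simpson weights (1, 2, 2, 1)/6.
#'
#' @param state Current state vector.
#' @param t Current time.
#' @param h Step size (positive).
#' @param rhs Derivative function with signature `rhs(t, state)`.
#' @return The state advanced to `t + h`.
#' @export
rk4_step <- function(state, t, h, rhs) {
  if (!is.numeric(h) || h <= 0)
    stop("rk4_step: h must be positive", call. = FALSE)
  k1 <- rhs(t, state)
  k2 <- rhs(t + h / 2, state + (h / 2) * k1)
  k3 <- rhs(t + h / 2, state + (h / 2) * k2)
  k4 <- rhs(t + h, state + h * k3)
  out <- state + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  if (!all(is.finite(out)))
    stop("rk4_step: non-finite stage values at t = ", signif(t, 6),
         " (step size too large or invalid state)", call. = FALSE)
  out
}

#' Fixed-step RK4 integration of a generic system
#'
#' Marches from `state0` at `t = 0` until `t_max`, or stops earlier once the
#' max-norm of the right-hand side falls below `steady_state_tol` (the
#' steady-state stop makes the result horizon-independent). States are
#' recorded every `record_stride` steps; the final state is always recorded.
#'
#' @param rhs Derivative function `rhs(t, state)` returning a vector the same
#'   length as `state`.
#' @param state0 Initial state (names, if any, are kept on the trajectory).
#' @param config An [integration_config()].
#' @param params Optional parameter record stored on the trajectory.
#' @param variant Label stored on the trajectory
#'   (`"nondimensional"`, `"reduced"`, `"dimensional"` or `"generic"`).
#' @return A `trajectory` object: a list with `times` (strictly increasing
#'   grid), `states` (matrix, one row per recorded time), `params`,
#'   `variant`, `h`, and `steady_state` (whether the stop rule fired).
#' @seealso [simulate_model()] for the model-aware front end.
#' @export
rk4_integrate <- function(rhs, state0, config = integration_config(),
                          params = NULL, variant = "generic") {
  stopifnot(inherits(config, "integration_config"))
  h <- config$h
  stride <- config$record_stride
  tol <- config$steady_state_tol
  n_max <- ceiling(config$t_max / h - 1e-9)
  d <- length(state0)
  n_rec <- n_max %/% stride + 2L
  states <- matrix(NA_real_, n_rec, d)
  times <- numeric(n_rec)
  s <- as.numeric(state0)
  states[1L, ] <- s
  times[1L] <- 0
  nrec <- 1L
  steady <- FALSE
  i <- 0L
  while (TRUE) {
    k1 <- rhs(i * h, s)
    if (tol > 0 && max(abs(k1)) < tol) { steady <- TRUE; break }
    if (i >= n_max) break
    # reuse k1: remaining three RK4 stages
    t0 <- i * h
    k2 <- rhs(t0 + h / 2, s + (h / 2) * k1)
    k3 <- rhs(t0 + h / 2, s + (h / 2) * k2)
    k4 <- rhs(t0 + h, s + h * k3)
    s <- s + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(s)))
      stop("rk4_integrate: non-finite state at t = ", signif(t0 + h, 6),
           call. = FALSE)
    i <- i + 1L
    if (i %% stride == 0L) {
      nrec <- nrec + 1L
      states[nrec, ] <- s
      times[nrec] <- i * h
    }
  }
  if (times[nrec] < i * h) {  # record the final state off-stride
    nrec <- nrec + 1L
    states[nrec, ] <- s
    times[nrec] <- i * h
  }
  states <- states[seq_len(nrec), , drop = FALSE]
  colnames(states) <- names(state0)
  structure(list(times = times[seq_len(nrec)], states = states,
                 params = params, variant = variant, h = h,
                 steady_state = steady),
            class = "trajectory")
}

#' Simulate the mitotic-entry model
#'
#' Wires the chosen right-hand-side variant and its default initial state to
#' the fixed-step RK4 integrator, and verifies the conservation laws on the
#' result. For the non-dimensional variant the sums `xa + xn + x + w`,
#' `ya + yn` and `z + w` must stay within `1e-6` of their initial values
#' (drift beyond that aborts — it signals a step size too large); the
#' dimensional variant is checked against its totals, and the reduced
#' variant's implied `xn` must stay non-negative to tolerance.
#'
#' @param p A [nondim_params()] (variants `"nondimensional"`, `"reduced"`) or
#'   [dimensional_params()] (variant `"dimensional"`) object.
#' @param variant Which system to integrate.
#' @param config An [integration_config()].
#' @param state0 Optional initial state; defaults to
#'   [default_initial_state()] / [reduced_initial_state()] (dimensional mode
#'   scales the non-dimensional default by the totals).
#' @return A `trajectory` (see [rk4_integrate()]); its `conservation_drift`
#'   element records the worst deviation observed.
#' @examples
#' \donttest{
#' tr <- simulate_model(nondim_params(), "reduced",
#'                      integration_config(h = 1e-2))
#' utils::tail(as.data.frame(tr), 1)
#' }
#' @export
simulate_model <- function(p,
                           variant = c("nondimensional", "reduced",
                                       "dimensional"),
                           config = integration_config(),
                           state0 = NULL) {
  variant <- match.arg(variant)
  if (variant == "dimensional") {
    stopifnot(inherits(p, "dimensional_params"))
    validate_dimensional_params(p)
  } else {
    stopifnot(inherits(p, "nondim_params"))
    validate_nondim_params(p)
  }
  omega <- p$hill$omega; nu <- p$hill$nu; k <- p$hill$k; vth <- p$hill$vth
  if (variant == "reduced") {
    if (is.null(state0)) state0 <- reduced_initial_state(p)
    a2 <- p$alpha2; a3 <- p$alpha3; a4 <- p$alpha4
    delta <- p$delta; gamma <- p$gamma
    rhs <- function(t, s) {
      xn <- 1 - gamma + s[3L] - s[1L]
      f <- if (s[1L] <= 0) omega else omega + nu / (1 + (vth / s[1L])^k)
      c(a2 * xn * s[2L],
        a3 * s[1L] * (1 - s[2L]),
        -a4 * f * xn * s[3L] + delta * (gamma - s[3L]))
    }
  } else {
    a1 <- p$alpha1; a2 <- p$alpha2; a3 <- p$alpha3; a4 <- p$alpha4
    delta <- p$delta
    if (variant == "dimensional") {
      beta <- p$beta; kcycb <- p$K_CYCB
      if (is.null(state0)) {
        np <- nondimensionalize(p)
        state0 <- dimensionalize_state(default_initial_state(np),
                                       attr(np, "scales"))
      }
    } else {
      beta <- 1; kcycb <- 1
      if (is.null(state0)) state0 <- default_initial_state(p)
    }
    rhs <- function(t, s) {
      xa <- s[2L]
      f <- if (xa <= 0) omega else omega + nu / (1 + (vth / xa)^k)
      bind <- a1 * s[1L] * s[8L]
      act <- a2 * s[3L] * s[4L]
      fb <- a3 * xa * s[5L]
      seq6 <- a4 * f * s[3L] * s[6L] - delta * s[7L]
      c(-bind, act, bind - act - seq6, fb, -fb, -seq6, seq6,
        -bind + beta * (kcycb - s[8L]))
    }
  }
  tr <- rk4_integrate(rhs, state0, config, params = p, variant = variant)
  tr$conservation_drift <- check_conservation(tr, hard_tol = 1e-6)
  tr
}

#' Conservation drift along a trajectory
#'
#' Largest absolute deviation of the conserved sums from their initial
#' values over all recorded times (non-dimensional: `xa+xn+x+w`, `ya+yn`,
#' `z+w`; dimensional: the same sums against the totals). For the reduced
#' variant the checked quantity is violation of the state bounds
#' (`xa, ya` in `[0, 1]`, `z` in `[0, gamma]`, implied `xn >= 0`).
#'
#' @param traj A `trajectory`.
#' @param hard_tol If the drift exceeds this, abort with an error
#'   (`Inf` disables).
#' @return The maximum drift (invisible errors aside).
#' @export
check_conservation <- function(traj, hard_tol = Inf) {
  st <- traj$states
  drift <- if (traj$variant %in% c("nondimensional", "dimensional")) {
    sums <- cbind(st[, "x"] + st[, "xa"] + st[, "xn"] + st[, "w"],
                  st[, "ya"] + st[, "yn"],
                  st[, "z"] + st[, "w"])
    max(abs(sweep(sums, 2L, sums[1L, ])))
  } else if (traj$variant == "reduced") {
    gamma <- traj$params$gamma
    xn <- 1 - gamma + st[, "z"] - st[, "xa"]
    max(0, -min(st[, "xa"]), st[, "xa"] - 1, -min(st[, "ya"]),
        st[, "ya"] - 1, -min(st[, "z"]), st[, "z"] - gamma, -min(xn))
  } else {
    0
  }
  if (drift > hard_tol)
    stop("conservation drift ", signif(drift, 4), " exceeds ",
         signif(hard_tol, 4), "; reduce the step size", call. = FALSE)
  drift
}

#' Empirical global-error coefficient of the RK4 scheme
#'
#' Integrates the same initial-value problem at step `h` and at a much finer
#' reference step `h_ref` over a fixed horizon, aligns the two grids and
#' reports the maximum absolute difference over all grid points and state
#' components, together with the implied error coefficient
#' `C = max|error| / h^4`. With a fourth-order scheme the maximum error
#' scales as `C h^4` for small `h`.
#'
#' @param rhs Derivative function `rhs(t, state)`.
#' @param state0 Initial state.
#' @param h Step size under test.
#' @param h_ref Reference step; must satisfy `h_ref <= h / 8` and divide `h`
#'   to give integer grid alignment.
#' @param t_max Common fixed horizon (no steady-state stop, so both runs
#'   share the grid).
#' @return List with `max_error`, `coefficient` (`max_error / h^4`), `h`,
#'   `h_ref` and `t_max`.
#' @export
empirical_error_coefficient <- function(rhs, state0, h, h_ref = h / 16,
                                        t_max = 25) {
  if (h_ref > h / 8 + 1e-15)
    stop("empirical_error_coefficient: h_ref must be <= h/8", call. = FALSE)
  ratio <- h / h_ref
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("empirical_error_coefficient: h must be an integer multiple of ",
         "h_ref (grids would not overlap)", call. = FALSE)
  ratio <- round(ratio)
  cfg <- function(step) integration_config(h = step, t_max = t_max,
                                           steady_state_tol = 0)
  coarse <- rk4_integrate(rhs, state0, cfg(h))
  fine <- rk4_integrate(rhs, state0, cfg(h_ref))
  idx <- seq(1L, nrow(fine$states), by = ratio)
  n <- min(length(idx), nrow(coarse$states))
  err <- max(abs(coarse$states[seq_len(n), , drop = FALSE] -
                   fine$states[idx[seq_len(n)], , drop = FALSE]))
  list(max_error = err, coefficient = err / h^4, h = h, h_ref = h_ref,
       t_max = t_max)
}

#' Observed convergence order of the integrator
#'
#' Estimates the order from global errors at several step sizes against one
#' fine reference grid: the mean slope of `log2(error)` between successive
#' halvings.
#'
#' @param rhs Derivative function `rhs(t, state)`.
#' @param state0 Initial state.
#' @param hs Decreasing step sizes (each an integer multiple of `h_ref`).
#' @param h_ref Common reference step.
#' @param t_max Fixed horizon.
#' @return List with `order` (mean slope), `errors` and `hs`.
#' @export
convergence_order <- function(rhs, state0, hs = c(4e-3, 2e-3, 1e-3),
                              h_ref = min(hs) / 16, t_max = 25) {
  hs <- sort(hs, decreasing = TRUE)
  ratios <- hs / h_ref
  if (any(abs(ratios - round(ratios)) > 1e-9))
    stop("convergence_order: every h must be an integer multiple of h_ref",
         call. = FALSE)
  cfg <- function(step) integration_config(h = step, t_max = t_max,
                                           steady_state_tol = 0)
  fine <- rk4_integrate(rhs, state0, cfg(h_ref))
  errs <- vapply(hs, function(h) {
    coarse <- rk4_integrate(rhs, state0, cfg(h))
    idx <- seq(1L, nrow(fine$states), by = round(h / h_ref))
    n <- min(length(idx), nrow(coarse$states))
    max(abs(coarse$states[seq_len(n), , drop = FALSE] -
              fine$states[idx[seq_len(n)], , drop = FALSE]))
  }, numeric(1))
  slopes <- diff(log(errs)) / diff(log(hs))
  list(order = mean(slopes), errors = errs, hs = hs)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%s variant): %d recorded points, t in [0, %g], h = %g\n",
              x$variant, length(x$times), max(x$times), x$h))
  if (isTRUE(x$steady_state)) cat("  stopped at steady state\n")
  if (!is.null(x$conservation_drift))
    cat(sprintf("  max conservation drift: %.3g\n", x$conservation_drift))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(t = x$times, x$states, check.names = FALSE)
}

#' Export a trajectory as CSV or JSON
#'
#' CSV columns are `t` followed by the state components in the fixed order
#' (`x, xa, xn, ya, yn, z, w, c` for the full systems; `xa, ya, z` reduced),
#' printed with 15 significant digits and no locale-dependent formatting.
#' The JSON form embeds the parameter record.
#'
#' @param traj A `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  txt <- vapply(seq_len(nrow(df)), function(i)
    paste(sprintf("%.15g", as.numeric(df[i, ])), collapse = ","),
    character(1))
  writeLines(c(paste(colnames(df), collapse = ","), txt), path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
write_trajectory_json <- function(traj, path) {
  obj <- list(variant = traj$variant, h = traj$h,
              steady_state = isTRUE(traj$steady_state),
              params = params_as_list(traj$params),
              columns = colnames(traj$states),
              times = traj$times,
              states = unname(apply(traj$states, 1L, as.numeric,
                                    simplify = FALSE)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

params_as_list <- function(p) {
  if (is.null(p)) return(NULL)
  out <- lapply(unclass(p), function(v) if (is.list(v)) unclass(v) else v)
  attr(out, "scales") <- NULL
  out
}

#' Read a trajectory back from CSV
#'
#' @param path CSV file written by [write_trajectory_csv()].
#' @param params,variant Optional metadata to reattach.
#' @return A `trajectory` object.
#' @export
read_trajectory_csv <- function(path, params = NULL, variant = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "t")
    stop("trajectory CSV must start with a 't' column", call. = FALSE)
  st <- as.matrix(df[, -1L, drop = FALSE])
  if (is.null(variant))
    variant <- if (ncol(st) == 3L) "reduced" else "nondimensional"
  times <- df$t
  structure(list(times = times, states = st, params = params,
                 variant = variant,
                 h = if (length(times) > 1L) times[2L] - times[1L] else NA_real_,
                 steady_state = NA),
            class = "trajectory")
}
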