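# Scenario orchestration: with/without-CDC6 comparison, equilibrium
# location (S1 = no activation, S2 = full activation) and numerical
# stability classification on the reduced system.

#' Simulate the model with or without CDC6
#'
#' With CDC6 present the default initial state applies. With CDC6 absent the
#' total CDC6 pool is removed (`gamma = 0`, so `z(0) = 0`, `w(0) = 0`, and
#' the ternary-complex trace `eps_w` is forced to zero), emulating
#' immunodepletion of CDC6 from the extract.
#'
#' @param p A [nondim_params()] object.
#' @param cdc6_present Logical flag.
#' @param config An [integration_config()].
#' @return A `trajectory` of the non-dimensional full system.
#' @export
run_scenario <- function(p, cdc6_present = TRUE,
                         config = integration_config()) {
  stopifnot(inherits(p, "nondim_params"))
  if (!cdc6_present) {
    p <- nondim_params(alpha1 = p$alpha1, alpha2 = p$alpha2,
                       alpha3 = p$alpha3, alpha4 = p$alpha4,
                       delta = p$delta, gamma = 0, hill = p$hill,
                       eps_xa = p$eps_xa, eps_xn = p$eps_xn,
                       eps_ya = p$eps_ya, eps_w = 0)
  }
  if (p$eps_w > p$gamma)
    stop("run_scenario: eps_w exceeds gamma", call. = FALSE)
  simulate_model(p, "nondimensional", config)
}

#' Compare activation with and without CDC6
#'
#' Runs both scenarios with identical settings, extends the
#' earlier-stopping run so that both trajectories share one time grid, and
#' reports the inflection structure, activation metrics and the activation
#' delay `t50(with) - t50(without)` attributable to CDC6.
#'
#' @param p A [nondim_params()] object.
#' @param config An [integration_config()].
#' @param ... Passed to [count_inflections()] via
#'   [trajectory_inflections()].
#' @return A `cdc6_comparison` object: lists `with_cdc6` and `without_cdc6`
#'   (each holding `trajectory`, `inflections`, `metrics`) plus `delay`.
#' @export
compare_cdc6 <- function(p, config = integration_config(), ...) {
  tr_with <- run_scenario(p, TRUE, config)
  tr_without <- run_scenario(p, FALSE, config)
  t_end <- max(max(tr_with$times), max(tr_without$times))
  tr_with <- extend_to(tr_with, t_end, config)
  tr_without <- extend_to(tr_without, t_end, config)
  arm <- function(tr) list(trajectory = tr,
                           inflections = trajectory_inflections(tr, ...),
                           metrics = activation_metrics(tr))
  a <- arm(tr_with)
  b <- arm(tr_without)
  delay <- a$metrics$t50 - b$metrics$t50
  structure(list(with_cdc6 = a, without_cdc6 = b, delay = delay),
            class = "cdc6_comparison")
}

# Continue a steady-state-stopped trajectory on the same grid up to t_end.
extend_to <- function(traj, t_end, config) {
  t_last <- max(traj$times)
  if (t_end - t_last < config$h / 2) return(traj)
  cfg <- integration_config(h = config$h, t_max = t_end - t_last,
                            steady_state_tol = 0,
                            record_stride = config$record_stride)
  s0 <- traj$states[nrow(traj$states), ]
  more <- simulate_model(traj$params, traj$variant, cfg, state0 = s0)
  traj$times <- c(traj$times, t_last + more$times[-1L])
  traj$states <- rbind(traj$states, more$states[-1L, , drop = FALSE])
  traj$steady_state <- more$steady_state
  traj$conservation_drift <- max(traj$conservation_drift,
                                 more$conservation_drift)
  traj
}

#' @export
print.cdc6_comparison <- function(x, ...) {
  cat("CDC6 presence/absence comparison\n")
  cat(sprintf("  with CDC6:    %d inflection point(s), t50 = %s\n",
              x$with_cdc6$inflections$count,
              format(signif(x$with_cdc6$metrics$t50, 5))))
  cat(sprintf("  without CDC6: %d inflection point(s), t50 = %s\n",
              x$without_cdc6$inflections$count,
              format(signif(x$without_cdc6$metrics$t50, 5))))
  cat(sprintf("  activation delay (t50 difference): %s\n",
              format(signif(x$delay, 5))))
  invisible(x)
}

#' Write a CDC6 comparison report as JSON
#'
#' @param cmp A `cdc6_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(cmp, path) {
  stopifnot(inherits(cmp, "cdc6_comparison"))
  arm <- function(a) list(
    inflections = list(count = a$inflections$count,
                       times = as.numeric(a$inflections$times),
                       initial_sign = a$inflections$initial_sign,
                       is_diauxic = a$inflections$is_diauxic),
    metrics = a$metrics,
    t_end = max(a$trajectory$times))
  jsonlite::write_json(list(with_cdc6 = arm(cmp$with_cdc6),
                            without_cdc6 = arm(cmp$without_cdc6),
                            delay = cmp$delay),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Locate the no-activation (S1) and full-activation (S2) equilibria
#'
#' S2 is the fully activated state: all CDK1 in active complexes
#' (`xa = 1`), CDC25 fully active (`ya = 1`), CDC6 unbound (`z = gamma`,
#' `w = 0`) and cyclin B saturated (`c = 1`). S1 is the state reached when
#' the positive feedback never starts (`xa = ya = 0`, all seed traces zero):
#' free CDK1 is exhausted into inactive complexes, cyclin saturates, and
#' CDC6 partitions between free and ternary-complex form by the binding
#' balance at basal rate, `alpha4 omega (1 - w)(gamma - w) = delta w`, a
#' quadratic in `w` solved in closed form (stable root in
#' `[0, min(1, gamma)]`). Both states are verified as fixed points by a
#' residual check on the right-hand side.
#'
#' @param p A [nondim_params()] object.
#' @param residual_tol Maximum allowed max-norm of the right-hand side at
#'   each equilibrium; exceeding it after Newton refinement of the CDC6
#'   partition is an error.
#' @return An `equilibrium_report`: list with `s1`, `s2` (full state
#'   vectors), `s1_residual`, `s2_residual`, and stability classifications
#'   `s1_classification`, `s2_classification` (see [classify_stability()]).
#' @export
find_equilibria <- function(p, residual_tol = 1e-10) {
  stopifnot(inherits(p, "nondim_params"))
  validate_nondim_params(p)
  s2 <- c(x = 0, xa = 1, xn = 0, ya = 1, yn = 0, z = p$gamma, w = 0, c = 1)
  w1 <- s1_cdc6_partition(p)
  s1 <- c(x = 0, xa = 0, xn = 1 - w1, ya = 0, yn = 1, z = p$gamma - w1,
          w = w1, c = 1)
  r1 <- max(abs(rhs_nondimensional(s1, p)))
  r2 <- max(abs(rhs_nondimensional(s2, p)))
  if (r1 > residual_tol || r2 > residual_tol)
    stop("find_equilibria: fixed-point residual above tolerance (S1: ",
         signif(r1, 3), ", S2: ", signif(r2, 3), ")", call. = FALSE)
  st1 <- classify_stability(p, "S1")
  st2 <- classify_stability(p, "S2")
  structure(list(s1 = s1, s2 = s2, s1_residual = r1, s2_residual = r2,
                 s1_classification = st1, s2_classification = st2),
            class = "equilibrium_report")
}

# CDC6 partition at the no-activation equilibrium: w solves
# alpha4*omega*(1 - w)*(gamma - w) = delta*w on [0, min(1, gamma)].
# Stable closed-form quadratic root, polished by Newton.
s1_cdc6_partition <- function(p) {
  a0 <- p$alpha4 * p$hill$omega
  if (a0 == 0 || p$gamma == 0) return(0)
  # a0 w^2 - (a0 (1 + gamma) + delta) w + a0 gamma = 0
  b <- -(a0 * (1 + p$gamma) + p$delta)
  cc <- a0 * p$gamma
  disc <- sqrt(b^2 - 4 * a0 * cc)
  q <- -(b - disc) / 2        # b < 0, so this is the stable combination
  w <- cc / q                 # smaller root, lies in [0, min(1, gamma)]
  g <- function(w) a0 * (1 - w) * (p$gamma - w) - p$delta * w
  gp <- function(w) a0 * (2 * w - 1 - p$gamma) - p$delta
  for (i in 1:3) w <- w - g(w) / gp(w)
  w
}

#' Jacobian of the reduced system
#'
#' Analytic 3x3 Jacobian of the reduced right-hand side at a reduced state
#' `(xa, ya, z)`, using the exact Hill-function derivative.
#'
#' @param state Reduced state `(xa, ya, z)`.
#' @param p A [nondim_params()] object.
#' @return A 3x3 matrix with rows/columns ordered `(xa, ya, z)`.
#' @export
reduced_jacobian <- function(state, p) {
  xa <- state[[1L]]; ya <- state[[2L]]; z <- state[[3L]]
  xn <- 1 - p$gamma + z - xa
  f <- hill_rate(xa, p$hill)
  fp <- hill_derivative(xa, p$hill)
  J <- matrix(0, 3L, 3L, dimnames = list(reduced_state_names,
                                         reduced_state_names))
  J[1L, ] <- c(-p$alpha2 * ya, p$alpha2 * xn, p$alpha2 * ya)
  J[2L, ] <- c(p$alpha3 * (1 - ya), -p$alpha3 * xa, 0)
  J[3L, ] <- c(-p$alpha4 * z * (fp * xn - f), 0,
               -p$alpha4 * f * (xn + z) - p$delta)
  J
}

# d f / d xa of the Hill switch, in the overflow-safe form
# nu*k/xa * r/(1+r)^2 with r = (vth/xa)^k.
hill_derivative <- function(xa, hp) {
  if (xa <= 0) {
    if (hp$k > 1) return(0)
    if (hp$k == 1) return(hp$nu / hp$vth)
    stop("hill_derivative: unbounded at xa = 0 for k < 1", call. = FALSE)
  }
  r <- (hp$vth / xa)^hp$k
  hp$nu * hp$k / xa * r / (1 + r)^2
}

#' Numerical stability classification of an equilibrium
#'
#' Evaluates the reduced-system Jacobian at the equilibrium's reduced
#' coordinates and labels it by the signs of the eigenvalue real parts:
#' `"asymptotically stable"` when all are negative, `"unstable"` when any is
#' positive, `"neutral"` otherwise. Eigenvalues with `|Re| < tol` are
#' reported as neutral directions, not suppressed. The full system has
#' structural neutral directions from its conservation laws, which is why
#' the classification is done on the reduced system.
#'
#' @param p A [nondim_params()] object.
#' @param which `"S1"` or `"S2"`.
#' @param tol Real-part magnitude below which an eigenvalue counts as
#'   neutral.
#' @return A `stability_report`: list with `label`, `eigenvalues`,
#'   `n_neutral`, `jacobian` and the reduced `state`.
#' @export
classify_stability <- function(p, which = c("S2", "S1"), tol = 1e-9) {
  which <- match.arg(which)
  state <- if (which == "S2") {
    c(xa = 1, ya = 1, z = p$gamma)
  } else {
    w1 <- s1_cdc6_partition(p)
    c(xa = 0, ya = 0, z = p$gamma - w1)
  }
  J <- reduced_jacobian(state, p)
  ev <- eigen(J, only.values = TRUE)$values
  re <- Re(ev)
  label <- if (any(re > tol)) {
    "unstable"
  } else if (all(re < -tol)) {
    "asymptotically stable"
  } else {
    "neutral"
  }
  structure(list(label = label, eigenvalues = ev,
                 n_neutral = sum(abs(re) <= tol), jacobian = J,
                 state = state, which = which),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$which, x$label))
  cat("  eigenvalues:", paste(format(signif(x$eigenvalues, 5)),
                              collapse = ", "), "\n")
  if (x$n_neutral > 0)
    cat("  neutral directions:", x$n_neutral, "\n")
  invisible(x)
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("Equilibria of the non-dimensional system\n")
  cat(sprintf("  S1 (no activation):   residual %.2e, %s\n",
              x$s1_residual, x$s1_classification$label))
  cat(sprintf("  S2 (full activation): residual %.2e, %s\n",
              x$s2_residual, x$s2_classification$label))
  invisible(x)
}

#' Write an equilibrium report as JSON
#'
#' @param eq An `equilibrium_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_equilibria_json <- function(eq, path) {
  stopifnot(inherits(eq, "equilibrium_report"))
  arm <- function(s, r, cl) list(
    state = as.list(s), residual = r, stability = cl$label,
    eigenvalues_re = Re(cl$eigenvalues), eigenvalues_im = Im(cl$eigenvalues))
  jsonlite::write_json(
    list(s1 = arm(eq$s1, eq$s1_residual, eq$s1_classification),
         s2 = arm(eq$s2, eq$s2_residual, eq$s2_classification)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Perturb the no-activation equilibrium and integrate
#'
#' Adds a small active-complex trace to S1 and integrates to steady state;
#' with any positive seed the positive feedback ignites and the system
#' leaves S1 for S2. Used to demonstrate numerically that S1 is unstable
#' and S2 attracting.
#'
#' @param p A [nondim_params()] object.
#' @param eps_xa Size of the perturbation on `xa`.
#' @param config An [integration_config()].
#' @return List with the final state, its distance (max-norm) to S2, and the
#'   trajectory.
#' @export
perturb_s1 <- function(p, eps_xa = 1e-6, config = integration_config()) {
  eq <- find_equilibria(p)
  s0 <- eq$s1
  s0[["xa"]] <- s0[["xa"]] + eps_xa
  s0[["xn"]] <- s0[["xn"]] - eps_xa  # keep the CDK1 conservation sum exact
  tr <- simulate_model(p, "nondimensional", config, state0 = s0)
  fin <- tr$states[nrow(tr$states), ]
  list(final = fin, distance_to_s2 = max(abs(fin - eq$s2)), trajectory = tr)
}
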