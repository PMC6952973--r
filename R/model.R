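# Model right-hand sides: the Hill switch, the dimensional and
# non-dimensional eight-species systems, and the reduced three-variable
# system on the post-accumulation manifold (x = 0, c = 1).
#
# State component order is fixed throughout: x, xa, xn, ya, yn, z, w, c
# (free CDK1, active complex, inactive complex, active and inactive CDC25,
# free CDC6, ternary CDK1/CYCB/CDC6 complex, cyclin B). Reduced states are
# (xa, ya, z).

full_state_names <- c("x", "xa", "xn", "ya", "yn", "z", "w", "c")
reduced_state_names <- c("xa", "ya", "z")

#' Hill-switch rate of CDC6 binding
#'
#' Evaluates \eqn{f(x_a) = \omega + \nu x_a^k / (v_{th}^k + x_a^k)}, the
#' activity-dependent rate at which CDC6 binds inactive CDK1/cyclin B. The
#' computation uses the overflow-safe form
#' \eqn{\omega + \nu / (1 + (v_{th}/x_a)^k)} for `xa > 0`.
#'
#' @param xa Active-complex level(s), non-negative (vectorised).
#' @param hp A [hill_params()] object.
#' @return Rate value(s) in `[omega, omega + nu]`, non-decreasing in `xa`.
#' @examples
#' hill_rate(0.25, hill_params())  # midpoint: omega + nu/2
#' @export
hill_rate <- function(xa, hp) {
  validate_hill_params(hp)
  if (!is.numeric(xa) || anyNA(xa) || any(xa < 0))
    stop("hill_rate: xa must be numeric and non-negative", call. = FALSE)
  out <- rep(hp$omega, length(xa))
  pos <- xa > 0
  if (any(pos))
    out[pos] <- hp$omega + hp$nu / (1 + (hp$vth / xa[pos])^hp$k)
  out
}

# Unvalidated scalar Hill evaluation for the integration hot path.
hill_fast <- function(xa, omega, nu, k, vth) {
  if (xa <= 0) return(omega)
  omega + nu / (1 + (vth / xa)^k)
}

#' Time derivatives of the non-dimensional eight-species system
#'
#' Mass-action kinetics of cyclin B binding, CDC25-mediated activation, the
#' CDK1-CDC25 positive feedback, and reversible CDC6 sequestration of
#' inactive complexes with a Hill-switch binding rate. In these units the
#' conservation laws are `xa + xn + x + w = 1`, `ya + yn = 1` and
#' `z + w = gamma`, and cyclin production relaxes as `1 - c`. The returned
#' derivative components of each conserved group cancel exactly.
#'
#' @param state Named numeric vector `(x, xa, xn, ya, yn, z, w, c)`,
#'   non-negative.
#' @param p A [nondim_params()] object.
#' @return Named derivative vector in the same order.
#' @export
rhs_nondimensional <- function(state, p) {
  check_state_full(state)
  x <- state[[1L]]; xa <- state[[2L]]; xn <- state[[3L]]
  ya <- state[[4L]]; yn <- state[[5L]]; z <- state[[6L]]
  w <- state[[7L]]; cc <- state[[8L]]
  f <- hill_fast(xa, p$hill$omega, p$hill$nu, p$hill$k, p$hill$vth)
  bind <- p$alpha1 * x * cc
  act <- p$alpha2 * xn * ya
  fb <- p$alpha3 * xa * yn
  seq6 <- p$alpha4 * f * xn * z - p$delta * w
  c(x = -bind,
    xa = act,
    xn = bind - act - seq6,
    ya = fb,
    yn = -fb,
    z = -seq6,
    w = seq6,
    c = -bind + (1 - cc))
}

#' Time derivatives of the dimensional eight-species system
#'
#' As [rhs_nondimensional()] but in concentration/time units: cyclin B is
#' produced towards its saturation level with turnover rate `beta`
#' (`dc/dt = -alpha1 x c + beta (K_CYCB - c)`), and the Hill threshold `vth`
#' is on the concentration scale. Conserved totals are `K_CDK1`, `K_CDC25`
#' and `K_CDC6`.
#'
#' @param state Named numeric vector `(x, xa, xn, ya, yn, z, w, c)`,
#'   non-negative.
#' @param p A [dimensional_params()] object.
#' @return Named derivative vector in the same order.
#' @export
rhs_dimensional <- function(state, p) {
  check_state_full(state)
  x <- state[[1L]]; xa <- state[[2L]]; xn <- state[[3L]]
  ya <- state[[4L]]; yn <- state[[5L]]; z <- state[[6L]]
  w <- state[[7L]]; cc <- state[[8L]]
  f <- hill_fast(xa, p$hill$omega, p$hill$nu, p$hill$k, p$hill$vth)
  bind <- p$alpha1 * x * cc
  act <- p$alpha2 * xn * ya
  fb <- p$alpha3 * xa * yn
  seq6 <- p$alpha4 * f * xn * z - p$delta * w
  c(x = -bind,
    xa = act,
    xn = bind - act - seq6,
    ya = fb,
    yn = -fb,
    z = -seq6,
    w = seq6,
    c = -bind + p$beta * (p$K_CYCB - cc))
}

#' Time derivatives of the reduced three-variable system
#'
#' On the manifold where free CDK1 is exhausted (`x = 0`) and cyclin B has
#' saturated (`c = 1`), the conservation laws leave three independent
#' variables `(xa, ya, z)` with `xn = 1 - gamma + z - xa`, `w = gamma - z`
#' and `yn = 1 - ya`:
#' \deqn{\dot x_a = \alpha_2 (1-\gamma+z-x_a) y_a,\quad
#'       \dot y_a = \alpha_3 x_a (1-y_a),\quad
#'       \dot z = -\alpha_4 f(x_a)(1-\gamma+z-x_a) z + \delta(\gamma-z).}
#'
#' @param state Named numeric vector `(xa, ya, z)`.
#' @param p A [nondim_params()] object.
#' @param tol Tolerance on the implied inactive-complex level: an implied
#'   `xn < -tol` is a consistency error.
#' @return Named derivative vector `(xa, ya, z)`.
#' @export
rhs_reduced <- function(state, p, tol = 1e-9) {
  if (length(state) != 3L || anyNA(state))
    stop("rhs_reduced: state must be numeric (xa, ya, z)", call. = FALSE)
  xa <- state[[1L]]; ya <- state[[2L]]; z <- state[[3L]]
  xn <- 1 - p$gamma + z - xa
  if (xn < -tol)
    stop("rhs_reduced: implied inactive-complex level is negative (xn = ",
         signif(xn, 4), ")", call. = FALSE)
  f <- hill_fast(xa, p$hill$omega, p$hill$nu, p$hill$k, p$hill$vth)
  c(xa = p$alpha2 * xn * ya,
    ya = p$alpha3 * xa * (1 - ya),
    z = -p$alpha4 * f * xn * z + p$delta * (p$gamma - z))
}

check_state_full <- function(state) {
  if (length(state) != 8L || anyNA(state))
    stop("state must be a numeric vector of the 8 species ",
         "(x, xa, xn, ya, yn, z, w, c)", call. = FALSE)
  invisible(state)
}

#' Default initial state of the non-dimensional system
#'
#' The pre-mitotic initial condition: almost all CDK1 free, small seed traces
#' of active/inactive complex and active CDC25, CDC6 almost entirely unbound,
#' and no cyclin B yet (`c(0) = 0`):
#' `x = 1 - eps_xa - eps_xn - eps_w`, `xa = eps_xa`, `xn = eps_xn`,
#' `ya = eps_ya`, `yn = 1 - eps_ya`, `z = gamma - eps_w`, `w = eps_w`,
#' `c = 0`. All conservation sums hold exactly.
#'
#' @param p A [nondim_params()] object.
#' @return Named state vector `(x, xa, xn, ya, yn, z, w, c)`.
#' @export
default_initial_state <- function(p) {
  stopifnot(inherits(p, "nondim_params"))
  validate_nondim_params(p)
  c(x = 1 - p$eps_xa - p$eps_xn - p$eps_w,
    xa = p$eps_xa, xn = p$eps_xn,
    ya = p$eps_ya, yn = 1 - p$eps_ya,
    z = p$gamma - p$eps_w, w = p$eps_w,
    c = 0)
}

#' Default initial state of the reduced system
#'
#' The reduced coordinates of the default initial condition: the seed traces
#' of active complex and active CDC25, with CDC6 unbound apart from `eps_w`.
#'
#' @param p A [nondim_params()] object.
#' @return Named state vector `(xa, ya, z)`.
#' @export
reduced_initial_state <- function(p) {
  stopifnot(inherits(p, "nondim_params"))
  validate_nondim_params(p)
  c(xa = p$eps_xa, ya = p$eps_ya, z = p$gamma - p$eps_w)
}

#' Embed a reduced state into the full eight-species state
#'
#' Uses the manifold relations `x = 0`, `c = 1`,
#' `xn = 1 - gamma + z - xa`, `w = gamma - z`, `yn = 1 - ya`.
#'
#' @param state Reduced state `(xa, ya, z)`.
#' @param p A [nondim_params()] object.
#' @return Named full state vector.
#' @export
embed_reduced_state <- function(state, p) {
  xa <- state[[1L]]; ya <- state[[2L]]; z <- state[[3L]]
  c(x = 0, xa = xa, xn = 1 - p$gamma + z - xa,
    ya = ya, yn = 1 - ya, z = z, w = p$gamma - z, c = 1)
}
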