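# Parameter records: Hill-switch parameters, non-dimensional and dimensional
# model parameters, the non-dimensionalisation map and config file I/O.

#' Hill-switch parameters for the CDC6 binding rate
#'
#' The rate at which CDC6 binds inactive CDK1/cyclin B complexes is modelled
#' as a Hill function of the active complex level `xa`:
#' \deqn{f(x_a) = \omega + \nu \frac{x_a^k}{v_{th}^k + x_a^k}}
#' so the binding speed jumps from a basal rate `omega` towards
#' `omega + nu` once `xa` crosses the threshold `vth`, with sharpness set by
#' the Hill coefficient `k`.
#'
#' @param omega Basal binding rate when `xa = 0` (non-negative).
#' @param nu Switch amplitude: the rate increase at saturation (non-negative).
#' @param k Hill coefficient controlling switch steepness (positive).
#' @param vth Switch threshold on the active-complex level (positive).
#'
#' @return An object of class `hill_params`.
#' @examples
#' hp <- hill_params()
#' hill_rate(c(0, 0.25, 1), hp)
#' @export
hill_params <- function(omega = 0.6, nu = 8, k = 20, vth = 0.25) {
  hp <- list(omega = omega, nu = nu, k = k, vth = vth)
  validate_hill_params(hp)
  structure(hp, class = "hill_params")
}

validate_hill_params <- function(hp) {
  num <- vapply(hp[c("omega", "nu", "k", "vth")], function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))
  if (!all(num))
    stop("hill_params: omega, nu, k, vth must be finite scalars", call. = FALSE)
  if (hp$omega < 0) stop("hill_params: omega must be >= 0", call. = FALSE)
  if (hp$nu < 0) stop("hill_params: nu must be >= 0", call. = FALSE)
  if (hp$k <= 0) stop("hill_params: k must be > 0", call. = FALSE)
  if (hp$vth <= 0) stop("hill_params: vth must be > 0", call. = FALSE)
  invisible(hp)
}

#' Non-dimensional model parameters
#'
#' Parameters of the rescaled mitotic-entry model, in which all species are
#' fractions of their total pools and time is measured in units of the cyclin
#' B turnover rate. Defaults are the reference parameter set used throughout
#' the package.
#'
#' The four mass-action rates are: `alpha1` (cyclin B binding to CDK1),
#' `alpha2` (activation of inactive complexes by active CDC25),
#' `alpha3` (activation of CDC25 by active complexes, closing the positive
#' feedback loop) and `alpha4` (CDC6 binding of inactive complexes, modulated
#' by the Hill switch). `delta` is the dissociation rate of the ternary
#' CDK1/CYCB/CDC6 complex and `gamma` the total CDC6 pool relative to the
#' total CDK1 pool. The `eps_*` values are the small initial traces of active
#' complex, inactive complex, active CDC25 and ternary complex required to
#' seed the feedback loop.
#'
#' @param alpha1,alpha2,alpha3,alpha4 Non-negative dimensionless rates.
#' @param delta Non-negative dimensionless dissociation rate.
#' @param gamma Non-negative total CDC6 relative to total CDK1.
#' @param hill A [hill_params()] object (threshold on the dimensionless scale).
#' @param eps_xa,eps_xn,eps_ya,eps_w Non-negative initial traces; must satisfy
#'   `eps_xa + eps_xn + eps_w < 1`, `eps_ya <= 1` and `eps_w <= gamma`.
#'
#' @return An object of class `nondim_params`.
#' @examples
#' p <- nondim_params()
#' p$alpha2
#' @export
nondim_params <- function(alpha1 = 1, alpha2 = 30, alpha3 = 1, alpha4 = 7,
                          delta = 4, gamma = 1, hill = hill_params(),
                          eps_xa = 0.001, eps_xn = 0.001,
                          eps_ya = 0, eps_w = 0) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
            alpha4 = alpha4, delta = delta, gamma = gamma, hill = hill,
            eps_xa = eps_xa, eps_xn = eps_xn, eps_ya = eps_ya, eps_w = eps_w)
  validate_nondim_params(p)
  structure(p, class = "nondim_params")
}

validate_nondim_params <- function(p) {
  rates <- c("alpha1", "alpha2", "alpha3", "alpha4", "delta", "gamma",
             "eps_xa", "eps_xn", "eps_ya", "eps_w")
  ok <- vapply(p[rates], function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0, logical(1))
  if (!all(ok))
    stop("nondim_params: ", paste(rates[!ok], collapse = ", "),
         " must be finite non-negative scalars", call. = FALSE)
  validate_hill_params(p$hill)
  if (p$eps_xa + p$eps_xn + p$eps_w >= 1)
    stop("nondim_params: eps_xa + eps_xn + eps_w must be < 1", call. = FALSE)
  if (p$eps_ya > 1)
    stop("nondim_params: eps_ya must be <= 1", call. = FALSE)
  if (p$eps_w > p$gamma)
    stop("nondim_params: eps_w must be <= gamma", call. = FALSE)
  invisible(p)
}

#' Dimensional model parameters
#'
#' Mass-action parameters of the mitotic-entry model in concentration/time
#' units, together with the total pools of CDK1, CDC25, CDC6 and the cyclin B
#' saturation level. The published parameter values are stated on the
#' non-dimensional scale only, so the dimensional defaults use unit totals and
#' unit cyclin turnover (`beta = 1`), under which both modes coincide.
#'
#' @param alpha1,alpha2,alpha3,alpha4 Mass-action rate constants
#'   (per concentration per time, non-negative).
#' @param beta Cyclin B turnover rate (per time, positive).
#' @param delta Ternary-complex dissociation rate (per time, non-negative).
#' @param K_CDK1,K_CDC25,K_CDC6,K_CYCB Total concentrations (positive).
#' @param hill A [hill_params()] object with `vth` on the concentration scale.
#' @param eps_xa,eps_xn,eps_ya,eps_w Initial trace concentrations, within the
#'   corresponding totals.
#'
#' @return An object of class `dimensional_params`.
#' @seealso [nondimensionalize()]
#' @export
dimensional_params <- function(alpha1 = 1, alpha2 = 30, alpha3 = 1,
                               alpha4 = 7, beta = 1, delta = 4,
                               K_CDK1 = 1, K_CDC25 = 1, K_CDC6 = 1,
                               K_CYCB = 1, hill = hill_params(),
                               eps_xa = 0.001, eps_xn = 0.001,
                               eps_ya = 0, eps_w = 0) {
  p <- list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
            alpha4 = alpha4, beta = beta, delta = delta,
            K_CDK1 = K_CDK1, K_CDC25 = K_CDC25, K_CDC6 = K_CDC6,
            K_CYCB = K_CYCB, hill = hill,
            eps_xa = eps_xa, eps_xn = eps_xn, eps_ya = eps_ya, eps_w = eps_w)
  validate_dimensional_params(p)
  structure(p, class = "dimensional_params")
}

validate_dimensional_params <- function(p) {
  pos <- c("beta", "K_CDK1", "K_CDC25", "K_CDC6", "K_CYCB")
  nn <- c("alpha1", "alpha2", "alpha3", "alpha4", "delta",
          "eps_xa", "eps_xn", "eps_ya", "eps_w")
  okp <- vapply(p[pos], function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v > 0, logical(1))
  okn <- vapply(p[nn], function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0, logical(1))
  if (!all(okp))
    stop("dimensional_params: ", paste(pos[!okp], collapse = ", "),
         " must be finite positive scalars", call. = FALSE)
  if (!all(okn))
    stop("dimensional_params: ", paste(nn[!okn], collapse = ", "),
         " must be finite non-negative scalars", call. = FALSE)
  validate_hill_params(p$hill)
  if (p$eps_xa + p$eps_xn + p$eps_w >= p$K_CDK1)
    stop("dimensional_params: initial CDK1 traces exceed K_CDK1", call. = FALSE)
  if (p$eps_ya > p$K_CDC25)
    stop("dimensional_params: eps_ya exceeds K_CDC25", call. = FALSE)
  if (p$eps_w > p$K_CDC6)
    stop("dimensional_params: eps_w exceeds K_CDC6", call. = FALSE)
  invisible(p)
}

#' Non-dimensionalise a dimensional parameter set
#'
#' Rescales all species by their total pools (CDK1-family species, including
#' free CDC6, by `K_CDK1`; CDC25 species by `K_CDC25`; cyclin B by `K_CYCB`)
#' and time by the cyclin turnover rate `beta`. The rate map is
#' `alpha1* = alpha1 K_CYCB / beta`, `alpha2* = alpha2 K_CDC25 / beta`,
#' `alpha3* = alpha3 K_CDK1 / beta`, `alpha4* = alpha4 K_CDK1 / beta`,
#' `delta* = delta / beta`, `gamma = K_CDC6 / K_CDK1` and
#' `vth* = vth / K_CDK1`; `omega` and `nu` are rate multipliers and carry over
#' unchanged.
#'
#' @param p A [dimensional_params()] object.
#' @return A [nondim_params()] object with an attribute `scales` (a list with
#'   `beta`, `K_CDK1`, `K_CDC25`, `K_CDC6`, `K_CYCB`) sufficient to invert the
#'   map with [dimensionalize()].
#' @examples
#' dp <- dimensional_params(alpha2 = 3, K_CDC25 = 10)
#' nondimensionalize(dp)$alpha2  # 30
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "dimensional_params"))
  hp <- hill_params(omega = p$hill$omega, nu = p$hill$nu, k = p$hill$k,
                    vth = p$hill$vth / p$K_CDK1)
  np <- nondim_params(
    alpha1 = p$alpha1 * p$K_CYCB / p$beta,
    alpha2 = p$alpha2 * p$K_CDC25 / p$beta,
    alpha3 = p$alpha3 * p$K_CDK1 / p$beta,
    alpha4 = p$alpha4 * p$K_CDK1 / p$beta,
    delta = p$delta / p$beta,
    gamma = p$K_CDC6 / p$K_CDK1,
    hill = hp,
    eps_xa = p$eps_xa / p$K_CDK1,
    eps_xn = p$eps_xn / p$K_CDK1,
    eps_ya = p$eps_ya / p$K_CDC25,
    eps_w = p$eps_w / p$K_CDK1)
  attr(np, "scales") <- list(beta = p$beta, K_CDK1 = p$K_CDK1,
                             K_CDC25 = p$K_CDC25, K_CDC6 = p$K_CDC6,
                             K_CYCB = p$K_CYCB)
  np
}

#' Invert the non-dimensionalisation
#'
#' @param np A [nondim_params()] object.
#' @param scales The scale record, as stored by [nondimensionalize()] in the
#'   `scales` attribute (the default).
#' @return A [dimensional_params()] object; `nondimensionalize()` followed by
#'   `dimensionalize()` is the identity.
#' @export
dimensionalize <- function(np, scales = attr(np, "scales")) {
  stopifnot(inherits(np, "nondim_params"))
  if (is.null(scales))
    stop("dimensionalize: no scale record available", call. = FALSE)
  s <- scales
  if (abs(np$gamma - s$K_CDC6 / s$K_CDK1) > 1e-12 * max(1, np$gamma))
    stop("dimensionalize: gamma inconsistent with scale record", call. = FALSE)
  dimensional_params(
    alpha1 = np$alpha1 * s$beta / s$K_CYCB,
    alpha2 = np$alpha2 * s$beta / s$K_CDC25,
    alpha3 = np$alpha3 * s$beta / s$K_CDK1,
    alpha4 = np$alpha4 * s$beta / s$K_CDK1,
    beta = s$beta, delta = np$delta * s$beta,
    K_CDK1 = s$K_CDK1, K_CDC25 = s$K_CDC25, K_CDC6 = s$K_CDC6,
    K_CYCB = s$K_CYCB,
    hill = hill_params(omega = np$hill$omega, nu = np$hill$nu, k = np$hill$k,
                       vth = np$hill$vth * s$K_CDK1),
    eps_xa = np$eps_xa * s$K_CDK1, eps_xn = np$eps_xn * s$K_CDK1,
    eps_ya = np$eps_ya * s$K_CDC25, eps_w = np$eps_w * s$K_CDK1)
}

#' Map a dimensional state to the non-dimensional scale (and back)
#'
#' @param state Named state vector in the order
#'   `x, xa, xn, ya, yn, z, w, c`.
#' @param scales Scale record from [nondimensionalize()].
#' @return The rescaled state vector.
#' @export
nondimensionalize_state <- function(state, scales) {
  s <- scales
  fac <- c(x = s$K_CDK1, xa = s$K_CDK1, xn = s$K_CDK1, ya = s$K_CDC25,
           yn = s$K_CDC25, z = s$K_CDK1, w = s$K_CDK1, c = s$K_CYCB)
  state / fac[names(state)]
}

#' @rdname nondimensionalize_state
#' @export
dimensionalize_state <- function(state, scales) {
  s <- scales
  fac <- c(x = s$K_CDK1, xa = s$K_CDK1, xn = s$K_CDK1, ya = s$K_CDC25,
           yn = s$K_CDC25, z = s$K_CDK1, w = s$K_CDK1, c = s$K_CYCB)
  state * fac[names(state)]
}

config_keys <- c("alpha1", "alpha2", "alpha3", "alpha4", "delta", "gamma",
                 "omega", "nu", "k", "vth",
                 "eps_xa", "eps_xn", "eps_ya", "eps_w")

#' Read and write non-dimensional parameter configurations
#'
#' Parameter sets are stored as flat key-value YAML (JSON is a YAML subset
#' and also accepted) with keys `alpha1..alpha4, delta, gamma, omega, nu, k,
#' vth, eps_xa, eps_xn, eps_ya, eps_w`. The configuration bundled at
#' `system.file("extdata", "params-reference.yaml", package = "cdk1diauxia")`
#' holds the reference parameter set.
#'
#' @param path File path.
#' @return `read_params_config()` returns a [nondim_params()] object;
#'   `write_params_config()` returns `path` invisibly.
#' @export
read_params_config <- function(path) {
  if (!file.exists(path))
    stop("parameter config not found: ", path, call. = FALSE)
  kv <- yaml::read_yaml(path)
  missing <- setdiff(config_keys, names(kv))
  if (length(missing))
    stop("parameter config missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(kv), config_keys)
  if (length(extra))
    stop("parameter config has unknown keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  nondim_params(
    alpha1 = kv$alpha1, alpha2 = kv$alpha2, alpha3 = kv$alpha3,
    alpha4 = kv$alpha4, delta = kv$delta, gamma = kv$gamma,
    hill = hill_params(omega = kv$omega, nu = kv$nu, k = kv$k, vth = kv$vth),
    eps_xa = kv$eps_xa, eps_xn = kv$eps_xn,
    eps_ya = kv$eps_ya, eps_w = kv$eps_w)
}

#' @param p A [nondim_params()] object.
#' @rdname read_params_config
#' @export
write_params_config <- function(p, path) {
  stopifnot(inherits(p, "nondim_params"))
  kv <- list(alpha1 = p$alpha1, alpha2 = p$alpha2, alpha3 = p$alpha3,
             alpha4 = p$alpha4, delta = p$delta, gamma = p$gamma,
             omega = p$hill$omega, nu = p$hill$nu, k = p$hill$k,
             vth = p$hill$vth,
             eps_xa = p$eps_xa, eps_xn = p$eps_xn,
             eps_ya = p$eps_ya, eps_w = p$eps_w)
  yaml::write_yaml(kv, path, precision = 15)
  invisible(path)
}

#' @export
print.nondim_params <- function(x, ...) {
  cat("Non-dimensional mitotic-entry model parameters\n")
  cat(sprintf("  alpha1=%g alpha2=%g alpha3=%g alpha4=%g delta=%g gamma=%g\n",
              x$alpha1, x$alpha2, x$alpha3, x$alpha4, x$delta, x$gamma))
  cat(sprintf("  Hill switch: omega=%g nu=%g k=%g vth=%g\n",
              x$hill$omega, x$hill$nu, x$hill$k, x$hill$vth))
  cat(sprintf("  initial traces: eps_xa=%g eps_xn=%g eps_ya=%g eps_w=%g\n",
              x$eps_xa, x$eps_xn, x$eps_ya, x$eps_w))
  invisible(x)
}

#' @export
print.dimensional_params <- function(x, ...) {
  cat("Dimensional mitotic-entry model parameters\n")
  cat(sprintf("  alpha1=%g alpha2=%g alpha3=%g alpha4=%g beta=%g delta=%g\n",
              x$alpha1, x$alpha2, x$alpha3, x$alpha4, x$beta, x$delta))
  cat(sprintf("  totals: K_CDK1=%g K_CDC25=%g K_CDC6=%g K_CYCB=%g\n",
              x$K_CDK1, x$K_CDC25, x$K_CDC6, x$K_CYCB))
  cat(sprintf("  Hill switch: omega=%g nu=%g k=%g vth=%g\n",
              x$hill$omega, x$hill$nu, x$hill$k, x$hill$vth))
  invisible(x)
}
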