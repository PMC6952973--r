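# Synthetic empirical-style activation curves: a double-logistic generator
# whose inflection structure is known in closed form, used to exercise the
# empirical diauxia detector independently of the ODE code.

#' Specification of a synthetic activation curve
#'
#' The curve is the sum of two logistic rises sampled on a uniform grid,
#' optionally with additive Gaussian noise — the canonical shape of a
#' two-phase (diauxic) kinase-activation time course. With well-separated
#' phases the second derivative has the sign pattern `+,-,+,-`, i.e. three
#' sign changes; setting the second phase amplitude to zero
#' (`plateau = phase1_height`) leaves a single logistic with one inflection.
#'
#' Defaults emulate a slow two-phase activation over roughly half an hour of
#' experimental time: a first rise around 8 min to a mid level, a pause, and
#' a second rise around 20 min to the plateau, sampled every half minute
#' with mild measurement noise.
#'
#' @param n_points Number of samples.
#' @param t_end Duration of the sampled window (minutes, arbitrary units).
#' @param phase1_mid,phase2_mid Midpoints of the two rises
#'   (`phase1_mid < phase2_mid`).
#' @param phase1_rate,phase2_rate Logistic steepnesses (positive).
#' @param phase1_height Level reached after the first rise (positive).
#' @param plateau Final level (`>= phase1_height`).
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (non-negative).
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(n_points = 60L, t_end = 30,
                         phase1_mid = 8, phase2_mid = 20,
                         phase1_rate = 1.2, phase2_rate = 1.5,
                         phase1_height = 0.45, plateau = 1,
                         noise_sd = 0.02, seed = 42L) {
  sp <- list(n_points = as.integer(n_points), t_end = t_end,
             phase1_mid = phase1_mid, phase2_mid = phase2_mid,
             phase1_rate = phase1_rate, phase2_rate = phase2_rate,
             phase1_height = phase1_height, plateau = plateau,
             noise_sd = noise_sd, seed = as.integer(seed))
  validate_fixture_spec(sp)
  structure(sp, class = "fixture_spec")
}

validate_fixture_spec <- function(sp) {
  if (sp$n_points < 7L)
    stop("fixture_spec: n_points must be >= 7", call. = FALSE)
  if (!(sp$t_end > 0))
    stop("fixture_spec: t_end must be positive", call. = FALSE)
  if (!(sp$phase1_mid < sp$phase2_mid))
    stop("fixture_spec: phase1_mid must be < phase2_mid", call. = FALSE)
  if (sp$phase1_rate <= 0 || sp$phase2_rate <= 0)
    stop("fixture_spec: rates must be positive", call. = FALSE)
  if (sp$phase1_height <= 0)
    stop("fixture_spec: phase1_height must be positive", call. = FALSE)
  if (sp$plateau < sp$phase1_height)
    stop("fixture_spec: plateau must be >= phase1_height", call. = FALSE)
  if (sp$noise_sd < 0)
    stop("fixture_spec: noise_sd must be >= 0", call. = FALSE)
  invisible(sp)
}

#' Generate a synthetic activation curve
#'
#' @param spec A [fixture_spec()].
#' @param path Optional CSV path; when given, the curve is also written with
#'   [write_curve_csv()].
#' @return A `curve_series`. The noiseless double-logistic values are kept in
#'   the `smoothed` slot for reference.
#' @examples
#' cv <- generate_fixture_curve(fixture_spec(noise_sd = 0))
#' empirical_curve_inflections(cv)$count
#' @export
generate_fixture_curve <- function(spec = fixture_spec(), path = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  validate_fixture_spec(spec)
  tt <- seq(0, spec$t_end, length.out = spec$n_points)
  clean <- spec$phase1_height /
    (1 + exp(-spec$phase1_rate * (tt - spec$phase1_mid))) +
    (spec$plateau - spec$phase1_height) /
    (1 + exp(-spec$phase2_rate * (tt - spec$phase2_mid)))
  noise <- if (spec$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(spec$seed)
    stats::rnorm(spec$n_points, 0, spec$noise_sd)
  } else {
    numeric(spec$n_points)
  }
  cv <- curve_series(tt, clean + noise, smoothed = clean)
  if (!is.null(path)) write_curve_csv(cv, path)
  cv
}
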