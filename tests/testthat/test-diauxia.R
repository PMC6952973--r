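# Second-derivative computation, inflection counting, diauxia
# classification, activation metrics and the empirical-curve detector.

test_that("analytic second derivative matches its hand-evaluated seed value", {
  tr <- ref_full_traj()
  sec <- second_derivative_xa(tr)
  # alpha2 * xn0 * alpha3 * xa0 * yn0 = 30 * 0.001 * 1 * 0.001 * 1
  expect_equal(sec[1], 3e-5, tolerance = 1e-12)
  expect_gt(sec[1], 0)
})

test_that("second derivative vanishes when xn = ya = 0", {
  p <- nondim_params()
  s <- c(x = 0, xa = 0.8, xn = 0, ya = 0, yn = 1, z = 0.8, w = 0.2, c = 1)
  tr <- structure(list(times = c(0, 1), states = rbind(s, s), params = p,
                       variant = "nondimensional", h = 1),
                  class = "trajectory")
  expect_equal(second_derivative_xa(tr), c(0, 0))
})

test_that("dimensional trajectories are rejected by the diauxia analysis", {
  tr <- simulate_model(dimensional_params(), "dimensional",
                       integration_config(h = 1e-2, t_max = 1))
  expect_error(second_derivative_xa(tr), "unsupported")
})

test_that("analytic and central-difference second derivatives agree to O(h^2)", {
  # oracle: central differences of the recorded xa series; their deviation
  # from the analytic values must shrink quadratically with the grid spacing
  fd_error <- function(tr, stride) {
    idx <- seq(1L, length(tr$times), by = stride)
    xa <- tr$states[idx, "xa"]
    sec <- second_derivative_xa(tr)[idx]
    h <- tr$h * stride
    n <- length(xa)
    fd <- (xa[-c(1, 2)] - 2 * xa[-c(1, n)] + xa[-c(n - 1, n)]) / h^2
    max(abs(fd - sec[2:(n - 1)]))
  }
  for (tr in list(ref_full_traj(), ref_reduced_traj())) {
    e1 <- fd_error(tr, 1L)
    e2 <- fd_error(tr, 2L)
    e4 <- fd_error(tr, 4L)
    expect_lt(e1 / max(abs(second_derivative_xa(tr))), 1e-3)
    expect_gt(e2 / e1, 3); expect_lt(e2 / e1, 5)   # second-order shrinkage
    expect_gt(e4 / e2, 3); expect_lt(e4 / e2, 5)
  }
})

test_that("the model run with CDC6 present has exactly three inflections", {
  rep <- trajectory_inflections(ref_full_traj())
  expect_identical(rep$count, 3L)
  expect_identical(rep$initial_sign, 1L)
  expect_true(rep$is_diauxic)
  expect_length(rep$times, 3L)
  expect_true(all(diff(rep$times) > 0))
})

test_that("the reduced system run is diauxic with 3 (allowed: 3 or 4) inflections", {
  rep <- trajectory_inflections(ref_reduced_traj())
  expect_identical(rep$initial_sign, 1L)
  expect_true(rep$count %in% c(3L, 4L))
  expect_identical(rep$count, 3L)
  expect_true(classify_diauxic(rep))
})

test_that("count_inflections handles closed-form and degenerate series", {
  tt <- seq(0, 30, length.out = 2000)
  logistic_d2 <- function(t, m, r) {  # oracle: r^2 s(1-s)(1-2s), one zero at m
    s <- 1 / (1 + exp(-r * (t - m)))
    r^2 * s * (1 - s) * (1 - 2 * s)
  }
  one <- count_inflections(logistic_d2(tt, 15, 1), tt)
  expect_identical(one$count, 1L)
  expect_equal(one$times, 15, tolerance = 0.05)
  expect_false(classify_diauxic(one))
  two_phase <- 0.45 * logistic_d2(tt, 8, 1.2) + 0.55 * logistic_d2(tt, 20, 1.5)
  three <- count_inflections(two_phase, tt)
  expect_identical(three$count, 3L)
  expect_true(classify_diauxic(three))
  expect_warning(flat <- count_inflections(rep(0, 100), seq_len(100)),
                 "deadband")
  expect_identical(flat$count, 0L)
  expect_false(classify_diauxic(flat))
})

test_that("short sign blips below the persistence threshold are ignored", {
  tt <- seq_len(200)
  v <- c(rep(1, 90), rep(-1e-6, 3), rep(1, 17), rep(-1, 90))
  rep3 <- count_inflections(v, tt, deadband = 1e-9, persistence = 5L)
  expect_identical(rep3$count, 1L)   # only the persistent change counts
  rep1 <- count_inflections(v, tt, deadband = 1e-9, persistence = 1L)
  expect_identical(rep1$count, 3L)   # blip counted twice without persistence
})

test_that("inflection count is invariant to trajectory recording stride", {
  p <- nondim_params()
  base <- integration_config()
  cfg10 <- integration_config(h = base$h, t_max = base$t_max,
                              steady_state_tol = base$steady_state_tol,
                              record_stride = 10L)
  r1 <- trajectory_inflections(ref_full_traj())
  r10 <- trajectory_inflections(simulate_model(p, "nondimensional", cfg10))
  expect_identical(r10$count, r1$count)
  expect_equal(r10$times, r1$times, tolerance = 0.05)
})

test_that("activation metrics order the threshold crossings", {
  m <- activation_metrics(ref_full_traj())
  expect_lt(abs(m$final_xa - 1), 1e-3)
  expect_true(m$t10 <= m$t50 && m$t50 <= m$t90)
  # no activation: thresholds reported absent, not as an error
  p0 <- nondim_params(eps_xa = 0, eps_ya = 0)
  tr0 <- simulate_model(p0, "nondimensional",
                        integration_config(h = 1e-3, t_max = 30))
  m0 <- activation_metrics(tr0)
  expect_true(is.na(m0$t10) && is.na(m0$t50) && is.na(m0$t90))
})

test_that("the empirical detector recovers the known inflection structure", {
  diaux <- generate_fixture_curve(fixture_spec(noise_sd = 0))
  rep3 <- empirical_curve_inflections(diaux)
  expect_identical(rep3$count, 3L)
  expect_true(classify_diauxic(rep3))
  single <- generate_fixture_curve(fixture_spec(noise_sd = 0, plateau = 0.45))
  rep1 <- empirical_curve_inflections(single)
  expect_identical(rep1$count, 1L)
  expect_false(classify_diauxic(rep1))
})

test_that("flat noisy curves are reported as degenerate with zero count", {
  set.seed(5)
  flat <- curve_series(seq(0, 30, length.out = 60),
                       0.5 + rnorm(60, sd = 0.01))
  expect_warning(rep0 <- empirical_curve_inflections(flat, window = 9L),
                 "degenerate")
  expect_identical(rep0$count, 0L)
})

test_that("the empirical detector enforces its minimum sample size", {
  expect_error(
    empirical_curve_inflections(curve_series(1:5, c(0, 0.1, 0.5, 0.9, 1))),
    "at least 7")
})

test_that("curve series validate their invariants and round-trip CSV", {
  expect_error(curve_series(c(1, 2, 2), c(1, 2, 3)), "strictly increasing")
  expect_error(curve_series(1:3, 1:4), "equal length")
  cv <- generate_fixture_curve(fixture_spec())
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, path)
  back <- read_curve_csv(path)
  expect_equal(back$times, cv$times)
  expect_equal(back$values, cv$values)
})
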