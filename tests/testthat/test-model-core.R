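# Hill switch, right-hand sides, non-dimensionalisation and initial states.

test_that("hill_rate matches its closed form at the anchor points", {
  hp <- hill_params()  # omega 0.6, nu 8, k 20, vth 0.25
  expect_equal(hill_rate(0, hp), 0.6)                 # basal rate at xa = 0
  expect_equal(hill_rate(0.25, hp), 0.6 + 8 / 2)      # midpoint at xa = vth
  expect_equal(hill_rate(1e6, hp), 8.6)               # saturation omega + nu
  expect_error(hill_rate(-0.1, hp), "non-negative")
})

test_that("hill_rate is bounded in [omega, omega+nu] and monotone", {
  set.seed(11)
  for (i in 1:20) {
    hp <- hill_params(omega = runif(1, 0, 2), nu = runif(1, 0, 10),
                      k = runif(1, 0.5, 30), vth = runif(1, 0.05, 1))
    xa <- sort(c(0, runif(50, 0, 3), 10^runif(5, 1, 8)))
    f <- hill_rate(xa, hp)
    expect_true(all(f >= hp$omega - 1e-12))
    expect_true(all(f <= hp$omega + hp$nu + 1e-12))
    expect_true(all(diff(f) >= -1e-12))
  }
})

test_that("non-dimensional rhs reproduces hand-evaluated initial derivatives", {
  p <- nondim_params()
  s0 <- default_initial_state(p)
  d <- rhs_nondimensional(s0, p)
  expect_equal(d[["xa"]], 0)          # ya(0) = 0 blocks activation
  expect_equal(d[["ya"]], 0.001)      # alpha3 * xa0 * yn0 = 1 * 0.001 * 1
  expect_equal(d[["c"]], 1)           # c(0) = 0 gives pure production
})

test_that("derivatives of the conserved groups cancel exactly", {
  set.seed(23)
  p <- nondim_params()
  for (i in 1:25) {
    s <- random_conserved_state(p$gamma)
    d <- rhs_nondimensional(s, p)
    expect_equal(d[["x"]] + d[["xa"]] + d[["xn"]] + d[["w"]], 0)
    expect_equal(d[["ya"]] + d[["yn"]], 0)
    expect_equal(d[["z"]] + d[["w"]], 0)
  }
  dp <- dimensional_params(beta = 2.5, K_CDK1 = 3, K_CDC25 = 0.5,
                           K_CDC6 = 2, K_CYCB = 4)
  s <- c(x = 1, xa = 0.5, xn = 1, ya = 0.2, yn = 0.3, z = 1.5, w = 0.5,
         c = 2)
  d <- rhs_dimensional(s, dp)
  expect_equal(d[["x"]] + d[["xa"]] + d[["xn"]] + d[["w"]], 0)
  expect_equal(d[["ya"]] + d[["yn"]], 0)
  expect_equal(d[["z"]] + d[["w"]], 0)
  expect_equal(d[["x"]], 0 - dp$alpha1 * 1 * 2)  # -alpha1 x c
})

test_that("dimensional rhs with c = 0 freezes free CDK1", {
  dp <- dimensional_params()
  s <- c(x = 0.9, xa = 0.02, xn = 0.05, ya = 0.1, yn = 0.9, z = 0.97,
         w = 0.03, c = 0)
  expect_equal(rhs_dimensional(s, dp)[["x"]], 0)
})

test_that("dimensional rhs equals the rescaled non-dimensional rhs", {
  # oracle: substitute the scaling maps by hand on random states;
  # d(state)/dt = scale * beta * d(state*)/dt*. The scaled cyclin equation
  # matches the dimensional one when the cyclin pool equals the CDK1 pool
  # (1:1 stoichiometry of complex formation), so K_CYCB = K_CDK1 here; the
  # unequal-pool case is checked separately below.
  set.seed(31)
  for (i in 1:10) {
    kcdk1 <- runif(1, 0.5, 3)
    dp <- dimensional_params(
      alpha1 = runif(1, 0.5, 2), alpha2 = runif(1, 5, 40),
      alpha3 = runif(1, 0.5, 2), alpha4 = runif(1, 2, 10),
      beta = runif(1, 0.5, 3), delta = runif(1, 1, 6),
      K_CDK1 = kcdk1, K_CDC25 = runif(1, 0.5, 3),
      K_CDC6 = runif(1, 0.5, 3), K_CYCB = kcdk1,
      hill = hill_params(vth = 0.25 * runif(1, 0.5, 3)))
    np <- nondimensionalize(dp)
    scales <- attr(np, "scales")
    s_dim <- c(x = runif(1, 0, dp$K_CDK1), xa = runif(1, 0, dp$K_CDK1),
               xn = runif(1, 0, dp$K_CDK1), ya = runif(1, 0, dp$K_CDC25),
               yn = runif(1, 0, dp$K_CDC25), z = runif(1, 0, dp$K_CDC6),
               w = runif(1, 0, dp$K_CDC6), c = runif(1, 0, dp$K_CYCB))
    s_star <- nondimensionalize_state(s_dim, scales)
    d_star <- rhs_nondimensional(s_star, np)
    d_dim <- rhs_dimensional(s_dim, dp)
    fac <- c(x = scales$K_CDK1, xa = scales$K_CDK1, xn = scales$K_CDK1,
             ya = scales$K_CDC25, yn = scales$K_CDC25, z = scales$K_CDK1,
             w = scales$K_CDK1, c = scales$K_CYCB)
    expect_equal(d_dim, d_star * fac * scales$beta, tolerance = 1e-12)
  }
  # with unequal pools only the cyclin component can deviate
  dp <- dimensional_params(K_CDK1 = 2, K_CYCB = 0.5, K_CDC25 = 1.5,
                           K_CDC6 = 1, beta = 1.3)
  np <- nondimensionalize(dp)
  sc <- attr(np, "scales")
  s_dim <- c(x = 0.4, xa = 0.3, xn = 0.8, ya = 0.2, yn = 1.3, z = 0.7,
             w = 0.3, c = 0.25)
  d_dim <- rhs_dimensional(s_dim, dp)
  d_star <- rhs_nondimensional(nondimensionalize_state(s_dim, sc), np)
  fac <- c(x = 2, xa = 2, xn = 2, ya = 1.5, yn = 1.5, z = 2, w = 2, c = 0.5)
  back <- d_star * fac * sc$beta
  expect_equal(d_dim[1:7], back[1:7], tolerance = 1e-12)
})

test_that("nondimensionalize applies the stated scale map and round-trips", {
  expect_equal(nondimensionalize(dimensional_params())$alpha2, 30)  # unit scales
  np <- nondimensionalize(dimensional_params(alpha2 = 3, K_CDC25 = 10))
  expect_equal(np$alpha2, 30)
  np2 <- nondimensionalize(dimensional_params(K_CDC6 = 2, K_CDK1 = 4,
                                              eps_xa = 0.001, eps_xn = 0.001,
                                              hill = hill_params(vth = 1)))
  expect_equal(np2$gamma, 0.5)
  expect_equal(np2$hill$vth, 0.25)
  dp <- dimensional_params(alpha1 = 1.3, alpha2 = 7, alpha3 = 0.4,
                           alpha4 = 2.2, beta = 1.7, delta = 0.9,
                           K_CDK1 = 2, K_CDC25 = 3, K_CDC6 = 1.5,
                           K_CYCB = 0.8, eps_xa = 0.01, eps_xn = 0.02,
                           eps_ya = 0.05, eps_w = 0.03)
  back <- dimensionalize(nondimensionalize(dp))
  for (k in setdiff(names(dp), "hill"))
    expect_equal(back[[k]], dp[[k]], tolerance = 1e-12)
  expect_equal(unclass(back$hill), unclass(dp$hill), tolerance = 1e-12)
  # state round-trip
  s <- c(x = 0.3, xa = 0.2, xn = 0.5, ya = 1.1, yn = 1.9, z = 0.7, w = 0.8,
         c = 0.4)
  sc <- attr(nondimensionalize(dp), "scales")
  expect_equal(dimensionalize_state(nondimensionalize_state(s, sc), sc), s)
  expect_error(nondimensionalize(structure(list(), class = "nondim_params")))
})

test_that("default initial state honours the trace parameters exactly", {
  p <- nondim_params()
  s0 <- default_initial_state(p)
  expect_equal(s0[["x"]], 0.998)       # 1 - 0.001 - 0.001 - 0
  expect_equal(s0[["yn"]], 1)
  expect_equal(s0[["c"]], 0)
  expect_equal(sum(s0[c("x", "xa", "xn", "w")]), 1)
  expect_equal(s0[["z"]] + s0[["w"]], p$gamma)
  p2 <- nondim_params(eps_xa = 0.05, eps_xn = 0.1, eps_ya = 0.2,
                      eps_w = 0.3, gamma = 0.5)
  s2 <- default_initial_state(p2)
  expect_equal(s2[["c"]], 0)
  expect_equal(sum(s2[c("x", "xa", "xn", "w")]), 1)
  expect_equal(s2[["ya"]] + s2[["yn"]], 1)
  expect_equal(s2[["z"]] + s2[["w"]], 0.5)
})

test_that("parameter invariants are enforced as configuration errors", {
  expect_error(nondim_params(eps_xa = 0.6, eps_xn = 0.5), "must be < 1")
  expect_error(nondim_params(eps_w = 0.5, gamma = 0.2), "eps_w")
  expect_error(nondim_params(alpha1 = -1), "non-negative")
  expect_error(hill_params(k = 0), "k must be > 0")
  expect_error(hill_params(vth = -1), "vth must be > 0")
  expect_error(dimensional_params(beta = 0), "positive")
  expect_error(dimensional_params(K_CDK1 = 0.001), "exceed K_CDK1")
})

test_that("reduced rhs matches its anchor examples and consistency error", {
  p <- nondim_params()
  # implied xn = 0 freezes activation
  s <- c(xa = 1 - p$gamma + 0.7, ya = 0.5, z = 0.7)
  expect_equal(rhs_reduced(s, p)[["xa"]], 0)
  # fully active CDC25 stops its own growth
  expect_equal(rhs_reduced(c(xa = 0.3, ya = 1, z = 0.8), p)[["ya"]], 0)
  # unbound CDC6 with inactive complexes around: net binding, z decreases
  expect_lt(rhs_reduced(c(xa = 0.4, ya = 0.2, z = p$gamma), p)[["z"]], 0)
  expect_error(rhs_reduced(c(xa = 0.9, ya = 0.5, z = 0.1), p),
               "negative")
})

test_that("reduced rhs agrees with the full rhs on the reduced manifold", {
  set.seed(47)
  for (i in 1:20) {
    gamma <- runif(1, 0.2, 1.5)
    p <- nondim_params(gamma = gamma)
    z <- runif(1, max(0, gamma - 1), gamma)
    xa <- runif(1, 0, 1 - gamma + z)
    s_red <- c(xa = xa, ya = runif(1), z = z)
    s_full <- embed_reduced_state(s_red, p)
    d_full <- rhs_nondimensional(s_full, p)
    d_red <- rhs_reduced(s_red, p)
    expect_equal(d_red[["xa"]], d_full[["xa"]], tolerance = 1e-13)
    expect_equal(d_red[["ya"]], d_full[["ya"]], tolerance = 1e-13)
    expect_equal(d_red[["z"]], d_full[["z"]], tolerance = 1e-13)
  }
})
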