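# Shared lazily-computed objects so expensive reference trajectories are
# integrated once per test run.

.traj_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .traj_cache, inherits = FALSE))
    assign(key, fn(), envir = .traj_cache)
  get(key, envir = .traj_cache, inherits = FALSE)
}

ref_full_traj <- function() {
  cached("full", function()
    simulate_model(nondim_params(), "nondimensional"))
}

ref_reduced_traj <- function() {
  cached("reduced", function()
    simulate_model(nondim_params(), "reduced"))
}

ref_comparison <- function() {
  cached("comparison", function() compare_cdc6(nondim_params()))
}

# A state away from the axes, used for derivative spot checks.
generic_full_state <- function() {
  c(x = 0.2, xa = 0.25, xn = 0.3, ya = 0.4, yn = 0.6, z = 0.75, w = 0.25,
    c = 0.5)
}

# Random full states satisfying the non-dimensional conservation laws.
random_conserved_state <- function(gamma) {
  xs <- stats::runif(4)
  xs <- xs / sum(xs)                  # x, xa, xn, w summing to 1
  w <- min(xs[4], gamma)              # w also bounded by the CDC6 pool
  ya <- stats::runif(1)
  c(x = xs[1], xa = xs[2], xn = xs[3] + (xs[4] - w), ya = ya, yn = 1 - ya,
    z = gamma - w, w = w, c = stats::runif(1))
}
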