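---
title: "Modelling diauxic CDK1/cyclin B activation under CDC6 inhibition"
author: "cdk1diauxia"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdk1diauxia)
```

## The biological setting and the model

Entry into mitosis is driven by the activity of the CDK1/cyclin B complex.
During G2, cyclin B accumulates and binds CDK1, but the complex is kept
inactive by inhibitory phosphorylation; the phosphatase CDC25 removes those
phosphates, and active CDK1/cyclin B in turn activates more CDC25 — a
positive feedback loop that, once seeded, drives the whole pool to full
activation. In *Xenopus laevis* one-cell embryo extracts, CDK1 activation
curves often rise in two phases separated by a visible slowdown, and
removing CDC6 from the extract abolishes the slow phase. The model
implemented here explains that observation by letting CDC6 reversibly
sequester *inactive* CDK1/cyclin B into a ternary complex, with a binding
rate that switches up sharply once active CDK1/cyclin B passes a threshold.

Eight species are tracked (all as fractions of their pools in the
non-dimensional system): free CDK1 `x`, active and inactive complex
`xa`/`xn`, active and inactive CDC25 `ya`/`yn`, free CDC6 `z`, the ternary
complex `w`, and cyclin B `c`. Mass-action kinetics give

$$
\begin{aligned}
\dot x &= -\alpha_1 x c, &
\dot x_a &= \alpha_2 x_n y_a, &
\dot x_n &= \alpha_1 x c - \alpha_2 x_n y_a - B,\\
\dot y_a &= \alpha_3 x_a y_n, &
\dot y_n &= -\alpha_3 x_a y_n, &
\dot z &= -B,\\
\dot w &= B, &
\dot c &= -\alpha_1 x c + (1 - c), &
B &= \alpha_4 f(x_a)\, x_n z - \delta w,
\end{aligned}
$$

with the Hill switch
$f(x_a) = \omega + \nu\, x_a^k / (v_{th}^k + x_a^k)$: CDC6 binds inactive
complexes at basal rate $\omega$ until `xa` crosses $v_{th}$, after which
the rate approaches $\omega + \nu$. Three conservation laws hold exactly:
`x + xa + xn + w = 1`, `ya + yn = 1`, `z + w = γ` (γ is total CDC6 relative
to total CDK1). The marginal dissociation of the inactive complex back into
CDK1 and cyclin B is not modelled.

The default (reference) parameter set, also bundled as
`inst/extdata/params-reference.yaml`:

| parameter | value | meaning |
|---|---|---|
| $\alpha_1$ | 1 | cyclin B binding to CDK1 |
| $\alpha_2$ | 30 | activation of `xn` by active CDC25 |
| $\alpha_3$ | 1 | activation of CDC25 by `xa` (feedback) |
| $\alpha_4$ | 7 | CDC6 binding of `xn` (scaled by $f$) |
| $\delta$ | 4 | ternary-complex dissociation |
| $\gamma$ | 1 | total CDC6 / total CDK1 |
| $\omega,\ \nu$ | 0.6, 8 | basal rate and switch amplitude of $f$ |
| $k,\ v_{th}$ | 20, 0.25 | switch steepness and threshold |
| $\varepsilon_{xa},\varepsilon_{xn}$ | 0.001 | seed traces of active/inactive complex |
| $\varepsilon_{ya},\varepsilon_{w}$ | 0 | seed traces of active CDC25 / ternary complex |

The initial condition ties the seeds to the parameter record:
`x(0) = 1 − εxa − εxn − εw`, `xa(0) = εxa`, `xn(0) = εxn`, `ya(0) = εya`,
`yn(0) = 1 − εya`, `z(0) = γ − εw`, `w(0) = εw`, `c(0) = 0`.

Once free CDK1 is exhausted (`x = 0`) and cyclin B has saturated (`c = 1`),
the conservation laws leave a three-variable system in `(xa, ya, z)` with
`xn = 1 − γ + z − xa`; this *reduced* system (`variant = "reduced"`) is
used for the stability analysis and for the integrator error study, because
it has no structurally neutral directions.

### A note on the dimensional mode and scaling

Only non-dimensional parameter values are published, so the dimensional
mode defaults to unit totals and unit cyclin turnover (`beta = 1`), under
which the two modes coincide; dimensional mode is a unit-convention layer,
not a calibrated model. The scale map
(`alpha1* = alpha1 K_CYCB / beta`, …, `vth* = vth / K_CDK1`; `omega` and
`nu` are dimensionless rate multipliers and carry over) makes the
non-dimensional cyclin equation the exact image of the dimensional one
only when `K_CYCB = K_CDK1` — the natural stoichiometric convention, since
each complex consumes one cyclin measured in CDK1-pool units. The package
treats the non-dimensional system as primary and does not constrain the
dimensional totals; with unequal pools the discrepancy is confined to the
cyclin component.

## Numerical integration

Integration uses a hand-rolled classical fixed-step RK4 scheme
(`rk4_integrate()`), not an adaptive library solver, because the global
error of the *fixed-step* scheme is what makes the inflection counts
trustworthy: `empirical_error_coefficient()` measures the worst
global error at the working step against a 16-fold finer self-reference,
and `convergence_order()` confirms fourth-order shrinkage. At the working
step `h = 1/1000` (non-dimensional time) the measured worst error on the
reduced system over a horizon of 25 time units is about `3e-10` — roughly
eight orders of magnitude below the second-derivative features being
counted — and the observed order is ≈ 4.0.

Defaults: `h = 1/1000`; horizon `t_max = 200` with a steady-state stop
when the right-hand side max-norm falls below `1e-8`, which makes results
horizon-independent (the reference run stops near `t ≈ 23`). Conservation
sums are checked on every trajectory: drift beyond `1e-6` aborts the run
(it indicates an overly large step); at the default step the observed
drift is at round-off level (`~1e-14`).

```{r simulate}
p <- nondim_params()
tr <- simulate_model(p, "nondimensional")
tr
```

## Counting inflection points

Diauxic behaviour is formalised as *more than one inflection point* of the
`xa` curve. The second derivative is computed analytically along the flow
(`second_derivative_xa()`): differentiating
$\dot x_a = \alpha_2 x_n y_a$ once more and substituting the model
right-hand side gives
$\ddot x_a = \alpha_2(\dot x_n y_a + x_n \dot y_a)$, so the zeros counted
are those of an exact expression evaluated on the numerical solution, not
of a noisy difference quotient (central differencing is retained in the
test suite as an independent oracle).

Sign changes are counted with two guards (`count_inflections()`): values
within a *deadband* of `1e-10` times the peak magnitude count as zero, and
a sign run must persist for at least 5 grid points to count. Both guards
exist to suppress round-off chatter near zero crossings of a smooth curve;
at the default step they are inactive for the reference runs (the shortest
genuine sign run spans ~200 grid points). A zero at `t = 0` is not a sign
change. Crossing times are linearly interpolated between the flanking
samples.

```{r inflections}
trajectory_inflections(tr)
```

At the reference parameters the full model with CDC6 shows exactly three
inflection points and the reduced system likewise three, starting from a
positive second derivative (`3e-5` at `t = 0` for the full system); with
CDC6 absent a single inflection remains. Depending on parameters the
reduced system can also show four sign changes with a negative initial
sign; the detector reports count and initial sign and asserts neither.

```{r compare}
cmp <- compare_cdc6(p)
cmp
```

`compare_cdc6()` runs both arms with steady-state stopping and then
extends the earlier-stopping arm (integrating on from its settled state)
so both share one grid; the delay is the difference in the time to half of
the final activation level, by linear interpolation.

## Equilibria and stability

Two biologically meaningful fixed points exist. S2 is full activation
(`xa = ya = 1`, `z = γ`, `w = 0`, `c = 1`). S1 is the state reached when
both activation seeds are zero: the feedback never starts, free CDK1 is
consumed into inactive complexes, and CDC6 partitions between free and
bound forms by the basal-rate balance
$\alpha_4 \omega (1 - w)(\gamma - w) = \delta w$. Because $f(0) = \omega$
is constant, this balance is a quadratic in `w`; the package uses the
numerically stable closed-form root (polished by a few Newton steps)
rather than iterative bracketing, and verifies both states by a
right-hand-side residual check at tolerance `1e-10`.

Stability is classified on the reduced system's analytic Jacobian
(`reduced_jacobian()`, finite-difference checked in the tests): the full
system's conservation laws would contribute structural zero eigenvalues
that say nothing about the biology. At the reference parameters S1 is
unstable (eigenvalues $\pm\sqrt{\alpha_2 \alpha_3 x_n^{S1}}$ appear as a
saddle pair) and S2 is asymptotically stable. Eigenvalues with
`|Re| < 1e-9` are labelled neutral and reported, not suppressed — e.g.
`alpha3 = 0` freezes the CDC25 direction. These are numerical
verifications, not proofs: `perturb_s1()` additionally demonstrates the
instability dynamically (a `1e-6` seed drives the system to within `1e-3`
of S2).

```{r equilibria}
find_equilibria(p)
```

## The empirical-curve detector and the synthetic generator

`empirical_curve_inflections()` applies the same counting logic to
measured activity curves: a centred moving average (width `window`,
default 5 samples) tames sampling noise, a smoothing spline
(`stats::smooth.spline`) provides a twice-differentiable fit, and the
spline's second derivative is evaluated on a 10-fold refined grid.
Choices worth knowing:

* the smoothing method for published experimental curves is not specified
  anywhere authoritative, so both smoothing widths are exposed as
  parameters rather than hard-coded;
* the deadband default is `1e-3` of the peak second-derivative magnitude —
  far wider than for analytic model derivatives — because spline curvature
  estimates carry boundary artifacts at about that level;
* if the smoothed curve's range does not exceed six times the estimated
  noise (the moving-average residual), the curve is declared degenerate
  (count 0 with a warning) rather than letting the spline hallucinate
  curvature in noise;
* with the default `spline_smoothing = NULL` the spar is chosen by
  generalised cross-validation, which is accurate for clean curves but
  under-smooths noisy ones (the moving average leaves correlated
  residuals GCV mistakes for signal); for visibly noisy data pass
  `spline_smoothing` around 0.6–0.8.

The synthetic generator (`generate_fixture_curve()`) produces a
double-logistic rise with optional Gaussian noise — deliberately *not* the
ODE model, so the detector is exercised against curves whose inflection
structure is known in closed form (three sign changes for well-separated
phases, one for a single logistic). Defaults emulate a slow two-phase
activation over ~30 min sampled every half minute with noise at 2% of the
plateau: realistic shape, amplitude and sampling for kinase-activity time
courses. The generator does not emulate saturation artifacts, baseline
drift, or heteroscedastic detection noise, so a detector pass here shows
correctness of the counting logic, not robustness to every laboratory
artifact.

```{r detector}
cv <- generate_fixture_curve(fixture_spec(noise_sd = 0))
empirical_curve_inflections(cv)
```

## Problem sizes, tolerances and limitations

* Headline analyses integrate ~23,000 steps (full model to steady state at
  `h = 1/1000`); the error study uses a horizon of 25 time units with a
  reference grid of 400,000 steps. These sizes keep every analysis in the
  seconds-to-a-minute range on a single core.
* Steady-state tolerance `1e-8` (max-norm of the derivative); equilibrium
  residual tolerance `1e-10`; conservation hard limit `1e-6` with observed
  drift `~1e-14`; neutral-eigenvalue threshold `1e-9`.
* Model time is non-dimensional (units of cyclin turnover). No mapping to
  laboratory minutes is asserted anywhere: the experimental activation
  times reported for extracts are wet-lab quantities outside the model's
  reach, and the with/without-CDC6 contrast is compared qualitatively
  (ordering of t50, counts), not in minutes.
* The parameter region producing a negative initial second derivative
  with four sign changes is not catalogued here; the detector reports
  whatever it finds, and a parameter scan would be the natural follow-up.
* Stochastic variants, the cyclin A activation route, and explicit
  Wee1/Myt1 kinases are out of scope, as are bifurcation/continuation
  analyses.
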