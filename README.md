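# cdk1diauxia

Mass-action modelling of the two-phase ("diauxic") activation of
CDK1/cyclin B at mitotic entry, and of the delaying role played by CDC6.

## Scientific problem

The transition into mitosis is triggered when the CDK1/cyclin B kinase
switches on. The switch is driven by positive feedback: active CDK1/cyclin B
activates the phosphatase CDC25, which in turn activates more CDK1/cyclin B.
In embryo extracts the measured activation curve often rises in *two*
phases separated by a transient slowdown, and depleting CDC6 removes the
slowdown. This package implements an ordinary-differential-equation model
in which CDC6 reversibly sequesters inactive CDK1/cyclin B into a ternary
complex, with a binding rate that switches up sharply (a steep Hill
function of active CDK1/cyclin B) once activation passes a threshold. The
interplay of feedback and switched sequestration reproduces the two-phase
rise, which the package formalises and detects as *multiple inflection
points* of the activation curve.

Eight species are tracked in the non-dimensional model: free CDK1 `x`,
active/inactive CDK1–cyclin B complex `xa`/`xn`, active/inactive CDC25
`ya`/`yn`, free CDC6 `z`, the CDC6-bound ternary complex `w`, and cyclin B
`c`. Mass-action kinetics with the switch
`f(xa) = omega + nu * xa^k / (vth^k + xa^k)` give

```
x'  = -a1 x c                         ya' =  a3 xa yn        z' = -B
xa' =  a2 xn ya                       yn' = -a3 xa yn        w' =  B
xn' =  a1 x c - a2 xn ya - B          c'  = -a1 x c + (1 - c)
B   =  a4 f(xa) xn z - delta w
```

with exact conservation of the CDK1, CDC25 and CDC6 pools. A reduced
three-variable system on the invariant manifold `x = 0, c = 1` supports the
stability analysis and the integrator error study. See the methods
vignette (`vignettes/cdc6-diauxic-activation.Rmd`) for parameters,
assumptions and numerical choices.

## What the package provides

* `nondim_params()` / `dimensional_params()` — validated parameter records
  with the reference values as defaults; YAML read/write.
* `rk4_integrate()` / `simulate_model()` — a hand-rolled classical
  fixed-step fourth-order Runge–Kutta integrator with steady-state
  stopping and conservation checking, plus `empirical_error_coefficient()`
  and `convergence_order()` to measure its global accuracy.
* `second_derivative_xa()`, `count_inflections()`,
  `trajectory_inflections()`, `classify_diauxic()`,
  `activation_metrics()` — analytic curvature along the flow and robust
  sign-change counting (deadband + persistence).
* `compare_cdc6()`, `find_equilibria()`, `classify_stability()`,
  `perturb_s1()` — the with/without-CDC6 contrast, both fixed points, and
  eigenvalue stability on the reduced system.
* `empirical_curve_inflections()` and `generate_fixture_curve()` — a
  spline-based inflection detector for sampled activity curves and a
  deterministic double-logistic generator with known inflection structure.
* `cli_main()` and the `inst/scripts/cdk1sim` wrapper — a small command
  line (`simulate`, `compare`, `inflections`, `equilibria`, `fixture`)
  writing CSV/JSON.

## Worked example

```r
library(cdk1diauxia)

p <- nondim_params()        # reference parameter set
cmp <- compare_cdc6(p)      # both scenarios at h = 1/1000
cmp
#> CDC6 presence/absence comparison
#>   with CDC6:    3 inflection point(s), t50 = 3.591
#>   without CDC6: 1 inflection point(s), t50 = 2.4764
#>   activation delay (t50 difference): 1.1146

trajectory_inflections(cmp$with_cdc6$trajectory)
#> Inflection report: 3 sign change(s) -- diauxic
#>   at t = 2.5495, 2.7493, 3.5741
#>   initial second-derivative sign: 1

find_equilibria(p)
#> Equilibria of the non-dimensional system
#>   S1 (no activation):   residual 2.22e-16, unstable
#>   S2 (full activation): residual 0.00e+00, asymptotically stable
```

With CDC6 present the activation curve carries three inflection points
(diauxic); without CDC6 a single one remains, and half-activation arrives
about 1.11 non-dimensional time units earlier. The integrator's measured
global error at the working step `h = 1/1000` is about `3e-10` with an
observed convergence order of ≈ 4.0.

The same analyses from the shell:

```sh
Rscript inst/scripts/cdk1sim compare --out comparison.json
Rscript inst/scripts/cdk1sim simulate --variant reduced --out reduced.csv
Rscript inst/scripts/cdk1sim fixture --noise-sd 0 --out curve.csv
Rscript inst/scripts/cdk1sim inflections --curve curve.csv --out report.json
```

## License

MIT (see `LICENSE`).
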