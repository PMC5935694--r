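# lvimm

Tools for a classical question in theoretical ecology: the Lotka–Volterra
predator–prey system

$$\frac{dx}{dt} = r x - a x y, \qquad \frac{dy}{dt} = b x y - m y$$

is never asymptotically stable — its coexistence point $(m/b,\, r/a)$ is a
neutral center and orbits cycle forever — yet real predator–prey pairs often
coexist stably. `lvimm` implements and analyzes a minimal resolution: adding a
small immigration term to the prey equation ($C(x) = c$ or $c/x$), to the
predator equation ($D(y) = d$ or $d/y$), or to both, under Holling type I
(linear), II (hyperbolic, $a x/(1+hx)$) and III (sigmoid, $a x^2/(1+hx^2)$)
functional responses. Arbitrarily small inflows turn the center into a stable
focus whose oscillation amplitude decays like $e^{-\gamma t}$ with closed-form
rates ($\gamma = bc/2m$ for constant prey immigration, $ad/2r$, $b^2c/m^2$,
$a^2d/r^2$ for the other three cases), while sign-flipped terms (emigration)
destabilize, and randomly pulsed inflows still average the cycles out.

The package is aimed at modellers who want these claims as runnable,
certifiable objects: exact vector fields, closed-form and Newton-certified
equilibria, analytic Jacobians with trace/determinant classification, an
adaptive Dormand–Prince integrator checked against the system's first
integral, envelope-based decay-rate estimation from trajectories, seeded
pulsed-immigration ensembles, and a scenario suite that reproduces the full
stability matrix (response type × immigration case).

## Worked example

Constant prey immigration `c = 0.01` with the standard demonstration rates
`r = 0.1, a = 0.1, b = 0.3, m = 0.2`:

```r
library(lvimm)
p   <- lv_params(r = 0.1, a = 0.1, b = 0.3, m = 0.2)
mod <- case_model(p, "A1", c = 0.01)      # dx/dt gains the constant +0.01

(eq <- equilibrium_closed_form(p, "A1", 0.01))
#> Equilibrium [A1]: (x*, y*) = (0.66666667, 1.15)  feasible  residual 5.20e-18

classify_equilibrium(mod, eq)
#> Stability: asymptotically_stable
#>   Tr(J) = -0.015, Det(J) = 0.023
#>   eigenvalues: -0.0075 +0.151472i, -0.0075 -0.151472i
#>   gamma: numeric 0.0075, analytic 0.0075
#>   beta = 0.03
```

The equilibrium shifts from the classical $(0.667, 0.5/a = 1)$ to
$(0.667, 1.15)$ and becomes a stable focus: the eigenvalues acquire the real
part $-0.0075$, exactly the analytic decay rate $\gamma = bc/2m$. Integrating
the system and fitting the oscillation envelope recovers the same number
dynamically:

```r
tr <- lv_integrate(mod, 5, 5, t_end = 2000)
estimate_decay_rate(tr, eq)
#> Decay estimate: gamma_hat = 0.00750284 from 86 peaks (R^2 = 1.0000)
#>   on t in [218.4, 1980.9]
```

The full stability matrix — three response types crossed with no immigration
and the four immigration cases — is one call:

```r
run_scenario_suite()[, c("type", "case", "expected", "observed", "agree")]
#>  type case   expected   observed agree
#>     I none not_stable not_stable  TRUE
#>     I   A1     stable     stable  TRUE
#>     ...                                 (15 rows, all TRUE:
#>   III   D1     stable     stable  TRUE   type II is unstable without
#>                                          immigrants, type III stable when
#>                                          beta = rb - hmr > 0, and every
#>                                          immigration cell is stable)
```

A command-line wrapper covers the same operations
(`simulate`, `stability`, `ensemble`, `suite`, `decay`):

```sh
Rscript inst/cli/lvimm.R suite --out verdicts.csv   # exit 1 on any disagreement
```

## Package layout

- `R/model.R`, `R/immigration.R`, `R/params.R` — types, vector field, config I/O
- `R/equilibria.R`, `R/stability.R` — closed forms, Newton roots, Jacobian,
  classification, γ and β
- `R/solver.R`, `R/simulate.R`, `R/ensemble.R` — Dormand–Prince integrator,
  trajectories, pulsed ensembles
- `R/decay.R`, `R/suite.R`, `R/cli.R` — envelope fitting, scenario grid, CLI
- `vignettes/immigration-stabilization.Rmd` — model, assumptions, numerical
  choices and limitations
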