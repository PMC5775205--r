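# crowdingLV

Tools for studying how a *crowding effect* — per-capita mortality that
rises nonlinearly with a species' own density — changes the outcome of
Lotka-Volterra (LV) competition. In the classical LV model, complete
competitors cannot coexist (the competitive exclusion principle); this
package simulates and analyses a modified model in which the mortality
rate of species *i* is

```
m_i(x_i) = m_i0 + d_i * x_i^delta ,
```

so that intraspecific crowding becomes increasingly punishing near the
carrying capacity (K_i = 1 throughout). The n-species dynamics are

```
dx_i/dt = b_i x_i (1 - x_i - sum_{j != i} alpha_ij x_j) - (m_i0 + d_i x_i^delta) x_i
```

with birth rate `b_i`, baseline mortality `m_i0`, crowding coefficient
`d_i`, crowding exponent `delta`, and competition coefficients
`alpha_ij`. Two comparison variants are included: an aggregation-type
mortality law `m_i0 * x_i^(1+epsilon)` and a nonlinear-competition model
in which interspecific terms enter squared (`alpha_ij x_j^2`), each with
and without the crowding term.

The package is for theoretical ecologists who want to reproduce,
perturb, and extend this family of models: it provides a fast adaptive
ODE integrator (Dormand-Prince 5(4), compiled), an interior-equilibrium
solver by scalar reduction, stability classification from analytic
Jacobians, two-species isocline/phase-plane analysis with the four
classical competition cases, sweep machinery over `delta` and `d`, a
registry of ready-made scenarios, and a command-line interface
(`exec/lvcrowding`).

## Worked example

Switching on crowding in a classical exclusion scenario (case "a" of the
two-species phase plane: `alpha_12 = 0.8`, `alpha_21 = 1.2`):

```r
library(crowdingLV)
spec <- lv_model("crowding", b = c(1, 1), m0 = 0.1, d = 0.5,
                 alpha = matrix(c(1, 1.2, 0.8, 1), 2), delta = 1)
equilibrium_shift(spec, d_low = 0, d_high = 0.5, x0 = c(0.5, 0.2))
#> <lv_eqpair> crowding switched from d = 0 to 0.5
#>   E1 = 0.9, 1.7911e-157 (stable)
#>   E2 = 0.48837, 0.2093 (stable)
#>   displacement = 0.46178
```

Without crowding (`d = 0`) the system runs to the boundary attractor
E1: species 1 sits at its single-species equilibrium `1 - m0/b = 0.9`
and species 2 is excluded. With `d = 0.5` the attractor E2 is strictly
interior and locally stable — the crowding effect rescues coexistence.

For communities with identical competition coefficients (`alpha = 1`)
the interior equilibrium can be computed without integrating, by
reducing the equilibrium conditions to one scalar fixed-point equation
in the total density S:

```r
spec <- lv_model("crowding", b = c(1, 1.8), m0 = 0.1, d = 0.3,
                 alpha = 1, delta = 1, n = 2)
solve_interior_equilibrium(spec)
#> <lv_equilibrium> stable
#>   x* = 0.204301, 0.634409
#>   residual = 3.93e-12  max Re(lambda) = -0.07938
```

The weaker competitor (`b = 1`) persists at lower but positive density.

From a shell:

```sh
lvcrowding scenarios                    # list the registered fixtures
lvcrowding simulate --scenario fig6d --out results/
lvcrowding isoclines --scenario fig1c --out results/
lvcrowding sweep --scenario fig3c --out results/
```

## Acceptance script

`scripts/acceptance.R` exercises the package end to end: it integrates
the headline comparison scenarios and prints their survivor counts, runs
the four-case phase-plane analysis with and without crowding, sweeps the
crowding exponent over [0, 5], and cross-checks the scalar-reduction
equilibrium solver against long-time integration on 20 randomly drawn
communities (seeded). Run it from the repository root against the
installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
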