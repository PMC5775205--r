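---
title: "Crowding effects and multispecies coexistence in Lotka-Volterra competition"
author: "crowdingLV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowding effects and multispecies coexistence in Lotka-Volterra competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdingLV)
```

## The model family

Classical Lotka-Volterra (LV) competition assumes *linear* density
dependence: each additional individual reduces per-capita growth by the
same amount, and per-capita mortality is a constant. Under that
assumption complete competitors cannot coexist — one species excludes
the others (the competitive exclusion principle). Field populations,
however, often show a *crowding effect*: mortality climbs steeply once
density approaches the carrying capacity. This package studies a
minimal way of adding that effect to the LV skeleton: a power-law
mortality term in the species' own density,

$$\frac{dx_i}{dt} = b_i x_i \Big(1 - x_i - \sum_{j \ne i} \alpha_{ij}
x_j\Big) - \big(m_{i0} + d_i x_i^{\delta}\big)\, x_i ,$$

with densities scaled so that every carrying capacity is
$K_i = 1$. When all $d_i = 0$ the model *is* the classical LV system
(variant `"classical"`); when $d_i > 0$ the mortality rate
$m_i = m_{i0} + d_i x_i^\delta$ grows without bound in density, which
acts as extra *intra*specific pressure concentrated near $K$. That is
the mechanism of interest: because every species brakes itself hardest
near its own carrying capacity, total density settles well below the
level at which superior competitors could starve out inferior ones, and
many-species interior equilibria become attainable.

Two comparison variants isolate how specific this mechanism is:

* **Aggregation mortality** (`"aggregation"`):
  $m_{i0}\, x_i^{1+\varepsilon}$ replaces the whole mortality term. For
  small $\varepsilon$ this is a gentle, almost-linear distortion — but
  its inverse ($x_i \propto r^{1/\varepsilon}$ at equilibrium) is
  extremely steep, so equilibria spread over many orders of magnitude
  and coexistence of many similar species becomes fragile.
* **Nonlinear competition** (`"nonlinear_competition"`,
  `"combined"`): interspecific terms enter squared,
  $b_i x_i (1 - x_i - \sum_{j \ne i}\alpha_{ij} x_j^2) - m_i x_i$,
  weakening the impact of rare competitors. `"combined"` adds the
  crowding mortality on top.

### Generalizing the written two-species forms to n species

The source equations are written for two species; the multispecies
scenarios all use $\alpha_{ij} = 1$, for which the generalization above
is the only natural one (growth term $b_i x_i(1 - \sum_j x_j)$). Two
choices were genuinely open and are fixed here as package conventions:

* the competition sum uses $\alpha_{ii} = 1$ always; user-supplied
  diagonals different from 1 are rejected as structural errors, because
  the intraspecific coefficient is what the $K = 1$ normalization
  already fixed;
* in the squared-competition variants only *inter*specific terms are
  squared ($x_j^2$, $j \ne i$) and the own-density term stays linear,
  matching the written two-species form. Squaring the own term as well
  would make interior equilibria impossible for unequal birth rates
  (the bracket $1 - \sum_j x_j^2$ would have to equal $m_{i0}/b_i$ for
  every $i$ simultaneously), contradicting the multispecies coexistence
  the comparison is about.

## Parameters

| parameter | meaning | units | default / range used |
|---|---|---|---|
| $b_i$ | birth rate | 1/time | scenarios use $1 \le b_i \le 2$ |
| $m_{i0}$ | baseline mortality | 1/time | 0.1 or 0.3 |
| $d_i$ | crowding coefficient | 1/time | 0, 0.1, 0.3 or 0.5 |
| $\delta$ | crowding exponent | — | swept over $[0, 5]$ |
| $\varepsilon$ | aggregation exponent increment | — | 0.01 |
| $\alpha_{ij}$ | effect of species $j$ on $i$ | — | 1 in multispecies runs; 0.4--1.3 in the 2-species cases |
| $x_i(0)$ | initial density | fraction of $K$ | scenario-specific |

`lv_validate()` reports the study's stated ranges as *warnings*, not
errors: the published two-species cases themselves use
$\alpha_{ij}$ up to 1.3 against a stated range of $(0, 1]$, so the
ranges are treated as advisory. The constraint
$0 < m_{i0} + d_i \le 1$ (mortality must not exceed the birth-scaled
unit rate at carrying capacity) is likewise advisory. Structural
problems — negative rates, dimension mismatches, a non-unit diagonal —
are hard errors at construction time.

$\delta = 0$ is outside the model's stated domain $\delta \in (0,
\infty)$ but appears as the left endpoint of every published sweep. It
is supported as an *explicit degenerate mode* in which mortality is the
constant $m_{i0} + d_i$ (i.e. a classical model with a shifted
baseline), and flagged by `lv_validate()` and in sweep results.

## Numerical choices

**Integration.** No ODE-solver package is assumed; the integrator is a
compiled adaptive Dormand-Prince 5(4) scheme with embedded error
control, `rtol = 1e-8`, `atol = 1e-10`, and step-size limiting so that
output samples (default 501 over a horizon of 2000 time units) are hit
exactly. For $\delta < 1$ the mortality term is non-Lipschitz at
$x = 0$; the right-hand side therefore evaluates $x^\delta$ as 0 for
$x \le 0$, and after every accepted step negative components are
clamped to 0. Clamping magnitudes are tracked: anything above $10^{-9}$
raises a warning, since at that size it would no longer be attributable
to roundoff. In practice clamps stay far below $10^{-12}$ because
extinction trajectories approach the axis smoothly from above.

**Horizon and extinction threshold.** The source study never prints its
simulation horizon. The default, 2000 time units, is long enough that
every registered scenario passes `detect_steady_state()` (max
$|dx/dt| < 10^{-7}$) except the deliberately slow aggregation runs, and
the acceptance tests additionally verify that survivor counts are
unchanged at horizon 4000. The extinction threshold defaults to
$10^{-4}$ on the $K = 1$ density scale — 0.01% of carrying capacity —
and is recorded in every survivor report.

**Interior equilibria by scalar reduction.** With all
$\alpha_{ij} = 1$ and $d_i > 0$, equilibrium requires
$b_i(1 - S) - m_{i0} = d_i x_i^\delta$ with $S = \sum_j x_j$, so each
positive density is an explicit function of the total:
$x_i(S) = \max\big(0, (b_i(1-S) - m_{i0})/d_i\big)^{1/\delta}$. The map
$g(S) = \sum_i x_i(S) - S$ is strictly decreasing, positive near 0
whenever any species can grow, and equals $-S < 0$ at
$S_{\max} = \max_i (1 - m_{i0}/b_i)$, so bisection on
$(0, S_{\max}]$ is guaranteed to bracket the unique root; it is run to
a bracket width of $10^{-12}$, giving RHS residuals around
$10^{-11}$ or better. If no positive density exists anywhere the solver
reports absence rather than returning a boundary state. General
$\alpha$ matrices are refused with a pointer to `lv_integrate()` —
there the equilibrium structure is genuinely multidimensional.

**Stability.** Jacobians are analytic for every variant. The apparent
$x^{\delta-1}$ singularity of $\partial m_i/\partial x_i$ at the axis
cancels in the product rule: $\partial\,[m(x)x]/\partial x = m_0 +
d(\delta+1)x^\delta$, which is finite and continuous for all
$\delta > 0$, so the analytic form is used on the whole closed orthant
and no finite-difference fallback is required (a central-difference
implementation is kept as a cross-check and agrees to better than
$10^{-6}$ relative error on random interior states). An equilibrium is
classified `stable`/`unstable` when the largest eigenvalue real part
clears a margin of $10^{-7}$, and `marginal` inside the band — the band
matters for genuinely degenerate configurations such as the classical
model with identical species and $\alpha = 1$, which has a whole line
of equilibria and an exact zero eigenvalue.

**Isoclines.** In the two-species phase plane the zero isocline of
species 1 is closed form for *every* $\delta$ (the crowding term
involves only $x_1$, the coordinate being gridded), giving
$x_2 = (b_1(1 - x_1) - m_{10} - d_1 x_1^\delta)/(b_1\alpha_{12})$. For
species 2 the condition must be solved for $x_2$ at each grid value of
$x_1$: closed form when $d_2 = 0$ (the classical straight line through
$(K, 0)$ and $(0, K/\alpha)$) or $\delta = 1$, otherwise by bracketed
root-finding on $[0, 2]$ — safe because the per-capita condition is
strictly decreasing in $x_2$. Grid points with no nonnegative solution
are omitted. The default extent $[0, 1.4]$ covers all intercepts of the
published cases at $K = 1$.

**Phase-plane cases and E1.** The four classical cases are classified
from the sign pattern of $K_2 - K_1/\alpha_{12}$ and $K_1 -
K_2/\alpha_{21}$; equality within $10^{-12}$ is reported as
`degenerate` rather than forced into a label. In the exclusion cases
the reference equilibrium E1 of `equilibrium_shift()` is defined as the
attractor actually reached from the scenario's initial condition — a
boundary state — not the unstable interior crossing, because that is
the state against which the crowding-induced interior equilibrium E2 is
meaningfully compared.

**Sweeps.** Default grids follow the published ranges: 51 points on
$\delta \in [0, 5]$, 26 points on $[0, 1]$, and 26 points on
$d \in [0, 0.5]$ for the ratio surface (resolutions are not printed in
the source and are package choices). Every grid row is an independent
integration from the same initial state; results are deterministic and
independent of execution order by construction, and
`regime_boundary()` reports coexistence windows at grid resolution
without sub-grid refinement. Ratio-surface cells whose denominator
species is below the extinction threshold are `NA`, not infinities.

## The scenario registry as a stated world

`lv_scenario()` transcribes every published figure panel into a fixture
(`fig1a`..`fig6i`), with sweep-product panels registered as sweep or
surface scenarios. These fixtures *are* the tested world: parameters,
initial densities and thresholds come from the captions, and the
defaults above fill only what the captions omit (horizon, grid
resolutions, and the single drawn-isocline $\delta$ of the `fig1*`
fixtures, which defaults to 1 — the value at which coexistence is
reported to occur — and is exposed as an argument). A green test
therefore establishes that *these equations at these parameters*
behave as asserted; it does not establish anything about demographic
noise, spatial structure, Allee effects at low density, or parameter
regimes outside the stated ranges, none of which are modelled.

## Reproducibility notes

The acceptance tests (`tests/testthat/test-acceptance.R`) assert the
source study's headline claims exactly as stated, and the suite leaves
a claim red when a faithful integration of the stated equations cannot
reproduce it. Three such discrepancies are worth recording, all
confirmed by the package's own equilibrium solver and independently by
a second ODE implementation during development:

* **10-species crowding run (`fig6g`), "seven species survive".** Under
  the captioned parameters ($m_{i0} = 0.1$, $d = 0.3$, $\delta = 0.4$,
  $b_i = 1 + 0.1(i-1)$) the scalar reduction yields a unique interior
  equilibrium with *all ten* densities at or above 0.006 — robustly
  above any sensible threshold, stable, and horizon-independent.
  Rerunning the same panel with $m_{i0} = 0.3$ (the value the caption
  assigns to the *other* panels) yields exactly seven survivors, which
  strongly suggests the published count comes from a baseline-mortality
  inconsistency between caption and code. The package implements the
  caption.
* **2-species nonlinear competition (`fig6b`), "one species extinct".**
  The system $b = (1.0, 1.1)$, $m_{i0} = 0.3$ has a unique interior
  equilibrium near $(0.276, 0.651)$ that is reached from the captioned
  initial condition; no integrator or horizon choice produces an
  extinction.
* **10-species aggregation run (`fig5f`), "five species survive".** At
  the default threshold all ten species are above $10^{-4}$ at horizon
  2000 (nine asymptotically). Five is what one counts with a *visual*
  threshold of roughly 0.01: species 6--10 end at 0.02--0.52, species
  1--5 at or below 0.009. The aggregation equilibrium
  $x_i \propto (b_i(1-S)/m_{i0})^{1/\varepsilon}$ with
  $\varepsilon = 0.01$ spreads similar species over orders of
  magnitude, so the qualitative contrast with the crowding model —
  which keeps all ten at commensurate densities — is real even though
  the printed count depends on the threshold.

Two further quantitative claims hold only approximately: the
$\delta$-regime statement (coexist at small $\delta$, exclusion by
$\delta = 5$) is exact for the unequal-$\alpha$ two-species cases
(`fig2a/b/d`, verified green in the sweep tests) but not for the
equal-$\alpha$, unequal-$b$ setup of `fig3`, whose interior equilibrium
remains stable over the whole swept range; and the "equal density"
property of the nonlinear-competition equilibria is visual rather than
exact — the measured coefficients of variation are 26% (5 species) and
12% (10 species), since $b_i(1 - x_i - \sum_{j\ne i} x_j^2) = m_{i0}$
cannot cancel distinct $b_i$ exactly.

## Limitations

Beyond the scope limits above: the equilibrium solver covers only the
$\alpha = 1$ crowding variant (other configurations go through
integration); no continuation or branch tracking of equilibria across
parameter values is attempted — sweeps re-integrate from the same
initial condition instead, which is what the published figures show;
separatrices of the bistable case d are not computed; and the
integrator is explicit, which is adequate here (the stiffness induced
by $\delta < 1$ powers near the axis is mild) but would need revisiting
for much larger rate constants.
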