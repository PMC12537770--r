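---
title: "Three-species competition dynamics: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-species competition dynamics: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvtrio)
```

# The question and the models

A resident *E. coli*–yeast co-culture, propagated by daily batch growth and
dilution, is challenged by a third, bacterial species. Whether the invader
establishes, excludes a resident, or is itself excluded is treated as a
deterministic outcome of three-species competitive Lotka–Volterra dynamics
observed at the end of a 24-h batch.

The classic field (`derivatives_classic()`) is

$$\frac{dN_i}{dt} = N_i r_i \left(1 - \frac{N_i + \sum_{j \ne i} \alpha_{ij} N_j}{K_i}\right),$$

with $\alpha_{ij}$ the per-capita effect of species $j$ on species $i$
relative to $i$'s self-limitation. The frequency-dependent field
(`derivatives_freqdep()`, the package default) replaces each interspecific
term by

$$\alpha_{ij}\,\frac{N_j}{N_E + N_Y + N_B}\,N_j,$$

leaving the self term unweighted. The weighting captures encounter-rate
dilution in a well-mixed batch: a numerically rare species, however large
its $\alpha$, exerts little pressure. Two properties matter for the
analysis and are enforced by tests: the two fields coincide whenever all
interspecific $\alpha$ are zero, and setting one species' density to zero
reduces the three-species frequency-dependent model exactly to the
two-species one. The frequency-dependent pair model is what admits a stable
*E. coli*–yeast equilibrium frequency approached from either rare side,
which is the empirical behaviour the resident community shows; the classic
field is retained for comparison.

Assumptions worth stating: purely competitive interactions
($\alpha_{ij} \ge 0$); no demographic stochasticity, no explicit resources,
no evolution within a simulation; batch conditions are identical across
cycles; dilution is instantaneous and unbiased across species.

# Parameters, units, defaults

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| $r_E, r_Y, r_B$ | h⁻¹ | 0.7, 0.35, 0.6 | bacteria roughly twice as fast as yeast; all strains reach carrying capacity within a 24-h batch |
| $K_E, K_Y, K_B$ | cells/mL | 10⁹, 10⁸, 10⁹ | bacterial saturation densities near 10⁹; yeast about tenfold lower, giving the ~10:1 *E. coli*:yeast abundance ratio seen at pair equilibrium |
| $N_{0,E}, N_{0,Y}, N_{0,B}$ | cells/mL | 10⁷ each | the mixing density used when species are co-cultured with yeast |
| $\alpha_{ij}$ (off-axis) | — | 0.01 | effectively non-interacting background, the baseline all sweeps hold fixed |
| extinction threshold | cells/mL | 10⁴ | see below |
| dilution factor | — | $2^{-10}$/day | two sequential 1:2⁵ dilutions per daily cycle; 10 doublings/day, 70 generations over 7 cycles |
| cycle length | h | 24 | daily transfer |
| equilibration | cycles | 3 | pair-only cycles before the invader is introduced |

The exact empirical $r$ and $K$ values behind the published phase diagrams
are not available here; the defaults above are representative values chosen
once from the documented densities and growth behaviour. The qualitative
structure of the phase diagrams — which boundaries exist and roughly where —
is robust to moderate changes in these values, and the acceptance checks
accordingly allow a ±0.5 band on boundary positions. Everything is
overridable through `lv_community()` or a YAML config (`read_config()`).

**Extinction threshold.** Classification happens at the end of the 24-h
batch (`classify_simulation()`, with `at_any_time = TRUE` as an option). A
population at 10⁴ cells/mL is counted extinct because the serial protocol,
approximated as a 1000× daily dilution, drives a competitively suppressed
population of that size below a single cell within two further cycles
(`extinction_rationale()`: 10⁴ → 10 after dilution → ~10² after a day of
roughly tenfold suppressed regrowth → below one cell at the next dilution).
Within a simulated transfer, populations below 10⁻³ cells/mL at a cycle
boundary are floored to zero so that physically extinct populations cannot
regrow from numerically tiny remnants.

# Phase-diagram sweeps

`run_sweep()` varies two coefficients over 0–3 in steps of 0.01 (endpoints
inclusive, hence 301 × 301 cells; inclusivity is our choice, the grid
resolution is the protocol's), holds the other four at 0.01, integrates the
frequency-dependent model for a single 24-h batch per cell — the sweep
emulates one batch, not the full week of transfers — and classifies the
endpoint. Each cell is a pure function of the spec, so grids are
deterministic and order-independent; `find_boundary()` reports transitions
at grid resolution (±0.01) without bisection refinement. Five outcome
categories are used: coexistence, single-species extinctions (competitor /
*E. coli* / yeast), and an explicit `multiple_extinct` for cells where two
or more species fall below threshold, which the published four-colour
legend does not need but which general grids can produce.

On the default parameterisation the two headline boundaries along
$\alpha_{BE}$ (the effect of *E. coli* on the competitor) are: with
$\alpha_{YB} = 3$, yeast is rescued from extirpation once
$\alpha_{BE}$ exceeds ~1 (computed boundary 1.02); and the competitor is
itself excluded once $\alpha_{BE}$ exceeds ~2 (computed boundary 2.26 on
the weak-interaction slice). These are recomputed from scratch by
`scripts/acceptance.R`.

# Growth-curve fitting

`fit_logistic()` fits $N(t) = K/(1 + ((K - N_0)/N_0)e^{-rt})$ by bounded
Levenberg–Marquardt least squares. Initialisation: $K$ from the maximum
OD, $N_0$ from the first positive reading, $r$ from the log-linear slope of
the early phase (fallback 0.1 h⁻¹ if that slope is unusable). All
parameters are constrained positive. A flat or declining series, or any fit
yielding $r \le 0$, returns `converged = FALSE` with reason "no growth
detected" rather than raising — plates routinely contain blanks and failed
wells, and a fit table should carry them. Optional constant blank
subtraction floors corrected values at 10⁻⁶ OD.

Two open choices were resolved as follows. The spent-media metric
(`spent_media_difference()`, growth in spent over growth in fresh minus 1)
defaults to **maximum OD** as its growth measure, the stationary-phase
density being the quantity the spent-media comparison is framed around;
comparisons on the fitted rate are available by simply passing `r_fit`
values instead. The growth-rate prediction rule
(`predict_pairwise_outcome()`) is stated in one direction — a competitor
more than 1 SD faster excludes the focal strain; within 1 SD they coexist —
and we apply the mirrored rule symmetrically, each comparison measured
against the *threatened* strain's own replicate SD (the slower strain's
uncertainty is what determines whether the gap is credible). A gap of
exactly 1 SD counts as "within", hence coexistence.

# Numerical choices

Integration uses `deSolve::lsoda` with the derivative fields compiled in C,
relative tolerance 10⁻⁸ and absolute tolerance 10⁻³ cells/mL; output is
clamped at zero. Verification is dual-route: endpoints agree with a
fixed-step classical RK4 oracle at $dt = 0.001$ h to within 10⁻⁴ relative,
and with the logistic closed form to within 10⁻⁶ relative when all
interspecific $\alpha$ are zero. Dilution between cycles is exact
multiplication, so the start of cycle $k{+}1$ equals the end of cycle $k$
times the dilution factor bit-for-bit. Zero-total-population states are
given zero rates (avoiding 0/0 in the frequency weights). Degenerate
inputs — fewer than four OD points, non-monotone times, ties in the
replicate majority vote, zero chi-square marginals, zero-variance paired
differences — raise immediately with messages naming the problem.

# What the synthetic data does and does not emulate

The generators reproduce the statistical structure the pipeline assumes:
logistic OD curves sampled every 10 min over 24 h with i.i.d. Gaussian
measurement noise floored at zero, randomised 96-well layouts with five
replicates per strain; two-gate flow-cytometry counts as a binomial split
of up to 10⁵ events (relative frequencies only, as cytometry provides);
CFU spot counts as Poisson draws with mean density × 20 µL × dilution; and
replicated competition series in which the dynamics are deterministic and
replicates differ only in observation noise. They do **not** emulate
instrument drift, well-position or evaporation effects, gating error,
plate-to-plate batch effects, demographic stochasticity, or evolution
during the experiment. Passing the recovery tests therefore shows the
pipeline is correct and well-conditioned under its own noise model, not
that real plates meet that model.

Problem sizes used by the test suite and acceptance script: 50-curve
recovery batteries at noise SD 0.01 OD; RK4 oracle batteries of four or
five random parameter draws over 24 h; one full 301 × 301 sweep plus
301-point slices; 7-cycle transfer simulations. These sizes make the
recovery medians and boundary positions stable to well within the asserted
tolerances.

# Known limitations

* Outcomes are endpoint classifications of deterministic ODEs; near-boundary
  cells (within a step or two of a phase boundary) can flip under small
  parameter changes, which is why boundary assertions carry a ±0.5 band.
* The 24-h single-batch sweep ignores multi-day transient effects a full
  serial-transfer sweep might reveal; `simulate_serial_transfer()` exists
  precisely so users can check particular cells over the full week.
* No more than three species, no resource-explicit dynamics, no Gompertz or
  Baranyi growth alternatives, no priority-effect (inoculation-order)
  modelling beyond the delayed-invader protocol.
* The chi-square and paired-t utilities are deliberately small; they are not
  a general statistics layer.
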