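# lvtrio

Tools for asking when a two-species microbial community resists invasion by
a third species. The motivating system is a co-evolved *Escherichia
coli*–*Saccharomyces cerevisiae* (yeast) co-culture propagated by daily
serial transfer and challenged with an invading bacterial competitor; the
package provides the full computational side of that analysis for anyone
studying pairwise and three-way competition in batch co-culture:

* **Growth kinetics** — logistic fits of plate-reader OD curves
  (`fit_logistic()`, `fit_plate()`), the spent-media resource-overlap metric
  (`spent_media_difference()`), and a growth-rate-based predictor of
  pairwise competition outcomes (`predict_pairwise_outcome()`).
* **Community dynamics** — classic and frequency-dependent three-species
  Lotka–Volterra models (`lv_community()`, `integrate_batch()`), daily
  serial-transfer and delayed-invader protocols
  (`simulate_serial_transfer()`, `simulate_invasion()`).
* **Outcomes** — extinction-threshold classification of simulation
  endpoints (`classify_simulation()`), majority-rule designation of
  replicated experiments (`classify_replicates()`), assay detection limits,
  and the small statistics the analysis needs (`chi_square_2x2()`,
  `paired_t_and_bonferroni()`).
* **Phase diagrams** — sweeps of interaction-coefficient pairs with
  per-cell outcome classification (`sweep_spec()`, `run_sweep()`,
  `find_boundary()`, `export_phase_diagram()`).
* **Synthetic data** — generators for every input class (noisy OD plates,
  two-gate flow-cytometry counts, Poisson CFU spot counts, replicated
  competition series), so the whole pipeline is testable without any
  external data.

## The model

Populations `N_E`, `N_Y`, `N_B` (cells/mL) of *E. coli*, yeast and the
competitor follow competitive Lotka–Volterra dynamics,

    dN_i/dt = N_i r_i (1 − (N_i + Σ_j α_ij N_j) / K_i)

with intrinsic growth rates `r_i` (h⁻¹), carrying capacities `K_i` and
interaction coefficients `α_ij` (the effect of species j on species i). The
frequency-dependent variant, used for all phase-diagram work, weights each
interspecific term by the partner's relative abundance:

    α_ij N_j  →  α_ij (N_j / (N_E + N_Y + N_B)) N_j

so that a rare species exerts little pressure regardless of its α — which is
what lets an *E. coli*–yeast pair sit at a stable equilibrium frequency and
makes invasion outcomes depend on how strongly the residents push back.
A species is classified extinct when its population is at or below 10⁴
cells/mL after a 24-h batch: under the ~1000× daily dilution of the transfer
protocol, a suppressed population at that size is diluted to extinction
within two further days (`extinction_rationale()`).

## Worked example

Invade an equilibrated *E. coli*–yeast pair with a competitor that *E. coli*
suppresses strongly (`α_BE = 2.5`), using the default representative
parameters:

```r
library(lvtrio)
comm <- default_community(alphas = interaction_matrix(alpha_BE = 2.5))
traj <- simulate_invasion(comm, equilibration_cycles = 3, total_cycles = 7)
traj
#> LV trajectory: 1687 points, 168 h, 7 cycle(s)
#>   final state: N_E = 1e+09, N_Y = 5.68e+07, N_B = 0 cells/mL
classify_simulation(final_state(traj))
#> competitor_extinct (extinct: B)
```

The pair equilibrates for three daily cycles, the competitor is introduced
at 10⁷ cells/mL, and because `α_BE > 2` the residents exclude it: its
population hits the extinction floor while *E. coli* and yeast persist near
their joint equilibrium (~95% *E. coli*, matching the roughly 10:1
abundance ratio of the empirical pairs).

Fitting a noisy growth curve and quantifying spent-media growth:

```r
tt <- seq(0, 24, by = 1/6)                       # 10-min sampling, 24 h
set.seed(42)
od <- logistic_od(tt, K = 1, r = 0.5, N0 = 0.01) + rnorm(length(tt), 0, 0.01)
fit_logistic(growth_curve(tt, od, sample_id = "A1", strain_id = "ecoli"))
#> Logistic fit [A1]: K = 0.9978, r = 0.5063 /h, N0 = 0.009502 (SSE 0.0144)
spent_media_difference(0.52, 0.95)
#> [1] -0.4526316
```

The fitted `r` and `K` recover the generating values within the noise, and
the spent-media metric of −0.45 says the strain reaches less than half its
fresh-media growth in media its competitor has already exhausted.

A command-line entry point wrapping the same functions is installed at
`system.file("scripts", "lvtrio", package = "lvtrio")`, with subcommands
`fit-growth`, `simulate`, `invade`, `sweep`, `classify` and `synth`; every
run writes a JSON manifest recording inputs, configuration, seed and
versions.

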