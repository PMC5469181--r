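# cryptdrift

Mutation accumulation in intestinal stem-cell niches: how somatic drift
ages an epithelium, and why niche size is a trade-off between aging and
tumorigenesis.

Renewing epithelia are maintained by many small, independent stem-cell
populations. Each crypt's niche of `X1` stem cells divides symmetrically at
rate λ and competes neutrally for space; displaced cells commit to
differentiation at rate ν, amplify through `R` transit-amplifying
doublings, and sustain a postmitotic pool with steady state

    Z* = 2^R ν λ X1 / (δ (ν − λ)).

Mutations that change λ fix in the niche with the Moran-ring probability
`(1 − 1/r)/(1 − r^−X1)`; mutations that change ν are invisible inside the
niche and fix neutrally at `1/X1`. Drawing effects from a mirrored
exponential DFE (beneficial fraction `P_B`, means `s+`/`s−`), weighting by
fixation, and iterating over successive fixed mutations gives the expected
drift of the niche rates — a somatic Muller's ratchet — which propagates
through `Z*` to whole-tissue attrition curves, and whose tail beyond the
rate-ordering inversion λ > ν gives the probability of tumorigenesis. The
package is aimed at modellers of somatic evolution and stem-cell dynamics
who want these pipelines as tested, composable functions.

## What is in the box

* `crypt_parameters()`, `crypt_steady_state()`, `integrate_means()`,
  `commitment_rate()`, `population_ratio()` — the deterministic crypt
  compartment model.
* `dfe_parameters()`, `dfe_yeast()`, `fixation_probability()`,
  `fixation_summary()`, `posterior_fixed_density()`, `density_sequence()`,
  `expected_effect_boundary()` — the mutation-fixation machinery.
* `tissue_scenario()`, `mutation_count_distribution()`,
  `tissue_trajectory()`, `linear_slope()`, `human_scenarios()` —
  organism-scale attrition.
* `crossing_probability()`, `tumor_probability()`, `niche_size_scan()` —
  the aging/tumorigenesis trade-off at constant tissue output.
* `gillespie_crypt()`, `ring_fixation()`, `serial_ratchet()` — exact
  stochastic simulators used as independent oracles.
* `scenario_preset()`, `run_report()` — mouse small-intestine and human
  colon parameterizations and an end-to-end summary table.

The `analysis/` directory holds the numbered workflow
(`01_crypt_steady_state.R` … `05_stochastic_checks.R`); each script prints
what it finds and writes tables under `results/`.

## Worked example

```r
library(cryptdrift)

mouse <- scenario_preset("mouse_si")
crypt_steady_state(mouse$crypt)
#> Crypt steady state (cells):
#>   X2 = 9
#>   Y  =  1.5,  3.0,  6.0, 12.0, 24.0, 48.0  (total 94.5 )
#>   Z  = 576

fixation_summary(6, dfe_yeast(), "division", lam0 = 0.2)
#> Fixation summary (division, X1 = 6): p_hat = 0.10314,
#>   E[ratio] = 0.90608, mu_hat = 1.559e-05 /crypt/day

scn <- tissue_scenario(mouse$crypt, dfe_yeast(), "division", 1095)
tr <- tissue_trajectory(scn)
100 * (1 - tr$fraction[nrow(tr)])
#> 0.351
```

Reading: the mouse crypt's six TA pools and 576 postmitotic cells follow
from the closed-form steady state. A fitness-affecting mutation in the
6-cell niche fixes with total probability 0.103 (mostly by drift), and the
expected division rate *falls* by 9.4% per fixed mutation; over three
adult years the expected epithelium shrinks by 0.35%. The same pipeline
with human colon parameters gives 0.5% (20-cell niche) to 12% (6-cell
niche) lifetime decline for division-rate mutations, and 5.8% to 22% for
neutrally fixing differentiation-rate mutations (`human_scenarios()`).

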