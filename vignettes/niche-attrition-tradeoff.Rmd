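---
title: "Somatic drift in stem-cell niches: model, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic drift in stem-cell niches: model, methods, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptdrift)
```

## The model

Intestinal epithelium is renewed by small, independent populations of stem
cells. Each crypt carries a niche of `X1` "working" stem cells that divide
symmetrically at rate $\lambda$ and compete neutrally for space; displaced
stem cells ($X_2$) keep dividing at $\lambda$ and commit to differentiation
at rate $\nu$; committed cells double through $R$ transit-amplifying (TA)
rounds at rate $\gamma$ and enter the postmitotic pool $Z$, which dies at
rate $\delta$. The niche size is held fixed, and homeostasis requires
$\nu > \lambda$. The stationary postmitotic pool is

$$Z^* = \frac{2^R \nu \lambda X_1}{\delta(\nu - \lambda)},$$

which `crypt_steady_state()` evaluates both from this closed form and from
the terminal TA flux $2\gamma Y_R^*/\delta$ (the two must agree to relative
$10^{-12}$). A key property of $Z^*$ is amplification: a mutation that
changes $\lambda_0$ to $\lambda_1$ changes the tissue by
$(\lambda_1/\lambda_0)\,(\nu-\lambda_0)/(\nu-\lambda_1)$, so a 10% rate
change moves the tissue by over 20% at mouse parameters
(`population_ratio()`).

With the mouse parameters (6-cell niche, $\lambda = 0.2$/d, 15 LGR5+ cells
total so $\nu = 1/3$/d, $\gamma = 2$/d, $R = 6$, 3-day postmitotic
lifespan), the TA pools are $(1.5, 3, 6, 12, 24, 48)$ and $Z^* = 576$
cells. The same displaced-pool balance gives the human colon commitment
rates: $\nu = \lambda\,T/(T - X_1)$ with $T = 36$ putative stem cells and
weekly division, i.e. 0.171/d for a 6-cell niche and 0.321/d for a 20-cell
niche (`commitment_rate()`).

Because $X_2$, the TA pools, and $Z$ are all linear amplifiers of the niche
output, mutation accumulation is modelled entirely inside the niche and
propagated through $Z^*$.

## Mutations, fixation, and the somatic ratchet

Fitness-affecting mutations arrive at rate $\mu$ per division, i.e. at
$\mu \lambda_0 X_1$ per niche per day. Their proportional effect on the
targeted rate follows a mirrored exponential: beneficial with probability
$P_B$ and mean effect $s_+$, deleterious otherwise with mean $s_-$. For
division-rate mutations, "beneficial" raises $\lambda$; for
differentiation-rate mutations it lowers $\nu$ (longer-lived output), and
the deleterious branch is unbounded upward. The branch truncated at rate
zero is renormalized to its own mass, so the beneficial fraction remains
exactly $P_B$ (`dfe_density()`, flag `renormalize`). All worked scenarios
use the budding-yeast mutation-accumulation estimates
$\mu = 1.26\times 10^{-4}$, $s_+ = 0.061$, $s_- = 0.217$, $P_B = 5.75\%$
(`dfe_yeast()`); these are the only DFE measurements of comparable
completeness, and absolute magnitudes downstream inherit their uncertainty.

A mutant lineage with relative division rate $r$ fixes in a ring of `X1`
competing cells with probability $(1 - r^{-1})/(1 - r^{-X_1})$
(`fixation_probability()`; the neutral limit $1/X_1$ is substituted within
$10^{-8}$ of $r = 1$ to avoid catastrophic cancellation). Differentiation-
rate mutations are invisible inside the niche and fix neutrally at $1/X_1$.
Weighting the DFE by fixation and normalizing gives the posterior density
of the rate after one *fixed* mutation; its normalizer $\hat p$ is the
total fixation probability, and $\hat\mu = \hat p\,\mu\,\lambda_0 X_1$ is
the arrival rate of fixed sweeps (`fixation_summary()`,
`posterior_fixed_density()`). Iterating the posterior as a Markov kernel
gives the rate density after $m$ fixations (`density_sequence()`); because
small niches fix deleterious mutations by drift, the expected division rate
declines with every fixation — Muller's ratchet in somatic tissue.

Two facts make the pipeline cheap and well-conditioned:

* the posterior relative effect is scale-free, so the expected rate after
  $m$ fixations is exactly $r_0 \rho^m$ with
  $\rho = E[\text{posterior ratio}]$; trajectories and slopes use this
  closed route, while the full kernel recursion provides densities (and a
  cross-check — the two agree to $<10^{-3}$ in the tests);
* $\hat p$ and $\rho$ are one-dimensional integrals, evaluated by adaptive
  quadrature on each branch's own exponential scale (substituting
  $u = \text{effect}/s$), which keeps them accurate for arbitrarily small
  effect sizes (the drift limit $\hat p \to 1/X_1$ is recovered to
  $10^{-4}$).

## Tissue dynamics and human projections

Fixed sweeps arrive as a Poisson process, so at age $t$ a fraction
$e^{-\hat\mu t}(\hat\mu t)^m/m!$ of crypts carries $m$ fixed mutations
(`mutation_count_distribution()`). The expected epithelium is the mixture
of the per-$m$ steady states; by default the expected rate is plugged into
$Z^*$ (`tissue_trajectory()`, mode `"expected_rate"`). The alternative
`"expected_z"` averages $Z^*$ over the full density, restricted to
non-tumorigenic crypts; $Z^*$ is convex in the rate, so this Jensen gap
makes the default slightly pessimistic (about $6\times10^{-4}$ of the
tissue for the mouse scenario — documented rather than hidden).

The curves are nearly linear in $t$, and the first-order slope has closed
forms: for division-rate mutations
$-\theta \lambda_0 \mu \hat p X_1 (r_\lambda - 1)/(r_\lambda - \theta)$
with $\theta = \nu/\lambda_0$, and for differentiation-rate mutations
$-\mu \lambda_0 (r_\nu - 1)/(\theta r_\nu - 1)$, which contains neither
$X_1$ nor $\hat p$: neutral fixation ($1/X_1$) exactly cancels the mutation
supply ($\mu\lambda_0 X_1$). The slopes involve no TA or postmitotic
parameters, which is what allows human projections at all
(`linear_slope()`, `human_scenarios()`): mouse TA/death rates are carried
in the human presets only as placeholders that the slope never reads.
Lifetimes are 3 adult years for the mouse and 75 for humans
(config-overridable). The resulting end-of-life declines — 0.35% (mouse,
division), 0.50% and 11.7% (human, division, niche 20/6), 5.8% and 22.4%
(human, differentiation) — are what `scripts/acceptance.R` recomputes.

## The tumorigenesis trade-off

A crypt turns tumorigenic when the rate ordering inverts
($\lambda > \nu$): the mass of the $m$-fixation density beyond the
opposing rate is the crossing probability $q_m$
(`crossing_probability()`), and crypt-weighted increments
$n_m \Delta q_m$ summed over $m$ give the tissue-level probability
(`tumor_probability()`). Two readings of "summed over all mutations" are
implemented: incremental $\Delta q_m$ (default; a crossed crypt is not
recounted, and increments are floored at zero because late in the ratchet
the upper tail is dragged *down* again) and the literal cumulative sum.
Both give the same optimum in the niche-size scan.

`niche_size_scan()` varies `X1` with half of the putative stem cells in
the niche (so $\nu = 2\lambda$ at every size; a fixed-$\nu$ variant is a
flag) and crypt number $\propto 1/Z^*(X_1)$ so total tissue output is
constant. For division-rate mutations tumour risk has an interior minimum:
small niches mean many crypts and drift-prone fixation; large niches give
selection more power to fix the rare large beneficials. At mouse
parameters the scan's minimum falls at $X_1 = 6$, with $X_1 = 7$ within
0.3% on a valley that is flat to ~0.5% across 5–9 — the optimum sits at
the empirically reported niche size, but its exact integer location is not
robust (it moves by one cell when the assumed lifetime changes by a factor
of ~1.5, and the two aggregation modes agree on 6). For
differentiation-rate mutations the risk is proportional to $1/X_1$ (no
optimum) while attrition is exactly niche-size invariant — the trade-off
only exists when mutations are under selection in the niche. Absolute
tumour probabilities scale with the assumed crypt counts
($10^6$ mouse, $10^7$ human colon, order-of-magnitude conventions) and are
not meaningful beyond shape and cross-species ordering.

## Stochastic validation

`stochastic` counterparts validate every analytic layer, with fixed seeds
and lockstep-vectorized replicates:

* `gillespie_crypt()` — exact (direct-method) realizations of the crypt
  transition system; ensemble means agree with the mean-field ODE
  (`integrate_means()`, stiff-capable `lsoda` at rtol $10^{-9}$, since
  $\gamma \gg \lambda$ separates scales) within Monte-Carlo error.
* `ring_fixation()` — explicit cells-on-a-ring dynamics (divider replaces
  a uniformly chosen neighbour; a directed variant would only rescale
  time); frequencies match the fixation formula within binomial error, at
  $10^5$ replicates in the acceptance checks. It also measures how many new
  mutations arise during one fixation/loss sweep: below one per sweep for
  all scanned niche sizes (0.13 at $X_1 = 50$), supporting the
  one-mutant-at-a-time assumption. Conditional on fixation the count
  exceeds one for $X_1 \gtrsim 30$, so the assumption thins at the large
  end of the scan; both statistics are reported.
* `serial_ratchet()` — draw-accept simulation of successive fixations;
  ensemble means match the kernel recursion.

## Numerical choices

The density recursion runs on a log-spaced rate grid (default $2^{12}$
nodes; $2^{11}$ inside scans) with the baseline rate exactly on a node:
the rate after $m$ fixations is a product of relative effects, so constant
relative resolution keeps every kernel column equally resolved, and the
density's jump discontinuity at the baseline lands on the diagonal node
(assigned the two-sided average, which restores second-order trapezoid
accuracy). Grid spans are sized from closed-form tail bounds
(equal-split-dominated for products of exponentials), the mass outside the
grid is checked analytically at construction ($<10^{-8}$) and at the grid
edges on every iteration, and a grid-doubling test pins the resolution
error. Each kernel column is the discretized posterior at one baseline —
itself a normalized density — so columns are normalized to unit trapezoid
mass and the recursion conserves probability to machine precision; the
quadrature-consistency guard (discrete vs adaptive mass, $2\times10^{-3}$)
catches grossly under-resolved grids instead.

Problem sizes were chosen for desk-scale reproducibility: scans over
$X_1 = 2..30$ at $2^{11}$ grid nodes, Gillespie ensembles of a few hundred
replicates over 50–100 days, $10^4$–$10^5$ fixation replicates. The full
test suite and the acceptance script each run in a few minutes on one CPU.

## Limitations

The simulators and pipeline emulate an idealized crypt: fixed niche
size, no crypt fission or Paneth cells, no spatial structure beyond the
one-dimensional ring (bowl-like or weighted geometries would weaken
selection), a single exponential DFE without epistasis or mutators, and no
compensatory feedback on mutant crypts. Passing tests therefore show
internal consistency of this model and its published parameterizations —
not that real epithelium ages at these rates. Absolute tumour
probabilities and the exact integer location of the optimal niche size are
the least robust outputs; directions, orderings, invariances, and the
existence of the interior optimum are the robust ones.
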