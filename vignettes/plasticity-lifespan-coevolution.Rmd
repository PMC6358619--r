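---
title: "Coevolution of reversible plasticity and life history: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coevolution of reversible plasticity and life history: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastevol)
```

## The question the model asks

Organisms that can repeatedly revise their phenotype during life —
reversible plasticity — should suffer less from becoming "out of date" as
their environment drifts away from the state they last matched. If being
out of date is a form of senescence, plasticity might not merely *require*
a long life to pay off; it might *select for* one, by shifting the classic
reproduction–survival trade-off towards survival. `plastevol` implements an
individual-based model in which both traits are heritable and free to
coevolve: `u`, the updating schedule (how steeply the per-step probability
of refreshing the phenotype rises with time since the last refresh), and
`r`, reproductive effort. Lifespan is not a parameter anywhere — it emerges
from mortality, which is shaped by both genes.

## Model structure

**Environment.** A scalar optimum follows
\(E_t = p\,E_{t-1} + (1-p)\,\zeta_t\), \(\zeta_t \sim N(0,1)\). The weight
`p` sets the autocorrelation, but note it also sets the stationary variance
\((1-p)/(1+p)\): slow environments are also narrow ones. To separate the
two effects the package provides an ARMA(2,1) environment family whose
lag-1 autocorrelation and total variance can be targeted independently
(`arma21_from_target()`); the shape coefficients (`ar2`, `ma1`) are fixed,
the first AR coefficient is solved by root-finding on the theoretical
autocorrelation (`stats::ARMAacf()`), and the innovation SD is rescaled
through the psi-weight variance. By default `simulate_env()` draws
\(E_0\) from the stationary distribution so no burn-in is needed; an
all-zeros start is available as an option.

**Individuals.** Each carries phenotype `x`, genes `u` and `r`, age, and
the integer time \(T_u\) since its last update. At the start of each step
ages and \(T_u\) increment; an individual then updates with probability
\(1 - e^{-u T_u}\). Newborns have no defined \(T_u\) (encoded as `NA`) and
update with probability 1 — some plasticity always occurs. An update sets
\(x \leftarrow E_t + N(0, \epsilon)\) and resets \(T_u\) to 0; since
probability at \(T_u = 0\) is 0, the first opportunity after an update uses
\(T_u = 1\), making `u` a per-step updating intensity. Both `N(0, 0.01)`
(mutation) and `N(0, ε)` (updating error) are read with the second argument
as a **standard deviation**; both are configurable.

**Vital rates.** Mismatch is \(m = |x - E_t|\). Expected clutch size is
\(c = \min(10, r)\,e^{-m^2}(1 - \kappa U)\) with `U = 1` for updaters
(default \(\kappa = 0.4\)); death probability is
\(\alpha_0 + m + \rho r^2\) (defaults \(\alpha_0 = 0.05\),
\(\rho = 0.01\)), clamped to \([0,1]\) since the linear form can exceed 1.
Newborns pay the updating cost \(\kappa\) for their forced first update; the
model does not exempt them.

**Turnover.** Reproduction precedes mortality within a step, so parents
dying this step still enter the recruitment lottery. Dead adults leave
vacancies filled by recruits whose parents are drawn *with replacement*
with probability proportional to expected clutch size — clutch sizes act as
continuous multinomial weights, not integer litter counts, so one parent
can supply several recruits. Offspring genes are
\(u' = e^{\log u + \mu}\), \(r' = e^{\log r + \mu}\),
\(\mu \sim N(0, 0.01^2)\) independently per locus, keeping both genes
positive and mutation driftless on the log scale. If every clutch weight is
zero (possible only when \(\kappa = 1\) makes updaters' clutches exactly
zero), vacancies stay open and the population can shrink to extinction —
reported as a run *status*, never an error. Otherwise the population
returns exactly to capacity every step.

A consequence worth stating plainly: because clutch weights are strictly
positive whenever \(\kappa < 1\), a population in which *every* adult dies
*every* step (e.g. under a high cost of reproduction, \(\rho = 0.05\), with
runaway effort) does not go extinct — it persists as an all-newborn
population with mean age 0 and no survival selection. That is this
implementation's realization of the "so high reproductive efforts that all
individuals die" regime.

## Variants

`mismatch_mode` switches where mismatch acts: `"both"` (main model),
`"mortality_only"` (the \(e^{-m^2}\) fecundity factor dropped; the
\(1-\kappa U\) updating cost is retained, because the variant targets
mismatch effects, not updating costs), `"fecundity_only"` (the `m` term
dropped from mortality), and `"none"`. The `"none"` mode is a diagnostic
extension: combined with \(\kappa = 0\), \(\rho = 0\) and
\(\epsilon = 0\) it makes every updating schedule selectively equivalent,
which is the configuration under which the test suite checks that mean
\(\log u\) performs a pure random walk (a drift control for hidden
selection introduced by bookkeeping).

## Randomness and reproducibility

A run has one master seed. The environment and the demography draw from
separate sub-seeds derived by a counter-based modular hash, so the same
environmental realization can be held fixed while life-history variants
change — paired comparisons compare responses to the *same* weather.
`run_grid()` derives one seed per (u_init, r_init, replicate) cell the same
way. Identical configurations reproduce byte-identical results;
this is asserted in the tests via `identical()` on whole result objects.

## Default conditions and problem sizes

The study conditions are `N = 2000` individuals and `t_max = 50000` steps,
with initial-genotype grids `u_init = 10^seq(-2, 1, by = 0.5)` (seven
values, 0.01–10) and `r_init = c(1, 4, 7)` — these are the `sim_config()`
and `run_grid()` defaults, and a single full-scale run takes on the order
of tens of minutes on one CPU. The test suite and the acceptance script
work at `N = 500`, `t_max = 5000`, with scenario grids
`p ∈ {0.1, 0.5, 0.9} × ε ∈ {0, 0.6}`, a three-point `u_init` grid
`{0.01, 0.3162, 10}`, and three replicate seeds (162 runs). At that scale
the qualitative cross-population patterns are already stable — effort
negatively rank-correlated with plasticity, lifespan positively, senescence
slopes concentrated in low-plasticity populations, error-prone updating
depressing evolved `u` — and these are checked directionally, not as point
values. Trajectories are recorded every 50 steps by default;
individual-level panels are kept only for the last 10 steps, the window of
the mismatch~age senescence regression.

## Summary statistics

`summary()` of a run reports cross-sectional means over the standing
population at `t_max` — including that step's age-0 recruits — so "mean
age" is the lifespan proxy of a census, not mean age at death. The
senescence slope is the OLS slope of mismatch on age pooled over the final
10 steps (each individual contributes up to 10 rows; no within-individual
clustering correction, deliberately matching a simple linear regression).
With all ages identical the slope is undefined and reported as `NA`, which
happens systematically in the all-newborn regime described above.
`pattern_tests()` computes Spearman rank correlations across runs, a 1-D
k-means clustering of \(\log_{10}\) evolved `u` into 2–3 updating regimes,
and flags scenarios whose within-scenario clusters sit more than an order
of magnitude apart — the signature of alternative evolutionary equilibria
reachable from different starting genotypes.

## Numerical and design choices

* Death probabilities are clamped rather than renormalized; probability
  semantics require it and the formula is silent above 1.
* `min(10, r)` caps *realized* fecundity while the gene value itself is
  unbounded; once a population sits in the everyone-dies-every-step
  regime, `r` above the cap is selectively nearly neutral and can drift to
  values well above 10. Rank-based cross-run statistics are insensitive to
  this.
* The half-open interval `[0, 1)` for `p` excludes the degenerate frozen
  environment; `p → 1` is approachable but variance then collapses.
* k-means on 1-D log-gene values uses 10 random starts; with fewer unique
  values than clusters the cluster count is reduced rather than erroring.
* The speed-of-evolution contrast (effort reaches the halfway point to its
  evolved value before plasticity does) is measured on the raw scale for
  `r` and the log scale for `u`, since `u` moves across orders of
  magnitude.

## What the generator does and does not emulate

The simulator *is* the study object here — there is no external data — but
its environment is deliberately minimal: a single scalar optimum, Gaussian
innovations, no spatial structure, no regime switches, no seasonality.
Passing tests therefore show that the coevolutionary feedback (plasticity
↔ pace of life) follows from the stated assumptions; they do not show that
any real population's lifespan–plasticity covariance arises this way.
Sexual reproduction, diploidy and recombination are out of scope, as is
age-dependent `u` (schedules depend only on time since the last update).

## Known limitations

* Scaled-down sweeps (smaller `N`, shorter `t_max`) retain more
  between-replicate variance in evolved `u` than full-scale runs;
  directional pattern checks are the honest claims at that scale.
* Extinction is reachable only through all-zero clutch weights
  (\(\kappa = 1\) with universal updating); under the default costs the
  population never dies out, it turns over completely instead.
* The ARMA(2,1) shape defaults (`ar2 = 0`, `ma1 = 0.3`) are one reasonable
  choice of the decoupling family, exposed as arguments precisely because
  no canonical values exist.
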