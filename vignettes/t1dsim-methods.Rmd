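---
title: "Modelling T1D progression in the NOD mouse: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling T1D progression in the NOD mouse: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`t1dsim` simulates autoimmune destruction of pancreatic beta cells in the
non-obese diabetic (NOD) mouse as a hybrid model: a spatial, stochastic
agent-based core coupled to two closed-form kinetic submodels, followed by a
statistical analysis stack (Latin hypercube calibration, one-at-a-time local
sensitivity with one-way ANOVA, eFAST global sensitivity, and
therapy-directed campaigns).

The arena is a bounded 2D patch grid (default 201 x 201) split into three
bands: the islet region (bottom ~70% of rows), and a top band split between
the pancreatic lymph nodes (PLN) and circulation. Twenty-five islet centres
are drawn at random in the islet band and furnished with 8080 immobile
beta-cell patches — about one percent of the ~900,000 beta cells of a NOD
pancreas — inside disks of radius 38 patches (disks may overlap and clip at
region borders; the beta-cell count is enforced exactly). With a 100 um
islet diameter this puts the patch length at `100 / (2 * 38) = 1.32` um.
Only the relative placement matters for the dynamics: interactions are
driven by random encounters, not by anatomical morphology, which is why a
schematic band layout is adequate.

One tick is one hour. Each tick fires, in order: antigen shedding by
apoptotic beta cells; dendritic-cell (DC) movement and phagocytosis; DC
migration to the PLN as antigen-presenting cells (APCs) after a 15-18 day
delay; APC-naive CD8+ binding in the PLN (short contact 6-8 h, then stable
contact 2-24 h, then activation); activated-cell differentiation cycles
(4-8 h), PLN egress after 3-5 days and a 120 h transit to islets;
restimulation by autoantigen into cytotoxic T lymphocytes (CTLs); CTL
random walk, contact killing, and proliferation (a per-run fraction drawn
from 15.4-23.8% divides into 4-7 offspring every 120 h); mass-action DC
recruitment; beta-cell quiescence and replication; and lifespan
bookkeeping (any agent past its drawn lifespan is removed).

Two kinetic submodels couple population counts to the agent rules:

* **DC recruitment** (mass action): the number of DCs recruited from
  circulation per hour is `k_r * beta_AP * DC_c`, where `beta_AP` is the
  apoptotic beta-cell count and `DC_c` the (constant) circulating DC count.
  `k_r` is drawn once per run from `Normal(mu_r, sigma_r)` truncated at
  zero. The product is generally non-integer; the default is a Poisson draw
  with that mean, which preserves the expectation and adds demographic
  noise (deterministic rounding is available).
* **Quiescence shortening** (power law): a surviving beta cell re-enters
  division after `T = (1 - beta_AP / beta_init)^gamma * T0` with
  `T0 = 168` h. The exponent is calibrated from the glucose-stimulated
  measurement (quiescence 7 d at rest, 2 d at 70% apoptosis):
  `gamma = log(2/7) / log(0.3) = 1.04`, rounded to 1
  (`estimate_gamma(7, 2, 0.7)`).

Overt T1D is scored when the surviving healthy fraction falls to a per-run
threshold drawn uniformly in [0.10, 0.30]; onset is only scored within 20
weeks of autoimmunity and censored runs are recorded as 32 weeks.

## Design choices where the biology is open

Several mechanisms are under-determined by the available descriptions; the
package resolves them as follows.

* **Region geometry.** Band fractions (`top_frac = 0.3`,
  `pln_col_frac = 0.5`) are configurable; only relative placement matters.
  The grid is bounded (a pancreas projection, not a torus); agents that
  would step off the grid or out of their region stay put that tick.
* **CTL speed.** In-vivo CTLs move 10-15 um/min, i.e. hundreds of patch
  lengths per hour at 1.32 um per patch — meaninglessly far on a 201-patch
  grid. Movement is therefore an effective per-tick displacement
  (`ctl_step_cells`, default 4 patches/h in a uniform random direction),
  chosen so a CTL traverses an islet diameter in a few hours, preserving
  the encounter-rate role of motility rather than its literal magnitude.
* **Killing contact.** Moore-neighbourhood (8 neighbours plus own patch)
  contact suffices; each CTL makes one kill attempt per hour against one
  randomly chosen adjacent healthy beta cell, succeeding with probability
  `ctl_kill_prob`. The default 0.05/h corresponds to the order of one to
  two kills per CTL per day, the scale of conjugation-limited killing;
  values near 1 would imply hundreds of kills per CTL per week and collapse
  the islets within days of the first effector wave.
* **Antigens.** Modelled as short-lived point agents: one antigen per
  apoptotic event plus renewed shedding every 12 h while the cell remains
  apoptotic. DCs engulf antigens within their Moore neighbourhood.
  Restimulation of islet-resident activated cells is triggered by free
  antigen or by contact with damaged (apoptotic or dead) beta patches —
  residual antigen deposits persist at sites of destruction; without this
  the multi-week DC pipeline (15-18 days islet to PLN) would outlive every
  antigen of the initial apoptotic wave and autoimmunity could never
  re-ignite.
* **Binding capacities.** The APC-side cap (`max_naive_binding`) limits
  simultaneous naive partners per APC. The naive-side "binding sites"
  parameter is implemented as a lifetime budget of distinct APC contacts a
  naive cell can accept; a naive cell engages one APC at a time.
* **Proliferation gate.** The measured 15.4-23.8% "fraction of CTLs
  proliferating" is implemented as a per-run drawn gate: on each 120 h
  proliferation clock, that fraction of CTLs divides (4-7 offspring). The
  alternative reading — an emergent observable — is not implementable
  without an extra free parameter.
* **Beta-cell fate.** Dead beta patches persist as inert obstacles.
  Replication is niche-limited: cells re-enter division only while the
  healthy count is below its initial value, so regeneration refills losses
  (producing honeymoon rebounds) without unbounded growth. Each cell's
  threshold is its own baseline (168 h) times the current global
  quiescence factor; initial quiescence clocks are desynchronised
  uniformly over [0, 168) h.
* **Recruitment placement.** Recruited DCs extravasate at apoptotic
  beta-cell patches (sites of insulitis) and resident DCs live on islet
  patches; both otherwise wander the islet region.
* **Update order.** Agent classes fire in the numbered order above;
  within-class processing is vectorised over agents whose random draws are
  made per agent per tick, so no agent is systematically favoured.
* **Randomness.** All randomness flows from the single run seed through
  R's RNG; `run_simulation(config, seed)` is bit-reproducible. Drawn
  per-run quantities (onset threshold, `k_r`, proliferation fraction) are
  made at world construction.

## Unknown parameters, defaults, and calibration

Twenty-one parameters are not fixed by measurement (`parameter_ranges()`).
The shipped defaults are repository defaults chosen inside the stated
ranges — they are not published values. The CTL lifespan default (120 h) is
anchored by the therapy worked example (a 5% dose reduces it to 114 h).
The aggression parameters (`ctl_kill_prob`, `restim_prob`,
`dc_recruit_mu`, `apoptotic_duration_h`) were calibrated by pilot
simulation at the reduced scale against the qualitative targets the model
is meant to reproduce: infiltrating CD8+ counts low before week 8 and
rising sharply around it, oscillatory effector waves with honeymoon
rebounds of the beta mass, and an onset-week distribution that is unimodal
with its mass between weeks 12 and 20. This mirrors the calibration role of
the Latin hypercube fit: `lhs_sample()` stratifies each range into `n`
equal-width strata sampled exactly once (the design is exact by
construction), `select_default()` scores candidates by the (optionally
SEM-weighted) sum of squared differences between simulated and observed
mean infiltrating-CD8 counts at weeks 4-14 over replicate runs, and the
best candidate becomes the default set.

Calibration identifiability at reduced scale is stratum-level, not
point-level, and profile-wise rather than joint: replicate noise in weekly
CD8 counts makes near-truth candidates statistically indistinguishable
from the truth with affordable replicate counts, and the CTL-lifespan and
DC-recruitment parameters trade off along a compensation ridge (a shorter
effector lifespan with stronger recruitment reproduces the same CD8
curve). The package's self-consistency check therefore screens one
sensitive parameter at a time over its full range (the others held at the
generating values) and asserts that the winning candidate lands within one
stratum of the generating value, rather than that the exact generating set
ranks first in a joint screen.

## Sensitivity analysis

**Local (OAT + ANOVA).** For each parameter, nine level means span the
default +/- 20% in 5% steps; each level is jittered by
`Normal(level, 0.06 * default)` truncated to the physical range (extending
coverage toward +/- 30%), with 20 replicate runs per level recording the
onset week (censored runs enter as 32 weeks, as the onset axis implies).
Box summaries use the ceiling-index order statistics
(`Q1 = x(ceil(0.25 N))`, `Q3 = x(ceil(0.75 N))`); the median follows the
standard convention of averaging the two central order statistics for even
N (the transposed odd/even labelling sometimes seen in print is a
typographical artefact). The one-way ANOVA is the standard
`SSR/SSE` decomposition with `F ~ F(M-1, N_total-M)` at alpha = 0.05.

**Global (eFAST).** The five sensitive parameters are encoded on search
curves `q = 1/2 + arcsin(sin(omega * s)) / pi` over an n-point s grid and
mapped to values through each factor's quantile function. The driver gets
`omega_max = floor((n-1)/(2m))` (24 at n = 200, m = 4); complementary
factors get frequencies at most `floor(omega_max/(2m))`, assigned by
cycling 1, 2, ... — with five factors and a bound of 3 the complementary
frequencies necessarily repeat, which is the standard practice; the
design-time guard is that every complementary harmonic `p * omega_c`
(p <= m) stays below the driver, so no aliasing into the driver's band.
First-order variance takes the driver's harmonics
(`D_i = 2 * sum Lambda at p*omega, p <= m`); the total-order term removes
the complementary low-frequency band
(`D_T = D - 2 * sum Lambda_j, j <= omega/2`), the standard low-frequency
complement. Constant output is flagged and reported as zero indices. In
"reduced" mode (onset cases only) the filtered series is re-indexed on its
own equispaced grid before the Fourier sums; because filtering breaks the
original equi-spacing, reduced-mode indices are approximate and are
labelled as such. Phase shifts (resampling curves) default to zero — a
single deterministic curve — and are configurable.

## Therapy campaigns

Three interventions are modelled as persistent fractional reductions from
the administration week onward: T1 reduces CTL longevity, T2 the mean DC
recruitment rate (applied to the drawn `k_r`), T3 the APC binding capacity.
"Dose" is the fractional reduction (the anchor: dose 0.05 on T1 takes
120 h to 114 h); at most two components combine. Therapy affects newly
drawn lifespans only — CTLs alive at administration keep their lifespans.
`estimate_p_t1d()` reports the onset fraction over seeded replicate runs;
`therapy_grid()` shares seeds across (week, dose) cells so contrasts are
paired.

## Reduced scales, problem sizes, and what the tests show

Full-scale runs (8080 beta cells, 20-week horizon) are expensive; all
distribution-level checks run at reduced scales built by `mini_world()`,
which keeps the complete rule set and parameter schema while shrinking
geometry and pools. Scaling is not neutral for the mass-action recruitment
term — a product of two scaled populations — so `mini_world()` rescales
`mu_r` (and `sigma_r`) by the inverse of the beta-cell ratio, preserving
per-capita recruitment intensity. The shipped test suite uses a 5-islet,
320-beta-cell world (immune pools at 10% of full scale) for
distribution-level checks: 30-seed onset distributions, 20 paired seeds for
the CTL-lifespan direction, 100 runs for conservation/determinism audits,
and 3 calibration seeds with 7-stratum designs; unit and campaign tests use
a 3-islet, 108-beta-cell world, with an aggressive variant (large initial
apoptotic insult, fast effector kinetics) where guaranteed onset within 10
weeks is needed. These sizes were chosen as the smallest at which the
qualitative regimes (ignition, oscillation, honeymoon, onset) are stable.

The surrogate weekly CD8 series (`surrogate_cd8_series()`) is a synthetic
stand-in for unpublished experimental counts: a sigmoid centred near week 8
with a superimposed oscillation, multiplicative noise, and SEM from the
replicate counts of the validation experiment (7, 6, 5, 6, 7, 12 animals).
It reproduces the qualitative structure (low before week 8, sharp rise,
continued increase to week 14) but not the real data's absolute scale,
autocorrelation, or inter-animal variance structure — so passing
calibration tests demonstrates self-consistency of the fitting machinery,
not agreement with experiment.

## Numerical notes and known limitations

* Censored runs are recorded as 32 weeks everywhere a numeric response is
  needed; this convention enters the ANOVA response and the eFAST output.
* Counts are integers throughout; fractional parameter values that act as
  caps (e.g. a therapy-reduced binding capacity) are compared as reals.
* The ANOVA kernel delegates to `stats::lm`/`stats::anova`; the degenerate
  all-constant case is defined as F = 0, p = 1.
* Activated cells in transit carry no lifespan (the 3-5 day PLN residence
  and 120 h transit already bound their pre-islet life); once
  islet-resident they age on the effector (CTL) lifespan.
* Incidence at the reduced scale is ~70%, not 100%: some runs restore
  homeostasis after the first effector wave. This is consistent with the
  incomplete penetrance of spontaneous diabetes in NOD colonies, but it is
  a scale-dependent emergent property, not a calibrated quantity.
* The model excludes CD4+ T cells, regulatory T cells, cytokine fields,
  anti-CD3 therapy, and glucose/insulin state variables (glucose enters
  only through the apoptotic fraction in the quiescence law); no 3D
  geometry, vasculature, or continuous-space physics.
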