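---
title: "Methods: severity-adjusted ICU benchmarking with DEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: severity-adjusted ICU benchmarking with DEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icudea)
```

This vignette documents the models implemented in `icudea`, the assumptions
behind them, the numerical choices, and what the synthetic-data validation
does and does not demonstrate about real cohorts.

## 1. Severity adjustment

### Mortality (SMR)

Expected deaths are computed per admission from the SAPS-3 logistic
equation, `logit(p) = intercept + slope * ln(score + offset)`, with the
published global coefficients (−32.6659, 7.3068, 20.5958) as the default
`saps3_coefficients()`. The unit's SMR is observed deaths over the sum of
these probabilities. Two conventions coexist in practice for the *observed*
count: deaths occurring in the ICU and deaths occurring anywhere in the
hospital. The SAPS-3 equation predicts hospital mortality, so
`outcome = "hospital"` is the default, but `outcome = "icu"` is supported —
in that case the coefficient set should be one calibrated to ICU deaths
(the synthetic generator returns such a set). Units with zero expected
deaths receive a missing SMR, never an infinity, and are excluded from DEA
with a warning, since envelopment models require strictly positive data.

### Resource use (SRU)

ICU length of stay is the resource surrogate. The cohort is partitioned
into SAPS-3 quantile bands (deciles by default; `n_strata` is tunable),
and each band's *reference use per survivor* is the total ICU LOS of all
patients in the band divided by the band's survivors. A unit's expected use
is its survivor count per band times the reference; its SRU is observed
total LOS over that expectation. Two consequences worth knowing:

- The whole cohort, treated as one unit, has SRU exactly 1 — the
  standardization is closed by construction, and the test suite asserts
  this identity to machine precision.
- A unit with no survivors has undefined SRU; it is kept in the performance
  table with a missing value and flagged.

Bands with no survivors are merged into the adjacent lower band so every
reference value is finite. The stratification scheme (quantile bands on the
severity score, survivor-based pricing) is the conventional one for this
metric; the band count is the main tunable, and deciles are a reasonable
default for cohorts of tens of thousands of admissions.

## 2. The envelopment models

`dea()` solves the variable-returns-to-scale envelopment program per unit —
radial phase first, then a slack-maximization phase at the fixed radial
score. Phase 2 resolves the indeterminacy of peer weights at alternative
optima and provides the standard strongly-efficient projection used for
targets: `target = (Σ λ x, Σ λ y)`. The convexity constraint `Σ λ = 1`
(variable returns to scale) is appropriate because ICUs differ widely in
size and a proportional scaling of a small unit's inputs need not scale its
outcomes.

Orientations follow managerial control: staffing (model A) and occupancy
(model C) are actionable, so those models ask how much input could shrink
at the observed performance (input orientation, θ ≤ 1); bed stock and
contracted hours are hard to change, so the structure model (B) asks how
much the outcomes should improve instead (output orientation, φ ≥ 1).

Undesirable variables — SMR and SRU, where smaller is better, and occupancy,
where *higher* utilisation is the harder operating condition — enter the
model as reciprocals. The reciprocal is an involution, applied once on the
way in and once on the way out, so reported targets are on the original,
interpretable scale (e.g. a model-scale `1/SMR` target of 2 is an SMR
target of 0.5).

### Numerical choices

- **Efficiency tolerance**: a unit is efficient when `|score − 1| ≤ 1e-6`.
  Weak efficiency (radial score 1 with nonzero slacks) is reported as a
  separate flag; published counts rarely make the distinction, so both are
  available.
- **LP solver**: the LPs are solved by a dense two-phase primal simplex
  with Bland's anti-cycling rule implemented in the package, behind a thin
  `solve_lp()` interface so the backend can be swapped. Variable order is
  fixed and pivoting is smallest-index, so repeated runs produce identical
  bases — peer sets are reproducible even where the LP has alternative
  optima. Feasibility tolerances are 1e-9; the self-solution `λ_o = 1`
  guarantees feasibility on any valid instance.
- **Data validation**: zeros or negatives in any model variable are
  rejected (or the unit excluded with a warning at the pipeline level)
  rather than ε-substituted; ε-substitution silently distorts the frontier.
- **Quantiles**: all medians, IQRs and severity-band boundaries use the
  linear-interpolation convention (R type 7), stated here once because
  published tables rarely say which convention they used.
- **Tie at the efficiency-matrix median**: a value equal to the cohort
  median counts as "low". The rule is configurable (`tie = "lt"`), and with
  an odd number of distinct values the median unit itself is "low" on both
  axes under the default.

The test suite validates the solver against an independent brute-force
oracle that enumerates every basic feasible solution of the envelopment
polytope (exact up to linear-solve precision) on hundreds of random small
instances, plus closed-form worked instances, units-invariance, dominance,
monotonicity under DMU addition, and projection-onto-frontier checks.

## 3. The synthetic cohort generator

The generator emulates the marginal structure of a large multicenter
ICU cohort; its defaults are the study conditions the package targets:

- **Severity**: SAPS-3 from a zero-truncated normal, location 44, scale 15
  (reproduces quartiles 34/54), rounded to integer points.
- **Mortality**: per-admission probability is the SAPS-3 risk times a
  unit-level lognormal multiplier (SD `unit_effect_sd`, default 0.25 —
  chosen to give an SMR spread comparable to the published IQR 0.79–1.21),
  clipped at 1. A scalar intercept shift, found by root-finding on the
  realized severities and multipliers, calibrates pooled ICU mortality to
  12% and hospital mortality to 18%. One uniform draw per patient drives
  both death indicators, so ICU death implies hospital death while both
  margins hold. The two shifted coefficient sets are returned so that SMRs
  can be computed against the equation that actually generated the deaths;
  under `unit_effect_sd = 0` every unit's true SMR is 1.
- **Length of stay**: lognormal with marginal meanlog 1.0 and sdlog 1.2.
  An exact lognormal match of the published median 3 with IQR [1, 6] is
  impossible (the log-quartile midpoint 0.90 differs from the log-median
  1.10); the compromise favours the IQR — fitted median 2.7, IQR
  [1.2, 6.1]. The location increases by 0.3 per SD of SAPS-3 (sicker
  patients stay longer) with the residual scale reduced to preserve the
  marginal spread, and a unit-level lognormal multiplier (SD 0.30) drives
  SRU dispersion.
- **Units**: bed counts from the published band frequencies
  (40/48/11/1% for <10, 11–30, 31–50, >50), staffing ratios and weekly
  hours lognormal with meanlog at the published medians and sdlog from the
  published IQRs, occupancy from Beta(14.76, 3.48) — a least-squares
  quantile match of the published quartiles 0.75/0.83/0.87 — and
  organizational categories at the published frequencies. Units nest in
  hospitals (~0.6 hospitals per unit) that carry administration, size and
  bed count. Admission counts are proportional to beds × occupancy at 88
  admissions per occupied bed, sized so the default 93-unit cohort has
  roughly 130,000 admissions.
- **Independence**: staffing ratios, hours and occupancy are drawn
  independently because their joint distribution is not published. Real
  cohorts correlate these (e.g. occupancy with size); group-level contrasts
  on synthetic data are therefore structural checks, not predictions.

What the generator deliberately does not emulate: readmissions, transfers,
within-hospital correlation of ICU performance, case-mix differences across
unit types, and any dependence of severity on the admitting unit. Passing
tests on synthetic data therefore demonstrate the *correctness of the
computations* (metrics, LPs, classification, summaries) under realistic
marginals — not that any particular real-world cohort will show the same
efficient-unit counts or group rankings.

### The planted frontier

For exact end-to-end validation, `plant_frontier()` rewrites a unit table
so the chosen units form the efficient set of all three models by
construction: planted units sit on a common geometric ladder (every
model-scale input and output scaled by the same factor between consecutive
planted units, which makes them mutually non-dominated frontier vertices in
both orientations), and every other unit is a strictly dominated copy of
one planted unit (inputs inflated, outputs deflated by at least the
dominance margin). Recovery of exactly the planted set by `dea()` is then a
theorem, and the suite asserts it at margins 0.1–0.2 on up to 20 units.

## 4. Grouped reporting

`group_efficiency_summary()` reports mean scores, SMR and SRU by hospital
administration (public / philanthropic / for-profit), hospital size
(< 100, 100–200 inclusive, > 200 beds), specialization (a specialized ICU
is any type other than mixed or medical), and terciles of the ICU-to-
hospital bed proportion. The tercile cutoffs default to the fixed published
values (low ≤ 4.70%, high ≥ 9.57%, boundaries inclusive outward) for
comparability, with `tercile_mode = "data"` recomputing them from the data
at hand. No significance tests are attached: with ~93 units and ~30 per
category these are descriptive contrasts.

## 5. Problem sizes and reproducibility

The shipped validation works at deliberately chosen scales: oracle
comparisons on instances of up to 5 units and 3 variables (where exhaustive
vertex enumeration is exact and instant), planted frontiers of 5–20 units,
null-model SMR checks at ~10,000 admissions per unit, and full-calibration
checks on five complete 93-unit, ~130,000-admission cohorts — the whole
suite runs in well under a minute. Every random draw flows from a single
integer seed; identical configuration and seed give byte-identical CSV
output, and the pipeline writes a JSON manifest (inputs, seed, tolerances,
package version) alongside its tables so a run can be reproduced exactly.

## 6. Known limitations

- Deterministic frontier: measurement noise in SMR/SRU moves the frontier;
  no stochastic-frontier or bootstrap machinery is included.
- Constant returns, super-efficiency, multiplier weight restrictions and
  Malmquist indices are out of scope.
- The SRU stratification bands and the SAPS-3 coefficient set are
  conventions; results are comparable across units within one run, but
  absolute SMR/SRU levels shift with either choice.
- Peer sets at degenerate optima are reproducible (deterministic solver)
  but not unique in the mathematical sense; alternative optimal peer sets
  can exist.
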