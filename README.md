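# icudea

Severity-adjusted benchmarking of intensive care units (ICUs) with data
envelopment analysis (DEA), for intensivists, hospital managers and
health-services researchers who want to compare units on *both* their
outcomes and the resources those outcomes consume.

## What it computes

Classical ICU benchmarking reduces a unit to two severity-adjusted metrics:

- **SMR** (standardized mortality ratio): observed deaths divided by the
  deaths expected from admission severity. Expected deaths come from the
  SAPS-3 logistic equation
  `logit(p) = α + β ln(score + γ)` (global coefficients
  α = −32.6659, β = 7.3068, γ = 20.5958, overridable).
- **SRU** (standardized resource use): observed ICU bed-days divided by the
  bed-days expected for the unit's case mix, with ICU length of stay as the
  resource surrogate. Expected use prices each survivor at the cohort's mean
  LOS-per-survivor within severity strata (SAPS-3 deciles by default).

The efficiency matrix splits units at the cohort medians of SMR and SRU into
*most efficient*, *overachieving*, *least efficient* and *underachieving*
quadrants — informative, but blind to staffing and structure.

DEA closes that gap. Each ICU is a decision-making unit with inputs
(staffing ratios, beds, weekly hours, occupancy) and outputs (SMR, SRU).
The variable-returns-to-scale (BCC) envelopment program for unit *o* in
input orientation is

```
min θ   s.t.  Σ_j λ_j x_ij ≤ θ x_io   (all inputs i)
              Σ_j λ_j y_rj ≥ y_ro     (all outputs r)
              Σ_j λ_j = 1,  λ ≥ 0
```

and in output orientation the radial factor φ multiplies the outputs
instead (θ ∈ (0,1], φ ∈ [1,∞); efficient ⇔ score = 1). A second LP phase
maximizes the remaining slacks, which yields the frontier projection
`(Σ λ_j x_j, Σ λ_j y_j)` — the *targets* a non-efficient unit should reach —
and the peer (reference) units behind it. Undesirable variables (SMR, SRU,
and occupancy where fuller is harder) enter as reciprocals `1/x`; targets
are reported back on the original scale.

Three built-in models mirror the standard benchmarking perspectives:

| Model | Focus     | Inputs                                   | Orientation |
|-------|-----------|------------------------------------------|-------------|
| A     | staffing  | physicians, nurses, nursing technicians, physiotherapists per 10 beds | input  |
| B     | structure | ICU beds, physician hours/week, nurse hours/week | output |
| C     | capacity  | bed occupancy rate (reciprocal)          | input       |

All three use SMR and SRU (reciprocals) as outputs.

A calibrated synthetic cohort generator (93 units, SAPS-3 median 44 with
IQR 34–54, ICU/hospital mortality 12%/18%, ICU LOS median ≈ 3 days,
occupancy quartiles 0.75/0.83/0.87, published staffing distributions) makes
every stage testable without patient data, including a *planted frontier*
mode where the efficient set is known by construction.

## Worked example

```r
library(icudea)

sim  <- simulate_cohort(cohort_config(n_units = 12, seed = 42))
perf <- unit_performance(sim$patients, sim$coefficients_hospital)
head(perf[, c("unit_id", "n_admissions", "smr", "sru")], 3)
#>   unit_id n_admissions       smr       sru
#> 1    U001         1899 1.0471182 0.8653534
#> 2    U002         1346 0.7169190 1.1931533
#> 3    U003         2824 0.9011018 1.0700370

fit <- run_model(builtin_model_specs()$A, sim$units, perf)
fit
#> Model A (staffing, input-oriented): 12 units, 10 efficient

subset(fit$scores, !efficient)
#>    unit_id     score efficient weakly_efficient reference_count
#> 3     U003 0.8914132     FALSE            FALSE               0
#> 11    U011 0.8163591     FALSE            FALSE               0
```

Unit U011 scores θ ≈ 0.82 in the staffing model: a frontier peer mix
delivers its SMR/SRU with ~18% less staffing per 10 beds. Its row in
`fit$targets` gives the staffing levels and SMR/SRU it should aim for. The
efficiency matrix and the grouped summaries come from
`classify_quadrants(perf)`, `quadrant_dea_summary()` and
`group_efficiency_summary()`, or in one call with CSV outputs:

```r
run_pipeline(list(simulate = list(n_units = 93), seed = 1, out_dir = "out"))
```

A thin command-line wrapper ships in `inst/cli/icu-dea`
(`icu-dea simulate|metrics|run`).

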