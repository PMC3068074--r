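# psakit

Desk-scale R tools for the quantitative core of prostate-cancer treatment
decision support: PSA kinetics, pretreatment risk stratification,
treatment-guideline evaluation and post-treatment outcome auditing, plus a
synthetic-cohort simulator so everything can be exercised and verified
without clinical data.

It is written for biostatisticians and clinical informaticians who need
the computations behind a decision-support workflow as plain, testable
functions over delimited files rather than inside a hospital web stack.

## What it computes

**PSA kinetics.** For a window of longitudinal PSA measurements
$(t_i, P_i)$:

* velocity from the linear model $P_i = P_0 + \mathrm{PSAV}\,t_i$ (OLS),
  or as the secant $(P_2-P_1)/(t_2-t_1)$ through two chosen markers, with
  flags at the 0.75 and 2 ng/mL/yr cut-offs (strict comparison);
* doubling time from the log-linear fit,
  $T_D = \ln 2 / \widehat{\beta}$ with $\widehat\beta$ the OLS slope of
  $\ln P_i$ on $t_i$, or from two markers as
  $T_D = (t_2-t_1)\ln 2/\ln(P_2/P_1)$; a non-rising PSA yields
  "undefined", never a negative time;
* density $\mathrm{PSAD} = \mathrm{PSA}/\text{prostate volume}$.

**Risk stratification.** The three-tier classification from T category,
PSA and Gleason sum — low (T1c/T2a and PSA ≤ 10 and Gleason ≤ 6),
intermediate (T2b or Gleason 7 or 10 < PSA ≤ 20), high (T2c or PSA > 20
or Gleason ≥ 8), evaluated worst-tier-first — with each tier's published
5-year PSA-failure band (<25 / 25–50 / >50 %) and 5-/10-year
failure-free survival (85/83, 60/46, 30/29 %). A pluggable Partin-style
table maps (stage, PSA range, Gleason) to pathologic-stage probabilities;
the packaged table is a synthetic stand-in (see
`?read_partin_table`).

**Guideline graphs.** YAML-defined decision DAGs whose nodes carry
predicates over clinical facts, evaluated under three-valued logic
(missing facts never highlight a step), rendered as a text path or
Graphviz dot.

**Outcome audit.** Biochemical success tables by modality and follow-up
month: success means PSA < 0.2 ng/mL after surgery or < 2 ng/mL after
radiotherapy (or below the pre-treatment value, as a second criterion),
using the measurement nearest each nominal month within ±45 days.

**Simulation.** `simulate_cohort()` writes cohorts with exponential PSA
growth at known doubling times, treatment-induced decline to a nadir,
optional recurrence, log-normal measurement noise and visit dropout —
together with a ground-truth sidecar for verification.

## Worked example

```r
library(psakit)

# A patient staged T1c with PSA 32.4 ng/mL and Gleason score 5-6:
group <- stratify(parse_tnm("T1c"), 32.4, parse_gleason("5-6"))
group
#> [1] "high"
risk_profile(group)
#> <risk_profile> high risk
#>   5-yr PSA failure: > 50%
#>   PSA failure-free survival: 30% (5 yr), 29% (10 yr)
```

The stage and grade alone look favourable, but a PSA above 20 ng/mL
places the patient in the high-risk tier: expected 5-year PSA failure
above 50%, with 30% and 29% failure-free survival at 5 and 10 years.

Kinetics and auditing on a simulated cohort:

```r
sim <- simulate_cohort(sim_params(n_patients = 95, seed = 1), "cohort")
rec <- sim$cohort[[1]]

w <- kinetics_window(rec$psa_series, to = rec$treatments[[1]]$date - 1)
psav_regression(w)
#> <kinetics_result> (regression, n = 13)
#>   initial PSA: 16.8 ng/mL
#>   PSAV: 5.076 ng/mL per year
psadt_regression(w)
#> <kinetics_result> (regression, n = 13)
#>   initial PSA: 17.61 ng/mL
#>   PSADT: 40.9 months
```

This patient's pre-treatment PSA rises by about 5 ng/mL per year — far
beyond both the 0.75 and 2 ng/mL/yr cut-offs — doubling roughly every 41
months. `audit_cohort(sim$cohort)` then tabulates
`successes/total(percent%)` per modality and follow-up month.

The same operations are available from a shell via the installed CLI
script (`system.file("cli", "psakit", package = "psakit")`):

```sh
psakit stratify --tnm T1c --psa 32.4 --gleason 5-6
psakit simulate --n 95 --seed 1 --out-dir cohort
psakit audit --cohort-dir cohort
psakit guideline --psa 82.35 --tnm T2cN0M0 --gleason 4+3 \
    --life-expectancy 15 --lymph-node-pct 38 --symptomatic FALSE
```

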