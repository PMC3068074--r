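---
title: "PSA kinetics, risk tiers and guideline evaluation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSA kinetics, risk tiers and guideline evaluation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psakit)
```

psakit packages the analytic core of a prostate-cancer decision-support
workflow: longitudinal PSA kinetics, three-tier pretreatment risk
stratification, a data-driven treatment-guideline graph, and
post-treatment biochemical outcome auditing, together with a cohort
simulator that provides ground truth for all of them. This vignette
explains the models, the defaults and the design decisions; it states no
empirical result beyond what the package's own tests compute.

## PSA kinetics

Serum PSA in untreated prostate cancer is well described by exponential
growth, so two scales carry the clinically used parameters:

* On the natural scale, a window of measurements is summarised by the
  linear model $P_i = P_0 + \mathrm{PSAV}\, t_i$, fitted by ordinary least
  squares (`psav_regression()`). The slope is the **PSA velocity** and the
  intercept the **initial PSA** at the window start. The alternative
  two-marker estimator (`psav_two_marker()`) is the secant slope
  $(P_2-P_1)/(t_2-t_1)$ through two chosen measurements; with exactly two
  points the estimators coincide, which the test suite checks numerically.
* On the log scale, exponential growth makes $\ln P_i$ linear in time, and
  the **doubling time** is $T_D = \ln 2 / \beta$ where $\beta$ is the OLS
  slope of $\ln P_i$ on $t_i$ (`psadt_regression()`). The two-marker form
  interpolates the line through $(t_1, \ln P_1)$ and $(t_2, \ln P_2)$,
  giving $T_D = (t_2-t_1)\ln 2 / \ln(P_2/P_1)$ (`psadt_two_marker()`).

Regression over the whole window is the default because it uses every
selected measurement and is the only averaging procedure with a clean
statistical definition; the two-marker estimators are provided because
clinicians routinely reason from two chosen dates, and they are also the
closed-form oracle against which the regressions are tested.

Three conventions matter and are fixed package-wide:

* **Units.** Elapsed time is computed in days between ISO dates and
  converted with 30.44 days/month and 365.25 days/year. Velocity defaults
  to ng/mL **per year** because the decision cut-offs (0.75 and 2
  ng/mL/yr) are annual; doubling time defaults to **months**, its usual
  clinical unit. Both are configurable.
* **Undefined doubling time.** A non-increasing PSA has no doubling time.
  The estimators return `NA` ("undefined") rather than a negative number,
  which is clinically meaningless; callers who need a hard value get a
  domain error at the CLI (exit code 4).
* **Strict flagging.** A velocity "in excess of" a cut-off is flagged with
  a strict inequality; a velocity exactly at 0.75 ng/mL/yr is not flagged.

Non-positive PSA values make the log fit undefined and raise an error;
they are never silently dropped, because silent data exclusion would
undermine auditability of a decision-support computation.

## Risk stratification

`stratify()` implements the three-tier classification from T category,
PSA and Gleason sum, with the published outcome lookup exposed by
`risk_profile()`. Because the intermediate and high rows are disjunctions,
the tiers overlap; precedence is **high, then intermediate, then low**, so
the worse tier always governs — the conservative reading for a risk tool,
and the one consistent with the canonical example in which a T1c, Gleason
5–6 patient with PSA 32.4 ng/mL is high-risk on PSA alone.

The criteria live in a data file (`inst/extdata/risk_criteria.csv`), not
in code, so a site can adjust them. The schema needed one extension
beyond plain bounds: a `logic` column (`all`/`any`), because the low-risk
row is a conjunction of its stage, PSA and Gleason conditions while the
other rows are disjunctions — a purely columnar schema cannot express
both. PSA bounds follow the printed inequalities exactly (low requires
$\le 10$; intermediate $>10$ and $\le 20$; high $>20$), so PSA 10 is
low-compatible and PSA 20 intermediate-compatible.

Two further conventions:

* A Gleason **range** such as "5–6" matches grade criteria via its
  maximum element (worst-case reading).
* Stages outside T1c–T2c are representable (the full T1a–T4 enumeration
  parses) but are `unclassified` unless PSA or Gleason alone trigger a
  tier: the stratifier never invents coverage the criteria do not have.
  When Gleason 7 co-occurs with PSA > 20 the precedence rule yields
  high; the criteria themselves are silent on that corner, and the
  package treats precedence as its own design choice.

The Partin lookup (`partin_lookup()`) is a pluggable table in the same
spirit: published editions are not redistributed, so the packaged
`partin_synthetic.csv` is a clearly labelled synthetic stand-in with
plausible magnitudes, intended to be replaced by a file in the same
schema. PSA ranges in the table are lower-closed/upper-open so every
boundary value falls in exactly one cell.

## Guideline graphs

Guideline *content* is data, not code: graphs are authored in YAML and
validated at load time (unique ids, no dangling edges, acyclicity with
the offending cycle reported, exactly one entry node, predicates only
over declared facts). The packaged `guideline_prostate.yaml` is a
deliberately simplified risk-tier-to-therapy flow for demonstration and
testing; it claims fidelity to no published guideline.

Predicates use a deliberately small language — comparisons, `%in%` over
category sets, and `&&`/`||`/`!` — parsed into R expressions and walked
against a whitelist, so no arbitrary code can execute from a guideline
file. Evaluation is Kleene three-valued: a missing fact makes a
comparison *unknown*, `unknown && FALSE` is still `FALSE`, and an unknown
predicate never highlights a node (it is recorded as unmet instead). This
mirrors incremental data entry in clinic: partial facts give partial,
never wrong, highlighting, and adding facts can only extend the
highlighted set while existing predicate outcomes stand — a property the
test suite checks on randomly generated DAGs.

## Outcome auditing

A treatment is a biochemical success at a follow-up month when the PSA
near that visit is **less than** 0.2 ng/mL (surgery) or 2 ng/mL
(radiotherapy); the inequality is strict, so a boundary value fails. A
second, modality-agnostic criterion asks whether PSA fell below its
pre-treatment value. Other modalities (hormonal, chemotherapy, watchful
waiting) have no accepted threshold and support only the
below-pretreatment criterion.

Follow-up visits rarely land on the nominal month, so "the PSA at month
*m*" is operationalised as the measurement nearest to the treatment date
plus *m* months, within ±45 days; patients without a measurement in the
window are not evaluable at that month and leave the denominator. This
reproduces the varying denominators of real follow-up series, where
missed visits simply drop out. Cell percentages round half away from
zero, the convention that matches published audit cells such as
19/24 = 79%.

## The cohort simulator

`simulate_cohort()` generates records with a ground-truth sidecar so
estimator and audit behaviour can be verified against known values. Per
patient: baseline PSA $P_0 \sim U(2, 20)$ ng/mL and true doubling time
$D \sim U(12, 48)$ months drive exponential growth $P(t) = P_0\,2^{t/D}$,
sampled quarterly over three years; treatment (surgery with probability
61/95, matching the treatment split of a published pilot cohort of 95
patients, else radiotherapy) follows 21 days after the last pre-treatment
visit and drops PSA to a modality nadir (0.05 / 1.0 ng/mL); with
probability 0.2 regrowth at the patient's own doubling time resumes after
a uniform 3–9-month delay; every measurement carries multiplicative
log-normal noise (`sdlog = noise_cv`, default 0.1), and follow-up visits
(months 1, 3, 6, 9, 12) are independently missed with probability 0.1.

Choices worth explaining:

* **Noise model.** Multiplicative log-normal, because PSA is positive and
  assay error scales with level.
* **Tracking length.** Three years of quarterly pre-treatment
  measurements, consistent with clinical guidance that doubling-time
  estimation needs at least 18–24 months of data: with doubling times up
  to 48 months, a materially shorter window would leave the slope
  statistically unidentifiable at 10% assay noise.
* **Treatment lag.** 21 days between the last pre-treatment visit and
  treatment keeps every pre-treatment measurement outside the ±45-day
  audit window of the month-1 visit, so the audit can never mistake a
  pre-treatment PSA for a follow-up value.
* **Ground truth as a file.** The simulator writes its bookkeeping (true
  doubling time, modality, recurrence flag, per-visit threshold outcome)
  to a `truth.csv` sidecar, so tests compare against a file rather than
  reaching into simulator state.
* **Determinism.** Each patient has a private seed derived from the
  cohort seed, so identical parameters give byte-identical files and
  individual trajectories are reproducible out of context.

What the simulator does **not** emulate — and what passing tests
therefore do not show about real data: PSA drops to the post-treatment
nadir instantly, whereas clinically PSA declines over weeks (surgery) to
many months (radiotherapy), so simulated early-month success rates are
higher than real series report; there is no benign PSA variation
(prostatitis, assay changes), no hormonal-therapy dynamics, and no
correlation between stage, grade and growth rate. It is a test harness
with known answers, not a calibrated natural-history model.

## Problem sizes and numerical tolerances

The test suite exercises: exhaustive parser grids (all 81 TNM
combinations, all 25 Gleason pattern pairs), a 401-point PSA grid by 9
Gleason sums by 4 stages for stratifier monotonicity, exact-exponential
recovery over a 5×5 grid of baselines and doubling times at relative
tolerance $10^{-6}$, two-point estimator agreement at $10^{-9}$, and
simulated cohorts of 200 patients for parameter recovery (median relative
doubling-time error below $10^{-6}$ noiseless and below 10% at 10% noise)
and 80 patients for the audit/ground-truth round trip. These sizes give
stable medians while keeping the default suite fast.

## Known limitations

The stratifier covers exactly the published criteria domain; nomogram
probability models and survival modelling are out of scope. The Partin
fixture is synthetic. The guideline engine evaluates whatever graph it is
given — correctness of guideline *content* is the author's responsibility,
and the packaged graph is illustrative only. The audit reports fractions,
not statistical comparisons between modalities.
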