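# Simplified prostate-cancer treatment flow for demonstration and testing.
# Authored for this package; NOT a transcription of any published guideline.
entry: confirmed
facts:
  psa: numeric            # ng/mL
  t_category: category    # T1a..T4
  gleason_sum: numeric    # 2..10
  life_expectancy_years: numeric
  lymph_node_involvement_pct: numeric
  symptomatic: logical
nodes:
  - id: confirmed
    label: Biopsy-confirmed prostate cancer
    kind: decision
    predicate: true
  - id: metastatic_workup
    label: Nodal involvement suspected (>20%)
    kind: decision
    predicate: "lymph_node_involvement_pct > 20"
  - id: localized
    label: Likely organ-confined disease
    kind: decision
    predicate: "lymph_node_involvement_pct <= 20"
  - id: low_risk
    label: "Low risk: T1c/T2a, PSA <= 10, Gleason <= 6"
    kind: decision
    predicate: "t_category %in% c('T1c','T2a') && psa <= 10 && gleason_sum <= 6"
  - id: higher_risk
    label: "Intermediate/high risk features"
    kind: decision
    predicate: "t_category %in% c('T2b','T2c','T3a','T3b','T4') || psa > 10 || gleason_sum >= 7"
  - id: short_le
    label: Limited life expectancy (< 10 years)
    kind: decision
    predicate: "life_expectancy_years < 10"
  - id: long_le
    label: Life expectancy >= 10 years
    kind: decision
    predicate: "life_expectancy_years >= 10"
  - id: watchful_waiting
    label: Watchful waiting / active surveillance
    kind: therapy
  - id: surgery
    label: Radical prostatectomy
    kind: therapy
  - id: radiotherapy
    label: External-beam radiotherapy
    kind: therapy
  - id: hormonal
    label: Androgen-deprivation (hormonal) therapy
    kind: therapy
  - id: followup
    label: PSA follow-up schedule
    kind: terminal
edges:
  - {from: confirmed, to: metastatic_workup}
  - {from: confirmed, to: localized}
  - {from: metastatic_workup, to: hormonal}
  - {from: metastatic_workup, to: radiotherapy, predicate: "symptomatic == FALSE"}
  - {from: localized, to: low_risk}
  - {from: localized, to: higher_risk}
  - {from: low_risk, to: watchful_waiting, predicate: "life_expectancy_years < 10"}
  - {from: low_risk, to: surgery, predicate: "life_expectancy_years >= 10"}
  - {from: higher_risk, to: short_le}
  - {from: higher_risk, to: long_le}
  - {from: short_le, to: radiotherapy}
  - {from: long_le, to: surgery, predicate: "psa <= 20"}
  - {from: long_le, to: radiotherapy, predicate: "psa > 20"}
  - {from: surgery, to: followup}
  - {from: radiotherapy, to: followup}
  - {from: hormonal, to: followup}
  - {from: watchful_waiting, to: followup}
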