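# Locally modified index: SUM of applicable risk weights times the
# creatinine-ratio injury tier only. Weights are illustrative placeholders
# for local risk factors; replace with weights derived for your unit.
preset: mrai_local
positivity_cutoff: 8
mrai_mode: true
schwartz_k_umol: 36.5
assumed_ecrcl: 120
risk_weights:
  icu_admission: 1
  sepsis: 4
  severe_malaria: 2
  age_under_1: 2
  ventilation: 3
  vasopressors: 3
injury_dscr_tiers:
  - {lower: -.inf, score: 1, strict: false}
  - {lower: 1.0,  score: 2, strict: true}
  - {lower: 1.5,  score: 4, strict: false}
  - {lower: 2.0,  score: 8, strict: false}
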