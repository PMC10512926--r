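# Original renal angina index: highest applicable risk stratum times the
# higher of the creatinine-ratio and fluid-overload injury tiers.
preset: rai_original
positivity_cutoff: 8
mrai_mode: false
schwartz_k_umol: 36.5
assumed_ecrcl: 120
risk_weights:
  icu_admission: 1
  transplant: 3
  ventilation_and_vasopressors: 5
injury_dscr_tiers:
  - {lower: -.inf, score: 1, strict: false}
  - {lower: 1.0,  score: 2, strict: true}
  - {lower: 1.5,  score: 4, strict: false}
  - {lower: 2.0,  score: 8, strict: false}
injury_fo_tiers:
  - {lower: -.inf, score: 1}
  - {lower: 5,    score: 2}
  - {lower: 10,   score: 4}
  - {lower: 15,   score: 8}
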