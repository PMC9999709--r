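# Index cohorts representing the four WHO/ISH risk bands, for the
# scenarios with and without diabetes. Bands are as published; the
# representative scalar values (sbp, total_cholesterol) are the points
# inside each band at which the packaged Framingham-type general CVD
# equation is evaluated, chosen so that each profile's computed 10-year
# risk falls inside its own band. Open-ended published bands (">180",
# ">310", "<195", "<270") are stored with wide finite limits.

without_diabetes:
  low:
    cohort_label: low
    age_entry: 40
    sex: male
    sbp_band: [120, 139]
    sbp: 130
    total_cholesterol_band: [100, 195]
    total_cholesterol: 180
    hdl: 40
    smoker: false
    diabetic: false
  moderate:
    cohort_label: moderate
    age_entry: 40
    sex: female
    sbp_band: [140, 159]
    sbp: 150
    total_cholesterol_band: [310, 400]
    total_cholesterol: 330
    hdl: 46
    smoker: true
    diabetic: false
  high:
    cohort_label: high
    age_entry: 40
    sex: female
    sbp_band: [160, 179]
    sbp: 178
    total_cholesterol_band: [310, 400]
    total_cholesterol: 330
    hdl: 46
    smoker: true
    diabetic: false
  very_high:
    cohort_label: very_high
    age_entry: 40
    sex: male
    sbp_band: [180, 230]
    sbp: 190
    total_cholesterol_band: [310, 400]
    total_cholesterol: 330
    hdl: 41
    smoker: true
    diabetic: false

with_diabetes:
  low:
    cohort_label: low
    age_entry: 40
    sex: female
    sbp_band: [120, 139]
    sbp: 130
    total_cholesterol_band: [100, 195]
    total_cholesterol: 180
    hdl: 46
    smoker: false
    diabetic: true
  moderate:
    cohort_label: moderate
    age_entry: 40
    sex: female
    sbp_band: [140, 159]
    sbp: 150
    total_cholesterol_band: [310, 400]
    total_cholesterol: 330
    hdl: 46
    smoker: false
    diabetic: true
  high:
    cohort_label: high
    age_entry: 40
    sex: male
    sbp_band: [160, 179]
    sbp: 165
    total_cholesterol_band: [100, 270]
    total_cholesterol: 220
    hdl: 40
    smoker: true
    diabetic: true
  very_high:
    cohort_label: very_high
    age_entry: 40
    sex: male
    sbp_band: [180, 230]
    sbp: 190
    total_cholesterol_band: [100, 270]
    total_cholesterol: 240
    hdl: 41
    smoker: true
    diabetic: true
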