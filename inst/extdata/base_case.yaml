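# Published base-case parameter tables for the IraPEN cost-effectiveness
# model. Cohort costs are printed for the diabetic cohorts; the
# diabetes_medication_annual_cost_usd block is a documented assumption
# used to derive non-diabetic cohort costs (metformin annual cost taken
# from the low-risk column's medication cost; sulfonylurea assumed).
# The very-high IRR column sums to 961,415 but the source prints 961,416;
# the printed total is stored and the 1-IRR discrepancy documented.

currency_conversion:
  inflation_factor: 1.3059998552507781   # implied exactly by 165,804 -> 216,540
  exchange_rate_irr_per_usd: 41965.116279069767   # implied by 216,540 IRR = $5.16

cohort_costs:
  low:
    components_irr:
      behvarz_visit_screening: 108173
      nutrition_consultation: 38400
      fixed_costs: 19231
    total_irr_printed: 165804
    inflated_irr_printed: 216540
    cost_without_medication_usd: 5.16
    medication_cost_usd: 16.00
    model_cost_usd: 21.63
  moderate:
    components_irr:
      behvarz_visit_screening: 324519
      physician_visit: 216346
      nutrition_consultation: 38400
      fixed_costs: 19231
    total_irr_printed: 598496
    inflated_irr_printed: 781636
    cost_without_medication_usd: 18.61
    medication_cost_usd: 38.85
    model_cost_usd: 57.46
  high:
    components_irr:
      behvarz_visit_screening: 432692
      physician_visit: 288462
      nutrition_consultation: 38400
      psychiatrist_consultation: 38400
      fixed_costs: 19231
    total_irr_printed: 817185
    inflated_irr_printed: 1067243
    cost_without_medication_usd: 25.41
    medication_cost_usd: 48.27
    model_cost_usd: 73.68
  very_high:
    components_irr:
      behvarz_visit_screening: 432692
      physician_visit: 432692
      nutrition_consultation: 38400
      psychiatrist_consultation: 38400
      fixed_costs: 19231
    total_irr_printed: 961416          # components sum to 961,415
    inflated_irr_printed: 1255609
    cost_without_medication_usd: 29.90
    medication_cost_usd: 55.39
    model_cost_usd: 85.29

# assumption: annual cost of the diabetes medications included in each
# diabetic cohort's package (metformin $16/yr from the low-risk column;
# sulfonylurea, added for high/very-high, assumed $6/yr)
diabetes_medication_annual_cost_usd:
  low: 16.00
  moderate: 16.00
  high: 22.00
  very_high: 22.00

treatments:
  ace_inhibitor:
    rr_chd: 0.81
    rr_chd_ci: [0.70, 0.94]
    rr_stroke: 0.65
    rr_stroke_ci: [0.52, 0.82]
  thiazide:
    rr_chd: 0.84
    rr_chd_ci: [0.75, 0.95]
    rr_stroke: 0.63
    rr_stroke_ci: [0.57, 0.71]
  beta_blocker:
    rr_chd: 0.90
    rr_chd_ci: [0.78, 1.03]
    rr_stroke: 0.83
    rr_stroke_ci: [0.72, 0.97]
  statin:
    rr_chd: 0.86
    rr_chd_ci: [0.82, 0.90]
    rr_stroke: 0.90
    rr_stroke_ci: [0.85, 0.95]
  metformin:
    rr_chd: 0.67
    rr_chd_ci: [0.51, 0.89]
    rr_stroke: 0.80
    rr_stroke_ci: [0.50, 1.27]
  sulfonylurea:
    rr_chd: 0.85
    rr_chd_ci: [0.74, 0.97]
    rr_stroke: 0.91
    rr_stroke_ci: [0.73, 1.13]
  lifestyle_counseling:
    rr_chd: 0.86
    rr_chd_ci: [0.81, 0.91]
    rr_stroke: 0.86
    rr_stroke_ci: [0.81, 0.91]

state_costs:
  chd_year1: {mean: 519, se: 51}
  chd_subsequent: {mean: 173, se: 17}
  stroke_year1: {mean: 5691, se: 569}
  stroke_subsequent: {mean: 1422, se: 142}

utilities:
  chd_year1: {mean: 0.67, se: 0.024}
  chd_subsequent: {mean: 0.82, se: 0.012}
  stroke_year1: {mean: 0.33, se: 0.033}
  stroke_subsequent: {mean: 0.52, se: 0.027}

economics:
  discount_rate: 0.035
  horizon_cycles: 40
  wtp_threshold: 4091            # 1 x GDP per capita, USD per QALY

fatalities:
  chd_case_fatality_year1: 0.25
  prehospital_chd_death_fraction: 0.60   # costless prehospital CHD deaths
  stroke_case_fatality_year1: 0.25       # published plausible range 0.22-0.34
  fatal_stroke_cost_fraction: 0.40       # share of first-year stroke cost for fatal cases
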