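# Framingham general cardiovascular disease risk profile (sex-specific
# Cox survival form on log-transformed risk factors), the packaged
# default 10-year total-CVD risk equation. Alternative published
# coefficient sets of the same shape can be swapped in via
# load_risk_coefficients(path).
#
# risk = 1 - baseline_survival ^ exp(lp - mean_lp)
# lp   = b1*ln(age) + b2*ln(total_cholesterol) + b3*ln(hdl)
#        + b4*ln(sbp) + b5*smoker + b6*diabetic
version: 1
name: framingham_general_cvd_2008
functional_form: cox_survival
outcome: cvd            # combined equation; split into CHD and stroke below
chd_stroke_split: 0.75  # share of CVD events that are CHD (assumption)
age_range: [30, 74]

male:
  coefficients:
    ln_age: 3.06117
    ln_total_cholesterol: 1.12370
    ln_hdl: -0.93263
    ln_sbp_untreated: 1.93303
    ln_sbp_treated: 1.99881
    smoker: 0.65451
    diabetic: 0.57367
  mean_lp: 23.9802
  baseline_survival: 0.88936

female:
  coefficients:
    ln_age: 2.32888
    ln_total_cholesterol: 1.20904
    ln_hdl: -0.70833
    ln_sbp_untreated: 2.76157
    ln_sbp_treated: 2.82263
    smoker: 0.52873
    diabetic: 0.69154
  mean_lp: 26.1931
  baseline_survival: 0.95012
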