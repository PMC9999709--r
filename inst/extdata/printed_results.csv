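table,cohort,sex,row,cost,qaly,ly,icer
base_without_diabetes,low,male,status_quo,845,18.12,32.27,
base_without_diabetes,low,male,irapen,918,18.12,32.27,
base_without_diabetes,low,male,incremental,73,0,0,Undefined
base_without_diabetes,moderate,female,status_quo,979,17.89,32.37,
base_without_diabetes,moderate,female,irapen,1375,18.38,33.06,
base_without_diabetes,moderate,female,incremental,396,0.49,0.69,804
base_without_diabetes,high,female,status_quo,1204,17.68,32.13,
base_without_diabetes,high,female,irapen,1594,18.38,33.09,
base_without_diabetes,high,female,incremental,391,0.71,0.96,551
base_without_diabetes,very_high,male,status_quo,2348,15.83,29.3,
base_without_diabetes,very_high,male,irapen,2296,17.02,30.75,
base_without_diabetes,very_high,male,incremental,-52,1.19,1.45,-44
base_with_diabetes,low,female,status_quo,647,18.59,33.36,
base_with_diabetes,low,female,irapen,866,18.9,33.82,
base_with_diabetes,low,female,incremental,219,0.31,0.46,711
base_with_diabetes,moderate,female,status_quo,1027,17.75,32.17,
base_with_diabetes,moderate,female,irapen,1560,18.59,33.37,
base_with_diabetes,moderate,female,incremental,533,0.85,1.2,630
base_with_diabetes,high,male,status_quo,2429,15.91,29.46,
base_with_diabetes,high,male,irapen,2361,17.53,31.5,
base_with_diabetes,high,male,incremental,-68,1.61,2.04,-42
base_with_diabetes,very_high,male,status_quo,2810,15.31,28.74,
base_with_diabetes,very_high,male,irapen,2678,17.18,31.03,
base_with_diabetes,very_high,male,incremental,-133,1.87,2.29,-71
heterogeneity_with_diabetes,very_high,female,status_quo,2133,16.17,30.18,
heterogeneity_with_diabetes,very_high,female,irapen,2393,17.9,32.42,
heterogeneity_with_diabetes,very_high,female,incremental,260,1.73,2.24,151
heterogeneity_without_diabetes,very_high,female,status_quo,1522,17.19,31.46,
heterogeneity_without_diabetes,very_high,female,irapen,1912,18.13,32.71,
heterogeneity_without_diabetes,very_high,female,incremental,390,0.93,1.25,418
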