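# Synthetic-cohort specification for women: seven published profile-cluster
# centroids (mean/sd of the six analysis variables), per-cluster condition
# prevalences, mean comorbidity counts (>=5 binned as 5 when computing the
# mean), and per-cluster education. Height/BMI are sex-level and used to
# back-derive raw gait speed and grip strength. Background prevalences are
# sex-level rates for conditions not profiled per cluster.
sex: woman
height: {mean: 1.53, sd: 0.07}
bmi: {mean: 27.6, sd: 4.5}
educ: {mean: 13.1, sd: 5.4}
background_prevalence:
  IADLD: 0.229
  DEPR: 0.363
  FELL: 0.454
  MI: 0.061
  CHF: 0.022
  CVA: 0.036
  COPD: 0.056
  ARTH: 0.136
  PUD: 0.442
  LIVER: 0.083
  DIAB: 0.136
  HEMI: 0.078
  CKD: 0.010
  CANCER: 0.124
  AIDS: 0.0
  OSTEO: 0.818
truncation:
  age: [60.0, .inf]
  gait_height: [0.0, .inf]
  grip_bmi: [0.0, .inf]
  balance: [0.0, 45.0]
  lam_pct: [0.0, 100.0]
  fat_pct: [0.0, 100.0]
clusters:
  - label: 1
    size: 20
    mean: {age: 62.9, gait_height: 0.804, grip_bmi: 0.951, balance: 39.0, lam_pct: 24.8, fat_pct: 34.6}
    sd:   {age: 2.2,  gait_height: 0.162, grip_bmi: 0.140, balance: 12.5, lam_pct: 1.4,  fat_pct: 2.9}
    prevalence: {CI: 0.050, ADLD: 0.050, FF: 0.250, PVD: 0.450, HTN: 0.150}
    comorbid_rate: 1.650
    educ: {mean: 13.9, sd: 4.6}
  - label: 2
    size: 81
    mean: {age: 66.2, gait_height: 0.747, grip_bmi: 0.781, balance: 43.0, lam_pct: 22.3, fat_pct: 40.9}
    sd:   {age: 4.9,  gait_height: 0.140, grip_bmi: 0.139, balance: 6.8,  lam_pct: 1.2,  fat_pct: 2.8}
    prevalence: {CI: 0.099, ADLD: 0.037, FF: 0.481, PVD: 0.494, HTN: 0.272}
    comorbid_rate: 1.691
    educ: {mean: 13.7, sd: 5.9}
  - label: 3
    size: 72
    mean: {age: 66.1, gait_height: 0.666, grip_bmi: 0.545, balance: 42.6, lam_pct: 19.9, fat_pct: 46.3}
    sd:   {age: 4.2,  gait_height: 0.114, grip_bmi: 0.166, balance: 6.1,  lam_pct: 1.2,  fat_pct: 2.7}
    prevalence: {CI: 0.111, ADLD: 0.056, FF: 0.667, PVD: 0.486, HTN: 0.389}
    comorbid_rate: 1.861
    educ: {mean: 14.2, sd: 5.2}
  - label: 4
    size: 25
    mean: {age: 66.4, gait_height: 0.666, grip_bmi: 0.646, balance: 8.2,  lam_pct: 20.0, fat_pct: 45.8}
    sd:   {age: 4.3,  gait_height: 0.111, grip_bmi: 0.128, balance: 6.2,  lam_pct: 1.0,  fat_pct: 2.1}
    prevalence: {CI: 0.080, ADLD: 0.160, FF: 0.640, PVD: 0.440, HTN: 0.440}
    comorbid_rate: 2.120
    educ: {mean: 12.8, sd: 5.3}
  - label: 5
    size: 68
    mean: {age: 73.3, gait_height: 0.746, grip_bmi: 0.524, balance: 31.7, lam_pct: 23.2, fat_pct: 38.7}
    sd:   {age: 4.9,  gait_height: 0.127, grip_bmi: 0.179, balance: 15.1, lam_pct: 1.8,  fat_pct: 4.2}
    prevalence: {CI: 0.074, ADLD: 0.074, FF: 0.647, PVD: 0.368, HTN: 0.588}
    comorbid_rate: 2.059
    educ: {mean: 14.1, sd: 4.2}
  - label: 6
    size: 17
    mean: {age: 76.3, gait_height: 0.559, grip_bmi: 0.652, balance: 7.9,  lam_pct: 24.6, fat_pct: 34.4}
    sd:   {age: 4.8,  gait_height: 0.094, grip_bmi: 0.215, balance: 7.2,  lam_pct: 1.3,  fat_pct: 3.4}
    prevalence: {CI: 0.118, ADLD: 0.118, FF: 0.647, PVD: 0.471, HTN: 0.412}
    comorbid_rate: 2.000
    educ: {mean: 12.2, sd: 6.1}
  - label: 7
    size: 129
    mean: {age: 77.1, gait_height: 0.536, grip_bmi: 0.433, balance: 4.8,  lam_pct: 20.8, fat_pct: 44.3}
    sd:   {age: 5.5,  gait_height: 0.153, grip_bmi: 0.139, balance: 6.8,  lam_pct: 2.0,  fat_pct: 4.3}
    prevalence: {CI: 0.233, ADLD: 0.225, FF: 0.814, PVD: 0.651, HTN: 0.643}
    comorbid_rate: 2.695
    educ: {mean: 11.6, sd: 5.6}
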