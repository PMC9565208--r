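# Synthetic-cohort specification for men: seven published profile-cluster
# centroids, per-cluster PVD/HTN prevalences and mean comorbidity counts
# (>=5 binned as 5 when computing the mean). Conditions without per-cluster
# rates use the sex-level background prevalences. Height/BMI back-derive raw
# gait speed and grip strength; education is sex-level.
sex: man
height: {mean: 1.67, sd: 0.07}
bmi: {mean: 27.2, sd: 4.0}
educ: {mean: 16.0, sd: 5.4}
background_prevalence:
  CI: 0.134
  ADLD: 0.100
  IADLD: 0.033
  DEPR: 0.255
  FF: 0.453
  FELL: 0.360
  MI: 0.140
  CHF: 0.013
  CVA: 0.013
  COPD: 0.067
  ARTH: 0.053
  PUD: 0.340
  LIVER: 0.073
  DIAB: 0.253
  HEMI: 0.073
  CKD: 0.013
  CANCER: 0.120
  AIDS: 0.0
  OSTEO: 0.613
truncation:
  age: [60.0, .inf]
  gait_height: [0.0, .inf]
  grip_bmi: [0.0, .inf]
  balance: [0.0, 45.0]
  lam_pct: [0.0, 100.0]
  fat_pct: [0.0, 100.0]
clusters:
  - label: 1
    size: 27
    mean: {age: 70.0, gait_height: 0.760, grip_bmi: 1.440, balance: 44.1, lam_pct: 30.0, fat_pct: 26.4}
    sd:   {age: 5.1,  gait_height: 0.151, grip_bmi: 0.238, balance: 4.8,  lam_pct: 1.6,  fat_pct: 3.5}
    prevalence: {PVD: 0.222, HTN: 0.296}
    comorbid_rate: 1.462
  - label: 2
    size: 21
    mean: {age: 65.2, gait_height: 0.690, grip_bmi: 1.106, balance: 34.4, lam_pct: 28.7, fat_pct: 30.5}
    sd:   {age: 3.5,  gait_height: 0.110, grip_bmi: 0.168, balance: 15.8, lam_pct: 1.0,  fat_pct: 2.5}
    prevalence: {PVD: 0.048, HTN: 0.238}
    comorbid_rate: 0.857
  - label: 3
    size: 29
    mean: {age: 67.9, gait_height: 0.708, grip_bmi: 1.054, balance: 43.5, lam_pct: 25.5, fat_pct: 35.3}
    sd:   {age: 5.2,  gait_height: 0.112, grip_bmi: 0.222, balance: 4.9,  lam_pct: 1.4,  fat_pct: 2.6}
    prevalence: {PVD: 0.172, HTN: 0.310}
    comorbid_rate: 1.379
  - label: 4
    size: 31
    mean: {age: 78.4, gait_height: 0.504, grip_bmi: 1.077, balance: 8.3,  lam_pct: 28.1, fat_pct: 29.5}
    sd:   {age: 4.7,  gait_height: 0.139, grip_bmi: 0.194, balance: 9.1,  lam_pct: 2.3,  fat_pct: 4.3}
    prevalence: {PVD: 0.387, HTN: 0.677}
    comorbid_rate: 2.645
  - label: 5
    size: 27
    mean: {age: 71.8, gait_height: 0.635, grip_bmi: 0.888, balance: 5.4,  lam_pct: 25.5, fat_pct: 34.6}
    sd:   {age: 5.4,  gait_height: 0.113, grip_bmi: 0.213, balance: 5.1,  lam_pct: 1.5,  fat_pct: 3.0}
    prevalence: {PVD: 0.333, HTN: 0.593}
    comorbid_rate: 2.037
  - label: 6
    size: 10
    mean: {age: 78.5, gait_height: 0.640, grip_bmi: 0.685, balance: 39.1, lam_pct: 24.7, fat_pct: 35.5}
    sd:   {age: 7.2,  gait_height: 0.142, grip_bmi: 0.193, balance: 8.6,  lam_pct: 1.3,  fat_pct: 3.3}
    prevalence: {PVD: 0.600, HTN: 0.500}
    comorbid_rate: 2.900
  - label: 7
    size: 5
    mean: {age: 75.8, gait_height: 0.418, grip_bmi: 0.469, balance: 5.0,  lam_pct: 22.7, fat_pct: 40.6}
    sd:   {age: 6.4,  gait_height: 0.124, grip_bmi: 0.144, balance: 9.1,  lam_pct: 1.4,  fat_pct: 5.3}
    prevalence: {PVD: 0.200, HTN: 0.800}
    comorbid_rate: 3.200
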