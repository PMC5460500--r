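{
  "a0": 0.0079481518283106,
  "a1": 0.138647952055875,
  "a2": 4.96911898622517,
  "b0": 0.0134059332798458,
  "b1": 0.00221909060883935,
  "b2": 0.490798753500789,
  "c0": 0.000864420573247209,
  "c1": 0.0257383133079562,
  "c2": 2.44128094933358,
  "individual_risk_anchors": {
    "q": [0, 0.5, 0.8, 0.95, 1],
    "m": [0.05, 0.35, 1.2, 3, 12]
  },
  "adenoma_risk_anchors_early": {
    "q": [0, 0.6, 0.8, 0.93, 1],
    "m": [0.02, 0.3, 1.5, 5, 30]
  },
  "adenoma_risk_anchors_advanced": {
    "q": [0, 0.6, 0.8, 0.93, 1],
    "m": [0.01, 0.1, 0.6, 4, 35]
  },
  "sex_factors": [1.81346578075922, 1.46525105212791, 1.89457276978806],
  "rectum_factors": [1.5, 6.57700083715454],
  "stage_progression": [1.2, 1, 0.9, 2.56266109183243, 0.477333563036037, 30.2443335704713],
  "stage_regression": [0.015, 0.008, 0.005, 0.003, 0.002, 0.001],
  "stage_cancer_risk": [1.28941044548042e-05, 2.57882089096084e-05, 5.15764178192168e-05, 9.67057834110315e-05, 0.000193411566822063],
  "direct_cancer_risk": [2.52616989723248e-07, 2.52616989723248e-07, 3.78925484584872e-07, 3.78925484584872e-07, 3.78925484584872e-07, 3.78925484584872e-07, 7.57850969169744e-07, 7.57850969169744e-07, 1.01046795889299e-06, 1.51570193833949e-06, 1.76831892806274e-06, 2.39986140237086e-06, 2.39986140237086e-06],
  "sojourn_mean_y": 3,
  "sojourn_sd_y": 0.5,
  "dwell_variant": 8,
  "location_dist": [0.09, 0.06, 0.13, 0.1, 0.08, 0.04, 0.07, 0.07, 0.04, 0.09, 0.09, 0.07, 0.07],
  "symptomatic_stage_dist": [0.18, 0.3, 0.29, 0.23],
  "stage_time_weights": [0.3, 0.3, 0.22, 0.18],
  "survival_5y": [0.94, 0.82, 0.62, 0.11],
  "male_fraction": 0.5,
  "schema": "cmost-params/1"
}
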