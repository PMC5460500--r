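{
  "a0": 0.0079481518283106,
  "a1": 0.138647952055875,
  "a2": 4.96911898622517,
  "b0": 0.0114090733399678,
  "b1": 0.000845750638275628,
  "b2": 0.430156820421454,
  "c0": 0.000829775822705016,
  "c1": 0.0253027225314092,
  "c2": 2.38524477683833,
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
  "sex_factors": [1.81346578075922, 1.02836835325519, 1.06265738767518],
  "rectum_factors": [1.5, 7.43224805367317],
  "stage_progression": [1.2, 1, 0.9, 1.16949112837348, 0.66110627940753, 6.67552355234666],
  "stage_regression": [0.015, 0.008, 0.005, 0.003, 0.002, 0.001],
  "stage_cancer_risk": [0.000106519992760523, 0.000213039985521046, 0.000426079971042092, 0.000798899945703922, 0.00159779989140784],
  "direct_cancer_risk": [5.762468487427e-07, 5.762468487427e-07, 8.6437027311405e-07, 8.6437027311405e-07, 8.6437027311405e-07, 8.6437027311405e-07, 1.7287405462281e-06, 1.7287405462281e-06, 2.3049873949708e-06, 3.4574810924562e-06, 4.0337279411989e-06, 5.47434506305565e-06, 5.47434506305565e-06],
  "sojourn_mean_y": 3,
  "sojourn_sd_y": 0.5,
  "dwell_variant": 19,
  "location_dist": [0.09, 0.06, 0.13, 0.1, 0.08, 0.04, 0.07, 0.07, 0.04, 0.09, 0.09, 0.07, 0.07],
  "symptomatic_stage_dist": [0.18, 0.3, 0.29, 0.23],
  "stage_time_weights": [0.3, 0.3, 0.22, 0.18],
  "survival_5y": [0.94, 0.82, 0.62, 0.11],
  "male_fraction": 0.5,
  "schema": "cmost-params/1"
}
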