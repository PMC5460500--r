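{
  "a0": 0.0077043059204867,
  "a1": 0.140271807298427,
  "a2": 5.0109369976736,
  "b0": 0.0302185012580525,
  "b1": 0.0172774791978229,
  "b2": 1.89331843636827,
  "c0": 0.000834267762542471,
  "c1": 0.0255865441971452,
  "c2": 2.35114084719337,
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
  "sex_factors": [1.88211346544099, 1.03842305401791, 1.12190190364554],
  "rectum_factors": [1.5, 7.01718178861557],
  "stage_progression": [1.2, 1, 0.9, 1.29083114216709, 0.642891262853002, 6.3023191469918],
  "stage_regression": [0.015, 0.008, 0.005, 0.003, 0.002, 0.001],
  "stage_cancer_risk": [7.05075687832514e-05, 0.000141015137566503, 0.000282030275133006, 0.000528806765874386, 0.00105761353174877],
  "direct_cancer_risk": [5.762468487427e-07, 5.762468487427e-07, 8.6437027311405e-07, 8.6437027311405e-07, 8.6437027311405e-07, 8.6437027311405e-07, 1.7287405462281e-06, 1.7287405462281e-06, 2.3049873949708e-06, 3.4574810924562e-06, 4.0337279411989e-06, 5.47434506305565e-06, 5.47434506305565e-06],
  "sojourn_mean_y": 3,
  "sojourn_sd_y": 0.5,
  "dwell_variant": 13,
  "location_dist": [0.09, 0.06, 0.13, 0.1, 0.08, 0.04, 0.07, 0.07, 0.04, 0.09, 0.09, 0.07, 0.07],
  "symptomatic_stage_dist": [0.18, 0.3, 0.29, 0.23],
  "stage_time_weights": [0.3, 0.3, 0.22, 0.18],
  "survival_5y": [0.94, 0.82, 0.62, 0.11],
  "male_fraction": 0.5,
  "schema": "cmost-params/1"
}
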