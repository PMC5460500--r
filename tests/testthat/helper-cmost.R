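# shared fixtures built in code

# red acceptance criteria are reported individually; do not let the progress
# reporter abort the run before the unit files execute
options(testthat.progress.max_fails = 100L)

# flat-rate parameter set for analytic oracles: constant initiation
# (a1 = 0 -> sigmoid = a0/2), no progression/regression, direct cancer off,
# all heterogeneity multipliers 1, single colon segment (cecum), one-quarter
# sojourn
flat_params <- function(lambda2 = 0.004, h2 = 0.01) {
  unit <- list(q = c(0, 1), m = c(1, 1))
  natural_history_params(
    a0 = 2 * lambda2, a1 = 0, a2 = 0,
    b0 = 0, c0 = 1, c1 = 0, c2 = 0,
    individual_risk_anchors = unit,
    adenoma_risk_anchors_early = unit,
    adenoma_risk_anchors_advanced = unit,
    sex_factors = c(initiation = 1, early = 1, advanced = 1),
    rectum_factors = c(early = 1, advanced = 1),
    stage_progression = rep(0, 6),
    stage_regression = rep(0, 6),
    stage_cancer_risk = c(h2, 0, 0, 0, 0),
    direct_cancer_risk = rep(0, 13),
    location_dist = c(rep(0, 12), 1),
    sojourn_mean_y = 0.25, sojourn_sd_y = 0.01,
    survival_5y = rep(1, 4))  # no CRC deaths: keeps person-time analytic
}

# life table with no background mortality before the horizon
immortal_life_table <- function() {
  lt <- load_life_table()
  lt$qx <- c(rep(0, 100), 1)
  lt
}

# sterile parameters: no lesions ever
sterile_params <- function() {
  natural_history_params(a0 = 0, b0 = 0, c0 = 0,
                         stage_cancer_risk = rep(0, 5),
                         direct_cancer_risk = rep(0, 13))
}

fixture_params <- function(dwell = 13) cmost_params(dwell)
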