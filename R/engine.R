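#' Simulate a population
#'
#' Runs the quarterly-step life-history engine for `n` independent
#' individuals from birth to death or age 100.  Within every quarter the
#' event order is fixed: natural history (adenoma initiation, per-lesion
#' progression / fast malignant transformation / regression, direct
#' carcinoma initiation, cancer stage advance, symptom onset), then
#' endoscopy (screening, surveillance or diagnostic), then treatment cost
#' accrual and death resolution.  Deterministic given
#' `(params, plan, n, seed)`; the screening arm and a baseline run with the
#' same seed share natural-history randomness individual by individual.
#'
#' @param params `cmost_params`.
#' @param life_table `cmost_life_table` (default: shipped table).
#' @param plan `cmost_plan` (default: no screening).
#' @param n number of individuals (>= 1).
#' @param seed integer master seed.
#' @param model `cmost_screening_model`.
#' @param costs `cmost_cost_table`.
#' @return an object of class `cmost_result`: per-age-year tallies
#'   (person-years, adenoma prevalence by sex, CRC incidence by stage / mode
#'   of detection / side, deaths by cause, procedures by context,
#'   complications, cost streams) plus scalar diagnostics (pathway counts,
#'   synchronous-cancer fraction, adenoma dwell-time histogram in quarters,
#'   conservation counters).
#' @export
simulate_population <- function(params, life_table = load_life_table(),
                                plan = no_screening_plan(), n = 10000L,
                                seed = 1L, model = screening_model(),
                                costs = default_costs()) {
  validate_params(params)
  if (n < 1) stop("n must be >= 1")
  cdf <- death_cdf_quarterly(life_table)
  raw <- sim_population_cpp(as_engine_params(params), unclass(model),
                            as_engine_plan(plan), unclass(costs),
                            cdf, as.integer(n), as.integer(seed))
  ages <- 0:100
  dimmed <- function(v, k, nm) {
    m <- matrix(v, ncol = k, byrow = TRUE)
    rownames(m) <- ages; colnames(m) <- nm
    m
  }
  res <- list(
    n = raw$n, seed = raw$seed, plan = plan,
    py = stats::setNames(raw$py, ages),
    alive_at = dimmed(raw$alive_at, 2, c("female", "male")),
    early_at = dimmed(raw$early_at, 2, c("female", "male")),
    adv_at = dimmed(raw$adv_at, 2, c("female", "male")),
    carrier_at = stats::setNames(raw$carrier_at, ages),
    multi_at = stats::setNames(raw$multi_at, ages),
    inc_stage = dimmed(raw$inc_stage, 4, paste0("stage", 1:4)),
    inc_sex = dimmed(raw$inc_sex, 2, c("female", "male")),
    inc_mode = dimmed(raw$inc_mode, 3, c("symptomatic", "screening", "other")),
    inc_side = dimmed(raw$inc_side, 3, c("rectum", "left_colon", "right_colon")),
    crc_death = stats::setNames(raw$crc_death, ages),
    oth_death = stats::setNames(raw$oth_death, ages),
    compl_death = stats::setNames(raw$compl_death, ages),
    colonoscopies = dimmed(raw$colono, 4,
                           c("screening", "surveillance", "diagnostic", "followup")),
    sigmoidoscopies = stats::setNames(raw$sig, ages),
    fobt_tests = stats::setNames(raw$fobt, ages),
    polypectomies = stats::setNames(raw$polypectomy, ages),
    complications = rbind(no_polypectomy = raw$compl_nopoly,
                          polypectomy = raw$compl_poly),
    n_colono = c(no_polypectomy = raw$ncol_nopoly, polypectomy = raw$ncol_poly,
                 total = raw$ncol_total, reached_cecum = raw$reach_cecum_n),
    cost = rbind(procedures = raw$cost_proc, complications = raw$cost_compl,
                 treatment = raw$cost_treat),
    origin_init = stats::setNames(raw$origin_init, c("adenomatous", "fast", "direct")),
    origin_diag = stats::setNames(raw$origin_diag, c("adenomatous", "fast", "direct")),
    sync_diag = raw$sync_diag, total_diag = raw$total_diag,
    dwell_hist = raw$dwell_hist,
    years_lost = raw$years_lost,
    stage_mode = matrix(raw$stage_mode, 2, 4,
                        dimnames = list(c("symptomatic", "asymptomatic"),
                                        paste0("stage", 1:4))),
    trial = list(cases = stats::setNames(raw$trial_cases,
                                         c("rectum", "left_colon", "right_colon")),
                 cases_total = raw$trial_cases_tot,
                 deaths = raw$trial_deaths, n = raw$trial_n),
    conservation = c(initiated = raw$aden_init, disappeared = raw$aden_disappear,
                     resected = raw$aden_resect, transformed = raw$aden_transform,
                     remaining = raw$aden_alive_end),
    clip_warnings = raw$clip_warnings)
  colnames(res$complications) <- names(model$complication_p)
  colnames(res$cost) <- ages
  if (res$clip_warnings > 0)
    warning(sprintf("%d per-quarter event probabilities exceeded 1 and were clipped",
                    as.integer(res$clip_warnings)))
  class(res) <- "cmost_result"
  res
}

# flatten a cmost_params for the C++ engine
as_engine_params <- function(p) {
  list(a0 = p$a0, a1 = p$a1, a2 = p$a2, b0 = p$b0, b1 = p$b1, b2 = p$b2,
       c0 = p$c0, c1 = p$c1, c2 = p$c2,
       indiv_q = p$individual_risk_anchors$q, indiv_m = p$individual_risk_anchors$m,
       lesion_early_q = p$adenoma_risk_anchors_early$q,
       lesion_early_m = p$adenoma_risk_anchors_early$m,
       lesion_adv_q = p$adenoma_risk_anchors_advanced$q,
       lesion_adv_m = p$adenoma_risk_anchors_advanced$m,
       sex_factors = as.numeric(p$sex_factors),
       rectum_factors = as.numeric(p$rectum_factors),
       stage_progression = p$stage_progression,
       stage_regression = p$stage_regression,
       stage_cancer_risk = p$stage_cancer_risk,
       direct_cancer_risk = p$direct_cancer_risk,
       sojourn_mean_y = p$sojourn_mean_y, sojourn_sd_y = p$sojourn_sd_y,
       location_dist = p$location_dist,
       symptomatic_stage_dist = p$symptomatic_stage_dist,
       stage_time_weights = p$stage_time_weights,
       survival_5y = p$survival_5y,
       male_fraction = p$male_fraction)
}

#' Sample preclinical sojourn times
#'
#' Draws sojourn times (cancer initiation to symptom onset) from the
#' engine's truncated-normal sampler: normal with the configured mean and
#' standard deviation, rejected while non-positive, rounded to whole
#' quarters with a one-quarter floor.
#'
#' @param n number of draws.
#' @param params `cmost_params`.
#' @param seed integer seed.
#' @return sojourn times in years (multiples of 0.25).
#' @export
sample_sojourn <- function(n, params = natural_history_params(), seed = 1L) {
  sample_sojourn_cpp(as.integer(n), params$sojourn_mean_y, params$sojourn_sd_y,
                     as.integer(seed)) / 4
}

#' @export
print.cmost_result <- function(x, ...) {
  cat("<cmost_result> n =", x$n, " seed =", x$seed,
      " modality =", x$plan$modality, "\n")
  cat(sprintf("  CRC diagnoses: %d (synchronous %.1f%%), CRC deaths: %d\n",
              as.integer(x$total_diag),
              if (x$total_diag > 0) 100 * x$sync_diag / x$total_diag else 0,
              as.integer(sum(x$crc_death))))
  cat(sprintf("  colonoscopies: %d, sigmoidoscopies: %d, polypectomies: %d\n",
              as.integer(x$n_colono[["total"]]), as.integer(sum(x$sigmoidoscopies)),
              as.integer(sum(x$polypectomies))))
  cat(sprintf("  total cost: %.0f, person-years: %.0f\n",
              sum(x$cost), sum(x$py)))
  invisible(x)
}

#' Lifetime and age-specific summaries of a run
#'
#' @param x `cmost_result`.
#' @param age_range two ages delimiting the summary window (inclusive).
#' @return list with incidence and mortality per 100,000 person-years in
#'   the window, cumulative counts, and procedure totals.
#' @export
summarize_result <- function(x, age_range = c(0, 100)) {
  idx <- (age_range[1]:age_range[2]) + 1
  py <- sum(x$py[idx])
  inc <- sum(x$inc_stage[idx, ])
  mort <- sum(x$crc_death[idx])
  list(incidence_per_100k = 1e5 * inc / py,
       mortality_per_100k = 1e5 * mort / py,
       cases = inc, crc_deaths = mort, person_years = py,
       colonoscopies = sum(x$colonoscopies[idx, ]))
}
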