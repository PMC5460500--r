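#' Sigmoidoscopy trial emulation
#'
#' Emulates a large randomized rectosigmoidoscopy prevention trial:
#' individuals enroll at a uniform age between 55 and 74, attenders receive
#' a one-time sigmoidoscopy (a configurable fraction a second one a few
#' years later), positive findings trigger a colonoscopy, and intention-to-
#' treat incidence and mortality are compared against a paired no-screening
#' arm over an 11.9-year follow-up window.
#'
#' @param params `cmost_params`.
#' @param n individuals per arm.
#' @param seed master seed (shared by both arms).
#' @param adherence fraction ever screened (intention to treat).
#' @param second_frac fraction of attenders receiving a second
#'   sigmoidoscopy.
#' @param second_gap_y years between the two screens.
#' @param enroll enrollment age range.
#' @param followup_y follow-up horizon from enrollment.
#' @param life_table,model,costs shared inputs.
#' @return list with overall / right-sided / left-sided incidence reduction,
#'   mortality reduction, and the raw windowed case counts.
#' @export
run_trial_emulation <- function(params, n = 77445L, seed = 1L,
                                adherence = 0.835, second_frac = 0.78,
                                second_gap_y = 4, enroll = c(55, 74),
                                followup_y = 11.9,
                                life_table = load_life_table(),
                                model = screening_model(),
                                costs = default_costs()) {
  pl <- screening_plan("sigmoidoscopy", enroll[1], adherence = adherence)
  pl$trial_mode <- TRUE
  pl$trial_enroll <- enroll
  pl$trial_followup_y <- followup_y
  pl$trial_second_frac <- second_frac
  pl$trial_second_gap_y <- second_gap_y
  pl0 <- pl; pl0$adherence <- 0
  scr <- simulate_population(params, life_table, pl, n, seed, model, costs)
  bas <- simulate_population(params, life_table, pl0, n, seed, model, costs)
  red <- function(s, b) if (b > 0) 1 - s / b else 0
  left_s <- scr$trial$cases[["rectum"]] + scr$trial$cases[["left_colon"]]
  left_b <- bas$trial$cases[["rectum"]] + bas$trial$cases[["left_colon"]]
  list(
    incidence_reduction = red(scr$trial$cases_total, bas$trial$cases_total),
    right_incidence_reduction = red(scr$trial$cases[["right_colon"]],
                                    bas$trial$cases[["right_colon"]]),
    left_incidence_reduction = red(left_s, left_b),
    mortality_reduction = red(scr$trial$deaths, bas$trial$deaths),
    cases = c(screened = scr$trial$cases_total, baseline = bas$trial$cases_total),
    deaths = c(screened = scr$trial$deaths, baseline = bas$trial$deaths),
    n = n)
}

#' Decennial colonoscopy scenario
#'
#' Screening colonoscopies at 10-year intervals between ages 50 and 75
#' (i.e., at 50, 60 and 70) with guideline surveillance, compared to a
#' paired no-screening arm.  Reported per 1000 individuals in the style of
#' the cross-model comparison tables; life-years gained are undiscounted
#' in that convention.
#'
#' @inheritParams run_trial_emulation
#' @param adherence screening adherence (comparison convention: 1).
#' @param config `cmost_econ_config` for the discounted extras.
#' @return list of per-1000 outcomes.
#' @export
run_decennial_colonoscopy <- function(params, n = 100000L, seed = 1L,
                                      adherence = 1,
                                      life_table = load_life_table(),
                                      model = screening_model(),
                                      costs = default_costs(),
                                      config = econ_config()) {
  pl <- screening_plan("colonoscopy", 50, 75, 10, adherence = adherence)
  scr <- simulate_population(params, life_table, pl, n, seed, model, costs)
  bas <- simulate_population(params, life_table, no_screening_plan(), n, seed,
                             model, costs)
  cmp <- compare_arms(scr, bas, config)
  lyg <- cmp$lyg_per_1000
  cols <- cmp$total_colonoscopies_per_1000
  list(
    incidence_reduction = cmp$incidence_reduction,
    mortality_reduction = cmp$mortality_reduction,
    lyg_per_1000 = lyg,
    screening_colonoscopies_per_1000 = cmp$screening_colonoscopies_per_1000,
    surveillance_colonoscopies_per_1000 = cmp$surveillance_colonoscopies_per_1000,
    total_colonoscopies_per_1000 = cols,
    crc_cases_prevented_per_1000 = cmp$cases_prevented_per_1000,
    crc_deaths_prevented_per_1000 = cmp$crc_deaths_prevented_per_1000,
    colonoscopies_per_case_prevented =
      if (cmp$cases_prevented_per_1000 > 0)
        cols / cmp$cases_prevented_per_1000 else NA_real_,
    colonoscopies_per_lyg = if (lyg > 0) cols / lyg else NA_real_,
    comparison = cmp)
}

#' Maximum clinical incidence reduction
#'
#' A hypothetical perfect intervention removes every adenoma and every
#' undiagnosed cancer at the given age; all CRC observed afterwards stems
#' from newly formed lesions (direct pathway plus new adenomas).  Returns
#' the CRC incidence-by-age curve after the intervention.
#'
#' @inheritParams run_trial_emulation
#' @param intervention_age age of the perfect clean-out (default 65).
#' @return list with `age`, `incidence_per_100k` (post-intervention ages)
#'   and the full `cmost_result`.
#' @export
run_max_clinical_incidence_reduction <- function(params, n = 100000L, seed = 1L,
                                                 intervention_age = 65,
                                                 life_table = load_life_table(),
                                                 model = screening_model(),
                                                 costs = default_costs()) {
  pl <- no_screening_plan()
  pl$perfect_removal_age <- intervention_age
  res <- simulate_population(params, life_table, pl, n, seed, model, costs)
  ages <- intervention_age:100
  inc <- sapply(ages, function(a)
    1e5 * sum(res$inc_stage[a + 1, ]) / max(res$py[a + 1], 1e-9))
  list(age = ages, incidence_per_100k = inc, result = res)
}

#' Single-colonoscopy age sweep
#'
#' One screening colonoscopy at each candidate age (with surveillance),
#' compared against the common paired no-screening baseline, reporting
#' incidence and mortality reduction, discounted and undiscounted
#' life-years gained per 1000 and cost per discounted LYG, plus the argmax
#' / argmin ages on the grid.
#'
#' @inheritParams run_trial_emulation
#' @param ages candidate screening ages (grid within 40-75).
#' @param config `cmost_econ_config`.
#' @return list with a per-age data.frame `sweep` and an `optima` list.
#' @export
run_single_colonoscopy_sweep <- function(params, ages = 40:75, n = 200000L,
                                         seed = 1L,
                                         life_table = load_life_table(),
                                         model = screening_model(),
                                         costs = default_costs(),
                                         config = econ_config()) {
  if (any(ages < 40 | ages > 75)) stop("sweep ages must lie in [40, 75]")
  bas <- simulate_population(params, life_table, no_screening_plan(), n, seed,
                             model, costs)
  rows <- lapply(ages, function(a) {
    pl <- screening_plan("colonoscopy", a)
    scr <- simulate_population(params, life_table, pl, n, seed, model, costs)
    cmp <- compare_arms(scr, bas, config)
    data.frame(age = a,
               incidence_reduction = cmp$incidence_reduction,
               mortality_reduction = cmp$mortality_reduction,
               lyg_per_1000 = cmp$lyg_per_1000,
               lyg_disc_per_1000 = cmp$lyg_disc_per_1000,
               cost_per_lyg = cmp$cost_per_lyg)
  })
  sweep <- do.call(rbind, rows)
  ok <- !is.na(sweep$cost_per_lyg) & sweep$lyg_disc_per_1000 > 0
  optima <- list(
    incidence_age = sweep$age[which.max(sweep$incidence_reduction)],
    mortality_age = sweep$age[which.max(sweep$mortality_reduction)],
    lyg_disc_age = sweep$age[which.max(sweep$lyg_disc_per_1000)],
    lyg_age = sweep$age[which.max(sweep$lyg_per_1000)],
    cost_age = if (any(ok)) sweep$age[ok][which.min(sweep$cost_per_lyg[ok])]
               else NA_real_)
  list(sweep = sweep, optima = optima, grid = ages)
}
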