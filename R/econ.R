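#' Present value of an age-indexed stream
#'
#' Discounts a yearly stream (costs or life-years, indexed by cohort age
#' year 0..100) to the configured reference age at the configured annual
#' rate, end-of-year convention: \eqn{PV = \sum_t x_t / (1+r)^{t - t_0}}.
#'
#' @param stream numeric vector indexed by age year (names or positions
#'   0..100).
#' @param config `cmost_econ_config`.
#' @return scalar present value.
#' @export
discount <- function(stream, config = econ_config()) {
  r <- config$discount_rate
  if (r < 0) stop("negative discount rate")
  t <- if (!is.null(names(stream))) as.numeric(names(stream))
       else seq_along(stream) - 1
  sum(stream / (1 + r)^(t - config$reference_age))
}

#' Treatment cost stream for one cancer record
#'
#' Reference implementation of the three-phase rule applied inside the
#' engine: the initial-phase cost is charged in the diagnosis quarter;
#' the continuing annual rate is charged quarterly afterwards up to 5 years
#' post-diagnosis; in case of death from CRC the terminal annual rate
#' replaces the continuing rate during the last 12 months before death
#' (terminal-dominant on overlap, initial retained); no cost accrues after
#' death or beyond the 5-year horizon.
#'
#' @param stage cancer stage 1-4 at detection.
#' @param diagnosis_age age (years) at diagnosis.
#' @param death_age age at death, or `NA` if the individual survives past
#'   the window.
#' @param crc_death logical: was the death caused by CRC?
#' @param costs `cmost_cost_table`.
#' @return data.frame with columns `quarter` (age in years, quarterly grid)
#'   and `cost`.
#' @export
accrue_treatment_costs <- function(stage, diagnosis_age, death_age = NA,
                                   crc_death = FALSE, costs = default_costs()) {
  if (!stage %in% 1:4) stop("stage must be 1-4")
  dq <- round(diagnosis_age * 4)
  end_q <- dq + 19
  if (!is.na(death_age)) end_q <- min(end_q, round(death_age * 4) - 1)
  if (end_q < dq) end_q <- dq  # initial phase always charged
  qs <- dq:end_q
  cost <- numeric(length(qs))
  term_start <- if (crc_death && !is.na(death_age)) round(death_age * 4) - 4 else Inf
  for (i in seq_along(qs)) {
    q <- qs[i]
    if (q == dq) cost[i] <- costs$treat_initial[stage]
    else if (q >= term_start) cost[i] <- costs$treat_terminal[stage] / 4
    else cost[i] <- costs$treat_continuing[stage] / 4
  }
  data.frame(quarter = qs / 4, cost = cost)
}

#' Compare a screening arm with its paired baseline
#'
#' Both runs must use the same population size and master seed (common
#' random numbers).  Reductions are `1 - screened/unscreened` cumulative
#' rates; life-years gained and incremental costs are discounted with
#' `config` before forming the cost-effectiveness ratio.
#'
#' @param screened,unscreened `cmost_result` objects.
#' @param config `cmost_econ_config`.
#' @return list with incidence and mortality reduction, LYG per 1000
#'   (discounted and undiscounted), incremental discounted cost per 1000,
#'   cost per discounted LYG (`NA` when discounted LYG <= 0), procedure
#'   counts per 1000, and a cost-effectiveness flag at the conventional
#'   100,000 USD/LYG threshold.
#' @export
compare_arms <- function(screened, unscreened, config = econ_config()) {
  if (screened$n != unscreened$n || screened$seed != unscreened$seed)
    stop("arms must be paired: same n and same master seed")
  n <- screened$n
  inc_s <- sum(screened$inc_stage); inc_u <- sum(unscreened$inc_stage)
  mort_s <- sum(screened$crc_death); mort_u <- sum(unscreened$crc_death)
  inc_red <- if (inc_u > 0) 1 - inc_s / inc_u else 0
  mort_red <- if (mort_u > 0) 1 - mort_s / mort_u else 0
  ages <- 0:100
  ly_s <- stats::setNames(screened$py, ages)
  ly_u <- stats::setNames(unscreened$py, ages)
  lyg <- sum(ly_s - ly_u)
  lyg_disc <- discount(ly_s, config) - discount(ly_u, config)
  cost_s <- stats::setNames(colSums(screened$cost), ages)
  cost_u <- stats::setNames(colSums(unscreened$cost), ages)
  dcost <- discount(cost_s, config) - discount(cost_u, config)
  ratio <- if (lyg_disc > 0) dcost / lyg_disc else NA_real_
  per1000 <- function(v) 1000 * v / n
  list(
    incidence_reduction = inc_red,
    mortality_reduction = mort_red,
    lyg_per_1000 = per1000(lyg),
    lyg_disc_per_1000 = per1000(lyg_disc),
    delta_cost_disc_per_1000 = per1000(dcost),
    cost_per_lyg = ratio,
    cost_effective = !is.na(ratio) && ratio < 1e5,
    cases_prevented_per_1000 = per1000(inc_u - inc_s),
    crc_deaths_prevented_per_1000 = per1000(mort_u - mort_s),
    screening_colonoscopies_per_1000 = per1000(sum(screened$colonoscopies[, "screening"])),
    surveillance_colonoscopies_per_1000 = per1000(sum(screened$colonoscopies[, "surveillance"])),
    total_colonoscopies_per_1000 = per1000(sum(screened$colonoscopies)),
    extra_colonoscopies_per_1000 =
      per1000(sum(screened$colonoscopies) - sum(unscreened$colonoscopies)))
}
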