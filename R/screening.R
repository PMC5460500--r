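#' Endoscopy and stool-test model
#'
#' Bundles the instrument characteristics shared by every screening arm:
#' colonoscopy reach (95% cecal intubation on average), per-stage adenoma
#' detection, flexure detection penalty, complication probabilities (major
#' bleed 4/10^4, minor bleed 11/10^4, mucosal burn 3/10^4, perforation
#' 7/10^4, all doubled after polypectomy), rectosigmoidoscopy reach (rectum
#' to the left flexure, on average 6 of 13 segments) and detection penalties
#' (-25% early, -12.5% advanced adenomas), stool-test sensitivity and
#' specificity, and guideline surveillance intervals.
#'
#' @param ... named overrides for any field.
#' @return an object of class `cmost_screening_model`.
#' @export
screening_model <- function(...) {
  m <- list(
    detect_adenoma = c(0.75, 0.75, 0.85, 0.85, 0.95, 0.95),
    detect_cancer = 0.95,
    flexure_penalty = 0.90,
    flexure_segments = c(6L, 9L),      # splenic, hepatic flexure
    reach_cecum = 0.95,
    incomplete_range = c(8L, 12L),     # deepest segment if cecum not reached
    complication_p = c(major_bleed = 4, minor_bleed = 11, mucosal_burn = 3,
                       perforation = 7) / 1e4,
    complication_polyp_mult = 2,
    perforation_fatality = 0.05,
    sig_complication_mult = 0.1,
    sig_reach_lo = 5L,                 # deepest segment 5, 6 or 7
    sig_reach_p = c(0.2, 0.6, 0.2),    # mean 6 of 13 segments
    sig_penalty_early = 0.75,
    sig_penalty_adv = 0.875,
    fobt_sens_early = 0.05, fobt_sens_adv = 0.12, fobt_sens_cancer = 0.40,
    fobt_spec = 0.98,
    surv_interval_crc = 4L,            # quarters: 1 y after CRC resection
    surv_interval_adv = 12L,           # 3 y: advanced adenoma or >= 3 adenomas
    surv_interval_small = 20L,         # 5 y: 1-2 small adenomas
    surv_stop_q = 340L)                # no surveillance past age 85
  dots <- list(...)
  bad <- setdiff(names(dots), names(m))
  if (length(bad)) stop("unknown screening-model field(s): ", paste(bad, collapse = ", "))
  m[names(dots)] <- dots
  stopifnot(all(unlist(m[c("detect_adenoma", "detect_cancer", "reach_cecum",
                           "complication_p", "fobt_spec")]) >= 0),
            all(m$detect_adenoma <= 1), m$reach_cecum <= 1)
  class(m) <- "cmost_screening_model"
  m
}

#' Screening plan
#'
#' A plan has a modality, a start and stop age, a screening interval, an
#' adherence fraction (drawn once per individual: consistent attenders) and
#' a follow-up adherence for referral colonoscopies after a positive
#' sigmoidoscopy or stool test.
#'
#' @param modality one of `"none"`, `"colonoscopy"`, `"sigmoidoscopy"`,
#'   `"fobt"`.
#' @param start_age,stop_age screening window in years (`start < stop`
#'   unless a single round is meant; `stop_age` defaults to `start_age`).
#' @param interval_y interval between rounds, years (>= 1).
#' @param adherence,fu_adherence fractions in `[0, 1]`.
#' @param surveillance logical: schedule guideline surveillance after
#'   positive findings.
#' @return an object of class `cmost_plan`.
#' @export
screening_plan <- function(modality = "none", start_age = 50, stop_age = NULL,
                           interval_y = 10, adherence = 1, fu_adherence = 1,
                           surveillance = TRUE) {
  modality <- match.arg(modality, c("none", "colonoscopy", "sigmoidoscopy", "fobt"))
  if (is.null(stop_age)) stop_age <- start_age
  if (stop_age < start_age) stop("stop_age must be >= start_age")
  if (interval_y < 1) stop("interval_y must be >= 1 year")
  if (adherence < 0 || adherence > 1) stop("adherence must be in [0, 1]")
  ages <- if (modality == "none") numeric(0) else seq(start_age, stop_age, by = interval_y)
  structure(list(
    modality = modality, start_age = start_age, stop_age = stop_age,
    interval_y = interval_y, screen_ages = ages,
    adherence = adherence, fu_adherence = fu_adherence,
    surveillance_on = isTRUE(surveillance),
    trial_mode = FALSE, trial_enroll = c(55, 74), trial_followup_y = 11.9,
    trial_second_frac = 0, trial_second_gap_y = 4,
    perfect_removal_age = NA_real_), class = "cmost_plan")
}

#' @rdname screening_plan
#' @export
no_screening_plan <- function() screening_plan("none")

#' Surveillance interval after a procedure
#'
#' Deterministic guideline rule table: detected CRC implies review at 1
#' year; an advanced adenoma or three or more adenomas imply 3 years; one or
#' two small adenomas imply 5 years; no findings return the individual to
#' routine screening.
#'
#' @param findings list with counts `n_adenomas`, `n_advanced` and logical
#'   `cancer`.
#' @param model a `cmost_screening_model` (supplies the intervals).
#' @return follow-up interval in years, or `NA` if no surveillance is due.
#' @export
schedule_surveillance <- function(findings, model = screening_model()) {
  need <- c("n_adenomas", "n_advanced", "cancer")
  if (!all(need %in% names(findings)))
    stop("findings must contain: ", paste(need, collapse = ", "))
  if (isTRUE(findings$cancer)) return(model$surv_interval_crc / 4)
  if (findings$n_advanced > 0 || findings$n_adenomas >= 3)
    return(model$surv_interval_adv / 4)
  if (findings$n_adenomas >= 1) return(model$surv_interval_small / 4)
  NA_real_
}

# internal: flatten a plan for the C++ engine
as_engine_plan <- function(plan) {
  mod <- match(plan$modality, c("none", "colonoscopy", "sigmoidoscopy", "fobt")) - 1L
  list(
    modality = mod,
    screen_quarters = as.integer(round(plan$screen_ages * 4)),
    adherence = plan$adherence, fu_adherence = plan$fu_adherence,
    surveillance_on = plan$surveillance_on,
    trial_mode = plan$trial_mode,
    trial_lo_q = as.integer(round(plan$trial_enroll[1] * 4)),
    trial_hi_q = as.integer(round(plan$trial_enroll[2] * 4)),
    trial_fu_q = as.integer(round(plan$trial_followup_y * 4)),
    trial_gap_q = as.integer(round(plan$trial_second_gap_y * 4)),
    trial_second_frac = plan$trial_second_frac,
    perfect_q = if (is.na(plan$perfect_removal_age)) 0L
                else as.integer(round(plan$perfect_removal_age * 4)))
}

#' Sample colonoscopy complications
#'
#' Draws per-procedure complication indicators from the same probability
#' model the engine applies (major bleed, minor bleed, mucosal burn,
#' perforation; all doubled after polypectomy).  Intended for empirical
#' rate checks at large n.
#'
#' @param n number of procedures.
#' @param model `cmost_screening_model`.
#' @param polypectomy logical: apply the polypectomy multiplier.
#' @param seed integer seed.
#' @return named vector of complication counts.
#' @export
sample_complications <- function(n, model = screening_model(),
                                 polypectomy = FALSE, seed = 1L) {
  counts <- sample_complications_cpp(as.integer(n), model$complication_p,
                                     model$complication_polyp_mult,
                                     isTRUE(polypectomy), as.integer(seed))
  stats::setNames(as.numeric(counts), names(model$complication_p))
}
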