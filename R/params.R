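#' Natural-history parameter set
#'
#' Creates the full set of calibratable constants and age/sex/location risk
#' functions governing the adenoma-carcinoma sequence.  Age-dependent adenoma
#' initiation follows a sigmoid \eqn{a_0 / (1 + \exp(-(a_1 y - a_2)))} in age
#' \eqn{y} (years); early and advanced adenoma progression follow Gaussians
#' \eqn{b_0 \exp(-(b_1 y - b_2)^2)} and \eqn{c_0 \exp(-(c_1 y - c_2)^2)}.
#' All rates are per quarter-year time step.  Heterogeneity between
#' individuals and between lesions is injected through piecewise-linear
#' cumulative-density anchor curves mapping a uniform quantile to a risk
#' multiplier.
#'
#' @param dwell_variant target median adenoma dwell time in years (8, 13 or
#'   19); a label carried with the parameter set and enforced during
#'   calibration, not a runtime switch.
#' @param ... named overrides for any field (see Details).
#'
#' @details Fields: `a0,a1,a2`, `b0,b1,b2`, `c0,c1,c2`;
#'   `individual_risk_anchors`, `adenoma_risk_anchors_early`,
#'   `adenoma_risk_anchors_advanced` (each a list with `q` quantiles and `m`
#'   multipliers); `sex_factors` (male multipliers for initiation, early and
#'   advanced progression); `rectum_factors` (early, advanced);
#'   `stage_progression` (6), `stage_regression` (6, not calibrated),
#'   `stage_cancer_risk` (5), `direct_cancer_risk` (13, one per colon
#'   segment); `sojourn_mean_y`, `sojourn_sd_y`; plus engine configuration
#'   tables: `location_dist` (13), `symptomatic_stage_dist` (4),
#'   `stage_time_weights` (4), `survival_5y` (4), `male_fraction`.
#'
#' @return an object of class `cmost_params`.
#' @export
natural_history_params <- function(dwell_variant = 13, ...) {
  p <- list(
    a0 = 0.012, a1 = 0.12, a2 = 4.8,
    b0 = 0.018, b1 = 0.040, b2 = 2.30,
    c0 = 0.0020, c1 = 0.030, c2 = 2.28,
    individual_risk_anchors = list(
      q = c(0, 0.50, 0.80, 0.95, 1),
      m = c(0.05, 0.35, 1.20, 3.00, 12.0)),
    adenoma_risk_anchors_early = list(
      q = c(0, 0.60, 0.80, 0.93, 1),
      m = c(0.02, 0.30, 1.50, 5.00, 30.0)),
    adenoma_risk_anchors_advanced = list(
      q = c(0, 0.60, 0.80, 0.93, 1),
      m = c(0.01, 0.10, 0.60, 4.00, 35.0)),
    sex_factors = c(initiation = 1.40, early = 1.10, advanced = 1.10),
    rectum_factors = c(early = 1.50, advanced = 5.00),
    stage_progression = c(1.2, 1.0, 0.9, 0.8, 0.7, 0.9),
    stage_regression = c(0.015, 0.008, 0.005, 0.003, 0.002, 0.001),
    stage_cancer_risk = c(8e-05, 1.6e-04, 3.2e-04, 6e-04, 1.2e-03),
    direct_cancer_risk = 2.3e-05 *
      c(0.02, 0.02, 0.03, 0.03, 0.03, 0.03, 0.06, 0.06, 0.08, 0.12, 0.14,
        0.19, 0.19),
    sojourn_mean_y = 3.0, sojourn_sd_y = 0.5,
    dwell_variant = dwell_variant,
    location_dist = c(0.09, 0.06, 0.13, 0.10, 0.08, 0.04, 0.07, 0.07, 0.04,
                      0.09, 0.09, 0.07, 0.07),
    symptomatic_stage_dist = c(0.18, 0.30, 0.29, 0.23),
    stage_time_weights = c(0.50, 0.25, 0.15, 0.10),
    survival_5y = c(0.94, 0.82, 0.62, 0.11),
    male_fraction = 0.5)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  class(p) <- "cmost_params"
  validate_params(p)
  p
}

#' Validate a natural-history parameter set
#'
#' Checks arities, non-negativity of all rate constants, monotone anchor
#' CDFs on the unit quantile axis and a positive sojourn standard deviation.
#'
#' @param p a `cmost_params` object (or plain list with the same fields).
#' @return `p`, invisibly; errors otherwise.
#' @export
validate_params <- function(p) {
  need <- c("a0", "a1", "a2", "b0", "b1", "b2", "c0", "c1", "c2",
            "individual_risk_anchors", "adenoma_risk_anchors_early",
            "adenoma_risk_anchors_advanced", "sex_factors", "rectum_factors",
            "stage_progression", "stage_regression", "stage_cancer_risk",
            "direct_cancer_risk", "sojourn_mean_y", "sojourn_sd_y",
            "dwell_variant", "location_dist", "symptomatic_stage_dist",
            "stage_time_weights", "survival_5y", "male_fraction")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter field(s): ", paste(miss, collapse = ", "))
  chk_len <- function(field, n)
    if (length(p[[field]]) != n)
      stop(sprintf("%s must have %d entries, got %d", field, n, length(p[[field]])))
  chk_len("stage_progression", 6); chk_len("stage_regression", 6)
  chk_len("stage_cancer_risk", 5); chk_len("direct_cancer_risk", 13)
  chk_len("location_dist", 13); chk_len("symptomatic_stage_dist", 4)
  chk_len("stage_time_weights", 4); chk_len("survival_5y", 4)
  chk_len("sex_factors", 3); chk_len("rectum_factors", 2)
  rates <- c(p$a0, p$b0, p$c0, p$stage_progression, p$stage_regression,
             p$stage_cancer_risk, p$direct_cancer_risk)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0")
  for (nm in c("individual_risk_anchors", "adenoma_risk_anchors_early",
               "adenoma_risk_anchors_advanced")) {
    a <- p[[nm]]
    if (length(a$q) != length(a$m) || length(a$q) < 2)
      stop(nm, ": q and m must be equal-length vectors (>= 2 anchors)")
    if (a$q[1] != 0 || a$q[length(a$q)] != 1 || is.unsorted(a$q))
      stop(nm, ": quantile axis must be nondecreasing from 0 to 1")
    if (is.unsorted(a$m) || any(a$m < 0))
      stop(nm, ": multipliers must be nondecreasing and >= 0")
  }
  if (!is.finite(p$sojourn_sd_y) || p$sojourn_sd_y <= 0)
    stop("sojourn_sd_y must be > 0")
  if (abs(sum(p$symptomatic_stage_dist) - 1) > 1e-6)
    stop("symptomatic_stage_dist must sum to 1")
  if (any(p$survival_5y < 0 | p$survival_5y > 1))
    stop("survival_5y entries must be in [0, 1]")
  invisible(p)
}

#' Age-dependent adenoma initiation rate
#'
#' Sigmoid in age, scaled by the male correction factor and the individual's
#' risk multiplier, clipped to `[0, 1]`.  The returned value is a per-quarter
#' initiation probability.
#'
#' @param p `cmost_params`.
#' @param age age in years, in `[0, 100]`.
#' @param sex `"female"` or `"male"`.
#' @param multiplier individual risk multiplier (default 1).
#' @return per-quarter probability of a new adenoma.
#' @export
initiation_rate <- function(p, age, sex = "female", multiplier = 1) {
  if (any(age < 0) || any(age > 100)) stop("age must be in [0, 100]")
  sexf <- ifelse(match.arg(sex, c("female", "male")) == "male",
                 p$sex_factors[["initiation"]], 1)
  r <- p$a0 / (1 + exp(-(p$a1 * age - p$a2))) * sexf * multiplier
  pmin(pmax(r, 0), 1)
}

#' Age-dependent adenoma progression rates
#'
#' Gaussian base rates per quarter: `early_progression_rate()` governs stage
#' I-IV transitions, `advanced_progression_rate()` stage V-VI transitions and
#' the fast adenoma-to-carcinoma route.
#'
#' @inheritParams initiation_rate
#' @return per-quarter base rate at `age`.
#' @export
early_progression_rate <- function(p, age) {
  if (any(age < 0) || any(age > 100)) stop("age must be in [0, 100]")
  p$b0 * exp(-(p$b1 * age - p$b2)^2)
}

#' @rdname early_progression_rate
#' @export
advanced_progression_rate <- function(p, age) {
  if (any(age < 0) || any(age > 100)) stop("age must be in [0, 100]")
  p$c0 * exp(-(p$c1 * age - p$c2)^2)
}

# shared piecewise-linear interpolation through anchor points
.pwl <- function(anchors, u) {
  stats::approx(anchors$q, anchors$m, xout = u, rule = 2, ties = "ordered")$y
}

#' Sample an individual adenoma-risk multiplier
#'
#' Maps a uniform population quantile through the anchored CDF by
#' piecewise-linear interpolation; monotone in `u`.
#'
#' @param p `cmost_params`.
#' @param u quantile(s) in `[0, 1]`.
#' @param which one of `"individual"`, `"lesion_early"`, `"lesion_advanced"`.
#' @return risk multiplier(s).
#' @export
sample_individual_risk <- function(p, u, which = "individual") {
  if (any(u < 0) || any(u > 1)) stop("u must be in [0, 1]")
  a <- switch(match.arg(which, c("individual", "lesion_early", "lesion_advanced")),
              individual      = p$individual_risk_anchors,
              lesion_early    = p$adenoma_risk_anchors_early,
              lesion_advanced = p$adenoma_risk_anchors_advanced)
  .pwl(a, u)
}

#' Save / load a parameter file
#'
#' Parameter sets are stored as versioned JSON key trees; a save-load round
#' trip reproduces the object exactly (up to double-precision printing).
#'
#' @param p `cmost_params`.
#' @param path file path (JSON).
#' @return `load_params` returns a validated `cmost_params`.
#' @export
save_params <- function(p, path) {
  validate_params(p)
  obj <- unclass(p)
  obj$schema <- "cmost-params/1"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema) || !identical(obj$schema, "cmost-params/1"))
    stop("not a recognised parameter file (missing schema tag)")
  obj$schema <- NULL
  # named vectors lose names through JSON; restore the documented ones
  obj$sex_factors <- stats::setNames(as.numeric(obj$sex_factors),
                                     c("initiation", "early", "advanced"))
  obj$rectum_factors <- stats::setNames(as.numeric(obj$rectum_factors),
                                        c("early", "advanced"))
  class(obj) <- "cmost_params"
  validate_params(obj)
  obj
}

#' Shipped calibrated parameter sets
#'
#' Loads one of the calibrated parameter fixtures shipped with the package
#' (produced by [calibrate_full()] against the shipped benchmark fixture).
#'
#' @param dwell_variant 8, 13 or 19.
#' @return `cmost_params`.
#' @export
cmost_params <- function(dwell_variant = 13) {
  f <- system.file("extdata", sprintf("params_cmost%d.json", dwell_variant),
                   package = "cmost")
  if (f == "") stop("no shipped parameter fixture for dwell variant ", dwell_variant)
  load_params(f)
}

#' @export
print.cmost_params <- function(x, ...) {
  cat("<cmost_params> dwell variant:", x$dwell_variant, "years\n")
  cat(sprintf("  initiation sigmoid: a0=%.4g a1=%.3g a2=%.3g\n", x$a0, x$a1, x$a2))
  cat(sprintf("  early progression:  b0=%.4g b1=%.3g b2=%.3g (peak age %.0f)\n",
              x$b0, x$b1, x$b2, x$b2 / x$b1))
  cat(sprintf("  advanced progression: c0=%.4g c1=%.3g c2=%.3g (peak age %.0f)\n",
              x$c0, x$c1, x$c2, x$c2 / x$c1))
  cat(sprintf("  sojourn: N(%.2g, %.2g^2) years; direct-cancer total %.3g/quarter\n",
              x$sojourn_mean_y, x$sojourn_sd_y, sum(x$direct_cancer_risk)))
  invisible(x)
}
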