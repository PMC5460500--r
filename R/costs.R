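#' Cost table
#'
#' Unit costs (2012 USD, payer perspective) for procedures, complications
#' and stage- and phase-specific cancer treatment.  Treatment is split into
#' an initial phase (first 3 months, charged once at diagnosis), a
#' continuing phase (annual rate, charged quarterly up to 5 years after
#' diagnosis) and a terminal phase (annual rate over the last 12 months
#' before death from colorectal cancer, replacing the continuing rate).
#' The shipped fixture `inst/extdata/costs.csv` is a synthetic
#' Medicare-schedule-style table; all values are configurable.
#'
#' @param path optional CSV with columns `item`, `stage`, `value` to
#'   override the defaults (stage `NA` for flat items).
#' @return an object of class `cmost_cost_table`.
#' @export
cost_table <- function(path = NULL) {
  ct <- list(
    colonoscopy = 750, polypectomy = 250, sigmoidoscopy = 250, fobt = 20,
    complication_costs = c(major_bleed = 4000, minor_bleed = 300,
                           mucosal_burn = 3000, perforation = 15000),
    treat_initial = c(32000, 45000, 55000, 65000),
    treat_continuing = c(2000, 2500, 3500, 8000),
    treat_terminal = c(52000, 55000, 60000, 70000))
  if (!is.null(path)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("item", "stage", "value") %in% names(df)))
      stop("cost CSV needs columns item, stage, value")
    for (i in seq_len(nrow(df))) {
      it <- df$item[i]; st <- df$stage[i]; v <- df$value[i]
      if (v < 0) stop("costs must be >= 0")
      if (it %in% c("colonoscopy", "polypectomy", "sigmoidoscopy", "fobt")) {
        ct[[it]] <- v
      } else if (it %in% names(ct$complication_costs)) {
        ct$complication_costs[[it]] <- v
      } else if (it %in% c("treat_initial", "treat_continuing", "treat_terminal")) {
        if (is.na(st) || st < 1 || st > 4) stop("treatment cost rows need stage 1-4")
        ct[[it]][st] <- v
      } else stop("unknown cost item: ", it)
    }
  }
  if (any(unlist(ct) < 0)) stop("costs must be >= 0")
  class(ct) <- "cmost_cost_table"
  ct
}

#' Load the shipped cost fixture
#' @return `cmost_cost_table`.
#' @export
default_costs <- function() {
  f <- system.file("extdata", "costs.csv", package = "cmost")
  if (f == "") cost_table() else cost_table(f)
}

#' Economic configuration
#'
#' @param discount_rate annual discount rate (default 0.03, must be >= 0).
#' @param reference_age discounting reference point on the cohort age axis
#'   (default 0 = cohort birth; the cost-per-LYG ratio is invariant to this
#'   choice, absolute present values are not).
#' @return an object of class `cmost_econ_config`.
#' @export
econ_config <- function(discount_rate = 0.03, reference_age = 0) {
  if (discount_rate < 0) stop("discount_rate must be >= 0")
  structure(list(discount_rate = discount_rate, reference_age = reference_age,
                 treatment_horizon_y = 5),
            class = "cmost_econ_config")
}
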