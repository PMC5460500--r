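#' Period life table
#'
#' Reads a life table CSV with columns `age` (0-100) and `qx` (annual
#' probability of death from causes other than colorectal cancer).  The
#' package ships a stylized 2008 US-style period table under
#' `inst/extdata/life_table_2008.csv`.
#'
#' @param path CSV path; default is the shipped table.
#' @return a data.frame of class `cmost_life_table` with columns `age`, `qx`.
#' @export
load_life_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "life_table_2008.csv", package = "cmost")
  lt <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(lt))) stop("life table needs columns age, qx")
  lt <- lt[order(lt$age), c("age", "qx")]
  if (!identical(as.integer(lt$age), 0:100))
    stop("life table must cover ages 0..100 exactly")
  if (any(lt$qx < 0 | lt$qx > 1)) stop("qx must be probabilities in [0, 1]")
  class(lt) <- c("cmost_life_table", "data.frame")
  lt
}

#' Quarterly cumulative death CDF from an annual life table
#'
#' Converts annual death probabilities to quarterly hazards
#' (\eqn{q_{quarter} = 1 - (1-q_x)^{1/4}}) and returns the cumulative
#' probability of death by the end of each quarter from birth.  Death is
#' forced by the end of age 100 (simulation horizon).
#'
#' @param lt a `cmost_life_table`.
#' @return numeric vector of length 404 (quarters 0..403), nondecreasing,
#'   ending at 1.
#' @export
death_cdf_quarterly <- function(lt) {
  qx <- lt$qx
  qx[length(qx)] <- 1  # horizon: nobody outlives age 100
  surv <- 1
  cdf <- numeric(404)
  for (a in 0:100) {
    hq <- 1 - (1 - qx[a + 1])^(1 / 4)
    for (k in 0:3) {
      q <- 4 * a + k
      if (q >= 404) break
      surv <- surv * (1 - hq)
      cdf[q + 1] <- 1 - surv
    }
  }
  cdf[404] <- 1
  cdf
}
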