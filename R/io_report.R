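#' Write a run to an output directory
#'
#' Emits open, diff-able files: per-age tally CSVs, scalar diagnostics as
#' JSON, and a run manifest (parameter hash, seed, n, package version,
#' scenario id, timestamp).  `read_outputs()` restores the tallies; a
#' write-read round trip is exact and re-running the manifest's seed and n
#' with the same parameters reproduces the tallies bit-identically.
#'
#' @param result `cmost_result`.
#' @param dir output directory (created if missing).
#' @param params the `cmost_params` used (hashed into the manifest).
#' @param scenario free-text scenario id for the manifest.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(result, dir, params = NULL, scenario = "run") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ages <- 0:100
  tall <- data.frame(
    age = ages, py = result$py,
    alive_f = result$alive_at[, 1], alive_m = result$alive_at[, 2],
    early_f = result$early_at[, 1], early_m = result$early_at[, 2],
    adv_f = result$adv_at[, 1], adv_m = result$adv_at[, 2],
    carriers = result$carrier_at, multi = result$multi_at,
    inc_stage1 = result$inc_stage[, 1], inc_stage2 = result$inc_stage[, 2],
    inc_stage3 = result$inc_stage[, 3], inc_stage4 = result$inc_stage[, 4],
    inc_f = result$inc_sex[, 1], inc_m = result$inc_sex[, 2],
    inc_symptomatic = result$inc_mode[, 1], inc_screening = result$inc_mode[, 2],
    inc_other = result$inc_mode[, 3],
    inc_rectum = result$inc_side[, 1], inc_left = result$inc_side[, 2],
    inc_right = result$inc_side[, 3],
    crc_death = result$crc_death, oth_death = result$oth_death,
    compl_death = result$compl_death,
    col_screening = result$colonoscopies[, 1],
    col_surveillance = result$colonoscopies[, 2],
    col_diagnostic = result$colonoscopies[, 3],
    col_followup = result$colonoscopies[, 4],
    sigmoidoscopies = result$sigmoidoscopies, fobt = result$fobt_tests,
    polypectomies = result$polypectomies,
    cost_procedures = result$cost[1, ], cost_complications = result$cost[2, ],
    cost_treatment = result$cost[3, ])
  utils::write.csv(tall, file.path(dir, "tallies.csv"), row.names = FALSE)
  scal <- list(
    n = result$n, seed = result$seed,
    complications = as.list(as.data.frame(t(result$complications))),
    n_colono = as.list(result$n_colono),
    origin_init = as.list(result$origin_init),
    origin_diag = as.list(result$origin_diag),
    sync_diag = result$sync_diag, total_diag = result$total_diag,
    years_lost = result$years_lost,
    stage_mode = list(symptomatic = unname(result$stage_mode[1, ]),
                      asymptomatic = unname(result$stage_mode[2, ])),
    dwell_hist = result$dwell_hist,
    trial = result$trial, conservation = as.list(result$conservation),
    clip_warnings = result$clip_warnings)
  jsonlite::write_json(scal, file.path(dir, "scalars.json"),
                       auto_unbox = TRUE, digits = NA)
  phash <- if (!is.null(params)) {
    tf <- tempfile(fileext = ".json"); on.exit(unlink(tf), add = TRUE)
    save_params(params, tf)
    unname(tools::md5sum(tf))
  } else NA_character_
  manifest <- list(schema = "cmost-manifest/1", scenario = scenario,
                   n = result$n, seed = result$seed,
                   modality = result$plan$modality,
                   params_md5 = phash,
                   package_version = as.character(utils::packageVersion("cmost")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_outputs
#' @export
read_outputs <- function(dir) {
  tf <- file.path(dir, "tallies.csv"); sf <- file.path(dir, "scalars.json")
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(tf) || !file.exists(sf) || !file.exists(mf))
    stop("partial or corrupt output directory: ", dir)
  list(tallies = utils::read.csv(tf),
       scalars = jsonlite::read_json(sf, simplifyVector = TRUE),
       manifest = jsonlite::read_json(mf, simplifyVector = TRUE))
}

#' Benchmark-comparison plot
#'
#' Plots predicted against target for every benchmark row of a calibration
#' result, marking points within 20% of their benchmark as green squares
#' and the rest as red squares, one panel per category.
#'
#' @param calibration `cmost_calibration`.
#' @param file optional output file (PDF); when `NULL`, plots on the
#'   current device.
#' @return invisibly, the flag vector used (in table row order).
#' @export
plot_benchmark_comparison <- function(calibration, file = NULL) {
  tab <- calibration$table
  if (!is.null(file)) {
    grDevices::pdf(file, width = 9, height = 6)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  cats <- unique(tab$category)
  nc <- ceiling(sqrt(length(cats)))
  graphics::par(mfrow = c(ceiling(length(cats) / nc), nc), mar = c(4, 4, 2, 1))
  for (cat in cats) {
    d <- tab[tab$category == cat, ]
    x <- if (all(is.finite(d$age_lo))) (d$age_lo + d$age_hi) / 2 else seq_len(nrow(d))
    ylim <- range(c(d$value, d$predicted), na.rm = TRUE)
    graphics::plot(x, d$value, type = "b", lty = 2, col = "blue", pch = 15,
                   xlab = "age / index", ylab = cat, ylim = ylim, main = cat)
    graphics::points(x, d$predicted, pch = 15,
                     col = ifelse(d$within20, "forestgreen", "red"))
    graphics::lines(x, d$predicted, col = "black")
  }
  invisible(tab$within20)
}
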