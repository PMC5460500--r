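test_that("complication rates match their specification, doubled after polypectomy", {
  m <- screening_model()
  n <- 4e6
  base <- sample_complications(n, m, FALSE, 42)
  poly <- sample_complications(n, m, TRUE, 43)
  target <- c(4, 11, 3, 7) / 1e4
  expect_equal(as.numeric(base) / n, target, tolerance = 0.15)
  expect_equal(as.numeric(poly) / n, 2 * target, tolerance = 0.15)
})

test_that("in-engine complication rates agree with the stand-alone sampler", {
  # colonoscopy screening every 5 years, all lesions suppressed: every
  # procedure is polypectomy-free and complication draws are at baseline
  p <- sterile_params()
  pl <- screening_plan("colonoscopy", 50, 75, 5)
  r <- simulate_population(p, n = 40000, seed = 6, plan = pl)
  n_proc <- r$n_colono[["no_polypectomy"]]
  expect_gt(n_proc, 1e5)
  expect_equal(unname(r$n_colono[["polypectomy"]]), 0)
  rate <- r$complications["no_polypectomy", ] / n_proc
  expect_equal(unname(rate), c(4, 11, 3, 7) / 1e4, tolerance = 0.35)
})

test_that("cecal intubation frequency is 95%", {
  p <- sterile_params()
  pl <- screening_plan("colonoscopy", 50, 75, 5)
  r <- simulate_population(p, n = 25000, seed = 9, plan = pl)
  frac <- r$n_colono[["reached_cecum"]] / r$n_colono[["total"]]
  expect_gt(r$n_colono[["total"]], 1e5)
  expect_equal(unname(frac), 0.95, tolerance = 0.005 / 0.95)
})

test_that("sigmoidoscopy never sees the cecum and removes nothing", {
  # all adenomas in the cecum: sigmoidoscopy generates no referrals and no
  # polypectomies
  p <- natural_history_params(location_dist = c(rep(0, 12), 1),
                              stage_cancer_risk = rep(0, 5),
                              direct_cancer_risk = rep(0, 13),
                              stage_progression = rep(0, 6))
  pl <- screening_plan("sigmoidoscopy", 55, 70, 5)
  r <- simulate_population(p, n = 10000, seed = 12, plan = pl)
  expect_gt(sum(r$sigmoidoscopies), 1e4)
  expect_equal(sum(r$colonoscopies[, "followup"]), 0)
  expect_equal(sum(r$polypectomies), 0)
  expect_equal(unname(r$conservation[["resected"]]), 0)
})

test_that("a full-detection colonoscopy empties the adenoma list", {
  p <- natural_history_params(stage_cancer_risk = rep(0, 5),
                              direct_cancer_risk = rep(0, 13))
  m <- screening_model(detect_adenoma = rep(1, 6), reach_cecum = 1,
                       flexure_penalty = 1)
  pl <- screening_plan("colonoscopy", 75, adherence = 1, surveillance = FALSE)
  scr <- simulate_population(p, n = 20000, seed = 21, plan = pl, model = m)
  bas <- simulate_population(p, n = 20000, seed = 21)
  # carriers just after the clean-out reflect at most one year of new
  # initiations; the unscreened arm carries the accumulated stock
  expect_lt(scr$carrier_at[77], 0.12 * bas$carrier_at[77])
})

test_that("surveillance rule table maps findings to guideline intervals", {
  m <- screening_model()
  expect_equal(schedule_surveillance(list(n_adenomas = 1, n_advanced = 1,
                                          cancer = FALSE), m), 3)
  expect_equal(schedule_surveillance(list(n_adenomas = 3, n_advanced = 0,
                                          cancer = FALSE), m), 3)
  expect_equal(schedule_surveillance(list(n_adenomas = 2, n_advanced = 0,
                                          cancer = FALSE), m), 5)
  expect_equal(schedule_surveillance(list(n_adenomas = 0, n_advanced = 0,
                                          cancer = TRUE), m), 1)
  expect_true(is.na(schedule_surveillance(list(n_adenomas = 0, n_advanced = 0,
                                               cancer = FALSE), m)))
  expect_error(schedule_surveillance(list(foo = 1), m), "findings")
})

test_that("zero-yield stool testing is indistinguishable from no screening", {
  p <- fixture_params()
  m <- screening_model(fobt_sens_early = 0, fobt_sens_adv = 0,
                       fobt_sens_cancer = 0, fobt_spec = 1)
  pl <- screening_plan("fobt", 50, 75, 1)
  scr <- simulate_population(p, n = 8000, seed = 31, plan = pl, model = m)
  bas <- simulate_population(p, n = 8000, seed = 31)
  expect_identical(scr$inc_stage, bas$inc_stage)
  expect_identical(scr$crc_death, bas$crc_death)
  expect_identical(scr$py, bas$py)
  expect_gt(sum(scr$fobt_tests), 0)
})

test_that("zero adherence reproduces the baseline arm exactly", {
  p <- fixture_params()
  pl <- screening_plan("colonoscopy", 50, 75, 10, adherence = 0)
  scr <- simulate_population(p, n = 8000, seed = 32, plan = pl)
  bas <- simulate_population(p, n = 8000, seed = 32)
  expect_identical(scr$inc_stage, bas$inc_stage)
  expect_identical(scr$py, bas$py)
  expect_equal(sum(scr$colonoscopies[, "screening"]), 0)
})

test_that("screening procedure volume scales with adherence", {
  p <- sterile_params()
  count_at <- function(adh) {
    pl <- screening_plan("colonoscopy", 50, 75, 10, adherence = adh)
    r <- simulate_population(p, n = 30000, seed = 14, plan = pl)
    sum(r$colonoscopies[, "screening"])
  }
  full <- count_at(1)
  half <- count_at(0.5)
  expect_equal(half / full, 0.5, tolerance = 0.03)
})

test_that("an annual stool-test program reduces incidence", {
  p <- fixture_params()
  pl <- screening_plan("fobt", 50, 75, 1, adherence = 1)
  scr <- simulate_population(p, n = 40000, seed = 15, plan = pl)
  bas <- simulate_population(p, n = 40000, seed = 15)
  expect_lt(sum(scr$inc_stage), sum(bas$inc_stage))
})
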