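test_that("zero-adherence trial emulation shows no effect", {
  p <- fixture_params()
  tr <- run_trial_emulation(p, n = 20000, seed = 61, adherence = 0)
  expect_equal(tr$incidence_reduction, 0)
  expect_equal(tr$mortality_reduction, 0)
  expect_equal(unname(tr$cases[["screened"]]), unname(tr$cases[["baseline"]]))
})

test_that("a blind instrument yields flat sweep curves", {
  p <- fixture_params()
  m <- screening_model(detect_adenoma = rep(0, 6), detect_cancer = 0)
  sw <- run_single_colonoscopy_sweep(p, ages = c(50, 60), n = 10000, seed = 62,
                                     model = m)
  expect_true(all(abs(sw$sweep$incidence_reduction) < 0.02))
  expect_true(all(abs(sw$sweep$mortality_reduction) < 0.05))
})

test_that("perfect clean-out at 65 suppresses incidence immediately after", {
  p <- fixture_params()
  mx <- run_max_clinical_incidence_reduction(p, n = 40000, seed = 63)
  bas <- simulate_population(p, n = 40000, seed = 63)
  base_inc <- 1e5 * sum(bas$inc_stage[66:67, ]) / sum(bas$py[66:67])
  post_inc <- mean(mx$incidence_per_100k[mx$age %in% 65:66])
  expect_lt(post_inc, 0.35 * base_inc)
  # incidence recovers as new lesions accumulate
  late_inc <- mean(mx$incidence_per_100k[mx$age %in% 80:85])
  expect_gt(late_inc, post_inc)
})

test_that("without direct cancers and initiation, nothing follows the clean-out", {
  p <- natural_history_params(a0 = 0, direct_cancer_risk = rep(0, 13))
  mx <- run_max_clinical_incidence_reduction(p, n = 5000, seed = 64)
  expect_equal(sum(mx$result$inc_stage), 0)
})

test_that("decennial colonoscopy reporting is internally consistent", {
  p <- fixture_params()
  d <- run_decennial_colonoscopy(p, n = 20000, seed = 65)
  expect_gt(d$incidence_reduction, 0.2)
  expect_gt(d$mortality_reduction, d$incidence_reduction * 0.5)
  expect_equal(d$total_colonoscopies_per_1000,
               d$comparison$total_colonoscopies_per_1000)
  expect_equal(d$colonoscopies_per_lyg,
               d$total_colonoscopies_per_1000 / d$lyg_per_1000)
  expect_gt(d$screening_colonoscopies_per_1000, 1000)
})
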