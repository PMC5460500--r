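test_that("sterile parameters give zero lesions and pure life-table mortality", {
  r <- simulate_population(sterile_params(), n = 20000, seed = 3)
  expect_equal(sum(r$inc_stage), 0)
  expect_equal(unname(r$conservation[["initiated"]]), 0)
  expect_equal(sum(r$crc_death), 0)
  expect_equal(sum(r$oth_death), r$n)
  # survivorship matches the closed-form life-table curve (chi-square)
  lt <- load_life_table()
  cdf <- death_cdf_quarterly(lt)
  ages <- seq(10, 95, by = 5)
  surv_exp <- 1 - cdf[ages * 4 + 1]       # P(alive at start of age a)
  alive_obs <- rowSums(r$alive_at)[ages + 1]
  expected <- r$n * surv_exp
  chi2 <- sum((alive_obs - expected)^2 / pmax(expected * (1 - surv_exp), 1))
  # generous bound: statistic is not exactly chi-square (shared individuals)
  expect_lt(chi2, 3 * length(ages))
})

test_that("same seed reproduces tallies bit-identically", {
  p <- fixture_params()
  r1 <- simulate_population(p, n = 4000, seed = 99)
  r2 <- simulate_population(p, n = 4000, seed = 99)
  expect_identical(r1$inc_stage, r2$inc_stage)
  expect_identical(r1$py, r2$py)
  expect_identical(r1$cost, r2$cost)
  expect_identical(r1$conservation, r2$conservation)
})

test_that("adenoma bookkeeping is conserved", {
  p <- fixture_params()
  for (seed in c(1, 2)) {
    r <- simulate_population(p, n = 5000, seed = seed,
                             plan = screening_plan("colonoscopy", 50, 75, 10))
    cons <- r$conservation
    expect_equal(cons[["initiated"]],
                 cons[["disappeared"]] + cons[["resected"]] +
                   cons[["transformed"]] + cons[["remaining"]])
  }
})

test_that("raising a0 raises adenoma prevalence at 60 (paired seeds)", {
  p_lo <- natural_history_params()
  p_hi <- natural_history_params(a0 = p_lo$a0 * 1.5)
  r_lo <- simulate_population(p_lo, n = 30000, seed = 5)
  r_hi <- simulate_population(p_hi, n = 30000, seed = 5)
  prev <- function(r) sum(r$early_at[61, ] + r$adv_at[61, ]) / sum(r$alive_at[61, ])
  expect_gt(prev(r_hi), prev(r_lo))
})

test_that("with fast and direct routes off, all cancers arise from stage-VI adenomas", {
  p <- natural_history_params(stage_cancer_risk = rep(0, 5),
                              direct_cancer_risk = rep(0, 13))
  r <- simulate_population(p, n = 20000, seed = 8)
  expect_gt(sum(r$origin_init), 0)
  expect_equal(unname(r$origin_init[["fast"]]), 0)
  expect_equal(unname(r$origin_init[["direct"]]), 0)
})

test_that("stage-I regression removes lesions", {
  p <- natural_history_params(stage_regression = c(0.2, rep(0, 5)),
                              b0 = 0, stage_cancer_risk = rep(0, 5),
                              direct_cancer_risk = rep(0, 13))
  r <- simulate_population(p, n = 5000, seed = 2)
  expect_gt(r$conservation[["disappeared"]], 0)
  expect_equal(unname(r$conservation[["transformed"]]), 0)
})

test_that("small-rate incidence matches the two-compartment analytic solution", {
  lam <- 0.004; h <- 0.01
  p <- flat_params(lambda2 = lam, h2 = h)
  n <- 40000
  # a blind instrument: the diagnostic colonoscopy a symptomatic cancer
  # triggers must not resect bystander adenomas, which the independent-
  # compartment closed form does not model
  m <- screening_model(detect_adenoma = rep(0, 6), detect_cancer = 0)
  pl <- no_screening_plan(); pl$surveillance_on <- FALSE
  r <- simulate_population(p, life_table = immortal_life_table(), n = n,
                           seed = 17, plan = pl, model = m)
  # expected cumulative diagnoses per person by end of quarter T (simulation
  # starts lesions at quarter 80; transformation possible in the initiation
  # quarter; diagnosis follows one quarter after transformation)
  exp_cum <- function(T2) {
    s <- 80:(T2 - 1)
    lam * sum(1 - (1 - h)^(T2 - s))
  }
  for (age in c(40, 60, 80)) {
    T2 <- age * 4
    obs <- sum(r$inc_stage[1:age, ]) / n
    expect_equal(obs, exp_cum(T2), tolerance = 0.06, label = paste("age", age))
  }
})

test_that("sojourn sampler is a truncated, quarter-rounded normal", {
  s <- sample_sojourn(1e5, natural_history_params(), seed = 123)
  expect_equal(mean(s), 3.0, tolerance = 0.01)
  # quarter rounding adds ~1/48 variance on top of 0.5^2
  expect_equal(stats::sd(s), 0.5, tolerance = 0.02)
  expect_true(all(s > 0))
  s2 <- sample_sojourn(1e6, natural_history_params(sojourn_mean_y = 0.5), seed = 5)
  expect_true(all(s2 > 0))
})

test_that("stage-4 survival zero kills within a quarter of diagnosis", {
  p <- natural_history_params(survival_5y = rep(0, 4))
  r <- simulate_population(p, life_table = immortal_life_table(),
                           n = 10000, seed = 4)
  expect_gt(r$total_diag, 0)
  # every diagnosis is lethal within one quarter; the only escapes are
  # diagnoses in the final horizon quarter
  expect_gte(sum(r$crc_death), 0.98 * r$total_diag)
  expect_gte(r$years_lost, 0)
})
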