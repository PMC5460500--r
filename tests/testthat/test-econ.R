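test_that("discounting follows the closed form", {
  cfg0 <- econ_config(discount_rate = 0)
  x <- stats::setNames(c(1, 2, 3), c(0, 1, 2))
  expect_equal(discount(x, cfg0), 6)
  # a single unit 10 years after the reference at 3%
  y <- stats::setNames(1, 10)
  expect_equal(discount(y, econ_config()), 1 / 1.03^10, tolerance = 1e-10)
  expect_equal(round(discount(y, econ_config()), 4), 0.7441)
  expect_error(econ_config(discount_rate = -0.01), "discount")
  # linearity / order independence over stream decomposition
  cfg <- econ_config()
  a <- stats::setNames(runif(5), 3:7); b <- stats::setNames(runif(5), 3:7)
  expect_equal(discount(a + b, cfg), discount(a, cfg) + discount(b, cfg))
})

test_that("treatment cost phases follow the three-phase rule", {
  ct <- cost_table()
  # survivor past 5 years: initial + 19 continuing quarters, no terminal
  s <- accrue_treatment_costs(2, 60, NA, FALSE, ct)
  expect_equal(nrow(s), 20)
  expect_equal(s$cost[1], ct$treat_initial[2])
  expect_true(all(s$cost[-1] == ct$treat_continuing[2] / 4))
  # death from CRC 6 months after diagnosis: initial retained, terminal
  # dominates the remaining quarters
  s2 <- accrue_treatment_costs(4, 60, 60.5, TRUE, ct)
  expect_equal(s2$cost[1], ct$treat_initial[4])
  expect_true(all(s2$cost[-1] == ct$treat_terminal[4] / 4))
  expect_lte(max(s2$quarter), 60.5)
  # zero cost table gives a zero stream
  zero <- cost_table()
  zero$treat_initial <- zero$treat_continuing <- zero$treat_terminal <- rep(0, 4)
  expect_equal(sum(accrue_treatment_costs(1, 55, 58, TRUE, zero)$cost), 0)
})

test_that("identical arms compare to zero effect and undefined ratio", {
  p <- fixture_params()
  a <- simulate_population(p, n = 5000, seed = 77)
  b <- simulate_population(p, n = 5000, seed = 77)
  cmp <- compare_arms(a, b)
  expect_equal(cmp$incidence_reduction, 0)
  expect_equal(cmp$mortality_reduction, 0)
  expect_equal(cmp$lyg_per_1000, 0)
  expect_true(is.na(cmp$cost_per_lyg))
  # pairing is enforced
  c2 <- simulate_population(p, n = 5000, seed = 78)
  expect_error(compare_arms(a, c2), "paired")
})

test_that("engine procedure costs decompose exactly into unit costs", {
  p <- fixture_params()
  ct <- default_costs()
  pl <- screening_plan("colonoscopy", 50, 75, 10)
  r <- simulate_population(p, n = 10000, seed = 41, plan = pl, costs = ct)
  proc_expected <- ct$colonoscopy * r$n_colono[["total"]] +
    ct$polypectomy * sum(r$polypectomies)
  expect_equal(sum(r$cost["procedures", ]), proc_expected)
  compl_expected <- sum(colSums(r$complications) * ct$complication_costs)
  expect_equal(sum(r$cost["complications", ]), compl_expected)
  # treatment costs present iff cancers were diagnosed
  expect_gt(r$total_diag, 0)
  expect_gt(sum(r$cost["treatment", ]), 0)
  r0 <- simulate_population(sterile_params(), n = 2000, seed = 41)
  expect_equal(sum(r0$cost["treatment", ]), 0)
})

test_that("discounted life-years gained never exceed undiscounted", {
  p <- fixture_params()
  pl <- screening_plan("colonoscopy", 55)
  scr <- simulate_population(p, n = 30000, seed = 51, plan = pl)
  bas <- simulate_population(p, n = 30000, seed = 51)
  cmp <- compare_arms(scr, bas)
  expect_gt(cmp$lyg_per_1000, 0)
  expect_lt(cmp$lyg_disc_per_1000, cmp$lyg_per_1000)
})
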