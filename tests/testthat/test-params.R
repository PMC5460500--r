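test_that("initiation rate follows the sigmoid closed form", {
  p <- natural_history_params(a0 = 0.02, a1 = 0.1, a2 = 5,
                              sex_factors = c(initiation = 1.3, early = 1, advanced = 1))
  # independently evaluated closed form at age 60: 0.02 * sigmoid(1.0)
  expect_equal(initiation_rate(p, 60), 0.02 / (1 + exp(-1)), tolerance = 1e-12)
  # midpoint age a2/a1 gives half the plateau
  expect_equal(initiation_rate(p, 50), 0.01, tolerance = 1e-12)
  # saturation toward a0
  expect_equal(initiation_rate(p, 100), 0.02, tolerance = 0.01)
  # sex and individual multipliers enter multiplicatively, clipped at 1
  expect_equal(initiation_rate(p, 60, "male", 2),
               2 * 1.3 * initiation_rate(p, 60), tolerance = 1e-12)
  expect_equal(initiation_rate(p, 60, multiplier = 1e6), 1)
  expect_error(initiation_rate(p, -1), "age")
})

test_that("progression rates are the stated Gaussians", {
  p <- natural_history_params(b0 = 0.05, b1 = 0.04, b2 = 2.4,
                              c0 = 0.03, c1 = 0.05, c2 = 3.0)
  # peak value b0 at age b2/b1, symmetric around it
  expect_equal(early_progression_rate(p, 60), 0.05)
  expect_equal(early_progression_rate(p, 60 + 7), early_progression_rate(p, 60 - 7))
  # closed form at age 50: b1*y - b2 = -0.4
  expect_equal(early_progression_rate(p, 50), 0.05 * exp(-0.16), tolerance = 1e-12)
  # advanced Gaussian peaks at c2/c1 = 60 with value c0
  expect_equal(advanced_progression_rate(p, 60), 0.03)
  expect_equal(advanced_progression_rate(p, 45), 0.03 * exp(-(0.05 * 45 - 3)^2),
               tolerance = 1e-12)
  expect_error(early_progression_rate(p, 101), "age")
})

test_that("rate functions are finite and non-negative over the age range", {
  set.seed(42)
  for (k in 1:20) {
    p <- natural_history_params(a0 = runif(1, 0, 0.05), a1 = runif(1, 0, 0.3),
                                a2 = runif(1, 0, 10), b0 = runif(1, 0, 0.2),
                                b1 = runif(1, 0, 0.1), b2 = runif(1, 0, 5))
    ages <- seq(0, 100, by = 0.5)
    vals <- c(initiation_rate(p, ages), early_progression_rate(p, ages),
              advanced_progression_rate(p, ages))
    expect_true(all(is.finite(vals)) && all(vals >= 0))
    expect_true(all(initiation_rate(p, ages) <= p$a0))
    expect_true(all(early_progression_rate(p, ages) <= p$b0))
  }
})

test_that("individual-risk CDF sampling matches the anchor curve", {
  p <- natural_history_params()
  a <- p$individual_risk_anchors
  expect_equal(sample_individual_risk(p, 0), min(a$m))
  expect_equal(sample_individual_risk(p, 1), max(a$m))
  expect_error(sample_individual_risk(p, 1.2), "u")
  # monotone in u
  u <- seq(0, 1, by = 0.01)
  expect_true(all(diff(sample_individual_risk(p, u)) >= 0))
  # empirical distribution of 1e5 draws matches the anchor CDF (KS < 0.01):
  # P(M <= pwl(q)) must equal q at interior quantiles
  set.seed(7)
  draws <- sample_individual_risk(p, stats::runif(1e5))
  qgrid <- seq(0.02, 0.98, by = 0.02)
  ks <- max(abs(sapply(qgrid, function(q)
    mean(draws <= sample_individual_risk(p, q)) - q)))
  expect_lt(ks, 0.01)
})

test_that("parameter files round-trip and reject bad arity", {
  p <- natural_history_params(a0 = 0.0123)
  f <- tempfile(fileext = ".json")
  save_params(p, f)
  q <- load_params(f)
  for (nm in setdiff(names(p), c("individual_risk_anchors",
                                 "adenoma_risk_anchors_early",
                                 "adenoma_risk_anchors_advanced")))
    expect_equal(q[[nm]], p[[nm]], tolerance = 1e-12, label = nm)
  expect_equal(q$individual_risk_anchors$m, p$individual_risk_anchors$m)
  # a file with 12 segment risks must be rejected
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$direct_cancer_risk <- obj$direct_cancer_risk[1:12]
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, auto_unbox = TRUE, digits = NA)
  expect_error(load_params(f2), "13")
  expect_error(load_params(tempfile()), ".")
})

test_that("shipped CMOST13 fixture loads with its dwell label", {
  p <- cmost_params(13)
  expect_s3_class(p, "cmost_params")
  expect_equal(p$dwell_variant, 13)
})
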