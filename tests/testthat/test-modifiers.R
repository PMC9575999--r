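test_that("zero modifiers reproduce the baseline hazard exactly", {
  m0 <- hazard_modifiers()
  for (age in c(0, 1, 5, 12))
    expect_identical(modified_hazard(toy_params, m0, age, "wet", 80, 2015),
                     siler_hazard(toy_params, age))
})

test_that("season effect is a hazard ratio", {
  m <- hazard_modifiers(beta_S = log(1.27))
  hw <- modified_hazard(toy_params, m, 5, "wet", 40, 2015)
  hd <- modified_hazard(toy_params, m, 5, "dry", 40, 2015)
  expect_equal(hw / hd, 1.27)
})

test_that("negative location slope raises hazard toward the southeast", {
  m <- hazard_modifiers(beta_L = -0.005)
  h_se <- modified_hazard(toy_params, m, 5, "dry", 30, 2015)
  h_nw <- modified_hazard(toy_params, m, 5, "dry", 130, 2015)
  expect_gt(h_se, h_nw)
  expect_equal(h_se / h_nw, exp(-0.005 * (30 - 130)))
})

test_that("year effects look up by calendar year, reference zero elsewhere", {
  m <- hazard_modifiers(beta_Y = c(`2014` = 0.3, `2015` = -0.3))
  h14 <- modified_hazard(toy_params, m, 5, "dry", 0, 2014)
  h16 <- modified_hazard(toy_params, m, 5, "dry", 0, 2016)
  expect_equal(h14 / h16, exp(0.3))
  expect_error(modified_hazard(toy_params, m, 5, "dry", 0, 2016,
                               strict = TRUE), "strict")
})

test_that("piecewise cumulative hazard is additive and split-invariant", {
  seg1 <- data.frame(age_start = 2, age_end = 4, season = "dry",
                     location_km = 50, year = 2015)
  m0 <- hazard_modifiers()
  expect_equal(cumulative_hazard_piecewise(toy_params, m0, seg1),
               siler_cumhaz(toy_params, 4) - siler_cumhaz(toy_params, 2))
  # splitting at an arbitrary point leaves the result unchanged
  split <- data.frame(age_start = c(2, 3.137), age_end = c(3.137, 4),
                      season = "dry", location_km = 50, year = 2015)
  expect_equal(cumulative_hazard_piecewise(toy_params, m0, split),
               cumulative_hazard_piecewise(toy_params, m0, seg1))
  # gap or overlap errors
  bad <- data.frame(age_start = c(2, 3.2), age_end = c(3, 4),
                    season = "dry", location_km = 50, year = 2015)
  expect_error(cumulative_hazard_piecewise(toy_params, m0, bad), "partition")
})

test_that("two-season path matches quadrature of the modified hazard", {
  m <- hazard_modifiers(beta_S = log(2))
  path <- data.frame(age_start = c(1, 2.4), age_end = c(2.4, 3.6),
                     season = c("wet", "dry"), location_km = 0, year = 2015)
  oracle <- integrate(function(a)
    siler_hazard(toy_params, a) * ifelse(a < 2.4, 2, 1), 1, 3.6,
    rel.tol = 1e-10, subdivisions = 500L)$value
  expect_equal(cumulative_hazard_piecewise(toy_params, m, path), oracle,
               tolerance = 1e-8)
})

test_that("cumulative hazard scales with the exponentiated modifier", {
  seg <- data.frame(age_start = 0.5, age_end = 2, season = "wet",
                    location_km = 10, year = 2014)
  base <- cumulative_hazard_piecewise(toy_params, hazard_modifiers(), seg)
  for (b in c(0.4, 1.1)) {
    m <- hazard_modifiers(beta_S = b)
    expect_equal(cumulative_hazard_piecewise(toy_params, m, seg),
                 exp(b) * base)
  }
  # monotone in beta_S on a wet segment
  vals <- sapply(c(-0.5, 0, 0.5, 1), function(b)
    cumulative_hazard_piecewise(toy_params, hazard_modifiers(beta_S = b), seg))
  expect_true(all(diff(vals) > 0))
})

test_that("dissociation survival is 1 before onset, quadratic after", {
  expect_equal(dissociation_probability(8, 0.5), 1)
  expect_equal(dissociation_probability(0, c(0.2, 1, 3)), c(1, 1, 1))
  expect_equal(dissociation_probability(8, 1.0), exp(-0.25))
  # quadrature oracle for the hazard integral
  oracle <- exp(-integrate(function(u) pmax(0, 8 * (u - 0.75)), 0, 1,
                           rel.tol = 1e-10)$value)
  expect_equal(dissociation_probability(8, 1.0), oracle, tolerance = 1e-8)
  expect_error(dissociation_probability(-1, 1), "gamma_D")
})

test_that("first-year survival reduces to baseline when modifiers vanish", {
  expect_equal(first_year_survival(anchor_params), 0.56, tolerance = 1e-6)
  # wet-season modifier lowers first-year survival along the canonical path
  s_mod <- first_year_survival(anchor_params,
                               hazard_modifiers(beta_S = log(1.27)))
  expect_lt(s_mod, 0.56)
  expect_gt(s_mod, 0.45)
})
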