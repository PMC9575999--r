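test_that("censored cow under constant hazard gives exponential loglik", {
  df <- cow_table("2014-01-01", 4, c("2014-01-01", "2016-01-01"),
                  censored_on = "2016-01-01")
  cc <- make_cc_data(df)
  T_exp <- years_between("2014-01-01", "2016-01-01")
  expect_equal(cc_loglik(cc, constant_hazard(0.1)), -0.1 * T_exp)
  # doubling hazard lowers loglik by exactly the cumulative-hazard difference
  expect_equal(cc_loglik(cc, constant_hazard(0.2)),
               cc_loglik(cc, constant_hazard(0.1)) - 0.1 * T_exp)
})

test_that("death interval adds log(1 - exp(-H)) and is left-truncated", {
  df <- cow_table("2014-01-01", 5, c("2014-01-01", "2015-01-01"),
                  death_found = "2015-01-15")
  cc <- make_cc_data(df)
  h <- 0.5
  T1 <- years_between("2014-01-01", "2015-01-01")
  T2 <- years_between("2015-01-01", "2015-01-15")
  expect_equal(cc_loglik(cc, constant_hazard(h)),
               -h * T1 + log(1 - exp(-h * T2)))
  # left truncation: the same history entered at an older age has an
  # identical constant-hazard likelihood (exposure depends on duration only)
  df2 <- cow_table("2014-01-01", 9, c("2014-01-01", "2015-01-01"),
                   death_found = "2015-01-15")
  expect_equal(cc_loglik(make_cc_data(df2), constant_hazard(h)),
               cc_loglik(cc, constant_hazard(h)))
  # but differs under age-dependent hazard
  expect_false(isTRUE(all.equal(cc_loglik(make_cc_data(df2), toy_params),
                                cc_loglik(cc, toy_params))))
})

test_that("death probability matches Monte-Carlo exponential lifetimes", {
  h <- 0.5
  T1 <- 1; T2 <- 0.04
  df <- cow_table("2014-01-01", 5,
                  c("2014-01-01", as.character(as.Date("2014-01-01") + round(T1 * 365.25))),
                  death_found = as.Date("2014-01-01") + round((T1 + T2) * 365.25))
  cc <- make_cc_data(df)
  t1 <- years_between("2014-01-01", as.Date("2014-01-01") + round(T1 * 365.25))
  t2 <- years_between(as.Date("2014-01-01") + round(T1 * 365.25),
                      as.Date("2014-01-01") + round((T1 + T2) * 365.25))
  set.seed(99)
  n <- 1e6
  life <- rexp(n, h)
  p_mc <- mean(life > t1 & life <= t1 + t2)
  p_model <- exp(cc_loglik(cc, constant_hazard(h)))
  se <- sqrt(p_mc * (1 - p_mc) / n)
  expect_lt(abs(p_model - p_mc), 4 * se)
})

test_that("sub-day death intervals use the hazard density", {
  df <- cow_table("2014-01-01", 5, c("2014-01-01", "2015-01-01"),
                  death_found = "2015-01-01")
  cc <- make_cc_data(df)
  expect_equal(nrow(cc$exact), 1L)
  h <- 0.3
  expect_equal(cc_loglik(cc, constant_hazard(h)),
               -h * years_between("2014-01-01", "2015-01-01") + log(h))
})

test_that("poaching-suspect cows are removed entirely", {
  df1 <- cow_table("2014-01-01", 4, c("2014-01-01", "2015-01-01"),
                   censored_on = "2015-01-01", id = "C001")
  df2 <- cow_table("2014-01-01", 6, c("2014-01-01", "2014-06-01"),
                   death_found = "2014-06-20", status_death = "poaching_suspect",
                   id = "C002")
  cc <- make_cc_data(rbind(df1, df2))
  expect_equal(cc$n_cows, 1L)
  expect_equal(cc$n_poaching_excluded, 1L)
  expect_equal(cc_loglik(cc, constant_hazard(0.1)),
               cc_loglik(make_cc_data(df1), constant_hazard(0.1)))
})

test_that("record order does not change the likelihood", {
  df <- rbind(
    cow_table("2014-01-01", 4, c("2014-01-01", "2014-08-01", "2015-03-01"),
              death_found = "2015-03-20", id = "A"),
    cow_table("2014-05-01", 7, c("2014-05-01", "2015-05-01"),
              censored_on = "2015-05-01", id = "B"))
  shuffled <- df[sample(nrow(df)), ]
  expect_equal(cc_loglik(make_cc_data(shuffled), toy_params,
                         hazard_modifiers(beta_S = 0.2)),
               cc_loglik(make_cc_data(df), toy_params,
                         hazard_modifiers(beta_S = 0.2)))
})

test_that("malformed histories are rejected", {
  df <- cow_table("2014-01-01", 0, c("2014-01-01"), censored_on = "2015-01-01")
  expect_error(make_cc_data(df), "entry_age")
  df2 <- cow_table("2014-01-01", 4, c("2014-01-01", "2015-06-01"),
                   death_found = "2015-01-01")
  expect_error(make_cc_data(df2), "before last alive")
})
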