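test_that("zero hazard produces no deaths; fixed seed reproduces output", {
  sc <- fast_scenario(params = siler_params(0, 1, 0, 0, 1), poach_rate = 0)
  cows <- simulate_cows(sc, seed = 5)
  expect_true(all(is.na(cows$truth$death_date)))
  expect_true(all(cows$records$status %in% c("alive", "censored")))
  again <- simulate_cows(sc, seed = 5)
  expect_identical(cows$records, again$records)
  other <- simulate_cows(sc, seed = 6)
  expect_false(identical(cows$records, other$records))
})

test_that("death counts match the constant-hazard binomial expectation", {
  h <- 0.15
  sc <- sim_scenario(params = constant_hazard(h),
                     mods = hazard_modifiers(gamma_D = 0),
                     n_years = 5, n_initial = 120, topup = 0, poach_rate = 0,
                     collar_life_years = 99)
  cows <- simulate_cows(sc, seed = 13)
  tr <- cows$truth
  expos <- years_between(tr$entry_date, tr$censor_date)
  p_die <- 1 - exp(-h * expos)
  expected <- sum(p_die)
  sd_ <- sqrt(sum(p_die * (1 - p_die)))
  observed <- sum(!is.na(tr$death_date))
  expect_lt(abs(observed - expected), 3.5 * sd_)   # ~99.9% bound
})

test_that("all streams are mutually consistent with the truth record", {
  sc <- fast_scenario()
  obs <- simulate_observation_set(sc, seed = 17)
  tr <- obs$truth$cows
  recs <- obs$cows
  for (i in seq_len(nrow(tr))) {
    if (is.na(tr$death_date[i])) next
    sights <- recs$event_date[recs$cow_id == tr$cow_id[i] &
                                recs$status == "alive"]
    expect_true(all(sights <= tr$death_date[i]))
  }
  # calf observations only while the mother is under observation
  co <- obs$calf
  for (i in seq_len(nrow(tr))) {
    if (is.na(tr$death_date[i])) next
    cdates <- co$date[co$cow_id == tr$cow_id[i]]
    expect_true(all(cdates <= tr$death_date[i]))
  }
})

test_that("zero fecundity gives calf-free herd counts", {
  sc <- fast_scenario(f = 1e-12)
  hd <- simulate_herd_counts(sc, seed = 3)
  expect_true(all(hd$n_calves == 0))
  expect_true(all(hd$n_cows > 0))
})

test_that("herd-count fractions track the model expectation at scale", {
  sc <- sim_scenario(counts_per_year = 250, n_years = 6)
  hd <- simulate_herd_counts(sc, seed = 23)
  hd <- hd[!in_calving_window(hd$date), ]
  # pool counts from month 8 (June-ish), compare to the model's fraction
  m <- format(hd$date, "%m") == "06"
  frac_obs <- sum(hd$n_calves[m]) / sum(hd$n_calves[m] + hd$n_cows[m])
  frac_exp <- mean(sapply(which(m)[1:50], function(i)
    hc_expected_calf_fraction(0.68, sc$params, sc$mods, hd$date[i])))
  expect_lt(abs(frac_obs - frac_exp), 0.03)
})

test_that("perfect detection of immortal calves recovers fecundity", {
  sc <- fast_scenario(params = siler_params(0, 1, 0, 0, 1),
                      mods = hazard_modifiers(gamma_D = 0),
                      p = 1 - 1e-12, q = 1e-12, poach_rate = 0)
  cows <- simulate_cows(sc, seed = 29)
  ch <- simulate_calf_histories(sc, cows, seed = 29)
  agg <- aggregate(detected ~ cow_id + calf_year, ch$records, mean)
  # detection sequences are constant per cow-year
  expect_true(all(agg$detected %in% c(0, 1)))
  fhat <- mean(agg$detected)
  n <- nrow(agg)
  expect_lt(abs(fhat - 0.68), 3.5 * sqrt(0.68 * 0.32 / n))
})

test_that("generating parameters beat perturbed ones in their own likelihoods", {
  sc <- sim_scenario(n_years = 6)
  obs <- simulate_observation_set(sc, seed = 37)
  os <- suppressWarnings(load_and_validate(obs$cows, obs$herd, obs$calf))
  ll_cc <- cc_loglik(os$cc, sc$params, sc$mods)
  ll_hc <- hc_loglik(os$hc, 0.68, sc$params, sc$mods)
  ll_cd <- cd_loglik(os$cd, 0.68, sc$p, sc$q, sc$params, sc$mods)
  for (fac in c(0.8, 1.2)) {
    pert <- siler_params(sc$params[["a1"]] * fac, sc$params[["b1"]],
                         sc$params[["a2"]] * fac, sc$params[["a3"]] * fac,
                         sc$params[["b3"]])
    expect_gt(ll_cc, cc_loglik(os$cc, pert, sc$mods))
    expect_gt(ll_hc, hc_loglik(os$hc, 0.68 * fac, pert, sc$mods))
    expect_gt(ll_cd, cd_loglik(os$cd, 0.68 * fac, min(sc$p * fac, 0.99),
                               sc$q, pert, sc$mods))
  }
})
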