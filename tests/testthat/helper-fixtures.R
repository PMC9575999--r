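# shared in-code fixtures for the test suite

# the default baseline curve through the study's survival anchors
anchor_params <- siler_from_anchors()

# a generic well-behaved parameter set used where the anchors are irrelevant
toy_params <- siler_params(a1 = 1, b1 = 2, a2 = 0.05, a3 = 0.002, b3 = 0.4)

constant_hazard <- function(h) siler_params(0, 1, h, 0, 1)

# quadrature of the baseline hazard (independent oracle for cumulative hazard)
quad_cumhaz <- function(params, from, to) {
  integrate(function(a) siler_hazard(params, a), from, to,
            rel.tol = 1e-10, subdivisions = 1000L)$value
}

# one-cow event table: entry, sightings at given dates, optional death
cow_table <- function(entry_date, entry_age, sight_dates, location = 50,
                      death_found = NULL, censored_on = NULL,
                      status_death = "found_dead", id = "C001") {
  rows <- data.frame(cow_id = id, entry_date = as.Date(entry_date),
                     entry_age_yr = entry_age,
                     event_date = as.Date(sight_dates),
                     location_km = location, status = "alive")
  if (!is.null(death_found))
    rows <- rbind(rows, data.frame(cow_id = id, entry_date = as.Date(entry_date),
                                   entry_age_yr = entry_age,
                                   event_date = as.Date(death_found),
                                   location_km = location,
                                   status = status_death))
  if (!is.null(censored_on))
    rows <- rbind(rows, data.frame(cow_id = id, entry_date = as.Date(entry_date),
                                   entry_age_yr = entry_age,
                                   event_date = as.Date(censored_on),
                                   location_km = NA_real_, status = "censored"))
  rows
}

# calf observation table for a single cow-year
calf_table <- function(dates, detected, calf_year = 2014L, id = "C001") {
  data.frame(cow_id = id, calf_year = calf_year, date = as.Date(dates),
             detected = as.integer(detected))
}

# brute-force enumeration of the calf-detection forward probability over all
# hidden-state paths (states: 1 no-calf, 2 present, 3 dead, 4 dissociated)
enumerate_cd_prob <- function(dates, det, f, p, q, params, mods,
                              location_fun = migratory_location,
                              calf_year = 2014L) {
  dates <- as.Date(dates)
  J <- length(dates)
  pulse <- birth_pulse_date(calf_year)
  t_obs <- years_between(pulse, dates)
  s <- a <- numeric(J)
  t_prev <- 0
  prev_date <- pulse
  for (j in seq_len(J)) {
    s[j] <- if (dates[j] > prev_date) {
      seg <- covariate_segments(prev_date, dates[j],
                                years_between(pulse, prev_date), location_fun)
      exp(-cumulative_hazard_piecewise(params, mods, seg))
    } else 1
    a[j] <- dissociation_probability(mods$gamma_D, t_obs[j]) /
      dissociation_probability(mods$gamma_D, t_prev)
    t_prev <- t_obs[j]
    prev_date <- dates[j]
  }
  TR <- lapply(seq_len(J), function(j) {
    m <- matrix(0, 4, 4)
    m[1, 1] <- 1
    m[2, 2] <- s[j] * a[j]; m[3, 2] <- 1 - s[j]; m[4, 2] <- s[j] * (1 - a[j])
    m[3, 3] <- 1; m[4, 4] <- 1
    m
  })
  emit <- function(state, d) {
    if (state == 2) (if (d) p else 1 - p) else (if (d) q else 1 - q)
  }
  # enumerate every path (initial state, state at each observation)
  paths <- as.matrix(expand.grid(rep(list(1:4), J + 1L)))
  init <- c(1 - f, f, 0, 0)
  total <- 0
  for (r in seq_len(nrow(paths))) {
    st <- paths[r, ]
    w <- init[st[1]]
    for (j in seq_len(J)) {
      if (w == 0) break
      w <- w * TR[[j]][st[j + 1L], st[j]] * emit(st[j + 1L], det[j])
    }
    total <- total + w
  }
  total
}

# small synthetic scenario for fast end-to-end tests
fast_scenario <- function(...) {
  sim_scenario(n_years = 3L, n_initial = 30L, topup = 8L,
               counts_per_year = 40L, ...)
}
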