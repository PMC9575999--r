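#' Simulation scenario
#'
#' Bundles the true parameters and observation-process settings used to
#' generate synthetic observation sets with the study's structure: a
#' collared cohort of adult cows maintained by annual top-ups, biweekly
#' ground sighting attempts, Siler-shaped mortality modified by season,
#' location and year along a deterministic migratory path, a 1 October birth
#' pulse, herd-composition counts, calf detection with error probabilities
#' `p` and `q`, calf dissociation beyond age 0.75 yr, and occasional
#' poaching-suspect removals.
#'
#' Default parameter values are the study's expected values: fecundity
#' 0.68, detection probabilities p = 0.89 and q = 0.02, wet-season hazard
#' ratio exp(beta_S) = 1.27, and a baseline Siler curve through annual
#' survival 0.91 at age 2, 0.57 at age 10, 0.02 at age 16 with first-year
#' survivorship 0.56 ([siler_from_anchors()]).
#'
#' @param params true [siler_params()]; default [siler_from_anchors()].
#' @param mods true [hazard_modifiers()]; default wet-season ratio 1.27,
#'   no location/year effects, dissociation slope 30 (most calves
#'   dissociated well before the next birth pulse).
#' @param f true fecundity (scalar, or named per-year vector).
#' @param p,q true calf detection probabilities.
#' @param start_year first study year; collaring starts 15 May.
#' @param n_years study span in years.
#' @param n_initial initial collared cohort size.
#' @param topup animals added each 1 November.
#' @param entry_age_range uniform range of tooth-estimated entry ages (yr).
#' @param sighting_interval_days baseline cadence of sighting attempts.
#' @param intensive_interval_days cadence during the intensified field
#'   periods August--November (recruitment and fecundity around the pulse)
#'   and April--May (wet-season calf survival).
#' @param sighting_success per-attempt probability of locating a cow.
#' @param collar_life_years censoring horizon per collar.
#' @param poach_rate probability a death is flagged poaching-suspect.
#' @param counts_per_year herd counts scheduled per year (uniform dates;
#'   counts falling in the 1 Sep--31 Oct window are generated and later
#'   excluded by the reader, exercising the filter).
#' @param classified_mean mean classified calves-plus-cows per herd count.
#' @param location_noise_km s.d. of individual scatter around the canonical
#'   migratory path at sightings.
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(params = siler_from_anchors(),
                         mods = hazard_modifiers(beta_S = log(1.27),
                                                 gamma_D = 30),
                         f = 0.68, p = 0.89, q = 0.02,
                         start_year = 2012L, n_years = 8L,
                         n_initial = 45L, topup = 10L,
                         entry_age_range = c(2, 10),
                         sighting_interval_days = 14L,
                         intensive_interval_days = 7L,
                         sighting_success = 0.9,
                         collar_life_years = 5,
                         poach_rate = 0.05,
                         counts_per_year = 60L,
                         classified_mean = 57,
                         location_noise_km = 5) {
  structure(as.list(environment()), class = "sim_scenario")
}

#' Study-year range of a scenario
#'
#' Complete calendar years of the study (the partial first and last years
#' are excluded from year-effect vectors).
#'
#' @param scenario a [sim_scenario()].
#' @return integer vector of complete years.
#' @export
study_years <- function(scenario) {
  seq(scenario$start_year + 1L, scenario$start_year + scenario$n_years - 1L)
}

scenario_f_for_year <- function(scenario, year) {
  f <- scenario$f
  if (length(f) == 1L && is.null(names(f))) return(rep(unname(f), length(year)))
  idx <- match(as.character(year), names(f))
  out <- unname(f[idx])
  out[is.na(idx)] <- mean(f)
  out
}

# sighting attempt schedule: baseline biweekly, with the intensified
# periods (Aug-Nov and Apr-May) visited at the intensive cadence
sighting_attempts <- function(from, to, sc) {
  base <- seq(from, to, by = sc$sighting_interval_days)
  months <- as.integer(format(base, "%m"))
  intensive <- months %in% c(4L, 5L, 8L, 9L, 10L, 11L)
  extra <- base[intensive] + sc$intensive_interval_days
  sort(unique(c(base, extra[extra <= to])))
}

# simulate death times by thinning on a weekly grid of the modified
# hazard along the canonical path; NA when the animal survives past `end`
sim_death_times <- function(n, start_dates, start_ages,
                            end_dates, params, mods, location_fun) {
  out <- rep(as.Date(NA), n)
  for (i in seq_len(n)) {
    if (end_dates[i] <= start_dates[i]) next
    grid <- seq(start_dates[i], end_dates[i], by = 7L)
    if (grid[length(grid)] < end_dates[i]) grid <- c(grid, end_dates[i])
    mid <- grid[-length(grid)] + as.numeric(diff(grid)) / 2
    dt <- as.numeric(diff(grid)) / DAYS_PER_YEAR
    age <- start_ages[i] + years_between(start_dates[i], mid)
    h <- modified_hazard(params, mods, age, season_of(mid),
                         location_fun(mid), as.integer(format(mid, "%Y")))
    cum <- cumsum(h * dt)
    e <- rexp(1)
    k <- which(cum >= e)[1]
    if (!is.na(k)) {
      # uniform placement within the fatal week
      frac <- (e - c(0, cum)[k]) / (cum[k] - c(0, cum)[k])
      out[i] <- grid[k] + round(frac * as.numeric(grid[k + 1L] - grid[k]))
    }
  }
  out
}

#' Simulate collared-cow histories
#'
#' Draws entry cohorts per the deployment schedule, simulates death times by
#' thinning from the covariate-modified hazard along the canonical migratory
#' path, generates biweekly sighting attempts with imperfect success, and
#' reports deaths as last-alive / found-dead intervals (the carcass is found
#' at the next attempted visit). A fraction of deaths is flagged
#' poaching-suspect; those animals are excluded by the reader.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @return list with `records` (long event table as read by
#'   [make_cc_data()]) and `truth` (per-cow true entry/death/censor data).
#' @export
simulate_cows <- function(scenario, seed = 1L) {
  set.seed(seed)
  sc <- scenario
  study_start <- as.Date(sprintf("%d-05-15", sc$start_year))
  study_end <- as.Date(sprintf("%d-05-15", sc$start_year + sc$n_years))
  dep_dates <- c(study_start,
                 as.Date(sprintf("%d-11-01",
                                 seq(sc$start_year, sc$start_year + sc$n_years - 2L))))
  dep_n <- c(sc$n_initial, rep(sc$topup, length(dep_dates) - 1L))
  entry_date <- rep(dep_dates, dep_n)
  n <- length(entry_date)
  entry_age <- runif(n, sc$entry_age_range[1], sc$entry_age_range[2])
  censor_date <- pmin(entry_date + round(sc$collar_life_years * DAYS_PER_YEAR),
                      study_end)
  death_date <- sim_death_times(n, entry_date, entry_age, censor_date,
                                sc$params, sc$mods, migratory_location)
  records <- list(); truth <- list()
  for (i in seq_len(n)) {
    id <- sprintf("C%03d", i)
    end_obs <- min(censor_date[i], death_date[i], na.rm = TRUE)
    attempts <- sighting_attempts(entry_date[i], study_end, sc)
    seen <- attempts[attempts <= end_obs &
                       runif(length(attempts)) < sc$sighting_success]
    seen <- unique(c(entry_date[i], seen))
    loc <- migratory_location(seen) + rnorm(length(seen), 0, sc$location_noise_km)
    rec <- data.frame(cow_id = id, entry_date = entry_date[i],
                      entry_age_yr = entry_age[i], event_date = seen,
                      location_km = loc, status = "alive")
    died <- !is.na(death_date[i]) && death_date[i] <= censor_date[i]
    if (died) {
      found <- attempts[attempts > death_date[i]][1]
      if (is.na(found)) found <- death_date[i] + 1L
      status <- if (runif(1) < sc$poach_rate) "poaching_suspect" else "found_dead"
      rec <- rbind(rec, data.frame(cow_id = id, entry_date = entry_date[i],
                                   entry_age_yr = entry_age[i],
                                   event_date = found,
                                   location_km = migratory_location(found),
                                   status = status))
    } else {
      rec <- rbind(rec, data.frame(cow_id = id, entry_date = entry_date[i],
                                   entry_age_yr = entry_age[i],
                                   event_date = min(censor_date[i], study_end),
                                   location_km = NA_real_,
                                   status = "censored"))
    }
    records[[i]] <- rec
    truth[[i]] <- data.frame(cow_id = id, entry_date = entry_date[i],
                             entry_age_yr = entry_age[i],
                             death_date = if (died) death_date[i] else as.Date(NA),
                             censor_date = censor_date[i],
                             poaching = died && rec$status[nrow(rec)] == "poaching_suspect")
  }
  list(records = do.call(rbind, records), truth = do.call(rbind, truth))
}

#' Simulate herd-composition counts
#'
#' Schedules counts uniformly through each study year; for each count the
#' classified calves-plus-cows total is Poisson around the scenario mean and
#' the calf count is binomial with the model's expected calf fraction at the
#' true parameters, the count date, and the canonical herd location.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @return data.frame with columns `date`, `location_km`, `n_calves`,
#'   `n_cows` (includes counts inside the calving exclusion window, which
#'   the reader removes).
#' @export
simulate_herd_counts <- function(scenario, seed = 1L) {
  set.seed(seed + 1L)
  sc <- scenario
  yrs <- study_years(sc)
  dates <- as.Date(unlist(lapply(yrs, function(y) {
    d0 <- as.Date(sprintf("%d-01-01", y))
    sort(d0 + sample.int(365L, sc$counts_per_year, replace = TRUE) - 1L)
  })), origin = "1970-01-01")
  n <- length(dates)
  total <- pmax(5L, rpois(n, sc$classified_mean))
  frac <- vapply(seq_len(n), function(i) {
    t <- years_between(birth_pulse_date(calf_year_of(dates[i])), dates[i])
    if (t <= 0) return(NA_real_)
    hc_expected_calf_fraction(scenario_f_for_year(sc, calf_year_of(dates[i])),
                              sc$params, sc$mods, dates[i])
  }, numeric(1))
  keep <- !is.na(frac)
  dates <- dates[keep]; total <- total[keep]; frac <- frac[keep]
  n_calves <- rbinom(length(dates), total, frac)
  data.frame(date = dates, location_km = migratory_location(dates),
             n_calves = n_calves, n_cows = total - n_calves)
}

#' Simulate calf-detection histories
#'
#' For each collared cow under observation at a 1 October birth pulse, a
#' calf is produced with the year's fecundity; calf death times follow the
#' modified calf hazard from birth, dissociation times follow the
#' quadratic-survival dissociation process, and the calf is lost if its
#' mother dies. At each of the cow's sightings within the calf-year the
#' calf is detected with probability `p` while present and associated, and
#' falsely detected with probability `q` otherwise.
#'
#' @param scenario a [sim_scenario()].
#' @param cows result of [simulate_cows()].
#' @param seed integer seed.
#' @return list with `records` (table read by [make_cd_data()]) and
#'   `truth` (per cow-year true calf fate).
#' @export
simulate_calf_histories <- function(scenario, cows, seed = 1L) {
  set.seed(seed + 2L)
  sc <- scenario
  sight <- cows$records[cows$records$status == "alive", ]
  out <- list(); truth <- list()
  for (y in study_years(sc)) {
    pulse <- birth_pulse_date(y)
    nxt <- birth_pulse_date(y + 1L)
    for (i in seq_len(nrow(cows$truth))) {
      tr <- cows$truth[i, ]
      if (tr$poaching) next
      alive_end <- min(tr$death_date, tr$censor_date, na.rm = TRUE)
      if (tr$entry_date > pulse || alive_end <= pulse) next
      obs_dates <- sight$event_date[sight$cow_id == tr$cow_id &
                                      sight$event_date > pulse &
                                      sight$event_date < nxt]
      if (!length(obs_dates)) next
      has_calf <- runif(1) < scenario_f_for_year(sc, y)
      calf_end <- as.Date(NA); dis_date <- as.Date(NA)
      if (has_calf) {
        calf_death <- sim_death_times(1L, pulse, 0, nxt, sc$params,
                                      sc$mods, migratory_location)
        g <- sc$mods$gamma_D
        dis_t <- if (g > 0) 0.75 + sqrt(2 * rexp(1) / g) else Inf
        dis_date <- if (is.finite(dis_t) && dis_t < 1)
          pulse + round(dis_t * DAYS_PER_YEAR) else as.Date(NA)
        ends <- c(calf_death, tr$death_date)
        ends <- ends[!is.na(ends)]
        calf_end <- if (length(ends)) min(ends) else as.Date(NA)
      }
      present <- function(d) {
        has_calf & (is.na(calf_end) | d < calf_end) &
          (is.na(dis_date) | d < dis_date)
      }
      pres <- vapply(obs_dates, present, logical(1))
      det <- ifelse(pres, runif(length(pres)) < sc$p,
                    runif(length(pres)) < sc$q)
      out[[length(out) + 1L]] <- data.frame(
        cow_id = tr$cow_id, calf_year = y, date = obs_dates,
        detected = as.integer(det),
        location_km = migratory_location(obs_dates))
      truth[[length(truth) + 1L]] <- data.frame(
        cow_id = tr$cow_id, calf_year = y, has_calf = has_calf,
        calf_death = if (has_calf) calf_end else as.Date(NA),
        dissociated = dis_date)
    }
  }
  list(records = do.call(rbind, out), truth = do.call(rbind, truth))
}

#' Simulate a full observation set
#'
#' Runs the three stream generators from one scenario and seed and returns
#' both the observation tables and the ground truth.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed (all three streams derive their seeds from it).
#' @return list with `cows`, `herd`, `calf` observation tables, plus
#'   `truth` (list of per-stream truth tables) and the scenario.
#' @export
simulate_observation_set <- function(scenario = sim_scenario(), seed = 1L) {
  cows <- simulate_cows(scenario, seed)
  herd <- simulate_herd_counts(scenario, seed)
  calf <- simulate_calf_histories(scenario, cows, seed)
  list(cows = cows$records, herd = herd, calf = calf$records,
       truth = list(cows = cows$truth, calf = calf$truth),
       scenario = scenario, seed = seed)
}
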