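#' Leslie projection configuration
#'
#' Biannual female-only projection over 51 half-year age classes covering
#' ages 1.0 to 26.0 yr (the top class absorbing, well above plausible
#' maximum age), a 50-year normalized warm-up to the stable age
#' distribution, a 5-year free projection for the growth rate, a calf sex
#' ratio of 0.5, and fecundity equal for all cows aged 2.0 yr and older and
#' zero for yearlings.
#'
#' @param n_classes number of half-year age classes.
#' @param age_min age at entry to the first class (yr).
#' @param warmup_years,horizon_years warm-up and free-projection lengths.
#' @param sex_ratio calf sex ratio (female fraction).
#' @param adult_age_min minimum age (yr) at which fecundity applies.
#' @param n_runs posterior projection runs.
#' @return a `leslie_config` list.
#' @export
leslie_config <- function(n_classes = 51L, age_min = 1, warmup_years = 50L,
                          horizon_years = 5L, sex_ratio = 0.5,
                          adult_age_min = 2, n_runs = 5000L) {
  structure(list(n_classes = n_classes, age_min = age_min,
                 warmup_years = warmup_years, horizon_years = horizon_years,
                 sex_ratio = sex_ratio, adult_age_min = adult_age_min,
                 n_runs = n_runs),
            class = "leslie_config")
}

#' Build the biannual transition operators
#'
#' Builds one transition matrix per half-year step (the Jun--Nov step uses
#' the dry-season hazard modifier, the Dec--May step the wet one). The
#' state vector is the 51 half-year age classes preceded by two internal
#' calf pipeline classes (ages 0--0.5 and 0.5--1.0) that carry each birth
#' cohort into the 1.0-yr class one year after the pulse with total
#' first-year survival `S1`. Class-to-class survival is the Siler
#' survivorship ratio over the class's half-year age span under the step's
#' seasonal modifier; the oldest class is absorbing with its own survival.
#' Recruitment `sex_ratio * f` is applied to all classes aged
#' `adult_age_min` and above at the birth-pulse (dry) step.
#'
#' @param params a [siler_params()] object (adult survival curve).
#' @param f fecundity.
#' @param S1 first-year calf survival; if `NULL`, taken from the
#'   survivorship of `params` at age 1.
#' @param mods a [hazard_modifiers()] object (only `beta_S` matters here).
#' @param location_km,year covariates at which the hazard is evaluated
#'   (defaults: reference location 0 and no year effect).
#' @param config a [leslie_config()].
#' @return list with matrices `dry` and `wet`, the annualized operator
#'   `annual` (dry step then wet step), and bookkeeping attributes.
#' @export
build_transition <- function(params, f, S1 = NULL, mods = hazard_modifiers(),
                             location_km = 0, year = NA,
                             config = leslie_config()) {
  k <- config$n_classes
  ages <- config$age_min + 0.5 * (seq_len(k) - 1L)
  if (is.null(S1)) S1 <- siler_survivorship(params, 1)
  stopifnot(f >= 0, f <= 1, S1 > 0, S1 <= 1)
  phi_for <- function(season) {
    m <- exp(log_modifier(mods, season, location_km, year))
    phi <- exp(-m * (siler_cumhaz(params, ages + 0.5) -
                       siler_cumhaz(params, ages)))
    if (any(phi < 0 | phi > 1)) stop("implied class survival outside [0,1]")
    phi
  }
  # split first-year survival across the two pipeline steps by the baseline
  # cumulative-hazard weight of each half-year
  H1 <- siler_cumhaz(params, 1)
  w <- if (H1 > 0) siler_cumhaz(params, 0.5) / H1 else 0.5
  s_a <- S1^w
  s_b <- S1^(1 - w)
  n <- k + 2L  # states: c1, c2, classes 1..k
  adult <- 2L + seq_len(k)
  build <- function(season, pulse) {
    phi <- phi_for(season)
    M <- matrix(0, n, n)
    for (i in seq_len(k - 1L)) M[adult[i + 1L], adult[i]] <- phi[i]
    M[adult[k], adult[k]] <- phi[k]
    if (pulse) {
      M[1L, adult[ages >= config$adult_age_min]] <- config$sex_ratio * f
      M[adult[1L], 2L] <- s_b       # c2 -> 1.0-yr class
    } else {
      M[2L, 1L] <- s_a              # c1 -> c2
    }
    M
  }
  Mdry <- build("dry", pulse = TRUE)
  Mwet <- build("wet", pulse = FALSE)
  list(dry = Mdry, wet = Mwet, annual = Mwet %*% Mdry,
       ages = ages, adult_idx = adult, config = config)
}

#' Project the population and derive lambda, stable structure, turnover
#'
#' Runs the biannual projection: a normalized warm-up (total relative
#' abundance reset to 1 after each step) until the age distribution is
#' stable, then a free projection over the horizon. The annual growth rate
#' is `lambda = (N_end / N_start)^(1/horizon)` on the 51-class abundance
#' total; turnover is the net annual mortality fraction (deaths from the
#' 51 classes during a year over start-of-year abundance), averaged over
#' the horizon.
#'
#' @param transition result of [build_transition()].
#' @param init optional initial 51-class abundance vector (default
#'   uniform).
#' @param tol warm-up convergence tolerance on the per-class change in age
#'   distribution between the final two same-season iterations (the damping
#'   ratio of this operator leaves changes around 1e-7 after 50 years).
#' @return list with `lambda`, `stable_age` (51-class proportions at end of
#'   warm-up), `trajectory` (relative 51-class abundance per year of the
#'   free projection), `turnover`, `converged`.
#' @export
project <- function(transition, init = NULL, tol = 1e-6) {
  cf <- transition$config
  k <- cf$n_classes
  adult <- transition$adult_idx
  x <- numeric(k + 2L)
  x[adult] <- if (is.null(init)) rep(1 / k, k) else init / sum(init)
  steps <- list(transition$dry, transition$wet)
  prev_dist <- NULL
  for (yr in seq_len(cf$warmup_years)) {
    for (M in steps) { x <- M %*% x; x <- x / sum(x) }
    dist <- x[adult] / sum(x[adult])
    if (yr == cf$warmup_years - 1L) prev_dist <- dist
  }
  dist <- x[adult] / sum(x[adult])
  dmax <- max(abs(dist - prev_dist))
  if (dmax > tol)
    warning("warm-up not converged: max class change ", signif(dmax, 3))
  stable <- as.vector(dist)
  # free projection
  x <- x / sum(x[adult])  # relative population size 1 at horizon start
  N0 <- sum(x[adult])
  traj <- numeric(cf$horizon_years)
  turnover_y <- numeric(cf$horizon_years)
  for (yr in seq_len(cf$horizon_years)) {
    nstart <- sum(x[adult])
    deaths <- 0
    for (M in steps) {
      surv_in <- colSums(M[adult, adult, drop = FALSE])  # per-class survival
      deaths <- deaths + sum(x[adult] * (1 - surv_in))
      x <- M %*% x
    }
    traj[yr] <- sum(x[adult])
    turnover_y[yr] <- deaths / nstart
  }
  lambda <- (traj[cf$horizon_years] / N0)^(1 / cf$horizon_years)
  list(lambda = lambda, stable_age = stable, trajectory = traj,
       turnover = mean(turnover_y), converged = dmax <= tol)
}

#' Posterior projection of growth rate and age structure
#'
#' Pairs independent posterior draws of the adult survival model (CC) and
#' the herd-count model (HC), builds a transition per pair, projects, and
#' summarizes lambda, the stable age structure, and turnover (the latter
#' restricted to runs with near-stable growth, 0.98 < lambda < 1.02).
#'
#' @param cc_draws data.frame of natural-scale adult-model posterior draws
#'   (columns `a1, b1, a2, a3, b3`; see [stage_draws()]).
#' @param hc_draws data.frame of herd-count model draws (columns `f` and
#'   the Siler parameters driving first-year survival).
#' @param config a [leslie_config()].
#' @param n_runs number of projection runs (default from `config`).
#' @param seed integer seed for the draw pairing.
#' @param mods a [hazard_modifiers()] applied to adult survival.
#' @return list with `lambda` (vector per run), `lambda_ev`, `lambda_hpd`,
#'   `turnover_ev`, `turnover_hpd`, `stable_age_ev`, `stable_age_hpd`
#'   (2 x 51), `n_stable_runs`.
#' @export
posterior_projection <- function(cc_draws, hc_draws, config = leslie_config(),
                                 n_runs = config$n_runs, seed = 1L,
                                 mods = hazard_modifiers()) {
  set.seed(seed)
  replace_cc <- n_runs > nrow(cc_draws)
  replace_hc <- n_runs > nrow(hc_draws)
  if (replace_cc || replace_hc)
    message("sampling posterior draws with replacement (chains shorter than n_runs)")
  icc <- sample.int(nrow(cc_draws), n_runs, replace = TRUE)
  ihc <- sample.int(nrow(hc_draws), n_runs, replace = TRUE)
  lam <- numeric(n_runs); trn <- numeric(n_runs)
  ages <- matrix(NA_real_, n_runs, config$n_classes)
  for (r in seq_len(n_runs)) {
    pc <- cc_draws[icc[r], ]
    ph <- hc_draws[ihc[r], ]
    adult_params <- siler_params(pc$a1, pc$b1, pc$a2, pc$a3, pc$b3)
    calf_params <- siler_params(ph$a1, ph$b1, ph$a2, ph$a3, ph$b3)
    calf_mods <- hazard_modifiers(
      beta_S = if ("beta_S" %in% names(hc_draws)) ph$beta_S else 0)
    S1 <- first_year_survival(calf_params, calf_mods)
    tr <- build_transition(adult_params, f = ph$f, S1 = S1, mods = mods,
                           config = config)
    pr <- project(tr)
    lam[r] <- pr$lambda; trn[r] <- pr$turnover
    ages[r, ] <- pr$stable_age
  }
  stable_mask <- lam > 0.98 & lam < 1.02
  list(lambda = lam,
       lambda_ev = mean(lam), lambda_hpd = hpd_interval(lam),
       turnover_ev = if (any(stable_mask)) mean(trn[stable_mask]) else NA_real_,
       turnover_hpd = if (sum(stable_mask) > 1)
         hpd_interval(trn[stable_mask]) else c(NA_real_, NA_real_),
       stable_age_ev = colMeans(ages),
       stable_age_hpd = apply(ages, 2, hpd_interval),
       n_stable_runs = sum(stable_mask))
}
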