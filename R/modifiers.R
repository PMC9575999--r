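#' Season/location/year hazard modifiers
#'
#' Multiplicative (proportional-hazards) modification of the baseline Siler
#' hazard: the hazard is multiplied by
#' `exp(beta_S * I(wet) + beta_L * location + beta_Y[year])`.
#' `beta_S` measures how much more hazardous the wet season is, `beta_L` how
#' hazard changes per km along the migratory axis (measured from a reference
#' point beyond the southeastern extreme, so a negative `beta_L` means higher
#' hazard in the southeast), and `beta_Y` is a per-year log-hazard increment
#' constrained to sum to zero across study years so the baseline remains the
#' across-year mean. `gamma_D` is the slope of the calf dissociation hazard
#' with age beyond 0.75 yr.
#'
#' @param beta_S wet-season log-hazard increment (dimensionless).
#' @param beta_L log-hazard slope per km of migratory-axis distance.
#' @param beta_Y named numeric vector of per-year log-hazard increments
#'   (names are calendar years); empty by default.
#' @param gamma_D dissociation-hazard slope (1/yr per yr), >= 0.
#' @return an object of class `hazard_modifiers`.
#' @export
#' @examples
#' m <- hazard_modifiers(beta_S = log(1.27))
#' p <- siler_from_anchors()
#' modified_hazard(p, m, age = 5, season = "wet", location_km = 0,
#'                 year = 2015) / siler_hazard(p, 5)  # 1.27
hazard_modifiers <- function(beta_S = 0, beta_L = 0, beta_Y = numeric(),
                             gamma_D = 0) {
  if (gamma_D < 0) stop("gamma_D must be >= 0")
  if (length(beta_Y) && is.null(names(beta_Y)))
    stop("beta_Y must be named by calendar year")
  structure(list(beta_S = beta_S, beta_L = beta_L,
                 beta_Y = beta_Y, gamma_D = gamma_D),
            class = "hazard_modifiers")
}

# log of the multiplicative modifier for given covariates (vectorized)
log_modifier <- function(mods, season, location_km, year, strict = FALSE) {
  by <- rep(0, length(year))
  if (length(mods$beta_Y)) {
    idx <- match(as.character(year), names(mods$beta_Y))
    if (strict && anyNA(idx)) stop("year absent from beta_Y (strict mode)")
    by[!is.na(idx)] <- mods$beta_Y[idx[!is.na(idx)]]
  } else if (strict) {
    stop("beta_Y empty (strict mode)")
  }
  mods$beta_S * (season == "wet") + mods$beta_L * location_km + by
}

#' Covariate-modified Siler hazard
#'
#' @param params a [siler_params()] object.
#' @param mods a [hazard_modifiers()] object.
#' @param age age in years.
#' @param season `"wet"` or `"dry"`.
#' @param location_km distance along the migratory axis.
#' @param year calendar year (years absent from `beta_Y` are treated as the
#'   reference level 0 unless `strict = TRUE`).
#' @param strict error on years absent from `beta_Y`.
#' @return hazard (1/yr).
#' @export
modified_hazard <- function(params, mods, age, season, location_km, year,
                            strict = FALSE) {
  siler_hazard(params, age) *
    exp(log_modifier(mods, season, location_km, year, strict))
}

#' Cumulative modified hazard along a piecewise-constant covariate path
#'
#' Integrates the modified hazard over `[age_start, age_end]` where the path
#' is given as covariate-constant segments. Within each segment the modifier
#' is constant, so the integral is `exp(modifier) * [H0(end) - H0(start)]`
#' with `H0` the closed-form baseline cumulative hazard; the result is
#' additive over adjacent segments.
#'
#' @param params a [siler_params()] object.
#' @param mods a [hazard_modifiers()] object.
#' @param segments data.frame with columns `age_start`, `age_end`, `season`,
#'   `location_km`, `year` forming a contiguous non-overlapping partition.
#' @return dimensionless cumulative hazard.
#' @export
cumulative_hazard_piecewise <- function(params, mods, segments) {
  s <- segments
  stopifnot(all(c("age_start", "age_end", "season", "location_km", "year")
                %in% names(s)))
  if (nrow(s) == 0L) return(0)
  if (any(s$age_end < s$age_start)) stop("segment with age_end < age_start")
  if (nrow(s) > 1L &&
      any(abs(s$age_start[-1] - s$age_end[-nrow(s)]) > 1e-9))
    stop("segments must partition the interval (no gaps or overlaps)")
  dH0 <- siler_cumhaz(params, s$age_end) - siler_cumhaz(params, s$age_start)
  sum(exp(log_modifier(mods, s$season, s$location_km, s$year)) * dH0)
}

#' First-year survival along the canonical migratory path
#'
#' Survivorship of a calf from the 1 October birth pulse to age 1 under the
#' covariate-modified hazard, integrating season, location and year effects
#' along the migratory path the population actually follows. This is the
#' estimand behind reported first-year survival; it equals the baseline
#' `siler_survivorship(params, 1)` only when all modifiers are zero.
#'
#' @param params a [siler_params()] object.
#' @param mods a [hazard_modifiers()] object.
#' @param calf_year calendar year of the birth pulse (default 2015, a
#'   representative non-leap year; only matters through `beta_Y` and leap
#'   days).
#' @param location_fun migratory-axis location function.
#' @param to_age integrate to this age (default 1).
#' @return survivorship probability.
#' @export
first_year_survival <- function(params, mods = hazard_modifiers(),
                                calf_year = 2015L,
                                location_fun = migratory_location,
                                to_age = 1) {
  pulse <- birth_pulse_date(calf_year)
  seg <- covariate_segments(pulse, pulse + ceiling(to_age * DAYS_PER_YEAR), 0,
                            location_fun)
  # date rounding overshoots to_age by a fraction of a day; trim exactly
  seg <- seg[seg$age_start < to_age, , drop = FALSE]
  seg$age_end[nrow(seg)] <- to_age
  exp(-cumulative_hazard_piecewise(params, mods, seg))
}

#' Calf association (non-dissociation) survivorship
#'
#' Calves begin to dissociate from their mothers after age 0.75 yr; the
#' dissociation hazard is `gamma_D * (age - 0.75)` past that onset, so the
#' probability a surviving calf is still associated at `age` is 1 up to 0.75
#' and `exp(-gamma_D * (age - 0.75)^2 / 2)` beyond.
#'
#' @param gamma_D dissociation-hazard slope, >= 0.
#' @param age calf age in years (vectorized).
#' @return probability still associated.
#' @export
#' @examples
#' dissociation_probability(8, c(0.5, 0.75, 1.0))
dissociation_probability <- function(gamma_D, age) {
  if (gamma_D < 0) stop("gamma_D must be >= 0")
  if (any(age < 0)) stop("age must be >= 0")
  exp(-gamma_D * pmax(0, age - 0.75)^2 / 2)
}
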