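#' Season calendar for the migratory system
#'
#' The study system has a wet season spanning December through May and a dry
#' season spanning June through November. Calving is a pulse around 1 October
#' (in the dry season), and herd-composition counts taken during the calving
#' window 1 September to 31 October are excluded from the count-based model
#' because calf status cannot be scored reliably then.
#'
#' @name season-calendar
NULL

DAYS_PER_YEAR <- 365.25

#' Season of a calendar date
#'
#' @param date a `Date` vector (or string coercible to `Date`).
#' @return character vector, `"wet"` (Dec--May) or `"dry"` (Jun--Nov).
#' @export
#' @examples
#' season_of(as.Date(c("2015-01-15", "2015-07-01", "2015-12-01")))
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  ifelse(m >= 6L & m <= 11L, "dry", "wet")
}

#' Is a date inside the calving-season count-exclusion window (1 Sep--31 Oct)?
#'
#' @param date a `Date` vector.
#' @return logical vector.
#' @export
in_calving_window <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  m == 9L | m == 10L
}

#' Birth-pulse date for a given calf-year
#'
#' Calving peaks around 1 October; the calf-year label is the calendar year
#' containing that pulse.
#'
#' @param year integer calendar year.
#' @return `Date` vector of 1 October of each year.
#' @export
birth_pulse_date <- function(year) {
  as.Date(sprintf("%d-10-01", as.integer(year)))
}

#' Elapsed years between two dates (365.25-day years)
#'
#' @param from,to `Date` vectors.
#' @return numeric years.
#' @export
years_between <- function(from, to) {
  as.numeric(as.Date(to) - as.Date(from)) / DAYS_PER_YEAR
}

# Dates at which season or calendar year changes: 1 Jan, 1 Jun, 1 Dec.
# Used to cut an observation interval into covariate-constant segments.
season_breaks <- function(from, to) {
  from <- as.Date(from); to <- as.Date(to)
  yrs <- seq(as.integer(format(from, "%Y")) - 1L,
             as.integer(format(to, "%Y")) + 1L)
  br <- as.Date(c(sprintf("%d-01-01", yrs),
                  sprintf("%d-06-01", yrs),
                  sprintf("%d-12-01", yrs)))
  sort(br[br > from & br < to])
}

#' Cut a date interval into season/year-constant segments
#'
#' Splits `[from, to]` at every 1 January, 1 June and 1 December so that each
#' segment lies within a single season and calendar year. Location along the
#' migratory axis is evaluated at each segment midpoint via `location_fun`.
#'
#' @param from,to `Date` scalars, `from < to`.
#' @param age_at_from age (yr) of the animal at `from`.
#' @param location_fun function mapping a `Date` vector to km along the
#'   migratory axis.
#' @return data.frame with columns `age_start`, `age_end`, `season`,
#'   `location_km`, `year` (one row per segment).
#' @export
covariate_segments <- function(from, to, age_at_from, location_fun) {
  from <- as.Date(from); to <- as.Date(to)
  stopifnot(to > from)
  cuts <- c(from, season_breaks(from, to), to)
  s <- cuts[-length(cuts)]
  e <- cuts[-1]
  mid <- s + as.numeric(e - s) / 2
  data.frame(
    age_start = age_at_from + years_between(from, s),
    age_end = age_at_from + years_between(from, e),
    season = season_of(mid),
    location_km = location_fun(mid),
    year = as.integer(format(mid, "%Y"))
  )
}
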