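#' Canonical migratory location path
#'
#' Deterministic piecewise-linear annual cycle of location along the
#' migratory axis (km from a reference point beyond the southeastern extreme
#' of the range): the population is in the southeastern range December
#' through April, migrates northwest during May--June, holds the northwestern
#' range July--September, and returns southeast during October--November.
#'
#' @param date a `Date` vector.
#' @param se_km,nw_km locations of the southeastern and northwestern ranges.
#' @return location in km (vectorized).
#' @export
#' @examples
#' migratory_location(as.Date(c("2015-01-15", "2015-08-01", "2015-05-31")))
migratory_location <- function(date, se_km = 30, nw_km = 130) {
  date <- as.Date(date)
  yd <- as.integer(format(date, "%j"))
  # breakpoints (day of year, non-leap basis): 1 May = 121, 1 Jul = 182,
  # 1 Oct = 274, 1 Dec = 335
  x <- numeric(length(yd))
  x[yd < 121 | yd >= 335] <- se_km
  mig_n <- yd >= 121 & yd < 182
  x[mig_n] <- se_km + (nw_km - se_km) * (yd[mig_n] - 121) / (182 - 121)
  x[yd >= 182 & yd < 274] <- nw_km
  mig_s <- yd >= 274 & yd < 335
  x[mig_s] <- nw_km + (se_km - nw_km) * (yd[mig_s] - 274) / (335 - 274)
  x
}

#' Calf-year of a date
#'
#' The calf-year is the calendar year of the most recent 1 October birth
#' pulse at or before the date.
#'
#' @param date a `Date` vector.
#' @return integer calendar year of the pulse.
#' @export
calf_year_of <- function(date) {
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  ifelse(date >= birth_pulse_date(y), y, y - 1L)
}
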