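#' Expected calf fraction in a classified herd count
#'
#' At time `t` after the 1 October birth pulse, the expected ratio of calves
#' to cows is `r = f * S_c(t)`, where `f` is fecundity and `S_c(t)` the
#' modified-hazard survivorship of a calf from the pulse to the count date,
#' so the expected fraction of calves among classified calves-plus-cows is
#' `r / (1 + r)`. Within-year cow mortality is ignored in the ratio (a dying
#' cow's calf is assumed lost with her, leaving the ratio approximately
#' unchanged). The calf's covariate exposure before the count follows the
#' canonical migratory path.
#'
#' @param f fecundity (probability a cow produces a calf at the pulse).
#' @param params a [siler_params()] object (calf hazard shares the full
#'   Siler curve from birth).
#' @param mods a [hazard_modifiers()] object.
#' @param count_date `Date` scalar, after the pulse of its calf-year.
#' @param location_fun maps dates to migratory-axis km (default
#'   [migratory_location()]).
#' @return expected calf fraction in (0, 1).
#' @export
#' @examples
#' # f = 0.68 and calf survivorship 0.56 give fraction 0.3808/1.3808
#' p <- siler_from_anchors()
#' hc_expected_calf_fraction(0.68, p, count_date = as.Date("2015-09-30"))
hc_expected_calf_fraction <- function(f, params, mods = hazard_modifiers(),
                                      count_date,
                                      location_fun = migratory_location) {
  count_date <- as.Date(count_date)
  pulse <- birth_pulse_date(calf_year_of(count_date))
  t <- years_between(pulse, count_date)
  if (t <= 0) stop("count date must be strictly after the birth pulse")
  seg <- covariate_segments(pulse, count_date, 0, location_fun)
  Sc <- exp(-cumulative_hazard_piecewise(params, mods, seg))
  r <- f * Sc
  r / (1 + r)
}

#' Prepare herd-count data
#'
#' Precomputes, for each retained count record, the calf covariate-segment
#' decomposition from its birth pulse to the count date. Records dated
#' inside the calving-season exclusion window (1 Sep--31 Oct) or with zero
#' classified calves-plus-cows are dropped with a warning count.
#'
#' @param df data.frame with columns `date`, `location_km`, `n_calves`,
#'   `n_cows`.
#' @param location_fun maps dates to migratory-axis km for the calf's
#'   pre-count exposure.
#' @return an object of class `hc_data`.
#' @export
make_hc_data <- function(df, location_fun = migratory_location) {
  need <- c("date", "location_km", "n_calves", "n_cows")
  if (!all(need %in% names(df)))
    stop("herd-count table must have columns: ", paste(need, collapse = ", "))
  df$date <- as.Date(df$date)
  if (any(df$n_calves < 0 | df$n_cows < 0)) stop("negative counts")
  n_window <- sum(in_calving_window(df$date))
  df <- df[!in_calving_window(df$date), , drop = FALSE]
  n_empty <- sum(df$n_calves + df$n_cows == 0)
  if (n_empty) warning(n_empty, " herd counts with zero classified animals skipped")
  df <- df[df$n_calves + df$n_cows > 0, , drop = FALSE]
  segs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    pulse <- birth_pulse_date(calf_year_of(df$date[i]))
    s <- covariate_segments(pulse, df$date[i], 0, location_fun)
    s$rec <- i
    segs[[i]] <- s
  }
  structure(list(
    records = data.frame(n_calves = df$n_calves, n_cows = df$n_cows,
                         calf_year = calf_year_of(df$date), date = df$date),
    segments = do.call(rbind, segs),
    n_excluded_window = n_window,
    n_skipped_empty = n_empty
  ), class = "hc_data")
}

#' Herd-count log-likelihood
#'
#' Binomial likelihood for the number of calves among classified
#' calves-plus-cows in each count, with success probability
#' [hc_expected_calf_fraction()] at the record's date.
#'
#' @param data an `hc_data` object from [make_hc_data()].
#' @param f fecundity: a scalar applied to every year, or a named vector by
#'   calf-year.
#' @param params a [siler_params()] object.
#' @param mods a [hazard_modifiers()] object.
#' @return log-likelihood.
#' @export
hc_loglik <- function(data, f, params, mods = hazard_modifiers()) {
  stopifnot(inherits(data, "hc_data"))
  s <- data$segments
  dH0 <- siler_cumhaz(params, s$age_end) - siler_cumhaz(params, s$age_start)
  dH <- exp(log_modifier(mods, s$season, s$location_km, s$year)) * dH0
  Sc <- exp(-as.vector(rowsum(dH, s$rec)))
  rec <- data$records
  fr <- if (length(f) == 1L && is.null(names(f))) rep(f, nrow(rec)) else {
    idx <- match(as.character(rec$calf_year), names(f))
    # calf-years outside the estimated (complete-year) set share the mean
    out <- unname(f[idx])
    out[is.na(idx)] <- mean(f)
    out
  }
  r <- fr * Sc
  pfrac <- r / (1 + r)
  sum(dbinom(rec$n_calves, rec$n_calves + rec$n_cows, pfrac, log = TRUE))
}
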