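#' Prepare calf-detection data
#'
#' Groups dated binary calf-detection observations into cow-years keyed by
#' the 1 October birth pulse, and precomputes the calf covariate-segment
#' decomposition between consecutive observations (used to move probability
#' mass out of the calf-present state between sightings). Each cow-year is
#' segmented in one pass: the span from the pulse to the last observation
#' is cut at every observation date and every season/year boundary.
#'
#' @param df data.frame with columns `cow_id`, `calf_year`, `date`,
#'   `detected` (0/1 or logical).
#' @param location_fun maps dates to migratory-axis km.
#' @return an object of class `cd_data`.
#' @export
make_cd_data <- function(df, location_fun = migratory_location) {
  need <- c("cow_id", "calf_year", "date", "detected")
  if (!all(need %in% names(df)))
    stop("calf-observation table must have columns: ",
         paste(need, collapse = ", "))
  df$date <- as.Date(df$date)
  df$detected <- as.logical(df$detected)
  key <- interaction(df$cow_id, df$calf_year, drop = TRUE)
  cys <- levels(key)
  obs <- list(); segs <- list(); meta <- list()
  for (i in seq_along(cys)) {
    d <- df[key == cys[i], , drop = FALSE]
    d <- d[order(d$date), , drop = FALSE]
    pulse <- birth_pulse_date(d$calf_year[1])
    if (any(d$date < pulse))
      stop("observation before birth pulse for cow-year ", cys[i])
    nxt <- birth_pulse_date(d$calf_year[1] + 1L)
    if (any(d$date >= nxt))
      stop("observation after next birth pulse for cow-year ", cys[i])
    t <- years_between(pulse, d$date)
    obs[[i]] <- data.frame(cy = i, j = seq_along(t), t = t, det = d$detected)
    last <- d$date[nrow(d)]
    if (last > pulse) {
      b <- sort(unique(c(pulse, season_breaks(pulse, last), d$date)))
      mid <- b[-length(b)] + as.numeric(diff(b)) / 2
      # j: index of the first observation at or after each segment's end
      j <- findInterval(as.numeric(b[-1]) - 0.5, as.numeric(d$date)) + 1L
      segs[[length(segs) + 1L]] <- data.frame(
        age_start = years_between(pulse, b[-length(b)]),
        age_end = years_between(pulse, b[-1]),
        season = season_of(mid),
        location_km = location_fun(mid),
        year = as.integer(format(mid, "%Y")),
        cy = i, j = j)
    }
    meta[[i]] <- data.frame(cy = i, cow_id = d$cow_id[1],
                            calf_year = d$calf_year[1], n_obs = nrow(d))
  }
  cow_years <- do.call(rbind, meta)
  obs <- do.call(rbind, obs)
  segments <- do.call(rbind, segs)
  # precompute the fixed index structures the likelihood loops over
  ncy <- nrow(cow_years)
  maxJ <- max(cow_years$n_obs)
  Tm <- matrix(NA_real_, ncy, maxJ)
  DET <- matrix(NA, ncy, maxJ)
  Tm[cbind(obs$cy, obs$j)] <- obs$t
  DET[cbind(obs$cy, obs$j)] <- obs$det
  if (!is.null(segments)) {
    segments$cyj <- (segments$j - 1L) * ncy + segments$cy
    grp <- sort(unique(segments$cyj))
    segments$grp <- match(segments$cyj, grp)
    seg_target <- grp
  } else {
    seg_target <- integer()
  }
  # observation times carried forward across the NA padding (row-wise), so
  # interval ratios are 1 where a cow-year has no further observations
  Tfill <- Tm
  Tfill[is.na(Tfill)] <- 0
  Tfill <- t(apply(Tfill, 1L, cummax))
  if (maxJ == 1L) Tfill <- t(Tfill)
  structure(list(
    cow_years = cow_years, obs = obs, segments = segments,
    Tm = Tm, DET = DET, Tfill = Tfill, seg_target = seg_target,
    # static pieces reused every likelihood evaluation
    seg_age_start = segments$age_start, seg_age_end = segments$age_end,
    seg_season = segments$season, seg_loc = segments$location_km,
    seg_year = segments$year, seg_grp = segments$grp,
    idx_det = which(!is.na(DET) & DET),
    idx_ndet = which(!is.na(DET) & !DET),
    diss_quad = pmax(Tfill - 0.75, 0)^2 / 2
  ), class = "cd_data")
}

#' Calf-detection log-likelihood (hidden-state forward recursion)
#'
#' Per cow-year, a forward recursion over the hidden states no-calf-born,
#' calf-present, calf-dead, and calf-dissociated. At the birth pulse the
#' calf-present state holds mass `f` and no-calf-born holds `1 - f`. Between
#' observations, calf-present mass survives with the modified calf hazard
#' and remains associated per the dissociation process
#' ([dissociation_probability()]). At each observation the calf is detected
#' with probability `p` if present (and associated), and falsely detected
#' with probability `q` from any other state. Returns the summed log of the
#' total forward mass across cow-years.
#'
#' @param data a `cd_data` object from [make_cd_data()].
#' @param f fecundity: scalar, or named vector by calf-year.
#' @param p probability of correctly detecting a cow's calf, in (0, 1).
#' @param q probability of falsely detecting another cow's calf, in (0, 1).
#' @param params a [siler_params()] object (calf mortality hazard).
#' @param mods a [hazard_modifiers()] object; `mods$gamma_D` drives
#'   dissociation.
#' @return log-likelihood.
#' @export
cd_loglik <- function(data, f, p, q, params, mods = hazard_modifiers()) {
  stopifnot(inherits(data, "cd_data"))
  if (p <= 0 || p >= 1 || q < 0 || q >= 1)
    stop("p must be in (0,1) and q in [0,1)")
  ncy <- nrow(data$cow_years)
  maxJ <- max(data$cow_years$n_obs)
  # survival ratio over each inter-observation interval, matrix [ncy, maxJ]
  S <- matrix(1, ncy, maxJ)
  if (length(data$seg_grp)) {
    dH0 <- siler_cumhaz(params, data$seg_age_end) -
      siler_cumhaz(params, data$seg_age_start)
    dH <- exp(log_modifier(mods, data$seg_season, data$seg_loc,
                           data$seg_year)) * dH0
    agg <- rowsum(dH, data$seg_grp, reorder = TRUE)
    S[data$seg_target] <- exp(-agg[, 1])
  }
  fcy <- if (length(f) == 1L && is.null(names(f))) rep(f, ncy) else {
    idx <- match(as.character(data$cow_years$calf_year), names(f))
    # calf-years outside the estimated (complete-year) set share the mean
    fcy <- unname(f[idx])
    fcy[is.na(idx)] <- mean(f)
    fcy
  }
  if (any(fcy <= 0 | fcy >= 1)) stop("fecundity must be in (0,1)")

  # association survival at each (carried-forward) observation time and the
  # per-interval ratios; padded intervals contribute a ratio of 1
  Dm <- exp(-mods$gamma_D * data$diss_quad)
  A <- Dm / cbind(1, Dm[, -maxJ, drop = FALSE])
  EP <- matrix(1, ncy, maxJ); EO <- matrix(1, ncy, maxJ)
  EP[data$idx_det] <- p; EP[data$idx_ndet] <- 1 - p
  EO[data$idx_det] <- q; EO[data$idx_ndet] <- 1 - q

  N <- 1 - fcy; P <- fcy; D <- rep(0, ncy); X <- rep(0, ncy)
  for (j in seq_len(maxJ)) {
    sj <- S[, j]; aj <- A[, j]
    newP <- P * sj * aj
    D <- (D + P * (1 - sj)) * EO[, j]
    X <- (X + P * sj * (1 - aj)) * EO[, j]
    P <- newP * EP[, j]
    N <- N * EO[, j]
  }
  sum(log(N + P + D + X))
}
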