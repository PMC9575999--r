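#' Load and validate the three observation tables
#'
#' Reads the delimited observation files (or accepts in-memory data frames),
#' checks schemas, applies the study filters -- cows flagged
#' poaching-suspect are removed entirely, herd counts dated inside the
#' calving-season window (1 Sep--31 Oct) are excluded -- and records a
#' validation log with row counts by exclusion reason, so that input rows
#' always equal retained plus excluded.
#'
#' @param cows path to the cow event table (CSV with columns `cow_id`,
#'   `entry_date`, `entry_age_yr`, `event_date`, `location_km`, `status`)
#'   or a data.frame.
#' @param herd path/data.frame of herd counts (`date`, `location_km`,
#'   `n_calves`, `n_cows`).
#' @param calf path/data.frame of calf observations (`cow_id`, `calf_year`,
#'   `date`, `detected`), or `NULL` to disable the calf-detection stage.
#' @param location_fun migratory-axis location function for calf exposure.
#' @return an `observation_set` list with prepared `cc`, `hc`, `cd` data,
#'   the complete-year range `years`, and a `validation` data.frame.
#' @export
load_and_validate <- function(cows, herd, calf = NULL,
                              location_fun = migratory_location) {
  read_tbl <- function(x, what) {
    if (is.data.frame(x)) return(x)
    if (!file.exists(x)) stop(what, " file not found: ", x)
    read.csv(x, stringsAsFactors = FALSE)
  }
  cows <- read_tbl(cows, "cows")
  herd <- read_tbl(herd, "herd counts")
  vlog <- list()

  cows$entry_date <- as.Date(cows$entry_date)
  cows$event_date <- as.Date(cows$event_date)
  if (anyNA(cows$event_date)) stop("malformed event_date in cows table")
  cc <- make_cc_data(cows)
  vlog[[1]] <- data.frame(table = "cows", reason = "poaching-suspect",
                          rows = cc$n_poaching_excluded)

  herd$date <- as.Date(herd$date)
  if (anyNA(herd$date)) stop("malformed date in herd-count table")
  if (any(herd$n_calves < 0 | herd$n_cows < 0))
    stop("negative counts in herd-count table")
  hc <- suppressWarnings(make_hc_data(herd, location_fun))
  vlog[[2]] <- data.frame(table = "herd_counts",
                          reason = c("calving-window", "zero-classified"),
                          rows = c(hc$n_excluded_window, hc$n_skipped_empty))

  cd <- NULL
  if (!is.null(calf)) {
    calf <- read_tbl(calf, "calf observations")
    if (nrow(calf) == 0L) {
      warning("empty calf-observation table: calf-detection stage disabled")
    } else {
      calf$date <- as.Date(calf$date)
      cd <- make_cd_data(calf, location_fun)
    }
  }
  ev_years <- as.integer(format(cows$event_date, "%Y"))
  yr_range <- range(ev_years)
  years <- seq(yr_range[1] + 1L, yr_range[2] - 1L)
  structure(list(cc = cc, hc = hc, cd = cd, years = years,
                 validation = do.call(rbind, vlog)),
            class = "observation_set")
}

#' Write posterior chains to delimited text with a JSON run manifest
#'
#' One row per chain and step, one column per parameter (transformed
#' scale), plus `<basename>_manifest.json` recording seed, dimensions,
#' acceptance rates and convergence diagnostics.
#'
#' @param chains a `posterior_chains` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chains <- function(chains, path) {
  s <- chains$samples
  n <- dim(s)[1]; m <- dim(s)[3]
  df <- data.frame(chain = rep(seq_len(m), each = n),
                   step = rep(seq_len(n), m))
  pooled <- pooled_samples(chains)
  df <- cbind(df, as.data.frame(pooled))
  write.csv(df, path, row.names = FALSE)
  manifest <- list(seed = chains$seed, n_chains = m, n_steps = n,
                   burn_steps = chains$burn_steps,
                   acceptance = chains$acceptance,
                   split_rhat = as.list(chains$rhat))
  jsonlite::write_json(manifest,
                       sub("\\.csv$", "_manifest.json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
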