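## Coral-Reef-Watch-style heat-stress metrics.
##
## The chain is: daily SST -> monthly climatology -> maximal monthly mean
## (MMM) -> daily hotspot values (SST - MMM, retained only when SST exceeds
## MMM by at least 1 degree C) -> 84-day cumulative bleaching-alert flags ->
## yearly and overall bleaching-alert frequencies (BAF).
##
## All functions take a long tibble of daily SST with columns
## cell_id, t (day index, strictly increasing per cell), year, month, sst.

#' Monthly SST climatology
#'
#' Mean SST per cell and calendar month over the baseline years (default:
#' the full series). Missing SST days are excluded from the means.
#'
#' @param sst long tibble with columns `cell_id`, `year`, `month`, `sst`
#' @param baseline_years optional integer vector of years to use
#' @return tibble `cell_id`, `month`, `clim_sst` (12 rows per cell)
#' @export
monthly_climatology <- function(sst, baseline_years = NULL) {
  check_cols(sst, c("cell_id", "year", "month", "sst"), "sst")
  base <- if (is.null(baseline_years)) sst else
    filter(sst, .data$year %in% baseline_years)
  clim <- base |>
    group_by(.data$cell_id, .data$month) |>
    summarise(clim_sst = mean(.data$sst, na.rm = TRUE),
              n_obs = sum(!is.na(.data$sst)), .groups = "drop")
  bad <- clim |> filter(.data$n_obs == 0)
  missing_months <- clim |>
    count(.data$cell_id) |>
    filter(.data$n < 12)
  if (nrow(bad) > 0 || nrow(missing_months) > 0) {
    mo <- unique(c(bad$month,
                   setdiff(1:12, clim$month[clim$cell_id %in% missing_months$cell_id])))
    ra_abort(paste0(
      "Climatology undefined: no SST observations for month(s) ",
      paste(sort(mo), collapse = ", "), " in the baseline."
    ))
  }
  select(clim, "cell_id", "month", "clim_sst")
}

#' Maximal monthly mean (MMM)
#'
#' The warmest month's climatological mean per cell: the bleaching reference
#' temperature.
#'
#' @param climatology output of [monthly_climatology()]
#' @return tibble `cell_id`, `mmm`
#' @export
maximal_monthly_mean <- function(climatology) {
  check_cols(climatology, c("cell_id", "month", "clim_sst"), "climatology")
  if (any(!is.finite(climatology$clim_sst))) {
    ra_abort("Climatology contains non-finite entries.")
  }
  climatology |>
    group_by(.data$cell_id) |>
    summarise(mmm = max(.data$clim_sst), .groups = "drop")
}

#' Daily hotspot values
#'
#' hotspot(t) = SST(t) - MMM when SST(t) >= MMM + `min_excess` (the
#' "at least 1 degree C" retention rule, boundary inclusive), else 0.
#' Missing SST gives a missing hotspot.
#'
#' @param sst long daily SST tibble (see [monthly_climatology()]), with `t`
#' @param mmm tibble `cell_id`, `mmm` from [maximal_monthly_mean()]
#' @param min_excess retention threshold in degrees C (default 1)
#' @return `sst` with an added `hotspot` column
#' @export
hotspot_series <- function(sst, mmm, min_excess = 1) {
  check_cols(sst, c("cell_id", "t", "year", "sst"), "sst")
  check_cols(mmm, c("cell_id", "mmm"), "mmm")
  if (any(!is.finite(mmm$mmm))) ra_abort("`mmm` contains non-finite values.")
  sst |>
    inner_join(mmm, by = "cell_id") |>
    mutate(hotspot = dplyr::if_else(
      .data$sst >= .data$mmm + min_excess, .data$sst - .data$mmm, 0
    )) |>
    select(-"mmm")
}

#' Bleaching-alert flags
#'
#' A day is under bleaching alert when the cumulated hotspot values over the
#' trailing `window_days`-day window (ending at and including the day) are
#' positive. Days with less than a full window of history use the available
#' prefix; missing hotspots count as zero in the sum (hotspots are
#' non-negative, so the sum is positive iff some observed day in the window
#' is a hotspot day).
#'
#' @param hotspot output of [hotspot_series()]
#' @param window_days accumulation window length (default 84, i.e. 3 months)
#' @return `hotspot` with an added integer `alert` column (0/1)
#' @export
alert_flags <- function(hotspot, window_days = 84) {
  check_cols(hotspot, c("cell_id", "t", "year", "hotspot"), "hotspot")
  if (window_days < 1) ra_abort("`window_days` must be >= 1.")
  hotspot |>
    arrange(.data$cell_id, .data$t) |>
    group_by(.data$cell_id) |>
    mutate(alert = {
      h <- tidyr::replace_na(.data$hotspot, 0)
      cs <- cumsum(h)
      lag_cs <- c(rep(0, min(window_days, length(cs))),
                  head(cs, max(0, length(cs) - window_days)))
      as.integer((cs - lag_cs) > 0)
    }) |>
    ungroup()
}

#' Yearly bleaching-alert frequency (BAF_year)
#'
#' Fraction of days flagged per cell and calendar year. Years before
#' `first_valid_year` are omitted (the early years would bias BAF through an
#' MMM estimated from too little data).
#'
#' @param flags output of [alert_flags()]
#' @param first_valid_year first calendar year reported
#' @return tibble `cell_id`, `year`, `baf_year`
#' @export
annual_alert_frequency <- function(flags, first_valid_year) {
  check_cols(flags, c("cell_id", "year", "alert"), "flags")
  out <- flags |>
    filter(.data$year >= first_valid_year) |>
    group_by(.data$cell_id, .data$year) |>
    summarise(baf_year = mean(.data$alert), .groups = "drop")
  if (nrow(out) == 0) {
    ra_abort("No data at or after `first_valid_year`.")
  }
  out
}

#' Overall bleaching-alert frequency (BAF_overall)
#'
#' Unweighted mean of BAF_year over a year range.
#'
#' @param baf_year tibble from [annual_alert_frequency()]
#' @param years years to average over (default: all years present per cell)
#' @return tibble `cell_id`, `baf_overall`
#' @export
overall_baf <- function(baf_year, years = NULL) {
  check_cols(baf_year, c("cell_id", "year", "baf_year"), "baf_year")
  x <- baf_year
  if (!is.null(years)) {
    if (length(years) == 0) ra_abort("`years` must be non-empty.")
    x <- filter(x, .data$year %in% years)
    have <- x |> count(.data$cell_id)
    if (nrow(have) == 0 || any(have$n < length(years))) {
      ra_abort("Requested year(s) missing from `baf_year` for some cell.")
    }
  }
  x |>
    group_by(.data$cell_id) |>
    summarise(baf_overall = mean(.data$baf_year), .groups = "drop")
}

#' Thermal covariates for a survey record
#'
#' For a survey in `survey_year`: BAF_previous_year is BAF_year of the year
#' before the survey; the overall alert frequency is the mean BAF_year from
#' `first_valid_year` up to two years before the survey.
#'
#' @param baf_year tibble from [annual_alert_frequency()]
#' @param survey_year calendar year of the survey
#' @param first_valid_year first year entering the overall average
#' @return tibble `cell_id`, `survey_year`, `baf_previous_year`,
#'   `baf_overall_to_lag2`
#' @export
survey_thermal_covariates <- function(baf_year, survey_year,
                                      first_valid_year) {
  check_cols(baf_year, c("cell_id", "year", "baf_year"), "baf_year")
  if (survey_year - 2 < first_valid_year) {
    ra_abort("Insufficient BAF history: survey_year - 2 precedes the first valid year.")
  }
  prev <- baf_year |>
    filter(.data$year == survey_year - 1) |>
    select("cell_id", baf_previous_year = "baf_year")
  overall <- baf_year |>
    filter(.data$year >= first_valid_year, .data$year <= survey_year - 2) |>
    group_by(.data$cell_id) |>
    summarise(baf_overall_to_lag2 = mean(.data$baf_year),
              n_years = dplyr::n(), .groups = "drop")
  expected <- survey_year - 1 - first_valid_year
  if (nrow(prev) == 0 || any(overall$n_years < expected)) {
    ra_abort("Insufficient BAF history for the requested survey year.")
  }
  prev |>
    inner_join(select(overall, -"n_years"), by = "cell_id") |>
    mutate(survey_year = survey_year, .after = "cell_id")
}

#' One-call thermal summary
#'
#' Convenience wrapper running climatology, MMM, hotspot, alert flags and the
#' BAF family in one pass.
#'
#' @inheritParams monthly_climatology
#' @inheritParams alert_flags
#' @inheritParams annual_alert_frequency
#' @param min_excess hotspot retention threshold, degrees C
#' @param years years entering BAF_overall (default: all valid years)
#' @return list with `mmm`, `flags`, `baf_year`, `baf_overall`
#' @export
thermal_summary <- function(sst, baseline_years = NULL, min_excess = 1,
                            window_days = 84, first_valid_year,
                            years = NULL) {
  mmm <- maximal_monthly_mean(monthly_climatology(sst, baseline_years))
  flags <- alert_flags(hotspot_series(sst, mmm, min_excess), window_days)
  baf_year <- annual_alert_frequency(flags, first_valid_year)
  list(
    mmm = mmm,
    flags = flags,
    baf_year = baf_year,
    baf_overall = overall_baf(baf_year, years)
  )
}
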