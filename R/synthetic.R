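## Synthetic seascape generators.
##
## Each generator is a pure function of its arguments and a seed, and returns
## the simulated data together with the ground truth that produced it, so
## every downstream stage of the pipeline can be tested against a planted
## truth without any external satellite, genomic or survey data.

#' Generate a toy reef grid
#'
#' Builds a regular n_x-by-n_y pixel grid and marks a connected set of cells
#' as reef. Reef cells are grown from a random start cell by repeatedly
#' annexing a random 8-adjacent frontier cell, so the reef always forms one
#' connected component under 8-adjacency.
#'
#' @param n_x,n_y grid dimensions (n_x * n_y >= 4)
#' @param reef_fraction fraction of cells that are reef, in (0, 1]
#' @param cell_area_km2 area of each reef cell in km^2
#' @param seed integer seed
#' @param margin width (in cells) of an all-sea band around the domain that
#'   stays reef-free, emulating a study-area border offshore of every reef
#'   (default 0: reefs may touch the edge)
#' @return a tibble with columns `cell_id`, `x`, `y`, `area_km2`, `is_reef`;
#'   one row per grid cell, reef cells flagged by `is_reef`
#' @examples
#' gen_reef_grid(4, 4, 0.5, 25, seed = 1)
#' @export
gen_reef_grid <- function(n_x, n_y, reef_fraction, cell_area_km2, seed,
                          margin = 0) {
  stopifnot(n_x >= 1, n_y >= 1, n_x * n_y >= 4, margin >= 0)
  if (reef_fraction <= 0 || reef_fraction > 1) {
    ra_abort("`reef_fraction` must be in (0, 1].")
  }
  stopifnot(cell_area_km2 > 0)
  n_cells <- n_x * n_y
  n_reef <- round(reef_fraction * n_cells)
  if (n_reef < 1) {
    ra_abort("`reef_fraction` too small: no reef cell can be placed.")
  }
  interior <- function(x, y) {
    x > margin & x <= n_x - margin & y > margin & y <= n_y - margin
  }
  n_interior <- max(0, (n_x - 2 * margin)) * max(0, (n_y - 2 * margin))
  if (n_reef > n_interior) {
    ra_abort("Impossible layout: more reef cells requested than interior cells inside the margin.")
  }

  grid <- tidyr::expand_grid(y = seq_len(n_y), x = seq_len(n_x)) |>
    mutate(cell_id = dplyr::row_number(), .before = 1)

  idx <- function(x, y) (y - 1L) * n_x + x
  eligible <- interior(grid$x, grid$y)
  withr_seed(seed, {
    reef <- rep(FALSE, n_cells)
    start <- sample(which(eligible), 1)
    reef[start] <- TRUE
    while (sum(reef) < n_reef) {
      frontier <- which(!reef & eligible & vapply(seq_len(n_cells), function(i) {
        xi <- (i - 1L) %% n_x + 1L
        yi <- (i - 1L) %/% n_x + 1L
        nx <- pmax(1L, xi - 1L):pmin(n_x, xi + 1L)
        ny <- pmax(1L, yi - 1L):pmin(n_y, yi + 1L)
        any(reef[idx(rep(nx, length(ny)), rep(ny, each = length(nx)))])
      }, logical(1)))
      reef[frontier[sample.int(length(frontier), 1)]] <- TRUE
    }
  })
  grid |>
    mutate(
      is_reef = reef[.data$cell_id],
      area_km2 = ifelse(.data$is_reef, cell_area_km2, NA_real_)
    ) |>
    select("cell_id", "x", "y", "area_km2", "is_reef")
}

## evaluate code with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Generate a daily SST series with planted heat anomalies
#'
#' The noise-free signal is a sinusoidal annual cycle (maximum in
#' `peak_month`) plus rectangular anomalies; independent Gaussian noise is
#' added on top. The returned truth lists, per cell, exactly the days the
#' bleaching-alert definitions flag when applied to the noise-free signal
#' (monthly climatology over the full series, maximal monthly mean, hotspot
#' retained when SST exceeds MMM by at least `hotspot_min_excess` degrees,
#' 84-day trailing alert window including the current day).
#'
#' Synthetic series use a 365-day calendar without leap days.
#'
#' @param grid reef grid from [gen_reef_grid()]; only reef cells get a series
#' @param n_years number of years (>= 2)
#' @param baseline_temp annual mean temperature, degrees C
#' @param seasonal_amplitude half-range of the annual cycle, degrees C
#' @param anomalies data frame with columns `cell_id`, `start_day`,
#'   `duration`, `magnitude` (degrees C), or NULL for none
#' @param noise_sd sd of daily Gaussian noise, degrees C
#' @param peak_month calendar month of the climatological maximum (default 2,
#'   the austral late summer)
#' @param hotspot_min_excess retention threshold for hotspot values, degrees C
#' @param window_days alert accumulation window, days
#' @param seed integer seed
#' @param start_year calendar year of day 1
#' @return a list with `sst` (tibble: `cell_id`, `t`, `year`, `month`,
#'   `day_of_year`, `sst`) and `truth` (list with `planted_alert_days`,
#'   `mmm`, `rng_seed`)
#' @export
gen_sst_series <- function(grid, n_years, baseline_temp = 26,
                           seasonal_amplitude = 2, anomalies = NULL,
                           noise_sd = 0.1, peak_month = 2,
                           hotspot_min_excess = 1, window_days = 84,
                           seed = 1, start_year = 2001) {
  stopifnot(n_years >= 2)
  cells <- grid$cell_id[grid$is_reef]
  n_days <- 365L * n_years
  t <- seq_len(n_days)
  doy <- ((t - 1L) %% 365L) + 1L
  year <- start_year + (t - 1L) %/% 365L
  month <- doy_to_month(doy)
  # peak mid-month of peak_month
  peak_doy <- month_start[peak_month] + (month_len[peak_month] - 1) / 2
  cycle <- baseline_temp +
    seasonal_amplitude * cos(2 * pi * (doy - peak_doy) / 365)

  anom <- matrix(0, nrow = n_days, ncol = length(cells),
                 dimnames = list(NULL, as.character(cells)))
  if (!is.null(anomalies) && nrow(anomalies) > 0) {
    check_cols(anomalies, c("cell_id", "start_day", "duration", "magnitude"),
               "anomalies")
    for (k in seq_len(nrow(anomalies))) {
      a <- anomalies[k, ]
      if (a$duration < 1) ra_abort("Anomaly duration must be >= 1 day.")
      days <- a$start_day + seq_len(a$duration) - 1L
      if (a$start_day < 1 || max(days) > n_days) {
        ra_abort("Anomaly lies outside the series span.")
      }
      if (!a$cell_id %in% cells) {
        ra_abort(paste0("Anomaly cell ", a$cell_id, " is not a reef cell."))
      }
      anom[days, as.character(a$cell_id)] <-
        anom[days, as.character(a$cell_id)] + a$magnitude
    }
  }

  signal <- matrix(cycle, nrow = n_days, ncol = length(cells)) + anom

  noise <- withr_seed(seed, {
    matrix(rnorm(n_days * length(cells), sd = noise_sd),
           nrow = n_days, ncol = length(cells))
  })

  # ground truth from the noise-free signal, computed cell by cell with
  # plain loops (kept independent of the thermal module's grouped pipeline)
  truth_alert <- vector("list", length(cells))
  truth_mmm <- numeric(length(cells))
  for (j in seq_along(cells)) {
    s <- signal[, j]
    monthly <- vapply(1:12, function(m) mean(s[month == m]), numeric(1))
    mmm <- max(monthly)
    hot <- as.numeric(s >= mmm + hotspot_min_excess)
    cs <- cumsum(hot)
    wsum <- cs - c(rep(0, window_days), head(cs, -window_days))
    truth_alert[[j]] <- which(wsum > 0)
    truth_mmm[j] <- mmm
  }

  sst <- tibble(
    cell_id = rep(cells, each = n_days),
    t = rep(t, length(cells)),
    year = rep(year, length(cells)),
    month = rep(month, length(cells)),
    day_of_year = rep(doy, length(cells)),
    sst = as.vector(signal + noise)
  )

  list(
    sst = sst,
    truth = list(
      planted_alert_days = tibble(
        cell_id = rep(cells, lengths(truth_alert)),
        t = unlist(truth_alert, use.names = FALSE)
      ),
      mmm = tibble(cell_id = cells, mmm = truth_mmm),
      rng_seed = seed
    )
  )
}

#' Generate daily surface-current fields
#'
#' Every pixel of the grid (reef or not) is treated as sea; daily eastward
#' (`u`) and northward (`v`) velocities are the prescribed drift plus
#' independent Gaussian noise.
#'
#' @param grid grid from [gen_reef_grid()]
#' @param drift_east,drift_north mean velocities, m/s
#' @param noise_sd daily velocity noise sd, m/s
#' @param n_days number of days (>= 1)
#' @param seed integer seed
#' @return tibble with columns `x`, `y`, `day`, `u`, `v`
#' @export
gen_current_field <- function(grid, drift_east, drift_north, noise_sd,
                              n_days, seed = 1) {
  stopifnot(n_days >= 1)
  n_pix <- nrow(grid)
  withr_seed(seed, {
    tibble(
      x = rep(grid$x, n_days),
      y = rep(grid$y, n_days),
      day = rep(seq_len(n_days), each = n_pix),
      u = drift_east + rnorm(n_pix * n_days, sd = noise_sd),
      v = drift_north + rnorm(n_pix * n_days, sd = noise_sd)
    )
  })
}

#' Generate per-individual genotype tables from a planted logistic law
#'
#' Adaptive genotype g is present in an individual at site s with probability
#' `plogis(intercepts[g] + slopes[g] * baf_s)`; neutral genotypes are
#' Bernoulli with site-independent frequencies drawn uniformly on
#' `neutral_freq_range`.
#'
#' @param site_baf data frame with columns `site_id`, `baf` (one row per
#'   site), or a named numeric vector of BAF values
#' @param n_per_site individuals sampled per site (>= 5, the site retention
#'   threshold used downstream)
#' @param intercepts,slopes planted coefficients, one per adaptive genotype
#' @param n_neutral number of neutral genotypes
#' @param species species label attached to every individual
#' @param neutral_freq_range range of neutral genotype frequencies
#' @param seed integer seed
#' @return list with `genotypes` (tibble: `individual_id`, `site_id`,
#'   `species`, `genotype_id`, `presence`, `adaptive`) and `truth`
#' @export
gen_genotype_data <- function(site_baf, n_per_site, intercepts, slopes,
                              n_neutral = 0, species = "sp1",
                              neutral_freq_range = c(0.1, 0.9), seed = 1) {
  if (is.numeric(site_baf) && !is.null(names(site_baf))) {
    site_baf <- tibble(site_id = names(site_baf), baf = unname(site_baf))
  }
  check_cols(site_baf, c("site_id", "baf"), "site_baf")
  if (nrow(site_baf) == 0) ra_abort("`site_baf` must contain at least one site.")
  stopifnot(length(intercepts) == length(slopes), n_per_site >= 5)
  n_adaptive <- length(intercepts)

  withr_seed(seed, {
    inds <- tibble(
      site_id = rep(site_baf$site_id, each = n_per_site),
      baf = rep(site_baf$baf, each = n_per_site)
    ) |>
      mutate(individual_id = paste0(species, "_ind", dplyr::row_number()))

    adapt <- purrr::map_dfr(seq_len(n_adaptive), function(g) {
      p <- plogis(intercepts[g] + slopes[g] * inds$baf)
      tibble(
        individual_id = inds$individual_id,
        site_id = inds$site_id,
        species = species,
        genotype_id = paste0(species, "_adaptive_", g),
        presence = rbinom(nrow(inds), 1, p),
        adaptive = TRUE
      )
    })

    neutral <- NULL
    if (n_neutral > 0) {
      freqs <- runif(n_neutral, neutral_freq_range[1], neutral_freq_range[2])
      neutral <- purrr::map_dfr(seq_len(n_neutral), function(g) {
        tibble(
          individual_id = inds$individual_id,
          site_id = inds$site_id,
          species = species,
          genotype_id = paste0(species, "_neutral_", g),
          presence = rbinom(nrow(inds), 1, freqs[g]),
          adaptive = FALSE
        )
      })
    }

    list(
      genotypes = bind_rows(adapt, neutral),
      truth = list(
        gea_coefficients = tibble(
          genotype_id = paste0(species, "_adaptive_", seq_len(n_adaptive)),
          intercept = intercepts, slope = slopes
        ),
        rng_seed = seed
      )
    )
  })
}

#' Generate coral-cover survey records from a known beta mixed model
#'
#' Cover rates follow Beta(mu * phi, (1 - mu) * phi) with
#' `logit(mu) = intercept + sum(coef * standardized covariate) + station
#' intercept`. Covariates are drawn with realistic dependence: a latent
#' station heat level drives both the yearly previous-year alert frequency
#' and (through a logistic link) the probability of adaptation, while the
#' two connectivity indices share a common lognormal factor. Stations are
#' visited in runs of unequal length.
#'
#' @param n_stations number of survey stations (>= 2)
#' @param years_per_station integer length-2 range of visits per station
#' @param fixed_effects named list/vector of coefficients on standardized
#'   covariates; recognised names: `intercept`, `baf_prev`, `pa_heat`,
#'   `oci`, `ici`, `baf_prev_x_pa`, `baf_prev_x_oci`, `baf_prev_x_ici`
#' @param station_sd sd of station random intercepts (logit scale, >= 0)
#' @param precision beta precision parameter phi (> 0)
#' @param seed integer seed
#' @param years calendar years surveys may fall in
#' @return list with `surveys` (tibble: `station_id`, `year`, `cover_rate`,
#'   `baf_previous_year`, `baf_overall_to_lag2`, `pa_heat`, `oci`, `ici`)
#'   and `truth`
#' @export
gen_survey_data <- function(n_stations, years_per_station = c(3, 15),
                            fixed_effects = list(intercept = 0),
                            station_sd = 0.3, precision = 30, seed = 1,
                            years = 2003:2017) {
  if (precision <= 0) ra_abort("`precision` must be positive.")
  if (station_sd < 0) ra_abort("`station_sd` must be non-negative.")
  stopifnot(n_stations >= 2, length(years_per_station) == 2)
  fe <- as.list(fixed_effects)
  known <- c("intercept", "baf_prev", "pa_heat", "oci", "ici",
             "baf_prev_x_pa", "baf_prev_x_oci", "baf_prev_x_ici")
  bad <- setdiff(names(fe), known)
  if (length(bad) > 0) {
    ra_abort(paste0("Unknown fixed effect(s): ", paste(bad, collapse = ", ")))
  }
  co <- function(nm) if (is.null(fe[[nm]])) 0 else fe[[nm]]

  withr_seed(seed, {
    station_heat <- runif(n_stations, 0.05, 0.20)
    conn_factor <- rnorm(n_stations)
    station_int <- rnorm(n_stations, 0, station_sd)
    span <- years_per_station[1]:years_per_station[2]
    n_years <- pmin(span[sample.int(length(span), n_stations, replace = TRUE)],
                    length(years))

    recs <- purrr::map_dfr(seq_len(n_stations), function(s) {
      ys <- sort(sample(years, n_years[s]))
      tibble(
        station_id = paste0("st", s),
        year = ys,
        baf_previous_year = pmax(0, station_heat[s] + rnorm(n_years[s], 0, 0.05)),
        baf_overall_to_lag2 = pmax(0, station_heat[s] + rnorm(n_years[s], 0, 0.01)),
        oci = exp(0.8 * conn_factor[s] + rnorm(n_years[s], 0, 0.01)) * 100,
        ici = exp(0.8 * conn_factor[s] + rnorm(n_years[s], 0, 0.4)) * 100,
        .station_int = station_int[s]
      )
    })
    recs$pa_heat <- plogis(-3 + 25 * recs$baf_overall_to_lag2)

    z <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
    zb <- z(recs$baf_previous_year)
    zp <- z(recs$pa_heat)
    zo <- z(recs$oci)
    zi <- z(recs$ici)
    eta <- co("intercept") + co("baf_prev") * zb + co("pa_heat") * zp +
      co("oci") * zo + co("ici") * zi +
      co("baf_prev_x_pa") * zb * zp +
      co("baf_prev_x_oci") * zb * zo +
      co("baf_prev_x_ici") * zb * zi +
      recs$.station_int
    mu <- plogis(eta)
    recs$cover_rate <- rbeta(nrow(recs), mu * precision, (1 - mu) * precision)
    recs$.station_int <- NULL

    list(
      surveys = recs,
      truth = list(
        fixed_effects = fe,
        station_sd = station_sd,
        precision = precision,
        rng_seed = seed
      )
    )
  })
}
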