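## Coral-cover change vs heat stress, adaptation and connectivity.
##
## Survey records (station, year, cover rate) are joined to their thermal,
## adaptation and connectivity covariates and modelled with beta-regression
## mixed models: logit mean link, one precision parameter, station random
## intercepts (Laplace marginal likelihood via glmmTMB, the estimation route
## standard for beta GLMMs). Univariate screens, BAF-by-moderator
## interaction models and AIC comparison mirror the analysis design.

#' Join survey records to their covariates
#'
#' For every (station, year) record: BAF_previous_year and the overall alert
#' frequency up to two years before the survey are taken from the station's
#' reef cell's yearly BAF series; PA_HEAT is predicted from the record's own
#' overall BAF via the pooled adaptation model; OCI/ICI come from the cell's
#' connectivity indices.
#'
#' @param surveys tibble `station_id`, `year`, `cover_rate`
#' @param station_cells tibble `station_id`, `cell_id` mapping stations to
#'   reef cells
#' @param baf_year tibble `cell_id`, `year`, `baf_year` from
#'   [annual_alert_frequency()]
#' @param pa_model a `pa_model` from [fit_pooled_glmm()]
#' @param indices tibble `cell_id`, `oci_km2`, `ici_km2` from
#'   [connectivity_indices()]
#' @param first_valid_year first year entering the overall BAF average
#' @return tibble of cover records with `baf_previous_year`,
#'   `baf_overall_to_lag2`, `pa_heat`, `oci`, `ici`
#' @export
join_covariates <- function(surveys, station_cells, baf_year, pa_model,
                            indices, first_valid_year) {
  check_cols(surveys, c("station_id", "year", "cover_rate"), "surveys")
  check_cols(station_cells, c("station_id", "cell_id"), "station_cells")
  unmapped <- setdiff(surveys$station_id, station_cells$station_id)
  if (length(unmapped) > 0) {
    ra_abort(paste0("Station(s) not mapped to a reef cell: ",
                    paste(unique(unmapped), collapse = ", ")))
  }
  no_idx <- setdiff(station_cells$cell_id, indices$cell_id)
  if (length(no_idx) > 0) {
    ra_abort(paste0("No connectivity indices for cell(s): ",
                    paste(unique(no_idx), collapse = ", ")))
  }

  recs <- surveys |> inner_join(station_cells, by = "station_id")
  short <- recs |> filter(.data$year - 2 < first_valid_year)
  if (nrow(short) > 0) {
    ra_abort(paste0("Insufficient BAF history for station(s): ",
                    paste(unique(short$station_id), collapse = ", ")))
  }

  thermal <- recs |>
    distinct(.data$cell_id, .data$year) |>
    purrr::pmap_dfr(function(cell_id, year) {
      survey_thermal_covariates(
        filter(baf_year, .data$cell_id == !!cell_id),
        survey_year = year, first_valid_year = first_valid_year
      ) |>
        select(-"survey_year") |>
        mutate(year = !!year)
    })

  recs |>
    inner_join(thermal, by = c("cell_id", "year")) |>
    mutate(pa_heat = predict_pa_heat(pa_model, .data$baf_overall_to_lag2)) |>
    inner_join(
      select(indices, "cell_id", oci = "oci_km2", ici = "ici_km2"),
      by = "cell_id"
    )
}

## squeeze boundary rates into (0, 1): (y (n - 1) + 0.5) / n
squeeze_rates <- function(y) {
  n <- length(y)
  (y * (n - 1) + 0.5) / n
}

#' Fit a beta-regression mixed model of cover rates
#'
#' Beta likelihood with logit mean link and a single precision parameter,
#' plus station random intercepts. Covariates named in `fixed_terms` are
#' standardized to mean 0 / sd 1 before fitting (`a:b` denotes the product
#' of the two standardized covariates, with no main effect of `b` implied).
#'
#' @param records cover-record tibble (see [join_covariates()]); must contain
#'   `cover_rate`, `station_id` and every covariate named in `fixed_terms`
#' @param fixed_terms character vector of fixed-effect terms, e.g.
#'   `c("baf_previous_year")` or `c("baf_previous_year",
#'   "baf_previous_year:ici")`
#' @param squeeze if TRUE (default), cover rates of exactly 0 or 1 are pulled
#'   inside the unit interval by `(y * (n - 1) + 0.5) / n`; if FALSE such
#'   values are an error
#' @return object of class `cover_fit` with `tidy()`/`glance()` methods
#' @export
fit_beta_glmm <- function(records, fixed_terms, squeeze = TRUE) {
  check_cols(records, c("cover_rate", "station_id"), "records")
  if (dplyr::n_distinct(records$station_id) < 2) {
    ra_abort("Need at least 2 stations for a station random intercept.")
  }
  y <- records$cover_rate
  if (any(y < 0 | y > 1)) ra_abort("`cover_rate` must lie in [0, 1].")
  if (any(y <= 0 | y >= 1)) {
    if (!squeeze) {
      ra_abort(paste(
        "Cover rates on the boundary of (0, 1); refit with `squeeze = TRUE`",
        "to apply the (y * (n - 1) + 0.5) / n transform."
      ))
    }
    y <- squeeze_rates(y)
  }

  vars <- unique(unlist(strsplit(fixed_terms, ":", fixed = TRUE)))
  check_cols(records, vars, "records")
  dat <- tibble(.cover = y, station_id = factor(records$station_id))
  for (v in vars) dat[[v]] <- standardize(records[[v]])
  for (term in fixed_terms) {
    pieces <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (length(pieces) > 1) {
      dat[[gsub(":", "_x_", term)]] <-
        Reduce(`*`, lapply(pieces, function(v) dat[[v]]))
    }
  }
  terms_r <- gsub(":", "_x_", fixed_terms)
  fml <- stats::as.formula(paste(
    ".cover ~", paste(terms_r, collapse = " + "), "+ (1 | station_id)"
  ))
  fit <- glmmTMB::glmmTMB(fml, data = dat,
                          family = glmmTMB::beta_family(link = "logit"))
  conv <- isTRUE(fit$sdr$pdHess) && fit$fit$convergence == 0
  if (!conv) {
    warn("Beta GLMM did not converge cleanly; inspect `$fit`.",
         class = "reefadapt_nonconvergence")
  }
  fe <- glmmTMB::fixef(fit)$cond
  se <- sqrt(diag(stats::vcov(fit)$cond))
  z <- fe / se
  ll <- as.numeric(logLik(fit))
  k <- attr(logLik(fit), "df")
  structure(
    list(
      fit = fit,
      terms = tibble(
        term = names(fe), estimate = unname(fe), std.error = unname(se),
        statistic = unname(z), p.value = 2 * pnorm(-abs(unname(z)))
      ),
      station_sd = attr(glmmTMB::VarCorr(fit)$cond$station_id, "stddev")[[1]],
      precision = glmmTMB::sigma(fit),
      logLik = ll, k = k, AIC = 2 * k - 2 * ll,
      n = nrow(dat), converged = conv,
      fixed_terms = fixed_terms
    ),
    class = "cover_fit"
  )
}

#' @export
print.cover_fit <- function(x, ...) {
  cat(sprintf(
    "<cover_fit> cover ~ %s + (1 | station)  [beta, logit link]\n",
    paste(x$fixed_terms, collapse = " + ")
  ))
  print(as.data.frame(x$terms), row.names = FALSE, digits = 3)
  cat(sprintf("  station sd %.3f, precision %.1f, logLik %.1f, AIC %.1f%s\n",
              x$station_sd, x$precision, x$logLik, x$AIC,
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' @rdname fit_beta_glmm
#' @param x a `cover_fit`
#' @param ... unused
#' @export
tidy.cover_fit <- function(x, ...) x$terms

#' @rdname fit_beta_glmm
#' @export
glance.cover_fit <- function(x, ...) {
  tibble(
    logLik = x$logLik, AIC = x$AIC, df = x$k, nobs = x$n,
    station_sd = x$station_sd, precision = x$precision,
    converged = x$converged
  )
}

#' Univariate screen of the four indicators
#'
#' One beta GLMM per indicator (BAF_previous_year, PA_HEAT, ICI, OCI), each
#' as the unique fixed effect with the station random intercept.
#'
#' @param records cover-record tibble with the four covariate columns
#' @param squeeze see [fit_beta_glmm()]
#' @return named list of 4 `cover_fit`s
#' @export
univariate_screen <- function(records, squeeze = TRUE) {
  covs <- c("baf_previous_year", "pa_heat", "ici", "oci")
  check_cols(records, covs, "records")
  setNames(
    lapply(covs, function(v) fit_beta_glmm(records, v, squeeze)),
    covs
  )
}

#' BAF-by-moderator interaction models
#'
#' Three beta GLMMs, each with fixed effects BAF_previous_year and its
#' product with one moderator (PA_HEAT, ICI or OCI) -- no main effect of the
#' moderator -- plus the station random intercept. Set
#' `moderator_main_effect = TRUE` to add the moderator's main effect.
#'
#' @inheritParams univariate_screen
#' @param moderator_main_effect include the moderator main effect
#' @return named list of 3 `cover_fit`s
#' @export
interaction_models <- function(records, squeeze = TRUE,
                               moderator_main_effect = FALSE) {
  mods <- c("pa_heat", "ici", "oci")
  check_cols(records, c("baf_previous_year", mods), "records")
  setNames(
    lapply(mods, function(m) {
      terms <- c("baf_previous_year",
                 if (moderator_main_effect) m,
                 paste0("baf_previous_year:", m))
      fit_beta_glmm(records, terms, squeeze)
    }),
    paste0("baf_x_", mods)
  )
}

#' Rank fitted models by AIC
#'
#' @param fits named list of `cover_fit`s on identical records
#' @return tibble `model`, `k`, `logLik`, `AIC`, `dAIC`, sorted by AIC
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "cover_fit")))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) > 1) {
    ra_abort("Models were fitted on differing record sets; AIC is not comparable.")
  }
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  tibble(
    model = nm,
    k = unname(vapply(fits, function(f) f$k, numeric(1))),
    logLik = unname(vapply(fits, function(f) f$logLik, numeric(1))),
    AIC = unname(vapply(fits, function(f) f$AIC, numeric(1)))
  ) |>
    arrange(.data$AIC) |>
    mutate(dAIC = .data$AIC - min(.data$AIC))
}
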