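## Genotype-environment association against heat stress.
##
## Per-genotype logistic models of presence vs BAF_overall, leave-one-
## population-out cross-validation with a random-genotype baseline, a pooled
## binomial mixed model across genotypes and species, and the PA_HEAT
## prediction (probability of carrying putatively adaptive variants at a
## given BAF).

## Newton-Raphson ridge logistic on (intercept, slope); the workhorse behind
## fit_genotype_logistic and the cross-validation loops. Penalty is
## ridge * ||beta||^2 subtracted from the Bernoulli log-likelihood.
logistic_ridge_fit <- function(y, x, ridge = 0, maxit = 100, tol = 1e-10) {
  n <- length(y)
  b <- c(0, 0)
  pen <- 2 * ridge
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- b[1] + b[2] * x
    p <- plogis(eta)
    w <- p * (1 - p)
    g <- c(sum(y - p), sum((y - p) * x)) - pen * b
    H <- matrix(c(sum(w) + pen, sum(w * x),
                  sum(w * x), sum(w * x^2) + pen), 2, 2)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    # halve the step while it worsens the penalized log-likelihood
    # log(1 + exp(e)) written overflow-safe
    ll <- function(bb) {
      e <- bb[1] + bb[2] * x
      sum(y * e - (pmax(e, 0) + log1p(exp(-abs(e))))) - ridge * sum(bb^2)
    }
    ll0 <- ll(b)
    lambda <- 1
    repeat {
      bn <- b + lambda * step
      if (ll(bn) >= ll0 - 1e-12 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    b <- bn
    if (max(abs(lambda * step)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- b[1] + b[2] * x
  p <- plogis(eta)
  w <- p * (1 - p)
  H <- matrix(c(sum(w) + pen, sum(w * x),
                sum(w * x), sum(w * x^2) + pen), 2, 2)
  vcov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  list(
    coef = b, vcov = vcov,
    loglik = sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))),
    converged = converged
  )
}

## strict complete separation in one covariate
is_separated <- function(y, x) {
  if (all(y == 1) || all(y == 0)) return(TRUE)
  max(x[y == 1]) < min(x[y == 0]) || max(x[y == 0]) < min(x[y == 1])
}

#' Fit a per-genotype logistic genotype-environment association model
#'
#' Maximizes the Bernoulli log-likelihood of genotype presence with a logit
#' link in BAF, minus an optional ridge penalty `ridge * ||coefficients||^2`.
#' The small default penalty keeps estimates finite under the
#' quasi-separation that extreme sites produce; `ridge = 0` gives the plain
#' MLE and signals non-convergence under complete separation.
#'
#' @param data data frame with columns `presence` (0/1) and `baf`
#' @param ridge ridge penalty lambda (>= 0; default 1e-4)
#' @param genotype_id optional label stored in the fit
#' @return object of class `gea_fit` with `tidy()` and `glance()` methods
#' @export
fit_genotype_logistic <- function(data, ridge = 1e-4, genotype_id = NA_character_) {
  check_cols(data, c("presence", "baf"), "data")
  y <- data$presence
  x <- data$baf
  if (!all(y %in% c(0, 1))) ra_abort("`presence` must be binary 0/1.")
  if (length(unique(x)) < 2) ra_abort("Need at least 2 distinct `baf` values.")
  if (ridge < 0) ra_abort("`ridge` must be >= 0.")
  sep <- is_separated(y, x)
  if (ridge == 0 && !(all(y == 1) || all(y == 0)) && !sep &&
      length(unique(y)) < 2) {
    ra_abort("Both presence classes required when `ridge` is 0.")
  }
  fit <- logistic_ridge_fit(y, x, ridge)
  converged <- fit$converged && !(ridge == 0 && sep)
  if (ridge == 0 && sep) {
    warn("Complete separation: maximum-likelihood estimates do not exist; use ridge > 0.",
         class = "reefadapt_separation")
  }
  structure(
    list(
      genotype_id = genotype_id,
      intercept = fit$coef[1], slope = fit$coef[2],
      vcov = fit$vcov, ridge = ridge, converged = converged,
      loglik = fit$loglik, n = length(y)
    ),
    class = "gea_fit"
  )
}

#' @export
print.gea_fit <- function(x, ...) {
  cat("<gea_fit>", if (!is.na(x$genotype_id)) x$genotype_id else "",
      sprintf("intercept %.3f, slope %.3f (per unit BAF), ridge %g, %s\n",
              x$intercept, x$slope, x$ridge,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @rdname fit_genotype_logistic
#' @param x a `gea_fit`
#' @param ... unused
#' @export
tidy.gea_fit <- function(x, ...) {
  est <- c(x$intercept, x$slope)
  se <- sqrt(diag(x$vcov))
  z <- est / se
  tibble(
    term = c("(Intercept)", "baf"),
    estimate = est, std.error = se, statistic = z,
    p.value = 2 * pnorm(-abs(z))
  )
}

#' @rdname fit_genotype_logistic
#' @export
glance.gea_fit <- function(x, ...) {
  tibble(logLik = x$loglik, nobs = x$n, ridge = x$ridge,
         converged = x$converged)
}

#' Expected genotype frequency at a BAF value
#'
#' @param model a `gea_fit`
#' @param baf numeric BAF value(s)
#' @return expected presence frequency in (0, 1)
#' @export
predict_genotype_frequency <- function(model, baf) {
  stopifnot(inherits(model, "gea_fit"))
  if (!model$converged) {
    ra_abort("Model did not converge; refusing to predict.")
  }
  plogis(model$intercept + model$slope * baf)
}

## observed presence frequency per site for one genotype's rows
.site_freqs <- function(rows) {
  rows |>
    group_by(.data$site_id) |>
    summarise(obs = mean(.data$presence), n = dplyr::n(), .groups = "drop")
}

## leave-one-population-out r for a single genotype (rows joined with baf)
.loo_r_one <- function(rows, ridge) {
  sites <- rows |>
    group_by(.data$site_id, .data$baf) |>
    summarise(obs = mean(.data$presence), .groups = "drop")
  if (nrow(sites) < 3) return(NA_real_)
  if (sd(sites$obs) == 0) return(NA_real_)
  pred <- vapply(seq_len(nrow(sites)), function(k) {
    train <- rows[rows$site_id != sites$site_id[k], ]
    f <- logistic_ridge_fit(train$presence, train$baf, ridge)
    plogis(f$coef[1] + f$coef[2] * sites$baf[k])
  }, numeric(1))
  cor(pred, sites$obs)
}

#' Leave-one-population-out cross-validation of the GEA models
#'
#' For every genotype: refit the logistic model excluding each sampling site
#' in turn, predict the excluded site's genotype frequency from its BAF, and
#' correlate (Pearson) predicted with observed frequencies across sites.
#' Genotypes whose observed frequency does not vary across sites have an
#' undefined r and are reported as NA (excluded from aggregation).
#'
#' @param genotypes tibble with `individual_id`, `site_id`, `species`,
#'   `genotype_id`, `presence`
#' @param site_env tibble `site_id`, `baf`
#' @param ridge ridge penalty for the refits
#' @return tibble `species`, `genotype_id`, `r`, `n_sites`
#' @seealso [cv_summary()] for the per-species mean and sd
#' @export
loo_population_cv <- function(genotypes, site_env, ridge = 1e-4) {
  check_cols(genotypes,
             c("individual_id", "site_id", "species", "genotype_id", "presence"),
             "genotypes")
  check_cols(site_env, c("site_id", "baf"), "site_env")
  dat <- inner_join(genotypes, site_env, by = "site_id")
  if (nrow(dat) == 0) ra_abort("No genotype rows match `site_env` sites.")
  dat |>
    group_by(.data$species, .data$genotype_id) |>
    group_modify(function(rows, key) {
      tibble(
        r = .loo_r_one(rows, ridge),
        n_sites = dplyr::n_distinct(rows$site_id)
      )
    }) |>
    ungroup()
}

#' Per-species summary of cross-validation correlations
#'
#' @param cv tibble from [loo_population_cv()]
#' @return tibble `species`, `mean_r`, `sd_r`, `n_genotypes`, `n_undefined`
#' @export
cv_summary <- function(cv) {
  check_cols(cv, c("species", "r"), "cv")
  cv |>
    group_by(.data$species) |>
    summarise(
      mean_r = mean(.data$r, na.rm = TRUE),
      sd_r = sd(.data$r, na.rm = TRUE),
      n_genotypes = sum(!is.na(.data$r)),
      n_undefined = sum(is.na(.data$r)),
      .groups = "drop"
    )
}

#' Random-genotype cross-validation baseline
#'
#' The same leave-one-population-out procedure applied to genotypes drawn at
#' random (with replacement) from a pool of non-adaptive genotypes; the
#' resulting correlation distribution calibrates how much of the adaptive
#' genotypes' predictability is expected by chance.
#'
#' @param neutral_genotypes genotype tibble (as in [loo_population_cv()])
#'   containing the random pool
#' @param site_env tibble `site_id`, `baf`
#' @param n_draws genotypes drawn per species (default 1000)
#' @param seed integer seed for the draw
#' @param ridge ridge penalty for the refits
#' @return tibble `species`, `mean_r`, `sd_r`, `n_draws`
#' @export
random_genotype_baseline <- function(neutral_genotypes, site_env,
                                     n_draws = 1000, seed = 1, ridge = 1e-4) {
  stopifnot(n_draws >= 1)
  cv <- loo_population_cv(neutral_genotypes, site_env, ridge)
  withr_seed(seed, {
    cv |>
      group_by(.data$species) |>
      group_modify(function(g, key) {
        rs <- g$r[sample.int(nrow(g), n_draws, replace = TRUE)]
        tibble(
          mean_r = mean(rs, na.rm = TRUE),
          sd_r = sd(rs, na.rm = TRUE),
          n_draws = n_draws
        )
      }) |>
      ungroup()
  })
}

#' Pooled genotype-environment mixed model across genotypes and species
#'
#' One binomial-logit mixed model of presence on BAF over all putatively
#' adaptive genotypes, with random intercepts for genotype, individual and
#' species (the Laplace-approximated marginal likelihood, via glmmTMB).
#' Random terms that are unidentifiable on the data at hand (fewer than two
#' levels, or an individual term with a single row per individual) are
#' dropped with a warning and their variance reported as zero.
#'
#' @param genotypes tibble `individual_id`, `site_id`, `species`,
#'   `genotype_id`, `presence` (adaptive genotypes only)
#' @param site_env tibble `site_id`, `baf`
#' @return object of class `pa_model` with `tidy()`/`glance()` methods
#' @export
fit_pooled_glmm <- function(genotypes, site_env) {
  check_cols(genotypes,
             c("individual_id", "site_id", "species", "genotype_id", "presence"),
             "genotypes")
  check_cols(site_env, c("site_id", "baf"), "site_env")
  dat <- inner_join(genotypes, site_env, by = "site_id")
  if (nrow(dat) == 0) ra_abort("No genotype rows match `site_env` sites.")

  re_terms <- c(genotype_id = "genotype_id", individual_id = "individual_id",
                species = "species")
  keep <- vapply(re_terms, function(v) dplyr::n_distinct(dat[[v]]) >= 2,
                 logical(1))
  rows_per_ind <- nrow(dat) / dplyr::n_distinct(dat$individual_id)
  if (keep["individual_id"] && rows_per_ind < 2) {
    keep["individual_id"] <- FALSE
  }
  dropped <- names(re_terms)[!keep]
  if (length(dropped) > 0) {
    warn(paste0(
      "Random term(s) unidentifiable and dropped (variance pinned at 0): ",
      paste(dropped, collapse = ", ")
    ))
  }

  ranef_sd <- setNames(rep(0, 3), names(re_terms))
  if (any(keep)) {
    fml <- stats::as.formula(paste(
      "presence ~ baf +",
      paste(sprintf("(1 | %s)", re_terms[keep]), collapse = " + ")
    ))
    fit <- glmmTMB::glmmTMB(fml, data = dat, family = stats::binomial())
    singular <- grepl("singular convergence", fit$fit$message %||% "")
    conv <- fit$fit$convergence == 0 || singular
    if (singular) {
      warn("Singular convergence: a random-effect variance sits at the zero boundary.",
           class = "reefadapt_boundary")
    }
    if (!isTRUE(fit$sdr$pdHess)) {
      # typical at a zero-variance boundary: point estimates remain usable,
      # standard errors are not
      warn("Hessian not positive definite (variance at boundary?); standard errors are unreliable.",
           class = "reefadapt_boundary")
    }
    vc <- glmmTMB::VarCorr(fit)$cond
    for (nm in names(vc)) ranef_sd[nm] <- attr(vc[[nm]], "stddev")
    fe <- glmmTMB::fixef(fit)$cond
    se <- sqrt(diag(stats::vcov(fit)$cond))
    ll <- as.numeric(logLik(fit))
    aic <- AIC(fit)
  } else {
    fit <- stats::glm(presence ~ baf, data = dat, family = stats::binomial())
    conv <- fit$converged
    fe <- coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    ll <- as.numeric(logLik(fit))
    aic <- AIC(fit)
  }
  if (!conv) {
    warn("Pooled GLMM did not converge cleanly; inspect `$fit`.",
         class = "reefadapt_nonconvergence")
  }
  structure(
    list(
      fit = fit,
      intercept = unname(fe[1]), slope = unname(fe[2]),
      se = unname(se), ranef_sd = ranef_sd,
      converged = conv, n = nrow(dat), logLik = ll, AIC = aic
    ),
    class = "pa_model"
  )
}

#' @export
print.pa_model <- function(x, ...) {
  cat(sprintf(
    "<pa_model> logit(P) = %.3f + %.3f * BAF  (n = %d, %s)\n",
    x$intercept, x$slope, x$n,
    if (x$converged) "converged" else "NOT converged"
  ))
  cat("  random-intercept sd:",
      paste(sprintf("%s %.3f", names(x$ranef_sd), x$ranef_sd),
            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fit_pooled_glmm
#' @param x a `pa_model`
#' @param ... unused
#' @export
tidy.pa_model <- function(x, ...) {
  est <- c(x$intercept, x$slope)
  z <- est / x$se
  tibble(
    term = c("(Intercept)", "baf"),
    estimate = est, std.error = x$se, statistic = z,
    p.value = 2 * pnorm(-abs(z))
  )
}

#' @rdname fit_pooled_glmm
#' @export
glance.pa_model <- function(x, ...) {
  tibble(
    logLik = x$logLik, AIC = x$AIC, nobs = x$n, converged = x$converged,
    sd_genotype = x$ranef_sd[["genotype_id"]],
    sd_individual = x$ranef_sd[["individual_id"]],
    sd_species = x$ranef_sd[["species"]]
  )
}

#' Predict the probability of heat-stress adaptation (PA_HEAT)
#'
#' Population-level prediction (random effects at zero) of the pooled model:
#' `plogis(intercept + slope * BAF)`. A strictly monotone transform of BAF
#' whenever the slope is non-zero.
#'
#' @param model a `pa_model`
#' @param baf numeric BAF values, or a data frame with a `baf_overall` column
#'   (e.g. from [overall_baf()])
#' @return numeric vector, or the data frame with a `pa_heat` column added
#' @export
predict_pa_heat <- function(model, baf) {
  stopifnot(inherits(model, "pa_model"))
  if (!model$converged) ra_abort("Pooled model did not converge; refusing to predict.")
  if (is.data.frame(baf)) {
    check_cols(baf, "baf_overall", "baf")
    return(mutate(baf,
                  pa_heat = plogis(model$intercept +
                                     model$slope * .data$baf_overall)))
  }
  plogis(model$intercept + model$slope * baf)
}
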