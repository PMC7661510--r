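# Genotype-environment association models, cross-validation, pooled GLMM.

make_gea_data <- function(n, intercept, slope, baf = NULL, seed = 1) {
  set.seed(seed)
  baf <- baf %||% runif(n, 0, 0.3)
  tibble::tibble(baf = baf,
                 presence = rbinom(n, 1, plogis(intercept + slope * baf)))
}

test_that("unpenalized fit matches glm and a likelihood grid search", {
  d <- make_gea_data(300, -1, 10, seed = 2)
  f <- fit_genotype_logistic(d, ridge = 0)
  g <- glm(presence ~ baf, data = d, family = binomial())
  expect_equal(c(f$intercept, f$slope), unname(coef(g)), tolerance = 1e-6)
  expect_equal(sqrt(diag(f$vcov)), unname(sqrt(diag(vcov(g)))),
               tolerance = 1e-5)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-8)

  # tiny dataset vs brute-force penalized-likelihood grid (refined twice)
  tiny <- tibble::tibble(baf = c(0, 0.1, 0.2, 0.3, 0.15, 0.05),
                         presence = c(0, 1, 1, 1, 0, 1))
  lam <- 0.05
  f <- fit_genotype_logistic(tiny, ridge = lam)
  pll <- function(b0, b1) {
    eta <- b0 + b1 * tiny$baf
    sum(tiny$presence * eta - log1p(exp(eta))) - lam * (b0^2 + b1^2)
  }
  b0s <- seq(-5, 5, length.out = 201)
  b1s <- seq(-30, 30, length.out = 201)
  for (pass in 1:3) {
    ll <- outer(b0s, b1s, Vectorize(pll))
    i <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    c0 <- b0s[i[1]]; c1 <- b1s[i[2]]
    w0 <- diff(range(b0s)) / 20; w1 <- diff(range(b1s)) / 20
    b0s <- seq(c0 - w0, c0 + w0, length.out = 201)
    b1s <- seq(c1 - w1, c1 + w1, length.out = 201)
  }
  expect_equal(f$intercept, c0, tolerance = 1e-3)
  expect_equal(f$slope, c1, tolerance = 1e-3)
})

test_that("separation is a non-convergence signal at ridge 0 but not with ridge", {
  sep <- tibble::tibble(baf = c(0, 0.05, 0.25, 0.3),
                        presence = c(0, 0, 1, 1))
  expect_warning(f0 <- fit_genotype_logistic(sep, ridge = 0),
                 class = "reefadapt_separation")
  expect_false(f0$converged)
  expect_error(predict_genotype_frequency(f0, 0.1), "converge")

  f1 <- fit_genotype_logistic(sep, ridge = 1e-2)
  expect_true(f1$converged)
  expect_true(is.finite(f1$slope))
})

test_that("predicted frequencies follow the logistic form", {
  m <- structure(list(genotype_id = "g", intercept = 0, slope = 0,
                      vcov = diag(2), ridge = 0, converged = TRUE,
                      loglik = 0, n = 10), class = "gea_fit")
  expect_equal(predict_genotype_frequency(m, c(-1, 0, 2)), rep(0.5, 3))
  m$intercept <- -2; m$slope <- 20
  expect_equal(predict_genotype_frequency(m, 0.1), 0.5)
  p <- predict_genotype_frequency(m, seq(0, 0.3, by = 0.05))
  expect_true(all(diff(p) > 0))
})

test_that("leave-one-population-out CV is near-perfect on model-consistent data", {
  # observed site frequencies placed exactly on a logistic curve
  baf <- seq(0, 0.3, length.out = 8)
  n_per <- 50
  p <- plogis(-2 + 15 * baf)
  rows <- purrr::map_dfr(seq_along(baf), function(s) {
    k <- round(p[s] * n_per)
    tibble::tibble(
      individual_id = paste0("s", s, "_", seq_len(n_per)),
      site_id = paste0("s", s), species = "sp",
      genotype_id = "g1",
      presence = c(rep(1, k), rep(0, n_per - k))
    )
  })
  env <- tibble::tibble(site_id = paste0("s", seq_along(baf)), baf = baf)
  cv <- loo_population_cv(rows, env)
  expect_gt(cv$r, 0.99)
  expect_equal(cv$n_sites, 8)

  # zero-variance genotype reported as NA and excluded from the summary
  flat <- dplyr::mutate(rows, genotype_id = "g2", presence = 1)
  cv2 <- loo_population_cv(dplyr::bind_rows(rows, flat), env)
  expect_true(is.na(cv2$r[cv2$genotype_id == "g2"]))
  s <- cv_summary(cv2)
  expect_equal(s$n_genotypes, 1)
  expect_equal(s$n_undefined, 1)

  # minimal case: 3 sites
  cv3 <- loo_population_cv(
    dplyr::filter(rows, site_id %in% c("s1", "s4", "s8")),
    env
  )
  expect_true(is.finite(cv3$r))
})

test_that("random-genotype baseline is centred near zero and reproducible", {
  sites <- tibble::tibble(site_id = paste0("s", 1:8),
                          baf = seq(0, 0.3, length.out = 8))
  sim <- gen_genotype_data(sites, 40, intercepts = numeric(0),
                           slopes = numeric(0), n_neutral = 40, seed = 21)
  ne <- sim$genotypes
  b1 <- random_genotype_baseline(ne, sites, n_draws = 200, seed = 5)
  b2 <- random_genotype_baseline(ne, sites, n_draws = 200, seed = 5)
  expect_identical(b1, b2)
  # leave-one-out prediction of a no-signal genotype anticorrelates mildly
  # with the observed frequencies, so the baseline sits at or slightly
  # below zero -- never anywhere near the adaptive genotypes' correlations
  expect_lt(b1$mean_r, 0.15)
  expect_gt(b1$mean_r, -0.6)

  single <- random_genotype_baseline(ne, sites, n_draws = 1, seed = 2)
  expect_equal(single$n_draws, 1)
})

test_that("pooled GLMM degenerates to plain logistic and predicts monotone PA", {
  sites <- tibble::tibble(site_id = paste0("s", 1:10),
                          baf = seq(0, 0.3, length.out = 10))
  sim <- gen_genotype_data(sites, 60, intercepts = rep(-2, 5),
                           slopes = rep(15, 5), seed = 31)
  ad <- dplyr::filter(sim$genotypes, adaptive)
  suppressWarnings(pm <- fit_pooled_glmm(ad, sites))
  dat <- dplyr::inner_join(ad, sites, by = "site_id")
  pg <- glm(presence ~ baf, data = dat, family = binomial())
  expect_equal(c(pm$intercept, pm$slope), unname(coef(pg)), tolerance = 1e-2)

  pa <- predict_pa_heat(pm, seq(0, 0.3, by = 0.02))
  expect_true(all(diff(pa) > 0))
  expect_true(all(pa > 0 & pa < 1))

  df <- tibble::tibble(cell_id = 1:3, baf_overall = c(0.0, 0.08, 0.16))
  out <- predict_pa_heat(pm, df)
  expect_true(out$pa_heat[3] > out$pa_heat[2])
  expect_equal(out$pa_heat,
               plogis(pm$intercept + pm$slope * df$baf_overall))

  # single genotype, single species reduces to a plain logistic fit
  one <- dplyr::filter(ad, genotype_id == "sp1_adaptive_1")
  expect_warning(pm1 <- fit_pooled_glmm(one, sites), "unidentifiable")
  expect_equal(unname(pm1$ranef_sd), c(0, 0, 0))
  g1 <- glm(presence ~ baf,
            data = dplyr::inner_join(one, sites, by = "site_id"),
            family = binomial())
  expect_equal(c(pm1$intercept, pm1$slope), unname(coef(g1)),
               tolerance = 1e-6)
})

test_that("tidy and glance expose the fit in broom form", {
  d <- make_gea_data(200, -1, 10, seed = 4)
  f <- fit_genotype_logistic(d)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(td$estimate, c(f$intercept, f$slope))
  expect_true(all(td$p.value > 0 & td$p.value <= 1))
  expect_equal(glance(f)$nobs, 200)
})
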