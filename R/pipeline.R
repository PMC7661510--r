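## Deterministic end-to-end orchestration on synthetic seascapes, plus the
## collated per-reef report. Each stage writes plain CSV artifacts; a JSON
## manifest records every knob, the per-stage seeds and file hashes so runs
## are auditable and reproducible.

default_config <- function() {
  list(
    seed = 1,
    grid = list(n_x = 12, n_y = 10, reef_fraction = 0.15, cell_area_km2 = 25,
                margin = 3),
    sst = list(n_years = 8, start_year = 2001, baseline_temp = 26,
               seasonal_amplitude = 2, noise_sd = 0.05, n_anomalies = 14,
               anomaly_magnitude = 2.5, anomaly_duration = 15),
    thermal = list(window_days = 84, min_excess = 1, first_valid_year = 2003),
    currents = list(drift_east = -0.05, drift_north = 0.02, noise_sd = 0.05,
                    n_days = 20),
    graph = list(epsilon = 0.01, neighborhood = 8),
    indices = list(cdt = NULL, granularity = 10),
    genotypes = list(n_sites = 8, n_per_site = 20, n_adaptive = 4,
                     n_neutral = 30, slope = 15, intercept = -1.5,
                     n_species = 2, ridge = 1e-4, baseline_draws = 100),
    structure = list(n_snps = 60, n_per_site = 12, pca_threshold = 0.8,
                     alpha = 0.05, n_perm = 199, min_samples = 5),
    surveys = list(n_stations = 15, intercept = -0.5, beta_baf_prev = -0.4,
                   station_sd = 0.2, precision = 40)
  )
}

merge_config <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    ra_abort(paste0("Unknown config key(s): ",
                    paste0(path, unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "$"))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults and overrides them with the supplied
#' values; unknown keys are rejected. Every stochastic stage derives its own
#' seed from the global `seed` via [child_seed()].
#'
#' @param ... named overrides, e.g. `seed = 7`,
#'   `grid = list(n_x = 10)`
#' @return a `reef_config` list
#' @export
reef_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(default_config(), user)
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  structure(cfg, class = "reef_config")
}

## diploid genotype calls whose per-site allele frequencies follow a smooth
## function of the supplied spatial basis (e.g. the leading dbMEM axes of the
## seascape distances), so genetic structure mirrors seascape connectivity
gen_diploid_genotypes <- function(sites, basis, n_per_site, n_snps,
                                  n_axes = 2, effect_sd = 1.2, seed = 1) {
  check_cols(sites, "site_id", "sites")
  basis <- as_numeric_matrix(basis)
  stopifnot(nrow(basis) == nrow(sites))
  k <- min(n_axes, ncol(basis))
  Z <- scale(basis[, seq_len(k), drop = FALSE])
  withr_seed(seed, {
    a <- runif(n_snps, -1, 1)
    B <- matrix(rnorm(n_snps * k, 0, effect_sd), k, n_snps)
    P <- plogis(sweep(Z %*% B, 2, a, `+`)) # sites x snps
    purrr::map_dfr(seq_len(nrow(sites)), function(s) {
      tibble(
        individual_id = rep(paste0(sites$site_id[s], "_i", seq_len(n_per_site)),
                            times = n_snps),
        site_id = sites$site_id[s],
        snp_id = rep(paste0("snp", seq_len(n_snps)), each = n_per_site),
        genotype = rbinom(n_per_site * n_snps, 2, rep(P[s, ], each = n_per_site))
      )
    })
  })
}

write_stage <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  readr::write_csv(df, path)
  path
}

#' Run the synthetic seascape pipeline end to end
#'
#' Generates a toy archipelago and runs every stage in order -- thermal
#' metrics, transition graph, connectivity indices, adaptation models,
#' genetic-structure RDA, cover models -- writing all artifacts as CSV plus a
#' JSON manifest (config, per-stage seeds, file hashes). Idempotent: the same
#' config writes byte-identical artifacts.
#'
#' @param config a `reef_config`
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list with the main in-memory results and the
#'   manifest path
#' @export
run_reef_pipeline <- function(config = reef_config(), out_dir) {
  stopifnot(inherits(config, "reef_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- lapply(
    setNames(nm = c("grid", "sst", "currents", "genotypes", "structure",
                    "surveys", "cv", "rda")),
    function(s) child_seed(config$seed, s)
  )
  files <- character(0)

  # --- grid ---------------------------------------------------------------
  g <- config$grid
  grid <- gen_reef_grid(g$n_x, g$n_y, g$reef_fraction, g$cell_area_km2,
                        seed = seeds$grid, margin = g$margin)
  files["grid"] <- write_stage(grid, out_dir, "grid.csv")
  reef_cells <- grid$cell_id[grid$is_reef]

  # --- thermal ------------------------------------------------------------
  s <- config$sst
  th <- config$thermal
  n_days <- 365 * s$n_years
  # marine heatwaves strike in the warm season (around the climatological
  # peak), in random years and cells
  anoms <- withr_seed(seeds$sst, {
    tibble(
      cell_id = sample(reef_cells, s$n_anomalies, replace = TRUE),
      start_day = (sample.int(s$n_years, s$n_anomalies, replace = TRUE) - 1) *
        365 + sample(10:70, s$n_anomalies, replace = TRUE),
      duration = s$anomaly_duration,
      magnitude = s$anomaly_magnitude
    )
  })
  sim_sst <- gen_sst_series(
    grid, s$n_years, s$baseline_temp, s$seasonal_amplitude, anoms,
    noise_sd = s$noise_sd, seed = seeds$sst, start_year = s$start_year
  )
  thermal <- thermal_summary(
    sim_sst$sst, min_excess = th$min_excess, window_days = th$window_days,
    first_valid_year = th$first_valid_year
  )
  files["baf_year"] <- write_stage(thermal$baf_year, out_dir, "baf_year.csv")
  files["baf_overall"] <- write_stage(thermal$baf_overall, out_dir,
                                      "baf_overall.csv")

  # --- graph and indices ----------------------------------------------------
  cu <- config$currents
  uv <- gen_current_field(grid, cu$drift_east, cu$drift_north, cu$noise_sd,
                          cu$n_days, seed = seeds$currents)
  graph <- build_transition_graph(temporal_mean_field(uv),
                                  neighborhood = config$graph$neighborhood,
                                  epsilon = config$graph$epsilon)
  costs <- least_cost_matrix(graph, grid)
  files["cost_matrix"] <- write_stage(costs, out_dir, "cost_matrix.csv")
  borders <- border_distances(graph, grid)
  files["border_distances"] <- write_stage(borders, out_dir,
                                           "border_distances.csv")
  cdt <- config$indices$cdt
  if (is.null(cdt)) {
    m <- border_minima(borders)
    cdt <- select_cdt(m$min_to_border, m$min_from_border,
                      config$indices$granularity)
  }
  idx <- connectivity_indices(costs, grid, cdt)
  files["indices"] <- write_stage(idx, out_dir, "indices.csv")

  # --- adaptation ------------------------------------------------------------
  ge <- config$genotypes
  site_cells <- withr_seed(seeds$genotypes,
                           sample(reef_cells, min(ge$n_sites, length(reef_cells))))
  sites <- grid |>
    filter(.data$cell_id %in% site_cells) |>
    transmute(site_id = paste0("site", .data$cell_id),
              cell_id = .data$cell_id, x = .data$x, y = .data$y) |>
    inner_join(thermal$baf_overall, by = "cell_id")
  site_env <- sites |> select("site_id", baf = "baf_overall")
  sims <- lapply(seq_len(ge$n_species), function(sp) {
    gen_genotype_data(
      site_env, ge$n_per_site,
      intercepts = rep(ge$intercept, ge$n_adaptive),
      slopes = rep(ge$slope, ge$n_adaptive),
      n_neutral = ge$n_neutral, species = paste0("sp", sp),
      seed = child_seed(seeds$genotypes, paste0("species", sp))
    )
  })
  genotypes <- bind_rows(lapply(sims, `[[`, "genotypes"))
  adaptive <- filter(genotypes, .data$adaptive)
  neutral <- filter(genotypes, !.data$adaptive)

  gea <- adaptive |>
    inner_join(site_env, by = "site_id") |>
    group_by(.data$species, .data$genotype_id) |>
    group_modify(function(rows, key) {
      f <- fit_genotype_logistic(rows, ridge = ge$ridge)
      tibble(intercept = f$intercept, slope = f$slope,
             converged = f$converged)
    }) |>
    ungroup()
  files["gea_coefficients"] <- write_stage(gea, out_dir,
                                           "gea_coefficients.csv")

  cv <- loo_population_cv(adaptive, site_env, ridge = ge$ridge)
  baseline <- random_genotype_baseline(neutral, site_env,
                                       n_draws = ge$baseline_draws,
                                       seed = seeds$cv, ridge = ge$ridge)
  cv_report <- cv_summary(cv) |>
    left_join(baseline, by = "species", suffix = c("_adaptive", "_baseline"))
  files["cv_report"] <- write_stage(cv_report, out_dir, "cv_report.csv")

  pa_model <- fit_pooled_glmm(adaptive, site_env)
  pa <- predict_pa_heat(pa_model, thermal$baf_overall)
  files["pa_heat"] <- write_stage(pa, out_dir, "pa_heat.csv")

  # --- genetic structure vs seascape distances ------------------------------
  st <- config$structure
  dmat <- site_cost_distances(graph, sites)
  mems <- dbmem(dmat)
  diploid <- gen_diploid_genotypes(sites, mems, st$n_per_site, st$n_snps,
                                   seed = seeds$structure)
  maf <- site_allele_frequencies(diploid, min_samples = st$min_samples)
  pcs <- pca_cumulative(hellinger_transform(maf), threshold = st$pca_threshold)
  mems <- dbmem(dmat[maf$site_id, maf$site_id])
  sel <- forward_select_rda(pcs, mems, alpha = st$alpha, n_perm = st$n_perm,
                            seed = seeds$rda)
  rda <- if (length(sel) > 0) {
    rda_anova(pcs, mems$vectors[, sel, drop = FALSE],
              n_perm = st$n_perm, seed = seeds$rda)
  } else {
    NULL
  }
  structure_report <- tibble(
    n_sites = nrow(maf),
    n_pcs = sum(startsWith(names(pcs), "PC")),
    n_mems = ncol(mems$vectors),
    selected = paste(sel, collapse = ";"),
    r2 = if (is.null(rda)) NA_real_ else rda$r2,
    adj_r2 = if (is.null(rda)) NA_real_ else rda$adj_r2,
    pseudo_f = if (is.null(rda)) NA_real_ else rda$pseudo_f,
    p_value = if (is.null(rda)) NA_real_ else rda$p_value
  )
  files["structure_report"] <- write_stage(structure_report, out_dir,
                                           "structure_report.csv")

  # --- cover models -----------------------------------------------------------
  sv <- config$surveys
  last_year <- s$start_year + s$n_years - 1
  survey_years <- (th$first_valid_year + 2):last_year
  station_cells <- withr_seed(seeds$surveys, tibble(
    station_id = paste0("st", seq_len(sv$n_stations)),
    cell_id = sample(reef_cells, sv$n_stations, replace = TRUE)
  ))
  surveys <- withr_seed(child_seed(seeds$surveys, "years"), {
    purrr::map_dfr(seq_len(sv$n_stations), function(i) {
      ny <- sample(2:length(survey_years), 1)
      tibble(station_id = station_cells$station_id[i],
             year = sort(sample(survey_years, ny)),
             cover_rate = NA_real_)
    })
  })
  recs <- join_covariates(surveys, station_cells, thermal$baf_year, pa_model,
                          idx, th$first_valid_year)
  recs <- withr_seed(child_seed(seeds$surveys, "cover"), {
    zb <- if (sd(recs$baf_previous_year) > 0) {
      standardize(recs$baf_previous_year)
    } else {
      recs$baf_previous_year * 0
    }
    sta <- rnorm(sv$n_stations, 0, sv$station_sd)
    names(sta) <- station_cells$station_id
    mu <- plogis(sv$intercept + sv$beta_baf_prev * zb + sta[recs$station_id])
    mutate(recs, cover_rate = rbeta(nrow(recs), mu * sv$precision,
                                    (1 - mu) * sv$precision))
  })
  files["cover_records"] <- write_stage(recs, out_dir, "cover_records.csv")

  uni <- univariate_screen(recs)
  inter <- interaction_models(recs)
  ranking <- compare_models(c(uni, inter))
  files["cover_models"] <- write_stage(ranking, out_dir, "cover_models.csv")

  # --- manifest ----------------------------------------------------------------
  manifest <- list(
    package = "reefadapt",
    version = as.character(utils::packageVersion("reefadapt")),
    config = unclass(config),
    seeds = seeds,
    cdt = cdt,
    files = as.list(unname(vapply(files, basename, character(1)))),
    md5 = as.list(setNames(unname(tools::md5sum(files)), basename(files)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(
    grid = grid, thermal = thermal, graph = graph, costs = costs,
    cdt = cdt, indices = idx, gea = gea, cv = cv_report,
    pa_model = pa_model, structure = structure_report,
    cover_ranking = ranking, manifest = manifest_path
  ))
}

#' Collate the per-reef indicator report
#'
#' One row per reef cell with its overall bleaching-alert frequency, the
#' predicted probability of heat-stress adaptation and both connectivity
#' indices, read back from a pipeline artifact directory.
#'
#' @param out_dir directory written by [run_reef_pipeline()]
#' @return tibble `cell_id`, `baf_overall`, `pa_heat`, `oci_km2`, `ici_km2`
#' @export
reef_report <- function(out_dir) {
  need <- c("baf_overall.csv", "pa_heat.csv", "indices.csv")
  missing <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing) > 0) {
    ra_abort(paste0("Missing artifact(s): ", paste(missing, collapse = ", ")))
  }
  rd <- function(f) readr::read_csv(file.path(out_dir, f),
                                    show_col_types = FALSE)
  rd("baf_overall.csv") |>
    inner_join(select(rd("pa_heat.csv"), "cell_id", "pa_heat"),
               by = "cell_id") |>
    inner_join(select(rd("indices.csv"), "cell_id", "oci_km2", "ici_km2"),
               by = "cell_id")
}
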