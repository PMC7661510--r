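# Independent oracles and small fixture builders used across tests.

# exhaustive directed shortest path by depth-first enumeration of simple
# paths with cost pruning (independent of igraph)
bf_shortest <- function(edges, from, to, n_nodes) {
  adj <- split(seq_len(nrow(edges)), edges$from)
  best <- Inf
  visit <- function(node, cost, seen) {
    if (cost >= best) return(invisible())
    if (node == to) {
      best <<- cost
      return(invisible())
    }
    for (e in adj[[as.character(node)]]) {
      nxt <- edges$to[e]
      if (!seen[nxt]) {
        seen[nxt] <- TRUE
        visit(nxt, cost + edges$cost[e], seen)
        seen[nxt] <- FALSE
      }
    }
  }
  seen <- rep(FALSE, n_nodes)
  seen[from] <- TRUE
  visit(from, 0, seen)
  best
}

# long cost tibble -> matrix in cell order
widen_costs <- function(costs, cells) {
  m <- matrix(NA_real_, length(cells), length(cells),
              dimnames = list(cells, cells))
  m[cbind(match(costs$from_cell, cells), match(costs$to_cell, cells))] <-
    costs$cost
  m
}

# a tiny sea world: full grid, mild eastward drift, no mask
small_world <- function(n_x = 4, n_y = 3, drift_u = 0.1, drift_v = 0,
                        epsilon = 0.01, neighborhood = 8, seed = 1) {
  grid <- gen_reef_grid(n_x, n_y, 1.0, 25, seed = seed)
  field <- tibble::tibble(x = grid$x, y = grid$y, u = drift_u, v = drift_v)
  graph <- build_transition_graph(field, neighborhood = neighborhood,
                                  epsilon = epsilon)
  list(grid = grid, field = field, graph = graph)
}

# random current world for property tests
random_world <- function(n_x, n_y, seed, epsilon = 0.01, neighborhood = 8) {
  set.seed(seed)
  grid <- gen_reef_grid(n_x, n_y, 1.0, 25, seed = seed)
  field <- tibble::tibble(
    x = grid$x, y = grid$y,
    u = rnorm(nrow(grid), 0, 0.1), v = rnorm(nrow(grid), 0, 0.1)
  )
  graph <- build_transition_graph(field, neighborhood = neighborhood,
                                  epsilon = epsilon)
  list(grid = grid, field = field, graph = graph)
}

# daily SST tibble for a single cell from a vector of values (365-day years)
sst_from_values <- function(values, cell_id = 1, start_year = 2001) {
  n <- length(values)
  t <- seq_len(n)
  doy <- ((t - 1) %% 365) + 1
  tibble::tibble(
    cell_id = cell_id, t = t,
    year = start_year + (t - 1) %/% 365,
    month = reefadapt:::doy_to_month(doy),
    day_of_year = doy,
    sst = values
  )
}

# hotspot tibble with given positive days (one cell, n days)
hotspot_on_days <- function(days, n, value = 1.5, start_year = 2001) {
  h <- rep(0, n)
  h[days] <- value
  sst_from_values(rep(26, n), start_year = start_year) |>
    dplyr::mutate(hotspot = h)
}

# minimal hand-built transition graph from an explicit edge list
manual_graph <- function(nodes_xy, edges) {
  structure(
    list(
      nodes = tibble::tibble(
        node = seq_len(nrow(nodes_xy)),
        x = nodes_xy[, 1], y = nodes_xy[, 2], u = 0, v = 0
      ),
      edges = edges, resolution_km = 1, epsilon = 0.01, neighborhood = 8
    ),
    class = "transition_graph"
  )
}

# minimal pa_model for plumbing tests
fake_pa_model <- function(intercept = -2, slope = 15) {
  structure(
    list(intercept = intercept, slope = slope, converged = TRUE,
         se = c(0.1, 1), ranef_sd = c(genotype_id = 0, individual_id = 0,
                                      species = 0),
         n = 0, logLik = NA_real_, AIC = NA_real_),
    class = "pa_model"
  )
}

# minimal cover_fit for AIC-arithmetic tests
fake_cover_fit <- function(logLik, k, n = 100) {
  structure(
    list(logLik = logLik, k = k, AIC = 2 * k - 2 * logLik, n = n,
         terms = tibble::tibble(), converged = TRUE, fixed_terms = "x"),
    class = "cover_fit"
  )
}
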