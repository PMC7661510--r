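## Current-driven seascape transition graph and directed least-cost distances.
##
## A current field (temporal mean of daily u/v stacks, optionally resampled
## to a finer grid and land-masked) becomes a directed graph over sea pixels:
## moving with the current is cheap, against it costs up to L / epsilon.
## Directed shortest-path distances between reef cells and to/from the study
## area border feed the connectivity indices.

#' Temporal mean of daily current fields
#'
#' Per-pixel arithmetic mean of eastward (`u`) and northward (`v`) velocity
#' over days, missing days excluded. Pixels with no observation at all are
#' dropped (treated as non-sea).
#'
#' @param uv long tibble with columns `x`, `y`, `day`, `u`, `v`
#' @return tibble `x`, `y`, `u`, `v` (one row per retained pixel)
#' @export
temporal_mean_field <- function(uv) {
  check_cols(uv, c("x", "y", "day", "u", "v"), "uv")
  if (nrow(uv) == 0) ra_abort("`uv` is empty.")
  uv |>
    group_by(.data$x, .data$y) |>
    summarise(
      n_obs = sum(!is.na(.data$u) & !is.na(.data$v)),
      u = mean(.data$u, na.rm = TRUE),
      v = mean(.data$v, na.rm = TRUE),
      .groups = "drop"
    ) |>
    filter(.data$n_obs > 0) |>
    select("x", "y", "u", "v")
}

## infer the (regular) grid spacing of a field from its coordinates
field_spacing <- function(field) {
  ux <- sort(unique(field$x))
  uy <- sort(unique(field$y))
  steps <- c(diff(ux), diff(uy))
  if (length(steps) == 0) ra_abort("Field has a single pixel; no spacing.")
  min(steps)
}

#' Bilinear resampling of a current field to a finer grid
#'
#' Standard bilinear interpolation of `u` and `v` onto a grid refined by an
#' integer factor; values at the source pixel centers are preserved exactly.
#' The field must be rectangular (resample before masking land).
#'
#' @param field tibble `x`, `y`, `u`, `v` on a regular rectangular grid
#' @param factor integer refinement factor (>= 2); the target resolution is
#'   the source resolution divided by `factor`
#' @return tibble `x`, `y`, `u`, `v` on the finer grid
#' @export
resample_bilinear <- function(field, factor) {
  check_cols(field, c("x", "y", "u", "v"), "field")
  if (factor < 2 || factor != round(factor)) {
    ra_abort("`factor` must be an integer >= 2 (target finer than source).")
  }
  ux <- sort(unique(field$x))
  uy <- sort(unique(field$y))
  if (nrow(field) != length(ux) * length(uy)) {
    ra_abort("Field is not rectangular; resample before masking.")
  }
  to_mat <- function(col) {
    m <- matrix(NA_real_, nrow = length(uy), ncol = length(ux))
    m[cbind(match(field$y, uy), match(field$x, ux))] <- field[[col]]
    m
  }
  dx <- if (length(ux) > 1) min(diff(ux)) else 0
  dy <- if (length(uy) > 1) min(diff(uy)) else 0
  xp <- if (dx > 0) seq(min(ux), max(ux), by = dx / factor) else ux
  yp <- if (dy > 0) seq(min(uy), max(uy), by = dy / factor) else uy
  gridp <- tidyr::expand_grid(y = yp, x = xp)
  tibble(
    x = gridp$x,
    y = gridp$y,
    u = pracma::interp2(ux, uy, to_mat("u"), gridp$x, gridp$y, method = "linear"),
    v = pracma::interp2(ux, uy, to_mat("v"), gridp$x, gridp$y, method = "linear")
  )
}

#' Remove land pixels from a current field
#'
#' @param field tibble `x`, `y`, `u`, `v`
#' @param land_mask tibble with columns `x`, `y`, `land` (TRUE/1 = land)
#' @return the field restricted to sea pixels
#' @export
apply_land_mask <- function(field, land_mask) {
  check_cols(field, c("x", "y"), "field")
  check_cols(land_mask, c("x", "y", "land"), "land_mask")
  land <- land_mask |>
    filter(as.logical(.data$land)) |>
    select("x", "y")
  out <- anti_join(field, land, by = c("x", "y"))
  if (nrow(out) == 0) ra_abort("Land mask removed every pixel.")
  out
}

#' Build the directed transition graph over sea pixels
#'
#' For each ordered pair of adjacent sea pixels (i, j) with unit direction
#' d and center distance L (km), the conductance is
#' `max(0, w . d) + epsilon` where w is the mean of the current vectors at i
#' and j (m/s); the edge cost is `L / conductance`. Travelling with the
#' current is cheap; against it the cost is at most L / epsilon. `epsilon`
#' is a base diffusion keeping upstream movement possible and is the main
#' modelling knob of the graph.
#'
#' @param field sea-pixel tibble `x`, `y`, `u`, `v`
#' @param neighborhood 4 or 8 (diagonal steps at L * sqrt(2))
#' @param epsilon base conductance in m/s (> 0)
#' @param resolution_km physical size of one coordinate step in km (default:
#'   the coordinate spacing itself)
#' @return a `transition_graph`: list with `nodes` (tibble `node`, `x`, `y`,
#'   `u`, `v`), `edges` (tibble `from`, `to`, `cost`), and the parameters
#' @export
build_transition_graph <- function(field, neighborhood = 8, epsilon = 0.01,
                                   resolution_km = NULL) {
  check_cols(field, c("x", "y", "u", "v"), "field")
  if (epsilon <= 0) ra_abort("`epsilon` must be > 0 (zero would create infinite costs).")
  if (!neighborhood %in% c(4, 8)) ra_abort("`neighborhood` must be 4 or 8.")
  if (nrow(field) < 2) ra_abort("Need at least 2 sea pixels.")

  spacing <- field_spacing(field)
  if (is.null(resolution_km)) resolution_km <- spacing

  nodes <- field |>
    arrange(.data$y, .data$x) |>
    mutate(node = dplyr::row_number(), .before = 1)

  # integer lattice indices for exact neighbor lookup
  ix <- round((nodes$x - min(nodes$x)) / spacing)
  iy <- round((nodes$y - min(nodes$y)) / spacing)
  key <- paste(ix, iy)
  lookup <- setNames(nodes$node, key)

  steps <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (neighborhood == 8) {
    steps <- c(steps, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  }

  edges <- purrr::map_dfr(steps, function(s) {
    j <- unname(lookup[paste(ix + s[1], iy + s[2])])
    ok <- !is.na(j)
    if (!any(ok)) return(NULL)
    i <- nodes$node[ok]
    j <- j[ok]
    len <- resolution_km * sqrt(sum(s^2))
    dhat <- s / sqrt(sum(s^2))
    wbar_u <- (nodes$u[i] + nodes$u[j]) / 2
    wbar_v <- (nodes$v[i] + nodes$v[j]) / 2
    cond <- pmax(0, wbar_u * dhat[1] + wbar_v * dhat[2]) + epsilon
    tibble(from = i, to = j, cost = len / cond)
  })

  structure(
    list(nodes = nodes, edges = edges, resolution_km = resolution_km,
         epsilon = epsilon, neighborhood = neighborhood),
    class = "transition_graph"
  )
}

#' @export
print.transition_graph <- function(x, ...) {
  cat("<transition_graph> ", nrow(x$nodes), " sea pixels, ",
      nrow(x$edges), " directed edges\n",
      "  neighborhood ", x$neighborhood, ", epsilon ", x$epsilon,
      " m/s, resolution ", x$resolution_km, " km\n", sep = "")
  invisible(x)
}

## igraph view of a transition graph
as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    data.frame(from = graph$edges$from, to = graph$edges$to,
               weight = graph$edges$cost),
    directed = TRUE,
    vertices = data.frame(name = graph$nodes$node)
  )
}

## nearest sea node for each row of a coordinate table; errors naming ids
## beyond the snap radius
snap_to_nodes <- function(graph, pts, ids, snap_radius = NULL) {
  if (is.null(snap_radius)) snap_radius <- 1.5 * field_spacing(graph$nodes)
  nn <- vapply(seq_len(nrow(pts)), function(k) {
    d2 <- (graph$nodes$x - pts$x[k])^2 + (graph$nodes$y - pts$y[k])^2
    i <- which.min(d2)
    if (sqrt(d2[i]) > snap_radius) NA_integer_ else graph$nodes$node[i]
  }, integer(1))
  if (anyNA(nn)) {
    ra_abort(paste0(
      "No sea node within the snap radius for: ",
      paste(ids[is.na(nn)], collapse = ", ")
    ))
  }
  nn
}

#' Directed least-cost distances between reef cells
#'
#' Each reef cell is represented by the sea pixel nearest its centroid; the
#' matrix entry (i, j) is the cost of the cheapest directed path from i's
#' node to j's node. Unreachable pairs carry `Inf`.
#'
#' @param graph a `transition_graph`
#' @param grid reef grid tibble (`cell_id`, `x`, `y`, `is_reef`)
#' @param snap_radius max centroid-to-node distance (coordinate units);
#'   default 1.5 grid steps
#' @return long tibble `from_cell`, `to_cell`, `cost`
#' @export
least_cost_matrix <- function(graph, grid, snap_radius = NULL) {
  check_cols(grid, c("cell_id", "x", "y", "is_reef"), "grid")
  reef <- filter(grid, .data$is_reef)
  if (nrow(reef) == 0) ra_abort("Grid contains no reef cells.")
  nn <- snap_to_nodes(graph, reef, reef$cell_id, snap_radius)
  g <- as_igraph(graph)
  vids <- as.character(nn)
  d <- igraph::distances(g, v = vids, to = vids, mode = "out",
                         algorithm = "dijkstra")
  tibble(
    from_cell = rep(reef$cell_id, each = nrow(reef)),
    to_cell = rep(reef$cell_id, times = nrow(reef)),
    cost = as.vector(t(d))
  )
}

#' Least-cost distances to and from the study-area border
#'
#' For every reef cell, the minimum directed cost to any border node and
#' from any border node. By default the border is the set of sea pixels on
#' the bounding box of the field. The global minima over cells (the
#' quantities that calibrate the connectivity threshold CDt) are attached as
#' attribute `minima` and returned by [border_minima()].
#'
#' @inheritParams least_cost_matrix
#' @param border_nodes integer node ids forming the border (default: sea
#'   pixels on the domain bounding box)
#' @return tibble `cell_id`, `cost_to_border`, `cost_from_border`, with
#'   attribute `minima`
#' @export
border_distances <- function(graph, grid, border_nodes = NULL,
                             snap_radius = NULL) {
  reef <- filter(grid, .data$is_reef)
  if (is.null(border_nodes)) {
    nd <- graph$nodes
    border_nodes <- nd$node[nd$x == min(nd$x) | nd$x == max(nd$x) |
                              nd$y == min(nd$y) | nd$y == max(nd$y)]
  }
  if (length(border_nodes) == 0) ra_abort("Border node set is empty.")
  nn <- snap_to_nodes(graph, reef, reef$cell_id, snap_radius)
  g <- as_igraph(graph)
  vids <- as.character(nn)
  bids <- as.character(border_nodes)
  d_to <- igraph::distances(g, v = vids, to = bids, mode = "out",
                            algorithm = "dijkstra")
  d_from <- igraph::distances(g, v = vids, to = bids, mode = "in",
                              algorithm = "dijkstra")
  out <- tibble(
    cell_id = reef$cell_id,
    cost_to_border = unname(apply(d_to, 1, min)),
    cost_from_border = unname(apply(d_from, 1, min))
  )
  attr(out, "minima") <- list(
    min_to_border = min(out$cost_to_border),
    min_from_border = min(out$cost_from_border)
  )
  out
}

#' Global border-distance minima
#'
#' @param border_dists output of [border_distances()]
#' @return list with `min_to_border` and `min_from_border`
#' @export
border_minima <- function(border_dists) {
  m <- attr(border_dists, "minima")
  if (is.null(m)) {
    m <- list(min_to_border = min(border_dists$cost_to_border),
              min_from_border = min(border_dists$cost_from_border))
  }
  m
}
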