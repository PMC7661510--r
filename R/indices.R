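## Per-reef dispersal indices from the least-cost matrix.
##
## OCI (outbound connectivity index): total area of the reef cells a focal
## cell can reach within the cost-distance threshold CDt. ICI (inbound): the
## total area of the cells that can reach it. CDt is calibrated against the
## border distances so a cell's dispersal neighborhood never spills over the
## edge of the study area.

#' Select the cost-distance threshold (CDt)
#'
#' The largest multiple of `granularity` strictly below the smaller of the
#' two border minima: the widest neighborhood extent that cannot produce
#' border effects. With border minima of 836 and 801 cost units and the
#' default granularity of 100 this yields 800 units.
#'
#' @param min_to_border,min_from_border global minima over reef cells of the
#'   least-cost distance to / from the study-area border (cost units)
#' @param granularity rounding step in cost units (default 100)
#' @return the threshold CDt in cost units
#' @examples
#' select_cdt(836, 801) # 800
#' @export
select_cdt <- function(min_to_border, min_from_border, granularity = 100) {
  stopifnot(is.numeric(min_to_border), is.numeric(min_from_border),
            granularity > 0)
  if (min_to_border <= 0 || min_from_border <= 0) {
    ra_abort("Border minima must be positive.")
  }
  m <- min(min_to_border, min_from_border)
  if (m <= granularity) {
    ra_abort("Border minima too small: no positive multiple of `granularity` lies strictly below them.")
  }
  cdt <- floor(m / granularity) * granularity
  if (cdt >= m) cdt <- cdt - granularity
  cdt
}

## shared worker: total neighbor area within cdt along one direction
.index_one_way <- function(costs, areas, cdt, focal_col, other_col,
                           include_self) {
  x <- costs |>
    filter(is.finite(.data$cost), .data$cost <= cdt)
  if (!include_self) {
    x <- filter(x, .data$from_cell != .data$to_cell)
  }
  x |>
    inner_join(areas, by = setNames("cell_id", other_col)) |>
    group_by(cell_id = .data[[focal_col]]) |>
    summarise(index = sum(.data$area_km2), .groups = "drop") |>
    tidyr::complete(cell_id = areas$cell_id, fill = list(index = 0)) |>
    arrange(match(.data$cell_id, areas$cell_id))
}

#' Outbound connectivity index (OCI)
#'
#' Total area (km^2) of the reef cells reachable from the focal cell within
#' the cost-distance threshold. The focal cell itself is excluded by default.
#'
#' @param costs long tibble `from_cell`, `to_cell`, `cost` from
#'   [least_cost_matrix()]
#' @param grid reef grid with `cell_id`, `area_km2`, `is_reef`
#' @param cdt cost-distance threshold (> 0)
#' @param include_self count the focal cell's own area (default FALSE)
#' @return tibble `cell_id`, `oci_km2`
#' @export
outbound_index <- function(costs, grid, cdt, include_self = FALSE) {
  check_cols(costs, c("from_cell", "to_cell", "cost"), "costs")
  stopifnot(cdt > 0)
  areas <- grid |> filter(.data$is_reef) |> select("cell_id", "area_km2")
  .index_one_way(costs, areas, cdt, "from_cell", "to_cell", include_self) |>
    rename(oci_km2 = "index")
}

#' Inbound connectivity index (ICI)
#'
#' Total area (km^2) of the reef cells that can reach the focal cell within
#' the cost-distance threshold.
#'
#' @inheritParams outbound_index
#' @return tibble `cell_id`, `ici_km2`
#' @export
inbound_index <- function(costs, grid, cdt, include_self = FALSE) {
  check_cols(costs, c("from_cell", "to_cell", "cost"), "costs")
  stopifnot(cdt > 0)
  areas <- grid |> filter(.data$is_reef) |> select("cell_id", "area_km2")
  .index_one_way(costs, areas, cdt, "to_cell", "from_cell", include_self) |>
    rename(ici_km2 = "index")
}

#' Both connectivity indices in one table
#'
#' @inheritParams outbound_index
#' @return tibble `cell_id`, `oci_km2`, `ici_km2`, `cdt`
#' @export
connectivity_indices <- function(costs, grid, cdt, include_self = FALSE) {
  outbound_index(costs, grid, cdt, include_self) |>
    inner_join(inbound_index(costs, grid, cdt, include_self),
               by = "cell_id") |>
    mutate(cdt = cdt)
}
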