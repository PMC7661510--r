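# Transition graph and directed least-cost distances.

test_that("temporal mean field averages pixels and drops empty ones", {
  uv <- tidyr::expand_grid(x = 1:2, y = 1, day = 1:4) |>
    dplyr::mutate(u = ifelse(day %% 2 == 0, 1, -1), v = 0.5)
  f <- temporal_mean_field(uv)
  expect_equal(f$u, c(0, 0))
  expect_equal(f$v, c(0.5, 0.5))

  one <- temporal_mean_field(dplyr::filter(uv, day == 1))
  expect_equal(one$u, c(-1, -1))

  uv2 <- uv
  uv2$u[uv2$x == 2] <- NA
  expect_equal(nrow(temporal_mean_field(uv2)), 1)
})

test_that("bilinear resampling preserves constants, ramps and centers", {
  f <- tidyr::expand_grid(x = 1:3, y = 1:3) |>
    dplyr::mutate(u = 0.2, v = -0.1)
  r <- resample_bilinear(f, 2)
  expect_true(all(r$u == 0.2) && all(r$v == -0.1))
  expect_equal(nrow(r), 25)

  ramp <- tidyr::expand_grid(x = 1:3, y = 1:3) |>
    dplyr::mutate(u = x, v = y)
  r <- resample_bilinear(ramp, 2)
  expect_equal(r$u, r$x)
  expect_equal(r$v, r$y)

  sq <- tibble::tibble(x = c(1, 2, 1, 2), y = c(1, 1, 2, 2),
                       u = c(0, 1, 1, 2), v = 0)
  r <- resample_bilinear(sq, 2)
  expect_equal(r$u[r$x == 1.5 & r$y == 1.5], 1)

  expect_error(resample_bilinear(f, 1), "factor")
})

test_that("land mask removes pixels and can split the domain", {
  w <- small_world(5, 1, drift_u = 0)
  field <- w$field
  expect_identical(
    apply_land_mask(field, dplyr::mutate(field, land = FALSE)),
    field
  )
  masked <- apply_land_mask(field, dplyr::mutate(field, land = x == 3))
  expect_equal(nrow(masked), 4)
  g <- build_transition_graph(masked, neighborhood = 4, epsilon = 0.01)
  expect_false(any(g$nodes$x == 3))
  cm <- least_cost_matrix(g, w$grid[w$grid$x != 3, ])
  across <- dplyr::filter(cm, from_cell == 1, to_cell == 5)
  expect_true(is.infinite(across$cost))

  expect_error(apply_land_mask(field, dplyr::mutate(field, land = TRUE)),
               "every pixel")
})

test_that("edge costs follow the downstream-conductance formula", {
  w <- small_world(4, 1, drift_u = 0.1, epsilon = 0.01, neighborhood = 4)
  e <- w$graph$edges
  east <- dplyr::filter(e, to == from + 1)
  west <- dplyr::filter(e, to == from - 1)
  expect_equal(unique(east$cost), 1 / 0.11)
  expect_equal(unique(west$cost), 1 / 0.01)

  still <- small_world(3, 3, drift_u = 0, epsilon = 0.02)
  e <- still$graph$edges
  expect_true(all(abs(e$cost - ifelse(
    abs(still$graph$nodes$x[e$from] - still$graph$nodes$x[e$to]) +
      abs(still$graph$nodes$y[e$from] - still$graph$nodes$y[e$to]) == 2,
    sqrt(2) / 0.02, 1 / 0.02
  )) < 1e-12))

  expect_error(build_transition_graph(w$field, epsilon = 0),
               "epsilon")
})

test_that("least-cost distances match manual and brute-force oracles", {
  # 3 nodes, direct A->C more expensive than via B
  g <- manual_graph(
    cbind(c(0, 10, 20), c(0, 0, 0)),
    tibble::tibble(from = c(1, 2, 1), to = c(2, 3, 3), cost = c(1, 2, 4))
  )
  grid <- tibble::tibble(cell_id = 1:3, x = c(0, 10, 20), y = 0,
                         area_km2 = 25, is_reef = TRUE)
  cm <- least_cost_matrix(g, grid, snap_radius = 1)
  m <- widen_costs(cm, 1:3)
  expect_equal(m["1", "3"], 3)
  expect_equal(diag(m), c(`1` = 0, `2` = 0, `3` = 0))
  expect_true(is.infinite(m["3", "1"]))

  # random sparse worlds vs exhaustive path enumeration
  for (s in 1:20) {
    w <- random_world(3, 3, seed = s)
    cm <- least_cost_matrix(w$graph, w$grid)
    reef_nodes <- w$graph$nodes$node
    for (pair in list(c(1, 9), c(9, 1), c(2, 7))) {
      expect_equal(
        widen_costs(cm, w$grid$cell_id)[pair[1], pair[2]],
        bf_shortest(w$graph$edges, pair[1], pair[2], nrow(w$graph$nodes)),
        tolerance = 1e-10
      )
    }
  }
})

test_that("current reversal transposes the cost matrix", {
  for (s in 1:5) {
    w <- random_world(4, 3, seed = 100 + s)
    cm <- least_cost_matrix(w$graph, w$grid)
    rev_field <- dplyr::mutate(w$field, u = -u, v = -v)
    cm_rev <- least_cost_matrix(
      build_transition_graph(rev_field, neighborhood = 8, epsilon = 0.01),
      w$grid
    )
    m1 <- widen_costs(cm, w$grid$cell_id)
    m2 <- widen_costs(cm_rev, w$grid$cell_id)
    expect_equal(m1, t(m2))
  }
})

test_that("directed triangle inequality holds", {
  w <- random_world(4, 3, seed = 77)
  m <- widen_costs(least_cost_matrix(w$graph, w$grid), w$grid$cell_id)
  n <- nrow(m)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(m[i, k], m[i, j] + m[j, k] + 1e-9)
  }
})

test_that("stronger drift shortens downstream and lengthens upstream paths", {
  weak <- small_world(5, 2, drift_u = 0.05)
  strong <- small_world(5, 2, drift_u = 0.2)
  mw <- widen_costs(least_cost_matrix(weak$graph, weak$grid),
                    weak$grid$cell_id)
  ms <- widen_costs(least_cost_matrix(strong$graph, strong$grid),
                    strong$grid$cell_id)
  east_pairs <- which(outer(weak$grid$x, weak$grid$x, `<`), arr.ind = TRUE)
  expect_true(all(ms[east_pairs] <= mw[east_pairs] + 1e-12))
  west_pairs <- east_pairs[, 2:1]
  expect_true(all(ms[west_pairs] >= mw[west_pairs] - 1e-12))
})

test_that("border distances are directional and symmetric without current", {
  still <- small_world(5, 5, drift_u = 0, epsilon = 0.01)
  bd <- border_distances(still$graph, still$grid)
  expect_equal(bd$cost_to_border, bd$cost_from_border)

  # interior reef one step from border: distance = one step cost
  grid <- still$grid
  grid$is_reef <- grid$x == 2 & grid$y == 2
  bd <- border_distances(still$graph, grid)
  expect_equal(bd$cost_to_border, 1 / 0.01)

  expect_error(border_distances(still$graph, grid, border_nodes = integer(0)),
               "empty")

  # brute force on a small drifted world
  w <- random_world(3, 3, seed = 12)
  grid <- w$grid
  grid$is_reef <- grid$cell_id == 5
  bd <- border_distances(w$graph, grid)
  border <- w$graph$nodes$node[w$graph$nodes$x %in% c(1, 3) |
                                 w$graph$nodes$y %in% c(1, 3)]
  oracle_to <- min(vapply(border, function(b) {
    bf_shortest(w$graph$edges, 5, b, 9)
  }, numeric(1)))
  oracle_from <- min(vapply(border, function(b) {
    bf_shortest(w$graph$edges, b, 5, 9)
  }, numeric(1)))
  expect_equal(bd$cost_to_border, oracle_to, tolerance = 1e-10)
  expect_equal(bd$cost_from_border, oracle_from, tolerance = 1e-10)
})
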