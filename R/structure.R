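## Genetic structure vs seascape connectivity.
##
## Response side: per-site minor-allele frequencies -> Hellinger transform ->
## PCA kept to 80% cumulative variance. Predictor side: symmetrized least-
## cost distances between sampling sites -> distance-based Moran's
## eigenvector maps (dbMEM, the classical PCNM construction). The two meet in
## a redundancy analysis with forward selection and a permutation anova.

#' Per-site minor-allele frequencies
#'
#' Genotypes are diploid allele counts (0/1/2 copies of the counted allele).
#' The minor allele is defined globally across all sites; per retained site
#' the frequency is (copies of the minor allele) / (2 * called samples).
#' Sites with fewer samples than `min_samples` are dropped.
#'
#' @param genotypes long tibble `individual_id`, `site_id`, `snp_id`,
#'   `genotype` (0/1/2, NA allowed)
#' @param min_samples site retention threshold (default 5)
#' @return wide tibble: `site_id`, `n_samples`, one column per SNP; dropped
#'   sites listed in attribute `dropped_sites`
#' @export
site_allele_frequencies <- function(genotypes, min_samples = 5) {
  check_cols(genotypes, c("individual_id", "site_id", "snp_id", "genotype"),
             "genotypes")
  g <- genotypes
  if (!all(g$genotype %in% c(0, 1, 2, NA))) {
    ra_abort("`genotype` must be allele counts 0, 1 or 2 (NA allowed).")
  }
  n_by_site <- g |>
    group_by(.data$site_id) |>
    summarise(n_samples = dplyr::n_distinct(.data$individual_id),
              .groups = "drop")
  kept <- n_by_site |> filter(.data$n_samples >= min_samples)
  dropped <- setdiff(n_by_site$site_id, kept$site_id)
  if (nrow(kept) == 0) ra_abort("All sites fall below the sample threshold.")

  # orient each SNP to its globally minor allele
  glob <- g |>
    filter(!is.na(.data$genotype)) |>
    group_by(.data$snp_id) |>
    summarise(p = sum(.data$genotype) / (2 * dplyr::n()), .groups = "drop") |>
    mutate(flip = .data$p > 0.5)

  freqs <- g |>
    filter(.data$site_id %in% kept$site_id, !is.na(.data$genotype)) |>
    group_by(.data$site_id, .data$snp_id) |>
    summarise(freq = sum(.data$genotype) / (2 * dplyr::n()),
              .groups = "drop") |>
    left_join(select(glob, "snp_id", "flip"), by = "snp_id") |>
    mutate(freq = ifelse(.data$flip, 1 - .data$freq, .data$freq)) |>
    select(-"flip") |>
    tidyr::pivot_wider(names_from = "snp_id", values_from = "freq")

  out <- kept |>
    inner_join(freqs, by = "site_id") |>
    relocate("site_id", "n_samples")
  attr(out, "dropped_sites") <- dropped
  out
}

#' Hellinger transformation
#'
#' Each entry becomes the square root of its share of the row total, so the
#' squared entries of every row sum to 1 and Euclidean distances between rows
#' become ecologically meaningful.
#'
#' @param freqs data frame of non-negative values; columns named in
#'   `id_cols` are carried through untouched
#' @param id_cols identifier columns to exclude from the transform
#' @return the transformed data frame
#' @export
hellinger_transform <- function(freqs, id_cols = intersect(
                                  c("site_id", "n_samples"), names(freqs))) {
  num_cols <- setdiff(names(freqs), id_cols)
  m <- as.matrix(freqs[num_cols])
  if (any(m < 0, na.rm = TRUE)) ra_abort("Negative entries are not allowed.")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    offenders <- if ("site_id" %in% names(freqs)) {
      freqs$site_id[rs == 0]
    } else {
      which(rs == 0)
    }
    ra_abort(paste0("All-zero row(s): ", paste(offenders, collapse = ", ")))
  }
  freqs[num_cols] <- sqrt(m / rs)
  freqs
}

#' Principal components up to a cumulative-variance threshold
#'
#' Column-centers the matrix and returns the smallest leading set of
#' principal-component scores whose cumulative share of total variance
#' reaches `threshold` (default 0.80).
#'
#' @param x data frame; `id_cols` carried through
#' @param threshold cumulative variance proportion in (0, 1]
#' @param id_cols identifier columns excluded from the decomposition
#' @return data frame of id columns plus PC score columns; eigenvalues and
#'   variance shares in attributes `eigenvalues`, `var_explained`
#' @export
pca_cumulative <- function(x, threshold = 0.80, id_cols = intersect(
                             c("site_id", "n_samples"), names(x))) {
  if (threshold <= 0 || threshold > 1) {
    ra_abort("`threshold` must be in (0, 1].")
  }
  m <- as.matrix(x[setdiff(names(x), id_cols)])
  if (nrow(m) < 2) ra_abort("Need at least 2 rows for a PCA.")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  share <- cumsum(ev) / sum(ev)
  k <- which(share >= threshold - 1e-12)[1]
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  out <- bind_cols(x[id_cols], scores)
  attr(out, "eigenvalues") <- ev
  attr(out, "var_explained") <- share
  out
}

#' Symmetrized least-cost distances between sampling sites
#'
#' Directed least-cost distances are computed both ways between every pair of
#' sites (each mapped to its nearest sea node) and reconciled into one
#' symmetric matrix: by default the arithmetic mean of the two directions
#' (`min` and `max` available).
#'
#' @param graph a `transition_graph`
#' @param sites tibble `site_id`, `x`, `y`
#' @param symmetrize one of "mean", "min", "max"
#' @param snap_radius see [least_cost_matrix()]
#' @return symmetric matrix with site ids as dimnames
#' @export
site_cost_distances <- function(graph, sites, symmetrize = c("mean", "min", "max"),
                                snap_radius = NULL) {
  check_cols(sites, c("site_id", "x", "y"), "sites")
  symmetrize <- match.arg(symmetrize)
  nn <- snap_to_nodes(graph, sites, sites$site_id, snap_radius)
  g <- as_igraph(graph)
  vids <- as.character(nn)
  d <- igraph::distances(g, v = vids, to = vids, mode = "out",
                         algorithm = "dijkstra")
  if (any(!is.finite(d))) {
    ra_abort("Unreachable site pair: dbMEM requires finite distances.")
  }
  s <- switch(symmetrize,
              mean = (d + t(d)) / 2,
              min = pmin(d, t(d)),
              max = pmax(d, t(d)))
  dimnames(s) <- list(sites$site_id, sites$site_id)
  s
}

## longest edge of the minimum spanning tree of a symmetric distance matrix
## (Prim's algorithm; n sites is small)
mst_longest_edge <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  longest <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    longest <- max(longest, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  longest
}

#' Distance-based Moran's eigenvector maps (dbMEM / PCNM)
#'
#' Classical construction: distances above the truncation threshold (the
#' longest edge of the minimum spanning tree, keeping the truncated graph
#' connected) are replaced by four times the threshold; the truncated matrix
#' is double-centered (-D^2/2 metric) and eigen-decomposed; eigenvectors with
#' positive eigenvalues, scaled by the square root of their eigenvalue, form
#' orthogonal spatial predictors.
#'
#' @param d symmetric distance matrix with zero diagonal (>= 3 sites)
#' @param truncation optional threshold overriding the MST rule
#' @return object of class `dbmem_basis`: list with `vectors` (sites x axes
#'   matrix), `values` (eigenvalues) and `truncation`
#' @export
dbmem <- function(d, truncation = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 3) ra_abort("dbMEM needs at least 3 sites.")
  if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0)) {
    ra_abort("`d` must be symmetric with a zero diagonal.")
  }
  t0 <- truncation %||% mst_longest_edge(d)
  dt <- d
  dt[dt > t0] <- 4 * t0
  diag(dt) <- 0
  # principal coordinates of the truncated matrix
  a <- -0.5 * dt^2
  n <- nrow(a)
  cmat <- diag(n) - matrix(1 / n, n, n)
  gmat <- cmat %*% a %*% cmat
  e <- eigen((gmat + t(gmat)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  keep <- e$values > tol
  vectors <- sweep(e$vectors[, keep, drop = FALSE], 2,
                   sqrt(e$values[keep]), `*`)
  colnames(vectors) <- paste0("MEM", seq_len(ncol(vectors)))
  rownames(vectors) <- rownames(d)
  structure(
    list(vectors = vectors, values = e$values[keep], truncation = t0),
    class = "dbmem_basis"
  )
}

#' @export
print.dbmem_basis <- function(x, ...) {
  cat("<dbmem_basis>", ncol(x$vectors), "positive-eigenvalue axes over",
      nrow(x$vectors), "sites; truncation", signif(x$truncation, 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.dbmem_basis <- function(x, ...) as.data.frame(x$vectors)

## coerce Y/X arguments (tibble with ids, dbmem_basis, matrix) to a plain
## numeric matrix
as_numeric_matrix <- function(x) {
  if (inherits(x, "dbmem_basis")) return(x$vectors)
  if (is.data.frame(x)) {
    x <- x[vapply(x, is.numeric, logical(1))]
    return(as.matrix(x))
  }
  as.matrix(x)
}

## core RDA fit: multivariate least squares of centered Y on centered X
rda_core <- function(Y, X) {
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  qr_x <- qr(Xc)
  fitted <- qr.fitted(qr_x, Yc)
  ss_tot <- sum(Yc^2)
  ss_fit <- sum(fitted^2)
  list(
    fitted = fitted, ss_tot = ss_tot, ss_fit = ss_fit,
    r2 = ss_fit / ss_tot, n = nrow(Yc), m = qr_x$rank
  )
}

adj_r2 <- function(r2, n, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)

## pseudo-F for an RDA fit; a numerically zero residual gives F = Inf
rda_f <- function(core) {
  resid <- max(0, core$ss_tot - core$ss_fit)
  if (resid <= core$ss_tot * 1e-12) return(Inf)
  (core$ss_fit / core$m) / (resid / (core$n - core$m - 1))
}

#' Redundancy analysis with a permutation anova
#'
#' Regresses the (centered) multivariate response on the predictors; the
#' canonical axes are the principal components of the fitted values. Global
#' significance comes from unrestricted row permutations of the response:
#' p = (1 + #permuted F >= observed F) / (n_perm + 1).
#'
#' @param Y response (data frame / matrix of PC scores; id columns ignored)
#' @param X predictors (data frame, matrix or `dbmem_basis`)
#' @param n_perm number of permutations (default 999, i.e. 1000 including
#'   the observed ordering)
#' @param seed integer seed for the permutations
#' @return object of class `rda_result` with `tidy()`/`glance()` methods:
#'   selected predictors, R2, adjusted R2, pseudo-F, p-value, site scores
#' @export
rda_anova <- function(Y, X, n_perm = 999, seed = 1) {
  Ym <- as_numeric_matrix(Y)
  Xm <- as_numeric_matrix(X)
  if (nrow(Ym) != nrow(Xm)) ra_abort("Y and X must have the same rows.")
  n <- nrow(Ym)
  if (ncol(Xm) >= n - 1) ra_abort("Model saturated: as many predictors as residual df.")
  core <- rda_core(Ym, Xm)
  f_obs <- rda_f(core)
  perm_f <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      rda_f(rda_core(Ym[sample.int(n), , drop = FALSE], Xm))
    }, numeric(1))
  })
  p <- (1 + sum(perm_f >= f_obs)) / (n_perm + 1)
  sv <- svd(core$fitted)
  k <- sum(sv$d > max(sv$d) * 1e-9)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  colnames(scores) <- paste0("RDA", seq_len(k))
  structure(
    list(
      predictors = colnames(Xm) %||% paste0("X", seq_len(ncol(Xm))),
      r2 = core$r2,
      adj_r2 = max(0, adj_r2(core$r2, n, core$m)),
      pseudo_f = f_obs, p_value = p, n_perm = n_perm,
      site_scores = scores, n = n, m = core$m
    ),
    class = "rda_result"
  )
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf(
    "<rda_result> %d predictor(s); R2 = %.3f, adj R2 = %.3f, pseudo-F = %.2f, p = %.4g (%d permutations)\n",
    x$m, x$r2, x$adj_r2, x$pseudo_f, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' @rdname rda_anova
#' @param x an `rda_result`
#' @param ... unused
#' @export
tidy.rda_result <- function(x, ...) {
  tibble(predictor = x$predictors)
}

#' @rdname rda_anova
#' @export
glance.rda_result <- function(x, ...) {
  tibble(
    r.squared = x$r2, adj.r.squared = x$adj_r2, statistic = x$pseudo_f,
    p.value = x$p_value, n_perm = x$n_perm, n_sites = x$n,
    n_predictors = x$m
  )
}

#' Forward selection of dbMEM predictors for the RDA
#'
#' Greedy forward selection with the standard double stopping rule plus a
#' global pre-test: selection starts only if the full model (all candidates)
#' is itself significant at `alpha` under the permutation anova -- the
#' safeguard that keeps the procedure's type-I error near nominal. At each
#' step the candidate giving the largest adjusted-R2 increase is admitted if
#' its marginal permutation p-value (partial F of the added term, unrestricted
#' row permutations of Y) is at most `alpha` and the running adjusted R2
#' stays at or below the full-model adjusted R2. May select the empty set.
#'
#' @param Y response (PC scores)
#' @param X candidate predictors (`dbmem_basis`, data frame or matrix)
#' @param alpha admission threshold on the marginal permutation p-value
#' @param n_perm permutations per admission test
#' @param seed integer seed
#' @param global_test run the full-model significance gate first (default
#'   TRUE)
#' @return character vector of selected predictor names (possibly empty),
#'   with the selection path in attribute `path`
#' @export
forward_select_rda <- function(Y, X, alpha = 0.05, n_perm = 999, seed = 1,
                               global_test = TRUE) {
  Ym <- as_numeric_matrix(Y)
  Xm <- as_numeric_matrix(X)
  if (is.null(colnames(Xm))) colnames(Xm) <- paste0("X", seq_len(ncol(Xm)))
  n <- nrow(Ym)
  full_core <- rda_core(Ym, Xm)
  full_adj <- adj_r2(full_core$r2, n, min(full_core$m, n - 2))
  if (global_test && ncol(Xm) < n - 1) {
    gl <- rda_anova(Ym, Xm, n_perm = n_perm, seed = child_seed(seed, "global"))
    if (gl$p_value > alpha) {
      return(structure(character(0), path = tibble(),
                       full_adj_r2 = full_adj, global_p = gl$p_value))
    }
  }

  selected <- character(0)
  path <- list()
  cur_adj <- 0
  withr_seed(seed, {
    repeat {
      remaining <- setdiff(colnames(Xm), selected)
      if (length(remaining) == 0) break
      if (length(selected) + 1 >= n - 1) break
      cand_adj <- vapply(remaining, function(v) {
        cc <- rda_core(Ym, Xm[, c(selected, v), drop = FALSE])
        adj_r2(cc$r2, n, cc$m)
      }, numeric(1))
      best <- remaining[which.max(cand_adj)]
      best_adj <- max(cand_adj)
      if (best_adj <= cur_adj + 1e-9 || best_adj > full_adj + 1e-12) break

      # marginal permutation test of the added term given the current set
      Xnew <- Xm[, c(selected, best), drop = FALSE]
      part_f <- function(Yp) {
        c0 <- if (length(selected) > 0) {
          rda_core(Yp, Xm[, selected, drop = FALSE])$ss_fit
        } else {
          0
        }
        c1 <- rda_core(Yp, Xnew)
        added <- max(0, c1$ss_fit - c0)
        if (added <= c1$ss_tot * 1e-12) return(0)
        resid <- max(0, c1$ss_tot - c1$ss_fit)
        if (resid <= c1$ss_tot * 1e-12) return(Inf)
        added / (resid / (c1$n - c1$m - 1))
      }
      f_obs <- part_f(Ym)
      f_perm <- vapply(seq_len(n_perm), function(i) {
        part_f(Ym[sample.int(n), , drop = FALSE])
      }, numeric(1))
      p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
      path[[length(path) + 1]] <- tibble(
        predictor = best, adj_r2 = best_adj, p_value = p
      )
      if (p > alpha) break
      selected <- c(selected, best)
      cur_adj <- best_adj
    }
  })
  structure(selected, path = bind_rows(path), full_adj_r2 = full_adj)
}
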