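# MAF -> Hellinger -> PCA response; dbMEM predictors; forward-selected RDA.

test_that("site allele frequencies use the global minor allele and the sample filter", {
  g <- tibble::tibble(
    individual_id = paste0("i", 1:5), site_id = "A",
    snp_id = "snp1", genotype = c(0, 1, 2, 1, 1)
  )
  out <- site_allele_frequencies(g, min_samples = 5)
  expect_equal(out$snp1, 0.5)

  # site with 4 samples is excluded and reported
  g2 <- dplyr::bind_rows(g, tibble::tibble(
    individual_id = paste0("j", 1:4), site_id = "B",
    snp_id = "snp1", genotype = c(0, 0, 1, 1)
  ))
  out2 <- site_allele_frequencies(g2, min_samples = 5)
  expect_equal(out2$site_id, "A")
  expect_equal(attr(out2, "dropped_sites"), "B")
  expect_error(site_allele_frequencies(g, min_samples = 10), "threshold")

  # monomorphic SNP: frequency 0 everywhere
  mono <- tidyr::expand_grid(individual_id = paste0("i", 1:6),
                             site_id = c("A")) |>
    dplyr::mutate(snp_id = "m", genotype = 0)
  expect_equal(site_allele_frequencies(mono)$m, 0)

  # the globally major allele is flipped to its minor complement
  maj <- tibble::tibble(
    individual_id = rep(paste0("i", 1:5), 2),
    site_id = rep(c("A", "B"), each = 5),
    snp_id = "s", genotype = c(2, 2, 2, 1, 2, 2, 2, 2, 2, 1)
  )
  out3 <- site_allele_frequencies(maj)
  expect_equal(out3$s, c(1 - 9 / 10, 1 - 9 / 10))
})

test_that("Hellinger transform normalizes rows to unit sum of squares", {
  m <- tibble::tibble(site_id = c("a", "b"), s1 = c(4, 1), s2 = c(0, 1),
                      s3 = c(0, 2))
  h <- hellinger_transform(m)
  expect_equal(unlist(h[1, -1], use.names = FALSE), c(1, 0, 0))
  expect_equal(unlist(h[2, -1], use.names = FALSE),
               c(0.5, 0.5, sqrt(0.5)))

  set.seed(3)
  big <- as.data.frame(matrix(runif(20 * 7), 20, 7))
  hb <- hellinger_transform(big, id_cols = character(0))
  expect_equal(rowSums(as.matrix(hb)^2), rep(1, 20))

  zero <- tibble::tibble(site_id = "z", s1 = 0, s2 = 0)
  expect_error(hellinger_transform(zero), "z")
})

test_that("PCA keeps the minimal axes reaching the variance threshold", {
  # construct scores with planted variance shares 0.6 / 0.2 / 0.2
  set.seed(8)
  n <- 40
  base <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  X <- base %*% diag(sqrt(c(0.6, 0.2, 0.2) * (n - 1)))
  df <- as.data.frame(X)
  out <- pca_cumulative(df, threshold = 0.8, id_cols = character(0))
  expect_equal(ncol(out), 2)

  X1 <- base %*% diag(sqrt(c(0.9, 0.06, 0.04) * (n - 1)))
  out1 <- pca_cumulative(as.data.frame(X1), threshold = 0.8,
                         id_cols = character(0))
  expect_equal(ncol(out1), 1)

  # all PCs reconstruct the centered matrix
  full <- pca_cumulative(df, threshold = 1, id_cols = character(0))
  pc <- prcomp(as.matrix(df))
  recon <- as.matrix(full) %*% t(pc$rotation)
  expect_equal(recon, scale(as.matrix(df), scale = FALSE),
               ignore_attr = TRUE, tolerance = 1e-10)

  expect_error(pca_cumulative(df, threshold = 1.2, id_cols = character(0)),
               "threshold")
})

test_that("site cost distances are symmetrized as requested", {
  g <- manual_graph(
    cbind(c(0, 10), c(0, 0)),
    tibble::tibble(from = c(1, 2), to = c(2, 1), cost = c(2, 4))
  )
  sites <- tibble::tibble(site_id = c("A", "B"), x = c(0, 10), y = 0)
  expect_equal(site_cost_distances(g, sites, snap_radius = 1)["A", "B"], 3)
  expect_equal(site_cost_distances(g, sites, "min", snap_radius = 1)["A", "B"], 2)
  expect_equal(site_cost_distances(g, sites, "max", snap_radius = 1)["A", "B"], 4)

  still <- small_world(4, 4, drift_u = 0)
  sites <- tibble::tibble(site_id = paste0("s", 1:3),
                          x = c(1, 4, 2), y = c(1, 4, 3))
  d <- site_cost_distances(still$graph, sites)
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 3), sites$site_id))

  disc <- manual_graph(
    cbind(c(0, 10), c(0, 0)),
    tibble::tibble(from = 1, to = 2, cost = 1)
  )
  expect_error(site_cost_distances(disc, sites[1:2, ] |>
                                     dplyr::mutate(x = c(0, 10), y = 0),
                                   snap_radius = 1),
               "Unreachable")
})

test_that("dbMEM matches vegan's pcnm and a hand PCoA on 3 points", {
  # 3 equidistant collinear points: hand-computable double centering
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  mb <- dbmem(d)
  expect_equal(mb$truncation, 1)
  dt <- d; dt[dt > 1] <- 4
  a <- -0.5 * dt^2
  cmat <- diag(3) - matrix(1 / 3, 3, 3)
  ev <- eigen(cmat %*% a %*% cmat, symmetric = TRUE)
  keep <- ev$values > 1e-9 * max(ev$values)
  hand <- sweep(ev$vectors[, keep, drop = FALSE], 2,
                sqrt(ev$values[keep]), `*`)
  expect_equal(abs(mb$vectors), abs(hand), ignore_attr = TRUE,
               tolerance = 1e-8)

  skip_if_not_installed("vegan")
  set.seed(9)
  xy <- matrix(runif(24), 12, 2)
  dd <- as.matrix(dist(xy))
  mb <- dbmem(dd)
  pv <- vegan::pcnm(as.dist(dd))
  expect_equal(mb$truncation, pv$threshold)
  expect_equal(ncol(mb$vectors), sum(pv$values > 1e-9 * max(pv$values)))
  expect_equal(mb$values, pv$values[pv$values > 1e-9 * max(pv$values)],
               tolerance = 1e-8)

  # columns centered, orthogonal; doubling distances keeps directions
  v <- mb$vectors
  expect_equal(colMeans(v), rep(0, ncol(v)), ignore_attr = TRUE,
               tolerance = 1e-10)
  cp <- crossprod(v)
  expect_equal(cp - diag(diag(cp)), matrix(0, ncol(v), ncol(v)),
               ignore_attr = TRUE, tolerance = 1e-8)
  mb2 <- dbmem(2 * dd)
  cors <- vapply(seq_len(ncol(v)), function(j) {
    abs(cor(mb$vectors[, j], mb2$vectors[, j]))
  }, numeric(1))
  expect_true(all(cors > 1 - 1e-8))

  expect_error(dbmem(matrix(0, 2, 2)), "3 sites")
})

test_that("RDA matches vegan and its own closed forms", {
  set.seed(1)
  n <- 15
  X <- matrix(rnorm(n * 3), n, 3)
  colnames(X) <- paste0("MEM", 1:3)
  B <- matrix(c(1, 0, 0, 0, 2, 0), 3, 2)
  Y <- X %*% B + matrix(rnorm(n * 2, sd = 0.3), n, 2)
  r <- rda_anova(Y, X, n_perm = 499, seed = 2)

  # closed-form adjusted R2
  expect_equal(r$adj_r2, 1 - (1 - r$r2) * (n - 1) / (n - 3 - 1))

  skip_if_not_installed("vegan")
  v <- vegan::rda(Y ~ X)
  expect_equal(r$r2, vegan::RsquareAdj(v)$r.squared, tolerance = 1e-10)
  expect_equal(r$adj_r2, vegan::RsquareAdj(v)$adj.r.squared,
               tolerance = 1e-10)
  av <- vegan::anova.cca(v, permutations = 499)
  expect_equal(r$pseudo_f, av$F[1], tolerance = 1e-10)
})

test_that("noiseless response gives the extreme permutation p-value", {
  set.seed(4)
  X <- matrix(rnorm(12 * 2), 12, 2)
  Y <- X %*% matrix(c(1, -1, 2, 0), 2, 2)
  r <- rda_anova(Y, X, n_perm = 199, seed = 3)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  expect_equal(r$p_value, 1 / 200)
  expect_error(rda_anova(Y[1:3, ], X[1:3, ]), "saturated")
})

test_that("forward selection recovers a planted axis and respects the null", {
  set.seed(10)
  X <- matrix(rnorm(20 * 6), 20, 6)
  colnames(X) <- paste0("MEM", 1:6)
  Y <- cbind(2 * X[, 1], -X[, 1])
  sel <- forward_select_rda(Y, X, alpha = 0.05, n_perm = 199, seed = 1)
  expect_equal(as.character(sel), "MEM1")

  # fixed seed: identical selection
  sel2 <- forward_select_rda(Y, X, alpha = 0.05, n_perm = 199, seed = 1)
  expect_identical(as.character(sel), as.character(sel2))

  # null response: mostly empty selections
  empty <- 0
  for (i in 1:20) {
    set.seed(200 + i)
    Yn <- matrix(rnorm(20 * 3), 20, 3)
    if (length(forward_select_rda(Yn, X, alpha = 0.05, n_perm = 99,
                                  seed = i)) == 0) {
      empty <- empty + 1
    }
  }
  expect_gte(empty, 15)
})

test_that("the Hellinger-PCA-RDA pipeline is invariant to SNP column order", {
  set.seed(12)
  freqs <- tibble::tibble(site_id = paste0("s", 1:10)) |>
    dplyr::bind_cols(as.data.frame(matrix(runif(10 * 6), 10, 6)))
  X <- matrix(rnorm(10 * 2), 10, 2)

  run <- function(f) {
    pcs <- pca_cumulative(hellinger_transform(f), threshold = 0.8)
    r <- rda_anova(pcs, X, n_perm = 99, seed = 5)
    c(r$r2, r$adj_r2, r$pseudo_f, r$p_value)
  }
  shuffled <- freqs[, c("site_id", sample(names(freqs)[-1]))]
  expect_equal(run(freqs), run(shuffled), tolerance = 1e-10)
})
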