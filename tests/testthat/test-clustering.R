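# Weighted geographic-abundance dissimilarity, PAM, CLARA.

pts <- function(lat, lon, ab, cell_id = seq_along(lat) - 1L) {
  data.frame(cell_id = cell_id, lat = lat, lon = lon, abundance = ab)
}

test_that("dissimilarity is symmetric, zero on identical points, and scale-aware", {
  p2 <- pts(c(3, 3), c(7, 7), c(5, 5))
  expect_equal(as.vector(build_dissimilarity(p2)), 0)

  set.seed(1)
  pr <- pts(runif(10), runif(10), runif(10, 1, 2))
  D <- as.matrix(build_dissimilarity(pr))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 10))

  # two points differing only in abundance by the full range, weight 1/3:
  # scaled coordinates are (0,0,0) and (0,0,1/3), distance exactly 1/3
  pa <- pts(c(1, 1), c(2, 2), c(4, 10))
  expect_equal(as.vector(build_dissimilarity(pa, 1 / 3)), 1 / 3)

  expect_error(build_dissimilarity(pts(1, 1, 0)), "occupied")
})

test_that("PAM with k = n is perfect and matches exhaustive search on small n", {
  set.seed(2)
  p <- pts(runif(6), runif(6), runif(6, 1, 2))
  D <- build_dissimilarity(p)
  fit <- pam_medoids(D, 6)
  expect_equal(fit$objective, 0)
  expect_setequal(fit$medoids, 1:6)

  # well-separated triplets: PAM must find the exact optimum
  p3 <- pts(lat = c(0, 0.1, 0.2, 10, 10.1, 10.2, 20, 20.1, 20.2),
            lon = rep(0, 9), ab = rep(1, 9))
  D3 <- build_dissimilarity(p3)
  fit3 <- pam_medoids(D3, 3)
  oracle <- brute_force_medoids(D3, 3)
  expect_equal(fit3$objective, oracle$objective, tolerance = 1e-12)
  expect_equal(sort(unique(fit3$clustering[1:3])), 1)
  expect_equal(length(unique(fit3$clustering[c(1, 4, 7)])), 3)

  expect_error(pam_medoids(D3, 10), "exceed")
})

test_that("PAM beats random medoid sets", {
  set.seed(3)
  p <- pts(runif(30), runif(30), runif(30, 1, 5))
  D <- build_dissimilarity(p)
  dm <- as.matrix(D)
  fit <- pam_medoids(D, 4)
  for (trial in 1:20) {
    med <- sample(30, 4)
    obj <- sum(apply(dm[, med, drop = FALSE], 1, min))
    expect_lte(fit$objective, obj + 1e-12)
  }
})

test_that("CLARA equals PAM when the subsample is the full set, and never beats brute force", {
  set.seed(4)
  p <- pts(runif(12), runif(12), runif(12, 1, 3))
  cfg <- clustering_config(k = 3, sample_size = 50, seed = 5)
  cla <- clara(p, cfg)
  pam_fit <- pam_medoids(build_dissimilarity(p), 3)
  expect_equal(cla$total_dissimilarity, pam_fit$objective, tolerance = 1e-12)
  expect_setequal(cla$medoid_cell_ids, p$cell_id[pam_fit$medoids])

  oracle <- brute_force_medoids(build_dissimilarity(p), 3)
  expect_gte(cla$total_dissimilarity, oracle$objective - 1e-12)

  expect_error(clara(p, clustering_config(k = 3, sample_size = 2)), "at least k")
  expect_error(clara(p[1:2, ], clustering_config(k = 3)), "fewer points")
})

test_that("CLARA produces k non-empty clusters partitioning the points", {
  set.seed(6)
  p <- pts(runif(60, 0, 10), runif(60, 0, 10), runif(60, 1, 4))
  cfg <- clustering_config(k = 5, seed = 7)
  res <- clara(p, cfg)
  expect_equal(sort(unique(res$cluster)), 1:5)
  expect_equal(length(res$cluster), 60)
  expect_equal(sum(res$abundance_share), 1, tolerance = 1e-12)
  expect_true(all(res$medoid_cell_ids %in% p$cell_id))
  # medoids belong to their own clusters
  med_cl <- res$cluster[match(res$medoid_cell_ids, p$cell_id)]
  expect_setequal(med_cl, 1:5)
})

test_that("point order does not change the partition", {
  set.seed(8)
  p <- pts(runif(50, 0, 5), runif(50, 0, 5), runif(50, 1, 2))
  cfg <- clustering_config(k = 4, seed = 9)
  r1 <- clara(p, cfg)
  shuffle <- sample(50)
  r2 <- clara(p[shuffle, ], cfg)
  m1 <- r1$cluster[order(r1$cell_id)]
  m2 <- r2$cluster[order(r2$cell_id)]
  # same partition up to label names: co-membership matrices agree
  expect_identical(outer(m1, m1, "=="), outer(m2, m2, "=="))
  expect_identical(sort(r1$medoid_cell_ids), sort(r2$medoid_cell_ids))
})

test_that("raising the abundance weight flips clusters from geographic to abundance strata", {
  # two sites x two abundance levels
  p <- pts(lat = c(0, 0, 10, 10), lon = c(0, 0, 10, 10),
           ab = c(1, 100, 1, 100), cell_id = 0:3)
  geo <- clara(p, clustering_config(k = 2, abundance_weight = 0, seed = 1))
  expect_identical(geo$cluster[1], geo$cluster[2])
  expect_identical(geo$cluster[3], geo$cluster[4])
  strat <- clara(p, clustering_config(k = 2, abundance_weight = 50, seed = 1))
  expect_identical(strat$cluster[1], strat$cluster[3])
  expect_identical(strat$cluster[2], strat$cluster[4])
  expect_false(strat$cluster[1] == strat$cluster[2])
})

test_that("weekly clustering is deterministic and falls back below k cells", {
  g <- tiny_grid(5, 5)
  cube <- stationary_cube(g, n_weeks = 2)
  cfg <- clustering_config(k = 3, seed = 10)
  cl <- cluster_weekly(cube, cfg)
  a1 <- cl[["spA"]][[1]]; a2 <- cl[["spA"]][[2]]
  expect_identical(a1$cluster, a2$cluster)       # identical surfaces
  expect_identical(a1$medoid_cell_ids, a2$medoid_cell_ids)
  expect_equal(sort(unique(a1$cluster)), 1:3)

  # a week with fewer occupied cells than k collapses to one cluster
  vals <- array(0, dim = c(1, 1, n_cells(g)))
  vals[1, 1, 1:2] <- c(5, 5)
  sparse <- abundance_cube(vals, g, "spB", 1L)
  expect_warning(clb <- cluster_weekly(sparse, cfg), "one cluster")
  expect_equal(clb[["spB"]][[1]]$k, 1)
  expect_true(all(clb[["spB"]][[1]]$cluster == 1))
})

test_that("optional rebalancing nudges shares toward equality", {
  set.seed(11)
  # one heavy blob, one light blob
  p <- pts(lat = c(runif(30, 0, 1), runif(30, 9, 10)),
           lon = runif(60), ab = c(runif(30, 5, 6), runif(30, 0.5, 1)))
  base <- clara(p, clustering_config(k = 2, seed = 12))
  reb <- clara(p, clustering_config(k = 2, seed = 12, rebalance = TRUE))
  spread <- function(s) max(s) - min(s)
  expect_lte(spread(reb$abundance_share), spread(base$abundance_share))
})
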