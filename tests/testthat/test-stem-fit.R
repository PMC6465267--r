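# Base-model support rules, ensemble prediction and its closed-form limit.

# Hand-built checklists: n events at grid cell centers on given days, with
# fixed unit effort so expected count = abundance at the cell.
manual_checklists <- function(grid, n, counts, days = NULL, seed = 1) {
  set.seed(seed)
  cells <- sample(n_cells(grid), n, replace = TRUE) - 1L
  if (is.null(days)) days <- sample.int(60, n, replace = TRUE)
  data.frame(
    checklist_id = seq_len(n),
    lat = grid$cells$lat[cells + 1], lon = grid$cells$lon[cells + 1],
    cell_id = cells, day_of_year = days,
    week = pmin(ceiling(days / 7), 52),
    year = 2010L, start_time = 7, duration_h = 1, distance_km = 1,
    party_size = 1L, species_id = "spX",
    count = counts(cells, days)
  )
}

one_block_design <- function(grid, n_partitions = 1, seed = 1) {
  # an extent far north of the split, smaller than one 10-degree block
  design_ensemble(grid_extent(grid), n_partitions = n_partitions, seed = seed)
}

test_that("blocks below the checklist or detection minimum produce no base model", {
  g <- tiny_grid(3, 3, 8.4, origin = c(30, -90))
  des <- one_block_design(g)
  cfg <- stem_config(min_support = 1)

  cl49 <- manual_checklists(g, 49, function(cells, days) rep(1L, 49),
                            days = rep(10L, 49))
  expect_warning(f <- fit_stem(cl49, "spX", des, cfg, grid = g),
                 "no spatiotemporal block")
  expect_equal(f$n_models, 0)

  # 50+ training checklists but only 9 detections
  mk <- function(n, n_det) {
    manual_checklists(g, n, function(cells, days)
      c(rep(1L, n_det), rep(0L, n - n_det)), days = rep(10L, n))
  }
  expect_warning(f9 <- fit_stem(mk(60, 9), "spX", des, cfg, grid = g,
                                seed = 2),
                 "no spatiotemporal block")
  expect_equal(f9$n_models, 0)

  f10 <- fit_stem(mk(80, 20), "spX", des, cfg, grid = g, seed = 2)
  expect_gte(f10$n_models, 1)
})

test_that("with one block of constant detections the estimate is the product formula", {
  g <- tiny_grid(3, 3, 8.4, origin = c(30, -90))
  des <- one_block_design(g)
  cfg <- stem_config(min_support = 1)
  # every checklist detects exactly 3 birds -> occupancy 1, conditional
  # abundance 3, ensemble estimate 3
  cl <- manual_checklists(g, 100, function(cells, days) rep(3L, 100),
                          days = rep(10L, 100))
  fit <- fit_stem(cl, "spX", des, cfg, grid = g)
  est <- predict_abundance(fit, g, weeks = 2)   # day 11, same block
  expect_equal(as.vector(est$values), rep(3, n_cells(g)), tolerance = 1e-3)
})

test_that("estimates are missing wherever support is below the threshold", {
  g <- tiny_grid(3, 3, 8.4, origin = c(30, -90))
  des <- one_block_design(g, n_partitions = 10)
  cl <- manual_checklists(g, 500, function(cells, days) rep(2L, 500),
                          days = sample.int(60, 500, replace = TRUE))
  cfg50 <- stem_config(min_support = 50)
  fit <- fit_stem(cl, "spX", des, cfg50, grid = g)
  est <- predict_abundance(fit, g, weeks = 2)
  # at most 10 partitions can contribute: support < 50 everywhere
  expect_true(all(is.na(est$values)))
  expect_true(all(est$support <= 10))

  cfg5 <- stem_config(min_support = 5)
  fit5 <- fit_stem(cl, "spX", des, cfg5, grid = g)
  est5 <- predict_abundance(fit5, g, weeks = 2)
  expect_true(all(!is.na(est5$values)))
})

test_that("restricting partitions never increases support (monotonicity)", {
  g <- tiny_grid(4, 4, 8.4, origin = c(30, -90))
  des <- one_block_design(g, n_partitions = 8)
  cl <- manual_checklists(g, 800, function(cells, days)
    rpois(800, 1 + cells / 8), days = sample.int(90, 800, replace = TRUE),
    seed = 5)
  cfg <- stem_config(min_support = 1)
  fit <- fit_stem(cl, "spX", des, cfg, grid = g)
  full <- predict_abundance(fit, g, weeks = 1:4)
  half <- predict_abundance(fit, g, weeks = 1:4, partitions = 1:4)
  expect_true(all(half$support <= full$support))
  expect_true(all(full$support <= 8))
  expect_true(all(full$values >= 0, na.rm = TRUE))
})

test_that("a tree base learner recovers a step-function abundance surface", {
  g <- make_planning_grid(4, 8, 8.4, origin = c(30, -90))
  des <- one_block_design(g)
  cfg <- stem_config(learner = "tree", min_support = 1)
  split_col <- 4
  truth <- function(cells) ifelse(cells %% 8 >= split_col, 5L, 1L)
  cl <- manual_checklists(g, 400, function(cells, days) truth(cells),
                          days = rep(15L, 400))
  fit <- fit_stem(cl, "spX", des, cfg, grid = g)
  est <- predict_abundance(fit, g, weeks = 2)
  expect_equal(as.vector(est$values), truth(0:(n_cells(g) - 1)),
               tolerance = 0.15)
})

test_that("the holdout is withheld from training and summarised honestly", {
  g <- tiny_grid(4, 4, 8.4, origin = c(30, -90))
  des <- one_block_design(g)
  cfg <- stem_config(min_support = 1, holdout_fraction = 0.2)
  cl <- manual_checklists(g, 200, function(cells, days) rpois(200, 2),
                          days = rep(10L, 200), seed = 8)
  fit <- fit_stem(cl, "spX", des, cfg, grid = g)
  expect_equal(nrow(fit$holdout), 40)
  v <- validate_stem(fit, g)
  expect_equal(v$n, 40)
  expect_true(is.finite(v$mae))
})
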