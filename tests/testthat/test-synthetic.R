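# Synthetic landscape generators: species cubes, checklists, costs,
# land cover.

test_that("weekly abundance totals are conserved and cubes are seeded", {
  g <- tiny_grid(6, 6)
  cube <- simulate_community(g, n_species = 3, total_abundance = 250,
                             n_weeks = 52, seed = 5)
  totals <- apply(cube$values, c(1, 2), sum)
  expect_equal(as.vector(totals), rep(250, 3 * 52), tolerance = 1e-6)
  cube2 <- simulate_community(g, n_species = 3, total_abundance = 250,
                              n_weeks = 52, seed = 5)
  expect_identical(cube$values, cube2$values)
})

test_that("a non-moving species with no roughness has identical weekly surfaces", {
  g <- tiny_grid(5, 5)
  cube <- stationary_cube(g, n_weeks = 52)
  for (w in 2:52) {
    expect_equal(cube$values[1, w, ], cube$values[1, 1, ])
  }
})

test_that("route length must match the weeks simulated", {
  g <- tiny_grid()
  p <- species_params("x", 10, matrix(c(14, -85), 1, 2,
                                      dimnames = list(NULL, c("lat", "lon"))),
                      spread_km = 10)
  cube <- simulate_species(p, g, seed = 1)
  expect_equal(length(cube$weeks), 1L)  # one route row -> one week
  expect_error(species_params("x", 10, matrix(1, 2, 3), 10), "lat, lon")
  expect_error(species_params("x", -1, matrix(1, 1, 2), 10), "positive")
})

test_that("checklists have one row per species per event and honor empties", {
  g <- tiny_grid(4, 4)
  cube <- simulate_community(g, n_species = 2, n_weeks = 4, seed = 2)
  cl <- simulate_checklists(cube, 100, seed = 3)
  expect_equal(nrow(cl), 200)
  expect_true(all(cl$count >= 0 & cl$count == round(cl$count)))
  expect_true(all(cl$duration_h > 0 & cl$distance_km > 0 & cl$party_size >= 1))
  expect_true(all(cl$day_of_year >= 1 & cl$day_of_year <= 366))

  zero <- abundance_cube(array(0, dim = c(1, 2, n_cells(g))), g, "z", 1:2)
  clz <- simulate_checklists(zero, 50, seed = 4)
  expect_true(all(clz$count == 0))
})

test_that("Monte-Carlo mean count matches the closed form under certain detection", {
  g <- make_planning_grid(1, 1, 8.4)
  a <- 5
  cube <- abundance_cube(array(a, dim = c(1, 1, 1)), g, "s", 1L)
  em <- effort_model(occ_intercept = Inf, detect_per_person = 1,
                     duration_meanlog = log(2), duration_sdlog = 0,
                     distance_meanlog = log(3), distance_sdlog = 0)
  n <- 10000
  cl <- simulate_checklists(cube, n, effort = em, detection_scale = 0.4,
                            seed = 99)
  mu <- expected_count(a, duration_h = 2, distance_km = 3,
                       detection_scale = 0.4)
  se <- sd(cl$count) / sqrt(n)
  expect_lt(abs(mean(cl$count) - mu), 3 * se)
})

test_that("simulated counts carry the abundance signal (positive slope)", {
  g <- tiny_grid(8, 8)
  cube <- simulate_community(g, n_species = 1, total_abundance = 400,
                             n_weeks = 8, seed = 6)
  cl <- simulate_checklists(cube, 10000, seed = 7)
  truth <- cube$values[cbind(1, cl$week, cl$cell_id + 1)]
  fit <- lm(cl$count ~ truth)
  expect_gt(coef(fit)[2], 0)
  expect_lt(summary(fit)$coefficients[2, 4], 1e-6)
})

test_that("cost surfaces match their mode contracts", {
  g <- tiny_grid(6, 6)
  u <- make_cost_surface(g, "uniform")
  expect_true(all(u$cost == 1))
  f1 <- make_cost_surface(g, "footprint", seed = 8)
  f2 <- make_cost_surface(g, "footprint", seed = 8)
  expect_identical(f1$cost, f2$cost)
  expect_gte(min(f1$cost), 0)
  expect_lte(max(f1$cost), 50)
  expect_error(make_cost_surface(g, "road"))
})

test_that("land cover classes follow the configured mixing proportions", {
  g <- tiny_grid(5, 5)
  lc1 <- make_landcover(g, n_classes = 1, fine_factor = 4, seed = 1)
  expect_true(all(lc1$classes == 1))

  props <- c(0.5, 0.3, 0.2)
  lc <- make_landcover(make_planning_grid(10, 10, 8.4), n_classes = 3,
                       fine_factor = 10, seed = 2, proportions = props)
  n <- length(lc$classes)
  expect_gte(n, 10000)
  for (k in 1:3) {
    phat <- mean(lc$classes == k)
    se <- sqrt(props[k] * (1 - props[k]) / n)
    expect_lt(abs(phat - props[k]), 3 * se)
  }
  # fine resolution: factor 28 on 8.4 km cells gives 0.3 km pixels
  lc28 <- make_landcover(tiny_grid(2, 2), n_classes = 2, fine_factor = 28,
                         seed = 3)
  expect_equal(lc28$fine_cell_size_km, 0.3)
})

test_that("generators leave the caller's RNG stream untouched", {
  g <- tiny_grid(4, 4)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(make_cost_surface(g, "footprint", seed = 5))
  invisible(make_landcover(g, 3, 4, seed = 5))
  after <- runif(1)
  expect_identical(before, after)
})
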