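# Feature construction and the Minimize cx s.t. Ax >= b assembly.

test_that("feature counts follow the approach: species weekly, species-week yearly", {
  g <- make_planning_grid(1, 4, 8.4)
  set.seed(1)
  vals <- array(runif(117 * 52 * 4, 0.1, 1), dim = c(117, 52, 4))
  cube <- abundance_cube(vals, g, sprintf("sp%03d", 1:117), 1:52)
  weekly <- build_features(cube, approach = "weekly", week = 7)
  expect_equal(nrow(weekly), 117)
  yearly <- build_features(cube, approach = "yearly")
  expect_equal(nrow(yearly), 117 * 52)
})

test_that("a 30% target on a 100-individual week asks for 30 individuals", {
  g <- tiny_grid(5, 5)
  cube <- stationary_cube(g, n_weeks = 4, total = 100)
  feats <- build_features(cube, approach = "yearly", target_proportion = 0.30)
  expect_equal(feats$total_abundance, rep(100, 4), tolerance = 1e-9)
  expect_equal(feats$target_level, rep(30, 4), tolerance = 1e-9)
})

test_that("clustered features partition each species-week's representation", {
  g <- tiny_grid(6, 6)
  cube <- simulate_community(g, n_species = 2, n_weeks = 2, seed = 3)
  clusters <- cluster_weekly(cube, clustering_config(k = 3, seed = 4))
  single <- build_features(cube, approach = "yearly")
  clustered <- build_features(cube, clusters = clusters, approach = "yearly")
  expect_equal(nrow(clustered), 2 * 2 * 3)
  # cluster features of one species-week sum to the single feature
  for (sp in c("sp01", "sp02")) {
    for (w in 1:2) {
      tot_cl <- sum(clustered$total_abundance[clustered$species_id == sp &
                                                clustered$week == w])
      tot_single <- single$total_abundance[single$species_id == sp &
                                             single$week == w]
      expect_equal(tot_cl, tot_single, tolerance = 1e-9)
    }
  }
})

test_that("problems carry costs, sparse representation and build-time feasibility flags", {
  g <- make_planning_grid(1, 3, 8.4)
  vals <- array(0, dim = c(1, 1, 3))
  vals[1, 1, ] <- c(60, 30, 10)
  cube <- abundance_cube(vals, g, "s", 1L)
  feats <- build_features(cube, approach = "weekly", week = 1,
                          target_proportion = 0.3)
  prob <- build_problem(feats, make_cost_surface(g, "uniform"))
  expect_equal(prob$c, rep(1, 3))
  expect_equal(as.vector(prob$A), c(60, 30, 10))
  expect_equal(prob$b, 30)
  expect_false(any(prob$infeasible))

  # an unreachable target is flagged when the problem is built
  feats2 <- build_features(cube, approach = "weekly", week = 1,
                           target_proportion = 1.5)
  expect_warning(prob2 <- build_problem(feats2,
                                        make_cost_surface(g, "uniform")),
                 "infeasible")
  expect_true(all(prob2$infeasible))
  expect_equal(solve_bruteforce(prob2)$status, "infeasible")

  # single feature, single cell holding everything
  g1 <- make_planning_grid(1, 1, 8.4)
  cube1 <- abundance_cube(array(42, dim = c(1, 1, 1)), g1, "s", 1L)
  p1 <- build_problem(build_features(cube1, approach = "weekly", week = 1),
                      make_cost_surface(g1, "uniform"))
  expect_equal(dim(p1$A), c(1, 1))
  expect_equal(as.vector(p1$A), 42)
})

test_that("zero-cost units are floored so free cells cannot hide in solutions", {
  g <- make_planning_grid(1, 3, 8.4)
  vals <- array(0, dim = c(1, 1, 3)); vals[1, 1, ] <- c(5, 5, 5)
  cube <- abundance_cube(vals, g, "s", 1L)
  feats <- build_features(cube, approach = "weekly", week = 1)
  fake_cost <- structure(list(cost = c(0, 1, 2), mode = "footprint",
                              grid = g), class = "cost_surface")
  prob <- build_problem(feats, fake_cost)
  expect_equal(prob$c[1], 1e-6)
})

test_that("the (60,30,10) instance is solved by one cell, identically by both solvers", {
  g <- make_planning_grid(1, 3, 8.4)
  vals <- array(0, dim = c(1, 1, 3)); vals[1, 1, ] <- c(60, 30, 10)
  cube <- abundance_cube(vals, g, "s", 1L)
  prob <- build_problem(build_features(cube, approach = "weekly", week = 1,
                                       target_proportion = 0.3),
                        make_cost_surface(g, "uniform"))
  bf <- solve_bruteforce(prob)
  ex <- solve_exact(prob)
  expect_equal(bf$objective, 1)
  expect_equal(ex$objective, 1)
  expect_equal(ex$status, "optimal")
  # lexicographic tie-break: the oracle picks the first qualifying cell
  expect_equal(bf$x, c(1L, 0L, 0L))
})

test_that("brute force handles trivial targets and refuses oversized instances", {
  g <- make_planning_grid(1, 3, 8.4)
  vals <- array(0, dim = c(1, 1, 3)); vals[1, 1, ] <- c(5, 5, 5)
  cube <- abundance_cube(vals, g, "s", 1L)
  prob <- build_problem(build_features(cube, approach = "weekly", week = 1),
                        make_cost_surface(g, "uniform"))
  prob$b[] <- 0
  bf <- solve_bruteforce(prob)
  expect_equal(bf$objective, 0)
  expect_equal(sum(bf$x), 0)

  g21 <- make_planning_grid(1, 21, 8.4)
  v21 <- array(1, dim = c(1, 1, 21))
  cube21 <- abundance_cube(v21, g21, "s", 1L)
  p21 <- build_problem(build_features(cube21, approach = "weekly", week = 1),
                       make_cost_surface(g21, "uniform"))
  expect_error(solve_bruteforce(p21), "20")
})

test_that("verify_solution reports attainment and shortfalls independently", {
  g <- make_planning_grid(1, 3, 8.4)
  vals <- array(0, dim = c(1, 1, 3)); vals[1, 1, ] <- c(60, 30, 10)
  cube <- abundance_cube(vals, g, "s", 1L)
  prob <- build_problem(build_features(cube, approach = "weekly", week = 1,
                                       target_proportion = 0.3),
                        make_cost_surface(g, "uniform"))
  sol <- solve_exact(prob)
  rep_opt <- verify_solution(prob, sol)
  expect_true(attr(rep_opt, "pass"))
  expect_equal(rep_opt$shortfall, 0)

  rep_empty <- verify_solution(prob, c(0, 0, 0))
  expect_false(attr(rep_empty, "pass"))
  expect_equal(rep_empty$shortfall, prob$b)

  rep_cell2 <- verify_solution(prob, c(0, 1, 0))
  expect_equal(rep_cell2$attained, 30)
  expect_equal(rep_cell2$shortfall, 0)
  expect_equal(attr(rep_cell2, "objective"), 1)
})

test_that("zero-abundance features are dropped with a message", {
  g <- make_planning_grid(1, 3, 8.4)
  vals <- array(0, dim = c(2, 1, 3))
  vals[1, 1, ] <- c(1, 2, 3)     # species 2 entirely absent
  cube <- abundance_cube(vals, g, c("a", "b"), 1L)
  expect_message(feats <- build_features(cube, approach = "weekly", week = 1),
                 "dropped")
  expect_equal(nrow(feats), 1)
  expect_equal(feats$species_id, "a")
})
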