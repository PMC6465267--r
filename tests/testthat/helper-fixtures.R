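# Shared fixtures: everything is generated in code at test time.

tiny_grid <- function(n_rows = 4, n_cols = 5, cell_size_km = 8.4,
                      origin = c(14, -85)) {
  make_planning_grid(n_rows, n_cols, cell_size_km, origin)
}

# A fully deterministic single-species cube: stationary Gaussian kernel,
# no roughness noise.
stationary_cube <- function(grid, n_weeks = 3, total = 100,
                            spread_km = 15) {
  ext <- grid_extent(grid)
  center <- c(mean(ext[c("lat_min", "lat_max")]),
              mean(ext[c("lon_min", "lon_max")]))
  route <- matrix(rep(center, each = n_weeks), n_weeks, 2,
                  dimnames = list(NULL, c("lat", "lon")))
  p <- species_params("spA", total, route, spread_km, noise_sd = 0)
  simulate_species(p, grid, seed = 1)
}

# Random small minimum set cover instance with guaranteed-feasible targets.
random_problem <- function(seed, n_units_max = 15, n_features_max = 6,
                           footprint = FALSE) {
  set.seed(seed)
  n_units <- sample(3:n_units_max, 1)
  n_feat <- sample(1:n_features_max, 1)
  g <- make_planning_grid(1, n_units, 8.4)
  vals <- array(0, dim = c(n_feat, 1, n_units))
  for (f in seq_len(n_feat)) {
    occupied <- sample(n_units, sample(2:n_units, 1))
    vals[f, 1, occupied] <- stats::runif(length(occupied), 0.1, 10)
  }
  cube <- abundance_cube(vals, g, paste0("f", seq_len(n_feat)), 1L)
  feats <- build_features(cube, approach = "weekly", week = 1,
                          target_proportion = stats::runif(1, 0.1, 0.6))
  cost <- if (footprint) {
    structure(list(cost = stats::runif(n_units, 0, 50), mode = "footprint",
                   grid = g), class = "cost_surface")
  } else {
    make_cost_surface(g, "uniform")
  }
  build_problem(feats, cost)
}

# Independent exhaustive k-medoids oracle: best objective over all medoid
# sets (for n small enough to enumerate).
brute_force_medoids <- function(D, k) {
  dm <- as.matrix(D)
  n <- nrow(dm)
  sets <- utils::combn(n, k)
  best <- Inf
  best_set <- NULL
  for (s in seq_len(ncol(sets))) {
    med <- sets[, s]
    obj <- sum(apply(dm[, med, drop = FALSE], 1, min))
    if (obj < best - 1e-12) {
      best <- obj
      best_set <- med
    }
  }
  list(objective = best, medoids = best_set)
}

# Minimal scenario_result stub for agreement-map algebra tests.
fake_result <- function(selection, approach = "yearly") {
  structure(
    list(config = scenario_config(approach, "single", "shared_use"),
         selection = selection, n_solves = 1L,
         objective = sum(selection > 0),
         summed_area_km2 = sum(selection > 0),
         union_area_km2 = sum(selection > 0),
         attainment = NULL, status = "optimal"),
    class = "scenario_result"
  )
}
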