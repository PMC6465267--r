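# Scenario engine --------------------------------------------------------

#' Define one planning scenario
#'
#' A scenario is one combination of the three binary planning axes:
#' temporal approach (`weekly`: one independent optimization per week whose
#' solutions are summed, vs `yearly`: one optimization with every
#' species-week as a feature), population treatment (`single` range-wide
#' target per species vs `clustered` targets per regional abundance
#' cluster), and cost metric (`shared_use`: uniform cost 1, vs
#' `intact_habitat`: human-footprint cost).
#'
#' @param approach `"weekly"` or `"yearly"`.
#' @param population `"single"` or `"clustered"`.
#' @param cost_mode `"shared_use"` (uniform) or `"intact_habitat"`
#'   (footprint).
#' @param target_proportion Representation target (default 0.30).
#' @param k Clusters per species-week in clustered scenarios (default 5).
#' @param gap_tolerance Relative MIP gap passed to the solver (default 0).
#' @return A `scenario_config`.
#' @export
scenario_config <- function(approach = c("weekly", "yearly"),
                            population = c("single", "clustered"),
                            cost_mode = c("shared_use", "intact_habitat"),
                            target_proportion = 0.30, k = 5L,
                            gap_tolerance = 0) {
  structure(
    list(approach = match.arg(approach),
         population = match.arg(population),
         cost_mode = match.arg(cost_mode),
         target_proportion = target_proportion, k = as.integer(k),
         gap_tolerance = gap_tolerance),
    class = "scenario_config"
  )
}

#' All eight scenario combinations
#' @inheritParams scenario_config
#' @return Named list of the 8 distinct `scenario_config`s.
#' @export
all_scenario_configs <- function(target_proportion = 0.30, k = 5L,
                                 gap_tolerance = 0) {
  out <- list()
  for (ap in c("weekly", "yearly")) {
    for (po in c("single", "clustered")) {
      for (cm in c("shared_use", "intact_habitat")) {
        out[[paste(ap, po, cm, sep = "_")]] <-
          scenario_config(ap, po, cm, target_proportion, k, gap_tolerance)
      }
    }
  }
  out
}

#' Run one planning scenario
#'
#' Builds and solves the scenario's minimum set cover problem(s) and
#' assembles the map products: under the weekly approach one problem is
#' solved per week and the solutions summed, so the selection map counts how
#' many weekly solutions picked each cell (0..n_weeks); under the yearly
#' approach a single problem covers every species-week and the map is
#' binary. Both the summed area (weekly: total over per-week solution
#' areas) and the union area of selected cells are reported, along with the
#' per-feature attainment of every solve.
#'
#' @param config A `scenario_config`.
#' @param cube An `abundance_cube` (all species).
#' @param cost A `cost_surface` consistent with `config$cost_mode`.
#' @param clusters Cluster assignments from [cluster_weekly()] (required for
#'   clustered scenarios).
#' @param weeks Weeks to plan for (default all weeks of the cube).
#' @return A `scenario_result`: list with `config`, `selection` (integer per
#'   cell), `n_solves`, `objective` (sum over solves), `summed_area_km2`,
#'   `union_area_km2`, `attainment` (data frame over all solves), `status`.
#' @export
run_scenario <- function(config, cube, cost, clusters = NULL, weeks = NULL) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(cube, "abundance_cube"),
            inherits(cost, "cost_surface"))
  expected_mode <- if (config$cost_mode == "shared_use") "uniform"
                   else "footprint"
  if (cost$mode != expected_mode) {
    stop(sprintf("scenario %s needs a %s cost surface", config$cost_mode,
                 expected_mode), call. = FALSE)
  }
  if (config$population == "clustered" && is.null(clusters)) {
    stop("clustered scenarios need `clusters`", call. = FALSE)
  }
  if (is.null(weeks)) weeks <- cube$weeks
  cl <- if (config$population == "clustered") clusters else NULL
  cell_area <- cube$grid$cells$area_km2

  if (config$approach == "yearly") {
    sub <- cube
    sub$values <- cube$values[, match(weeks, cube$weeks), , drop = FALSE]
    sub$weeks <- as.integer(weeks)
    feats <- build_features(sub, clusters = cl, approach = "yearly",
                            target_proportion = config$target_proportion)
    prob <- build_problem(feats, cost)
    sol <- solve_exact(prob, gap_tolerance = config$gap_tolerance)
    if (sol$status == "infeasible") {
      stop("yearly problem infeasible", call. = FALSE)
    }
    att <- verify_solution(prob, sol)
    att$solve <- "yearly"
    selection <- sol$x
    area <- sum(cell_area * sol$x)
    return(structure(
      list(config = config, selection = selection, n_solves = 1L,
           objective = sol$objective, summed_area_km2 = area,
           union_area_km2 = area, attainment = att, status = sol$status),
      class = "scenario_result"))
  }

  # weekly: independent problems, solved as one batch
  probs <- lapply(weeks, function(w) {
    feats <- build_features(cube, clusters = cl, approach = "weekly",
                            week = w,
                            target_proportion = config$target_proportion)
    build_problem(feats, cost)
  })
  sols <- solve_exact_many(probs, gap_tolerance = config$gap_tolerance)
  selection <- integer(n_cells(cube$grid))
  summed_area <- 0
  objective <- 0
  atts <- vector("list", length(weeks))
  status <- "optimal"
  for (i in seq_along(weeks)) {
    if (sols[[i]]$status == "infeasible") {
      stop("weekly problem infeasible in week ", weeks[i], call. = FALSE)
    }
    if (sols[[i]]$status != "optimal") status <- sols[[i]]$status
    selection <- selection + sols[[i]]$x
    summed_area <- summed_area + sum(cell_area * sols[[i]]$x)
    objective <- objective + sols[[i]]$objective
    a <- verify_solution(probs[[i]], sols[[i]])
    a$solve <- paste0("week_", weeks[i])
    atts[[i]] <- a
  }
  structure(
    list(config = config, selection = selection, n_solves = length(weeks),
         objective = objective, summed_area_km2 = summed_area,
         union_area_km2 = sum(cell_area * (selection > 0)),
         attainment = do.call(rbind, atts), status = status),
    class = "scenario_result"
  )
}

#' Run all eight scenarios on one set of inputs
#'
#' Convenience driver: computes the two cost surfaces (uniform and
#' footprint), the weekly cluster assignments, and runs every combination of
#' the three scenario axes on the same abundance cube.
#'
#' @param cube An `abundance_cube`.
#' @param weeks Weeks to plan for (default all).
#' @param target_proportion Representation target (default 0.30).
#' @param k Clusters per species-week (default 5).
#' @param seed Seed for the footprint cost surface and clustering.
#' @param gap_tolerance Relative MIP gap (default 0).
#' @return Named list of 8 `scenario_result`s.
#' @export
run_all_scenarios <- function(cube, weeks = NULL, target_proportion = 0.30,
                              k = 5L, seed = 1L, gap_tolerance = 0) {
  stopifnot(inherits(cube, "abundance_cube"))
  grid <- cube$grid
  costs <- list(
    shared_use = make_cost_surface(grid, "uniform"),
    intact_habitat = make_cost_surface(grid, "footprint", seed = seed)
  )
  clusters <- cluster_weekly(cube, clustering_config(k = k, seed = seed))
  configs <- all_scenario_configs(target_proportion, k, gap_tolerance)
  lapply(configs, function(cfg) {
    run_scenario(cfg, cube, costs[[cfg$cost_mode]],
                 clusters = clusters, weeks = weeks)
  })
}

#' Agreement between scenario solutions
#'
#' Binarizes each scenario's selection map (a weekly map counts as selected
#' where the cell was picked in at least `weekly_threshold` weeks) and sums
#' the binary maps per cell, giving the number of scenarios (0 to
#' `length(results)`) that selected each cell.
#'
#' @param results List of `scenario_result`s on the same grid (typically
#'   the 8 from [run_all_scenarios()]).
#' @param weekly_threshold Minimum weekly selection count for a cell of a
#'   weekly scenario to count as selected (default 1).
#' @return Integer vector per cell.
#' @export
agreement_map <- function(results, weekly_threshold = 1L) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "scenario_result")))
  n <- length(results[[1L]]$selection)
  if (!all(vapply(results, function(r) length(r$selection), 0L) == n)) {
    stop("scenario results are on different grids", call. = FALSE)
  }
  agree <- integer(n)
  for (r in results) {
    thr <- if (r$config$approach == "weekly") weekly_threshold else 1L
    agree <- agree + as.integer(r$selection >= thr)
  }
  agree
}

#' Percent area difference between two scenario results
#'
#' Computes `100 * (area_b - area_a) / area_b`: the percent of scenario b's
#' area saved by scenario a (positive when a is smaller, e.g. the reduction
#' achieved by yearly planning relative to summed weekly planning).
#'
#' @param result_a,result_b `scenario_result`s on the same grid.
#' @param metric `"summed"` (per-solve areas summed; repeat-counted cells
#'   count every time) or `"union"` (area of the union of selected cells).
#' @return Percent difference (scalar).
#' @export
compare_area <- function(result_a, result_b,
                         metric = c("summed", "union")) {
  metric <- match.arg(metric)
  if (length(result_a$selection) != length(result_b$selection)) {
    stop("results are on different grids", call. = FALSE)
  }
  field <- paste0(metric, "_area_km2")
  area_a <- result_a[[field]]
  area_b <- result_b[[field]]
  if (area_b == 0) stop("reference area is zero", call. = FALSE)
  100 * (area_b - area_a) / area_b
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("scenario_result [%s, %s, %s]: %d solve(s), summed %.1f km2, union %.1f km2 (%s)\n",
              x$config$approach, x$config$population, x$config$cost_mode,
              x$n_solves, x$summed_area_km2, x$union_area_km2, x$status))
  invisible(x)
}
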