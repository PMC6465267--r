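# Cost surfaces and categorical land cover ------------------------------

#' Generate a planning-unit cost surface
#'
#' Two cost metrics drive the prioritization scenarios: a constant area-based
#' cost (`"uniform"`, every planning unit costs 1, for shared-use planning)
#' and a human-footprint-style index (`"footprint"`, a spatially
#' autocorrelated surface clipped to the footprint index range 0-50, for
#' intact-habitat planning).
#'
#' @param grid A `planning_grid`.
#' @param mode `"uniform"` or `"footprint"`.
#' @param seed Integer seed (footprint mode).
#' @param range_km Correlation range of the footprint field, km.
#' @param mean_cost,sd_cost Centre and spread of the footprint field before
#'   clipping to `[0, 50]`.
#' @return A `cost_surface`: list with `cost` (numeric per cell) and `mode`.
#' @export
make_cost_surface <- function(grid, mode = c("uniform", "footprint"),
                              seed = 1L, range_km = 30,
                              mean_cost = 20, sd_cost = 12) {
  stopifnot(inherits(grid, "planning_grid"))
  mode <- match.arg(mode)
  if (mode == "uniform") {
    cost <- rep(1, n_cells(grid))
  } else {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    z <- matrix(stats::rnorm(n_cells(grid)), grid$n_rows, grid$n_cols,
                byrow = TRUE)
    z <- smooth_field(z, sigma_cells = range_km / grid$cell_size_km)
    z <- (z - mean(z)) / stats::sd(z)
    cost <- pmin(50, pmax(0, mean_cost + sd_cost * as.vector(t(z))))
  }
  structure(list(cost = cost, mode = mode, grid = grid),
            class = "cost_surface")
}

#' Generate a categorical land-cover raster
#'
#' Produces a fine-resolution categorical land cover nested inside the
#' planning grid: each planning cell is subdivided into
#' `fine_factor x fine_factor` fine cells (e.g. `fine_factor = 28` turns
#' 8.4 km planning units into 0.3 km land-cover pixels), and each fine cell
#' is assigned one of `n_classes` classes drawn independently from
#' `proportions`.
#'
#' @param grid A `planning_grid`.
#' @param n_classes Number of land-cover classes (>= 1).
#' @param fine_factor Fine cells per planning-cell edge (>= 1).
#' @param seed Integer seed.
#' @param proportions Mixing proportions over classes (default equal);
#'   normalised internally.
#' @param class_names Labels, default `class_1..class_n`.
#' @return A `landcover_raster`: list with `classes` (integer matrix
#'   `[fine_rows, fine_cols]`, row 1 = southern edge), `fine_cell_size_km`,
#'   `fine_factor`, `class_names`, `grid`.
#' @export
make_landcover <- function(grid, n_classes = 6L, fine_factor = 28L, seed = 1L,
                           proportions = NULL, class_names = NULL) {
  stopifnot(inherits(grid, "planning_grid"))
  if (n_classes < 1 || fine_factor < 1) {
    stop("`n_classes` and `fine_factor` must be >= 1", call. = FALSE)
  }
  n_classes <- as.integer(n_classes); fine_factor <- as.integer(fine_factor)
  if (is.null(proportions)) proportions <- rep(1 / n_classes, n_classes)
  if (length(proportions) != n_classes || any(proportions < 0)) {
    stop("`proportions` must be nonnegative, one per class", call. = FALSE)
  }
  proportions <- proportions / sum(proportions)
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(n_classes))
  nr <- grid$n_rows * fine_factor
  nc <- grid$n_cols * fine_factor
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cls <- matrix(sample.int(n_classes, nr * nc, replace = TRUE,
                           prob = proportions), nr, nc)
  structure(
    list(classes = cls, fine_cell_size_km = grid$cell_size_km / fine_factor,
         fine_factor = fine_factor, class_names = class_names, grid = grid,
         proportions = proportions),
    class = "landcover_raster"
  )
}

#' @export
print.cost_surface <- function(x, ...) {
  cat(sprintf("cost_surface (%s): %d cells, cost in [%.3g, %.3g]\n",
              x$mode, length(x$cost), min(x$cost), max(x$cost)))
  invisible(x)
}

#' @export
print.landcover_raster <- function(x, ...) {
  cat(sprintf("landcover_raster: %d x %d fine cells of %.3g km, %d classes\n",
              nrow(x$classes), ncol(x$classes), x$fine_cell_size_km,
              length(x$class_names)))
  invisible(x)
}
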