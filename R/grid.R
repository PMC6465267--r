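# Planning grid ---------------------------------------------------------

# km per degree of latitude (and of longitude under the locally-flat
# approximation used throughout the package).
KM_PER_DEG <- 111.32

#' Create a regular planning grid
#'
#' Builds the grid of square planning units on which abundance surfaces,
#' cost surfaces and prioritization problems are defined. The grid is treated
#' as locally flat: cell centers are laid out in km offsets from the origin
#' and converted to degrees at 111.32 km per degree. Cell ids are 0-based and
#' row-major; rows increase northward, columns eastward. Cell extents are
#' half-open: a point on a shared edge belongs to the cell whose lower edge
#' it touches.
#'
#' @param n_rows,n_cols Number of rows and columns (positive integers).
#' @param cell_size_km Side length of a planning unit in km. The default
#'   8.4 km matches the rendering resolution of the weekly abundance
#'   surfaces.
#' @param origin Numeric vector `c(lat, lon)`: the south-west corner of the
#'   grid, in degrees.
#' @return A `planning_grid` object: a list with `n_rows`, `n_cols`,
#'   `cell_size_km`, `origin`, and a data frame `cells` with one row per
#'   planning unit (`cell_id`, `row`, `col`, `x_km`, `y_km`, `lat`, `lon`,
#'   `area_km2`).
#' @examples
#' g <- make_planning_grid(4, 5, cell_size_km = 8.4, origin = c(10, -85))
#' nrow(g$cells)           # 20
#' g$cells$area_km2[1]     # 70.56
#' @export
make_planning_grid <- function(n_rows, n_cols, cell_size_km = 8.4,
                               origin = c(0, -80)) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != as.integer(n_rows) || n_cols != as.integer(n_cols)) {
    stop("`n_rows` and `n_cols` must be positive integers", call. = FALSE)
  }
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1L ||
      cell_size_km <= 0) {
    stop("`cell_size_km` must be a single positive number", call. = FALSE)
  }
  if (length(origin) != 2L || !is.numeric(origin)) {
    stop("`origin` must be c(lat, lon)", call. = FALSE)
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  x_km <- (col - 0.5) * cell_size_km
  y_km <- (row - 0.5) * cell_size_km
  cells <- data.frame(
    cell_id = seq_len(n_rows * n_cols) - 1L,
    row = row, col = col,
    x_km = x_km, y_km = y_km,
    lat = origin[1] + y_km / KM_PER_DEG,
    lon = origin[2] + x_km / KM_PER_DEG,
    area_km2 = cell_size_km^2
  )
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size_km = cell_size_km,
         origin = c(lat = unname(origin[1]), lon = unname(origin[2])),
         cells = cells),
    class = "planning_grid"
  )
}

#' Number of planning units in a grid
#' @param grid A `planning_grid`.
#' @return Integer count of cells.
#' @export
n_cells <- function(grid) {
  stopifnot(inherits(grid, "planning_grid"))
  grid$n_rows * grid$n_cols
}

#' Locate planning units containing points
#'
#' Maps geographic points to 0-based cell ids using the half-open cell
#' extents `[edge, edge + size)`. Points outside the grid get `NA`.
#'
#' @param grid A `planning_grid`.
#' @param lat,lon Numeric vectors of coordinates in degrees.
#' @return Integer vector of 0-based cell ids (NA outside the grid).
#' @export
cell_at <- function(grid, lat, lon) {
  stopifnot(inherits(grid, "planning_grid"))
  x_km <- (lon - grid$origin["lon"]) * KM_PER_DEG
  y_km <- (lat - grid$origin["lat"]) * KM_PER_DEG
  col <- floor(x_km / grid$cell_size_km)
  row <- floor(y_km / grid$cell_size_km)
  id <- as.integer(row * grid$n_cols + col)
  bad <- row < 0 | row >= grid$n_rows | col < 0 | col >= grid$n_cols
  id[bad] <- NA_integer_
  id
}

#' Geographic extent of a grid
#' @param grid A `planning_grid`.
#' @return Named numeric vector `lat_min`, `lat_max`, `lon_min`, `lon_max`.
#' @export
grid_extent <- function(grid) {
  stopifnot(inherits(grid, "planning_grid"))
  size_deg_lat <- grid$n_rows * grid$cell_size_km / KM_PER_DEG
  size_deg_lon <- grid$n_cols * grid$cell_size_km / KM_PER_DEG
  c(lat_min = unname(grid$origin["lat"]),
    lat_max = unname(grid$origin["lat"]) + size_deg_lat,
    lon_min = unname(grid$origin["lon"]),
    lon_max = unname(grid$origin["lon"]) + size_deg_lon)
}

#' @export
print.planning_grid <- function(x, ...) {
  cat(sprintf("planning_grid: %d x %d cells of %.2f km (%d units, %.1f km2 total)\n",
              x$n_rows, x$n_cols, x$cell_size_km, n_cells(x),
              sum(x$cells$area_km2)))
  invisible(x)
}

#' Synthetic smooth elevation surface
#'
#' Generates a spatially autocorrelated "elevation" covariate on the planning
#' grid (a stand-in for a real digital elevation model), used as a spatial
#' predictor by the abundance estimator.
#'
#' @param grid A `planning_grid`.
#' @param seed Integer seed.
#' @param range_km Correlation range of the surface (Gaussian smoothing
#'   scale), km.
#' @return Numeric vector of length `n_cells(grid)` (mean ~0, sd ~1).
#' @export
make_elevation <- function(grid, seed = 1L, range_km = 40) {
  stopifnot(inherits(grid, "planning_grid"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z <- matrix(stats::rnorm(n_cells(grid)), grid$n_rows, grid$n_cols,
              byrow = TRUE)
  z <- smooth_field(z, sigma_cells = range_km / grid$cell_size_km)
  z <- (z - mean(z)) / stats::sd(z)
  # back to row-major cell order
  as.vector(t(z))
}

# Separable Gaussian smoothing of a matrix (reflecting edges).
smooth_field <- function(mat, sigma_cells) {
  if (sigma_cells <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma_cells))
  k <- stats::dnorm(seq(-half, half), sd = sigma_cells)
  k <- k / sum(k)
  smooth_vec <- function(v) {
    n <- length(v)
    if (n == 1L) return(v)
    idx <- seq_len(n)
    out <- numeric(n)
    period <- 2L * n - 2L
    for (o in seq(-half, half)) {
      t <- (idx + o - 1L) %% period
      j <- ifelse(t < n, t, period - t) + 1L
      out <- out + k[o + half + 1L] * v[j]
    }
    out
  }
  m2 <- apply(mat, 2L, smooth_vec)
  t(apply(m2, 1L, smooth_vec))
}

# Save/restore .Random.seed so seeded generators do not disturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
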