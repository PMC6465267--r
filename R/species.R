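# Synthetic migratory species and abundance cubes -----------------------

#' Parameters of a synthetic migratory species
#'
#' Describes a species whose weekly distribution is an isotropic Gaussian
#' kernel centred on a 52-step migration route, holding a constant weekly
#' population total.
#'
#' @param species_id Character label.
#' @param total_abundance Total relative abundance (individuals) present in
#'   every week; must be positive.
#' @param route A 52 x 2 matrix or data frame of weekly kernel centres
#'   (columns `lat`, `lon`, degrees), one row per week.
#' @param spread_km Standard deviation of the abundance kernel, km (> 0).
#' @param noise_sd Standard deviation (log scale) of seeded multiplicative
#'   lognormal roughness applied to the kernel before weekly renormalisation;
#'   0 gives a perfectly smooth Gaussian surface.
#' @param range_floor Relative occupancy floor: cells whose kernel value
#'   falls below `range_floor` times the weekly maximum are set to zero
#'   before renormalisation, giving the species a finite weekly range
#'   (default 1e-4). Set to 0 for an untruncated kernel.
#' @return A `species_params` object.
#' @export
species_params <- function(species_id, total_abundance, route, spread_km,
                           noise_sd = 0.15, range_floor = 1e-4) {
  route <- as.matrix(route)
  if (ncol(route) != 2L) stop("`route` must have columns lat, lon", call. = FALSE)
  if (!is.numeric(total_abundance) || total_abundance <= 0) {
    stop("`total_abundance` must be positive", call. = FALSE)
  }
  if (!is.numeric(spread_km) || spread_km <= 0) {
    stop("`spread_km` must be positive", call. = FALSE)
  }
  colnames(route) <- c("lat", "lon")
  structure(
    list(species_id = as.character(species_id),
         total_abundance = total_abundance,
         route = route, spread_km = spread_km, noise_sd = noise_sd,
         range_floor = range_floor),
    class = "species_params"
  )
}

#' Build a 52-week migration route between two stationary ranges
#'
#' Produces a weekly route that sits on the non-breeding grounds early in the
#' year, migrates to the breeding grounds, stays, and returns — linear
#' interpolation between the stationary phases. Weeks are 1..52.
#'
#' @param breeding,nonbreeding `c(lat, lon)` of the two stationary centres.
#' @param breeding_weeks Integer weeks spent stationary on the breeding
#'   grounds (default 24:35, midsummer).
#' @param nonbreeding_weeks Integer weeks stationary on the non-breeding
#'   grounds (default weeks 49:52 and 1:8).
#' @param n_weeks Number of weeks (default 52).
#' @return A `n_weeks` x 2 matrix of (lat, lon).
#' @export
migration_route <- function(breeding, nonbreeding,
                            breeding_weeks = 24:35,
                            nonbreeding_weeks = c(49:52, 1:8),
                            n_weeks = 52L) {
  lat <- numeric(n_weeks); lon <- numeric(n_weeks)
  phase <- rep(NA_character_, n_weeks)
  phase[breeding_weeks] <- "breeding"
  phase[nonbreeding_weeks] <- "nonbreeding"
  pos <- matrix(NA_real_, n_weeks, 2L)
  if (length(breeding_weeks)) {
    pos[breeding_weeks, ] <- matrix(breeding, length(breeding_weeks), 2L,
                                    byrow = TRUE)
  }
  if (length(nonbreeding_weeks)) {
    pos[nonbreeding_weeks, ] <- matrix(nonbreeding,
                                       length(nonbreeding_weeks), 2L,
                                       byrow = TRUE)
  }
  # interpolate the migration legs circularly between known weeks
  known <- which(!is.na(pos[, 1L]))
  if (length(known) == 0L) stop("no stationary weeks given", call. = FALSE)
  for (w in seq_len(n_weeks)) {
    if (!is.na(pos[w, 1L])) next
    # distance forward/backward to nearest known week (circular)
    dist_fwd <- (known - w) %% n_weeks
    dist_bwd <- (w - known) %% n_weeks
    nxt <- known[which.min(dist_fwd)]
    prv <- known[which.min(dist_bwd)]
    gap <- (nxt - prv) %% n_weeks
    frac <- if (gap == 0) 0 else ((w - prv) %% n_weeks) / gap
    pos[w, ] <- (1 - frac) * pos[prv, ] + frac * pos[nxt, ]
  }
  colnames(pos) <- c("lat", "lon")
  pos
}

#' Simulate the true weekly abundance cube of one species
#'
#' For each week, relative abundance over the grid is an isotropic Gaussian
#' kernel (sd `spread_km`, in km space) centred on that week's route
#' position, optionally roughened by seeded lognormal noise, then rescaled so
#' the weekly total equals `total_abundance` exactly. The result is a
#' deterministic function of (params, grid, seed).
#'
#' @param params A `species_params`.
#' @param grid A `planning_grid`.
#' @param seed Integer seed for the roughness noise.
#' @return An `abundance_cube` with one species.
#' @export
simulate_species <- function(params, grid, seed = 1L) {
  stopifnot(inherits(params, "species_params"), inherits(grid, "planning_grid"))
  n_weeks <- nrow(params$route)
  vals <- matrix(0, n_weeks, n_cells(grid))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  noise <- if (params$noise_sd > 0) {
    matrix(stats::rlnorm(n_weeks * n_cells(grid), 0, params$noise_sd),
           n_weeks, n_cells(grid))
  } else NULL
  cx <- grid$cells$x_km
  cy <- grid$cells$y_km
  for (w in seq_len(n_weeks)) {
    px <- (params$route[w, "lon"] - grid$origin["lon"]) * KM_PER_DEG
    py <- (params$route[w, "lat"] - grid$origin["lat"]) * KM_PER_DEG
    d2 <- (cx - px)^2 + (cy - py)^2
    a <- exp(-d2 / (2 * params$spread_km^2))
    if (!is.null(noise)) a <- a * noise[w, ]
    a[a < params$range_floor * max(a)] <- 0
    s <- sum(a)
    if (s <= 0) stop("kernel vanished numerically for week ", w, call. = FALSE)
    vals[w, ] <- a * (params$total_abundance / s)
  }
  abundance_cube(array(vals, dim = c(1L, n_weeks, n_cells(grid))),
                 grid = grid, species = params$species_id,
                 weeks = seq_len(n_weeks))
}

#' Construct an abundance cube
#'
#' The container for species x week x planning-cell relative abundance, true
#' or estimated. Estimated cubes may contain `NA` where ensemble support is
#' insufficient, and may carry a `support` array.
#'
#' @param values Numeric array `[n_species, n_weeks, n_cells]` (nonnegative
#'   or NA).
#' @param grid The `planning_grid` the cells refer to.
#' @param species Character vector of species ids.
#' @param weeks Integer vector of week numbers.
#' @param support Optional integer array `[n_weeks, n_cells]` of contributing
#'   base-model counts (estimated cubes).
#' @return An `abundance_cube`.
#' @export
abundance_cube <- function(values, grid, species, weeks, support = NULL) {
  stopifnot(inherits(grid, "planning_grid"))
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3-d array", call. = FALSE)
  if (dim(values)[1L] != length(species) || dim(values)[2L] != length(weeks) ||
      dim(values)[3L] != n_cells(grid)) {
    stop("`values` dimensions must be [species, weeks, cells]", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) stop("abundance must be nonnegative",
                                          call. = FALSE)
  dimnames(values) <- list(species, NULL, NULL)
  structure(
    list(values = values, grid = grid, species = as.character(species),
         weeks = as.integer(weeks), support = support),
    class = "abundance_cube"
  )
}

#' Combine single-species cubes into a community cube
#' @param ... `abundance_cube` objects on the same grid and weeks.
#' @return An `abundance_cube` stacking all species.
#' @export
bind_cubes <- function(...) {
  cubes <- list(...)
  if (length(cubes) == 1L && is.list(cubes[[1L]]) &&
      !inherits(cubes[[1L]], "abundance_cube")) {
    cubes <- cubes[[1L]]
  }
  stopifnot(length(cubes) >= 1L,
            all(vapply(cubes, inherits, TRUE, "abundance_cube")))
  g <- cubes[[1L]]$grid
  wk <- cubes[[1L]]$weeks
  for (cb in cubes[-1L]) {
    if (!identical(cb$weeks, wk) || n_cells(cb$grid) != n_cells(g)) {
      stop("cubes must share grid and weeks", call. = FALSE)
    }
  }
  sp <- unlist(lapply(cubes, `[[`, "species"))
  vals <- array(0, dim = c(length(sp), length(wk), n_cells(g)))
  i <- 1L
  for (cb in cubes) {
    k <- length(cb$species)
    vals[i:(i + k - 1L), , ] <- cb$values
    i <- i + k
  }
  abundance_cube(vals, g, sp, wk)
}

#' Extract one species-week abundance surface
#' @param cube An `abundance_cube`.
#' @param species Species id (label or index).
#' @param week Week number (position in `cube$weeks`).
#' @return Numeric vector over cells.
#' @export
cube_slice <- function(cube, species, week) {
  stopifnot(inherits(cube, "abundance_cube"))
  si <- if (is.character(species)) match(species, cube$species) else species
  wi <- match(week, cube$weeks)
  if (is.na(si) || is.na(wi)) stop("species/week not in cube", call. = FALSE)
  cube$values[si, wi, ]
}

#' @export
print.abundance_cube <- function(x, ...) {
  cat(sprintf("abundance_cube: %d species x %d weeks x %d cells (%s)\n",
              length(x$species), length(x$weeks), dim(x$values)[3L],
              if (anyNA(x$values)) "estimated, with unsupported cells"
              else "fully defined"))
  invisible(x)
}

#' Simulate a multi-species community of migrants
#'
#' Convenience wrapper: builds `n_species` species with routes interpolated
#' between randomly drawn breeding (northern) and non-breeding (southern)
#' centres inside the grid, and stacks their simulated cubes.
#'
#' @param grid A `planning_grid`.
#' @param n_species Number of species.
#' @param total_abundance Per-week population total for every species.
#' @param spread_km Kernel sd in km (recycled over species).
#' @param n_weeks Number of weeks to simulate (default 52).
#' @param seed Integer seed.
#' @return An `abundance_cube` with `n_species` species.
#' @export
simulate_community <- function(grid, n_species = 5L, total_abundance = 100,
                               spread_km = NULL, n_weeks = 52L, seed = 1L) {
  stopifnot(inherits(grid, "planning_grid"))
  ext <- grid_extent(grid)
  if (is.null(spread_km)) spread_km <- 1.2 * grid$cell_size_km
  spread_km <- rep_len(spread_km, n_species)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lat_span <- ext["lat_max"] - ext["lat_min"]
  lon_span <- ext["lon_max"] - ext["lon_min"]
  cubes <- vector("list", n_species)
  sub_seeds <- sample.int(.Machine$integer.max, n_species)
  for (s in seq_len(n_species)) {
    breeding <- c(ext["lat_min"] + stats::runif(1, 0.7, 0.95) * lat_span,
                  ext["lon_min"] + stats::runif(1, 0.15, 0.85) * lon_span)
    nonbreeding <- c(ext["lat_min"] + stats::runif(1, 0.05, 0.3) * lat_span,
                     ext["lon_min"] + stats::runif(1, 0.15, 0.85) * lon_span)
    wk <- seq_len(n_weeks)
    route <- migration_route(
      breeding, nonbreeding,
      breeding_weeks = intersect(24:35, wk),
      nonbreeding_weeks = intersect(c(49:52, 1:8), wk),
      n_weeks = n_weeks
    )
    p <- species_params(sprintf("sp%02d", s), total_abundance, route,
                        spread_km[s])
    cubes[[s]] <- simulate_species(p, grid, seed = sub_seeds[s])
  }
  bind_cubes(cubes)
}
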