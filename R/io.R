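# Plain-text import/export ----------------------------------------------

#' Write an abundance cube as a long-format CSV
#'
#' One row per (species, week, cell) with a `value` column (`NA` for
#' unsupported estimates); the grid dimensions travel in a header comment so
#' the cube can be rebuilt with [read_abundance_csv()].
#'
#' @param cube An `abundance_cube`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_abundance_csv <- function(cube, path) {
  stopifnot(inherits(cube, "abundance_cube"))
  g <- cube$grid
  hdr <- sprintf("# grid %d %d %.10g %.10g %.10g", g$n_rows, g$n_cols,
                 g$cell_size_km, g$origin["lat"], g$origin["lon"])
  d <- expand.grid(cell_id = g$cells$cell_id, week = cube$weeks,
                   species_id = cube$species,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("species_id", "week", "cell_id")]
  d$value <- as.vector(aperm(cube$values, c(3L, 2L, 1L)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' Read an abundance cube written by [write_abundance_csv()]
#' @param path CSV file.
#' @return An `abundance_cube`.
#' @export
read_abundance_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), " ")[[1L]]
  if (hdr[2L] != "grid") stop("missing grid header", call. = FALSE)
  grid <- make_planning_grid(as.integer(hdr[3L]), as.integer(hdr[4L]),
                             as.numeric(hdr[5L]),
                             origin = c(as.numeric(hdr[6L]),
                                        as.numeric(hdr[7L])))
  d <- utils::read.csv(path, skip = 1L)
  species <- unique(d$species_id)
  weeks <- sort(unique(d$week))
  vals <- array(NA_real_, dim = c(length(species), length(weeks),
                                  n_cells(grid)))
  vals[cbind(match(d$species_id, species), match(d$week, weeks),
             d$cell_id + 1L)] <- d$value
  abundance_cube(vals, grid, species, weeks)
}

#' Export a prioritization problem as sparse-triplet CSV files
#'
#' Writes `<stem>_A.csv` (feature_id, unit_id, r), `<stem>_c.csv`
#' (unit_id, cost) and `<stem>_b.csv` (feature_id, target) so the problem
#' can be handed to any external MILP backend.
#'
#' @param problem A `prioritization_problem`.
#' @param stem Path prefix for the three files.
#' @return Character vector of the three paths, invisibly.
#' @export
write_problem_csv <- function(problem, stem) {
  stopifnot(inherits(problem, "prioritization_problem"))
  trip <- Matrix::summary(problem$A)
  paths <- paste0(stem, c("_A.csv", "_c.csv", "_b.csv"))
  utils::write.csv(data.frame(feature_id = trip$i, unit_id = trip$j - 1L,
                              r = trip$x),
                   paths[1L], row.names = FALSE)
  utils::write.csv(data.frame(unit_id = seq_along(problem$c) - 1L,
                              cost = problem$c),
                   paths[2L], row.names = FALSE)
  utils::write.csv(data.frame(feature_id = seq_along(problem$b),
                              target = problem$b),
                   paths[3L], row.names = FALSE)
  invisible(paths)
}

#' Write a scenario selection map as CSV
#' @param result A `scenario_result`.
#' @param path Output file (columns cell_id, selected).
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(result, path) {
  stopifnot(inherits(result, "scenario_result"))
  utils::write.csv(data.frame(cell_id = seq_along(result$selection) - 1L,
                              selected = result$selection),
                   path, row.names = FALSE)
  invisible(path)
}
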