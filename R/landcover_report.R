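# Land cover accounting of scenario selections --------------------------

#' Warp a planning-grid selection onto the fine land-cover grid
#'
#' Every fine land-cover cell inherits the selection state of the planning
#' unit that contains it (pure containment, no resampling: the fine grid
#' nests exactly inside the planning grid).
#'
#' @param selection Binary/logical vector per planning cell (a weekly count
#'   map can be passed through `selection > 0` first; any positive value
#'   counts as selected).
#' @param landcover A `landcover_raster` nested in the same grid.
#' @return Logical matrix on the fine grid (`[fine_rows, fine_cols]`).
#' @export
warp_selection <- function(selection, landcover) {
  stopifnot(inherits(landcover, "landcover_raster"))
  grid <- landcover$grid
  if (length(selection) != n_cells(grid)) {
    stop("selection length must equal the number of planning units",
         call. = FALSE)
  }
  f <- landcover$fine_factor
  sel <- matrix(as.logical(selection > 0), grid$n_rows, grid$n_cols,
                byrow = TRUE)
  sel[rep(seq_len(grid$n_rows), each = f),
      rep(seq_len(grid$n_cols), each = f), drop = FALSE]
}

#' Map fine land-cover classes to broader classes
#'
#' @param fine_class_id Integer fine class ids.
#' @param broad_class Character broad class per fine id. Fine classes not
#'   listed fall into `"other"`.
#' @return A `class_aggregation` data frame.
#' @export
class_aggregation <- function(fine_class_id, broad_class) {
  stopifnot(length(fine_class_id) == length(broad_class),
            !anyDuplicated(fine_class_id))
  structure(data.frame(fine_class_id = as.integer(fine_class_id),
                       broad_class = as.character(broad_class)),
            class = c("class_aggregation", "data.frame"))
}

#' Cells available to conservation (species presence mask)
#'
#' A planning cell is available when at least `min_species` species have
#' nonzero (estimated) abundance there in any week of the year. The
#' threshold is configurable because availability could also be read as
#' requiring more than one species.
#'
#' @param cube An `abundance_cube`.
#' @param min_species Minimum number of species present (default 1).
#' @return Logical vector per planning cell.
#' @export
availability_mask <- function(cube, min_species = 1L) {
  stopifnot(inherits(cube, "abundance_cube"))
  vals <- cube$values
  vals[is.na(vals)] <- 0
  present <- apply(vals > 0, c(1L, 3L), any)    # species x cell
  colSums(present) >= min_species
}

#' Tabulate selected and available area per land-cover class
#'
#' Counts fine cells of each (broad) land-cover class inside the selection
#' mask and inside the availability mask, converting to km2. With a total
#' aggregation map, the per-class selected areas sum exactly to the total
#' selected area.
#'
#' @param mask Logical fine-grid matrix from [warp_selection()].
#' @param landcover The `landcover_raster`.
#' @param aggregation Optional `class_aggregation`; default: every fine
#'   class is its own broad class (named by `class_names`).
#' @param availability Optional logical vector per planning cell (see
#'   [availability_mask()]); default all cells available.
#' @return Data frame with `broad_class`, `area_available_km2`,
#'   `area_selected_km2`.
#' @export
tabulate_landcover <- function(mask, landcover, aggregation = NULL,
                               availability = NULL) {
  stopifnot(inherits(landcover, "landcover_raster"))
  if (!identical(dim(mask), dim(landcover$classes))) {
    stop("mask and land cover are not congruent", call. = FALSE)
  }
  n_fine_classes <- length(landcover$class_names)
  if (is.null(aggregation)) {
    aggregation <- class_aggregation(seq_len(n_fine_classes),
                                     landcover$class_names)
  }
  broad_of <- rep("other", n_fine_classes)
  hit <- match(seq_len(n_fine_classes), aggregation$fine_class_id)
  broad_of[!is.na(hit)] <- aggregation$broad_class[hit[!is.na(hit)]]

  if (is.null(availability)) {
    avail_fine <- matrix(TRUE, nrow(mask), ncol(mask))
  } else {
    avail_fine <- warp_selection(availability, landcover)
  }
  cell_area <- landcover$fine_cell_size_km^2
  broad_levels <- unique(broad_of)
  cls <- landcover$classes
  area_sel <- vapply(broad_levels, function(bc) {
    sum(mask & matrix(broad_of[cls] == bc, nrow(cls), ncol(cls))) * cell_area
  }, numeric(1))
  area_avail <- vapply(broad_levels, function(bc) {
    sum(avail_fine & matrix(broad_of[cls] == bc, nrow(cls),
                            ncol(cls))) * cell_area
  }, numeric(1))
  data.frame(broad_class = broad_levels,
             area_available_km2 = area_avail,
             area_selected_km2 = area_sel,
             row.names = NULL)
}
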