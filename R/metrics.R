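# Landscape composition/configuration metrics ---------------------------

#' Landscape metrics in a square neighborhood around each location
#'
#' Computes, per land-cover class, the FRAGSTATS-style composition and
#' configuration metrics used as spatial predictors by the abundance
#' estimator, inside a `window_km` x `window_km` neighborhood centred on
#' each location (default 2.8 km, i.e. 784 ha with 0.3 km pixels):
#'
#' * `pland` — percent of the neighborhood in the class (sums to 100 over
#'   classes at each location);
#' * `lpi` — largest patch index, percent of the neighborhood occupied by
#'   the largest contiguous (4-connected) patch of the class;
#' * `pd` — patch density, patches of the class per km2 of neighborhood;
#' * `ed` — edge density, km of class edge per km2 of neighborhood. Edges
#'   are fine-cell sides shared with a different class or with the window
#'   boundary.
#'
#' Windows that extend past the raster edge are clipped and metrics computed
#' on the clipped area.
#'
#' @param landcover A `landcover_raster`.
#' @param locations Data frame with columns `lat`, `lon`.
#' @param window_km Side of the square neighborhood, km.
#' @return A data frame with columns `location`, `class_id`, `class_name`,
#'   `pland`, `lpi`, `pd`, `ed` (one row per location x class present in the
#'   window).
#' @export
compute_landscape_metrics <- function(landcover, locations, window_km = 2.8) {
  stopifnot(inherits(landcover, "landcover_raster"))
  if (!all(c("lat", "lon") %in% names(locations))) {
    stop("`locations` needs lat and lon columns", call. = FALSE)
  }
  if (window_km <= 0) stop("`window_km` must be positive", call. = FALSE)
  grid <- landcover$grid
  fs <- landcover$fine_cell_size_km
  nr <- nrow(landcover$classes); nc <- ncol(landcover$classes)
  half <- window_km / 2
  out <- vector("list", nrow(locations))
  for (i in seq_len(nrow(locations))) {
    x <- (locations$lon[i] - grid$origin["lon"]) * KM_PER_DEG
    y <- (locations$lat[i] - grid$origin["lat"]) * KM_PER_DEG
    # fine cells whose centers fall inside the window, clipped to the raster
    j0 <- max(1L, ceiling((x - half) / fs + 0.5))
    j1 <- min(nc, floor((x + half) / fs + 0.5))
    i0 <- max(1L, ceiling((y - half) / fs + 0.5))
    i1 <- min(nr, floor((y + half) / fs + 0.5))
    if (i0 > i1 || j0 > j1) stop("empty neighborhood at location ", i,
                                 call. = FALSE)
    win <- landcover$classes[i0:i1, j0:j1, drop = FALSE]
    out[[i]] <- window_metrics(win, fs, landcover$class_names, i)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Metrics on one window (class matrix), shared by the public API and tests.
window_metrics <- function(win, fine_size_km, class_names, location = 1L) {
  n_tot <- length(win)
  area_km2 <- n_tot * fine_size_km^2
  labels <- label_patches(win)
  present <- sort(unique(as.vector(win)))
  rows <- lapply(present, function(cl) {
    cells <- win == cl
    n_cl <- sum(cells)
    patch_ids <- unique(labels[cells])
    patch_sizes <- tabulate(match(labels[cells], patch_ids))
    edge_km <- class_edge_length(win, cl) * fine_size_km
    data.frame(
      location = location,
      class_id = cl,
      class_name = class_names[cl],
      pland = 100 * n_cl / n_tot,
      lpi = 100 * max(patch_sizes) / n_tot,
      pd = length(patch_ids) / area_km2,
      ed = edge_km / area_km2
    )
  })
  do.call(rbind, rows)
}

# 4-connected component labelling of a categorical matrix (patches are
# maximal same-class regions). Small windows only; iterative flood fill.
label_patches <- function(win) {
  nr <- nrow(win); nc <- ncol(win)
  labels <- matrix(0L, nr, nc)
  current <- 0L
  for (start in seq_len(nr * nc)) {
    if (labels[start] != 0L) next
    current <- current + 1L
    cl <- win[start]
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (labels[p] != 0L) next
      labels[p] <- current
      pr <- (p - 1L) %% nr + 1L
      pc <- (p - 1L) %/% nr + 1L
      for (nb in list(c(pr - 1L, pc), c(pr + 1L, pc),
                      c(pr, pc - 1L), c(pr, pc + 1L))) {
        if (nb[1L] >= 1L && nb[1L] <= nr && nb[2L] >= 1L && nb[2L] <= nc) {
          q <- (nb[2L] - 1L) * nr + nb[1L]
          if (labels[q] == 0L && win[q] == cl) stack <- c(stack, q)
        }
      }
    }
  }
  labels
}

# Number of unit edges of class `cl` cells adjacent to a different class or
# to the window boundary.
class_edge_length <- function(win, cl) {
  nr <- nrow(win); nc <- ncol(win)
  m <- win == cl
  edges <- 0L
  # horizontal neighbors
  if (nc > 1L) {
    a <- m[, -nc, drop = FALSE]; b <- m[, -1L, drop = FALSE]
    edges <- edges + sum(a & !b) + sum(!a & b)
  }
  if (nr > 1L) {
    a <- m[-nr, , drop = FALSE]; b <- m[-1L, , drop = FALSE]
    edges <- edges + sum(a & !b) + sum(!a & b)
  }
  # window boundary
  edges + sum(m[1L, ]) + sum(m[nr, ]) + sum(m[, 1L]) + sum(m[, nc])
}

#' Pivot landscape metrics to one row per location
#'
#' Reshapes [compute_landscape_metrics()] output to a wide design matrix
#' (`pland_class_k`, `lpi_class_k`, ... columns, absent classes = 0) for use
#' as model covariates.
#'
#' @param metrics Long data frame from [compute_landscape_metrics()].
#' @param n_classes Total number of classes (columns to materialise).
#' @return Data frame, one row per location.
#' @export
landscape_metrics_wide <- function(metrics, n_classes) {
  locs <- sort(unique(metrics$location))
  cols <- c("pland", "lpi", "pd", "ed")
  out <- data.frame(location = locs)
  for (m in cols) {
    for (cl in seq_len(n_classes)) {
      v <- numeric(length(locs))
      sel <- metrics$class_id == cl
      if (any(sel)) {
        v[match(metrics$location[sel], locs)] <- metrics[[m]][sel]
      }
      out[[paste0(m, "_class_", cl)]] <- v
    }
  }
  out
}
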