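# Regional abundance clustering (k-medoids / CLARA) ---------------------

#' Clustering configuration
#'
#' Controls the per-species-week delineation of occupied cells into regional
#' abundance clusters. The dissimilarity between cells mixes geography and
#' abundance: each of latitude, longitude and abundance is min-max scaled to
#' `[0, 1]`, the abundance axis is then multiplied by `abundance_weight`
#' (default 1/3, so clusters are driven primarily by geography), and
#' Euclidean distance is taken on the resulting 3-vectors.
#'
#' @param k Number of clusters (default 5).
#' @param abundance_weight Weight of the abundance axis (default 1/3).
#' @param n_samples Number of CLARA subsamples (default 5).
#' @param sample_size Subsample size; default `min(n, 40 + 2k)`.
#' @param rebalance Logical: run the optional greedy boundary pass that
#'   nudges per-cluster abundance shares toward `1/k` (default FALSE; equal
#'   shares are reported, never enforced, by default).
#' @param seed Integer seed for subsampling.
#' @return A `clustering_config` list.
#' @export
clustering_config <- function(k = 5L, abundance_weight = 1 / 3,
                              n_samples = 5L, sample_size = NULL,
                              rebalance = FALSE, seed = 1L) {
  stopifnot(k >= 1, abundance_weight >= 0, n_samples >= 1)
  structure(
    list(k = as.integer(k), abundance_weight = abundance_weight,
         n_samples = as.integer(n_samples), sample_size = sample_size,
         rebalance = rebalance, seed = seed),
    class = "clustering_config"
  )
}

# Min-max scale the (lat, lon, abundance) columns; a degenerate dimension
# (all values equal) contributes 0 rather than erroring.
scale_cluster_points <- function(points, abundance_weight) {
  scale1 <- function(v) {
    r <- range(v)
    if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else rep(0, length(v))
  }
  cbind(lat = scale1(points$lat),
        lon = scale1(points$lon),
        abundance = abundance_weight * scale1(points$abundance))
}

#' Geographic-abundance dissimilarity matrix
#'
#' Builds the weighted dissimilarity used for regional clustering: min-max
#' scale latitude, longitude and abundance to `[0, 1]`, multiply the
#' abundance axis by `abundance_weight`, and take Euclidean distances.
#'
#' @param points Data frame of occupied cells with columns `lat`, `lon`,
#'   `abundance` (all abundances > 0).
#' @param abundance_weight Weight of the abundance axis (default 1/3).
#' @return A [stats::dist] object.
#' @export
build_dissimilarity <- function(points, abundance_weight = 1 / 3) {
  if (nrow(points) < 1L) stop("need at least one point", call. = FALSE)
  if (any(points$abundance <= 0)) {
    stop("only occupied cells (abundance > 0) are clustered", call. = FALSE)
  }
  stats::dist(scale_cluster_points(points, abundance_weight))
}

#' k-medoids partition of a dissimilarity matrix (PAM)
#'
#' Runs the BUILD + SWAP k-medoids algorithm (via [cluster::pam]) on a
#' precomputed dissimilarity. Because SWAP converges to a local optimum of
#' the total dissimilarity, the deterministic BUILD start is supplemented by
#' `restarts` seeded random starts (each followed by SWAP to convergence)
#' and the best local optimum is kept — the standard multi-start refinement
#' of k-medoids. Deterministic given `seed`.
#'
#' @param D A [stats::dist] object.
#' @param k Number of medoids, `1 <= k <= n`.
#' @param restarts Number of additional random medoid starts (default 10).
#' @param seed Integer seed for the random starts.
#' @return List with `medoids` (indices into the points), `clustering`
#'   (cluster label per point), `objective` (total dissimilarity to nearest
#'   medoid).
#' @export
pam_medoids <- function(D, k, restarts = 10L, seed = 1L) {
  n <- attr(D, "Size")
  if (k > n) stop("`k` cannot exceed the number of points", call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (k == n) {
    # degenerate: every point is its own medoid
    return(list(medoids = seq_len(n), clustering = seq_len(n),
                objective = 0))
  }
  dm <- as.matrix(D)
  run <- function(init) {
    fit <- if (is.null(init)) {
      cluster::pam(D, k = k, diss = TRUE, keep.diss = FALSE,
                   pamonce = FALSE)
    } else {
      cluster::pam(D, k = k, diss = TRUE, keep.diss = FALSE,
                   medoids = init, pamonce = FALSE)
    }
    med <- as.integer(fit$id.med)
    assign <- assign_to_medoids(dm[, med, drop = FALSE])
    list(medoids = med, clustering = assign$cluster,
         objective = sum(assign$dist))
  }
  best <- run(NULL)
  if (restarts > 0L && n > k) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    for (r in seq_len(restarts)) {
      cand <- run(sort(sample.int(n, k)))
      if (cand$objective < best$objective - 1e-12) best <- cand
    }
  }
  best
}

# Nearest-medoid assignment; ties go to the lowest medoid index.
assign_to_medoids <- function(dist_to_medoids) {
  cl <- max.col(-dist_to_medoids, ties.method = "first")
  list(cluster = cl,
       dist = dist_to_medoids[cbind(seq_len(nrow(dist_to_medoids)), cl)])
}

#' CLARA clustering of occupied cells (one species-week)
#'
#' The CLARA extension of k-medoids for large point sets: draw `n_samples`
#' subsamples of `sample_size` points, run PAM on each subsample's
#' dissimilarity, assign *all* points to the nearest candidate medoid, and
#' keep the medoid set with the smallest total dissimilarity over all
#' points. When `n <= sample_size` the single subsample is the full set and
#' the result equals PAM on the full data.
#'
#' @param points Data frame of occupied cells: `cell_id`, `lat`, `lon`,
#'   `abundance` (> 0).
#' @param config A `clustering_config`.
#' @return A `cluster_assignment`: list with `cell_id`, `cluster` (1..k),
#'   `medoid_cell_ids`, `total_dissimilarity`, `abundance_share` (fraction
#'   of the week's abundance per cluster, sums to 1), `k`.
#' @export
clara <- function(points, config = clustering_config()) {
  stopifnot(inherits(config, "clustering_config"))
  n <- nrow(points)
  k <- config$k
  if (n < k) stop("fewer points than clusters", call. = FALSE)
  sample_size <- config$sample_size
  if (is.null(sample_size)) sample_size <- min(n, 40L + 2L * k)
  if (sample_size < k) stop("`sample_size` must be at least k", call. = FALSE)
  # order-invariance: work on points sorted by cell_id
  ord <- order(points$cell_id)
  points <- points[ord, , drop = FALSE]
  scaled <- scale_cluster_points(points, config$abundance_weight)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  full_sample <- n <= sample_size
  n_draws <- if (full_sample) 1L else config$n_samples
  best <- NULL
  for (s in seq_len(n_draws)) {
    sub <- if (full_sample) seq_len(n) else sort(sample.int(n, sample_size))
    D_sub <- stats::dist(scaled[sub, , drop = FALSE])
    fit <- pam_medoids(D_sub, k)
    med <- sub[fit$medoids]
    d2m <- point_medoid_distances(scaled, med)
    assign <- assign_to_medoids(d2m)
    obj <- sum(assign$dist)
    if (is.null(best) || obj < best$objective) {
      best <- list(medoids = med, cluster = assign$cluster, objective = obj)
    }
  }
  res <- finalize_assignment(points, best, k)
  if (config$rebalance) res <- rebalance_clusters(res, points, scaled)
  res
}

point_medoid_distances <- function(scaled, medoids) {
  out <- matrix(0, nrow(scaled), length(medoids))
  for (j in seq_along(medoids)) {
    out[, j] <- sqrt(rowSums(sweep(scaled, 2L, scaled[medoids[j], ])^2))
  }
  out
}

finalize_assignment <- function(points, best, k) {
  ab <- tapply(points$abundance, factor(best$cluster, levels = seq_len(k)),
               sum, default = 0)
  structure(
    list(cell_id = points$cell_id, cluster = best$cluster,
         medoid_cell_ids = points$cell_id[best$medoids],
         total_dissimilarity = best$objective,
         abundance_share = as.numeric(ab) / sum(points$abundance),
         k = k),
    class = "cluster_assignment"
  )
}

# Greedy boundary pass: repeatedly move the cheapest cell from the cluster
# with the largest abundance share to the one with the smallest, while the
# spread of shares shrinks. Off by default; equal shares are a reporting
# concept, not a constraint.
rebalance_clusters <- function(res, points, scaled, max_moves = 100L) {
  total <- sum(points$abundance)
  med_idx <- match(res$medoid_cell_ids, points$cell_id)
  d2m <- point_medoid_distances(scaled, med_idx)
  for (it in seq_len(max_moves)) {
    shares <- vapply(seq_len(res$k), function(cl)
      sum(points$abundance[res$cluster == cl]) / total, numeric(1))
    hi <- which.max(shares); lo <- which.min(shares)
    if (shares[hi] - shares[lo] < 1 / (2 * res$k)) break
    cand <- which(res$cluster == hi)
    cand <- cand[!points$cell_id[cand] %in% res$medoid_cell_ids]
    if (!length(cand)) break
    cost <- d2m[cand, lo] - d2m[cand, hi]
    mv <- cand[which.min(cost)]
    new_shares <- shares
    new_shares[hi] <- shares[hi] - points$abundance[mv] / total
    new_shares[lo] <- shares[lo] + points$abundance[mv] / total
    if (max(new_shares) - min(new_shares) >= shares[hi] - shares[lo]) break
    res$cluster[mv] <- lo
  }
  ab <- tapply(points$abundance, factor(res$cluster, levels = seq_len(res$k)),
               sum, default = 0)
  res$abundance_share <- as.numeric(ab) / total
  res
}

#' Occupied cells of one species-week as clustering input
#' @param cube An `abundance_cube`.
#' @param species Species id or index.
#' @param week Week number.
#' @return Data frame `cell_id`, `lat`, `lon`, `abundance` (only cells with
#'   abundance > 0; missing estimates excluded).
#' @export
cluster_points <- function(cube, species, week) {
  a <- cube_slice(cube, species, week)
  keep <- which(!is.na(a) & a > 0)
  data.frame(cell_id = cube$grid$cells$cell_id[keep],
             lat = cube$grid$cells$lat[keep],
             lon = cube$grid$cells$lon[keep],
             abundance = a[keep])
}

#' Cluster every species-week surface of a cube
#'
#' Runs [clara()] independently on the occupied cells of each species-week.
#' The clusters are re-drawn each week: no cluster identity is tracked
#' across weeks. A week with fewer than `k` occupied cells falls back to a
#' single cluster with a warning.
#'
#' @param cube An `abundance_cube`.
#' @param config A `clustering_config`.
#' @return Nested list: `result[[species]][[week index]]` is a
#'   `cluster_assignment`.
#' @export
cluster_weekly <- function(cube, config = clustering_config()) {
  stopifnot(inherits(cube, "abundance_cube"))
  out <- vector("list", length(cube$species))
  names(out) <- cube$species
  for (si in seq_along(cube$species)) {
    out[[si]] <- vector("list", length(cube$weeks))
    for (wi in seq_along(cube$weeks)) {
      pts <- cluster_points(cube, si, cube$weeks[wi])
      if (nrow(pts) == 0L) {
        warning(sprintf("species %s week %d has no occupied cells",
                        cube$species[si], cube$weeks[wi]), call. = FALSE)
        out[[si]][[wi]] <- structure(
          list(cell_id = integer(0), cluster = integer(0),
               medoid_cell_ids = integer(0), total_dissimilarity = 0,
               abundance_share = numeric(0), k = 0L),
          class = "cluster_assignment")
        next
      }
      cfg <- config
      if (nrow(pts) < config$k) {
        warning(sprintf("species %s week %d has %d occupied cells < k = %d; using one cluster",
                        cube$species[si], cube$weeks[wi], nrow(pts),
                        config$k), call. = FALSE)
        cfg$k <- 1L
      }
      out[[si]][[wi]] <- clara(pts, cfg)
    }
  }
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d cells in %d clusters, total dissimilarity %.4f\n",
              length(x$cell_id), x$k, x$total_dissimilarity))
  cat("abundance shares:", paste(sprintf("%.3f", x$abundance_share),
                                 collapse = " "), "\n")
  invisible(x)
}
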