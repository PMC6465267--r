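# Minimum set cover problem construction --------------------------------

#' Build conservation features from abundance cubes
#'
#' A conservation feature is an abundance layer with a representation
#' target. Four constructions are supported, crossing the planning approach
#' with the population treatment:
#'
#' * `weekly`, single population: one feature per species for the given
#'   `week`;
#' * `weekly`, clustered: one feature per species-cluster for the given
#'   week (the representation of a cluster feature is restricted to that
#'   cluster's cells);
#' * `yearly`, single: one feature per species-week over all weeks of the
#'   cube;
#' * `yearly`, clustered: one feature per species-cluster-week.
#'
#' Each feature's target is `target_proportion` times its total abundance
#' (e.g. a species totalling 100 individuals in a week with a 0.30 target
#' must have 30 individuals covered). Missing estimates contribute nothing.
#' Features whose total abundance is zero are dropped with a message.
#'
#' @param cube An `abundance_cube` (all species).
#' @param clusters Optional nested cluster assignments from
#'   [cluster_weekly()]; required for the clustered constructions.
#' @param approach `"weekly"` or `"yearly"`.
#' @param week Week number (required when `approach = "weekly"`).
#' @param target_proportion Fraction of each feature's total to represent
#'   (default 0.30).
#' @return A `feature_set`: data frame with columns `feature_id`,
#'   `species_id`, `week`, `cluster`, `total_abundance`, `target_level`, and
#'   list-columns `cells` (0-based ids) and `r` (representation levels).
#' @export
build_features <- function(cube, clusters = NULL,
                           approach = c("weekly", "yearly"), week = NULL,
                           target_proportion = 0.30) {
  stopifnot(inherits(cube, "abundance_cube"))
  approach <- match.arg(approach)
  if (target_proportion <= 0) stop("`target_proportion` must be positive",
                                   call. = FALSE)
  if (length(cube$weeks) == 0L) stop("`cube` has no weeks", call. = FALSE)
  weeks <- if (approach == "weekly") {
    if (is.null(week)) stop("`week` is required for the weekly approach",
                            call. = FALSE)
    week
  } else cube$weeks

  rows <- list()
  dropped <- 0L
  for (si in seq_along(cube$species)) {
    for (w in weeks) {
      wi <- match(w, cube$weeks)
      a <- cube$values[si, wi, ]
      a[is.na(a)] <- 0
      if (is.null(clusters)) {
        parts <- list(list(cluster = NA_integer_, cells = which(a > 0)))
      } else {
        asg <- clusters[[cube$species[si]]][[wi]]
        if (is.null(asg)) stop("no cluster assignment for species ",
                               cube$species[si], " week ", w, call. = FALSE)
        parts <- lapply(seq_len(max(asg$k, 0L)), function(cl) {
          ids <- asg$cell_id[asg$cluster == cl]
          list(cluster = cl, cells = intersect(ids + 1L, which(a > 0)))
        })
      }
      for (part in parts) {
        tot <- sum(a[part$cells])
        if (tot <= 0) { dropped <- dropped + 1L; next }
        rows[[length(rows) + 1L]] <- list(
          species_id = cube$species[si], week = w, cluster = part$cluster,
          total_abundance = tot,
          target_level = target_proportion * tot,
          cells = as.integer(part$cells - 1L),
          r = a[part$cells]
        )
      }
    }
  }
  if (dropped > 0L) {
    message(dropped, " zero-abundance feature(s) dropped")
  }
  if (length(rows) == 0L) stop("no features with positive abundance",
                               call. = FALSE)
  out <- data.frame(
    feature_id = seq_along(rows),
    species_id = vapply(rows, `[[`, "", "species_id"),
    week = vapply(rows, `[[`, 0, "week"),
    cluster = vapply(rows, function(r) as.integer(r$cluster), 0L),
    total_abundance = vapply(rows, `[[`, 0, "total_abundance"),
    target_level = vapply(rows, `[[`, 0, "target_level")
  )
  out$cells <- lapply(rows, `[[`, "cells")
  out$r <- lapply(rows, `[[`, "r")
  attr(out, "n_cells") <- dim(cube$values)[3L]
  attr(out, "target_proportion") <- target_proportion
  class(out) <- c("feature_set", "data.frame")
  out
}

#' Assemble the minimum set cover problem (Minimize cx s.t. Ax >= b)
#'
#' Builds the integer program whose binary decision variables say whether
#' each planning unit is selected: `c` is the per-unit cost, `A` the sparse
#' representation matrix with `A[i, j]` the abundance of feature `i` in unit
#' `j`, and `b` the feature targets, all constraints with sense `>=`.
#' Zero costs are floored at `cost_floor` so free cells cannot bloat
#' solutions invisibly. Features whose total attainable representation falls
#' short of their target are flagged infeasible at build time (with a
#' warning naming them).
#'
#' @param features A `feature_set` from [build_features()].
#' @param cost A `cost_surface` (or bare numeric cost vector).
#' @param cost_floor Minimum cost applied to zero-cost units (default 1e-6).
#' @return A `prioritization_problem`: list with `c`, `A`
#'   (`Matrix::sparseMatrix`), `b`, `features`, `n_units`, `infeasible`.
#' @export
build_problem <- function(features, cost, cost_floor = 1e-6) {
  stopifnot(inherits(features, "feature_set"))
  n_units <- attr(features, "n_cells")
  cvec <- if (inherits(cost, "cost_surface")) cost$cost else as.numeric(cost)
  if (length(cvec) != n_units) stop("cost length must match planning units",
                                    call. = FALSE)
  if (any(cvec < 0)) stop("costs must be nonnegative", call. = FALSE)
  cvec <- pmax(cvec, cost_floor)
  i <- rep(seq_len(nrow(features)), lengths(features$cells))
  j <- unlist(features$cells) + 1L
  v <- unlist(features$r)
  A <- Matrix::sparseMatrix(i = i, j = j, x = v,
                            dims = c(nrow(features), n_units))
  b <- features$target_level
  attainable <- Matrix::rowSums(A)
  infeasible <- attainable < b - 1e-9
  if (any(infeasible)) {
    warning("infeasible feature(s) at build time: ",
            paste(sprintf("%s w%d%s", features$species_id[infeasible],
                          features$week[infeasible],
                          ifelse(is.na(features$cluster[infeasible]), "",
                                 paste0(" c", features$cluster[infeasible]))),
                  collapse = ", "), call. = FALSE)
  }
  structure(
    list(c = cvec, A = A, b = b, features = features,
         n_units = n_units, infeasible = infeasible),
    class = "prioritization_problem"
  )
}

#' @export
print.prioritization_problem <- function(x, ...) {
  cat(sprintf("prioritization_problem: %d features x %d units (%d nonzeros)%s\n",
              length(x$b), x$n_units, length(x$A@x),
              if (any(x$infeasible)) sprintf(", %d infeasible",
                                             sum(x$infeasible)) else ""))
  invisible(x)
}

#' Verify a solution against the problem it solves
#'
#' Recomputes attained representation `Ax`, per-feature shortfall
#' `max(0, b - Ax)`, and the objective `c . x`, independently of the solver.
#'
#' @param problem A `prioritization_problem`.
#' @param solution A `prioritization_solution` (or bare 0/1 vector).
#' @return Data frame with one row per feature (`feature_id`, `species_id`,
#'   `week`, `cluster`, `target`, `attained`, `shortfall`); attributes
#'   `objective` and `pass` (TRUE iff every shortfall is ~0).
#' @export
verify_solution <- function(problem, solution) {
  stopifnot(inherits(problem, "prioritization_problem"))
  x <- if (inherits(solution, "prioritization_solution")) solution$x
       else as.numeric(solution)
  if (length(x) != problem$n_units) stop("solution length mismatch",
                                         call. = FALSE)
  attained <- as.numeric(problem$A %*% x)
  shortfall <- pmax(0, problem$b - attained)
  out <- data.frame(
    feature_id = problem$features$feature_id,
    species_id = problem$features$species_id,
    week = problem$features$week,
    cluster = problem$features$cluster,
    target = problem$b,
    attained = attained,
    shortfall = shortfall
  )
  attr(out, "objective") <- sum(problem$c * x)
  attr(out, "pass") <- all(shortfall <= 1e-6 * pmax(1, problem$b))
  out
}
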