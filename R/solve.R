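# Exact and brute-force solvers -----------------------------------------

#' Solve a prioritization problem exactly (integer linear programming)
#'
#' Minimizes `c . x` over binary `x` subject to `A x >= b`, using the HiGHS
#' branch-and-bound solver (through SciPy's `milp` interface, run in a
#' bundled Python helper). With the default `gap_tolerance = 0` the returned
#' solution is proven optimal; a positive tolerance allows an early stop at
#' a bounded relative gap for large instances.
#'
#' @param problem A `prioritization_problem`.
#' @param gap_tolerance Relative MIP gap (default 0: prove optimality).
#' @param time_limit Optional time limit in seconds.
#' @return A `prioritization_solution`: list with `x` (integer 0/1 per
#'   unit), `objective` (`c . x`, recomputed in R), `status` (`"optimal"`,
#'   `"feasible_gap"` or `"infeasible"`), `gap`.
#' @export
solve_exact <- function(problem, gap_tolerance = 0, time_limit = NULL) {
  solve_exact_many(list(problem), gap_tolerance = gap_tolerance,
                   time_limit = time_limit)[[1L]]
}

#' Solve several prioritization problems in one solver invocation
#'
#' Identical to [solve_exact()] applied to each element, but amortises the
#' solver start-up over the batch (used for the 52 independent weekly
#' solves).
#'
#' @param problems List of `prioritization_problem`s.
#' @inheritParams solve_exact
#' @return List of `prioritization_solution`s.
#' @export
solve_exact_many <- function(problems, gap_tolerance = 0, time_limit = NULL) {
  stopifnot(length(problems) >= 1L,
            all(vapply(problems, inherits, TRUE, "prioritization_problem")))
  payload <- lapply(problems, function(p) {
    trip <- Matrix::summary(p$A)
    list(c = p$c, b = p$b,
         i = trip$i - 1L, j = trip$j - 1L, v = trip$x,
         n_units = p$n_units,
         gap = gap_tolerance,
         time_limit = if (is.null(time_limit)) -1 else time_limit)
  })
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)))
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "solve_milp.py", package = "flywayplan")
  if (script == "") stop("bundled solver script not found", call. = FALSE)
  status <- system2(find_python(), c(shQuote(script), shQuote(infile),
                                     shQuote(outfile)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile)) {
    stop("exact solver failed: ", paste(status, collapse = "\n"),
         call. = FALSE)
  }
  res <- jsonlite::read_json(outfile, simplifyVector = FALSE)
  lapply(seq_along(problems), function(k) {
    r <- res[[k]]
    if (identical(r$status, "infeasible")) {
      return(structure(list(x = NULL, objective = NA_real_,
                            status = "infeasible", gap = NA_real_),
                       class = "prioritization_solution"))
    }
    x <- as.integer(round(unlist(r$x)))
    gap <- as.numeric(r$gap)
    structure(
      list(x = x,
           objective = sum(problems[[k]]$c * x),
           status = if (gap <= max(gap_tolerance, 1e-9)) "optimal"
                    else "feasible_gap",
           gap = gap),
      class = "prioritization_solution"
    )
  })
}

find_python <- function() {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("no python interpreter on PATH (required for solve_exact)",
                     call. = FALSE)
  py
}

#' Exhaustive oracle for small prioritization problems
#'
#' Enumerates all 2^n subsets of planning units (n <= 20) and returns the
#' minimum-cost feasible selection. Among equal-cost optima the
#' lexicographically smallest selection (compared as the sorted vector of
#' selected unit ids) wins, which makes the oracle fully deterministic.
#' Used as the independent reference for [solve_exact()].
#'
#' @param problem A `prioritization_problem` with at most 20 units.
#' @return A `prioritization_solution` (status `"optimal"` or
#'   `"infeasible"`).
#' @export
solve_bruteforce <- function(problem) {
  stopifnot(inherits(problem, "prioritization_problem"))
  n <- problem$n_units
  if (n > 20L) stop("brute force limited to 20 planning units", call. = FALSE)
  A <- as.matrix(problem$A)
  b <- problem$b
  cost <- problem$c
  best_x <- NULL
  best_obj <- Inf
  for (code in 0:(2^n - 1)) {
    x <- as.integer(intToBits(code)[seq_len(n)] == 1L)
    if (any(A %*% x < b - 1e-9)) next
    obj <- sum(cost * x)
    if (obj < best_obj - 1e-12 ||
        (abs(obj - best_obj) <= 1e-12 && lex_smaller(x, best_x))) {
      best_obj <- obj
      best_x <- x
    }
  }
  if (is.null(best_x)) {
    return(structure(list(x = NULL, objective = NA_real_,
                          status = "infeasible", gap = NA_real_),
                     class = "prioritization_solution"))
  }
  structure(list(x = best_x, objective = best_obj, status = "optimal",
                 gap = 0),
            class = "prioritization_solution")
}

# TRUE if selection x (0/1) is lexicographically smaller than y as sorted
# id vectors: the first unit where they differ is selected in x only.
lex_smaller <- function(x, y) {
  if (is.null(y)) return(TRUE)
  d <- which(x != y)
  if (!length(d)) return(FALSE)
  x[d[1L]] == 1L
}

#' @export
print.prioritization_solution <- function(x, ...) {
  if (x$status == "infeasible") {
    cat("prioritization_solution: infeasible\n")
  } else {
    cat(sprintf("prioritization_solution: %d units selected, objective %.6g (%s)\n",
                sum(x$x), x$objective, x$status))
  }
  invisible(x)
}
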