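# Checklist observation process -----------------------------------------

#' Parameters of the checklist observation process
#'
#' The observation model is a two-part, zero-inflated count process designed
#' to mirror the structure the abundance estimator assumes. A checklist at a
#' cell with true abundance `a` records, for each species, a count drawn as:
#'
#' * occupancy/availability: with probability
#'   `plogis(occ_intercept + occ_slope * log(a))` the species is present and
#'   available (0 if `a = 0`);
#' * detection: an available species is found with probability
#'   `1 - (1 - detect_per_person)^party_size` (party size affects detection
#'   only);
#' * count: if found, `Poisson(detection_scale * a * duration_h *
#'   sqrt(1 + distance_km))` — mean proportional to true abundance times an
#'   increasing function of search effort.
#'
#' Setting `occ_intercept = Inf` and `detect_per_person = 1` makes
#' presence/detection certain, so the expected count has the closed form
#' `detection_scale * a * duration_h * sqrt(1 + distance_km)`.
#'
#' @param occ_intercept,occ_slope Logistic occupancy parameters on
#'   log-abundance.
#' @param detect_per_person Per-person detection probability in (0, 1].
#' @param duration_meanlog,duration_sdlog Lognormal parameters for checklist
#'   duration (hours).
#' @param distance_meanlog,distance_sdlog Lognormal parameters for transect
#'   distance (km).
#' @param party_lambda Party size is `1 + Poisson(party_lambda)`.
#' @param start_time_range Hours (0-24) between which checklists start.
#' @param years Calendar years checklists are drawn from.
#' @param effort_density Optional nonnegative weight per planning cell giving
#'   the spatial density of observer effort; default uniform. (The spatial
#'   distribution of real observer effort is not modelled; this knob lets
#'   users impose one.)
#' @return An `effort_model` list.
#' @export
effort_model <- function(occ_intercept = 2, occ_slope = 1.5,
                         detect_per_person = 0.9,
                         duration_meanlog = 0, duration_sdlog = 0.4,
                         distance_meanlog = 0, distance_sdlog = 0.4,
                         party_lambda = 0.7,
                         start_time_range = c(5, 12),
                         years = 2004:2016,
                         effort_density = NULL) {
  structure(
    list(occ_intercept = occ_intercept, occ_slope = occ_slope,
         detect_per_person = detect_per_person,
         duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog,
         distance_meanlog = distance_meanlog, distance_sdlog = distance_sdlog,
         party_lambda = party_lambda, start_time_range = start_time_range,
         years = years, effort_density = effort_density),
    class = "effort_model"
  )
}

#' Simulate checklist-style observations from a true abundance cube
#'
#' Draws `n_checklists` search events (location, date, effort covariates) and
#' one count per species per event from the zero-inflated observation process
#' described in [effort_model()]. Days of year map to weeks as
#' `week = min(ceiling(day / 7), n_weeks)`.
#'
#' @param cube A (true) `abundance_cube` with no missing values.
#' @param n_checklists Number of search events (>= 1).
#' @param effort An `effort_model`.
#' @param detection_scale Positive scale linking abundance x effort to the
#'   expected count.
#' @param seed Integer seed.
#' @return A data frame with one row per checklist x species:
#'   `checklist_id`, `lat`, `lon`, `cell_id`, `day_of_year`, `week`, `year`,
#'   `start_time`, `duration_h`, `distance_km`, `party_size`, `species_id`,
#'   `count`.
#' @export
simulate_checklists <- function(cube, n_checklists, effort = effort_model(),
                                detection_scale = 1, seed = 1L) {
  stopifnot(inherits(cube, "abundance_cube"), inherits(effort, "effort_model"))
  if (length(cube$species) == 0L || all(dim(cube$values) == 0L)) {
    stop("`cube` is empty", call. = FALSE)
  }
  if (anyNA(cube$values)) stop("`cube` must be fully defined", call. = FALSE)
  if (n_checklists < 1) stop("`n_checklists` must be >= 1", call. = FALSE)
  if (detection_scale <= 0) stop("`detection_scale` must be positive",
                                 call. = FALSE)
  grid <- cube$grid
  n_weeks <- length(cube$weeks)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  w_cell <- effort$effort_density
  if (is.null(w_cell)) w_cell <- rep(1, n_cells(grid))
  cell <- sample.int(n_cells(grid), n_checklists, replace = TRUE,
                     prob = w_cell) - 1L
  # uniform position within the cell
  row <- cell %/% grid$n_cols
  col <- cell %% grid$n_cols
  sz <- grid$cell_size_km
  x_km <- (col + stats::runif(n_checklists)) * sz
  y_km <- (row + stats::runif(n_checklists)) * sz
  day <- sample.int(7L * n_weeks, n_checklists, replace = TRUE)
  week <- pmin(ceiling(day / 7), n_weeks)
  events <- data.frame(
    checklist_id = seq_len(n_checklists),
    lat = grid$origin["lat"] + y_km / KM_PER_DEG,
    lon = grid$origin["lon"] + x_km / KM_PER_DEG,
    cell_id = cell,
    day_of_year = day,
    week = week,
    year = sample(effort$years, n_checklists, replace = TRUE),
    start_time = stats::runif(n_checklists, effort$start_time_range[1],
                              effort$start_time_range[2]),
    duration_h = stats::rlnorm(n_checklists, effort$duration_meanlog,
                               effort$duration_sdlog),
    distance_km = stats::rlnorm(n_checklists, effort$distance_meanlog,
                                effort$distance_sdlog),
    party_size = 1L + stats::rpois(n_checklists, effort$party_lambda),
    row.names = NULL
  )

  p_det <- 1 - (1 - effort$detect_per_person)^events$party_size
  out <- vector("list", length(cube$species))
  for (si in seq_along(cube$species)) {
    wi <- match(events$week, cube$weeks)
    a <- cube$values[cbind(si, wi, events$cell_id + 1L)]
    p_occ <- ifelse(a > 0,
                    stats::plogis(effort$occ_intercept +
                                    effort$occ_slope * log(a)),
                    0)
    mu <- detection_scale * a * events$duration_h *
      sqrt(1 + events$distance_km)
    present <- stats::runif(nrow(events)) < p_occ * p_det
    cnt <- integer(nrow(events))
    cnt[present] <- stats::rpois(sum(present), mu[present])
    df <- events
    df$species_id <- cube$species[si]
    df$count <- cnt
    out[[si]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expected checklist count under certain detection
#'
#' Closed-form mean of the observation process when occupancy and detection
#' are certain: `detection_scale * abundance * duration_h *
#' sqrt(1 + distance_km)`. Used as the analytic reference for Monte-Carlo
#' checks of [simulate_checklists()].
#'
#' @param abundance True abundance at the cell.
#' @param duration_h,distance_km Effort covariates.
#' @param detection_scale Scale as in [simulate_checklists()].
#' @return Expected count.
#' @export
expected_count <- function(abundance, duration_h, distance_km,
                           detection_scale = 1) {
  detection_scale * abundance * duration_h * sqrt(1 + distance_km)
}
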