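# Ensemble abundance estimator (spatiotemporal block design) ------------

#' Configuration of the ensemble abundance estimator
#'
#' Holds the hyperparameters of the two-step (occupancy x conditional
#' abundance) base models, the ensemble support rule, and the standardized
#' search effort at which relative abundance is rendered (expected count on a
#' 1 h, 1 km search by a single observer starting at 7:00).
#'
#' @param learner Base learner pair: `"glm"` (logistic + Poisson GLM; fast
#'   and deterministic, the default), `"tree"` (rpart classification +
#'   regression trees), or `"gbm"` (boosted regression trees via xgboost,
#'   using `bag_fraction`, `shrinkage`, `n_trees` and the two tree depths).
#' @param bag_fraction,shrinkage,n_trees Boosting hyperparameters (defaults
#'   0.80, 0.05, 1000).
#' @param depth_occupancy,depth_abundance Tree depths of the occurrence and
#'   abundance steps (defaults 5 and 10).
#' @param min_checklists Minimum checklists in a spatiotemporal block for a
#'   base model to be fitted (default 50).
#' @param min_detections Minimum detections of the species in the block
#'   (default 10).
#' @param min_support Minimum number of contributing base models for an
#'   ensemble estimate to be rendered (default 50); cells below this are
#'   missing.
#' @param holdout_fraction Fraction of checklists withheld for validation
#'   (default 0.10); used only for reporting, never for fitting.
#' @param predictors Character vector of model terms. Spatial terms default
#'   to a quadratic surface in lat/lon plus elevation; temporal terms to day
#'   of year, year and start time; effort terms to log duration, log(1 +
#'   distance) and party size.
#' @param standardized_effort Named list giving the effort at which estimates
#'   are rendered.
#' @return A `stem_config` list.
#' @export
stem_config <- function(learner = c("glm", "tree", "gbm"),
                        bag_fraction = 0.80, shrinkage = 0.05, n_trees = 1000L,
                        depth_occupancy = 5L, depth_abundance = 10L,
                        min_checklists = 50L, min_detections = 10L,
                        min_support = 50L, holdout_fraction = 0.10,
                        predictors = NULL,
                        standardized_effort = list(start_time = 7,
                                                   duration_h = 1,
                                                   distance_km = 1,
                                                   party_size = 1L)) {
  learner <- match.arg(learner)
  stopifnot(bag_fraction > 0, shrinkage > 0, n_trees > 0,
            depth_occupancy > 0, depth_abundance > 0,
            min_checklists > 0, min_detections > 0, min_support > 0,
            holdout_fraction > 0, holdout_fraction < 1)
  if (is.null(predictors)) {
    predictors <- c("lat", "lon", "I(lat^2)", "I(lon^2)", "I(lat*lon)",
                    "elev", "day_of_year", "I(lat*day_of_year)",
                    "I(lon*day_of_year)", "year", "start_time",
                    "log_duration", "log_distance", "party_size")
  }
  structure(
    list(learner = learner, bag_fraction = bag_fraction,
         shrinkage = shrinkage, n_trees = as.integer(n_trees),
         depth_occupancy = as.integer(depth_occupancy),
         depth_abundance = as.integer(depth_abundance),
         min_checklists = as.integer(min_checklists),
         min_detections = as.integer(min_detections),
         min_support = as.integer(min_support),
         holdout_fraction = holdout_fraction,
         predictors = predictors,
         standardized_effort = standardized_effort),
    class = "stem_config"
  )
}

#' Design the Monte-Carlo ensemble of spatiotemporal partitions
#'
#' Draws `n_partitions` randomly offset tilings of the study extent into
#' spatiotemporal blocks. Blocks are `north_block_deg` degrees square north
#' of `latitude_split_deg` and `south_block_deg` degrees square south of it
#' (defaults 10, 20 and 12: smaller blocks where observation density is
#' higher), crossed with 30-continuous-day windows that wrap around the year
#' end. Within a partition every (location, day) belongs to exactly one
#' block.
#'
#' Note 366 is not divisible by 30, so in every partition one temporal
#' window per year absorbs the 6 leftover days (36 days); all others are
#' exactly 30.
#'
#' @param extent Named numeric vector `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max` (e.g. from [grid_extent()]).
#' @param n_partitions Number of random partitions (default 100).
#' @param north_block_deg,south_block_deg,latitude_split_deg Block sizes and
#'   the latitude dividing them.
#' @param day_window Temporal window length in days (default 30).
#' @param seed Integer seed.
#' @return A `stem_design`: list with the parameters above and a data frame
#'   `partitions` of per-partition uniform offsets.
#' @export
design_ensemble <- function(extent, n_partitions = 100L,
                            north_block_deg = 10, south_block_deg = 20,
                            latitude_split_deg = 12, day_window = 30L,
                            seed = 1L) {
  req <- c("lat_min", "lat_max", "lon_min", "lon_max")
  if (!all(req %in% names(extent))) {
    stop("`extent` must be named lat_min/lat_max/lon_min/lon_max",
         call. = FALSE)
  }
  if (extent["lat_max"] <= extent["lat_min"] ||
      extent["lon_max"] <= extent["lon_min"]) {
    stop("`extent` is empty", call. = FALSE)
  }
  if (n_partitions < 1) stop("`n_partitions` must be >= 1", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_partitions <- as.integer(n_partitions)
  partitions <- data.frame(
    partition = seq_len(n_partitions),
    lat_off_n = stats::runif(n_partitions, 0, north_block_deg),
    lon_off_n = stats::runif(n_partitions, 0, north_block_deg),
    lat_off_s = stats::runif(n_partitions, 0, south_block_deg),
    lon_off_s = stats::runif(n_partitions, 0, south_block_deg),
    day_off = sample.int(366L, n_partitions, replace = TRUE) - 1L
  )
  structure(
    list(extent = extent, n_partitions = n_partitions,
         north_block_deg = north_block_deg, south_block_deg = south_block_deg,
         latitude_split_deg = latitude_split_deg,
         day_window = as.integer(day_window), partitions = partitions),
    class = "stem_design"
  )
}

# Block key for each (lat, lon, day) in one partition; vectorised.
# Keys are strings band|bx|by|bt. The last temporal index is capped so the
# 366-day circle is tiled (final window absorbs the remainder days).
block_key <- function(design, partition, lat, lon, day) {
  p <- design$partitions[partition, ]
  north <- lat >= design$latitude_split_deg
  size <- ifelse(north, design$north_block_deg, design$south_block_deg)
  lat_off <- ifelse(north, p$lat_off_n, p$lat_off_s)
  lon_off <- ifelse(north, p$lon_off_n, p$lon_off_s)
  bx <- floor((lon - lon_off) / size)
  by <- floor((lat - lat_off) / size)
  n_windows <- 366L %/% design$day_window
  bt <- pmin(((day - 1L - p$day_off) %% 366L) %/% design$day_window,
             n_windows - 1L)
  paste(ifelse(north, "N", "S"), bx, by, bt, sep = "|")
}

#' Describe the block containing a location-date in each partition
#'
#' Returns the spatial and temporal span of the spatiotemporal block that
#' contains `(lat, lon, day)` under each partition of the design (useful for
#' verifying the tiling: each location-date is covered by exactly one block
#' per partition).
#'
#' @param design A `stem_design`.
#' @param lat,lon,day Scalars: location (degrees) and day of year.
#' @return Data frame, one row per partition: block key, `lon_min`,
#'   `lon_max`, `lat_min`, `lat_max`, `day_start`, `n_days`.
#' @export
locate_block <- function(design, lat, lon, day) {
  stopifnot(inherits(design, "stem_design"))
  n_windows <- 366L %/% design$day_window
  out <- lapply(seq_len(design$n_partitions), function(i) {
    p <- design$partitions[i, ]
    north <- lat >= design$latitude_split_deg
    size <- if (north) design$north_block_deg else design$south_block_deg
    lat_off <- if (north) p$lat_off_n else p$lat_off_s
    lon_off <- if (north) p$lon_off_n else p$lon_off_s
    bx <- floor((lon - lon_off) / size)
    by <- floor((lat - lat_off) / size)
    bt <- min(((day - 1L - p$day_off) %% 366L) %/% design$day_window,
              n_windows - 1L)
    n_days <- if (bt == n_windows - 1L) {
      366L - design$day_window * (n_windows - 1L)
    } else design$day_window
    data.frame(
      partition = i,
      key = block_key(design, i, lat, lon, day),
      lon_min = bx * size + lon_off, lon_max = (bx + 1) * size + lon_off,
      lat_min = by * size + lat_off, lat_max = (by + 1) * size + lat_off,
      day_start = (p$day_off + bt * design$day_window) %% 366L + 1L,
      n_days = n_days
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Build the model frame (response + predictors) from checklist rows.
stem_model_frame <- function(rows, grid, elevation = NULL) {
  elev <- if (is.null(elevation)) rep(0, nrow(rows)) else
    elevation[rows$cell_id + 1L]
  data.frame(
    count = rows$count,
    detected = as.integer(rows$count > 0),
    lat = rows$lat, lon = rows$lon, elev = elev,
    day_of_year = rows$day_of_year, year = rows$year,
    start_time = rows$start_time,
    log_duration = log(rows$duration_h),
    log_distance = log1p(rows$distance_km),
    party_size = rows$party_size
  )
}

# --- base learner pair --------------------------------------------------

fit_base_model <- function(d, config) {
  rhs <- paste(config$predictors, collapse = " + ")
  occ_fml <- stats::as.formula(paste("detected ~", rhs))
  abd_fml <- stats::as.formula(paste("count ~", rhs))
  pos <- d[d$detected == 1L, , drop = FALSE]
  switch(config$learner,
    glm = {
      occ <- suppressWarnings(stats::glm(occ_fml, data = d,
                                         family = stats::binomial()))
      abd <- suppressWarnings(stats::glm(abd_fml, data = pos,
                                         family = stats::poisson()))
      list(occ = occ, abd = abd, learner = "glm",
           lambda_cap = max(pos$count))
    },
    tree = {
      occ <- rpart::rpart(occ_fml, data = d, method = "anova",
                          control = rpart::rpart.control(cp = 0.001,
                                                         minbucket = 5))
      abd <- rpart::rpart(abd_fml, data = pos, method = "anova",
                          control = rpart::rpart.control(cp = 0.001,
                                                         minbucket = 5))
      list(occ = occ, abd = abd, learner = "tree",
           lambda_cap = max(pos$count))
    },
    gbm = {
      if (!requireNamespace("xgboost", quietly = TRUE)) {
        stop("learner 'gbm' needs the xgboost package", call. = FALSE)
      }
      mm <- stats::model.matrix(occ_fml, d)[, -1L, drop = FALSE]
      occ <- xgboost::xgboost(
        data = mm, label = d$detected, nrounds = config$n_trees,
        params = list(objective = "binary:logistic",
                      max_depth = config$depth_occupancy,
                      eta = config$shrinkage,
                      subsample = config$bag_fraction, nthread = 1L),
        verbose = 0)
      mmp <- stats::model.matrix(abd_fml, pos)[, -1L, drop = FALSE]
      abd <- xgboost::xgboost(
        data = mmp, label = pos$count, nrounds = config$n_trees,
        params = list(objective = "count:poisson",
                      max_depth = config$depth_abundance,
                      eta = config$shrinkage,
                      subsample = config$bag_fraction, nthread = 1L),
        verbose = 0)
      list(occ = occ, abd = abd, learner = "gbm",
           occ_fml = occ_fml, abd_fml = abd_fml,
           lambda_cap = max(pos$count))
    }
  )
}

predict_base_model <- function(model, newdata) {
  switch(model$learner,
    glm = {
      p <- suppressWarnings(stats::predict(model$occ, newdata = newdata,
                                           type = "response"))
      lam <- suppressWarnings(stats::predict(model$abd, newdata = newdata,
                                             type = "response"))
      # local models must not extrapolate beyond counts seen in their block
      lam <- pmin(lam, model$lambda_cap)
      pmax(0, p) * pmax(0, lam)
    },
    tree = {
      p <- pmin(1, pmax(0, stats::predict(model$occ, newdata = newdata)))
      lam <- pmax(0, stats::predict(model$abd, newdata = newdata))
      p * lam
    },
    gbm = {
      nd <- newdata
      nd$detected <- 0L; nd$count <- 0L
      mm <- stats::model.matrix(model$occ_fml, nd)[, -1L, drop = FALSE]
      p <- stats::predict(model$occ, mm)
      lam <- pmin(stats::predict(model$abd, mm), model$lambda_cap)
      pmax(0, p) * pmax(0, lam)
    }
  )
}

#' Fit the ensemble of block-local zero-inflated base models
#'
#' Withholds `holdout_fraction` of checklists, then, for every partition of
#' the design and every spatiotemporal block containing at least
#' `min_checklists` training checklists with at least `min_detections`
#' detections of the species, fits a two-step base model: an occupancy step
#' predicting detection, and an abundance step predicting the count
#' conditional on detection. Blocks failing the support rule are removed
#' from the ensemble.
#'
#' @param checklists Checklist data frame from [simulate_checklists()] (or
#'   with the same columns).
#' @param species Species id to model.
#' @param design A `stem_design` from [design_ensemble()].
#' @param config A `stem_config`.
#' @param grid The `planning_grid` (used to attach cell-level covariates).
#' @param elevation Optional elevation covariate per planning cell (see
#'   [make_elevation()]); if absent the `elev` predictor is dropped.
#' @param seed Integer seed (holdout split).
#' @return A `stem_fit`: list with `models` (named list keyed
#'   partition|block), `design`, `config`, `species`, `holdout` (validation
#'   rows), `n_models`, and `train_years`.
#' @export
fit_stem <- function(checklists, species, design, config = stem_config(),
                     grid = NULL, elevation = NULL, seed = 1L) {
  stopifnot(inherits(design, "stem_design"), inherits(config, "stem_config"))
  rows <- checklists[checklists$species_id == species, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no checklists for species ", species,
                             call. = FALSE)
  if (is.null(elevation)) {
    config$predictors <- setdiff(config$predictors, "elev")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- unique(rows$checklist_id)
  n_hold <- max(1L, round(config$holdout_fraction * length(ids)))
  hold_ids <- sample(ids, n_hold)
  holdout <- rows[rows$checklist_id %in% hold_ids, , drop = FALSE]
  train <- rows[!rows$checklist_id %in% hold_ids, , drop = FALSE]
  frame <- stem_model_frame(train, grid, elevation)

  models <- new.env(parent = emptyenv())
  n_models <- 0L
  for (p in seq_len(design$n_partitions)) {
    keys <- block_key(design, p, train$lat, train$lon, train$day_of_year)
    for (k in unique(keys)) {
      idx <- which(keys == k)
      if (length(idx) < config$min_checklists) next
      d <- frame[idx, , drop = FALSE]
      if (sum(d$detected) < config$min_detections) next
      m <- tryCatch(fit_base_model(d, config), error = function(e) NULL)
      if (is.null(m)) next
      assign(paste(p, k, sep = "|"), m, envir = models)
      n_models <- n_models + 1L
    }
  }
  if (n_models == 0L) {
    warning("no spatiotemporal block met the support rule; empty ensemble",
            call. = FALSE)
  }
  structure(
    list(models = models, design = design, config = config,
         species = species, holdout = holdout, n_models = n_models,
         train_years = sort(unique(train$year)), elevation = elevation),
    class = "stem_fit"
  )
}

#' Predict the weekly relative-abundance cube from a fitted ensemble
#'
#' For every week and planning cell, averages `occupancy x conditional
#' abundance` over all base models whose spatiotemporal block contains the
#' cell centre and the week's mid-week day, evaluating each at the
#' standardized search effort. Estimates with fewer than
#' `config$min_support` contributing models are missing (`NA`).
#'
#' @param fit A `stem_fit`.
#' @param grid A `planning_grid` to predict on.
#' @param weeks Integer weeks to render (default 1:52).
#' @param partitions Optional subset of partition indices to use (default
#'   all; restricting partitions can only lower support).
#' @return An estimated `abundance_cube` (one species) carrying a
#'   `support` array `[week, cell]`.
#' @export
predict_abundance <- function(fit, grid, weeks = 1:52, partitions = NULL) {
  stopifnot(inherits(fit, "stem_fit"), inherits(grid, "planning_grid"))
  config <- fit$config
  design <- fit$design
  if (is.null(partitions)) partitions <- seq_len(design$n_partitions)
  nc <- n_cells(grid)
  est <- matrix(0, length(weeks), nc)
  support <- matrix(0L, length(weeks), nc)
  eff <- config$standardized_effort
  base_nd <- data.frame(
    lat = grid$cells$lat, lon = grid$cells$lon,
    elev = if (is.null(fit$elevation)) rep(0, nc) else fit$elevation,
    day_of_year = 0L,
    year = stats::median(fit$train_years),
    start_time = eff$start_time,
    log_duration = log(eff$duration_h),
    log_distance = log1p(eff$distance_km),
    party_size = eff$party_size
  )
  for (wi in seq_along(weeks)) {
    day <- (weeks[wi] - 1L) * 7L + 4L
    nd <- base_nd
    nd$day_of_year <- day
    for (p in partitions) {
      keys <- block_key(design, p, nd$lat, nd$lon, day)
      for (k in unique(keys)) {
        m <- get0(paste(p, k, sep = "|"), envir = fit$models)
        if (is.null(m)) next
        idx <- which(keys == k)
        pred <- predict_base_model(m, nd[idx, , drop = FALSE])
        est[wi, idx] <- est[wi, idx] + pred
        support[wi, idx] <- support[wi, idx] + 1L
      }
    }
  }
  vals <- ifelse(support >= config$min_support, est / pmax(1L, support),
                 NA_real_)
  vals <- pmax(vals, 0)
  abundance_cube(array(vals, dim = c(1L, length(weeks), nc)),
                 grid = grid, species = fit$species, weeks = weeks,
                 support = support)
}

#' @export
print.stem_fit <- function(x, ...) {
  cat(sprintf("stem_fit: species %s, %d base models over %d partitions (%s learner)\n",
              x$species, x$n_models, x$design$n_partitions,
              x$config$learner))
  invisible(x)
}

#' Holdout validation summary of a fitted ensemble
#'
#' Predicts expected counts for the withheld checklists (at their observed
#' effort, not the standardized effort) and reports rank correlation and
#' mean absolute error against observed counts. Reporting only — the holdout
#' never influences fitting.
#'
#' @param fit A `stem_fit`.
#' @param grid The `planning_grid`.
#' @return List with `n`, `spearman`, `mae`.
#' @export
validate_stem <- function(fit, grid) {
  stopifnot(inherits(fit, "stem_fit"))
  h <- fit$holdout
  if (nrow(h) == 0L) return(list(n = 0L, spearman = NA_real_, mae = NA_real_))
  frame <- stem_model_frame(h, grid, fit$elevation)
  pred <- rep(0, nrow(h)); supp <- rep(0L, nrow(h))
  for (p in seq_len(fit$design$n_partitions)) {
    keys <- block_key(fit$design, p, h$lat, h$lon, h$day_of_year)
    for (k in unique(keys)) {
      m <- get0(paste(p, k, sep = "|"), envir = fit$models)
      if (is.null(m)) next
      idx <- which(keys == k)
      pred[idx] <- pred[idx] + predict_base_model(m, frame[idx, , drop = FALSE])
      supp[idx] <- supp[idx] + 1L
    }
  }
  ok <- supp > 0L
  pred[ok] <- pred[ok] / supp[ok]
  list(n = sum(ok),
       spearman = if (sum(ok) > 2)
         suppressWarnings(stats::cor(pred[ok], h$count[ok],
                                     method = "spearman")) else NA_real_,
       mae = mean(abs(pred[ok] - h$count[ok])))
}
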