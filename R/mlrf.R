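# Regression-forest growth prediction and clipping-replacement dosing.

mlrf_feature_names <- c("soil_moisture_3d", "traffic_weekly", "ndre",
                        "root_zone", "days_between_mowing",
                        "tmax", "tmin", "tavg", "precip",
                        "rhmax", "rhmin", "rhavg", "wind_avg", "et",
                        "n_rate_recent")

#' Assemble the growth-model feature table from observations
#'
#' Builds one feature row per clipping-collection event: the running-mean
#' soil moisture of the event and the previous event, weekly traffic
#' intensity, NDRE at collection, the root-zone label, days since the last
#' mowing, the event day's weather (Tmax, Tmin, Tavg, precipitation, RHmax,
#' RHmin, RHavg, average wind, reference ET) and the fertilizer N applied in
#' the 14 days up to the event. The target is the clipping mass collected at
#' the event (the sum of daily growth since the previous collection).
#'
#' Events whose date has no weather row are excluded with a message.
#'
#' @param observations daily observation data.frame
#'   (`date, clipping_yield, ndre, soil_moisture, traffic, ...`), e.g.
#'   `run_season(...)$observations`.
#' @param weather weather series covering the observation dates.
#' @param fert_log fertilization log (`date, dose_kg_ha`); may be `NULL`.
#' @param root_zone zone label (character) or a [root_zone_profile()].
#' @param sampling_interval days between collection events (default 2,
#'   "approximately every other day" mowing).
#' @param provenance free-text tag recording which seasons the rows came
#'   from.
#' @return An object of class `training_set`: list with `features`
#'   (data.frame), `targets` (g m-2 per collection), `dates`, `provenance`.
#' @export
build_features <- function(observations, weather, fert_log = NULL,
                           root_zone = "A", sampling_interval = 2L,
                           provenance = "unspecified") {
  if (inherits(root_zone, "root_zone_profile")) root_zone <- root_zone$zone_id
  obs <- observations[order(as.Date(observations$date)), , drop = FALSE]
  obs$date <- as.Date(obs$date)
  wdates <- as.Date(weather$date)
  n <- nrow(obs)
  ev <- seq(as.integer(sampling_interval), n, by = as.integer(sampling_interval))
  if (length(ev) == 0 || !any(obs$date %in% wdates))
    stop("no overlapping observation/weather dates to assemble features from",
         call. = FALSE)

  rows <- vector("list", length(ev))
  targets <- numeric(length(ev))
  keep <- logical(length(ev))
  prev_start <- 1L
  prev_moisture <- obs$soil_moisture[1]
  fdates <- if (!is.null(fert_log) && nrow(fert_log)) as.Date(fert_log$date) else as.Date(character())
  for (k in seq_along(ev)) {
    i <- ev[k]
    d <- obs$date[i]
    wi <- match(d, wdates)
    targets[k] <- sum(obs$clipping_yield[prev_start:i])
    sm3 <- mean(c(obs$soil_moisture[i], prev_moisture))
    n_recent <- if (length(fdates)) {
      sum(fert_log$dose_kg_ha[fdates > d - 14 & fdates <= d])
    } else 0
    if (!is.na(wi)) {
      keep[k] <- TRUE
      rows[[k]] <- data.frame(
        soil_moisture_3d = sm3,
        traffic_weekly = obs$traffic[i],
        ndre = obs$ndre[i],
        root_zone = root_zone,
        days_between_mowing = i - prev_start + 1L,
        tmax = weather$tmax[wi], tmin = weather$tmin[wi],
        tavg = weather$tavg[wi], precip = weather$precip[wi],
        rhmax = weather$rhmax[wi], rhmin = weather$rhmin[wi],
        rhavg = weather$rhavg[wi], wind_avg = weather$wind_avg[wi],
        et = weather$et[wi],
        n_rate_recent = n_recent,
        stringsAsFactors = FALSE)
    }
    prev_start <- i + 1L
    prev_moisture <- obs$soil_moisture[i]
  }
  if (!all(keep))
    message(sum(!keep), " collection event(s) dropped: no weather for their dates")
  features <- do.call(rbind, rows[keep])
  structure(list(features = features,
                 targets = targets[keep],
                 dates = obs$date[ev[keep]],
                 provenance = provenance),
            class = "training_set")
}

#' Combine training sets from several seasons or zones
#' @param ... `training_set` objects.
#' @return A single `training_set`.
#' @export
combine_training_sets <- function(...) {
  sets <- list(...)
  structure(list(features = do.call(rbind, lapply(sets, `[[`, "features")),
                 targets = unlist(lapply(sets, `[[`, "targets")),
                 dates = do.call(c, lapply(sets, `[[`, "dates")),
                 provenance = paste(vapply(sets, `[[`, "", "provenance"),
                                    collapse = " + ")),
            class = "training_set")
}

#' Train the regression-forest growth model
#'
#' Fits a [regression_forest()] of per-collection clipping yield on the
#' feature set, reproducibly under `seed`. If every feature column is
#' degenerate (zero variance) a mean predictor is returned with a warning.
#'
#' @param train a `training_set` from [build_features()].
#' @param seed integer seed.
#' @param n_trees trees in the ensemble (default 500).
#' @param min_rows minimum training rows required (default 50).
#' @param ... further arguments to [regression_forest()].
#' @return An object of class `growth_predictor`.
#' @export
train_growth_model <- function(train, seed = 1L, n_trees = 500,
                               min_rows = 50, ...) {
  stopifnot(inherits(train, "training_set"))
  if (nrow(train$features) < min_rows)
    stop(sprintf("need >= %d training rows, got %d", min_rows,
                 nrow(train$features)), call. = FALSE)
  if (any(train$targets < 0)) stop("targets must be non-negative", call. = FALSE)
  enc <- encode_predictors(train$features)$matrix
  if (all(apply(enc, 2, function(c) stats::var(c) < 1e-24))) {
    warning("all features are degenerate (zero variance); returning a mean predictor",
            call. = FALSE)
    return(structure(list(forest = NULL, mean = mean(train$targets),
                          seed = as.integer(seed),
                          provenance = train$provenance),
                     class = "growth_predictor"))
  }
  forest <- regression_forest(train$features, train$targets,
                              n_trees = n_trees, seed = seed, ...)
  structure(list(forest = forest, mean = mean(train$targets),
                 seed = as.integer(seed), provenance = train$provenance),
            class = "growth_predictor")
}

#' Per-event clipping predictions
#'
#' @param object a `growth_predictor`.
#' @param newdata feature data.frame (columns as in [build_features()]).
#' @param ... unused.
#' @return Non-negative predicted clipping per collection event, g m-2.
#' @export
predict.growth_predictor <- function(object, newdata, ...) {
  if (NROW(newdata) == 0) stop("empty feature set", call. = FALSE)
  if (is.null(object$forest)) return(rep(object$mean, NROW(newdata)))
  pmax(0, predict(object$forest, newdata))
}

#' Predicted two-week cumulative clipping yield
#'
#' Sums the per-event predictions over the collection events of the upcoming
#' 14-day interval.
#'
#' @param model a `growth_predictor`.
#' @param features feature rows for the interval's collection events.
#' @return Predicted cumulative clipping, g m-2 per two weeks (>= 0).
#' @export
predict_biweekly_yield <- function(model, features) {
  sum(predict(model, features))
}

#' Clipping-replacement dosing rule
#'
#' Converts a predicted two-week clipping yield into a nitrogen dose. The
#' target band `[low, high]` corresponds to visual quality between 6 and 7
#' (daily clipping 1.25-1.6 g m-2 d-1):
#' within the band, the dose replaces the nitrogen the predicted clippings
#' remove (`yield x tissue_n x 10` kg ha-1); below the band the dose is
#' computed from the band median (`median_target`), pushing growth up into
#' the band; above the band no nitrogen is applied.
#'
#' @param low,high band bounds, g m-2 per two weeks (defaults 17.5, 22.5).
#' @param median_target band median used by the below-band branch
#'   (default 20).
#' @param ncp [nitrogen_cycle_params()].
#' @return An object of class `mlrf_dose_rule`.
#' @export
mlrf_dose_rule <- function(low = 17.5, high = 22.5, median_target = 20,
                           ncp = nitrogen_cycle_params()) {
  if (!(low < median_target && median_target < high))
    stop("need low < median_target < high", call. = FALSE)
  structure(list(low = low, high = high, median_target = median_target,
                 ncp = ncp),
            class = "mlrf_dose_rule")
}

#' Three-branch clipping-replacement dose
#'
#' @param predicted_yield predicted cumulative clipping for the coming two
#'   weeks, g m-2 (>= 0).
#' @param rule a [mlrf_dose_rule()].
#' @param decision_date optional date attached to the recommendation.
#' @return A [recommendation()]; the branch taken is one of `"replacement"`
#'   (in band, dose = yield x tissue N x 10), `"below-band"`
#'   (dose from the band median) or `"above-band"` (zero dose).
#' @examples
#' mlrf_dose(20)$dose_kg_ha   # 7.8
#' mlrf_dose(25)$dose_kg_ha   # 0
#' @export
mlrf_dose <- function(predicted_yield, rule = mlrf_dose_rule(),
                      decision_date = NA) {
  if (!is.finite(predicted_yield) || predicted_yield < 0)
    stop("`predicted_yield` must be finite and non-negative", call. = FALSE)
  k <- rule$ncp$tissue_n_fraction * rule$ncp$area_mass_conversion
  if (predicted_yield > rule$high) {
    recommendation(decision_date, 0, "mlrf", "above-band",
                   info = list(predicted_yield = predicted_yield))
  } else if (predicted_yield < rule$low) {
    recommendation(decision_date, rule$median_target * k, "mlrf", "below-band",
                   info = list(predicted_yield = predicted_yield))
  } else {
    recommendation(decision_date, predicted_yield * k, "mlrf", "replacement",
                   info = list(predicted_yield = predicted_yield))
  }
}

#' Regression-forest dosing strategy
#'
#' On each decision day, assembles forecast-free feature rows for the
#' upcoming 14-day interval (weather from the supplied realized series;
#' NDRE, soil moisture and traffic persisted from the latest readings;
#' nitrogen rate from the previous application), predicts the interval's
#' cumulative clipping with the trained forest, and doses through
#' [mlrf_dose()]. Supply either a fitted `model` or `train_runs`
#' (prior-season `season_run`s) from which the model is trained when the
#' season starts.
#'
#' @param model a fitted `growth_predictor`, or `NULL`.
#' @param train_runs list of prior `season_run` objects used to train when
#'   `model` is `NULL`.
#' @param rule a [mlrf_dose_rule()].
#' @param sampling_interval days between collection events (default 2).
#' @param n_trees,seed forest training controls (used with `train_runs`).
#' @return An object of classes `strategy_mlrf`/`n_strategy`.
#' @export
strategy_mlrf <- function(model = NULL, train_runs = NULL,
                          rule = mlrf_dose_rule(), sampling_interval = 2L,
                          n_trees = 500, seed = 1L) {
  if (is.null(model) && is.null(train_runs))
    stop("strategy_mlrf needs a fitted model or prior-season training runs",
         call. = FALSE)
  structure(list(model = model, train_runs = train_runs, rule = rule,
                 sampling_interval = as.integer(sampling_interval),
                 n_trees = n_trees, seed = as.integer(seed), name = "mlrf"),
            class = c("strategy_mlrf", "n_strategy"))
}

#' @export
strategy_begin.strategy_mlrf <- function(strategy, ...) {
  if (!is.null(strategy$model)) return(strategy)
  sets <- lapply(strategy$train_runs, function(run) {
    build_features(run$observations, run$weather, run$fert_log,
                   root_zone = run$zone,
                   sampling_interval = strategy$sampling_interval,
                   provenance = paste0("virtual season, zone ", run$zone$zone_id))
  })
  train <- do.call(combine_training_sets, sets)
  strategy$model <- train_growth_model(train, seed = strategy$seed,
                                       n_trees = strategy$n_trees)
  strategy$train_runs <- NULL
  strategy
}

# Feature rows for the collection events of the interval starting today.
# Weather comes from the supplied (realized) series; canopy and management
# readings persist from the latest observation; N rate is the previous
# interval's application.
upcoming_features <- function(strategy, ctx) {
  i <- ctx$day_index
  n <- nrow(ctx$weather)
  days <- seq(i + strategy$sampling_interval - 1L,
              min(n, i + ctx$interval_days - 1L),
              by = strategy$sampling_interval)
  if (length(days) == 0) days <- i
  last_obs <- if (!is.null(ctx$observations) && nrow(ctx$observations))
    ctx$observations[nrow(ctx$observations), ] else NULL
  ndre_now <- if (!is.null(last_obs)) last_obs$ndre else ctx$state$ndre
  n_recent <- if (!is.null(ctx$fert_log) && nrow(ctx$fert_log))
    ctx$fert_log$dose_kg_ha[nrow(ctx$fert_log)] else 0
  do.call(rbind, lapply(days, function(d) {
    data.frame(
      soil_moisture_3d = mean(ctx$management$moisture[max(1L, d - strategy$sampling_interval):d]),
      traffic_weekly = ctx$management$traffic[d],
      ndre = ndre_now,
      root_zone = ctx$zone$zone_id,
      days_between_mowing = strategy$sampling_interval,
      tmax = ctx$weather$tmax[d], tmin = ctx$weather$tmin[d],
      tavg = ctx$weather$tavg[d], precip = ctx$weather$precip[d],
      rhmax = ctx$weather$rhmax[d], rhmin = ctx$weather$rhmin[d],
      rhavg = ctx$weather$rhavg[d], wind_avg = ctx$weather$wind_avg[d],
      et = ctx$weather$et[d],
      n_rate_recent = n_recent,
      stringsAsFactors = FALSE)
  }))
}

#' @export
decide.strategy_mlrf <- function(strategy, ctx) {
  if (is.null(strategy$model))
    stop("mlrf strategy is untrained; call strategy_begin() or supply a model",
         call. = FALSE)
  feats <- upcoming_features(strategy, ctx)
  y_hat <- predict_biweekly_yield(strategy$model, feats)
  mlrf_dose(y_hat, strategy$rule, decision_date = ctx$date)
}
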