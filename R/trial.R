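# End-to-end virtual trials: years x zones x strategies x replicates.

#' Configuration of a virtual fertilization trial
#'
#' Mirrors the field design the package emulates: several growing seasons on
#' two root zones, four nitrogen strategies plus an unfertilized control,
#' with replicate plots in a completely randomized design. When the
#' regression-forest strategy is included, the first year is run under the
#' experience schedule on every zone to create its training data (as a field
#' calibration year would); the remaining years are the evaluation years on
#' which every strategy is applied. After each evaluation year the
#' experience-plot data of that year are added to the forest's training
#' pool.
#'
#' @param climate a [climate_config()].
#' @param zones named list of [root_zone_profile()]s (default
#'   [default_zones()]).
#' @param strategies character vector among
#'   `"gp", "experience", "mlrf", "ndre"` (all four by default). An
#'   unfertilized control is always added for NUE accounting.
#' @param years total years including any training year (default 2).
#'   `"mlrf"` requires `years >= 2`.
#' @param replicates plots per zone x strategy (default 4).
#' @param master_seed integer master seed; all plot, year and training seeds
#'   are derived from it.
#' @param ncp,growth,gp_rule,ndre_rule,mlrf_rule,experience per-strategy
#'   parameter objects.
#' @param n_trees forest size for the mlrf strategy (default 500).
#' @param calibration_doses fixed biweekly doses (kg ha-1) applied to the
#'   calibration-year plots on every zone (default `c(0, 5, 10, 17.5)`).
#'   The gradient makes the training data span the nitrogen-status range the
#'   forest must later predict over; a forest trained only on well-fertilized
#'   turf cannot extrapolate to nitrogen-starved canopies.
#' @param interval_days shared decision interval (default 14).
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(climate = climate_config(),
                         zones = default_zones(),
                         strategies = c("gp", "experience", "mlrf", "ndre"),
                         years = 2L, replicates = 4L, master_seed = 1L,
                         ncp = nitrogen_cycle_params(),
                         growth = growth_params(),
                         gp_rule = gp_dose_rule(ncp = ncp),
                         ndre_rule = strategy_ndre(),
                         mlrf_rule = mlrf_dose_rule(ncp = ncp),
                         experience = strategy_experience(),
                         n_trees = 500,
                         calibration_doses = c(0, 5, 10, 17.5),
                         interval_days = 14L) {
  strategies <- match.arg(strategies,
                          c("gp", "experience", "mlrf", "ndre"),
                          several.ok = TRUE)
  if (anyDuplicated(strategies)) stop("strategy names must be unique", call. = FALSE)
  if (years < 1) stop("`years` must be >= 1", call. = FALSE)
  if ("mlrf" %in% strategies && years < 2)
    stop("the mlrf strategy needs at least one training year before its first decision year (years >= 2)",
         call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  structure(list(climate = climate, zones = zones, strategies = strategies,
                 years = as.integer(years), replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed),
                 ncp = ncp, growth = growth, gp_rule = gp_rule,
                 ndre_rule = ndre_rule, mlrf_rule = mlrf_rule,
                 experience = experience, n_trees = n_trees,
                 calibration_doses = calibration_doses,
                 interval_days = as.integer(interval_days)),
            class = "trial_config")
}

make_strategy <- function(name, config, train_runs = NULL, year_seed = 0L) {
  switch(name,
    gp = strategy_gp(config$gp_rule),
    experience = config$experience,
    ndre = config$ndre_rule,
    control = strategy_fixed(0),
    mlrf = strategy_mlrf(train_runs = train_runs, rule = config$mlrf_rule,
                         n_trees = config$n_trees,
                         seed = derive_seed(config$master_seed, 777L, year_seed)),
    stop("unknown strategy: ", name, call. = FALSE))
}

#' Run a virtual fertilization trial
#'
#' Executes the full design described in [trial_config()] and assembles the
#' comparison report: one nitrogen-budget row per plot, per-strategy totals,
#' and predicted/observed ratio statistics for the two growth-predicting
#' strategies (growth potential and regression forest). Budgets and NUE are
#' accumulated over the evaluation years (the training year is calibration
#' only). Fully reproducible from `master_seed`.
#'
#' @param config a [trial_config()].
#' @return An object of class `trial_report`: list with `summary` (one row
#'   per plot), `strategy_totals`, `ratio_stats`, `fert_logs`,
#'   `metadata`.
#' @export
run_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  zones <- config$zones
  strategies <- c(config$strategies, "control")
  has_mlrf <- "mlrf" %in% config$strategies
  years_train <- if (has_mlrf) 1L else 0L
  eval_years <- seq.int(years_train + 1L, config$years)

  # one weather series per year, shared by every plot (same facility)
  weather_by_year <- lapply(seq_len(config$years), function(y) {
    cl <- config$climate
    cl$season_start <- cl$season_start + 365L * (y - 1L)
    generate_weather(cl, seed = derive_seed(config$master_seed, 9000L, y))
  })

  # calibration year(s): a fixed-dose nitrogen gradient on every zone, so
  # the forest's training data cover the nitrogen-status range
  train_runs <- list()
  if (years_train > 0) {
    for (y in seq_len(years_train)) {
      for (zi in seq_along(zones)) {
        for (di in seq_along(config$calibration_doses)) {
          run <- run_season(zones[[zi]],
                            strategy = strategy_fixed(config$calibration_doses[di],
                                                      name = "calibration"),
                            seed = derive_seed(config$master_seed, y, zi, 0L, di),
                            ncp = config$ncp, growth = config$growth,
                            weather = weather_by_year[[y]],
                            interval_days = config$interval_days)
          train_runs[[length(train_runs) + 1L]] <- run
        }
      }
    }
  }

  rows <- list()
  fert_logs <- list()
  interval_records <- list()
  plot_runs <- list()   # per zone/strategy/replicate: list of yearly runs

  for (y in eval_years) {
    weather <- weather_by_year[[y]]
    for (s in strategies) {
      # build (and for the forest, train) each strategy once per year; the
      # trained model is then shared by every plot of that year
      strat <- strategy_begin(make_strategy(s, config, train_runs = train_runs,
                                            year_seed = y))
      for (zi in seq_along(zones)) {
        zone <- zones[[zi]]
        for (r in seq_len(config$replicates)) {
          seed <- derive_seed(config$master_seed, y, zi, match(s, strategies), r)
          run <- run_season(zone, strategy = strat, seed = seed,
                            ncp = config$ncp, growth = config$growth,
                            weather = weather,
                            interval_days = config$interval_days)
          key <- paste(zone$zone_id, s, r, sep = "|")
          plot_runs[[key]] <- c(plot_runs[[key]], list(run))
          log <- run$fert_log
          log$zone <- zone$zone_id; log$replicate <- r; log$year <- y
          fert_logs[[length(fert_logs) + 1L]] <- log
          if (s %in% c("gp", "mlrf")) {
            interval_records[[length(interval_records) + 1L]] <-
              prediction_intervals(run, s, config)
          }
        }
      }
    }
    # growing training pool: this year's plots join next year's forest
    # training data (one replicate per zone and strategy)
    if (has_mlrf && y < config$years) {
      for (zi in seq_along(zones)) {
        for (s in intersect(strategies, c("experience", "mlrf", "ndre", "gp"))) {
          key <- paste(zones[[zi]]$zone_id, s, 1L, sep = "|")
          yr_runs <- plot_runs[[key]]
          train_runs[[length(train_runs) + 1L]] <- yr_runs[[length(yr_runs)]]
        }
      }
    }
  }

  # control clipping per zone (mean over replicates, cumulative over eval years)
  control_clip <- vapply(zones, function(z) {
    keys <- paste(z$zone_id, "control", seq_len(config$replicates), sep = "|")
    mean(vapply(keys, function(k)
      sum(vapply(plot_runs[[k]], function(run) run$final_state$cum_clipping, 0)),
      0))
  }, 0)

  for (key in names(plot_runs)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    zid <- parts[1]; s <- parts[2]; r <- as.integer(parts[3])
    runs <- plot_runs[[key]]
    cum_clip <- sum(vapply(runs, function(run) run$final_state$cum_clipping, 0))
    cum_n <- sum(vapply(runs, season_n_applied, 0))
    obs <- do.call(rbind, lapply(runs, `[[`, "observations"))
    b <- n_budget(cum_clip, cum_n, control_clip[[zid]], config$ncp)
    rows[[length(rows) + 1L]] <- data.frame(
      zone = zid, strategy = s, replicate = r,
      cum_n_applied = cum_n, cum_clipping = cum_clip,
      uptake = b$uptake, nue = b$nue,
      mean_daily_clipping = mean(obs$clipping_yield),
      mean_ndre = mean(obs$ndre),
      mean_quality = mean(obs$quality),
      seed = runs[[1]]$seed,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  summary <- summary[order(summary$zone, summary$strategy, summary$replicate), ]
  rownames(summary) <- NULL

  totals <- stats::aggregate(
    cbind(cum_n_applied, cum_clipping, nue, mean_quality, mean_ndre) ~ zone + strategy,
    data = summary, FUN = mean, na.action = stats::na.pass)

  ratios <- list()
  if (length(interval_records)) {
    ir <- do.call(rbind, interval_records)
    for (s in intersect(c("gp", "mlrf"), unique(ir$strategy))) {
      for (zid in unique(ir$zone)) {
        sel <- ir$strategy == s & ir$zone == zid & ir$observed > 0
        if (any(sel))
          ratios[[paste(s, zid, sep = ".")]] <-
            ratio_stats(ir$predicted[sel], ir$observed[sel])
      }
    }
  }

  structure(list(summary = summary,
                 strategy_totals = totals,
                 ratio_stats = ratios,
                 fert_logs = do.call(rbind, fert_logs),
                 control_clipping = control_clip,
                 metadata = list(master_seed = config$master_seed,
                                 years = config$years,
                                 eval_years = eval_years,
                                 replicates = config$replicates,
                                 strategies = strategies,
                                 plot_seeds = stats::setNames(
                                   vapply(plot_runs, function(rs) rs[[1]]$seed, 0L),
                                   names(plot_runs)),
                                 package_version = as.character(utils::packageVersion("greenkeeper")))),
            class = "trial_report")
}

# Predicted vs observed biweekly clipping for one growth-predicting run.
# For the forest the prediction is the logged predicted yield; for the GP
# strategy it is mean GP x maximum growth rate x interval (its implied
# growth forecast).
prediction_intervals <- function(run, strategy, config) {
  log <- run$fert_log
  n <- nrow(run$observations)
  obs <- run$observations$clipping_yield
  dates <- run$observations$date
  pred <- numeric(nrow(log)); observed <- numeric(nrow(log))
  for (k in seq_len(nrow(log))) {
    i <- match(log$date[k], dates)
    span <- i:min(n, i + run$interval_days - 1L)
    observed[k] <- sum(obs[span])
    pred[k] <- if (strategy == "mlrf") log$input_value[k]
               else log$input_value[k] * config$gp_rule$max_growth_rate *
                    run$interval_days
  }
  data.frame(strategy = strategy, zone = run$zone$zone_id,
             date = log$date, predicted = pred, observed = observed,
             stringsAsFactors = FALSE)
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("Virtual N trial (master seed %d): %d plots\n",
              x$metadata$master_seed, nrow(x$summary)))
  print(x$strategy_totals, digits = 3)
  invisible(x)
}

#' Export a trial report to CSV and JSON
#'
#' Writes `report.csv` (one row per plot), `fertilization_log.csv`, and
#' `report.json` (summary, totals, ratio statistics and full metadata
#' including the master seed and every per-plot seed). The CSV/JSON pair
#' round-trips through [read_report()].
#'
#' @param report a `trial_report`.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
export_report <- function(report, dir) {
  stopifnot(inherits(report, "trial_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  utils::write.csv(report$summary, file.path(dir, "report.csv"), row.names = FALSE)
  write_fert_csv(report$fert_logs, file.path(dir, "fertilization_log.csv"))
  payload <- list(
    summary = report$summary,
    strategy_totals = report$strategy_totals,
    ratio_stats = lapply(report$ratio_stats, function(r)
      r[c("min", "q25", "median", "q75", "max")]),
    control_clipping = as.list(report$control_clipping),
    metadata = report$metadata)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Re-import an exported trial report
#'
#' @param dir directory written by [export_report()].
#' @return A list with `summary`, `fert_log` and `metadata`.
#' @export
read_report <- function(dir) {
  summary <- utils::read.csv(file.path(dir, "report.csv"), stringsAsFactors = FALSE)
  js <- jsonlite::read_json(file.path(dir, "report.json"), simplifyVector = TRUE)
  fert <- read_fert_csv(file.path(dir, "fertilization_log.csv"))
  list(summary = summary, fert_log = fert, metadata = js$metadata,
       strategy_totals = js$strategy_totals, ratio_stats = js$ratio_stats)
}
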