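# Decision strategies: the common decide() interface, the experience-based
# schedule, and the NDRE virtual-reference threshold rule.

#' Consult a strategy for a nitrogen recommendation
#'
#' Generic dispatched on the strategy object. `ctx` is the decision context
#' assembled by [run_season()]: day index and date, the weather series, the
#' observation history to date, the management series, the current
#' [plot_state()], the zone, the decision interval and the fertilization log.
#'
#' @param strategy a strategy object.
#' @param ctx decision context (list).
#' @return A [recommendation()].
#' @export
decide <- function(strategy, ctx) UseMethod("decide")

# Hook called once before a season starts (used by the forest strategy to
# train on supplied prior seasons). Default: no-op.
strategy_begin <- function(strategy, ...) UseMethod("strategy_begin")
#' @export
strategy_begin.default <- function(strategy, ...) strategy

#' Experience-based fixed schedule
#'
#' The traditional plan: a fixed dose at every biweekly application over the
#' growing season, regardless of conditions (10 kg ha-1 every other week over
#' a ~30-week season, i.e. ~150 kg ha-1 per season).
#'
#' @param dose dose per application, kg ha-1 (default 10).
#' @param interval_days days between applications (default 14).
#' @param season_weeks length of the season in weeks (default 30).
#' @param season_start first day of the season (default "2021-05-01"); used
#'   by the standalone [experience_dose()] date arithmetic.
#' @return An object of classes `strategy_experience`/`n_strategy`.
#' @export
strategy_experience <- function(dose = 10, interval_days = 14,
                                season_weeks = 30,
                                season_start = "2021-05-01") {
  stop_if_not_number(dose, "dose", lower = 0)
  stop_if_not_number(interval_days, "interval_days", lower = 1)
  structure(list(dose = dose, interval_days = as.integer(interval_days),
                 season_weeks = season_weeks,
                 season_start = as.Date(season_start),
                 name = "experience"),
            class = c("strategy_experience", "n_strategy"))
}

#' @export
decide.strategy_experience <- function(strategy, ctx) {
  recommendation(date = ctx$date, dose_kg_ha = strategy$dose,
                 strategy = "experience", branch = "scheduled",
                 info = list(dose = strategy$dose))
}

#' Experience-schedule dose for an arbitrary date
#'
#' Standalone date-based form of the schedule: returns the configured dose on
#' each biweekly application date (season start, start + 14, ...), zero
#' between applications, and a zero dose flagged `"off-season"` outside the
#' configured season. The seasonal total is
#' `dose * floor(season_weeks / 2)`.
#'
#' @param decision_date a `Date` (or ISO string).
#' @param schedule a [strategy_experience()].
#' @return A [recommendation()].
#' @examples
#' s <- strategy_experience()
#' experience_dose("2021-05-15", s)$dose_kg_ha # 10 (day 14 of the season)
#' @export
experience_dose <- function(decision_date, schedule = strategy_experience()) {
  d <- as.Date(decision_date)
  off <- as.integer(d - schedule$season_start)
  season_days <- schedule$season_weeks * 7
  if (off < 0 || off >= season_days) {
    return(recommendation(d, 0, "experience", "off-season"))
  }
  if (off %% schedule$interval_days == 0) {
    recommendation(d, schedule$dose, "experience", "scheduled")
  } else {
    recommendation(d, 0, "experience", "between-applications")
  }
}

#' NDRE virtual-reference threshold rule
#'
#' Withholds nitrogen while the canopy reads sufficiently "green": if the
#' mean NDRE over the preceding `lookback_days` exceeds `threshold` (the
#' virtual-reference reading of turf at minimally acceptable quality 6), no
#' fertilizer is applied; otherwise a fixed dose is applied. At a window mean
#' exactly equal to the threshold the rule fertilizes (withholding requires
#' strictly greater).
#'
#' @param threshold NDRE reference value (default 0.28).
#' @param dose dose when below or at the threshold, kg ha-1 (default 10).
#' @param lookback_days length of the NDRE averaging window (default 14).
#' @return An object of classes `strategy_ndre`/`n_strategy`.
#' @export
strategy_ndre <- function(threshold = 0.28, dose = 10, lookback_days = 14) {
  stop_if_not_number(threshold, "threshold", lower = 1e-12)
  if (threshold >= 1) stop("`threshold` must be in (0, 1)", call. = FALSE)
  stop_if_not_number(dose, "dose", lower = 0)
  structure(list(threshold = threshold, dose = dose,
                 lookback_days = as.integer(lookback_days),
                 name = "ndre"),
            class = c("strategy_ndre", "n_strategy"))
}

#' NDRE-rule dose from a reading history
#'
#' Averages the NDRE readings in the half-open window
#' `(decision_date - lookback_days, decision_date]` and applies the
#' two-branch rule. The recommendation records the window mean and the
#' branch taken.
#'
#' @param ndre_history data.frame with `date` and `ndre` columns.
#' @param decision_date decision `Date`.
#' @param rule a [strategy_ndre()].
#' @return A [recommendation()].
#' @export
ndre_dose <- function(ndre_history, decision_date, rule = strategy_ndre()) {
  d <- as.Date(decision_date)
  if (is.null(ndre_history) || nrow(ndre_history) == 0)
    stop("ndre_dose requires at least one NDRE reading in the lookback window",
         call. = FALSE)
  dates <- as.Date(ndre_history$date)
  in_win <- dates > d - rule$lookback_days & dates <= d
  if (!any(in_win))
    stop("no NDRE readings within the lookback window", call. = FALSE)
  m <- mean(ndre_history$ndre[in_win])
  if (m > rule$threshold) {
    recommendation(d, 0, "ndre", "sufficient", info = list(mean_ndre = m))
  } else {
    recommendation(d, rule$dose, "ndre", "fertilize", info = list(mean_ndre = m))
  }
}

#' @export
decide.strategy_ndre <- function(strategy, ctx) {
  obs <- ctx$observations
  if (is.null(obs) || nrow(obs) == 0) {
    # First decision of a season: no canopy history yet, so fertilize
    # (sufficiency cannot be established).
    return(recommendation(ctx$date, strategy$dose, "ndre", "first-application"))
  }
  ndre_dose(obs[, c("date", "ndre")], ctx$date, strategy)
}

#' Growth-potential dosing strategy
#'
#' Wraps [gp_dose()] for use inside [run_season()]: at each decision the mean
#' growth potential over the days since the previous application (up to
#' `rule$interval_days`, fewer at the start of a season) scales the capped
#' replacement dose. Weather-only: recommendations are identical across root
#' zones.
#'
#' @param rule a [gp_dose_rule()].
#' @param params a [gp_params()].
#' @return An object of classes `strategy_gp`/`n_strategy`.
#' @export
strategy_gp <- function(rule = gp_dose_rule(), params = gp_params()) {
  structure(list(rule = rule, params = params, name = "gp"),
            class = c("strategy_gp", "n_strategy"))
}

#' @export
decide.strategy_gp <- function(strategy, ctx) {
  i <- ctx$day_index
  lb <- ctx$weather[max(1L, i - strategy$rule$interval_days + 1L):i, , drop = FALSE]
  gp_dose(lb, strategy$rule, strategy$params, decision_date = ctx$date)
}

#' Fixed-dose strategy
#'
#' Applies the same dose at every decision (use `dose = 0` for an
#' unfertilized control plot).
#'
#' @param dose dose per application, kg ha-1.
#' @param name strategy label (default "fixed", or "control" when the dose
#'   is zero).
#' @return An object of classes `strategy_fixed`/`n_strategy`.
#' @export
strategy_fixed <- function(dose, name = if (dose == 0) "control" else "fixed") {
  stop_if_not_number(dose, "dose", lower = 0)
  structure(list(dose = dose, name = name),
            class = c("strategy_fixed", "n_strategy"))
}

#' @export
decide.strategy_fixed <- function(strategy, ctx) {
  recommendation(ctx$date, strategy$dose, strategy$name, "fixed")
}

#' @export
print.n_strategy <- function(x, ...) {
  cat(sprintf("N strategy: %s\n", x$name))
  invisible(x)
}
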