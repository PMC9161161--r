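# Growth potential model and its fertilizer dosing application.

#' Temperature-based turfgrass growth potential
#'
#' Gaussian growth potential
#' `GP = exp(-0.5 * ((T - t_opt) / var)^2)`, a 0-1 index of expected growth
#' for a given average air temperature. For cool-season grass (`t_opt = 20`,
#' `var = 5.5`) the potential is 100% at 20 C and falls symmetrically toward
#' 0 at 0 and 40 C.
#'
#' @param tavg average air temperature, degrees C (vectorized).
#' @param params a [gp_params()].
#' @return Growth potential in (0, 1], same length as `tavg`.
#' @examples
#' growth_potential(20)           # 1
#' growth_potential(c(15, 25))    # symmetric about the optimum
#' @export
growth_potential <- function(tavg, params = gp_params()) {
  stopifnot(inherits(params, "gp_params"))
  if (!is.numeric(tavg) || any(!is.finite(tavg)))
    stop("`tavg` must be finite numeric", call. = FALSE)
  exp(-0.5 * ((tavg - params$t_opt) / params$var)^2)
}

#' Growth-potential dosing rule
#'
#' Couples the growth potential to a nitrogen dose through a maximum daily
#' growth rate: at full potential the rule replaces the nitrogen contained in
#' `max_growth_rate` grams of clippings per m2 per day over the application
#' interval. With the defaults (3.2 g m-2 d-1, 3.9% tissue N, 14 days) the
#' biweekly cap is 3.2 x 0.039 x 14 x 10 = 17.47 kg ha-1.
#'
#' @param max_growth_rate maximum daily clipping growth rate, g m-2 d-1
#'   (default 3.2). Usually calibrated from a prior season via
#'   [calibrate_max_daily_n()].
#' @param interval_days days between fertilization events (default 14).
#' @param ncp [nitrogen_cycle_params()].
#' @return An object of class `gp_dose_rule`.
#' @export
gp_dose_rule <- function(max_growth_rate = 3.2, interval_days = 14,
                         ncp = nitrogen_cycle_params()) {
  stop_if_not_number(max_growth_rate, "max_growth_rate", lower = 1e-12)
  stop_if_not_number(interval_days, "interval_days", lower = 1)
  structure(
    list(max_growth_rate = max_growth_rate,
         interval_days = as.integer(interval_days),
         ncp = ncp),
    class = "gp_dose_rule")
}

#' Calibrate the maximum daily nitrogen use rate from prior growth data
#'
#' The maximum daily N use rate is the nitrogen contained in the chosen
#' quantile (default: the maximum) of a prior season's daily clipping yields:
#' `quantile(prior_clipping) * tissue_n_fraction`, in g N m-2 d-1.
#'
#' @param prior_clipping non-negative daily clipping yields from a previous
#'   season on the same root zone, g m-2 d-1.
#' @param ncp [nitrogen_cycle_params()].
#' @param quantile which quantile of the prior yields to treat as the
#'   maximum growth rate, in (0, 1] (default 1, the observed maximum).
#' @return Maximum daily N use rate, g N m-2 d-1.
#' @examples
#' calibrate_max_daily_n(c(1, 2, 3.2)) # 3.2 * 0.039 = 0.1248
#' @export
calibrate_max_daily_n <- function(prior_clipping, ncp = nitrogen_cycle_params(),
                                  quantile = 1) {
  if (length(prior_clipping) == 0)
    stop("cannot calibrate from an empty clipping series", call. = FALSE)
  if (any(!is.finite(prior_clipping)) || any(prior_clipping < 0))
    stop("`prior_clipping` must be finite and non-negative", call. = FALSE)
  stop_if_not_number(quantile, "quantile", lower = 1e-12, upper = 1)
  as.numeric(stats::quantile(prior_clipping, probs = quantile, names = FALSE) *
               ncp$tissue_n_fraction)
}

#' Growth-potential nitrogen dose for one application event
#'
#' The dose equals the mean growth potential over the lookback window times
#' the maximum daily N use rate times the number of days in the interval,
#' converted to kg ha-1:
#' `dose = mean(GP) * max_growth_rate * tissue_n_fraction * interval_days * 10`.
#' Because mean GP is at most 1, the dose never exceeds the cap
#' `max_growth_rate * tissue_n_fraction * interval_days * 10`
#' (17.47 kg ha-1 at the defaults).
#'
#' @param weather_lookback weather rows (needing only `tavg` and `date`) for
#'   the days since the previous application; at the first event of a season
#'   all available days are used.
#' @param rule a [gp_dose_rule()].
#' @param params a [gp_params()].
#' @param decision_date optional date attached to the recommendation.
#' @return A [recommendation()] in kg ha-1, with the window-mean GP recorded.
#' @export
gp_dose <- function(weather_lookback, rule = gp_dose_rule(),
                    params = gp_params(), decision_date = NA) {
  stopifnot(inherits(rule, "gp_dose_rule"))
  if (is.null(weather_lookback) || NROW(weather_lookback) == 0)
    stop("gp_dose requires at least one day of weather lookback", call. = FALSE)
  gp_mean <- mean(growth_potential(weather_lookback$tavg, params))
  cap_daily_n <- rule$max_growth_rate * rule$ncp$tissue_n_fraction  # g N m-2 d-1
  dose <- gp_mean * cap_daily_n * rule$interval_days *
    rule$ncp$area_mass_conversion
  recommendation(date = decision_date, dose_kg_ha = dose, strategy = "gp",
                 branch = "gp_scaled", info = list(mean_gp = gp_mean))
}

#' A dated nitrogen dose recommendation
#'
#' The common currency of all strategies: a date, a dose in kg ha-1, the
#' strategy that produced it, the rule branch taken, and the branch's input
#' diagnostics (mean GP, window-mean NDRE, or predicted yield), so every
#' recommendation is auditable.
#'
#' @param date decision date.
#' @param dose_kg_ha nitrogen dose, kg ha-1 (>= 0).
#' @param strategy strategy label.
#' @param branch label of the rule branch that produced the dose.
#' @param info named list of diagnostic inputs.
#' @return An object of class `recommendation`.
#' @export
recommendation <- function(date, dose_kg_ha, strategy, branch, info = list()) {
  if (!is.finite(dose_kg_ha) || dose_kg_ha < 0)
    stop("dose must be finite and non-negative", call. = FALSE)
  structure(list(date = date, dose_kg_ha = dose_kg_ha,
                 strategy = strategy, branch = branch, info = info),
            class = "recommendation")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(sprintf("N recommendation [%s] %s: %.1f kg ha-1 (branch: %s)\n",
              x$strategy, as.character(x$date), x$dose_kg_ha, x$branch))
  if (length(x$info))
    cat("  inputs:", paste(sprintf("%s=%.4g", names(x$info),
                                   unlist(x$info)), collapse = ", "), "\n")
  invisible(x)
}
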