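# Stochastic daily weather generator for the virtual green.

#' Climate configuration for the synthetic weather generator
#'
#' Describes a single growing season: a seasonal sinusoid for average air
#' temperature (rising from the season edges to a mid-season peak, emulating
#' a May-to-October upper-Midwest season) plus AR(1) day-to-day noise, a
#' simple wet-day/exponential-amount precipitation process, and relative
#' humidity/wind/reference-ET processes derived from the temperature series.
#'
#' @param season_start first day of the season (`Date` or ISO string,
#'   default "2021-05-01").
#' @param season_length_days length of the season in days (default 210,
#'   about 30 weeks). Must be at least 28: the decision rules need one
#'   14-day lookback plus one subsequent decision.
#' @param mean_peak_temp mid-season peak of the average-temperature sinusoid,
#'   degrees C (default 23).
#' @param temp_amplitude difference between the peak and the season edges,
#'   degrees C (default 8). With the defaults the season-long mean
#'   temperature is near 20 C.
#' @param temp_ar1_coeff AR(1) coefficient of the temperature noise, in
#'   `[0, 1)` (default 0.7).
#' @param temp_noise_sd innovation standard deviation of the temperature
#'   noise, degrees C (default 1.5).
#' @param precip_wet_prob probability a day is wet (default 0.35).
#' @param precip_mean_mm mean precipitation on wet days, mm (default 6).
#' @param seed integer seed; identical seed gives an identical series.
#' @return An object of class `climate_config`.
#' @export
climate_config <- function(season_start = "2021-05-01",
                           season_length_days = 210,
                           mean_peak_temp = 23,
                           temp_amplitude = 8,
                           temp_ar1_coeff = 0.7,
                           temp_noise_sd = 1.5,
                           precip_wet_prob = 0.35,
                           precip_mean_mm = 6,
                           seed = 1L) {
  stop_if_not_number(season_length_days, "season_length_days", lower = 1)
  if (season_length_days < 28)
    stop("`season_length_days` must be >= 28 (one 14-day lookback plus one decision)",
         call. = FALSE)
  stop_if_not_number(temp_ar1_coeff, "temp_ar1_coeff", lower = 0)
  if (temp_ar1_coeff >= 1)
    stop("`temp_ar1_coeff` must be in [0, 1)", call. = FALSE)
  stop_if_not_number(temp_noise_sd, "temp_noise_sd", lower = 0)
  stop_if_not_number(precip_wet_prob, "precip_wet_prob", lower = 0, upper = 1)
  structure(
    list(season_start = as.Date(season_start),
         season_length_days = as.integer(season_length_days),
         mean_peak_temp = mean_peak_temp,
         temp_amplitude = temp_amplitude,
         temp_ar1_coeff = temp_ar1_coeff,
         temp_noise_sd = temp_noise_sd,
         precip_wet_prob = precip_wet_prob,
         precip_mean_mm = precip_mean_mm,
         seed = as.integer(seed)),
    class = "climate_config")
}

#' Generate a season of synthetic daily weather
#'
#' Returns one row per day with the fields every decision strategy consumes:
#' `date, tmax, tmin, tavg, precip, rhmax, rhmin, rhavg, wind_avg, et`.
#' Temperatures follow the configured sinusoid plus AR(1) noise; `tmax`/`tmin`
#' are `tavg` plus/minus a positive diurnal spread; reference ET is a
#' deterministic increasing function of `tavg` and atmospheric dryness
#' `(100 - rhavg)`. Generated series always satisfy
#' `tmin <= tavg <= tmax`, `0 <= rhmin <= rhavg <= rhmax <= 100`,
#' `precip >= 0`, `et >= 0`.
#'
#' @param config a [climate_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return A `data.frame` of class `weather_series`, one row per day.
#' @examples
#' w <- generate_weather(climate_config(seed = 7))
#' mean(w$tavg) # Wisconsin-like season mean, ~18-21 C
#' @export
generate_weather <- function(config, seed = NULL) {
  stopifnot(inherits(config, "climate_config"))
  if (is.null(seed)) seed <- config$seed
  n <- config$season_length_days
  with_seed(seed, {
    d <- seq_len(n)
    base <- (config$mean_peak_temp - config$temp_amplitude) +
      config$temp_amplitude * sin(pi * (d - 0.5) / n)
    eps <- stats::rnorm(n, 0, config$temp_noise_sd)
    ar <- numeric(n)
    for (i in d) ar[i] <- if (i == 1) eps[1] else config$temp_ar1_coeff * ar[i - 1] + eps[i]
    tavg <- base + ar
    spread_hi <- 4.5 + abs(stats::rnorm(n, 0, 1))
    spread_lo <- 4.5 + abs(stats::rnorm(n, 0, 1))
    tmax <- tavg + spread_hi
    tmin <- tavg - spread_lo

    wet <- stats::runif(n) < config$precip_wet_prob
    precip <- ifelse(wet, stats::rexp(n, rate = 1 / config$precip_mean_mm), 0)

    rhavg <- pmin(95, pmax(30, 70 + 8 * wet + stats::rnorm(n, 0, 6)))
    rhmax <- pmin(100, rhavg + 12 + abs(stats::rnorm(n, 0, 4)))
    rhmin <- pmax(0, rhavg - 18 - abs(stats::rnorm(n, 0, 5)))
    wind <- stats::rlnorm(n, log(9), 0.35)

    # Deterministic reference ET: increasing in temperature and dryness.
    et <- pmax(0, 0.2 + 0.006 * pmax(tavg, 0) * (100 - rhavg))

    out <- data.frame(
      date = config$season_start + (d - 1L),
      tmax = tmax, tmin = tmin, tavg = tavg,
      precip = precip,
      rhmax = rhmax, rhmin = rhmin, rhavg = rhavg,
      wind_avg = wind, et = et)
    class(out) <- c("weather_series", "data.frame")
    out
  })
}

weather_columns <- c("date", "tmax", "tmin", "tavg", "precip",
                     "rhmax", "rhmin", "rhavg", "wind_avg", "et")

#' Read or write a weather CSV
#'
#' The on-disk format is a headered CSV with ISO dates and columns
#' `date,tmax,tmin,tavg,precip,rhmax,rhmin,rhavg,wind_avg,et`.
#'
#' @param path file path.
#' @param weather a weather `data.frame` (for writing).
#' @return `read_weather_csv` returns a validated `weather_series`
#'   data.frame; `write_weather_csv` returns `path` invisibly.
#' @export
read_weather_csv <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(weather_columns, names(w))
  if (length(missing))
    stop("weather CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  w <- w[weather_columns]
  w$date <- as.Date(w$date)
  validate_weather(w)
  class(w) <- c("weather_series", "data.frame")
  w
}

#' @rdname read_weather_csv
#' @export
write_weather_csv <- function(weather, path) {
  utils::write.csv(weather[weather_columns], path, row.names = FALSE)
  invisible(path)
}

validate_weather <- function(w) {
  with(w, {
    if (any(tmin > tavg + 1e-9) || any(tavg > tmax + 1e-9))
      stop("weather violates tmin <= tavg <= tmax", call. = FALSE)
    if (any(rhmin < -1e-9) || any(rhmin > rhavg + 1e-9) ||
        any(rhavg > rhmax + 1e-9) || any(rhmax > 100 + 1e-9))
      stop("weather violates 0 <= rhmin <= rhavg <= rhmax <= 100", call. = FALSE)
    if (any(precip < 0) || any(et < 0))
      stop("precip and et must be non-negative", call. = FALSE)
  })
  invisible(w)
}
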