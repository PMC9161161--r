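# Virtual putting green: root zones, plot state, the daily nitrogen-cycle
# step, and whole-season runs under a fertilization policy.
#
# The simulator realizes the simplified sand-based-green N cycle: clipping
# removal is the only nitrogen output, fertilization plus a constant
# background mineralization are the only inputs; leaching, volatilization and
# denitrification are taken as negligible.

#' A sand-based root zone profile
#'
#' Root zones differ in soil organic matter and hence in the background
#' nitrogen they mineralize; that difference is what makes zone-specific
#' recommendations emerge from the nitrogen-responsive strategies.
#'
#' @param zone_id short categorical label ("A", "B", ...).
#' @param som_level qualitative soil-organic-matter scalar (g kg-1-like
#'   units; default 1). Used to set the mineralization rate when
#'   `mineralization_rate` is not given.
#' @param mineralization_rate background soil N supply, g N m-2 d-1
#'   (default `0.012 * som_level`).
#' @param moisture_baseline typical volumetric soil moisture, percent
#'   (default 18).
#' @return An object of class `root_zone_profile`.
#' @export
root_zone_profile <- function(zone_id, som_level = 1,
                              mineralization_rate = 0.012 * som_level,
                              moisture_baseline = 18) {
  stop_if_not_number(mineralization_rate, "mineralization_rate", lower = 0)
  stop_if_not_number(moisture_baseline, "moisture_baseline", lower = 0, upper = 100)
  structure(list(zone_id = as.character(zone_id), som_level = som_level,
                 mineralization_rate = mineralization_rate,
                 moisture_baseline = moisture_baseline),
            class = "root_zone_profile")
}

#' The two default root zones
#'
#' A low-organic-matter zone "A" and a higher-organic-matter zone "B",
#' mirroring the contrast between two USGA-construction research greens of
#' differing SOM and CEC.
#'
#' @return A named list of two [root_zone_profile()]s.
#' @export
default_zones <- function() {
  list(A = root_zone_profile("A", som_level = 0.85, moisture_baseline = 17),
       B = root_zone_profile("B", som_level = 1.20, moisture_baseline = 19))
}

#' Initial state of a virtual plot
#'
#' @param soil_n_pool initial plant-available soil N, g N m-2 (default 0.15,
#'   a modest spring residual).
#' @param growth [growth_params()] used to set the initial NDRE consistent
#'   with the initial pool.
#' @return An object of class `plot_state`.
#' @export
plot_state <- function(soil_n_pool = 0.15, growth = growth_params()) {
  stop_if_not_number(soil_n_pool, "soil_n_pool", lower = 0)
  s <- soil_n_pool / (soil_n_pool + growth$k_n)
  structure(list(soil_n_pool = soil_n_pool,
                 initial_pool = soil_n_pool,
                 cum_clipping = 0,
                 cum_n_applied = 0,     # g N m-2 (x10 for kg ha-1)
                 cum_uptake = 0,
                 cum_mineralization = 0,
                 last_mow_date = as.Date(NA),
                 ndre = ndre_response(growth, s)),
            class = "plot_state")
}

#' Advance a virtual plot by one day
#'
#' Computes the day's clipping yield
#' `Y = gmax * GP(tavg) * f_N * f_water * f_traffic * lognormal noise`,
#' removes the corresponding nitrogen from the soil pool, adds fertilizer and
#' mineralization inputs, and reads out NDRE and visual quality. Only the
#' nitrogen-dependent part of growth draws on the pool; uptake is capped by
#' the nitrogen actually available, so the pool never goes negative and mass
#' balance holds exactly: at all times
#' `initial pool + applied + mineralized - uptake == pool`.
#'
#' Random draws (yield noise, NDRE sensor noise) come from the current RNG
#' stream; seed at the season level (see [run_season()]).
#'
#' @param state a [plot_state()].
#' @param day one row of a weather series (needs `date` and `tavg`).
#' @param zone a [root_zone_profile()].
#' @param ncp [nitrogen_cycle_params()].
#' @param fert_today nitrogen applied this morning, kg ha-1 (>= 0).
#' @param growth [growth_params()].
#' @param moisture volumetric soil moisture, percent (default: the zone
#'   baseline).
#' @param traffic traffic intensity, rounds per week (default 30).
#' @return A list with the updated `state` and an `obs` row
#'   (`date, clipping_yield, ndre, soil_moisture, traffic, quality`).
#' @export
step_plot <- function(state, day, zone, ncp = nitrogen_cycle_params(),
                      fert_today = 0, growth = growth_params(),
                      moisture = zone$moisture_baseline, traffic = 30) {
  stopifnot(inherits(state, "plot_state"), inherits(zone, "root_zone_profile"))
  if (!is.finite(fert_today) || fert_today < 0)
    stop("`fert_today` must be non-negative (kg ha-1)", call. = FALSE)

  fert_g <- fert_today / ncp$area_mass_conversion
  miner <- zone$mineralization_rate
  pool_in <- state$soil_n_pool + fert_g + miner

  env <- growth_potential(day$tavg, growth$gp) *
    moisture_factor(growth, moisture) * traffic_factor(growth, traffic)
  noise <- if (growth$yield_noise_sd > 0) {
    # mean-one lognormal so noise does not bias seasonal totals
    stats::rlnorm(1, -growth$yield_noise_sd^2 / 2, growth$yield_noise_sd)
  } else 1

  s <- pool_in / (pool_in + growth$k_n)      # saturating N status in [0, 1)
  y_n_pot <- growth$gmax * env * (1 - growth$n_floor) * s * noise
  uptake <- min(y_n_pot * ncp$tissue_n_fraction, pool_in)
  y_n <- uptake / ncp$tissue_n_fraction
  y_resid <- growth$gmax * env * growth$n_floor * noise  # reserve-fuelled
  y <- y_n + y_resid

  ndre <- ndre_response(growth, s) +
    if (growth$ndre_noise_sd > 0) stats::rnorm(1, 0, growth$ndre_noise_sd) else 0
  ndre <- min(1, max(0, ndre))

  state$soil_n_pool <- pool_in - uptake
  state$cum_clipping <- state$cum_clipping + y
  state$cum_n_applied <- state$cum_n_applied + fert_g
  state$cum_uptake <- state$cum_uptake + uptake
  state$cum_mineralization <- state$cum_mineralization + miner
  state$last_mow_date <- day$date
  state$ndre <- ndre

  obs <- data.frame(date = day$date,
                    clipping_yield = y,
                    ndre = ndre,
                    soil_moisture = moisture,
                    traffic = traffic,
                    quality = quality_from_clipping(y, growth$quality))
  list(state = state, obs = obs)
}

# AR(1) soil-moisture series around the zone baseline and a weekly traffic
# series (rounds per week, constant within a week). Drawn from the current
# RNG stream.
generate_management <- function(zone, n_days, traffic_mean = 30, traffic_sd = 6,
                                moisture_sd = 1.5, moisture_ar1 = 0.8) {
  eps <- stats::rnorm(n_days, 0, moisture_sd)
  m <- numeric(n_days)
  for (i in seq_len(n_days)) {
    m[i] <- if (i == 1) eps[1] else moisture_ar1 * m[i - 1] + eps[i]
  }
  moisture <- pmin(45, pmax(5, zone$moisture_baseline + m))
  n_weeks <- ceiling(n_days / 7)
  wk <- pmax(0, stats::rnorm(n_weeks, traffic_mean, traffic_sd))
  traffic <- wk[ceiling(seq_len(n_days) / 7)]
  data.frame(moisture = moisture, traffic = traffic)
}

#' Simulate one plot-season under a fertilization policy
#'
#' Generates (or accepts) a season of weather, soil moisture and traffic,
#' then walks the virtual plot through the season day by day. On each
#' decision day (days 1, 1+interval, 1+2*interval, ... by default) the
#' strategy is consulted through [decide()] and its recommended dose is
#' applied that morning. All randomness is governed by `seed`.
#'
#' @param zone a [root_zone_profile()].
#' @param climate a [climate_config()] (ignored when `weather` is supplied).
#' @param strategy a strategy object (see [strategy_experience()],
#'   [strategy_gp()], [strategy_ndre()], [strategy_mlrf()],
#'   [strategy_fixed()]).
#' @param seed integer seed for plot-level noise (and for the weather when
#'   `weather` is not supplied).
#' @param ncp,growth shared parameter objects.
#' @param weather optional pre-generated weather series (so several plots can
#'   share one site's weather).
#' @param management optional data.frame with `moisture` and `traffic`
#'   columns, one row per day.
#' @param interval_days days between decision points (default 14).
#' @param state optional initial [plot_state()].
#' @return An object of class `season_run`: list with `observations` (daily
#'   data.frame), `fert_log` (one row per decision), `weather`, `management`,
#'   `final_state`, `zone`, `seed`.
#' @export
run_season <- function(zone, climate = climate_config(), strategy,
                       seed = 1L, ncp = nitrogen_cycle_params(),
                       growth = growth_params(), weather = NULL,
                       management = NULL, interval_days = 14L,
                       state = plot_state(growth = growth)) {
  stopifnot(inherits(zone, "root_zone_profile"))
  if (is.null(weather)) weather <- generate_weather(climate, seed = derive_seed(seed, 101L))
  n <- nrow(weather)
  if (n < 2 * 1) stop("weather series is empty", call. = FALSE)
  decision_days <- seq(1L, n, by = as.integer(interval_days))

  with_seed(derive_seed(seed, 202L), {
    if (is.null(management)) management <- generate_management(zone, n)

    obs_list <- vector("list", n)
    fert_list <- vector("list", length(decision_days))
    strategy <- strategy_begin(strategy, zone = zone, weather = weather)
    k <- 0L
    for (i in seq_len(n)) {
      fert <- 0
      if (i %in% decision_days) {
        k <- k + 1L
        ctx <- list(day_index = i,
                    date = weather$date[i],
                    weather = weather,
                    observations = if (i > 1) do.call(rbind, obs_list[seq_len(i - 1L)]) else NULL,
                    management = management,
                    state = state,
                    zone = zone,
                    interval_days = as.integer(interval_days),
                    fert_log = if (k > 1L) do.call(rbind, fert_list[seq_len(k - 1L)]) else NULL)
        rec <- decide(strategy, ctx)
        fert <- rec$dose_kg_ha
        fert_list[[k]] <- data.frame(
          date = weather$date[i],
          dose_kg_ha = rec$dose_kg_ha,
          strategy = rec$strategy,
          branch = rec$branch,
          input_value = if (length(rec$info)) unlist(rec$info)[[1]] else NA_real_,
          stringsAsFactors = FALSE)
      }
      st <- step_plot(state, weather[i, ], zone, ncp, fert, growth,
                      moisture = management$moisture[i],
                      traffic = management$traffic[i])
      state <- st$state
      obs_list[[i]] <- st$obs
    }
    structure(list(observations = do.call(rbind, obs_list),
                   fert_log = do.call(rbind, fert_list),
                   weather = weather,
                   management = management,
                   final_state = state,
                   zone = zone,
                   seed = seed,
                   interval_days = as.integer(interval_days)),
              class = "season_run")
  })
}

#' @export
print.season_run <- function(x, ...) {
  cat(sprintf("season_run: zone %s, %d days, %d decisions\n",
              x$zone$zone_id, nrow(x$observations), nrow(x$fert_log)))
  cat(sprintf("  N applied %.1f kg ha-1 | clipping %.1f g m-2 | mean quality %.1f | mean NDRE %.3f\n",
              sum(x$fert_log$dose_kg_ha), x$final_state$cum_clipping,
              mean(x$observations$quality), mean(x$observations$ndre)))
  invisible(x)
}

#' Total nitrogen applied over a season run
#' @param run a `season_run`.
#' @return kg ha-1.
#' @export
season_n_applied <- function(run) sum(run$fert_log$dose_kg_ha)
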