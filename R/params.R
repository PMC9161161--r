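# Parameter containers shared across strategies and the simulator.

#' Nitrogen cycle constants
#'
#' Holds the two constants every dosing and budget equation relies on: the
#' tissue nitrogen concentration of dry clippings and the areal mass
#' conversion from g m-2 to kg ha-1.
#'
#' Tissue N of putting-green creeping bentgrass varies between roughly 2.5 and
#' 5% over a season; all computations here assume a constant 3.9% (the
#' seasonal average reported for this system), so clipping N removal is
#' `clipping mass x 0.039`.
#'
#' @param tissue_n_fraction fraction of dry clipping mass that is nitrogen
#'   (dimensionless, default 0.039). Must lie in (0, 0.10).
#' @return An object of class `nitrogen_cycle_params`.
#' @examples
#' ncp <- nitrogen_cycle_params()
#' ncp$tissue_n_fraction # 0.039
#' @export
nitrogen_cycle_params <- function(tissue_n_fraction = 0.039) {
  stop_if_not_number(tissue_n_fraction, "tissue_n_fraction")
  if (tissue_n_fraction <= 0 || tissue_n_fraction >= 0.10)
    stop("`tissue_n_fraction` must lie strictly between 0 and 0.10", call. = FALSE)
  structure(
    list(tissue_n_fraction = tissue_n_fraction,
         area_mass_conversion = 10),  # g m-2 -> kg ha-1, exact
    class = "nitrogen_cycle_params")
}

#' @export
print.nitrogen_cycle_params <- function(x, ...) {
  cat("Nitrogen cycle constants\n")
  cat(sprintf("  tissue N fraction : %.3f (%.1f%%)\n",
              x$tissue_n_fraction, 100 * x$tissue_n_fraction))
  cat("  g m-2 -> kg ha-1  : x 10\n")
  invisible(x)
}

#' Growth-potential model parameters
#'
#' Parameters of the Gaussian temperature response used by the growth
#' potential model for cool-season (C3) turfgrass: an optimum average air
#' temperature `t_opt` and a spread `var` controlling how fast potential
#' declines away from the optimum.
#'
#' @param t_opt optimal average air temperature, degrees C (default 20).
#' @param var spread parameter, degrees C (default 5.5). Must be > 0.
#' @return An object of class `gp_params`.
#' @export
gp_params <- function(t_opt = 20, var = 5.5) {
  stop_if_not_number(t_opt, "t_opt")
  stop_if_not_number(var, "var")
  if (var <= 0) stop("`var` must be positive", call. = FALSE)
  structure(list(t_opt = t_opt, var = var), class = "gp_params")
}

#' Physiological parameters of the virtual green
#'
#' Controls the simulator's daily clipping response
#' `Y = gmax * GP(tavg) * f_N * f_water * f_traffic * noise` and the mapping
#' from plant nitrogen status to NDRE. All mass-per-area values are g m-2.
#'
#' `f_N = n_floor + (1 - n_floor) * pool / (pool + k_n)` is a saturating
#' (Michaelis-Menten) nitrogen limitation factor; only its pool-dependent part
#' removes nitrogen from the soil pool, so a small nitrogen-independent
#' residual growth (`n_floor`) persists on exhausted root zones, mimicking
#' growth from internal reserves. `k_n` is chosen so that an unfertilized
#' plot supplied only by mineralization produces roughly one third of the
#' clipping of a well-fertilized plot.
#'
#' NDRE is a saturating function of `f_N`:
#' `ndre = ndre_min + (ndre_max - ndre_min) * f_N / (f_N + k_ndre)`, with
#' `k_ndre` calibrated at construction time so that a canopy at minimally
#' acceptable visual quality 6 (daily clipping 1.25 g m-2 d-1 at optimal
#' temperature) reads NDRE = `ndre_at_quality6` (default 0.28).
#'
#' @param gmax maximum daily clipping yield, g m-2 d-1 (default 3.2).
#' @param k_n half-saturation constant of the nitrogen response, g N m-2
#'   (default 0.5).
#' @param n_floor residual growth fraction at zero available N (default 0.05).
#' @param moisture_opt volumetric soil moisture at which growth is unimpeded,
#'   percent (default 20).
#' @param moisture_coef quadratic penalty per squared fractional deviation
#'   from `moisture_opt` (default 2).
#' @param traffic_coef linear yield penalty per round of play per week
#'   (default 0.002).
#' @param yield_noise_sd standard deviation of the multiplicative lognormal
#'   yield noise, log scale (default 0.10).
#' @param ndre_noise_sd standard deviation of additive Gaussian NDRE sensor
#'   noise (default 0.005).
#' @param ndre_min,ndre_max asymptotes of the NDRE response (defaults 0.22,
#'   0.40).
#' @param ndre_at_quality6 NDRE reading anchored to visual quality 6
#'   (default 0.28).
#' @param gp reference `gp_params` used for the temperature factor.
#' @param quality reference [quality_map()] used to anchor NDRE calibration.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(gmax = 3.2, k_n = 0.5, n_floor = 0.05,
                          moisture_opt = 20, moisture_coef = 2,
                          traffic_coef = 0.002,
                          yield_noise_sd = 0.10, ndre_noise_sd = 0.005,
                          ndre_min = 0.22, ndre_max = 0.40,
                          ndre_at_quality6 = 0.28,
                          gp = gp_params(), quality = quality_map()) {
  stop_if_not_number(gmax, "gmax", lower = 1e-9)
  stop_if_not_number(k_n, "k_n", lower = 1e-9)
  stop_if_not_number(n_floor, "n_floor", lower = 0, upper = 0.5)
  stop_if_not_number(yield_noise_sd, "yield_noise_sd", lower = 0)
  stop_if_not_number(ndre_noise_sd, "ndre_noise_sd", lower = 0)
  if (!(ndre_min < ndre_at_quality6 && ndre_at_quality6 < ndre_max))
    stop("need ndre_min < ndre_at_quality6 < ndre_max", call. = FALSE)

  p <- list(gmax = gmax, k_n = k_n, n_floor = n_floor,
            moisture_opt = moisture_opt, moisture_coef = moisture_coef,
            traffic_coef = traffic_coef,
            yield_noise_sd = yield_noise_sd, ndre_noise_sd = ndre_noise_sd,
            ndre_min = ndre_min, ndre_max = ndre_max,
            ndre_at_quality6 = ndre_at_quality6,
            gp = gp, quality = quality)

  # Calibrate the NDRE half-saturation constant: find the nitrogen factor
  # f_N* at which a plot growing at optimal temperature and nominal moisture/
  # traffic produces the quality-6 clipping rate, then solve
  # ndre(f_N*) == ndre_at_quality6 for k_ndre.
  y6 <- clipping_at_quality(quality, 6)           # g m-2 d-1 at quality 6
  env0 <- moisture_factor(p, moisture_opt) * traffic_factor(p, 30)
  ftot <- y6 / (gmax * env0)                      # n_floor + (1-n_floor) f_N*
  fstar <- (ftot - n_floor) / (1 - n_floor)
  if (fstar <= 0 || fstar >= 1)
    stop("NDRE calibration failed: quality-6 clipping rate unreachable with these parameters",
         call. = FALSE)
  span <- ndre_max - ndre_min
  frac <- (ndre_at_quality6 - ndre_min) / span
  p$k_ndre <- fstar * (1 - frac) / frac
  p$f_n_quality6 <- fstar
  structure(p, class = "growth_params")
}

# Saturating N limitation in [n_floor, 1); pool in g N m-2.
n_factor <- function(p, pool) {
  p$n_floor + (1 - p$n_floor) * pool / (pool + p$k_n)
}

# Mild quadratic moisture penalty around the optimum, floored at 0.2.
moisture_factor <- function(p, moisture_pct) {
  pmax(0.2, 1 - p$moisture_coef * ((moisture_pct - p$moisture_opt) / 100)^2)
}

# Linear wear penalty from rounds of play, floored at 0.2.
traffic_factor <- function(p, rounds_wk) {
  pmax(0.2, 1 - p$traffic_coef * rounds_wk)
}

# Noise-free NDRE for a given nitrogen limitation factor.
ndre_response <- function(p, f_n) {
  p$ndre_min + (p$ndre_max - p$ndre_min) * f_n / (f_n + p$k_ndre)
}
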