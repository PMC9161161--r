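# Shared fixtures: small climates and zones used across test files.

# constant 20 C, noise-free: growth potential is exactly 1 every day
climate_const20 <- function(days = 210) {
  climate_config(mean_peak_temp = 20, temp_amplitude = 0, temp_noise_sd = 0,
                 season_length_days = days)
}

zone_a <- function() default_zones()$A
zone_b <- function() default_zones()$B

# biweekly interval sums of per-event values, by event date
biweekly_sums <- function(values, dates) {
  iv <- ceiling(as.integer(dates - dates[1] + 1) / 14)
  tapply(values, iv, sum)
}
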