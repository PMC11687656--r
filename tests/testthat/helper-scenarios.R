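# shared fixtures: small synthetic days and a reduced-length fit wrapper
# used by the unit tests (the acceptance tests use the package defaults)

one_day <- function(season = "summer", seed = 1, ...) {
  generate_scenario(scenario_preset(season, n_days = 1, seed = seed, ...))
}

quick_fit <- function(fs, seed = 1, ...) {
  suppressWarnings(fit_day(fs, seed = seed, iter = 1500, burn = 700, ...))
}

# a minimal constant-forcing series (no light, flat temperature)
flat_forcing <- function(n = 144, temp = 15, press = 1, sal = 0,
                         DO_obs = NULL, dt_days = 1 / 288) {
  t0 <- as.POSIXct("2023-06-01 00:00:00", tz = "UTC")
  forcing_series(t = t0 + 86400 * dt_days * (seq_len(n) - 1L),
                 I = rep(0, n), temp = rep(temp, n), press = press,
                 sal = sal, DO_obs = DO_obs, dt_days = dt_days)
}

write_sensor_fixture <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("timestamp,value", lines), path)
  path
}
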