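#' Diel light curve
#'
#' Half-sinusoid photosynthetically active radiation: zero outside the
#' photoperiod (night light is taken as exactly zero, as headwater-stream
#' loggers typically record), rising from sunrise to a noon peak and back.
#' Sunrise and sunset are placed symmetrically around 12:00.
#'
#' @param t_of_day hour of day in \[0, 24).
#' @param photoperiod_hours day length, in (0, 24).
#' @param peak_PAR noon maximum, µmol m⁻² s⁻¹.
#' @return PAR at `t_of_day`, µmol m⁻² s⁻¹; vectorised.
#' @export
diel_par <- function(t_of_day, photoperiod_hours, peak_PAR) {
  if (any(t_of_day < 0 | t_of_day >= 24)) stop("t_of_day must be in [0, 24)")
  if (photoperiod_hours <= 0 || photoperiod_hours >= 24)
    stop("photoperiod_hours must be in (0, 24)")
  if (peak_PAR < 0) stop("peak_PAR must be >= 0")
  sunrise <- 12 - photoperiod_hours / 2
  x <- (t_of_day - sunrise) / photoperiod_hours
  ifelse(x > 0 & x < 1, peak_PAR * sin(pi * x), 0)
}

#' Diel temperature curve
#'
#' Sinusoidal water temperature with an afternoon maximum (default 15:00).
#' The mean over a full period equals `T_mean` exactly.
#'
#' @param t_of_day hour of day in \[0, 24).
#' @param T_mean daily mean temperature, °C.
#' @param amplitude half peak-to-trough range, °C, >= 0.
#' @param phase_lag_hours hour of the daily maximum.
#' @return Temperature at `t_of_day`, °C; vectorised.
#' @export
diel_temperature <- function(t_of_day, T_mean, amplitude,
                             phase_lag_hours = 15) {
  if (amplitude < 0) stop("amplitude must be >= 0")
  T_mean + amplitude * cos(2 * pi * (t_of_day - phase_lag_hours) / 24)
}

#' Seasonal synthetic-scenario presets
#'
#' Ready-made scenario settings emulating the seasonal metabolic regimes of
#' a temperate karst headwater stream: daily GPP peaking near
#' 18 mg O₂ L⁻¹ d⁻¹ in summer and near 3.8 in winter; daily |ER| around 17
#' (summer), 9.2 (winter), 25 (late spring) and 22 (fall) mg O₂ L⁻¹ d⁻¹; a
#' mean reaeration coefficient of 9.8 d⁻¹; water temperatures spanning
#' roughly 1-30 °C across seasons; salinity fixed at 0.12 ppt.  The preset
#' numerics are documented package constants, not fitted values.
#'
#' @param season `"spring"`, `"summer"`, `"fall"` or `"winter"`.
#' @param ... overrides for any [synthetic_scenario()] field.
#' @return A `synthetic_scenario` list.
#' @export
scenario_preset <- function(season = c("summer", "winter", "spring", "fall"),
                            ...) {
  season <- match.arg(season)
  base <- switch(season,
    summer = list(start_date = "2023-07-01", photoperiod_hours = 14,
                  peak_PAR = 1400, T_mean = 24, T_diel_amplitude = 2.5,
                  gpp_daily = 18, er_daily = 17),
    spring = list(start_date = "2023-05-01", photoperiod_hours = 13.5,
                  peak_PAR = 1200, T_mean = 16, T_diel_amplitude = 2,
                  gpp_daily = 10, er_daily = 25),
    fall = list(start_date = "2023-10-01", photoperiod_hours = 11,
                peak_PAR = 800, T_mean = 14, T_diel_amplitude = 2,
                gpp_daily = 6, er_daily = 22),
    winter = list(start_date = "2023-01-10", photoperiod_hours = 10,
                  peak_PAR = 500, T_mean = 5, T_diel_amplitude = 1.5,
                  gpp_daily = 3.8, er_daily = 9.2))
  args <- utils::modifyList(c(base, list(season = season)), list(...))
  do.call(synthetic_scenario, args)
}

#' Define a synthetic sensor-campaign scenario
#'
#' Describes a multi-day logger deployment: diel light and temperature
#' shapes, day-to-day variability, the true metabolic regime (expressed in
#' daily units and inverted internally to the per-interval model
#' parameters) and the observation-noise level.
#'
#' @param season label used downstream for grouping.
#' @param n_days number of days, >= 1.
#' @param dt_days sampling interval, days (default 5 minutes).
#' @param start_date first calendar day (`"YYYY-MM-DD"`).
#' @param photoperiod_hours,peak_PAR,T_mean,T_diel_amplitude diel shapes,
#'   see [diel_par()] and [diel_temperature()].
#' @param T_day_to_day_sd sd of the daily mean-temperature perturbation, °C.
#' @param par_day_to_day_sd sd of the lognormal day-to-day peak-PAR factor.
#' @param gpp_daily target daily GPP, mg O₂ L⁻¹ d⁻¹ (inverted to `A`
#'   against the noise-free preset light curve).
#' @param er_daily target daily |ER|, mg O₂ L⁻¹ d⁻¹ (inverted to `R`).
#' @param K_O2 true reaeration coefficient, d⁻¹.
#' @param sigma_obs observation noise sd, mg L⁻¹.
#' @param DO_0 initial DO, mg L⁻¹; `NULL` starts near the nighttime
#'   steady-state deficit below saturation.
#' @param press_atm,sal_ppt constant pressure and salinity.
#' @param theta,p fixed model constants.
#' @param seed integer seed used by [generate_scenario()].
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(season = "summer", n_days = 3,
                               dt_days = 1 / 288,
                               start_date = "2023-07-01",
                               photoperiod_hours = 14, peak_PAR = 1400,
                               T_mean = 24, T_diel_amplitude = 2.5,
                               T_day_to_day_sd = 0.8,
                               par_day_to_day_sd = 0.1,
                               gpp_daily = 18, er_daily = 17, K_O2 = 9.8,
                               sigma_obs = 0.1, DO_0 = NULL,
                               press_atm = 1, sal_ppt = 0.12,
                               theta = 1.072, p = 1, seed = 1L) {
  stopifnot(n_days >= 1, dt_days > 0,
            photoperiod_hours > 0, photoperiod_hours < 24,
            peak_PAR >= 0, T_day_to_day_sd >= 0, par_day_to_day_sd >= 0,
            gpp_daily >= 0, er_daily >= 0, K_O2 >= 0, sigma_obs >= 0)
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' Generate a synthetic forcing series with known truth
#'
#' Builds multi-day forcing from the diel light and temperature generators
#' (with seeded day-to-day Gaussian/lognormal perturbations), derives the
#' per-interval true parameters from the scenario's daily targets by
#' closed-form inversion against the noise-free preset curves, forward
#' simulates DO with [simulate_do()] and adds Gaussian observation noise.
#'
#' The returned series carries a `truth` attribute -- a data frame of the
#' noise-free realised daily GPP, ER, NEP and `K_O2` per day (sums of the
#' generator's per-interval values, exact by construction) -- and a
#' `true_params` attribute with the generating [metab_params()].
#'
#' @param scenario a [synthetic_scenario()] or [scenario_preset()].
#' @return A [forcing_series()] with `DO_obs` filled in.
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  per_day <- round(1 / sc$dt_days)
  n <- per_day * sc$n_days
  t0 <- as.POSIXct(paste(sc$start_date, "00:00:00"), tz = "UTC")
  t <- t0 + 86400 * sc$dt_days * (seq_len(n) - 1L)
  hour <- (as.numeric(t - t0, units = "days") %% 1) * 24
  day <- rep(seq_len(sc$n_days), each = per_day)

  # closed-form inversion of the daily targets on the noise-free curves
  hour1 <- hour[seq_len(per_day)]
  I_base <- diel_par(hour1, sc$photoperiod_hours, sc$peak_PAR)
  A <- if (sum(I_base) > 0) sc$gpp_daily / sum(I_base^sc$p) else 0
  T_base <- diel_temperature(hour1, sc$T_mean, sc$T_diel_amplitude)
  R <- sc$er_daily / sum(sc$theta^(T_base - mean(T_base)))

  with_seed(sc$seed, {
    par_fac <- exp(stats::rnorm(sc$n_days, 0, sc$par_day_to_day_sd))
    t_shift <- stats::rnorm(sc$n_days, 0, sc$T_day_to_day_sd)
    I <- diel_par(hour, sc$photoperiod_hours, sc$peak_PAR) * par_fac[day]
    temp <- diel_temperature(hour, sc$T_mean, sc$T_diel_amplitude) +
      t_shift[day]
    DO_0 <- sc$DO_0
    if (is.null(DO_0)) {
      sat0 <- o2_saturation(temp[1L], sc$press_atm, sc$sal_ppt)
      DO_0 <- sat0 - if (sc$K_O2 > 0) sc$er_daily / sc$K_O2 else 0
      if (DO_0 <= 0.5) DO_0 <- 0.5
    }
    fs <- forcing_series(t = t, I = I, temp = temp, press = sc$press_atm,
                         sal = sc$sal_ppt, dt_days = sc$dt_days)
    params <- metab_params(A = A, R = R, K_O2 = sc$K_O2,
                           sigma_obs = max(sc$sigma_obs, 1e-6),
                           p = sc$p, theta = sc$theta)
    sim <- tryCatch(simulate_do(fs, params, DO_0 = DO_0),
                    error = function(e)
                      stop("scenario drives DO non-positive (",
                           conditionMessage(e),
                           "); adjust er_daily, K_O2 or DO_0",
                           call. = FALSE))
    DO_obs <- sim$DO_mod + stats::rnorm(n, 0, sc$sigma_obs)
    DO_obs[1L] <- sim$DO_mod[1L]  # initial state treated as known
    if (any(DO_obs <= 0))
      stop("observation noise drove DO non-positive; reduce sigma_obs")
    out <- forcing_series(t = t, I = I, temp = temp, press = sc$press_atm,
                          sal = sc$sal_ppt, DO_obs = DO_obs,
                          dt_days = sc$dt_days)
    truth <- data.frame(
      day_index = seq_len(sc$n_days),
      date = as.Date(sc$start_date) + seq_len(sc$n_days) - 1L,
      GPP = as.numeric(tapply(sim$gpp, day, sum)),
      ER = -as.numeric(tapply(sim$er, day, sum)),
      K_O2 = sc$K_O2)
    truth$NEP <- truth$GPP + truth$ER
    attr(out, "truth") <- truth
    attr(out, "true_params") <- params
    attr(out, "DO_true") <- sim$DO_mod
    attr(out, "season") <- sc$season
    out
  })
}

#' Truth record of a generated scenario
#'
#' @param fs a series from [generate_scenario()].
#' @return The `truth` data frame (daily GPP, ER, NEP, K_O2).
#' @export
scenario_truth <- function(fs) {
  tr <- attr(fs, "truth")
  if (is.null(tr)) stop("no truth record: not a generated scenario")
  tr
}
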