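#' Metabolic parameters of the diel oxygen model
#'
#' The single-station model describes the change in dissolved oxygen over
#' each measurement interval as the sum of three processes:
#'
#' \deqn{\Delta DO_i = A I_i^p - R\,\theta^{T_i - \bar T}
#'   + K_{O2}\,\Delta t\, 1.0241^{T_i - \bar T} D_i}
#'
#' where \eqn{I_i} is PAR, \eqn{T_i} water temperature, \eqn{\bar T} the
#' daily mean water temperature and \eqn{D_i} the saturation deficit.
#' `A` (production per quantum of light) and `R` (respiration at the daily
#' mean temperature) are *per-interval* quantities, so daily totals are
#' plain sums of the interval values.  `K_O2` is the reaeration coefficient
#' in d⁻¹; its interval contribution is scaled by `dt_days`.
#'
#' @param A production per quantum of light, mg O₂ L⁻¹ per
#'   (µmol m⁻² s⁻¹)ᵖ per interval, >= 0.
#' @param R respiration per interval at the daily mean temperature,
#'   mg O₂ L⁻¹, >= 0.
#' @param K_O2 reaeration coefficient, d⁻¹, >= 0.
#' @param sigma_obs observation-noise standard deviation, mg L⁻¹, > 0.
#' @param p light-saturation exponent, > 0; fixed at 1 by default.
#' @param theta temperature coefficient of respiration, > 0; default 1.072
#'   (approximately a Q10 of 2).
#' @return A list of class `metab_params`.
#' @export
metab_params <- function(A, R, K_O2, sigma_obs = 0.1, p = 1, theta = 1.072) {
  stopifnot(is.numeric(A), is.numeric(R), is.numeric(K_O2))
  if (A < 0) stop("A must be >= 0")
  if (R < 0) stop("R must be >= 0")
  if (K_O2 < 0) stop("K_O2 must be >= 0")
  if (sigma_obs <= 0) stop("sigma_obs must be > 0")
  if (p <= 0) stop("p must be > 0")
  if (theta <= 0) stop("theta must be > 0")
  structure(list(A = A, R = R, K_O2 = K_O2, sigma_obs = sigma_obs,
                 p = p, theta = theta),
            class = "metab_params")
}

#' @export
print.metab_params <- function(x, ...) {
  cat(sprintf(
    "<metab_params> A = %.4g, R = %.4g (per interval), K_O2 = %.4g /d,\n",
    x$A, x$R, x$K_O2))
  cat(sprintf("  sigma_obs = %.4g mg/L, p = %g, theta = %g\n",
              x$sigma_obs, x$p, x$theta))
  invisible(x)
}

#' Process increments of the oxygen model
#'
#' The three per-interval terms of the mass balance, exposed individually.
#' `gpp_increment()` is the photosynthetic gain `A * I^p`; `er_increment()`
#' the respiratory loss `R * theta^(temp - temp_mean)`;
#' `reaeration_increment()` the atmospheric exchange
#' `K_O2 * dt_days * 1.0241^(temp - temp_mean) * deficit`, negative when the
#' water is supersaturated (`deficit < 0`).
#'
#' @param A,p,R,theta,K_O2 see [metab_params()].
#' @param I PAR, µmol m⁻² s⁻¹, >= 0.
#' @param temp,temp_mean interval and daily-mean water temperature, °C.
#' @param dt_days interval length, days.
#' @param deficit saturation deficit `DO_sat - DO`, mg L⁻¹ (sign-carrying).
#' @return Increment in mg O₂ L⁻¹ per interval (all vectorised).
#' @name increments
NULL

#' @rdname increments
#' @export
gpp_increment <- function(A, I, p = 1) {
  if (any(A < 0)) stop("A must be >= 0")
  if (any(I < 0)) stop("I must be >= 0")
  if (any(p <= 0)) stop("p must be > 0")
  A * I^p
}

#' @rdname increments
#' @export
er_increment <- function(R, temp, temp_mean, theta = 1.072) {
  if (any(R < 0)) stop("R must be >= 0")
  if (any(theta <= 0)) stop("theta must be > 0")
  R * theta^(temp - temp_mean)
}

#' @rdname increments
#' @export
reaeration_increment <- function(K_O2, dt_days, temp, temp_mean, deficit) {
  if (any(K_O2 < 0)) stop("K_O2 must be >= 0")
  if (any(dt_days <= 0)) stop("dt_days must be > 0")
  K_O2 * dt_days * 1.0241^(temp - temp_mean) * deficit
}

#' Daily mean temperature per day block
#' @keywords internal
daily_mean_temp <- function(temp, day_index) {
  ave(temp, day_index, FUN = mean)
}

#' Forward-simulate dissolved oxygen
#'
#' Explicit (forward-Euler) integration of the three-term oxygen mass
#' balance at the measurement resolution.  The increment at index `i` is
#' applied between samples `i` and `i + 1`; the saturation deficit is
#' recomputed from [o2_saturation()] at every step, and the respiration and
#' reaeration temperature factors reference the mean water temperature of
#' the calendar day the sample falls in.
#'
#' @param forcing a [forcing_series()].
#' @param params a [metab_params()].
#' @param DO_0 initial DO, mg L⁻¹, > 0.  Defaults to the first observed DO
#'   when present, else the initial saturation concentration.
#' @return A data frame of class `do_simulation` with columns `t`, `I`,
#'   `temp`, `DO_mod`, `gpp`, `er`, `reaeration`, `DO_sat`,
#'   `percent_local`, `day_index`.  The component columns hold the
#'   per-interval increment *rates* at each sample; for every step,
#'   `DO_mod[i+1] - DO_mod[i] == gpp[i] - er[i] + reaeration[i]` exactly.
#' @export
simulate_do <- function(forcing, params, DO_0 = NULL) {
  validate_forcing(forcing)
  if (!inherits(params, "metab_params")) params <- do.call(metab_params, params)
  n <- nrow(forcing)
  dt <- attr(forcing, "dt_days")
  if (is.null(DO_0)) {
    DO_0 <- if (!is.na(forcing$DO_obs[1L])) forcing$DO_obs[1L] else
      o2_saturation(forcing$temp[1L], forcing$press[1L], forcing$sal[1L])
  }
  if (DO_0 <= 0) stop("DO_0 must be > 0")
  tbar <- daily_mean_temp(forcing$temp, forcing$day_index)
  DO_sat <- o2_saturation(forcing$temp, forcing$press, forcing$sal)
  gpp <- gpp_increment(params$A, forcing$I, params$p)
  er <- er_increment(params$R, forcing$temp, tbar, params$theta)
  kfac <- params$K_O2 * dt * 1.0241^(forcing$temp - tbar)
  DO <- numeric(n)
  rea <- numeric(n)
  DO[1L] <- DO_0
  for (i in seq_len(n - 1L)) {
    rea[i] <- kfac[i] * (DO_sat[i] - DO[i])
    DO[i + 1L] <- DO[i] + (gpp[i] - er[i] + rea[i])
    if (DO[i + 1L] <= 0)
      stop("simulated DO dropped to <= 0 at step ", i + 1L,
           "; parameters are inconsistent with the forcing")
  }
  rea[n] <- kfac[n] * (DO_sat[n] - DO[n])
  out <- data.frame(t = forcing$t, I = forcing$I, temp = forcing$temp,
                    DO_mod = DO, gpp = gpp, er = er, reaeration = rea,
                    DO_sat = DO_sat, percent_local = 100 * DO / DO_sat,
                    day_index = forcing$day_index)
  attr(out, "dt_days") <- dt
  attr(out, "params") <- params
  class(out) <- c("do_simulation", "data.frame")
  out
}

#' Write a simulation to CSV
#' @param sim a `do_simulation` from [simulate_do()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  out <- sim
  out$t <- format(sim$t, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
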