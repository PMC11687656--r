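#' Temperature-pH scaling-law prediction of stream DO
#'
#' Empirical power-law predictor of stream dissolved-oxygen concentration
#' from absolute water temperature and pH:
#' `DO = 10^18.94 * T_w^-7.46 * pH^0.45` (mg L⁻¹).  The leading constant is
#' the base-10 exponent of the published scaling model; all three constants
#' are exposed for sensitivity analysis but default to the published fit.
#'
#' @param T_w water temperature, K, > 0.
#' @param pH pH, in (0, 14).
#' @param log10_constant base-10 logarithm of the leading constant.
#' @param temp_exponent exponent on `T_w` (negative).
#' @param ph_exponent exponent on `pH` (positive).
#' @return Predicted DO, mg L⁻¹; vectorised.
#' @examples
#' scaling_law_do(293.15, 7)  # ~8.2 mg/L
#' @export
scaling_law_do <- function(T_w, pH, log10_constant = 18.94,
                           temp_exponent = -7.46, ph_exponent = 0.45) {
  if (any(T_w <= 0)) stop("T_w must be > 0 K")
  if (any(pH <= 0 | pH >= 14)) stop("pH must be in (0, 14)")
  10^log10_constant * T_w^temp_exponent * pH^ph_exponent
}

#' Hypoxia flag
#'
#' Hypoxia is a dissolved-oxygen concentration strictly below 2 mg L⁻¹.
#'
#' @param DO_obs DO, mg L⁻¹, >= 0.
#' @param threshold hypoxia threshold, mg L⁻¹ (default 2).
#' @return Logical vector, `TRUE` where `DO_obs < threshold`.
#' @export
hypoxia_flag <- function(DO_obs, threshold = 2) {
  if (any(DO_obs < 0)) stop("DO_obs must be >= 0")
  DO_obs < threshold
}

#' Hypoxia-risk region classification
#'
#' A day is vulnerable to hypoxia when the gas-transfer coefficient
#' (`K_O2 * depth`, m d⁻¹) is below 10 m d⁻¹ *and* net ecosystem production
#' is below -10 mg O₂ L⁻¹ d⁻¹: oxygen consumed by respiration can then be
#' replaced neither by reaeration nor by photosynthesis.  Both inequalities
#' are strict.
#'
#' @param K_O2 reaeration coefficient, d⁻¹, >= 0.
#' @param depth stream depth, m, > 0.
#' @param NEP daily net ecosystem production, mg O₂ L⁻¹ d⁻¹.
#' @param date optional day labels carried through.
#' @param k_threshold gas-transfer risk threshold, m d⁻¹ (default 10).
#' @param nep_threshold NEP risk threshold, mg O₂ L⁻¹ d⁻¹ (default -10).
#' @return A data frame of class `risk_assessment` with columns `date`
#'   (when given), `K_O2`, `depth`, `K_gas_transfer`, `NEP`, `at_risk`.
#' @export
risk_region <- function(K_O2, depth, NEP, date = NULL,
                        k_threshold = 10, nep_threshold = -10) {
  if (any(K_O2 < 0)) stop("K_O2 must be >= 0")
  if (any(depth <= 0)) stop("depth must be > 0")
  kgt <- K_O2 * depth
  out <- data.frame(K_O2 = K_O2, depth = depth, K_gas_transfer = kgt,
                    NEP = NEP,
                    at_risk = kgt < k_threshold & NEP < nep_threshold)
  if (!is.null(date)) out <- cbind(date = date, out)
  class(out) <- c("risk_assessment", "data.frame")
  out
}

#' Daily oxygen risk report
#'
#' Combines the fitted daily metabolism with the observed DO record into a
#' per-day risk table: gas-transfer coefficient, NEP, risk-region
#' membership, hypoxic-interval counts and the daily DO range.
#'
#' @param daily daily results (see [seasonal_summary()] for the expected
#'   columns; needs `date`, `day_index`, `K_O2`, `NEP`).
#' @param forcing the matching [forcing_series()] with observed DO.
#' @param depth stream depth, m: a constant or one value per day.
#' @param hypoxia_threshold mg L⁻¹, default 2.
#' @return A data frame, one row per day: `date`, `K_O2`, `depth`,
#'   `K_gas_transfer`, `NEP`, `at_risk`, `hypoxic_intervals`, `min_DO`,
#'   `max_DO`, `amplitude`.
#' @export
risk_report <- function(daily, forcing, depth, hypoxia_threshold = 2) {
  validate_forcing(forcing)
  depth <- rep_len(depth, nrow(daily))
  rr <- risk_region(daily$K_O2, depth, daily$NEP, date = daily$date)
  do_stats <- lapply(daily$day_index, function(d) {
    v <- forcing$DO_obs[forcing$day_index == d]
    v <- v[!is.na(v)]
    data.frame(hypoxic_intervals = sum(hypoxia_flag(v, hypoxia_threshold)),
               min_DO = min(v), max_DO = max(v),
               amplitude = max(v) - min(v))
  })
  out <- cbind(as.data.frame(rr), do.call(rbind, do_stats))
  rownames(out) <- NULL
  out
}
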