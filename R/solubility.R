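#' Equilibrium oxygen solubility in fresh water
#'
#' Benson-Krause equilibrium dissolved-oxygen concentration at a given water
#' temperature, with the standard salinity correction and the USGS barometric
#' pressure correction (vapour-pressure and theta terms).  This is the
#' formulation behind the familiar solubility tables (9.09 mg L⁻¹ at 20 °C,
#' 1 atm, fresh water).
#'
#' Solubility is strictly decreasing in temperature and salinity and
#' increasing in pressure.  The fit is valid for roughly -1 to 45 °C;
#' temperatures outside that range raise an error.
#'
#' @param temp_c water temperature, °C, in \[-1, 45\].
#' @param press_atm barometric pressure, atm, > 0.
#' @param sal_ppt salinity, ppt, >= 0.
#' @return Saturation DO concentration, mg L⁻¹.  Vectorised over all three
#'   arguments.
#' @references Benson & Krause (1984) Limnol. Oceanogr. 29:620-632;
#'   USGS Technical Memorandum 2011.03 (DOTABLES).
#' @examples
#' o2_saturation(20, 1, 0)     # ~9.09
#' o2_saturation(20, 1, 0.12)  # salinity barely matters at stream levels
#' @export
o2_saturation <- function(temp_c, press_atm = 1, sal_ppt = 0) {
  if (any(!is.finite(temp_c))) stop("temperature must be finite")
  if (any(temp_c < -1 | temp_c > 45))
    stop("temperature outside the solubility-formulation range [-1, 45] degC")
  if (any(!is.finite(press_atm)) || any(press_atm <= 0))
    stop("pressure must be finite and > 0")
  if (any(!is.finite(sal_ppt)) || any(sal_ppt < 0))
    stop("salinity must be finite and >= 0")
  TK <- temp_c + 273.15
  # Benson-Krause, 1 atm moist air, fresh water (mg/L)
  lnC <- -139.34411 + 1.575701e5 / TK - 6.642308e7 / TK^2 +
    1.243800e10 / TK^3 - 8.621949e11 / TK^4
  # salinity factor
  Fs <- exp(-sal_ppt * (0.017674 - 10.754 / TK + 2140.7 / TK^2))
  # pressure factor: Pwv = water vapour pressure (atm), theta from t (degC)
  Pwv <- exp(11.8571 - 3840.70 / TK - 216961 / TK^2)
  theta <- 0.000975 - 1.426e-5 * temp_c + 6.436e-8 * temp_c^2
  Fp <- press_atm * (1 - Pwv / press_atm) * (1 - theta * press_atm) /
    ((1 - Pwv) * (1 - theta))
  exp(lnC) * Fs * Fp
}

#' Saturation state of an oxygen observation
#'
#' @param DO dissolved oxygen, mg L⁻¹.
#' @param temp_c,press_atm,sal_ppt passed to [o2_saturation()].
#' @return A data frame with `DO_sat` (mg L⁻¹), `deficit`
#'   (`DO_sat - DO`, negative when supersaturated) and `percent_local`
#'   (`100 * DO / DO_sat`).
#' @export
saturation_state <- function(DO, temp_c, press_atm = 1, sal_ppt = 0) {
  DO_sat <- o2_saturation(temp_c, press_atm, sal_ppt)
  data.frame(DO_sat = DO_sat, deficit = DO_sat - DO,
             percent_local = 100 * DO / DO_sat)
}

#' Percent of local saturation
#'
#' @param DO_obs observed DO, mg L⁻¹.
#' @param DO_sat saturation DO, mg L⁻¹, > 0.
#' @return `100 * DO_obs / DO_sat`; values above 100 indicate
#'   supersaturation.
#' @export
percent_saturation <- function(DO_obs, DO_sat) {
  if (any(!is.finite(DO_sat)) || any(DO_sat <= 0))
    stop("DO_sat must be finite and > 0")
  100 * DO_obs / DO_sat
}
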