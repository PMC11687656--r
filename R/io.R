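#' Convert illuminance to PAR
#'
#' HOBO-style pendant loggers record illuminance in lux; the metabolism model
#' wants photosynthetic photon flux density (PAR, µmol m⁻² s⁻¹).  A constant
#' factor of 0.0185 µmol m⁻² s⁻¹ per lux is the standard field conversion for
#' daylight spectra.  An optional multiplicative `calibration_scale` lets a
#' site-specific cross-calibration against a quantum PAR sensor be applied on
#' top of the constant factor; it defaults to 1 (uncorrected).
#'
#' @param illuminance numeric vector, lux, non-negative.
#' @param calibration_scale positive scalar multiplier.
#' @return PAR in µmol m⁻² s⁻¹: `illuminance * 0.0185 * calibration_scale`.
#' @examples
#' lux_to_par(1000)        # 18.5
#' lux_to_par(1000, 1.23)  # 22.755
#' @export
lux_to_par <- function(illuminance, calibration_scale = 1.0) {
  if (!is.numeric(illuminance)) stop("illuminance must be numeric")
  bad <- which(!is.na(illuminance) & illuminance < 0)
  if (length(bad))
    stop("negative illuminance at index ", bad[1L],
         " (", illuminance[bad[1L]], " lux)")
  if (!is.numeric(calibration_scale) || length(calibration_scale) != 1L ||
      calibration_scale <= 0)
    stop("calibration_scale must be a positive scalar")
  illuminance * 0.0185 * calibration_scale
}

#' Known sensor variables and their units
#'
#' @keywords internal
SENSOR_VARIABLES <- c(DO = "mg/L", temperature = "degC", illuminance = "lux",
                      PAR = "umol/m2/s", pressure = "atm", depth = "m",
                      pH = "pH")

#' Read a delimited logger export
#'
#' Reads one variable's time series from a miniDOT/HOBO/EXO2-style delimited
#' text export.  The file layout is described by `dialect`, a list with
#' entries:
#' \describe{
#'   \item{timestamp_col}{name of the timestamp column.}
#'   \item{value_col}{name of the value column.}
#'   \item{timestamp_format}{[strptime()] format, default
#'     `"%Y-%m-%d %H:%M:%S"`.}
#'   \item{sep}{field separator, default `","`.}
#'   \item{skip}{header lines to skip before the column-name row, default 0.}
#' }
#'
#' Records are sorted by timestamp.  Duplicate timestamps are collapsed by a
#' keep-first policy with a warning.  Timestamps are parsed as local standard
#' time (no DST), stored as UTC.
#'
#' @param path file path.
#' @param variable one of `DO`, `temperature`, `illuminance`, `PAR`,
#'   `pressure`, `depth`, `pH`.
#' @param dialect list as described above.
#' @return A data frame of class `sensor_records` with columns `timestamp`,
#'   `variable`, `value`.
#' @export
read_sensor_file <- function(path, variable,
                             dialect = list(timestamp_col = "timestamp",
                                            value_col = "value")) {
  variable <- match.arg(variable, names(SENSOR_VARIABLES))
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- dialect$sep %||% ","
  skip <- dialect$skip %||% 0L
  fmt <- dialect$timestamp_format %||% "%Y-%m-%d %H:%M:%S"
  raw <- utils::read.table(path, sep = sep, skip = skip, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty sensor file: ", path)
  ts_col <- dialect$timestamp_col %||% "timestamp"
  val_col <- dialect$value_col %||% "value"
  for (cn in c(ts_col, val_col))
    if (!cn %in% names(raw)) stop("column '", cn, "' not found in ", path)
  ts <- as.POSIXct(raw[[ts_col]], tz = "UTC", format = fmt)
  if (anyNA(ts)) {
    line <- which(is.na(ts))[1L]
    stop("unparseable timestamp at data line ", line, " of ", path,
         ": '", raw[[ts_col]][line], "'")
  }
  value <- suppressWarnings(as.numeric(raw[[val_col]]))
  if (anyNA(value)) {
    line <- which(is.na(value))[1L]
    stop("non-numeric value at data line ", line, " of ", path)
  }
  ord <- order(ts)
  ts <- ts[ord]; value <- value[ord]
  dup <- duplicated(ts)
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) in ", path,
            "; keeping first occurrence")
    ts <- ts[!dup]; value <- value[!dup]
  }
  if (any(!is.finite(value))) stop("non-finite value in ", path)
  message(length(ts), " ", variable, " records read from ", basename(path))
  out <- data.frame(timestamp = ts, variable = variable, value = value,
                    stringsAsFactors = FALSE)
  class(out) <- c("sensor_records", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble aligned forcing from multi-logger streams
#'
#' Places independently logged streams onto one uniform time grid.  The grid
#' spans the interval covered by *all* required streams (DO, temperature and
#' light) at spacing `dt_days`.  Each stream is matched to the grid by
#' nearest-neighbour within half a step; grid points with no sample within
#' half a step are filled by linear interpolation provided the surrounding
#' gap does not exceed `max_gap_minutes`, otherwise an error identifies the
#' gap.  An `illuminance` stream is converted to PAR via [lux_to_par()].
#' Pressure and salinity may be supplied as streams or as constants.
#'
#' @param records_by_variable named list of `sensor_records` (names from
#'   `DO`, `temperature`, `illuminance` or `PAR`, `pressure`, `depth`, `pH`).
#' @param dt_days grid spacing in days; default 5 minutes.
#' @param max_gap_minutes longest gap (minutes) that may be bridged by
#'   linear interpolation; default 30.
#' @param pressure_atm constant pressure used when no pressure stream is
#'   given.
#' @param salinity_ppt constant salinity (default 0.12 ppt).
#' @param calibration_scale passed to [lux_to_par()].
#' @return A [forcing_series()].
#' @export
assemble_forcing <- function(records_by_variable, dt_days = 1 / 288,
                             max_gap_minutes = 30, pressure_atm = 1,
                             salinity_ppt = 0.12, calibration_scale = 1.0) {
  if (dt_days <= 0) stop("dt_days must be > 0")
  rv <- records_by_variable
  if (is.null(rv$DO) || is.null(rv$temperature))
    stop("DO and temperature streams are required")
  if (is.null(rv$PAR) && is.null(rv$illuminance))
    stop("a light stream (PAR or illuminance) is required")
  light <- rv$PAR
  if (is.null(light)) {
    light <- rv$illuminance
    light$value <- lux_to_par(light$value, calibration_scale)
  }
  req <- list(DO = rv$DO, temperature = rv$temperature, light = light)
  start <- max(vapply(req, function(r) as.numeric(min(r$timestamp)), 0))
  end <- min(vapply(req, function(r) as.numeric(max(r$timestamp)), 0))
  if (end - start < 86400 * dt_days)
    stop("sensor streams do not overlap on a common interval")
  step <- 86400 * dt_days
  grid <- seq(start, end, by = step)
  t <- as.POSIXct(grid, tz = "UTC", origin = "1970-01-01")

  regrid <- function(rec, what) {
    ts <- as.numeric(rec$timestamp); v <- rec$value
    idx <- findInterval(grid, ts, all.inside = TRUE)
    lo <- ts[idx]; hi <- ts[idx + 1L]
    near <- ifelse(grid - lo <= hi - grid, idx, idx + 1L)
    out <- v[near]
    far <- abs(ts[near] - grid) > step / 2 + 1e-9
    if (any(far)) {
      gap_min <- (hi - lo)[far] / 60
      too_wide <- gap_min > max_gap_minutes
      if (any(too_wide)) {
        k <- which(far)[which(too_wide)[1L]]
        stop(sprintf(
          "%s gap of %.1f min around %s exceeds max_gap_minutes = %g",
          what, (hi[k] - lo[k]) / 60,
          format(t[k], "%Y-%m-%d %H:%M:%S"), max_gap_minutes))
      }
      w <- (grid[far] - lo[far]) / (hi[far] - lo[far])
      out[far] <- (1 - w) * v[idx[far]] + w * v[idx[far] + 1L]
    }
    out
  }

  DO <- regrid(req$DO, "DO")
  temp <- regrid(req$temperature, "temperature")
  I <- pmax(regrid(req$light, "light"), 0)
  press <- if (!is.null(rv$pressure)) regrid(rv$pressure, "pressure") else pressure_atm
  forcing_series(t = t, I = I, temp = temp, press = press, sal = salinity_ppt,
                 DO_obs = DO, dt_days = dt_days)
}
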