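#' Construct a forcing series
#'
#' A `forcing_series` holds the uniform-interval environmental drivers needed
#' by the dissolved-oxygen model -- photosynthetically active radiation (PAR),
#' water temperature, atmospheric pressure and salinity -- together with the
#' observed dissolved-oxygen record (when available) and a calendar-day index.
#' It is an ordinary data frame with columns `t`, `I`, `temp`, `press`, `sal`,
#' `DO_obs`, `day_index` and a `dt_days` attribute giving the sampling
#' interval in days (5-minute sampling is `1/288`).
#'
#' Timestamps are treated as local standard time with no daylight-saving
#' adjustment; days are delimited at local midnight.  Internally they are
#' stored in the UTC representation so that arithmetic is free of DST jumps.
#'
#' @param t timestamps, `POSIXct` (or coercible via [as.POSIXct()] with
#'   `tz = "UTC"`); must be strictly increasing with uniform spacing.
#' @param I PAR, µmol m⁻² s⁻¹, non-negative (zero at night).
#' @param temp water temperature, °C.
#' @param press atmospheric pressure, atm; a scalar is recycled.
#' @param sal salinity, ppt; a scalar is recycled.  Defaults to 0.12 ppt,
#'   a typical headwater-stream constant.
#' @param DO_obs observed dissolved oxygen, mg L⁻¹, strictly positive;
#'   may be `NULL` for pure simulation.
#' @param dt_days sampling interval in days.  Inferred from `t` when `NULL`.
#'
#' @return A data frame of class `forcing_series`.
#' @seealso [assemble_forcing()] to build one from raw logger files,
#'   [write_forcing()] / [read_forcing()] for on-disk round trips.
#' @export
forcing_series <- function(t, I, temp, press = 1, sal = 0.12, DO_obs = NULL,
                           dt_days = NULL) {
  t <- as.POSIXct(t, tz = "UTC")
  n <- length(t)
  if (n < 2L) stop("a forcing series needs at least 2 samples")
  press <- rep_len(press, n)
  sal <- rep_len(sal, n)
  if (is.null(DO_obs)) DO_obs <- rep(NA_real_, n)
  fs <- data.frame(t = t, I = as.numeric(I), temp = as.numeric(temp),
                   press = as.numeric(press), sal = as.numeric(sal),
                   DO_obs = as.numeric(DO_obs))
  fs$day_index <- day_index_from_time(t)
  dt_obs <- as.numeric(difftime(t[2L], t[1L], units = "days"))
  if (is.null(dt_days)) dt_days <- dt_obs
  attr(fs, "dt_days") <- dt_days
  class(fs) <- c("forcing_series", "data.frame")
  validate_forcing(fs)
  fs
}

#' @rdname forcing_series
#' @param x object to test or coerce.
#' @export
is_forcing_series <- function(x) inherits(x, "forcing_series")

day_index_from_time <- function(t) {
  d <- as.Date(t, tz = "UTC")
  as.integer(factor(d, levels = unique(d)))
}

#' Validate a forcing series
#'
#' Checks the structural invariants: uniform timestamp spacing (relative
#' tolerance 1e-6), finite non-negative PAR, positive pressure, non-negative
#' salinity, positive observed DO where present, and contiguous day blocks.
#' Called by every function that consumes a `forcing_series`.
#'
#' @param fs a [forcing_series()].
#' @return `fs`, invisibly, or an error describing the violated invariant.
#' @export
validate_forcing <- function(fs) {
  stopifnot(is.data.frame(fs))
  need <- c("t", "I", "temp", "press", "sal", "DO_obs", "day_index")
  miss <- setdiff(need, names(fs))
  if (length(miss)) stop("forcing series lacks columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(fs)
  if (n < 2L) stop("forcing series needs >= 2 samples")
  dt <- attr(fs, "dt_days")
  if (is.null(dt) || !is.finite(dt) || dt <= 0)
    stop("dt_days attribute must be a positive number")
  steps <- diff(as.numeric(fs$t)) / 86400
  if (any(steps <= 0)) stop("timestamps must be strictly increasing")
  if (any(abs(steps - dt) > 1e-6 * dt))
    stop("timestamp spacing is not uniform at dt_days = ", signif(dt, 6))
  if (any(!is.finite(fs$I)) || any(fs$I < 0))
    stop("PAR (I) must be finite and >= 0")
  if (any(!is.finite(fs$temp))) stop("temperature must be finite")
  if (any(!is.finite(fs$press)) || any(fs$press <= 0))
    stop("pressure must be finite and > 0")
  if (any(!is.finite(fs$sal)) || any(fs$sal < 0))
    stop("salinity must be finite and >= 0")
  obs <- fs$DO_obs[!is.na(fs$DO_obs)]
  if (any(obs <= 0)) stop("observed DO must be > 0")
  # each day block contiguous
  di <- fs$day_index
  if (any(diff(di) < 0) || !identical(unique(di), sort(unique(di))))
    stop("day_index blocks must be contiguous and increasing")
  invisible(fs)
}

#' Write / read a forcing series as tidy CSV
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces every value exactly.
#'
#' @param fs a [forcing_series()].
#' @param path file path.
#' @return `write_forcing()` returns `path` invisibly; `read_forcing()`
#'   returns a `forcing_series`.
#' @export
write_forcing <- function(fs, path) {
  validate_forcing(fs)
  out <- data.frame(
    t = format(fs$t, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    I = fmt_num(fs$I), temp = fmt_num(fs$temp), press = fmt_num(fs$press),
    sal = fmt_num(fs$sal), DO_obs = fmt_num(fs$DO_obs),
    day_index = fs$day_index, stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fmt_num <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 17))

#' @rdname write_forcing
#' @export
read_forcing <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  t <- as.POSIXct(raw$t, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  fs <- forcing_series(t = t, I = raw$I, temp = raw$temp, press = raw$press,
                       sal = raw$sal, DO_obs = raw$DO_obs)
  fs
}

#' Extract one calendar day from a forcing series
#'
#' @param fs a [forcing_series()].
#' @param day integer day index (as in `fs$day_index`).
#' @return A `forcing_series` restricted to that day.
#' @export
forcing_day <- function(fs, day) {
  validate_forcing(fs)
  keep <- fs$day_index == day
  if (!any(keep)) stop("no samples with day_index == ", day)
  out <- fs[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dt_days") <- attr(fs, "dt_days")
  class(out) <- c("forcing_series", "data.frame")
  out
}

#' @export
print.forcing_series <- function(x, ...) {
  dt <- attr(x, "dt_days")
  cat(sprintf("<forcing_series> %d samples, %d day(s), dt = %.6g d (%.3g min)\n",
              nrow(x), length(unique(x$day_index)), dt, dt * 1440))
  cat(sprintf("  %s .. %s\n", format(x$t[1L]), format(x$t[nrow(x)])))
  if (all(is.na(x$DO_obs))) cat("  (no observed DO)\n")
  invisible(x)
}
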