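#' Map a month to its meteorological season
#'
#' March-May is spring, June-August summer, September-November fall and
#' December-February winter.
#'
#' @param month integer month(s), 1-12.
#' @return Character vector of season labels.
#' @export
assign_season <- function(month) {
  if (any(!month %in% 1:12)) stop("month must be an integer in 1..12")
  c("winter", "winter", "spring", "spring", "spring", "summer", "summer",
    "summer", "fall", "fall", "fall", "winter")[month]
}

#' Classify a day's trophic state
#'
#' A day is autotrophic when gross primary production meets or exceeds the
#' magnitude of ecosystem respiration (NEP = GPP + ER >= 0) and
#' heterotrophic otherwise; the balanced boundary case counts as
#' autotrophic.
#'
#' @param GPP daily gross primary production, mg O₂ L⁻¹ d⁻¹, >= 0.
#' @param ER daily ecosystem respiration, mg O₂ L⁻¹ d⁻¹, <= 0 (signed).
#' @return `"autotrophic"` or `"heterotrophic"`, vectorised.
#' @export
classify_trophic <- function(GPP, ER) {
  if (any(GPP < 0)) stop("GPP must be >= 0")
  if (any(ER > 0)) stop("ER must be <= 0 (a negative flux)")
  ifelse(GPP + ER >= 0, "autotrophic", "heterotrophic")
}

#' Arrhenius (metabolic-theory) fit of respiration on temperature
#'
#' Ordinary least squares of `ln|ER|` on inverse absolute temperature.
#' Under the metabolic theory of ecology the slope is `-E_A / k_B`, so the
#' activation energy is recovered as `E_A = -slope * k_B` with
#' `k_B = 8.617e-5` eV K⁻¹.  The intercept estimates the composite
#' `ln(b0 * M^(3/4))`, in which the mass and normalisation terms are not
#' separately identifiable.
#'
#' @param er per-interval respiration magnitudes, all > 0 (zero-respiration
#'   intervals must be excluded upstream).
#' @param temp_c water temperature, °C, same length.
#' @return A list of class `arrhenius_fit`: `slope` (K), `intercept`,
#'   `E_A` (eV), `r_squared`, `p_value` (two-sided, for the slope), `n`.
#' @export
arrhenius_fit <- function(er, temp_c) {
  if (length(er) != length(temp_c)) stop("er and temp_c lengths differ")
  if (length(er) < 3L) stop("need at least 3 points")
  if (any(er <= 0)) stop("all er values must be > 0 (log scale)")
  TK <- temp_c + 273.15
  if (stats::sd(TK) == 0) stop("temperature is constant; slope undefined")
  inv_T <- 1 / TK
  fit <- stats::lm(log(er) ~ inv_T)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 E_A = -slope * 8.617e-5,
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2L, 4L],
                 n = length(er)),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "Arrhenius fit (n = %d): slope %.1f K, E_A = %.3f eV, R2 = %.3f, p = %.3g\n",
    x$n, x$slope, x$E_A, x$r_squared, x$p_value))
  invisible(x)
}

#' Per-day Arrhenius fits
#'
#' Fits [arrhenius_fit()] to every day's set of per-interval respiration
#' values, the convention used for high-frequency metabolism records.
#'
#' @param er per-interval |ER| values, > 0.
#' @param temp_c matching temperatures, °C.
#' @param day_index matching day labels.
#' @return A data frame with one row per day: `day_index`, `slope`,
#'   `E_A`, `r_squared`, `p_value`, `n`.
#' @export
arrhenius_by_day <- function(er, temp_c, day_index) {
  stopifnot(length(er) == length(temp_c), length(er) == length(day_index))
  days <- unique(day_index)
  rows <- lapply(days, function(d) {
    k <- day_index == d
    f <- tryCatch(arrhenius_fit(er[k], temp_c[k]), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(day_index = d, slope = f$slope, E_A = f$E_A,
               r_squared = f$r_squared, p_value = f$p_value, n = f$n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Light-temperature regression of instantaneous GPP
#'
#' Least-squares fit of per-interval GPP on water temperature and PAR,
#' `GPP = a*T + b*I`, with no intercept by default (the physically natural
#' form: no production without light at freezing).  Reports the multiple
#' correlation between fitted and observed values.
#'
#' @param GPP per-interval GPP values.
#' @param temp_c water temperature, °C.
#' @param I PAR, µmol m⁻² s⁻¹.
#' @param include_intercept add an intercept term (off by default).
#' @return A list of class `gpp_regression`: `coefficients` (named
#'   `temp` and `I`, plus `(Intercept)` when requested), `multiple_r`,
#'   `fitted`, `n`.
#' @export
gpp_regression <- function(GPP, temp_c, I, include_intercept = FALSE) {
  n <- length(GPP)
  if (length(temp_c) != n || length(I) != n) stop("input lengths differ")
  if (n < 3L) stop("need at least 3 points")
  if (anyNA(GPP) || anyNA(temp_c) || anyNA(I)) stop("missing values")
  df <- data.frame(GPP = GPP, temp = temp_c, I = I)
  fml <- if (include_intercept) GPP ~ temp + I else GPP ~ 0 + temp + I
  X <- stats::model.matrix(fml, df)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design (collinear inputs)")
  fit <- stats::lm(fml, data = df)
  fitted <- unname(stats::fitted(fit))
  r <- if (stats::sd(fitted) > 0 && stats::sd(GPP) > 0)
    stats::cor(fitted, GPP) else NA_real_
  structure(list(coefficients = stats::coef(fit), multiple_r = r,
                 fitted = fitted, n = n),
            class = "gpp_regression")
}

#' @export
print.gpp_regression <- function(x, ...) {
  cat("GPP ~", paste(sprintf("%.3g*%s", x$coefficients,
                             names(x$coefficients)), collapse = " + "),
      sprintf(" (multiple r = %.3f, n = %d)\n", x$multiple_r, x$n))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties.  The p-value uses the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of
#' freedom by default; `method = "permutation"` gives an exact-style
#' two-sided permutation p-value instead.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @param seed optional seed for the permutation draw.
#' @return A list of class `spearman_cor`: `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, method = c("t", "permutation"),
                         n_perm = 2000, seed = NULL) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 3L) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance in ranks; correlation undefined")
  rho <- stats::cor(rx, ry)
  p <- if (method == "t") {
    if (abs(rho) >= 1) 0 else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
  } else {
    with_seed(seed, {
      perm <- vapply(seq_len(n_perm),
                     function(i) stats::cor(rx, sample(ry)), 0)
      (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
    })
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d, p = %.3g, %s)\n",
              x$rho, x$n, x$p_value, x$method))
  invisible(x)
}

#' Diel amplitude of a daily series
#'
#' Maximum minus minimum within each calendar day.
#'
#' @param x observed values (e.g. DO, mg L⁻¹).
#' @param day_index optional day labels; when `NULL` the whole vector is
#'   one day.
#' @return A named numeric vector of per-day amplitudes (>= 0).
#' @export
diel_amplitude <- function(x, day_index = NULL) {
  if (!length(x)) stop("empty series")
  if (is.null(day_index)) day_index <- rep(1L, length(x))
  vapply(split(x, day_index), function(v) max(v) - min(v), 0)
}

#' Seasonal summary of daily metabolism
#'
#' Groups accepted days by season and reports medians and quartiles of
#' GPP, ER, NEP and `K_O2` (and of daily median DO and diel DO amplitude
#' when supplied) plus trophic-state day counts.
#'
#' @param daily a daily results table (from [metab()]'s `daily` element or
#'   [read.csv()] of its export) with columns `date`, `GPP`, `ER`, `NEP`,
#'   `K_O2`, `accepted`, and optionally `DO_median` and `amplitude`.
#' @param accepted_only drop days rejected by the ppp band (default TRUE).
#' @return A data frame with one row per season present.
#' @export
seasonal_summary <- function(daily, accepted_only = TRUE) {
  d <- daily
  if (accepted_only && "accepted" %in% names(d)) d <- d[d$accepted, ]
  if (!nrow(d)) {
    warning("no accepted days; empty summary")
    return(data.frame())
  }
  season <- assign_season(as.integer(format(as.Date(d$date), "%m")))
  troph <- classify_trophic(d$GPP, d$ER)
  q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  rows <- lapply(split(seq_len(nrow(d)), season), function(k) {
    s <- d[k, ]
    out <- data.frame(season = assign_season(
      as.integer(format(as.Date(s$date[1L]), "%m"))))
    for (v in intersect(c("GPP", "ER", "NEP", "K_O2", "DO_median",
                          "amplitude"), names(s))) {
      qq <- q(s[[v]])
      out[[paste0(v, "_q25")]] <- qq[1L]
      out[[paste0(v, "_median")]] <- qq[2L]
      out[[paste0(v, "_q75")]] <- qq[3L]
    }
    out$n_days <- nrow(s)
    out$n_autotrophic <- sum(troph[k] == "autotrophic")
    out$n_heterotrophic <- sum(troph[k] == "heterotrophic")
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(match(out$season, c("spring", "summer", "fall", "winter"))), ,
      drop = FALSE]
}
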