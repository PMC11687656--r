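#' Fit the single-station metabolism model to a multi-day oxygen record
#'
#' The central fitting function.  Each calendar day in `forcing` with a
#' complete DO record and at least 48 samples is fitted independently by
#' [fit_day()]; per-day posteriors are summarised into daily gross primary
#' production (GPP), ecosystem respiration (ER, a negative flux), net
#' ecosystem production (NEP = GPP + ER) and the reaeration coefficient
#' `K_O2`, each with credible intervals, a posterior-predictive p-value and
#' the resulting quality-control flag.
#'
#' @param forcing a [forcing_series()] with observed DO.
#' @param priors a [metab_priors()].
#' @param chains,iter,burn MCMC settings passed to [fit_day()].
#' @param seed integer master seed; day `d` is fitted with seed
#'   `seed + d` so runs are reproducible end to end.
#' @param p,theta fixed model constants, see [metab_params()].
#' @param level credible-interval level for the daily summaries.
#' @param discrepancy posterior-predictive discrepancy, see
#'   [posterior_predictive_pvalue()].
#' @param quiet suppress per-day progress messages.
#' @return An object of class `metab_fit`: a list with `daily` (data frame,
#'   one row per fitted day -- see [summarize_daily()]), `fits` (list of
#'   `metab_draws`), `forcing`, `failed` (named character vector of days
#'   that could not be fitted) and the call settings.
#' @seealso [summary.metab_fit()], [predict.metab_fit()],
#'   [simulate.metab_fit()], [plot.metab_fit()]
#' @export
metab <- function(forcing, priors = metab_priors(), chains = 4, iter = 3000,
                  burn = 1500, seed = NULL, p = 1, theta = 1.072,
                  level = 0.95,
                  discrepancy = c("omnibus", "lag1_autocorr",
                                  "sq_std_resid"),
                  quiet = FALSE) {
  validate_forcing(forcing)
  discrepancy <- match.arg(discrepancy)
  days <- unique(forcing$day_index)
  fits <- list()
  rows <- list()
  failed <- character()
  for (d in days) {
    fd <- forcing_day(forcing, d)
    if (nrow(fd) < 48L || anyNA(fd$DO_obs)) {
      failed[as.character(d)] <- "incomplete day (needs >= 48 DO samples)"
      next
    }
    day_seed <- if (is.null(seed)) NULL else seed + d
    res <- tryCatch({
      fit <- fit_day(forcing, day = d, priors = priors, chains = chains,
                     iter = iter, burn = burn, seed = day_seed,
                     p = p, theta = theta)
      ppp <- posterior_predictive_pvalue(
        fit, discrepancy = discrepancy,
        seed = if (is.null(day_seed)) NULL else day_seed + 1L)
      list(fit = fit, row = summarize_daily(fit, level = level, ppp = ppp))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[as.character(d)] <- conditionMessage(res)
      next
    }
    fits[[as.character(d)]] <- res$fit
    rows[[as.character(d)]] <- cbind(day_index = d, res$row)
    if (!quiet)
      message(sprintf("day %s: GPP %.2f, ER %.2f, K_O2 %.1f, ppp %.2f%s",
                      format(res$row$date), res$row$GPP, res$row$ER,
                      res$row$K_O2, res$row$ppp,
                      if (res$row$accepted) "" else "  [rejected]"))
  }
  if (!length(rows)) stop("no complete day could be fitted")
  daily <- do.call(rbind, rows)
  rownames(daily) <- NULL
  structure(list(daily = daily, fits = fits, forcing = forcing,
                 failed = failed, level = level,
                 settings = list(chains = chains, iter = iter, burn = burn,
                                 seed = seed, p = p, theta = theta,
                                 discrepancy = discrepancy),
                 priors = priors),
            class = "metab_fit")
}

#' @export
print.metab_fit <- function(x, ...) {
  d <- x$daily
  cat(sprintf("<metab_fit> %d day(s) fitted, %d accepted (ppp in [0.1, 0.9])\n",
              nrow(d), sum(d$accepted)))
  if (length(x$failed))
    cat("  failed days:", paste(names(x$failed), collapse = ", "), "\n")
  cat(sprintf("  GPP %.2f..%.2f, ER %.2f..%.2f mg O2/L/d, K_O2 %.1f..%.1f /d\n",
              min(d$GPP), max(d$GPP), min(d$ER), max(d$ER),
              min(d$K_O2), max(d$K_O2)))
  invisible(x)
}

#' Summarise a metabolism fit
#'
#' @param object a `metab_fit`.
#' @param ... unused.
#' @return An object of class `summary.metab_fit` printing the daily table,
#'   trophic-state counts and convergence information.
#' @export
summary.metab_fit <- function(object, ...) {
  d <- object$daily
  troph <- classify_trophic(d$GPP, d$ER)
  out <- list(daily = d,
              n_days = nrow(d),
              n_accepted = sum(d$accepted),
              trophic_counts = table(factor(troph, c("autotrophic",
                                                     "heterotrophic"))),
              rhat_max = max(d$rhat_max),
              level = object$level)
  class(out) <- "summary.metab_fit"
  out
}

#' @export
print.summary.metab_fit <- function(x, ...) {
  cat(sprintf("Daily metabolism: %d day(s), %d accepted by the ppp band\n",
              x$n_days, x$n_accepted))
  cat(sprintf("Trophic state: %d autotrophic, %d heterotrophic day(s)\n",
              x$trophic_counts[["autotrophic"]],
              x$trophic_counts[["heterotrophic"]]))
  cat(sprintf("Worst split R-hat: %.3f\n\n", x$rhat_max))
  cols <- c("date", "GPP", "GPP_lo", "GPP_hi", "ER", "ER_lo", "ER_hi",
            "NEP", "K_O2", "ppp", "accepted")
  df <- x$daily[, cols]
  df[-1] <- lapply(df[-1], function(v) if (is.numeric(v)) round(v, 3) else v)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Posterior-mean parameters per fitted day
#'
#' @param object a `metab_fit`.
#' @param ... unused.
#' @return A matrix (days x parameters) of posterior means of `A`, `R`,
#'   `K_O2` and `sigma_obs`.
#' @export
coef.metab_fit <- function(object, ...) {
  out <- t(vapply(object$fits, function(f) colMeans(f$draws),
                  numeric(4L)))
  rownames(out) <- vapply(object$fits,
                          function(f) format(f$day_data$date), "")
  out
}

#' Posterior-mean modeled DO path
#'
#' For each fitted day, the modeled DO trajectory averaged over (a thinned
#' subset of) posterior draws.
#'
#' @param object a `metab_fit`.
#' @param ndraws number of posterior draws averaged per day.
#' @param ... unused.
#' @return A data frame `t`, `day_index`, `DO_obs`, `DO_fit`.
#' @export
predict.metab_fit <- function(object, ndraws = 100, ...) {
  res <- lapply(object$fits, function(f) {
    dd <- f$day_data
    m <- nrow(f$draws)
    idx <- unique(round(seq(1L, m, length.out = min(ndraws, m))))
    acc <- matrix(0, length(idx), dd$n)
    keep <- logical(length(idx))
    for (k in seq_along(idx)) {
      th <- f$draws[idx[k], ]
      DO <- forward_day(th[1L], th[2L], th[3L], dd)
      if (!is.null(DO)) { acc[k, ] <- DO; keep[k] <- TRUE }
    }
    data.frame(t = dd$t, day_index = f$day,
               DO_obs = dd$y, DO_fit = colMeans(acc[keep, , drop = FALSE]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @export
fitted.metab_fit <- function(object, ...) predict(object, ...)$DO_fit

#' Residuals of a metabolism fit
#'
#' @param object a `metab_fit`.
#' @param ... passed to [predict.metab_fit()].
#' @return Observed minus posterior-mean modeled DO, mg L⁻¹.
#' @export
residuals.metab_fit <- function(object, ...) {
  pr <- predict(object, ...)
  pr$DO_obs - pr$DO_fit
}

#' Posterior-predictive DO series
#'
#' Draws replicate observation series from the fitted model: for each
#' simulation a posterior draw is selected at random, the day is
#' forward-simulated and Gaussian observation noise added.
#'
#' @param object a `metab_fit`.
#' @param nsim number of replicate series.
#' @param seed optional seed.
#' @param ... unused.
#' @return A data frame with columns `t`, `day_index` and `sim_1` ..
#'   `sim_nsim`.
#' @export
simulate.metab_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    per_day <- lapply(object$fits, function(f) {
      dd <- f$day_data
      sims <- matrix(NA_real_, dd$n, nsim)
      for (s in seq_len(nsim)) {
        th <- f$draws[sample.int(nrow(f$draws), 1L), ]
        DO <- forward_day(th[1L], th[2L], th[3L], dd)
        if (is.null(DO)) next
        sims[, s] <- DO + stats::rnorm(dd$n, 0, th[4L])
        sims[1L, s] <- DO[1L]  # initial state is conditioned on
      }
      cbind(data.frame(t = dd$t, day_index = f$day), as.data.frame(sims))
    })
    out <- do.call(rbind, per_day)
    names(out)[-(1:2)] <- paste0("sim_", seq_len(nsim))
    rownames(out) <- NULL
    out
  })
}

#' Plot a metabolism fit
#'
#' Observed DO (points), posterior-mean modeled DO (line) and the
#' saturation concentration (dashed) over time.
#'
#' @param x a `metab_fit`.
#' @param ... passed to [plot()].
#' @export
plot.metab_fit <- function(x, ...) {
  pr <- predict(x)
  sat <- unlist(lapply(x$fits, function(f) f$day_data$DO_sat))
  graphics::plot(pr$t, pr$DO_obs, pch = 16, cex = 0.3, col = "grey40",
                 xlab = "time", ylab = "DO (mg/L)", ...)
  graphics::lines(pr$t, pr$DO_fit, col = "steelblue", lwd = 2)
  graphics::lines(pr$t, sat, col = "tomato", lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("observed", "fitted", "saturation"),
                   col = c("grey40", "steelblue", "tomato"),
                   pch = c(16, NA, NA), lty = c(NA, 1, 2), lwd = c(NA, 2, 1))
  invisible(x)
}

#' Write the daily results table
#'
#' One row per fitted day, in the layout produced by [summarize_daily()].
#'
#' @param fit a `metab_fit` (or its `daily` data frame).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_daily_results <- function(fit, path) {
  d <- if (inherits(fit, "metab_fit")) fit$daily else fit
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
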