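#' Prior specification for the metabolic parameters
#'
#' Defaults are deliberately vague: uniform on generous non-negative ranges
#' for `A`, `R` and `K_O2` and half-normal for the observation noise.  A
#' weakly informative alternative can be expressed through the same
#' constructor, e.g. a truncated-normal reaeration prior centred on a known
#' site value via `K_O2_mean`/`K_O2_sd`.
#'
#' @param A_max upper bound of the uniform prior on `A`
#'   (mg O₂ L⁻¹ per (µmol m⁻² s⁻¹) per interval).
#' @param R_max upper bound of the uniform prior on `R` (mg O₂ L⁻¹ per
#'   interval).
#' @param K_O2_max upper bound of the uniform prior on `K_O2` (d⁻¹).
#' @param sigma_scale scale of the half-normal prior on `sigma_obs` (mg L⁻¹).
#' @param K_O2_mean,K_O2_sd optional mean/sd of a normal prior on `K_O2`
#'   truncated to `[0, K_O2_max]`; both `NULL` (uniform) by default.
#' @return A list of class `metab_priors`.
#' @export
metab_priors <- function(A_max = 0.1, R_max = 1, K_O2_max = 100,
                         sigma_scale = 1, K_O2_mean = NULL, K_O2_sd = NULL) {
  stopifnot(A_max > 0, R_max > 0, K_O2_max > 0, sigma_scale > 0)
  if (xor(is.null(K_O2_mean), is.null(K_O2_sd)))
    stop("supply both K_O2_mean and K_O2_sd, or neither")
  structure(list(A_max = A_max, R_max = R_max, K_O2_max = K_O2_max,
                 sigma_scale = sigma_scale,
                 K_O2_mean = K_O2_mean, K_O2_sd = K_O2_sd),
            class = "metab_priors")
}

# precomputed per-day quantities used by the likelihood loop
day_data <- function(fd, p = 1, theta = 1.072) {
  validate_forcing(fd)
  if (length(unique(fd$day_index)) != 1L)
    stop("day_data expects a single calendar day; use forcing_day()")
  if (anyNA(fd$DO_obs)) stop("day has missing DO observations")
  tbar <- mean(fd$temp)
  list(y = fd$DO_obs, n = nrow(fd), dt = attr(fd, "dt_days"),
       Ip = fd$I^p, theta_pow = theta^(fd$temp - tbar),
       rea_pow = 1.0241^(fd$temp - tbar),
       DO_sat = o2_saturation(fd$temp, fd$press, fd$sal),
       DO_0 = fd$DO_obs[1L], date = as.Date(fd$t[1L], tz = "UTC"),
       t = fd$t, p = p, theta = theta, tbar = tbar)
}

# forward model for one day given (A, R, K); returns modeled DO or NULL if
# the trajectory leaves the positive orthant
forward_day <- function(A, R, K, dd) {
  gpp <- A * dd$Ip
  er <- R * dd$theta_pow
  kf <- K * dd$dt * dd$rea_pow
  DO <- numeric(dd$n)
  DO[1L] <- dd$DO_0
  for (i in seq_len(dd$n - 1L)) {
    DO[i + 1L] <- DO[i] + gpp[i] - er[i] + kf[i] * (dd$DO_sat[i] - DO[i])
    if (DO[i + 1L] <= 0) return(NULL)
  }
  DO
}

log_prior_vec <- function(th, priors) {
  A <- th[1L]; R <- th[2L]; K <- th[3L]; s <- th[4L]
  if (A < 0 || A > priors$A_max || R < 0 || R > priors$R_max ||
      K < 0 || K > priors$K_O2_max || s <= 0) return(-Inf)
  lp <- -log(priors$A_max) - log(priors$R_max) +
    stats::dnorm(s, 0, priors$sigma_scale, log = TRUE) + log(2)
  if (is.null(priors$K_O2_mean)) {
    lp <- lp - log(priors$K_O2_max)
  } else {
    lp <- lp + stats::dnorm(K, priors$K_O2_mean, priors$K_O2_sd, log = TRUE)
  }
  lp
}

log_post_vec <- function(th, dd, priors) {
  lp <- log_prior_vec(th, priors)
  if (!is.finite(lp)) return(-Inf)
  DO <- forward_day(th[1L], th[2L], th[3L], dd)
  if (is.null(DO)) return(-Inf)
  # first sample fixes the initial state, so it carries no information
  ll <- sum(stats::dnorm(dd$y[-1L], DO[-1L], th[4L], log = TRUE))
  if (!is.finite(ll)) return(-Inf)
  lp + ll
}

#' Log-posterior density of the daily model
#'
#' Gaussian observation likelihood of the observed DO around the forward
#' simulation (the first sample of the day is treated as the known initial
#' state), plus the log-prior.  Returns `-Inf` outside the prior support or
#' when the forward trajectory collapses to non-positive DO.
#'
#' @param params a [metab_params()] (its `p` and `theta` are taken as
#'   fixed model constants).
#' @param forcing a single-day [forcing_series()] with observed DO.
#' @param priors a [metab_priors()].
#' @return Scalar log-density.
#' @export
log_posterior <- function(params, forcing, priors = metab_priors()) {
  if (!inherits(params, "metab_params")) params <- do.call(metab_params, params)
  dd <- day_data(forcing, p = params$p, theta = params$theta)
  log_post_vec(c(params$A, params$R, params$K_O2, params$sigma_obs),
               dd, priors)
}

# run body with a private, restorable RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# split-chain potential scale reduction factor, one value per column
split_rhat <- function(chain_list) {
  halves <- list()
  for (ch in chain_list) {
    m <- nrow(ch) %/% 2L
    halves <- c(halves, list(ch[seq_len(m), , drop = FALSE],
                             ch[(m + 1L):(2L * m), , drop = FALSE]))
  }
  n <- nrow(halves[[1L]])
  vapply(seq_len(ncol(halves[[1L]])), function(j) {
    means <- vapply(halves, function(h) mean(h[, j]), 0)
    vars <- vapply(halves, function(h) stats::var(h[, j]), 0)
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
}

map_estimate <- function(dd, priors) {
  # Conditioned on the *observed* DO path, the one-step model is linear in
  # (A, R, K*dt): dDO_i = A*I_i^p - R*theta_pow_i + K*dt*rea_pow_i*D_i.
  # A non-negative least-squares pass on the observed increments therefore
  # gives a near-exact initial estimate, refined by Nelder-Mead on the true
  # (sequentially simulated) posterior.
  n <- dd$n
  dy <- diff(dd$y)
  D <- dd$DO_sat - dd$y
  X <- cbind(dd$Ip[-n], -dd$theta_pow[-n], (dd$dt * dd$rea_pow * D)[-n])
  cf <- tryCatch(stats::lm.fit(X, dy)$coefficients,
                 error = function(e) c(NA, NA, NA))
  cf[!is.finite(cf)] <- 0
  A0 <- min(max(cf[1L], 0), priors$A_max * 0.99)
  R0 <- min(max(cf[2L], 1e-6), priors$R_max * 0.99)
  K0 <- min(max(cf[3L], 0.5), priors$K_O2_max * 0.99)
  # one-step residual noise is a difference of two observation errors
  s0 <- stats::sd(dy - X %*% pmax(cf, 0)) / sqrt(2)
  s0 <- min(max(s0, 1e-3, na.rm = TRUE), 5 * priors$sigma_scale)
  obj <- function(th) {
    v <- -log_post_vec(th, dd, priors)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- list(c(A0, R0, K0, s0),
                 c(A0, R0 * 2, K0 * 2, s0 * 2),
                 c(max(A0 / 2, 1e-8), R0 / 2, max(K0 / 2, 0.5), s0))
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(s, obj, method = "Nelder-Mead",
                            control = list(maxit = 1000)), silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10)
    stop("posterior is non-finite everywhere tried; check data and priors")
  pmin(pmax(best$par, c(0, 0, 0, 1e-3)),
       c(priors$A_max, priors$R_max, priors$K_O2_max, Inf))
}

#' Fit the metabolism model to one day by MCMC
#'
#' Adaptive random-walk Metropolis targeting [log_posterior()] for the free
#' parameters (`A`, `R`, `K_O2`, `sigma_obs`; `p` and `theta` are fixed
#' constants).  Chains start from jittered optimiser estimates; during
#' burn-in the proposal is a diagonal Gaussian with acceptance-rate tuning,
#' after which the proposal covariance is frozen at the scaled empirical
#' covariance of the late burn-in draws.  A split-chain potential scale
#' reduction factor is reported and a warning raised when it exceeds 1.1.
#'
#' @param forcing a [forcing_series()]; either a single day or a series from
#'   which `day` selects one.
#' @param day day index within `forcing` (default: its first day).
#' @param priors a [metab_priors()].
#' @param chains number of chains (>= 2 for the convergence diagnostic).
#' @param iter iterations per chain, including burn-in.
#' @param burn burn-in iterations discarded from each chain.
#' @param seed integer seed; identical seeds give identical draws.
#' @param p,theta fixed light-saturation exponent and respiration
#'   temperature coefficient.
#' @return A list of class `metab_draws`: `draws` (matrix with columns
#'   `A`, `R`, `K_O2`, `sigma_obs`), `rhat`, `accept_rate`, `n_chains`,
#'   `n_iter`, `n_burn`, `seed`, and the per-day model data needed by
#'   [summarize_daily()] and [posterior_predictive_pvalue()].
#' @export
fit_day <- function(forcing, day = NULL, priors = metab_priors(),
                    chains = 4, iter = 3000, burn = 1500, seed = NULL,
                    p = 1, theta = 1.072) {
  validate_forcing(forcing)
  if (is.null(day)) day <- forcing$day_index[1L]
  fd <- forcing_day(forcing, day)
  if (nrow(fd) < 48L)
    stop("day ", day, " has ", nrow(fd),
         " observations; at least 48 are required")
  if (chains < 2L) stop("at least 2 chains are required")
  if (iter <= burn) stop("iter must exceed burn")
  dd <- day_data(fd, p = p, theta = theta)

  with_seed(seed, {
    th0 <- map_estimate(dd, priors)
    npar <- 4L
    # random walk on log-parameters: removes the positivity boundary and
    # makes proposal scales dimensionless.  A zero MAP component (e.g. A on
    # a lightless day) is floored before taking logs.
    z_floor <- c(1e-10, 1e-8, 1e-4, 1e-4)
    z0 <- log(pmax(th0, z_floor))
    log_post_z <- function(z) {
      th <- exp(z)
      lp <- log_post_vec(th, dd, priors)
      if (!is.finite(lp)) return(-Inf)
      lp + sum(z)  # Jacobian of the exp transform
    }
    chain_draws <- vector("list", chains)
    accepts <- numeric(chains)
    for (c_i in seq_len(chains)) {
      z <- z0 + stats::rnorm(npar, 0, 0.2)
      lp <- log_post_z(z)
      if (!is.finite(lp)) { z <- z0; lp <- log_post_z(z) }
      if (!is.finite(lp)) stop("could not initialise chain ", c_i,
                               ": posterior non-finite at start")
      scale <- 0.1
      L <- diag(scale, npar)
      lambda <- 1
      zdraws <- matrix(NA_real_, iter, npar)
      n_acc <- 0L
      block_acc <- 0L
      for (it in seq_len(iter)) {
        prop <- z + lambda * drop(stats::rnorm(npar) %*% L)
        lp_prop <- log_post_z(prop)
        if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
          z <- prop; lp <- lp_prop
          n_acc <- n_acc + 1L; block_acc <- block_acc + 1L
        }
        zdraws[it, ] <- z
        if (it <= burn && it %% 50L == 0L) {
          # global scale tuning towards ~0.3 acceptance
          lambda <- lambda * exp(0.8 * (block_acc / 50 - 0.3))
          block_acc <- 0L
          if (it >= 200L) {
            # re-estimate the proposal covariance from the recent window
            win <- zdraws[max(1L, it - 500L):it, , drop = FALSE]
            S <- 2.38^2 / npar * stats::cov(win) + diag(1e-8, npar)
            Lc <- try(chol(S), silent = TRUE)
            if (!inherits(Lc, "try-error")) L <- Lc
          }
        }
      }
      chain_draws[[c_i]] <- exp(zdraws[(burn + 1L):iter, , drop = FALSE])
      accepts[c_i] <- n_acc / iter
    }
    rhat <- split_rhat(chain_draws)
    names(rhat) <- c("A", "R", "K_O2", "sigma_obs")
    if (max(rhat) > 1.1)
      warning(sprintf("split-chain R-hat %.3f > 1.1 on day %s; ",
                      max(rhat), format(dd$date)),
              "consider longer chains")
    all_draws <- do.call(rbind, chain_draws)
    colnames(all_draws) <- c("A", "R", "K_O2", "sigma_obs")
    structure(list(draws = all_draws, rhat = rhat,
                   accept_rate = mean(accepts), n_chains = chains,
                   n_iter = iter, n_burn = burn, seed = seed,
                   day = day, day_data = dd, map = th0,
                   priors = priors),
              class = "metab_draws")
  })
}

#' @export
print.metab_draws <- function(x, ...) {
  cat(sprintf("<metab_draws> day %s: %d draws (%d chains x %d kept)\n",
              format(x$day_data$date), nrow(x$draws), x$n_chains,
              x$n_iter - x$n_burn))
  cat(sprintf("  max split R-hat %.3f, mean acceptance %.2f\n",
              max(x$rhat), x$accept_rate))
  print(round(apply(x$draws, 2L, stats::quantile,
                    c(0.025, 0.5, 0.975)), 5))
  invisible(x)
}

#' Posterior-predictive p-value for a fitted day
#'
#' For a subsample of posterior draws, replicate datasets are simulated from
#' the fitted observation model and a discrepancy statistic is compared
#' between replicated and observed data; the p-value is the fraction of
#' replicates whose discrepancy meets or exceeds the observed one.  Values
#' near 0 or 1 indicate misfit; the conventional plausibility band is
#' \[0.1, 0.9\].
#'
#' Three discrepancies are available.  `"sq_std_resid"` is the sum of
#' squared standardised residuals; because the observation-noise scale is
#' itself estimated, it is insensitive to structured misfit (an inflated
#' sigma absorbs the magnitude).  `"lag1_autocorr"` is `n` times the
#' squared lag-1 autocorrelation of the standardised residuals -- nearly
#' pivotal, hence sharply sensitive to serial structure but close to
#' uniform under the model.  The default, `"omnibus"`, is their sum: it
#' keeps the conservative in-band behaviour of the chi-square part on
#' well-specified days while the autocorrelation part still explodes under
#' structured misfit such as an unmodelled drift.
#'
#' @param draws a `metab_draws` from [fit_day()].
#' @param discrepancy `"omnibus"`, `"lag1_autocorr"` or `"sq_std_resid"`.
#' @param n_rep number of posterior draws used (subsampled evenly).
#' @param seed optional seed for the replicate noise.
#' @return Scalar p-value in \[0, 1\].
#' @export
posterior_predictive_pvalue <- function(draws,
                                        discrepancy = c("omnibus",
                                                        "lag1_autocorr",
                                                        "sq_std_resid"),
                                        n_rep = 200, seed = NULL) {
  stopifnot(inherits(draws, "metab_draws"))
  discrepancy <- match.arg(discrepancy)
  dd <- draws$day_data
  m <- nrow(draws$draws)
  idx <- unique(round(seq(1L, m, length.out = min(n_rep, m))))
  d_chisq <- function(r) sum(r^2)
  d_lag1 <- function(r) {
    n <- length(r)
    rc <- r - mean(r)
    n * (sum(rc[-1L] * rc[-n]) / sum(rc^2))^2
  }
  disc <- switch(discrepancy,
    sq_std_resid = d_chisq,
    lag1_autocorr = d_lag1,
    omnibus = function(r) d_chisq(r) + d_lag1(r))
  with_seed(seed, {
    exceed <- logical(length(idx))
    for (k in seq_along(idx)) {
      th <- draws$draws[idx[k], ]
      DO <- forward_day(th[1L], th[2L], th[3L], dd)
      if (is.null(DO)) { exceed[k] <- NA; next }
      mu <- DO[-1L]
      y <- dd$y[-1L]
      r_obs <- (y - mu) / th[4L]
      r_rep <- stats::rnorm(length(mu))
      exceed[k] <- disc(r_rep) >= disc(r_obs)
    }
    mean(exceed, na.rm = TRUE)
  })
}

#' Summarise a fitted day as daily metabolism
#'
#' Per-interval GPP and ER series are computed for every posterior draw and
#' summed over the day (the daily-total convention: a day's value is the sum
#' of its interval values); `NEP = GPP + ER` holds exactly draw by draw, ER
#' being carried as a negative flux.  Posterior means, medians and central
#' credible intervals are reported together with the posterior-predictive
#' p-value and the resulting acceptance flag (`0.1 <= ppp <= 0.9`).
#'
#' @param draws a `metab_draws` from [fit_day()].
#' @param level credible-interval level (default 0.95).
#' @param ppp optionally, a precomputed posterior-predictive p-value; when
#'   `NULL` it is computed with the default discrepancy (seeded from the
#'   fit's seed when available).
#' @return A one-row data frame with columns `date`, `GPP`, `GPP_median`,
#'   `GPP_lo`, `GPP_hi`, `ER`, `ER_median`, `ER_lo`, `ER_hi`, `NEP`,
#'   `NEP_lo`, `NEP_hi`, `K_O2`, `K_O2_lo`, `K_O2_hi`, `sigma_obs`, `ppp`,
#'   `accepted`, `n_obs`, `rhat_max`, `seed`.
#' @export
summarize_daily <- function(draws, level = 0.95, ppp = NULL) {
  stopifnot(inherits(draws, "metab_draws"))
  dd <- draws$day_data
  th <- draws$draws
  totals <- daily_totals(th, dd)
  gpp_d <- totals$GPP
  er_d <- totals$ER
  nep_d <- totals$NEP
  if (is.null(ppp))
    ppp <- posterior_predictive_pvalue(
      draws, seed = if (!is.null(draws$seed)) draws$seed + 1L else NULL)
  a <- (1 - level) / 2
  qs <- function(x) stats::quantile(x, c(a, 1 - a), names = FALSE)
  g <- qs(gpp_d); e <- qs(er_d); nn <- qs(nep_d); k <- qs(th[, "K_O2"])
  out <- data.frame(
    date = dd$date,
    GPP = mean(gpp_d), GPP_median = stats::median(gpp_d),
    GPP_lo = g[1L], GPP_hi = g[2L],
    ER = mean(er_d), ER_median = stats::median(er_d),
    ER_lo = e[1L], ER_hi = e[2L],
    NEP = mean(gpp_d) + mean(er_d), NEP_lo = nn[1L], NEP_hi = nn[2L],
    K_O2 = mean(th[, "K_O2"]), K_O2_lo = k[1L], K_O2_hi = k[2L],
    sigma_obs = mean(th[, "sigma_obs"]),
    ppp = ppp, accepted = ppp >= 0.1 & ppp <= 0.9,
    n_obs = dd$n, rhat_max = max(draws$rhat),
    seed = if (is.null(draws$seed)) NA_integer_ else draws$seed)
  rownames(out) <- NULL
  out
}

#' Per-draw daily totals
#'
#' The daily GPP/ER/NEP posterior sample underlying [summarize_daily()],
#' useful for custom summaries.
#'
#' @param draws a `metab_draws`.
#' @return A data frame with one row per posterior draw: `GPP`, `ER`,
#'   `NEP`, `K_O2`, `sigma_obs`.
#' @export
daily_draws <- function(draws) {
  stopifnot(inherits(draws, "metab_draws"))
  totals <- daily_totals(draws$draws, draws$day_data)
  data.frame(totals, K_O2 = draws$draws[, "K_O2"],
             sigma_obs = draws$draws[, "sigma_obs"])
}

# daily totals as literal sums of the per-interval process values, so the
# summation convention ("a day's value is the sum of its interval values")
# holds bit-for-bit for every draw
daily_totals <- function(th, dd) {
  gpp <- vapply(th[, "A"], function(a) sum(a * dd$Ip), 0)
  er <- vapply(th[, "R"], function(r) -sum(r * dd$theta_pow), 0)
  data.frame(GPP = gpp, ER = er, NEP = gpp + er)
}
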