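test_that("the log-posterior respects the prior support", {
  fs <- one_day("summer", seed = 21)
  pr <- metab_priors()
  good <- metab_params(A = 1e-4, R = 0.05, K_O2 = 9.8, sigma_obs = 0.1)
  expect_true(is.finite(log_posterior(good, fs, pr)))
  over <- metab_params(A = pr$A_max * 2, R = 0.05, K_O2 = 9.8)
  expect_identical(log_posterior(over, fs, pr), -Inf)
  over_k <- metab_params(A = 1e-4, R = 0.05, K_O2 = pr$K_O2_max + 1)
  expect_identical(log_posterior(over_k, fs, pr), -Inf)
})

test_that("near-noiseless data peaks the posterior at the truth", {
  fs <- generate_scenario(scenario_preset("summer", n_days = 1, seed = 31,
                                          sigma_obs = 1e-4))
  tp <- attr(fs, "true_params")
  truth <- metab_params(tp$A, tp$R, tp$K_O2, sigma_obs = 1e-4)
  lp0 <- log_posterior(truth, fs)
  for (f in c(0.98, 1.02)) {
    expect_lt(log_posterior(metab_params(tp$A * f, tp$R, tp$K_O2, 1e-4), fs), lp0)
    expect_lt(log_posterior(metab_params(tp$A, tp$R * f, tp$K_O2, 1e-4), fs), lp0)
    expect_lt(log_posterior(metab_params(tp$A, tp$R, tp$K_O2 * f, 1e-4), fs), lp0)
  }
})

test_that("doubling sigma shifts the posterior by the Gaussian identity", {
  fs <- one_day("winter", seed = 32)
  tp <- attr(fs, "true_params")
  pr <- metab_priors()
  s <- 0.2
  lp1 <- log_posterior(metab_params(tp$A, tp$R, tp$K_O2, s), fs, pr)
  lp2 <- log_posterior(metab_params(tp$A, tp$R, tp$K_O2, 2 * s), fs, pr)
  # likelihood part: -m log 2 + (3/8) SSR / s^2 with m residuals; prior
  # part: half-normal ratio.  Reconstruct SSR from the simulated path.
  sim <- simulate_do(fs, tp, DO_0 = fs$DO_obs[1L])
  ssr <- sum((fs$DO_obs[-1L] - sim$DO_mod[-1L])^2)
  m <- nrow(fs) - 1L
  lik_diff <- -m * log(2) + 3 / 8 * ssr / s^2
  prior_diff <- dnorm(2 * s, 0, pr$sigma_scale, log = TRUE) -
    dnorm(s, 0, pr$sigma_scale, log = TRUE)
  expect_equal(lp2 - lp1, lik_diff + prior_diff, tolerance = 1e-8)
})

test_that("identical seeds reproduce identical draws", {
  fs <- one_day("fall", seed = 33)
  f1 <- quick_fit(fs, seed = 7)
  f2 <- quick_fit(fs, seed = 7)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$rhat, f2$rhat)
  f3 <- quick_fit(fs, seed = 8)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a lightless day pins daily GPP at zero", {
  fs <- flat_forcing(n = 288, temp = 8)
  sim <- simulate_do(fs, metab_params(A = 0, R = 0.02, K_O2 = 9.8),
                     DO_0 = 10)
  set.seed(99)
  fs$DO_obs <- pmax(sim$DO_mod + rnorm(288, 0, 0.1), 0.5)
  fs$DO_obs[1L] <- sim$DO_mod[1L]
  fit <- quick_fit(fs, seed = 5)
  dl <- daily_draws(fit)
  expect_true(all(dl$GPP == 0))
  s <- summarize_daily(fit, ppp = 0.5)
  expect_lt(abs(s$ER - (-0.02 * 288)) / (0.02 * 288), 0.15)
})

test_that("daily summaries conserve their per-interval sums", {
  fs <- one_day("spring", seed = 34)
  fit <- quick_fit(fs, seed = 6)
  dl <- daily_draws(fit)
  s <- summarize_daily(fit, ppp = 0.5)
  # independent recomputation of the per-draw daily sums
  fd <- forcing_day(fs, 1)
  tbar <- mean(fd$temp)
  for (k in c(1L, nrow(dl) %/% 2L, nrow(dl))) {
    gpp_k <- sum(gpp_increment(fit$draws[k, "A"], fd$I))
    er_k <- -sum(er_increment(fit$draws[k, "R"], fd$temp, tbar))
    expect_equal(dl$GPP[k], gpp_k)
    expect_equal(dl$ER[k], er_k)
  }
  expect_identical(dl$NEP, dl$GPP + dl$ER)
  expect_equal(s$GPP, mean(dl$GPP))
  expect_equal(s$NEP, s$GPP + s$ER)
})

test_that("the ppp band drives the acceptance flag strictly", {
  fs <- one_day("summer", seed = 35)
  fit <- quick_fit(fs, seed = 9)
  expect_false(summarize_daily(fit, ppp = 0.95)$accepted)
  expect_false(summarize_daily(fit, ppp = 0.05)$accepted)
  expect_true(summarize_daily(fit, ppp = 0.9)$accepted)
  expect_true(summarize_daily(fit, ppp = 0.1)$accepted)
  expect_true(summarize_daily(fit, ppp = 0.5)$accepted)
})

test_that("the near-pivotal discrepancy yields roughly uniform p-values", {
  # posterior-predictive calibration sanity check at coarse tolerance
  ppps <- vapply(1:10, function(s) {
    fs <- one_day("summer", seed = 400 + s)
    posterior_predictive_pvalue(quick_fit(fs, seed = 500 + s),
                                "lag1_autocorr", seed = 600 + s)
  }, 0)
  D <- max(abs(sort(ppps) - (seq_along(ppps) - 0.5) / length(ppps)))
  expect_lt(D, 0.45)
  expect_gt(max(ppps) - min(ppps), 0.2)
})

test_that("vague and weakly informative priors agree on identified days", {
  fs <- one_day("summer", seed = 36)
  vague <- quick_fit(fs, seed = 10)
  tight <- quick_fit(fs, seed = 10,
                     priors = metab_priors(A_max = 0.01, R_max = 0.3,
                                           sigma_scale = 0.3,
                                           K_O2_mean = 10, K_O2_sd = 5))
  sv <- summarize_daily(vague, ppp = 0.5)
  st <- summarize_daily(tight, ppp = 0.5)
  expect_lt(abs(sv$GPP - st$GPP) / sv$GPP, 0.1)
  expect_lt(abs(sv$ER - st$ER) / abs(sv$ER), 0.1)
})

test_that("short or incomplete days are rejected", {
  fs <- flat_forcing(n = 40, DO_obs = rep(9, 40))
  expect_error(fit_day(fs), "48")
  fs2 <- one_day("summer", seed = 37)
  expect_error(fit_day(fs2, day = 2), "day_index")
})

test_that("multi-day fits assemble a coherent daily table", {
  fs <- generate_scenario(scenario_preset("summer", n_days = 2, seed = 38))
  fit <- suppressMessages(suppressWarnings(
    metab(fs, seed = 11, iter = 1500, burn = 700, quiet = TRUE)))
  expect_s3_class(fit, "metab_fit")
  expect_equal(nrow(fit$daily), 2L)
  expect_identical(fit$daily$NEP, fit$daily$GPP + fit$daily$ER)
  expect_true(all(fit$daily$GPP >= 0))
  expect_true(all(fit$daily$ER <= 0))
  cf <- coef(fit)
  expect_equal(dim(cf), c(2L, 4L))
  pr <- predict(fit)
  expect_equal(nrow(pr), nrow(fs))
  expect_lt(mean(abs(residuals(fit))), 0.2)
  sims <- simulate(fit, nsim = 2, seed = 12)
  expect_equal(ncol(sims), 4L)
  expect_false(anyNA(sims$sim_1))
  sm <- summary(fit)
  expect_equal(sum(sm$trophic_counts), 2L)
})
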