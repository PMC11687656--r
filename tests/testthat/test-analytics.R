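test_that("every month maps to exactly one meteorological season", {
  expect_equal(assign_season(3), "spring")
  expect_equal(assign_season(12), "winter")
  all_seasons <- assign_season(1:12)
  expect_equal(unname(table(all_seasons)[c("spring", "summer", "fall",
                                           "winter")]),
               rep(3L, 4), ignore_attr = TRUE)
  expect_equal(all_seasons[c(6, 9)], c("summer", "fall"))
  expect_error(assign_season(13), "month")
  expect_error(assign_season(0), "month")
})

test_that("trophic classification puts the balanced boundary with autotrophy", {
  expect_equal(classify_trophic(4, -6), "heterotrophic")
  expect_equal(classify_trophic(6, -6), "autotrophic")
  expect_equal(classify_trophic(6, -4), "autotrophic")
  expect_equal(classify_trophic(c(1, 5), c(-2, -2)),
               c("heterotrophic", "autotrophic"))
  expect_error(classify_trophic(-1, -2), "GPP")
  expect_error(classify_trophic(1, 2), "ER")
})

test_that("the Arrhenius fit recovers the theta-generated activation energy", {
  # ER generated by the exponential temperature term with theta = 1.072:
  # the analytic slope mapping gives E_A = ln(theta) * k_B * T1 * T2
  temp <- seq(10, 30, length.out = 400)
  er <- er_increment(0.05, temp, mean(temp), theta = 1.072)
  fit <- arrhenius_fit(er, temp)
  EA_analytic <- log(1.072) * 8.617e-5 * 283.15 * 303.15  # 0.51425 eV
  expect_lt(abs(fit$E_A - EA_analytic) / EA_analytic, 0.01)
  expect_lt(fit$slope, 0)
  expect_gt(fit$r_squared, 0.999)
  expect_lt(fit$p_value, 1e-10)

  # theta = 1: no temperature dependence
  er_flat <- er_increment(0.05, temp, mean(temp), theta = 1)
  fit0 <- arrhenius_fit(er_flat + rep(c(0, 1e-12), 200), temp)
  expect_lt(abs(fit0$E_A), 1e-6)

  # brute-force round trip: implied theta from the fitted slope
  theta_hat <- exp(-fit$slope / (283.15 * 303.15))
  expect_lt(abs(theta_hat - 1.072) / 1.072, 0.01)
})

test_that("Arrhenius preconditions are enforced", {
  expect_error(arrhenius_fit(c(1, 2), c(10, 20)), "at least 3")
  expect_error(arrhenius_fit(c(1, 0, 2), c(10, 15, 20)), "> 0")
  expect_error(arrhenius_fit(c(1, 2, 3), c(10, 10, 10)), "constant")
})

test_that("per-day Arrhenius fits return one significant row per day", {
  fs <- generate_scenario(scenario_preset("fall", n_days = 3, seed = 13))
  tp <- attr(fs, "true_params")
  tbar <- ave(fs$temp, fs$day_index, FUN = mean)
  er <- er_increment(tp$R, fs$temp, tbar)
  out <- arrhenius_by_day(er, fs$temp, fs$day_index)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$slope < 0))
  expect_true(all(out$p_value < 0.05))
})

test_that("the GPP regression matches the normal-equations oracle", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 60
    temp <- runif(n, 5, 30)
    I <- runif(n, 0, 1500)
    gpp <- 0.001 * temp + 0.0005 * I + rnorm(n, 0, 0.05)
    fit <- gpp_regression(gpp, temp, I)
    X <- cbind(temp, I)
    beta <- solve(t(X) %*% X, t(X) %*% gpp)  # brute-force normal equations
    expect_equal(unname(fit$coefficients), unname(drop(beta)),
                 tolerance = 1e-10)
  }
  # noiseless: machine-precision recovery
  temp <- seq(5, 25, length.out = 50); I <- seq(0, 1000, length.out = 50)^1.3
  gpp <- 0.001 * temp + 0.0005 * I
  fit <- gpp_regression(gpp, temp, I)
  expect_equal(unname(fit$coefficients), c(0.001, 0.0005), tolerance = 1e-9)
  expect_gt(fit$multiple_r, 0.9999)
  # degenerate: zero response
  fit0 <- gpp_regression(rep(0, 10), 1:10, (1:10)^2)
  expect_equal(unname(fit0$coefficients), c(0, 0))
  # rank-deficient design
  expect_error(gpp_regression(1:5, 1:5, 2 * (1:5)), "rank")
  # optional intercept
  fit_i <- gpp_regression(gpp + 3, temp, I, include_intercept = TRUE)
  expect_equal(unname(fit_i$coefficients[1L]), 3, tolerance = 1e-6)
})

test_that("Spearman correlation matches an explicit average-rank oracle", {
  x <- c(1, 2, 2, 3, 5, 5, 5, 8)
  y <- c(2, 1, 4, 4, 6, 7, 7, 9)
  # brute-force: assign average ranks by hand, Pearson on the ranks
  avg_rank <- function(v) {
    sapply(v, function(vi) mean(which(sort(v) == vi)))
  }
  rho_oracle <- cor(avg_rank(x), avg_rank(y))
  s <- spearman_cor(x, y)
  expect_identical(s$rho, rho_oracle)
  # and against the stats implementation
  expect_equal(s$rho, unname(cor(x, y, method = "spearman")))

  expect_equal(spearman_cor(1:10, exp(1:10))$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_cor(1:10, exp(1:10))$p_value, 0)
  expect_error(spearman_cor(rep(1, 5), 1:5), "variance")

  # permutation p-value agrees in order of magnitude with the t version
  set.seed(11)
  x2 <- rnorm(30); y2 <- x2 + rnorm(30)
  pt_ <- spearman_cor(x2, y2)$p_value
  pp_ <- spearman_cor(x2, y2, method = "permutation", seed = 2)$p_value
  expect_lt(pp_, 0.01)
  expect_lt(pt_, 0.01)
})

test_that("diel amplitude is a translation-invariant daily range", {
  expect_equal(unname(diel_amplitude(rep(5, 10))), 0)
  expect_equal(unname(diel_amplitude(c(7, 9, 8))), 2)
  x <- runif(50)
  expect_equal(diel_amplitude(x + 100), diel_amplitude(x))
  amps <- diel_amplitude(c(1, 3, 10, 14), day_index = c(1, 1, 2, 2))
  expect_equal(unname(amps), c(2, 4))
})

test_that("the seasonal summary groups accepted days and counts trophy", {
  daily <- data.frame(
    date = seq(as.Date("2023-01-15"), by = "month", length.out = 12),
    GPP = c(4, 4, 8, 9, 10, 16, 18, 17, 9, 7, 6, 4),
    ER = -c(9, 9, 20, 24, 25, 17, 16, 17, 22, 22, 20, 10),
    K_O2 = rep(9.8, 12), accepted = rep(TRUE, 12))
  daily$NEP <- daily$GPP + daily$ER
  ss <- seasonal_summary(daily)
  expect_equal(nrow(ss), 4L)
  expect_equal(ss$season, c("spring", "summer", "fall", "winter"))
  expect_equal(sum(ss$n_days), 12L)
  expect_equal(sum(ss$n_autotrophic + ss$n_heterotrophic), 12L)
  expect_equal(ss$GPP_median[ss$season == "summer"], 17)
  # rejected days drop out
  daily$accepted[daily$GPP == 18] <- FALSE
  ss2 <- seasonal_summary(daily)
  expect_equal(sum(ss2$n_days), 11L)
  expect_warning(seasonal_summary(daily[FALSE, ]), "no accepted")
})
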