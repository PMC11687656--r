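# frozen independent values: published solubility-table concentrations
# (fresh water, 1 atm moist air) at 5, 20 and 25 degC
TABLE_DO_SAT <- c("5" = 12.770, "20" = 9.092, "25" = 8.263)

test_that("oxygen solubility matches the published table values", {
  for (tc in names(TABLE_DO_SAT))
    expect_lt(abs(o2_saturation(as.numeric(tc), 1, 0) - TABLE_DO_SAT[[tc]]),
              0.05)
})

test_that("solubility is monotone in temperature, salinity and pressure", {
  tt <- seq(0, 40, by = 0.5)
  expect_true(all(diff(o2_saturation(tt, 1, 0)) < 0))
  ss <- seq(0, 30, by = 0.5)
  expect_true(all(diff(o2_saturation(20, 1, ss)) < 0))
  pp <- seq(0.5, 1.5, by = 0.01)
  expect_true(all(diff(o2_saturation(20, pp, 0)) > 0))
  expect_error(o2_saturation(50), "range")
  expect_error(o2_saturation(-5), "range")
})

test_that("stream-level salinity differences are negligible", {
  a <- o2_saturation(c(5, 15, 25), 1, 0.12)
  b <- o2_saturation(c(5, 15, 25), 1, 0.25)
  expect_true(all(abs(a / b - 1) < 0.005))
})

test_that("process increments follow their closed forms", {
  expect_equal(gpp_increment(1e-3, 0), 0)
  expect_equal(gpp_increment(1e-3, 500), 0.5)
  expect_equal(gpp_increment(2e-3, 500), 2 * gpp_increment(1e-3, 500))
  expect_error(gpp_increment(-1, 10), "A")

  expect_equal(er_increment(0.05, 18, 18), 0.05)
  expect_equal(er_increment(0.05, 28, 18, theta = 1.072),
               0.05 * 2.0042313616543384)  # 1.072^10
  expect_equal(er_increment(0.05, 3, 29, theta = 1), 0.05)

  expect_equal(reaeration_increment(9.8, 1 / 288, 15, 15, 0), 0)
  expect_equal(reaeration_increment(9.8, 1 / 288, 15, 15, 1),
               0.03402777777777778)
  expect_lt(reaeration_increment(9.8, 1 / 288, 15, 15, -1), 0)
})

test_that("pure reaeration relaxes the deficit geometrically", {
  # closed form of the linear recurrence: D_n = D_0 (1 - K dt)^n
  fs <- flat_forcing(n = 144, temp = 15)  # 12 h of 5-minute steps
  K <- 9.8; dt <- 1 / 288
  sat <- o2_saturation(15, 1, 0)
  D0 <- 3
  sim <- simulate_do(fs, metab_params(A = 0, R = 0, K_O2 = K),
                     DO_0 = sat - D0)
  D <- sat - sim$DO_mod
  expected <- D0 * (1 - K * dt)^(0:143)
  expect_lt(max(abs(D - expected) / expected), 1e-12)
  # same from above saturation
  sim2 <- simulate_do(fs, metab_params(A = 0, R = 0, K_O2 = K),
                      DO_0 = sat + D0)
  expect_lt(max(abs((sim2$DO_mod - sat) / (D0 * (1 - K * dt)^(0:143)) - 1)),
            1e-12)
})

test_that("respiration alone gives an exactly linear decline", {
  fs <- flat_forcing(n = 100, temp = 15)
  sim <- simulate_do(fs, metab_params(A = 0, R = 0.01, K_O2 = 0), DO_0 = 9)
  expect_equal(sim$DO_mod, 9 - 0.01 * (0:99))
})

test_that("a parameter-free model leaves DO constant", {
  fs <- flat_forcing(n = 50)
  sim <- simulate_do(fs, metab_params(A = 0, R = 0, K_O2 = 0), DO_0 = 7.5)
  expect_equal(sim$DO_mod, rep(7.5, 50))
})

test_that("saturation is a fixed point with no metabolism", {
  fs <- flat_forcing(n = 100, temp = 12)
  sat <- o2_saturation(12, 1, 0)
  sim <- simulate_do(fs, metab_params(A = 0, R = 0, K_O2 = 9.8), DO_0 = sat)
  expect_equal(sim$DO_mod, rep(sat, 100))
})

test_that("every step conserves the three-component bookkeeping exactly", {
  fs <- one_day("summer", seed = 9)
  sim <- simulate_do(fs, attr(fs, "true_params"), DO_0 = fs$DO_obs[1L])
  n <- nrow(sim)
  lhs <- diff(sim$DO_mod)
  rhs <- (sim$gpp - sim$er + sim$reaeration)[-n]
  # exact up to the final rounding of the state update itself
  expect_lt(max(abs(lhs - rhs)), 1e-13)
  # night-time GPP identically zero
  expect_true(all(sim$gpp[sim$I == 0] == 0))
})

test_that("increasing A never decreases modeled DO", {
  fs <- one_day("spring", seed = 4)
  p0 <- attr(fs, "true_params")
  lo <- simulate_do(fs, p0, DO_0 = 8)
  hi <- simulate_do(fs, metab_params(A = p0$A * 1.5, R = p0$R,
                                     K_O2 = p0$K_O2), DO_0 = 8)
  expect_true(all(hi$DO_mod >= lo$DO_mod))
})

test_that("simulation flags a collapse to non-positive DO", {
  fs <- flat_forcing(n = 100)
  expect_error(simulate_do(fs, metab_params(A = 0, R = 0.2, K_O2 = 0),
                           DO_0 = 5), "inconsistent")
})
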