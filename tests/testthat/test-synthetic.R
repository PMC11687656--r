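test_that("the diel light curve is a half-sinusoid with dark nights", {
  expect_equal(diel_par(0, 14, 1400), 0)
  expect_equal(diel_par(12, 14, 1400), 1400)  # solar noon
  expect_equal(diel_par(4.9, 14, 1400), 0)    # just before sunrise at 5:00
  expect_equal(diel_par(19.1, 14, 1400), 0)   # just after sunset at 19:00
  # continuity at sunrise
  expect_lt(diel_par(5.001, 14, 1400), 1)
  # closed-form integral: peak * photoperiod * 2 / pi (in PAR-hours)
  h <- seq(0, 24, length.out = 200001); h <- h[-length(h)]
  quad <- sum(diel_par(h, 14, 1400)) * (24 / 200000)
  expect_equal(quad, 1400 * 14 * 2 / pi, tolerance = 1e-6)
})

test_that("the diel temperature curve has the stated mean, range and phase", {
  expect_equal(diel_temperature(c(0, 6, 18), 10, 0), rep(10, 3))
  h <- (0:287) / 288 * 24
  tt <- diel_temperature(h, 16, 3)
  expect_equal(mean(tt), 16, tolerance = 1e-12)
  expect_equal(h[which.max(tt)], 15)  # default afternoon peak
  expect_equal(max(tt) - min(tt), 6, tolerance = 1e-4)
})

test_that("scenario generation is deterministic under a seed", {
  a <- generate_scenario(scenario_preset("fall", n_days = 2, seed = 42))
  b <- generate_scenario(scenario_preset("fall", n_days = 2, seed = 42))
  expect_identical(a$DO_obs, b$DO_obs)
  expect_identical(a$I, b$I)
  expect_identical(scenario_truth(a), scenario_truth(b))
  c <- generate_scenario(scenario_preset("fall", n_days = 2, seed = 43))
  expect_false(identical(a$DO_obs, c$DO_obs))
})

test_that("seasonal presets hit the configured daily metabolic regimes", {
  # expectations of the day-to-day lognormal light factor: median 1
  targets <- list(summer = c(18, 17), winter = c(3.8, 9.2),
                  spring = c(10, 25), fall = c(6, 22))
  for (season in names(targets)) {
    tr <- do.call(rbind, lapply(1:12, function(s)
      scenario_truth(generate_scenario(
        scenario_preset(season, n_days = 1, seed = 800 + s)))))
    expect_equal(median(tr$GPP), targets[[season]][1], tolerance = 0.15)
    expect_equal(median(-tr$ER), targets[[season]][2], tolerance = 0.1)
    expect_true(all(tr$ER < 0))
    expect_equal(tr$K_O2, rep(9.8, 12))
  }
})

test_that("the truth record equals the per-interval sums exactly", {
  fs <- generate_scenario(scenario_preset("summer", n_days = 3, seed = 5))
  tr <- scenario_truth(fs)
  tp <- attr(fs, "true_params")
  gpp_daily <- tapply(gpp_increment(tp$A, fs$I, tp$p), fs$day_index, sum)
  expect_identical(as.numeric(gpp_daily), tr$GPP)
  expect_identical(tr$NEP, tr$GPP + tr$ER)
})

test_that("summer days swing more than winter days and DO stays plausible", {
  amp <- function(season, s) {
    fs <- generate_scenario(scenario_preset(season, n_days = 1, seed = s))
    diel_amplitude(fs$DO_obs, fs$day_index)
  }
  summer <- vapply(1:8, function(s) amp("summer", s), 0)
  winter <- vapply(1:8, function(s) amp("winter", s), 0)
  expect_gt(min(summer), max(winter))
  for (season in c("spring", "summer", "fall", "winter"))
    for (s in seq(1, 100, by = 4)) {
      fs <- generate_scenario(scenario_preset(season, n_days = 1, seed = s))
      expect_true(all(fs$DO_obs > 2 & fs$DO_obs < 15))
    }
})

test_that("scenarios that would drive DO negative fail loudly", {
  expect_error(generate_scenario(synthetic_scenario(
    er_daily = 120, K_O2 = 2, gpp_daily = 0, DO_0 = 3, seed = 1)),
    "adjust")
})
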