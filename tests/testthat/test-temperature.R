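test_that("critical laws are linear in T - Tc and undefined at or below Tc", {
  law <- critical_law(0.022, Tc = 14.4)
  expect_equal(rate_at(law, 27), 0.2772)
  expect_equal(rate_at(critical_law(0.188), 19.4), 0.94)
  expect_equal(rate_at(law, 14.4 + 1e-9), 0.022e-9, tolerance = 1e-6)
  expect_error(rate_at(law, 14.4), "critical")
  expect_error(rate_at(law, 10), "critical")
  expect_error(critical_law(-1), "positive")
})

test_that("segmentation period diverges at Tc and matches the printed law", {
  expect_equal(segmentation_period(27), 5.32 / 12.6)
  expect_equal(segmentation_period(27), 0.4222, tolerance = 1e-4)
  # reciprocal coefficient is the clock-frequency slope
  expect_equal(1 / 5.32, 0.188, tolerance = 1e-3)
  # "factor three" between 20 and 32 C
  expect_equal(segmentation_period(20) / segmentation_period(32), 17.6 / 5.6)
  expect_equal(segmentation_period(20) / segmentation_period(32), 3,
               tolerance = 0.1)
  # monotone divergence approaching Tc
  temps <- seq(15, 25, by = 0.5)
  expect_true(all(diff(segmentation_period(temps)) < 0))
  expect_error(segmentation_period(14.4), "critical")
  # rate * period = 1 when the slope is the reciprocal coefficient
  law <- critical_law(1 / 5.32)
  for (T in c(16, 22, 28, 34)) {
    expect_equal(rate_at(law, T) * segmentation_period(T), 1)
  }
})

test_that("fgf8 decay rate carries the ln2 factor between delta-Ct slope and 1/tau", {
  expect_equal(log(2) * 0.022, 0.0152, tolerance = 5e-3)
  expect_equal(fgf8_decay_rate(14.4 + 1), log(2) * 0.022)
  expect_equal(fgf8_decay_rate(27), log(2) * 0.022 * 12.6)
  expect_equal(1 / fgf8_decay_rate(27), 5.2, tolerance = 0.01)
  expect_error(fgf8_decay_rate(14), "critical")
})

test_that("time and stage conversions are exact inverses", {
  expect_equal(time_to_stage(4.5, 27), 4.5 / (5.32 / 12.6))
  expect_equal(time_to_stage(4.5, 27), 10.66, tolerance = 1e-3)
  expect_equal(stage_to_time(0, 27), 0)
  for (T in c(20, 27, 31)) {
    t <- runif(5, 0, 12)
    expect_lt(max(abs(t - stage_to_time(time_to_stage(t, T), T))), 1e-12)
  }
})

test_that("per-somite and per-hour slopes convert multiplicatively", {
  expect_equal(slope_convert(0.122, 0.188), 0.022936)
  expect_equal(slope_convert(0.122, 0.188), 0.022, tolerance = 0.05)
  expect_equal(slope_convert(1, 1), 1)
  expect_equal(0.022 / 0.188, 0.117, tolerance = 1e-2)
  expect_error(slope_convert(-0.1, 0.188), "positive")
  # consistency chain: converted slope feeds the decay-rate coefficient
  a <- slope_convert(0.122, 0.188)
  expect_equal(fgf8_decay_rate(27, a = a), log(2) * 0.122 * 0.188 * 12.6)
})

test_that("fit_critical_law inverts noise-free data exactly", {
  temps <- c(20, 26, 32)
  obs <- tibble::tibble(temperature_C = temps,
                        rate = c(0.1232, 0.2552, 0.3872), sd = 0.01)
  fit <- fit_critical_law(obs)
  expect_equal(fit$estimates$slope, 0.022, tolerance = 1e-10)
  expect_equal(fit$estimates$Tc, 14.4, tolerance = 1e-8)
  expect_equal(fit$estimates$chi2, 0, tolerance = 1e-16)
  expect_equal(fit$estimates$df, 1L)
  # two points: exact fit, df = 0, chi2 = 0
  fit2 <- fit_critical_law(obs[1:2, ])
  expect_equal(fit2$estimates$df, 0L)
  expect_equal(fit2$estimates$chi2, 0, tolerance = 1e-16)
  # errors
  expect_error(fit_critical_law(dplyr::mutate(obs, temperature_C = 25)),
               "singular")
  expect_error(fit_critical_law(dplyr::mutate(obs, rate = rev(rate))),
               "Tc undefined")
})

test_that("noise-free generator round trip recovers (a, Tc) to 1e-10 relative", {
  cfg <- synth_config(rate_frac_noise = 0,
                      rate_temperatures_C = seq(18, 32, by = 2))
  obs <- gen_rate_table(cfg, seed = 1)
  for (shared in c(FALSE, TRUE)) {
    fit <- fit_critical_law(obs, share_tc = shared)
    expect_equal(fit$estimates$Tc / 14.4, rep(1, 4), tolerance = 1e-8)
    expect_equal(fit$estimates$slope / cfg$rate_laws$slope[
      match(fit$estimates$observable, cfg$rate_laws$observable)],
      rep(1, 4), tolerance = 1e-10)
  }
})

test_that("shared-Tc fit is never better than the unconstrained fits", {
  cfg <- synth_config(rate_frac_noise = 0.08)
  for (s in 1:20) {
    obs <- gen_rate_table(cfg, seed = s)
    free <- fit_critical_law(obs, share_tc = FALSE)
    shared <- fit_critical_law(obs, share_tc = TRUE)
    expect_gte(shared$chi2_total, free$chi2_total - 1e-8)
    expect_equal(shared$df_total, nrow(obs) - 5L)
  }
})
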