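p0 <- morphogen_params(F0 = 1, lambda = 260, tau = 4.5)
r500 <- threshold_rule((1 / 260) * exp(-500 / 260))
clk <- clock_schedule(period = 0.4222, n_somites = 5)

test_that("boundary series is arithmetic with spacing tau_s * lambda / tau", {
  bs <- boundary_series(p0, r500, clk)
  expect_s3_class(bs, "boundary_series")
  expect_equal(bs$x_um[1], 500, tolerance = 1e-12)
  spacing <- 0.4222 * 260 / 4.5
  expect_equal(spacing, 24.4, tolerance = 0.01) # ~24 um per somite at 27 C
  expect_equal(unique(round(bs$l_um[-1], 10)), round(spacing, 10))
  expect_true(all(diff(bs$x_um) < 0))
  # frozen from the bisection oracle (closed form agrees)
  expect_equal(bs$x_um[6], 378.031, tolerance = 1e-4)
})

test_that("closed-form positions match the bisection oracle on random draws", {
  set.seed(7)
  for (i in 1:10) {
    sc <- random_scenario()
    bs <- boundary_series(sc$params, sc$rule, sc$clock)
    oracle <- oracle_boundary_bisection(sc$params, sc$rule, sc$clock)
    expect_equal(bs$x_um, oracle, tolerance = 1e-6)
  }
})

test_that("series truncates with a warning when x would go below zero", {
  long <- clock_schedule(period = 2, n_somites = 30)
  expect_warning(bs <- boundary_series(p0, r500, long), "truncated")
  expect_true(attr(bs, "truncated"))
  expect_true(all(bs$x_um >= 0))
  expect_lt(nrow(bs), 31)
})

test_that("general decay profile reduces to and generalises the exponential series", {
  # exponential profile reproduces boundary_series exactly
  f_exp <- function(t) 1 * exp(-t / 4.5)
  expect_equal(boundary_series_general(f_exp, p0, r500, clk)$x_um,
               boundary_series(p0, r500, clk)$x_um, tolerance = 1e-12)
  # constant source: the PSM does not shrink
  bs_const <- boundary_series_general(function(t) 1, p0, r500, clk)
  expect_equal(diff(bs_const$x_um), rep(0, 5))
  # algebraic decay: spacing lambda*ln((1+t2/tau)/(1+t1/tau)), decreasing in n
  f_alg <- function(t) 1 / (1 + t / 4.5)
  bs_alg <- boundary_series_general(f_alg, p0, r500, clk)
  t_n <- bs_alg$t_h
  expected_spacing <- 260 * log((1 + t_n[-1] / 4.5) / (1 + t_n[-6] / 4.5))
  expect_equal(bs_alg$l_um[-1], expected_spacing, tolerance = 1e-10)
  expect_true(all(diff(bs_alg$l_um[-1]) < 0))
  expect_error(boundary_series_general(function(t) -1, p0, r500, clk),
               "positive")
})

test_that("a spatially uniform exogenous source leaves every boundary unchanged", {
  clk20 <- clock_schedule(period = 0.4222, n_somites = 15)
  base <- boundary_series(p0, r500, clk20)
  pert <- apply_perturbation(p0, r500, clk20,
                             uniform_source(function(t) 0.11 * t + 1))
  expect_identical(base$x_um, pert$x_um)
})

test_that("a persistent threshold change alters exactly one somite size", {
  clk20 <- clock_schedule(period = 0.4222, n_somites = 20)
  r900 <- threshold_rule((1 / 260) * exp(-900 / 260)) # anchor at 900 um
  base <- boundary_series(p0, r900, clk20)
  pert <- apply_perturbation(p0, r900, clk20,
                             threshold_change(factor = 2, from_index = 10))
  # the first post-perturbation somite differs by lambda ln 2
  expect_equal(abs(pert$l_um[12] - base$l_um[12]), 260 * log(2),
               tolerance = 1e-10)
  expect_equal(260 * log(2), 180.2, tolerance = 1e-3)
  # every other size equals baseline spacing
  diffs <- which(abs(pert$l_um - base$l_um) > 1e-9)
  expect_identical(diffs, 12L) # row 12 holds l_11
  expect_equal(pert$l_um[13:21], base$l_um[13:21], tolerance = 1e-12)
  # unit factor is a no-op
  same <- apply_perturbation(p0, r900, clk20, threshold_change(1, 10))
  expect_equal(same$x_um, base$x_um)
  expect_error(threshold_change(0, 5), "positive")
})

test_that("single-somite perturbation property holds across random scenarios", {
  set.seed(11)
  for (i in 1:10) {
    sc <- random_scenario(n_somites = 8)
    k <- exp(runif(1, -0.3, 0.3))
    np <- sample(2:5, 1)
    base <- boundary_series(sc$params, sc$rule, sc$clock)
    pert <- apply_perturbation(sc$params, sc$rule, sc$clock,
                               threshold_change(k, np))
    changed <- which(abs(pert$l_um - base$l_um) > 1e-9)
    if (abs(k - 1) > 1e-6) expect_identical(changed, np + 2L)
  }
})
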