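make_records <- function(goi_ct, ref_ct, sample = "s1") {
  tibble::tibble(
    sample = sample,
    gene = rep(c("fgf8", "rpl13a"), c(length(goi_ct), length(ref_ct))),
    temperature_C = 27, stage = 10, time_h = NA_real_,
    replicate = c(seq_along(goi_ct), seq_along(ref_ct)),
    ct = c(goi_ct, ref_ct)
  )
}

test_that("delta-Ct is the difference of replicate-mean Cts", {
  rec <- make_records(c(20, 20, 20), c(16, 16, 16))
  pts <- delta_ct_table(rec, "fgf8", "rpl13a")
  expect_equal(pts$delta_ct, 4)
  expect_equal(pts$sd, 0)
  expect_equal(pts$n_replicates, 3L)
  # one fewer cycle on the gene of interest = doubled concentration
  rec2 <- make_records(c(19, 19, 19), c(16, 16, 16))
  expect_equal(delta_ct_table(rec2, "fgf8", "rpl13a")$delta_ct, 3)
  # single replicate gets the floor sd
  rec3 <- make_records(20, 16)
  expect_equal(delta_ct_table(rec3, "fgf8", "rpl13a")$sd, 0.2)
  expect_equal(delta_ct_table(rec3, "fgf8", "rpl13a", sd_floor = 0.5)$sd, 0.5)
})

test_that("samples missing a gene are dropped with a warning; no overlap errors", {
  rec <- dplyr::bind_rows(
    make_records(c(20, 21), c(16, 16), sample = "s1"),
    dplyr::filter(make_records(c(22, 22), c(17, 17), sample = "s2"),
                  gene == "fgf8"))
  expect_warning(pts <- delta_ct_table(rec, "fgf8", "rpl13a"), "dropped")
  expect_equal(nrow(pts), 1L)
  only_goi <- dplyr::filter(make_records(c(20, 20), c(16, 16)), gene == "fgf8")
  expect_error(delta_ct_table(only_goi, "fgf8", "rpl13a"), "not found")
})

test_that("noise-free generated tables recover the generating stage law exactly", {
  cfg <- synth_config(ct_noise_sd = 0, temperatures_C = 27)
  pts <- delta_ct_table(gen_ct_table(cfg, seed = 1), "fgf8", "rpl13a")
  expect_equal(pts$delta_ct, 0.122 * pts$stage + 3.955, tolerance = 1e-12)
  # Eq.-1 consistency: known concentration ratio is recovered exactly
  expect_equal(relative_concentration(pts$delta_ct),
               2^-(0.122 * pts$stage + 3.955), tolerance = 1e-12)
})

test_that("relative concentration is 2^(-delta Ct)", {
  expect_equal(relative_concentration(4), 0.0625)
  expect_equal(relative_concentration(0), 1)
  expect_equal(relative_concentration(3.955), 0.0645, tolerance = 1e-3)
})

test_that("weighted line fit solves the normal equations", {
  f1 <- fit_weighted_line(c(0, 1, 2), c(1, 2, 3), rep(1, 3))
  expect_equal(f1$slope, 1)
  expect_equal(f1$intercept, 1)
  expect_equal(f1$chi2, 0, tolerance = 1e-16)
  expect_equal(f1$df, 1L)
  f2 <- fit_weighted_line(c(0, 1, 2), c(1, 2, 4), rep(1, 3))
  expect_equal(f2$slope, 1.5)
  expect_equal(f2$intercept, 5 / 6)
  expect_equal(f2$chi2, 1 / 6, tolerance = 1e-10)
  expect_error(fit_weighted_line(c(1, 1, 1), c(1, 2, 3)), "singular")
  expect_error(fit_weighted_line(c(0, 1), c(1, 2), c(1, -1)), "positive")
})

test_that("rescaling all sds moves chi2 but not the estimates", {
  set.seed(3)
  x <- 1:8; y <- 0.5 * x + rnorm(8); sd <- runif(8, 0.5, 2)
  a <- fit_weighted_line(x, y, sd)
  b <- fit_weighted_line(x, y, 3 * sd)
  expect_equal(a$slope, b$slope)
  expect_equal(a$intercept, b$intercept)
  expect_equal(b$chi2, a$chi2 / 9)
})

test_that("closed-form fit agrees with a brute-force minimiser", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    x <- sort(runif(n, 0, 20))
    y <- runif(1, -2, 2) * x + runif(1, -5, 5) + rnorm(n)
    sd <- runif(n, 0.3, 3)
    fit <- fit_weighted_line(x, y, sd)
    brute <- oracle_wls(x, y, sd)
    expect_equal(fit$slope, brute$slope, tolerance = 1e-8)
    expect_equal(fit$intercept, brute$intercept, tolerance = 1e-8)
  }
})

test_that("stage fits recover generating slopes with calibrated uncertainty", {
  cfg <- synth_config(ct_noise_sd = 0, temperatures_C = 27,
                      genes = tibble::tibble(gene = "fgf8",
                                             slope_per_somite = 0.094,
                                             intercept_cycles = 3.955))
  pts <- delta_ct_table(gen_ct_table(cfg, seed = 5), "fgf8", "rpl13a")
  expect_equal(fit_dct_vs_stage(pts)$slope, 0.094, tolerance = 1e-12)
  # Monte-Carlo: slope bias small relative to se and 2-se coverage >= 90%
  cfg_mc <- synth_config(temperatures_C = 27, stages = 5:13,
                         genes = tibble::tibble(gene = "fgf8",
                                                slope_per_somite = 0.094,
                                                intercept_cycles = 3.955))
  fits <- purrr::map_dfr(1:300, function(s) {
    pts <- delta_ct_table(gen_ct_table(cfg_mc, seed = s), "fgf8", "rpl13a")
    f <- fit_dct_vs_stage(pts)
    tibble::tibble(slope = f$slope, se = f$slope_se)
  })
  expect_lt(abs(mean(fits$slope) - 0.094), 0.1 * mean(fits$se))
  expect_gte(mean(abs(fits$slope - 0.094) <= 2 * fits$se), 0.90)
})

test_that("a constant gene's slope is within 2 se of zero in most runs", {
  cfg <- synth_config(temperatures_C = 27, stages = 5:13,
                      genes = tibble::tibble(gene = "xpc",
                                             slope_per_somite = 0,
                                             intercept_cycles = 2))
  ok <- vapply(1:300, function(s) {
    pts <- delta_ct_table(gen_ct_table(cfg, seed = s), "xpc", "rpl13a")
    f <- fit_dct_vs_stage(pts)
    abs(f$slope) <= 2 * f$slope_se
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("genes are classified by the |slope|/se z-score", {
  f <- structure(list(slope = 0.094, slope_se = 0.013), class = "wls_fit")
  cls <- classify_gene(f, gene = "fgf8")
  expect_equal(cls$class, "time-varying")
  expect_equal(cls$z, 7.23, tolerance = 1e-2)
  f2 <- structure(list(slope = 0.01, slope_se = 0.02), class = "wls_fit")
  expect_equal(classify_gene(f2)$class, "constant")
  # decreasing delta-Ct (increasing transcript, myog-like) is time-varying too
  f3 <- structure(list(slope = -0.08, slope_se = 0.02), class = "wls_fit")
  expect_equal(classify_gene(f3)$class, "time-varying")
  f4 <- structure(list(slope = 0, slope_se = 0), class = "wls_fit")
  expect_equal(classify_gene(f4)$class, "constant")
})

test_that("decay-time conventions differ by ln 2 and must be named", {
  expect_error(decay_time_from_slope(0.094), "convention")
  expect_equal(decay_time_from_slope(0.094, "fig5"), 1 / 0.094)
  expect_equal(decay_time_from_slope(0.094, "fig5"), 10.6, tolerance = 1e-2)
  expect_equal(decay_time_from_slope(0.094, "eq1"), 1 / (log(2) * 0.094))
  expect_equal(decay_time_from_slope(0.094, "eq1"), 15.3, tolerance = 1e-2)
  expect_equal(decay_time_from_slope(1, "fig5"), 1)
  expect_error(decay_time_from_slope(-0.1, "fig5"), "positive")
})

test_that("reference stability ranks by Ct spread then co-variation", {
  samples <- sprintf("s%02d", 1:10)
  base <- rnorm(10) # shared biological variation
  set.seed(8)
  rec <- tibble::tibble(
    sample = rep(samples, 3),
    gene = rep(c("flat", "cov1", "cov2"), each = 10),
    temperature_C = 27, stage = rep(1:10, 3), time_h = NA_real_,
    replicate = 1L,
    ct = c(rep(15, 10), 16 + base, 18 + base)
  )
  tab <- reference_stability(rec, c("flat", "cov1", "cov2"))
  expect_equal(tab$gene[1], "flat")
  expect_equal(tab$sd_ct[1], 0)
  expect_equal(tab$mean_cor[tab$gene == "cov1"], 1, tolerance = 1e-12)
  # a drifting candidate ranks last among three
  set.seed(9)
  stages <- 1:12
  rec2 <- tibble::tibble(
    sample = rep(sprintf("d%02d", stages), 3),
    gene = rep(c("stable1", "stable2", "drifty"), each = 12),
    temperature_C = 27, stage = rep(stages, 3), time_h = NA_real_,
    replicate = 1L,
    ct = c(15 + rnorm(12, 0, 0.05), 16 + rnorm(12, 0, 0.05),
           17 + 0.1 * stages + rnorm(12, 0, 0.05))
  )
  tab2 <- reference_stability(rec2, c("stable1", "stable2", "drifty"))
  expect_equal(tab2$gene[3], "drifty")
})
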