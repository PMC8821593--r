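#' Chi-square-weighted straight-line fit
#'
#' Minimises sum(((y - slope*x - intercept)/sd)^2) in closed form via the
#' weighted normal equations; parameter errors come from the inverse normal
#' matrix. When `sd` is absent, unit weights are used, the reported chi2 is
#' the residual sum of squares (flagged via `weighted = FALSE`), and the
#' standard errors are scaled by sqrt(RSS/df) as in ordinary least squares.
#'
#' @param x predictor values (n >= 2, not all identical).
#' @param y response values.
#' @param sd per-point standard deviations (> 0), or NULL for unit weights.
#' @return A `wls_fit` object: slope, slope_se, intercept, intercept_se,
#'   cov_slope_intercept, chi2, df = n - 2, n, weighted.
#' @examples
#' fit_weighted_line(c(0, 1, 2), c(1, 2, 4), sd = c(1, 1, 1))
#' @export
fit_weighted_line <- function(x, y, sd = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("at least 2 points are required", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("singular design: all x values identical", call. = FALSE)
  }
  weighted <- !is.null(sd)
  if (weighted) {
    stopifnot(length(sd) == n)
    if (any(!is.finite(sd)) || any(sd <= 0)) {
      stop("all sd values must be finite and strictly positive", call. = FALSE)
    }
    w <- 1 / sd^2
  } else {
    w <- rep(1, n)
  }
  S <- sum(w); Sx <- sum(w * x); Sy <- sum(w * y)
  Sxx <- sum(w * x^2); Sxy <- sum(w * x * y)
  delta <- S * Sxx - Sx^2
  slope <- (S * Sxy - Sx * Sy) / delta
  intercept <- (Sxx * Sy - Sx * Sxy) / delta
  chi2 <- sum(w * (y - slope * x - intercept)^2)
  df <- n - 2L
  var_slope <- S / delta
  var_intercept <- Sxx / delta
  cov_si <- -Sx / delta
  if (!weighted) {
    scale2 <- if (df > 0) chi2 / df else 1
    var_slope <- var_slope * scale2
    var_intercept <- var_intercept * scale2
    cov_si <- cov_si * scale2
  }
  structure(list(slope = slope, slope_se = sqrt(var_slope),
                 intercept = intercept, intercept_se = sqrt(var_intercept),
                 cov_slope_intercept = cov_si, chi2 = chi2, df = df,
                 n = n, weighted = weighted),
            class = "wls_fit")
}

#' @export
print.wls_fit <- function(x, ...) {
  cat(sprintf("slope = %.6g +/- %.3g, intercept = %.6g +/- %.3g\n",
              x$slope, x$slope_se, x$intercept, x$intercept_se))
  cat(sprintf("chi2 = %.4g, df = %d%s\n", x$chi2, x$df,
              if (x$weighted) "" else " (unit weights: chi2 is a residual sum of squares)"))
  invisible(x)
}

#' Per-sample delta-Ct table from replicate Ct records
#'
#' delta-Ct = mean Ct of the gene of interest minus mean Ct of the reference
#' gene per sample, replicates averaged arithmetically first (each unit of
#' delta-Ct corresponds to a two-fold concentration ratio). The per-point sd
#' combines the standard errors of the two replicate means in quadrature;
#' samples where either gene has a single replicate get the floor sd.
#' Samples missing the reference gene are dropped with a warning.
#'
#' @param records tibble of Ct records with columns `sample`, `gene`,
#'   `temperature_C`, `stage`, `time_h`, `replicate`, `ct`.
#' @param goi gene of interest name.
#' @param reference reference gene name.
#' @param sd_floor minimum sd (cycles) used when a replicate sd cannot be
#'   estimated (default 0.2).
#' @return Tibble of delta-Ct points ordered by stage (then time):
#'   `sample`, `temperature_C`, `stage`, `time_h`, `delta_ct`, `sd`,
#'   `n_replicates`.
#' @export
delta_ct_table <- function(records, goi, reference, sd_floor = 0.2) {
  stopifnot(is.data.frame(records),
            all(c("sample", "gene", "ct") %in% names(records)))
  records <- tibble::as_tibble(records)
  for (col in c("temperature_C", "stage", "time_h")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  sub <- dplyr::filter(records, .data$gene %in% c(goi, reference))
  if (!any(sub$gene == goi)) stop("gene of interest '", goi, "' not found",
                                  call. = FALSE)
  per_gene <- sub |>
    dplyr::group_by(.data$sample, .data$gene) |>
    dplyr::summarise(
      temperature_C = .data$temperature_C[1],
      stage = .data$stage[1], time_h = .data$time_h[1],
      mean_ct = mean(.data$ct),
      sem2 = ifelse(dplyr::n() > 1,
                    stats::var(.data$ct) / dplyr::n(), NA_real_),
      n_rep = dplyr::n(), .groups = "drop"
    )
  wide <- per_gene |>
    tidyr::pivot_wider(id_cols = c("sample", "temperature_C", "stage", "time_h"),
                       names_from = "gene",
                       values_from = c("mean_ct", "sem2", "n_rep"))
  ref_col <- paste0("mean_ct_", reference)
  goi_col <- paste0("mean_ct_", goi)
  if (!ref_col %in% names(wide)) {
    stop("reference gene '", reference, "' not found in any sample",
         call. = FALSE)
  }
  dropped <- is.na(wide[[ref_col]]) | is.na(wide[[goi_col]])
  if (all(dropped)) {
    stop("no sample has both '", goi, "' and '", reference, "'", call. = FALSE)
  }
  if (any(dropped)) {
    warning(sum(dropped), " sample(s) dropped: missing '", goi, "' or '",
            reference, "'", call. = FALSE)
    wide <- wide[!dropped, ]
  }
  sem2_g <- wide[[paste0("sem2_", goi)]]
  sem2_r <- wide[[paste0("sem2_", reference)]]
  single <- is.na(sem2_g) | is.na(sem2_r)
  sd_out <- sqrt(dplyr::coalesce(sem2_g, 0) + dplyr::coalesce(sem2_r, 0))
  sd_out[single] <- pmax(sd_out[single], sd_floor)
  out <- tibble::tibble(
    sample = wide$sample,
    temperature_C = wide$temperature_C,
    stage = wide$stage,
    time_h = wide$time_h,
    delta_ct = wide[[goi_col]] - wide[[ref_col]],
    sd = sd_out,
    n_replicates = pmin(wide[[paste0("n_rep_", goi)]],
                        wide[[paste0("n_rep_", reference)]])
  )
  dplyr::arrange(out, .data$stage, .data$time_h)
}

#' Relative concentration from a delta-Ct value
#'
#' Assuming a doubling per PCR cycle, the concentration of the gene of
#' interest relative to the reference is 2^(-delta_ct).
#'
#' @param delta_ct delta-Ct in cycles; vectorised.
#' @return Dimensionless concentration ratio.
#' @examples
#' relative_concentration(4) # 1/16
#' @export
relative_concentration <- function(delta_ct) {
  2^(-delta_ct)
}

#' Fit delta-Ct against somite stage (or time)
#'
#' Weighted straight-line fit of the delta-Ct points on the chosen axis.
#' Point sds below `sd_floor` (e.g. exactly-zero replicate spread) are
#' raised to the floor so that weights stay finite.
#'
#' @param points delta-Ct tibble from [delta_ct_table()] (columns
#'   `delta_ct`, `sd`, and `stage` or `time_h`).
#' @param axis `"stage"` (default) or `"time"`.
#' @param sd_floor minimum sd in cycles (default 0.2).
#' @return A `wls_fit` object (see [fit_weighted_line()]).
#' @export
fit_dct_vs_stage <- function(points, axis = c("stage", "time"), sd_floor = 0.2) {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(points))
  x <- if (axis == "stage") points$stage else points$time_h
  if (sum(is.finite(x)) < 3 || length(unique(x[is.finite(x)])) < 2) {
    stop("need at least 3 points spanning at least 2 ", axis, " values",
         call. = FALSE)
  }
  sd <- pmax(points$sd, sd_floor)
  fit_weighted_line(x, points$delta_ct, sd)
}

#' Pooled multi-temperature collapse fit
#'
#' Converts each point's time axis to somite stage with the clock period at
#' its own temperature (s = t / tau_s(T)), pools all temperatures, and fits
#' one line delta-Ct = a' s + b. Under critical scaling the per-hour slopes
#' a (T - Tc) all collapse onto the common per-stage slope a' = a / a_s.
#'
#' @param points delta-Ct tibble with columns `temperature_C`, `time_h`,
#'   `delta_ct`, `sd`, spanning >= 2 temperatures.
#' @inheritParams segmentation_period
#' @param sd_floor minimum point sd in cycles.
#' @return A `wls_fit` with an extra `per_temperature` tibble attribute
#'   (chi2 of each temperature's points about the pooled line).
#' @export
pooled_collapse_fit <- function(points,
                                coeff = somite_constants()$period_coeff_h_C,
                                Tc = somite_constants()$Tc_C,
                                sd_floor = 0.2) {
  stopifnot(is.data.frame(points),
            all(c("temperature_C", "time_h", "delta_ct", "sd") %in% names(points)))
  temps <- unique(points$temperature_C)
  if (length(temps) < 2) stop("need points from at least 2 temperatures",
                              call. = FALSE)
  check_above_tc(temps, Tc)
  pts <- dplyr::mutate(tibble::as_tibble(points),
                       stage_scaled = time_to_stage(.data$time_h,
                                                    .data$temperature_C,
                                                    coeff, Tc),
                       sd_eff = pmax(.data$sd, sd_floor))
  fit <- fit_weighted_line(pts$stage_scaled, pts$delta_ct, pts$sd_eff)
  per_t <- pts |>
    dplyr::mutate(resid = (.data$delta_ct - fit$slope * .data$stage_scaled -
                             fit$intercept) / .data$sd_eff) |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::summarise(chi2 = sum(.data$resid^2), n = dplyr::n(),
                     .groups = "drop")
  attr(fit, "per_temperature") <- per_t
  fit
}

#' F-test for collapse of multi-temperature series onto one curve
#'
#' Compares a single pooled line on the rescaled stage axis against separate
#' per-temperature lines via a nested-model F ratio
#' F = ((X_pooled - X_sep) / (df_pooled - df_sep)) / (X_sep / df_sep).
#' By default X is the unweighted residual sum of squares, under which F is
#' exactly F-distributed for homoscedastic Gaussian noise; `use_sd = TRUE`
#' uses the per-point-sd-weighted chi-squares instead (appropriate when the
#' sds are known rather than estimated from a few replicates). A small F
#' (large p) means the temperatures collapse onto one curve.
#'
#' @inheritParams pooled_collapse_fit
#' @param use_sd weight residuals by the per-point sds?
#' @return A `collapse_test` object: statistic, df1, df2, p_value, the
#'   pooled `wls_fit`, and a per-temperature fit table.
#' @export
collapse_test <- function(points,
                          coeff = somite_constants()$period_coeff_h_C,
                          Tc = somite_constants()$Tc_C,
                          use_sd = FALSE, sd_floor = 0.2) {
  stopifnot(is.data.frame(points))
  temps <- unique(points$temperature_C)
  if (length(temps) < 2) stop("need at least 2 temperatures", call. = FALSE)
  counts <- table(points$temperature_C)
  if (any(counts < 3)) stop("each temperature needs at least 3 points",
                            call. = FALSE)
  pts <- dplyr::mutate(tibble::as_tibble(points),
                       stage_scaled = time_to_stage(.data$time_h,
                                                    .data$temperature_C,
                                                    coeff, Tc))
  sd_arg <- function(d) if (use_sd) pmax(d$sd, sd_floor) else NULL
  pooled <- fit_weighted_line(pts$stage_scaled, pts$delta_ct, sd_arg(pts))
  sep <- pts |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::group_map(function(d, key) {
      f <- fit_weighted_line(d$stage_scaled, d$delta_ct, sd_arg(d))
      tibble::tibble(temperature_C = key$temperature_C, slope = f$slope,
                     slope_se = f$slope_se, chi2 = f$chi2, df = f$df)
    }) |>
    dplyr::bind_rows()
  n <- nrow(pts); k <- length(temps)
  df1 <- 2L * k - 2L
  df2 <- n - 2L * k
  if (df2 <= 0) stop("too few points for per-temperature fits", call. = FALSE)
  chi2_sep <- sum(sep$chi2)
  f_stat <- ((pooled$chi2 - chi2_sep) / df1) / (chi2_sep / df2)
  structure(list(statistic = f_stat, df1 = df1, df2 = df2,
                 p_value = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
                 pooled = pooled, per_temperature = sep, use_sd = use_sd),
            class = "collapse_test")
}

#' @export
print.collapse_test <- function(x, ...) {
  cat(sprintf("collapse F = %.4g on (%d, %d) df, p = %.4g\n",
              x$statistic, x$df1, x$df2, x$p_value))
  invisible(x)
}

#' Classify a gene as time-varying or constant
#'
#' A transcript is called time-varying when its fitted delta-Ct slope is at
#' least `z_threshold` standard errors away from zero (two-sided); genes
#' like fgf8 and myog vary during somitogenesis while others (fgf4, xpc)
#' stay constant between the 5- and 21-somite stages.
#'
#' @param fit a `wls_fit` from [fit_dct_vs_stage()].
#' @param gene gene name for the output record.
#' @param z_threshold |slope|/se cut-off (default 2).
#' @return One-row tibble: `gene`, `class` (`"time-varying"` or
#'   `"constant"`), `z`.
#' @export
classify_gene <- function(fit, gene = NA_character_, z_threshold = 2) {
  stopifnot(inherits(fit, "wls_fit"))
  z <- if (fit$slope_se > 0) abs(fit$slope) / fit$slope_se
       else if (fit$slope == 0) 0 else Inf
  tibble::tibble(gene = gene,
                 class = ifelse(z >= z_threshold, "time-varying", "constant"),
                 z = z)
}

#' Decay time constant from a delta-Ct slope
#'
#' Two conventions are in circulation and differ by a factor ln(2): reading
#' the slope as that of -ln(concentration) gives tau = 1/slope, while
#' reading it as a delta-Ct (log2) slope gives 1/tau = ln(2) * slope. The
#' convention must be named explicitly; there is no default.
#'
#' @param slope fitted positive slope (per somite or per hour; the returned
#'   time constant is in the reciprocal axis unit).
#' @param convention `"fig5"` for 1/slope (natural-log reading) or `"eq1"`
#'   for 1/(ln(2) * slope) (log2 delta-Ct reading).
#' @return Decay time constant in the axis units of the slope.
#' @examples
#' decay_time_from_slope(0.094, "fig5") # about 11 somitic periods
#' @export
decay_time_from_slope <- function(slope, convention) {
  if (missing(convention)) {
    stop("`convention` must be given explicitly: \"fig5\" (tau = 1/slope) ",
         "or \"eq1\" (tau = 1/(ln2 * slope))", call. = FALSE)
  }
  convention <- match.arg(convention, c("fig5", "eq1"))
  if (any(slope <= 0)) stop("slope must be strictly positive", call. = FALSE)
  switch(convention, fig5 = 1 / slope, eq1 = 1 / (log(2) * slope))
}

#' Reference-gene stability ranking
#'
#' Simplified BestKeeper-style score: for each candidate, the standard
#' deviation of its per-sample mean Ct across samples (primary criterion,
#' ascending) and its mean pairwise Pearson correlation with the other
#' candidates (secondary, descending). A stable reference gene has low Ct
#' spread; high co-variation with other references indicates shared
#' technical rather than biological variation. This is not the full
#' BestKeeper geometric-mean index.
#'
#' @param records Ct records tibble (see [delta_ct_table()]).
#' @param candidates character vector of >= 2 candidate gene names.
#' @return Tibble ranked best-first: `gene`, `sd_ct`, `mean_cor`, `n_samples`.
#' @export
reference_stability <- function(records, candidates) {
  stopifnot(is.data.frame(records), length(candidates) >= 2)
  per <- records |>
    dplyr::filter(.data$gene %in% candidates) |>
    dplyr::group_by(.data$sample, .data$gene) |>
    dplyr::summarise(mean_ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "mean_ct")
  n_samp <- nrow(per)
  present <- intersect(candidates, names(per))
  keep <- present[vapply(present, function(g) {
    ok <- mean(!is.na(per[[g]])) > 0.5
    if (!ok) warning("candidate '", g, "' missing in >50% of samples: excluded",
                     call. = FALSE)
    ok
  }, logical(1))]
  if (length(keep) < 2) stop("fewer than 2 usable candidates", call. = FALSE)
  if (n_samp < 3) stop("at least 3 samples are required", call. = FALSE)
  mat <- as.matrix(per[keep])
  # a zero-variance candidate has undefined correlations; drop those pairs
  cors <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
  out <- tibble::tibble(
    gene = keep,
    sd_ct = unname(apply(mat, 2, stats::sd, na.rm = TRUE)),
    mean_cor = vapply(seq_along(keep),
                      function(i) mean(cors[i, -i], na.rm = TRUE), numeric(1)),
    n_samples = unname(colSums(!is.na(mat)))
  )
  dplyr::arrange(out, .data$sd_ct, dplyr::desc(.data$mean_cor))
}
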