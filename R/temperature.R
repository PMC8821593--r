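#' Critical-slowing-down rate law
#'
#' Near the critical temperature Tc every measured developmental rate is
#' proportional to (T - Tc): rates vanish at Tc and all characteristic
#' times diverge as 1/(T - Tc).
#'
#' @param slope rate units per degree C (> 0).
#' @param Tc critical temperature, degrees C.
#' @param label observable name (for reports and plots).
#' @return An object of class `critical_law`.
#' @examples
#' law <- critical_law(0.188, label = "clock frequency")
#' rate_at(law, 27)
#' @export
critical_law <- function(slope, Tc = somite_constants()$Tc_C, label = "rate") {
  stopifnot(is.numeric(slope), is.numeric(Tc))
  if (slope <= 0) stop("slope must be strictly positive", call. = FALSE)
  structure(list(slope = slope, Tc = Tc, label = label),
            class = "critical_law")
}

check_above_tc <- function(temp, Tc) {
  if (any(temp <= Tc)) {
    stop("temperature at or below critical temperature Tc = ", Tc,
         " degrees C: rate is not defined", call. = FALSE)
  }
  invisible(temp)
}

#' Evaluate a critical law at a temperature
#'
#' @param law a [critical_law()] object.
#' @param temp temperature, degrees C; must exceed `law$Tc`. Vectorised.
#' @return slope * (temp - Tc), in the law's rate units.
#' @export
rate_at <- function(law, temp) {
  stopifnot(inherits(law, "critical_law"))
  check_above_tc(temp, law$Tc)
  law$slope * (temp - law$Tc)
}

#' Segmentation period at a temperature
#'
#' tau_s = coeff / (T - Tc) hours: the clock period diverges as T
#' approaches Tc from above. Its reciprocal is the clock frequency
#' f_s = a_s (T - Tc) with a_s = 1/coeff.
#'
#' @param temp temperature, degrees C (> Tc); vectorised.
#' @param coeff period coefficient, hour-degree C.
#' @param Tc critical temperature, degrees C.
#' @return Period in hours.
#' @examples
#' segmentation_period(27) # about 25 minutes
#' @export
segmentation_period <- function(temp,
                                coeff = somite_constants()$period_coeff_h_C,
                                Tc = somite_constants()$Tc_C) {
  stopifnot(coeff > 0)
  check_above_tc(temp, Tc)
  coeff / (temp - Tc)
}

#' Fgf8 mRNA decay rate at a temperature
#'
#' The measured per-hour delta-Ct slope scales as alpha = a (T - Tc); the
#' concentration decay rate on the natural-log scale is 1/tau = ln(2) * alpha,
#' i.e. ln(2) * a * (T - Tc) per hour.
#'
#' @param temp temperature, degrees C (> Tc); vectorised.
#' @param a delta-Ct temperature slope, cycles h^-1 per degree C.
#' @param Tc critical temperature, degrees C.
#' @return Decay rate 1/tau in h^-1.
#' @export
fgf8_decay_rate <- function(temp,
                            a = somite_constants()$a_dct_per_h_C,
                            Tc = somite_constants()$Tc_C) {
  stopifnot(a > 0)
  check_above_tc(temp, Tc)
  log(2) * a * (temp - Tc)
}

#' Convert between developmental time and somite stage
#'
#' Somite stage counts elapsed segmentation periods: s = t / tau_s(T).
#' The two functions are exact inverses at any temperature above Tc.
#'
#' @param t time in hours (for `time_to_stage`).
#' @param s somite stage, possibly non-integer (for `stage_to_time`).
#' @inheritParams segmentation_period
#' @return Stage (somite count) or time (hours), respectively.
#' @export
time_to_stage <- function(t, temp,
                          coeff = somite_constants()$period_coeff_h_C,
                          Tc = somite_constants()$Tc_C) {
  t / segmentation_period(temp, coeff, Tc)
}

#' @rdname time_to_stage
#' @export
stage_to_time <- function(s, temp,
                          coeff = somite_constants()$period_coeff_h_C,
                          Tc = somite_constants()$Tc_C) {
  s * segmentation_period(temp, coeff, Tc)
}

#' Convert a per-somite slope to a per-hour-per-degree slope
#'
#' A delta-Ct slope of a' cycles per somite, combined with a clock
#' frequency slope of a_s somites per hour per degree, gives a per-hour
#' delta-Ct temperature slope a = a' * a_s.
#'
#' @param a_prime slope per somite (> 0).
#' @param a_s clock-frequency slope, somites h^-1 per degree C (> 0).
#' @return a = a_prime * a_s, cycles h^-1 per degree C.
#' @examples
#' slope_convert(0.122, 0.188)
#' @export
slope_convert <- function(a_prime, a_s) {
  if (any(a_prime <= 0) || any(a_s <= 0)) {
    stop("both slopes must be strictly positive", call. = FALSE)
  }
  a_prime * a_s
}

# single-observable weighted fit of rate on T, Tc = -intercept/slope with
# delta-method error propagation
fit_one_law <- function(temperature, rate, sd) {
  fit <- fit_weighted_line(temperature, rate, sd)
  a <- fit$slope
  b <- fit$intercept
  if (a <= 0) {
    stop("fitted slope is not positive: Tc undefined for this observable",
         call. = FALSE)
  }
  Tc <- -b / a
  # Tc = -b/a: dTc/da = b/a^2, dTc/db = -1/a
  va <- fit$slope_se^2
  vb <- fit$intercept_se^2
  cab <- fit$cov_slope_intercept
  vTc <- (b / a^2)^2 * va + vb / a^2 - 2 * (b / a^3) * cab
  list(slope = a, slope_se = fit$slope_se, Tc = Tc,
       Tc_se = sqrt(max(vTc, 0)), chi2 = fit$chi2, df = fit$df,
       weighted = fit$weighted)
}

# profile chi2 over a shared Tc: for fixed Tc the best slope per observable
# is the weighted regression through the origin of rate on (T - Tc)
shared_tc_chi2 <- function(Tc, groups) {
  sum(vapply(groups, function(g) {
    w <- 1 / g$sd^2
    d <- g$temperature_C - Tc
    s_hat <- sum(w * g$rate * d) / sum(w * d^2)
    sum(w * (g$rate - s_hat * d)^2)
  }, numeric(1)))
}

#' Fit critical-scaling laws to rate-versus-temperature data
#'
#' Weighted least-squares line fits of rate on temperature; the critical
#' temperature is the x-intercept, Tc = -intercept/slope, with its error
#' propagated by the delta method. With `share_tc = TRUE` a single Tc is
#' profiled over all observables (per-observable slopes re-solved in closed
#' form at each candidate Tc), minimising the total chi-square; its error
#' comes from the curvature of the profile chi-square at the optimum.
#'
#' @param obs tibble of rate observations with columns `temperature_C`,
#'   `rate`, optional `sd` (> 0) and optional `observable` (defaults to a
#'   single group). Each observable needs >= 3 points over >= 2 distinct
#'   temperatures.
#' @param share_tc fit one common Tc across observables?
#' @return A `scaling_fit` object: list with tibble `estimates`
#'   (observable, slope, slope_se, Tc, Tc_se, chi2, df), and fields
#'   `share_tc`, `chi2_total`, `df_total`, `weighted`.
#' @examples
#' obs <- tibble::tibble(temperature_C = c(20, 26, 32),
#'                       rate = 0.022 * (c(20, 26, 32) - 14.4),
#'                       sd = 0.01)
#' fit_critical_law(obs)
#' @export
fit_critical_law <- function(obs, share_tc = FALSE) {
  stopifnot(is.data.frame(obs),
            all(c("temperature_C", "rate") %in% names(obs)))
  obs <- tibble::as_tibble(obs)
  if (!"observable" %in% names(obs)) obs$observable <- "rate"
  weighted <- "sd" %in% names(obs) && !all(is.na(obs$sd))
  if (weighted && any(obs$sd <= 0)) {
    stop("all sd values must be strictly positive", call. = FALSE)
  }
  if (!weighted) obs$sd <- 1
  groups <- split(obs, obs$observable)
  for (g in groups) {
    if (nrow(g) < 2) stop("each observable needs at least 2 observations",
                          call. = FALSE)
    if (length(unique(g$temperature_C)) < 2) {
      stop("singular design: all temperatures identical", call. = FALSE)
    }
  }
  if (!share_tc) {
    est <- purrr::map2_dfr(groups, names(groups), function(g, nm) {
      f <- fit_one_law(g$temperature_C, g$rate, if (weighted) g$sd else NULL)
      tibble::tibble(observable = nm, slope = f$slope, slope_se = f$slope_se,
                     Tc = f$Tc, Tc_se = f$Tc_se, chi2 = f$chi2, df = f$df)
    })
    out <- list(estimates = est, share_tc = FALSE,
                chi2_total = sum(est$chi2), df_total = sum(est$df),
                weighted = weighted)
  } else {
    t_min <- min(obs$temperature_C)
    opt <- stats::optimize(shared_tc_chi2, groups = groups,
                           interval = c(t_min - 100, t_min - 1e-9),
                           tol = 1e-10)
    Tc <- opt$minimum
    # golden-section stops at sqrt(eps) scale; polish with parabolic steps
    for (i in 1:3) {
      h <- 1e-5
      c0 <- shared_tc_chi2(Tc, groups)
      cp <- shared_tc_chi2(Tc + h, groups)
      cm <- shared_tc_chi2(Tc - h, groups)
      curv <- cp - 2 * c0 + cm
      if (!is.finite(curv) || curv <= 0) break
      step <- -h * (cp - cm) / (2 * curv)
      if (!is.finite(step) || abs(step) < 1e-13) break
      Tc <- Tc + step
    }
    chi2 <- shared_tc_chi2(Tc, groups)
    # curvature of the profile chi2: Delta chi2 = 1 marks one standard error
    h <- 1e-3
    d2 <- (shared_tc_chi2(Tc + h, groups) - 2 * chi2 +
             shared_tc_chi2(Tc - h, groups)) / h^2
    Tc_se <- if (d2 > 0) sqrt(2 / d2) else NA_real_
    est <- purrr::map2_dfr(groups, names(groups), function(g, nm) {
      w <- 1 / g$sd^2
      d <- g$temperature_C - Tc
      s_hat <- sum(w * g$rate * d) / sum(w * d^2)
      tibble::tibble(observable = nm, slope = s_hat,
                     slope_se = 1 / sqrt(sum(w * d^2)),
                     Tc = Tc, Tc_se = Tc_se,
                     chi2 = sum(w * (g$rate - s_hat * d)^2),
                     df = NA_integer_)
    })
    out <- list(estimates = est, share_tc = TRUE, chi2_total = chi2,
                df_total = nrow(obs) - (length(groups) + 1L),
                weighted = weighted)
  }
  class(out) <- "scaling_fit"
  out
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(if (x$share_tc) "Shared-Tc critical-scaling fit\n"
      else "Critical-scaling fit(s)\n")
  print(x$estimates)
  cat(sprintf("total chi2 = %.4g, df = %d%s\n", x$chi2_total, x$df_total,
              if (x$weighted) "" else " (unit weights: chi2 is a residual sum of squares)"))
  invisible(x)
}
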