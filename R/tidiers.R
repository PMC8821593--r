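#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for weighted line fits
#'
#' @param x a `wls_fit` object.
#' @param ... unused.
#' @return `tidy`: one row per term (slope, intercept) with `estimate`,
#'   `std.error`, `statistic`. `glance`: one row with `chi2`, `df`,
#'   `p.value` (upper-tail chi-square probability; NA for unit-weight fits,
#'   where chi2 is a residual sum of squares), `nobs`, `weighted`.
#' @export
tidy.wls_fit <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept"),
    estimate = c(x$slope, x$intercept),
    std.error = c(x$slope_se, x$intercept_se),
    statistic = c(x$slope / x$slope_se, x$intercept / x$intercept_se)
  )
}

#' @rdname tidy.wls_fit
#' @export
glance.wls_fit <- function(x, ...) {
  tibble::tibble(
    chi2 = x$chi2, df = x$df,
    p.value = if (x$weighted && x$df > 0)
      stats::pchisq(x$chi2, x$df, lower.tail = FALSE) else NA_real_,
    nobs = x$n, weighted = x$weighted
  )
}

#' Tidiers for critical-scaling fits
#'
#' @param x a `scaling_fit` object from [fit_critical_law()].
#' @param ... unused.
#' @return `tidy`: one row per observable and term with `estimate` and
#'   `std.error`. `glance`: one row with total `chi2`, `df`, `shared_tc`,
#'   `weighted`.
#' @export
tidy.scaling_fit <- function(x, ...) {
  x$estimates |>
    tidyr::pivot_longer(cols = c("slope", "Tc"), names_to = "term",
                        values_to = "estimate") |>
    dplyr::mutate(std.error = ifelse(.data$term == "slope",
                                     .data$slope_se, .data$Tc_se)) |>
    dplyr::select("observable", "term", "estimate", "std.error")
}

#' @rdname tidy.scaling_fit
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2_total, df = x$df_total,
                 shared_tc = x$share_tc, weighted = x$weighted)
}

#' Tidiers for the collapse F-test
#'
#' @param x a `collapse_test` object.
#' @param ... unused.
#' @return `tidy`: the per-temperature slope table. `glance`: one row with
#'   `statistic`, `df1`, `df2`, `p.value`.
#' @export
tidy.collapse_test <- function(x, ...) {
  x$per_temperature
}

#' @rdname tidy.collapse_test
#' @export
glance.collapse_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
                 p.value = x$p_value)
}
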