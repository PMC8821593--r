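#' Registry of published-fit constants for zebrafish somitogenesis
#'
#' Single place holding the fitted constants the package uses as defaults.
#' Every derived quantity (segmentation period, decay rates, boundary
#' spacings) is recomputed from these at call time; nothing downstream
#' hard-codes a derived number.
#'
#' @return Named list:
#' \describe{
#'   \item{Tc_C}{critical temperature, degrees C, below which all
#'     developmental rates extrapolate to zero.}
#'   \item{a_dct_per_h_C}{temperature slope of the per-hour delta-Ct(fgf8)
#'     rate: alpha = a (T - Tc), cycles h^-1 per degree C.}
#'   \item{a_s_somite_per_h_C}{temperature slope of the segmentation-clock
#'     frequency f_s = a_s (T - Tc), somites h^-1 per degree C.}
#'   \item{period_coeff_h_C}{segmentation-period law tau_s = coeff/(T - Tc),
#'     hour-degree C.}
#'   \item{a_prime_per_somite}{per-stage slope of delta-Ct(fgf8) after the
#'     multi-temperature collapse onto somite stage, cycles per somite.}
#'   \item{b_dct_cycles}{intercept of the collapsed delta-Ct line, cycles.}
#'   \item{a_fig5_per_somite}{per-stage slope of -ln<[fgf8 mRNA]> at 27
#'     degrees C (natural-log concentration scale).}
#'   \item{lambda_um}{spatial decay length of the Fgf8 mRNA field, micron.}
#'   \item{tau_h}{temporal decay constant of the field at 27 degrees C, h.}
#'   \item{v_psm_um_per_h}{PSM shrinkage rate at 27 degrees C, micron/h.}
#'   \item{beta_tail_um_per_h_C}{temperature slope of the tail growth rate,
#'     micron h^-1 per degree C.}
#'   \item{beta_psm_um_per_h_C}{temperature slope of the PSM shrinkage rate
#'     (magnitude), micron h^-1 per degree C.}
#' }
#' @examples
#' k <- somite_constants()
#' k$period_coeff_h_C / (27 - k$Tc_C) # segmentation period at 27 C, hours
#' @export
somite_constants <- function() {
  list(
    Tc_C = 14.4,
    a_dct_per_h_C = 0.022,
    a_s_somite_per_h_C = 0.188,
    period_coeff_h_C = 5.32,
    a_prime_per_somite = 0.122,
    b_dct_cycles = 3.955,
    a_fig5_per_somite = 0.094,
    lambda_um = 260,
    tau_h = 4.5,
    v_psm_um_per_h = 58,
    beta_tail_um_per_h_C = 4.79,
    beta_psm_um_per_h_C = 5.08
  )
}

# shared seed guard: library mode refuses unseeded stochastic calls
check_seed <- function(seed) {
  if (is.null(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("a single finite `seed` is required for stochastic operations",
         call. = FALSE)
  }
  as.integer(seed)
}
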