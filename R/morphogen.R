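#' Fgf8 morphogen field parameters
#'
#' The mRNA field is produced at the tail end and decays on a length scale
#' `lambda` towards the anterior PSM while its source amplitude decays in
#' time with constant `tau`:
#' \deqn{u(x, t) = F_0 \exp(-x/\lambda - t/\tau)}
#' with `x` the distance to the tail end in micron (increasing anteriorly).
#'
#' @param F0 source amplitude at x = 0, t = 0 (concentration, arbitrary
#'   units; > 0).
#' @param lambda spatial decay length, micron (> 0).
#' @param tau temporal decay constant, hours (> 0).
#' @return An object of class `morphogen_params`.
#' @examples
#' morphogen_params(F0 = 1, lambda = 260, tau = 4.5)
#' @export
morphogen_params <- function(F0 = 1,
                             lambda = somite_constants()$lambda_um,
                             tau = somite_constants()$tau_h) {
  stopifnot(is.numeric(F0), is.numeric(lambda), is.numeric(tau))
  if (F0 <= 0 || lambda <= 0 || tau <= 0) {
    stop("F0, lambda and tau must all be strictly positive", call. = FALSE)
  }
  structure(list(F0 = F0, lambda = lambda, tau = tau),
            class = "morphogen_params")
}

#' Gradient threshold rule for boundary determination
#'
#' A somite boundary forms where the spatial gradient of the Fgf8 signal
#' falls to the threshold `eta_t`. If the protein signal is a monotone
#' transfer function G of the mRNA field, only the local slope G' at the
#' threshold concentration enters; it is carried here as a single scalar.
#'
#' @param eta_t gradient threshold, concentration per micron (> 0).
#' @param g_prime slope of the transfer function at threshold
#'   (dimensionless, >= 0; default 1 = identity transfer).
#' @return An object of class `threshold_rule`.
#' @export
threshold_rule <- function(eta_t, g_prime = 1) {
  stopifnot(is.numeric(eta_t), is.numeric(g_prime))
  if (eta_t <= 0) stop("eta_t must be strictly positive", call. = FALSE)
  if (g_prime < 0) stop("g_prime must be non-negative", call. = FALSE)
  structure(list(eta_t = eta_t, g_prime = g_prime), class = "threshold_rule")
}

#' Segmentation clock schedule
#'
#' The clock is abstracted to its period: boundary n forms at
#' t_n = t0 + n * period.
#'
#' @param period segmentation period tau_s, hours (> 0).
#' @param n_somites number of boundaries after n = 0 (positive integer).
#' @param t0 time of boundary n = 0, hours.
#' @return An object of class `clock_schedule`.
#' @export
clock_schedule <- function(period, n_somites, t0 = 0) {
  stopifnot(is.numeric(period), is.numeric(n_somites), is.numeric(t0))
  if (period <= 0) stop("period must be strictly positive", call. = FALSE)
  if (n_somites < 1 || n_somites != round(n_somites)) {
    stop("n_somites must be a positive integer", call. = FALSE)
  }
  structure(list(period = period, n_somites = as.integer(n_somites), t0 = t0),
            class = "clock_schedule")
}

#' Evaluate the morphogen field u(x, t)
#'
#' @param x distance from the tail end, micron (>= 0); vectorised.
#' @param t time, hours; vectorised (recycled against `x`).
#' @param params a [morphogen_params()] object.
#' @return Concentration F0 * exp(-x/lambda - t/tau), strictly positive.
#' @examples
#' p <- morphogen_params(1, 260, 4.5)
#' field_value(260, 0, p) # one decay length: exp(-1)
#' @export
field_value <- function(x, t, params) {
  stopifnot(inherits(params, "morphogen_params"))
  if (any(x < 0)) stop("x is a distance from the tail end and must be >= 0",
                       call. = FALSE)
  params$F0 * exp(-x / params$lambda - t / params$tau)
}

#' Spatially integrated mean concentration
#'
#' Integral of the field over the PSM. Over an unbounded domain this is
#' F0 * lambda * exp(-t/tau); over a finite PSM of length L it is
#' F0 * lambda * (1 - exp(-L/lambda)) * exp(-t/tau). Either way the temporal
#' decay is exp(-t/tau), which is what the qPCR delta-Ct measures.
#'
#' @param t time, hours; vectorised.
#' @param params a [morphogen_params()] object.
#' @param psm_length PSM length, micron (> 0), or `Inf` for the unbounded
#'   integral (default).
#' @return Concentration times micron.
#' @export
mean_concentration <- function(t, params, psm_length = Inf) {
  stopifnot(inherits(params, "morphogen_params"))
  if (psm_length <= 0) stop("psm_length must be strictly positive",
                            call. = FALSE)
  domain <- if (is.infinite(psm_length)) 1 else 1 - exp(-psm_length / params$lambda)
  params$F0 * params$lambda * domain * exp(-t / params$tau)
}

#' Magnitude of the spatial gradient of the field
#'
#' For the exponential field the spatial derivative is -u(x,t)/lambda, so
#' the magnitude is exactly `field_value(x, t, params) / lambda`. A
#' spatially uniform addition to the field leaves it unchanged.
#'
#' @inheritParams field_value
#' @return Concentration per micron (> 0).
#' @export
gradient_magnitude <- function(x, t, params) {
  field_value(x, t, params) / params$lambda
}

#' Anchor position of the determination wavefront
#'
#' Position x0 where the gradient threshold is met at t = 0:
#' \deqn{x_0 = \lambda \ln(G' F_0 / (\eta_t \lambda))}
#' A negative value means the threshold is never reached inside the domain;
#' it is returned as-is with a warning.
#'
#' @param params a [morphogen_params()] object.
#' @param rule a [threshold_rule()] object with `g_prime > 0`.
#' @return Anchor position in micron, possibly negative (with a warning).
#' @export
anchor_position <- function(params, rule) {
  stopifnot(inherits(params, "morphogen_params"),
            inherits(rule, "threshold_rule"))
  if (rule$g_prime <= 0) {
    stop("anchor position requires a strictly positive transfer slope g_prime",
         call. = FALSE)
  }
  x0 <- params$lambda * log(rule$g_prime * params$F0 / (rule$eta_t * params$lambda))
  if (x0 < 0) {
    warning("threshold is never reached inside the domain (anchor x0 < 0)",
            call. = FALSE)
  }
  x0
}

new_boundary_series <- function(n, t_h, x_um, truncated) {
  out <- tibble::tibble(
    n = as.integer(n), t_h = t_h, x_um = x_um,
    l_um = c(NA_real_, abs(diff(x_um)))
  )
  attr(out, "truncated") <- truncated
  class(out) <- c("boundary_series", class(out))
  out
}

truncate_below_zero <- function(n, t_h, x_um) {
  keep <- x_um >= 0
  truncated <- !all(keep)
  if (truncated) {
    first_bad <- which(!keep)[1]
    if (first_bad == 1L) stop("anchor below domain: no boundary has x >= 0",
                              call. = FALSE)
    idx <- seq_len(first_bad - 1L)
    warning("boundary series truncated where x_n would fall below 0",
            call. = FALSE)
    n <- n[idx]; t_h <- t_h[idx]; x_um <- x_um[idx]
  }
  new_boundary_series(n, t_h, x_um, truncated)
}

#' Somite boundary positions under the exponential field
#'
#' At each clock tick t_n = t0 + n tau_s the wavefront sits where the
#' thresholded gradient crosses eta_t, giving the arithmetic series
#' x_n = x0 - t_n * lambda/tau: the PSM shrinks at the constant velocity
#' lambda/tau set entirely by the Fgf8 dynamics, and every somite has
#' tail-frame size tau_s * lambda / tau.
#'
#' @inheritParams anchor_position
#' @param clock a [clock_schedule()] object.
#' @return A `boundary_series` tibble with columns `n`, `t_h` (formation
#'   time), `x_um` (distance from tail end) and `l_um` (tail-frame size
#'   |x_n - x_(n-1)|, NA for n = 0). Attribute `truncated` flags a series
#'   cut where x_n would go below 0.
#' @examples
#' p <- morphogen_params(1, 260, 4.5)
#' r <- threshold_rule(eta_t = (1 / 260) * exp(-500 / 260))
#' boundary_series(p, r, clock_schedule(0.4222, 5))
#' @export
boundary_series <- function(params, rule, clock) {
  stopifnot(inherits(clock, "clock_schedule"))
  x0 <- anchor_position(params, rule)
  n <- 0:clock$n_somites
  t_h <- clock$t0 + n * clock$period
  x_um <- x0 - t_h * params$lambda / params$tau
  truncate_below_zero(n, t_h, x_um)
}

#' Boundary positions under a general temporal decay profile
#'
#' Generalises [boundary_series()] to a field u = F(t) exp(-x/lambda) whose
#' source amplitude F(t) need not decay exponentially:
#' x_n = lambda * ln(G' F(t_n) / (eta_t lambda)). With
#' F(t) = F0 exp(-t/tau) this reduces exactly to the arithmetic series.
#'
#' @param decay_profile function of time (hours) returning the source
#'   amplitude; must be strictly positive at every boundary time.
#' @inheritParams boundary_series
#' @return A `boundary_series` tibble (see [boundary_series()]).
#' @export
boundary_series_general <- function(decay_profile, params, rule, clock) {
  stopifnot(is.function(decay_profile), inherits(clock, "clock_schedule"),
            inherits(params, "morphogen_params"),
            inherits(rule, "threshold_rule"))
  if (rule$g_prime <= 0) stop("g_prime must be strictly positive", call. = FALSE)
  n <- 0:clock$n_somites
  t_h <- clock$t0 + n * clock$period
  amp <- vapply(t_h, decay_profile, numeric(1))
  if (any(!is.finite(amp)) || any(amp <= 0)) {
    stop("decay_profile must be strictly positive and finite at all boundary times",
         call. = FALSE)
  }
  x_um <- params$lambda * log(rule$g_prime * amp / (rule$eta_t * params$lambda))
  truncate_below_zero(n, t_h, x_um)
}

#' Perturbations of the boundary-placing experiment
#'
#' `uniform_source(offset)` adds a spatially uniform, possibly
#' time-dependent, exogenous source c(t) to the field; because a uniform
#' addition has zero spatial gradient, boundary positions are unchanged.
#' `threshold_change(factor, from_index)` rescales the gradient threshold by
#' `factor` for all boundaries after index `from_index` (e.g. a drug applied
#' at somite stage n_p), shifting each later boundary by -lambda * ln(factor)
#' so that exactly one somite size differs from baseline.
#'
#' @param offset function of time (hours) giving the uniform added
#'   concentration.
#' @param factor multiplicative change of eta_t (> 0).
#' @param from_index somite index n_p at which the change takes effect;
#'   boundaries n > n_p use the new threshold.
#' @return A perturbation object for [apply_perturbation()].
#' @export
uniform_source <- function(offset) {
  stopifnot(is.function(offset))
  structure(list(offset = offset), class = "uniform_source")
}

#' @rdname uniform_source
#' @export
threshold_change <- function(factor, from_index) {
  stopifnot(is.numeric(factor), is.numeric(from_index))
  if (factor <= 0) stop("threshold factor must be strictly positive",
                        call. = FALSE)
  structure(list(factor = factor, from_index = as.integer(from_index)),
            class = "threshold_change")
}

#' Boundary series under a perturbation
#'
#' @inheritParams boundary_series
#' @param perturbation a [uniform_source()] or [threshold_change()] object.
#' @return A `boundary_series` tibble. For a uniform source it equals the
#'   baseline exactly; for a threshold change every x_n with n > from_index
#'   is shifted by -lambda * ln(factor), altering exactly one somite size.
#' @export
apply_perturbation <- function(params, rule, clock, perturbation) {
  base <- boundary_series(params, rule, clock)
  if (inherits(perturbation, "uniform_source")) {
    # d/dx [u(x,t) + c(t)] = du/dx: the gradient, hence every crossing,
    # is insensitive to a spatially uniform source
    return(base)
  }
  if (inherits(perturbation, "threshold_change")) {
    shift <- -params$lambda * log(perturbation$factor)
    x_um <- base$x_um + ifelse(base$n > perturbation$from_index, shift, 0)
    return(truncate_below_zero(base$n, base$t_h, x_um))
  }
  stop("unknown perturbation type", call. = FALSE)
}

#' Kinematic kymograph model
#'
#' In the lab frame the tail elongates at a constant rate while the PSM
#' shortens at a constant rate, so the determination front moves at their
#' sum. `v_psm_shrink` stores the shrinkage magnitude (>= 0); a fitted PSM
#' slope of -5.08 um/h/degree corresponds to `v_psm_shrink = 5.08 (T - Tc)`.
#'
#' @param v_tail tail elongation rate, micron/h (>= 0).
#' @param v_psm_shrink PSM shortening rate magnitude, micron/h (>= 0).
#' @param psm_length_0 PSM length at t = 0, micron (> 0).
#' @param period segmentation period, hours (> 0).
#' @return An object of class `kymograph_model`.
#' @export
kymograph_model <- function(v_tail, v_psm_shrink, psm_length_0,
                            period = somite_constants()$period_coeff_h_C /
                              (27 - somite_constants()$Tc_C)) {
  stopifnot(is.numeric(v_tail), is.numeric(v_psm_shrink),
            is.numeric(psm_length_0), is.numeric(period))
  if (v_tail < 0 || v_psm_shrink < 0) {
    stop("rates must be non-negative magnitudes", call. = FALSE)
  }
  if (psm_length_0 <= 0 || period <= 0) {
    stop("psm_length_0 and period must be strictly positive", call. = FALSE)
  }
  structure(list(v_tail = v_tail, v_psm_shrink = v_psm_shrink,
                 psm_length_0 = psm_length_0, period = period),
            class = "kymograph_model")
}

#' Simulate a kymograph trace
#'
#' Noise-free kinematics: tail = v_tail * t, psm = L0 - v_psm_shrink * t,
#' front = tail - psm. Gaussian measurement noise of sd `noise_sd` is added
#' independently to the tail and PSM columns at every sample; the front is
#' recomputed from the noisy columns so front = tail - psm holds on every
#' row. The simulation truncates (with a warning and `truncated` attribute)
#' where the PSM length would go negative.
#'
#' @param model a [kymograph_model()] object.
#' @param duration simulated span, hours (> 0).
#' @param sampling sampling interval, hours (> 0).
#' @param noise_sd measurement noise sd, micron (>= 0).
#' @param seed integer seed; required whenever `noise_sd > 0`.
#' @return A `kymograph_trace` tibble with columns `t_h`, `tail_um`,
#'   `psm_um`, `front_um`.
#' @examples
#' m <- kymograph_model(60.4, 64.0, 500)
#' simulate_kymograph(m, duration = 2, sampling = 0.5)
#' @export
simulate_kymograph <- function(model, duration, sampling = 0.25,
                               noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "kymograph_model"))
  if (duration <= 0 || sampling <= 0) {
    stop("duration and sampling must be strictly positive", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  t_h <- seq(0, duration, by = sampling)
  psm <- model$psm_length_0 - model$v_psm_shrink * t_h
  truncated <- any(psm < 0)
  if (truncated) {
    warning("trace truncated where PSM length would go negative", call. = FALSE)
    keep <- psm >= 0
    t_h <- t_h[keep]; psm <- psm[keep]
  }
  tail_um <- model$v_tail * t_h
  if (noise_sd > 0) {
    withr::local_seed(check_seed(seed))
    tail_um <- tail_um + stats::rnorm(length(t_h), 0, noise_sd)
    psm <- psm + stats::rnorm(length(t_h), 0, noise_sd)
  }
  out <- tibble::tibble(t_h = t_h, tail_um = tail_um, psm_um = psm,
                        front_um = tail_um - psm)
  attr(out, "sampling_h") <- sampling
  attr(out, "noise_sd_um") <- noise_sd
  attr(out, "truncated") <- truncated
  class(out) <- c("kymograph_trace", class(out))
  out
}

#' Estimate kinematic rates from a kymograph trace
#'
#' Straight-line fits of the tail and PSM columns against time (see
#' [fit_weighted_line()]; unit weights with residual-scaled standard
#' errors). The wavefront velocity is reported as the magnitude sum
#' v_tail + v_psm_shrink with its error combined in quadrature.
#'
#' @param trace a `kymograph_trace` tibble (>= 3 samples).
#' @return A tibble with columns `quantity` (`v_tail`, `v_psm_shrink`,
#'   `v_front`), `estimate` (micron/h) and `se`.
#' @export
estimate_velocities <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("t_h", "tail_um", "psm_um") %in% names(trace)))
  if (nrow(trace) < 3) stop("at least 3 samples are required", call. = FALSE)
  f_tail <- fit_weighted_line(trace$t_h, trace$tail_um)
  f_psm <- fit_weighted_line(trace$t_h, trace$psm_um)
  v_tail <- f_tail$slope
  v_shrink <- -f_psm$slope
  tibble::tibble(
    quantity = c("v_tail", "v_psm_shrink", "v_front"),
    estimate = c(v_tail, v_shrink, v_tail + v_shrink),
    se = c(f_tail$slope_se, f_psm$slope_se,
           sqrt(f_tail$slope_se^2 + f_psm$slope_se^2))
  )
}
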