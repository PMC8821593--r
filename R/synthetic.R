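#' Configuration of the default synthetic study
#'
#' Bundles the parameters of the simulated experiment the generators
#' produce: replicate RT-qPCR Ct tables whose gene-wise mean delta-Ct is
#' linear in somite stage with temperature-scaled per-hour slope, kymograph
#' traces with rates beta * (T - Tc), and rate-versus-temperature tables.
#' Defaults mirror the published fits in [somite_constants()] and the study
#' design: incubator temperatures 23/26/27/29/31 degrees C, somite stages
#' 5 to 21, three PCR replicates, Gaussian Ct noise of 0.3 cycles.
#'
#' @param genes tibble of gene-of-interest specs: columns `gene`,
#'   `slope_per_somite` (0 for a constant gene) and `intercept_cycles`.
#' @param reference_gene reference gene name.
#' @param reference_ct reference gene baseline Ct, cycles.
#' @param temperatures_C incubation temperatures, degrees C.
#' @param stages somite stages sampled.
#' @param replicates PCR replicates per (sample, gene).
#' @param ct_noise_sd Gaussian Ct noise sd, cycles.
#' @param period_coeff,Tc segmentation-period law constants (see
#'   [segmentation_period()]).
#' @param beta_tail,beta_psm temperature slopes of the tail growth and PSM
#'   shrinkage rates, micron h^-1 per degree C.
#' @param psm_length_0 PSM length at the start of a kymograph, micron.
#' @param kymo_duration,kymo_sampling kymograph span and sampling interval, h.
#' @param kymo_noise_sd kymograph position noise sd, micron.
#' @param rate_laws tibble of rate observables: columns `observable`,
#'   `slope` (rate units per degree C).
#' @param rate_temperatures_C temperatures of the rate table, degrees C.
#' @param rate_frac_noise fractional Gaussian noise on generated rates.
#' @return A `synth_config` list.
#' @export
synth_config <- function(
    genes = tibble::tibble(
      gene = "fgf8",
      slope_per_somite = somite_constants()$a_prime_per_somite,
      intercept_cycles = somite_constants()$b_dct_cycles),
    reference_gene = "rpl13a",
    reference_ct = 16,
    temperatures_C = c(23, 26, 27, 29, 31),
    stages = 5:21,
    replicates = 3,
    ct_noise_sd = 0.3,
    period_coeff = somite_constants()$period_coeff_h_C,
    Tc = somite_constants()$Tc_C,
    beta_tail = somite_constants()$beta_tail_um_per_h_C,
    beta_psm = somite_constants()$beta_psm_um_per_h_C,
    psm_length_0 = 800,
    kymo_duration = 6,
    kymo_sampling = 0.25,
    kymo_noise_sd = 5,
    rate_laws = tibble::tibble(
      observable = c("fgf8_decay", "clock_frequency",
                     "tail_growth", "psm_shrinkage"),
      slope = c(somite_constants()$a_dct_per_h_C,
                somite_constants()$a_s_somite_per_h_C,
                somite_constants()$beta_tail_um_per_h_C,
                somite_constants()$beta_psm_um_per_h_C)),
    rate_temperatures_C = c(23, 26, 27, 29, 31),
    rate_frac_noise = 0.05) {
  stopifnot(is.data.frame(genes), nrow(genes) >= 1,
            all(c("gene", "slope_per_somite", "intercept_cycles") %in% names(genes)),
            ct_noise_sd >= 0, kymo_noise_sd >= 0, rate_frac_noise >= 0,
            replicates >= 1)
  structure(list(
    genes = genes, reference_gene = reference_gene,
    reference_ct = reference_ct, temperatures_C = temperatures_C,
    stages = stages, replicates = as.integer(replicates),
    ct_noise_sd = ct_noise_sd, period_coeff = period_coeff, Tc = Tc,
    beta_tail = beta_tail, beta_psm = beta_psm,
    psm_length_0 = psm_length_0, kymo_duration = kymo_duration,
    kymo_sampling = kymo_sampling, kymo_noise_sd = kymo_noise_sd,
    rate_laws = rate_laws, rate_temperatures_C = rate_temperatures_C,
    rate_frac_noise = rate_frac_noise
  ), class = "synth_config")
}

#' Generate a replicate Ct table
#'
#' One sample per (temperature, stage). The reference gene's Ct is its
#' baseline plus Gaussian noise; each gene of interest's Ct is baseline +
#' slope * stage + intercept plus Gaussian noise, so the expected delta-Ct
#' is exactly slope * stage + intercept (Gaussian noise on Ct corresponds
#' to multiplicative log-normal noise on concentration). Both the stage and
#' the equivalent time at that temperature (t = s * tau_s(T)) are recorded,
#' so the output feeds both stage-axis fits and the time-axis collapse.
#'
#' @param config a [synth_config()] object.
#' @param seed integer seed (required; generation is deterministic per seed).
#' @return Ct records tibble: `sample`, `gene`, `temperature_C`, `stage`,
#'   `time_h`, `replicate`, `ct`.
#' @examples
#' head(gen_ct_table(synth_config(), seed = 1))
#' @export
gen_ct_table <- function(config = synth_config(), seed) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(config$genes) == 0) stop("empty gene list", call. = FALSE)
  withr::local_seed(check_seed(seed))
  grid <- tidyr::expand_grid(
    temperature_C = config$temperatures_C,
    stage = config$stages,
    gene = c(config$reference_gene, config$genes$gene),
    replicate = seq_len(config$replicates)
  )
  specs <- stats::setNames(config$genes$slope_per_somite, config$genes$gene)
  icpts <- stats::setNames(config$genes$intercept_cycles, config$genes$gene)
  grid |>
    dplyr::mutate(
      sample = sprintf("T%g_s%02d", .data$temperature_C, .data$stage),
      time_h = stage_to_time(.data$stage, .data$temperature_C,
                             config$period_coeff, config$Tc),
      mu = config$reference_ct +
        ifelse(.data$gene == config$reference_gene, 0,
               specs[.data$gene] * .data$stage + icpts[.data$gene]),
      ct = .data$mu + stats::rnorm(dplyr::n(), 0, config$ct_noise_sd)
    ) |>
    dplyr::select("sample", "gene", "temperature_C", "stage", "time_h",
                  "replicate", "ct")
}

#' Generate a kymograph trace at a temperature
#'
#' Delegates to [simulate_kymograph()] with the critically scaled rates
#' v_tail = beta_tail * (T - Tc) and v_psm_shrink = beta_psm * (T - Tc).
#'
#' @inheritParams gen_ct_table
#' @param temp temperature, degrees C (> Tc).
#' @return A `kymograph_trace` tibble (see [simulate_kymograph()]).
#' @export
gen_kymograph <- function(config = synth_config(), temp, seed) {
  stopifnot(inherits(config, "synth_config"))
  check_above_tc(temp, config$Tc)
  model <- kymograph_model(
    v_tail = config$beta_tail * (temp - config$Tc),
    v_psm_shrink = config$beta_psm * (temp - config$Tc),
    psm_length_0 = config$psm_length_0,
    period = segmentation_period(temp, config$period_coeff, config$Tc)
  )
  simulate_kymograph(model, duration = config$kymo_duration,
                     sampling = config$kymo_sampling,
                     noise_sd = config$kymo_noise_sd, seed = seed)
}

#' Generate a rate-versus-temperature table
#'
#' For every observable law and temperature: true rate slope * (T - Tc),
#' observed rate true * (1 + Gaussian(0, fractional noise)), and an sd
#' column equal to fractional noise times the true rate. With fractional
#' noise 0 the rates are exact and the sd column is NA (downstream fits then
#' use unit weights).
#'
#' @inheritParams gen_ct_table
#' @return Rate observations tibble: `observable`, `temperature_C`, `rate`,
#'   `sd`, suitable for [fit_critical_law()].
#' @export
gen_rate_table <- function(config = synth_config(), seed) {
  stopifnot(inherits(config, "synth_config"))
  if (length(config$rate_temperatures_C) < 2) {
    stop("need at least 2 temperatures", call. = FALSE)
  }
  check_above_tc(config$rate_temperatures_C, config$Tc)
  withr::local_seed(check_seed(seed))
  tidyr::expand_grid(observable = config$rate_laws$observable,
                     temperature_C = config$rate_temperatures_C) |>
    dplyr::left_join(config$rate_laws, by = "observable") |>
    dplyr::mutate(
      true_rate = .data$slope * (.data$temperature_C - config$Tc),
      rate = .data$true_rate *
        (1 + stats::rnorm(dplyr::n(), 0, config$rate_frac_noise)),
      sd = if (config$rate_frac_noise > 0)
        config$rate_frac_noise * .data$true_rate else NA_real_
    ) |>
    dplyr::select("observable", "temperature_C", "rate", "sd")
}
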