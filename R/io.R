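ct_cols <- c("sample", "gene", "temperature_C", "stage", "time_h",
             "replicate", "ct")

#' Read a Ct table from delimited text
#'
#' Comma-separated, header row, "." decimal, UTF-8. Required columns:
#' `sample,gene,temperature_C,stage,time_h,replicate,ct`. `stage` or
#' `time_h` may be empty on a row, but not both; `ct` must be finite.
#' Offending rows are reported by line number.
#'
#' @param path file path.
#' @return Ct records tibble in the schema of [gen_ct_table()].
#' @export
read_ct_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # column presence is validated below; silence readr's parser-name warning
  df <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    sample = readr::col_character(), gene = readr::col_character(),
    temperature_C = readr::col_double(), stage = readr::col_double(),
    time_h = readr::col_double(), replicate = readr::col_integer(),
    ct = readr::col_double()), progress = FALSE))
  missing_cols <- setdiff(ct_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  # +1 for the header: report file line numbers
  bad_axis <- which(is.na(df$stage) & is.na(df$time_h))
  if (length(bad_axis) > 0) {
    stop("both stage and time_h empty on line(s) ",
         paste(bad_axis + 1L, collapse = ", "), call. = FALSE)
  }
  bad_ct <- which(!is.finite(df$ct))
  if (length(bad_ct) > 0) {
    stop("missing or non-finite ct on line(s) ",
         paste(bad_ct + 1L, collapse = ", "), call. = FALSE)
  }
  df[ct_cols]
}

#' Write tables in the package's delimited-text dialect
#'
#' Comma separator, header row, "." decimal, UTF-8. `write_ct_csv` emits the
#' Ct schema read back by [read_ct_csv()]; `write_boundary_csv` emits
#' `n,t_h,x_um,l_um`; `write_trace_csv` emits `t_h,tail_um,psm_um,front_um`;
#' `write_rate_csv` emits `observable,temperature_C,rate,sd` read back by
#' [read_rate_csv()]; `write_dct_csv` emits the delta-Ct point schema.
#'
#' @param records,series,trace,obs,points the table to write.
#' @param path output file path.
#' @return The input, invisibly.
#' @export
write_ct_csv <- function(records, path) {
  stopifnot(all(ct_cols %in% names(records)))
  readr::write_csv(records[ct_cols], path, progress = FALSE)
  invisible(records)
}

#' @rdname write_ct_csv
#' @export
write_boundary_csv <- function(series, path) {
  stopifnot(all(c("n", "t_h", "x_um", "l_um") %in% names(series)))
  readr::write_csv(series[c("n", "t_h", "x_um", "l_um")], path,
                   progress = FALSE)
  invisible(series)
}

#' @rdname write_ct_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(all(c("t_h", "tail_um", "psm_um", "front_um") %in% names(trace)))
  readr::write_csv(trace[c("t_h", "tail_um", "psm_um", "front_um")], path,
                   progress = FALSE)
  invisible(trace)
}

#' @rdname write_ct_csv
#' @export
write_rate_csv <- function(obs, path) {
  stopifnot(all(c("observable", "temperature_C", "rate", "sd") %in% names(obs)))
  readr::write_csv(obs[c("observable", "temperature_C", "rate", "sd")], path,
                   progress = FALSE)
  invisible(obs)
}

#' @rdname write_ct_csv
#' @export
write_dct_csv <- function(points, path) {
  readr::write_csv(points, path, progress = FALSE)
  invisible(points)
}

#' Read a rate-versus-temperature table
#'
#' Columns: `observable,temperature_C,rate,sd` (sd may be empty).
#'
#' @param path file path.
#' @return Rate observations tibble for [fit_critical_law()].
#' @export
read_rate_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(
    observable = readr::col_character(),
    temperature_C = readr::col_double(),
    rate = readr::col_double(), sd = readr::col_double()),
    progress = FALSE)
  need <- c("observable", "temperature_C", "rate", "sd")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df[need]
}

#' Read a boundary-placement scenario from a YAML config
#'
#' Sections: `field` (F0, lambda, tau), `threshold` (eta_t, g_prime),
#' `clock` (period, n_somites, t0) and optional `perturbations`, a list of
#' `{type: uniform_source, slope: <per hour>}` or
#' `{type: threshold_change, factor: k, from_index: n_p}` entries.
#'
#' @param path YAML file path.
#' @return List with `params`, `rule`, `clock` objects and a list of
#'   perturbation objects.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (sec in c("field", "threshold", "clock")) {
    if (is.null(cfg[[sec]])) stop("config is missing section '", sec, "'",
                                  call. = FALSE)
  }
  params <- morphogen_params(F0 = cfg$field$F0 %||% 1,
                             lambda = cfg$field$lambda,
                             tau = cfg$field$tau)
  rule <- threshold_rule(eta_t = cfg$threshold$eta_t,
                         g_prime = cfg$threshold$g_prime %||% 1)
  clock <- clock_schedule(period = cfg$clock$period,
                          n_somites = cfg$clock$n_somites,
                          t0 = cfg$clock$t0 %||% 0)
  perts <- lapply(cfg$perturbations %||% list(), function(p) {
    switch(p$type,
      uniform_source = {
        slope <- p$slope %||% 0
        offset0 <- p$offset %||% 0
        uniform_source(function(t) offset0 + slope * t)
      },
      threshold_change = threshold_change(p$factor, p$from_index),
      stop("unknown perturbation type: ", p$type, call. = FALSE))
  })
  list(params = params, rule = rule, clock = clock, perturbations = perts)
}

#' Run a boundary-placement scenario
#'
#' Computes the baseline boundary series and, for each configured
#' perturbation, the perturbed series.
#'
#' @param scenario list from [read_scenario_config()].
#' @return List with `baseline` (a `boundary_series`) and `perturbed`, a
#'   list of `boundary_series` (one per perturbation).
#' @export
run_scenario <- function(scenario) {
  stopifnot(all(c("params", "rule", "clock") %in% names(scenario)))
  baseline <- boundary_series(scenario$params, scenario$rule, scenario$clock)
  perturbed <- lapply(scenario$perturbations %||% list(), function(p) {
    apply_perturbation(scenario$params, scenario$rule, scenario$clock, p)
  })
  list(baseline = baseline, perturbed = perturbed)
}

#' Assemble and write a run report
#'
#' A run report records the command name, the configuration it was given,
#' the fitted quantities, any warnings, the seed and the package version, so
#' that every number in it can be reproduced from the echoed configuration
#' plus the seed.
#'
#' @param command short name of the analysis performed.
#' @param config configuration list to echo.
#' @param results named list (or tibble) of fitted quantities.
#' @param warnings character vector of warnings raised.
#' @param seed the seed used (NULL for deterministic runs).
#' @return A `run_report` list.
#' @export
run_report <- function(command, config, results, warnings = character(),
                       seed = NULL) {
  structure(list(command = command, config = config, results = results,
                 warnings = warnings, seed = seed,
                 package_version = as.character(utils::packageVersion("somitempo"))),
            class = "run_report")
}

#' @rdname run_report
#' @param report a `run_report` object.
#' @param path output JSON path.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(report)
}
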