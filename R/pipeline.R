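#' Pipeline run configuration
#'
#' Assembles a validated configuration for the pipeline runners, with
#' defaults mirroring the protocol: 60 s end trims, slope gate R^2 >= 0.90,
#' saturation floor 0.80, window gate R^2 >= 0.98 over >= 4 temperatures,
#' acclimation (control) temperature 29 degC, two reference genes.
#'
#' @param ... Named overrides of any default field (see
#'   [default_run_config()]); unknown names are an error.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- default_run_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          "bad_config")
  }
  cfg <- modifyList(defaults, over)
  stopifnot(cfg$trim_seconds >= 0,
            cfg$r2_min_slope >= 0, cfg$r2_min_slope <= 1,
            cfg$saturation_min >= 0, cfg$saturation_min <= 1,
            cfg$r2_min_window >= 0, cfg$r2_min_window <= 1,
            cfg$min_span >= 3)
  class(cfg) <- "run_config"
  cfg
}

#' Default pipeline configuration values
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    traces_csv = "traces.csv",
    metadata_csv = "metadata.csv",
    cq_csv = "cq.csv",
    output_dir = ".",
    trim_seconds = 60,
    r2_min_slope = 0.90,
    saturation_min = 0.80,
    r2_min_window = 0.98,
    min_span = 4,
    plateau_tol = NULL,
    acclimation_temperature = 29,
    reference_genes = c("ActB", "S18"),
    target_genes = NULL,
    efficiencies = NULL,
    calibration = "all_samples",
    control_groups = "control_29C",
    seed = 1
  )
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file whose keys are [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), "bad_config")
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

provenance_header <- function(cfg) {
  sprintf("aeroscope %s; seed=%s; trim=%ss; r2_slope>=%s; sat>=%s; r2_window>=%s",
          as.character(utils::packageVersion("aeroscope")), cfg$seed,
          cfg$trim_seconds, cfg$r2_min_slope, cfg$saturation_min,
          cfg$r2_min_window)
}

resolve_out <- function(cfg, name) {
  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
  file.path(cfg$output_dir, name)
}

#' Run the synthetic-study generator
#'
#' Writes `traces.csv`, `metadata.csv` and `manifest.json` for the default
#' two-ramp design (warm and cold ramps, 8 animals each) plus a `cq.csv`
#' emulating the heat/cold-shock expression experiment, into
#' `config$output_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config = run_config()) {
  study <- simulate_study(seed = config$seed,
                          dir = config$output_dir)
  cqres <- generate_cq(cq_scenario(), seed = config$seed)
  cq_path <- resolve_out(config, "cq.csv")
  write.csv(cqres$cq, cq_path, row.names = FALSE)
  jsonlite::write_json(cqres$manifest, resolve_out(config, "cq_manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(traces = resolve_out(config, "traces.csv"),
                 metadata = resolve_out(config, "metadata.csv"),
                 manifest = resolve_out(config, "manifest.json"),
                 cq = cq_path))
}

#' Run the respirometry stage
#'
#' Reads the trace and metadata CSVs named in the config, extracts
#' blank-corrected mass-specific rates, writes `rates.csv` and a QC report
#' (`qc_report.csv`) counting every exclusion by reason.
#'
#' @param config A [run_config()].
#' @return The rate-record data frame, invisibly.
#' @export
run_respirometry <- function(config = run_config()) {
  traces <- read_o2_traces(file.path(config$output_dir, config$traces_csv))
  metadata <- read_chamber_metadata(file.path(config$output_dir,
                                              config$metadata_csv))
  rates <- process_traces(traces, metadata,
                          trim_seconds = config$trim_seconds,
                          r2_min = config$r2_min_slope,
                          saturation_min = config$saturation_min)
  write_rates(rates, resolve_out(config, "rates.csv"),
              header = provenance_header(config))
  qc <- attr(rates, "qc_summary")
  qc_df <- data.frame(reason = names(qc), n = as.integer(qc),
                      stringsAsFactors = FALSE)
  write.csv(qc_df, resolve_out(config, "qc_report.csv"), row.names = FALSE)
  message(sprintf("respirometry: %d rate records (%d QC-excluded)",
                  nrow(rates), sum(!rates$qc_pass)))
  invisible(rates)
}

#' Run the thermal-window stage
#'
#' Reads `rates.csv`, aggregates the per-temperature profile, locates the
#' aerobic window and writes `profile.csv` plus `thermal_window.json` with
#' TMMR/TSMR, critical temperatures, TAS, Q10s and the thermal optimum.
#'
#' @param config A [run_config()].
#' @return The `thermal_window_result`, invisibly.
#' @export
run_thermal_window <- function(config = run_config()) {
  rates <- read_rates(file.path(config$output_dir, "rates.csv"))
  res <- thermal_window_analysis(
    rates, r2_min = config$r2_min_window, min_span = config$min_span,
    plateau_tol = config$plateau_tol,
    acclimation_temperature = config$acclimation_temperature)
  prof <- res$profile
  con <- file(resolve_out(config, "profile.csv"), "w")
  writeLines(paste0("# ", provenance_header(config)), con)
  write.csv(as.data.frame(prof), con, row.names = FALSE)
  close(con)
  thermal_window_json(res, resolve_out(config, "thermal_window.json"))
  invisible(res)
}

#' Run the qPCR relative-expression stage
#'
#' Reads the Cq CSV, runs the CNRQ chain with geNorm stability checks and
#' Mann-Whitney group comparisons, and writes `cnrq.csv`,
#' `expression_summary.csv`, `comparisons.csv` and `genorm.csv`.
#'
#' @param config A [run_config()].
#' @return The `expression_result`, invisibly.
#' @export
run_qpcr <- function(config = run_config()) {
  cq <- read_cq_table(file.path(config$output_dir, config$cq_csv))
  res <- qpcr_analysis(cq,
                       reference_genes = config$reference_genes,
                       target_genes = config$target_genes,
                       efficiencies = config$efficiencies,
                       calibration = config$calibration,
                       control_groups = config$control_groups)
  write.csv(res$cnrq, resolve_out(config, "cnrq.csv"), row.names = FALSE)
  write.csv(res$summary, resolve_out(config, "expression_summary.csv"),
            row.names = FALSE)
  write.csv(res$genorm, resolve_out(config, "genorm.csv"), row.names = FALSE)
  if (!is.null(res$comparisons)) {
    write.csv(res$comparisons, resolve_out(config, "comparisons.csv"),
              row.names = FALSE)
  }
  invisible(res)
}

#' Run the full pipeline
#'
#' `simulate` (when requested) then respirometry, thermal window and qPCR.
#'
#' @param config A [run_config()].
#' @param simulate Generate synthetic inputs first (default `TRUE` when the
#'   configured trace CSV does not yet exist).
#' @return A list with the stage results, invisibly.
#' @export
run_all <- function(config = run_config(),
                    simulate = !file.exists(file.path(config$output_dir,
                                                      config$traces_csv))) {
  if (simulate) run_simulate(config)
  rates <- run_respirometry(config)
  window <- run_thermal_window(config)
  expr <- run_qpcr(config)
  invisible(list(rates = rates, window = window, expression = expr))
}
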