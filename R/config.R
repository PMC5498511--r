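#' Read an experiment configuration from YAML
#'
#' A single YAML file with optional top-level blocks `generator`, `mcmc`
#' and `scenario`; each block's keys are the arguments of
#' [generator_config()], [mcmc_settings()] and [scenario_config()]. Absent
#' keys fall back to the function defaults.
#'
#' @param path YAML file path.
#' @return a list with elements `generator` (a `generator_config`) and
#'   `scenario` (a `scenario_config`, with its `mcmc` settings filled in).
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gen <- do.call(generator_config, raw$generator %||% list())
  mcmc <- do.call(mcmc_settings, raw$mcmc %||% list())
  scen_args <- raw$scenario %||% list()
  scen_args$mcmc <- mcmc
  scen <- do.call(scenario_config, scen_args)
  list(generator = gen, scenario = scen)
}

#' Run a configured experiment end to end
#'
#' Generates (or accepts) the genotype panel, runs the replicated scenario
#' grid, and writes `results.csv` (long per-replicate form), `table1.txt`
#' (formatted accuracy grid) and `run.json` (configuration echo) into
#' `out_dir`.
#'
#' @param config a list as returned by [read_experiment_config()], or a
#'   path to the YAML file.
#' @param out_dir output directory, created if needed.
#' @param panel_data optional pre-built [genotype_panel()]; when `NULL`
#'   the configured generator is run.
#' @param verbose print progress.
#' @return the `accuracy_table`, invisibly.
#' @export
run_experiment <- function(config, out_dir, panel_data = NULL,
                           verbose = TRUE) {
  if (is.character(config)) config <- read_experiment_config(config)
  if (is.null(panel_data)) panel_data <- generate_panel(config$generator)
  tab <- run_scenario(panel_data, config$scenario, verbose = verbose)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tidy(tab), file.path(out_dir, "results.csv"),
                   row.names = FALSE)
  writeLines(format_accuracy_table(tab), file.path(out_dir, "table1.txt"))
  scen <- unclass(config$scenario)
  scen$mcmc <- unclass(scen$mcmc)
  jsonlite::write_json(
    list(generator = unclass(config$generator),
         scenario = scen,
         r_version = as.character(getRversion())),
    file.path(out_dir, "run.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(tab)
}
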