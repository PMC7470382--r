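#' Read a run configuration file
#'
#' Plain hierarchical key-value (YAML) config with units stated in field
#' names. Recognised keys: `scenario` (one of `treatment-7d`,
#' `treatment-10d`, `prophylaxis-90d`, `renal-treatment`,
#' `renal-prophylaxis`, `renal-half-maintenance`), `drug`, `strategy`,
#' `weight_kg` (scalar or vector), `days`, `months`, `n_subjects`, `omega`,
#' `seed`, and `pk_config` (path to a PK parameter file, resolved relative
#' to the config's directory).
#'
#' @param path config file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$.dir <- dirname(normalizePath(path))
  validate_run_config(cfg)
}

.scenarios <- c("treatment-7d", "treatment-10d", "prophylaxis-90d",
                "renal-treatment", "renal-prophylaxis",
                "renal-half-maintenance")

validate_run_config <- function(cfg) {
  if (is.null(cfg$scenario) || !cfg$scenario %in% .scenarios)
    stop("unrecognised scenario: ", cfg$scenario %||% "<missing>",
         " (expected one of ", paste(.scenarios, collapse = ", "), ")")
  cfg$drug <- cfg$drug %||% "chloroquine"
  cfg$strategy <- cfg$strategy %||% "flat"
  cfg$weight_kg <- cfg$weight_kg %||% 62
  cfg$n_subjects <- cfg$n_subjects %||% 1000
  cfg$omega <- cfg$omega %||% 0.30
  cfg$seed <- cfg$seed %||% 1L
  if (!is.null(cfg$pk_config)) {
    p <- cfg$pk_config
    if (!file.exists(p) && !is.null(cfg$.dir))
      p <- file.path(cfg$.dir, cfg$pk_config)
    if (!file.exists(p)) stop("pk_config file not found: ", cfg$pk_config)
    cfg$pk_config <- p
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.schedule_for_scenario <- function(cfg, formulation) {
  weight <- cfg$weight_kg[1]
  sched <- switch(cfg$scenario,
    "treatment-7d" = ,
    "renal-treatment" = ,
    "renal-half-maintenance" =
      build_treatment_schedule(cfg$strategy, weight, formulation,
                               days = cfg$days %||% 7),
    "treatment-10d" =
      build_treatment_schedule(cfg$strategy, weight, formulation,
                               days = cfg$days %||% 10),
    "prophylaxis-90d" = ,
    "renal-prophylaxis" =
      build_prophylaxis_schedule(weight, formulation,
                                 months = cfg$months %||% 3))
  if (cfg$scenario == "renal-half-maintenance")
    sched <- halve_maintenance(sched)
  sched
}

#' Run a dosing-simulation scenario end to end
#'
#' Builds the scenario's dose schedule, simulates the virtual population,
#' and writes the output bundle: per-subject profiles CSV
#' (`subject_id,time_h,conc_um`), an exposure-summary JSON, a
#' threshold-exceedance report, and run metadata (seed, config hash,
#' package version, parameter provenance). Renal scenarios apply a 90%
#' reduction of the renal clearance fraction; `renal-half-maintenance`
#' additionally halves only the maintenance doses, leaving loading doses
#' unchanged. Config validation happens before any computation and a
#' failure writes nothing.
#'
#' @param config a `run_config` from [read_run_config()], or a path.
#' @param out_dir output directory.
#' @param params optional [pk_parameters()] overriding the config's
#'   `pk_config` (default: the illustrative fixture for the config's drug).
#' @param threshold safety threshold for the exceedance report (uM whole
#'   blood; default 10).
#' @return Invisibly, a list with the simulated population, the exposure
#'   summary and the written file paths.
#' @export
run_scenario <- function(config, out_dir, params = NULL, threshold = 10) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  formulation <- drug_formulation(config$drug)
  if (is.null(params))
    params <- if (!is.null(config$pk_config)) read_pk_config(config$pk_config)
              else make_fixture_pk_set(config$drug)
  if (grepl("^renal", config$scenario))
    params <- apply_renal_impairment(params, 0.9)
  sched <- .schedule_for_scenario(config, formulation)
  spec <- population_spec(n_subjects = config$n_subjects,
                          omega = config$omega, seed = config$seed,
                          weights = config$weight_kg)
  pop <- simulate_population(params, sched, spec)
  summ <- summarize_population(pop)
  rep <- threshold_report(pop, threshold)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(profiles = file.path(out_dir, "profiles.csv"),
                exposure = file.path(out_dir, "exposure.json"),
                thresholds = file.path(out_dir, "thresholds.json"),
                schedule = file.path(out_dir, "schedule.csv"),
                metadata = file.path(out_dir, "metadata.json"))
  long <- data.frame(
    subject_id = rep(pop$subjects$subject_id, each = length(pop$time_h)),
    time_h = rep(pop$time_h, times = nrow(pop$conc_um)),
    conc_um = as.vector(t(pop$conc_um)))
  utils::write.csv(long, paths$profiles, row.names = FALSE)
  write_schedule_csv(sched, paths$schedule)
  jsonlite::write_json(list(
    cmax_quantiles = as.list(summ$cmax_quantiles),
    auc_quantiles = as.list(summ$auc_quantiles),
    auc_horizon_h = summ$auc_horizon,
    mean_profile = data.frame(time_h = summ$time_h, mean = summ$mean_profile,
                              pi_low = summ$pi_low, pi_high = summ$pi_high)),
    paths$exposure, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  jsonlite::write_json(list(
    threshold_um = threshold, overall_fraction = attr(rep, "overall"),
    by_weight = rep), paths$thresholds, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run_metadata(config), paths$metadata,
                       auto_unbox = TRUE, digits = NA)
  invisible(list(population = pop, exposure = summ, thresholds = rep,
                 paths = paths))
}

run_metadata <- function(config) {
  cfg <- unclass(config)
  cfg$.dir <- NULL
  canon <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  tf <- tempfile(); writeLines(canon, tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)
  list(package = "quinpk",
       version = as.character(utils::packageVersion("quinpk")),
       seed = config$seed, config = cfg, config_md5 = hash,
       parameter_provenance = if (is.null(config$pk_config))
         "illustrative fixture" else config$pk_config,
       timestamp = format(Sys.time(), tz = "UTC"))
}

#' Run the poisoning analysis end to end
#'
#' Loads and validates a cohort CSV, computes binned mortality with
#' bootstrap CIs, and the threshold statistics (zero-death threshold on
#' the standard grid, mortality above 20 uM). Writes the bins CSV
#' (`lower,upper,n,deaths,mortality,ci_low,ci_high`) and a summary JSON
#' with all settings logged.
#'
#' @param cohort_path cohort CSV path (header `study_id,conc_um,died`).
#' @param out_dir output directory.
#' @param edges bin edges (uM), default [default_bin_edges()].
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @return Invisibly, a list with the cohort, bins and written paths.
#' @export
run_poisoning <- function(cohort_path, out_dir,
                          edges = default_bin_edges(), n_boot = 2000,
                          seed = 1L) {
  if (!file.exists(cohort_path))
    stop("cohort file not found: ", cohort_path)
  coh <- tryCatch(load_cohort(cohort_path),
                  error = function(e)
                    stop("while loading ", cohort_path, ": ",
                         conditionMessage(e), call. = FALSE))
  edges[length(edges)] <- max(edges[length(edges)],
                              max(coh$conc_um) + 1e-9)
  bins <- binned_mortality(coh, edges, n_boot = n_boot, seed = seed)
  zdt <- zero_death_threshold(coh)
  m20 <- mortality_above(coh, 20)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(bins = file.path(out_dir, "mortality_bins.csv"),
                summary = file.path(out_dir, "poisoning_summary.json"))
  utils::write.csv(as.data.frame(bins), paths$bins, row.names = FALSE)
  jsonlite::write_json(list(
    n = attr(coh, "n"), n_deaths = attr(coh, "n_deaths"),
    conc_range_um = attr(coh, "conc_range"),
    zero_death_threshold_um = as.numeric(zdt),
    mortality_above_20um = m20,
    parent_equivalent_of_15um = parent_fraction_correction(15),
    settings = list(edges = edges, n_boot = n_boot, seed = seed,
                    package = "quinpk",
                    version = as.character(utils::packageVersion("quinpk")))),
    paths$summary, auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = coh, bins = bins, paths = paths))
}
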