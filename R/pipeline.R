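#' Run configuration
#'
#' Paths and options for a full pipeline run. Either a simulation config
#' (synthetic study) or a records JSON path (user data) must be given.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim A [sim_config()] for synthetic runs, or `NULL`.
#' @param records_path Path to a records JSON for real-data runs, or
#'   `NULL`.
#' @param fcd_path,measures_path,retention_path,reference_path Paths to
#'   the food-composition inputs; the bundled toy tables are used when
#'   `NULL`.
#' @param nutrient_panels Named list `role -> nutrient vector` (defaults
#'   to [default_nutrient_panel()] per role).
#' @param seed Integer seed recorded in the manifest and forwarded to
#'   the simulator.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, records_path = NULL,
                       fcd_path = NULL, measures_path = NULL,
                       retention_path = NULL, reference_path = NULL,
                       nutrient_panels = list(
                         mother = default_nutrient_panel("mother"),
                         child = default_nutrient_panel("child")),
                       seed = 1L) {
  if (is.null(sim) && is.null(records_path)) {
    stop("run_config needs either a simulation config or a records path")
  }
  if (!is.null(records_path) && !file.exists(records_path)) {
    stop("records path does not exist: ", records_path)
  }
  for (p in c(fcd_path, measures_path, retention_path, reference_path)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  if (!is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, sim = sim, records_path = records_path,
                 fcd_path = fcd_path, measures_path = measures_path,
                 retention_path = retention_path,
                 reference_path = reference_path,
                 nutrient_panels = nutrient_panels, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(config, out_dir, stage, extra = list()) {
  manifest <- c(list(
    package = "sharedplate",
    version = as.character(utils::packageVersion("sharedplate")),
    stage = stage, seed = config$seed, config_hash = config_hash(config)
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Simulate a synthetic study and write its files
#'
#' Writes `records.json`, `daily_truth.csv` (the embedded exact truth),
#' `long_daily.csv` and `long_period_means.csv` (draws from the analysis
#' model), `truth.json` (generating parameters) and `manifest.json`
#' (seed, config hash, package version) under `out_dir`.
#'
#' @param config A [run_config()] with a `sim` component, or a
#'   [sim_config()] directly.
#' @param out_dir Output directory (overrides the run config's).
#' @return Invisibly, a list of the written paths.
#' @export
run_simulate <- function(config, out_dir = NULL) {
  if (inherits(config, "sim_config")) {
    config <- run_config(out_dir %||% stop("out_dir required"), sim = config,
                         seed = config$seed)
  }
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim %||% stop("no simulation config in this run config")
  gen <- generate_records(sim)
  long <- generate_long(sim)
  paths <- list(
    records = file.path(out_dir, "records.json"),
    daily_truth = file.path(out_dir, "daily_truth.csv"),
    long_daily = file.path(out_dir, "long_daily.csv"),
    long_period_means = file.path(out_dir, "long_period_means.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_records(gen$records, paths$records)
  utils::write.csv(gen$truth, paths$daily_truth, row.names = FALSE)
  utils::write.csv(long$daily, paths$long_daily, row.names = FALSE)
  utils::write.csv(long$period_means, paths$long_period_means,
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(sim), n_truncated = long$truth$n_truncated,
         n_withdrawn = long$truth$n_withdrawn),
    paths$truth, auto_unbox = TRUE, digits = NA, force = TRUE, pretty = TRUE)
  write_manifest(config, out_dir, "simulate",
                 list(n_households = sim$n_households))
  message(sprintf("simulate: %d households -> %s",
                  sim$n_households, out_dir))
  invisible(paths)
}

load_inputs <- function(config) {
  panel <- unique(unlist(config$nutrient_panels))
  fcd <- if (is.null(config$fcd_path)) {
    toy_fcd(nutrient_panel = panel)
  } else {
    load_fcd(config$fcd_path, nutrient_panel = panel,
             measures_path = config$measures_path)
  }
  rf <- if (is.null(config$retention_path)) toy_retention()
        else load_retention(config$retention_path)
  refs <- if (is.null(config$reference_path)) toy_reference_portions()
          else load_reference_portions(config$reference_path)
  list(fcd = fcd, rf = rf, refs = refs)
}

#' Run the full pipeline: simulate/load, compute intakes, validate
#'
#' Chains the whole workflow on simulated or user-supplied records:
#' intake records -> per-participant daily and period intakes ->
#' inclusion filter -> per-role, per-nutrient weighted mixed-model
#' validity analysis. Writes tidy CSVs for daily and period intakes, the
#' inclusion report, a per-role summary report, candidate-model
#' diagnostics JSON, and a manifest carrying the seed and config hash.
#' Stage-level counts (households, participants included/excluded,
#' servings imputed per hierarchy level) are logged via [message()].
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `validity_report`, the inclusion
#'   result, and the written paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- load_inputs(config)
  if (!is.null(config$sim)) {
    sim_paths <- run_simulate(config)
    records <- read_records(sim_paths$records)
  } else {
    records <- read_records(config$records_path)
  }
  message(sprintf("records: %d households, %d participants",
                  length(records$households),
                  nrow(participants_table(records))))
  daily <- compute_daily_intakes(records, inputs$fcd, inputs$rf,
                                 inputs$refs)
  imp <- attr(daily, "imputation_log")
  if (!is.null(imp)) {
    tab <- table(imp$level)
    message(sprintf("engine: %d participant-days; %d imputed servings (%s)",
                    nrow(daily), nrow(imp),
                    paste(sprintf("level %s: %d", names(tab), tab),
                          collapse = ", ")))
  } else {
    message(sprintf("engine: %d participant-days; no imputed servings",
                    nrow(daily)))
  }
  incl <- inclusion_filter(records)
  message(sprintf("inclusion: %d of %d participants included",
                  length(incl$included), nrow(incl$report)))
  pm <- period_means(daily)
  pm <- pm[pm$participant_id %in% incl$included, , drop = FALSE]
  pm <- pm[pm$n_days >= 2, , drop = FALSE]
  report <- run_validity_analysis(pm, nutrient_panel = config$nutrient_panels)
  paths <- list(
    daily = file.path(out_dir, "daily_intakes.csv"),
    period = file.path(out_dir, "period_intakes.csv"),
    inclusion = file.path(out_dir, "inclusion_report.csv"),
    summary = file.path(out_dir, "validity_summary.csv"),
    diagnostics = file.path(out_dir, "model_diagnostics.json")
  )
  utils::write.csv(daily, paths$daily, row.names = FALSE)
  utils::write.csv(pm, paths$period, row.names = FALSE)
  utils::write.csv(incl$report, paths$inclusion, row.names = FALSE)
  utils::write.csv(report$summary, paths$summary, row.names = FALSE)
  diags <- lapply(report$details, function(d) {
    list(selected = d$selected, trend_stats = as.list(d$trend_stats),
         bland_altman = lapply(d$bland_altman, unclass))
  })
  jsonlite::write_json(diags, paths$diagnostics, auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  write_manifest(config, out_dir, "pipeline",
                 list(n_included = length(incl$included)))
  message(sprintf("report: %d role x nutrient rows -> %s",
                  nrow(report$summary), paths$summary))
  invisible(list(report = report, inclusion = incl, paths = paths,
                 period_intakes = pm))
}
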