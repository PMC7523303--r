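#' Pipeline configuration and run manifests
#'
#' A run is driven by a YAML configuration naming the input files (cause
#' list, deaths, redistribution rules, life tables, disease models,
#' prevalence, risk pairs, quality ratings). With `demo: true`, any input
#' not named falls back to the package's built-in demonstration fixtures and
#' deaths are simulated from the configured seed. Every stage that moves
#' death weight records its before/after totals in the run manifest.
#'
#' @name pipeline
NULL

#' Load a pipeline configuration
#' @param path YAML configuration file
#' @return a named list of configuration values
#' @export
load_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_format("cannot parse config '%s': %s", path, conditionMessage(e))
  })
  cfg$files <- cfg$files %||% list()
  cfg
}

cfg_cause_list <- function(cfg) {
  if (!is.null(cfg$files$cause_list)) load_cause_list(cfg$files$cause_list)
  else if (isTRUE(cfg$demo)) demo_cause_list()
  else stop_config("config needs files:cause_list (or demo: true)")
}

cfg_rules <- function(cfg, cl) {
  if (!is.null(cfg$files$rules)) read_redistribution_rules(cfg$files$rules, cl)
  else if (isTRUE(cfg$demo)) demo_redistribution_rules()
  else stop_config("config needs files:rules (or demo: true)")
}

cfg_life_table <- function(cfg) {
  if (!is.null(cfg$files$life_table)) read_life_table(cfg$files$life_table)
  else if (isTRUE(cfg$demo)) demo_life_table()
  else stop_config("config needs files:life_table (or demo: true)")
}

cfg_models <- function(cfg) {
  if (!is.null(cfg$files$models)) read_disease_models(cfg$files$models)
  else if (isTRUE(cfg$demo)) demo_disease_models()
  else stop_config("config needs files:models (or demo: true)")
}

cfg_risks <- function(cfg) {
  if (!is.null(cfg$files$risks)) read_risk_pairs(cfg$files$risks)
  else if (isTRUE(cfg$demo)) demo_risk_pairs()
  else stop_config("config needs files:risks (or demo: true)")
}

cfg_sim <- function(cfg, seed) {
  simulation_config(
    seed = seed,
    n_deaths = cfg$n_deaths %||% 20000L,
    true_cause_distribution = cfg$true_cause_distribution %||%
      demo_true_cause_distribution(),
    garble_fraction = cfg$garble_fraction %||% 0.105,
    assoc_mention_prob = cfg$assoc_mention_prob %||% 0.9,
    garble_cause = unlist(cfg$garble_cause) %||% demo_garble_distribution())
}

file_digest <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Run the full burden pipeline
#'
#' Simulate (or read) deaths, redistribute ill-defined causes, compute YLL,
#' YLD, DALY and HALE, attribute burden to risk factors, summarise the
#' quality index, and write all outputs plus a run manifest to `out_dir`.
#'
#' @param cfg configuration list from [load_config()] (or an equivalent
#'   list; `list(demo = TRUE)` runs entirely on built-in fixtures)
#' @param seed integer seed governing all randomness of the run
#' @param out_dir output directory (created if needed)
#' @param log function used for progress messages (default writes to
#'   standard error)
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(cfg, seed, out_dir, log = cli_log("info")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cl <- cfg_cause_list(cfg)
  rules <- cfg_rules(cfg, cl)
  lt <- cfg_life_table(cfg)
  models <- cfg_models(cfg)
  risks <- cfg_risks(cfg)
  stages <- list()

  # --- deaths ---------------------------------------------------------
  if (!is.null(cfg$files$deaths)) {
    log("info", sprintf("reading deaths from %s", cfg$files$deaths))
    deaths <- read_deaths(cfg$files$deaths, cl)
  } else {
    sim <- cfg_sim(cfg, seed)
    log("info", sprintf("simulating %d deaths (seed %d)", sim$n_deaths, seed))
    gen <- generate_deaths(sim, cl)
    deaths <- gen$records
    readr::write_csv(tibble::tibble(cause_id = names(gen$truth),
                                    weight = as.numeric(gen$truth)),
                     file.path(out_dir, "truth.csv"))
  }
  write_deaths(deaths, file.path(out_dir, "deaths.csv"))
  stages$deaths <- list(rows = nrow(deaths), weight = total_weight(deaths))

  # --- redistribution -------------------------------------------------
  log("info", "redistributing ill-defined causes of death")
  rd <- redistribute(deaths, rules, cl)
  write_deaths(rd$records, file.path(out_dir, "redistributed_deaths.csv"))
  write_redistribution_report(rd$report,
                              file.path(out_dir, "redistribution_report.yaml"))
  write_redistribution_report(rd$report,
                              file.path(out_dir, "redistribution_report.csv"))
  stages$redistribution <- list(
    rows = nrow(rd$records),
    weight_in = rd$report$total_weight_in,
    weight_out = rd$report$total_weight_out,
    redistributed_fraction = rd$report$redistributed_fraction)

  # --- fatal burden ---------------------------------------------------
  log("info", "computing years of life lost")
  yll <- compute_yll(rd$records, cl, lt)

  # --- non-fatal burden -----------------------------------------------
  if (!is.null(cfg$files$prevalence)) {
    prevalence <- read_prevalence(cfg$files$prevalence)
  } else {
    prevalence <- generate_prevalence(seed + 1L, models,
                                      age_groups = unique(yll$age_group))
  }
  log("info", "computing years lived with disability")
  yld <- compute_yld(prevalence, models)

  log("info", "assembling DALY")
  burden <- assemble_daly(yll, yld, quiet = TRUE)
  write_burden_table(burden, file.path(out_dir, "burden.csv"))
  stages$burden <- list(cells = nrow(burden),
                        yll = sum(burden$yll), yld = sum(burden$yld),
                        daly = sum(burden$daly))

  # --- HALE -----------------------------------------------------------
  hl <- if (!is.null(cfg$files$hale_life_table)) {
    read_hale_life_table(cfg$files$hale_life_table)
  } else {
    demo_hale_life_table()
  }
  yld_per_person <- cfg$hale_yld_rate %||% 0.12
  hale <- compute_hale(hl, rep(yld_per_person, nrow(hl)))
  readr::write_csv(dplyr::mutate(hale, dplyr::across(dplyr::where(is.numeric),
                                                     ~ round(.x, 6))),
                   file.path(out_dir, "hale.csv"))
  stages$hale <- list(le_at_birth = hale$le[1], hale_at_birth = hale$hale[1])

  # --- risk attribution ----------------------------------------------
  log("info", "attributing burden to risk factors")
  pafs <- purrr::map_dfr(risks, function(p) {
    tibble::tibble(risk_id = p$risk_id, cause_id = p$outcome,
                   paf = compute_paf(p))
  })
  pafs <- pafs[pafs$cause_id %in% burden$cause_id, ]
  attributable <- attribute_burden(pafs, burden)
  readr::write_csv(attributable, file.path(out_dir, "attributable.csv"))
  stages$attribution <- list(pairs = nrow(pafs),
                             attributable_daly = sum(attributable$daly))

  # --- quality index --------------------------------------------------
  ratings <- if (!is.null(cfg$files$quality_ratings)) {
    read_quality_ratings(cfg$files$quality_ratings)
  } else {
    table2_fixture()
  }
  qs <- summarise_quality(ratings)
  write_quality_summary(qs, file.path(out_dir, "quality_summary.csv"))
  writeLines(render_quality_table(qs), file.path(out_dir, "quality_table.txt"))

  # --- manifest -------------------------------------------------------
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.yaml$", outputs)]
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, cfg_file)
  manifest <- list(
    tool = sprintf("burdenr %s",
                   as.character(utils::packageVersion("burdenr"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    inputs = file_digest(unlist(cfg$files) %||% character()),
    stages = stages,
    conservation = list(
      weight_in = rd$report$total_weight_in,
      weight_out = rd$report$total_weight_out,
      relative_error = abs(rd$report$total_weight_out -
                             rd$report$total_weight_in) /
        max(rd$report$total_weight_in, 1)),
    outputs = file_digest(outputs))
  unlink(cfg_file)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  log("info", sprintf("wrote %d outputs to %s", length(outputs), out_dir))
  invisible(manifest)
}
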