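# End-to-end orchestration: simulate -> fit -> indicators -> aggregate ->
# validate -> report, with a single configuration list, derived seeds, and
# a JSON run log. Each stage reads the previous stage's artifacts from the
# output directory, so stages can be re-run independently.

#' Default pipeline configuration
#'
#' @return nested list with blocks `world` (synthetic-world settings),
#'   `model` (grid and horizon), `fit` (MCMC settings), `report`
#'   (reported years), and scalars `seed`, `marital_group`, `horizon`.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    marital_group = "both",
    horizon = 2030,
    world = list(),           # overrides for synthetic_config()
    model = list(),           # overrides for fp_model_config()
    fit = list(chains = 2, iterations = 5000, burn_in = 2500, thin = 5,
               adapt = 500),
    validate = list(scheme = "random_leaveout", fraction_or_cutoff = 0.2),
    report = list(years = c(1990, 2000, 2010, 2019, 2030))
  )
}

load_pipeline_config <- function(config) {
  base <- default_pipeline_config()
  if (is.null(config)) return(base)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  utils::modifyList(base, config)
}

pipeline_log <- function(output, subcommand, seed, extra = list()) {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  subcommand = subcommand, seed = seed,
                  package_version = as.character(
                    utils::packageVersion("fpest"))),
             extra)
  logfile <- file.path(output, "log.json")
  log <- if (file.exists(logfile)) jsonlite::read_json(logfile) else list()
  log[[length(log) + 1]] <- entry
  jsonlite::write_json(log, logfile, auto_unbox = TRUE, pretty = TRUE)
  invisible(logfile)
}

groups_to_run <- function(marital_group) {
  switch(marital_group,
         both = c("MWRA", "UWRA"),
         mwra = "MWRA", MWRA = "MWRA",
         uwra = "UWRA", UWRA = "UWRA",
         stop("unknown marital group: ", marital_group))
}

#' Run a pipeline stage
#'
#' Subcommands: `simulate` writes a synthetic-world fixture;
#' `fit` fits the model per marital group, extrapolates to the horizon and
#' stores draws plus convergence diagnostics; `indicators` writes per-group
#' results tables; `aggregate` combines the two groups into all-women
#' results; `validate` runs a cross-validation exercise; `report`
#' assembles summary tables of the global percent and count indicators at
#' the reporting years, refusing to run while convergence flags are
#' present unless `force = TRUE`.
#'
#' @param subcommand one of `simulate`, `fit`, `indicators`, `aggregate`,
#'   `validate`, `report`.
#' @param config configuration list or YAML path (see
#'   [default_pipeline_config()]); `NULL` for defaults.
#' @param seed overrides the config seed.
#' @param output output directory (created if needed).
#' @param force let `report` proceed despite convergence flags.
#' @param marital_group `"both"`, `"mwra"` or `"uwra"` (overrides config).
#' @return invisible list of written artifact paths.
#' @export
run_pipeline <- function(subcommand = c("simulate", "fit", "indicators",
                                        "aggregate", "validate", "report"),
                         config = NULL, seed = NULL, output = "fpest-out",
                         force = FALSE, marital_group = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- load_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(marital_group)) cfg$marital_group <- marital_group
  dir.create(output, recursive = TRUE, showWarnings = FALSE)
  groups <- groups_to_run(cfg$marital_group)
  model_cfg <- do.call(fp_model_config, cfg$model)
  artifacts <- list()

  if (subcommand == "simulate") {
    wcfg <- do.call(synthetic_config,
                    utils::modifyList(list(seed = cfg$seed), cfg$world))
    world <- generate_world(wcfg)
    surveys <- generate_surveys(world, wcfg)
    paths <- write_fixture(world, surveys, file.path(output, "world"))
    artifacts$fixture <- unname(paths)
  } else if (subcommand == "fit") {
    fx <- read_fixture(file.path(output, "world"))
    flags <- character(0)
    for (mg in groups) {
      model <- fp_model(fx$observations, fx$countries, mg, model_cfg)
      fit <- do.call(run_mcmc, c(list(model = model,
                                      seed = derive_seed(cfg$seed,
                                                         match(mg, groups))),
                                 cfg$fit))
      fit <- extrapolate(fit, horizon_end = cfg$horizon + 0.5,
                         seed = cfg$seed)
      conv <- check_convergence(fit)
      ddir <- file.path(output, paste0("draws_", tolower(mg)))
      save_draws(fit, ddir)
      utils::write.csv(conv, file.path(ddir, "convergence.csv"),
                       row.names = FALSE)
      if (!isTRUE(attr(conv, "pass"))) flags <- c(flags, mg)
      artifacts[[paste0("draws_", mg)]] <- ddir
    }
    jsonlite::write_json(list(flagged_groups = flags),
                         file.path(output, "convergence_flags.json"),
                         auto_unbox = TRUE)
  } else if (subcommand == "indicators") {
    fx <- read_fixture(file.path(output, "world"))
    for (mg in groups) {
      fit <- load_draws(file.path(output, paste0("draws_", tolower(mg))))
      tab <- indicator_table(fit, populations = fx$populations,
                             years = cfg$report$years,
                             aggregates = "world",
                             countries = fx$countries)
      p <- file.path(output, paste0("results_", tolower(mg), ".csv"))
      write_results(tab, p)
      artifacts[[paste0("results_", mg)]] <- p
    }
  } else if (subcommand == "aggregate") {
    fx <- read_fixture(file.path(output, "world"))
    fit_m <- load_draws(file.path(output, "draws_mwra"))
    fit_u <- load_draws(file.path(output, "draws_uwra"))
    tab <- wra_indicator_table(fit_m, fit_u, fx$populations,
                               years = cfg$report$years,
                               aggregates = "world",
                               countries = fx$countries)
    p <- file.path(output, "results_wra.csv")
    write_results(tab, p)
    artifacts$results_WRA <- p
  } else if (subcommand == "validate") {
    fx <- read_fixture(file.path(output, "world"))
    for (mg in groups) {
      cv <- cross_validate(fx$observations, fx$countries, mg,
                           scheme = cfg$validate$scheme,
                           fraction_or_cutoff =
                             cfg$validate$fraction_or_cutoff,
                           seed = cfg$seed, config = model_cfg,
                           fit_args = cfg$fit)
      p <- file.path(output, paste0("cv_", tolower(mg), ".json"))
      jsonlite::write_json(cv$metrics, p, auto_unbox = TRUE, pretty = TRUE,
                           dataframe = "rows")
      utils::write.csv(cv$left_out,
                       file.path(output, paste0("cv_", tolower(mg), ".csv")),
                       row.names = FALSE)
      artifacts[[paste0("cv_", mg)]] <- p
    }
  } else if (subcommand == "report") {
    flagfile <- file.path(output, "convergence_flags.json")
    if (file.exists(flagfile)) {
      flags <- jsonlite::read_json(flagfile)$flagged_groups
      if (length(flags) > 0 && !force) {
        stop("convergence flags present for: ",
             paste(unlist(flags), collapse = ", "),
             "; rerun fit with more iterations or use force = TRUE")
      }
    }
    tabs <- list()
    for (f in c("results_mwra.csv", "results_uwra.csv", "results_wra.csv")) {
      p <- file.path(output, f)
      if (file.exists(p)) tabs[[f]] <- read_results(p)
    }
    if (length(tabs) == 0) stop("no results tables found; run indicators")
    all_tab <- do.call(rbind, tabs)
    world_tab <- round_results(
      all_tab[all_tab$unit == "World", , drop = FALSE])
    p <- file.path(output, "report_global.csv")
    utils::write.csv(world_tab, p, row.names = FALSE)
    artifacts$report <- p
  }
  pipeline_log(output, subcommand, cfg$seed,
               list(artifacts = unlist(artifacts, use.names = FALSE)))
  invisible(artifacts)
}
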