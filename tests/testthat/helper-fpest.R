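# Shared fixtures. Worlds and fits are cached per test run so several test
# files can reuse the same MCMC output.

.fp_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fp_cache)) {
    assign(key, force(expr), envir = .fp_cache)
  }
  get(key, envir = .fp_cache)
}

# the shipped default world: 3 regions x 2 subregions x 3 countries
default_world_config <- function() synthetic_config(seed = 20260901)

default_world <- function() {
  cached("default_world", generate_world(default_world_config()))
}

default_surveys <- function() {
  cached("default_surveys", generate_surveys(default_world()))
}

default_fixture_dir <- function() {
  system.file("extdata", "default_world", package = "fpest")
}

# a small world for fast MCMC-dependent tests: 2 regions x 1 x 2 = 4
# countries, denser surveys
tiny_world_config <- function() {
  synthetic_config(seed = 42, n_regions = 2, n_subregions_per_region = 1,
                   n_countries_per_subregion = 2,
                   surveys_per_country_mean = 6)
}

tiny_world <- function() cached("tiny_world", generate_world(tiny_world_config()))

tiny_surveys <- function() {
  cached("tiny_surveys", generate_surveys(tiny_world()))
}

tiny_model_config <- function() {
  fp_model_config(grid_start = 1970.5, grid_end = 2019.5)
}

tiny_fit_args <- function() {
  list(chains = 2, iterations = 2200, burn_in = 1000, thin = 3,
       adapt = 400)
}

tiny_fit <- function() {
  cached("tiny_fit", {
    model <- fp_model(tiny_surveys(), tiny_world()$countries, "MWRA",
                      tiny_model_config())
    do.call(run_mcmc, c(list(model = model, seed = 7), tiny_fit_args()))
  })
}

# the reduced-scale recovery fit on the default fixture (MWRA)
default_fit_mwra <- function() {
  cached("default_fit_mwra", {
    model <- fp_model(default_surveys(), default_world()$countries, "MWRA")
    run_mcmc(model, chains = 2, iterations = 9000, burn_in = 4000,
             thin = 5, seed = 11, adapt = 1000)
  })
}

default_fit_uwra <- function() {
  cached("default_fit_uwra", {
    model <- fp_model(default_surveys(), default_world()$countries, "UWRA")
    run_mcmc(model, chains = 2, iterations = 7000, burn_in = 3000,
             thin = 5, seed = 12, adapt = 1000)
  })
}

# hand-written well-formed observation CSV fixture
write_obs_fixture <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      country_code = c("AAA", "AAA", "BBB"),
      marital_group = c("MWRA", "MWRA", "UWRA"),
      start_year = c(1995, 2004, 2010),
      end_year = c(1996, NA, 2011),
      ref_time = NA,
      source_type = c("DHS", "MICS", "National"),
      prev_modern = c(0.30, 0.35, 0.10),
      prev_traditional = c(0.10, 0.08, 0.02),
      unmet_any = c(0.20, 0.18, NA),
      se_modern = c(0.01, 0.012, 0.02),
      se_traditional = c(0.005, 0.006, NA),
      se_unmet = c(0.012, NA, NA),
      nonstandard_age = c(FALSE, TRUE, FALSE),
      subnational_geography = FALSE,
      nonstandard_union_definition = FALSE,
      method_misclassification = "none")
  }
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  path
}

toy_countries <- function() {
  structure(data.frame(
    country_code = c("AAA", "BBB", "CCC"),
    name = c("Alpha", "Beta", "Gamma"),
    subregion = c("SubA", "SubA", "SubB"),
    region = c("RegionNorth", "RegionNorth", "RegionSouth"),
    sexual_activity_group = c("group1_other", "group0_low", "group1_other"),
    group_assignment_source = "manual",
    stringsAsFactors = FALSE), class = c("fp_countries", "data.frame"))
}
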