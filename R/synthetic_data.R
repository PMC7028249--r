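# Synthetic worlds: hierarchy, populations, ground-truth trajectories and
# survey observations drawn from the same generative process the model
# assumes, so that every pipeline stage is testable without any download
# and parameter recovery can be measured against known truth.

#' Synthetic-world configuration
#'
#' Defaults describe a small multi-region world: 3 regions x 2 subregions
#' x 3 countries (18 countries), an annual grid 1970.5-2030.5, surveys
#' fielded 1975-2015, one third of countries in the low-sexual-activity
#' group, and hyperparameters (trend levels, AR(1) persistence, source-type
#' errors, bias shifts) at values typical of national family-planning
#' survey compilations. Married women have higher prevalence levels and
#' earlier trend midpoints than unmarried women; low-activity-group
#' countries get strongly reduced unmarried prevalence and unmet-need
#' levels.
#'
#' @param seed integer seed; the whole world is a deterministic function of
#'   the configuration including this seed.
#' @param n_regions,n_subregions_per_region,n_countries_per_subregion
#'   world size.
#' @param year_start,year_end integer range of the annual truth grid
#'   (mid-year values `year_start + 0.5` ...).
#' @param survey_years numeric range of fieldwork years.
#' @param surveys_per_country_mean mean surveys per country per marital
#'   group (count is `1 + Poisson(mean - 1)`).
#' @param source_type_probs named sampling probabilities over source types.
#' @param group0_share share of countries in the low-sexual-activity group.
#' @param flag_probs named probabilities of the population-definition flags
#'   and of the method-misclassification categories.
#' @param missing_traditional_prob probability a survey reports only a
#'   single combined prevalence figure (enters flagged
#'   `modern_only_reported` with traditional missing).
#' @param missing_unmet_prob probability the unmet-need component is
#'   missing.
#' @param missing_se_prob probability reported standard errors are missing
#'   (they are then imputed by the reader).
#' @param n_eff_meanlog,n_eff_sdlog lognormal parameters of the survey
#'   effective sample size.
#' @param hyper optional list overriding elements of the default
#'   hyperparameter block (see the built defaults in the function body).
#' @return list of class `fp_synthetic_config`.
#' @export
synthetic_config <- function(seed = 1,
                             n_regions = 3,
                             n_subregions_per_region = 2,
                             n_countries_per_subregion = 3,
                             year_start = 1970, year_end = 2030,
                             survey_years = c(1975, 2015),
                             surveys_per_country_mean = 4,
                             source_type_probs = c(DHS = 0.40, MICS = 0.25,
                                                   PMA = 0.10,
                                                   National = 0.15,
                                                   Other = 0.10),
                             group0_share = 1 / 3,
                             flag_probs = c(nonstandard_age = 0.06,
                                            subnational_geography = 0.05,
                                            nonstandard_union_definition = 0.05,
                                            sterilization_omitted = 0.03,
                                            folk_in_modern = 0.02,
                                            other = 0.02),
                             missing_traditional_prob = 0.10,
                             missing_unmet_prob = 0.20,
                             missing_se_prob = 0.15,
                             n_eff_meanlog = log(3000), n_eff_sdlog = 0.5,
                             hyper = list()) {
  default_hyper <- list(
    # world-level means of country parameters on their transformed scales,
    # per marital group; group0_offset applies to UWRA countries in the
    # low-sexual-activity group
    world_mean = list(
      MWRA = list(p_tilde = 0.8, omega = -2.2, T_mid = 1995, r_tilde = 1.2,
                  rho = -2.3, t_r = 1990, alpha = 0.0),
      UWRA = list(p_tilde = 0.3, omega = -2.2, T_mid = 2000, r_tilde = 1.4,
                  rho = -2.3, t_r = 1995, alpha = 0.2)
    ),
    group0_offset = list(p_tilde = -3.0, r_tilde = 0, alpha = -4.0),
    # hierarchy sds per level (region / subregion / country)
    level_sd = list(
      p_tilde = c(0.35, 0.20, 0.30), omega = c(0.12, 0.08, 0.15),
      T_mid = c(5, 3, 5), r_tilde = c(0.30, 0.20, 0.30),
      rho = c(0.12, 0.08, 0.15), t_r = c(5, 3, 5),
      alpha = c(0.30, 0.20, 0.30)
    ),
    beta1 = -1.0, beta2 = -0.5,
    ar = list(P = c(phi = 0.85, sigma = 0.09),
              R = c(phi = 0.85, sigma = 0.08),
              Z = c(phi = 0.80, sigma = 0.09)),
    tau = c(DHS = 0.04, MICS = 0.06, PMA = 0.06, National = 0.10,
            Other = 0.12),
    bias = c(nonstandard_age = 0.10, subnational_geography = -0.06,
             nonstandard_union_definition = 0.08,
             misclass_modern_only_reported = -0.10,
             misclass_sterilization_omitted = -0.15,
             misclass_folk_in_modern = 0.12,
             misclass_other = 0.05),
    # populations: log10 women 15-49 uniform, constant growth rate,
    # country-specific logistic rise of the unmarried share
    pop = list(log10_range = c(5.3, 7.3), growth = c(0.012, 0.005),
               unmarried_level = c(-0.9, 0.3),
               unmarried_slope = c(0.012, 0.006))
  )
  cfg <- list(
    seed = as.integer(seed), n_regions = n_regions,
    n_subregions_per_region = n_subregions_per_region,
    n_countries_per_subregion = n_countries_per_subregion,
    year_start = year_start, year_end = year_end,
    survey_years = survey_years,
    surveys_per_country_mean = surveys_per_country_mean,
    source_type_probs = source_type_probs,
    group0_share = group0_share, flag_probs = flag_probs,
    missing_traditional_prob = missing_traditional_prob,
    missing_unmet_prob = missing_unmet_prob,
    missing_se_prob = missing_se_prob,
    n_eff_meanlog = n_eff_meanlog, n_eff_sdlog = n_eff_sdlog,
    hyper = utils::modifyList(default_hyper, hyper)
  )
  stopifnot(cfg$n_regions >= 1, cfg$n_subregions_per_region >= 1,
            cfg$n_countries_per_subregion >= 1,
            cfg$group0_share >= 0, cfg$group0_share <= 1,
            all(cfg$flag_probs >= 0 & cfg$flag_probs <= 1))
  class(cfg) <- "fp_synthetic_config"
  cfg
}

sim_ar1 <- function(n, phi, sigma) {
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma)
  innov <- sigma * sqrt(1 - phi^2)
  for (t in 2:n) x[t] <- phi * x[t - 1] + stats::rnorm(1, 0, innov)
  x
}

#' Generate a synthetic world
#'
#' Draws the country hierarchy, populations by marital group, ground-truth
#' country parameters from the configured hierarchical distributions
#' (group-structured for the UWRA level/asymptote parameters), AR(1)
#' deviation series and latent trajectories for both marital groups.
#'
#' @param config [synthetic_config()].
#' @return list of class `fp_world`: `countries` (`fp_countries`),
#'   `populations` (`fp_populations`-shaped), `truth` (per marital group:
#'   parameter table, deviation arrays, trajectory arrays), `years`.
#' @export
generate_world <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "fp_synthetic_config"))
  set.seed(derive_seed(config$seed, 1L))
  hy <- config$hyper
  nR <- config$n_regions
  nS <- config$n_subregions_per_region
  nC <- config$n_countries_per_subregion
  C <- nR * nS * nC
  region <- rep(sprintf("Region%02d", seq_len(nR)), each = nS * nC)
  subregion <- rep(sprintf("Region%02d.Sub%d", rep(seq_len(nR), each = nS),
                           rep(seq_len(nS), nR)), each = nC)
  code <- sprintf("C%02d", seq_len(C))
  n_g0 <- round(config$group0_share * C)
  g0 <- sample(seq_len(C), n_g0)
  grp <- ifelse(seq_len(C) %in% g0, "group0_low", "group1_other")
  # proportion sexually active consistent with the <2% assignment rule
  psa <- ifelse(grp == "group0_low", stats::runif(C, 0.002, 0.019),
                stats::runif(C, 0.05, 0.60))
  countries <- data.frame(
    country_code = code, name = paste("Country", code),
    subregion = subregion, region = region,
    proportion_sexually_active = round(psa, 4),
    sexual_activity_group = grp,
    group_assignment_source = "dhs_mics_proportion",
    stringsAsFactors = FALSE)
  class(countries) <- c("fp_countries", "data.frame")

  years <- seq(config$year_start + 0.5, config$year_end + 0.5, by = 1)
  nT <- length(years)

  draw_params <- function(mg) {
    wm <- hy$world_mean[[mg]]
    out <- data.frame(country_code = code, stringsAsFactors = FALSE)
    for (p in fp_param_names()) {
      sdl <- hy$level_sd[[p]]
      structured <- mg == "UWRA" && p %in% names(hy$group0_offset) &&
        hy$group0_offset[[p]] != 0
      if (structured) {
        # separate region/subregion effects per (group, geography) cell,
        # mirroring the activity-augmented hierarchy
        cell_r <- paste(grp, region, sep = "|")
        cell_s <- paste(grp, subregion, sep = "|")
        top <- wm[[p]] + ifelse(grp == "group0_low",
                                hy$group0_offset[[p]], 0)
        mu_r <- stats::rnorm(length(unique(cell_r)), 0, sdl[1])
        names(mu_r) <- unique(cell_r)
        mu_s <- stats::rnorm(length(unique(cell_s)), 0, sdl[2])
        names(mu_s) <- unique(cell_s)
        theta <- top + mu_r[cell_r] + mu_s[cell_s] +
          stats::rnorm(C, 0, sdl[3])
      } else {
        mu_r <- stats::rnorm(nR, 0, sdl[1])
        names(mu_r) <- unique(region)
        mu_s <- stats::rnorm(nR * nS, 0, sdl[2])
        names(mu_s) <- unique(subregion)
        theta <- wm[[p]] + mu_r[region] + mu_s[subregion] +
          stats::rnorm(C, 0, sdl[3])
      }
      out[[p]] <- unname(fp_param_backtransform(p, theta))
    }
    out
  }

  make_truth <- function(mg) {
    params <- draw_params(mg)
    eps <- list(P = matrix(NA_real_, C, nT), R = matrix(NA_real_, C, nT),
                Z = matrix(NA_real_, C, nT))
    traj <- list(P = matrix(NA_real_, C, nT), R = matrix(NA_real_, C, nT),
                 Zstar = matrix(NA_real_, C, nT))
    for (i in seq_len(C)) {
      eps$P[i, ] <- sim_ar1(nT, hy$ar$P["phi"], hy$ar$P["sigma"])
      eps$R[i, ] <- sim_ar1(nT, hy$ar$R["phi"], hy$ar$R["sigma"])
      eps$Z[i, ] <- sim_ar1(nT, hy$ar$Z["phi"], hy$ar$Z["sigma"])
      st <- latent_trajectories(
        list(p_tilde = params$p_tilde[i], omega = params$omega[i],
             T_mid = params$T_mid[i], r_tilde = params$r_tilde[i],
             rho = params$rho[i], t_r = params$t_r[i],
             alpha = params$alpha[i]),
        eps$P[i, ], eps$R[i, ], eps$Z[i, ], years,
        beta1 = hy$beta1, beta2 = hy$beta2)
      validate_latent_state(st)
      traj$P[i, ] <- st$P; traj$R[i, ] <- st$R; traj$Zstar[i, ] <- st$Zstar
    }
    list(params = params, eps = eps, traj = traj)
  }
  truth <- list(MWRA = make_truth("MWRA"), UWRA = make_truth("UWRA"))

  # populations: women 15-49 by country-year and marital group
  pp <- hy$pop
  base <- 10^stats::runif(C, pp$log10_range[1], pp$log10_range[2])
  growth <- stats::rnorm(C, pp$growth[1], pp$growth[2])
  ua <- stats::rnorm(C, pp$unmarried_level[1], pp$unmarried_level[2])
  ub <- stats::rnorm(C, pp$unmarried_slope[1], pp$unmarried_slope[2])
  yrs_int <- config$year_start:config$year_end
  pops <- list()
  for (i in seq_len(C)) {
    wra <- base[i] * exp(growth[i] * (yrs_int - yrs_int[1]))
    ushare <- stats::plogis(ua[i] + ub[i] * (yrs_int - 1990))
    uwra <- round(wra * ushare)
    wra <- round(wra)
    pops[[i]] <- data.frame(
      country_code = rep(code[i], 2 * length(yrs_int)),
      marital_group = rep(c("MWRA", "UWRA"), each = length(yrs_int)),
      year = rep(yrs_int, 2),
      count = c(wra - uwra, uwra), stringsAsFactors = FALSE)
  }
  populations <- do.call(rbind, pops)
  class(populations) <- c("fp_populations", "data.frame")

  out <- list(countries = countries, populations = populations,
              truth = truth, years = years, config = config)
  class(out) <- "fp_world"
  out
}

#' @export
print.fp_world <- function(x, ...) {
  cat("fp_world:", nrow(x$countries), "countries,",
      x$config$n_regions, "regions, grid", x$years[1], "-",
      x$years[length(x$years)], "\n")
  cat("  group0 countries:",
      sum(x$countries$sexual_activity_group == "group0_low"), "\n")
  invisible(x)
}

# linear interpolation of a transformed latent series at a decimal year
interp_logit <- function(series_logit, years, at) {
  stats::approx(years, series_logit, xout = at, rule = 2)$y
}

#' Generate survey observations from a synthetic world
#'
#' Surveys are drawn per country and marital group: fieldwork midpoints
#' uniform over the configured range, source types from the configured mix,
#' flags by their probabilities. Observations equal the transformed truth
#' interpolated at the fieldwork midpoint, plus the active flag biases,
#' plus normal noise with sampling variance (from a lognormal effective
#' sample size) and the source type's nonsampling variance, then
#' back-transformed. Some observations lack the traditional-method split
#' (entering as flagged total-prevalence figures) or the unmet-need
#' component; some lack reported standard errors.
#'
#' @param world `fp_world`.
#' @param config the world's configuration (defaults to `world$config`).
#' @return `fp_observations` data frame (both marital groups) with
#'   attribute `manifest`: per-group observation and country counts.
#' @export
generate_surveys <- function(world, config = world$config) {
  set.seed(derive_seed(config$seed, 2L))
  hy <- config$hyper
  years <- world$years
  code <- world$countries$country_code
  C <- length(code)
  rows <- list()
  for (mg in marital_groups()) {
    tru <- world$truth[[mg]]
    for (i in seq_len(C)) {
      n_i <- 1 + stats::rpois(1, max(config$surveys_per_country_mean - 1, 0))
      for (k in seq_len(n_i)) {
        rt <- stats::runif(1, config$survey_years[1], config$survey_years[2])
        src <- sample(names(config$source_type_probs), 1,
                      prob = config$source_type_probs)
        fl <- stats::runif(3) < config$flag_probs[c(
          "nonstandard_age", "subnational_geography",
          "nonstandard_union_definition")]
        miss_tr <- stats::runif(1) < config$missing_traditional_prob
        mis <- "none"
        if (miss_tr) {
          mis <- "modern_only_reported"
        } else {
          pm <- config$flag_probs[c("sterilization_omitted",
                                    "folk_in_modern", "other")]
          u <- stats::runif(1)
          cum <- cumsum(pm)
          hit <- which(u < cum)
          if (length(hit) > 0) mis <- names(pm)[hit[1]]
        }
        # truth at fieldwork midpoint, on transformed scales
        lP <- interp_logit(logit(tru$traj$P[i, ]), years, rt)
        lR <- interp_logit(logit(tru$traj$R[i, ]), years, rt)
        lZ <- interp_logit(logit(tru$traj$Zstar[i, ]), years, rt)
        P0 <- inv_logit(lP); R0 <- inv_logit(lR); Z0 <- inv_logit(lZ)
        m0 <- P0 * R0; t0 <- P0 * (1 - R0); u0 <- (1 - P0) * Z0
        n_eff <- stats::rlnorm(1, config$n_eff_meanlog, config$n_eff_sdlog)
        se_m <- sqrt(m0 * (1 - m0) / n_eff)
        se_t <- sqrt(t0 * (1 - t0) / n_eff)
        se_u <- sqrt(u0 * (1 - u0) / n_eff)
        tau <- hy$tau[[src]]
        bias_of <- function(comp) {
          b <- 0
          map <- bias_component_map()
          active <- c(nonstandard_age = fl[1], subnational_geography = fl[2],
                      nonstandard_union_definition = fl[3])
          for (nm in names(active)) {
            if (active[[nm]] && comp %in% map[[nm]]) b <- b + hy$bias[[nm]]
          }
          if (mis != "none") {
            key <- paste0("misclass_", mis)
            if (comp %in% map[[key]]) b <- b + hy$bias[[key]]
          }
          b
        }
        if (miss_tr) {
          # single combined figure reported as "modern": total prevalence
          # with the modern_only_reported bias on the total component
          vT <- (se_m^2 + se_t^2) / (P0 * (1 - P0))^2
          yT <- stats::rnorm(1, lP + bias_of("total"), sqrt(vT + tau^2))
          Pobs <- inv_logit(yT)
          m_rep <- Pobs; t_rep <- NA_real_
          se_m_rep <- sqrt(P0 * (1 - P0) / n_eff); se_t_rep <- NA_real_
        } else {
          vT <- (se_m^2 + se_t^2) / (P0 * (1 - P0))^2
          vR <- (t0^2 * se_m^2 + m0^2 * se_t^2) / P0^4 / (R0 * (1 - R0))^2
          yT <- stats::rnorm(1, lP + bias_of("total"), sqrt(vT + tau^2))
          yR <- stats::rnorm(1, lR + bias_of("ratio"), sqrt(vR + tau^2))
          Pobs <- inv_logit(yT); Robs <- inv_logit(yR)
          m_rep <- Pobs * Robs; t_rep <- Pobs * (1 - Robs)
          se_m_rep <- se_m; se_t_rep <- se_t
        }
        miss_u <- stats::runif(1) < config$missing_unmet_prob
        if (miss_u) {
          u_rep <- NA_real_; se_u_rep <- NA_real_
        } else {
          vZ <- (se_u^2 + Z0^2 * (se_m^2 + se_t^2)) / (1 - P0)^2 /
            (Z0 * (1 - Z0))^2
          yZ <- stats::rnorm(1, lZ + bias_of("zstar"), sqrt(vZ + tau^2))
          u_rep <- inv_logit(yZ) * (1 - Pobs)
          se_u_rep <- se_u
        }
        if (stats::runif(1) < config$missing_se_prob) {
          se_m_rep <- NA_real_; se_t_rep <- NA_real_; se_u_rep <- NA_real_
        }
        rows[[length(rows) + 1]] <- data.frame(
          country_code = code[i], marital_group = mg, ref_time = rt,
          source_type = src, prev_modern = m_rep, prev_traditional = t_rep,
          unmet_any = u_rep, se_modern = se_m_rep,
          se_traditional = se_t_rep, se_unmet = se_u_rep,
          nonstandard_age = fl[1], subnational_geography = fl[2],
          nonstandard_union_definition = fl[3],
          method_misclassification = mis, stringsAsFactors = FALSE)
      }
    }
  }
  obs <- do.call(rbind, rows)
  out <- validate_observations(obs, countries = world$countries)
  has_prev <- !is.na(out$prev_modern)
  manifest <- list()
  for (mg in marital_groups()) {
    manifest[[mg]] <- list(
      n_obs = sum(out$marital_group == mg),
      n_prevalence_obs = sum(out$marital_group == mg & has_prev),
      n_unmet_obs = sum(out$marital_group == mg & !is.na(out$unmet_any)),
      n_countries = length(unique(out$country_code[out$marital_group == mg])))
  }
  attr(out, "manifest") <- manifest
  out
}

#' Write a synthetic world and its surveys as a fixture directory
#'
#' Emits the exact CSV schemas the readers consume (per-group observation
#' files, a country table, populations) plus truth parameter tables and a
#' JSON manifest with file checksums and survey counts. The fixture
#' round-trips losslessly through the `data_io` readers.
#'
#' @param world `fp_world`.
#' @param surveys observations from [generate_surveys()].
#' @param dir output directory.
#' @return named vector of written file paths, invisibly.
#' @export
write_fixture <- function(world, surveys, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    observations_mwra = file.path(dir, "observations_mwra.csv"),
    observations_uwra = file.path(dir, "observations_uwra.csv"),
    countries = file.path(dir, "countries.csv"),
    populations = file.path(dir, "populations.csv"),
    truth_params_mwra = file.path(dir, "truth_params_mwra.csv"),
    truth_params_uwra = file.path(dir, "truth_params_uwra.csv"))
  obs <- as.data.frame(surveys)
  utils::write.csv(obs[obs$marital_group == "MWRA",
                       setdiff(names(obs), grep("_imputed$", names(obs),
                                                value = TRUE))],
                   paths["observations_mwra"], row.names = FALSE, na = "")
  utils::write.csv(obs[obs$marital_group == "UWRA",
                       setdiff(names(obs), grep("_imputed$", names(obs),
                                                value = TRUE))],
                   paths["observations_uwra"], row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(world$countries), paths["countries"],
                   row.names = FALSE, na = "")
  utils::write.csv(as.data.frame(world$populations), paths["populations"],
                   row.names = FALSE, na = "")
  utils::write.csv(world$truth$MWRA$params, paths["truth_params_mwra"],
                   row.names = FALSE)
  utils::write.csv(world$truth$UWRA$params, paths["truth_params_uwra"],
                   row.names = FALSE)
  manifest <- list(
    seed = world$config$seed,
    n_countries = nrow(world$countries),
    years = range(world$years),
    surveys = attr(surveys, "manifest"),
    checksums = as.list(tools::md5sum(unname(paths)))
  )
  names(manifest$checksums) <- basename(unname(paths))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, manifest = file.path(dir, "manifest.json")))
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return list with `observations` (both groups, validated), `countries`,
#'   `populations`, `manifest`.
#' @export
read_fixture <- function(dir) {
  countries <- read_country_records(file.path(dir, "countries.csv"))
  obs_m <- read_survey_observations(file.path(dir, "observations_mwra.csv"),
                                    countries = countries)
  obs_u <- read_survey_observations(file.path(dir, "observations_uwra.csv"),
                                    countries = countries)
  obs <- rbind(as.data.frame(obs_m), as.data.frame(obs_u))
  class(obs) <- c("fp_observations", "data.frame")
  attr(obs, "report") <- list(
    mwra = attr(obs_m, "report"), uwra = attr(obs_u, "report"))
  list(observations = obs,
       countries = countries,
       populations = read_populations(file.path(dir, "populations.csv")),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json")))
}
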