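# Model validation: out-of-sample predictive checks, the sexual-activity
# group sensitivity analysis, and parameter/trajectory recovery against
# synthetic truth.

# posterior predictive draws for a set of observations given fitted draws:
# transformed latent interpolated at ref_time + bias shifts + noise with
# sampling + source-type variance
posterior_predictive <- function(draws, obs, seed = 1) {
  set.seed(derive_seed(seed, 271L))
  nd <- n_draws(draws)
  tr_obs <- transform_observation(obs)
  grid <- draws$years
  nT <- length(grid)
  P <- pool_chains(draws$P); R <- pool_chains(draws$R)
  Z <- pool_chains(draws$Z)
  X <- flag_design(obs)
  map <- bias_component_map()
  aff <- function(comp) vapply(map, function(m) comp %in% m, logical(1))
  bias <- draws$bias
  dim(bias) <- c(dim(bias)[1], nd)
  tau <- draws$tau
  dim(tau) <- c(dim(tau)[1], nd)
  lP <- logit(P); lR <- logit(R); lZ <- logit(Z)
  out <- vector("list", nrow(obs))
  for (i in seq_len(nrow(obs))) {
    ci <- match(obs$country_code[i], draws$countries)
    if (is.na(ci)) stop("left-out observation for unfitted country ",
                        obs$country_code[i])
    i0 <- min(max(floor(obs$ref_time[i] - grid[1]) + 1L, 1L), nT - 1L)
    w <- min(max(1 - (obs$ref_time[i] - grid[i0]), 0), 1)
    srctau <- tau[match(obs$source_type[i], source_types()), ]
    pred_comp <- function(larr, comp, y, v) {
      if (is.na(y)) return(NULL)
      lat <- w * larr[ci, i0, ] + (1 - w) * larr[ci, i0 + 1, ]
      shift <- as.vector(X[i, ] %*% (bias * aff(comp)[row(bias)]))
      mu <- lat + shift
      yrep <- stats::rnorm(nd, mu, sqrt(v + srctau^2))
      list(y = y, yrep = yrep, mu = mu)
    }
    out[[i]] <- list(
      total = pred_comp(lP, "total", tr_obs$l_total[i], tr_obs$v_total[i]),
      ratio = pred_comp(lR, "ratio", tr_obs$l_ratio[i], tr_obs$v_ratio[i]),
      zstar = pred_comp(lZ, "zstar", tr_obs$l_zstar[i], tr_obs$v_zstar[i]))
  }
  out
}

#' Cross-validate the model on left-out observations
#'
#' Splits the observations by one of three schemes, refits the model on
#' the training part, and evaluates the left-out observations against
#' their posterior predictive distributions: empirical coverage of the
#' 95% prediction intervals, median absolute error and mean error (on the
#' total-prevalence proportion scale).
#'
#' @param observations `fp_observations` for one marital group.
#' @param countries country table.
#' @param marital_group `"MWRA"` or `"UWRA"`.
#' @param scheme `"random_leaveout"` (leave out a fraction at random),
#'   `"leave_last_per_country"` (most recent observation of each country
#'   with more than one), or `"leave_recent_period"` (all observations
#'   after a cutoff year).
#' @param fraction_or_cutoff leave-out fraction (random scheme, default
#'   0.2) or cutoff year (recent-period scheme).
#' @param seed integer seed controlling the split and the refit.
#' @param config model configuration.
#' @param fit_args list of arguments passed to [run_mcmc()].
#' @return list of class `fp_cv`: `metrics` (coverage, mae, me, n_left_out
#'   per component and pooled), `left_out` per-observation table, and the
#'   split indices.
#' @export
cross_validate <- function(observations, countries, marital_group,
                           scheme = c("random_leaveout",
                                      "leave_last_per_country",
                                      "leave_recent_period"),
                           fraction_or_cutoff = 0.2, seed = 1,
                           config = fp_model_config(), fit_args = list()) {
  scheme <- match.arg(scheme)
  obs <- as.data.frame(observations)
  obs <- obs[obs$marital_group == marital_group, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations for ", marital_group)
  set.seed(derive_seed(seed, 17L))
  idx_out <- switch(
    scheme,
    random_leaveout = {
      n_out <- round(fraction_or_cutoff * nrow(obs))
      sort(sample(nrow(obs), n_out))
    },
    leave_last_per_country = {
      unlist(lapply(split(seq_len(nrow(obs)), obs$country_code),
                    function(ix) {
                      if (length(ix) < 2) return(integer(0))
                      ix[which.max(obs$ref_time[ix])]
                    }), use.names = FALSE)
    },
    leave_recent_period = which(obs$ref_time > fraction_or_cutoff)
  )
  train <- obs[setdiff(seq_len(nrow(obs)), idx_out), , drop = FALSE]
  test <- obs[idx_out, , drop = FALSE]
  if (nrow(train) == 0) stop("scheme leaves no training observations")
  class(train) <- c("fp_observations", "data.frame")
  # countries losing all observations drop out of the refit; their
  # left-out rows cannot be scored and are excluded with a note
  keep <- test$country_code %in% unique(train$country_code)
  n_unscorable <- sum(!keep)
  test <- test[keep, , drop = FALSE]
  model <- fp_model(train, countries, marital_group, config)
  fit <- do.call(run_mcmc, c(list(model = model), fit_args,
                             if (is.null(fit_args$seed)) list(seed = seed)))
  rows <- list()
  if (nrow(test) > 0) {
    pp <- posterior_predictive(fit, test, seed = seed)
    for (i in seq_along(pp)) {
      for (comp in names(pp[[i]])) {
        pc <- pp[[i]][[comp]]
        if (is.null(pc)) next
        qs <- stats::quantile(pc$yrep, c(0.025, 0.5, 0.975), names = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
          row = i, country_code = test$country_code[i],
          ref_time = test$ref_time[i], component = comp,
          observed = pc$y, predicted = qs[2],
          lower95 = qs[1], upper95 = qs[3],
          covered = pc$y >= qs[1] & pc$y <= qs[3],
          err_prop = inv_logit(qs[2]) - inv_logit(pc$y),
          stringsAsFactors = FALSE)
      }
    }
  }
  left_out <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  metr <- function(df) {
    if (is.null(df) || nrow(df) == 0) {
      return(data.frame(coverage = NA_real_, mae = NA_real_, me = NA_real_,
                        n = 0L))
    }
    data.frame(coverage = mean(df$covered),
               mae = stats::median(abs(df$err_prop)),
               me = mean(df$err_prop), n = nrow(df))
  }
  by_comp <- if (is.null(left_out)) list() else
    lapply(split(left_out, left_out$component), metr)
  metrics <- do.call(rbind, c(list(pooled = metr(left_out)), by_comp))
  metrics$set <- rownames(metrics)
  out <- list(metrics = metrics, left_out = left_out, idx_out = idx_out,
              n_unscorable = n_unscorable, scheme = scheme, fit = fit)
  class(out) <- "fp_cv"
  out
}

#' Sensitivity of results to one country's sexual-activity group
#'
#' Refits the UWRA model with the named country's group flipped and
#' reports the maximum absolute change in the country's indicator medians
#' and in the all-country aggregate medians. Flipping twice returns the
#' original assignment.
#'
#' @param country_code country to flip.
#' @param observations UWRA observations.
#' @param countries classified country table.
#' @param populations population table (for aggregate medians).
#' @param years years at which medians are compared.
#' @param config model configuration.
#' @param fit_args arguments for [run_mcmc()] (applied to both fits).
#' @param seed integer seed shared by both fits.
#' @return list: `country_diff` and `aggregate_diff` tables (indicator,
#'   year, median_base, median_flipped, abs_change), and the two fitted
#'   group assignments.
#' @export
sensitivity_group_swap <- function(country_code, observations, countries,
                                   populations, years = c(1990, 2019),
                                   config = fp_model_config(),
                                   fit_args = list(), seed = 1) {
  countries <- classify_countries(countries)
  i <- match(country_code, countries$country_code)
  if (is.na(i)) stop("unknown country: ", country_code)
  flipped <- countries
  flipped$sexual_activity_group[i] <-
    ifelse(countries$sexual_activity_group[i] == "group0_low",
           "group1_other", "group0_low")
  flipped$group_assignment_source[i] <- "manual"
  fit_one <- function(ctab) {
    model <- fp_model(observations, ctab, "UWRA", config)
    do.call(run_mcmc, c(list(model = model), fit_args,
                        if (is.null(fit_args$seed)) list(seed = seed)))
  }
  fit_base <- fit_one(countries)
  fit_flip <- fit_one(flipped)
  tab <- function(fit) {
    indicator_table(fit, populations = populations, years = years,
                    aggregates = "world")
  }
  tb <- tab(fit_base)
  tf <- tab(fit_flip)
  key <- function(d) paste(d$unit, d$year, d$indicator, d$scale)
  m <- match(key(tb), key(tf))
  diff <- data.frame(unit = tb$unit, year = tb$year,
                     indicator = tb$indicator, scale = tb$scale,
                     median_base = tb$median, median_flipped = tf$median[m],
                     abs_change = abs(tb$median - tf$median[m]),
                     stringsAsFactors = FALSE)
  pct <- diff[diff$scale == "percent", , drop = FALSE]
  list(
    country_diff = pct[pct$unit == country_code, , drop = FALSE],
    aggregate_diff = pct[pct$unit == "World", , drop = FALSE],
    group_base = countries$sexual_activity_group[i],
    group_flipped = flipped$sexual_activity_group[i],
    max_country_change = max(pct$abs_change[pct$unit == country_code],
                             na.rm = TRUE),
    max_aggregate_change = max(pct$abs_change[pct$unit == "World"],
                               na.rm = TRUE))
}

#' Recovery of synthetic truth from posterior draws
#'
#' Pointwise comparison of fitted trajectories against the generator's
#' ground truth: bias and RMSE of the posterior median, and empirical
#' coverage of the 95% uncertainty intervals over country-years, for total
#' prevalence, modern prevalence and unmet need. Coverage estimates are
#' binomial proportions; the summary includes their Monte-Carlo standard
#' errors.
#'
#' @param world `fp_world` holding the truth.
#' @param draws `fp_draws` fitted to surveys from that world (same marital
#'   group and country codes).
#' @param years optional subset of mid-year grid points to score
#'   (defaults to the fitted grid).
#' @return list of class `fp_recovery`: `by_point` (country-year table),
#'   `summary` (per quantity: bias, rmse, coverage, coverage_se, n).
#' @export
recovery_report <- function(world, draws, years = NULL) {
  mg <- draws$marital_group
  tru <- world$truth[[mg]]
  ci <- match(draws$countries, world$countries$country_code)
  if (anyNA(ci)) stop("draws and truth country sets do not match")
  years <- years %||% draws$years
  ti_d <- match(years, draws$years)
  ti_w <- match(years, world$years)
  if (anyNA(ti_d) || anyNA(ti_w)) stop("scored years missing from grids")
  P <- pool_chains(draws$P); R <- pool_chains(draws$R)
  Z <- pool_chains(draws$Z)
  quantities <- list(
    total_prevalence = list(
      draws = function() P,
      truth = tru$traj$P),
    modern_prevalence = list(
      draws = function() P * R,
      truth = tru$traj$P * tru$traj$R),
    unmet_any = list(
      draws = function() (1 - P) * Z,
      truth = (1 - tru$traj$P) * tru$traj$Zstar))
  rows <- list()
  for (qn in names(quantities)) {
    q <- quantities[[qn]]
    arr <- q$draws()
    for (a in seq_along(draws$countries)) {
      for (b in seq_along(years)) {
        v <- arr[a, ti_d[b], ]
        s <- summarize_draws(v)
        tv <- q$truth[ci[a], ti_w[b]]
        rows[[length(rows) + 1]] <- data.frame(
          quantity = qn, country_code = draws$countries[a],
          year = years[b], truth = tv, median = unname(s["median"]),
          lower95 = unname(s["lower95"]), upper95 = unname(s["upper95"]),
          covered = tv >= s["lower95"] & tv <= s["upper95"],
          err = unname(s["median"]) - tv, stringsAsFactors = FALSE)
      }
    }
  }
  by_point <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(by_point, by_point$quantity),
                                function(d) {
    cov <- mean(d$covered)
    data.frame(quantity = d$quantity[1], bias = mean(d$err),
               rmse = sqrt(mean(d$err^2)), coverage = cov,
               coverage_se = sqrt(cov * (1 - cov) / nrow(d)),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  out <- list(by_point = by_point, summary = summ)
  class(out) <- "fp_recovery"
  out
}

#' @export
print.fp_recovery <- function(x, ...) {
  cat("Parameter-recovery report (pointwise over country-years)\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Calibration study over replicate synthetic worlds
#'
#' Repeats generate-fit-score over independent replicate worlds and pools
#' the trajectory coverage, giving a Monte-Carlo estimate of interval
#' calibration under the model's own generative assumptions.
#'
#' @param n_replicates number of replicate worlds.
#' @param base_config `synthetic_config()` template; each replicate uses a
#'   seed derived from `seed`.
#' @param marital_group group to fit.
#' @param fit_args arguments for [run_mcmc()].
#' @param config model configuration.
#' @param seed master seed.
#' @param years years scored per replicate.
#' @return list: `coverage` pooled across replicates with Monte-Carlo
#'   standard error, `per_replicate` data frame.
#' @export
calibration_study <- function(n_replicates = 5,
                              base_config = synthetic_config(),
                              marital_group = "MWRA",
                              fit_args = list(), config = fp_model_config(),
                              seed = 1, years = NULL) {
  reps <- list()
  for (r in seq_len(n_replicates)) {
    cfg <- base_config
    cfg$seed <- derive_seed(seed, 1000L + r)
    world <- generate_world(cfg)
    surveys <- generate_surveys(world, cfg)
    model <- fp_model(surveys, world$countries, marital_group, config)
    fit <- do.call(run_mcmc, c(list(model = model), fit_args,
                               if (is.null(fit_args$seed))
                                 list(seed = derive_seed(seed, 2000L + r))))
    rec <- recovery_report(world, fit, years = years)
    s <- rec$summary
    reps[[r]] <- data.frame(replicate = r,
                            coverage = stats::weighted.mean(s$coverage, s$n),
                            bias = stats::weighted.mean(s$bias, s$n),
                            n = sum(s$n))
  }
  per <- do.call(rbind, reps)
  cov <- stats::weighted.mean(per$coverage, per$n)
  list(coverage = cov,
       coverage_se = sqrt(cov * (1 - cov) / sum(per$n)),
       bias = stats::weighted.mean(per$bias, per$n),
       per_replicate = per)
}
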