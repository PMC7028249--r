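# Generative model components. A country-year latent state is
# (P, R, Zstar): total contraceptive prevalence, modern share of use, and
# unmet-need share among non-users. Systematic trends are logistic in time
# (P, R) or quadratic-in-P on the logit scale (Zstar); stationary AR(1)
# deviations act additively on the transformed scales.

#' Systematic logistic trend of total contraceptive prevalence
#'
#' `p_tilde / (1 + exp(-omega * (t - midpoint)))`: a logistic diffusion
#' curve with asymptote `p_tilde`, pace `omega` (per year) and midpoint
#' year `midpoint`. Strictly increasing in `t` with range `(0, p_tilde)`.
#'
#' @param t decimal year (vectorized).
#' @param p_tilde asymptote, in (0,1).
#' @param omega growth pace per year, > 0.
#' @param midpoint year at which half the asymptote is reached.
#' @return proportion(s) in (0, p_tilde).
#' @export
systematic_total_trend <- function(t, p_tilde, omega, midpoint) {
  stopifnot(all(omega > 0), all(p_tilde > 0 & p_tilde < 1))
  p_tilde * stats::plogis(omega * (t - midpoint))
}

#' Systematic logistic trend of the modern share of contraceptive use
#'
#' Same functional form as [systematic_total_trend()], applied to the
#' ratio of modern-method use to use of any method.
#'
#' @param t decimal year.
#' @param r_tilde asymptote of the modern share, in (0,1).
#' @param rho pace per year, > 0.
#' @param midpoint midpoint year of modern-share growth.
#' @return proportion(s) in (0, r_tilde).
#' @export
systematic_ratio_trend <- function(t, r_tilde, rho, midpoint) {
  stopifnot(all(rho > 0), all(r_tilde > 0 & r_tilde < 1))
  r_tilde * stats::plogis(rho * (t - midpoint))
}

#' Systematic unmet-need share among non-users as a function of prevalence
#'
#' `logistic(alpha + beta1 * P + beta2 * P^2)`, the systematic part of the
#' unmet-need share among women not using contraception, driven by total
#' prevalence P rather than time. The unmet-need prevalence is
#' `(1 - P)` times this share, so it vanishes as P approaches 1; a very
#' negative country level `alpha` reproduces the low-sexual-activity regime
#' where both prevalence and unmet need are near zero.
#'
#' @param P total contraceptive prevalence in \[0,1\].
#' @param alpha country-level intercept, logit units.
#' @param beta1,beta2 global coefficients on P and P^2, logit units.
#' @return proportion(s) in (0,1).
#' @export
unmet_share_curve <- function(P, alpha, beta1, beta2) {
  stopifnot(all(P >= 0 & P <= 1))
  stats::plogis(alpha + beta1 * P + beta2 * P^2)
}

#' Log density of a stationary AR(1) deviation series
#'
#' Mean-zero stationary AR(1) on the annual grid: the first element is
#' N(0, sigma^2), subsequent elements are N(phi * previous,
#' sigma^2 * (1 - phi^2)), so the stationary marginal standard deviation is
#' `sigma` at every lag.
#'
#' @param x numeric vector of deviations (logit scale).
#' @param phi autocorrelation, |phi| < 1.
#' @param sigma stationary standard deviation, > 0.
#' @return scalar log density.
#' @export
ar1_logdensity <- function(x, phi, sigma) {
  if (abs(phi) >= 1) stop("nonstationary phi: |phi| must be < 1")
  stopifnot(sigma > 0, length(x) >= 1)
  ll <- stats::dnorm(x[1], 0, sigma, log = TRUE)
  if (length(x) > 1) {
    innov_sd <- sigma * sqrt(1 - phi^2)
    ll <- ll + sum(stats::dnorm(x[-1], phi * x[-length(x)], innov_sd,
                                log = TRUE))
  }
  ll
}

#' Sample an AR(1) deviation series forward
#'
#' Sequentially samples from the AR(1) conditional distributions starting
#' from a last observed deviation; used to extrapolate deviation processes
#' beyond the fitted period. Reproducible under `set.seed()` (or pass
#' `seed`).
#'
#' @param last_deviation deviation at the last fitted grid year.
#' @param phi autocorrelation, |phi| < 1.
#' @param sigma stationary standard deviation, >= 0 (0 gives a
#'   deterministic decay toward 0).
#' @param horizon number of steps to sample.
#' @param seed optional integer seed.
#' @return numeric vector of length `horizon`.
#' @export
ar1_sample_forward <- function(last_deviation, phi, sigma, horizon,
                               seed = NULL) {
  if (abs(phi) >= 1) stop("nonstationary phi: |phi| must be < 1")
  stopifnot(sigma >= 0, horizon >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (horizon == 0) return(numeric(0))
  innov_sd <- sigma * sqrt(1 - phi^2)
  out <- numeric(horizon)
  prev <- last_deviation
  for (h in seq_len(horizon)) {
    prev <- phi * prev + stats::rnorm(1, 0, innov_sd)
    out[h] <- prev
  }
  out
}

#' Map observation flags to affected transformed components
#'
#' Population-definition flags (nonstandard age group, subnational
#' geography, nonstandard union definition) shift all three transformed
#' components. Method-misclassification categories shift the component a
#' different method categorization bites: a survey reporting a single
#' "modern" figure with no traditional methods enters as a total-prevalence
#' observation biased on the total component, while misclassified method
#' splits (sterilization omitted, folk methods counted as modern) bias the
#' modern-share component.
#'
#' @return named list: for each flag category, the character vector of
#'   affected components among `"total"`, `"ratio"`, `"zstar"`.
#' @export
bias_component_map <- function() {
  all3 <- c("total", "ratio", "zstar")
  list(
    nonstandard_age = all3,
    subnational_geography = all3,
    nonstandard_union_definition = all3,
    misclass_modern_only_reported = "total",
    misclass_sterilization_omitted = "ratio",
    misclass_folk_in_modern = "ratio",
    misclass_other = "ratio"
  )
}

flag_categories <- function() names(bias_component_map())

# 0/1 matrix (n_obs x categories) of active flags per observation row
flag_design <- function(obs) {
  X <- matrix(0, nrow(obs), length(flag_categories()),
              dimnames = list(NULL, flag_categories()))
  X[, "nonstandard_age"] <- as.numeric(obs$nonstandard_age)
  X[, "subnational_geography"] <- as.numeric(obs$subnational_geography)
  X[, "nonstandard_union_definition"] <-
    as.numeric(obs$nonstandard_union_definition)
  for (lev in setdiff(misclassification_levels(), "none")) {
    X[, paste0("misclass_", lev)] <-
      as.numeric(obs$method_misclassification == lev)
  }
  X
}

#' Transform survey observations to the model scale
#'
#' Maps component prevalences to the transformed observation vector:
#' logit total prevalence (`modern + traditional`), logit modern share
#' (`modern / total`), and logit unmet share among non-users
#' (`unmet / (1 - total)`); sampling variances follow by first-order
#' (delta-method) error propagation from the component standard errors,
#' treating component sampling errors as independent. Missing components
#' propagate as NA, never zeros; rows with `modern + traditional > 1`
#' must be quarantined upstream and raise an error here.
#'
#' @param obs `fp_observations` data frame (boundary-nudged, SEs present
#'   or imputed for observed components).
#' @return data frame with columns `l_total`, `l_ratio`, `l_zstar`
#'   (transformed values) and `v_total`, `v_ratio`, `v_zstar` (sampling
#'   variances on the transformed scale).
#' @export
transform_observation <- function(obs) {
  m <- obs$prev_modern
  tr <- obs$prev_traditional
  u <- obs$unmet_any
  bad <- !is.na(m) & !is.na(tr) & (m + tr > 1)
  if (any(bad)) {
    stop("modern + traditional > 1 in rows: ",
         paste(which(bad), collapse = ", "), " (quarantine upstream)")
  }
  # both components -> total and ratio identified; traditional missing with
  # modern present -> the reported figure enters as a total-prevalence
  # observation (subject to the modern_only_reported misclassification
  # bias) and the modern share stays missing
  total <- ifelse(is.na(m), NA_real_, ifelse(is.na(tr), m, m + tr))
  ratio <- ifelse(is.na(m) | is.na(tr) | total <= 0, NA_real_, m / total)
  zstar <- ifelse(is.na(u) | is.na(total) | total >= 1, NA_real_,
                  u / (1 - total))
  total <- nudge_boundary(total)
  zstar <- nudge_boundary(zstar)
  ratio <- nudge_boundary(ratio)
  se_m <- obs$se_modern
  se_t <- obs$se_traditional
  se_u <- obs$se_unmet
  v_total_raw <- ifelse(is.na(tr), se_m^2, se_m^2 + se_t^2)
  v_total <- v_total_raw / (total * (1 - total))^2
  v_ratio <- (tr^2 * se_m^2 + m^2 * se_t^2) / total^4 /
    (ratio * (1 - ratio))^2
  v_zstar <- (se_u^2 + zstar^2 * v_total_raw) / (1 - total)^2 /
    (zstar * (1 - zstar))^2
  out <- data.frame(
    l_total = logit(total),
    l_ratio = logit(ratio),
    l_zstar = logit(zstar),
    v_total = ifelse(is.na(total), NA_real_, v_total),
    v_ratio = ifelse(is.na(ratio), NA_real_, v_ratio),
    v_zstar = ifelse(is.na(zstar), NA_real_, v_zstar)
  )
  out
}

#' Expected transformed observation under the latent state and flags
#'
#' The expected value of a transformed observation is the (interpolated)
#' transformed latent state plus the sum of the bias shifts of the
#' observation's active flags, per affected component. A flag-free
#' observation has expectation exactly equal to the transformed latent
#' state.
#'
#' @param latent named numeric vector or 1-row data frame with `l_total`,
#'   `l_ratio`, `l_zstar` at the observation's reference time.
#' @param obs 1-row `fp_observations` data frame carrying the flags.
#' @param measurement list with element `bias`: named numeric vector of
#'   additive shifts per flag category (see [bias_component_map()]).
#' @return named numeric vector (`l_total`, `l_ratio`, `l_zstar`).
#' @export
expected_observation <- function(latent, obs, measurement) {
  lat <- unlist(latent[c("l_total", "l_ratio", "l_zstar")])
  X <- flag_design(obs)[1, ]
  bias <- measurement$bias
  map <- bias_component_map()
  shift <- c(total = 0, ratio = 0, zstar = 0)
  for (k in names(map)) {
    if (X[[k]] > 0) {
      b <- if (k %in% names(bias)) bias[[k]] else 0
      shift[map[[k]]] <- shift[map[[k]]] + b * X[[k]]
    }
  }
  c(l_total = unname(lat[1] + shift["total"]),
    l_ratio = unname(lat[2] + shift["ratio"]),
    l_zstar = unname(lat[3] + shift["zstar"]))
}

#' Observation log likelihood
#'
#' Independent normals per transformed component with total variance equal
#' to the sampling variance plus the squared source-type nonsampling error
#' `tau_s`. Missing components contribute nothing; a dataset's likelihood
#' is the sum of per-observation terms.
#'
#' @param obs_t 1-row output of [transform_observation()].
#' @param expected named vector from [expected_observation()].
#' @param obs 1-row observation (for its `source_type`).
#' @param measurement list with `bias` (see [expected_observation()]) and
#'   `tau`: named nonnegative vector of nonsampling standard deviations per
#'   source type.
#' @return scalar log likelihood.
#' @export
observation_loglik <- function(obs_t, expected, obs, measurement) {
  tau <- measurement$tau[[obs$source_type]]
  if (is.null(tau) || is.na(tau)) stop("no tau for source type ",
                                       obs$source_type)
  if (tau < 0) stop("tau must be nonnegative")
  ll <- 0
  for (comp in c("total", "ratio", "zstar")) {
    y <- obs_t[[paste0("l_", comp)]]
    if (is.na(y)) next
    v <- obs_t[[paste0("v_", comp)]] + tau^2
    ll <- ll + stats::dnorm(y, expected[[paste0("l_", comp)]], sqrt(v),
                            log = TRUE)
  }
  ll
}

#' Build latent-state trajectories from parameters and deviations
#'
#' Combines systematic trends with AR(1) deviation series on the
#' transformed scales and derives the prevalence decomposition:
#' `prev_modern = P * R`, `prev_traditional = P * (1 - R)`,
#' `unmet_any = (1 - P) * Zstar`. All derived quantities lie in \[0,1\] and
#' sum to at most 1 by construction.
#'
#' @param params list or 1-row data frame with `p_tilde`, `omega`,
#'   `T_mid`, `r_tilde`, `rho`, `t_r`, `alpha` for one country, plus global
#'   `beta1`, `beta2` (either inside `params` or given separately).
#' @param eps_P,eps_R,eps_Z deviation vectors on the grid (0 for the
#'   systematic trajectory).
#' @param years numeric grid of decimal years.
#' @param beta1,beta2 global unmet-curve coefficients (defaults taken from
#'   `params` if present).
#' @return data frame with `year`, `P`, `R`, `Zstar`, `prev_modern`,
#'   `prev_traditional`, `unmet_any`.
#' @export
latent_trajectories <- function(params, eps_P, eps_R, eps_Z, years,
                                beta1 = params$beta1, beta2 = params$beta2) {
  stopifnot(length(eps_P) == length(years), length(eps_R) == length(years),
            length(eps_Z) == length(years))
  P <- inv_logit(logit(systematic_total_trend(years, params$p_tilde,
                                              params$omega, params$T_mid)) +
                   eps_P)
  R <- inv_logit(logit(systematic_ratio_trend(years, params$r_tilde,
                                              params$rho, params$t_r)) +
                   eps_R)
  Zstar <- inv_logit(logit(unmet_share_curve(P, params$alpha, beta1, beta2)) +
                       eps_Z)
  data.frame(year = years, P = P, R = R, Zstar = Zstar,
             prev_modern = P * R,
             prev_traditional = P * (1 - R),
             unmet_any = (1 - P) * Zstar)
}

#' Check latent-state invariants
#'
#' @param state data frame from [latent_trajectories()].
#' @return TRUE invisibly; errors on violation.
#' @export
validate_latent_state <- function(state) {
  with(state, {
    stopifnot(all(P >= 0 & P <= 1), all(R >= 0 & R <= 1),
              all(Zstar >= 0 & Zstar <= 1),
              all(prev_modern >= 0), all(prev_traditional >= 0),
              all(unmet_any >= 0),
              all(prev_modern + prev_traditional + unmet_any <= 1 + 1e-12))
  })
  invisible(TRUE)
}

#' Model configuration
#'
#' Collects the tunable model constants: the annual estimation grid
#' (mid-year values), the projection horizon, prior hyperparameters, the
#' flag-category list and which country parameters carry the
#' sexual-activity group level in the UWRA hierarchy (levels/asymptotes
#' only by default, not pace/timing).
#'
#' @param grid_start,grid_end first/last mid-year of the estimation grid
#'   fitted by MCMC.
#' @param horizon_end last mid-year of the projection horizon.
#' @param projection_from calendar year from which estimates are labelled
#'   projections.
#' @param priors named list of prior hyperparameters (see defaults).
#' @param group_structured_params country parameters whose hierarchy
#'   includes the sexual-activity group level in UWRA mode.
#' @return list of class `fp_model_config`.
#' @export
fp_model_config <- function(grid_start = 1970.5, grid_end = 2019.5,
                            horizon_end = 2030.5, projection_from = 2020,
                            priors = list(), group_structured_params =
                              c("p_tilde", "r_tilde", "alpha")) {
  default_priors <- list(
    # world-level means (transformed scales): Normal(mean, sd)
    world_mean = list(p_tilde = c(0, 10), omega = c(-2.2, 1),
                      T_mid = c(2000, 10), r_tilde = c(0, 10),
                      rho = c(-2.2, 1), t_r = c(2000, 10),
                      alpha = c(0, 10)),
    # half-Normal sds of hierarchy levels; year-scale parameters get a
    # wider scale because their natural spread is measured in years
    level_sd_scale = list(p_tilde = 1, omega = 0.5, T_mid = 10,
                          r_tilde = 1, rho = 0.5, t_r = 10, alpha = 1),
    beta_sd = 5,            # beta1, beta2 ~ Normal(0, beta_sd^2)
    bias_sd = 0.5,          # bias_k ~ Normal(0, bias_sd^2)
    tau_sd = 0.2,           # tau_s ~ half-Normal(tau_sd)
    sigma_sd = 0.5,         # AR stationary sds ~ half-Normal(sigma_sd)
    phi_max = 0.95          # phi ~ Uniform(0, phi_max)
  )
  priors <- utils::modifyList(default_priors, priors)
  out <- list(grid = seq(grid_start, grid_end, by = 1),
              horizon_end = horizon_end,
              projection_from = projection_from,
              priors = priors,
              flag_categories = flag_categories(),
              group_structured_params = group_structured_params)
  class(out) <- "fp_model_config"
  out
}
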