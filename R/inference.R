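# Posterior inference. The joint model (logistic systematic trends, AR(1)
# deviations, quadratic-in-prevalence unmet curve, hierarchical country
# parameters, bias and source-type error terms) is expressed in the BUGS
# language and sampled with JAGS, the same family of Gibbs engine the
# published estimates of these indicators rely on. The run_mcmc contract --
# not the engine -- is what the rest of the package depends on.

fp_param_names <- function() {
  c("p_tilde", "omega", "T_mid", "r_tilde", "rho", "t_r", "alpha")
}

# JAGS-side node stems per country parameter (transformed scale)
fp_param_nodes <- function() {
  c(p_tilde = "lptilde", omega = "lomega", T_mid = "Tmid",
    r_tilde = "lrtilde", rho = "lrho", t_r = "trmid", alpha = "alpha")
}

# back-transformation from the sampling (transformed) scale
fp_param_backtransform <- function(param, x) {
  switch(param,
         p_tilde = inv_logit(x), omega = exp(x), T_mid = x,
         r_tilde = inv_logit(x), rho = exp(x), t_r = x, alpha = x)
}

#' Build a fittable model object
#'
#' Assembles the JAGS model code and data block for one marital group:
#' transformed observations with delta-method sampling variances, grid
#' interpolation indices, flag design matrices split by affected component,
#' and the hierarchy index vectors (purely geographic for MWRA; with the
#' sexual-activity group level spliced between world and region for the
#' configured level/asymptote parameters in UWRA mode).
#'
#' @param observations `fp_observations` (validated).
#' @param countries classified `fp_countries` table.
#' @param marital_group `"MWRA"` or `"UWRA"`.
#' @param config [fp_model_config()].
#' @return object of class `fp_model` (code, data, indices, metadata).
#' @export
fp_model <- function(observations, countries, marital_group,
                     config = fp_model_config()) {
  marital_group <- match.arg(marital_group, marital_groups())
  obs <- as.data.frame(observations)
  obs <- obs[obs$marital_group == marital_group, , drop = FALSE]
  if (nrow(obs) == 0) stop("no observations for ", marital_group)
  mode <- if (marital_group == "MWRA") "geographic" else
    "geographic_by_activity"
  if (mode == "geographic_by_activity") {
    countries <- classify_countries(countries)
  }
  with_data <- intersect(countries$country_code, unique(obs$country_code))
  dropped <- setdiff(unique(obs$country_code), countries$country_code)
  if (length(dropped) > 0) {
    stop("observations for countries absent from the country table: ",
         paste(dropped, collapse = ", "))
  }
  ctry <- countries[countries$country_code %in% with_data, , drop = FALSE]
  ctry <- ctry[order(ctry$country_code), , drop = FALSE]
  obs <- obs[obs$country_code %in% ctry$country_code, , drop = FALSE]
  hierarchy <- build_hierarchy(ctry, mode)
  C <- nrow(ctry)
  grid <- config$grid
  nT <- length(grid)

  # geographic chain indices
  sub_labels <- sort(unique(ctry$subregion))
  reg_labels <- sort(unique(ctry$region))
  subg <- match(ctry$subregion, sub_labels)
  regof_g <- match(ctry$region[match(sub_labels, ctry$subregion)], reg_labels)

  # activity-augmented chain (group x geography) for level/asymptote params
  if (mode == "geographic_by_activity") {
    asub_key <- paste(ctry$sexual_activity_group, ctry$subregion, sep = "|")
    areg_key <- paste(ctry$sexual_activity_group, ctry$region, sep = "|")
    asub_labels <- sort(unique(asub_key))
    areg_labels <- sort(unique(areg_key))
    grp_labels <- sort(unique(ctry$sexual_activity_group))
    suba <- match(asub_key, asub_labels)
    aregof <- match(areg_key[match(asub_labels, asub_key)], areg_labels)
    grpof <- match(sub("\\|.*$", "", areg_labels), grp_labels)
  } else {
    asub_labels <- sub_labels; areg_labels <- reg_labels
    grp_labels <- character(0)
    suba <- subg; aregof <- regof_g; grpof <- integer(0)
  }

  # observation blocks
  tr_obs <- transform_observation(obs)
  i0 <- pmin(pmax(floor(obs$ref_time - grid[1]) + 1L, 1L), nT - 1L)
  wobs <- pmin(pmax(1 - (obs$ref_time - grid[i0]), 0), 1)
  X <- flag_design(obs)
  map <- bias_component_map()
  K <- length(map)
  aff <- function(comp) {
    vapply(map, function(m) comp %in% m, logical(1))
  }
  XbT <- sweep(X, 2, as.numeric(aff("total")), `*`)
  XbR <- sweep(X, 2, as.numeric(aff("ratio")), `*`)
  XbZ <- sweep(X, 2, as.numeric(aff("zstar")), `*`)
  fill_v <- function(v) ifelse(is.na(v), 1, pmax(v, 1e-8))
  src <- match(obs$source_type, source_types())

  pr <- config$priors
  structured <- if (mode == "geographic_by_activity") {
    config$group_structured_params
  } else {
    character(0)
  }

  data <- list(
    C = C, nT = nT, year = grid, N = nrow(obs),
    Sg = length(sub_labels), Rg = length(reg_labels),
    Sa = length(asub_labels), Ra = length(areg_labels),
    G = length(grp_labels),
    subg = subg, regofg = regof_g,
    suba = suba, aregof = aregof, grpof = grpof,
    oc = match(obs$country_code, ctry$country_code),
    ot = i0, wobs = wobs, srctype = src,
    ylT = tr_obs$l_total, ylR = tr_obs$l_ratio, ylZ = tr_obs$l_zstar,
    vT = fill_v(tr_obs$v_total), vR = fill_v(tr_obs$v_ratio),
    vZ = fill_v(tr_obs$v_zstar),
    XbT = XbT, XbR = XbR, XbZ = XbZ, K = K, nsrc = length(source_types()),
    prec_bias = 1 / pr$bias_sd^2, prec_beta = 1 / pr$beta_sd^2,
    tau_scale = pr$tau_sd, sigma_scale = pr$sigma_sd, phi_max = pr$phi_max
  )
  if (mode != "geographic_by_activity") {
    # the activity-augmented chain collapses onto the geographic one
    data$G <- NULL; data$grpof <- NULL
    data$Sa <- NULL; data$Ra <- NULL
    data$suba <- NULL; data$aregof <- NULL
  }

  code <- build_jags_code(mode, structured, pr)
  out <- list(code = code, data = data, countries = ctry,
              hierarchy = hierarchy, observations = obs,
              marital_group = marital_group, mode = mode, config = config,
              grid = grid,
              index = list(sub_labels = sub_labels, reg_labels = reg_labels,
                           asub_labels = asub_labels,
                           areg_labels = areg_labels,
                           grp_labels = grp_labels, structured = structured))
  class(out) <- "fp_model"
  out
}

#' @export
print.fp_model <- function(x, ...) {
  cat("fp_model:", x$marital_group, "(", x$mode, ")\n")
  cat("  countries:", nrow(x$countries), " observations:",
      nrow(x$observations), "\n")
  cat("  grid:", x$grid[1], "-", x$grid[length(x$grid)], "\n")
  invisible(x)
}

# Assemble the BUGS-language model. Each country parameter gets a normal
# hierarchy on its transformed scale; `structured` parameters additionally
# route through the sexual-activity group level.
build_jags_code <- function(mode, structured, priors) {
  nodes <- fp_param_nodes()
  wm <- priors$world_mean
  ls <- priors$level_sd_scale
  act <- mode == "geographic_by_activity"
  blocks <- character(0)
  ctry_lines <- character(0)
  for (p in fp_param_names()) {
    nd <- nodes[[p]]
    s <- act && (p %in% structured)
    subidx <- if (s) "suba" else "subg"
    S <- if (s) "Sa" else "Sg"
    Rr <- if (s) "Ra" else "Rg"
    regof <- if (s) "aregof" else "regofg"
    top <- if (s) sprintf("mu.grp.%s[grpof[r]]", nd) else
      sprintf("mu.w.%s", nd)
    ctry_lines <- c(ctry_lines, sprintf(
      "    %s[c] ~ dnorm(mu.sub.%s[%s[c]], prec.ctry.%s)", nd, nd, subidx, nd))
    blk <- c(
      sprintf("  for (s in 1:%s) {", S),
      sprintf("    mu.sub.%s[s] ~ dnorm(mu.reg.%s[%s[s]], prec.sub.%s)",
              nd, nd, regof, nd),
      "  }",
      sprintf("  for (r in 1:%s) {", Rr),
      sprintf("    mu.reg.%s[r] ~ dnorm(%s, prec.reg.%s)", nd, top, nd),
      "  }")
    if (s) {
      blk <- c(blk,
               "  for (g in 1:G) {",
               sprintf("    mu.grp.%s[g] ~ dnorm(mu.w.%s, prec.grp.%s)",
                       nd, nd, nd),
               "  }",
               sprintf("  sd.grp.%s ~ dnorm(0, %.8g) T(0,)", nd,
                       1 / ls[[p]]^2),
               sprintf("  prec.grp.%s <- pow(sd.grp.%s, -2)", nd, nd))
    }
    blk <- c(blk,
             sprintf("  mu.w.%s ~ dnorm(%.8g, %.8g)", nd, wm[[p]][1],
                     1 / wm[[p]][2]^2),
             sprintf("  sd.ctry.%s ~ dnorm(0, %.8g) T(0,)", nd, 1 / ls[[p]]^2),
             sprintf("  prec.ctry.%s <- pow(sd.ctry.%s, -2)", nd, nd),
             sprintf("  sd.sub.%s ~ dnorm(0, %.8g) T(0,)", nd, 1 / ls[[p]]^2),
             sprintf("  prec.sub.%s <- pow(sd.sub.%s, -2)", nd, nd),
             sprintf("  sd.reg.%s ~ dnorm(0, %.8g) T(0,)", nd, 1 / ls[[p]]^2),
             sprintf("  prec.reg.%s <- pow(sd.reg.%s, -2)", nd, nd))
    blocks <- c(blocks, blk)
  }
  paste(c(
    "model {",
    "  for (c in 1:C) {",
    ctry_lines,
    "    ptilde[c] <- ilogit(lptilde[c])",
    "    omega[c] <- exp(lomega[c])",
    "    rtilde[c] <- ilogit(lrtilde[c])",
    "    rho[c] <- exp(lrho[c])",
    "    eps.P[c,1] ~ dnorm(0, prec.st.P)",
    "    eps.R[c,1] ~ dnorm(0, prec.st.R)",
    "    eps.Z[c,1] ~ dnorm(0, prec.st.Z)",
    "    for (t in 2:nT) {",
    "      eps.P[c,t] ~ dnorm(phi.P * eps.P[c,t-1], prec.in.P)",
    "      eps.R[c,t] ~ dnorm(phi.R * eps.R[c,t-1], prec.in.R)",
    "      eps.Z[c,t] ~ dnorm(phi.Z * eps.Z[c,t-1], prec.in.Z)",
    "    }",
    "    for (t in 1:nT) {",
    "      lP[c,t] <- logit(ptilde[c] * ilogit(omega[c] * (year[t] - Tmid[c]))) + eps.P[c,t]",
    "      P[c,t] <- ilogit(lP[c,t])",
    "      lR[c,t] <- logit(rtilde[c] * ilogit(rho[c] * (year[t] - trmid[c]))) + eps.R[c,t]",
    "      R[c,t] <- ilogit(lR[c,t])",
    "      lZ[c,t] <- alpha[c] + beta1 * P[c,t] + beta2 * P[c,t] * P[c,t] + eps.Z[c,t]",
    "      Z[c,t] <- ilogit(lZ[c,t])",
    "    }",
    "  }",
    blocks,
    "  beta1 ~ dnorm(0, prec_beta)",
    "  beta2 ~ dnorm(0, prec_beta)",
    "  for (k in 1:K) { bias[k] ~ dnorm(0, prec_bias) }",
    "  for (s in 1:nsrc) { tau[s] ~ dnorm(0, pow(tau_scale, -2)) T(0,) }",
    "  phi.P ~ dunif(0, phi_max)",
    "  phi.R ~ dunif(0, phi_max)",
    "  phi.Z ~ dunif(0, phi_max)",
    "  sigma.P ~ dnorm(0, pow(sigma_scale, -2)) T(0,)",
    "  sigma.R ~ dnorm(0, pow(sigma_scale, -2)) T(0,)",
    "  sigma.Z ~ dnorm(0, pow(sigma_scale, -2)) T(0,)",
    "  prec.st.P <- pow(sigma.P, -2)",
    "  prec.in.P <- prec.st.P / (1 - phi.P * phi.P)",
    "  prec.st.R <- pow(sigma.R, -2)",
    "  prec.in.R <- prec.st.R / (1 - phi.R * phi.R)",
    "  prec.st.Z <- pow(sigma.Z, -2)",
    "  prec.in.Z <- prec.st.Z / (1 - phi.Z * phi.Z)",
    "  for (i in 1:N) {",
    "    mlT[i] <- wobs[i] * lP[oc[i], ot[i]] + (1 - wobs[i]) * lP[oc[i], ot[i] + 1] + inprod(XbT[i,], bias[])",
    "    mlR[i] <- wobs[i] * lR[oc[i], ot[i]] + (1 - wobs[i]) * lR[oc[i], ot[i] + 1] + inprod(XbR[i,], bias[])",
    "    mlZ[i] <- wobs[i] * lZ[oc[i], ot[i]] + (1 - wobs[i]) * lZ[oc[i], ot[i] + 1] + inprod(XbZ[i,], bias[])",
    "    ylT[i] ~ dnorm(mlT[i], pow(vT[i] + pow(tau[srctype[i]], 2), -1))",
    "    ylR[i] ~ dnorm(mlR[i], pow(vR[i] + pow(tau[srctype[i]], 2), -1))",
    "    ylZ[i] ~ dnorm(mlZ[i], pow(vZ[i] + pow(tau[srctype[i]], 2), -1))",
    "  }",
    "}"), collapse = "\n")
}

# strip rjags' mcarray attributes, keeping the plain (dims, iter, chain) array
mcarray_to_array <- function(a) {
  out <- unclass(a)
  attr(out, "varname") <- NULL
  attr(out, "type") <- NULL
  attr(out, "elementnames") <- NULL
  out
}

monitored_nodes <- function(model) {
  nodes <- unname(fp_param_nodes())
  c("P", "R", "Z", "eps.P", "eps.R", "eps.Z", nodes,
    paste0("mu.sub.", nodes), paste0("mu.reg.", nodes),
    paste0("mu.w.", nodes),
    paste0("sd.ctry.", nodes), paste0("sd.sub.", nodes),
    paste0("sd.reg.", nodes),
    if (length(model$index$grp_labels) > 0) {
      snodes <- fp_param_nodes()[model$index$structured]
      c(paste0("mu.grp.", snodes), paste0("sd.grp.", snodes))
    },
    "beta1", "beta2", "bias", "tau",
    "phi.P", "phi.R", "phi.Z", "sigma.P", "sigma.R", "sigma.Z")
}

#' Run the MCMC sampler
#'
#' Fits the joint posterior by Gibbs/slice sampling in JAGS. `iterations`
#' counts post-adaptation iterations; the first `burn_in` of them are
#' discarded and the remainder thinned by `thin`. Identical
#' (model, settings, seed) give identical retained draws.
#'
#' @param model `fp_model` object.
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param iterations total post-adaptation iterations per chain.
#' @param burn_in discarded initial iterations (< `iterations`).
#' @param thin thinning interval.
#' @param seed integer seed; per-chain RNG streams are derived from it.
#' @param adapt JAGS adaptation iterations.
#' @param quiet suppress JAGS progress output.
#' @return object of class `fp_draws`: trajectory arrays `P`, `R`, `Z` and
#'   deviation arrays (country x year x iteration x chain), country
#'   parameter draws, hyperparameter draws, and metadata.
#' @export
run_mcmc <- function(model, chains = 2, iterations = 4000, burn_in = 2000,
                     thin = 2, seed = 1, adapt = 500, quiet = TRUE) {
  stopifnot(inherits(model, "fp_model"))
  if (iterations <= burn_in) stop("iterations must exceed burn_in")
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, ch))
  })
  jm <- tryCatch(
    rjags::jags.model(textConnection(model$code), data = model$data,
                      inits = inits, n.chains = chains, n.adapt = adapt,
                      quiet = quiet),
    error = function(e) stop("JAGS model failed to build: ",
                             conditionMessage(e)))
  if (burn_in > 0) update(jm, burn_in, progress.bar = "none")
  sam <- rjags::jags.samples(jm, monitored_nodes(model),
                             n.iter = iterations - burn_in, thin = thin,
                             progress.bar = "none")
  bad <- vapply(sam, function(a) anyNA(a) || any(!is.finite(a)), logical(1))
  if (any(bad)) {
    stop("non-finite posterior draws in block(s): ",
         paste(names(sam)[bad], collapse = ", "))
  }
  nodes <- fp_param_nodes()
  params <- lapply(fp_param_names(), function(p) {
    arr <- mcarray_to_array(sam[[nodes[[p]]]])
    fp_param_backtransform(p, arr)
  })
  names(params) <- fp_param_names()
  hyper <- sam[grep("^(mu|sd)\\.", names(sam), value = TRUE)]
  hyper <- lapply(hyper, mcarray_to_array)
  scalars <- lapply(sam[c("beta1", "beta2", "phi.P", "phi.R", "phi.Z",
                          "sigma.P", "sigma.R", "sigma.Z")],
                    mcarray_to_array)
  out <- list(
    P = mcarray_to_array(sam$P), R = mcarray_to_array(sam$R),
    Z = mcarray_to_array(sam$Z),
    eps = list(P = mcarray_to_array(sam$eps.P),
               R = mcarray_to_array(sam$eps.R),
               Z = mcarray_to_array(sam$eps.Z)),
    params = params, hyper = hyper, scalars = scalars,
    bias = mcarray_to_array(sam$bias), tau = mcarray_to_array(sam$tau),
    countries = model$countries$country_code,
    years = model$grid,
    projection = model$grid >= model$config$projection_from,
    marital_group = model$marital_group,
    index = model$index, mode = model$mode, config = model$config,
    meta = list(chains = chains, iterations = iterations, burn_in = burn_in,
                thin = thin, seed = seed, adapt = adapt,
                n_retained = dim(mcarray_to_array(sam$P))[3],
                config_hash = config_hash(model))
  )
  class(out) <- "fp_draws"
  out
}

# lightweight fingerprint of (code, data) for provenance logs
config_hash <- function(model) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(model$code, model$data), f)
  unname(tools::md5sum(f))
}

#' @export
print.fp_draws <- function(x, ...) {
  d <- dim(x$P)
  cat("fp_draws:", x$marital_group, "-", d[1], "countries x", d[2],
      "years x", d[3], "draws x", d[4], "chains\n")
  cat("  years", x$years[1], "-", x$years[length(x$years)],
      "| seed", x$meta$seed, "\n")
  invisible(x)
}

#' Number of retained draws (all chains pooled)
#' @param draws `fp_draws`.
#' @return integer.
#' @export
n_draws <- function(draws) dim(draws$P)[3] * dim(draws$P)[4]

# flatten [..., iter, chain] to [..., iter*chain]
pool_chains <- function(a) {
  d <- dim(a)
  n <- length(d)
  dim(a) <- c(d[-c(n - 1, n)], d[n - 1] * d[n])
  a
}

split_rhat <- function(mat) {
  # mat: iterations x chains; split each chain in half
  n <- nrow(mat)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Convergence diagnostics
#'
#' Split R-hat and effective sample size for all scalar hyperparameters
#' plus a stratified sample of latent trajectory nodes. Parameters with
#' R-hat above the threshold are flagged; chains with zero variance are
#' reported as degenerate (R-hat undefined).
#'
#' @param draws `fp_draws` from at least 2 chains.
#' @param rhat_threshold flagging threshold (default 1.1).
#' @param n_traj_countries,n_traj_years size of the stratified trajectory
#'   sample added to the monitored set.
#' @return data frame (`parameter`, `rhat`, `ess`, `flagged`, `degenerate`)
#'   with attribute `pass`.
#' @export
check_convergence <- function(draws, rhat_threshold = 1.1,
                              n_traj_countries = 5, n_traj_years = 3) {
  d <- dim(draws$P)
  if (d[4] < 2) stop("convergence diagnostics need at least 2 chains")
  mats <- list()
  for (nm in names(draws$scalars)) {
    mats[[nm]] <- draws$scalars[[nm]][1, , ]
  }
  for (s in seq_len(dim(draws$tau)[1])) {
    mats[[paste0("tau[", source_types()[s], "]")]] <- draws$tau[s, , ]
  }
  for (k in seq_len(dim(draws$bias)[1])) {
    mats[[paste0("bias[", flag_categories()[k], "]")]] <- draws$bias[k, , ]
  }
  for (nm in names(draws$hyper)) {
    a <- draws$hyper[[nm]]
    if (length(dim(a)) == 3) {
      for (j in seq_len(dim(a)[1])) {
        mats[[paste0(nm, "[", j, "]")]] <- a[j, , ]
      }
    } else {
      mats[[nm]] <- a[1, , ]
    }
  }
  cidx <- unique(round(seq(1, d[1], length.out = min(n_traj_countries, d[1]))))
  tidx <- unique(round(seq(1, d[2], length.out = min(n_traj_years, d[2]))))
  for (ci in cidx) {
    for (ti in tidx) {
      mats[[paste0("P[", draws$countries[ci], ",", draws$years[ti], "]")]] <-
        draws$P[ci, ti, , ]
    }
  }
  res <- lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    degenerate <- all(apply(m, 2, stats::var) < .Machine$double.eps)
    rhat <- if (degenerate) NA_real_ else split_rhat(m)
    ess <- tryCatch(
      sum(coda::effectiveSize(coda::as.mcmc.list(
        lapply(seq_len(ncol(m)), function(j) coda::mcmc(m[, j]))))),
      error = function(e) NA_real_)
    data.frame(parameter = nm, rhat = rhat, ess = ess,
               flagged = !degenerate & !is.na(rhat) & rhat > rhat_threshold,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "pass") <- !any(out$flagged)
  out
}

#' Extrapolate trajectories beyond the fitted grid
#'
#' Continues each retained trajectory to `horizon_end`: the systematic
#' logistic trends are evaluated at the new years from the draw's
#' time-invariant parameters, and the AR(1) deviation processes are
#' continued by sequential sampling from their conditional distributions.
#' Years at or after the configured projection start are labelled
#' projections. With a stationary sd of zero the continuation equals the
#' systematic trend.
#'
#' @param draws `fp_draws`.
#' @param horizon_end last mid-year of the extended grid.
#' @param seed integer seed for the forward sampling.
#' @return `fp_draws` with extended `P`, `R`, `Z`, `years` and
#'   `projection` label vector.
#' @export
extrapolate <- function(draws, horizon_end = NULL, seed = 1) {
  horizon_end <- horizon_end %||% draws$config$horizon_end
  years <- draws$years
  last <- years[length(years)]
  if (horizon_end < last) stop("horizon_end precedes the fitted grid")
  new_years <- seq(last + 1, horizon_end, by = 1)
  H <- length(new_years)
  if (H == 0) return(draws)
  d <- dim(draws$P)
  C <- d[1]; ni <- d[3]; nch <- d[4]
  set.seed(derive_seed(seed, 977L))
  phi <- lapply(c(P = "phi.P", R = "phi.R", Z = "phi.Z"),
                function(nm) as.vector(draws$scalars[[nm]]))
  sig <- lapply(c(P = "sigma.P", R = "sigma.R", Z = "sigma.Z"),
                function(nm) as.vector(draws$scalars[[nm]]))
  beta1 <- as.vector(draws$scalars$beta1)
  beta2 <- as.vector(draws$scalars$beta2)
  nd <- ni * nch
  par_flat <- lapply(draws$params, function(a) {
    dim(a) <- c(C, nd); a
  })
  extP <- array(NA_real_, c(C, H, nd))
  extR <- array(NA_real_, c(C, H, nd))
  extZ <- array(NA_real_, c(C, H, nd))
  eps_last <- lapply(draws$eps, function(a) {
    a <- a[, dim(a)[2], , , drop = FALSE]
    dim(a) <- c(C, nd); a
  })
  prevP <- eps_last$P; prevR <- eps_last$R; prevZ <- eps_last$Z
  innovP <- matrix(rep(sig$P * sqrt(1 - phi$P^2), each = C), C, nd)
  innovR <- matrix(rep(sig$R * sqrt(1 - phi$R^2), each = C), C, nd)
  innovZ <- matrix(rep(sig$Z * sqrt(1 - phi$Z^2), each = C), C, nd)
  phiPm <- matrix(rep(phi$P, each = C), C, nd)
  phiRm <- matrix(rep(phi$R, each = C), C, nd)
  phiZm <- matrix(rep(phi$Z, each = C), C, nd)
  b1m <- matrix(rep(beta1, each = C), C, nd)
  b2m <- matrix(rep(beta2, each = C), C, nd)
  for (h in seq_len(H)) {
    yr <- new_years[h]
    prevP <- phiPm * prevP + innovP * matrix(stats::rnorm(C * nd), C, nd)
    prevR <- phiRm * prevR + innovR * matrix(stats::rnorm(C * nd), C, nd)
    prevZ <- phiZm * prevZ + innovZ * matrix(stats::rnorm(C * nd), C, nd)
    sysP <- par_flat$p_tilde *
      stats::plogis(par_flat$omega * (yr - par_flat$T_mid))
    sysR <- par_flat$r_tilde *
      stats::plogis(par_flat$rho * (yr - par_flat$t_r))
    P <- inv_logit(logit(sysP) + prevP)
    R <- inv_logit(logit(sysR) + prevR)
    Z <- inv_logit(par_flat$alpha + b1m * P + b2m * P^2 + prevZ)
    extP[, h, ] <- P; extR[, h, ] <- R; extZ[, h, ] <- Z
  }
  bind_ext <- function(base, ext) {
    out <- array(NA_real_, c(C, d[2] + H, ni, nch))
    out[, seq_len(d[2]), , ] <- base
    dim(ext) <- c(C, H, ni, nch)
    out[, d[2] + seq_len(H), , ] <- ext
    out
  }
  draws$P <- bind_ext(draws$P, extP)
  draws$R <- bind_ext(draws$R, extR)
  draws$Z <- bind_ext(draws$Z, extZ)
  draws$years <- c(years, new_years)
  draws$projection <- draws$years >= draws$config$projection_from
  draws$meta$extrapolated_to <- horizon_end
  draws
}

#' Impute trajectories for a country with no observations
#'
#' Samples country parameters, per retained draw, from the fitted
#' hierarchical distribution at the country's hierarchy position (group /
#' region / subregion ancestry), then generates trajectories including
#' stationary AR(1) deviation noise. If the country's subregion holds no
#' fitted country the chain starts one level up and the corresponding
#' between-level variances are added, so the imputed uncertainty reflects
#' the country's distance from the data.
#'
#' @param draws `fp_draws` from a fitted model.
#' @param hierarchy `fp_hierarchy` containing the country (for UWRA fits,
#'   built in `geographic_by_activity` mode).
#' @param country 1-row `fp_countries` entry (or a data frame row) for the
#'   target country, with `subregion`, `region` and, for UWRA,
#'   `sexual_activity_group`.
#' @param seed integer seed.
#' @return list with `years`, arrays `P`, `R`, `Z`, `prev_modern`,
#'   `prev_traditional`, `unmet_any` of dimension (year x draw), and
#'   `params` (draw-level country parameters).
#' @export
impute_nodata_country <- function(draws, hierarchy, country, seed = 1) {
  if (!country$country_code %in% hierarchy$countries) {
    stop("country absent from hierarchy: ", country$country_code)
  }
  act <- draws$mode == "geographic_by_activity"
  idx <- draws$index
  nodes <- fp_param_nodes()
  nd <- n_draws(draws)
  set.seed(derive_seed(seed, 431L))
  grp <- if (act) country$sexual_activity_group else ""
  par_draws <- list()
  for (p in fp_param_names()) {
    nddd <- nodes[[p]]
    s <- act && (p %in% idx$structured)
    sub_lab <- if (s) paste(grp, country$subregion, sep = "|") else
      country$subregion
    reg_lab <- if (s) paste(grp, country$region, sep = "|") else
      country$region
    sub_labels <- if (s) idx$asub_labels else idx$sub_labels
    reg_labels <- if (s) idx$areg_labels else idx$reg_labels
    sd_ctry <- as.vector(draws$hyper[[paste0("sd.ctry.", nddd)]])
    extra_var <- rep(0, nd)
    if (sub_lab %in% sub_labels) {
      mu <- as.vector(draws$hyper[[paste0("mu.sub.", nddd)]][
        match(sub_lab, sub_labels), , ])
    } else if (reg_lab %in% reg_labels) {
      mu <- as.vector(draws$hyper[[paste0("mu.reg.", nddd)]][
        match(reg_lab, reg_labels), , ])
      extra_var <- as.vector(draws$hyper[[paste0("sd.sub.", nddd)]])^2
    } else if (s && grp %in% idx$grp_labels) {
      mu <- as.vector(draws$hyper[[paste0("mu.grp.", nddd)]][
        match(grp, idx$grp_labels), , ])
      extra_var <- as.vector(draws$hyper[[paste0("sd.sub.", nddd)]])^2 +
        as.vector(draws$hyper[[paste0("sd.reg.", nddd)]])^2
    } else {
      mu <- as.vector(draws$hyper[[paste0("mu.w.", nddd)]])
      extra_var <- as.vector(draws$hyper[[paste0("sd.sub.", nddd)]])^2 +
        as.vector(draws$hyper[[paste0("sd.reg.", nddd)]])^2 +
        if (s) as.vector(draws$hyper[[paste0("sd.grp.", nddd)]])^2 else 0
    }
    theta <- stats::rnorm(nd, mu, sqrt(sd_ctry^2 + extra_var))
    par_draws[[p]] <- fp_param_backtransform(p, theta)
  }
  years <- draws$years
  nT <- length(years)
  beta1 <- as.vector(draws$scalars$beta1)
  beta2 <- as.vector(draws$scalars$beta2)
  phi <- lapply(c(P = "phi.P", R = "phi.R", Z = "phi.Z"),
                function(nm) as.vector(draws$scalars[[nm]]))
  sig <- lapply(c(P = "sigma.P", R = "sigma.R", Z = "sigma.Z"),
                function(nm) as.vector(draws$scalars[[nm]]))
  sim_eps <- function(phi, sig) {
    e <- matrix(NA_real_, nT, nd)
    e[1, ] <- stats::rnorm(nd, 0, sig)
    innov <- sig * sqrt(1 - phi^2)
    for (t in 2:nT) e[t, ] <- phi * e[t - 1, ] + stats::rnorm(nd, 0, innov)
    e
  }
  eP <- sim_eps(phi$P, sig$P)
  eR <- sim_eps(phi$R, sig$R)
  eZ <- sim_eps(phi$Z, sig$Z)
  sysP <- outer(years, rep(1, nd)) # placeholder shape
  sysP <- par_draws$p_tilde[col(sysP)] *
    stats::plogis(par_draws$omega[col(sysP)] *
                    (years[row(sysP)] - par_draws$T_mid[col(sysP)]))
  sysR <- outer(years, rep(1, nd))
  sysR <- par_draws$r_tilde[col(sysR)] *
    stats::plogis(par_draws$rho[col(sysR)] *
                    (years[row(sysR)] - par_draws$t_r[col(sysR)]))
  P <- inv_logit(logit(sysP) + eP)
  R <- inv_logit(logit(sysR) + eR)
  Z <- inv_logit(par_draws$alpha[col(P)] + beta1[col(P)] * P +
                   beta2[col(P)] * P^2 + eZ)
  list(years = years, P = P, R = R, Z = Z,
       prev_modern = P * R, prev_traditional = P * (1 - R),
       unmet_any = (1 - P) * Z, params = par_draws)
}

#' Save posterior draws to disk
#'
#' One serialized container for the draw arrays plus a JSON metadata file
#' (seed, settings, configuration fingerprint).
#'
#' @param draws `fp_draws`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_draws <- function(draws, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(draws, file.path(dir, "draws.rds"))
  jsonlite::write_json(draws$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load posterior draws written by [save_draws()]
#' @param dir directory.
#' @return `fp_draws`.
#' @export
load_draws <- function(dir) readRDS(file.path(dir, "draws.rds"))
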