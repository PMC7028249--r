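test_that("identical seeds give bitwise-identical retained draws", {
  w <- tiny_world()
  s <- tiny_surveys()
  model <- fp_model(s, w$countries, "MWRA", tiny_model_config())
  args <- list(chains = 2, iterations = 600, burn_in = 300, thin = 3,
               adapt = 200, seed = 33)
  f1 <- do.call(run_mcmc, c(list(model = model), args))
  f2 <- do.call(run_mcmc, c(list(model = model), args))
  expect_identical(f1$P, f2$P)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$scalars, f2$scalars)
  f3 <- do.call(run_mcmc, c(list(model = model),
                            utils::modifyList(args, list(seed = 34))))
  expect_false(identical(f1$P, f3$P))
  expect_error(run_mcmc(model, iterations = 100, burn_in = 100),
               "exceed")
})

test_that("posterior draws respect the latent-state constraints", {
  fit <- tiny_fit()
  expect_true(all(fit$P >= 0 & fit$P <= 1))
  expect_true(all(fit$R >= 0 & fit$R <= 1))
  expect_true(all(fit$Z >= 0 & fit$Z <= 1))
  # modern prevalence never exceeds total in any draw
  expect_true(all(fit$P * fit$R <= fit$P + 1e-15))
})

test_that("convergence diagnostics flag pathologies and pass sane chains", {
  fit <- tiny_fit()
  conv <- check_convergence(fit)
  expect_true(all(c("parameter", "rhat", "ess", "flagged", "degenerate")
                  %in% names(conv)))
  # constructed pathology: shift one chain of a scalar far away
  broken <- fit
  broken$scalars$beta1[1, , 2] <- broken$scalars$beta1[1, , 2] + 50
  conv_b <- check_convergence(broken)
  expect_true(conv_b$flagged[conv_b$parameter == "beta1"])
  expect_gt(conv_b$rhat[conv_b$parameter == "beta1"], 5)
  # two identical constant chains: degenerate, not flagged
  degen <- fit
  degen$scalars$beta1[1, , ] <- 0.5
  conv_d <- check_convergence(degen)
  expect_true(conv_d$degenerate[conv_d$parameter == "beta1"])
  expect_false(conv_d$flagged[conv_d$parameter == "beta1"])
  # single chain is an error
  single <- fit
  single$P <- fit$P[, , , 1, drop = FALSE]
  expect_error(check_convergence(single), "2 chains")
  # long well-mixed iid chains pass easily
  iid <- matrix(rnorm(4000), 2000, 2)
  expect_lt(fpest:::split_rhat(iid), 1.05)
})

test_that("extrapolation labels projections and reduces to the trend
           when deviations vanish", {
  fit <- tiny_fit()
  ext <- extrapolate(fit, horizon_end = 2030.5, seed = 2)
  expect_equal(ext$years[length(ext$years)], 2030.5)
  # 2019 is an estimate, 2020 and beyond are projections
  expect_false(ext$projection[ext$years == 2019.5])
  expect_true(ext$projection[ext$years == 2020.5])
  expect_identical(extrapolate(fit, horizon_end = 2030.5, seed = 2)$P,
                   ext$P)
  # zero stationary sd and zero terminal deviation -> systematic trend
  degen <- fit
  for (nm in c("sigma.P", "sigma.R", "sigma.Z")) {
    degen$scalars[[nm]][] <- 0
  }
  for (nm in c("P", "R", "Z")) {
    degen$eps[[nm]][, dim(degen$eps[[nm]])[2], , ] <- 0
  }
  ext0 <- extrapolate(degen, horizon_end = 2030.5, seed = 2)
  i <- match(2030.5, ext0$years)
  sys30 <- degen$params$p_tilde *
    plogis(degen$params$omega * (2030.5 - degen$params$T_mid))
  expect_equal(ext0$P[, i, , ], sys30, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("projected deviation variance grows toward the stationary value", {
  fit <- tiny_fit()
  ext <- extrapolate(fit, horizon_end = 2030.5, seed = 6)
  sel <- which(ext$years > 2019.5)
  P <- fpest:::pool_chains(ext$P)
  pars <- lapply(fit$params, function(a) {
    dim(a) <- c(dim(a)[1], prod(dim(a)[2:3])); a
  })
  # deviations of the first country on the logit scale, per horizon year
  dev_var <- vapply(seq_along(sel), function(h) {
    yr <- ext$years[sel[h]]
    sys <- pars$p_tilde[1, ] * plogis(pars$omega[1, ] * (yr - pars$T_mid[1, ]))
    var(qlogis(P[1, sel[h], ]) - qlogis(sys))
  }, numeric(1))
  # grows with horizon toward the AR(1) forecast-variance limit
  expect_gt(dev_var[5], dev_var[1])
  dev_var0 <- var(qlogis(P[1, match(2019.5, ext$years), ]) -
                    qlogis(pars$p_tilde[1, ] *
                             plogis(pars$omega[1, ] *
                                      (2019.5 - pars$T_mid[1, ]))))
  sig2 <- mean(as.vector(fit$scalars$sigma.P)^2)
  phibar <- mean(as.vector(fit$scalars$phi.P))
  H <- length(dev_var)
  expect_equal(dev_var[H],
               sig2 * (1 - phibar^(2 * H)) + phibar^(2 * H) * dev_var0,
               tolerance = 0.35)
})

test_that("no-data imputation widens uncertainty and centres on the
           cluster mean", {
  w <- tiny_world()
  fit <- tiny_fit()
  # a brand-new country in a fitted subregion
  newc <- data.frame(country_code = "NEW",
                     subregion = w$countries$subregion[1],
                     region = w$countries$region[1],
                     sexual_activity_group =
                       w$countries$sexual_activity_group[1],
                     stringsAsFactors = FALSE)
  ctab <- rbind(w$countries[, names(newc)], newc)
  h <- build_hierarchy(cbind(ctab, name = ctab$country_code), "geographic")
  imp <- impute_nodata_country(fit, h, newc, seed = 4)
  expect_identical(impute_nodata_country(fit, h, newc, seed = 4)$P, imp$P)
  expect_true(all(imp$P >= 0 & imp$P <= 1))
  expect_true(all(imp$prev_modern + imp$prev_traditional +
                    imp$unmet_any <= 1 + 1e-12))
  # wider 95% bands than a data-rich country in the same subregion
  ci_width <- function(m) {
    apply(m, 1, function(x) diff(quantile(x, c(0.025, 0.975))))
  }
  fitted_same_sub <- which(w$countries$subregion == newc$subregion)[1]
  P_fitted <- fpest:::pool_chains(fit$P)[fitted_same_sub, , ]
  expect_gt(mean(ci_width(imp$P)), mean(ci_width(P_fitted)))
  # Monte-Carlo consistency: with country-level and AR spread removed the
  # imputed trajectory is exactly the subregion-mean systematic curve
  degen <- fit
  for (nm in c("sigma.P", "sigma.R", "sigma.Z")) degen$scalars[[nm]][] <- 0
  for (nm in names(degen$hyper)) {
    if (startsWith(nm, "sd.ctry.")) degen$hyper[[nm]][] <- 0
  }
  imp0 <- impute_nodata_country(degen, h, newc, seed = 4)
  si <- match(newc$subregion, fit$index$sub_labels)
  mu_sub <- plogis(degen$hyper$mu.sub.lptilde[si, , ])
  omega_sub <- exp(degen$hyper$mu.sub.lomega[si, , ])
  T_sub <- degen$hyper$mu.sub.Tmid[si, , ]
  yi <- match(2009.5, imp0$years)
  expected_P <- as.vector(mu_sub) *
    plogis(as.vector(omega_sub) * (2009.5 - as.vector(T_sub)))
  expect_equal(unname(imp0$P[yi, ]), unname(expected_P), tolerance = 1e-10)
  # unknown country is fatal
  bad <- newc; bad$country_code <- "NOPE"
  expect_error(impute_nodata_country(fit, h, bad, seed = 1),
               "absent from hierarchy")
})

test_that("projection intervals are at least as wide as end-of-data
           intervals", {
  fit <- extrapolate(tiny_fit(), horizon_end = 2030.5, seed = 8)
  P <- fpest:::pool_chains(fit$P)
  w_at <- function(yr) {
    i <- match(yr, fit$years)
    mean(apply(P[, i, ], 1, function(x)
      diff(quantile(x, c(0.025, 0.975)))))
  }
  expect_gte(w_at(2030.5), w_at(2015.5))
})
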