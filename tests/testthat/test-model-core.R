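test_that("logistic trends hit their midpoint, limits and closed form", {
  # midpoint: half the asymptote
  expect_equal(systematic_total_trend(2000, 0.8, 0.1, 2000), 0.4)
  expect_equal(systematic_ratio_trend(1995, 0.9, 0.08, 1995), 0.45)
  # saturation limits
  expect_equal(systematic_total_trend(-1e6, 0.8, 0.1, 2000), 0)
  expect_equal(systematic_total_trend(1e6, 0.8, 0.1, 2000), 0.8)
  # steep pace approaches a step at the midpoint
  expect_lt(systematic_ratio_trend(1994.9, 0.9, 1e4, 1995), 1e-10)
  expect_equal(systematic_ratio_trend(1995.1, 0.9, 1e4, 1995), 0.9)
  # closed-form value frozen from an independent evaluation of
  # 0.8 / (1 + exp(-1))
  expect_equal(systematic_total_trend(2010, 0.8, 0.1, 2000), 0.58484686,
               tolerance = 1e-7)
  # monotone nondecreasing in t and in the asymptote
  tt <- seq(1950, 2050, by = 0.5)
  v <- systematic_total_trend(tt, 0.7, 0.05, 1998)
  expect_true(all(diff(v) > 0))
  expect_true(all(systematic_total_trend(tt, 0.75, 0.05, 1998) >= v))
  expect_error(systematic_total_trend(2000, 0.8, -0.1, 2000))
})

test_that("unmet-need curve saturates, centres and matches its closed form", {
  expect_equal(unmet_share_curve(0.5, 0, 0, 0), 0.5)
  # low-sexual-activity regime: very negative level -> share near 0 at all P
  expect_true(all(unmet_share_curve(seq(0, 1, 0.1), -20, 0, 0) < 1e-6))
  # frozen closed form: plogis(1 - 2 * 0.3) = plogis(0.4)
  expect_equal(unmet_share_curve(0.3, 1, -2, 0), 0.59868766, tolerance = 1e-7)
  # unmet prevalence (1 - P) * share vanishes as P -> 1
  expect_equal((1 - 1) * unmet_share_curve(1, 2, 1, 1), 0)
})

test_that("AR(1) density matches the stationary multivariate normal", {
  # oracle: joint normal with covariance sigma^2 * phi^|i-j|
  set.seed(1)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    phi <- runif(1, -0.9, 0.9)
    sigma <- runif(1, 0.05, 0.5)
    x <- rnorm(n, 0, sigma)
    S <- sigma^2 * phi^abs(outer(seq_len(n), seq_len(n), "-"))
    Sinv <- solve(S)
    ld_oracle <- -0.5 * (n * log(2 * pi) + determinant(S)$modulus[1] +
                           drop(t(x) %*% Sinv %*% x))
    expect_equal(ar1_logdensity(x, phi, sigma), ld_oracle,
                 tolerance = 1e-10)
  }
  expect_error(ar1_logdensity(c(0, 0), 1, 0.1), "nonstationary")
})

test_that("forward AR(1) sampling has the right persistence and limits", {
  x <- ar1_sample_forward(0.2, 0.85, 0.1, 1e5, seed = 99)
  expect_equal(cor(x[-1], x[-length(x)]), 0.85, tolerance = 0.02)
  expect_equal(sd(x), 0.1, tolerance = 0.01)
  # white-noise limit
  y <- ar1_sample_forward(0.5, 0, 0.1, 1e5, seed = 100)
  expect_lt(abs(cor(y[-1], y[-length(y)])), 0.02)
  # degenerate: zero stationary sd -> deterministic decay (0 with phi * 0)
  expect_equal(ar1_sample_forward(0, 0.8, 0, 10, seed = 1), rep(0, 10))
  # reproducibility
  expect_identical(ar1_sample_forward(0.1, 0.5, 0.2, 50, seed = 5),
                   ar1_sample_forward(0.1, 0.5, 0.2, 50, seed = 5))
})

test_that("observation transform gives frozen logits and propagates NA", {
  obs <- validate_observations(data.frame(
    country_code = "AAA", marital_group = "MWRA", ref_time = 2000.5,
    source_type = "DHS",
    prev_modern = c(0.3, 0.25, 0.3), prev_traditional = c(0.1, 0.25, NA),
    unmet_any = c(0.12, NA, NA),
    se_modern = 0.01, se_traditional = c(0.01, 0.01, NA), se_unmet = 0.012,
    nonstandard_age = FALSE, subnational_geography = FALSE,
    nonstandard_union_definition = FALSE,
    method_misclassification = c("none", "none", "modern_only_reported")))
  tr <- transform_observation(obs)
  # frozen: qlogis(0.4), qlogis(0.75)
  expect_equal(tr$l_total[1], -0.405465108, tolerance = 1e-8)
  expect_equal(tr$l_ratio[1], 1.098612289, tolerance = 1e-8)
  # unmet share among non-users: 0.12 / 0.6
  expect_equal(tr$l_zstar[1], qlogis(0.2), tolerance = 1e-10)
  # symmetric split -> zero share logit
  expect_equal(tr$l_ratio[2], 0)
  expect_true(is.na(tr$l_zstar[2]))
  # modern-only report: enters as total prevalence, ratio unidentified
  expect_equal(tr$l_total[3], qlogis(0.3))
  expect_true(is.na(tr$l_ratio[3]))
  # delta-method variance of the total on the logit scale
  expect_equal(tr$v_total[1], (0.01^2 + 0.01^2) / (0.4 * 0.6)^2,
               tolerance = 1e-12)
  bad <- obs
  bad$prev_modern[1] <- 0.8
  bad$prev_traditional[1] <- 0.4
  expect_error(transform_observation(bad), "quarantine")
})

test_that("flag biases shift expected observations additively", {
  obs <- validate_observations(data.frame(
    country_code = "AAA", marital_group = "MWRA", ref_time = 2000.5,
    source_type = "DHS", prev_modern = 0.3, prev_traditional = 0.1,
    unmet_any = 0.12, se_modern = 0.01, se_traditional = 0.01,
    se_unmet = 0.012, nonstandard_age = FALSE,
    subnational_geography = FALSE, nonstandard_union_definition = FALSE,
    method_misclassification = "none"))
  latent <- c(l_total = -0.4, l_ratio = 1.1, l_zstar = -1.4)
  meas <- list(bias = c(nonstandard_age = 0.1,
                        subnational_geography = -0.06,
                        misclass_folk_in_modern = 0.12),
               tau = c(DHS = 0.04))
  # no flags -> identity
  expect_equal(expected_observation(latent, obs, meas), latent)
  # one flag on all components
  obs$nonstandard_age <- TRUE
  e1 <- expected_observation(latent, obs, meas)
  expect_equal(unname(e1 - latent), rep(0.1, 3))
  # second flag adds; a ratio-only misclassification hits only the share
  obs$subnational_geography <- TRUE
  obs$method_misclassification <- "folk_in_modern"
  e2 <- expected_observation(latent, obs, meas)
  expect_equal(unname(e2 - latent), c(0.04, 0.04 + 0.12, 0.04))
})

test_that("observation likelihood peaks correctly and adds over data", {
  obs <- validate_observations(data.frame(
    country_code = "AAA", marital_group = "MWRA", ref_time = 2000.5,
    source_type = "DHS", prev_modern = 0.3, prev_traditional = 0.1,
    unmet_any = 0.12, se_modern = 0.01, se_traditional = 0.01,
    se_unmet = 0.012, nonstandard_age = FALSE,
    subnational_geography = FALSE, nonstandard_union_definition = FALSE,
    method_misclassification = "none"))
  tr <- transform_observation(obs)
  expected <- c(l_total = tr$l_total[1], l_ratio = tr$l_ratio[1],
                l_zstar = tr$l_zstar[1])
  m0 <- list(bias = c(), tau = c(DHS = 0))
  # at tau = 0 and zero residual the density is the sampling-only peak
  peak <- sum(dnorm(0, 0, sqrt(c(tr$v_total[1], tr$v_ratio[1],
                                 tr$v_zstar[1])), log = TRUE))
  expect_equal(observation_loglik(tr[1, ], expected, obs[1, ], m0), peak)
  # at zero residual, inflating tau always lowers the density peak
  lls <- vapply(seq(0, 0.5, by = 0.05), function(tau) {
    observation_loglik(tr[1, ], expected, obs[1, ],
                       list(bias = c(), tau = c(DHS = tau)))
  }, numeric(1))
  expect_true(all(diff(lls) < 0))
  # and the total variance is exactly sampling + nonsampling, checked
  # against the explicit normal formula at a displaced residual
  expected_off <- expected + c(1, 1, 1)
  tau <- 0.3
  ll <- observation_loglik(tr[1, ], expected_off, obs[1, ],
                           list(bias = c(), tau = c(DHS = tau)))
  oracle <- sum(dnorm(c(tr$l_total[1], tr$l_ratio[1], tr$l_zstar[1]),
                      unname(expected_off),
                      sqrt(c(tr$v_total[1], tr$v_ratio[1], tr$v_zstar[1]) +
                             tau^2), log = TRUE))
  expect_equal(ll, oracle, tolerance = 1e-12)
  expect_error(observation_loglik(tr[1, ], expected, obs[1, ],
                                  list(bias = c(), tau = c(DHS = -1))),
               "nonnegative")
})

test_that("joint density of a tiny model matches a direct normal oracle", {
  # one country, three grid years, two observations; (eps, y) are jointly
  # normal because the observation mean is linear in the deviations, so the
  # factorized package density must match the full multivariate normal
  years <- c(2000.5, 2001.5, 2002.5)
  pars <- list(p_tilde = 0.8, omega = 0.1, T_mid = 2000, r_tilde = 0.9,
               rho = 0.08, t_r = 1995, alpha = 0.5)
  phi <- 0.8; sigma <- 0.1
  eps <- c(0.05, -0.02, 0.08)
  ltrend <- qlogis(systematic_total_trend(years, pars$p_tilde, pars$omega,
                                          pars$T_mid))
  # two observations at 2000.9 and 2002.1: weights onto adjacent grid years
  rt <- c(2000.9, 2002.1)
  i0 <- c(1, 2)
  w <- 1 - (rt - years[i0])
  v_samp <- c(0.004, 0.006)
  tau <- 0.05
  y <- c(0.9, 1.1)
  # package route: AR(1) density + independent normal likelihood terms
  mu_y <- w * (ltrend[i0] + eps[i0]) + (1 - w) * (ltrend[i0 + 1] + eps[i0 + 1])
  ll_pkg <- ar1_logdensity(eps, phi, sigma) +
    sum(dnorm(y, mu_y, sqrt(v_samp + tau^2), log = TRUE))
  # oracle: full 5-dimensional normal for (eps, y)
  W <- rbind(c(w[1], 1 - w[1], 0), c(0, w[2], 1 - w[2]))
  S_eps <- sigma^2 * phi^abs(outer(1:3, 1:3, "-"))
  S <- rbind(cbind(S_eps, S_eps %*% t(W)),
             cbind(W %*% S_eps,
                   W %*% S_eps %*% t(W) + diag(v_samp + tau^2)))
  m <- c(0, 0, 0, W %*% ltrend)
  x <- c(eps, y)
  ld_oracle <- -0.5 * (5 * log(2 * pi) + determinant(S)$modulus[1] +
                         drop(t(x - m) %*% solve(S) %*% (x - m)))
  expect_equal(ll_pkg, ld_oracle, tolerance = 1e-6)
})

test_that("latent trajectories respect the prevalence decomposition", {
  years <- seq(1970.5, 2030.5, by = 1)
  set.seed(3)
  for (rep in 1:10) {
    pars <- list(p_tilde = runif(1, 0.2, 0.95), omega = runif(1, 0.03, 0.3),
                 T_mid = runif(1, 1980, 2015), r_tilde = runif(1, 0.3, 0.98),
                 rho = runif(1, 0.03, 0.3), t_r = runif(1, 1980, 2010),
                 alpha = rnorm(1, 0, 2))
    st <- latent_trajectories(pars,
                              rnorm(length(years), 0, 0.3),
                              rnorm(length(years), 0, 0.3),
                              rnorm(length(years), 0, 0.3),
                              years, beta1 = -1, beta2 = -0.5)
    expect_true(validate_latent_state(st))
    expect_equal(st$prev_modern + st$prev_traditional, st$P)
    expect_equal(st$unmet_any, (1 - st$P) * st$Zstar)
  }
})
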