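test_that("worlds are reproducible and honour the group0 share", {
  w1 <- generate_world(synthetic_config(seed = 5))
  w2 <- generate_world(synthetic_config(seed = 5))
  expect_identical(w1$truth, w2$truth)
  expect_identical(w1$populations, w2$populations)
  w3 <- generate_world(synthetic_config(seed = 6))
  expect_false(identical(w1$truth$MWRA$params, w3$truth$MWRA$params))
  # no low-activity countries when the share is zero
  w0 <- generate_world(synthetic_config(seed = 5, group0_share = 0))
  expect_equal(sum(w0$countries$sexual_activity_group == "group0_low"), 0)
  # populations: MWRA + UWRA consistency and positivity
  expect_true(all(w1$populations$count >= 0))
})

test_that("low-activity countries get depressed unmarried prevalence and
           unmet levels", {
  w <- default_world()
  g0 <- w$countries$sexual_activity_group == "group0_low"
  p_2019 <- w$truth$UWRA$traj$P[, match(2019.5, w$years)]
  expect_lt(mean(p_2019[g0]), mean(p_2019[!g0]) / 2)
  u_2019 <- (1 - p_2019) * w$truth$UWRA$traj$Zstar[, match(2019.5, w$years)]
  expect_lt(mean(u_2019[g0]), mean(u_2019[!g0]))
})

test_that("hierarchical spread of country parameters matches the
           configured variances", {
  # wide world: many countries per subregion, one subregion per region,
  # so the between-country spread within subregions is directly the
  # country-level sd
  cfg <- synthetic_config(seed = 9, n_regions = 6,
                          n_subregions_per_region = 2,
                          n_countries_per_subregion = 42)
  w <- generate_world(cfg)
  theta <- qlogis(w$truth$MWRA$params$p_tilde)
  within_sd <- sqrt(mean(tapply(theta, w$countries$subregion, var)))
  expect_equal(within_sd, cfg$hyper$level_sd$p_tilde[3], tolerance = 0.15)
  tm <- w$truth$MWRA$params$T_mid
  within_sd_T <- sqrt(mean(tapply(tm, w$countries$subregion, var)))
  expect_equal(within_sd_T, cfg$hyper$level_sd$T_mid[3], tolerance = 0.15)
})

test_that("noiseless generation reproduces the truth at survey times", {
  cfg <- synthetic_config(
    seed = 11, n_regions = 1, n_subregions_per_region = 1,
    n_countries_per_subregion = 6,
    n_eff_meanlog = log(1e12),  # negligible sampling noise
    missing_traditional_prob = 0, missing_unmet_prob = 0,
    missing_se_prob = 0,
    flag_probs = c(nonstandard_age = 0, subnational_geography = 0,
                   nonstandard_union_definition = 0,
                   sterilization_omitted = 0, folk_in_modern = 0,
                   other = 0),
    hyper = list(tau = c(DHS = 0, MICS = 0, PMA = 0, National = 0,
                         Other = 0)))
  w <- generate_world(cfg)
  s <- generate_surveys(w, cfg)
  for (i in seq_len(nrow(s))) {
    mg <- s$marital_group[i]
    ci <- match(s$country_code[i], w$countries$country_code)
    lP <- approx(w$years, qlogis(w$truth[[mg]]$traj$P[ci, ]),
                 s$ref_time[i])$y
    lR <- approx(w$years, qlogis(w$truth[[mg]]$traj$R[ci, ]),
                 s$ref_time[i])$y
    P0 <- plogis(lP); R0 <- plogis(lR)
    expect_equal(s$prev_modern[i], P0 * R0, tolerance = 1e-4)
    expect_equal(s$prev_traditional[i], P0 * (1 - R0), tolerance = 1e-4)
  }
})

test_that("survey noise on the transformed scale is calibrated", {
  cfg <- synthetic_config(seed = 13, n_regions = 5,
                          n_subregions_per_region = 2,
                          n_countries_per_subregion = 15,
                          surveys_per_country_mean = 8,
                          missing_traditional_prob = 0,
                          missing_unmet_prob = 0, missing_se_prob = 0)
  w <- generate_world(cfg)
  s <- generate_surveys(w, cfg)
  tr <- transform_observation(s)
  # standardized residuals of the total component against interpolated truth
  z <- vapply(seq_len(nrow(s)), function(i) {
    mg <- s$marital_group[i]
    ci <- match(s$country_code[i], w$countries$country_code)
    lP <- approx(w$years, qlogis(w$truth[[mg]]$traj$P[ci, ]),
                 s$ref_time[i])$y
    tau <- cfg$hyper$tau[[s$source_type[i]]]
    bias <- 0
    if (s$nonstandard_age[i]) bias <- bias + cfg$hyper$bias[["nonstandard_age"]]
    if (s$subnational_geography[i])
      bias <- bias + cfg$hyper$bias[["subnational_geography"]]
    if (s$nonstandard_union_definition[i])
      bias <- bias + cfg$hyper$bias[["nonstandard_union_definition"]]
    (tr$l_total[i] - lP - bias) / sqrt(tr$v_total[i] + tau^2)
  }, numeric(1))
  expect_gt(length(z), 1000)
  expect_lt(abs(mean(z)), 0.1)
  expect_equal(sd(z), 1, tolerance = 0.1)
  # observation counts per country match the configured mean
  per_country <- table(s$country_code[s$marital_group == "MWRA"])
  expect_equal(mean(per_country), cfg$surveys_per_country_mean,
               tolerance = 0.15)
})

test_that("fixtures round-trip losslessly through the readers", {
  dir <- withr::local_tempdir()
  w <- tiny_world()
  s <- tiny_surveys()
  paths <- write_fixture(w, s, dir)
  fx <- read_fixture(dir)
  expect_equal(fx$manifest$seed, w$config$seed)
  # zero quarantined rows
  expect_equal(attr(fx$observations, "report")$mwra$rows_quarantined, 0)
  expect_equal(attr(fx$observations, "report")$uwra$rows_quarantined, 0)
  # same values (readers add imputation flags; compare shared columns)
  shared <- c("country_code", "marital_group", "ref_time", "source_type",
              "prev_modern", "prev_traditional", "unmet_any")
  orig <- as.data.frame(s)[order(s$marital_group, s$country_code,
                                 s$ref_time), shared]
  back <- as.data.frame(fx$observations)
  back <- back[order(back$marital_group, back$country_code, back$ref_time),
               shared]
  rownames(orig) <- rownames(back) <- NULL
  expect_equal(back, orig, tolerance = 1e-12)
  # checksums in the manifest describe the files on disk
  cs <- unlist(fx$manifest$checksums)
  on_disk <- tools::md5sum(file.path(dir, names(cs)))
  expect_equal(unname(on_disk), unname(cs))
})

test_that("the shipped default fixture matches its manifest and the
           generator", {
  dir <- default_fixture_dir()
  expect_true(nzchar(dir))
  fx <- read_fixture(dir)
  s <- summarize_dataset(fx$observations)
  for (mg in c("MWRA", "UWRA")) {
    expect_equal(
      s$by_indicator$n_obs[s$by_indicator$marital_group == mg &
                             s$by_indicator$indicator == "prevalence"],
      fx$manifest$surveys[[mg]]$n_prevalence_obs)
  }
  # the generator regenerates the identical world from the recorded seed
  w <- default_world()
  expect_equal(nrow(fx$countries), nrow(w$countries))
  expect_equal(fx$countries$sexual_activity_group,
               w$countries$sexual_activity_group)
  pop <- as.data.frame(fx$populations)
  key <- paste(pop$country_code, pop$marital_group, pop$year)
  wpop <- as.data.frame(w$populations)
  wkey <- paste(wpop$country_code, wpop$marital_group, wpop$year)
  expect_equal(pop$count, wpop$count[match(key, wkey)])
})
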