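test_that("the seven indicators satisfy the published arithmetic identities", {
  # global all-women medians for 2019: modern 44.3%, traditional such that
  # unmet-for-modern is 14.2% -> total need 58.5%, SDG 3.7.1 75.7%
  ind <- derive_indicators(percent_to_prop(44.3), 0, percent_to_prop(14.2))
  expect_equal(prop_to_percent(ind$total_demand), 58.5, tolerance = 1e-12)
  expect_equal(round(prop_to_percent(ind$demand_satisfied_modern), 1), 75.7)
  # married/in-union 2019: modern 57.1%, unmet for modern 18.2%
  ind_m <- derive_indicators(percent_to_prop(57.1), 0, percent_to_prop(18.2))
  expect_equal(prop_to_percent(ind_m$total_demand), 75.3, tolerance = 1e-12)
  expect_equal(round(prop_to_percent(ind_m$demand_satisfied_modern), 1), 75.8)
  # decomposed inputs: traditional users carry unmet need for modern methods
  ind2 <- derive_indicators(0.4, 0.1, 0.12)
  expect_equal(ind2$prev_any, 0.5)
  expect_equal(ind2$unmet_modern, 0.22)
  expect_equal(ind2$total_demand, 0.62)
  expect_equal(ind2$total_demand, ind2$prev_modern + ind2$unmet_modern)
  # empty-demand case: everything zero except an undefined SDG ratio
  ind0 <- derive_indicators(0, 0, 0)
  expect_equal(ind0$total_demand, 0)
  expect_true(is.na(ind0$demand_satisfied_modern))
  expect_error(derive_indicators(0.8, 0.3, 0.2), "exceeds 1")
  expect_error(derive_indicators(1.2, 0, 0), "\\[0,1\\]")
})

test_that("indicator identities hold per draw to machine precision", {
  fit <- tiny_fit()
  for (code in fit$countries[1:2]) {
    parts <- lapply(c("prev_any", "prev_modern", "prev_traditional",
                      "unmet_any", "unmet_modern", "total_demand",
                      "demand_satisfied_modern"),
                    function(q) fpest:::country_draws(fit, code, q))
    names(parts) <- c("prev_any", "prev_modern", "prev_traditional",
                      "unmet_any", "unmet_modern", "total_demand",
                      "demand_satisfied_modern")
    expect_equal(parts$prev_any,
                 parts$prev_modern + parts$prev_traditional,
                 tolerance = 1e-15)
    expect_equal(parts$total_demand,
                 parts$prev_any + parts$unmet_any, tolerance = 1e-15)
    expect_equal(parts$total_demand,
                 parts$prev_modern + parts$unmet_modern,
                 tolerance = 1e-15)
    expect_equal(parts$demand_satisfied_modern,
                 parts$prev_modern / parts$total_demand,
                 tolerance = 1e-15)
  }
})

test_that("count transformation is elementwise and mean-consistent", {
  expect_equal(to_counts(0, 5e6), 0)
  expect_equal(to_counts(0.5, 1e7), 5e6)
  set.seed(21)
  draws <- runif(1000)
  pop <- 2.5e6
  counts <- to_counts(draws, pop)
  expect_equal(mean(counts), mean(draws) * pop, tolerance = 1e-12)
  expect_error(to_counts(0.5, NA), "missing population")
  expect_error(to_counts(0.5, -2), "negative")
})

test_that("aggregation sums draws, not summaries", {
  # married 709 million + unmarried 133 million modern users -> 842 million
  # (single-draw degenerate posterior)
  expect_equal(aggregate_draws(list(709e6, 133e6)), 842e6)
  # brute-force loop oracle on 100 draws x 3 countries
  set.seed(31)
  mats <- lapply(1:3, function(i) matrix(runif(100 * 2), 100, 2))
  agg <- aggregate_draws(mats)
  oracle <- matrix(0, 100, 2)
  for (d in 1:100) {
    for (j in 1:2) {
      for (i in 1:3) oracle[d, j] <- oracle[d, j] + mats[[i]][d, j]
    }
  }
  expect_equal(agg, oracle, tolerance = 1e-15)
  # singleton aggregate is the member itself
  expect_identical(aggregate_draws(mats[1]), mats[[1]])
  # order invariance
  expect_equal(aggregate_draws(rev(mats)), agg)
  expect_error(aggregate_draws(list(1:10, 1:9)), "mismatch")
  # median of sums differs from sum of medians for skewed members, and the
  # pipeline must report the former
  a <- c(0.1, 0.2, 0.9)
  b <- c(0.9, 0.2, 0.1)  # anticorrelated members
  s_of_m <- median(a) + median(b)  # 0.4
  m_of_s <- unname(summarize_draws(aggregate_draws(list(a, b)))["median"])
  expect_false(isTRUE(all.equal(s_of_m, m_of_s)))
  expect_equal(m_of_s, 1.0)
})

test_that("posterior summaries use type-7 quantiles", {
  expect_equal(summarize_draws(rep(3.3, 50)),
               c(median = 3.3, lower95 = 3.3, upper95 = 3.3))
  x <- sample(1:1000)
  s <- summarize_draws(x)
  xs <- sort(x)
  # brute-force type-7: linear interpolation between order statistics
  q_oracle <- function(p) {
    h <- (length(xs) - 1) * p + 1
    xs[floor(h)] + (h - floor(h)) * (xs[ceiling(h)] - xs[floor(h)])
  }
  expect_equal(unname(s), c(q_oracle(0.5), q_oracle(0.025), q_oracle(0.975)))
  expect_error(summarize_draws(numeric(0)), "no draws")
  m <- cbind(a = 1:100, b = 101:200)
  sm <- summarize_draws(m)
  expect_equal(sm$median, c(50.5, 150.5))
})

test_that("changes are computed within trajectory with counting-oracle PPI", {
  set.seed(41)
  start <- rnorm(1000, 0.3, 0.05)
  end <- start + rnorm(1000, 0.02, 0.03)
  ch <- change_with_ppi(start, end)
  expect_equal(ch$ppi, sum(end - start > 0) / 1000)
  expect_equal(ch$ppd, 1 - ch$ppi)
  expect_equal(ch$median, median(end - start))
  # all draws increase -> PPI = 1
  expect_equal(change_with_ppi(start, start + 0.1)$ppi, 1)
  # exactly symmetric changes -> PPI = 0.5
  sym <- c(rep(-1, 500), rep(1, 500))
  expect_equal(change_with_ppi(rep(0, 1000), sym)$ppi, 0.5)
  expect_error(change_with_ppi(rnorm(10), rnorm(9)), "unpaired")
})

test_that("results tables are well-formed with draw-wise world aggregates", {
  fit <- extrapolate(tiny_fit(), horizon_end = 2030.5, seed = 3)
  w <- tiny_world()
  tab <- indicator_table(fit, populations = w$populations,
                         years = c(1990, 2019, 2030),
                         aggregates = c("world", "region"),
                         countries = w$countries)
  expect_true(all(tab$lower95 <= tab$median + 1e-12))
  expect_true(all(tab$median <= tab$upper95 + 1e-12))
  pct <- tab[tab$scale == "percent", ]
  expect_true(all(pct$median >= 0 & pct$median <= 100))
  expect_true(all(tab$median[tab$scale == "count"] >= 0))
  expect_true("World" %in% tab$unit)
  expect_true(all(unique(w$countries$region) %in% tab$unit))
  # world count median equals the draw-wise sum oracle for one cell
  pop <- fpest:::population_matrix(w$populations, "MWRA", fit$countries,
                                   2019.5)
  yi <- match(2019.5, fit$years)
  P <- fpest:::pool_chains(fit$P)
  R <- fpest:::pool_chains(fit$R)
  oracle <- summarize_draws(colSums(P[, yi, ] * R[, yi, ] * as.vector(pop)))
  got <- tab[tab$unit == "World" & tab$year == 2019 &
               tab$indicator == "prev_modern" & tab$scale == "count", ]
  expect_equal(got$median, unname(oracle["median"]), tolerance = 1e-12)
})

test_that("all-women results combine the marital groups on the count scale", {
  # degenerate single-draw check of the combination arithmetic via a tiny
  # hand-built draws pair
  fit <- tiny_fit()
  w <- tiny_world()
  tab <- wra_indicator_table(fit, fit, w$populations, years = 2010,
                             aggregates = "world")
  expect_true(all(tab$marital_group == "WRA"))
  # with identical group draws, the WRA percentage is the population-share
  # weighted mix of identical proportions, i.e. the proportion itself
  P <- fpest:::pool_chains(fit$P)
  yi <- match(2010.5, fit$years)
  pop_m <- fpest:::population_matrix(w$populations, "MWRA", fit$countries,
                                     2010.5)
  pop_u <- fpest:::population_matrix(w$populations, "UWRA", fit$countries,
                                     2010.5)
  ci <- 1
  mix <- summarize_draws(P[ci, yi, ])["median"]
  got <- tab[tab$unit == fit$countries[ci] & tab$indicator == "prev_any" &
               tab$scale == "percent", ]
  expect_equal(got$median, unname(prop_to_percent(mix)), tolerance = 1e-12)
  # counts: WRA = MWRA + UWRA within draw
  gotc <- tab[tab$unit == fit$countries[ci] & tab$indicator == "prev_any" &
                tab$scale == "count", ]
  oracle <- summarize_draws(P[ci, yi, ] * (pop_m[ci, 1] + pop_u[ci, 1]))
  expect_equal(gotc$median, unname(oracle["median"]), tolerance = 1e-12)
})

test_that("published rounding: percentages to 1 decimal, counts to
           millions", {
  tab <- data.frame(unit = "World", marital_group = "WRA", year = 2019,
                    indicator = "prev_modern",
                    scale = c("percent", "count"),
                    median = c(44.3456, 842.4e6),
                    lower95 = c(42.111, 800.2e6),
                    upper95 = c(46.999, 892.7e6))
  r <- round_results(tab)
  expect_equal(r$median, c(44.3, 842))
  expect_equal(r$upper95, c(47.0, 893))
  expect_equal(r$scale, c("percent", "count_millions"))
})
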