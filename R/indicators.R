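# The seven reported indicators, count-scale transformation, draw-wise
# aggregation, posterior summaries, and changes with posterior
# probabilities of increase/decrease.

#' Derive the seven family-planning indicators
#'
#' From the prevalence decomposition (modern, traditional, unmet need for
#' any method, all proportions summing to at most 1):
#' `prev_any = modern + traditional`;
#' `unmet_modern = unmet_any + traditional` (traditional-method users count
#' as having unmet need for modern methods);
#' `total_demand = prev_any + unmet_any = prev_modern + unmet_modern`;
#' `demand_satisfied_modern = prev_modern / total_demand` (undefined, NA,
#' when total demand is zero). Vectorized; inputs and outputs on the
#' proportion scale.
#'
#' @param prev_modern,prev_traditional,unmet_any proportions in \[0,1\]
#'   with `prev_modern + prev_traditional + unmet_any <= 1`.
#' @return data frame with columns `prev_any`, `prev_modern`,
#'   `prev_traditional`, `unmet_any`, `unmet_modern`, `total_demand`,
#'   `demand_satisfied_modern`.
#' @export
derive_indicators <- function(prev_modern, prev_traditional, unmet_any) {
  n <- max(length(prev_modern), length(prev_traditional), length(unmet_any))
  m <- rep_len(prev_modern, n)
  tr <- rep_len(prev_traditional, n)
  u <- rep_len(unmet_any, n)
  chk <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!chk(m) || !chk(tr) || !chk(u)) stop("inputs must be in [0,1]")
  s <- m + tr + u
  if (any(!is.na(s) & s > 1 + 1e-9)) {
    stop("prev_modern + prev_traditional + unmet_any exceeds 1")
  }
  prev_any <- m + tr
  unmet_modern <- u + tr
  total_demand <- prev_any + u
  dsm <- ifelse(!is.na(total_demand) & total_demand > 0, m / total_demand,
                NA_real_)
  data.frame(prev_any = prev_any, prev_modern = m, prev_traditional = tr,
             unmet_any = u, unmet_modern = unmet_modern,
             total_demand = total_demand, demand_satisfied_modern = dsm)
}

#' Transform proportion draws to counts of women
#'
#' Elementwise multiplication of posterior proportion draws by the
#' population of women 15-49 in the relevant marital group; every draw is
#' scaled, so posterior uncertainty propagates to the count scale.
#'
#' @param proportion numeric vector/array of proportion draws.
#' @param population population count(s); either a scalar or an object
#'   conforming to the draws' year dimension.
#' @return count draws, same shape as `proportion`.
#' @export
to_counts <- function(proportion, population) {
  if (anyNA(population)) stop("missing population counts")
  if (any(population < 0)) stop("negative population counts")
  proportion * population
}

#' Aggregate count draws across members
#'
#' Draw-wise summation over member countries (or marital groups), which
#' preserves cross-member correlation; the aggregate percentage is the
#' summed count divided by the summed population within each draw.
#'
#' @param count_draws list of draw matrices/vectors with identical draw
#'   indexing, or a 3-d array (member x ... x draw).
#' @return the draw-wise sum.
#' @export
aggregate_draws <- function(count_draws) {
  if (is.list(count_draws)) {
    dims <- lapply(count_draws, function(x) dim(x) %||% length(x))
    if (length(unique(vapply(dims, paste, collapse = "x",
                             FUN.VALUE = ""))) != 1) {
      stop("draw-count mismatch across aggregate members")
    }
    Reduce(`+`, count_draws)
  } else if (is.array(count_draws) && length(dim(count_draws)) >= 2) {
    apply(count_draws, seq_along(dim(count_draws))[-1], sum)
  } else {
    count_draws
  }
}

#' Posterior median and 95% uncertainty interval
#'
#' Quantiles at 0.5, 0.025 and 0.975 using linear interpolation between
#' order statistics (the default type-7 convention, fixed for
#' reproducibility).
#'
#' @param draws numeric vector (>= 1 draw) or matrix (draws x units).
#' @return for a vector, named vector (`median`, `lower95`, `upper95`);
#'   for a matrix, a data frame with one row per column.
#' @export
summarize_draws <- function(draws) {
  if (is.matrix(draws)) {
    out <- t(apply(draws, 2, summarize_draws))
    return(data.frame(median = out[, "median"], lower95 = out[, "lower95"],
                      upper95 = out[, "upper95"]))
  }
  if (length(draws) < 1 || all(is.na(draws))) stop("no draws to summarize")
  q <- stats::quantile(draws, c(0.5, 0.025, 0.975), names = FALSE,
                       type = 7, na.rm = FALSE)
  c(median = q[1], lower95 = q[2], upper95 = q[3])
}

#' Change over a period with posterior probability of an increase
#'
#' Changes are computed within trajectory (draw-paired start and end) and
#' only then summarized, which accounts for the correlation between the
#' start- and end-year estimates. PPI is the fraction of draws with a
#' positive change; PPD = 1 - PPI.
#'
#' @param draws_start,draws_end draw vectors paired by trajectory (equal
#'   length, same chain/iteration order).
#' @return list: `median`, `lower95`, `upper95` (of the change), `ppi`,
#'   `ppd`.
#' @export
change_with_ppi <- function(draws_start, draws_end) {
  if (length(draws_start) != length(draws_end)) {
    stop("unpaired draws: start and end must have identical draw indexing")
  }
  ch <- draws_end - draws_start
  s <- summarize_draws(ch)
  list(median = unname(s["median"]), lower95 = unname(s["lower95"]),
       upper95 = unname(s["upper95"]),
       ppi = mean(ch > 0), ppd = mean(ch <= 0))
}

# draws of one indicator for one country as [year x draw] matrix
country_draws <- function(draws, country_code, what = "prev_modern") {
  ci <- match(country_code, draws$countries)
  if (is.na(ci)) stop("country not in draws: ", country_code)
  P <- pool_chains(draws$P)[ci, , ]
  R <- pool_chains(draws$R)[ci, , ]
  Z <- pool_chains(draws$Z)[ci, , ]
  switch(what,
         P = P, R = R, Zstar = Z,
         prev_any = P,
         prev_modern = P * R,
         prev_traditional = P * (1 - R),
         unmet_any = (1 - P) * Z,
         unmet_modern = (1 - P) * Z + P * (1 - R),
         total_demand = P + (1 - P) * Z,
         demand_satisfied_modern = (P * R) / (P + (1 - P) * Z),
         stop("unknown quantity: ", what))
}

indicator_names <- function() {
  c("prev_any", "prev_modern", "prev_traditional", "unmet_any",
    "unmet_modern", "total_demand", "demand_satisfied_modern")
}

# population count for country x grid-year (years matched on floor())
population_matrix <- function(populations, marital_group, country_codes,
                              years) {
  pop <- as.data.frame(populations)
  pop <- pop[pop$marital_group == marital_group, , drop = FALSE]
  out <- matrix(NA_real_, length(country_codes), length(years),
                dimnames = list(country_codes, NULL))
  key <- paste(pop$country_code, pop$year)
  want <- outer(country_codes, floor(years), paste)
  out[] <- pop$count[match(want, key)]
  if (anyNA(out)) {
    miss <- which(is.na(out), arr.ind = TRUE)
    stop("missing population for country-years: ",
         paste(utils::head(paste(country_codes[miss[, 1]],
                                 floor(years)[miss[, 2]]), 5),
               collapse = ", "))
  }
  out
}

#' Build an indicator results table from posterior draws
#'
#' Summarizes the seven indicators per country and year as medians with
#' 95% uncertainty intervals, on the percentage scale and optionally (when
#' populations are supplied) on the count scale, and appends draw-wise
#' aggregates (world plus any grouping columns requested).
#'
#' @param draws `fp_draws` (possibly extrapolated).
#' @param populations population table (required for counts/aggregates).
#' @param years calendar years to report (matched to mid-year grid points);
#'   defaults to all years in the draws.
#' @param aggregates character: which aggregate levels to add; any of
#'   `"world"`, `"region"`, `"subregion"`. Aggregation is draw-wise on the
#'   count scale; aggregate percentages divide by the summed population.
#' @param countries country table used to map aggregate membership.
#' @return data frame in the results schema (`unit`, `marital_group`,
#'   `year`, `indicator`, `scale`, `median`, `lower95`, `upper95`).
#' @export
indicator_table <- function(draws, populations = NULL, years = NULL,
                            aggregates = "world", countries = NULL) {
  yr_grid <- draws$years
  if (is.null(years)) years <- floor(yr_grid)
  sel <- match(years + 0.5, yr_grid)
  if (anyNA(sel)) stop("years outside the draw grid: ",
                       paste(years[is.na(sel)], collapse = ", "))
  codes <- draws$countries
  mg <- draws$marital_group
  P <- pool_chains(draws$P)[, sel, , drop = FALSE]
  R <- pool_chains(draws$R)[, sel, , drop = FALSE]
  Z <- pool_chains(draws$Z)[, sel, , drop = FALSE]
  ind <- list(
    prev_any = P,
    prev_modern = P * R,
    prev_traditional = P * (1 - R),
    unmet_any = (1 - P) * Z,
    unmet_modern = (1 - P) * Z + P * (1 - R),
    total_demand = P + (1 - P) * Z,
    demand_satisfied_modern = (P * R) / (P + (1 - P) * Z))
  rows <- list()
  emit <- function(unit, year, indicator, scale, draws_vec) {
    s <- summarize_draws(draws_vec)
    rows[[length(rows) + 1]] <<- data.frame(
      unit = unit, marital_group = mg, year = year, indicator = indicator,
      scale = scale, median = unname(s["median"]),
      lower95 = unname(s["lower95"]), upper95 = unname(s["upper95"]),
      stringsAsFactors = FALSE)
  }
  pop <- if (!is.null(populations)) {
    population_matrix(populations, mg, codes, yr_grid[sel])
  }
  for (ci in seq_along(codes)) {
    for (yi in seq_along(sel)) {
      for (nm in indicator_names()) {
        v <- ind[[nm]][ci, yi, ]
        emit(codes[ci], years[yi], nm, "percent", prop_to_percent(v))
        if (!is.null(pop) && nm != "demand_satisfied_modern") {
          emit(codes[ci], years[yi], nm, "count",
               to_counts(v, pop[ci, yi]))
        }
      }
    }
  }
  if (!is.null(pop) && length(aggregates) > 0) {
    agg_members <- list()
    if ("world" %in% aggregates) agg_members$World <- codes
    for (lv in intersect(aggregates, c("region", "subregion"))) {
      if (is.null(countries)) stop("aggregates by ", lv,
                                   " need the countries table")
      for (g in unique(countries[[lv]])) {
        agg_members[[g]] <-
          intersect(codes, countries$country_code[countries[[lv]] == g])
      }
    }
    for (anm in names(agg_members)) {
      mem <- match(agg_members[[anm]], codes)
      for (yi in seq_along(sel)) {
        pop_sum <- sum(pop[mem, yi])
        for (nm in setdiff(indicator_names(), "demand_satisfied_modern")) {
          cnt <- aggregate_draws(lapply(mem, function(ci)
            to_counts(ind[[nm]][ci, yi, ], pop[ci, yi])))
          emit(anm, years[yi], nm, "count", cnt)
          emit(anm, years[yi], nm, "percent",
               prop_to_percent(cnt / pop_sum))
        }
        dsm_cnt_m <- aggregate_draws(lapply(mem, function(ci)
          to_counts(ind$prev_modern[ci, yi, ], pop[ci, yi])))
        dsm_cnt_d <- aggregate_draws(lapply(mem, function(ci)
          to_counts(ind$total_demand[ci, yi, ], pop[ci, yi])))
        emit(anm, years[yi], "demand_satisfied_modern", "percent",
             prop_to_percent(dsm_cnt_m / dsm_cnt_d))
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$unit, out$year, out$indicator), , drop = FALSE]
}

#' Combine MWRA and UWRA draws into all-women (WRA) results
#'
#' Married and unmarried estimates are combined on the count scale, draw
#' by draw, per country and year; all-women percentages divide the summed
#' counts by the summed population. Draw pairing across the two fits is by
#' retained-draw index.
#'
#' @param draws_mwra,draws_uwra `fp_draws` for the two marital groups on
#'   identical year grids and country sets.
#' @param populations population table covering both groups.
#' @param years calendar years to report.
#' @param aggregates,countries as in [indicator_table()].
#' @return results-schema data frame with `marital_group = "WRA"`.
#' @export
wra_indicator_table <- function(draws_mwra, draws_uwra, populations,
                                years = NULL, aggregates = "world",
                                countries = NULL) {
  stopifnot(identical(draws_mwra$countries, draws_uwra$countries),
            identical(draws_mwra$years, draws_uwra$years))
  nd1 <- n_draws(draws_mwra)
  nd2 <- n_draws(draws_uwra)
  nd <- min(nd1, nd2)
  yr_grid <- draws_mwra$years
  if (is.null(years)) years <- floor(yr_grid)
  sel <- match(years + 0.5, yr_grid)
  if (anyNA(sel)) stop("years outside the draw grid")
  codes <- draws_mwra$countries
  get_ind <- function(draws) {
    P <- pool_chains(draws$P)[, sel, seq_len(nd), drop = FALSE]
    R <- pool_chains(draws$R)[, sel, seq_len(nd), drop = FALSE]
    Z <- pool_chains(draws$Z)[, sel, seq_len(nd), drop = FALSE]
    list(prev_any = P, prev_modern = P * R, prev_traditional = P * (1 - R),
         unmet_any = (1 - P) * Z,
         unmet_modern = (1 - P) * Z + P * (1 - R),
         total_demand = P + (1 - P) * Z)
  }
  ind_m <- get_ind(draws_mwra)
  ind_u <- get_ind(draws_uwra)
  pop_m <- population_matrix(populations, "MWRA", codes, yr_grid[sel])
  pop_u <- population_matrix(populations, "UWRA", codes, yr_grid[sel])
  rows <- list()
  emit <- function(unit, year, indicator, scale, v) {
    s <- summarize_draws(v)
    rows[[length(rows) + 1]] <<- data.frame(
      unit = unit, marital_group = "WRA", year = year,
      indicator = indicator, scale = scale, median = unname(s["median"]),
      lower95 = unname(s["lower95"]), upper95 = unname(s["upper95"]),
      stringsAsFactors = FALSE)
  }
  units <- list()
  if ("world" %in% aggregates) units$World <- seq_along(codes)
  for (ci in seq_along(codes)) units[[codes[ci]]] <- ci
  for (lv in intersect(aggregates, c("region", "subregion"))) {
    for (g in unique(countries[[lv]])) {
      units[[g]] <- which(codes %in%
                            countries$country_code[countries[[lv]] == g])
    }
  }
  for (unm in names(units)) {
    mem <- units[[unm]]
    for (yi in seq_along(sel)) {
      pop_tot <- sum(pop_m[mem, yi]) + sum(pop_u[mem, yi])
      counts <- list()
      for (nm in names(ind_m)) {
        cnt <- aggregate_draws(lapply(mem, function(ci) {
          to_counts(ind_m[[nm]][ci, yi, ], pop_m[ci, yi]) +
            to_counts(ind_u[[nm]][ci, yi, ], pop_u[ci, yi])
        }))
        counts[[nm]] <- cnt
        emit(unm, years[yi], nm, "count", cnt)
        emit(unm, years[yi], nm, "percent",
             prop_to_percent(cnt / pop_tot))
      }
      emit(unm, years[yi], "demand_satisfied_modern", "percent",
           prop_to_percent(counts$prev_modern / counts$total_demand))
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$unit, out$year, out$indicator), , drop = FALSE]
}

#' Round a results table the way the published tables print
#'
#' Percentages to one decimal; counts to whole millions (reported in
#' millions).
#'
#' @param table results-schema data frame.
#' @return the table with `median`, `lower95`, `upper95` rounded (counts
#'   also rescaled to millions, with `scale` set to `count_millions`).
#' @export
round_results <- function(table) {
  num <- c("median", "lower95", "upper95")
  pct <- table$scale == "percent"
  table[pct, num] <- round(table[pct, num], 1)
  cnt <- table$scale == "count"
  table[cnt, num] <- round(table[cnt, num] / 1e6)
  table$scale[cnt] <- "count_millions"
  table
}
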