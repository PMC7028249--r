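# Reading, validation and writing of the tabular artifacts: survey
# observations, country classification records, population counts by marital
# group, and results tables.

#' Canonical observation schema
#'
#' Column names expected in an observation CSV. `ref_time` may be supplied
#' directly or derived from `start_year`/`end_year`.
#'
#' @return character vector of canonical column names.
#' @export
observation_schema <- function() {
  c("country_code", "marital_group", "start_year", "end_year", "ref_time",
    "source_type", "prev_modern", "prev_traditional", "unmet_any",
    "se_modern", "se_traditional", "se_unmet",
    "nonstandard_age", "subnational_geography",
    "nonstandard_union_definition", "method_misclassification")
}

# Midpoint-of-fieldwork reference time: start + (end - start)/2 when both
# given, single year -> year + 0.5.
compute_ref_time <- function(start_year, end_year) {
  end_year <- ifelse(is.na(end_year), start_year, end_year)
  ifelse(is.na(start_year), NA_real_,
         ifelse(end_year > start_year,
                start_year + (end_year - start_year) / 2,
                start_year + 0.5))
}

as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("true", "t", "1", "yes", "y")
  out[is.na(x) | x == ""] <- FALSE
  out
}

#' Read a survey-observation table
#'
#' Reads a CSV of survey estimates (one row per survey x marital group),
#' validates each row, quarantines rows that violate the observation
#' invariants, nudges boundary values of exactly 0 or 1 inward, and imputes
#' missing standard errors as the median SE of the same source type and
#' marital group. No row is silently dropped: rows in = rows accepted +
#' rows quarantined.
#'
#' @param path CSV file with a header row; see [observation_schema()].
#' @param marital_group optional filter, `"MWRA"` or `"UWRA"`; `NULL` keeps
#'   all rows.
#' @param countries optional country table (e.g. from
#'   [read_country_records()]); rows with a country code absent from it are
#'   quarantined.
#' @param ess assumed effective sample size used to nudge proportions of
#'   exactly 0 or 1 inward by `0.5/ess` before any logit transformation.
#' @param aliases optional named character vector mapping file column names
#'   to canonical schema names, for supplementary files whose headers drift.
#' @return a data frame of accepted observations (class `fp_observations`)
#'   with attributes `quarantine` (quarantined rows plus a `reason` column)
#'   and `report` (validation report list, see
#'   [write_validation_report()]).
#' @export
read_survey_observations <- function(path, marital_group = NULL,
                                     countries = NULL, ess = 1000,
                                     aliases = NULL) {
  if (!file.exists(path)) stop("observation file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(aliases)) {
    hit <- names(raw) %in% names(aliases)
    names(raw)[hit] <- unname(aliases[names(raw)[hit]])
  }
  required <- c("country_code", "source_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0 ||
      !any(c("ref_time", "start_year") %in% names(raw))) {
    stop("observation file misses required columns: ",
         paste(c(missing_cols,
                 if (!any(c("ref_time", "start_year") %in% names(raw)))
                   "ref_time|start_year"), collapse = ", "))
  }
  for (col in setdiff(observation_schema(), names(raw))) raw[[col]] <- NA
  if (!is.null(marital_group)) {
    marital_group <- match.arg(marital_group, marital_groups())
    raw <- raw[!is.na(raw$marital_group) & raw$marital_group == marital_group,
               , drop = FALSE]
  }
  n_in <- nrow(raw)
  if (n_in == 0) {
    out <- empty_observations()
    attr(out, "quarantine") <- cbind(empty_observations(),
                                     reason = character(0))
    attr(out, "report") <- list(rows_in = 0L, rows_accepted = 0L,
                                rows_quarantined = 0L, reasons = list(),
                                n_boundary_nudged = 0L, n_se_imputed = 0L)
    return(out)
  }
  obs <- data.frame(
    country_code = trimws(as.character(raw$country_code)),
    marital_group = as.character(raw$marital_group),
    ref_time = ifelse(!is.na(suppressWarnings(as.numeric(raw$ref_time))),
                      suppressWarnings(as.numeric(raw$ref_time)),
                      compute_ref_time(
                        suppressWarnings(as.numeric(raw$start_year)),
                        suppressWarnings(as.numeric(raw$end_year)))),
    source_type = as.character(raw$source_type),
    prev_modern = suppressWarnings(as.numeric(raw$prev_modern)),
    prev_traditional = suppressWarnings(as.numeric(raw$prev_traditional)),
    unmet_any = suppressWarnings(as.numeric(raw$unmet_any)),
    se_modern = suppressWarnings(as.numeric(raw$se_modern)),
    se_traditional = suppressWarnings(as.numeric(raw$se_traditional)),
    se_unmet = suppressWarnings(as.numeric(raw$se_unmet)),
    nonstandard_age = as_flag(raw$nonstandard_age),
    subnational_geography = as_flag(raw$subnational_geography),
    nonstandard_union_definition = as_flag(raw$nonstandard_union_definition),
    method_misclassification = ifelse(
      is.na(raw$method_misclassification) |
        raw$method_misclassification == "", "none",
      as.character(raw$method_misclassification)),
    stringsAsFactors = FALSE
  )
  validate_observations(obs, countries = countries, ess = ess, rows_in = n_in)
}

empty_observations <- function() {
  cols <- c("country_code", "marital_group", "ref_time", "source_type",
            "prev_modern", "prev_traditional", "unmet_any",
            "se_modern", "se_traditional", "se_unmet",
            "nonstandard_age", "subnational_geography",
            "nonstandard_union_definition", "method_misclassification")
  out <- as.data.frame(stats::setNames(replicate(length(cols), logical(0),
                                                 simplify = FALSE), cols))
  class(out) <- c("fp_observations", "data.frame")
  out
}

#' Validate an in-memory observation table
#'
#' Applies the row-level invariants of the observation schema: quarantines
#' invalid rows with a reason, nudges boundary proportions, imputes missing
#' standard errors, and attaches a validation report. Used by
#' [read_survey_observations()] and directly on generated observations.
#'
#' @param obs data frame with the canonical observation columns.
#' @param countries optional country table; unknown codes are quarantined.
#' @param ess assumed effective sample size for the boundary nudge.
#' @param rows_in number of raw input rows (defaults to `nrow(obs)`).
#' @return `fp_observations` data frame; see [read_survey_observations()].
#' @export
validate_observations <- function(obs, countries = NULL, ess = 1000,
                                  rows_in = nrow(obs)) {
  reason <- character(nrow(obs))
  add_reason <- function(reason, bad, msg) {
    ifelse(bad & !is.na(bad), paste0(reason, ifelse(reason == "", "", "; "),
                                     msg), reason)
  }
  bad_group <- !(obs$marital_group %in% marital_groups())
  reason <- add_reason(reason, bad_group, "unknown marital_group")
  if (!is.null(countries)) {
    reason <- add_reason(reason,
                         !(obs$country_code %in% countries$country_code),
                         "unknown country code")
  }
  bad_src <- !(obs$source_type %in% source_types())
  reason <- add_reason(reason, bad_src, "unknown source_type")
  bad_mis <- !(obs$method_misclassification %in% misclassification_levels())
  reason <- add_reason(reason, bad_mis, "unknown method_misclassification")
  all_missing <- is.na(obs$prev_modern) & is.na(obs$prev_traditional) &
    is.na(obs$unmet_any)
  reason <- add_reason(reason, all_missing, "no indicator value present")
  in01 <- function(x) is.na(x) | (x >= 0 & x <= 1)
  reason <- add_reason(reason, !in01(obs$prev_modern) |
                         !in01(obs$prev_traditional) | !in01(obs$unmet_any),
                       "proportion outside [0,1]")
  sum_prev <- obs$prev_modern + obs$prev_traditional
  reason <- add_reason(reason, !is.na(sum_prev) & sum_prev > 1,
                       "prev_modern + prev_traditional > 1")
  tot <- sum_prev + obs$unmet_any
  reason <- add_reason(reason, !is.na(tot) & tot > 1,
                       "prevalence + unmet_any > 1")
  reason <- add_reason(reason, is.na(obs$ref_time) | obs$ref_time < 1950 |
                         obs$ref_time >= 2020,
                       "ref_time outside [1950, 2020)")
  se_ok <- function(x) is.na(x) | x >= 0
  reason <- add_reason(reason, !se_ok(obs$se_modern) |
                         !se_ok(obs$se_traditional) | !se_ok(obs$se_unmet),
                       "negative standard error")

  quarantine <- obs[reason != "", , drop = FALSE]
  if (nrow(quarantine) > 0) quarantine$reason <- reason[reason != ""]
  else quarantine$reason <- character(0)
  acc <- obs[reason == "", , drop = FALSE]
  rownames(acc) <- NULL

  # boundary nudge (0/1 -> interior) before any transformation downstream
  n_nudged <- 0L
  for (col in c("prev_modern", "prev_traditional", "unmet_any")) {
    at_bound <- !is.na(acc[[col]]) & (acc[[col]] <= 0 | acc[[col]] >= 1)
    n_nudged <- n_nudged + sum(at_bound)
    acc[[col]] <- nudge_boundary(acc[[col]], ess = ess)
  }

  # missing-SE imputation: median of same source_type x marital_group,
  # falling back to the marital-group median, then a weak default
  n_imputed <- 0L
  for (comp in c("modern", "traditional", "unmet")) {
    val <- acc[[paste0(ifelse(comp == "unmet", "unmet_any",
                              paste0("prev_", comp)))]]
    se_col <- paste0("se_", comp)
    need <- !is.na(val) & is.na(acc[[se_col]])
    flag_col <- paste0(se_col, "_imputed")
    acc[[flag_col]] <- FALSE
    if (any(need)) {
      key <- interaction(acc$source_type, acc$marital_group, drop = FALSE)
      med_by <- tapply(acc[[se_col]], key, stats::median, na.rm = TRUE)
      imp <- med_by[as.character(key[need])]
      imp[is.na(imp)] <- stats::median(acc[[se_col]], na.rm = TRUE)
      imp[is.na(imp)] <- 0.03
      acc[[se_col]][need] <- as.numeric(imp)
      acc[[flag_col]][need] <- TRUE
      n_imputed <- n_imputed + sum(need)
    }
  }

  stopifnot(nrow(obs) == nrow(acc) + nrow(quarantine))
  report <- list(
    rows_in = as.integer(rows_in),
    rows_accepted = nrow(acc),
    rows_quarantined = nrow(quarantine),
    reasons = as.list(table(quarantine$reason)),
    n_boundary_nudged = as.integer(n_nudged),
    n_se_imputed = as.integer(n_imputed)
  )
  class(acc) <- c("fp_observations", "data.frame")
  attr(acc, "quarantine") <- quarantine
  attr(acc, "report") <- report
  acc
}

#' Write a JSON validation report
#'
#' @param obs `fp_observations` object carrying a `report` attribute.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
write_validation_report <- function(obs, path) {
  report <- attr(obs, "report")
  if (is.null(report)) stop("object carries no validation report")
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Summarize an observation compilation
#'
#' Counts observations and countries per indicator and marital group, the
#' share of countries with pre-1990 data, and how many countries have
#' married-women prevalence data but no unmarried-women prevalence data.
#' A country counts toward an indicator if at least one of its observations
#' carries that indicator; counts are invariant to row order.
#'
#' @param observations `fp_observations` (may mix marital groups).
#' @return list of class `fp_dataset_summary` with elements `by_indicator`
#'   (data frame: marital_group, indicator, n_obs, n_countries,
#'   share_countries_pre1990), `n_prevalence_obs_total` (both groups
#'   combined), and `n_countries_mwra_prev_no_uwra`.
#' @export
summarize_dataset <- function(observations) {
  obs <- as.data.frame(observations)
  has_prev <- !is.na(obs$prev_modern) | !is.na(obs$prev_traditional)
  has_unmet <- !is.na(obs$unmet_any)
  rows <- list()
  for (mg in marital_groups()) {
    for (ind in c("prevalence", "unmet")) {
      sel <- obs$marital_group == mg &
        (if (ind == "prevalence") has_prev else has_unmet)
      ctry <- unique(obs$country_code[sel])
      pre90 <- unique(obs$country_code[sel & obs$ref_time < 1990])
      rows[[paste(mg, ind)]] <- data.frame(
        marital_group = mg, indicator = ind,
        n_obs = sum(sel), n_countries = length(ctry),
        share_countries_pre1990 =
          if (length(ctry) > 0) length(pre90) / length(ctry) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  by_ind <- do.call(rbind, rows)
  rownames(by_ind) <- NULL
  mwra_prev <- unique(obs$country_code[obs$marital_group == "MWRA" & has_prev])
  uwra_prev <- unique(obs$country_code[obs$marital_group == "UWRA" & has_prev])
  out <- list(
    by_indicator = by_ind,
    n_prevalence_obs_total = sum(has_prev),
    n_countries_mwra_prev_no_uwra = length(setdiff(mwra_prev, uwra_prev))
  )
  class(out) <- "fp_dataset_summary"
  out
}

#' @export
print.fp_dataset_summary <- function(x, ...) {
  cat("Survey compilation summary\n")
  print(x$by_indicator, row.names = FALSE)
  cat("prevalence observations (both marital groups):",
      x$n_prevalence_obs_total, "\n")
  cat("countries with MWRA prevalence data but no UWRA prevalence data:",
      x$n_countries_mwra_prev_no_uwra, "\n")
  invisible(x)
}

#' Read a country classification table
#'
#' @param path CSV with columns `country_code`, `name`, `subregion`,
#'   `region`, and optionally `income_group`, `sexual_activity_group`,
#'   `group_assignment_source`, `proportion_sexually_active`,
#'   `attitude_indicator`, `religiosity_indicator`, `group_override`.
#' @return data frame of class `fp_countries`.
#' @export
read_country_records <- function(path) {
  if (!file.exists(path)) stop("country file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country_code", "name", "subregion", "region")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("country file misses columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(raw$country_code) > 0) {
    stop("duplicated country codes: ",
         paste(unique(raw$country_code[duplicated(raw$country_code)]),
               collapse = ", "))
  }
  # a subregion must sit inside exactly one region
  sr <- unique(raw[, c("subregion", "region")])
  dup <- sr$subregion[duplicated(sr$subregion)]
  if (length(dup) > 0) {
    stop("subregion mapped to multiple regions: ", paste(dup, collapse = ", "))
  }
  class(raw) <- c("fp_countries", "data.frame")
  raw
}

#' Read population counts of women 15-49 by country, year, marital group
#'
#' Validates that counts are nonnegative and, where all-women (`WRA`) rows
#' are present, that MWRA + UWRA sums match the WRA count; mismatches are
#' reported as warnings in the attached validation attribute.
#'
#' @param path CSV with columns `country_code`, `marital_group`, `year`,
#'   `count`.
#' @param tolerance relative tolerance for the MWRA + UWRA = WRA check.
#' @return data frame of class `fp_populations` with attribute `validation`.
#' @export
read_populations <- function(path, tolerance = 1e-6) {
  if (!file.exists(path)) stop("population file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country_code", "marital_group", "year", "count")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("population file misses columns: ", paste(miss, collapse = ", "),
         " (found: ", paste(names(raw), collapse = ", "), ")")
  }
  if (any(raw$count < 0, na.rm = TRUE)) stop("negative population counts")
  warn <- character(0)
  wide <- tryCatch(
    stats::reshape(raw, idvar = c("country_code", "year"),
                   timevar = "marital_group", direction = "wide"),
    error = function(e) NULL)
  if (!is.null(wide) && all(c("count.MWRA", "count.UWRA", "count.WRA") %in%
                            names(wide))) {
    mism <- abs(wide$count.MWRA + wide$count.UWRA - wide$count.WRA) >
      tolerance * pmax(wide$count.WRA, 1)
    mism[is.na(mism)] <- FALSE
    if (any(mism)) {
      warn <- paste0("MWRA + UWRA != WRA for ",
                     sum(mism), " country-years (e.g. ",
                     wide$country_code[which(mism)[1]], " ",
                     wide$year[which(mism)[1]], ")")
      warning(warn)
    }
  }
  class(raw) <- c("fp_populations", "data.frame")
  attr(raw, "validation") <- list(warnings = warn)
  raw
}

results_schema <- function() {
  c("unit", "marital_group", "year", "indicator", "scale",
    "median", "lower95", "upper95")
}

#' Write a results table
#'
#' Writes an indicator table as CSV at full stored precision, sorted by
#' unit, then year, then indicator.
#'
#' @param table data frame with the results schema (see
#'   [indicator_table()]).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_results <- function(table, path) {
  miss <- setdiff(results_schema(), names(table))
  if (length(miss) > 0) {
    stop("results table schema mismatch; missing: ",
         paste(miss, collapse = ", "),
         "; found: ", paste(names(table), collapse = ", "))
  }
  table <- table[order(table$unit, table$year, table$indicator), , drop = FALSE]
  utils::write.csv(as.data.frame(table)[, results_schema()], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return data frame with the results schema.
#' @export
read_results <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(results_schema(), names(raw))
  if (length(miss) > 0) {
    stop("results file schema mismatch; missing: ",
         paste(miss, collapse = ", "))
  }
  raw
}
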