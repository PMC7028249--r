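# Sexual-activity grouping of countries (UWRA model only) and construction
# of the hierarchical clustering trees used for borrowing of strength.

#' Default thresholds for sexual-activity group assignment
#'
#' The proportion rule is the primary, data-based rule: countries where
#' fewer than 2% of unmarried women report sexual activity in the past 28
#' days belong to the low-activity group (strict less-than, so exactly 0.02
#' falls in the other group). The attitude and religiosity cutoffs back up
#' countries without survey-based proportions; they are package constants
#' (configurable here), and a manual override column is the supported path
#' for reproducing any published country assignment exactly.
#'
#' @return named list with `proportion`, `attitude` (assign low-activity
#'   when the acceptance-of-unmarried-sex score is below this) and
#'   `religiosity` (assign low-activity when the proportion religious is
#'   above this).
#' @export
sexual_activity_thresholds <- function() {
  list(proportion = 0.02, attitude = 0.25, religiosity = 0.90)
}

#' Assign countries to sexual-activity groups
#'
#' Vectorized assignment with precedence: manual override, then the
#' proportion-sexually-active rule (< 2% to the low group), then the
#' attitude rule, then the religiosity rule. The provenance column records
#' which rule fired for each country.
#'
#' @param proportion_sexually_active proportion of UWRA sexually active in
#'   the past 28 days, in \[0,1\], or NA.
#' @param attitude_indicator acceptance-of-sex-between-unmarried-adults
#'   score in \[0,1\], or NA.
#' @param religiosity_indicator proportion religious in \[0,1\], or NA.
#' @param manual_override `"group0_low"`, `"group1_other"`, or NA.
#' @param thresholds list as returned by [sexual_activity_thresholds()].
#' @return data frame with columns `group` (factor levels `group0_low`,
#'   `group1_other`) and `provenance` (`manual`, `dhs_mics_proportion`,
#'   `attitudes`, `religiosity`).
#' @export
assign_sexual_activity_group <- function(proportion_sexually_active = NA,
                                         attitude_indicator = NA,
                                         religiosity_indicator = NA,
                                         manual_override = NA,
                                         thresholds =
                                           sexual_activity_thresholds()) {
  n <- max(length(proportion_sexually_active), length(attitude_indicator),
           length(religiosity_indicator), length(manual_override))
  p <- rep_len(proportion_sexually_active, n)
  a <- rep_len(attitude_indicator, n)
  r <- rep_len(religiosity_indicator, n)
  m <- rep_len(as.character(manual_override), n)
  m[!is.na(m) & m == ""] <- NA
  bad_m <- !is.na(m) & !(m %in% c("group0_low", "group1_other"))
  if (any(bad_m)) {
    stop("unknown manual override value: ",
         paste(unique(m[bad_m]), collapse = ", "))
  }
  group <- rep(NA_character_, n)
  prov <- rep(NA_character_, n)
  use <- !is.na(m)
  group[use] <- m[use]
  prov[use] <- "manual"
  use <- is.na(group) & !is.na(p)
  group[use] <- ifelse(p[use] < thresholds$proportion,
                       "group0_low", "group1_other")
  prov[use] <- "dhs_mics_proportion"
  use <- is.na(group) & !is.na(a)
  group[use] <- ifelse(a[use] < thresholds$attitude,
                       "group0_low", "group1_other")
  prov[use] <- "attitudes"
  use <- is.na(group) & !is.na(r)
  group[use] <- ifelse(r[use] > thresholds$religiosity,
                       "group0_low", "group1_other")
  prov[use] <- "religiosity"
  if (anyNA(group)) {
    stop("no classification input available for ", sum(is.na(group)),
         " country(ies); provide a manual override (group_override column)")
  }
  data.frame(group = group, provenance = prov, stringsAsFactors = FALSE)
}

#' Classify a country table
#'
#' Applies [assign_sexual_activity_group()] to the classification columns
#' of a country table, filling `sexual_activity_group` and
#' `group_assignment_source`. Countries with an existing
#' `sexual_activity_group` keep it unless `recompute = TRUE`.
#'
#' @param countries `fp_countries` data frame.
#' @param thresholds see [sexual_activity_thresholds()].
#' @param recompute recompute even where a group is already present.
#' @return the country table with `sexual_activity_group` and
#'   `group_assignment_source` filled.
#' @export
classify_countries <- function(countries,
                               thresholds = sexual_activity_thresholds(),
                               recompute = FALSE) {
  ctry <- countries
  if (is.null(ctry$sexual_activity_group)) {
    ctry$sexual_activity_group <- NA_character_
  }
  if (is.null(ctry$group_assignment_source)) {
    ctry$group_assignment_source <- NA_character_
  }
  todo <- recompute | is.na(ctry$sexual_activity_group)
  if (any(todo)) {
    getcol <- function(nm) {
      if (is.null(ctry[[nm]])) rep(NA_real_, nrow(ctry)) else ctry[[nm]]
    }
    res <- assign_sexual_activity_group(
      getcol("proportion_sexually_active")[todo],
      getcol("attitude_indicator")[todo],
      getcol("religiosity_indicator")[todo],
      if (is.null(ctry$group_override)) NA else ctry$group_override[todo],
      thresholds = thresholds)
    ctry$sexual_activity_group[todo] <- res$group
    ctry$group_assignment_source[todo] <- res$provenance
  }
  ctry
}

#' Build the hierarchical clustering tree
#'
#' `geographic` mode (used for the MWRA model) nests country within
#' subregion within region within world. `geographic_by_activity` (UWRA
#' model) inserts the two-category sexual-activity group level between
#' world and region, so region and subregion nodes are duplicated per
#' group and two countries in the same geographic subregion but different
#' activity groups have distinct ancestors below the world node.
#'
#' @param countries classified `fp_countries` table (UWRA mode requires a
#'   `sexual_activity_group` column).
#' @param mode `"geographic"` or `"geographic_by_activity"`.
#' @return object of class `fp_hierarchy`: a node table (`id`, `level`,
#'   `label`, `parent`) and a country ancestry table.
#' @export
build_hierarchy <- function(countries,
                            mode = c("geographic", "geographic_by_activity")) {
  mode <- match.arg(mode)
  need <- c("country_code", "subregion", "region")
  miss <- setdiff(need, names(countries))
  if (length(miss) > 0) stop("countries table misses: ",
                             paste(miss, collapse = ", "))
  if (any(is.na(countries$subregion)) || any(is.na(countries$region))) {
    stop("country with missing subregion/region: ",
         paste(countries$country_code[is.na(countries$subregion) |
                                        is.na(countries$region)],
               collapse = ", "))
  }
  grp <- if (mode == "geographic_by_activity") {
    if (is.null(countries$sexual_activity_group) ||
        anyNA(countries$sexual_activity_group)) {
      stop("geographic_by_activity mode needs sexual_activity_group for ",
           "every country")
    }
    countries$sexual_activity_group
  } else {
    rep("", nrow(countries))
  }
  glue_id <- function(...) paste(..., sep = "|")
  anc <- data.frame(
    country_code = countries$country_code,
    group = grp,
    region_node = if (mode == "geographic") countries$region
                  else glue_id(grp, countries$region),
    subregion_node = if (mode == "geographic") countries$subregion
                     else glue_id(grp, countries$subregion),
    stringsAsFactors = FALSE)

  nodes <- data.frame(id = "world", level = "world", label = "world",
                      parent = NA_character_, stringsAsFactors = FALSE)
  if (mode == "geographic_by_activity") {
    for (g in sort(unique(grp))) {
      nodes <- rbind(nodes, data.frame(id = g, level = "sexual_activity_group",
                                       label = g, parent = "world"))
    }
  }
  reg <- unique(anc[, c("region_node", "group")])
  for (i in seq_len(nrow(reg))) {
    nodes <- rbind(nodes, data.frame(
      id = reg$region_node[i], level = "region",
      label = sub("^[^|]*\\|", "", reg$region_node[i]),
      parent = if (mode == "geographic") "world" else reg$group[i]))
  }
  sub <- unique(data.frame(subregion_node = anc$subregion_node,
                           region_node = anc$region_node,
                           stringsAsFactors = FALSE))
  for (i in seq_len(nrow(sub))) {
    nodes <- rbind(nodes, data.frame(
      id = sub$subregion_node[i], level = "subregion",
      label = sub("^[^|]*\\|", "", sub$subregion_node[i]),
      parent = sub$region_node[i]))
  }
  nodes <- rbind(nodes, data.frame(
    id = anc$country_code, level = "country", label = anc$country_code,
    parent = anc$subregion_node))
  rownames(nodes) <- NULL
  out <- list(mode = mode, nodes = nodes, ancestry = anc,
              countries = countries$country_code)
  class(out) <- "fp_hierarchy"
  out
}

#' @export
print.fp_hierarchy <- function(x, ...) {
  cat("fp_hierarchy (", x$mode, "): ", length(x$countries), " countries, ",
      nrow(x$nodes), " nodes\n", sep = "")
  print(table(x$nodes$level))
  invisible(x)
}

#' Nodes of a hierarchy
#' @param hierarchy `fp_hierarchy`.
#' @return node data frame (`id`, `level`, `label`, `parent`).
#' @export
hierarchy_nodes <- function(hierarchy) hierarchy$nodes

#' Ancestry path of a country
#'
#' @param hierarchy `fp_hierarchy`.
#' @param country_code ISO3 code present in the hierarchy.
#' @return character vector of node ids from the country leaf up to the
#'   world root.
#' @export
country_ancestry <- function(hierarchy, country_code) {
  nodes <- hierarchy$nodes
  if (!(country_code %in% nodes$id[nodes$level == "country"])) {
    stop("country not in hierarchy: ", country_code)
  }
  path <- country_code
  cur <- country_code
  while (!is.na(nodes$parent[match(cur, nodes$id)])) {
    cur <- nodes$parent[match(cur, nodes$id)]
    path <- c(path, cur)
  }
  path
}
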