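#' fpest: estimation of family-planning indicators for all women
#'
#' Tools to estimate and project contraceptive prevalence and unmet need for
#' family planning among married/in-union (MWRA), unmarried (UWRA) and all
#' (WRA) women of reproductive age from compilations of survey estimates,
#' using a Bayesian hierarchical model with logistic-growth systematic trends
#' and AR(1) deviations fitted by MCMC.
#'
#' @keywords internal
"_PACKAGE"

# Internal scale convention: every prevalence/share is stored as a proportion
# on [0,1]; percentages on [0,100] exist only at the reporting boundary and
# all conversion goes through these two functions.

#' Convert proportions to percentages
#'
#' The single audited conversion between the internal proportion scale
#' (values in \[0,1\]) and the reporting percentage scale (values in
#' \[0,100\]). All printed/written percentages in the package pass through
#' here.
#'
#' @param x numeric vector of proportions in \[0,1\] (NA allowed).
#' @return numeric vector on the percentage scale.
#' @seealso [percent_to_prop()]
#' @export
prop_to_percent <- function(x) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    stop("prop_to_percent: values outside [0,1]: ",
         paste(utils::head(signif(x[bad], 4), 5), collapse = ", "))
  }
  100 * x
}

#' Convert percentages to proportions
#'
#' @param x numeric vector of percentages in \[0,100\] (NA allowed).
#' @return numeric vector of proportions in \[0,1\].
#' @seealso [prop_to_percent()]
#' @export
percent_to_prop <- function(x) {
  bad <- !is.na(x) & (x < 0 | x > 100)
  if (any(bad)) {
    stop("percent_to_prop: values outside [0,100]: ",
         paste(utils::head(signif(x[bad], 4), 5), collapse = ", "))
  }
  x / 100
}

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

# Nudge proportions at the boundary of [0,1] inward so logit transforms are
# finite. Half of 1/ess, with ess the assumed effective sample size.
nudge_boundary <- function(p, ess = 1000) {
  eps <- 0.5 / ess
  out <- p
  out[!is.na(p) & p <= 0] <- eps
  out[!is.na(p) & p >= 1] <- 1 - eps
  out
}

# Deterministic child seeds below 2^31, derived from one user-facing seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 1009) %%
               2147483399) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

marital_groups <- function() c("MWRA", "UWRA")

source_types <- function() c("DHS", "MICS", "PMA", "National", "Other")

misclassification_levels <- function() {
  c("none", "modern_only_reported", "sterilization_omitted",
    "folk_in_modern", "other")
}
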