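#' Load the condition registry and risk-factor parameter tables
#'
#' Reads the packaged (or a user-supplied) set of delimited-text parameter
#' tables and assembles the validated registry every other part of the engine
#' consumes: the 26 modelled conditions with their Cambridge Multimorbidity
#' Score (CMS) mapping and recovery rules, the exposure-to-condition risk
#' links, theoretical-minimum-risk exposure levels (TMRELs), the BMI mediation
#' coefficients, condition-on-condition ("parent") relative risks, and the
#' synthetic incidence/case-fatality/prevalence rate parameters used by the
#' population generator.
#'
#' The relative-risk magnitudes shipped with the package are illustrative
#' placeholders of realistic size (roughly 1.1--3.0 per category, or the
#' per-unit equivalent for continuous exposures). They are not meta-analytic
#' estimates and must not be used for epidemiological inference; the engine's
#' correctness does not depend on their provenance.
#'
#' @param path Directory containing the parameter tables. Defaults to the
#'   tables shipped with the package.
#' @param validate Logical; run the full invariant checks (default `TRUE`).
#' @return An object of class `morbsim_registry`: a list with elements
#'   `conditions`, `risk_links`, `tmrel`, `mediation`, `parents`, `rates`,
#'   `other_mortality`, `cms_weights` (named numeric, one per CMS condition)
#'   and `checksums`.
#' @export
#' @examples
#' reg <- load_registry()
#' nrow(reg$conditions) # 26 modelled conditions
#' length(reg$cms_weights) # 20 CMS conditions
load_registry <- function(path = NULL, validate = TRUE) {
  if (is.null(path)) {
    path <- system.file("extdata", package = "morbsim")
  }
  read_tbl <- function(name) {
    f <- file.path(path, name)
    if (!file.exists(f)) {
      stop("registry table missing: ", name, call. = FALSE)
    }
    fread(f, sep = "\t", header = TRUE, na.strings = "NA")
  }
  conditions <- read_tbl("conditions.tsv")
  risk_links <- read_tbl("risk_links.tsv")
  tmrel <- read_tbl("tmrel.tsv")
  mediation_tbl <- read_tbl("mediation.tsv")
  parents <- read_tbl("parent_conditions.tsv")
  rates <- read_tbl("synthetic_condition_rates.tsv")
  # the generator needs the sex restriction alongside the rate parameters
  rates[conditions, on = "modelled_name", sex_specific := i.sex_specific]
  other_mortality <- read_tbl("synthetic_other_mortality.tsv")
  checksums <- read_tbl("checksums.tsv")

  mediation <- list(
    delta_sbp_per_bmi_unit = mediation_tbl[parameter == "delta_sbp_per_bmi_unit", value],
    delta_tc_per_bmi_unit = mediation_tbl[parameter == "delta_tc_per_bmi_unit", value],
    bmi_floor = mediation_tbl[parameter == "bmi_floor", value]
  )

  cms_weights <- conditions[, .(w = cms_weight[1L]), by = cms_condition]
  weights <- setNames(cms_weights$w, cms_weights$cms_condition)

  # per-condition index of plain lists: the annual loop touches these tens of
  # thousands of times, so avoid data.table row subsetting on the hot path
  index <- lapply(conditions$modelled_name, function(cn) {
    lk <- risk_links[condition == cn]
    pr <- parents[condition == cn]
    list(
      cond = as.list(conditions[modelled_name == cn]),
      rates = as.list(rates[modelled_name == cn]),
      links = if (nrow(lk)) lapply(seq_len(nrow(lk)), function(i) as.list(lk[i])),
      parents = if (nrow(pr)) list(parent = pr$parent, rr = pr$rr)
    )
  })
  names(index) <- conditions$modelled_name

  reg <- structure(
    list(
      conditions = conditions,
      risk_links = risk_links,
      tmrel = tmrel,
      mediation = mediation,
      parents = parents,
      rates = rates,
      other_mortality = other_mortality,
      cms_weights = weights,
      checksums = checksums,
      index = index
    ),
    class = "morbsim_registry"
  )
  if (validate) validate_registry(reg)
  reg
}

#' Validate a registry against its structural invariants
#'
#' Checks every invariant of the registry contract and fails loudly, naming
#' the offending rows: 26 modelled conditions aggregating to 20 CMS
#' conditions, strictly positive weights consistent within each CMS condition
#' and matching the shipped checksums, cancer-only 10-year remission rules,
#' cross-referenced identifiers between tables, positive lags, cumulative
#' smoking effects restricted to COPD and lung/breast/colorectal cancers, and
#' non-modelled-cause mortality effects restricted to SBP, smoking and
#' physical activity.
#'
#' @param reg A `morbsim_registry`.
#' @return Invisibly `TRUE`; errors with a structured message otherwise.
#' @export
validate_registry <- function(reg) {
  cond <- reg$conditions
  links <- reg$risk_links
  fail <- function(...) stop("registry validation: ", ..., call. = FALSE)

  if (nrow(cond) == 0L) fail("conditions table is empty")
  if (anyDuplicated(cond$modelled_name)) {
    fail("duplicate modelled condition(s): ",
         paste(cond$modelled_name[duplicated(cond$modelled_name)], collapse = ", "))
  }
  if (nrow(cond) != 26L) fail("expected 26 modelled conditions, found ", nrow(cond))
  if (uniqueN(cond$cms_condition) != 20L) {
    fail("expected 20 CMS conditions, found ", uniqueN(cond$cms_condition))
  }
  if (any(cond$cms_weight <= 0)) {
    fail("non-positive CMS weight for: ",
         paste(cond$modelled_name[cond$cms_weight <= 0], collapse = ", "))
  }
  bad_w <- cond[, .(n = uniqueN(cms_weight)), by = cms_condition][n > 1L]
  if (nrow(bad_w)) {
    fail("inconsistent weights within CMS condition(s): ",
         paste(bad_w$cms_condition, collapse = ", "))
  }
  bad_cancer <- cond[recovery_rule == "cancer_10yr" & !is_cancer]
  if (nrow(bad_cancer)) {
    fail("cancer_10yr recovery on non-cancer: ",
         paste(bad_cancer$modelled_name, collapse = ", "))
  }
  four <- c("prostate_cancer", "breast_cancer", "colorectal_cancer", "lung_cancer")
  if (!all(cond[modelled_name %in% four, recovery_rule] == "cancer_10yr")) {
    fail("prostate/breast/colorectal/lung cancers must carry cancer_10yr recovery")
  }
  lifelong <- cond[, .(lifelong = all(recovery_rule == "none")), by = cms_condition]
  if (sum(lifelong$lifelong) != 14L) {
    fail("expected 14 lifelong CMS conditions, found ", sum(lifelong$lifelong))
  }

  unknown <- setdiff(links$condition, cond$modelled_name)
  if (length(unknown)) fail("risk link to unknown condition: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(links[, .(exposure, condition)])) {
    dup <- links[duplicated(links[, .(exposure, condition)])]
    fail("duplicate risk link(s): ", paste(dup$exposure, dup$condition, sep = "->", collapse = ", "))
  }
  if (any(links$lag_years <= 0)) fail("non-positive lag_years present")
  cancers <- cond[is_cancer == TRUE, modelled_name]
  mean_lag_cancer <- mean(links[condition %in% cancers, lag_years])
  mean_lag_other <- mean(links[!condition %in% cancers, lag_years])
  if (!(mean_lag_other >= 4 && mean_lag_other <= 5)) {
    fail("mean non-cancer lag outside 4-5 years: ", mean_lag_other)
  }
  if (abs(mean_lag_cancer - 9) > 1e-9) fail("mean cancer lag is not 9 years: ", mean_lag_cancer)
  cum_allowed <- c("copd", "lung_cancer", "breast_cancer", "colorectal_cancer")
  bad_cum <- links[cumulative == TRUE & !(exposure == "smoking" & condition %in% cum_allowed)]
  if (nrow(bad_cum)) {
    fail("cumulative effect only allowed for smoking on COPD/lung/breast/colorectal: ",
         paste(bad_cum$exposure, bad_cum$condition, sep = "->", collapse = ", "))
  }
  bad_nm <- links[affects_nonmodelled_mortality == TRUE &
                    !exposure %in% c("sbp", "smoking", "pa")]
  if (nrow(bad_nm)) {
    fail("non-modelled mortality effect restricted to SBP, smoking, physical activity; found: ",
         paste(bad_nm$exposure, collapse = ", "))
  }
  if (any(links$rr_per_unit <= 0)) fail("non-positive RR present in risk links")

  unknown_p <- setdiff(unique(c(reg$parents$condition, reg$parents$parent)), cond$modelled_name)
  if (length(unknown_p)) fail("parent table references unknown condition: ",
                              paste(unknown_p, collapse = ", "))
  if (any(reg$parents$rr <= 0)) fail("non-positive parent RR")

  if (!setequal(reg$rates$modelled_name, cond$modelled_name)) {
    fail("rate table does not cover the modelled conditions exactly")
  }

  med <- reg$mediation
  if (!(med$delta_sbp_per_bmi_unit > 0 && med$delta_tc_per_bmi_unit > 0)) {
    fail("mediation coefficients must be strictly positive")
  }

  # shipped checksums
  ck <- reg$checksums
  observed <- c(
    conditions.n_rows = nrow(cond),
    conditions.n_cms_conditions = uniqueN(cond$cms_condition),
    conditions.cms_weight_sum_distinct = round(sum(reg$cms_weights), 2),
    conditions.n_lifelong_cms = sum(lifelong$lifelong),
    risk_links.n_rows = nrow(links),
    risk_links.n_cumulative = sum(links$cumulative),
    tmrel.n_rows = nrow(reg$tmrel),
    parent_conditions.n_rows = nrow(reg$parents)
  )
  for (i in seq_len(nrow(ck))) {
    key <- paste(ck$table[i], ck$quantity[i], sep = ".")
    if (!isTRUE(all.equal(unname(observed[key]), ck$expected[i], tolerance = 1e-8))) {
      fail("checksum mismatch for ", key, ": expected ", ck$expected[i],
           ", observed ", observed[key])
    }
  }
  invisible(TRUE)
}

#' Write a registry back to delimited text
#'
#' Inverse of [load_registry()]; used for the round-trip contract that a
#' written registry reloads identically.
#'
#' @param reg A `morbsim_registry`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_registry <- function(reg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  med <- data.table(
    parameter = c("delta_sbp_per_bmi_unit", "delta_tc_per_bmi_unit", "bmi_floor"),
    value = c(reg$mediation$delta_sbp_per_bmi_unit,
              reg$mediation$delta_tc_per_bmi_unit, reg$mediation$bmi_floor),
    ci_lo = NA_real_, ci_hi = NA_real_,
    unit = c("mmHg per kg/m2", "mmol/L per kg/m2", "kg/m2")
  )
  out <- list(
    conditions.tsv = reg$conditions,
    risk_links.tsv = reg$risk_links,
    tmrel.tsv = reg$tmrel,
    mediation.tsv = med,
    parent_conditions.tsv = reg$parents,
    synthetic_condition_rates.tsv = reg$rates,
    synthetic_other_mortality.tsv = reg$other_mortality,
    checksums.tsv = reg$checksums
  )
  for (nm in names(out)) {
    fwrite(out[[nm]], file.path(dir, nm), sep = "\t", na = "NA", quote = FALSE)
  }
  invisible(dir)
}

#' @export
print.morbsim_registry <- function(x, ...) {
  cat("morbsim condition registry\n")
  cat("  modelled conditions: ", nrow(x$conditions),
      " (", uniqueN(x$conditions$cms_condition), " CMS conditions)\n", sep = "")
  cat("  risk links:          ", nrow(x$risk_links),
      " (", sum(x$risk_links$cumulative), " cumulative smoking links)\n", sep = "")
  cat("  parent-condition RRs:", nrow(x$parents), "\n")
  cat("  CMS weight range:    ", min(x$cms_weights), "-", max(x$cms_weights), "\n")
  invisible(x)
}

#' Cambridge Multimorbidity Score of a set of prevalent conditions
#'
#' Sums the general-outcome weights of the supplied CMS conditions. Scoring is
#' defined on the 20 CMS conditions, so modelled sub-conditions (e.g. the two
#' diabetes types, or the five modelled cancers) must first be aggregated to
#' their CMS condition; each CMS condition contributes its weight exactly once.
#' Use [modelled_to_cms()] for that aggregation.
#'
#' @param prevalent Character vector of CMS condition identifiers; duplicates
#'   are an error (a condition cannot be prevalent twice).
#' @param registry A `morbsim_registry` (defaults to the packaged one).
#' @return The dimensionless score (0 for an empty set).
#' @export
#' @examples
#' cms_score("dementia") # 2.50
#' cms_score(c("hypertension", "asthma", "hearing_loss")) # 0.36
cms_score <- function(prevalent, registry = load_registry(validate = FALSE)) {
  if (length(prevalent) == 0L) return(0)
  if (anyDuplicated(prevalent)) {
    stop("duplicate CMS condition(s): ",
         paste(unique(prevalent[duplicated(prevalent)]), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(prevalent, names(registry$cms_weights))
  if (length(unknown)) {
    stop("unknown CMS condition(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(registry$cms_weights[prevalent])
}

#' Aggregate modelled conditions to their CMS conditions
#'
#' @param modelled Character vector of modelled condition names (possibly with
#'   several members of the same CMS condition, e.g. both diabetes types).
#' @param registry A `morbsim_registry`.
#' @return Character vector of distinct CMS condition identifiers.
#' @export
modelled_to_cms <- function(modelled, registry = load_registry(validate = FALSE)) {
  cond <- registry$conditions
  unknown <- setdiff(modelled, cond$modelled_name)
  if (length(unknown)) {
    stop("unknown modelled condition(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  unique(cond$cms_condition[match(modelled, cond$modelled_name)])
}

#' Major-illness indicator
#'
#' Major illness is a CMS score strictly greater than the threshold (1.5 by
#' default; the threshold is configurable for sensitivity analysis).
#'
#' @param score Numeric vector of non-negative CMS scores.
#' @param threshold Score threshold (default 1.5).
#' @return Logical vector.
#' @export
#' @examples
#' is_major_illness(2.50) # dementia alone exceeds the threshold
#' is_major_illness(1.5) # FALSE: strict inequality
is_major_illness <- function(score, threshold = 1.5) {
  if (any(score < 0, na.rm = TRUE)) stop("negative CMS score", call. = FALSE)
  score > threshold
}
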