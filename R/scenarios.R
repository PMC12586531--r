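# Scenario engine: counterfactual transforms of base-case exposure
# trajectories from the scenario start year onward.

#' Define a counterfactual scenario
#'
#' A scenario is a declarative transform applied to base-case exposures from
#' `start_year` onward. Two families are supported: `"tmrel"` (all individuals
#' at the theoretical minimum risk exposure level) and
#' `"relative_improvement"` (a fractional reduction of the excess over the
#' TMREL, computed annually against that year's base-case value). Fruit and
#' vegetables always move together; environmental tobacco smoke is derived
#' from scenario smoking prevalence, never set independently.
#'
#' @param name Scenario label (used in the results cube).
#' @param family `"baseline"`, `"tmrel"` or `"relative_improvement"`.
#' @param factors Character subset of `c("smoking", "fruit_veg", "pa", "bmi",
#'   "tchol", "sbp")`, or `"all"`.
#' @param improvement_fraction Fraction of excess removed per year under
#'   `relative_improvement` (default 0.10); ignored for `tmrel`.
#' @param start_year First year the transform applies.
#' @param mediation_on Apply the BMI-to-SBP/total-cholesterol mediation in BMI
#'   improvement scenarios (off reproduces the direct-effect-only sensitivity
#'   analysis).
#' @param case_fatality_effects_on Whether risk-factor effects also apply to
#'   case fatality in this arm (off reproduces the no-case-fatality-effect
#'   sensitivity analysis).
#' @return A list of class `morbsim_scenario`.
#' @export
scenario <- function(name, family = c("baseline", "tmrel", "relative_improvement"),
                     factors = "all", improvement_fraction = 0.10,
                     start_year = 2023L, mediation_on = TRUE,
                     case_fatality_effects_on = TRUE) {
  family <- match.arg(family)
  all_factors <- c("smoking", "fruit_veg", "pa", "bmi", "tchol", "sbp")
  if (identical(factors, "all")) factors <- all_factors
  bad <- setdiff(factors, all_factors)
  if (length(bad) && family != "baseline") {
    stop("unknown scenario factor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (improvement_fraction < 0 || improvement_fraction > 1) {
    stop("improvement_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(list(name = name, family = family, factors = factors,
                 improvement_fraction = improvement_fraction,
                 start_year = as.integer(start_year),
                 mediation_on = mediation_on,
                 case_fatality_effects_on = case_fatality_effects_on),
            class = "morbsim_scenario")
}

#' @export
print.morbsim_scenario <- function(x, ...) {
  cat("morbsim scenario '", x$name, "': ", x$family, sep = "")
  if (x$family == "relative_improvement") {
    cat(" (fraction ", x$improvement_fraction, ")", sep = "")
  }
  cat("\n  factors:", paste(x$factors, collapse = ", "),
      "\n  from year:", x$start_year, "\n")
  invisible(x)
}

#' Sample theoretical minimum risk exposure levels for one iteration
#'
#' TMRELs with a triangular sampling distribution are redrawn once per
#' Monte-Carlo iteration (and held fixed within it); fixed TMRELs (physical
#' activity 7 days/week, smoking and ETS at zero) are returned as-is.
#'
#' @param tmrel_table The `tmrel` table of a registry.
#' @param master_seed,iteration Stream identifiers.
#' @return Named numeric vector of TMRELs by exposure.
#' @export
sample_tmrels <- function(tmrel_table, master_seed = 1L, iteration = 1L) {
  u <- runif_stream(nrow(tmrel_table), master_seed, iteration, "tmrel")
  v <- ifelse(tmrel_table$sampling_distribution == "triangular",
              qtriangular(u, tmrel_table$support_lo, tmrel_table$support_hi),
              tmrel_table$central)
  setNames(v, tmrel_table$exposure)
}

#' Apply the fractional excess-reduction rule to an exposure value
#'
#' Removes `fraction` of the excess of a harmful-direction exposure over its
#' TMREL: `base - fraction * max(base - tmrel, 0)`. Values at or below the
#' TMREL are unchanged; the result never crosses below the TMREL. Applied
#' annually against that year's base-case value.
#'
#' @param base_value Base-case exposure value(s).
#' @param tmrel Theoretical minimum risk exposure level.
#' @param fraction Fraction of excess removed, in `[0, 1]`.
#' @return Counterfactual exposure value(s).
#' @export
#' @examples
#' apply_relative_improvement(28, 22, 0.10) # 27.4
apply_relative_improvement <- function(base_value, tmrel, fraction) {
  if (any(fraction < 0)) stop("fraction must be non-negative", call. = FALSE)
  base_value - fraction * pmax(base_value - tmrel, 0)
}

#' Relative reduction in excess exposure above the TMREL
#'
#' Reporting helper: the share of the excess over the TMREL removed when an
#' exposure moves from `old_value` to `new_value`, `(old - new)/(old -
#' tmrel)`.
#'
#' @param old_value,new_value Exposure values (old must exceed the TMREL).
#' @param tmrel Theoretical minimum risk exposure level.
#' @return Dimensionless fraction.
#' @export
#' @examples
#' relative_excess_reduction(125.3, 122.6, 112) # 0.203
relative_excess_reduction <- function(old_value, new_value, tmrel) {
  if (any(old_value <= tmrel)) stop("no excess to reduce: old_value <= tmrel",
                                    call. = FALSE)
  (old_value - new_value) / (old_value - tmrel)
}

#' Mediated SBP and total-cholesterol change from a BMI decrease
#'
#' For simulants with base BMI at or above the mediation floor (25 kg/m2),
#' each unit of BMI decrease lowers SBP by 2.55 mmHg and total cholesterol by
#' 0.23 mmol/L; below the floor the mediated effect is zero.
#'
#' @param delta_bmi Non-negative BMI decrease (kg/m2).
#' @param bmi_base Base-case BMI (kg/m2).
#' @param spec Mediation parameter list (registry `$mediation`).
#' @return List with `delta_sbp` (mmHg) and `delta_tc` (mmol/L) decreases.
#' @export
#' @examples
#' reg <- load_registry()
#' apply_bmi_mediation(1.0, 30, reg$mediation) # 2.55 mmHg, 0.23 mmol/L
apply_bmi_mediation <- function(delta_bmi, bmi_base, spec) {
  if (any(delta_bmi < 0)) stop("delta_bmi must be non-negative", call. = FALSE)
  on <- bmi_base >= spec$bmi_floor
  list(delta_sbp = ifelse(on, spec$delta_sbp_per_bmi_unit * delta_bmi, 0),
       delta_tc = ifelse(on, spec$delta_tc_per_bmi_unit * delta_bmi, 0))
}

#' Move smoking histories to the theoretical minimum (no smoking)
#'
#' From the scenario start year, every current smoker becomes an ex-smoker
#' (years since quit counting from the start year), cigarettes per day are
#' zero, pack-years are frozen, and the initiation rate is zero (base-case
#' never-smokers who would have initiated do not). Idempotent.
#'
#' @param smoke Smoking matrices (`status`, `cig`, `pack_years`,
#'   `years_since_quit`) from the base case.
#' @param start_year Scenario start year.
#' @return Transformed smoking matrices.
#' @export
apply_tmrel_smoking <- function(smoke, start_year) {
  out <- lapply(smoke, function(m) m)
  yrs <- as.integer(colnames(smoke$status))
  c0 <- match(start_year, yrs)
  if (is.na(c0)) stop("start_year outside horizon", call. = FALSE)
  st0 <- smoke$status[, c0]
  py0 <- smoke$pack_years[, c0]
  ysq0 <- smoke$years_since_quit[, c0]
  ever <- st0 != 0L
  for (j in c0:length(yrs)) {
    y <- yrs[j]
    out$status[, j] <- fifelse(ever, 2L, 0L)
    out$cig[, j] <- 0
    out$pack_years[, j] <- fifelse(ever, py0, 0)
    out$years_since_quit[, j] <- fifelse(
      st0 == 2L, ysq0 + (y - start_year),
      fifelse(ever, y - start_year, 0L)
    )
  }
  out
}

#' Reduce the number of smokers and their consumption by a fraction
#'
#' A persistent random fraction of base-case current smokers (the same
#' individuals in every arm, via a dedicated uniform per simulant) are
#' ex-smokers in the scenario in every year they would have smoked; the
#' remaining smokers' cigarettes per day are scaled by `1 - fraction`.
#' Pack-years are re-accumulated along the counterfactual consumption path.
#'
#' @param smoke Base-case smoking matrices.
#' @param fraction Fraction in `[0, 1]`.
#' @param u_quit Persistent uniform per simulant (dedicated stream).
#' @param start_year Scenario start year.
#' @param entry_year Per-simulant entry years.
#' @return Transformed smoking matrices.
#' @export
apply_smoking_improvement <- function(smoke, fraction, u_quit, start_year,
                                      entry_year) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  if (fraction == 0) return(smoke)
  out <- lapply(smoke, function(m) m)
  yrs <- as.integer(colnames(smoke$status))
  c0 <- match(start_year, yrs)
  quitter <- u_quit < fraction
  py <- smoke$pack_years[, c0 - 1L]
  quit_since <- rep(NA_integer_, nrow(smoke$status))
  for (j in c0:length(yrs)) {
    y <- yrs[j]
    base_cur <- smoke$status[, j] == 1L
    scn_cur <- base_cur & !quitter
    forced_ex <- base_cur & quitter
    newly_forced <- forced_ex & is.na(quit_since)
    quit_since[newly_forced] <- pmax(y, entry_year[newly_forced])
    cigs <- ifelse(scn_cur, smoke$cig[, j] * (1 - fraction), 0)
    py <- py + ifelse(scn_cur, cigs / 20, 0)
    out$status[, j] <- ifelse(scn_cur, 1L,
                              ifelse(forced_ex | smoke$status[, j] == 2L, 2L, 0L))
    out$cig[, j] <- cigs
    out$pack_years[, j] <- ifelse(smoke$status[, j] == 0L, 0, py)
    out$years_since_quit[, j] <- ifelse(
      forced_ex, pmax(y - quit_since, 0L),
      ifelse(smoke$status[, j] == 2L & !is.na(quit_since), pmax(y - quit_since, 0L),
             out$years_since_quit[, j])
    )
  }
  out
}

#' Give one extra active day per week to a fraction of the population
#'
#' Each scenario year, a random `fraction` of simulants with fewer than 7
#' active days in the base case gain exactly one day; no one exceeds 7.
#' Recipients are resampled annually against that year's base-case
#' distribution from a dedicated stream, so the same individuals are selected
#' in the single-factor and combined arms.
#'
#' @param pa Base-case physical-activity matrix (days/week).
#' @param fraction Fraction in `[0, 1]`.
#' @param start_year Scenario start year.
#' @param master_seed,iteration Stream identifiers for the annual recipient
#'   draws.
#' @return Transformed matrix.
#' @export
apply_physical_activity_improvement <- function(pa, fraction, start_year,
                                                master_seed, iteration) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]", call. = FALSE)
  if (fraction == 0) return(pa)
  yrs <- as.integer(colnames(pa))
  out <- pa
  for (j in which(yrs >= start_year)) {
    u <- runif_stream(nrow(pa), master_seed, iteration, "pa_scn", yrs[j])
    gain <- u < fraction & pa[, j] < 7
    out[, j] <- pmin(pa[, j] + gain, 7)
  }
  out
}

# Full arm transform: base-case exposure bundle -> scenario bundle.
# arm bundle: list(traj = per-exposure matrices, smoke = smoking matrices,
# ets = logical matrix).
scenario_exposures <- function(popobj, base, scn, tmrels, registry,
                               master_seed, iteration) {
  if (scn$family == "baseline") return(base)
  traj <- base$traj
  smoke <- base$smoke
  yrs <- as.integer(colnames(traj$bmi))
  jj <- which(yrs >= scn$start_year)
  f <- scn$improvement_fraction
  fac <- scn$factors
  med <- NULL

  if (scn$family == "tmrel") {
    for (e in intersect(fac, c("bmi", "tchol", "sbp"))) {
      traj[[e]] <- base$traj[[e]]
      traj[[e]][, jj] <- tmrels[[e]]
    }
    if ("fruit_veg" %in% fac) {
      traj$fruit[, jj] <- tmrels[["fruit"]]
      traj$veg[, jj] <- tmrels[["veg"]]
    }
    if ("pa" %in% fac) traj$pa[, jj] <- 7
    if ("smoking" %in% fac) {
      smoke <- apply_tmrel_smoking(smoke, scn$start_year)
    }
  } else { # relative_improvement
    if ("bmi" %in% fac) {
      traj$bmi[, jj] <- apply_relative_improvement(base$traj$bmi[, jj],
                                                   tmrels[["bmi"]], f)
      if (scn$mediation_on) {
        med <- list(delta = base$traj$bmi[, jj, drop = FALSE] -
                      traj$bmi[, jj, drop = FALSE],
                    base_bmi = base$traj$bmi[, jj, drop = FALSE])
      }
    }
    for (e in intersect(fac, c("tchol", "sbp"))) {
      traj[[e]][, jj] <- apply_relative_improvement(base$traj[[e]][, jj],
                                                    tmrels[[e]], f)
    }
    if (!is.null(med)) {
      d <- apply_bmi_mediation(as.vector(med$delta), as.vector(med$base_bmi),
                               registry$mediation)
      sbp_new <- traj$sbp[, jj, drop = FALSE] - matrix(d$delta_sbp, ncol = length(jj))
      tc_new <- traj$tchol[, jj, drop = FALSE] - matrix(d$delta_tc, ncol = length(jj))
      # mediation never pushes an exposure below its TMREL (nor raises it)
      traj$sbp[, jj] <- pmax(sbp_new, pmin(traj$sbp[, jj, drop = FALSE], tmrels[["sbp"]]))
      traj$tchol[, jj] <- pmax(tc_new, pmin(traj$tchol[, jj, drop = FALSE], tmrels[["tchol"]]))
    }
    if ("fruit_veg" %in% fac) {
      traj$fruit[, jj] <- base$traj$fruit[, jj] * (1 + f)
      traj$veg[, jj] <- base$traj$veg[, jj] * (1 + f)
    }
    if ("pa" %in% fac) {
      traj$pa <- apply_physical_activity_improvement(base$traj$pa, f,
                                                     scn$start_year,
                                                     master_seed, iteration)
    }
    if ("smoking" %in% fac && f > 0) {
      u_quit <- runif_stream(nrow(popobj$pop), master_seed, iteration, "smoke_scn")
      smoke <- apply_smoking_improvement(smoke, f, u_quit, scn$start_year,
                                         popobj$pop$entry_year)
    }
  }
  ets <- build_ets_matrix(popobj, smoke$status, yrs)
  list(traj = traj, smoke = smoke, ets = ets)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
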