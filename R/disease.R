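# Disease engine: lagged exposures and prevalent diseases -> annual
# incidence and recovery, with PAF-style calibration of baseline incidence.

PROTECTIVE_EXPOSURES <- c("fruit", "veg", "pa")

#' Relative-risk multiplier for one risk link
#'
#' Log-linear dose response on the excess exposure: for harmful-direction
#' exposures (BMI, SBP, total cholesterol) the multiplier is
#' `rr_per_unit^max(x - tmrel, 0)`; for protective exposures (fruit,
#' vegetables, physical activity) the deficit below the TMREL carries the risk,
#' `rr_per_unit^max(tmrel - x, 0)` with `rr_per_unit > 1` encoding the risk of
#' deficit. The multiplier never falls below 1. Categorical links (ETS) are a
#' lookup: exposed carries `rr_per_unit`, unexposed 1. Smoking-status links
#' are handled by [smoking_cumulative_rr()].
#'
#' @param link One row of the risk-link table (or the same fields as a list).
#' @param exposure_lagged Exposure value(s) consulted at `year - lag_years`.
#' @param tmrel TMREL for this exposure (ignored for categorical links).
#' @return Multiplier(s) `>= 1` (categorical: `rr_per_unit` or 1).
#' @export
#' @examples
#' reg <- load_registry()
#' link <- reg$risk_links[exposure == "bmi" & condition == "dementia"]
#' compute_rr(link, 28, tmrel = 22) # 1.06^6
compute_rr <- function(link, exposure_lagged, tmrel) {
  switch(link$form,
         log_linear_continuous = {
           excess <- if (link$exposure %in% PROTECTIVE_EXPOSURES) {
             pmax(tmrel - exposure_lagged, 0)
           } else {
             pmax(exposure_lagged - tmrel, 0)
           }
           link$rr_per_unit^excess
         },
         categorical = fifelse(as.logical(exposure_lagged), link$rr_per_unit, 1),
         smoking_status = stop("use smoking_cumulative_rr() for smoking links",
                               call. = FALSE),
         stop("unknown risk-link form: ", link$form, call. = FALSE))
}

#' Smoking relative-risk multiplier, cumulative or fully reversible
#'
#' For the cumulative links (smoking on COPD and lung, breast and colorectal
#' cancer) the multiplier grows with pack-years, `rr^(pack_years/20)` with
#' `rr` the RR at a 20 pack-year reference, and after quitting the excess
#' decays exponentially in years since quit with a configurable half-life
#' (default 10 years) -- quitting never zeroes these risks immediately. For
#' non-cumulative smoking links risk is 100% reversible: current smokers (and
#' quitters within the link's lag) carry `rr`, longer-quit ex-smokers and
#' never-smokers carry 1.
#'
#' @param link One row of the risk-link table (`form == "smoking_status"`).
#' @param status Smoking status code(s): 0 never, 1 current, 2 ex.
#' @param pack_years,years_since_quit Smoking history vectors.
#' @param half_life Excess-decay half-life for cumulative links, years.
#' @return Multiplier(s) `>= 1`.
#' @export
smoking_cumulative_rr <- function(link, status, pack_years, years_since_quit,
                                  half_life = 10) {
  if (link$form != "smoking_status") {
    stop("not a smoking link: ", link$exposure, call. = FALSE)
  }
  if (link$cumulative) {
    peak <- link$rr_per_unit^(pack_years / 20)
    fifelse(status == 1L, peak,
            fifelse(status == 2L,
                    1 + (peak - 1) * 2^(-years_since_quit / half_life), 1))
  } else {
    fifelse(status == 1L, link$rr_per_unit,
            fifelse(status == 2L & years_since_quit < link$lag_years,
                    link$rr_per_unit, 1))
  }
}

# Product of all risk-link multipliers for one condition, vectorised over
# simulants. `links` is the registry index entry; `yrs` the integer years of
# the trajectory columns.
condition_link_multipliers <- function(links, arm, year, tmrels, half_life,
                                       yrs, n) {
  mult <- rep(1, n)
  if (is.null(links)) return(mult)
  jnow <- match(year, yrs)
  for (link in links) {
    if (link$form == "smoking_status") {
      if (link$cumulative) {
        # cumulative effect: current pack-year burden and quit decay
        m <- smoking_cumulative_rr(link, arm$smoke$status[, jnow],
                                   arm$smoke$pack_years[, jnow],
                                   arm$smoke$years_since_quit[, jnow], half_life)
      } else {
        # reversible effect: status consulted at the lagged year
        jlag <- match(max(year - link$lag_years, yrs[1L]), yrs)
        m <- smoking_cumulative_rr(link, arm$smoke$status[, jlag],
                                   arm$smoke$pack_years[, jlag],
                                   arm$smoke$years_since_quit[, jnow], half_life)
      }
    } else if (link$form == "categorical") { # ETS
      jlag <- match(max(year - link$lag_years, yrs[1L]), yrs)
      m <- compute_rr(link, arm$ets[, jlag], 0)
    } else {
      jlag <- match(max(year - link$lag_years, yrs[1L]), yrs)
      m <- compute_rr(link, arm$traj[[link$exposure]][, jlag],
                      tmrels[[link$exposure]])
    }
    mult <- mult * m
  }
  mult
}

# Multiplier from prevalent parent conditions, read from the PREVIOUS year's
# state matrix (no same-year feedback).
parent_multipliers <- function(par, dstate_prev) {
  mult <- rep(1, nrow(dstate_prev))
  if (is.null(par)) return(mult)
  for (i in seq_along(par$parent)) {
    mult <- mult * fifelse(dstate_prev[, par$parent[i]] == 1L, par$rr[i], 1)
  }
  mult
}

#' Back out baseline incidence from a stratum target via the attributable
#' fraction
#'
#' Population-attributable-fraction calibration: with target marginal rate
#' `t` and per-simulant multiplier products `m_i`, the baseline probability is
#' `p0 = t / mean(m_i)` over the at-risk stratum members (equivalently `p0 =
#' t * (1 - PAF)` with `PAF = 1 - 1/E[m]`), so that the expected marginal
#' incidence equals the target.
#'
#' @param target Per-simulant target rate(s) (constant within a calibration
#'   stratum).
#' @param multipliers Per-simulant products of risk multipliers.
#' @param stratum Per-simulant stratum labels over which the mean is taken.
#' @return Per-simulant baseline probabilities `p0`.
#' @export
#' @examples
#' # half the stratum at multiplier 2, half at 1, target 0.015 -> p0 = 0.01
#' calibrate_baseline(rep(0.015, 4), c(2, 2, 1, 1), rep("s", 4))
calibrate_baseline <- function(target, multipliers, stratum) {
  dt <- data.table(target = target, m = multipliers, stratum = stratum)
  mm <- dt[, .(Em = mean(m)), by = stratum]
  p0 <- dt[mm, on = "stratum", target / Em]
  pmin(pmax(p0, 0), 1)
}

# default calibration stratum: sex x 10-year age band
calibration_stratum <- function(age, sex) {
  band <- pmin(pmax(age %/% 10L, 3L), 9L)
  paste0(sex, "_", band, "0s")
}

#' Simulate one year of disease incidence
#'
#' Bernoulli incidence per at-risk simulant at `p0 x product of risk-link
#' multipliers x product of parent-condition multipliers` (clamped below 1),
#' evaluated condition by condition in the registry's fixed order with parent
#' effects reading the previous year's prevalence. Draws come from
#' condition-specific common-random-number streams indexed by simulant id, so
#' scenario arms that share a seed share event randomness.
#'
#' Calibration: the base-case arm estimates each calibration stratum's mean
#' multiplier `E[m]` among the at-risk and stores it; every arm then uses
#' `p0_i = target_i / E[m]`, so frozen base-case calibration lets scenario
#' multiplier changes translate into incidence changes.
#'
#' This is the engine-internal annual step; it mutates and returns the
#' disease-state matrices.
#'
#' @param state List with `dstate` (0 free / 1 active / 2 recovered),
#'   `donset` and `dstate_prev` matrices, simulant x modelled condition.
#' @param popobj A `morbsim_population`.
#' @param arm Arm exposure bundle (`traj`, `smoke`, `ets`).
#' @param registry A `morbsim_registry`.
#' @param year Calendar year.
#' @param alive Logical vector (alive and entered).
#' @param tmrels Named TMREL vector for this iteration.
#' @param p0_store Environment used as the calibration store.
#' @param is_base Whether this is the calibrating (base-case) arm.
#' @param master_seed,iteration Stream identifiers.
#' @param half_life Cumulative-smoking decay half-life (years).
#' @param age_y,strat Optional precomputed per-simulant age and calibration
#'   stratum for this year.
#' @return The updated `state`, with an attribute `new_cases` (named count).
#' @export
simulate_incidence <- function(state, popobj, arm, registry, year, alive,
                               tmrels, p0_store, is_base, master_seed,
                               iteration, half_life = 10, age_y = NULL,
                               strat = NULL) {
  pop <- popobj$pop
  n <- nrow(pop)
  if (is.null(age_y)) age_y <- pop$age_at_entry + (year - pop$entry_year)
  if (is.null(strat)) strat <- calibration_stratum(age_y, pop$sex)
  yrs <- as.integer(colnames(arm$smoke$status))
  dstate_prev <- state$dstate_prev
  new_cases <- integer(0)
  for (cn in names(registry$index)) {
    ix <- registry$index[[cn]]
    at_risk <- alive & (state$dstate[, cn] == 0L |
                          (state$dstate[, cn] == 2L & ix$cond$can_recur))
    if (!any(at_risk)) next
    mult <- condition_link_multipliers(ix$links, arm, year, tmrels, half_life,
                                       yrs, n)
    mult <- mult * parent_multipliers(ix$parents, dstate_prev)
    if (isTRUE(ix$cond$past_self_as_risk)) {
      mult <- mult * fifelse(state$dstate[, cn] == 2L, ix$cond$past_self_rr, 1)
    }
    idx <- which(at_risk)
    key <- paste0(cn, "_", year)
    target <- condition_target_rate(ix$rates, "incidence", age_y[idx],
                                    pop$sex[idx], pop$dimd[idx], year)
    if (is_base || is.null(p0_store$Em[[key]])) {
      em <- tapply(mult[idx], strat[idx], mean)
      p0_store$Em[[key]] <- list(em = em, overall = mean(mult[idx]))
    }
    emrec <- p0_store$Em[[key]]
    Em <- unname(emrec$em[strat[idx]])
    if (anyNA(Em)) {
      if (!isTRUE(p0_store$warned_empty)) {
        warning("empty calibration stratum; using the pooled mean multiplier",
                call. = FALSE)
        p0_store$warned_empty <- TRUE
      }
      Em[is.na(Em)] <- emrec$overall
    }
    p0 <- pmin(pmax(target / Em, 0), 1)
    p <- pmin(p0 * mult[idx], 0.999)
    u <- runif_stream(n, master_seed, iteration, "inc", year, cn)
    events <- idx[u[idx] < p]
    if (length(events)) {
      state$dstate[events, cn] <- 1L
      state$donset[events, cn] <- year
      new_cases[cn] <- length(events)
    }
  }
  attr(state, "new_cases") <- new_cases
  state
}

#' Apply annual recovery rules
#'
#' Cancers recover 10 years after onset (remission); conditions with
#' stochastic recovery (constipation, chronic pain, asthma, alcohol problems,
#' anxiety and depression) recover with their configured annual probability;
#' lifelong conditions never leave the active state. Recovered states are
#' retained (they matter for recurrence risk and, for non-recurring cancers,
#' exclude re-entry).
#'
#' @param state Disease state list (`dstate`, `donset`).
#' @param registry A `morbsim_registry`.
#' @param year Calendar year.
#' @param alive Logical vector.
#' @param master_seed,iteration Stream identifiers.
#' @return Updated state.
#' @export
apply_recovery <- function(state, registry, year, alive, master_seed, iteration) {
  for (cn in names(registry$index)) {
    ix <- registry$index[[cn]]
    if (ix$cond$recovery_rule == "none") next
    active <- alive & state$dstate[, cn] == 1L
    if (!any(active)) next
    if (ix$cond$recovery_rule == "cancer_10yr") {
      rec <- active & (year - state$donset[, cn]) >= 10L
    } else {
      u <- runif_stream(nrow(state$dstate), master_seed, iteration, "rec",
                        year, cn)
      rec <- active & u < ix$cond$recovery_prob
    }
    state$dstate[rec, cn] <- 2L
  }
  state
}
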