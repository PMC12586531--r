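# Mortality engine: condition-specific case fatality (sharing the incidence
# relative risks) plus risk-modified other-cause mortality, calibrated to the
# all-cause mortality envelope on the base-case arm.

# Per-simulant case-fatality probability for one active condition: the
# synthetic stratum target multiplied by the condition's risk links (equal RRs
# for incidence and case fatality) when case-fatality effects are on.
case_fatality_probability <- function(registry, condition_name, popobj, arm,
                                      year, alive, tmrels, cf_effects_on,
                                      half_life = 10, age_y = NULL) {
  pop <- popobj$pop
  if (is.null(age_y)) age_y <- pop$age_at_entry + (year - pop$entry_year)
  ix <- registry$index[[condition_name]]
  cf <- condition_target_rate(ix$rates, "case_fatality", age_y, pop$sex,
                              pop$dimd, year)
  if (cf_effects_on && !is.null(ix$links)) {
    links_cf <- Filter(function(l) isTRUE(l$affects_case_fatality), ix$links)
    if (length(links_cf)) {
      yrs <- as.integer(colnames(arm$smoke$status))
      cf <- cf * condition_link_multipliers(links_cf, arm, year, tmrels,
                                            half_life, yrs, nrow(pop))
    }
  }
  pmin(cf, 0.999)
}

# Other-cause (non-modelled) mortality hazard: envelope-shaped base rate
# multiplied by the SBP / smoking / physical-activity effects and by the
# configured prevalent-disease effects.
other_cause_probability <- function(registry, popobj, arm, dstate, year, tmrels,
                                    half_life = 10) {
  pop <- popobj$pop
  cfg <- popobj$config
  age_y <- pop$age_at_entry + (year - pop$entry_year)
  base <- cfg$other_cause_base %||% cfg$envelope
  p <- envelope_rate(age_y, pop$sex, year, base, cfg$start_year)
  om <- registry$other_mortality
  yrs <- as.integer(colnames(arm$smoke$status))
  for (i in seq_len(nrow(om))) {
    row <- as.list(registry$other_mortality[i])
    if (row$source_type == "exposure") {
      link <- list(exposure = row$source, form = row$form,
                   rr_per_unit = row$rr_per_unit,
                   lag_years = row$lag_years, cumulative = FALSE)
      if (row$form == "smoking_status") {
        jlag <- match(max(year - row$lag_years, yrs[1L]), yrs)
        jnow <- match(year, yrs)
        m <- smoking_cumulative_rr(link, arm$smoke$status[, jlag],
                                   arm$smoke$pack_years[, jlag],
                                   arm$smoke$years_since_quit[, jnow], half_life)
      } else {
        x <- lagged_exposure(arm$traj, row$source, year, row$lag_years)
        m <- compute_rr(link, x, tmrels[[row$source]])
      }
    } else {
      m <- ifelse(dstate[, row$source] == 1L, row$rr_per_unit, 1)
    }
    p <- p * m
  }
  pmin(p, 0.999)
}

#' Calibrate combined mortality to the envelope
#'
#' Computes the per-stratum scalar applied to every component hazard such
#' that the expected number of deaths under the combined competing-risk
#' probability `1 - prod(1 - f * p_k)` matches the all-cause mortality
#' envelope. Because the combination is nonlinear in `f`, the factor is found
#' by bisection per stratum (for a single dominant hazard this reduces to the
#' proportional-hazard ratio, e.g. a model rate double the envelope gives a
#' factor of about 0.5). Estimated once per year on the base-case arm and
#' frozen for the scenario arms of the same iteration, so that scenario risk
#' improvements translate into genuine mortality reductions rather than being
#' re-calibrated away.
#'
#' @param hazards Matrix of component death probabilities (simulant x cause),
#'   zero for causes not carried.
#' @param envelope_p Per-simulant envelope target probabilities.
#' @param stratum Per-simulant calibration stratum labels.
#' @param alive Logical mask of simulants in the denominator.
#' @param cap Maximum allowed factor; larger requirements warn and cap.
#' @param iterations Bisection iterations (default 30).
#' @return Named numeric vector of factors by stratum.
#' @export
calibrate_mortality <- function(hazards, envelope_p, stratum, alive,
                                cap = 10, iterations = 30L) {
  if (is.null(dim(hazards))) hazards <- matrix(hazards, ncol = 1L)
  H <- hazards[alive, , drop = FALSE]
  s <- stratum[alive]
  target <- tapply(envelope_p[alive], s, sum)
  levels <- names(target)
  si <- match(s, levels)
  lo <- rep(0, length(levels))
  hi <- rep(cap, length(levels))
  for (it in seq_len(iterations)) {
    f <- (lo + hi) / 2
    p <- 1 - exp(rowSums(log1p(-pmin(H * f[si], 0.999))))
    got <- tapply(p, s, sum)
    over <- got[levels] > target
    hi[over] <- f[over]
    lo[!over] <- f[!over]
  }
  f <- (lo + hi) / 2
  zero_target <- target[levels] < 1e-12
  f[zero_target] <- 0
  if (any(f >= cap * 0.999)) {
    warning("mortality calibration factor capped at ", cap, " for stratum ",
            paste(levels[f >= cap * 0.999], collapse = ", "), call. = FALSE)
  }
  setNames(f, levels)
}

#' Simulate one year of deaths with cause attribution
#'
#' Combines each simulant's competing annual risks -- one case-fatality
#' hazard per active condition plus the other-cause hazard -- as
#' `1 - prod(1 - f * p_k)` with the stratum calibration factor `f`, draws at
#' most one death per simulant, and attributes a single cause proportionally
#' to the component hazards.
#'
#' @param popobj A `morbsim_population`.
#' @param arm Arm exposure bundle.
#' @param state Disease state list.
#' @param registry A `morbsim_registry`.
#' @param year Calendar year.
#' @param alive Logical vector.
#' @param tmrels Named TMREL vector.
#' @param mort_store Environment holding frozen calibration factors keyed by
#'   year (filled on the base-case arm).
#' @param is_base Whether this arm calibrates (TRUE) or reuses factors.
#' @param cf_effects_on Risk-factor effects on case fatality switch.
#' @param master_seed,iteration Stream identifiers.
#' @param half_life Cumulative-smoking decay half-life (years).
#' @return List with `died` (logical), `cause` (character, NA if alive).
#' @export
simulate_deaths <- function(popobj, arm, state, registry, year, alive, tmrels,
                            mort_store, is_base, cf_effects_on, master_seed,
                            iteration, half_life = 10, age_y = NULL,
                            strat = NULL) {
  pop <- popobj$pop
  n <- nrow(pop)
  if (is.null(age_y)) age_y <- pop$age_at_entry + (year - pop$entry_year)
  if (is.null(strat)) strat <- calibration_stratum(age_y, pop$sex)
  conds <- registry$conditions$modelled_name

  hazards <- list()
  for (cn in conds) {
    active <- alive & state$dstate[, cn] == 1L
    if (!any(active)) next
    p <- case_fatality_probability(registry, cn, popobj, arm, year, alive,
                                   tmrels, cf_effects_on, half_life, age_y)
    p[!active] <- 0
    hazards[[cn]] <- p
  }
  hazards[["other_causes"]] <- {
    p <- other_cause_probability(registry, popobj, arm, state$dstate, year,
                                 tmrels, half_life)
    p[!alive] <- 0
    p
  }

  H <- do.call(cbind, hazards)
  key <- as.character(year)
  if (is_base || is.null(mort_store$factors[[key]])) {
    env_p <- envelope_rate(age_y, pop$sex, year, popobj$config$envelope,
                           popobj$config$start_year)
    mort_store$factors[[key]] <- calibrate_mortality(H, env_p, strat, alive)
  }
  f <- mort_store$factors[[key]][strat]
  f[is.na(f)] <- 1
  Hc <- pmin(H * f, 0.999)
  p_death <- 1 - exp(rowSums(log1p(-Hc)))

  u <- runif_stream(n, master_seed, iteration, "mort", year)
  u_cause <- runif_stream(n, master_seed, iteration, "mort_cause", year)
  died <- alive & u < p_death

  cause <- rep(NA_character_, n)
  if (any(died)) {
    Hd <- Hc[died, , drop = FALSE]
    tot <- rowSums(Hd)
    cum <- Hd
    for (j in seq_len(ncol(Hd))[-1L]) cum[, j] <- cum[, j - 1L] + Hd[, j]
    pick <- u_cause[died] * tot
    idx <- max.col(cum >= pick, ties.method = "first")
    cause[died] <- colnames(Hd)[idx]
  }
  list(died = died, cause = cause)
}
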