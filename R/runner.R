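# Runner: orchestrates iterations, scenario arms, random streams and the
# annual update loop (ageing/entrants -> exposures -> incidence -> recovery ->
# mortality -> outcome accumulation).

#' Run configuration
#'
#' @param n_simulants Initial cohort size.
#' @param n_iterations Monte-Carlo iterations (TMRELs and the synthetic cohort
#'   are redrawn per iteration).
#' @param master_seed Master seed; every stream seed is derived from it.
#' @param start_year First simulated year (burn-in and calibration window runs
#'   from here to `scenario_start - 1`).
#' @param scenario_start Year the counterfactual transforms begin; results are
#'   reported from this year.
#' @param end_year Last simulated year.
#' @param scenarios List of [scenario()] objects (a baseline arm is always
#'   run and need not be listed).
#' @param cms_threshold CMS score threshold for major illness (sensitivity
#'   analyses may override the default 1.5).
#' @param no_case_fatality_effect Sensitivity switch: risk-factor improvements
#'   do not affect case fatality in any arm.
#' @param smoking_half_life Excess-decay half-life (years) of the cumulative
#'   smoking effect after quitting.
#' @param generator Generator configuration; defaults to
#'   [default_generator_config()] at `n_simulants` over the run horizon.
#' @return List of class `morbsim_runconfig`.
#' @export
run_config <- function(n_simulants = 2000L, n_iterations = 100L,
                       master_seed = 1L, start_year = 2013L,
                       scenario_start = 2023L, end_year = 2043L,
                       scenarios = list(), cms_threshold = 1.5,
                       no_case_fatality_effect = FALSE,
                       smoking_half_life = 10,
                       generator = NULL) {
  if (!(start_year < scenario_start && scenario_start <= end_year)) {
    stop("need start_year < scenario_start <= end_year", call. = FALSE)
  }
  if (n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  if (is.null(generator)) {
    generator <- default_generator_config(n_simulants = n_simulants,
                                          start_year = start_year,
                                          end_year = end_year)
  }
  structure(list(n_simulants = as.integer(n_simulants),
                 n_iterations = as.integer(n_iterations),
                 master_seed = as.integer(master_seed),
                 start_year = as.integer(start_year),
                 scenario_start = as.integer(scenario_start),
                 end_year = as.integer(end_year),
                 scenarios = scenarios,
                 cms_threshold = cms_threshold,
                 no_case_fatality_effect = no_case_fatality_effect,
                 smoking_half_life = smoking_half_life,
                 generator = generator),
            class = "morbsim_runconfig")
}

# CMS scores for all simulants from the active-state matrix: each CMS
# condition contributes its weight once if any member modelled condition is
# active.
cms_scores_from_state <- function(dstate, registry) {
  cond <- registry$conditions
  cms <- names(registry$cms_weights)
  M <- vapply(cms, function(g) as.numeric(cond$cms_condition == g),
              numeric(nrow(cond)))
  any_active <- ((dstate == 1L) %*% M) > 0
  as.vector(any_active %*% registry$cms_weights[cms])
}

# One arm's annual loop over `years`, starting from `init` (state + vitals).
run_arm <- function(popobj, arm, registry, scn, years, iteration,
                    p0_store, mort_store, is_base, init, threshold,
                    master_seed, half_life, snapshot_year = NA_integer_,
                    collect_validation = FALSE, scenario_start = NA_integer_,
                    track_major = FALSE) {
  pop <- popobj$pop
  n <- nrow(pop)
  state <- list(dstate = init$dstate, donset = init$donset)
  alive <- init$alive
  death_year <- init$death_year
  death_cause <- init$death_cause
  cf_on <- scn$case_fatality_effects_on
  rows <- list()
  vrows <- list()
  snapshot <- NULL
  major_py <- if (track_major) {
    matrix(FALSE, n, length(years), dimnames = list(NULL, as.character(years)))
  }

  for (y in years) {
    present <- pop$entry_year <= y
    entering <- pop$entry_year == y & y > popobj$config$start_year
    alive[entering] <- TRUE
    alive_start <- alive & present
    age_y <- pop$age_at_entry + (y - pop$entry_year)
    strat_y <- calibration_stratum(age_y, pop$sex)
    score_start <- cms_scores_from_state(state$dstate, registry)
    state$dstate_prev <- state$dstate

    state <- simulate_incidence(state, popobj, arm, registry, y, alive_start,
                                attr(arm, "tmrels"), p0_store, is_base,
                                master_seed, iteration, half_life,
                                age_y = age_y, strat = strat_y)
    state <- apply_recovery(state, registry, y, alive_start, master_seed,
                            iteration)
    score_end <- cms_scores_from_state(state$dstate, registry)

    deaths <- simulate_deaths(popobj, arm, state, registry, y, alive_start,
                              attr(arm, "tmrels"), mort_store, is_base, cf_on,
                              master_seed, iteration, half_life,
                              age_y = age_y, strat = strat_y)
    alive[deaths$died] <- FALSE
    death_year[deaths$died] <- y
    death_cause[deaths$died] <- deaths$cause[deaths$died]

    rows[[as.character(y)]] <- accumulate_year(
      pop, y, iteration, scn$name, alive_start, alive & present, deaths$died,
      score_start, score_end, threshold
    )
    rows[[as.character(y)]][, n_entrants := sum(entering)]
    if (track_major) {
      major_py[, match(y, years)] <- (alive & present) &
        is_major_illness(score_end, threshold)
    }

    if (collect_validation && y < scenario_start) {
      vrows[[as.character(y)]] <- validation_rows(popobj, arm, registry, y,
                                                  alive_start, deaths$died,
                                                  score_start, score_end)
    }
    if (!is.na(snapshot_year) && y == snapshot_year) {
      snapshot <- list(dstate = state$dstate, donset = state$donset,
                       alive = alive, death_year = death_year,
                       death_cause = death_cause)
    }
  }
  list(rows = rbindlist(rows), validation = rbindlist(vrows),
       snapshot = snapshot, major_py = major_py,
       final = list(alive = alive, death_year = death_year,
                    death_cause = death_cause, state = state))
}

# burn-in validation rows: observed vs expected for mortality and exposures
validation_rows <- function(popobj, arm, registry, y, alive_start, died,
                            score_start, score_end) {
  pop <- popobj$pop
  cfg <- popobj$config
  age_y <- pop$age_at_entry + (y - pop$entry_year)
  out <- list()
  n0 <- sum(alive_start)
  # all-cause mortality vs envelope
  exp_rate <- mean(envelope_rate(age_y[alive_start], pop$sex[alive_start], y,
                                 cfg$envelope, cfg$start_year))
  obs_rate <- sum(died) / n0
  se <- sqrt(exp_rate * (1 - exp_rate) / n0)
  out[["mortality"]] <- data.table(year = y, quantity = "all_cause_mortality",
                                   observed = obs_rate, expected = exp_rate,
                                   se = se, z = (obs_rate - exp_rate) / se)
  # exposure means among the alive
  jy <- year_col(arm$traj$bmi, y)
  for (e in c("bmi", "sbp", "tchol", "fruit", "veg", "pa")) {
    v <- arm$traj[[e]][alive_start, jy]
    spec <- cfg$exposures[exposure == e]
    grid <- seq(0.025, 0.975, length.out = 20)
    expc <- mean(vapply(grid, function(g) {
      mean(project_exposure(spec, rep(g, n0), age_y[alive_start],
                            pop$sex[alive_start], pop$dimd[alive_start], y,
                            cfg$start_year))
    }, numeric(1)))
    se <- stats::sd(v) / sqrt(n0)
    out[[e]] <- data.table(year = y, quantity = paste0("mean_", e),
                           observed = mean(v), expected = expc, se = se,
                           z = (mean(v) - expc) / se)
  }
  rbindlist(out)
}

#' Run the microsimulation
#'
#' For each Monte-Carlo iteration: sample the iteration's TMRELs, generate the
#' synthetic population, precompute base-case exposure and smoking
#' trajectories, run the base-case arm from the start year (calibrating
#' baseline incidence via attributable fractions and mortality to the
#' envelope over the whole horizon), snapshot the state at the end of the
#' burn-in window, and replay every scenario arm from the scenario start year
#' under common random numbers with the calibration frozen. Outputs before
#' the scenario start are retained only in the validation report.
#'
#' @param config A [run_config()].
#' @param registry A `morbsim_registry`.
#' @param keep_person_years Also return per-simulant major-illness indicator
#'   matrices per arm and iteration (memory-heavy; used for audit and exact
#'   recount checks on small cohorts).
#' @return Object of class `morbsim_run`: list with `cube` (the results
#'   cube: one row per iteration, scenario, year, stratum), `validation`
#'   (burn-in discrepancy report rows from the base-case arm), `config` and
#'   optionally `person_years`.
#' @export
run_simulation <- function(config = run_config(), registry = load_registry(),
                           keep_person_years = FALSE) {
  years_all <- config$start_year:config$end_year
  max_lag <- max(registry$risk_links$lag_years)
  years_traj <- (config$start_year - max_lag):config$end_year
  scens <- config$scenarios
  if (config$no_case_fatality_effect) {
    scens <- lapply(scens, function(s) {
      s$case_fatality_effects_on <- FALSE
      s
    })
  }
  cube_rows <- list()
  val_rows <- list()
  person_years <- if (keep_person_years) list()
  for (iter in seq_len(config$n_iterations)) {
    tmrels <- sample_tmrels(registry$tmrel, config$master_seed, iter)
    popobj <- generate_population(config$generator,
                                  seed = stream_seed(config$master_seed, iter,
                                                     "genpop"),
                                  registry = registry)
    traj <- build_exposure_trajectories(popobj, years_traj)
    smoke <- simulate_smoking_histories(popobj, years_traj, traj,
                                        config$master_seed, iter)
    base_arm <- list(traj = traj, smoke = smoke,
                     ets = build_ets_matrix(popobj, smoke$status, years_traj))
    attr(base_arm, "tmrels") <- tmrels

    p0_store <- new.env(parent = emptyenv())
    p0_store$Em <- list()
    mort_store <- new.env(parent = emptyenv())
    mort_store$factors <- list()

    n <- nrow(popobj$pop)
    init0 <- list(dstate = popobj$dstate, donset = popobj$donset,
                  alive = popobj$pop$entry_year == config$start_year,
                  death_year = rep(NA_integer_, n),
                  death_cause = rep(NA_character_, n))
    base_scn <- scenario("baseline", "baseline",
                         start_year = config$scenario_start)
    base_res <- run_arm(popobj, base_arm, registry, base_scn, years_all, iter,
                        p0_store, mort_store, TRUE, init0,
                        config$cms_threshold, config$master_seed,
                        config$smoking_half_life,
                        snapshot_year = config$scenario_start - 1L,
                        collect_validation = TRUE,
                        scenario_start = config$scenario_start,
                        track_major = keep_person_years)
    cube_rows[[paste0("base_", iter)]] <-
      base_res$rows[year >= config$scenario_start]
    val_rows[[iter]] <- base_res$validation[, iteration := iter]
    if (keep_person_years) {
      keep_cols <- as.character(config$scenario_start:config$end_year)
      person_years[[paste0("baseline_", iter)]] <-
        base_res$major_py[, keep_cols, drop = FALSE]
    }

    for (scn in scens) {
      arm <- scenario_exposures(popobj, base_arm, scn, tmrels, registry,
                                config$master_seed, iter)
      attr(arm, "tmrels") <- tmrels
      res <- run_arm(popobj, arm, registry, scn,
                     config$scenario_start:config$end_year, iter,
                     p0_store, mort_store, FALSE, base_res$snapshot,
                     config$cms_threshold, config$master_seed,
                     config$smoking_half_life, track_major = keep_person_years)
      cube_rows[[paste0(scn$name, "_", iter)]] <- res$rows
      if (keep_person_years) {
        person_years[[paste0(scn$name, "_", iter)]] <- res$major_py
      }
    }
  }
  structure(list(cube = rbindlist(cube_rows),
                 validation = rbindlist(val_rows),
                 config = config,
                 person_years = person_years),
            class = "morbsim_run")
}

#' @export
print.morbsim_run <- function(x, ...) {
  cat("morbsim run: ", x$config$n_iterations, " iteration(s), ",
      uniqueN(x$cube$scenario), " arm(s), years ",
      min(x$cube$year), "-", max(x$cube$year), "\n", sep = "")
  cat("  cube rows:", nrow(x$cube), "\n")
  invisible(x)
}

#' Validation report for a run
#'
#' Compares base-case burn-in behaviour against the calibration targets:
#' all-cause mortality against the envelope and marginal exposure means
#' against the configured distributions, as standardised discrepancies
#' (observed minus expected over its standard error). Reporting only -- the
#' report is returned even when checks fail.
#'
#' @param run A `morbsim_run`.
#' @param z_threshold Absolute z flagging threshold (default 3).
#' @return `data.table` of the validation rows with a `flagged` column.
#' @export
validate_run <- function(run, z_threshold = 3) {
  v <- copy(run$validation)
  if (!nrow(v)) {
    warning("run carries no burn-in validation rows", call. = FALSE)
    return(v)
  }
  v[, flagged := abs(z) > z_threshold]
  v[]
}
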