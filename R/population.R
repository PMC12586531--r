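#' Default exposure specifications for the synthetic population
#'
#' One row per continuous exposure (plus cigarettes/day for smokers): the
#' marginal distribution family, its location parameters by age, sex and
#' deprivation decile, the log-linear annual trend, and the bounds values are
#' clamped to. Positive-scale exposures use a log link; physical activity
#' (bounded 0--7 days/week) uses a logit link on days/7. A simulant's value in
#' any stratum-year is the quantile of that stratum-year distribution at the
#' simulant's fixed lifetime rank, which enforces quintile-group persistence
#' and constant rank correlations by construction.
#'
#' Deprivation is coded 1 = most deprived decile; `dimd_slope` multiplies
#' `(5.5 - dimd)`, so a positive slope means higher exposure in more deprived
#' deciles. The defaults emulate broad English adult patterns (rising BMI,
#' falling blood pressure and cholesterol, social gradients in smoking, diet
#' and activity); they are synthetic, not survey estimates.
#'
#' @return A `data.table` with columns `exposure`, `link`, `m0`, `sex_effect`,
#'   `age_slope`, `dimd_slope`, `trend`, `sd`, `lower`, `upper`.
#' @export
default_exposure_specs <- function() {
  data.table(
    exposure  = c("bmi", "sbp", "tchol", "fruit", "veg", "pa", "cig"),
    link      = c("log", "log", "log", "log", "log", "logit7", "log"),
    m0        = c(log(27.5), log(128), log(5.5), log(200), log(210), 0, log(13)),
    sex_effect = c(0.01, 0.03, 0.00, -0.05, -0.04, 0.05, 0.05),
    age_slope = c(0.0015, 0.0040, 0.0010, 0.0020, 0.0015, -0.010, 0.0),
    dimd_slope = c(0.010, -0.0020, 0.000, -0.030, -0.025, -0.040, 0.030),
    trend     = c(0.0020, -0.0015, -0.0030, 0.0010, 0.0005, 0.0030, -0.0050),
    sd        = c(0.16, 0.11, 0.17, 0.50, 0.45, 1.2, 0.35),
    lower     = c(15, 80, 2, 0, 0, 0, 1),
    upper     = c(60, 220, 12, 1500, 1500, 7, 60)
  )
}

#' Default rank-correlation matrix between exposures
#'
#' Spearman correlations between the lifetime exposure ranks, realised through
#' a Gaussian copula (the Pearson correlation on the normal scores is
#' `2*sin(pi*rho/6)`). Clustering of adverse exposures (higher BMI with higher
#' blood pressure and cholesterol, lower activity with more smoking) is
#' represented with moderate values.
#'
#' @return A symmetric positive semi-definite matrix with dimnames the
#'   exposure names of [default_exposure_specs()].
#' @export
default_rank_correlations <- function() {
  nm <- c("bmi", "sbp", "tchol", "fruit", "veg", "pa", "cig")
  R <- diag(7)
  dimnames(R) <- list(nm, nm)
  set_r <- function(a, b, v) {
    R[a, b] <<- v
    R[b, a] <<- v
  }
  set_r("bmi", "sbp", 0.30)
  set_r("bmi", "tchol", 0.25)
  set_r("bmi", "fruit", -0.10)
  set_r("bmi", "pa", -0.15)
  set_r("sbp", "tchol", 0.20)
  set_r("fruit", "veg", 0.50)
  set_r("fruit", "pa", 0.15)
  set_r("fruit", "cig", -0.15)
  set_r("pa", "cig", -0.10)
  R
}

#' Generator configuration for the synthetic population
#'
#' @param n_simulants Initial cohort size at the start year.
#' @param start_year First simulated year.
#' @param end_year Last simulated year.
#' @param entrant_rate Annual share of `n_simulants` entering at age 30.
#' @param prop_male Proportion male.
#' @param age_decay Exponential decay of the initial age distribution over
#'   ages 30--100 (larger = younger cohort).
#' @param exposures Exposure specification table
#'   (see [default_exposure_specs()]).
#' @param rank_correlations Spearman correlation matrix between exposure ranks.
#' @param smoking List of smoking dynamics parameters: initial status model
#'   (`current0`, `current_dimd`, `current_age`, `ex0`), annual `initiation`
#'   and `cessation` rates.
#' @param ets_coupling Proportionality constant linking environmental tobacco
#'   smoke exposure probability to stratum smoking prevalence.
#' @param envelope All-cause mortality envelope parameters (`rate60`,
#'   `age_ln`, `male_ln`, `trend_ln`): rate = `rate60 *
#'   exp(age_ln*(age-60) + male_ln*[male] + trend_ln*(year-start_year))`.
#' @param other_cause_base Optional parameter list of the same shape for the
#'   pre-calibration other-cause (non-modelled) mortality hazard; `NULL`
#'   (default) uses the envelope shape, which the calibration then rescales.
#' @return A list of class `morbsim_genconfig`.
#' @export
default_generator_config <- function(n_simulants = 10000L,
                                     start_year = 2013L,
                                     end_year = 2043L,
                                     entrant_rate = 0.015,
                                     prop_male = 0.49,
                                     age_decay = 0.025,
                                     exposures = default_exposure_specs(),
                                     rank_correlations = default_rank_correlations(),
                                     smoking = list(current0 = 0.19,
                                                    current_dimd = 0.035,
                                                    current_age = -0.012,
                                                    ex0 = 0.25,
                                                    initiation = 0.002,
                                                    cessation = 0.03),
                                     ets_coupling = 0.8,
                                     envelope = list(rate60 = 0.005,
                                                     age_ln = 0.092,
                                                     male_ln = 0.30,
                                                     trend_ln = -0.010),
                                     other_cause_base = NULL) {
  structure(list(
    n_simulants = as.integer(n_simulants),
    start_year = as.integer(start_year),
    end_year = as.integer(end_year),
    entrant_rate = entrant_rate,
    prop_male = prop_male,
    age_decay = age_decay,
    exposures = exposures,
    rank_correlations = rank_correlations,
    smoking = smoking,
    ets_coupling = ets_coupling,
    envelope = envelope,
    other_cause_base = other_cause_base
  ), class = "morbsim_genconfig")
}

# All-cause mortality envelope rate (vectorised).
envelope_rate <- function(age, sex, year, env, start_year) {
  r <- env$rate60 * exp(env$age_ln * (age - 60) +
                          env$male_ln * (sex == "male") +
                          env$trend_ln * (year - start_year))
  pmin(r, 0.95)
}

# Synthetic stratum target rates from the packaged rate table.
# what: "incidence", "case_fatality" or "prevalence".
condition_target_rate <- function(rates_row, what, age, sex, dimd, year,
                                  ref_year = 2013L) {
  if (what == "incidence") {
    yr_eff <- switch(rates_row$trend_rule,
                     log_linear = rates_row$inc_trend_ln * (year - ref_year),
                     frozen = 0,   # incidence frozen at the reference year
                     none = 0)
    r <- rates_row$inc_rate60 *
      exp(rates_row$inc_age_ln * (age - 60) +
            rates_row$inc_dimd_ln * (5.5 - dimd) / 4.5 + yr_eff)
  } else if (what == "case_fatality") {
    r <- rates_row$cf_rate60 *
      exp(rates_row$cf_age_ln * (age - 60) +
            rates_row$cf_trend_ln * (year - ref_year))
  } else {
    r <- rates_row$prev60 *
      exp(rates_row$prev_age_ln * (age - 60) +
            rates_row$inc_dimd_ln * (5.5 - dimd) / 4.5)
    r[age < rates_row$prev_min_age] <- 0
  }
  if (rates_row$sex_specific != "both") r[sex != rates_row$sex_specific] <- 0
  pmin(pmax(r, 0), 0.95)
}

#' Generate a synthetic population and its calibration targets
#'
#' Creates the stand-in for survey and administrative inputs: an initial adult
#' cohort (ages 30--100) with jointly distributed, rank-persistent exposures,
#' smoking histories and seeded prevalent diseases, together with future
#' entrants (age 30 in their entry year) and the population/mortality targets
#' the simulator is calibrated to. Reproducible given `seed`; exposure ranks
#' are drawn from a Gaussian copula honouring the configured Spearman
#' correlations, and disease states are seeded from the synthetic initial
#' prevalence surface.
#'
#' @param config A `morbsim_genconfig` (see [default_generator_config()]).
#' @param seed Integer seed for the generator's random streams.
#' @param registry A `morbsim_registry`.
#' @return An object of class `morbsim_population`: list with `pop` (one row
#'   per simulant, including future entrants flagged by `entry_year`),
#'   `dstate`/`donset` (simulant-by-condition state and onset-year matrices;
#'   state 0 = free, 1 = active, 2 = recovered), `targets` (a
#'   `morbsim_targets`), `config` and `seed`.
#' @export
generate_population <- function(config = default_generator_config(),
                                seed = 1L,
                                registry = load_registry()) {
  n0 <- config$n_simulants
  y0 <- config$start_year
  years <- y0:config$end_year
  n_entr_y <- as.integer(round(n0 * config$entrant_rate))
  n_entr <- n_entr_y * (length(years) - 1L)
  n <- n0 + n_entr

  # demographics -------------------------------------------------------------
  u_age <- runif_stream(n0, seed, 0L, "gen_age")
  ages0 <- 30L + as.integer(floor(-log(1 - u_age * (1 - exp(-config$age_decay * 71))) /
                                    config$age_decay))
  ages0 <- pmin(ages0, 100L)
  u_sex <- runif_stream(n, seed, 0L, "gen_sex")
  sexes <- ifelse(u_sex < config$prop_male, "male", "female")
  u_dimd <- runif_stream(n, seed, 0L, "gen_dimd")
  dimds <- as.integer(ceiling(u_dimd * 10))
  dimds[dimds < 1L] <- 1L

  entry_years <- c(rep(y0, n0), rep(years[-1L], each = n_entr_y))
  age_at_entry <- c(ages0, rep(30L, n_entr))

  pop <- data.table(
    id = seq_len(n),
    sex = sexes,
    dimd = dimds,
    entry_year = entry_years,
    age_at_entry = age_at_entry,
    birth_year = entry_years - age_at_entry
  )

  # copula exposure ranks ----------------------------------------------------
  R_spear <- config$rank_correlations
  nm <- colnames(R_spear)
  if (!setequal(nm, config$exposures$exposure)) {
    stop("rank_correlations dimnames must match the exposure specs", call. = FALSE)
  }
  R_pear <- 2 * sin(pi * R_spear / 6)
  diag(R_pear) <- 1
  ev <- eigen(R_pear, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("infeasible exposure correlation matrix", call. = FALSE)
  L <- chol(R_pear + diag(1e-10, nrow(R_pear)))
  Z <- vapply(nm, function(e) rnorm_stream(n, seed, 0L, "gen_copula", tag = e),
              numeric(n))
  Zc <- Z %*% L
  ranks <- stats::pnorm(Zc)
  ranks <- pmin(pmax(ranks, 1e-6), 1 - 1e-6)
  for (j in seq_along(nm)) set(pop, j = paste0("rank_", nm[j]), value = ranks[, j])

  # persistent uniform for environmental tobacco smoke exposure
  pop[, u_ets := runif_stream(n, seed, 0L, "gen_ets")]

  # initial smoking state ----------------------------------------------------
  smk <- config$smoking
  p_cur <- plogis(qlogis(smk$current0) + smk$current_dimd * (5.5 - pop$dimd) +
                    smk$current_age * (pop$age_at_entry - 50))
  u1 <- runif_stream(n, seed, 0L, "gen_smoke")
  u2 <- runif_stream(n, seed, 0L, "gen_smoke_ysq")
  status0 <- ifelse(u1 < p_cur, 1L, ifelse(u1 < p_cur + smk$ex0, 2L, 0L))
  years_smokable <- pmax(pop$age_at_entry - 20L, 0L)
  ysq0 <- ifelse(status0 == 2L, 1L + as.integer(floor(u2 * pmin(20, pmax(years_smokable - 1L, 1L)))), 0L)
  pop[, `:=`(smoke_status0 = status0, smoke_ysq0 = ysq0)]

  # seeded prevalent diseases ------------------------------------------------
  conds <- registry$conditions$modelled_name
  dstate <- matrix(0L, n, length(conds), dimnames = list(NULL, conds))
  donset <- matrix(NA_integer_, n, length(conds), dimnames = list(NULL, conds))
  for (cn in conds) {
    row <- registry$rates[modelled_name == cn]
    prev <- condition_target_rate(row, "prevalence", pop$age_at_entry, pop$sex,
                                  pop$dimd, y0)
    prev[pop$entry_year > y0] <- condition_target_rate(
      row, "prevalence", 30L, pop$sex[pop$entry_year > y0],
      pop$dimd[pop$entry_year > y0], y0
    )
    u <- runif_stream(n, seed, 0L, "gen_seed_disease", tag = cn)
    u_back <- runif_stream(n, seed, 0L, "gen_seed_onset", tag = cn)
    seeded <- u < prev
    dstate[seeded, cn] <- 1L
    donset[seeded, cn] <- pop$entry_year[seeded] - as.integer(floor(u_back[seeded] * 9))
  }

  # calibration targets -------------------------------------------------------
  base_counts <- pop[entry_year == y0, .(count = .N), by = .(age = age_at_entry, sex, dimd)]
  entrants <- CJ(year = years[-1L], sex = c("male", "female"), dimd = 1:10)
  prop <- pop[entry_year > y0, .(p = .N / n_entr), by = .(sex, dimd)]
  entrants <- prop[entrants, on = c("sex", "dimd")]
  entrants[is.na(p), p := 0]
  entrants[, `:=`(entrants = p * n_entr_y, p = NULL)]
  targets <- project_population_targets(base_counts, entrants, config$envelope,
                                        years, registry, config)

  structure(list(pop = pop, dstate = dstate, donset = donset,
                 targets = targets, config = config, seed = seed),
            class = "morbsim_population")
}

#' @export
print.morbsim_population <- function(x, ...) {
  n0 <- sum(x$pop$entry_year == x$config$start_year)
  cat("morbsim synthetic population\n")
  cat("  initial cohort: ", n0, " simulants aged ",
      min(x$pop$age_at_entry), "-", max(x$pop$age_at_entry),
      " in ", x$config$start_year, "\n", sep = "")
  cat("  future entrants:", nrow(x$pop) - n0, "(age 30 at entry)\n")
  cat("  seeded active disease states:", sum(x$dstate == 1L), "\n")
  invisible(x)
}

#' Project population calibration targets over the horizon
#'
#' Builds the year-by-stratum target population counts from a base-year count
#' table, annual entrants and the all-cause mortality envelope, using the
#' closed accounting identity `counts(t+1, age+1) = counts(t, age) * (1 -
#' envelope_rate) + entrants`. Ages are capped in the open 100+ bin. The
#' returned object also carries the envelope and the synthetic incidence /
#' case-fatality / initial-prevalence surfaces.
#'
#' @param base_counts `data.table` with columns `age`, `sex`, `dimd`, `count`
#'   for the first year.
#' @param entrants `data.table` with columns `year`, `sex`, `dimd`,
#'   `entrants` (new age-30 entrants), covering every year after the first.
#' @param envelope Envelope parameter list (see [default_generator_config()]).
#' @param years Integer vector of simulated years (full horizon).
#' @param registry A `morbsim_registry`.
#' @param config Generator configuration (for the envelope reference year).
#' @return An object of class `morbsim_targets`: list with `counts`
#'   (year/age/sex/dimd), `entrants`, `envelope`, `rates`, `start_year`.
#' @export
project_population_targets <- function(base_counts, entrants, envelope, years,
                                       registry = load_registry(),
                                       config = default_generator_config()) {
  if (length(years) < 1L) stop("empty horizon", call. = FALSE)
  missing_years <- setdiff(years[-1L], unique(entrants$year))
  if (length(missing_years) && nrow(entrants)) {
    stop("entrants table has horizon gaps: ", paste(missing_years, collapse = ", "),
         call. = FALSE)
  }
  grid <- CJ(age = 30:100, sex = c("male", "female"), dimd = 1:10)
  cur <- base_counts[grid, on = c("age", "sex", "dimd")]
  cur[is.na(count), count := 0]
  cur[, year := years[1L]]
  out <- vector("list", length(years))
  out[[1L]] <- copy(cur)
  y0 <- years[1L]
  for (i in seq_along(years)[-1L]) {
    y <- years[i]
    surv <- copy(cur)
    surv[, count := count * (1 - envelope_rate(age, sex, y - 1L, envelope, y0))]
    surv[, age := pmin(age + 1L, 100L)]
    surv <- surv[, .(count = sum(count)), by = .(age, sex, dimd)]
    nxt <- surv[grid, on = c("age", "sex", "dimd")]
    nxt[is.na(count), count := 0]
    e <- entrants[year == y]
    if (nrow(e)) {
      nxt[e, on = c("sex", "dimd"), count := count + fifelse(age == 30L, entrants, 0),
          by = .EACHI]
    }
    nxt[, year := y]
    cur <- nxt
    out[[i]] <- copy(nxt)
  }
  counts <- rbindlist(out)
  setcolorder(counts, c("year", "age", "sex", "dimd", "count"))
  structure(list(counts = counts, entrants = entrants, envelope = envelope,
                 rates = registry$rates, start_year = y0),
            class = "morbsim_targets")
}

#' Verify the accounting identity of a target table
#'
#' Recomputes the projected counts from the base year, entrants and envelope
#' and errors if any stratum-year deviates from the stored counts by more than
#' `tol` (relative, default 0.5%).
#'
#' @param targets A `morbsim_targets`.
#' @param registry A `morbsim_registry`.
#' @param tol Relative tolerance.
#' @return Invisibly `TRUE`.
#' @export
verify_population_targets <- function(targets, registry = load_registry(),
                                      tol = 0.005) {
  years <- sort(unique(targets$counts$year))
  base <- targets$counts[year == years[1L], .(age, sex, dimd, count)]
  re <- project_population_targets(base, targets$entrants, targets$envelope,
                                   years, registry)
  cmp <- merge(targets$counts, re$counts, by = c("year", "age", "sex", "dimd"))
  dev <- cmp[, abs(count.x - count.y) / pmax(count.x, 1e-9)]
  keep <- cmp$count.x > 1  # ignore near-empty strata
  if (any(dev[keep] > tol)) {
    stop("population targets violate the accounting identity (max relative deviation ",
         signif(max(dev[keep]), 3), ")", call. = FALSE)
  }
  invisible(TRUE)
}
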