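# Exposure engine: annual exposure projection at fixed lifetime ranks,
# smoking dynamics and environmental tobacco smoke (ETS) derivation.
#
# Exposure values are a deterministic function of (rank, age, sex, dimd,
# year), so the lag buffer is realised as precomputed per-exposure matrices
# (simulant x year) spanning the horizon plus the longest risk-link lag;
# the value consulted for a link with lag L in year t is exactly the value
# produced for year t - L.

# location of the linked-scale distribution for one exposure spec row
exposure_location <- function(spec, age, sex, dimd, year, ref_year = 2013L) {
  spec$m0 + spec$sex_effect * (sex == "male") +
    spec$age_slope * (pmin(pmax(age, 30), 100) - 50) +
    spec$dimd_slope * (5.5 - dimd) +
    spec$trend * (year - ref_year)
}

#' Project an exposure value at a fixed rank
#'
#' Returns the quantile at `rank` of the stratum-year exposure distribution.
#' The location parameter evolves log-linearly in calendar time (log link for
#' positive-scale exposures, logit link on days/7 for physical activity) and
#' the result is clamped to the spec bounds. Because the rank is fixed for
#' life, quintile-group membership is constant and a zero trend yields a
#' constant value across years.
#'
#' @param spec One row of an exposure specification table
#'   ([default_exposure_specs()]).
#' @param rank Percentile rank in (0, 1), fixed per simulant.
#' @param age,sex,dimd Stratum: age in years, `"male"`/`"female"`, deprivation
#'   decile (1 = most deprived).
#' @param year Calendar year.
#' @param ref_year Year at which the trend is anchored.
#' @return Exposure value in the exposure's units.
#' @export
#' @examples
#' spec <- default_exposure_specs()[exposure == "bmi"]
#' project_exposure(spec, 0.5, age = 50, sex = "female", dimd = 5, year = 2013)
project_exposure <- function(spec, rank, age, sex, dimd, year, ref_year = 2013L) {
  if (any(rank <= 0 | rank >= 1)) stop("rank must be in (0, 1)", call. = FALSE)
  m <- exposure_location(spec, age, sex, dimd, year, ref_year)
  q <- m + spec$sd * qnorm(rank)
  v <- switch(spec$link,
              log = exp(q),
              logit7 = 7 * plogis(q),
              stop("unknown link: ", spec$link, call. = FALSE))
  v <- pmin(pmax(v, spec$lower), spec$upper)
  if (spec$link == "logit7") v <- round(v)
  v
}

# Precompute per-exposure trajectory matrices for all simulants over
# `years` (typically horizon plus max lag of back-filled history). Ages are
# the simulant's age in each year, clamped to the supported 30-100 band for
# pre-entry history.
build_exposure_trajectories <- function(popobj, years) {
  pop <- popobj$pop
  specs <- popobj$config$exposures
  ref_year <- popobj$config$start_year
  out <- list()
  for (i in seq_len(nrow(specs))) {
    spec <- specs[i]
    rk <- pop[[paste0("rank_", spec$exposure)]]
    M <- matrix(NA_real_, nrow(pop), length(years),
                dimnames = list(NULL, as.character(years)))
    for (j in seq_along(years)) {
      y <- years[j]
      age_y <- pop$age_at_entry + (y - pop$entry_year)
      M[, j] <- project_exposure(spec, rk, age_y, pop$sex, pop$dimd, y, ref_year)
    }
    out[[spec$exposure]] <- M
  }
  attr(out, "years") <- years
  out
}

# column index helper for trajectory/smoking matrices
year_col <- function(M, year) {
  j <- match(as.character(year), colnames(M))
  if (is.na(j)) stop("year ", year, " outside the precomputed horizon", call. = FALSE)
  j
}

# lagged exposure lookup: value produced for year - lag (clamped to the
# earliest back-filled column)
lagged_exposure <- function(traj, exposure, year, lag) {
  M <- traj[[exposure]]
  yrs <- as.integer(colnames(M))
  y <- max(year - lag, yrs[1L])
  M[, year_col(M, y)]
}

#' Advance smoking histories by one year
#'
#' Applies the annual stochastic smoking transitions to a table of smoking
#' histories: never-smokers initiate with probability `initiation`, current
#' smokers quit with probability `cessation`, pack-years accumulate by
#' cigarettes-per-day / 20 while current, and years-since-quit increments
#' while ex. Status codes: 0 never, 1 current, 2 ex.
#'
#' @param history `data.table` with columns `status`, `cigarettes_per_day`,
#'   `pack_years`, `years_since_quit` (modified by copy).
#' @param initiation,cessation Transition probabilities in `[0, 1]` (scalar or
#'   per-row).
#' @param u_init,u_cess Uniform draws, one per row (supply from a dedicated
#'   stream for common-random-number runs).
#' @param cig_if_current Cigarettes/day to assign to new initiators (and to
#'   carry for continuing smokers); scalar or per-row.
#' @return A new `data.table` with the updated history.
#' @export
update_smoking <- function(history, initiation, cessation, u_init, u_cess,
                           cig_if_current = history$cigarettes_per_day) {
  if (any(initiation < 0 | initiation > 1) || any(cessation < 0 | cessation > 1)) {
    stop("transition rates must be in [0, 1]", call. = FALSE)
  }
  h <- copy(history)
  civ <- if (length(cig_if_current) == 1L) rep(cig_if_current, nrow(h)) else cig_if_current
  was_current <- h$status == 1L
  was_ex <- h$status == 2L
  starts <- h$status == 0L & u_init < initiation
  quits <- was_current & u_cess < cessation
  # accumulate while current (before this year's transition takes effect at
  # year end): a full smoked year adds cig/20 pack-years
  h[was_current, pack_years := pack_years + cigarettes_per_day / 20]
  h[quits, `:=`(status = 2L, years_since_quit = 0L, cigarettes_per_day = 0)]
  h[was_ex, years_since_quit := years_since_quit + 1L]
  h[starts, status := 1L]
  now_current <- which(h$status == 1L)
  h[now_current, cigarettes_per_day := civ[now_current]]
  h
}

# Simulate base-case smoking history matrices for all simulants over `years`.
# Columns before the generator start year are back-filled with the initial
# state (only lagged *status* is ever consulted there).
simulate_smoking_histories <- function(popobj, years, traj, master_seed, iteration) {
  pop <- popobj$pop
  cfg <- popobj$config$smoking
  n <- nrow(pop)
  y0 <- popobj$config$start_year
  ny <- length(years)
  status <- matrix(0L, n, ny, dimnames = list(NULL, as.character(years)))
  cig <- matrix(0, n, ny, dimnames = list(NULL, as.character(years)))
  py <- matrix(0, n, ny, dimnames = list(NULL, as.character(years)))
  ysq <- matrix(0L, n, ny, dimnames = list(NULL, as.character(years)))

  cig_traj <- traj[["cig"]]
  j0 <- match(as.character(y0), colnames(status))
  st <- pop$smoke_status0
  cur_cig <- ifelse(st == 1L, pmax(round(cig_traj[, j0]), 1), 0)
  cur_py <- ifelse(st == 1L, cur_cig / 20 * pmax(pop$age_at_entry - 20, 0),
                   ifelse(st == 2L,
                          pmax(round(cig_traj[, j0]), 1) / 20 *
                            pmax(pop$age_at_entry - 20 - pop$smoke_ysq0, 1),
                          0))
  cur_ysq <- pop$smoke_ysq0

  # back-fill pre-start columns with the initial state
  for (j in seq_len(j0)) {
    status[, j] <- st
    cig[, j] <- cur_cig
    py[, j] <- cur_py
    ysq[, j] <- cur_ysq
  }

  h <- data.table(status = st, cigarettes_per_day = cur_cig,
                  pack_years = cur_py, years_since_quit = cur_ysq)
  for (j in (j0 + 1L):ny) {
    y <- years[j]
    age_y <- pop$age_at_entry + (y - pop$entry_year)
    init_rate <- ifelse(age_y < 40, cfg$initiation, 0)
    u_init <- runif_stream(n, master_seed, iteration, "smoke_init", y)
    u_cess <- runif_stream(n, master_seed, iteration, "smoke_cess", y)
    h <- update_smoking(h, init_rate, cfg$cessation, u_init, u_cess,
                        cig_if_current = pmax(round(cig_traj[, j]), 1))
    status[, j] <- h$status
    cig[, j] <- h$cigarettes_per_day
    py[, j] <- h$pack_years
    ysq[, j] <- h$years_since_quit
  }
  list(status = status, cig = cig, pack_years = py, years_since_quit = ysq)
}

#' Probability of environmental tobacco smoke exposure
#'
#' ETS exposure of a non-smoker is proportional to the smoking prevalence in
#' their stratum: `min(coupling * prevalence, 1)`. When smoking is eliminated
#' the ETS probability is zero. Current smokers carry direct smoking risk and
#' must not be passed in.
#'
#' @param is_current_smoker Logical vector.
#' @param smoking_prevalence Stratum smoking prevalence in `[0, 1]`.
#' @param coupling Non-negative proportionality constant.
#' @return ETS exposure probability in `[0, 1]`.
#' @export
derive_ets <- function(is_current_smoker, smoking_prevalence, coupling) {
  if (any(is_current_smoker)) {
    stop("ETS exposure is defined for non-smokers only", call. = FALSE)
  }
  if (any(smoking_prevalence < 0 | smoking_prevalence > 1)) {
    stop("prevalence must be in [0, 1]", call. = FALSE)
  }
  pmin(coupling * smoking_prevalence, 1)
}

# ETS exposure matrix for an arm: a simulant is exposed in year y iff their
# persistent uniform falls below coupling x smoking prevalence in their
# sex-by-quintile stratum that year (and they are not a current smoker).
# The persistent uniform makes population ETS prevalence non-increasing under
# any scenario that lowers smoking prevalence, and identical across arms.
build_ets_matrix <- function(popobj, smoke_status, years) {
  pop <- popobj$pop
  coupling <- popobj$config$ets_coupling
  n <- nrow(pop)
  ets <- matrix(FALSE, n, length(years), dimnames = list(NULL, as.character(years)))
  qg <- ceiling(pop$dimd / 2)
  strat <- paste(pop$sex, qg)
  for (j in seq_along(years)) {
    present <- pop$entry_year <= years[j]
    st <- smoke_status[, j]
    prev <- tapply((st == 1L)[present], strat[present], mean)
    pv <- unname(prev[strat])
    pv[is.na(pv)] <- 0
    p_exposed <- derive_ets(rep(FALSE, n), pv, coupling)
    ets[, j] <- pop$u_ets < p_exposed & st != 1L
  }
  ets
}
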