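# Outcomes: aggregation of simulant histories into the reported metrics with
# Monte-Carlo uncertainty, stratification, standardisation and inequality
# summaries.

age_group_of <- function(age) {
  g <- pmin(age %/% 10L * 10L, 90L)
  ifelse(g >= 90L, "90+", paste0(g, "-", g + 9L))
}

BIRTH_COHORTS <- list("1949-1953" = 1949:1953,
                      "1969-1973" = 1969:1973,
                      "1989-1993" = 1989:1993)

# One year's accumulation of cube rows for one arm-iteration.
# score_start/score_end: CMS scores at the start/end of the annual step;
# alive_start: alive at the start of the year (the mortality denominator).
accumulate_year <- function(pop, year, iteration, scenario_name,
                            alive_start, alive_end, died,
                            score_start, score_end, threshold) {
  age_y <- pop$age_at_entry + (year - pop$entry_year)
  major_start <- is_major_illness(score_start, threshold)
  major_end <- is_major_illness(score_end, threshold)
  at_risk <- alive_start & !major_start
  crossing <- at_risk & major_end

  strata <- list(
    overall = list(overall = rep(TRUE, nrow(pop))),
    quintile = split(seq_len(nrow(pop)), ceiling(pop$dimd / 2)),
    age_group = split(seq_len(nrow(pop)), age_group_of(age_y)),
    cohort = lapply(BIRTH_COHORTS, function(b) which(pop$birth_year %in% b))
  )
  rows <- list()
  for (st in names(strata)) {
    for (sv in names(strata[[st]])) {
      idx <- strata[[st]][[sv]]
      if (st == "overall") idx <- which(idx)
      rows[[paste(st, sv)]] <- data.table(
        iteration = iteration, scenario = scenario_name, year = year,
        stratum_type = st, stratum = as.character(sv),
        n_alive = sum(alive_end[idx]),
        n_major = sum(alive_end[idx] & major_end[idx]),
        n_without = sum(alive_end[idx] & !major_end[idx]),
        n_deaths = sum(died[idx]),
        n_alive_start = sum(alive_start[idx]),
        n_at_risk = sum(at_risk[idx]),
        n_crossings = sum(crossing[idx])
      )
    }
  }
  rbindlist(rows)
}

#' Incidence rate of major illness in a cube stratum-year
#'
#' New crossings of the CMS threshold (score moving from at-or-below to
#' strictly above within the year) divided by persons at risk (alive at the
#' start of the year and not yet major-ill).
#'
#' @param cube A results cube.
#' @param at_year Calendar year.
#' @param stratum_type,stratum Stratum selector (default overall).
#' @param scenario_name Scenario arm.
#' @return `data.table` with per-iteration rates; zero at-risk denominators
#'   are flagged as `NA` with a warning.
#' @export
major_illness_incidence <- function(cube, at_year, stratum_type = "overall",
                                    stratum = "overall",
                                    scenario_name = "baseline") {
  st <- stratum
  rows <- cube[year == at_year & cube$stratum_type == stratum_type &
                 cube$stratum == st & scenario == scenario_name]
  if (!nrow(rows)) stop("no cube rows match", call. = FALSE)
  out <- rows[, .(iteration, rate = n_crossings / n_at_risk)]
  if (any(rows$n_at_risk == 0L)) {
    warning("zero at-risk denominator; rate undefined", call. = FALSE)
    out[rows$n_at_risk == 0L, rate := NA_real_]
  }
  out
}

#' Case-years of major illness prevented or postponed
#'
#' Per iteration, the sum over the horizon of the difference in counts living
#' with major illness between the base-case and scenario arms (positive =
#' case-years prevented; negative values mean the scenario increases
#' case-years, e.g. when mortality falls more than incidence).
#'
#' @param cube A results cube containing both arms.
#' @param scenario_name Scenario arm.
#' @param base_name Comparator arm (default `"baseline"`).
#' @param horizon Years summed over.
#' @return `data.table` with per-iteration `case_years`.
#' @export
case_years_prevented <- function(cube, scenario_name, base_name = "baseline",
                                 horizon = 2023:2043) {
  b <- cube[scenario == base_name & stratum_type == "overall" & year %in% horizon,
            .(iteration, year, n_major)]
  s <- cube[scenario == scenario_name & stratum_type == "overall" &
              year %in% horizon, .(iteration, year, n_major)]
  if (!nrow(b) || !nrow(s)) stop("arm missing from cube", call. = FALSE)
  m <- merge(b, s, by = c("iteration", "year"), suffixes = c("_base", "_scen"))
  if (nrow(m) != nrow(b) || nrow(m) != nrow(s)) {
    stop("arms do not share iterations and years", call. = FALSE)
  }
  m[, .(case_years = sum(n_major_base - n_major_scen)), by = iteration]
}

#' Age-standardise prevalence to a reference population structure
#'
#' Weighted average of age-group-specific prevalence using reference
#' population counts as weights; removes demographic-change effects from
#' scenario comparisons (e.g. holding the 2023 age structure fixed).
#'
#' @param age_specific `data.table` with columns `age_group` and `prevalence`.
#' @param reference `data.table` with columns `age_group` and `count`.
#' @return Standardised proportion.
#' @export
standardise_to_reference <- function(age_specific, reference) {
  missing <- setdiff(reference$age_group[reference$count > 0],
                     age_specific$age_group)
  if (length(missing)) {
    stop("missing age group(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- merge(age_specific, reference, by = "age_group")
  sum(m$prevalence * m$count) / sum(m$count)
}

#' Deprivation gradient of a scenario effect
#'
#' Per iteration, the difference between the most-deprived (quintile group 1)
#' and least-deprived (quintile group 5) reductions in a metric under the
#' scenario versus the base case; positive = larger reduction among the most
#' deprived. `direction_probability` is the fraction of iterations with a
#' positive difference.
#'
#' @param cube A results cube.
#' @param at_year Calendar year.
#' @param scenario_name,base_name Arms compared.
#' @param metric `"prevalence"` (major illness among alive) for now.
#' @return List with `per_iteration` (differences), `difference` (mean) and
#'   `direction_probability`.
#' @export
inequality_gradient <- function(cube, at_year, scenario_name,
                                base_name = "baseline",
                                metric = "prevalence") {
  q <- cube[stratum_type == "quintile" & year == at_year &
              scenario %in% c(scenario_name, base_name)]
  if (!nrow(q)) stop("cube lacks quintile strata for that year", call. = FALSE)
  q[, prevalence := n_major / pmax(n_alive, 1L)]
  w <- dcast(q, iteration + stratum ~ scenario, value.var = "prevalence")
  setnames(w, c(base_name, scenario_name), c("base", "scen"))
  w[, reduction := base - scen]
  d <- dcast(w[stratum %in% c("1", "5")], iteration ~ stratum,
             value.var = "reduction")
  diffs <- d[["1"]] - d[["5"]]
  list(per_iteration = data.table(iteration = d$iteration, difference = diffs),
       difference = mean(diffs),
       direction_probability = mean(diffs > 0))
}

#' Summarise a cube metric across Monte-Carlo iterations
#'
#' Computes the per-iteration metric (optionally differenced against a
#' comparator arm within the same iteration, preserving the common-random-
#' number pairing), then returns the mean and the 2.5th/97.5th percentiles
#' (linear interpolation on the sorted values) across iterations.
#'
#' @param cube A results cube.
#' @param metric One of `"prevalence"`, `"incidence"`, `"mortality_per_10k"`,
#'   `"n_major"`, `"n_without"`, `"n_alive"`.
#' @param scenario_name Arm to summarise.
#' @param at_year Calendar year.
#' @param comparator Optional comparator arm; with `type = "absolute"` the
#'   per-iteration difference `comparator - scenario` is summarised, with
#'   `type = "relative"` the relative difference `(comparator -
#'   scenario)/comparator`.
#' @param type `"absolute"` or `"relative"` (ignored without a comparator).
#' @param stratum_type,stratum Stratum selector.
#' @return List of class `morbsim_summary`: `central`, `lower`, `upper`,
#'   `n_iterations`, `per_iteration`.
#' @export
summarise_cube <- function(cube, metric, scenario_name, at_year,
                           comparator = NULL, type = c("absolute", "relative"),
                           stratum_type = "overall", stratum = "overall") {
  type <- match.arg(type)
  st <- stratum_type
  sv <- stratum
  pick <- function(arm) {
    r <- cube[scenario == arm & year == at_year & cube$stratum_type == st &
                cube$stratum == sv]
    if (!nrow(r)) stop("no cube rows for arm ", arm, call. = FALSE)
    val <- switch(metric,
                  prevalence = r$n_major / pmax(r$n_alive, 1L),
                  incidence = r$n_crossings / pmax(r$n_at_risk, 1L),
                  mortality_per_10k = r$n_deaths / pmax(r$n_alive_start, 1L) * 1e4,
                  n_major = r$n_major,
                  n_without = r$n_without,
                  n_alive = r$n_alive,
                  stop("unknown metric: ", metric, call. = FALSE))
    r[, .(iteration, value = val)]
  }
  x <- pick(scenario_name)
  if (!is.null(comparator)) {
    y <- pick(comparator)
    m <- merge(y, x, by = "iteration", suffixes = c("_cmp", "_scn"))
    x <- m[, .(iteration,
               value = if (type == "absolute") value_cmp - value_scn
               else (value_cmp - value_scn) / value_cmp)]
  }
  v <- x$value
  out <- list(central = mean(v),
              lower = if (length(v) > 1L) unname(quantile(v, 0.025)) else NA_real_,
              upper = if (length(v) > 1L) unname(quantile(v, 0.975)) else NA_real_,
              n_iterations = length(v),
              per_iteration = x)
  class(out) <- "morbsim_summary"
  out
}

#' @export
print.morbsim_summary <- function(x, ...) {
  cat(sprintf("%.6g (95%% UI %.6g, %.6g) over %d iterations\n",
              x$central, x$lower, x$upper, x$n_iterations))
  invisible(x)
}
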