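test_that("threshold crossings are counted from scripted histories", {
  pop <- data.table::data.table(
    id = 1:4, sex = "female", dimd = 4L, entry_year = 2013L,
    age_at_entry = c(50L, 60L, 70L, 80L), birth_year = c(1973L, 1963L, 1953L, 1943L)
  )
  alive_start <- rep(TRUE, 4)
  alive_end <- c(TRUE, TRUE, TRUE, FALSE)
  died <- c(FALSE, FALSE, FALSE, TRUE)
  # simulant 1 gains dementia (2.50) from score 0: one crossing
  score_start <- c(0, 1.6, 0.3, 0)
  score_end <- c(2.50, 1.8, 0.3, 0)
  rows <- morbsim:::accumulate_year(pop, 2025L, 1L, "baseline", alive_start,
                                    alive_end, died, score_start, score_end, 1.5)
  ov <- rows[stratum_type == "overall"]
  expect_equal(ov$n_crossings, 1L)
  expect_equal(ov$n_at_risk, 3L) # simulant 2 already major at the year start
  expect_equal(ov$n_major, 2L) # 1 and 2 alive and major at year end
  expect_equal(ov$n_alive, 3L)
  expect_equal(ov$n_deaths, 1L)
  expect_equal(ov$n_major + ov$n_without, ov$n_alive)
})

test_that("incidence rates divide crossings by the at-risk population", {
  years <- 2023:2025
  cube <- fabricate_cube(2, years,
                         base_major = list(c(100, 110, 120), c(90, 100, 110)),
                         scen_major = list(c(100, 105, 110), c(90, 95, 100)))
  cube[scenario == "baseline" & year == 2024 & iteration == 1,
       `:=`(n_crossings = 3L, n_at_risk = 1000L)]
  r <- major_illness_incidence(cube, 2024, scenario_name = "baseline")
  expect_equal(r[iteration == 1, rate], 0.003)
  expect_equal(r[iteration == 2, rate], 0)
  cube0 <- data.table::copy(cube)[, n_at_risk := 0L]
  expect_warning(major_illness_incidence(cube0, 2024, scenario_name = "baseline"),
                 "zero")
})

test_that("case-years prevented sum the paired arm differences", {
  years <- 2023:2043
  base <- lapply(1:2, function(i) rep(1000L, 21))
  scen <- lapply(1:2, function(i) rep(900L, 21))
  cube <- fabricate_cube(2, years, base, scen)
  cy <- case_years_prevented(cube, "scn", horizon = years)
  expect_equal(cy$case_years, c(2100L, 2100L)) # 100 fewer in each of 21 years
  # identical arms: zero
  cube_id <- fabricate_cube(1, years, base[1], base[1])
  expect_equal(case_years_prevented(cube_id, "scn", horizon = years)$case_years, 0L)
  # negative totals are permitted (scenario increases case-years)
  cube_neg <- fabricate_cube(1, years, base[1],
                             list(rep(1100L, 21)))
  expect_equal(case_years_prevented(cube_neg, "scn", horizon = years)$case_years,
               -2100L)
  expect_error(case_years_prevented(cube, "absent"), "arm missing")
})

test_that("case-years match a brute-force per-simulant recount", {
  run <- small_run()
  horizon <- 2023:2043
  for (arm in c("tmrel_all", "improve10")) {
    cy <- case_years_prevented(run$cube, arm, horizon = horizon)
    for (it in 1:2) {
      base_py <- run$person_years[[paste0("baseline_", it)]]
      scen_py <- run$person_years[[paste0(arm, "_", it)]]
      brute <- sum(base_py) - sum(scen_py) # person-year count difference
      expect_equal(cy[iteration == it, case_years], brute)
    }
  }
})

test_that("age standardisation is a reference-weighted mean", {
  ref <- data.table::data.table(age_group = c("30-39", "40-49"),
                                count = c(3000, 1000))
  asp <- data.table::data.table(age_group = c("30-39", "40-49"),
                                prevalence = c(0.1, 0.3))
  expect_equal(standardise_to_reference(asp, ref), (0.1 * 3 + 0.3) / 4)
  # constant prevalence passes through
  aspc <- data.table::data.table(age_group = ref$age_group, prevalence = 0.2)
  expect_equal(standardise_to_reference(aspc, ref), 0.2)
  # ages with zero reference weight cannot move the result
  ref0 <- rbind(ref, data.table::data.table(age_group = "90+", count = 0))
  asp9 <- rbind(asp, data.table::data.table(age_group = "90+", prevalence = 1))
  expect_equal(standardise_to_reference(asp9, ref0),
               standardise_to_reference(asp, ref))
  expect_error(standardise_to_reference(asp[1], ref), "missing age")
})

test_that("the deprivation gradient reports sign and direction probability", {
  years <- 2043L
  rows <- list()
  for (it in 1:10) {
    for (q in 1:5) {
      for (arm in c("baseline", "scn")) {
        # scenario lowers prevalence by 1pp everywhere plus 0.4pp extra in the
        # most deprived quintile group
        prev <- 0.30 - (if (arm == "scn") 0.01 + 0.004 * (q == 1) else 0)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          iteration = it, scenario = arm, year = years,
          stratum_type = "quintile", stratum = as.character(q),
          n_alive = 10000L, n_major = round(prev * 10000), n_without = 0L,
          n_deaths = 0L, n_alive_start = 10000L, n_at_risk = 0L,
          n_crossings = 0L
        )
      }
    }
  }
  cube <- data.table::rbindlist(rows)
  g <- inequality_gradient(cube, 2043, "scn")
  expect_equal(g$difference, 0.004, tolerance = 1e-6)
  expect_equal(g$direction_probability, 1.0)
  # identical quintile effects: zero difference
  cube2 <- data.table::copy(cube)
  cube2[scenario == "scn", n_major := round(0.29 * 10000)]
  g2 <- inequality_gradient(cube2, 2043, "scn")
  expect_equal(g2$difference, 0)
})

test_that("summaries use paired differences and interpolated percentiles", {
  years <- 2043L
  base <- lapply(1:100, function(i) 500L + i)
  scen <- lapply(1:100, function(i) 400L + i)
  cube <- fabricate_cube(100, years, base, scen)
  s <- summarise_cube(cube, "n_major", "scn", 2043)
  v <- sapply(scen, identity)
  expect_equal(s$central, mean(v))
  expect_equal(s$lower, unname(quantile(v, 0.025)))
  expect_equal(s$upper, unname(quantile(v, 0.975)))
  # paired absolute difference is exactly 100 in every iteration
  d <- summarise_cube(cube, "n_major", "scn", 2043, comparator = "baseline")
  expect_equal(d$central, 100)
  expect_equal(d$upper - d$lower, 0)
  # relative difference definition: (base - scen)/base on the metric
  r <- summarise_cube(cube, "n_major", "scn", 2043, comparator = "baseline",
                      type = "relative")
  expect_equal(r$per_iteration$value, (unlist(base) - v) / unlist(base))
  # shuffling the iteration pairing must widen the interval
  cube_shuf <- data.table::copy(cube)
  cube_shuf[scenario == "scn", iteration := sample(iteration)]
  d2 <- summarise_cube(cube_shuf, "n_major", "scn", 2043,
                       comparator = "baseline")
  expect_gt(d2$upper - d2$lower, 0)
  # all-identical iterations collapse to a zero-width interval
  cube_id <- fabricate_cube(5, years, rep(list(600L), 5), rep(list(550L), 5))
  s_id <- summarise_cube(cube_id, "n_major", "scn", 2043)
  expect_equal(s_id$lower, s_id$upper)
})

test_that("counts are conserved and cohorts partition in a real run", {
  run <- small_run()
  cube <- run$cube
  expect_true(all(cube$n_major + cube$n_without == cube$n_alive))
  # quintile strata partition the overall rows
  q <- cube[stratum_type == "quintile",
            .(tot = sum(n_alive)), by = .(scenario, iteration, year)]
  ov <- cube[stratum_type == "overall",
             .(scenario, iteration, year, n_alive)]
  m <- merge(q, ov, by = c("scenario", "iteration", "year"))
  expect_equal(m$tot, m$n_alive)
  # birth cohorts are disjoint
  ch <- morbsim:::BIRTH_COHORTS
  expect_equal(length(Reduce(intersect, ch)), 0L)
  expect_equal(anyDuplicated(unlist(ch)), 0L)
})
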