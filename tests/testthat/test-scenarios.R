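test_that("relative-improvement rule removes the stated share of excess", {
  expect_equal(apply_relative_improvement(28, 22, 0.10), 27.4)
  expect_equal(apply_relative_improvement(22, 22, 0.10), 22)
  expect_equal(apply_relative_improvement(28, 22, 1.0), 22)
  expect_error(apply_relative_improvement(28, 22, -0.1), "non-negative")
  # never crosses below the TMREL, for any value and fraction
  set.seed(3)
  v <- runif(200, 15, 45)
  f <- runif(200)
  out <- apply_relative_improvement(v, 22, f)
  expect_true(all(out >= pmin(v, 22) - 1e-12))
  expect_true(all(out <= v + 1e-12))
})

test_that("relative excess reduction reproduces the reporting arithmetic", {
  expect_equal(round(100 * relative_excess_reduction(125.3, 122.6, 112), 1),
               20.3)
  expect_equal(relative_excess_reduction(130, 130, 112), 0)
  expect_equal(relative_excess_reduction(125.3, 112, 112), 1)
  expect_error(relative_excess_reduction(110, 108, 112), "no excess")
  # smoking prevalence fall 15.5% -> 12.9% is a 17% relative reduction
  expect_equal(round(100 * relative_excess_reduction(15.5, 12.9, 0)), 17)
})

test_that("BMI mediation applies the coefficients above the floor only", {
  med <- test_registry()$mediation
  d <- apply_bmi_mediation(1.0, 30, med)
  expect_equal(d$delta_sbp, 2.55)
  expect_equal(d$delta_tc, 0.23)
  d2 <- apply_bmi_mediation(0.6, 28, med)
  expect_equal(d2$delta_sbp, 1.53)
  expect_equal(d2$delta_tc, 0.138)
  d3 <- apply_bmi_mediation(1.0, 24, med)
  expect_equal(d3$delta_sbp, 0)
  expect_equal(d3$delta_tc, 0)
  expect_error(apply_bmi_mediation(-1, 30, med), "non-negative")
})

test_that("TMRELs are sampled within support and fixed within an iteration", {
  tm <- test_registry()$tmrel
  a <- sample_tmrels(tm, 1L, 1L)
  b <- sample_tmrels(tm, 1L, 1L)
  expect_identical(a, b)
  c <- sample_tmrels(tm, 1L, 2L)
  expect_false(identical(a, c))
  for (i in seq_len(nrow(tm))) {
    expect_gte(a[[tm$exposure[i]]], tm$support_lo[i])
    expect_lte(a[[tm$exposure[i]]], tm$support_hi[i])
  }
  expect_equal(a[["pa"]], 7)
  expect_equal(a[["smoking"]], 0)
})

test_that("TMREL smoking transform quits smokers, freezes history, is idempotent", {
  popobj <- cached("pop300", generate_population(
    default_generator_config(n_simulants = 300L), seed = 11L,
    registry = test_registry()
  ))
  years <- 2004:2043
  traj <- morbsim:::build_exposure_trajectories(popobj, years)
  smoke <- morbsim:::simulate_smoking_histories(popobj, years, traj, 11L, 1L)
  out <- apply_tmrel_smoking(smoke, 2023L)
  j23 <- match("2023", colnames(smoke$status))
  j30 <- match("2030", colnames(smoke$status))
  cur23 <- smoke$status[, j23] == 1L
  expect_true(all(out$status[cur23, j23] == 2L))
  expect_true(all(out$cig[, j23:ncol(out$cig)] == 0))
  # pack-years frozen at the quit year
  expect_equal(out$pack_years[cur23, j30], smoke$pack_years[cur23, j23])
  # years since quit count from the start year
  init23 <- cur23 & popobj$pop$entry_year <= 2023
  expect_equal(out$years_since_quit[init23, j30], rep(7L, sum(init23)))
  # base-case never-smokers (who never initiated by 2023) remain never
  nev <- smoke$status[, j23] == 0L
  expect_true(all(out$status[nev, j30] == 0L))
  # idempotence
  out2 <- apply_tmrel_smoking(out, 2023L)
  expect_identical(out, out2)
})

test_that("fractional smoking improvement removes the expected share of smokers", {
  popobj <- big_population()
  years <- 2004:2043
  traj <- morbsim:::build_exposure_trajectories(popobj, years)
  smoke <- morbsim:::simulate_smoking_histories(popobj, years, traj, 99L, 1L)
  u <- runif_stream(nrow(popobj$pop), 99L, 1L, "smoke_scn")
  out0 <- apply_smoking_improvement(smoke, 0, u, 2023L, popobj$pop$entry_year)
  expect_identical(out0, smoke)
  out <- apply_smoking_improvement(smoke, 0.10, u, 2023L, popobj$pop$entry_year)
  j <- match("2030", colnames(smoke$status))
  n_base <- sum(smoke$status[, j] == 1L)
  n_scn <- sum(out$status[, j] == 1L)
  se <- sqrt(n_base * 0.1 * 0.9)
  expect_lt(abs(n_scn - 0.9 * n_base), 4 * se)
  # remaining smokers consume 10% less
  still <- smoke$status[, j] == 1L & out$status[, j] == 1L
  expect_equal(out$cig[still, j], smoke$cig[still, j] * 0.9)
  # full elimination matches the TMREL smoking arm's statuses
  out1 <- apply_smoking_improvement(smoke, 1, u, 2023L, popobj$pop$entry_year)
  tm <- apply_tmrel_smoking(smoke, 2023L)
  jj <- which(2004:2043 >= 2023)
  expect_equal(out1$status[, jj] == 1L, tm$status[, jj] == 1L)
  expect_equal(sum(out1$status[, jj] == 1L), 0L)
})

test_that("physical-activity improvement adds one day to the configured share", {
  pa <- matrix(c(7, 3, 5, 2), 4, 3, dimnames = list(NULL, 2022:2024))
  out_all <- apply_physical_activity_improvement(pa, 1, 2023L, 1L, 1L)
  expect_equal(out_all[, "2022"], pa[, "2022"]) # before the start year
  expect_equal(out_all[, "2023"], c(7, 4, 6, 3)) # everyone below 7 gains 1
  popobj <- big_population()
  base_pa <- matrix(rep(pmin(round(7 * popobj$pop$rank_pa), 6), 2),
                    ncol = 2, dimnames = list(NULL, 2023:2024))
  out <- apply_physical_activity_improvement(base_pa, 0.1, 2023L, 2L, 1L)
  gain <- mean(out[, 1] - base_pa[, 1])
  expect_lt(abs(gain - 0.1), 0.01)
  expect_true(all(out <= 7))
  # saturated population unchanged
  sat <- matrix(7, 10, 1, dimnames = list(NULL, 2023))
  expect_equal(apply_physical_activity_improvement(sat, 1, 2023L, 1L, 1L), sat)
})

test_that("scenario transforms respect the dose ordering and exact rules", {
  popobj <- cached("pop2000", generate_population(
    default_generator_config(n_simulants = 2000L), seed = 5L,
    registry = test_registry()
  ))
  reg <- test_registry()
  years <- 2004:2043
  traj <- morbsim:::build_exposure_trajectories(popobj, years)
  smoke <- morbsim:::simulate_smoking_histories(popobj, years, traj, 5L, 1L)
  base <- list(traj = traj, smoke = smoke,
               ets = morbsim:::build_ets_matrix(popobj, smoke$status, years))
  tmrels <- sample_tmrels(reg$tmrel, 5L, 1L)
  s10 <- morbsim:::scenario_exposures(
    popobj, base, scenario("i10", "relative_improvement"), tmrels, reg, 5L, 1L
  )
  stm <- morbsim:::scenario_exposures(
    popobj, base, scenario("tm", "tmrel"), tmrels, reg, 5L, 1L
  )
  jj <- which(years >= 2023)
  # monotone dose: improvement BMI between the base case and the TMREL arm
  # (for simulants above the TMREL; below it neither transform raises risk)
  expect_true(all(s10$traj$bmi[, jj] <= base$traj$bmi[, jj] + 1e-12))
  above <- base$traj$bmi[, jj] >= tmrels[["bmi"]]
  expect_true(all(s10$traj$bmi[, jj][above] >= stm$traj$bmi[, jj][above] - 1e-12))
  # fruit/veg move together: exactly +10% and never negative
  expect_equal(s10$traj$fruit[, jj], base$traj$fruit[, jj] * 1.1)
  expect_equal(s10$traj$veg[, jj], base$traj$veg[, jj] * 1.1)
  expect_true(all(s10$traj$fruit >= 0))
  # pre-start columns untouched in every factor
  pre <- which(years < 2023)
  expect_identical(s10$traj$sbp[, pre], base$traj$sbp[, pre])
  expect_identical(stm$traj$sbp[, pre], base$traj$sbp[, pre])
  # TMREL sets the continuous factors to the sampled levels
  expect_true(all(stm$traj$bmi[, jj] == tmrels[["bmi"]]))
  expect_true(all(stm$traj$pa[, jj] == 7))
})

test_that("mediation lowers SBP in the BMI arm without crossing the TMREL", {
  popobj <- cached("pop2000", generate_population(
    default_generator_config(n_simulants = 2000L), seed = 5L,
    registry = test_registry()
  ))
  reg <- test_registry()
  years <- 2004:2043
  traj <- morbsim:::build_exposure_trajectories(popobj, years)
  smoke <- morbsim:::simulate_smoking_histories(popobj, years, traj, 5L, 1L)
  base <- list(traj = traj, smoke = smoke,
               ets = morbsim:::build_ets_matrix(popobj, smoke$status, years))
  tmrels <- sample_tmrels(reg$tmrel, 5L, 1L)
  bmi_only <- morbsim:::scenario_exposures(
    popobj, base, scenario("bmi", "relative_improvement", factors = "bmi"),
    tmrels, reg, 5L, 1L
  )
  bmi_direct <- morbsim:::scenario_exposures(
    popobj, base,
    scenario("bmi_direct", "relative_improvement", factors = "bmi",
             mediation_on = FALSE),
    tmrels, reg, 5L, 1L
  )
  j <- match("2030", colnames(traj$sbp))
  delta <- base$traj$bmi[, j] - bmi_only$traj$bmi[, j]
  med_on <- base$traj$bmi[, j] >= 25 & delta > 0 &
    base$traj$sbp[, j] > tmrels[["sbp"]] + 10
  expect_true(any(med_on))
  expect_equal(bmi_only$traj$sbp[med_on, j],
               base$traj$sbp[med_on, j] - 2.55 * delta[med_on])
  # direct-effect-only sensitivity leaves SBP and cholesterol untouched
  expect_identical(bmi_direct$traj$sbp, base$traj$sbp)
  expect_identical(bmi_direct$traj$tchol, base$traj$tchol)
  expect_true(all(bmi_only$traj$sbp[, j] >=
                    pmin(base$traj$sbp[, j], tmrels[["sbp"]]) - 1e-12))
})
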