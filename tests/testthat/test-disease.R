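test_that("dose-response multipliers follow the stated power law", {
  link <- list(exposure = "bmi", form = "log_linear_continuous",
               rr_per_unit = 1.2, lag_years = 5L, cumulative = FALSE)
  expect_equal(compute_rr(link, 22, 22), 1)
  expect_equal(compute_rr(link, 24, 22), 1.44)
  expect_equal(compute_rr(link, 18, 22), 1) # below TMREL, harmful factor
  # protective factor: risk of deficit below the TMREL
  plink <- list(exposure = "pa", form = "log_linear_continuous",
                rr_per_unit = 1.1, lag_years = 5L, cumulative = FALSE)
  expect_equal(compute_rr(plink, 7, 7), 1)
  expect_equal(compute_rr(plink, 5, 7), 1.1^2)
  expect_equal(compute_rr(plink, 7.5, 7), 1)
  # categorical: lookup
  clink <- list(exposure = "ets", form = "categorical", rr_per_unit = 1.25,
                lag_years = 5L, cumulative = FALSE)
  expect_equal(compute_rr(clink, c(TRUE, FALSE), 0), c(1.25, 1))
  expect_error(compute_rr(list(form = "weird"), 1, 0), "unknown")
})

test_that("cumulative smoking risk accumulates and decays, reversible links reset", {
  reg <- test_registry()
  cum <- as.list(reg$risk_links[exposure == "smoking" & condition == "copd"])
  expect_equal(smoking_cumulative_rr(cum, 0L, 0, 0L), 1)
  # monotone in pack-years for current smokers
  expect_gte(smoking_cumulative_rr(cum, 1L, 20, 0L),
             smoking_cumulative_rr(cum, 1L, 10, 0L))
  # excess decays with years since quit but never instantly reaches 1
  r1 <- smoking_cumulative_rr(cum, 2L, 20, 1L)
  r15 <- smoking_cumulative_rr(cum, 2L, 20, 15L)
  expect_gte(r1, r15)
  expect_gt(r1, 1)
  expect_gt(r15, 1)
  # default half-life 10y: excess halves after 10 years quit
  peak <- smoking_cumulative_rr(cum, 1L, 20, 0L)
  expect_equal(smoking_cumulative_rr(cum, 2L, 20, 10L) - 1, (peak - 1) / 2)
  # non-cumulative link: full reversibility after the lag
  ncum <- as.list(reg$risk_links[exposure == "smoking" &
                                   condition == "coronary_heart_disease"])
  expect_equal(smoking_cumulative_rr(ncum, 1L, 30, 0L), ncum$rr_per_unit)
  expect_equal(smoking_cumulative_rr(ncum, 2L, 30, 2L), ncum$rr_per_unit)
  expect_equal(smoking_cumulative_rr(ncum, 2L, 30, 6L), 1)
})

test_that("PAF calibration recovers the baseline from the mean multiplier", {
  expect_equal(calibrate_baseline(rep(0.02, 3), rep(1, 3), rep("s", 3)),
               rep(0.02, 3))
  expect_equal(calibrate_baseline(rep(0.015, 4), c(2, 2, 1, 1), rep("s", 4)),
               rep(0.01, 4))
  # stratified: each stratum calibrated with its own mean
  p0 <- calibrate_baseline(c(0.02, 0.02, 0.01, 0.01), c(2, 2, 1, 1),
                           c("a", "a", "b", "b"))
  expect_equal(p0, c(0.01, 0.01, 0.01, 0.01))
})

test_that("simulated marginal incidence matches the calibration target", {
  # one large stratum with known multipliers: closure within 3 binomial SEs
  n <- 50000L
  target <- 0.015
  mult <- rep(c(2, 1), each = n / 2)
  p0 <- calibrate_baseline(rep(target, n), mult, rep("s", n))
  expect_equal(unique(p0), 0.01)
  u <- runif_stream(n, 123L, 1L, "closure_test")
  inc <- mean(u < p0 * mult)
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(inc - target), 3 * se)
})

test_that("zero targets produce zero incidence through the engine", {
  reg0 <- tweak_registry(function(reg) {
    reg$rates[, inc_rate60 := 0]
    reg
  })
  cfg <- run_config(n_simulants = 400L, n_iterations = 1L, master_seed = 2L,
                    scenarios = list())
  run <- suppressWarnings(run_simulation(cfg, registry = reg0))
  expect_equal(sum(run$cube[stratum_type == "overall", n_crossings]), 0L)
})

test_that("recovery rules match the registry", {
  reg <- test_registry()
  n <- 6L
  conds <- reg$conditions$modelled_name
  dstate <- matrix(0L, n, length(conds), dimnames = list(NULL, conds))
  donset <- matrix(NA_integer_, n, length(conds), dimnames = list(NULL, conds))
  # breast cancer onset 2025: recovered by 2035, and cannot recur
  dstate[1L, "breast_cancer"] <- 1L
  donset[1L, "breast_cancer"] <- 2025L
  # dementia never recovers
  dstate[2L, "dementia"] <- 1L
  donset[2L, "dementia"] <- 2000L
  state <- list(dstate = dstate, donset = donset)
  alive <- rep(TRUE, n)
  s34 <- apply_recovery(state, reg, 2034L, alive, 1L, 1L)
  expect_equal(unname(s34$dstate[1L, "breast_cancer"]), 1L) # 9y: still active
  s35 <- apply_recovery(state, reg, 2035L, alive, 1L, 1L)
  expect_equal(unname(s35$dstate[1L, "breast_cancer"]), 2L) # 10y: remission
  expect_equal(unname(s35$dstate[2L, "dementia"]), 1L)

  # certain stochastic recovery empties the active set for that condition
  reg1 <- tweak_registry(function(reg) {
    reg$conditions[modelled_name == "asthma", recovery_prob := 1]
    reg
  })
  dstate2 <- dstate
  dstate2[, "asthma"] <- 1L
  srec <- apply_recovery(list(dstate = dstate2, donset = donset), reg1, 2030L,
                         alive, 1L, 1L)
  expect_true(all(srec$dstate[, "asthma"] == 2L))
})

test_that("recovered non-recurring cancers are never again at risk", {
  reg <- test_registry()
  popobj <- cached("pop300", generate_population(
    default_generator_config(n_simulants = 300L), seed = 11L,
    registry = reg
  ))
  years <- 2004:2043
  traj <- morbsim:::build_exposure_trajectories(popobj, years)
  smoke <- morbsim:::simulate_smoking_histories(popobj, years, traj, 11L, 1L)
  arm <- list(traj = traj, smoke = smoke,
              ets = morbsim:::build_ets_matrix(popobj, smoke$status, years))
  tmrels <- sample_tmrels(reg$tmrel, 11L, 1L)
  n <- nrow(popobj$pop)
  state <- list(dstate = popobj$dstate, donset = popobj$donset)
  state$dstate[, "breast_cancer"] <- 2L # everyone recovered
  state$dstate_prev <- state$dstate
  p0_store <- new.env()
  p0_store$Em <- list()
  out <- simulate_incidence(state, popobj, arm, reg, 2030L, rep(TRUE, n),
                            tmrels, p0_store, TRUE, 11L, 1L)
  expect_true(all(out$dstate[, "breast_cancer"] == 2L))
})

test_that("a binary doubling of risk is recovered from the simulated cohort", {
  # parameter recovery: exposed carry RR 2, estimate the risk ratio back
  n <- 50000L
  exposed <- runif_stream(n, 7L, 1L, "rr_expose") < 0.3
  mult <- fifelse(exposed, 2, 1)
  p0 <- calibrate_baseline(rep(0.012, n), mult, rep("s", n))
  u <- runif_stream(n, 7L, 1L, "rr_event")
  case <- u < p0 * mult
  r1 <- mean(case[exposed])
  r0 <- mean(case[!exposed])
  rr_hat <- r1 / r0
  se_log <- sqrt((1 - r1) / (r1 * sum(exposed)) + (1 - r0) / (r0 * sum(!exposed)))
  expect_lt(abs(log(rr_hat) - log(2)), 1.96 * se_log)
})

test_that("lifelong conditions are monotone in a closed deathless cohort", {
  reg <- test_registry()
  popobj <- cached("pop300", generate_population(
    default_generator_config(n_simulants = 300L), seed = 11L,
    registry = reg
  ))
  years <- 2013:2030
  traj <- morbsim:::build_exposure_trajectories(popobj, 2004:2043)
  smoke <- morbsim:::simulate_smoking_histories(popobj, 2004:2043, traj, 11L, 1L)
  arm <- list(traj = traj, smoke = smoke,
              ets = morbsim:::build_ets_matrix(popobj, smoke$status, 2004:2043))
  tmrels <- sample_tmrels(reg$tmrel, 11L, 1L)
  n <- nrow(popobj$pop)
  alive <- rep(TRUE, n)
  state <- list(dstate = popobj$dstate, donset = popobj$donset)
  p0_store <- new.env()
  p0_store$Em <- list()
  lifelong <- reg$conditions[recovery_rule == "none", modelled_name]
  prev <- colSums(state$dstate[, lifelong] == 1L)
  for (y in years) {
    state$dstate_prev <- state$dstate
    state <- suppressWarnings(
      simulate_incidence(state, popobj, arm, reg, y, alive, tmrels, p0_store,
                         TRUE, 11L, 1L)
    )
    state <- apply_recovery(state, reg, y, alive, 11L, 1L)
    now <- colSums(state$dstate[, lifelong] == 1L)
    expect_true(all(now >= prev))
    prev <- now
  }
})
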