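# Shared fixtures, memoised so expensive objects are built once per test run.

.morbsim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.morbsim_cache[[name]])) .morbsim_cache[[name]] <- expr
  .morbsim_cache[[name]]
}

test_registry <- function() cached("registry", load_registry())

# Registry with tables modified in place, round-tripped through text so the
# index is rebuilt consistently.
tweak_registry <- function(fn, validate = FALSE) {
  reg <- load_registry(validate = FALSE)
  res <- fn(reg)
  if (inherits(res, "morbsim_registry")) reg <- res
  dir <- tempfile("regtweak")
  write_registry(reg, dir)
  load_registry(dir, validate = validate)
}

# Small but full two-scenario run shared across outcome/runner tests.
small_run <- function() {
  cached("small_run", {
    cfg <- run_config(
      n_simulants = 1000L, n_iterations = 2L, master_seed = 5L,
      scenarios = list(scenario("tmrel_all", "tmrel"),
                       scenario("improve10", "relative_improvement"))
    )
    suppressWarnings(run_simulation(cfg, keep_person_years = TRUE))
  })
}

# Large synthetic cohort for distributional checks.
big_population <- function() {
  cached("big_population", {
    cfg <- default_generator_config(n_simulants = 50000L)
    generate_population(cfg, seed = 99L, registry = test_registry())
  })
}

# Hand-built results cube: per-iteration counts supplied directly.
fabricate_cube <- function(n_iter, years, base_major, scen_major,
                           n_alive = 1000L, scenario_name = "scn") {
  rows <- list()
  for (it in seq_len(n_iter)) {
    for (y in seq_along(years)) {
      for (arm in c("baseline", scenario_name)) {
        nm <- if (arm == "baseline") base_major[[it]][y] else scen_major[[it]][y]
        rows[[length(rows) + 1L]] <- data.table::data.table(
          iteration = it, scenario = arm, year = years[y],
          stratum_type = "overall", stratum = "overall",
          n_alive = n_alive, n_major = nm, n_without = n_alive - nm,
          n_deaths = 0L, n_alive_start = n_alive, n_at_risk = n_alive - nm,
          n_crossings = 0L
        )
      }
    }
  }
  data.table::rbindlist(rows)
}
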