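# Memoized fixtures shared across test files (built once per test run).

.fixture_cache <- new.env(parent = emptyenv())

with_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fast_control <- function(...) {
  fpca_control(grid_len = 51, bw_mean = 1, bw_cov = 2.5, ...)
}

small_cohort <- function() {
  with_fixture("small_cohort", generate_cohort(cohort_config(
    n_patients = 300, seed = 42)))
}

small_pipeline <- function() {
  with_fixture("small_pipeline", {
    ch <- small_cohort()
    fit_pipeline(ch$measurements, ch$patients, "longitudinal_3marker",
                 control = fast_control(), num_trees = 300, seed = 3)
  })
}

# Cohort whose hazard loads on the trend component (second eigenfunction)
# of CEA: rising postoperative trajectories increase the hazard.
trend_cohort <- function() {
  with_fixture("trend_cohort", {
    mks <- default_markers()
    cfg <- cohort_config(
      n_patients = 400, markers = mks,
      hazard = list(shape = 1.3, scale = 140,
                    beta = c("CEA.2" = 0.9),
                    beta_stage = c(I = 0, II = 0.3, III = 0.6)),
      spike = list(prob = 0, magnitude = 5), seed = 2024)
    generate_cohort(cfg)
  })
}

trend_pipeline <- function() {
  with_fixture("trend_pipeline", {
    ch <- trend_cohort()
    fit_pipeline(ch$measurements, ch$patients, "longitudinal_3marker",
                 control = fast_control(), num_trees = 300, seed = 5)
  })
}

# Covariate rows for two stage-II patients identical in everything.
matched_covariates <- function(pid) {
  data.frame(patient_id = pid, age = 60, sex = "male",
             primary_site = "colon", surgical_approach = "open",
             differentiation = "moderate", stage = "II", ln_yield = ">=12",
             mucinous = 0L, lymphovascular_invasion = 0L,
             perineural_invasion = 0L, adjuvant_chemo = 1L)
}

# Marker history on a fixed visit schedule; CEA follows `cea_values`,
# CA19-9 and CA125 sit at their typical postoperative levels.
marker_history <- function(pid, times, cea_values) {
  rbind(
    data.frame(patient_id = pid, marker = "CEA", time_months = times,
               value = cea_values),
    data.frame(patient_id = pid, marker = "CA19-9", time_months = times,
               value = rep(9.4, length(times))),
    data.frame(patient_id = pid, marker = "CA125", time_months = times,
               value = rep(18, length(times)))
  )
}
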