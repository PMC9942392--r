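# The generator must reproduce the statistical structure the pipeline
# assumes: reproducibility, the degenerate limits, and the links between
# scores, hazard and censoring.

test_that("identical seeds give identical cohorts, distinct seeds differ", {
  a <- generate_cohort(cohort_config(n_patients = 20, seed = 11))
  b <- generate_cohort(cohort_config(n_patients = 20, seed = 11))
  expect_identical(a, b)
  c <- generate_cohort(cohort_config(n_patients = 20, seed = 12))
  expect_false(identical(a$measurements$time_months, c$measurements$time_months))
})

test_that("degenerate process (zero eigenvalues, zero noise) returns exp(mean)", {
  mks <- default_markers()
  for (m in names(mks)) {
    mks[[m]]$lambda <- c(0, 0)
    mks[[m]]$sigma2 <- 0
  }
  ch <- generate_cohort(cohort_config(n_patients = 10, markers = mks,
                                      spike = list(prob = 0, magnitude = 5),
                                      seed = 3))
  for (m in names(mks)) {
    rows <- ch$measurements[ch$measurements$marker == m, ]
    mu_at <- approx(ch$truth$grid, ch$truth$mean_functions[[m]],
                    xout = rows$time_months, rule = 2)$y
    expect_equal(rows$value, exp(mu_at), tolerance = 1e-10)
  }
})

test_that("every patient has one preop visit and enough postop visits", {
  ch <- generate_cohort(cohort_config(n_patients = 50, seed = 8))
  for (pid in ch$patients$patient_id) {
    tm <- ch$measurements$time_months[ch$measurements$patient_id == pid &
                                        ch$measurements$marker == "CEA"]
    expect_equal(sum(tm < 0), 1)
    expect_gte(min(tm), -0.92 - 1e-9)
    expect_gte(sum(tm > 0 & tm <= 12), 2)
    expect_true(all(diff(sort(tm)) > 0))
  }
  expect_true(all(ch$measurements$value > 0))
})

test_that("zero hazard coefficients decouple scores from event times", {
  cfg <- cohort_config(n_patients = 2000,
                       hazard = list(shape = 1.3, scale = 180,
                                     beta = numeric(0),
                                     beta_stage = c(I = 0, II = 0, III = 0)),
                       seed = 21)
  ch <- generate_cohort(cfg)
  tau <- cor(ch$truth$scores[, "CEA.1"], ch$truth$true_time,
             method = "kendall")
  n <- 2000
  se_tau <- sqrt(2 * (2 * n + 5) / (9 * n * (n - 1)))
  expect_lt(abs(tau), 3 * se_tau)
})

test_that("survival simulation honours boundaries and the exponential mean", {
  sc <- matrix(0, 5000, 1, dimnames = list(NULL, "CEA.1"))
  stage <- rep("I", 5000)
  # tiny administrative horizon: everyone censored at the horizon
  out <- simulate_survival(sc, stage,
                           hazard = list(shape = 1.3, scale = 180,
                                         beta = c("CEA.1" = 0),
                                         beta_stage = c(I = 0)),
                           censoring = list(horizon = 0.001, rate = 0),
                           seed = 2)
  expect_true(all(out$event == 0))
  expect_true(all(out$time == 0.001))
  # exponential baseline (shape 1), no censoring: mean event time = scale
  lambda_rate <- 0.05
  out <- simulate_survival(sc, stage,
                           hazard = list(shape = 1, scale = 1 / lambda_rate,
                                         beta = c("CEA.1" = 0),
                                         beta_stage = c(I = 0)),
                           censoring = list(horizon = Inf, rate = 0),
                           seed = 3)
  se <- (1 / lambda_rate) / sqrt(5000)
  expect_lt(abs(mean(out$true_time) - 1 / lambda_rate), 3 * se)
  expect_true(all(out$event == 1))
})

test_that("stronger score coefficient strengthens the score-time association", {
  sc <- matrix(rnorm(4000, 0, 2), 4000, 1, dimnames = list(NULL, "CEA.1"))
  stage <- rep("I", 4000)
  mk <- function(b) simulate_survival(
    sc, stage,
    hazard = list(shape = 1.3, scale = 180, beta = c("CEA.1" = b),
                  beta_stage = c(I = 0)),
    censoring = list(horizon = Inf, rate = 0), seed = 7)
  r1 <- cor(sc[, 1], mk(0.35)$true_time, method = "spearman")
  r2 <- cor(sc[, 1], mk(0.70)$true_time, method = "spearman")
  expect_lt(r1, 0)
  expect_lt(r2, r1)
})

test_that("event proportion decreases as random censoring increases", {
  props <- sapply(c(0, 0.01, 0.05), function(rate) {
    ch <- generate_cohort(cohort_config(
      n_patients = 400, censoring = list(horizon = 72, rate = rate),
      seed = 33))
    mean(ch$patients$event)
  })
  expect_true(all(diff(props) < 0))
})

test_that("marginal variance of log values matches the eigenstructure", {
  mks <- default_markers()["CEA"]
  cfg <- cohort_config(n_patients = 4000, markers = mks,
                       score_correlation = diag(2),
                       visit = list(mean_visits = 6, min_visits = 4,
                                    jitter_sd = 1.2, preop_window_weeks = 4),
                       spike = list(prob = 0, magnitude = 5), seed = 5)
  ch <- generate_cohort(cfg)
  rows <- ch$measurements[ch$measurements$time_months >= 5.5 &
                            ch$measurements$time_months <= 6.5, ]
  mu_at <- approx(ch$truth$grid, ch$truth$mean_functions[["CEA"]],
                  xout = rows$time_months, rule = 2)$y
  resid <- log(rows$value) - mu_at
  v_emp <- var(resid)
  phi <- ch$truth$eigenfunctions[["CEA"]]
  g6 <- which.min(abs(ch$truth$grid - 6))
  v_theory <- 4 * phi[g6, 1]^2 + 1 * phi[g6, 2]^2 + mks$CEA$sigma2
  se <- v_theory * sqrt(2 / (nrow(rows) - 1))
  expect_lt(abs(v_emp - v_theory), 3 * se + 0.02)
})

test_that("invalid configurations are rejected", {
  bad <- matrix(c(1, 2, 2, 1), 2)  # not PSD (eigenvalue -1)
  mks <- default_markers()["CEA"]
  expect_error(cohort_config(markers = mks, score_correlation = bad),
               "positive semi-definite")
  expect_error(marker_spec("X", 5, c(0, 1), c(1, 1), lambda = c(-1, 0)),
               "negative variance")
  expect_error(cohort_config(hazard = list(shape = -1, scale = 180,
                                           beta = numeric(0))),
               "positive")
})

test_that("cohorts round-trip through the delimited text format", {
  ch <- generate_cohort(cohort_config(n_patients = 15, seed = 9))
  dir <- tempfile("cohort_")
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_equal(back$measurements$value, ch$measurements$value)
  expect_equal(back$patients$time, ch$patients$time)
  expect_equal(back$truth$true_time, ch$truth$true_time, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
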