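# Metric kernels against closed forms and brute-force oracles;
# cross-validation plumbing.

test_that("risk_at inverts conditional survival", {
  pred <- structure(list(s = 12, horizons = c(24, 36),
                         pi = matrix(c(1, 0.8, 0.9, 0.6), 2, 2,
                                     dimnames = list(NULL, c("24", "36")))),
                    class = "landmark_prediction")
  expect_equal(risk_at(pred, 24), c(0, 0.2))
  expect_equal(risk_at(pred, 36), c(0.1, 0.4))
  expect_error(risk_at(pred, 48), "not predicted")
  # risks non-decreasing in t per patient follows from monotone pi
  expect_true(all(risk_at(pred, 36) >= risk_at(pred, 24)))
})

test_that("AUC is 1 under perfect separation and 0.5 under noise", {
  time <- c(20, 25, 30, 70, 80, 90)
  event <- c(1, 1, 1, 0, 0, 0)
  risks <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  expect_equal(td_auc(risks, time, event, 12, 60), 1)
  set.seed(2)
  n <- 2000
  time <- runif(n, 13, 100)
  event <- rbinom(n, 1, 1)
  risks <- runif(n)
  auc <- td_auc(risks, time, event, 12, 60)
  n_case <- sum(time <= 60)
  se <- sqrt((n_case + (n - n_case) + 1) / (12 * n_case * (n - n_case)))
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("AUC and Brier match the brute-force oracles exactly", {
  hc <- hand_cohort()
  for (t in c(28, 40, 55)) {
    expect_equal(td_auc(hc$risk_new, hc$time, hc$event, 12, t),
                 oracle_auc(hc$risk_new, hc$time, hc$event, 12, t),
                 tolerance = 1e-12)
    expect_equal(brier_score(hc$risk_new, hc$time, hc$event, 12, t),
                 oracle_brier(hc$risk_new, hc$time, hc$event, 12, t),
                 tolerance = 1e-12)
  }
})

test_that("Brier score matches its closed forms", {
  # perfect 0/1 risks, no censoring
  time <- c(20, 30, 70, 80)
  event <- c(1, 1, 0, 0)
  expect_equal(brier_score(c(1, 1, 0, 0), time, event, 12, 60), 0)
  # constant risk p with uncensored binary outcomes
  p <- 0.3
  n <- 50
  set.seed(3)
  ev <- rbinom(n, 1, 0.4)
  time <- ifelse(ev == 1, 30, 90)
  q <- mean(ev)
  expect_equal(brier_score(rep(p, n), time, ev, 12, 60),
               q * (1 - p)^2 + (1 - q) * p^2, tolerance = 1e-12)
})

test_that("AUC is rank-invariant; Brier is not", {
  hc <- hand_cohort()
  a1 <- td_auc(hc$risk_new, hc$time, hc$event, 12, 40)
  a2 <- td_auc(plogis(5 * hc$risk_new), hc$time, hc$event, 12, 40)
  expect_equal(a1, a2, tolerance = 1e-12)
  b1 <- brier_score(hc$risk_new, hc$time, hc$event, 12, 40)
  b2 <- brier_score(plogis(5 * hc$risk_new), hc$time, hc$event, 12, 40)
  expect_false(isTRUE(all.equal(b1, b2)))
})

test_that("NRI matches enumeration and its invariances", {
  hc <- hand_cohort()
  r <- nri(hc$risk_new, hc$risk_old, hc$time, hc$event, 12, 40, n_boot = 200)
  expect_equal(r$nri, oracle_nri(hc$risk_new, hc$risk_old, hc$time,
                                 hc$event, 12, 40), tolerance = 1e-12)
  expect_true(r$ci[1] <= r$nri && r$nri <= r$ci[2])
  # ties count in neither direction; identical risks -> 0
  r0 <- nri(hc$risk_new, hc$risk_new, hc$time, hc$event, 12, 40, n_boot = 0)
  expect_equal(r0$nri, 0)
  expect_equal(r0$up_events + r0$down_events, 0)
  # within-group percentages sum to 100 when there are no ties
  rn <- hc$risk_new + 1e-6  # break the one tie against risk_old
  r1 <- nri(rn, hc$risk_old, hc$time, hc$event, 12, 40, n_boot = 0)
  expect_equal(r1$up_events + r1$down_events, 100)
  expect_equal(r1$up_nonevents + r1$down_nonevents, 100)
  # antisymmetry under swapping models
  r2 <- nri(hc$risk_old, hc$risk_new, hc$time, hc$event, 12, 40, n_boot = 0)
  expect_equal(r2$nri, -r$nri, tolerance = 1e-12)
})

test_that("NRI on a 6-patient cohort equals the exhaustive count", {
  time <- c(15, 20, 50, 70, 35, 80)
  event <- c(1, 1, 0, 0, 0, 0)   # patient 5 censored inside (s, t]
  rn <- c(0.8, 0.3, 0.2, 0.4, 0.5, 0.1)
  ro <- c(0.6, 0.5, 0.3, 0.2, 0.5, 0.2)
  r <- nri(rn, ro, time, event, 12, 40, n_boot = 0)
  expect_equal(r$nri, oracle_nri(rn, ro, time, event, 12, 40),
               tolerance = 1e-12)
  expect_equal(r$n_events, 2)
  expect_equal(r$n_nonevents, 3)  # censored-in-window patient excluded
})

test_that("IDI matches its oracle, bounds and antisymmetry", {
  hc <- hand_cohort()
  r <- idi(hc$risk_new, hc$risk_old, hc$time, hc$event, 12, 40, n_boot = 200)
  expect_equal(r$idi, oracle_idi(hc$risk_new, hc$risk_old, hc$time,
                                 hc$event, 12, 40), tolerance = 1e-12)
  expect_true(r$ci[1] <= r$idi && r$idi <= r$ci[2])
  r0 <- idi(hc$risk_new, hc$risk_new, hc$time, hc$event, 12, 40, n_boot = 0)
  expect_equal(r0$idi, 0)
  # perfect model against a useless constant model
  time <- c(20, 30, 70, 80); event <- c(1, 1, 0, 0)
  rp <- c(1, 1, 0, 0); ru <- rep(0.5, 4)
  expect_equal(idi(rp, ru, time, event, 12, 60, n_boot = 0)$idi, 1)
  r2 <- idi(hc$risk_old, hc$risk_new, hc$time, hc$event, 12, 40, n_boot = 0)
  expect_equal(r2$idi, -r$idi, tolerance = 1e-12)
})

test_that("stratified folds partition the cohort evenly", {
  event <- rbinom(83, 1, 0.3)
  fold <- cv_folds(event, folds = 10, seed = 4)
  expect_equal(sort(unique(fold)), 1:10)
  sizes <- table(fold)
  expect_lte(diff(range(sizes)), 1)
  ev_per_fold <- tapply(event, fold, sum)
  expect_lte(diff(range(ev_per_fold)), 2)
})

test_that("pooled out-of-fold metrics equal direct recomputation", {
  ch <- small_cohort()
  cv <- cross_validate(ch$measurements, ch$patients,
                       configurations = "basic", folds = 3,
                       horizons = c(36, 48), control = fast_control(),
                       num_trees = 100, seed = 6)
  expect_false(anyNA(cv$risks[["basic"]]))
  for (j in seq_along(c(36, 48))) {
    t <- c(36, 48)[j]
    direct_auc <- td_auc(cv$risks[["basic"]][, j], cv$time, cv$event, 12, t)
    row <- cv$metrics[cv$metrics$horizon == t, ]
    expect_equal(row$auc, direct_auc, tolerance = 1e-12)
    expect_equal(row$brier,
                 brier_score(cv$risks[["basic"]][, j], cv$time, cv$event,
                             12, t), tolerance = 1e-12)
  }
})

test_that("external validation on the training cohort is consistent", {
  pl <- small_pipeline()
  ch <- small_cohort()
  out <- external_validate(list(longitudinal_3marker = pl),
                           ch$measurements, ch$patients, t = 60)
  expect_equal(nrow(out), 1)
  expect_true(out$auc > 0.5 && out$auc <= 1)
  expect_true(out$brier >= 0 && out$brier <= 1)
  # equals a manual pass through the same trained model
  pts <- ch$patients[ch$patients$patient_id %in%
                       apply_landmark(ch$patients, 12), ]
  pred <- mfpcsurv:::predict_cohort(pl, ch$measurements, pts,
                                    pts$patient_id, 60)
  manual <- td_auc(1 - pred$pi[, 1], pts$time, pts$event, 12, 60)
  expect_equal(out$auc, manual, tolerance = 1e-12)
  expect_error(external_validate(pl, ch$measurements, ch$patients[0, ]),
               "empty external cohort")
})
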