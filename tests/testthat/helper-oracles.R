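# Independent brute-force oracles for the evaluation kernels, plus small
# simulation helpers that do not go through the package's generator or
# estimators.

# Censoring Kaplan-Meier evaluator built directly from survfit.
oracle_G <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(u) {
    i <- findInterval(u, fit$time)
    c(1, fit$surv)[i + 1]
  }
}

# IPCW cumulative/dynamic AUC by explicit double loop over all pairs.
oracle_auc <- function(risks, time, event, s, t) {
  keep <- time > s
  risks <- risks[keep]; time <- time[keep]; event <- event[keep]
  G <- oracle_G(time, event)
  num <- 0; sw_case <- 0; sw_ctrl <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] == 1 && time[i] <= t) sw_case <- sw_case + 1 / G(time[i] - 1e-9)
    if (time[i] > t) sw_ctrl <- sw_ctrl + 1 / G(t)
  }
  for (i in seq_len(n)) {
    if (!(event[i] == 1 && time[i] <= t)) next
    wi <- 1 / G(time[i] - 1e-9)
    for (j in seq_len(n)) {
      if (!(time[j] > t)) next
      wj <- 1 / G(t)
      cij <- if (risks[i] > risks[j]) 1 else if (risks[i] == risks[j]) 0.5 else 0
      num <- num + wi * wj * cij
    }
  }
  num / (sw_case * sw_ctrl)
}

# IPCW Brier score by explicit per-patient sum.
oracle_brier <- function(risks, time, event, s, t) {
  keep <- time > s
  risks <- risks[keep]; time <- time[keep]; event <- event[keep]
  G <- oracle_G(time, event)
  total <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (event[i] == 1 && time[i] <= t) {
      total <- total + (1 - risks[i])^2 / G(time[i] - 1e-9)
    } else if (time[i] > t) {
      total <- total + (0 - risks[i])^2 / G(t)
    }
  }
  total / n
}

# Category-free NRI by explicit enumeration of every patient.
oracle_nri <- function(rn, ro, time, event, s, t) {
  up_e <- down_e <- n_e <- 0
  up_n <- down_n <- n_n <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1 && time[i] > s && time[i] <= t) {
      n_e <- n_e + 1
      if (rn[i] > ro[i]) up_e <- up_e + 1
      if (rn[i] < ro[i]) down_e <- down_e + 1
    } else if (time[i] > t) {
      n_n <- n_n + 1
      if (rn[i] > ro[i]) up_n <- up_n + 1
      if (rn[i] < ro[i]) down_n <- down_n + 1
    }
  }
  100 * ((up_e - down_e) / n_e + (down_n - up_n) / n_n)
}

oracle_idi <- function(rn, ro, time, event, s, t) {
  ev <- event == 1 & time > s & time <= t
  ne <- time > t
  (mean(rn[ev]) - mean(ro[ev])) - (mean(rn[ne]) - mean(ro[ne]))
}

# Hand-set cohort of 8 patients with events, censoring and ties in risks.
hand_cohort <- function() {
  data.frame(
    time = c(14, 20, 26, 30, 33, 45, 50, 61),
    event = c(1, 1, 0, 1, 0, 1, 0, 0),
    risk_new = c(0.9, 0.7, 0.5, 0.7, 0.30, 0.4, 0.2, 0.1),
    risk_old = c(0.6, 0.7, 0.4, 0.5, 0.35, 0.5, 0.3, 0.1)
  )
}

# Exact continuous-time model on [-1, 12] used as a closed-form reference:
# phi1 constant, phi2 centered-linear, both orthonormal in L2.
ref_phi1 <- function(t) rep(1 / sqrt(13), length(t))
ref_phi2 <- function(t) (t - 5.5) / sqrt((6.5^3 - (-6.5)^3) / 3)
ref_mu <- function(t) 2 - 0.1 * t

# Sparse functional data simulated directly from the closed-form model
# (independent of the package's cohort generator).
sim_sparse_fpca <- function(n, lambda = c(4, 1), sigma2 = 0.1,
                            n_obs = 4:6, seed = 1) {
  set.seed(seed)
  rows <- vector("list", n)
  scores <- cbind(rnorm(n, 0, sqrt(lambda[1])), rnorm(n, 0, sqrt(lambda[2])))
  for (i in seq_len(n)) {
    k <- sample(n_obs, 1)
    tt <- sort(c(runif(1, -0.9, -0.05), runif(k, 0.2, 12)))
    y <- ref_mu(tt) + scores[i, 1] * ref_phi1(tt) + scores[i, 2] * ref_phi2(tt) +
      rnorm(length(tt), 0, sqrt(sigma2))
    rows[[i]] <- data.frame(patient_id = i, time = tt, y = y)
  }
  list(series = do.call(rbind, rows), scores = scores)
}
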