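# Time-dependent discrimination and calibration (IPCW AUC and Brier score),
# reclassification indices (NRI, IDI), tenfold cross-validation and
# external-cohort application.

#' Predicted event risk by a horizon
#'
#' `risk = 1 - conditional survival`.
#'
#' @param prediction a `landmark_prediction`.
#' @param t horizon among the predicted horizons.
#' @return numeric vector of per-patient risks in `[0, 1]`.
#' @export
risk_at <- function(prediction, t) {
  col <- match(as.character(t), colnames(prediction$pi))
  if (is.na(col)) stop("horizon ", t, " was not predicted")
  1 - prediction$pi[, col]
}

# Kaplan-Meier estimate of the censoring survivor function G on the
# landmark risk set, returned as a left-continuous step evaluator:
# G(u-) via `lag = TRUE`.
censor_km <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  function(u, lag = FALSE) {
    idx <- findInterval(u + if (lag) -1e-9 else 0, fit$time)
    c(1, fit$surv)[idx + 1]
  }
}

#' IPCW cumulative/dynamic time-dependent AUC
#'
#' Cases are events in `(s, t]`, controls are patients still at risk beyond
#' `t`. Pairs are weighted by the inverse Kaplan-Meier censoring survivor
#' function estimated on the landmark risk set: `1/G(T_i-)` for cases and
#' `1/G(t)` for controls. Tied risks count 1/2.
#'
#' @param risks predicted event risks by `t`.
#' @param time,event observed times and event indicators (risk set,
#'   `time > s`).
#' @param s landmark, months.
#' @param t horizon, months.
#' @return AUC in `[0, 1]`, or `NA` with a warning when there are no
#'   comparable pairs.
#' @export
td_auc <- function(risks, time, event, s, t) {
  keep <- time > s
  risks <- risks[keep]; time <- time[keep]; event <- event[keep]
  G <- censor_km(time, event)
  case <- event == 1 & time <= t
  ctrl <- time > t
  if (!any(case) || !any(ctrl)) {
    warning("no cases or no controls in (s, t]; AUC undefined")
    return(NA_real_)
  }
  wc <- 1 / G(time[case], lag = TRUE)
  wn <- rep(1 / G(t), sum(ctrl))
  rc <- risks[case]; rn <- risks[ctrl]
  conc <- outer(rc, rn, `>`) + 0.5 * outer(rc, rn, `==`)
  sum((wc %o% wn) * conc) / (sum(wc) * sum(wn))
}

#' IPCW Brier score at a horizon
#'
#' Squared error between the event indicator at `t` and the predicted risk,
#' reweighted for censoring: events in `(s, t]` get weight `1/G(T_i-)`,
#' patients beyond `t` get `1/G(t)`, patients censored in `(s, t]` get 0.
#'
#' @inheritParams td_auc
#' @return Brier score in `[0, 1]`.
#' @export
brier_score <- function(risks, time, event, s, t) {
  keep <- time > s
  risks <- risks[keep]; time <- time[keep]; event <- event[keep]
  G <- censor_km(time, event)
  n <- length(time)
  w <- numeric(n); d <- numeric(n)
  ev <- event == 1 & time <= t
  at_risk <- time > t
  gl <- G(time[ev], lag = TRUE)
  gt <- G(t)
  if (any(gl == 0) || (any(at_risk) && gt == 0)) {
    stop("censoring distribution reaches 0 before the horizon; ",
         "Brier score undefined")
  }
  w[ev] <- 1 / gl
  d[ev] <- 1
  w[at_risk] <- 1 / gt
  sum(w * (d - risks)^2) / n
}

# Shared status classification for NRI/IDI: events in (s, t], non-events
# known beyond t; patients censored in (s, t] have unknown status and are
# excluded.
classify_status <- function(time, event, s, t) {
  status <- rep(NA_integer_, length(time))
  status[event == 1 & time > s & time <= t] <- 1L
  status[time > t] <- 0L
  status
}

#' Combine group reclassification percentages into the overall NRI
#'
#' `NRI = (up_events - down_events) + (down_nonevents - up_nonevents)`,
#' all quantities in percent.
#'
#' @param up_events,down_events percent of events moved up / down.
#' @param up_nonevents,down_nonevents percent of non-events moved up / down.
#' @return overall NRI, percent.
#' @export
nri_combine <- function(up_events, down_events, up_nonevents, down_nonevents) {
  (up_events - down_events) + (down_nonevents - up_nonevents)
}

#' Combine group mean risks into the overall IDI
#'
#' `IDI = (mean risk new - old among events) - (mean risk new - old among
#' non-events)`.
#'
#' @param mean_new_events,mean_old_events mean predicted risks of events.
#' @param mean_new_nonevents,mean_old_nonevents mean predicted risks of
#'   non-events.
#' @return overall IDI (probability scale).
#' @export
idi_combine <- function(mean_new_events, mean_old_events,
                        mean_new_nonevents, mean_old_nonevents) {
  (mean_new_events - mean_old_events) -
    (mean_new_nonevents - mean_old_nonevents)
}

#' Category-free net reclassification improvement
#'
#' Among patients with known status at `t`, counts moves up (new risk above
#' old) and down; exact ties count in neither direction. Confidence
#' interval by percentile bootstrap over patients.
#'
#' @param risks_new,risks_old risk vectors from the two models, same
#'   patients.
#' @param time,event observed times and event indicators.
#' @param s,t landmark and horizon, months.
#' @param n_boot bootstrap resamples (0 skips the CI).
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return list: `nri` (percent), group percentages, `ci`, counts.
#' @export
nri <- function(risks_new, risks_old, time, event, s, t, n_boot = 1000,
                conf = 0.95, seed = 1) {
  stopifnot(length(risks_new) == length(risks_old))
  point <- nri_point(risks_new, risks_old, time, event, s, t)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(risks_new)
    bs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      nri_point(risks_new[idx], risks_old[idx], time[idx], event[idx],
                s, t)$nri
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  c(point, list(ci = ci))
}

nri_point <- function(risks_new, risks_old, time, event, s, t) {
  status <- classify_status(time, event, s, t)
  ev <- which(status == 1L); ne <- which(status == 0L)
  if (length(ev) == 0 || length(ne) == 0) {
    return(list(nri = NA_real_, up_events = NA_real_, down_events = NA_real_,
                up_nonevents = NA_real_, down_nonevents = NA_real_,
                n_events = length(ev), n_nonevents = length(ne)))
  }
  up_e <- 100 * mean(risks_new[ev] > risks_old[ev])
  down_e <- 100 * mean(risks_new[ev] < risks_old[ev])
  up_ne <- 100 * mean(risks_new[ne] > risks_old[ne])
  down_ne <- 100 * mean(risks_new[ne] < risks_old[ne])
  list(nri = nri_combine(up_e, down_e, up_ne, down_ne),
       up_events = up_e, down_events = down_e,
       up_nonevents = up_ne, down_nonevents = down_ne,
       n_events = length(ev), n_nonevents = length(ne))
}

#' Integrated discrimination improvement
#'
#' Difference in mean-risk separation between events and non-events of the
#' new versus the old model; percentile bootstrap CI.
#'
#' @inheritParams nri
#' @return list: `idi`, group mean risks, `ci`, counts.
#' @export
idi <- function(risks_new, risks_old, time, event, s, t, n_boot = 1000,
                conf = 0.95, seed = 1) {
  stopifnot(length(risks_new) == length(risks_old))
  point <- idi_point(risks_new, risks_old, time, event, s, t)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(risks_new)
    bs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      idi_point(risks_new[idx], risks_old[idx], time[idx], event[idx],
                s, t)$idi
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  c(point, list(ci = ci))
}

idi_point <- function(risks_new, risks_old, time, event, s, t) {
  status <- classify_status(time, event, s, t)
  ev <- which(status == 1L); ne <- which(status == 0L)
  if (length(ev) == 0 || length(ne) == 0) {
    return(list(idi = NA_real_, mean_new_events = NA_real_,
                mean_old_events = NA_real_, mean_new_nonevents = NA_real_,
                mean_old_nonevents = NA_real_,
                n_events = length(ev), n_nonevents = length(ne)))
  }
  mne <- mean(risks_new[ev]); moe <- mean(risks_old[ev])
  mnn <- mean(risks_new[ne]); mon <- mean(risks_old[ne])
  list(idi = idi_combine(mne, moe, mnn, mon),
       mean_new_events = mne, mean_old_events = moe,
       mean_new_nonevents = mnn, mean_old_nonevents = mon,
       n_events = length(ev), n_nonevents = length(ne))
}

#' Stratified cross-validation folds
#'
#' Patients are split into folds stratified on the event indicator; fold
#' sizes differ by at most one and the folds partition the cohort.
#'
#' @param event event indicators.
#' @param folds number of folds.
#' @param seed shuffle seed.
#' @return integer fold assignment per patient.
#' @export
cv_folds <- function(event, folds = 10, seed = 1) {
  stopifnot(folds >= 2)
  set.seed(seed)
  n <- length(event)
  ord <- c(sample(which(event == 1)), sample(which(event == 0)))
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(folds), n)
  fold
}

#' Cross-validated comparison of model configurations
#'
#' The whole pipeline (FPCA, MFPCA, forest) is refitted on each training
#' split; out-of-fold conditional risks are pooled before computing the
#' IPCW AUC and Brier score at each horizon.
#'
#' @param measurements,patients cohort tables.
#' @param configurations configurations to compare.
#' @param folds number of folds (default tenfold).
#' @param landmark landmark s, months.
#' @param horizons evaluation horizons, months.
#' @param control an [fpca_control()]; fixed bandwidths speed up refits.
#' @param M joint components for MFPCA.
#' @param num_trees,min_node_size forest hyperparameters.
#' @param seed seed for fold assignment and forests.
#' @return list: `metrics` (data.frame configuration x horizon with `auc`,
#'   `brier`), `risks` (per configuration: patients x horizons matrix of
#'   pooled out-of-fold risks), `time`, `event`, `fold`.
#' @export
cross_validate <- function(measurements, patients,
                           configurations = c("basic", "preop_3marker",
                                              "longitudinal_3marker"),
                           folds = 10, landmark = 12,
                           horizons = seq(18, 60, by = 6),
                           control = fpca_control(), M = "auto",
                           num_trees = 1000, min_node_size = 15, seed = 1) {
  elig <- filter_eligible(measurements, patients)
  pts <- patients[patients$patient_id %in% elig$eligible, , drop = FALSE]
  pts <- pts[pts$patient_id %in% apply_landmark(pts, landmark), , drop = FALSE]
  n <- nrow(pts)
  if (sum(pts$event) < folds) warning("fewer events than folds")
  fold <- cv_folds(pts$event, folds, seed)
  risks <- lapply(configurations, function(cf) {
    matrix(NA_real_, n, length(horizons),
           dimnames = list(as.character(pts$patient_id),
                           as.character(horizons)))
  })
  names(risks) <- configurations
  for (f in seq_len(folds)) {
    test_ids <- pts$patient_id[fold == f]
    train_pts <- pts[fold != f, , drop = FALSE]
    train_meas <- measurements[measurements$patient_id %in%
                                 train_pts$patient_id, , drop = FALSE]
    for (cf in configurations) {
      pl <- fit_pipeline(train_meas, train_pts, configuration = cf,
                         landmark = landmark, control = control, M = M,
                         num_trees = num_trees,
                         min_node_size = min_node_size, seed = seed)
      pred <- predict_cohort(pl, measurements, pts, test_ids, horizons)
      risks[[cf]][as.character(test_ids), ] <- 1 - pred$pi
    }
  }
  metrics <- do.call(rbind, lapply(configurations, function(cf) {
    do.call(rbind, lapply(seq_along(horizons), function(j) {
      t <- horizons[j]
      data.frame(configuration = cf, landmark = landmark, horizon = t,
                 auc = td_auc(risks[[cf]][, j], pts$time, pts$event,
                              landmark, t),
                 brier = brier_score(risks[[cf]][, j], pts$time, pts$event,
                                     landmark, t),
                 n_events = sum(pts$event == 1 & pts$time <= t),
                 n_at_risk = sum(pts$time > t))
    }))
  }))
  rownames(metrics) <- NULL
  list(metrics = metrics, risks = risks, time = pts$time, event = pts$event,
       patient_id = pts$patient_id, fold = fold)
}

# Conditional predictions for a set of patients using a fitted pipeline
# (no refitting): scores are re-estimated under the trained FPCA models.
predict_cohort <- function(pipeline, measurements, patients, ids, horizons) {
  cfg <- feature_configurations()[[pipeline$configuration]]
  pts <- patients[match(ids, patients$patient_id), , drop = FALSE]
  meas <- measurements[measurements$patient_id %in% ids &
                         measurements$time_months <= pipeline$feature_horizon,
                       , drop = FALSE]
  meas <- cap_and_log_table(meas, pipeline$limits)
  mscores <- NULL; cea_scores <- NULL
  if (cfg$scores != "none") {
    ord <- as.character(pts$patient_id)
    scores_list <- lapply(stats::setNames(MARKERS, MARKERS), function(m) {
      d <- meas[meas$marker == m, , drop = FALSE]
      sc <- estimate_scores(pipeline$fpca[[m]],
                            data.frame(patient_id = d$patient_id,
                                       time = d$time_months, y = d$y))
      sc$scores[ord, , drop = FALSE]
    })
    if (cfg$scores == "multivariate") {
      mscores <- mfpca_transform(pipeline$mfpca, scores_list)
    } else {
      cea_scores <- scores_list[["CEA"]]
    }
  }
  anchors <- extract_anchor_values(
    measurements[measurements$patient_id %in% ids, , drop = FALSE],
    pipeline$preop_window)
  features <- build_features(pipeline$configuration, pts, anchors, mscores,
                             cea_scores, pipeline$limits)
  predict_conditional(pipeline$forest, features, pipeline$landmark, horizons)
}

#' External validation of fitted pipelines
#'
#' No refitting: the external cohort is preprocessed with the training
#' rules, scores are estimated under the trained FPCA/MFPCA models, and the
#' IPCW AUC and Brier score are computed at `t` (default 60 months).
#'
#' @param pipelines named list of fitted [fit_pipeline()] objects.
#' @param measurements,patients external cohort tables.
#' @param t evaluation horizon, months.
#' @return data.frame with one row per pipeline: `auc`, `brier`, counts.
#' @export
external_validate <- function(pipelines, measurements, patients, t = 60) {
  if (nrow(patients) == 0) stop("empty external cohort")
  if (!is.list(pipelines) || inherits(pipelines, "marker_pipeline")) {
    pipelines <- list(model = pipelines)
  }
  s <- pipelines[[1]]$landmark
  elig <- filter_eligible(measurements, patients,
                          pipelines[[1]]$preop_window,
                          pipelines[[1]]$min_postop,
                          pipelines[[1]]$feature_horizon)
  pts <- patients[patients$patient_id %in% elig$eligible, , drop = FALSE]
  pts <- pts[pts$patient_id %in% apply_landmark(pts, s), , drop = FALSE]
  out <- do.call(rbind, lapply(names(pipelines), function(nm) {
    pl <- pipelines[[nm]]
    pred <- predict_cohort(pl, measurements, pts, pts$patient_id, t)
    r <- 1 - pred$pi[, 1]
    data.frame(configuration = nm, landmark = s, horizon = t,
               auc = td_auc(r, pts$time, pts$event, s, t),
               brier = brier_score(r, pts$time, pts$event, s, t),
               n_events = sum(pts$event == 1 & pts$time <= t),
               n_at_risk = sum(pts$time > t))
  }))
  rownames(out) <- NULL
  out
}
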