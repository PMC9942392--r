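# Landmark conditional survival prediction, updated as new marker
# measurements accrue, plus predicted marker trajectories.

#' Fit the full marker-to-survival pipeline on one cohort
#'
#' Applies eligibility filtering, caps and log-transforms the measurements,
#' restricts to the landmark risk set, fits sparse FPCA per marker on
#' measurements up to the feature horizon, combines scores by MFPCA (for
#' score-using configurations), assembles the configuration's feature table
#' and fits the survival forest.
#'
#' @param measurements long measurement table (`patient_id`, `marker`,
#'   `time_months`, `value`).
#' @param patients patient table (covariates, `time`, `event`).
#' @param configuration one of `names(feature_configurations())`.
#' @param landmark landmark time s, months; training uses the risk set
#'   `time > s`.
#' @param feature_horizon only measurements in `[-preop_window,
#'   feature_horizon]` feed the trajectory features.
#' @param limits a [reference_limits()].
#' @param control an [fpca_control()].
#' @param M joint components for MFPCA (`"auto"` = 99 percent variance).
#' @param preop_window,min_postop eligibility settings, months / count.
#' @param num_trees,min_node_size,seed forest hyperparameters.
#' @return object of class `marker_pipeline`.
#' @export
fit_pipeline <- function(measurements, patients,
                         configuration = "longitudinal_3marker",
                         landmark = 12, feature_horizon = 12,
                         limits = reference_limits(),
                         control = fpca_control(), M = "auto",
                         preop_window = 0.92, min_postop = 2,
                         num_trees = 1000, min_node_size = 15, seed = 1) {
  cfg <- feature_configurations()[[configuration]]
  if (is.null(cfg)) stop("unknown configuration: ", configuration)
  elig <- filter_eligible(measurements, patients, preop_window, min_postop,
                          feature_horizon)
  pts <- patients[patients$patient_id %in% elig$eligible, , drop = FALSE]
  risk_ids <- apply_landmark(pts, landmark)
  pts <- pts[pts$patient_id %in% risk_ids, , drop = FALSE]
  meas <- measurements[measurements$patient_id %in% risk_ids &
                         measurements$time_months <= feature_horizon, ,
                       drop = FALSE]
  meas <- cap_and_log_table(meas, limits)

  fpca <- NULL; mfpca <- NULL; mscores <- NULL; cea_scores <- NULL
  if (cfg$scores != "none") {
    fpca <- lapply(stats::setNames(MARKERS, MARKERS), function(m) {
      d <- meas[meas$marker == m, , drop = FALSE]
      fit_fpca(data.frame(patient_id = d$patient_id, time = d$time_months,
                          y = d$y), control, marker = m)
    })
    # align score rows to the patient table
    ord <- as.character(pts$patient_id)
    scores_list <- lapply(fpca, function(f) f$scores[ord, , drop = FALSE])
    if (cfg$scores == "multivariate") {
      mfpca <- fit_mfpca(scores_list, M = M, fpca_models = fpca)
      mscores <- mfpca$rho
    } else {
      cea_scores <- scores_list[["CEA"]]
    }
  }
  anchors <- extract_anchor_values(
    measurements[measurements$patient_id %in% risk_ids, , drop = FALSE],
    preop_window)
  features <- build_features(configuration, pts, anchors, mscores,
                             cea_scores, limits)
  forest <- rsf_fit(features, pts$time, pts$event, num_trees = num_trees,
                    min_node_size = min_node_size, seed = seed)
  structure(list(configuration = configuration, landmark = landmark,
                 feature_horizon = feature_horizon, limits = limits,
                 control = control, preop_window = preop_window,
                 min_postop = min_postop, fpca = fpca, mfpca = mfpca,
                 forest = forest, features = features, patients = pts,
                 anchors = anchors),
            class = "marker_pipeline")
}

#' Conditional survival from a fitted survival model
#'
#' The landmarking estimator \eqn{\hat\pi(s'|s) = \hat S(s') / \hat S(s)}
#' from the model's predicted survival curve for each feature row, clipped
#' to `[0, 1]`.
#'
#' @param model an `rsf_model`.
#' @param features feature rows (training schema); ignored when
#'   `oob = TRUE`.
#' @param s landmark, months.
#' @param horizons prediction horizons, months, each `> s` (a horizon equal
#'   to `s` returns probability 1).
#' @param oob use out-of-bag curves for the training rows.
#' @return object of class `landmark_prediction`: `s`, `horizons`, matrix
#'   `pi` (patients x horizons).
#' @export
predict_conditional <- function(model, features = NULL, s, horizons,
                                oob = FALSE) {
  if (any(horizons < s)) stop("horizons must not precede the landmark")
  S <- predict_survival(model, features, c(s, horizons), oob = oob)
  Ss <- S[, 1]
  if (any(Ss == 0)) {
    stop("predicted survival at the landmark is zero; conditional ",
         "probability undefined")
  }
  pi <- pmin(pmax(S[, -1, drop = FALSE] / Ss, 0), 1)
  colnames(pi) <- as.character(horizons)
  rownames(pi) <- if (oob) rownames(model$oob_survival) else rownames(features)
  structure(list(s = s, horizons = horizons, pi = pi),
            class = "landmark_prediction")
}

# BLUP scores for one patient's capped/log measurements under the
# pipeline's fitted FPCA models; a marker with no observations gets zero
# scores (shrinkage to the prior mean) and prior covariance.
patient_scores <- function(pipeline, meas) {
  out <- lapply(stats::setNames(MARKERS, MARKERS), function(m) {
    f <- pipeline$fpca[[m]]
    d <- meas[meas$marker == m, , drop = FALSE]
    if (nrow(d) == 0) {
      list(scores = matrix(0, 1, f$K,
                           dimnames = list("new", paste0("FPC", seq_len(f$K)))),
           cov = list(new = diag(f$lambda, f$K)))
    } else {
      estimate_scores(f, data.frame(patient_id = "new", time = d$time_months,
                                    y = d$y))
    }
  })
  out
}

#' Dynamic prediction for one patient
#'
#' Estimates the patient's FPC scores from all measurements up to `cutoff`,
#' projects them onto the joint components, rebuilds the feature row for
#' the pipeline's configuration and returns the conditional survival curve
#' plus predicted marker trajectories.
#'
#' @param pipeline a fitted [fit_pipeline()] object.
#' @param covariates one-row data.frame of the patient's covariates
#'   (same columns as the training patient table).
#' @param measurements the patient's long measurement table.
#' @param horizons prediction horizons, months.
#' @param cutoff measurement-history cutoff u, months (capped at the
#'   pipeline's feature horizon).
#' @return `landmark_prediction` with extra fields `scores`, `score_cov`
#'   and `trajectories` (per marker: grid, log-scale and original-scale
#'   fits).
#' @export
predict_patient <- function(pipeline, covariates, measurements,
                            horizons = seq(18, 60, by = 6), cutoff = Inf) {
  stopifnot(inherits(pipeline, "marker_pipeline"))
  cfg <- feature_configurations()[[pipeline$configuration]]
  u <- min(cutoff, pipeline$feature_horizon)
  meas <- measurements[measurements$time_months <= u, , drop = FALSE]
  meas <- cap_and_log_table(meas, pipeline$limits)
  mscores <- NULL; cea_scores <- NULL; sc <- NULL
  if (cfg$scores != "none") {
    sc <- patient_scores(pipeline, meas)
    scores_list <- lapply(sc, `[[`, "scores")
    if (cfg$scores == "multivariate") {
      mscores <- mfpca_transform(pipeline$mfpca, scores_list)
      rownames(mscores) <- as.character(covariates$patient_id)
    } else {
      cea_scores <- scores_list[["CEA"]]
      rownames(cea_scores) <- as.character(covariates$patient_id)
    }
  }
  anchors <- extract_anchor_values(measurements, pipeline$preop_window)
  anchors$patient_id <- covariates$patient_id
  features <- build_features(pipeline$configuration, covariates, anchors,
                             mscores, cea_scores, pipeline$limits)
  pred <- predict_conditional(pipeline$forest, features, pipeline$landmark,
                              horizons)
  if (!is.null(sc)) {
    pred$scores <- lapply(sc, function(x) as.vector(x$scores))
    pred$score_cov <- lapply(sc, function(x) x$cov[[1]])
    pred$trajectories <- lapply(stats::setNames(MARKERS, MARKERS), function(m) {
      predict_marker_trajectory(pipeline$fpca[[m]], pred$scores[[m]])
    })
  }
  pred$cutoff <- u
  pred
}

#' Update a prediction with a newly collected measurement
#'
#' Appends the capped/logged observation to the patient's history
#' (de-duplicating by marker and time, last value wins), re-estimates the
#' FPC scores on the augmented history, re-projects, rebuilds the feature
#' row and re-predicts.
#'
#' @param pipeline a fitted [fit_pipeline()] object.
#' @param covariates one-row covariate data.frame.
#' @param measurements the patient's measurement history (long format).
#' @param new_obs list or one-row data.frame with `marker`, `time_months`,
#'   `value`.
#' @param horizons prediction horizons, months.
#' @return the refreshed `landmark_prediction`.
#' @export
update_with_measurement <- function(pipeline, covariates, measurements,
                                    new_obs, horizons = seq(18, 60, by = 6)) {
  if (new_obs$time_months > pipeline$feature_horizon) {
    stop("measurement at ", new_obs$time_months, " months is beyond the ",
         "feature horizon; the model only uses measurements during ",
         pipeline$feature_horizon, " months after surgery")
  }
  if (new_obs$value <= 0) stop("marker value must be positive")
  add <- data.frame(patient_id = covariates$patient_id,
                    marker = new_obs$marker,
                    time_months = new_obs$time_months, value = new_obs$value)
  hist <- rbind(measurements[, c("patient_id", "marker", "time_months",
                                 "value")], add)
  # de-duplicate by (marker, time): last record wins
  key <- paste(hist$marker, hist$time_months)
  hist <- hist[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  hist <- hist[order(hist$marker, hist$time_months), , drop = FALSE]
  predict_patient(pipeline, covariates, hist, horizons)
}

#' Predicted marker trajectory from FPC scores
#'
#' Reconstruction \eqn{\mu + \sum_k \hat\xi_k \phi_k} on the model grid,
#' reported on the log scale and back-transformed to the original
#' (capped-scale) marker units.
#'
#' @param model an `fpca_model`.
#' @param scores score vector for one patient.
#' @return list: `grid`, `log_value`, `value`.
#' @export
predict_marker_trajectory <- function(model, scores) {
  tr <- fit_trajectory(model, scores)
  list(grid = tr$grid, log_value = as.vector(tr$fitted),
       value = exp(as.vector(tr$fitted)))
}

#' @export
print.landmark_prediction <- function(x, ...) {
  cat("Conditional survival from landmark s =", x$s, "months\n")
  print(round(x$pi, 4))
  invisible(x)
}
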