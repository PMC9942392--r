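# Random survival forest over named feature configurations, with
# out-of-bag machinery and permutation variable importance. The ensemble
# (log-rank splits, Nelson-Aalen leaf estimators, OOB error as
# 1 - concordance) is backed by ranger; this module owns the feature
# encoding, the configuration contract, and the prediction surface.

#' The six feature configurations
#'
#' Nested marker-feature sets on top of the demographic and
#' clinicopathological covariates: none (`basic`), preoperative CEA
#' (`preop_cea`), preoperative CEA+CA19-9+CA125 (`preop_3marker`), the
#' latter plus first postoperative values (`postop_3marker`), and the
#' longitudinal configurations adding FPC trajectory scores (univariate CEA
#' scores for `longitudinal_cea`, joint multivariate scores for
#' `longitudinal_3marker`).
#'
#' @return named list describing each configuration.
#' @export
feature_configurations <- function() {
  list(
    basic = list(preop = character(0), postop = character(0), scores = "none"),
    preop_cea = list(preop = "CEA", postop = character(0), scores = "none"),
    preop_3marker = list(preop = MARKERS, postop = character(0),
                         scores = "none"),
    postop_3marker = list(preop = MARKERS, postop = MARKERS, scores = "none"),
    longitudinal_cea = list(preop = "CEA", postop = character(0),
                            scores = "cea"),
    longitudinal_3marker = list(preop = MARKERS, postop = character(0),
                                scores = "multivariate")
  )
}

# One-hot encoding of the clinicopathological covariates with documented
# reference levels (female, colon, laparoscopic, well differentiation,
# stage I, <12 nodes).
encode_covariates <- function(patients) {
  data.frame(
    age = as.numeric(patients$age),
    sex_male = as.integer(patients$sex == "male"),
    site_rectum = as.integer(patients$primary_site == "rectum"),
    approach_open = as.integer(patients$surgical_approach == "open"),
    diff_moderate = as.integer(patients$differentiation == "moderate"),
    diff_poor = as.integer(patients$differentiation == "poor"),
    stage_II = as.integer(patients$stage == "II"),
    stage_III = as.integer(patients$stage == "III"),
    ln_yield_ge12 = as.integer(patients$ln_yield == ">=12"),
    mucinous = as.integer(patients$mucinous),
    lymphovascular_invasion = as.integer(patients$lymphovascular_invasion),
    perineural_invasion = as.integer(patients$perineural_invasion),
    adjuvant_chemo = as.integer(patients$adjuvant_chemo),
    row.names = as.character(patients$patient_id)
  )
}

#' Assemble the feature table for a configuration
#'
#' One row per patient: encoded covariates, then capped log-scale anchor
#' values and trajectory scores as the configuration requires.
#'
#' @param configuration one of `names(feature_configurations())`.
#' @param patients patient table (covariates; `patient_id`).
#' @param anchors output of [extract_anchor_values()] (raw values; capped
#'   and logged here), required by non-basic configurations.
#' @param mscores multivariate score matrix (rownames = patient ids),
#'   required by `longitudinal_3marker`.
#' @param cea_scores univariate CEA score matrix, required by
#'   `longitudinal_cea`.
#' @param limits a [reference_limits()].
#' @return data.frame of numeric features, rownames = patient ids.
#' @export
build_features <- function(configuration, patients, anchors = NULL,
                           mscores = NULL, cea_scores = NULL,
                           limits = reference_limits()) {
  cfgs <- feature_configurations()
  if (!configuration %in% names(cfgs)) {
    stop("unknown configuration: ", configuration)
  }
  if (nrow(patients) == 0) stop("empty patient list")
  cfg <- cfgs[[configuration]]
  ids <- as.character(patients$patient_id)
  out <- encode_covariates(patients)
  safe <- function(m) gsub("[^A-Za-z0-9]", "", m)
  need_anchor <- function(kind, markers) {
    if (length(markers) == 0) return(NULL)
    if (is.null(anchors)) stop("anchor values required for ", configuration)
    a <- anchors[match(patients$patient_id, anchors$patient_id), , drop = FALSE]
    for (m in markers) {
      col <- paste0(kind, "_", safe(m))
      if (!col %in% names(a)) stop("anchor column missing: ", col)
      v <- a[[col]]
      if (anyNA(v)) {
        stop("missing ", col, " for patient(s): ",
             paste(utils::head(ids[is.na(v)], 5), collapse = ", "))
      }
      out[[col]] <<- cap_and_log(v, m, limits)
    }
  }
  need_anchor("preop", cfg$preop)
  need_anchor("postop", cfg$postop)
  if (cfg$scores == "multivariate") {
    if (is.null(mscores)) stop("multivariate scores required for ", configuration)
    idx <- match(ids, rownames(mscores))
    if (anyNA(idx)) {
      stop("missing multivariate scores for patient(s): ",
           paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
    }
    out <- cbind(out, as.data.frame(mscores[idx, , drop = FALSE]))
  } else if (cfg$scores == "cea") {
    if (is.null(cea_scores)) stop("CEA scores required for ", configuration)
    idx <- match(ids, rownames(cea_scores))
    if (anyNA(idx)) {
      stop("missing CEA scores for patient(s): ",
           paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
    }
    sc <- as.data.frame(cea_scores[idx, , drop = FALSE])
    names(sc) <- paste0("CEA_", colnames(cea_scores))
    out <- cbind(out, sc)
  }
  rownames(out) <- ids
  out
}

#' Fit a random survival forest
#'
#' Log-rank splitting, Nelson-Aalen cumulative hazards in the leaves,
#' out-of-bag survival curves retained for internal evaluation, permutation
#' importance computed from the OOB error (1 - concordance). Defaults:
#' 1000 trees, sqrt(p) candidate features per split, minimum node size 15.
#'
#' @param features numeric feature data.frame (rownames = patient ids).
#' @param time,event observed times (months) and event indicators.
#' @param num_trees,mtry,min_node_size forest hyperparameters.
#' @param seed integer seed (single-threaded, so fully deterministic).
#' @return object of class `rsf_model`.
#' @export
rsf_fit <- function(features, time, event, num_trees = 1000, mtry = NULL,
                    min_node_size = 15, seed = 1) {
  stopifnot(nrow(features) == length(time), length(time) == length(event))
  if (sum(event) < 2) stop("need at least 2 events")
  if (any(time <= 0)) stop("times must be positive")
  if (length(unique(time)) < 2) stop("constant observed times")
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(features))))
  d <- cbind(data.frame(.time = time, .event = event), features)
  fit <- ranger::ranger(
    survival::Surv(.time, .event) ~ ., data = d,
    num.trees = num_trees, mtry = mtry, min.node.size = min_node_size,
    splitrule = "logrank", importance = "permutation",
    seed = seed, num.threads = 1
  )
  structure(list(fit = fit, schema = colnames(features),
                 death_times = fit$unique.death.times,
                 oob_survival = fit$survival,
                 oob_concordance = 1 - fit$prediction.error,
                 hyper = list(num_trees = num_trees, mtry = mtry,
                              min_node_size = min_node_size, seed = seed)),
            class = "rsf_model")
}

# Step-function evaluation of survival matrices (patients x death times)
# at arbitrary times; S = 1 before the first death time.
eval_survival_steps <- function(surv, death_times, times) {
  idx <- findInterval(times, death_times)
  out <- matrix(1, nrow(surv), length(times))
  pos <- which(idx > 0)
  if (length(pos) > 0) out[, pos] <- surv[, idx[pos], drop = FALSE]
  out
}

#' Predict ensemble-averaged survival probabilities
#'
#' @param model an `rsf_model`.
#' @param features feature rows matching the training schema.
#' @param times evaluation times, months.
#' @param oob use the stored out-of-bag curves for the training rows
#'   instead of re-predicting (features then ignored).
#' @return matrix (patients x times) of survival probabilities; step
#'   functions, non-increasing per patient, starting at 1.
#' @export
predict_survival <- function(model, features = NULL, times, oob = FALSE) {
  stopifnot(inherits(model, "rsf_model"))
  if (oob) {
    return(eval_survival_steps(model$oob_survival, model$death_times, times))
  }
  if (!identical(colnames(features), model$schema)) {
    stop("feature schema does not match training schema")
  }
  pr <- stats::predict(model$fit, data = features, num.threads = 1)
  sv <- pr$survival
  if (!is.matrix(sv)) sv <- matrix(sv, nrow = nrow(features))
  eval_survival_steps(sv, pr$unique.death.times, times)
}

#' Permutation variable importance
#'
#' Out-of-bag prediction-error increase (error = 1 - concordance) after
#' permuting each feature, as recorded during fitting; ranked descending.
#'
#' @param model an `rsf_model`.
#' @return data.frame: `feature`, `importance`, `rank`.
#' @export
compute_vimp <- function(model) {
  stopifnot(inherits(model, "rsf_model"))
  imp <- model$fit$variable.importance
  out <- data.frame(feature = names(imp), importance = as.numeric(imp))
  out$rank <- rank(-out$importance, ties.method = "first")
  out[order(out$rank), ]
}
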