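# Eligibility, truncation (capping), log transform, anchor values, landmark.

#' Reference upper limits and cap multiplier for the serum markers
#'
#' Defaults are the usual reference upper limits (CEA 5 ng/ml, CA19-9
#' 37 U/ml, CA125 35 U/ml); extreme values are truncated at `multiplier`
#' times the limit before log transformation.
#'
#' @param limits named numeric vector of upper reference limits.
#' @param multiplier cap multiplier, `> 1`.
#' @return object of class `reference_limits`.
#' @export
reference_limits <- function(limits = c("CEA" = 5, "CA19-9" = 37, "CA125" = 35),
                             multiplier = 10) {
  if (any(limits <= 0)) stop("reference limits must be positive")
  if (multiplier <= 1) stop("cap multiplier must exceed 1")
  structure(list(limits = limits, multiplier = multiplier),
            class = "reference_limits")
}

#' Cap a raw marker value and take the natural log
#'
#' Values above `multiplier * limit` are truncated there before the log, to
#' blunt the high intra-patient variability of these markers; e.g. CEA
#' 120 ng/ml becomes `log(50)`.
#'
#' @param value positive raw values, marker units.
#' @param marker single marker name with a configured limit.
#' @param limits a [reference_limits()].
#' @return numeric vector of log-scale values, `<= log(multiplier * limit)`.
#' @export
cap_and_log <- function(value, marker, limits = reference_limits()) {
  if (!marker %in% names(limits$limits)) {
    stop("unknown marker: ", marker)
  }
  bad <- which(!is.finite(value) | value <= 0)
  if (length(bad) > 0) {
    stop("non-positive ", marker, " value at record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  log(pmin(value, limits$multiplier * limits$limits[[marker]]))
}

# Apply cap_and_log across a long measurement table, adding a `y` column.
cap_and_log_table <- function(measurements, limits = reference_limits()) {
  measurements$y <- NA_real_
  for (m in unique(measurements$marker)) {
    idx <- measurements$marker == m
    measurements$y[idx] <- cap_and_log(measurements$value[idx], m, limits)
  }
  measurements
}

#' Eligibility filter: preoperative value plus enough postoperative values
#'
#' Keeps patients with at least one observation in `[-preop_window, 0)` and
#' at least `min_postop` observations in `(0, horizon]` for every marker in
#' `markers`. The exclusion log records the first failed rule per excluded
#' patient.
#'
#' @param measurements long table (`patient_id`, `marker`, `time_months`).
#' @param patients patient table with `patient_id`.
#' @param preop_window window before surgery, months (4 weeks = 0.92).
#' @param min_postop minimum postoperative count per marker.
#' @param horizon postoperative horizon, months.
#' @param markers marker names the rule applies to.
#' @return list with `eligible` (patient ids) and `exclusions`
#'   (data.frame `patient_id`, `rule`, `detail`).
#' @export
filter_eligible <- function(measurements, patients, preop_window = 0.92,
                            min_postop = 2, horizon = 12,
                            markers = MARKERS) {
  if (nrow(measurements) == 0 || nrow(patients) == 0) {
    stop("empty input table")
  }
  ids <- patients$patient_id
  excl <- list()
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    pid <- ids[i]
    rows <- measurements[measurements$patient_id == pid, , drop = FALSE]
    fail <- NULL
    for (m in markers) {
      tm <- rows$time_months[rows$marker == m]
      if (!any(tm >= -preop_window & tm < 0)) {
        fail <- c("no preoperative measurement in window",
                  sprintf("%s: none in [-%.2f, 0)", m, preop_window))
        break
      }
      if (sum(tm > 0 & tm <= horizon) < min_postop) {
        fail <- c("insufficient postoperative measurements",
                  sprintf("%s: %d < %d in (0, %g]", m,
                          sum(tm > 0 & tm <= horizon), min_postop, horizon))
        break
      }
    }
    if (is.null(fail)) {
      keep[i] <- TRUE
    } else {
      excl[[length(excl) + 1]] <- data.frame(patient_id = pid,
                                             rule = fail[1], detail = fail[2])
    }
  }
  exclusions <- if (length(excl) > 0) do.call(rbind, excl) else
    data.frame(patient_id = ids[0], rule = character(0), detail = character(0))
  list(eligible = ids[keep], exclusions = exclusions)
}

#' Preoperative and first postoperative anchor values per patient and marker
#'
#' The preoperative value is the observation closest to surgery among
#' negative times within the window (tie between equidistant values broken
#' towards the later-recorded row); the first postoperative value is the one
#' at the smallest positive time.
#'
#' @inheritParams filter_eligible
#' @return data.frame: `patient_id`, then `preop_<marker>` and
#'   `postop_<marker>` raw-value columns.
#' @export
extract_anchor_values <- function(measurements, preop_window = 0.92,
                                  markers = MARKERS) {
  ids <- sort(unique(measurements$patient_id))
  out <- data.frame(patient_id = ids)
  safe <- function(m) gsub("[^A-Za-z0-9]", "", m)
  for (m in markers) {
    pre <- post <- rep(NA_real_, length(ids))
    mm <- measurements[measurements$marker == m, , drop = FALSE]
    for (i in seq_along(ids)) {
      rows <- mm[mm$patient_id == ids[i], , drop = FALSE]
      neg <- which(rows$time_months >= -preop_window & rows$time_months < 0)
      if (length(neg) > 0) {
        d <- abs(rows$time_months[neg])
        # ties -> later-recorded row (largest index among minima)
        pick <- neg[max(which(d == min(d)))]
        pre[i] <- rows$value[pick]
      }
      pos <- which(rows$time_months > 0)
      if (length(pos) > 0) {
        post[i] <- rows$value[pos[which.min(rows$time_months[pos])]]
      }
    }
    out[[paste0("preop_", safe(m))]] <- pre
    out[[paste0("postop_", safe(m))]] <- post
  }
  out
}

#' Landmark risk set
#'
#' Retains patients whose observed time exceeds the landmark `s`; these form
#' the training and evaluation risk set for conditional prediction from `s`.
#'
#' @param patients patient table with `patient_id` and `time`.
#' @param s landmark, months, `>= 0`.
#' @return vector of retained patient ids.
#' @export
apply_landmark <- function(patients, s = 12) {
  stopifnot(s >= 0)
  patients$patient_id[patients$time > s]
}
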