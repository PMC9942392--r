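# Synthetic cohort generator with known ground truth.
#
# Emulates a perioperative tumor-marker study: three correlated serum markers
# (CEA ng/ml, CA19-9 U/ml, CA125 U/ml) observed sparsely and irregularly
# around curative surgery, log-scale latent trajectories with a
# Karhunen-Loeve structure, and overall survival whose log-hazard is linear
# in the leading trajectory scores and in AJCC stage.

months_per_week <- 0.23  # 4 weeks = 0.92 months

#' Specification of one synthetic marker process
#'
#' The latent log-scale trajectory is
#' \eqn{X_i(t) = \mu(t) + \sum_k \xi_{ik} \phi_k(t)} with observation noise
#' variance `sigma2`; raw values are `exp` of the noisy log process.
#'
#' @param name marker name.
#' @param ulim upper limit of the reference range, marker units.
#' @param mean_knots,mean_values knots (months) and log-scale values of the
#'   mean function; interpolated by a natural spline.
#' @param basis list of raw basis functions of time; orthonormalized on the
#'   simulation grid (Gram-Schmidt) to form the eigenfunctions.
#' @param lambda eigenvalues (log-scale variances), descending, `>= 0`.
#' @param sigma2 measurement-error variance on the log scale.
#' @return object of class `marker_spec`.
#' @export
marker_spec <- function(name, ulim, mean_knots, mean_values,
                        basis = list(function(t) rep(1, length(t)),
                                     function(t) t),
                        lambda = c(4, 1), sigma2 = 0.1) {
  stopifnot(ulim > 0, length(mean_knots) == length(mean_values),
            length(basis) == length(lambda))
  if (any(lambda < 0) || sigma2 < 0) {
    stop("negative variance components in marker spec for ", name)
  }
  if (is.unsorted(rev(lambda))) stop("eigenvalues must be descending")
  structure(list(name = name, ulim = ulim, mean_knots = mean_knots,
                 mean_values = mean_values, basis = basis,
                 lambda = lambda, sigma2 = sigma2),
            class = "marker_spec")
}

#' Default marker specifications
#'
#' Mean shapes follow the observed perioperative pattern: CEA and CA19-9
#' drop after surgery towards their postoperative medians, while CA125 rises
#' above its preoperative level early after surgery before declining.
#' Levels are the log of the cohort medians (CEA 3.9 -> 1.9 ng/ml, CA19-9
#' 12.6 -> 9.4 U/ml, CA125 12.9 -> 24.5 U/ml).
#'
#' @return named list of [marker_spec()] objects for CEA, CA19-9, CA125.
#' @export
default_markers <- function() {
  list(
    "CEA" = marker_spec("CEA", ulim = 5,
      mean_knots = c(-1, 0, 1, 3, 6, 12),
      mean_values = log(c(3.9, 3.9, 2.6, 1.9, 1.9, 1.9))),
    "CA19-9" = marker_spec("CA19-9", ulim = 37,
      mean_knots = c(-1, 0, 1, 3, 6, 12),
      mean_values = log(c(12.6, 12.6, 10.8, 9.4, 9.4, 9.4))),
    "CA125" = marker_spec("CA125", ulim = 35,
      mean_knots = c(-1, 0, 1, 3, 6, 12),
      mean_values = log(c(12.9, 12.9, 24.5, 21, 17, 15)))
  )
}

# Correlation among stacked true scores: leading scores of the three markers
# share correlation 0.5, second scores 0.3, no cross-order correlation.
default_score_correlation <- function(markers) {
  ks <- vapply(markers, function(m) length(m$lambda), integer(1))
  p <- sum(ks)
  labels <- unlist(lapply(seq_along(markers), function(i) {
    paste(markers[[i]]$name, seq_len(ks[i]), sep = ".")
  }))
  R <- diag(p)
  dimnames(R) <- list(labels, labels)
  ord <- sub("^.*\\.", "", labels)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      same_marker <- sub("\\.\\d+$", "", labels[i]) == sub("\\.\\d+$", "", labels[j])
      if (!same_marker && ord[i] == ord[j]) {
        R[i, j] <- R[j, i] <- if (ord[i] == "1") 0.5 else 0.3
      }
    }
  }
  R
}

#' Default hazard specification
#'
#' Weibull baseline (shape 1.3, scale 180 months) with log-hazard linear in
#' the leading true score of each marker (coefficient 0.35) and in AJCC
#' stage (II: 0.5, III: 1.0) -- the simplest mechanism that makes prognosis
#' depend on trajectory shape and stage.
#'
#' @param markers named list of [marker_spec()]s.
#' @return hazard specification list.
#' @export
default_hazard <- function(markers) {
  list(shape = 1.3, scale = 180,
       beta = stats::setNames(rep(0.35, length(markers)),
                              paste0(names(markers), ".1")),
       beta_stage = c(I = 0, II = 0.5, III = 1))
}

#' Synthetic cohort configuration
#'
#' Bundles every knob of the generator: the marker processes, the
#' cross-marker score correlation, the visit process, the survival hazard,
#' censoring, the spike (outlier) process, and the seed.
#'
#' @param n_patients cohort size.
#' @param markers named list of [marker_spec()]s.
#' @param score_correlation correlation matrix for the stacked true scores;
#'   must be symmetric positive semi-definite.
#' @param visit list: `mean_visits` (Poisson mean of postoperative visits
#'   within 12 months), `min_visits` (lower truncation), `jitter_sd` (months),
#'   `preop_window_weeks`.
#' @param hazard list: `shape`, `scale` of the Weibull baseline (months;
#'   `shape = 1` gives an exponential), `beta` named log-hazard coefficients
#'   on stacked true scores (names like `"CEA.1"`), `beta_stage` named vector
#'   over stages I-III.
#' @param censoring list: `horizon` administrative censoring (months),
#'   `rate` of additional exponential random censoring (per month).
#' @param spike list: `prob` of an extreme spike per observation and
#'   multiplicative `magnitude`.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 500,
                          markers = default_markers(),
                          score_correlation = default_score_correlation(markers),
                          visit = list(mean_visits = 4, min_visits = 2,
                                       jitter_sd = 0.8, preop_window_weeks = 4),
                          hazard = default_hazard(markers),
                          censoring = list(horizon = 72, rate = 0.004),
                          spike = list(prob = 0.02, magnitude = 5),
                          seed = 1) {
  stopifnot(n_patients >= 1, length(markers) >= 1)
  if (!isTRUE(all.equal(score_correlation, t(score_correlation)))) {
    stop("score correlation matrix must be symmetric")
  }
  ev <- eigen(score_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("score correlation matrix is not positive semi-definite")
  if (spike$prob < 0 || spike$prob > 1) stop("spike probability must be in [0,1]")
  if (hazard$shape <= 0 || hazard$scale <= 0) {
    stop("baseline hazard parameters must be positive")
  }
  structure(list(n_patients = n_patients, markers = markers,
                 score_correlation = score_correlation, visit = visit,
                 hazard = hazard, censoring = censoring, spike = spike,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Orthonormalize the raw basis of a marker spec on a dense grid, returning
# the mean and eigenfunction values (columns) on that grid.
marker_truth_on_grid <- function(spec, grid) {
  w <- quadrature_weights(grid)
  mu <- stats::spline(spec$mean_knots, spec$mean_values, xout = grid,
                      method = "natural")$y
  B <- vapply(spec$basis, function(f) f(grid), numeric(length(grid)))
  # Gram-Schmidt under the quadrature inner product
  for (k in seq_len(ncol(B))) {
    if (k > 1) {
      for (l in seq_len(k - 1)) {
        B[, k] <- B[, k] - sum(w * B[, k] * B[, l]) * B[, l]
      }
    }
    nrm <- sqrt(sum(w * B[, k]^2))
    if (nrm < 1e-12) stop("degenerate basis function ", k, " for ", spec$name)
    B[, k] <- B[, k] / nrm
    s <- sum(w * B[, k])
    # zero-integral shapes: orient by the value at the end of follow-up
    if (abs(s) < 1e-12) s <- B[length(grid), k]
    if (s < 0) B[, k] <- -B[, k]
  }
  list(mu = mu, phi = B)
}

# Matrix square root via symmetric eigendecomposition (tolerates singular
# PSD correlation matrices, unlike chol).
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate survival outcomes from true scores and stage
#'
#' Event times are drawn by inverse transform from a Weibull baseline with
#' log-hazard linear in the supplied score columns and in stage. Censoring is
#' the minimum of an administrative horizon and an exponential censoring
#' time, independent of the event time.
#'
#' @param scores matrix of true scores (patients x stacked components) with
#'   column names matching `names(hazard$beta)`.
#' @param stage character/factor vector of AJCC stages (`"I"`, `"II"`, `"III"`).
#' @param hazard,censoring as in [cohort_config()].
#' @param seed optional seed applied before drawing.
#' @return data.frame with `time`, `event`, `true_time`, `censor_time`.
#' @export
simulate_survival <- function(scores, stage, hazard, censoring, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (hazard$shape <= 0 || hazard$scale <= 0) {
    stop("baseline hazard parameters must be positive")
  }
  n <- length(stage)
  lp <- rep(0, n)
  if (length(hazard$beta) > 0) {
    miss <- setdiff(names(hazard$beta), colnames(scores))
    if (length(miss) > 0) stop("scores lack columns: ", paste(miss, collapse = ", "))
    lp <- lp + as.vector(scores[, names(hazard$beta), drop = FALSE] %*% hazard$beta)
  }
  if (!is.null(hazard$beta_stage)) lp <- lp + hazard$beta_stage[as.character(stage)]
  u <- stats::runif(n)
  true_time <- hazard$scale * (-log(u) * exp(-lp))^(1 / hazard$shape)
  cens <- rep(censoring$horizon, n)
  if (!is.null(censoring$rate) && censoring$rate > 0) {
    cens <- pmin(cens, stats::rexp(n, rate = censoring$rate))
  }
  time <- pmin(true_time, cens)
  data.frame(time = time, event = as.integer(true_time <= cens),
             true_time = true_time, censor_time = cens)
}

simulate_covariates <- function(n) {
  rcat <- function(levels, prob) {
    factor(sample(levels, n, replace = TRUE, prob = prob), levels = levels)
  }
  data.frame(
    age = pmin(pmax(round(stats::rnorm(n, 57, 11)), 20), 90),
    sex = rcat(c("female", "male"), c(0.407, 0.593)),
    primary_site = rcat(c("colon", "rectum"), c(0.513, 0.487)),
    surgical_approach = rcat(c("laparoscopic", "open"), c(0.379, 0.621)),
    differentiation = rcat(c("well", "moderate", "poor"), c(0.01, 0.66, 0.33)),
    stage = rcat(c("I", "II", "III"), c(0.13, 0.40, 0.47)),
    ln_yield = rcat(c("<12", ">=12"), c(0.198, 0.802)),
    mucinous = stats::rbinom(n, 1, 0.067),
    lymphovascular_invasion = stats::rbinom(n, 1, 0.085),
    perineural_invasion = stats::rbinom(n, 1, 0.021),
    adjuvant_chemo = stats::rbinom(n, 1, 0.862)
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' Every patient receives exactly one preoperative observation (uniform in
#' the configured window before surgery) and a truncated-Poisson number of
#' postoperative observations within 12 months (near-regular schedule with
#' Gaussian jitter). Marker values are `exp(log-scale Gaussian process +
#' noise)`, optionally hit by multiplicative spikes. Survival follows the
#' configured hazard. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `patients` (covariates + `time` + `event`),
#'   `measurements` (long format: `patient_id`, `marker`, `time_months`,
#'   `value`), and `truth` (true scores, event/censoring times, mean and
#'   eigenfunctions on a dense grid).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  grid <- seq(-1, 12, length.out = 201)

  truth_fns <- lapply(config$markers, marker_truth_on_grid, grid = grid)
  ks <- vapply(config$markers, function(m) length(m$lambda), integer(1))
  labels <- unlist(lapply(config$markers, function(m) {
    paste(m$name, seq_along(m$lambda), sep = ".")
  }), use.names = FALSE)
  if (nrow(config$score_correlation) != length(labels)) {
    stop("score correlation dimension does not match total score count")
  }
  lambda_stacked <- unlist(lapply(config$markers, function(m) m$lambda),
                           use.names = FALSE)

  # correlated standard scores, scaled to the marker eigenvalues
  Z <- matrix(stats::rnorm(n * sum(ks)), n, sum(ks)) %*%
    psd_sqrt(config$score_correlation)
  scores <- sweep(Z, 2, sqrt(lambda_stacked), `*`)
  colnames(scores) <- labels

  covars <- simulate_covariates(n)
  surv <- simulate_survival(scores, covars$stage, config$hazard,
                            config$censoring)

  pw <- config$visit$preop_window_weeks * months_per_week
  meas <- vector("list", n)
  for (i in seq_len(n)) {
    t_pre <- stats::runif(1, -pw, -1e-6)
    k <- max(config$visit$min_visits, stats::rpois(1, config$visit$mean_visits))
    base <- (seq_len(k) - 0.5) * 12 / k
    t_post <- sort(pmin(pmax(base + stats::rnorm(k, 0, config$visit$jitter_sd),
                             0.25), 12))
    t_post <- t_post + cumsum(c(0, diff(t_post) == 0)) * 1e-4  # break ties
    times <- c(t_pre, t_post)
    rows <- vector("list", length(config$markers))
    off <- 0
    for (m in seq_along(config$markers)) {
      spec <- config$markers[[m]]
      phi_t <- vapply(seq_len(ks[m]), function(j) {
        eval_grid(grid, truth_fns[[m]]$phi[, j], times)
      }, numeric(length(times)))
      mu_t <- eval_grid(grid, truth_fns[[m]]$mu, times)
      xi_m <- scores[i, off + seq_len(ks[m])]
      y_log <- mu_t + as.vector(phi_t %*% xi_m) +
        stats::rnorm(length(times), 0, sqrt(spec$sigma2))
      raw <- exp(y_log)
      if (config$spike$prob > 0) {
        hit <- stats::runif(length(raw)) < config$spike$prob
        raw[hit] <- raw[hit] * config$spike$magnitude
      }
      rows[[m]] <- data.frame(patient_id = i, marker = spec$name,
                              time_months = times, value = raw)
      off <- off + ks[m]
    }
    meas[[i]] <- do.call(rbind, rows)
  }
  measurements <- do.call(rbind, meas)
  rownames(measurements) <- NULL

  patients <- cbind(data.frame(patient_id = seq_len(n)), covars,
                    data.frame(time = surv$time, event = surv$event))

  truth <- list(
    grid = grid,
    scores = scores,
    blocks = stats::setNames(as.list(ks), names(config$markers)),
    true_time = surv$true_time,
    censor_time = surv$censor_time,
    mean_functions = lapply(truth_fns, `[[`, "mu"),
    eigenfunctions = lapply(truth_fns, `[[`, "phi"),
    eigenvalues = lapply(config$markers, function(m) m$lambda)
  )
  list(patients = patients, measurements = measurements, truth = truth)
}

#' Write / read a synthetic cohort as delimited text plus a JSON sidecar
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly (for `write_cohort`); the cohort list (for
#'   `read_cohort`, without the dense truth functions if absent).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$measurements, file.path(dir, "measurements.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$patients, file.path(dir, "patients.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(grid = tr$grid, scores = tr$scores, blocks = tr$blocks,
           true_time = tr$true_time, censor_time = tr$censor_time,
           eigenvalues = tr$eigenvalues),
      file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  measurements <- utils::read.delim(file.path(dir, "measurements.tsv"))
  patients <- utils::read.delim(file.path(dir, "patients.tsv"))
  truth <- NULL
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
  list(patients = patients, measurements = measurements, truth = truth)
}
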