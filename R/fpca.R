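# Sparse functional PCA by PACE: local-linear mean and covariance
# smoothing, weighted eigendecomposition, AIC choice of the number of
# components, and conditional-expectation (BLUP) scores.
#
# The model for log-scale marker values is
#   Y_ij = mu(t_ij) + sum_k xi_ik phi_k(t_ij) + eps_ij,
# with orthonormal eigenfunctions phi_k, scores xi_ik of variance lambda_k,
# and iid noise of variance sigma2.

#' Control settings for sparse FPCA
#'
#' @param range time range covered by the grid, months (preoperative window
#'   through the 12-month feature horizon).
#' @param grid_len number of equally spaced grid points.
#' @param bw_mean,bw_cov bandwidths for the mean and covariance smoothers
#'   (months), or `"auto"` for generalized cross-validation.
#' @param K number of components, or `"auto"` for AIC selection.
#' @param K_max cap on the number of retained components.
#' @param fve_floor noise floor: eigencomponents contributing less than
#'   this fraction of the total process variance are discarded before model
#'   selection (smoothing artifacts near the eigenvalue tail).
#' @param ridge added to the observation covariance when the error variance
#'   estimate is zero, keeping it invertible.
#' @return list of class `fpca_control`.
#' @export
fpca_control <- function(range = c(-1, 12), grid_len = 101,
                         bw_mean = "auto", bw_cov = "auto",
                         K = "auto", K_max = 10, fve_floor = 0.005,
                         ridge = 1e-8) {
  structure(list(range = range, grid_len = grid_len, bw_mean = bw_mean,
                 bw_cov = bw_cov, K = K, K_max = K_max,
                 fve_floor = fve_floor, ridge = ridge),
            class = "fpca_control")
}

#' Smoothed mean function of pooled sparse observations
#'
#' Local-linear Gaussian-kernel smoother of all (time, value) pairs pooled
#' across patients, evaluated on the grid; `"auto"` bandwidth by GCV.
#'
#' @param series data.frame with `time` and `y` (log-scale values).
#' @param grid evaluation grid.
#' @param bandwidth numeric bandwidth in months or `"auto"`.
#' @return list: `values` on the grid and `bandwidth` used.
#' @export
estimate_mean <- function(series, grid, bandwidth = "auto") {
  if (nrow(series) == 0) stop("no observations")
  if (length(unique(series$time)) < 2) {
    stop("mean estimation needs at least 2 distinct observation times")
  }
  h <- if (identical(bandwidth, "auto")) {
    select_bw_1d(series$time, series$y)
  } else bandwidth
  list(values = ll_smooth_1d(series$time, series$y, grid, h), bandwidth = h)
}

#' Smoothed covariance surface and measurement-error variance
#'
#' Raw within-patient cross-products of mean-centered values (distinct time
#' pairs only, so the error variance does not contaminate the surface) are
#' smoothed by a 2-D local-linear kernel on the grid. The error variance is
#' the average, over the central half of the range, of the smoothed diagonal
#' (which includes error) minus the surface diagonal, floored at zero. The
#' surface is symmetrized and projected to the nearest positive
#' semi-definite surface by truncating negative eigenvalues.
#'
#' @param series data.frame with `patient_id`, `time`, `y`.
#' @param mean_values mean function values on `grid`.
#' @param grid evaluation grid.
#' @param bandwidth bandwidth in months or `"auto"` (GCV).
#' @return list: `surface` (grid x grid), `sigma2`, `bandwidth`.
#' @export
estimate_covariance <- function(series, mean_values, grid, bandwidth = "auto") {
  resid <- series$y - eval_grid(grid, mean_values, series$time)
  sp <- split(data.frame(time = series$time, r = resid), series$patient_id)
  pairs <- lapply(sp, function(d) {
    n <- nrow(d)
    if (n < 2) return(NULL)
    idx <- which(outer(seq_len(n), seq_len(n), `!=`), arr.ind = TRUE)
    data.frame(t1 = d$time[idx[, 1]], t2 = d$time[idx[, 2]],
               cp = d$r[idx[, 1]] * d$r[idx[, 2]])
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) == 0) {
    stop("covariance estimation needs patients with >= 2 observations")
  }
  h <- if (identical(bandwidth, "auto")) {
    select_bw_2d(pairs$t1, pairs$t2, pairs$cp)
  } else bandwidth
  surface <- ll_smooth_2d(pairs$t1, pairs$t2, pairs$cp, grid, grid, h)
  surface <- (surface + t(surface)) / 2

  # diagonal including error: 1-D smooth of squared residuals
  v_diag <- ll_smooth_1d(series$time, resid^2, grid, h)
  central <- grid >= grid[1] + diff(range(grid)) / 4 &
    grid <= grid[length(grid)] - diff(range(grid)) / 4
  sigma2 <- max(0, mean(v_diag[central] - diag(surface)[central]))

  # PSD projection under the quadrature inner product
  w <- quadrature_weights(grid)
  ed <- eigendecompose(surface, grid, w, drop_tol = 0)
  keep <- ed$lambda > 0
  surface_psd <- if (any(keep)) {
    ed$phi[, keep, drop = FALSE] %*%
      (ed$lambda[keep] * t(ed$phi[, keep, drop = FALSE]))
  } else matrix(0, length(grid), length(grid))
  list(surface = (surface_psd + t(surface_psd)) / 2, sigma2 = sigma2,
       bandwidth = h)
}

#' Weighted eigendecomposition of a covariance surface
#'
#' Solves the functional eigenproblem under the trapezoidal quadrature rule,
#' so eigenfunctions are orthonormal with respect to the quadrature inner
#' product. Eigenvalues are sorted descending; each eigenfunction is
#' negated if its integral is negative (sign convention), and components
#' with eigenvalue `<= drop_tol` times the leading one are dropped.
#'
#' @param surface symmetric covariance matrix on `grid` x `grid`.
#' @param grid grid points.
#' @param weights quadrature weights (default from [quadrature_weights()]).
#' @param drop_tol relative eigenvalue threshold.
#' @return list: `lambda` (descending), `phi` (grid x K).
#' @export
eigendecompose <- function(surface, grid, weights = quadrature_weights(grid),
                           drop_tol = 1e-10) {
  sw <- sqrt(weights)
  M <- sw * t(sw * t(surface))   # diag(sw) %*% surface %*% diag(sw)
  ed <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lambda <- ed$values
  phi <- ed$vectors / sw
  if (drop_tol > 0 && length(lambda) > 0 && lambda[1] > 0) {
    keep <- lambda > drop_tol * lambda[1]
  } else {
    keep <- lambda > -Inf
  }
  lambda <- lambda[keep]
  phi <- phi[, keep, drop = FALSE]
  for (k in seq_len(ncol(phi))) {
    s <- sum(weights * phi[, k])
    # zero-integral shapes: orient by the value at the end of the range
    if (abs(s) < 1e-12) s <- phi[length(grid), k]
    if (s < 0) phi[, k] <- -phi[, k]
  }
  list(lambda = lambda, phi = phi)
}

# Interpolate model functions at a patient's observation times.
model_at_times <- function(grid, mu, phi, times) {
  K <- ncol(phi)
  Phi <- vapply(seq_len(K), function(k) eval_grid(grid, phi[, k], times),
                numeric(length(times)))
  if (!is.matrix(Phi)) Phi <- matrix(Phi, nrow = length(times))
  list(mu = eval_grid(grid, mu, times), Phi = Phi)
}

# BLUP scores for one patient given model components.
blup_scores <- function(times, y, grid, mu, phi, lambda, sigma2, ridge = 1e-8) {
  at <- model_at_times(grid, mu, phi, times)
  K <- length(lambda)
  Lam <- diag(lambda, K)
  s2 <- if (sigma2 > 0) sigma2 else ridge
  Sigma <- at$Phi %*% Lam %*% t(at$Phi) + diag(s2, length(times))
  resid <- y - at$mu
  A <- Lam %*% t(at$Phi) %*% solve(Sigma)
  xi <- as.vector(A %*% resid)
  cov <- Lam - A %*% at$Phi %*% Lam
  list(scores = xi, cov = (cov + t(cov)) / 2)
}

#' Number of components by AIC
#'
#' For each candidate K the pseudo-Gaussian log-likelihood of every
#' patient's observation vector is evaluated under the K-component model's
#' implied covariance \eqn{\Phi_i \Lambda_K \Phi_i' + \sigma^2 I} (the same
#' covariance that defines the conditional-expectation scores);
#' AIC = -2 logLik + 2K, ties broken towards smaller K.
#'
#' @param series data.frame with `patient_id`, `time`, `y`.
#' @param grid,mu,phi,lambda,sigma2 fitted model components (maximal K).
#' @param candidates candidate K values.
#' @return selected K (integer).
#' @export
select_k <- function(series, grid, mu, phi, lambda, sigma2,
                     candidates = seq_len(length(lambda))) {
  if (length(candidates) == 0) stop("empty candidate set")
  candidates <- sort(unique(pmin(candidates, length(lambda))))
  s2 <- max(sigma2, 1e-6)
  sp <- split(series[, c("time", "y")], series$patient_id)
  aic <- vapply(candidates, function(K) {
    ll <- 0
    for (d in sp) {
      at <- model_at_times(grid, mu, phi[, seq_len(K), drop = FALSE], d$time)
      Lam <- diag(lambda[seq_len(K)], K)
      Sigma <- at$Phi %*% Lam %*% t(at$Phi) + diag(s2, nrow(d))
      R <- chol(Sigma)
      z <- backsolve(R, d$y - at$mu, transpose = TRUE)
      ll <- ll - 0.5 * (nrow(d) * log(2 * pi) + 2 * sum(log(diag(R))) +
                          sum(z^2))
    }
    -2 * ll + 2 * K
  }, numeric(1))
  candidates[which.min(aic)]
}

#' Fit sparse FPCA to one marker's log-scale series
#'
#' Runs the full PACE pipeline: GCV-bandwidth local-linear mean, smoothed
#' covariance surface with error-variance split, weighted
#' eigendecomposition, AIC choice of K, and BLUP scores for every patient.
#'
#' @param series data.frame with `patient_id`, `time` (months), `y`
#'   (log-scale value).
#' @param control an [fpca_control()].
#' @param marker optional marker name stored with the model.
#' @return object of class `fpca_model`: grid, quadrature weights, `mu`,
#'   `phi` (grid x K), `lambda`, `sigma2`, `K`, bandwidths, per-patient
#'   `scores` matrix and list of posterior covariances.
#' @export
fit_fpca <- function(series, control = fpca_control(), marker = NULL) {
  stopifnot(all(c("patient_id", "time", "y") %in% names(series)))
  grid <- seq(control$range[1], control$range[2],
              length.out = control$grid_len)
  w <- quadrature_weights(grid)
  mn <- estimate_mean(series, grid, control$bw_mean)
  cv <- estimate_covariance(series, mn$values, grid, control$bw_cov)
  ed <- eigendecompose(cv$surface, grid, w)
  above_floor <- ed$lambda >= control$fve_floor * sum(ed$lambda)
  n_comp <- min(max(1, sum(above_floor)), length(ed$lambda), control$K_max)
  if (length(ed$lambda) == 0) stop("no positive eigenvalues in covariance estimate")
  lambda_all <- ed$lambda[seq_len(n_comp)]
  phi_all <- ed$phi[, seq_len(n_comp), drop = FALSE]
  K <- if (identical(control$K, "auto")) {
    select_k(series, grid, mn$values, phi_all, lambda_all, cv$sigma2)
  } else {
    min(control$K, n_comp)
  }
  model <- structure(list(
    marker = marker, grid = grid, w = w, mu = mn$values,
    phi = phi_all[, seq_len(K), drop = FALSE], lambda = lambda_all[seq_len(K)],
    sigma2 = cv$sigma2, K = K,
    lambda_all = lambda_all, phi_all = phi_all,
    bw_mean = mn$bandwidth, bw_cov = cv$bandwidth, ridge = control$ridge
  ), class = "fpca_model")
  sc <- estimate_scores(model, series)
  model$scores <- sc$scores
  model$score_cov <- sc$cov
  model
}

#' Conditional-expectation (BLUP) FPC scores
#'
#' \eqn{\hat\xi_i = \Lambda \Phi_i' \Sigma_{Y_i}^{-1} (Y_i - \mu_i)} with
#' \eqn{\Sigma_{Y_i} = \Phi_i \Lambda \Phi_i' + \sigma^2 I} built from
#' eigenfunction values interpolated at the patient's own times; also
#' returns the posterior covariance
#' \eqn{\Lambda - \Lambda \Phi_i' \Sigma_{Y_i}^{-1} \Phi_i \Lambda}.
#'
#' @param model an `fpca_model`.
#' @param series data.frame with `patient_id`, `time`, `y` for one or more
#'   patients.
#' @return list: `scores` (patients x K, rownames = patient ids) and `cov`
#'   (named list of K x K posterior covariances).
#' @export
estimate_scores <- function(model, series) {
  stopifnot(inherits(model, "fpca_model"))
  if (nrow(series) == 0) stop("no observations")
  sp <- split(series[, c("time", "y")], series$patient_id)
  scores <- matrix(NA_real_, length(sp), model$K,
                   dimnames = list(names(sp), paste0("FPC", seq_len(model$K))))
  covs <- vector("list", length(sp))
  names(covs) <- names(sp)
  for (i in seq_along(sp)) {
    b <- blup_scores(sp[[i]]$time, sp[[i]]$y, model$grid, model$mu, model$phi,
                     model$lambda, model$sigma2, model$ridge)
    scores[i, ] <- b$scores
    covs[[i]] <- b$cov
  }
  list(scores = scores, cov = covs)
}

#' Reconstruct latent trajectories from scores
#'
#' Exact identity \eqn{\hat X_i = \mu + \sum_k \hat\xi_{ik} \phi_k} on the
#' model grid.
#'
#' @param model an `fpca_model`.
#' @param scores numeric vector (one patient) or matrix (patients x K).
#' @return list of class `trajectory_fit`: `grid` and `fitted`
#'   (patients x grid matrix).
#' @export
fit_trajectory <- function(model, scores) {
  stopifnot(inherits(model, "fpca_model"))
  if (is.vector(scores)) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) != model$K) stop("score dimension does not match model K")
  fitted <- matrix(model$mu, nrow(scores), length(model$grid), byrow = TRUE) +
    scores %*% t(model$phi)
  structure(list(grid = model$grid, fitted = fitted), class = "trajectory_fit")
}

#' Serialize / restore an FPCA model as JSON
#'
#' @param model an `fpca_model`.
#' @param path file path.
#' @return `path` invisibly; `fpca_from_json` returns the model (without
#'   training scores).
#' @export
fpca_to_json <- function(model, path) {
  jsonlite::write_json(
    list(marker = model$marker, grid = model$grid, mu = model$mu,
         phi = model$phi, lambda = model$lambda, sigma2 = model$sigma2,
         K = model$K, bw_mean = model$bw_mean, bw_cov = model$bw_cov,
         ridge = model$ridge),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname fpca_to_json
#' @export
fpca_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$phi <- matrix(unlist(x$phi), length(x$grid), x$K)
  x$w <- quadrature_weights(x$grid)
  x$lambda_all <- x$lambda
  x$phi_all <- x$phi
  structure(x, class = "fpca_model")
}

#' @export
print.fpca_model <- function(x, ...) {
  cat("Sparse FPCA model", if (!is.null(x$marker)) paste0("(", x$marker, ")"),
      "\n  K =", x$K, " eigenvalues:",
      paste(signif(x$lambda, 4), collapse = ", "),
      "\n  sigma2 =", signif(x$sigma2, 4),
      " bandwidths:", signif(x$bw_mean, 3), "/", signif(x$bw_cov, 3), "\n")
  invisible(x)
}
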