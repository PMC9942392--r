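# Local-linear kernel smoothing wrappers (Gaussian kernel, C++ backends)
# and generalized cross-validation bandwidth selection.

#' Trapezoidal quadrature weights for a strictly increasing grid
#'
#' Weights are positive and sum to the interval length, so that
#' `sum(w * f(grid))` approximates the integral of `f` over the grid range.
#'
#' @param grid strictly increasing numeric vector.
#' @return numeric vector of weights, same length as `grid`.
#' @export
quadrature_weights <- function(grid) {
  n <- length(grid)
  if (n < 2 || any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing with at least 2 points")
  }
  dg <- diff(grid)
  w <- numeric(n)
  w[1] <- dg[1] / 2
  w[n] <- dg[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dg[-1] + dg[-(n - 1)]) / 2
  w
}

# Evaluate a grid function at arbitrary points by linear interpolation,
# extending constantly beyond the grid ends.
eval_grid <- function(grid, values, t) {
  stats::approx(grid, values, xout = t, rule = 2)$y
}

ll_smooth_1d <- function(x, y, xout, h, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  lls1d_cpp(as.numeric(x), as.numeric(y), as.numeric(w), as.numeric(xout),
            as.numeric(h))
}

ll_smooth_2d <- function(x1, x2, y, g1, g2, h, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x1))
  lls2d_cpp(as.numeric(x1), as.numeric(x2), as.numeric(y), as.numeric(w),
            as.numeric(g1), as.numeric(g2), as.numeric(h))
}

# GCV score n * RSS / (n - trace(H))^2 for the 1-D local-linear smoother.
gcv_1d <- function(x, y, h, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  res <- lls1d_gcv_cpp(as.numeric(x), as.numeric(y), as.numeric(w),
                       as.numeric(h))
  ok <- is.finite(res$fitted)
  n <- sum(ok)
  rss <- sum((y[ok] - res$fitted[ok])^2)
  tr <- sum(res$hat[ok])
  if (n - tr <= 1) return(Inf)
  n * rss / (n - tr)^2
}

# Candidate bandwidths spanning the data range; geometric spacing.
bw_candidates <- function(x, n_cand = 8, lower_frac = 0.03, upper_frac = 0.3) {
  r <- diff(range(x))
  exp(seq(log(lower_frac * r), log(upper_frac * r), length.out = n_cand))
}

select_bw_1d <- function(x, y, w = NULL, n_cand = 8) {
  cand <- bw_candidates(x, n_cand)
  scores <- vapply(cand, function(h) gcv_1d(x, y, h, w), numeric(1))
  if (all(!is.finite(scores))) return(cand[length(cand)])
  cand[which.min(scores)]
}

# GCV for the 2-D smoother; the raw covariance cloud is subsampled to keep
# the pairwise cost bounded (the score is computed within the subsample).
select_bw_2d <- function(x1, x2, y, w = NULL, n_cand = 6, max_points = 3000) {
  n <- length(x1)
  if (is.null(w)) w <- rep(1, n)
  idx <- seq_len(n)
  if (n > max_points) idx <- sort(sample.int(n, max_points))
  r <- max(diff(range(x1)), diff(range(x2)))
  cand <- exp(seq(log(0.08 * r), log(0.35 * r), length.out = n_cand))
  scores <- vapply(cand, function(h) {
    res <- lls2d_gcv_cpp(as.numeric(x1[idx]), as.numeric(x2[idx]),
                         as.numeric(y[idx]), as.numeric(w[idx]), h)
    if (res$n - res$trace <= 1) return(Inf)
    res$n * res$rss / (res$n - res$trace)^2
  }, numeric(1))
  if (all(!is.finite(scores))) return(cand[length(cand)])
  cand[which.min(scores)]
}
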