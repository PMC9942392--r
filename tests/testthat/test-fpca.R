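# Sparse FPCA machinery: smoothers, eigenproblem, AIC, BLUP scores,
# reconstruction.

grid51 <- seq(-1, 12, length.out = 51)
w51 <- quadrature_weights(grid51)

test_that("quadrature weights are positive and sum to the interval length", {
  expect_true(all(w51 > 0))
  expect_equal(sum(w51), 13)
})

test_that("mean smoother reproduces constants and linear trends", {
  set.seed(4)
  tt <- runif(600, -1, 12)
  const <- data.frame(patient_id = 1, time = tt, y = rep(2.5, 600))
  m <- estimate_mean(const, grid51, bandwidth = 1)
  expect_equal(m$values, rep(2.5, 51), tolerance = 1e-8)
  lin <- data.frame(patient_id = 1, time = tt, y = 2 - 0.1 * tt)
  m <- estimate_mean(lin, grid51, bandwidth = "auto")
  expect_lt(max(abs(m$values - (2 - 0.1 * grid51))), 0.01)
  expect_error(estimate_mean(lin[0, ], grid51), "no observations")
  expect_error(estimate_mean(data.frame(patient_id = 1, time = rep(1, 5),
                                        y = rnorm(5)), grid51),
               "distinct observation times")
})

test_that("eigendecomposition recovers constructed spectra", {
  phi <- sin(seq(0, pi, length.out = 51))
  phi <- phi / sqrt(sum(w51 * phi^2))
  C1 <- 2 * outer(phi, phi)
  ed <- eigendecompose(C1, grid51)
  expect_equal(ed$lambda[1], 2, tolerance = 1e-8)
  expect_lt(min(sum(w51 * (ed$phi[, 1] - phi)^2),
                sum(w51 * (ed$phi[, 1] + phi)^2)), 1e-12)
  # two orthogonal components, ordered
  psi <- cos(seq(0, pi, length.out = 51))
  psi <- psi - sum(w51 * psi * phi) * phi
  psi <- psi / sqrt(sum(w51 * psi^2))
  C2 <- 3 * outer(phi, phi) + 1 * outer(psi, psi)
  ed2 <- eigendecompose(C2, grid51)
  expect_equal(ed2$lambda[1:2], c(3, 1), tolerance = 1e-8)
  expect_equal(sum(w51 * ed2$phi[, 1]^2), 1, tolerance = 1e-10)
  expect_true(all(diff(ed2$lambda) <= 1e-12))
})

test_that("covariance surface is symmetric, PSD, and near zero for noise", {
  set.seed(11)
  rows <- do.call(rbind, lapply(1:300, function(i) {
    tt <- sort(runif(4, -1, 12))
    data.frame(patient_id = i, time = tt, y = rnorm(4, 0, 0.5))
  }))
  mu <- estimate_mean(rows, grid51, bandwidth = 1.5)
  cv <- estimate_covariance(rows, mu$values, grid51, bandwidth = 2.5)
  expect_identical(cv$surface, t(cv$surface))
  ev <- eigen(cv$surface, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  off <- cv$surface[abs(outer(grid51, grid51, `-`)) > 2]
  expect_lt(mean(abs(off)), 0.05 * 0.25 + 0.01)
  expect_lt(abs(cv$sigma2 - 0.25), 0.25 * 0.25)
  expect_error(estimate_covariance(rows[!duplicated(rows$patient_id), ],
                                   mu$values, grid51, bandwidth = 2),
               ">= 2 observations")
})

test_that("error variance is recovered in a dense rank-1 design", {
  set.seed(12)
  phi_fun <- ref_phi1
  rows <- do.call(rbind, lapply(1:1000, function(i) {
    tt <- sort(runif(12, -1, 12))
    a <- rnorm(1)
    data.frame(patient_id = i, time = tt,
               y = a * phi_fun(tt) + rnorm(12, 0, 0.5))
  }))
  mu <- estimate_mean(rows, grid51, bandwidth = 1.5)
  cv <- estimate_covariance(rows, mu$values, grid51, bandwidth = 2)
  expect_lt(abs(cv$sigma2 - 0.25), 0.1 * 0.25)
})

test_that("sparse fit recovers the generating eigenstructure and scores", {
  sim <- sim_sparse_fpca(600, lambda = c(4, 1), sigma2 = 0.1, seed = 31)
  f <- fit_fpca(sim$series, fast_control())
  expect_equal(f$K, 2)
  expect_lt(abs(f$lambda[1] - 4) / 4, 0.2)
  expect_lt(abs(f$lambda[2] - 1) / 1, 0.25)
  # orthonormality under the quadrature rule
  G <- t(f$phi) %*% (f$w * f$phi)
  expect_equal(G, diag(2), tolerance = 1e-6)
  ip1 <- abs(sum(f$w * f$phi[, 1] * ref_phi1(f$grid)))
  ip2 <- abs(sum(f$w * f$phi[, 2] * ref_phi2(f$grid)))
  expect_gt(ip1, 0.95)
  expect_gt(ip2, 0.95)
  ord <- order(as.numeric(rownames(f$scores)))
  expect_gt(abs(cor(f$scores[ord, 1], sim$scores[, 1])), 0.9)
  expect_gt(abs(cor(f$scores[ord, 2], sim$scores[, 2])), 0.9)
})

test_that("BLUP scores behave at the boundary cases", {
  sim <- sim_sparse_fpca(400, seed = 7)
  f <- fit_fpca(sim$series, fast_control())
  # observations exactly on the mean -> zero scores
  tt <- c(1, 4, 8, 11)
  sc <- estimate_scores(f, data.frame(patient_id = 1, time = tt,
                                      y = eval_at <- approx(f$grid, f$mu,
                                                            tt)$y))
  expect_equal(as.vector(sc$scores), c(0, 0), tolerance = 1e-10)
  # dense noise-free rank-1 patient with a = 1.7
  tt <- f$grid
  y <- approx(f$grid, f$mu, tt)$y + 1.7 * f$phi[, 1]
  sc <- estimate_scores(f, data.frame(patient_id = 1, time = tt, y = y))
  expect_lt(abs(sc$scores[1, 1] - 1.7), 0.05)
  # single observation: BLUP shrinks relative to the naive projection
  t1 <- 6
  y1 <- approx(f$grid, f$mu, t1)$y + 0.8
  sc1 <- estimate_scores(f, data.frame(patient_id = 1, time = t1, y = y1))
  naive <- 0.8 / approx(f$grid, f$phi[, 1], t1)$y
  expect_lt(abs(sc1$scores[1, 1]), abs(naive))
})

test_that("posterior covariance shrinks as observations accumulate", {
  sim <- sim_sparse_fpca(400, seed = 7)
  f <- fit_fpca(sim$series, fast_control())
  tt <- c(0.5, 2, 4, 6, 8, 10, 11.5)
  y <- approx(f$grid, f$mu, tt)$y + 0.6
  traces <- sapply(2:length(tt), function(k) {
    sc <- estimate_scores(f, data.frame(patient_id = 1, time = tt[1:k],
                                        y = y[1:k]))
    sum(diag(sc$cov[[1]]))
  })
  expect_true(all(diff(traces) <= 1e-10))
})

test_that("trajectory reconstruction is exact and improves with K", {
  sim <- sim_sparse_fpca(400, seed = 7)
  f <- fit_fpca(sim$series, fast_control())
  tr0 <- fit_trajectory(f, c(0, 0))
  expect_equal(as.vector(tr0$fitted), f$mu)
  # nested reconstructions of one noise-free patient
  truth <- ref_mu(f$grid) + 1.2 * ref_phi1(f$grid) - 0.9 * ref_phi2(f$grid)
  ise <- sapply(1:2, function(K) {
    fk <- f; fk$phi <- f$phi[, 1:K, drop = FALSE]
    fk$lambda <- f$lambda[1:K]; fk$K <- K
    sc <- estimate_scores(fk, data.frame(patient_id = 1, time = f$grid,
                                         y = truth))
    sum(f$w * (fit_trajectory(fk, sc$scores[1, ])$fitted - truth)^2)
  })
  expect_lt(ise[2], ise[1])
  # round trip at sigma2 -> 0: scores of the reconstruction reproduce
  f0 <- f; f0$sigma2 <- 0
  sc <- estimate_scores(f0, data.frame(patient_id = 1, time = f$grid,
                                       y = truth))
  rec <- fit_trajectory(f0, sc$scores[1, ])
  sc2 <- estimate_scores(f0, data.frame(patient_id = 1, time = f$grid,
                                        y = as.vector(rec$fitted)))
  expect_equal(as.vector(sc2$scores), as.vector(sc$scores), tolerance = 1e-6)
  expect_error(fit_trajectory(f, c(1, 2, 3)), "dimension")
})

test_that("dense noise-free scores converge to numerical projections", {
  sim <- sim_sparse_fpca(400, seed = 7)
  f <- fit_fpca(sim$series, fast_control())
  f$sigma2 <- 1e-10
  # a curve in the fitted eigenspace: BLUP and quadrature projection agree
  truth <- f$mu + 0.7 * f$phi[, 1] + 1.1 * f$phi[, 2]
  sc <- estimate_scores(f, data.frame(patient_id = 1, time = f$grid,
                                      y = truth))
  proj <- as.vector(t(f$phi) %*% (f$w * (truth - f$mu)))
  expect_equal(proj, c(0.7, 1.1), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(as.vector(sc$scores), proj, tolerance = 1e-4)
  # for a curve outside the fitted span, both routes agree to the
  # discretization error of the grid
  outside <- ref_mu(f$grid) + 0.7 * ref_phi1(f$grid) + 1.1 * ref_phi2(f$grid)
  sc2 <- estimate_scores(f, data.frame(patient_id = 1, time = f$grid,
                                       y = outside))
  proj2 <- as.vector(t(f$phi) %*% (f$w * (outside - f$mu)))
  expect_lt(max(abs(as.vector(sc2$scores) - proj2)), 0.02)
})

test_that("AIC selection honours the candidate set and noise-only data", {
  sim <- sim_sparse_fpca(200, lambda = c(4, 1), sigma2 = 0.1, seed = 13)
  f <- fit_fpca(sim$series, fast_control())
  k3 <- select_k(sim$series, f$grid, f$mu, f$phi_all, f$lambda_all,
                 f$sigma2, candidates = 3)
  expect_equal(k3, min(3, length(f$lambda_all)))
  # noise-only data: smallest candidate wins
  set.seed(14)
  noise <- do.call(rbind, lapply(1:200, function(i) {
    tt <- sort(runif(5, -1, 12))
    data.frame(patient_id = i, time = tt, y = rnorm(5, 0, 0.5))
  }))
  fn <- fit_fpca(noise, fast_control())
  kn <- select_k(noise, fn$grid, fn$mu, fn$phi_all, fn$lambda_all,
                 fn$sigma2, candidates = seq_len(length(fn$lambda_all)))
  expect_equal(kn, 1)
})

test_that("models survive a JSON round trip", {
  sim <- sim_sparse_fpca(150, seed = 5)
  f <- fit_fpca(sim$series, fast_control())
  path <- tempfile(fileext = ".json")
  fpca_to_json(f, path)
  g <- fpca_from_json(path)
  expect_equal(g$lambda, f$lambda, tolerance = 1e-12)
  expect_equal(g$phi, f$phi, tolerance = 1e-12, ignore_attr = TRUE)
  sc_f <- estimate_scores(f, sim$series[sim$series$patient_id == 1, ])
  sc_g <- estimate_scores(g, sim$series[sim$series$patient_id == 1, ])
  expect_equal(sc_f$scores, sc_g$scores, tolerance = 1e-10)
  unlink(path)
})
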