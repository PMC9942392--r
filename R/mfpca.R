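# Multivariate FPCA by eigendecomposition of the stacked univariate-score
# covariance: cross-marker correlation is modeled through the correlations
# among the markers' FPC scores.

#' Fit multivariate FPCA on stacked univariate score matrices
#'
#' Per-patient univariate FPC score vectors of all markers are stacked into
#' one vector; the sample covariance of the stacked scores is
#' eigendecomposed. Joint components are linear combinations of the
#' univariate components, so each joint eigenfunction has one block per
#' marker, derived by applying the eigenvector coefficients to the
#' univariate eigenfunctions.
#'
#' @param scores_list named list (by marker) of score matrices with
#'   identical rownames (patient ids).
#' @param M number of joint components, or `"auto"` = smallest M explaining
#'   at least 99 percent of the stacked variance.
#' @param standardize scale each score column to unit variance before
#'   stacking (default off: raw score scales carry the eigenvalue
#'   information).
#' @param fpca_models optional named list of `fpca_model`s used to derive
#'   the joint eigenfunction blocks.
#' @param ridge_tol if the number of patients is at most the stacked
#'   dimension, a ridge of `ridge_tol * mean(diag)` is added with a warning.
#' @return object of class `mfpca_model`: block layout, eigenvectors
#'   (stacked dim x M), eigenvalues, training scores `rho`,
#'   and per-marker eigenfunction blocks `psi` (grid x M each).
#' @export
fit_mfpca <- function(scores_list, M = "auto", standardize = FALSE,
                      fpca_models = NULL, ridge_tol = 1e-6) {
  stopifnot(length(scores_list) >= 1)
  ids <- rownames(scores_list[[1]])
  for (s in scores_list) {
    if (!identical(rownames(s), ids)) {
      stop("patient sets (or their order) differ across markers")
    }
  }
  blocks <- list()
  off <- 0
  for (m in names(scores_list)) {
    k <- ncol(scores_list[[m]])
    blocks[[m]] <- off + seq_len(k)
    off <- off + k
  }
  X <- do.call(cbind, scores_list)
  colnames(X) <- unlist(lapply(names(scores_list), function(m) {
    paste(m, seq_along(blocks[[m]]), sep = ".")
  }))
  scale_sd <- rep(1, ncol(X))
  if (standardize) {
    scale_sd <- apply(X, 2, stats::sd)
    scale_sd[scale_sd == 0] <- 1
    X <- sweep(X, 2, scale_sd, `/`)
  }
  S <- stats::cov(X)
  if (nrow(X) <= ncol(X)) {
    warning("fewer patients than stacked dimension; ridge-regularizing")
    S <- S + diag(ridge_tol * mean(diag(S)), ncol(S))
  }
  ed <- eigen((S + t(S)) / 2, symmetric = TRUE)
  values <- pmax(ed$values, 0)
  if (identical(M, "auto")) {
    pev <- cumsum(values) / sum(values)
    M <- min(which(pev >= 0.99))
  }
  M <- min(M, ncol(X))
  vectors <- ed$vectors[, seq_len(M), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (m in seq_len(M)) {
    j <- which.max(abs(vectors[, m]))
    if (vectors[j, m] < 0) vectors[, m] <- -vectors[, m]
  }
  rownames(vectors) <- colnames(X)
  rho <- X %*% vectors
  colnames(rho) <- paste0("MFPC", seq_len(M))
  psi <- NULL
  if (!is.null(fpca_models)) {
    psi <- lapply(names(blocks), function(m) {
      fpca_models[[m]]$phi %*% vectors[blocks[[m]], , drop = FALSE]
    })
    names(psi) <- names(blocks)
  }
  structure(list(blocks = blocks, scale_sd = scale_sd,
                 standardize = standardize, vectors = vectors,
                 values = values[seq_len(M)], values_all = values, M = M,
                 rho = rho, psi = psi),
            class = "mfpca_model")
}

#' Project univariate scores onto the joint components
#'
#' Deterministic linear map: stack (applying the training scaling if the
#' model standardized) and take inner products with the joint eigenvectors.
#' The map is not centered, so zero univariate scores give zero joint
#' scores; the covariance eigenstructure is unaffected by the mean.
#'
#' @param model an `mfpca_model`.
#' @param scores_list named list of univariate score matrices with the
#'   model's block layout.
#' @return matrix of multivariate scores (patients x M).
#' @export
mfpca_transform <- function(model, scores_list) {
  stopifnot(inherits(model, "mfpca_model"))
  if (!identical(names(scores_list), names(model$blocks))) {
    stop("marker layout does not match the fitted model")
  }
  for (m in names(model$blocks)) {
    if (ncol(scores_list[[m]]) != length(model$blocks[[m]])) {
      stop("score dimension mismatch for marker ", m)
    }
  }
  X <- do.call(cbind, scores_list)
  if (model$standardize) X <- sweep(X, 2, model$scale_sd, `/`)
  rho <- X %*% model$vectors
  colnames(rho) <- paste0("MFPC", seq_len(model$M))
  rownames(rho) <- rownames(scores_list[[1]])
  rho
}

#' Serialize / restore an MFPCA model as JSON
#'
#' @param model an `mfpca_model`.
#' @param path file path.
#' @return `path` invisibly; `mfpca_from_json` returns the model (without
#'   training scores and eigenfunction blocks).
#' @export
mfpca_to_json <- function(model, path) {
  jsonlite::write_json(
    list(blocks = model$blocks, scale_sd = model$scale_sd,
         standardize = model$standardize, vectors = model$vectors,
         values = model$values, M = model$M),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname mfpca_to_json
#' @export
mfpca_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(x$scale_sd)
  x$vectors <- matrix(unlist(x$vectors), p, x$M)
  labels <- unlist(lapply(names(x$blocks), function(m) {
    paste(m, seq_along(x$blocks[[m]]), sep = ".")
  }))
  rownames(x$vectors) <- labels
  structure(x, class = "mfpca_model")
}

#' @export
print.mfpca_model <- function(x, ...) {
  cat("MFPCA model: M =", x$M, "joint components over",
      length(x$scale_sd), "stacked univariate scores\n  eigenvalues:",
      paste(signif(x$values, 4), collapse = ", "), "\n")
  invisible(x)
}
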