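#' Decompose muscle excitations into synergies
#'
#' Factorizes an excitation matrix `E` (frames x muscles) into `p` synergy
#' excitations `W` (frames x p) and weights `H` (p x muscles):
#' \itemize{
#'   \item PCA: `E = W H + 1 mu' + residual`, where `mu` holds the channel
#'     means, `W` the first `p` principal-component scores and `H` the
#'     corresponding loadings.  Deterministic; each component's sign is fixed
#'     so its largest-magnitude loading is positive.
#'   \item NMF: `E = W H + residual` with `W, H >= 0`, fitted by alternating
#'     least squares from several seeded random initializations; the
#'     replicate with the smallest Frobenius reconstruction error wins.
#' }
#' Decomposition is intended per trial, on the padded gait-cycle matrix.
#'
#' @param E Numeric matrix, frames x muscles; non-negative for NMF.
#' @param p Number of synergies, `1 <= p <= min(dim(E))`.
#' @param algorithm `"pca"` or `"nmf"`.
#' @param replicates Number of NMF restarts (default 10).
#' @param seed Integer seed for the NMF initializations.
#' @param max_iter,tol NMF stopping rule: stop when the relative objective
#'   change drops below `tol` or after `max_iter` iterations.
#' @return Object of class `"synergy_model"`: `W`, `H`, `mu` (PCA only,
#'   otherwise `NULL`), `algorithm`, `p`, `vaf` (percent, uncentered pooled),
#'   `residual`, `channel_names`, and for NMF `replicate_errors`.
#' @export
synergy_decompose <- function(E, p, algorithm = c("pca", "nmf"),
                              replicates = 10, seed = NULL,
                              max_iter = 1000, tol = 1e-6) {
  algorithm <- match.arg(algorithm)
  E <- as.matrix(E)
  if (!all(is.finite(E))) stopf("E must be finite")
  if (!is_number(p) || p < 1 || p > min(dim(E)) || p != round(p))
    stopf("p must be an integer in [1, %d]", min(dim(E)))
  p <- as.integer(p)
  fit <- if (algorithm == "pca") decompose_pca_impl(E, p)
         else decompose_nmf_impl(E, p, replicates, seed, max_iter, tol)
  E_hat <- reconstruct_synergies(fit$W, fit$H, fit$mu)
  structure(
    c(fit, list(algorithm = algorithm, p = p, residual = E - E_hat,
                vaf = compute_vaf(E, E_hat),
                channel_names = colnames(E))),
    class = "synergy_model")
}

reconstruct_synergies <- function(W, H, mu = NULL) {
  E_hat <- W %*% H
  if (!is.null(mu)) E_hat <- sweep(E_hat, 2, mu, "+")
  E_hat
}

decompose_pca_impl <- function(E, p) {
  mu <- colMeans(E)
  pc <- stats::prcomp(E, center = TRUE, scale. = FALSE)
  W <- pc$x[, seq_len(p), drop = FALSE]
  H <- t(pc$rotation[, seq_len(p), drop = FALSE])
  # sign convention: largest-|loading| entry of each component positive
  for (k in seq_len(p)) {
    s <- sign(H[k, which.max(abs(H[k, ]))])
    if (s < 0) { H[k, ] <- -H[k, ]; W[, k] <- -W[, k] }
  }
  dimnames(W) <- list(NULL, paste0("syn", seq_len(p)))
  dimnames(H) <- list(paste0("syn", seq_len(p)), colnames(E))
  list(W = W, H = H, mu = mu)
}

# MATLAB-nnmf-style alternating least squares with nonnegativity by clamping.
decompose_nmf_impl <- function(E, p, replicates, seed, max_iter, tol) {
  if (any(E < 0))
    stopf("NMF requires a non-negative matrix; normalize or clamp excitations first")
  n <- nrow(E); m <- ncol(E)
  best <- NULL
  errs <- numeric(replicates)
  # minimal-norm least-squares via SVD: robust when factors lose rank
  # (routine for p at or above the effective rank of E)
  pinv_solve <- function(G, B) {
    s <- svd(G)
    keep <- s$d > max(s$d[1], 1e-300) * 1e-12
    s$v[, keep, drop = FALSE] %*%
      ((t(s$u[, keep, drop = FALSE]) %*% B) / s$d[keep])
  }
  with_seed(seed, {
    for (rep in seq_len(replicates)) {
      for (attempt in 1:5) { # restart a replicate whose factor zero-locks
        W <- matrix(stats::runif(n * p), n, p)
        H <- matrix(0, p, m)
        err_prev <- Inf; err <- Inf
        collapsed <- FALSE
        for (it in seq_len(max_iter)) {
          H <- pmax(pinv_solve(crossprod(W), crossprod(W, E)), 0)
          W <- pmax(t(pinv_solve(tcrossprod(H), tcrossprod(H, E))), 0)
          if (any(colSums(W) == 0) || any(rowSums(H) == 0)) {
            collapsed <- TRUE; break
          }
          err <- norm(E - W %*% H, "F")
          if (is.finite(err_prev) &&
              abs(err_prev - err) <= tol * max(err_prev, 1e-300)) break
          err_prev <- err
        }
        if (!collapsed) break
      }
      errs[rep] <- if (collapsed) Inf else err
      if (!collapsed && (is.null(best) || err < best$err))
        best <- list(W = W, H = H, err = err)
    }
  })
  if (is.null(best)) stopf("all NMF replicates collapsed to zero factors")
  dimnames(best$W) <- list(NULL, paste0("syn", seq_len(p)))
  dimnames(best$H) <- list(paste0("syn", seq_len(p)), colnames(E))
  list(W = best$W, H = best$H, mu = NULL, replicate_errors = errs)
}

#' Variance accounted for by a reconstruction
#'
#' Pooled, uncentered VAF in percent:
#' `100 * (1 - ||E - E_hat||_F^2 / ||E||_F^2)`.  Can be negative for fits
#' worse than predicting zero.
#'
#' @param E Original matrix (or vector).
#' @param E_hat Reconstruction of the same shape.
#' @return VAF in percent.
#' @export
compute_vaf <- function(E, E_hat) {
  E <- as.matrix(E); E_hat <- as.matrix(E_hat)
  if (!identical(dim(E), dim(E_hat))) stopf("E and E_hat must have the same shape")
  if (!all(is.finite(E)) || !all(is.finite(E_hat))) stopf("inputs must be finite")
  ss <- sum(E^2)
  if (ss == 0) stopf("VAF undefined: ||E|| = 0")
  100 * (1 - sum((E - E_hat)^2) / ss)
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("Synergy model: %s, p = %d, %d frames x %d muscles, VAF = %.2f%%\n",
              toupper(x$algorithm), x$p, nrow(x$W), ncol(x$H), x$vaf))
  invisible(x)
}
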