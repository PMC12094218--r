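#' Frisch-Waugh-Lovell reparameterization of the cosinor design
#'
#' Replaces the rhythmic regressors `X2` by their residuals after projecting
#' out the nuisance block `X1`:
#' `Z2 = (I - X1 (X1'X1)^{-1} X1') X2`.
#' The reparameterized design `[X1 Z2]` spans the same column space as
#' `[X1 X2]` but has orthogonal blocks (`X1'Z2 = 0`), so the Gram matrix `D`
#' is block-diagonal and the reduction in sum of squares between the nested
#' models becomes the clean quadratic form `beta2' Z2'Z2 beta2`. For the
#' standard cosinor model (`X1` = intercept) this is simply column-centering
#' of the cosine and sine regressors.
#'
#' Projections are computed from a QR factorization of `X1`, not from the
#' explicit inverse, for numerical stability with trend/block nuisances.
#'
#' @param X1 numeric n x q nuisance matrix of full column rank.
#' @param X2 numeric n x 2 matrix of rhythmic regressors (any n x k matrix
#'   is accepted; the cosinor case has k = 2).
#' @return Object of class `cosinor_reparam`: `Z2`, the p x p transition
#'   matrix `U` (so that `[X1 X2] \%*\% U = [X1 Z2]`), the projection
#'   coefficients `P = (X1'X1)^{-1} X1'X2` relating `lambda = beta1 + P beta2`,
#'   and the block-diagonal Gram matrix `D = [X1 Z2]'[X1 Z2]`.
#' @examples
#' d <- uniform_grid_design(5, 7, 24)
#' m <- cosinor_matrices(d)
#' rp <- orthogonalize(m$X1, m$X2)
#' colMeans(rp$Z2)  # ~ 0: centered rhythmic residuals
#' @export
orthogonalize <- function(X1, X2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (nrow(X1) != nrow(X2)) {
    stop("X1 and X2 must have the same number of rows", call. = FALSE)
  }
  q <- ncol(X1); k <- ncol(X2)
  qr1 <- qr(X1, tol = 1e-12)
  if (qr1$rank < q) {
    stop(sprintf("nuisance matrix X1 is rank deficient (rank %d < %d columns)",
                 qr1$rank, q), call. = FALSE)
  }
  P <- qr.coef(qr1, X2)            # (X1'X1)^{-1} X1'X2, via QR
  Z2 <- qr.resid(qr1, X2)
  U <- rbind(cbind(diag(q), -P), cbind(matrix(0, k, q), diag(k)))
  W <- cbind(X1, Z2)
  structure(list(Z2 = Z2, U = U, P = P, D = crossprod(W)),
            class = "cosinor_reparam")
}

#' @export
print.cosinor_reparam <- function(x, ...) {
  ortho <- max(abs(x$D[seq_len(nrow(x$P)), nrow(x$P) + seq_len(ncol(x$Z2)),
                       drop = FALSE]))
  cat(sprintf(
    "FWL reparameterization: q = %d nuisance, k = %d rhythmic columns; max |X1'Z2| = %.3g\n",
    nrow(x$P), ncol(x$Z2), ortho))
  invisible(x)
}

#' General noncentrality parameter for arbitrary nuisance structure
#'
#' Under the alternative, the scaled reduction in sum of squares
#' `beta2_hat' Z2'Z2 beta2_hat / sigma^2` follows a noncentral chi-squared
#' distribution with `p - q` degrees of freedom and noncentrality
#' `delta2 = beta2' Z2'Z2 beta2 / sigma^2`. This is the quantity that drives
#' the power of the rhythm-detection F test for any nuisance matrix `X1`;
#' with `X1` = intercept it collapses to the standard closed form
#' `n * A^2 / sigma^2 * sigma2_cosinor` (see [ncp_standard()]).
#'
#' @param X1 nuisance matrix (full column rank).
#' @param X2 rhythmic regressor matrix.
#' @param beta2 true rhythmic coefficients, e.g. `c(a1, a2)`.
#' @param sigma residual standard deviation, `> 0`.
#' @return The noncentrality parameter `delta2 >= 0` (dimensionless).
#' @export
general_ncp <- function(X1, X2, beta2, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("'sigma' must be > 0", call. = FALSE)
  }
  rp <- orthogonalize(X1, X2)
  beta2 <- as.numeric(beta2)
  if (length(beta2) != ncol(rp$Z2)) {
    stop("length(beta2) must equal ncol(X2)", call. = FALSE)
  }
  drop(crossprod(rp$Z2 %*% beta2)) / sigma^2
}

#' Reduction in sum of squares, two ways
#'
#' Computes the reduction in error sum of squares between the null model
#' (`X1` only) and the full model (`[X1 X2]`) both directly, by fitting the
#' two nested least-squares models, and as the quadratic form
#' `beta2_hat' Z2'Z2 beta2_hat` in the orthogonalized rhythmic block. The
#' two agree for every full-rank design; the naive uncentered form
#' `beta2_hat' X2'X2 beta2_hat` agrees only when `X1'X2 = 0` (for the
#' standard cosinor: only when the design is centered).
#'
#' @param y response vector.
#' @param X1 nuisance matrix.
#' @param X2 rhythmic regressor matrix.
#' @return List with `delta_ss` (direct `SSE_null - SSE_full`),
#'   `quadratic_form` (`beta2_hat' Z2'Z2 beta2_hat`), and
#'   `uncentered_form` (`beta2_hat' X2'X2 beta2_hat`, the fallacious
#'   expression, for comparison).
#' @export
ss_reduction <- function(y, X1, X2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  y <- as.numeric(y)
  X <- cbind(X1, X2)
  qr_full <- .ls_qr(X, "full design matrix [X1 X2]")
  qr_null <- .ls_qr(X1, "null design matrix X1")
  sse_full <- sum(qr.resid(qr_full, y)^2)
  sse_null <- sum(qr.resid(qr_null, y)^2)
  beta <- qr.coef(qr_full, y)
  beta2 <- beta[ncol(X1) + seq_len(ncol(X2))]
  rp <- orthogonalize(X1, X2)
  list(delta_ss = sse_null - sse_full,
       quadratic_form = drop(crossprod(rp$Z2 %*% beta2)),
       uncentered_form = drop(crossprod(X2 %*% beta2)))
}
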