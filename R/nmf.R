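## Nonnegative coding and dictionary updates for online NMF over patch
## minibatches. Both solvers are exact block coordinate descent: coding
## minimizes ||x - W h||_2^2 + lambda ||h||_1 over h >= 0 column by column
## (vectorized over all columns of the minibatch), and the dictionary update
## minimizes the quadratic surrogate tr(W' W P) - 2 tr(W' Q) column by
## column with entrywise projection onto [0, 1].

#' Nonnegative coding of patch columns against a dictionary
#'
#' For each column \eqn{x_j} of \code{X}, finds \eqn{h_j \ge 0} minimizing
#' \eqn{\|x_j - W h_j\|_2^2 + \lambda \|h_j\|_1} by cyclic coordinate
#' descent, run to a fixed tolerance.
#'
#' @param X k^2 x n matrix of vectorized patches (entries in [0, 1]).
#' @param W k^2 x r nonnegative dictionary matrix (or an \code{ndl} fit,
#'   whose coefficient matrix is used).
#' @param lambda Nonnegative L1 penalty on the codes (default 0).
#' @param rows Optional integer vector of vector positions to include in the
#'   least-squares objective (e.g. to ignore diagonal or on-chain entries);
#'   default all rows.
#' @param tol Convergence tolerance on the largest coordinate change.
#' @param max_iter Maximum number of full coordinate passes.
#' @return r x n nonnegative coefficient matrix H.
#' @export
code_patches <- function(X, W, lambda = 0, rows = NULL, tol = 1e-8,
                         max_iter = 1000) {
  if (inherits(W, "ndl")) W <- W$W
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (nrow(X) != nrow(W)) stop("row dimension of X and W must agree")
  if (lambda < 0) stop("`lambda` must be nonnegative")
  if (!is.null(rows)) {
    W_ <- W[rows, , drop = FALSE]
    X_ <- X[rows, , drop = FALSE]
  } else {
    W_ <- W; X_ <- X
  }
  r <- ncol(W_)
  n <- ncol(X_)
  G <- crossprod(W_)            # r x r
  Fm <- crossprod(W_, X_)       # r x n
  H <- matrix(0, r, n)
  diagG <- diag(G)
  active <- diagG > 1e-12
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(r)) {
      if (!active[j]) next
      gj <- G[j, , drop = FALSE] %*% H    # 1 x n
      hj <- pmax(0, H[j, ] + (Fm[j, ] - gj[1, ] - lambda / 2) / diagG[j])
      delta <- max(delta, max(abs(hj - H[j, ]), 0))
      H[j, ] <- hj
    }
    if (delta < tol) break
  }
  H
}

#' Dictionary update from aggregate statistics
#'
#' One or more passes of block coordinate descent on the columns of W for the
#' surrogate objective \eqn{tr(W^T W P) - 2 tr(W^T Q)}, with each updated
#' column projected entrywise onto [0, 1]. Columns whose aggregate code mass
#' \eqn{P_{jj}} is (numerically) zero were unused and are left untouched.
#'
#' @param W k^2 x r dictionary matrix.
#' @param P r x r symmetric positive semidefinite code aggregate.
#' @param Q k^2 x r data-code cross aggregate.
#' @param n_passes Number of full column sweeps (default 2).
#' @return Updated k^2 x r matrix with entries in [0, 1].
#' @export
update_dictionary <- function(W, P, Q, n_passes = 2) {
  r <- ncol(W)
  stopifnot(nrow(P) == r, ncol(P) == r, ncol(Q) == r, nrow(Q) == nrow(W))
  dP <- diag(P)
  skipped <- which(dP <= 1e-12)
  if (length(skipped) > 0 && any(dP > 1e-12))
    warning("dictionary update skipped ", length(skipped),
            " unused motif column(s)")
  for (pass in seq_len(n_passes)) {
    for (j in seq_len(r)) {
      if (dP[j] <= 1e-12) next
      wj <- W[, j] - (W %*% P[, j] - Q[, j]) / dP[j]
      W[, j] <- pmin(1, pmax(0, wj))
    }
  }
  W
}

## Surrogate objective value, used in tests for the monotonicity invariant.
surrogate_objective <- function(W, P, Q) {
  sum(crossprod(W) * P) - 2 * sum(W * Q)
}
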