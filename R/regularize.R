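# Shared regularization machinery: finite-difference penalty operators,
# a Lawson-Hanson non-negative least-squares solver, and L-curve corner
# selection. Used by the indirect Fourier transform (unconstrained ridge)
# and the inverse-Laplace correlogram inversion (non-negative ridge).

#' Finite-difference penalty operator
#'
#' @param n Number of coefficients.
#' @param order 1 for first differences, 2 for second differences.
#' @return A `(n - order) x n` matrix.
#' @keywords internal
diff_operator <- function(n, order = 1) {
  stopifnot(n > order)
  D <- diag(n)
  for (k in seq_len(order)) D <- diff(D)
  D
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves min ||A x - b||^2 subject to x >= 0.
#'
#' @param A Design matrix.
#' @param b Response vector.
#' @param tol Dual-feasibility tolerance relative to max gradient.
#' @param max_iter Iteration cap.
#' @return List with `x`, `residual_norm` and `iterations`.
#' @keywords internal
nnls_solve <- function(A, b, tol = 1e-10, max_iter = 10 * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))           # gradient of -0.5||Ax-b||^2 at x = 0
  scale <- max(abs(w), 1)
  iter <- 0L
  while (any(!passive & w > tol * scale) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      idx <- which(passive)
      z <- numeric(n)
      fit <- qr(A[, idx, drop = FALSE])
      z[idx] <- qr.coef(fit, b)
      z[idx][is.na(z[idx])] <- 0
      if (all(z[idx] > 0)) { x <- z; break }
      neg <- idx[z[idx] <= 0]
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[x <= .Machine$double.eps & passive] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, residual_norm = sqrt(sum((b - A %*% x)^2)), iterations = iter)
}

#' L-curve corner by maximum curvature
#'
#' Given per-regularizer residual norms rho and penalty norms eta (for an
#' increasing ladder of regularization strengths), locates the corner of the
#' (log rho, log eta) curve as the point of maximum (signed) curvature.
#' Degenerate curves (non-finite logs, fewer than 5 points, or no point of
#' positive curvature) return `NA` and the caller applies its fallback rule.
#'
#' @param rho Residual norms.
#' @param eta Penalty norms.
#' @return Index of the corner, or `NA_integer_`.
#' @keywords internal
lcurve_corner <- function(rho, eta) {
  x <- log(rho); y <- log(eta)
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 5) return(NA_integer_)
  idx <- which(ok)
  x <- x[ok]; y <- y[ok]
  m <- length(x)
  # centered-difference curvature along the parametric ladder
  dx <- (x[3:m] - x[1:(m - 2)]) / 2
  dy <- (y[3:m] - y[1:(m - 2)]) / 2
  ddx <- x[3:m] - 2 * x[2:(m - 1)] + x[1:(m - 2)]
  ddy <- y[3:m] - 2 * y[2:(m - 1)] + y[1:(m - 2)]
  denom <- (dx^2 + dy^2)^1.5
  kappa <- ifelse(denom > 0, (dx * ddy - dy * ddx) / denom, -Inf)
  if (!any(is.finite(kappa)) || max(kappa, na.rm = TRUE) <= 0) {
    return(NA_integer_)
  }
  idx[which.max(kappa) + 1L]
}

#' Default regularization ladder
#' @param from,to Decade range.
#' @param n Number of steps.
#' @keywords internal
alpha_ladder <- function(from = 1e-4, to = 1e4, n = 25) {
  exp(seq(log(from), log(to), length.out = n))
}
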