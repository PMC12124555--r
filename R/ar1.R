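# AR(1) time-correlation model: closed forms for the correlation matrix,
# its tridiagonal inverse, and the MAP estimate of theta via a cubic.

#' AR(1) correlation matrix
#'
#' Toeplitz matrix with entries \eqn{\theta^{|s-t|}}; unit diagonal,
#' determinant \eqn{(1-\theta^2)^{T'-1}}.
#'
#' @param theta AR(1) coefficient in (-1, 1).
#' @param tPrime dimension (number of observed times, >= 1).
#' @return T' x T' correlation matrix.
#' @export
sigmaT <- function(theta, tPrime) {
  if (abs(theta) >= 1) stop("theta must lie in (-1, 1)")
  idx <- seq_len(tPrime)
  theta^abs(outer(idx, idx, `-`))
}

#' Band matrices of the AR(1) inverse
#'
#' \code{b1} has ones on the first sub/super-diagonals (zero elsewhere);
#' \code{b2} is the identity with the first and last diagonal entries
#' zeroed.
#'
#' @param tPrime dimension.
#' @return list with matrices \code{b1} and \code{b2}.
#' @export
ar1Bands <- function(tPrime) {
  B1 <- matrix(0, tPrime, tPrime)
  if (tPrime >= 2) {
    i <- seq_len(tPrime - 1)
    B1[cbind(i, i + 1)] <- 1
    B1[cbind(i + 1, i)] <- 1
  }
  B2 <- diag(1, tPrime)
  B2[1, 1] <- 0
  B2[tPrime, tPrime] <- 0
  list(b1 = B1, b2 = B2)
}

#' Tridiagonal inverse of the AR(1) correlation matrix
#'
#' \eqn{\Sigma_T^{-1}(\theta) = (I - \theta B_1 + \theta^2 B_2) /
#' (1 - \theta^2)}.
#'
#' @inheritParams sigmaT
#' @return T' x T' tridiagonal matrix.
#' @export
sigmaTInv <- function(theta, tPrime) {
  if (abs(theta) >= 1) stop("theta must lie in (-1, 1)")
  B <- ar1Bands(tPrime)
  (diag(1, tPrime) - theta * B$b1 + theta^2 * B$b2) / (1 - theta^2)
}

# Right-multiply a matrix by sigmaTInv(theta, ncol(E)) in O(N'T') using
# the band structure.
.mulSigmaTInv <- function(E, theta) {
  Tn <- ncol(E)
  if (Tn == 1) return(E / 1)  # T' = 1: sigmaT = 1
  EB1 <- matrix(0, nrow(E), Tn)
  EB1[, 1] <- E[, 2]
  EB1[, Tn] <- E[, Tn - 1]
  if (Tn > 2)
    EB1[, 2:(Tn - 1)] <- E[, 1:(Tn - 2), drop = FALSE] +
      E[, 3:Tn, drop = FALSE]
  EB2 <- E
  EB2[, 1] <- 0
  EB2[, Tn] <- 0
  (E - theta * EB1 + theta^2 * EB2) / (1 - theta^2)
}

# Quadratic-form traces of Eq-style residual statistics:
# a = tr(E' SigmaN^-1 E), b = tr(E' SigmaN^-1 E B1), c = tr(E' SigmaN^-1 E B2)
.ar1Stats <- function(E, sigmaNInv) {
  G <- sigmaNInv %*% E
  Tn <- ncol(E)
  a <- sum(G * E)
  b <- if (Tn >= 2)
    2 * sum(E[, 1:(Tn - 1), drop = FALSE] * G[, 2:Tn, drop = FALSE]) else 0
  cc <- if (Tn > 2)
    sum(E[, 2:(Tn - 1), drop = FALSE] * G[, 2:(Tn - 1), drop = FALSE]) else 0
  list(a = a, b = b, c = cc)
}

#' Negative log-posterior profile for theta
#'
#' \deqn{N'(T'-1)\ln(1-\theta^2) + tr(E^\top \Sigma_N^{-1} E
#'   \Sigma_T^{-1}(\theta)) + N'T'\alpha/(1-\theta^2)}
#' up to terms constant in \eqn{\theta}. The trace is evaluated through the
#' tridiagonal band expansion, so the cost is O(N'T').
#'
#' @param theta value in (-1, 1) (vectorized).
#' @param E N' x T' residual matrix.
#' @param sigmaN N' x N' SPD node covariance.
#' @param alpha non-negative stationarity-prior strength.
#' @return cost value(s).
#' @export
thetaCost <- function(theta, E, sigmaN, alpha) {
  if (any(abs(theta) >= 1)) stop("theta must lie in (-1, 1)")
  st <- .ar1Stats(E, solve(sigmaN))
  np <- nrow(E); tp <- ncol(E)
  np * (tp - 1) * log(1 - theta^2) +
    (st$a - theta * st$b + theta^2 * st$c) / (1 - theta^2) +
    np * tp * alpha / (1 - theta^2)
}

#' MAP estimate of the AR(1) coefficient
#'
#' The stationary point of [thetaCost()] is the real root in (-1, 1) of the
#' cubic
#' \deqn{b/2 + (N'(T'-1) - a - c - N'T'\alpha)\theta + (b/2)\theta^2 -
#'   N'(T'-1)\theta^3}
#' with \eqn{a = tr(E^\top\Sigma_N^{-1}E)}, \eqn{b =
#' tr(E^\top\Sigma_N^{-1}E B_1)}, \eqn{c = tr(E^\top\Sigma_N^{-1}E B_2)}.
#' The cubic is solved with \code{polyroot}; if several real roots lie in
#' (-1, 1) the one minimizing [thetaCost()] is returned, and if none does
#' (degenerate inputs) the estimate falls back to a 1e-4-spaced grid search
#' with a warning.
#'
#' @param E N' x T' residual matrix.
#' @param sigmaN N' x N' SPD node covariance.
#' @param alpha non-negative stationarity-prior strength.
#' @return theta estimate in (-1, 1).
#' @export
thetaMap <- function(E, sigmaN, alpha) {
  np <- nrow(E); tp <- ncol(E)
  if (tp < 2) stop("at least two time points are required")
  sigmaNInv <- solve(sigmaN)
  st <- .ar1Stats(E, sigmaNInv)
  co <- c(st$b / 2,
          np * (tp - 1) - st$a - st$c - np * tp * alpha,
          st$b / 2,
          -np * (tp - 1))
  r <- polyroot(co)
  real <- Re(r)[abs(Im(r)) < 1e-8 * (1 + Mod(r))]
  feasible <- real[abs(real) < 1 - 1e-12]
  costAt <- function(th) {
    np * (tp - 1) * log(1 - th^2) +
      (st$a - th * st$b + th^2 * st$c) / (1 - th^2) +
      np * tp * alpha / (1 - th^2)
  }
  if (length(feasible) == 0) {
    warning("no real cubic root in (-1, 1); falling back to grid search")
    grid <- seq(-0.9999, 0.9999, by = 1e-4)
    return(grid[which.min(costAt(grid))])
  }
  feasible[which.min(costAt(feasible))]
}
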