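# Node-covariance estimation: autocorrelation-adjusted ML estimate,
# Rao-Blackwell Ledoit-Wolf shrinkage, and the alternating flip-flop.

#' Create a matrix-normal noise model
#'
#' @param theta AR(1) coefficient in (-1, 1).
#' @param sigmaN N' x N' SPD node covariance.
#' @param tPrime number of observed times.
#' @param alpha stationarity-prior strength (>= 0).
#' @return a [NoiseModel-class].
#' @export
noiseModel <- function(theta, sigmaN, tPrime, alpha = 0.1) {
  new("NoiseModel", theta = as.numeric(theta), alpha = as.numeric(alpha),
      sigmaN = as.matrix(sigmaN), tPrime = as.integer(tPrime))
}

#' Identity noise model
#'
#' The i.i.d. unit-variance special case under which GLS-KGR reduces to
#' plain KGR.
#'
#' @param nPrime,tPrime observed dimensions.
#' @param alpha stationarity-prior strength.
#' @return a [NoiseModel-class] with theta = 0 and sigmaN = I.
#' @export
identityNoiseModel <- function(nPrime, tPrime, alpha = 0.1) {
  noiseModel(0, diag(1, nPrime), tPrime, alpha)
}

#' Autocorrelation-adjusted maximum-likelihood node covariance
#'
#' \eqn{\Sigma_{ML} = E \Sigma_T^{-1}(\theta) E^\top / T'}: the sample node
#' covariance of the residuals after whitening the AR(1) time correlation
#' (reducing to \eqn{E E^\top / T'} at \eqn{\theta = 0}). Symmetric PSD.
#'
#' @param E N' x T' residual matrix.
#' @param theta AR(1) coefficient in (-1, 1).
#' @return N' x N' matrix.
#' @export
sigmaMl <- function(E, theta) {
  if (abs(theta) >= 1) stop("theta must lie in (-1, 1)")
  M <- .mulSigmaTInv(E, theta) %*% t(E) / ncol(E)
  (M + t(M)) / 2
}

#' Rao-Blackwell Ledoit-Wolf shrinkage coefficient
#'
#' \deqn{\hat\rho = \min\left[\frac{\frac{T'-2}{T'} tr(\Sigma_{ML}^2) +
#'   tr^2(\Sigma_{ML})}{(T'+2)\left(tr(\Sigma_{ML}^2) -
#'   tr^2(\Sigma_{ML})/N'\right)}, 1\right]}
#' clamped to [0, 1]. When \eqn{\Sigma_{ML}} is (numerically) proportional
#' to the identity the denominator vanishes and 1 is returned (the
#' shrinkage target then equals the estimate, so the value is immaterial).
#'
#' @param sigmaMlMatrix N' x N' symmetric PSD matrix.
#' @param nPrime,tPrime observed dimensions.
#' @return shrinkage weight in [0, 1].
#' @export
rhoRblw <- function(sigmaMlMatrix, nPrime, tPrime) {
  tr2sum <- sum(sigmaMlMatrix^2)        # tr(S^2) for symmetric S
  trsq <- sum(diag(sigmaMlMatrix))^2    # tr(S)^2
  den <- (tPrime + 2) * (tr2sum - trsq / nPrime)
  if (den <= 1e-14 * trsq) return(1)
  num <- (tPrime - 2) / tPrime * tr2sum + trsq
  min(max(num / den, 0), 1)
}

#' Shrinkage estimate of the node covariance
#'
#' Convex combination of the autocorrelation-adjusted ML estimate and its
#' scaled-identity target:
#' \eqn{\hat\Sigma_N = (1-\rho)\Sigma_{ML} + (\rho/N') tr(\Sigma_{ML}) I}.
#' The trace is preserved for every \eqn{\rho}.
#'
#' @param E N' x T' residual matrix (must not be identically zero).
#' @param theta AR(1) coefficient in (-1, 1).
#' @param rho shrinkage weight in [0, 1].
#' @return N' x N' SPD matrix.
#' @export
sigmaNShrinkage <- function(E, theta, rho) {
  if (all(E == 0)) stop("residuals are identically zero: no noise to estimate")
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  S <- sigmaMl(E, theta)
  (1 - rho) * S + (rho / nrow(S)) * sum(diag(S)) * diag(1, nrow(S))
}

# Clip eigenvalues so downstream Lambda^(-1/2) stays finite.
.spdFloor <- function(S, rel = 1e-10) {
  floorVal <- rel * sum(diag(S)) / nrow(S)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= floorVal) return(S)
  v <- pmax(e$values, floorVal)
  M <- e$vectors %*% (v * t(e$vectors))
  (M + t(M)) / 2
}

#' Flip-flop estimation of the matrix-normal noise covariances
#'
#' Alternates the closed-form AR(1) MAP update [thetaMap()] and the
#' shrinkage node-covariance update ([sigmaMl()] + [rhoRblw()] +
#' [sigmaNShrinkage()]) until both \eqn{|\Delta\theta|} and the relative
#' Frobenius change of \eqn{\hat\Sigma_N} drop below \code{tol}, or
#' \code{maxIter} is reached (the result is then flagged not converged).
#'
#' @param E N' x T' residual matrix.
#' @param alpha stationarity-prior strength.
#' @param tol convergence tolerance (default 1e-8).
#' @param maxIter iteration cap (default 100).
#' @param init optional [NoiseModel-class] starting point (default
#'   theta = 0, sigmaN = I).
#' @return list with \code{noise} (a [NoiseModel-class]), \code{rho} (last
#'   shrinkage weight), \code{iterations}, \code{converged}.
#' @export
flipFlop <- function(E, alpha = 0.1, tol = 1e-8, maxIter = 100, init = NULL) {
  if (any(!is.finite(E))) stop("E must be finite")
  np <- nrow(E); tp <- ncol(E)
  if (np < 2 || tp < 2) stop("flip-flop requires N' >= 2 and T' >= 2")
  if (all(E == 0)) stop("residuals are identically zero: no noise to estimate")
  theta <- if (is.null(init)) 0 else init@theta
  sigmaN <- if (is.null(init)) diag(1, np) else init@sigmaN
  converged <- FALSE
  rho <- NA_real_
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    thetaNew <- thetaMap(E, sigmaN, alpha)
    S <- sigmaMl(E, thetaNew)
    rho <- rhoRblw(S, np, tp)
    sigmaNew <- (1 - rho) * S + (rho / np) * sum(diag(S)) * diag(1, np)
    sigmaNew <- .spdFloor(sigmaNew)
    dTheta <- abs(thetaNew - theta)
    dSigma <- sqrt(sum((sigmaNew - sigmaN)^2)) /
      max(sqrt(sum(sigmaN^2)), .Machine$double.eps)
    theta <- thetaNew
    sigmaN <- sigmaNew
    if (dTheta < tol && dSigma < tol) {
      converged <- TRUE
      break
    }
  }
  list(noise = noiseModel(theta, sigmaN, tp, alpha), rho = rho,
       iterations = iter, converged = converged)
}
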