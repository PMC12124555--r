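# Laplace-approximation posterior uncertainty: dense oracle and the
# scalable N x T marginal-variance matrix.

#' Dense posterior covariance of the latent signal (verification oracle)
#'
#' \eqn{\Sigma_F = (S_T^\top \Sigma_T^{-1} S_T \otimes S_N^\top
#' \Sigma_N^{-1} S_N + \gamma K^{-1} \otimes H^{-2})^{-1}} with diagonal
#' jitter on \eqn{K} and \eqn{H^2}. NT x NT: guarded to
#' \code{N * T <= 2000} and exists to validate [marginalVariance()].
#' Column-major stacking: entry ((t-1)N + n) is node n at time t.
#'
#' @param graph a [SignalGraph-class].
#' @param filter a [GraphFilter-class].
#' @param gram T x T kernel Gram matrix.
#' @param gamma positive prior precision.
#' @param selection a [SelectionPattern-class].
#' @param sigmaN N' x N' SPD node covariance (default identity).
#' @param sigmaTMat T' x T' SPD time correlation (default identity).
#' @param jitter diagonal regularization added to K and H^2 before
#'   inversion.
#' @return NT x NT symmetric PSD matrix.
#' @export
posteriorCovarianceNaive <- function(graph, filter, gram, gamma, selection,
                                     sigmaN = NULL, sigmaTMat = NULL,
                                     jitter = 1e-10) {
  N <- selection@nNodes; Tn <- selection@nTimes
  if (N * Tn > 2000) stop("dense posterior guard: N * T must be <= 2000")
  stopifnot(gamma > 0)
  np <- length(selection@observedNodes)
  tp <- length(selection@observedTimes)
  if (is.null(sigmaN)) sigmaN <- diag(1, np)
  if (is.null(sigmaTMat)) sigmaTMat <- diag(1, tp)
  S <- .selectionMatrices(selection)
  H2 <- filterMatrix(graph, filter, squared = TRUE)
  K <- as.matrix(gram)
  A <- kronecker(t(S$St) %*% solve(sigmaTMat) %*% S$St,
                 t(S$Sn) %*% solve(sigmaN) %*% S$Sn) +
    gamma * kronecker(solve(K + jitter * diag(Tn)),
                      solve(H2 + jitter * diag(N)))
  Sf <- solve(A)
  (Sf + t(Sf)) / 2
}

#' Marginal posterior variances of the latent signal
#'
#' The N x T matrix \eqn{\Omega_F} holding the diagonal of the posterior
#' covariance \eqn{\Sigma_F}, computed at O(N^3 + T^3) cost without forming
#' \eqn{\Sigma_F}. Internally the required (in general non-symmetric)
#' eigenproblems of \eqn{S_T^\top \Sigma_T^{-1} S_T K} and \eqn{S_N^\top
#' \Sigma_N^{-1} S_N H^2} are realized through the symmetric congruence
#' \deqn{\Sigma_F = (K^{1/2} \otimes H)(C_T \otimes C_N + \gamma I)^{-1}
#'   (K^{1/2} \otimes H)}
#' with \eqn{C_N = H S_N^\top \Sigma_N^{-1} S_N H} and \eqn{C_T = K^{1/2}
#' S_T^\top \Sigma_T^{-1} S_T K^{1/2}}, which guarantees real spectra and
#' strictly positive variances. For plain KGR (identity covariances) the
#' result is the exact posterior variance, not an approximation.
#'
#' @inheritParams posteriorCovarianceNaive
#' @return a [MarginalVariance-class].
#' @seealso [predictionBand()]
#' @export
marginalVariance <- function(graph, filter, gram, gamma, selection,
                             sigmaN = NULL, sigmaTMat = NULL) {
  stopifnot(is(graph, "SignalGraph"), is(filter, "GraphFilter"), gamma > 0)
  N <- selection@nNodes; Tn <- selection@nTimes
  obsN <- selection@observedNodes
  obsT <- selection@observedTimes
  if (is.null(sigmaN)) sigmaN <- diag(1, length(obsN))
  if (is.null(sigmaTMat)) sigmaTMat <- diag(1, length(obsT))
  K <- as.matrix(gram)
  stopifnot(nrow(K) == Tn, ncol(K) == Tn)
  H <- filterMatrix(graph, filter)
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  Ks <- eK$vectors %*% (sqrt(pmax(eK$values, 0)) * t(eK$vectors))
  Cn <- if (length(obsN) == 0) matrix(0, N, N) else
    H[, obsN, drop = FALSE] %*% solve(sigmaN) %*%
      t(H[, obsN, drop = FALSE])
  Ct <- if (length(obsT) == 0) matrix(0, Tn, Tn) else
    Ks[, obsT, drop = FALSE] %*% solve(sigmaTMat) %*%
      t(Ks[, obsT, drop = FALSE])
  en <- eigen((Cn + t(Cn)) / 2, symmetric = TRUE)
  et <- eigen((Ct + t(Ct)) / 2, symmetric = TRUE)
  lamH <- pmax(en$values, 0)
  lamK <- pmax(et$values, 0)
  Wn <- (H %*% en$vectors)^2     # N x N, rows sum to diag(H^2)
  Wt <- (Ks %*% et$vectors)^2    # T x T, rows sum to diag(K)
  J <- 1 / (gamma + outer(lamH, lamK))
  omega <- Wn %*% J %*% t(Wt)
  omega <- pmax(omega, .Machine$double.xmin)
  new("MarginalVariance", omega = omega, gamma = gamma,
      selection = selection)
}

# Literal transcription of the Hadamard marginal-variance identity using
# the non-symmetric eigendecompositions; kept as an internal cross-check
# of the symmetric-congruence route used by marginalVariance().
.marginalVarianceEigen <- function(graph, filter, gram, gamma, selection,
                                   sigmaN = NULL, sigmaTMat = NULL) {
  obsN <- selection@observedNodes
  obsT <- selection@observedTimes
  if (is.null(sigmaN)) sigmaN <- diag(1, length(obsN))
  if (is.null(sigmaTMat)) sigmaTMat <- diag(1, length(obsT))
  N <- selection@nNodes; Tn <- selection@nTimes
  K <- as.matrix(gram)
  H2 <- filterMatrix(graph, filter, squared = TRUE)
  Mt <- matrix(0, Tn, Tn); Mt[obsT, obsT] <- solve(sigmaTMat)
  Mn <- matrix(0, N, N);  Mn[obsN, obsN] <- solve(sigmaN)
  et <- eigen(Mt %*% K)
  en <- eigen(Mn %*% H2)
  maxImT <- max(abs(Im(et$values))); maxImN <- max(abs(Im(en$values)))
  if (maxImT > 1e-8 * max(abs(et$values)) ||
      maxImN > 1e-8 * max(abs(en$values)))
    stop("non-real spectrum in the non-symmetric eigen route")
  Vt <- Re(et$vectors); lamK <- Re(et$values)
  Un <- Re(en$vectors); lamH <- Re(en$values)
  VtInv <- solve(Vt)
  UnInv <- solve(Un)
  J <- 1 / (gamma + outer(lamH, lamK))   # N x T (node rows, time cols)
  left  <- t(UnInv) * (H2 %*% Un)        # U^-T o (H^2 U)
  right <- VtInv * (t(Vt) %*% K)         # V^-1 o (V' K)
  left %*% J %*% right
}

#' Elementwise prediction bands
#'
#' \eqn{F^\star \pm k \sqrt{\Omega_F}}. The default k = 2 gives the
#' two-standard-deviation band; for GLS fits the Laplace plug-in makes it a
#' lower bound on the true predictive uncertainty.
#'
#' @param fit a [KgrFit-class], or an N x T matrix of point predictions.
#' @param omega a [MarginalVariance-class] computed for the same model.
#' @param k band half-width in standard deviations (default 2).
#' @return list with N x T matrices \code{lower} and \code{upper}.
#' @export
predictionBand <- function(fit, omega, k = 2) {
  fStar <- if (is(fit, "KgrFit")) fit@fStar else as.matrix(fit)
  stopifnot(is(omega, "MarginalVariance"))
  if (!all(dim(fStar) == dim(omega@omega)))
    stop("fit and omega dimensions do not match")
  sd <- sqrt(omega@omega)
  list(lower = fStar - k * sd, upper = fStar + k * sd)
}
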