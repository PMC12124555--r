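#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Weighted undirected graph with cached spectral decomposition
#'
#' Central graph container. Holds a symmetric non-negative adjacency matrix,
#' the (plain or symmetric-normalized) Laplacian and its full eigendecomposition
#' with eigenvalues sorted ascending. The decomposition is computed once at
#' construction and reused by all filtering and regression routines.
#'
#' @slot adjacency symmetric non-negative weight matrix with zero diagonal.
#' @slot nNodes number of vertices.
#' @slot normalized if \code{TRUE} the Laplacian is
#'   \eqn{D^{-1/2}(D-A)D^{-1/2}} (eigenvalues in [0, 2]), else \eqn{D-A}.
#' @slot laplacian the Laplacian matrix.
#' @slot eigenvalues Laplacian eigenvalues, ascending.
#' @slot eigenvectors orthogonal matrix of eigenvectors (columns match
#'   \code{eigenvalues}).
#' @slot nodeNames vertex labels.
#' @seealso [signalGraph()], [filterMatrix()], [cartesianProduct()]
#' @export
setClass("SignalGraph", representation(
  adjacency    = "matrix",
  nNodes       = "integer",
  normalized   = "logical",
  laplacian    = "matrix",
  eigenvalues  = "numeric",
  eigenvectors = "matrix",
  nodeNames    = "character"
), validity = function(object) {
  A <- object@adjacency
  n <- object@nNodes
  if (nrow(A) != n || ncol(A) != n)
    return("adjacency must be a square matrix matching nNodes")
  if (any(!is.finite(A))) return("adjacency entries must be finite")
  if (max(abs(A - t(A))) > 1e-10 * max(1, max(abs(A))))
    return("adjacency must be symmetric")
  if (any(A < 0)) return("adjacency entries must be non-negative")
  if (any(abs(diag(A)) > 0)) return("adjacency must have a zero diagonal")
  if (length(object@nodeNames) != n)
    return("nodeNames length must equal nNodes")
  TRUE
})

.filterFamilies <- c("inverse", "exponential", "relu", "sigmoid",
                     "cosine", "cutoff")

#' Spectral graph filter specification
#'
#' A low-pass filter is a non-increasing function \eqn{\eta(\lambda; \beta)}
#' of the Laplacian eigenvalues with \eqn{\eta(0) = 1}. Supported families:
#' \describe{
#'   \item{inverse}{\eqn{(1+\beta\lambda)^{-1}}}
#'   \item{exponential}{\eqn{\exp(-\beta\lambda)}}
#'   \item{relu}{\eqn{\max(1-\beta\lambda, 0)}}
#'   \item{sigmoid}{\eqn{2(1+\exp(\beta\lambda))^{-1}}}
#'   \item{cosine}{\eqn{\cos^\beta(\lambda\pi/2\lambda_{max})}}
#'   \item{cutoff}{1 if \eqn{\lambda \le \beta}, else 0}
#' }
#'
#' @slot family one of the family names above.
#' @slot beta positive filter parameter.
#' @seealso [graphFilter()], [filterEta()], [filterMatrix()]
#' @export
setClass("GraphFilter", representation(
  family = "character",
  beta   = "numeric"
), validity = function(object) {
  if (length(object@family) != 1 || !(object@family %in% .filterFamilies))
    return(paste("family must be one of:",
                 paste(.filterFamilies, collapse = ", ")))
  if (length(object@beta) != 1 || !is.finite(object@beta) || object@beta <= 0)
    return("beta must be a single positive number")
  TRUE
})

#' Observed node/time selection pattern
#'
#' Realizes the binary selection matrices \eqn{S_N} (N' x N) and \eqn{S_T}
#' (T' x T) as sorted index sets of observed nodes and times. The solvers work
#' with the index sets directly; no physical reordering of nodes or times is
#' ever performed. Empty index sets are permitted (the pure-prior limit used
#' by [marginalVariance()]); fitting requires at least one observed node and
#' time.
#'
#' @slot observedNodes sorted unique node indices (length N').
#' @slot observedTimes sorted unique time indices (length T').
#' @slot nNodes total number of nodes N.
#' @slot nTimes total number of times T.
#' @seealso [selectionPattern()], [randomSelection()]
#' @export
setClass("SelectionPattern", representation(
  observedNodes = "integer",
  observedTimes = "integer",
  nNodes        = "integer",
  nTimes        = "integer"
), validity = function(object) {
  on <- object@observedNodes; ot <- object@observedTimes
  if (anyDuplicated(on) || anyDuplicated(ot))
    return("observed indices must be unique")
  if (is.unsorted(on) || is.unsorted(ot))
    return("observed indices must be sorted ascending")
  if (length(on) > 0 && (any(on < 1) || any(on > object@nNodes)))
    return("observedNodes out of range")
  if (length(ot) > 0 && (any(ot < 1) || any(ot > object@nTimes)))
    return("observedTimes out of range")
  TRUE
})

#' Mercer kernel specification for the feature Gram matrix
#'
#' @slot family kernel family; only \code{"gaussian"},
#'   \eqn{\kappa(x_i, x_j) = \exp(-|x_i-x_j|^2 / 2\sigma^2)}.
#' @slot sigma positive bandwidth.
#' @seealso [kernelSpec()], [gramMatrix()]
#' @export
setClass("KernelSpec", representation(
  family = "character",
  sigma  = "numeric"
), validity = function(object) {
  if (!identical(object@family, "gaussian"))
    return("only the gaussian kernel family is supported")
  if (length(object@sigma) != 1 || !is.finite(object@sigma) ||
      object@sigma <= 0)
    return("sigma must be a single positive number")
  TRUE
})

#' Matrix-normal noise model with AR(1) time correlation
#'
#' Describes the error law \eqn{vec(E) \sim N(0, \Sigma_T(\theta) \otimes
#' \Sigma_N)} where \eqn{\Sigma_T(\theta)} is the T' x T' AR(1) correlation
#' matrix with entries \eqn{\theta^{|s-t|}} (unit diagonal) and
#' \eqn{\Sigma_N} is an unconstrained N' x N' SPD node covariance.
#'
#' @slot theta AR(1) coefficient in (-1, 1).
#' @slot alpha positive stationarity-prior strength.
#' @slot sigmaN N' x N' SPD node covariance.
#' @slot tPrime number of observed times T'.
#' @seealso [noiseModel()], [flipFlop()], [sigmaT()]
#' @export
setClass("NoiseModel", representation(
  theta  = "numeric",
  alpha  = "numeric",
  sigmaN = "matrix",
  tPrime = "integer"
), validity = function(object) {
  if (abs(object@theta) >= 1) return("theta must lie in (-1, 1)")
  if (object@alpha < 0) return("alpha must be non-negative")
  S <- object@sigmaN
  if (nrow(S) != ncol(S)) return("sigmaN must be square")
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    return("sigmaN must be symmetric")
  TRUE
})

#' Fitted kernel graph regression model
#'
#' Holds the latent-signal MAP estimate \eqn{F^\star} (N x T, defined at all
#' node-times including unobserved ones) together with the factor
#' decompositions that produced it, the spectral weight matrix J, and
#' references to the prior ingredients.
#'
#' @slot fStar N x T latent signal estimate.
#' @slot gamma prior precision.
#' @slot jMatrix N' x T' spectral weights \eqn{J_{ij} = 1/(\bar\lambda_j^K
#'   \bar\lambda_i^H + \gamma)}.
#' @slot factorization list with the eigenfactors (uBar, vBar, lamH, lamK and,
#'   for GLS fits, the covariance whitening factors).
#' @slot selection the [SelectionPattern-class] used.
#' @slot gram T x T kernel Gram matrix (or time filter matrix for product
#'   graph reconstruction).
#' @slot nodeCov N x N node-side prior covariance factor (\eqn{H^2} for KGR).
#' @slot residuals N' x T' observed-block residuals \eqn{Y - S_N F^\star
#'   S_T^\top}.
#' @seealso [fitKgr()], [predictSignal()]
#' @export
setClass("KgrFit", representation(
  fStar         = "matrix",
  gamma         = "numeric",
  jMatrix       = "matrix",
  factorization = "list",
  selection     = "SelectionPattern",
  gram          = "matrix",
  nodeCov       = "matrix",
  residuals     = "matrix"
))

#' Fitted GLS kernel graph regression model
#'
#' Extends [KgrFit-class] with the estimated matrix-normal noise model and
#' the alternating-algorithm bookkeeping.
#'
#' @slot noise the estimated [NoiseModel-class].
#' @slot outerIterations outer (signal / covariance alternation) iterations.
#' @slot innerIterations total inner flip-flop iterations summed over outer
#'   steps.
#' @slot converged logical convergence flag.
#' @slot history per-outer-iteration data.frame (theta, rho, sigmaN norm,
#'   cost, relative change in F).
#' @seealso [fitGlsKgr()]
#' @export
setClass("GlsKgrFit", contains = "KgrFit", representation(
  noise           = "NoiseModel",
  outerIterations = "integer",
  innerIterations = "integer",
  converged       = "logical",
  history         = "data.frame"
))

#' Marginal posterior variances of the latent signal
#'
#' The N x T matrix \eqn{\Omega_F} of per-node per-time posterior variances
#' obtained from the Laplace approximation (exact for plain KGR): the
#' re-stacked diagonal of the NT x NT posterior covariance, computed without
#' ever forming that matrix.
#'
#' @slot omega N x T matrix of marginal variances (strictly positive).
#' @slot gamma prior precision used.
#' @slot selection the [SelectionPattern-class] used.
#' @seealso [marginalVariance()], [predictionBand()]
#' @export
setClass("MarginalVariance", representation(
  omega     = "matrix",
  gamma     = "numeric",
  selection = "SelectionPattern"
), validity = function(object) {
  if (any(!is.finite(object@omega))) return("omega must be finite")
  if (any(object@omega <= 0)) return("omega entries must be strictly positive")
  TRUE
})
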