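# Spectral graph filters and the Gaussian spectral prior.

#' Create a graph filter
#'
#' @param family one of \code{"inverse"}, \code{"exponential"},
#'   \code{"relu"}, \code{"sigmoid"}, \code{"cosine"}, \code{"cutoff"}.
#' @param beta positive filter parameter.
#' @return a [GraphFilter-class].
#' @examples
#' filterEta(graphFilter("exponential", 1), 1)  # exp(-1)
#' @export
graphFilter <- function(family, beta = 1) {
  new("GraphFilter", family = tolower(family), beta = as.numeric(beta))
}

#' Evaluate a filter function on eigenvalues
#'
#' All families satisfy \eqn{\eta(0) = 1} and are non-increasing in
#' \eqn{\lambda}. Eigenvalues that are slightly negative due to roundoff
#' (above \code{-1e-10}) are clipped to zero.
#'
#' @param filter a [GraphFilter-class].
#' @param lambda non-negative eigenvalue(s).
#' @param lambdaMax largest Laplacian eigenvalue of the graph; required by
#'   the cosine family only.
#' @return values in [0, 1], vectorized over \code{lambda}.
#' @export
filterEta <- function(filter, lambda, lambdaMax = NULL) {
  stopifnot(is(filter, "GraphFilter"))
  if (any(lambda < -1e-10)) stop("eigenvalues must be non-negative")
  lam <- pmax(lambda, 0)
  b <- filter@beta
  switch(filter@family,
    inverse     = 1 / (1 + b * lam),
    exponential = exp(-b * lam),
    relu        = pmax(1 - b * lam, 0),
    sigmoid     = 2 / (1 + exp(b * lam)),
    cosine      = {
      if (is.null(lambdaMax))
        stop("the cosine family requires lambdaMax")
      if (lambdaMax <= 0) rep(1, length(lam))
      else cos(pmin(lam, lambdaMax) * pi / (2 * lambdaMax))^b
    },
    cutoff      = as.numeric(lam <= b),
    stop("unknown filter family: ", filter@family)
  )
}

#' Graph filter matrix
#'
#' \eqn{H = U \eta(\Lambda_L) U^\top}: symmetric PSD with eigenvalues in
#' [0, 1]. For an edgeless graph \eqn{H = I} for every family. The cosine
#' family uses the graph's cached largest eigenvalue.
#'
#' @param graph a [SignalGraph-class].
#' @param filter a [GraphFilter-class].
#' @param squared if \code{TRUE} return \eqn{H^2} (the spectral prior
#'   covariance up to \eqn{\gamma^{-1}}).
#' @return N x N symmetric matrix.
#' @export
filterMatrix <- function(graph, filter, squared = FALSE) {
  stopifnot(is(graph, "SignalGraph"))
  lam <- graph@eigenvalues
  eta <- filterEta(filter, lam, lambdaMax = max(lam))
  if (squared) eta <- eta^2
  U <- graph@eigenvectors
  M <- U %*% (eta * t(U))
  (M + t(M)) / 2
}

#' Sample from the graph spectral prior
#'
#' Draws \eqn{f_g = H f_w} where \eqn{f_w} is white Gaussian noise with
#' precision \eqn{\gamma}, i.e. samples from \eqn{N(0, \gamma^{-1} H^2)}:
#' smooth random signals concentrated on the low end of the graph spectrum.
#'
#' @param graph a [SignalGraph-class].
#' @param filter a [GraphFilter-class].
#' @param gamma positive precision.
#' @param nSamples number of draws.
#' @param seed optional integer seed.
#' @return N x nSamples matrix of samples.
#' @export
sampleSpectralPrior <- function(graph, filter, gamma = 1, nSamples = 1,
                                seed = NULL) {
  stopifnot(gamma > 0)
  if (!is.null(seed)) set.seed(seed)
  H <- filterMatrix(graph, filter)
  W <- matrix(stats::rnorm(graph@nNodes * nSamples), graph@nNodes, nSamples)
  H %*% W / sqrt(gamma)
}

#' Check whether a filter separates over a Cartesian product
#'
#' A filter is separable when \eqn{\eta(\Lambda_T \oplus \Lambda_N) =
#' \eta(\Lambda_T) \otimes \eta(\Lambda_N)} so the product-graph filter
#' factorizes as \eqn{H_T \otimes H_N}. The exponential family is separable
#' exactly; most others are not. Checked numerically over all eigenvalue
#' pairs of the two factor graphs (the cosine family evaluates the product
#' side at \eqn{\lambda_{max,T} + \lambda_{max,N}}).
#'
#' @param filter a [GraphFilter-class].
#' @param timeGraph,spaceGraph [SignalGraph-class] factor graphs.
#' @param tol deviation tolerance for declaring separability.
#' @return list with \code{separable} (logical) and \code{maxDeviation}.
#' @export
isSeparable <- function(filter, timeGraph, spaceGraph, tol = 1e-12) {
  lt <- timeGraph@eigenvalues
  ln <- spaceGraph@eigenvalues
  lmaxP <- max(lt) + max(ln)
  sums <- outer(lt, ln, `+`)
  prodSide <- filterEta(filter, as.vector(sums), lambdaMax = lmaxP)
  factSide <- as.vector(outer(filterEta(filter, lt, lambdaMax = lmaxP),
                              filterEta(filter, ln, lambdaMax = lmaxP)))
  dev <- max(abs(prodSide - factSide))
  list(separable = dev < tol, maxDeviation = dev)
}
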