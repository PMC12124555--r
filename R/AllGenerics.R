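# Generics and simple accessors for the S4 classes.

#' Number of vertices
#' @param x a [SignalGraph-class] or [SelectionPattern-class].
#' @return integer vertex count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setMethod("nNodes", "SignalGraph", function(x) x@nNodes)

#' @rdname nNodes
#' @export
setMethod("nNodes", "SelectionPattern", function(x) x@nNodes)

#' Adjacency matrix accessor
#' @param x a [SignalGraph-class].
#' @return the symmetric weight matrix.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname adjacencyMatrix
#' @export
setMethod("adjacencyMatrix", "SignalGraph", function(x) x@adjacency)

#' Laplacian matrix accessor
#'
#' Returns \eqn{L = D - A} (or its symmetric normalization
#' \eqn{D^{-1/2} L D^{-1/2}} when the graph was built with
#' \code{normalized = TRUE}).
#' @param x a [SignalGraph-class].
#' @return N x N Laplacian matrix.
#' @export
setGeneric("laplacianMatrix", function(x) standardGeneric("laplacianMatrix"))

#' @rdname laplacianMatrix
#' @export
setMethod("laplacianMatrix", "SignalGraph", function(x) x@laplacian)

#' Laplacian eigenvalues (ascending)
#' @param x a [SignalGraph-class].
#' @return numeric vector of eigenvalues sorted ascending.
#' @export
setGeneric("graphEigenvalues", function(x) standardGeneric("graphEigenvalues"))

#' @rdname graphEigenvalues
#' @export
setMethod("graphEigenvalues", "SignalGraph", function(x) x@eigenvalues)

#' Laplacian eigenvectors
#' @param x a [SignalGraph-class].
#' @return orthogonal matrix whose columns match [graphEigenvalues()].
#' @export
setGeneric("graphEigenvectors",
           function(x) standardGeneric("graphEigenvectors"))

#' @rdname graphEigenvectors
#' @export
setMethod("graphEigenvectors", "SignalGraph", function(x) x@eigenvectors)

#' Vertex labels
#' @param x a [SignalGraph-class].
#' @return character vector of node names.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname nodeNames
#' @export
setMethod("nodeNames", "SignalGraph", function(x) x@nodeNames)

#' Number of connected components
#'
#' Counted as the number of Laplacian eigenvalues below
#' \code{1e-8 * max(eigenvalues)} (all of them for an edgeless graph).
#' @param x a [SignalGraph-class].
#' @return integer component count.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname nComponents
#' @export
setMethod("nComponents", "SignalGraph", function(x) {
  lam <- x@eigenvalues
  thr <- 1e-8 * max(lam)
  if (max(lam) <= 0) return(length(lam))
  sum(lam < thr)
})

#' Observed node indices
#' @param x a [SelectionPattern-class].
#' @return sorted integer vector of observed node indices.
#' @export
setGeneric("observedNodes", function(x) standardGeneric("observedNodes"))

#' @rdname observedNodes
#' @export
setMethod("observedNodes", "SelectionPattern", function(x) x@observedNodes)

#' Observed time indices
#' @param x a [SelectionPattern-class].
#' @return sorted integer vector of observed time indices.
#' @export
setGeneric("observedTimes", function(x) standardGeneric("observedTimes"))

#' @rdname observedTimes
#' @export
setMethod("observedTimes", "SelectionPattern", function(x) x@observedTimes)

#' Latent signal estimate accessor
#' @param x a [KgrFit-class] (or subclass).
#' @return the N x T matrix \eqn{F^\star}.
#' @export
setGeneric("latentSignal", function(x) standardGeneric("latentSignal"))

#' @rdname latentSignal
#' @export
setMethod("latentSignal", "KgrFit", function(x) x@fStar)

#' Estimated noise model accessor
#' @param x a [GlsKgrFit-class].
#' @return the [NoiseModel-class].
#' @export
setGeneric("noiseEstimate", function(x) standardGeneric("noiseEstimate"))

#' @rdname noiseEstimate
#' @export
setMethod("noiseEstimate", "GlsKgrFit", function(x) x@noise)

#' Marginal variance matrix accessor
#' @param x a [MarginalVariance-class].
#' @return the N x T matrix of posterior variances.
#' @export
setGeneric("varianceMatrix", function(x) standardGeneric("varianceMatrix"))

#' @rdname varianceMatrix
#' @export
setMethod("varianceMatrix", "MarginalVariance", function(x) x@omega)

setMethod("show", "SignalGraph", function(object) {
  m <- sum(object@adjacency > 0) / 2
  cat(sprintf("SignalGraph: %d nodes, %d edges, %s Laplacian, %d component%s\n",
              object@nNodes, m,
              if (object@normalized) "normalized" else "plain",
              nComponents(object), if (nComponents(object) > 1) "s" else ""))
  invisible(object)
})

setMethod("show", "GraphFilter", function(object) {
  cat(sprintf("GraphFilter: family = %s, beta = %g\n",
              object@family, object@beta))
  invisible(object)
})

setMethod("show", "SelectionPattern", function(object) {
  cat(sprintf(
    "SelectionPattern: %d/%d nodes and %d/%d times observed (%.1f%% of node-times)\n",
    length(object@observedNodes), object@nNodes,
    length(object@observedTimes), object@nTimes,
    100 * length(object@observedNodes) * length(object@observedTimes) /
      (object@nNodes * object@nTimes)))
  invisible(object)
})

setMethod("show", "KernelSpec", function(object) {
  cat(sprintf("KernelSpec: %s kernel, sigma = %g\n",
              object@family, object@sigma))
  invisible(object)
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(
    "NoiseModel: AR(1) theta = %.4f, alpha = %g, sigmaN %d x %d (T' = %d)\n",
    object@theta, object@alpha, nrow(object@sigmaN), ncol(object@sigmaN),
    object@tPrime))
  invisible(object)
})

setMethod("show", "KgrFit", function(object) {
  cat(sprintf("%s: %d x %d latent signal, gamma = %g\n",
              class(object), nrow(object@fStar), ncol(object@fStar),
              object@gamma))
  cat(sprintf("  observed block: %d nodes x %d times; RMS residual %.4g\n",
              nrow(object@residuals), ncol(object@residuals),
              sqrt(mean(object@residuals^2))))
  invisible(object)
})

setMethod("show", "GlsKgrFit", function(object) {
  callNextMethod()
  cat(sprintf(
    "  noise: theta = %.4f; %d outer / %d inner iterations; converged: %s\n",
    object@noise@theta, object@outerIterations, object@innerIterations,
    object@converged))
  invisible(object)
})

setMethod("show", "MarginalVariance", function(object) {
  cat(sprintf(
    "MarginalVariance: %d x %d, range [%.4g, %.4g], gamma = %g\n",
    nrow(object@omega), ncol(object@omega), min(object@omega),
    max(object@omega), object@gamma))
  invisible(object)
})
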