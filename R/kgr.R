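# Kernel graph regression: efficient solver (observed-block
# eigendecompositions + Hadamard weights) and the dense brute-force oracle.

# Shared efficient core. K: T x T prior factor over times (kernel Gram
# matrix, or a time filter matrix for product-graph reconstruction);
# H2: N x N prior factor over nodes. All eigendecompositions are of the
# N' x N' and T' x T' observed blocks.
.kgrCore <- function(Y, K, H2, gamma, selection) {
  obsN <- selection@observedNodes
  obsT <- selection@observedTimes
  Kbar  <- K[obsT, obsT, drop = FALSE]
  H2bar <- H2[obsN, obsN, drop = FALSE]
  eK <- eigen((Kbar + t(Kbar)) / 2, symmetric = TRUE)
  eH <- eigen((H2bar + t(H2bar)) / 2, symmetric = TRUE)
  Vbar <- eK$vectors; lamK <- eK$values
  Ubar <- eH$vectors; lamH <- eH$values
  J <- 1 / (outer(lamH, lamK) + gamma)          # N' x T'
  inner <- J * crossprod(Ubar, Y %*% Vbar)      # J o (U'YV)
  fStar <- H2[, obsN, drop = FALSE] %*% (Ubar %*% inner %*% t(Vbar)) %*%
    K[obsT, , drop = FALSE]
  list(fStar = fStar, jMatrix = J,
       factorization = list(uBar = Ubar, vBar = Vbar,
                            lamH = lamH, lamK = lamK))
}

.checkFitInputs <- function(Y, gamma, selection, N, Tn) {
  if (!is.matrix(Y) || any(is.na(Y)) || any(!is.finite(Y)))
    stop("Y must be a fully finite matrix; missingness is expressed through ",
         "the selection pattern, not NA entries")
  if (length(gamma) != 1 || !is.finite(gamma) || gamma <= 0)
    stop("gamma must be a single positive number")
  if (selection@nNodes != N || selection@nTimes != Tn)
    stop("selection dimensions do not match the problem")
  if (length(selection@observedNodes) < 1 ||
      length(selection@observedTimes) < 1)
    stop("fitting requires at least one observed node and time")
  if (nrow(Y) != length(selection@observedNodes) ||
      ncol(Y) != length(selection@observedTimes))
    stop("Y must be N' x T', matching the selection pattern")
  invisible(TRUE)
}

.resolveGram <- function(features, kernel, gram, Tn) {
  if (!is.null(gram)) {
    stopifnot(nrow(gram) == Tn, ncol(gram) == Tn)
    return(as.matrix(gram))
  }
  if (is.null(features)) stop("either features or gram must be supplied")
  X <- as.matrix(features)
  if (ncol(X) != Tn) stop("features must have T columns")
  gramMatrix(X, kernel)
}

#' Fit a kernel graph regression model
#'
#' MAP estimate of the latent N x T graph signal F under the spectral prior
#' \eqn{vec(F) \sim N(0, \gamma^{-1} K \otimes H^2)} and i.i.d. unit-variance
#' observation noise on the observed node-time block. The solution
#' \deqn{F^\star = H^2 S_N^\top \bar U (J \circ (\bar U^\top Y \bar V))
#'   \bar V^\top S_T K, \quad J_{ij} = 1/(\bar\lambda_j^K \bar\lambda_i^H +
#'   \gamma)}
#' requires dense eigendecompositions only of the observed T' x T' and
#' N' x N' blocks, giving worst-case cubic cost in N and T.
#'
#' @param Y N' x T' observed signal block (rows follow
#'   \code{observedNodes(selection)}, columns \code{observedTimes(selection)}).
#' @param features M x T feature matrix (column t = covariates at time t);
#'   may be \code{NULL} when \code{gram} is given.
#' @param graph a [SignalGraph-class] on N nodes.
#' @param filter a [GraphFilter-class] defining \eqn{H}.
#' @param gamma positive prior precision.
#' @param selection a [SelectionPattern-class].
#' @param kernel a [KernelSpec-class] or Gaussian bandwidth (default
#'   bandwidth 1); ignored when \code{gram} is given.
#' @param gram optional precomputed T x T prior factor over times.
#' @return a [KgrFit-class].
#' @seealso [fitKgrNaive()] for the dense oracle, [fitGlsKgr()] for
#'   correlated noise.
#' @export
fitKgr <- function(Y, features, graph, filter, gamma, selection,
                   kernel = kernelSpec(1), gram = NULL) {
  stopifnot(is(graph, "SignalGraph"), is(filter, "GraphFilter"))
  .checkFitInputs(Y, gamma, selection, graph@nNodes, selection@nTimes)
  K <- .resolveGram(features, kernel, gram, selection@nTimes)
  H2 <- filterMatrix(graph, filter, squared = TRUE)
  core <- .kgrCore(Y, K, H2, gamma, selection)
  resid <- Y - core$fStar[selection@observedNodes, selection@observedTimes,
                          drop = FALSE]
  new("KgrFit", fStar = core$fStar, gamma = gamma, jMatrix = core$jMatrix,
      factorization = core$factorization, selection = selection,
      gram = K, nodeCov = H2, residuals = resid)
}

# Dense Kronecker-assembled solver used as an independent oracle.
.kgrNaiveCore <- function(Y, K, H2, gamma, selection, jitter = 1e-10) {
  N <- selection@nNodes; Tn <- selection@nTimes
  if (N * Tn > 2000)
    stop("naive solver guard: N * T must be <= 2000")
  S <- .selectionMatrices(selection)
  Kinv  <- solve(K + jitter * diag(Tn))
  H2inv <- solve(H2 + jitter * diag(N))
  A <- kronecker(crossprod(S$St), crossprod(S$Sn)) +
    gamma * kronecker(Kinv, H2inv)
  rhs <- kronecker(t(S$St), t(S$Sn)) %*% as.vector(Y)
  matrix(solve(A, rhs), N, Tn)
}

#' Dense brute-force KGR solver (verification oracle)
#'
#' Direct evaluation of \eqn{vec(F^\star) = (S_T^\top S_T \otimes S_N^\top
#' S_N + \gamma K^{-1} \otimes H^{-2})^{-1} (S_T^\top \otimes S_N^\top)
#' vec(Y)} with \code{1e-10} diagonal jitter on \eqn{K} and \eqn{H^2}
#' before inversion. O((NT)^3): guarded to \code{N * T <= 2000}. Exists to
#' validate [fitKgr()]; never use it for real problems.
#'
#' @inheritParams fitKgr
#' @return N x T matrix \eqn{F^\star}.
#' @export
fitKgrNaive <- function(Y, features, graph, filter, gamma, selection,
                        kernel = kernelSpec(1), gram = NULL) {
  stopifnot(is(graph, "SignalGraph"), is(filter, "GraphFilter"))
  .checkFitInputs(Y, gamma, selection, graph@nNodes, selection@nTimes)
  K <- .resolveGram(features, kernel, gram, selection@nTimes)
  H2 <- filterMatrix(graph, filter, squared = TRUE)
  .kgrNaiveCore(Y, K, H2, gamma, selection)
}

#' Extract latent-signal predictions
#'
#' Returns the requested block of \eqn{F^\star}; unobserved node-times are
#' the primary use case.
#'
#' @param fit a [KgrFit-class] (or subclass).
#' @param nodes node indices (default all).
#' @param times time indices (default all).
#' @return the requested submatrix of \eqn{F^\star}.
#' @export
predictSignal <- function(fit, nodes = NULL, times = NULL) {
  stopifnot(is(fit, "KgrFit"))
  N <- nrow(fit@fStar); Tn <- ncol(fit@fStar)
  if (is.null(nodes)) nodes <- seq_len(N)
  if (is.null(times)) times <- seq_len(Tn)
  nodes <- as.integer(nodes); times <- as.integer(times)
  if (any(nodes < 1) || any(nodes > N)) stop("node index out of range")
  if (any(times < 1) || any(times > Tn)) stop("time index out of range")
  fit@fStar[nodes, times, drop = FALSE]
}

#' Reconstruct a signal on a Cartesian product graph
#'
#' Time-vertex signal reconstruction: identical algebra to [fitKgr()] with
#' the kernel Gram matrix replaced by a time-graph filter matrix, realizing
#' the prior \eqn{vec(F) \sim N(0, \gamma^{-1} H_T \otimes H_N)}. An
#' edgeless time graph gives \eqn{H_T = I}: independent per-time graph
#' smoothing.
#'
#' @param Y N' x T' observed block.
#' @param timeGraph,spaceGraph [SignalGraph-class] factor graphs (T and N
#'   nodes).
#' @param timeFilter,spaceFilter [GraphFilter-class] filters defining
#'   \eqn{H_T} and \eqn{H_N}.
#' @param gamma positive prior precision.
#' @param selection a [SelectionPattern-class] over (N, T).
#' @return a [KgrFit-class] (with \code{gram} = \eqn{H_T}, \code{nodeCov} =
#'   \eqn{H_N}).
#' @export
reconstructProduct <- function(Y, timeGraph, spaceGraph, timeFilter,
                               spaceFilter, gamma, selection) {
  stopifnot(is(timeGraph, "SignalGraph"), is(spaceGraph, "SignalGraph"))
  .checkFitInputs(Y, gamma, selection, spaceGraph@nNodes, timeGraph@nNodes)
  Ht <- filterMatrix(timeGraph, timeFilter)
  Hn <- filterMatrix(spaceGraph, spaceFilter)
  core <- .kgrCore(Y, Ht, Hn, gamma, selection)
  resid <- Y - core$fStar[selection@observedNodes, selection@observedTimes,
                          drop = FALSE]
  new("KgrFit", fStar = core$fStar, gamma = gamma, jMatrix = core$jMatrix,
      factorization = core$factorization, selection = selection,
      gram = Ht, nodeCov = Hn, residuals = resid)
}
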