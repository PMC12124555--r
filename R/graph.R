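# Graph construction, Laplacians, GFT and Cartesian products.

.asDenseMatrix <- function(A) {
  if (inherits(A, "Matrix")) A <- as.matrix(A)
  if (!is.matrix(A) || !is.numeric(A))
    stop("adjacency must be a numeric matrix")
  A
}

.buildLaplacian <- function(A, normalized) {
  d <- rowSums(A)
  L <- diag(d, nrow(A)) - A
  if (normalized) {
    # degree-0 nodes keep a zero row/column in the normalized variant
    dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
    L <- dinv * t(dinv * L)  # D^-1/2 L D^-1/2
  }
  L
}

#' Construct a signal graph
#'
#' Builds a [SignalGraph-class] from a symmetric non-negative adjacency
#' matrix, computing the (optionally normalized) Laplacian and its full
#' eigendecomposition up front. Eigenvalues are sorted ascending and tiny
#' negative values from roundoff are clipped at zero.
#'
#' @param adjacency symmetric non-negative numeric matrix (dense or
#'   \pkg{Matrix} sparse) with zero diagonal.
#' @param normalized use the symmetric normalized Laplacian
#'   \eqn{D^{-1/2}(D-A)D^{-1/2}} (eigenvalues in [0, 2]) instead of
#'   \eqn{D - A}.
#' @param nodeNames optional vertex labels; defaults to the adjacency
#'   dimnames or \code{"v1"..."vN"}.
#' @return a [SignalGraph-class].
#' @examples
#' g <- signalGraph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
#' laplacianMatrix(g)
#' @export
signalGraph <- function(adjacency, normalized = FALSE, nodeNames = NULL) {
  A <- .asDenseMatrix(adjacency)
  if (is.null(nodeNames)) {
    nodeNames <- rownames(A)
    if (is.null(nodeNames)) nodeNames <- paste0("v", seq_len(nrow(A)))
  }
  dimnames(A) <- NULL
  L <- .buildLaplacian(A, normalized)
  e <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- order(e$values)        # ascending, stable
  lam <- pmax(e$values[ord], 0)
  new("SignalGraph", adjacency = A, nNodes = nrow(A),
      normalized = normalized, laplacian = L,
      eigenvalues = lam, eigenvectors = e$vectors[, ord, drop = FALSE],
      nodeNames = as.character(nodeNames))
}

#' Chain (path) graph
#'
#' Path graph on \code{n} nodes with unit edge weights; the standard
#' spatial graph for synthetic diffusion experiments.
#'
#' @param n number of nodes (>= 1).
#' @param normalized passed to [signalGraph()].
#' @return a [SignalGraph-class].
#' @examples
#' laplacianMatrix(chainGraph(3))
#' @export
chainGraph <- function(n, normalized = FALSE) {
  stopifnot(n >= 1)
  A <- matrix(0, n, n)
  if (n >= 2) {
    idx <- seq_len(n - 1)
    A[cbind(idx, idx + 1)] <- 1
    A[cbind(idx + 1, idx)] <- 1
  }
  signalGraph(A, normalized = normalized)
}

#' Edgeless graph
#'
#' @param n number of nodes.
#' @param normalized passed to [signalGraph()].
#' @return a [SignalGraph-class] with no edges (Laplacian zero, filter
#'   matrices equal the identity).
#' @export
edgelessGraph <- function(n, normalized = FALSE) {
  signalGraph(matrix(0, n, n), normalized = normalized)
}

#' Graph smoothness quadratic form
#'
#' \eqn{f^\top L f = \sum_{(i,j) \in E} A_{ij} (f_i - f_j)^2 \ge 0};
#' zero iff the signal is constant on every connected component (plain
#' Laplacian).
#'
#' @param f numeric signal of length N.
#' @param graph a [SignalGraph-class].
#' @return non-negative scalar.
#' @export
smoothness <- function(f, graph) {
  stopifnot(is(graph, "SignalGraph"))
  if (length(f) != graph@nNodes)
    stop("signal length must equal the number of nodes")
  as.numeric(crossprod(f, graph@laplacian %*% f))
}

#' Graph Fourier Transform
#'
#' Projects a signal onto the Laplacian eigenbasis, \eqn{a = U^\top f}.
#' Low-index coefficients correspond to smooth (low eigenvalue) components.
#'
#' @param f numeric signal of length N.
#' @param graph a [SignalGraph-class].
#' @return numeric coefficient vector of length N.
#' @seealso [igft()]
#' @export
gft <- function(f, graph) {
  stopifnot(is(graph, "SignalGraph"))
  if (length(f) != graph@nNodes)
    stop("signal length must equal the number of nodes")
  as.numeric(crossprod(graph@eigenvectors, f))
}

#' Inverse Graph Fourier Transform
#'
#' @param a coefficient vector of length N.
#' @param graph a [SignalGraph-class].
#' @return the reconstructed signal \eqn{U a}.
#' @export
igft <- function(a, graph) {
  stopifnot(is(graph, "SignalGraph"))
  if (length(a) != graph@nNodes)
    stop("coefficient length must equal the number of nodes")
  as.numeric(graph@eigenvectors %*% a)
}

#' Cartesian product of two graphs
#'
#' The product of a time-like graph on T nodes and a space-like graph on N
#' nodes has NT nodes and adjacency given by the Kronecker sum
#' \eqn{A_T \otimes I_N + I_T \otimes A_N}; its Laplacian is
#' \eqn{L_T \oplus L_N} and its spectrum is the multiset of all pairwise
#' eigenvalue sums.
#'
#' @param timeGraph,spaceGraph [SignalGraph-class] objects (plain
#'   Laplacian).
#' @return a [SignalGraph-class] on \code{nNodes(timeGraph) *
#'   nNodes(spaceGraph)} nodes; node (t, n) maps to index (t-1) * N + n.
#' @export
cartesianProduct <- function(timeGraph, spaceGraph) {
  stopifnot(is(timeGraph, "SignalGraph"), is(spaceGraph, "SignalGraph"))
  if (timeGraph@normalized || spaceGraph@normalized)
    stop("cartesianProduct is defined for plain-Laplacian graphs")
  At <- timeGraph@adjacency
  An <- spaceGraph@adjacency
  Tn <- nrow(At); N <- nrow(An)
  A <- kronecker(At, diag(1, N)) + kronecker(diag(1, Tn), An)
  labs <- as.vector(outer(nodeNames(spaceGraph), nodeNames(timeGraph),
                          function(n, t) paste(t, n, sep = ":")))
  signalGraph(A, nodeNames = labs)
}

#' Read a graph from an edge-list CSV or Matrix Market file
#'
#' Edge-list CSVs must have columns \code{source,target,weight} (weight
#' optional, default 1); each undirected edge appears once, duplicates
#' (either orientation) are an error. \code{.mtx} files are read with
#' \code{Matrix::readMM} and must be (structurally) symmetric with zero
#' diagonal. Node identifiers are mapped to contiguous indices in first-seen
#' order and kept as \code{nodeNames}.
#'
#' @param path file path (\code{.mtx} or delimited text).
#' @param normalized passed to [signalGraph()].
#' @return a [SignalGraph-class].
#' @export
readGraph <- function(path, normalized = FALSE) {
  if (!file.exists(path)) stop("graph file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    A <- as.matrix(Matrix::readMM(path))
    A <- (A + t(A)) / 2  # expand symmetric-storage .mtx
    if (max(abs(diag(A))) > 0) diag(A) <- 0
    return(signalGraph(A, normalized = normalized))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(df)))
    stop("edge list must have 'source' and 'target' columns")
  if (is.null(df$weight)) df$weight <- 1
  nodes <- unique(c(as.character(df$source), as.character(df$target)))
  i <- match(as.character(df$source), nodes)
  j <- match(as.character(df$target), nodes)
  if (any(i == j)) stop("self-loops are not allowed")
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key))
    stop("duplicate undirected edge(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  n <- length(nodes)
  A <- matrix(0, n, n)
  A[cbind(i, j)] <- df$weight
  A[cbind(j, i)] <- df$weight
  signalGraph(A, normalized = normalized, nodeNames = nodes)
}

#' Build a graph from point coordinates
#'
#' Plain geometric graph builder for sensor-network style data: computes
#' pairwise Euclidean distances, connects points by a minimum spanning tree
#' (connected by construction) or a symmetrized k-nearest-neighbour union,
#' and assigns edge weights \eqn{\exp(-d / \mathrm{median}(d))} where the
#' median is over all pairwise distances.
#'
#' @param coordinates numeric matrix, one row per point.
#' @param method \code{"mst"} or \code{"knn"}.
#' @param k neighbour count for \code{"knn"}.
#' @param normalized passed to [signalGraph()].
#' @return a [SignalGraph-class].
#' @export
buildDistanceGraph <- function(coordinates, method = c("mst", "knn"), k = 3,
                               normalized = FALSE) {
  method <- match.arg(method)
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) < 2) stop("need at least 2 points")
  if (any(!is.finite(coordinates))) stop("coordinates must be finite")
  D <- as.matrix(stats::dist(coordinates))
  med <- stats::median(D[upper.tri(D)])
  if (med <= 0) med <- 1
  W <- exp(-D / med)
  keep <- matrix(FALSE, nrow(D), ncol(D))
  if (method == "mst") {
    M <- ape::mst(stats::as.dist(D))
    keep <- M > 0
  } else {
    for (i in seq_len(nrow(D))) {
      ord <- order(D[i, ])          # index order breaks distance ties
      nb <- setdiff(ord, i)[seq_len(min(k, nrow(D) - 1))]
      keep[i, nb] <- TRUE
      keep[nb, i] <- TRUE
    }
  }
  A <- ifelse(keep, W, 0)
  diag(A) <- 0
  rn <- rownames(coordinates)
  signalGraph(A, normalized = normalized, nodeNames = rn)
}
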