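# Shared fixture builders: everything is generated in code under fixed seeds.

randomAdjacency <- function(n, density = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- up[sample.int(length(up), max(1, round(density * length(up))))]
  A[on] <- runif(length(on), 0.2, 1)
  A <- A + t(A)
  diag(A) <- 0
  A
}

randomGraph <- function(n, density = 0.6, seed = NULL, normalized = FALSE) {
  signalGraph(randomAdjacency(n, density, seed), normalized = normalized)
}

randomSpd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- matrix(rnorm(n * n), n)
  crossprod(R) / n + diag(0.5, n)
}

# A small random partially observed problem instance.
randomInstance <- function(n = 7, t = 9, nObs = 5, tObs = 6, seed = 1,
                           beta = 0.5, sigma = 2, family = "exponential") {
  set.seed(seed)
  g <- randomGraph(n, seed = seed)
  sel <- selectionPattern(sort(sample.int(n, nObs)),
                          sort(sample.int(t, tObs)), n, t)
  X <- matrix(rnorm(3 * t), 3, t)
  Y <- matrix(rnorm(nObs * tObs), nObs, tObs)
  list(graph = g, filter = graphFilter(family, beta), selection = sel,
       features = X, y = Y, kernel = kernelSpec(sigma),
       gram = gramMatrix(X, kernelSpec(sigma)))
}
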