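test_that("Laplacian matches its definition on simple graphs", {
  g <- chainGraph(3)
  expect_equal(laplacianMatrix(g),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
  expect_equal(laplacianMatrix(signalGraph(matrix(0, 1, 1))),
               matrix(0, 1, 1))
  # isolated node: zero row/column in both variants
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  for (norm in c(FALSE, TRUE)) {
    L <- laplacianMatrix(signalGraph(A, normalized = norm))
    expect_equal(L[3, ], c(0, 0, 0))
    expect_equal(L[, 3], c(0, 0, 0))
  }
})

test_that("adjacency validation rejects malformed inputs", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(signalGraph(bad), "symmetric")
  expect_error(signalGraph(matrix(c(0, -1, -1, 0), 2, 2)), "non-negative")
  expect_error(signalGraph(matrix(c(1, 0, 0, 0), 2, 2)), "diagonal")
})

test_that("plain Laplacian rows sum to zero and normalized spectrum is in [0, 2]", {
  for (s in 1:5) {
    g <- randomGraph(8, density = 0.5, seed = s)
    expect_lt(max(abs(rowSums(laplacianMatrix(g)))), 1e-12)
    gn <- signalGraph(adjacencyMatrix(g), normalized = TRUE)
    expect_lte(max(graphEigenvalues(gn)), 2 + 1e-10)
    expect_gte(min(graphEigenvalues(gn)), 0)
  }
})

test_that("spectral decomposition reconstructs L with ascending eigenvalues", {
  g <- randomGraph(9, seed = 42)
  U <- graphEigenvectors(g); lam <- graphEigenvalues(g)
  expect_false(is.unsorted(lam))
  rec <- U %*% (lam * t(U))
  expect_lt(max(abs(rec - laplacianMatrix(g))),
            1e-10 * max(abs(laplacianMatrix(g))))
})

test_that("near-zero eigenvalue count equals the number of components", {
  blockGraph <- function(sizes) {
    n <- sum(sizes)
    A <- matrix(0, n, n)
    off <- 0
    for (k in sizes) {
      idx <- off + seq_len(k)
      if (k > 1) A[idx, idx] <- randomAdjacency(k, density = 1, seed = k)
      off <- off + k
    }
    signalGraph(A)
  }
  expect_equal(nComponents(blockGraph(5)), 1)
  expect_equal(nComponents(blockGraph(c(4, 3))), 2)
  expect_equal(nComponents(blockGraph(c(3, 2, 4))), 3)
  expect_equal(nComponents(edgelessGraph(4)), 4)
})

test_that("smoothness equals the weighted edge-difference sum", {
  g <- randomGraph(6, seed = 7)
  A <- adjacencyMatrix(g)
  set.seed(8); f <- rnorm(6)
  brute <- 0
  for (i in 1:6) for (j in 1:6) if (j > i)
    brute <- brute + A[i, j] * (f[i] - f[j])^2
  expect_equal(smoothness(f, g), brute, tolerance = 1e-12)
  expect_equal(smoothness(rep(3, 6), g), 0, tolerance = 1e-10)
  # unit eigenvector -> its eigenvalue
  u3 <- graphEigenvectors(g)[, 3]
  expect_equal(smoothness(u3, g), graphEigenvalues(g)[3], tolerance = 1e-10)
  expect_error(smoothness(rnorm(5), g), "length")
})

test_that("GFT is orthonormal, invertible, and Parseval-consistent", {
  g <- randomGraph(7, seed = 10)
  u2 <- graphEigenvectors(g)[, 2]
  a <- gft(u2, g)
  expect_equal(a, replace(numeric(7), 2, 1), tolerance = 1e-10)
  set.seed(11); f <- rnorm(7)
  expect_equal(igft(gft(f, g), g), f, tolerance = 1e-10)
  expect_equal(sum(gft(f, g)^2 * graphEigenvalues(g)), smoothness(f, g),
               tolerance = 1e-9)
  expect_error(gft(rnorm(6), g), "length")
})

test_that("Cartesian products realize the Kronecker sum", {
  sq <- cartesianProduct(chainGraph(2), chainGraph(2))
  expect_equal(sort(graphEigenvalues(sq)), c(0, 2, 2, 4), tolerance = 1e-10)

  g <- randomGraph(5, seed = 12)
  same <- cartesianProduct(edgelessGraph(1), g)
  expect_equal(adjacencyMatrix(same), adjacencyMatrix(g))

  gt <- randomGraph(3, seed = 13); gn <- randomGraph(4, seed = 14)
  prod <- cartesianProduct(gt, gn)
  Lkron <- kronecker(laplacianMatrix(gt), diag(4)) +
    kronecker(diag(3), laplacianMatrix(gn))
  expect_equal(laplacianMatrix(prod), Lkron, tolerance = 1e-12)
  pairSums <- sort(as.vector(outer(graphEigenvalues(gt),
                                   graphEigenvalues(gn), `+`)))
  expect_equal(sort(graphEigenvalues(prod)), pairSums, tolerance = 1e-8)
})

test_that("graph files round-trip through edge-list CSV and Matrix Market", {
  g <- randomGraph(6, seed = 15)
  A <- adjacencyMatrix(g)
  edges <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  csv <- tempfile(fileext = ".csv")
  writeLines(c("source,target,weight",
               paste(paste0("n", edges[, 1]), paste0("n", edges[, 2]),
                     A[edges], sep = ",")), csv)
  g2 <- readGraph(csv)
  perm <- match(paste0("n", 1:6), nodeNames(g2))
  expect_equal(adjacencyMatrix(g2)[perm, perm], A, tolerance = 1e-12)

  dup <- tempfile(fileext = ".csv")
  writeLines(c("source,target,weight", "a,b,1", "b,a,2"), dup)
  expect_error(readGraph(dup), "duplicate")

  mtx <- tempfile(fileext = ".mtx")
  Matrix::writeMM(methods::as(Matrix::Matrix(A, sparse = TRUE),
                              "generalMatrix"), mtx)
  g3 <- readGraph(mtx)
  expect_equal(adjacencyMatrix(g3), A, tolerance = 1e-10)
})

test_that("coordinate graph builder produces the expected topologies", {
  path <- buildDistanceGraph(cbind(c(0, 1, 2), c(0, 0, 0)), method = "mst")
  expect_equal(nComponents(path), 1)
  A <- adjacencyMatrix(path)
  expect_equal(sum(A > 0) / 2, 2)      # 2 edges: a path
  expect_equal(A[1, 3], 0)             # endpoints not directly joined

  set.seed(16)
  g <- buildDistanceGraph(matrix(runif(24), 12, 2), method = "mst")
  expect_equal(nComponents(g), 1)

  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  g4 <- buildDistanceGraph(square, method = "knn", k = 2)
  A4 <- adjacencyMatrix(g4) > 0
  expect_equal(sum(A4) / 2, 4)         # 4-cycle
  expect_false(A4[1, 3]); expect_false(A4[2, 4])
})
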