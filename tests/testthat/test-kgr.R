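test_that("fully observed identity-prior fit reduces to Y / (1 + gamma)", {
  n <- 4; t <- 5
  g0 <- edgelessGraph(n)                 # H = I
  sel <- fullSelection(n, t)
  set.seed(41); Y <- matrix(rnorm(n * t), n, t)
  for (gamma in c(0.3, 1, 10)) {
    fit <- fitKgr(Y, NULL, g0, graphFilter("exponential", 1), gamma, sel,
                  gram = diag(t))
    expect_equal(latentSignal(fit), Y / (1 + gamma), tolerance = 1e-10)
    expect_equal(fitKgrNaive(Y, NULL, g0, graphFilter("exponential", 1),
                             gamma, sel, gram = diag(t)),
                 Y / (1 + gamma), tolerance = 1e-8)
  }
})

test_that("efficient solution equals the dense oracle and the intermediate form", {
  for (s in 1:20) {
    set.seed(s)
    inst <- randomInstance(n = sample(5:10, 1), t = sample(6:12, 1),
                           nObs = 4, tObs = 5, seed = s)
    gamma <- runif(1, 0.1, 3)
    fit <- fitKgr(inst$y, inst$features, inst$graph, inst$filter, gamma,
                  inst$selection, kernel = inst$kernel)
    naive <- fitKgrNaive(inst$y, inst$features, inst$graph, inst$filter,
                         gamma, inst$selection, kernel = inst$kernel)
    expect_lt(max(abs(latentSignal(fit) - naive)) / max(abs(naive)), 1e-8)
  }

  # reduced-dimension intermediate form as a second independent oracle
  inst <- randomInstance(n = 4, t = 5, nObs = 3, tObs = 4, seed = 99)
  gamma <- 0.7
  S <- KGraphReg:::.selectionMatrices(inst$selection)
  K <- inst$gram
  H2 <- filterMatrix(inst$graph, inst$filter, squared = TRUE)
  Kbar <- S$St %*% K %*% t(S$St)
  H2bar <- S$Sn %*% H2 %*% t(S$Sn)
  mid <- kronecker(K %*% t(S$St), H2 %*% t(S$Sn)) %*%
    solve(gamma * diag(3 * 4) + kronecker(Kbar, H2bar), as.vector(inst$y))
  fit <- fitKgr(inst$y, inst$features, inst$graph, inst$filter, gamma,
                inst$selection, kernel = inst$kernel)
  expect_equal(as.vector(latentSignal(fit)), as.vector(mid),
               tolerance = 1e-8)
})

test_that("fit is linear in Y, shrinks with gamma, and respects relabeling", {
  inst <- randomInstance(seed = 5)
  set.seed(6)
  Y2 <- matrix(rnorm(length(inst$y)), nrow(inst$y))
  args <- list(features = inst$features, graph = inst$graph,
               filter = inst$filter, selection = inst$selection,
               kernel = inst$kernel)
  f <- function(Y, gamma = 0.5)
    latentSignal(do.call(fitKgr, c(list(Y = Y, gamma = gamma), args)))
  expect_equal(f(inst$y + Y2), f(inst$y) + f(Y2), tolerance = 1e-9)

  norms <- sapply(c(0.1, 1, 10, 100, 1e4), function(g)
    sqrt(sum(f(inst$y, g)^2)))
  expect_true(all(diff(norms) < 1e-12))
  expect_lt(norms[5], 1e-2 * norms[1])   # gamma -> Inf: F* -> 0

  # permuting node labels commutes with fitting
  n <- nNodes(inst$graph)
  set.seed(7); perm <- sample.int(n)
  gPerm <- signalGraph(adjacencyMatrix(inst$graph)[perm, perm])
  obsPerm <- sort(match(observedNodes(inst$selection), perm))
  selPerm <- selectionPattern(obsPerm, observedTimes(inst$selection), n,
                              inst$selection@nTimes)
  # rows of Y follow sorted observed indices: map to the permuted order
  origOfPerm <- perm[obsPerm]
  Yperm <- inst$y[match(origOfPerm, observedNodes(inst$selection)), ]
  fPerm <- latentSignal(fitKgr(Yperm, inst$features, gPerm, inst$filter,
                               0.5, selPerm, kernel = inst$kernel))
  expect_equal(fPerm, f(inst$y)[perm, ], tolerance = 1e-8)
})

test_that("input validation rejects bad gamma, NaN observations, shape errors", {
  inst <- randomInstance(seed = 8)
  expect_error(fitKgr(inst$y, inst$features, inst$graph, inst$filter, -1,
                      inst$selection), "gamma")
  Ybad <- inst$y; Ybad[1, 1] <- NaN
  expect_error(fitKgr(Ybad, inst$features, inst$graph, inst$filter, 1,
                      inst$selection), "finite")
  expect_error(fitKgr(inst$y[-1, ], inst$features, inst$graph, inst$filter,
                      1, inst$selection), "matching")
  big <- fullSelection(50, 50)
  expect_error(fitKgrNaive(matrix(0, 50, 50), NULL, edgelessGraph(50),
                           inst$filter, 1, big, gram = diag(50)), "guard")
})

test_that("predictSignal returns the requested block of F*", {
  inst <- randomInstance(seed = 9)
  fit <- fitKgr(inst$y, inst$features, inst$graph, inst$filter, 0.5,
                inst$selection, kernel = inst$kernel)
  expect_equal(predictSignal(fit), latentSignal(fit))
  expect_equal(predictSignal(fit, nodes = 2, times = 3),
               latentSignal(fit)[2, 3, drop = FALSE])
  obs <- predictSignal(fit, observedNodes(inst$selection),
                       observedTimes(inst$selection))
  expect_equal(inst$y - obs, fit@residuals)
  expect_error(predictSignal(fit, nodes = 99), "range")
})

test_that("product-graph reconstruction matches KGR algebra and recovers signals", {
  # edgeless time graph: H_T = I, equivalent to gram = I
  gn <- randomGraph(5, seed = 51)
  selp <- selectionPattern(c(1, 2, 4), c(1, 3, 4, 6), 5, 6)
  set.seed(52); Y <- matrix(rnorm(12), 3, 4)
  flt <- graphFilter("exponential", 0.5)
  rp <- reconstructProduct(Y, edgelessGraph(6), gn, flt,
                           graphFilter("exponential", 1), 0.4, selp)
  kf <- fitKgr(Y, NULL, gn, flt, 0.4, selp, gram = diag(6))
  expect_equal(latentSignal(rp), latentSignal(kf), tolerance = 1e-9)

  # general time graph: beta-halving makes fitKgr's H^2 equal H_N
  gt <- chainGraph(6)
  rp2 <- reconstructProduct(Y, gt, gn, graphFilter("exponential", 0.8),
                            graphFilter("exponential", 1), 0.4, selp)
  kf2 <- fitKgr(Y, NULL, gn, graphFilter("exponential", 0.5), 0.4, selp,
                gram = filterMatrix(gt, graphFilter("exponential", 0.8)))
  expect_equal(latentSignal(rp2), latentSignal(kf2), tolerance = 1e-9)

  # smooth noiseless signal on chain x chain, 20% masked: tiny RMSE
  gt3 <- chainGraph(15); gn3 <- chainGraph(12)
  fltS <- graphFilter("exponential", 3)
  set.seed(53)
  W <- matrix(rnorm(12 * 15), 12, 15)
  Ftrue <- filterMatrix(gn3, fltS) %*% W %*% filterMatrix(gt3, fltS)
  sel3 <- randomSelection(12, 15, 0.8, 0.8, seed = 54)
  Yobs <- Ftrue[observedNodes(sel3), observedTimes(sel3)]
  rec <- reconstructProduct(Yobs, gt3, gn3, graphFilter("exponential", 1.5),
                            graphFilter("exponential", 1.5), 1e-6, sel3)
  hidden <- matrix(TRUE, 12, 15)
  hidden[observedNodes(sel3), observedTimes(sel3)] <- FALSE
  rmse <- sqrt(mean((latentSignal(rec)[hidden] - Ftrue[hidden])^2))
  expect_lt(rmse, 1e-2)
})
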