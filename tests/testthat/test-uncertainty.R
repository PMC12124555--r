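test_that("marginal variances equal the diagonal of the dense posterior", {
  for (s in 1:5) {
    inst <- randomInstance(n = 6, t = 7, nObs = 4, tObs = 5, seed = 60 + s)
    SN <- randomSpd(4, seed = 65 + s)
    ST <- sigmaT(0.35, 5)
    gamma <- runif(1, 0.3, 2)
    om <- marginalVariance(inst$graph, inst$filter, inst$gram, gamma,
                           inst$selection, sigmaN = SN, sigmaTMat = ST)
    Sf <- posteriorCovarianceNaive(inst$graph, inst$filter, inst$gram,
                                   gamma, inst$selection, sigmaN = SN,
                                   sigmaTMat = ST)
    target <- matrix(diag(Sf), 6, 7)
    expect_lt(max(abs(varianceMatrix(om) - target) / target), 1e-6)
    # the literal non-symmetric eigen route agrees with the congruence route
    omE <- KGraphReg:::.marginalVarianceEigen(inst$graph, inst$filter,
                                              inst$gram, gamma,
                                              inst$selection, sigmaN = SN,
                                              sigmaTMat = ST)
    expect_lt(max(abs(omE - varianceMatrix(om)) / varianceMatrix(om)), 1e-6)
  }
})

test_that("dense posterior is symmetric PSD and matches its factorized form", {
  inst <- randomInstance(n = 5, t = 6, nObs = 3, tObs = 4, seed = 68)
  SN <- randomSpd(3, seed = 69)
  ST <- sigmaT(-0.4, 4)
  Sf <- posteriorCovarianceNaive(inst$graph, inst$filter, inst$gram, 0.8,
                                 inst$selection, sigmaN = SN,
                                 sigmaTMat = ST)
  expect_equal(Sf, t(Sf))
  expect_gt(min(eigen(Sf, symmetric = TRUE)$values), 0)
  # (K (x) H^2)(StT' SigT^-1 StT K (x) SnN' SigN^-1 SnN H^2 + gamma I)^-1
  S <- KGraphReg:::.selectionMatrices(inst$selection)
  K <- inst$gram
  H2 <- filterMatrix(inst$graph, inst$filter, squared = TRUE)
  Mt <- t(S$St) %*% solve(ST) %*% S$St
  Mn <- t(S$Sn) %*% solve(SN) %*% S$Sn
  fact <- kronecker(K, H2) %*%
    solve(kronecker(Mt %*% K, Mn %*% H2) + 0.8 * diag(30))
  expect_equal(Sf, (fact + t(fact)) / 2, tolerance = 1e-6)
})

test_that("fully observed identity case gives variance 1 / (1 + gamma)", {
  n <- 4; t <- 5
  om <- marginalVariance(edgelessGraph(n), graphFilter("exponential", 1),
                         diag(t), 1.5, fullSelection(n, t))
  expect_equal(varianceMatrix(om), matrix(1 / 2.5, n, t),
               tolerance = 1e-10)
})

test_that("prior-dominated and pure-prior limits are reproduced", {
  inst <- randomInstance(n = 5, t = 6, nObs = 3, tObs = 4, seed = 70)
  K <- inst$gram
  H2 <- filterMatrix(inst$graph, inst$filter, squared = TRUE)
  gamma <- 1e8
  om <- marginalVariance(inst$graph, inst$filter, K, gamma, inst$selection)
  expect_equal(gamma * varianceMatrix(om), outer(diag(H2), diag(K)),
               tolerance = 1e-6)
  # empty selection: exact pure prior at any gamma
  empty <- selectionPattern(integer(0), integer(0), 5, 6)
  om0 <- marginalVariance(inst$graph, inst$filter, K, 0.7, empty)
  expect_equal(varianceMatrix(om0), outer(diag(H2), diag(K)) / 0.7,
               tolerance = 1e-9)
})

test_that("variances are positive and shrink as more nodes are observed", {
  inst <- randomInstance(n = 7, t = 8, nObs = 3, tObs = 6, seed = 71)
  selSmall <- inst$selection
  extra <- setdiff(1:7, observedNodes(selSmall))[1:2]
  selBig <- selectionPattern(sort(c(observedNodes(selSmall), extra)),
                             observedTimes(selSmall), 7, 8)
  omS <- varianceMatrix(marginalVariance(inst$graph, inst$filter,
                                         inst$gram, 0.6, selSmall))
  omB <- varianceMatrix(marginalVariance(inst$graph, inst$filter,
                                         inst$gram, 0.6, selBig))
  expect_true(all(omS > 0))
  expect_true(all(omB <= omS + 1e-12))
})

test_that("unobserved nodes carry at least the uncertainty of observed ones", {
  # vertex-transitive cycle: nodes are exchangeable up to rotation
  n <- 8
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, i %% n + 1] <- A[i %% n + 1, i] <- 1
  cyc <- signalGraph(A)
  sel <- selectionPattern(c(1, 3, 5, 7), 1:5, n, 5)
  om <- varianceMatrix(marginalVariance(cyc, graphFilter("exponential", 1),
                                        diag(5), 1, sel))
  expect_gt(min(om[c(2, 4, 6, 8), ]), max(om[c(1, 3, 5, 7), ]) - 1e-12)
})

test_that("prediction bands scale with k and wrap the point estimate", {
  inst <- randomInstance(seed = 72)
  fit <- fitKgr(inst$y, inst$features, inst$graph, inst$filter, 0.9,
                inst$selection, kernel = inst$kernel)
  om <- marginalVariance(inst$graph, inst$filter, inst$gram, 0.9,
                         inst$selection)
  b0 <- predictionBand(fit, om, k = 0)
  expect_equal(b0$lower, latentSignal(fit))
  expect_equal(b0$upper, latentSignal(fit))
  b1 <- predictionBand(fit, om, k = 1)
  b2 <- predictionBand(fit, om, k = 2)
  expect_equal(b2$upper - b2$lower, 2 * (b1$upper - b1$lower),
               tolerance = 1e-12)
  expect_error(predictionBand(matrix(0, 2, 2), om), "dimensions")
})

test_that("two-sigma bands cover a well-specified synthetic signal", {
  covg <- numeric(10)
  for (s in seq_len(10)) {
    sc <- simulateScenario(nNodes = 40, nTimes = 50, theta = 0,
                           signal = "prior", seed = 73 + s)
    K <- gramMatrix(sc$features, kernelSpec(sc$sigma))
    fit <- fitKgr(sc$y, NULL, sc$graph, sc$filter, sc$gamma, sc$selection,
                  gram = K)
    om <- marginalVariance(sc$graph, sc$filter, K, sc$gamma, sc$selection)
    b <- predictionBand(fit, om)
    covg[s] <- mean(sc$fTrue >= b$lower & sc$fTrue <= b$upper)
  }
  expect_gte(mean(covg), 0.85)
})
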