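# Synthetic-data generation: smooth latent signals via graph diffusion,
# matrix-normal AR(1)-by-dense errors, uniform masking, Gaussian features,
# and the sensitivity-sweep driver.

#' Smooth latent graph signal via diffusion filtering
#'
#' \eqn{F = H W} column by column, with W i.i.d. standard normal: each
#' column is a draw from the spectral prior \eqn{N(0, H^2)}. On an
#' edgeless graph \eqn{H = I} and F equals the raw noise.
#'
#' @param graph a [SignalGraph-class].
#' @param filter a [GraphFilter-class].
#' @param nTimes number of columns.
#' @param seed optional integer seed.
#' @return N x nTimes matrix.
#' @export
generateSmoothSignal <- function(graph, filter, nTimes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  H <- filterMatrix(graph, filter)
  W <- matrix(stats::rnorm(graph@nNodes * nTimes), graph@nNodes, nTimes)
  H %*% W
}

#' Sample a matrix-normal error matrix with AR(1) time correlation
#'
#' Draws \eqn{E} with \eqn{vec(E) \sim N(0, \Sigma_T(\theta) \otimes
#' \Sigma_N)}: rows carry the node covariance \eqn{\Sigma_N}, columns the
#' stationary AR(1) correlation \eqn{\theta^{|s-t|}} (generated exactly by
#' the stationary recursion \eqn{e_t = \theta e_{t-1} +
#' \sqrt{1-\theta^2}\,w_t}).
#'
#' @param sigmaN N' x N' SPD node covariance.
#' @param theta AR(1) coefficient in (-1, 1).
#' @param nPrime,tPrime dimensions of E.
#' @param seed optional integer seed.
#' @return N' x T' matrix.
#' @export
sampleMatrixNormalError <- function(sigmaN, theta, nPrime, tPrime,
                                    seed = NULL) {
  if (abs(theta) >= 1) stop("theta must lie in (-1, 1)")
  sigmaN <- as.matrix(sigmaN)
  stopifnot(nrow(sigmaN) == nPrime)
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(stats::rnorm(nPrime * tPrime), nPrime, tPrime)
  E <- W
  if (tPrime >= 2 && theta != 0) {
    s <- sqrt(1 - theta^2)
    for (t in 2:tPrime) E[, t] <- theta * E[, t - 1] + s * W[, t]
  }
  e <- eigen((sigmaN + t(sigmaN)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-10 * max(abs(e$values)))
    stop("sigmaN must be positive semi-definite")
  root <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  root %*% E
}

#' Squared-exponential node covariance
#'
#' \eqn{(\Sigma_N)_{ij} = \exp(-(i-j)^2) + j\,\delta_{ij}} with diagonal
#' jitter \code{j = 0.05}: unit-plus-jitter diagonal, rapidly decaying
#' off-diagonals, SPD.
#'
#' @param nPrime dimension.
#' @param jitter diagonal jitter (default 0.05).
#' @return N' x N' SPD matrix.
#' @export
squaredExpSigmaN <- function(nPrime, jitter = 0.05) {
  stopifnot(nPrime >= 1)
  idx <- seq_len(nPrime)
  exp(-outer(idx, idx, `-`)^2) + jitter * diag(1, nPrime)
}

#' Gaussian feature matrix
#'
#' i.i.d. standard normal M x T explanatory variables (default M = 12
#' feature rows).
#'
#' @param nTimes number of time columns.
#' @param nFeatures number of feature rows.
#' @param seed optional integer seed.
#' @return M x T matrix.
#' @export
gaussianFeatures <- function(nTimes, nFeatures = 12, seed = NULL) {
  stopifnot(nTimes >= 1, nFeatures >= 1)
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(nFeatures * nTimes), nFeatures, nTimes)
}

#' Simulate a full partially observed graph-regression scenario
#'
#' Baseline synthetic design: a smooth latent signal on a chain graph
#' (diffusion-filtered Gaussian noise), uniform random masking of nodes and
#' times, matrix-normal AR(1)-correlated observation errors on the observed
#' block, and Gaussian features. With \code{signal = "prior"} the latent
#' signal is drawn from the model prior \eqn{N(0, \gamma^{-1} K \otimes
#' H^2)} instead (useful for calibration studies, where the fitted model is
#' then exactly well-specified).
#'
#' @param nNodes,nTimes full problem dimensions (defaults 100 x 120).
#' @param pNodes,pTimes observed fractions (defaults 0.8).
#' @param filter [GraphFilter-class] used both to smooth the signal and as
#'   the model filter (default exponential, beta = 1).
#' @param theta true AR(1) noise coefficient.
#' @param sigmaNSpec \code{"identity"} or \code{"squared-exponential"}
#'   node covariance for the noise.
#' @param noiseScale multiplier on the error matrix (default 1).
#' @param nFeatures number of Gaussian feature rows (default 12).
#' @param graph optional [SignalGraph-class]; default chain graph.
#' @param signal \code{"diffusion"} (default) or \code{"prior"}.
#' @param gamma,sigma precision and kernel bandwidth used when
#'   \code{signal = "prior"} (defaults 1 and 4).
#' @param seed optional integer seed.
#' @return list with \code{graph}, \code{fTrue} (N x T), \code{features}
#'   (M x T), \code{y} (N' x T' observed block), \code{selection},
#'   \code{errors}, \code{theta}, \code{sigmaN}.
#' @export
simulateScenario <- function(nNodes = 100, nTimes = 120, pNodes = 0.8,
                             pTimes = 0.8,
                             filter = graphFilter("exponential", 1),
                             theta = 0, sigmaNSpec = c("identity",
                                                       "squared-exponential"),
                             noiseScale = 1, nFeatures = 12, graph = NULL,
                             signal = c("diffusion", "prior"), gamma = 1,
                             sigma = 4, seed = NULL) {
  sigmaNSpec <- match.arg(sigmaNSpec)
  signal <- match.arg(signal)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(graph)) graph <- chainGraph(nNodes)
  stopifnot(graph@nNodes == nNodes)
  sel <- randomSelection(nNodes, nTimes, pNodes, pTimes)
  X <- gaussianFeatures(nTimes, nFeatures)
  if (signal == "prior") {
    K <- gramMatrix(X, kernelSpec(sigma))
    eK <- eigen(K, symmetric = TRUE)
    Ks <- eK$vectors %*% (sqrt(pmax(eK$values, 0)) * t(eK$vectors))
    H <- filterMatrix(graph, filter)
    W <- matrix(stats::rnorm(nNodes * nTimes), nNodes, nTimes)
    fTrue <- H %*% W %*% Ks / sqrt(gamma)
  } else {
    H <- filterMatrix(graph, filter)
    W <- matrix(stats::rnorm(nNodes * nTimes), nNodes, nTimes)
    fTrue <- H %*% W
  }
  np <- length(sel@observedNodes); tp <- length(sel@observedTimes)
  sigmaN <- if (sigmaNSpec == "identity") diag(1, np) else
    squaredExpSigmaN(np)
  E <- noiseScale *
    sampleMatrixNormalError(sigmaN, theta, np, tp)
  Y <- fTrue[sel@observedNodes, sel@observedTimes, drop = FALSE] + E
  list(graph = graph, fTrue = fTrue, features = X, y = Y, selection = sel,
       errors = E, theta = theta, sigmaN = sigmaN, filter = filter,
       gamma = gamma, sigma = sigma)
}

#' Train/test RMSE of a latent-signal estimate
#'
#' Root mean squared deviation between the estimate and the true signal
#' over the observed node-times (train) and all remaining node-times
#' (test).
#'
#' @param fStar N x T estimate (or a [KgrFit-class]).
#' @param fTrue N x T true signal.
#' @param selection a [SelectionPattern-class].
#' @return named numeric vector \code{c(train = ..., test = ...)}.
#' @export
signalRmse <- function(fStar, fTrue, selection) {
  if (is(fStar, "KgrFit")) fStar <- fStar@fStar
  D2 <- (fStar - fTrue)^2
  mask <- matrix(FALSE, nrow(fTrue), ncol(fTrue))
  mask[selection@observedNodes, selection@observedTimes] <- TRUE
  c(train = sqrt(mean(D2[mask])), test = sqrt(mean(D2[!mask])))
}

#' Hyperparameter sensitivity sweep
#'
#' Runs the full generate/mask/fit/score pipeline over a grid of scenario
#' and model parameters, recording train and test RMSE and iteration
#' counts (outer + inner summed, for GLS fits) per replicate.
#'
#' @param grid data.frame; recognized columns (all optional, with
#'   defaults): \code{gamma} (1), \code{beta} (1), \code{sigma} (4),
#'   \code{alpha} (0.1), \code{theta} (0), \code{pNodes}/\code{pTimes}
#'   (0.8), \code{sigmaNSpec} ("identity"), \code{method} ("gls" or
#'   "kgr").
#' @param nReps replicates per grid row.
#' @param nNodes,nTimes scenario dimensions.
#' @param filterFamily filter family for both generation and fitting.
#' @param seed integer seed; replicate r of grid row g uses a
#'   deterministic derived seed.
#' @return tidy data.frame: one row per grid row x replicate with the
#'   parameters, \code{trainRMSE}, \code{testRMSE}, \code{iterations},
#'   \code{converged}.
#' @export
runSensitivitySweep <- function(grid, nReps = 1, nNodes = 100, nTimes = 120,
                                filterFamily = "exponential", seed = 1) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  getCol <- function(name, default) {
    if (name %in% names(grid)) grid[[name]] else rep(default, nrow(grid))
  }
  gammas <- getCol("gamma", 1); betas <- getCol("beta", 1)
  sigmas <- getCol("sigma", 4); alphas <- getCol("alpha", 0.1)
  thetas <- getCol("theta", 0)
  pN <- getCol("pNodes", 0.8); pT <- getCol("pTimes", 0.8)
  snSpec <- getCol("sigmaNSpec", "identity")
  method <- getCol("method", "gls")
  out <- vector("list", nrow(grid) * nReps)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    flt <- graphFilter(filterFamily, betas[g])
    for (r in seq_len(nReps)) {
      repSeed <- (seed * 10000L + g * 100L + r) %% .Machine$integer.max
      sc <- simulateScenario(nNodes = nNodes, nTimes = nTimes,
                             pNodes = pN[g], pTimes = pT[g], filter = flt,
                             theta = thetas[g], sigmaNSpec = snSpec[g],
                             seed = repSeed)
      if (method[g] == "gls") {
        fit <- fitGlsKgr(sc$y, sc$features, sc$graph, flt, gammas[g],
                         sc$selection, alpha = alphas[g],
                         kernel = kernelSpec(sigmas[g]))
        iters <- fit@outerIterations + fit@innerIterations
        conv <- fit@converged
      } else {
        fit <- fitKgr(sc$y, sc$features, sc$graph, flt, gammas[g],
                      sc$selection, kernel = kernelSpec(sigmas[g]))
        iters <- 1L
        conv <- TRUE
      }
      rmse <- signalRmse(fit, sc$fTrue, sc$selection)
      k <- k + 1L
      out[[k]] <- data.frame(
        gridRow = g, rep = r, gamma = gammas[g], beta = betas[g],
        sigma = sigmas[g], alpha = alphas[g], theta = thetas[g],
        pNodes = pN[g], pTimes = pT[g], method = method[g],
        trainRMSE = rmse[["train"]], testRMSE = rmse[["test"]],
        iterations = iters, converged = conv)
    }
  }
  do.call(rbind, out)
}
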