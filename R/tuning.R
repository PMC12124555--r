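# Cross-validated hyperparameter selection over (gamma, beta, sigma[, alpha]).

# Partition observed times into nFolds groups uniformly at random.
.timeFolds <- function(obsT, nFolds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nFolds < 2) stop("at least 2 folds are required")
  if (length(obsT) < nFolds) stop("fewer observed times than folds")
  split(obsT, sample(rep(seq_len(nFolds), length.out = length(obsT))))
}

# Mean held-out-fold MSE of one (gamma, beta, sigma[, alpha]) setting.
.cvLoss <- function(Y, features, graph, selection, folds, gamma, beta,
                    sigma, alpha, filterFamily, gls) {
  flt <- graphFilter(filterFamily, beta)
  obsT <- selection@observedTimes
  losses <- vapply(folds, function(holdOut) {
    trainT <- setdiff(obsT, holdOut)
    trainSel <- selectionPattern(selection@observedNodes, trainT,
                                 selection@nNodes, selection@nTimes)
    Ytrain <- Y[, match(trainT, obsT), drop = FALSE]
    fit <- tryCatch({
      if (gls)
        fitGlsKgr(Ytrain, features, graph, flt, gamma, trainSel,
                  alpha = alpha, kernel = kernelSpec(sigma))
      else
        fitKgr(Ytrain, features, graph, flt, gamma, trainSel,
               kernel = kernelSpec(sigma))
    }, error = function(e) NULL)
    if (is.null(fit)) return(NA_real_)
    pred <- fit@fStar[selection@observedNodes, holdOut, drop = FALSE]
    mean((pred - Y[, match(holdOut, obsT), drop = FALSE])^2)
  }, numeric(1))
  mean(losses)
}

#' Cross-validated hyperparameter tuning
#'
#' Grid search over (gamma, beta, sigma) and optionally alpha: the observed
#' times are partitioned uniformly at random into \code{nFolds} folds and
#' each grid point is scored by the mean held-out-fold MSE on the observed
#' nodes. With \code{refine = TRUE}, Nelder-Mead on the log-transformed
#' parameters polishes the best grid point.
#'
#' @param Y N' x T' observed block.
#' @param features M x T feature matrix.
#' @param graph a [SignalGraph-class].
#' @param selection a [SelectionPattern-class].
#' @param grid data.frame with columns \code{gamma}, \code{beta},
#'   \code{sigma} and optionally \code{alpha}.
#' @param nFolds number of CV folds (default 4).
#' @param filterFamily filter family name (default exponential).
#' @param gls fit [fitGlsKgr()] instead of [fitKgr()] in each fold.
#' @param refine polish the best grid point with Nelder-Mead on log
#'   parameters.
#' @param seed integer seed controlling the fold partition.
#' @return list with \code{best} (named parameter vector incl.
#'   \code{cvLoss}) and \code{cvTable} (the grid with a \code{cvLoss}
#'   column).
#' @export
tuneHyperparameters <- function(Y, features, graph, selection, grid,
                                nFolds = 4, filterFamily = "exponential",
                                gls = FALSE, refine = FALSE, seed = 1) {
  stopifnot(is.data.frame(grid),
            all(c("gamma", "beta", "sigma") %in% names(grid)))
  hasAlpha <- "alpha" %in% names(grid)
  folds <- .timeFolds(selection@observedTimes, nFolds, seed)
  loss <- vapply(seq_len(nrow(grid)), function(i) {
    .cvLoss(Y, features, graph, selection, folds, grid$gamma[i],
            grid$beta[i], grid$sigma[i],
            if (hasAlpha) grid$alpha[i] else 0.1, filterFamily, gls)
  }, numeric(1))
  if (all(!is.finite(loss)))
    stop("non-finite CV loss at every grid point")
  cvTable <- cbind(grid, cvLoss = loss)
  bestIdx <- which.min(loss)
  best <- as.list(grid[bestIdx, , drop = FALSE])
  best$cvLoss <- loss[bestIdx]
  if (refine) {
    par0 <- log(c(best$gamma, best$beta, best$sigma))
    obj <- function(p) {
      v <- .cvLoss(Y, features, graph, selection, folds, exp(p[1]),
                   exp(p[2]), exp(p[3]),
                   if (hasAlpha) best$alpha else 0.1, filterFamily, gls)
      if (!is.finite(v)) 1e10 else v
    }
    opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                        control = list(maxit = 100))
    if (opt$value < best$cvLoss) {
      best$gamma <- exp(opt$par[1])
      best$beta <- exp(opt$par[2])
      best$sigma <- exp(opt$par[3])
      best$cvLoss <- opt$value
    }
  }
  list(best = best, cvTable = cvTable)
}
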