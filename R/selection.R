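# Observed node/time selection patterns.

#' Create a selection pattern
#'
#' @param observedNodes integer indices of observed nodes (1-based).
#' @param observedTimes integer indices of observed times (1-based).
#' @param nNodes,nTimes total numbers of nodes and times.
#' @return a [SelectionPattern-class]; indices are sorted and must be
#'   unique and in range.
#' @export
selectionPattern <- function(observedNodes, observedTimes, nNodes, nTimes) {
  new("SelectionPattern",
      observedNodes = sort(as.integer(observedNodes)),
      observedTimes = sort(as.integer(observedTimes)),
      nNodes = as.integer(nNodes), nTimes = as.integer(nTimes))
}

#' Fully observed selection
#'
#' @param nNodes,nTimes total dimensions.
#' @return a [SelectionPattern-class] observing every node-time.
#' @export
fullSelection <- function(nNodes, nTimes) {
  selectionPattern(seq_len(nNodes), seq_len(nTimes), nNodes, nTimes)
}

#' Uniform random masking of nodes and times
#'
#' Samples \code{round(nNodes * pNodes)} nodes and \code{round(nTimes *
#' pTimes)} times uniformly at random without replacement; the complement
#' is hidden. With p = 0.8 on both axes, 64\% of all node-times are
#' observed.
#'
#' @param nNodes,nTimes total dimensions.
#' @param pNodes,pTimes observed fractions in (0, 1].
#' @param seed optional integer seed (same seed, same selection).
#' @return a [SelectionPattern-class].
#' @export
randomSelection <- function(nNodes, nTimes, pNodes = 0.8, pTimes = pNodes,
                            seed = NULL) {
  stopifnot(pNodes > 0, pNodes <= 1, pTimes > 0, pTimes <= 1)
  if (!is.null(seed)) set.seed(seed)
  nObs <- max(1L, round(nNodes * pNodes))
  tObs <- max(1L, round(nTimes * pTimes))
  selectionPattern(sample.int(nNodes, nObs), sample.int(nTimes, tObs),
                  nNodes, nTimes)
}

# Dense 0/1 selection matrices; used by the brute-force oracles only.
.selectionMatrices <- function(selection) {
  Sn <- matrix(0, length(selection@observedNodes), selection@nNodes)
  Sn[cbind(seq_along(selection@observedNodes), selection@observedNodes)] <- 1
  St <- matrix(0, length(selection@observedTimes), selection@nTimes)
  St[cbind(seq_along(selection@observedTimes), selection@observedTimes)] <- 1
  list(Sn = Sn, St = St)
}
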