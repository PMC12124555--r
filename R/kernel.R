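# Feature-space Mercer kernels.

#' Create a kernel specification
#'
#' @param sigma positive Gaussian bandwidth.
#' @param family kernel family; only \code{"gaussian"} is implemented.
#' @return a [KernelSpec-class].
#' @export
kernelSpec <- function(sigma, family = "gaussian") {
  new("KernelSpec", family = tolower(family), sigma = as.numeric(sigma))
}

#' Gram matrix of the time-indexed feature vectors
#'
#' \eqn{K_{ij} = \exp(-|x_i - x_j|^2 / 2\sigma^2)} over the columns of the
#' M x T feature matrix: symmetric positive semi-definite with unit
#' diagonal.
#'
#' @param features M x T numeric matrix; column t is the covariate vector
#'   at time t.
#' @param kernel a [KernelSpec-class], or a positive number taken as the
#'   Gaussian bandwidth.
#' @return T x T Gram matrix.
#' @export
gramMatrix <- function(features, kernel) {
  if (is.numeric(kernel) && length(kernel) == 1) kernel <- kernelSpec(kernel)
  stopifnot(is(kernel, "KernelSpec"))
  X <- as.matrix(features)
  if (any(!is.finite(X))) stop("features must be finite")
  sq <- colSums(X^2)
  D2 <- outer(sq, sq, `+`) - 2 * crossprod(X)
  D2 <- pmax(D2, 0)
  K <- exp(-D2 / (2 * kernel@sigma^2))
  diag(K) <- 1
  (K + t(K)) / 2
}
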