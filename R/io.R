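# Labeled CSV input/output and configuration handling.

#' Write a labeled numeric matrix as CSV
#'
#' 15 significant digits (so values round-trip to better than 1e-12
#' relative error); row labels in the first column, column labels in the
#' header. Identical input produces byte-identical files.
#'
#' @param m numeric matrix (dimnames used if present).
#' @param path output path.
#' @export
writeMatrixCsv <- function(m, path) {
  m <- as.matrix(m)
  rn <- rownames(m); cn <- colnames(m)
  if (is.null(rn)) rn <- paste0("r", seq_len(nrow(m)))
  if (is.null(cn)) cn <- paste0("c", seq_len(ncol(m)))
  lines <- c(paste(c("id", cn), collapse = ","),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rn[i], formatC(m[i, ], digits = 15, format = "g")),
                     collapse = ",")
             }, character(1)))
  writeLines(lines, path)
}

#' Read a labeled numeric matrix from CSV
#'
#' Inverse of [writeMatrixCsv()].
#'
#' @param path input path.
#' @return numeric matrix with dimnames.
#' @export
readMatrixCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- as.character(df[[1]])
  if (anyDuplicated(rn)) stop("duplicate row labels in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  m
}

#' Load a problem instance from a configuration
#'
#' The configuration (a YAML file path or an equivalent nested list) names
#' the input files and model settings:
#' \preformatted{
#' paths:
#'   graph: edges.csv        # edge list or .mtx
#'   features: X.csv         # rows = feature names, cols = all T times
#'   signal: Y.csv           # rows = observed node labels,
#'                           # cols = observed time labels
#' model:
#'   gamma: 1.0
#'   beta: 1.0
#'   sigma: 4.0
#'   alpha: 0.1
#'   filter: exponential
#'   normalized: false
#' }
#' The selection pattern is inferred from the Y row labels (must be a
#' subset of the graph node labels) and the Y column labels (must be a
#' subset of the feature column labels, whose order defines the time
#' axis).
#'
#' @param config YAML path or list.
#' @return list with \code{graph}, \code{features}, \code{y},
#'   \code{selection}, \code{model} (settings with defaults filled in).
#' @export
loadInputs <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  p <- config$paths
  if (is.null(p$graph) || is.null(p$features) || is.null(p$signal))
    stop("config$paths must name graph, features and signal files")
  model <- config$model
  if (is.null(model)) model <- list()
  defaults <- list(gamma = 1, beta = 1, sigma = 4, alpha = 0.1,
                   filter = "exponential", normalized = FALSE,
                   gls = TRUE, uncertainty = FALSE)
  for (nm in names(defaults))
    if (is.null(model[[nm]])) model[[nm]] <- defaults[[nm]]
  for (nm in c("gamma", "beta", "sigma", "alpha"))
    if (model[[nm]] <= 0) stop(nm, " must be positive")
  graph <- readGraph(p$graph, normalized = isTRUE(model$normalized))
  X <- readMatrixCsv(p$features)
  Y <- readMatrixCsv(p$signal)
  obsN <- match(rownames(Y), nodeNames(graph))
  if (anyNA(obsN))
    stop("unknown node label(s) in signal file: ",
         paste(rownames(Y)[is.na(obsN)], collapse = ", "))
  obsT <- match(colnames(Y), colnames(X))
  if (anyNA(obsT))
    stop("unknown time label(s) in signal file: ",
         paste(colnames(Y)[is.na(obsT)], collapse = ", "))
  ordN <- order(obsN); ordT <- order(obsT)
  Y <- Y[ordN, ordT, drop = FALSE]
  sel <- selectionPattern(sort(obsN), sort(obsT), graph@nNodes, ncol(X))
  list(graph = graph, features = unname(X), y = unname(Y),
       selection = sel, model = model,
       nodeLabels = nodeNames(graph), timeLabels = colnames(X))
}
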