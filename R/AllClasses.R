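#' @import methods
NULL

## Endpoint mark codes used throughout the package (pcalg-style amat coding):
## amat[i, j] is the mark at the j end of an edge between i and j.
## 0 = no edge, 1 = circle, 2 = arrow, 3 = tail.
MARK_NONE <- 0L
MARK_CIRCLE <- 1L
MARK_ARROW <- 2L
MARK_TAIL <- 3L

#' Mixed graph with typed endpoints
#'
#' Container for the graphs handled by the package: undirected skeletons,
#' DAGs, CPDAGs and partial ancestral graphs (PAGs). Edges carry one mark at
#' each endpoint (tail, arrow or circle); an undirected graph has all-tail
#' marks, a CPDAG uses tails and arrows only, and a PAG may use all three.
#' Nodes are typed as continuous or categorical so that edges can be scored
#' by class (CC, CD, DD).
#'
#' @slot nodes character vector of node names.
#' @slot types character vector, one of \code{"continuous"} or
#'   \code{"categorical"} per node.
#' @slot amat integer adjacency-mark matrix; \code{amat[i, j]} is the mark at
#'   the \code{j} end of an edge between \code{i} and \code{j}
#'   (0 none, 1 circle, 2 arrow, 3 tail).
#' @slot metadata list of algorithm provenance and parameters.
#'
#' @export
setClass("MixedGraph",
  representation(nodes = "character", types = "character",
                 amat = "matrix", metadata = "list"))

setValidity("MixedGraph", function(object) {
  p <- length(object@nodes)
  msg <- character(0)
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node names")
  if (length(object@types) != p)
    msg <- c(msg, "types must have one entry per node")
  if (!all(object@types %in% c("continuous", "categorical")))
    msg <- c(msg, "types must be 'continuous' or 'categorical'")
  if (!is.numeric(object@amat) || !all(dim(object@amat) == c(p, p)))
    msg <- c(msg, "amat must be a p x p numeric matrix")
  else {
    a <- object@amat
    if (!all(a %in% 0:3)) msg <- c(msg, "amat entries must be in 0:3")
    if (any(diag(a) != 0)) msg <- c(msg, "self-loops are not allowed")
    if (any((a == 0) != (t(a) == 0)))
      msg <- c(msg, "edge presence must be symmetric (marks at both ends)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MixedGraph
#'
#' @param nodes character vector of node names.
#' @param types per-node variable types (recycled if length 1).
#' @param amat optional pre-built mark matrix; defaults to the empty graph.
#' @param metadata list of provenance information.
#' @return A \linkS4class{MixedGraph}.
#' @export
MixedGraph <- function(nodes, types = "continuous", amat = NULL,
                       metadata = list()) {
  p <- length(nodes)
  types <- rep_len(types, p)
  if (is.null(amat)) {
    amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  } else {
    storage.mode(amat) <- "integer"
    dimnames(amat) <- list(nodes, nodes)
  }
  new("MixedGraph", nodes = nodes, types = types, amat = amat,
      metadata = metadata)
}

#' Data-generating DAG for the synthetic benchmark
#'
#' A \linkS4class{MixedGraph} restricted to a DAG, annotated with the number
#' of levels of each categorical node and (after parametrization) the
#' structural-equation parameters attached by the samplers.
#'
#' @slot nLevels named integer vector; number of levels per categorical node
#'   (entries for continuous nodes are \code{NA}).
#'
#' @export
setClass("TrueGraph", contains = "MixedGraph",
  representation(nLevels = "integer"))

#' Fitted empirical Bayes matrix factorization model
#'
#' State of a fitted EBMF model \eqn{Y = \sum_k l_k f_k^T + E} with
#' column-specific residual precisions \eqn{\tau_j} and point-normal priors
#' on loadings and factors estimated from the data. Loadings index samples
#' (n x K) and factors index features (p x K), following the flash
#' convention.
#'
#' @slot L posterior mean loadings, n x K.
#' @slot FF posterior mean factors, p x K.
#' @slot L2 posterior second moments of the loadings, n x K.
#' @slot F2 posterior second moments of the factors, p x K.
#' @slot gl list of fitted point-normal priors for each loading column
#'   (elements \code{pi0}, \code{s2}).
#' @slot gf list of fitted point-normal priors for each factor column.
#' @slot tau length-p vector of residual precisions.
#' @slot K number of active (nonzero) factors.
#' @slot objective numeric vector, the variational objective trace.
#'
#' @export
setClass("FactorModel",
  representation(L = "matrix", FF = "matrix", L2 = "matrix", F2 = "matrix",
                 gl = "list", gf = "list", tau = "numeric", K = "integer",
                 objective = "numeric"))

setValidity("FactorModel", function(object) {
  msg <- character(0)
  if (ncol(object@L) != ncol(object@FF))
    msg <- c(msg, "L and FF must have the same number of columns")
  if (object@K != ncol(object@L))
    msg <- c(msg, "K must equal the number of factor columns")
  if (length(object@tau) && length(object@tau) != nrow(object@FF))
    msg <- c(msg, "tau must have one precision per feature")
  if (length(msg)) msg else TRUE
})

#' PCA factor-number selection by the eigenvalue ratio test
#'
#' @slot eigenvalues decreasing eigenvalues of the centered covariance.
#' @slot kBar search cap (at most min(n, p) - 1).
#' @slot kHat selected number of components, the argmax of adjacent
#'   eigenvalue ratios.
#' @slot scores n x kHat principal component scores.
#'
#' @export
setClass("PcaSelection",
  representation(eigenvalues = "numeric", kBar = "integer", kHat = "integer",
                 scores = "matrix"))

#' Full record of one synthetic benchmark draw
#'
#' Holds the generating DAG, the sampled latent continuous factors Z and
#' categorical covariates D, the sparse loading matrix A, the observed
#' feature matrix X = Z A^T + E, and all generation parameters, so that any
#' downstream estimate can be scored against ground truth.
#'
#' @slot graph the generating \linkS4class{TrueGraph}.
#' @slot Z n x K latent factor values.
#' @slot D n x q data.frame of categorical covariates (factors).
#' @slot A p x K sparse loading matrix.
#' @slot X n x p observed feature matrix.
#' @slot noiseSd standard deviation of the observation noise E.
#' @slot regime correlation regime, \code{"LC"} or \code{"HC"}.
#' @slot model structural model, \code{"CG"} or \code{"LH"}.
#' @slot seed integer seed the draw was generated from.
#' @slot params list of every other generation parameter (coefficient
#'   ranges, level range, keep fraction, structural coefficients).
#'
#' @export
setClass("SimulationTruth",
  representation(graph = "TrueGraph", Z = "matrix", D = "data.frame",
                 A = "matrix", X = "matrix", noiseSd = "numeric",
                 regime = "character", model = "character", seed = "integer",
                 params = "list"))

#' Evaluation report for one method arm
#'
#' @slot factorRecovery list with \code{mcc}, \code{kTrue}, \code{kEst} and
#'   the injective \code{assignment} of estimated to source factors.
#' @slot edgeMetrics data.frame of adjacency/arrowhead precision and recall
#'   by edge class (rows CC, CD, DD, all).
#' @slot confounder named numeric with confounded-edge \code{ap}, \code{ar}
#'   and the fractional \code{tp}, \code{fp} tallies.
#' @slot meta list of provenance.
#'
#' @export
setClass("EvalReport",
  representation(factorRecovery = "list", edgeMetrics = "data.frame",
                 confounder = "numeric", meta = "list"))
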