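#' @include AllClasses.R
NULL

#' Node names of a graph
#' @param object a \linkS4class{MixedGraph}.
#' @return character vector of node names.
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))

#' Per-node variable types
#' @param object a \linkS4class{MixedGraph}.
#' @return character vector, \code{"continuous"} or \code{"categorical"}.
#' @export
setGeneric("nodeTypes", function(object) standardGeneric("nodeTypes"))

#' Endpoint-mark adjacency matrix
#' @param object a \linkS4class{MixedGraph}.
#' @return integer matrix; \code{amat[i, j]} is the mark at the \code{j} end
#'   (0 none, 1 circle, 2 arrow, 3 tail).
#' @export
setGeneric("markMatrix", function(object) standardGeneric("markMatrix"))

#' Edge list of a graph
#' @param object a \linkS4class{MixedGraph}.
#' @return data.frame with columns \code{from}, \code{to}, \code{markFrom},
#'   \code{markTo} (marks as \code{"tail"}, \code{"arrow"}, \code{"circle"});
#'   one row per edge with \code{from} before \code{to} in node order.
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' Number of edges
#' @param object a \linkS4class{MixedGraph}.
#' @return integer edge count.
#' @export
setGeneric("numEdges", function(object) standardGeneric("numEdges"))

#' Posterior mean loadings (samples x factors)
#' @param object a \linkS4class{FactorModel}.
#' @return numeric matrix.
#' @export
setGeneric("loadings", function(object) standardGeneric("loadings"))

#' Posterior mean factors (features x factors)
#' @param object a \linkS4class{FactorModel}.
#' @return numeric matrix.
#' @export
setGeneric("factorMatrix", function(object) standardGeneric("factorMatrix"))

#' Number of active factors
#' @param object a \linkS4class{FactorModel} or \linkS4class{PcaSelection}.
#' @return integer count.
#' @export
setGeneric("nFactors", function(object) standardGeneric("nFactors"))

setMethod("graphNodes", "MixedGraph", function(object) object@nodes)
setMethod("nodeTypes", "MixedGraph", function(object) {
  stats::setNames(object@types, object@nodes)
})
setMethod("markMatrix", "MixedGraph", function(object) object@amat)

setMethod("graphEdges", "MixedGraph", function(object) {
  a <- object@amat
  idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  nm <- object@nodes
  data.frame(from = nm[idx[, 1]], to = nm[idx[, 2]],
             markFrom = markName(a[cbind(idx[, 2], idx[, 1])]),
             markTo = markName(a[cbind(idx[, 1], idx[, 2])]),
             stringsAsFactors = FALSE)
})

setMethod("numEdges", "MixedGraph", function(object) {
  sum(object@amat[upper.tri(object@amat)] != 0L)
})

setMethod("loadings", "FactorModel", function(object) object@L)
setMethod("factorMatrix", "FactorModel", function(object) object@FF)
setMethod("nFactors", "FactorModel", function(object) object@K)
setMethod("nFactors", "PcaSelection", function(object) object@kHat)

setMethod("show", "MixedGraph", function(object) {
  kind <- object@metadata$kind
  if (is.null(kind)) kind <- "mixed graph"
  cat(sprintf("%s with %d nodes (%d continuous, %d categorical), %d edges\n",
              kind, length(object@nodes),
              sum(object@types == "continuous"),
              sum(object@types == "categorical"), numEdges(object)))
  invisible(object)
})

setMethod("show", "FactorModel", function(object) {
  cat(sprintf(
    "EBMF factor model: %d samples x %d features, K = %d active factors\n",
    nrow(object@L), nrow(object@FF), object@K))
  if (length(object@objective))
    cat(sprintf("  objective: %.6g (%d evaluations)\n",
                utils::tail(object@objective, 1), length(object@objective)))
  invisible(object)
})

setMethod("show", "PcaSelection", function(object) {
  cat(sprintf("PCA eigenvalue-ratio selection: K = %d (cap %d)\n",
              object@kHat, object@kBar))
  invisible(object)
})

setMethod("show", "SimulationTruth", function(object) {
  cat(sprintf(
    "%s-%s simulation: n = %d samples, K = %d latents, q = %d covariates, p = %d observed features\n",
    object@model, object@regime, nrow(object@Z), ncol(object@Z),
    ncol(object@D), ncol(object@X)))
  invisible(object)
})

setMethod("show", "EvalReport", function(object) {
  cat("Evaluation report\n")
  if (length(object@factorRecovery))
    cat(sprintf("  factor recovery: MCC = %.3f (k_true = %d, k_est = %d)\n",
                object@factorRecovery$mcc, object@factorRecovery$kTrue,
                object@factorRecovery$kEst))
  if (nrow(object@edgeMetrics)) {
    cat("  edge metrics:\n")
    print(object@edgeMetrics)
  }
  if (length(object@confounder))
    cat(sprintf("  confounded edges: AP = %.3f, AR = %.3f\n",
                object@confounder[["ap"]], object@confounder[["ar"]]))
  invisible(object)
})
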