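#' @include AllClasses.R graph-utils.R
NULL

#' Solve a linear sum assignment problem
#'
#' Hungarian algorithm (shortest augmenting paths with potentials),
#' minimizing total cost of an injective assignment of rows to columns.
#'
#' @param cost numeric cost matrix (any shape; the smaller dimension is
#'   fully assigned).
#' @return integer vector of length \code{nrow(cost)}; entry i is the
#'   column assigned to row i, or NA if row i is unassigned.
#' @export
solveAssignment <- function(cost) {
  n0 <- nrow(cost); m0 <- ncol(cost)
  transposed <- n0 > m0
  a <- if (transposed) t(cost) else cost
  n <- nrow(a); m <- ncol(a)
  u <- numeric(n); v <- numeric(m + 1)
  p <- integer(m + 1); way <- integer(m + 1)   # index j+1 <-> column j, 0 virtual
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- which(!used[-1])
      cur <- a[i0, free] - u[i0] - v[free + 1]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedCols <- which(used) - 1L
      for (j in usedCols) {
        if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
        v[j + 1] <- v[j + 1] - delta
      }
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  match <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1] > 0) match[p[j + 1]] <- j
  if (transposed) {
    out <- rep(NA_integer_, n0)
    out[match] <- seq_len(n)
    out
  } else match
}

#' Mean correlation coefficient between true and estimated factors
#'
#' Computes the K_est x K_true matrix of absolute Pearson correlations,
#' finds the injective assignment maximizing the total matched correlation
#' (linear sum assignment), and returns the mean of the matched absolute
#' correlations over \code{min(K_true, K_est)} pairs. Invariant to column
#' permutation, rescaling and sign flips of either argument. Constant
#' columns get correlation 0.
#'
#' @param zTrue n x K_true matrix of source factors.
#' @param zEst n x K_est matrix of estimated factors.
#' @return list with \code{mcc}, \code{assignment} (for each estimated
#'   column, the matched source column or NA), \code{kTrue}, \code{kEst},
#'   and the matched absolute correlations \code{matched}.
#' @export
matchFactorsMcc <- function(zTrue, zEst) {
  stopifnot(nrow(zTrue) == nrow(zEst))
  k1 <- ncol(zTrue); k2 <- ncol(zEst)
  stopifnot(k1 >= 1, k2 >= 1)
  C <- suppressWarnings(abs(stats::cor(zEst, zTrue)))
  C[!is.finite(C)] <- 0
  assignment <- solveAssignment(-C)          # maximize total correlation
  matched <- C[cbind(which(!is.na(assignment)),
                     assignment[!is.na(assignment)])]
  list(mcc = mean(matched), assignment = assignment,
       kTrue = k1, kEst = k2, matched = matched)
}

classPairs <- function(graph, edgeClass) {
  p <- length(graph@nodes)
  idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  if (edgeClass == "all") return(idx)
  cls <- vapply(seq_len(nrow(idx)),
                function(r) edgeClass(graph, idx[r, 1], idx[r, 2]), "")
  idx[cls == edgeClass, , drop = FALSE]
}

#' Adjacency precision and recall by edge class
#'
#' Skeleton-only comparison of an estimated graph against the generating
#' graph, restricted to pairs whose endpoint variable types form the given
#' class (CC, CD, DD, or all).
#'
#' @param trueGraph,estGraph \linkS4class{MixedGraph}s over the same nodes.
#' @param edgeClass \code{"CC"}, \code{"CD"}, \code{"DD"} or \code{"all"}.
#' @return list with \code{ap}, \code{ar} (NA when the denominator is
#'   empty), and the counts \code{correct}, \code{predicted}, \code{true}.
#' @export
adjacencyPr <- function(trueGraph, estGraph, edgeClass = "all") {
  stopifnot(identical(trueGraph@nodes, estGraph@nodes))
  at <- adjMatrix(trueGraph); ae <- adjMatrix(estGraph)
  idx <- classPairs(trueGraph, edgeClass)
  tv <- at[idx]; ev <- ae[idx]
  correct <- sum(tv & ev)
  list(ap = if (sum(ev)) correct / sum(ev) else NA_real_,
       ar = if (sum(tv)) correct / sum(tv) else NA_real_,
       correct = correct, predicted = sum(ev), true = sum(tv))
}

#' Arrowhead (orientation) precision and recall by edge class
#'
#' Scored only on edges present in both graphs. Each endpoint of a shared
#' edge contributes one outcome: an arrow endpoint is the positive class and
#' a non-arrow (tail or circle) endpoint the negative class, so a predicted
#' arrow over a true arrow is a TP, predicted arrow over true tail an FP,
#' predicted tail over true arrow an FN, and predicted tail over true tail
#' a TN.
#'
#' @inheritParams adjacencyPr
#' @return list with \code{ahp}, \code{ahr} (NA when undefined) and the
#'   endpoint tallies \code{tp}, \code{fp}, \code{fn}, \code{tn}.
#' @export
arrowheadPr <- function(trueGraph, estGraph, edgeClass = "all") {
  stopifnot(identical(trueGraph@nodes, estGraph@nodes))
  at <- trueGraph@amat; ae <- estGraph@amat
  idx <- classPairs(trueGraph, edgeClass)
  shared <- at[idx] != 0L & ae[idx] != 0L
  idx <- idx[shared, , drop = FALSE]
  tp <- fp <- fn <- tn <- 0L
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    for (end in list(c(i, j), c(j, i))) {
      ta <- at[end[1], end[2]] == MARK_ARROW
      ea <- ae[end[1], end[2]] == MARK_ARROW
      if (ea && ta) tp <- tp + 1L
      else if (ea && !ta) fp <- fp + 1L
      else if (!ea && ta) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(ahp = if (tp + fp) tp / (tp + fp) else NA_real_,
       ahr = if (tp + fn) tp / (tp + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Support of a loading matrix
#'
#' Boolean p x K support; an entry is in the support when its absolute
#' value exceeds \code{rel} times the largest absolute value in its column.
#' The default keeps entries within an order of magnitude of the column
#' maximum: posterior-mean loadings of truly unregulated features are not
#' numerically zero but carry estimation error of a few percent of the
#' column maximum, while design-scale loadings sit well above it.
#'
#' @param A p x K loading matrix.
#' @param rel relative threshold (0 keeps all nonzero entries).
#' @return logical p x K matrix.
#' @export
loadingSupport <- function(A, rel = 0.1) {
  cmax <- apply(abs(A), 2, max)
  cmax[cmax == 0] <- 1
  sweep(abs(A), 2, rel * cmax, `>`)
}

#' Expected confounded-edge adjacency implied by a loading matrix
#'
#' Two observed features are expected to be confounded when they load on a
#' common latent factor; each factor's support therefore induces a clique.
#'
#' @param A p x K loading matrix (or logical support matrix).
#' @param rel relative support threshold passed to
#'   \code{\link{loadingSupport}} when \code{A} is numeric.
#' @return symmetric logical p x p matrix with FALSE diagonal.
#' @export
expectedConfounderAdjacency <- function(A, rel = 0) {
  S <- if (is.logical(A)) A else {
    if (rel > 0) loadingSupport(A, rel) else A != 0
  }
  adj <- tcrossprod(S * 1) > 0
  diag(adj) <- FALSE
  adj
}

#' Confounded-edge precision and recall
#'
#' Scores predicted confounding against the expected confounder adjacency.
#' For a PAG, each predicted edge contributes fractional tallies by type:
#' a double-arrow edge (\code{<->}) counts as 1 TP when expected; a double
#' circle edge (\code{o-o}) as 1/3 TP + 2/3 FP when expected; a circle-arrow
#' edge (\code{o->}) as 1/2 TP + 1/2 FP when expected; any of the three is
#' 1 FP when not expected. Directed and undirected edges do not assert
#' confounding and contribute nothing. For a boolean adjacency (e.g. an
#' EBMF loading support) counting is whole-unit.
#'
#' @param predicted a \linkS4class{MixedGraph} PAG or a symmetric logical
#'   adjacency matrix.
#' @param expected symmetric logical matrix of expected confounded pairs.
#' @return list with \code{ap}, \code{ar} (NA when undefined), \code{tp},
#'   \code{fp} and \code{nExpected}.
#' @export
confoundedEdgePr <- function(predicted, expected) {
  nExpected <- sum(expected[upper.tri(expected)])
  tp <- 0; fp <- 0
  if (is(predicted, "MixedGraph")) {
    stopifnot(length(predicted@nodes) == nrow(expected))
    a <- predicted@amat
    idx <- which(upper.tri(a) & a != 0L, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      mi <- a[j, i]; mj <- a[i, j]           # marks at i and j ends
      w <- NULL
      if (mi == MARK_ARROW && mj == MARK_ARROW) w <- c(1, 0)
      else if (mi == MARK_CIRCLE && mj == MARK_CIRCLE) w <- c(1/3, 2/3)
      else if ((mi == MARK_CIRCLE && mj == MARK_ARROW) ||
               (mi == MARK_ARROW && mj == MARK_CIRCLE)) w <- c(1/2, 1/2)
      if (is.null(w)) next                   # --> or --- : no confounding claim
      if (expected[i, j]) { tp <- tp + w[1]; fp <- fp + w[2] }
      else fp <- fp + 1
    }
  } else {
    pm <- predicted
    stopifnot(all(dim(pm) == dim(expected)))
    idx <- which(upper.tri(pm) & pm, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      if (expected[idx[r, 1], idx[r, 2]]) tp <- tp + 1 else fp <- fp + 1
    }
  }
  list(ap = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       ar = if (nExpected > 0) tp / nExpected else NA_real_,
       tp = tp, fp = fp, nExpected = nExpected)
}

#' Full edge-metric table for a graph pair
#'
#' @inheritParams adjacencyPr
#' @return data.frame with one row per class (CC, CD, DD, all) and columns
#'   ap, ar, ahp, ahr.
#' @export
edgeMetricTable <- function(trueGraph, estGraph) {
  classes <- c("CC", "CD", "DD", "all")
  rows <- lapply(classes, function(cl) {
    adj <- adjacencyPr(trueGraph, estGraph, cl)
    arr <- arrowheadPr(trueGraph, estGraph, cl)
    data.frame(class = cl, ap = adj$ap, ar = adj$ar,
               ahp = arr$ahp, ahr = arr$ahr)
  })
  do.call(rbind, rows)
}
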