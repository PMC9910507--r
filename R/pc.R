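#' @include citest.R
NULL

## all subsets of size k of a candidate vector, as a list
subsetsOf <- function(cand, k) {
  if (k == 0) return(list(integer(0)))
  if (length(cand) < k) return(list())
  if (length(cand) == 1) return(list(cand))  # combn(n, k) scalar trap
  cmb <- utils::combn(cand, k)
  lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
}

## PC-stable skeleton phase: all edge removals are applied at the end of
## each depth, making the result independent of variable order. Returns the
## adjacency matrix and the first separating set found per removed pair.
pcSkeleton <- function(tester, alpha = 0.05, initAdj = NULL, maxDepth = 3L) {
  p <- length(tester$nodes)
  if (!is.null(tester$gauss)) {
    init <- if (is.null(initAdj)) matrix(TRUE, p, p) else initAdj
    diag(init) <- FALSE
    adj <- skeletonGaussCpp(tester$gauss$C, tester$gauss$n, alpha,
                            as.integer(maxDepth), init)
    return(list(adj = adj, sepsets = new.env(parent = emptyenv())))
  }
  adj <- if (is.null(initAdj)) matrix(TRUE, p, p) else initAdj
  diag(adj) <- FALSE
  sepsets <- new.env(parent = emptyenv())
  for (depth in 0:maxDepth) {
    nbrs <- lapply(seq_len(p), function(i) which(adj[i, ]))
    if (!any(lengths(nbrs) > depth)) break
    drop <- NULL
    for (x in seq_len(p - 1)) {
      for (y in seq((x + 1), p)) {
        if (y > p || !adj[x, y]) next
        gone <- FALSE
        for (side in list(c(x, y), c(y, x))) {
          if (gone) break
          cand <- setdiff(nbrs[[side[1]]], side[2])
          if (length(cand) < depth) next
          if (depth == 0 && identical(side, c(y, x))) next
          for (S in subsetsOf(cand, depth)) {
            if (tester$p(x, y, S) > alpha) {
              assign(paste(x, y, sep = "|"), S, envir = sepsets)
              gone <- TRUE
              break
            }
          }
        }
        if (gone) drop <- rbind(drop, c(x, y))
      }
    }
    if (!is.null(drop)) {
      adj[drop] <- FALSE
      adj[drop[, 2:1, drop = FALSE]] <- FALSE
    }
  }
  list(adj = adj, sepsets = sepsets)
}

## Maximum-p-value separating set for a pair, searching subsets (up to
## maxDepth) of either node's adjacency set in the given skeleton; memoized.
maxPSepset <- function(tester, adj, x, y, maxDepth, cache) {
  a <- min(x, y); b <- max(x, y)
  key <- paste(a, b, sep = "|")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  if (!is.null(tester$gauss)) {
    res <- maxPSepsetGaussCpp(tester$gauss$C, tester$gauss$n, a, b,
                              setdiff(which(adj[a, ]), b),
                              setdiff(which(adj[b, ]), a),
                              as.integer(maxDepth))
    out <- list(S = as.integer(res$sepset), p = res$p)
    cache[[key]] <- out
    return(out)
  }
  bestP <- -1; bestS <- integer(0)
  for (side in list(c(a, b), c(b, a))) {
    cand <- setdiff(which(adj[side[1], ]), side[2])
    for (depth in 0:min(maxDepth, length(cand))) {
      if (depth == 0 && identical(side, c(b, a))) next
      for (S in subsetsOf(cand, depth)) {
        pv <- tester$p(a, b, S)
        if (pv > bestP) { bestP <- pv; bestS <- S }
      }
    }
  }
  out <- list(S = bestS, p = bestP)
  cache[[key]] <- out
  out
}

## unshielded triples x - z - y (x < y) in an adjacency matrix
unshieldedTriples <- function(adj) {
  p <- nrow(adj)
  out <- NULL
  for (z in seq_len(p)) {
    nb <- which(adj[z, ])
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    for (k in seq_len(ncol(cmb))) {
      x <- cmb[1, k]; y <- cmb[2, k]
      if (!adj[x, y]) out <- rbind(out, c(x, z, y))
    }
  }
  out
}

## Meek rules R1-R3 applied to closure over an amat with tails/arrows.
## Directed i -> j means arrow at j and tail at i; an edge with arrows at
## both ends (conflict from sample noise) is left alone.
meekRules <- function(amat) {
  p <- nrow(amat)
  directed <- function(i, j) amat[i, j] == MARK_ARROW && amat[j, i] == MARK_TAIL
  undirected <- function(i, j) amat[i, j] == MARK_TAIL && amat[j, i] == MARK_TAIL
  adjacent <- function(i, j) amat[i, j] != 0L
  repeat {
    changed <- FALSE
    for (b in seq_len(p)) {
      for (cc in seq_len(p)) {
        if (b == cc || !undirected(b, cc)) next
        ## R1: a -> b - c, a and c nonadjacent => b -> c
        for (a in seq_len(p)) {
          if (a != cc && directed(a, b) && !adjacent(a, cc)) {
            amat[b, cc] <- MARK_ARROW; amat[cc, b] <- MARK_TAIL
            changed <- TRUE
            break
          }
        }
        if (!undirected(b, cc)) next
        ## R2: b -> d -> c with b - c => b -> c
        for (d in seq_len(p)) {
          if (d != b && d != cc && directed(b, d) && directed(d, cc)) {
            amat[b, cc] <- MARK_ARROW; amat[cc, b] <- MARK_TAIL
            changed <- TRUE
            break
          }
        }
        if (!undirected(b, cc)) next
        ## R3: b - c; exist nonadjacent d1, d2 with b - d1, b - d2,
        ## d1 -> c, d2 -> c => b -> c
        ds <- which(vapply(seq_len(p), function(d)
          d != b && d != cc && undirected(b, d) && directed(d, cc), TRUE))
        if (length(ds) >= 2) {
          cmb <- utils::combn(ds, 2)
          for (k in seq_len(ncol(cmb))) {
            if (!adjacent(cmb[1, k], cmb[2, k])) {
              amat[b, cc] <- MARK_ARROW; amat[cc, b] <- MARK_TAIL
              changed <- TRUE
              break
            }
          }
        }
      }
    }
    if (!changed) break
  }
  amat
}

#' PC-Max causal structure search
#'
#' PC-stable adjacency phase (edge removals applied concurrently at the end
#' of each depth) followed by collider orientation using maximum-p-value
#' separating sets - for each nonadjacent pair the conditioning set with the
#' highest test p-value decides collider membership, removing orientation
#' ambiguity - and Meek rules applied to closure. When an initial graph is
#' supplied (e.g. an MGM skeleton), the search is restricted to its
#' adjacencies.
#'
#' @param data data.frame of continuous (numeric) and categorical (factor)
#'   variables; ignored when \code{tester} is given.
#' @param alpha significance level of the CI tests.
#' @param initGraph optional undirected \linkS4class{MixedGraph} restricting
#'   the search.
#' @param maxDepth maximum conditioning set size.
#' @param tester optional tester object (e.g. from
#'   \code{\link{makeOracleTester}}) overriding \code{data}.
#' @return a CPDAG \linkS4class{MixedGraph}.
#' @export
pcMax <- function(data = NULL, alpha = 0.05, initGraph = NULL,
                  maxDepth = 3L, tester = NULL) {
  if (is.null(tester)) tester <- makeCiTester(data)
  p <- length(tester$nodes)
  initAdj <- if (!is.null(initGraph)) {
    stopifnot(identical(initGraph@nodes, tester$nodes))
    adjMatrix(initGraph)
  }
  sk <- pcSkeleton(tester, alpha, initAdj, maxDepth)
  adj <- sk$adj
  amat <- matrix(0L, p, p)
  amat[adj] <- MARK_TAIL
  mpCache <- new.env(parent = emptyenv())
  trip <- unshieldedTriples(adj)
  if (!is.null(trip)) {
    for (r in seq_len(nrow(trip))) {
      x <- trip[r, 1]; z <- trip[r, 2]; y <- trip[r, 3]
      best <- maxPSepset(tester, adj, x, y, maxDepth, mpCache)
      if (best$p > alpha && !(z %in% best$S)) {
        amat[x, z] <- MARK_ARROW
        amat[y, z] <- MARK_ARROW
      }
    }
  }
  amat <- meekRules(amat)
  MixedGraph(tester$nodes, tester$types, amat = amat,
             metadata = list(kind = "CPDAG", algorithm = "pcMax",
                             alpha = alpha, maxDepth = maxDepth))
}
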