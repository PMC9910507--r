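#' @include pc.R
NULL

## possible-d-sep set of node x: v is reachable from x along a path on
## which every interior vertex t (in subpath <s, t, u>) is either a
## collider (arrows at t from both sides) or part of a triangle (s and u
## adjacent).
possibleDsep <- function(amat, x) {
  p <- nrow(amat)
  adj <- amat != 0L
  reached <- matrix(FALSE, p, p)   # reached[s, t]: arrived at t from s
  queue <- lapply(which(adj[x, ]), function(v) c(x, v))
  for (q in queue) reached[q[1], q[2]] <- TRUE
  out <- rep(FALSE, p)
  while (length(queue)) {
    e <- queue[[1]]; queue <- queue[-1]
    s <- e[1]; t <- e[2]
    out[t] <- TRUE
    for (u in which(adj[t, ])) {
      if (u == s || reached[t, u]) next
      collider <- amat[s, t] == MARK_ARROW && amat[u, t] == MARK_ARROW
      triangle <- adj[s, u]
      if (collider || triangle) {
        reached[t, u] <- TRUE
        queue[[length(queue) + 1]] <- c(t, u)
      }
    }
  }
  out[x] <- FALSE
  which(out)
}

## orient unshielded colliders on a circle-marked amat given a sepset
## lookup function
orientCollidersPag <- function(amat, adj, sepsetFun) {
  trip <- unshieldedTriples(adj)
  if (!is.null(trip)) {
    for (r in seq_len(nrow(trip))) {
      x <- trip[r, 1]; z <- trip[r, 2]; y <- trip[r, 3]
      S <- sepsetFun(x, y)
      if (!is.null(S) && !(z %in% S)) {
        amat[x, z] <- MARK_ARROW
        amat[y, z] <- MARK_ARROW
      }
    }
  }
  amat
}

## FCI orientation rules R1-R4 applied to closure; loops run over
## adjacency lists so each pass is cheap on sparse graphs
fciRules <- function(amat, sepsetFun, maxPathLen = 10L) {
  p <- nrow(amat)
  repeat {
    changed <- FALSE
    nbr <- lapply(seq_len(p), function(i) which(amat[i, ] != 0L))
    for (b in seq_len(p)) {
      for (cc in nbr[[b]]) {
        ## R1: a *-> b o-* c, a and c nonadjacent => b -> c
        if (amat[cc, b] == MARK_CIRCLE) {
          for (a in nbr[[b]]) {
            if (a == cc) next
            if (amat[a, b] == MARK_ARROW && amat[a, cc] == 0L) {
              amat[b, cc] <- MARK_ARROW
              amat[cc, b] <- MARK_TAIL
              changed <- TRUE
              break
            }
          }
        }
        ## R2: b -> d *-> c or b *-> d -> c, with b *-o c => b *-> c
        if (amat[b, cc] == MARK_CIRCLE) {
          for (d in nbr[[b]]) {
            if (d == cc || amat[d, cc] == 0L) next
            chain1 <- amat[b, d] == MARK_ARROW && amat[d, b] == MARK_TAIL &&
              amat[d, cc] == MARK_ARROW
            chain2 <- amat[b, d] == MARK_ARROW &&
              amat[d, cc] == MARK_ARROW && amat[cc, d] == MARK_TAIL
            if (chain1 || chain2) {
              amat[b, cc] <- MARK_ARROW
              changed <- TRUE
              break
            }
          }
        }
      }
    }
    ## R3: a *-> b <-* c, a *-o d o-* c, a and c nonadjacent, d *-o b
    ##     => d *-> b  (loop over the collider node b and circle node d)
    for (b in seq_len(p)) {
      arrowsIn <- nbr[[b]][amat[nbr[[b]], b] == MARK_ARROW]
      if (length(arrowsIn) < 2) next
      for (d in nbr[[b]]) {
        if (amat[d, b] != MARK_CIRCLE) next
        cand <- arrowsIn[arrowsIn != d & amat[arrowsIn, d] == MARK_CIRCLE &
                           amat[d, arrowsIn] != 0L]
        if (length(cand) < 2) next
        pairs <- utils::combn(cand, 2)
        for (k in seq_len(ncol(pairs))) {
          if (amat[pairs[1, k], pairs[2, k]] == 0L) {
            amat[d, b] <- MARK_ARROW
            changed <- TRUE
            break
          }
        }
      }
    }
    ## R4: discriminating paths
    r4 <- applyR4(amat, sepsetFun, maxPathLen)
    if (r4$changed) { amat <- r4$amat; changed <- TRUE }
    if (!changed) break
  }
  amat
}

## R4: for each triple a *-> b o-* c with a -> c, search backwards for a
## discriminating path <d, ..., a, b, c>; interior vertices are colliders
## on the path and parents of c, d not adjacent to c.
applyR4 <- function(amat, sepsetFun, maxPathLen) {
  p <- nrow(amat)
  adjacent <- function(i, j) amat[i, j] != 0L
  changed <- FALSE
  for (b in seq_len(p)) {
    for (cc in seq_len(p)) {
      if (b == cc || !adjacent(b, cc) || amat[cc, b] != MARK_CIRCLE) next
      for (a in seq_len(p)) {
        if (a == b || a == cc) next
        if (!adjacent(a, b) || !adjacent(a, cc)) next
        ## a must be a collider on the path (arrows at a and b on edge a-b)
        ## and a parent of c
        if (amat[a, b] != MARK_ARROW || amat[b, a] != MARK_ARROW) next
        if (!(amat[a, cc] == MARK_ARROW && amat[cc, a] == MARK_TAIL)) next
        ## BFS backwards from a for the path origin d
        found <- NULL
        visited <- rep(FALSE, p); visited[c(a, b, cc)] <- TRUE
        frontier <- a
        len <- 0L
        while (length(frontier) && is.null(found) && len < maxPathLen) {
          len <- len + 1L
          nxt <- integer(0)
          for (r in frontier) {
            for (t in which(amat[, r] != 0L)) {
              if (visited[t] || t == r) next
              if (amat[t, r] != MARK_ARROW) next   # need t *-> r
              if (!adjacent(t, cc)) { found <- t; break }
              ## continue only through colliders that are parents of c
              if (amat[r, t] == MARK_ARROW &&
                  amat[t, cc] == MARK_ARROW && amat[cc, t] == MARK_TAIL) {
                visited[t] <- TRUE
                nxt <- c(nxt, t)
              }
            }
            if (!is.null(found)) break
          }
          frontier <- nxt
        }
        if (!is.null(found)) {
          S <- sepsetFun(found, cc)
          if (!is.null(S) && b %in% S) {
            amat[b, cc] <- MARK_ARROW
            amat[cc, b] <- MARK_TAIL
          } else {
            amat[a, b] <- MARK_ARROW; amat[b, a] <- MARK_ARROW
            amat[b, cc] <- MARK_ARROW; amat[cc, b] <- MARK_ARROW
          }
          changed <- TRUE
          break
        }
      }
    }
  }
  list(amat = amat, changed = changed)
}

#' FCI causal structure search
#'
#' Learns a partial ancestral graph (PAG) allowing for latent confounders:
#' PC-stable adjacency phase, possible-d-separation pruning, endpoints reset
#' to circles, collider orientation from separating sets, and orientation
#' rules R1-R4 applied to closure. Output edges are of types \code{-->},
#' \code{<->}, \code{o->} and \code{o-o} (plus \code{---} when both tails
#' are implied).
#'
#' @inheritParams pcMax
#' @param maxPOrientation use maximum-p-value separating sets for collider
#'   decisions (the FCI-Max variant) instead of the first separating set
#'   found during edge removal.
#' @param pdsepMax cap on the size of possible-d-sep conditioning sets
#'   (defaults to \code{maxDepth}).
#' @param pdsepCand cap on the number of possible-d-sep candidate nodes
#'   searched per edge (ranked by marginal association with the edge's
#'   first endpoint).
#' @return a PAG \linkS4class{MixedGraph}.
#' @export
fci <- function(data = NULL, alpha = 0.05, initGraph = NULL, maxDepth = 3L,
                maxPOrientation = FALSE, pdsepMax = NULL, pdsepCand = 10L,
                tester = NULL) {
  if (is.null(tester)) tester <- makeCiTester(data)
  if (is.null(pdsepMax)) pdsepMax <- maxDepth
  p <- length(tester$nodes)
  initAdj <- if (!is.null(initGraph)) {
    stopifnot(identical(initGraph@nodes, tester$nodes))
    adjMatrix(initGraph)
  }
  sk <- pcSkeleton(tester, alpha, initAdj, maxDepth)
  adj <- sk$adj
  sepsets <- sk$sepsets
  mpCache <- new.env(parent = emptyenv())
  ## direct (un-memoized) test for the high-volume pdsep stage: on the
  ## Gaussian fast path each subset is tested at most once anyway and the
  ## memo-key construction dominates the cost
  ptest <- if (!is.null(tester$gauss))
    function(x, y, S) ciGaussCpp(tester$gauss$C, tester$gauss$n,
                                 min(x, y), max(x, y), as.integer(S))
  else tester$p
  getSepset <- function(x, y) {
    a <- min(x, y); b <- max(x, y)
    if (maxPOrientation) {
      best <- maxPSepset(tester, adj, a, b, maxDepth, mpCache)
      if (best$p > alpha) return(best$S)
      return(NULL)
    }
    S <- sepsets[[paste(a, b, sep = "|")]]
    if (!is.null(S)) return(S)
    best <- maxPSepset(tester, adj, a, b, maxDepth, mpCache)
    if (best$p > alpha) best$S else NULL
  }
  ## provisional collider orientation to define possible-d-sep sets
  amat0 <- matrix(0L, p, p)
  amat0[adj] <- MARK_CIRCLE
  amat0 <- orientCollidersPag(amat0, adj, getSepset)
  ## possible-d-sep pruning; candidate sets are capped (strongest marginal
  ## association with x first) to keep the subset search tractable
  for (x in seq_len(p)) {
    pds <- possibleDsep(amat0, x)
    for (y in which(adj[x, ])) {
      if (!adj[x, y]) next
      cand <- setdiff(pds, y)
      if (length(cand) > pdsepCand) {
        p0 <- vapply(cand, function(v) ptest(x, v, integer(0)), 0)
        cand <- cand[order(p0)][seq_len(pdsepCand)]
      }
      removedEdge <- FALSE
      for (depth in seq_len(min(pdsepMax, length(cand)))) {
        for (S in subsetsOf(cand, depth)) {
          if (ptest(x, y, S) > alpha) {
            adj[x, y] <- FALSE; adj[y, x] <- FALSE
            assign(paste(min(x, y), max(x, y), sep = "|"), S,
                   envir = sepsets)
            removedEdge <- TRUE
            break
          }
        }
        if (removedEdge) break
      }
    }
  }
  ## final orientation on the pruned skeleton
  mpCache <- new.env(parent = emptyenv())
  amat <- matrix(0L, p, p)
  amat[adj] <- MARK_CIRCLE
  amat <- orientCollidersPag(amat, adj, getSepset)
  amat <- fciRules(amat, getSepset)
  MixedGraph(tester$nodes, tester$types, amat = amat,
             metadata = list(kind = "PAG", algorithm = "fci", alpha = alpha,
                             maxDepth = maxDepth,
                             maxPOrientation = maxPOrientation))
}
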