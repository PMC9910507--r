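## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths (different algorithms, or igraph) so that
## agreement is informative.

## DAG (mark matrix, 2 = arrow at column end, 3 = tail) -> CPDAG by
## v-structure detection plus Meek closure, edge-list style.
oracleCpdag <- function(amatDag) {
  p <- nrow(amatDag)
  dir <- matrix(FALSE, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    if (amatDag[i, j] == 2 && amatDag[j, i] == 3) dir[i, j] <- TRUE
  adj <- dir | t(dir)
  oriented <- matrix(FALSE, p, p)
  for (z in seq_len(p)) {
    pa <- which(dir[, z])
    if (length(pa) >= 2) for (a in pa) for (b in pa)
      if (a < b && !adj[a, b]) { oriented[a, z] <- TRUE; oriented[b, z] <- TRUE }
  }
  repeat {
    ch <- FALSE
    und <- function(i, j) adj[i, j] && !oriented[i, j] && !oriented[j, i]
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (!und(i, j)) next
      for (k in seq_len(p))
        if (k != j && oriented[k, i] && !adj[k, j]) {
          oriented[i, j] <- TRUE; ch <- TRUE; break
        }
      if (!und(i, j)) next
      for (k in seq_len(p))
        if (k != i && k != j && oriented[i, k] && oriented[k, j]) {
          oriented[i, j] <- TRUE; ch <- TRUE; break
        }
      if (!und(i, j)) next
      ks <- which(vapply(seq_len(p), function(k)
        k != i && k != j && und(i, k) && oriented[k, j], TRUE))
      if (length(ks) >= 2) for (a in ks) for (b in ks)
        if (a < b && !adj[a, b]) { oriented[i, j] <- TRUE; ch <- TRUE; break }
    }
    if (!ch) break
  }
  out <- matrix(0L, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) if (adj[i, j]) {
    if (oriented[i, j]) { out[i, j] <- 2L; out[j, i] <- 3L }
    else if (!oriented[j, i]) { out[i, j] <- 3L; out[j, i] <- 3L }
  }
  out
}

## exhaustive-permutation assignment maximum for small K
bruteAssignmentMax <- function(C) {
  k1 <- nrow(C); k2 <- ncol(C)
  k <- min(k1, k2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- -Inf
  if (k1 <= k2) {
    for (pm in perms(seq_len(k2))) {
      s <- sum(C[cbind(seq_len(k1), pm[seq_len(k1)])])
      best <- max(best, s)
    }
  } else {
    for (pm in perms(seq_len(k1))) {
      s <- sum(C[cbind(pm[seq_len(k2)], seq_len(k2))])
      best <- max(best, s)
    }
  }
  best
}

## brute-force pairwise adjacency tallies
bruteAdjacency <- function(trueG, estG, class) {
  at <- markMatrix(trueG); ae <- markMatrix(estG)
  ty <- nodeTypes(trueG)
  p <- length(ty)
  correct <- predicted <- trueCount <- 0
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    ncont <- sum(ty[c(i, j)] == "continuous")
    cl <- c("DD", "CD", "CC")[ncont + 1]
    if (class != "all" && cl != class) next
    tv <- at[i, j] != 0; ev <- ae[i, j] != 0
    if (tv) trueCount <- trueCount + 1
    if (ev) predicted <- predicted + 1
    if (tv && ev) correct <- correct + 1
  }
  list(ap = if (predicted) correct / predicted else NA_real_,
       ar = if (trueCount) correct / trueCount else NA_real_)
}

## brute-force endpoint enumeration for arrowhead scoring
bruteArrowhead <- function(trueG, estG, class) {
  at <- markMatrix(trueG); ae <- markMatrix(estG)
  ty <- nodeTypes(trueG)
  p <- length(ty)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    ncont <- sum(ty[c(i, j)] == "continuous")
    cl <- c("DD", "CD", "CC")[ncont + 1]
    if (class != "all" && cl != class) next
    if (at[i, j] == 0 || ae[i, j] == 0) next
    for (pr in list(c(i, j), c(j, i))) {
      ta <- at[pr[1], pr[2]] == 2
      ea <- ae[pr[1], pr[2]] == 2
      if (ea && ta) tp <- tp + 1
      if (ea && !ta) fp <- fp + 1
      if (!ea && ta) fn <- fn + 1
      if (!ea && !ta) tn <- tn + 1
    }
  }
  list(ahp = if (tp + fp) tp / (tp + fp) else NA_real_,
       ahr = if (tp + fn) tp / (tp + fn) else NA_real_)
}

## d-separation via igraph: moralize the ancestral subgraph, delete S,
## test connectivity
igraphDsep <- function(graph, x, y, S) {
  am <- markMatrix(graph)
  p <- nrow(am)
  dir <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    if (am[i, j] == 2 && am[j, i] == 3) dir[i, j] <- 1
  g <- igraph::graph_from_adjacency_matrix(dir, mode = "directed")
  nodes <- unique(c(x, y, S))
  anc <- unique(unlist(lapply(nodes, function(v)
    igraph::subcomponent(g, v, mode = "in"))))
  sub <- dir[anc, anc, drop = FALSE]
  q <- length(anc)
  mor <- sub + t(sub)
  for (j in seq_len(q)) {
    pa <- which(sub[, j] > 0)
    if (length(pa) > 1) for (a in pa) for (b in pa) if (a != b)
      mor[a, b] <- 1
  }
  keep <- !(anc %in% S)
  mor <- mor[keep, keep, drop = FALSE]
  ids <- anc[keep]
  gm <- igraph::graph_from_adjacency_matrix(mor > 0, mode = "undirected")
  xi <- match(x, ids); yi <- match(y, ids)
  is.infinite(igraph::distances(gm, v = xi, to = yi)[1, 1])
}

## random mark matrix over a random skeleton (tails/arrows), for scoring
## tests; not necessarily a valid CPDAG, which the metrics do not require
randomMarkGraph <- function(p, prob, seed) {
  set.seed(seed)
  am <- matrix(0L, p, p)
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    if (runif(1) < prob) {
      marks <- sample(c(2L, 3L), 2, replace = TRUE)
      am[i, j] <- marks[1]; am[j, i] <- marks[2]
    }
  }
  am
}

## small planted factor model: K sparse feature factors, dense loadings
plantedFactorData <- function(n, p, K, seed, noise = 1, corFactors = FALSE) {
  set.seed(seed)
  L <- matrix(rnorm(n * K, sd = 2), n, K)
  if (corFactors && K >= 2)
    for (k in 2:K) L[, k] <- 0.6 * L[, k - 1] + 0.8 * L[, k]
  FF <- matrix(0, p, K)
  for (k in seq_len(K)) FF[sample(p, max(5, round(p / (2 * K)))), k] <-
    rnorm(max(5, round(p / (2 * K))), sd = 1.5)
  list(Y = tcrossprod(L, FF) + matrix(rnorm(n * p, sd = noise), n, p),
       L = L, FF = FF)
}

## skeleton view of a graph (all marks to tails)
skeletonFrom <- function(g) {
  am <- markMatrix(g)
  am[am != 0L] <- 3L
  MixedGraph(g@nodes, unname(nodeTypes(g)), amat = am)
}

## reorder a graph's nodes to a reference order
reorderGraph <- function(g, nodes) {
  idx <- match(nodes, g@nodes)
  MixedGraph(g@nodes[idx], unname(nodeTypes(g))[idx],
             amat = markMatrix(g)[idx, idx])
}
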