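#' @include pc.R fci.R mgm.R
NULL

#' StARS stability selection of the CI-test significance level
#'
#' Runs the search on subsamples over a grid of alpha values, measures
#' edge-appearance instability 2 theta (1 - theta) averaged over node
#' pairs, monotonizes it from the sparse end, and selects the densest
#' (largest) alpha whose instability stays at or below the threshold; the
#' final graph is a full-data run at the selected alpha.
#'
#' @param data mixed data.frame.
#' @param alphaGrid ascending (sparse to dense) significance levels.
#' @param initGraph optional undirected restriction graph (e.g. an MGM
#'   skeleton) passed to every run.
#' @param nSubsamples number of subsamples.
#' @param subsampleSize rows per subsample (default
#'   \code{floor(10*sqrt(n))}, capped at n - 1).
#' @param threshold instability threshold.
#' @param seed integer seed.
#' @param algorithm \code{"pcmax"} or \code{"fci"}.
#' @param maxDepth maximum conditioning set size.
#' @return list with \code{alpha}, the final \code{graph}, and the
#'   \code{instability} per grid value.
#' @export
starsSelect <- function(data, alphaGrid = c(0.001, 0.01, 0.05, 0.1),
                        initGraph = NULL, nSubsamples = 20L,
                        subsampleSize = NULL, threshold = 0.05, seed = 1L,
                        algorithm = c("pcmax", "fci"), maxDepth = 3L) {
  algorithm <- match.arg(algorithm)
  runner <- function(d, alpha, init, tester = NULL) {
    if (algorithm == "pcmax")
      pcMax(d, alpha = alpha, initGraph = init, maxDepth = maxDepth,
            tester = tester)
    else fci(d, alpha = alpha, initGraph = init, maxDepth = maxDepth,
             tester = tester)
  }
  n <- nrow(data)
  if (is.null(subsampleSize))
    subsampleSize <- min(floor(10 * sqrt(n)), n - 1)
  alphaGrid <- sort(alphaGrid)
  p <- ncol(data)
  counts <- array(0, dim = c(p, p, length(alphaGrid)))
  subs <- withSeed(seed, lapply(seq_len(nSubsamples), function(i)
    sample.int(n, subsampleSize)))
  for (b in seq_len(nSubsamples)) {
    d <- data[subs[[b]], , drop = FALSE]
    tester <- makeCiTester(d)   # shared cache across the alpha grid
    for (i in seq_along(alphaGrid)) {
      g <- runner(d, alphaGrid[i], initGraph, tester)
      counts[, , i] <- counts[, , i] + adjMatrix(g)
    }
  }
  up <- upper.tri(matrix(0, p, p))
  instab <- vapply(seq_along(alphaGrid), function(i) {
    theta <- counts[, , i] / nSubsamples
    mean((2 * theta * (1 - theta))[up])
  }, 0)
  mono <- cummax(instab)
  ok <- which(mono <= threshold)
  alpha <- if (length(ok)) alphaGrid[max(ok)] else {
    warning("no alpha meets the instability threshold; using the sparsest")
    alphaGrid[1]
  }
  graph <- runner(data, alpha, initGraph)
  list(alpha = alpha, graph = graph, instability = instab,
       alphaGrid = alphaGrid)
}

#' Bootstrap ensemble of a structure-search algorithm
#'
#' Runs the algorithm on B bootstrap resamples (rows drawn with
#' replacement), keeps edges whose appearance frequency exceeds the
#' threshold, and assigns each kept edge its most frequent endpoint-mark
#' pattern (ties broken by lexicographic endpoint-pattern order).
#'
#' @param data mixed data.frame.
#' @param algorithm function \code{data -> MixedGraph}.
#' @param B number of bootstrap resamples (at least 2).
#' @param keepThreshold minimum appearance frequency (exclusive) for an
#'   edge to be kept.
#' @param seed integer seed.
#' @return a \linkS4class{MixedGraph} with edge frequencies in
#'   \code{metadata$frequency}.
#' @export
bootstrapEnsemble <- function(data, algorithm, B = 100L,
                              keepThreshold = 0.5, seed = 1L) {
  if (B < 2) stop("B must be at least 2")
  n <- nrow(data)
  draws <- withSeed(seed, lapply(seq_len(B), function(b)
    sample.int(n, n, replace = TRUE)))
  ref <- algorithm(data[draws[[1]], , drop = FALSE])
  p <- length(ref@nodes)
  freq <- matrix(0, p, p)
  patterns <- new.env(parent = emptyenv())
  tally <- function(g) {
    a <- g@amat
    idx <- which(upper.tri(a) & a != 0L, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      freq[i, j] <<- freq[i, j] + 1
      key <- paste(i, j, sep = "|")
      pat <- paste(markName(a[j, i]), markName(a[i, j]), sep = "*")
      tab <- patterns[[key]]
      if (is.null(tab)) tab <- integer(0)
      tab[pat] <- if (is.na(tab[pat])) 1L else tab[pat] + 1L
      patterns[[key]] <- tab
    }
  }
  tally(ref)
  for (b in 2:B) tally(algorithm(data[draws[[b]], , drop = FALSE]))
  freq <- freq / B
  amat <- matrix(0L, p, p)
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      if (freq[i, j] <= keepThreshold) next
      tab <- patterns[[paste(i, j, sep = "|")]]
      best <- sort(names(tab)[tab == max(tab)])[1]   # lexicographic tie-break
      mk <- strsplit(best, "*", fixed = TRUE)[[1]]
      amat[j, i] <- markCode(mk[1])   # mark at i
      amat[i, j] <- markCode(mk[2])   # mark at j
    }
  }
  MixedGraph(ref@nodes, ref@types, amat = amat,
             metadata = list(kind = "bootstrap ensemble", B = B,
                             keepThreshold = keepThreshold,
                             frequency = freq))
}
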