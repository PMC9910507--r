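#' @include AllClasses.R
NULL

markName <- function(code) {
  c("none", "circle", "arrow", "tail")[code + 1L]
}

markCode <- function(name) {
  m <- c(none = 0L, circle = 1L, arrow = 2L, tail = 3L)
  unname(m[name])
}

#' Set or remove an edge in a MixedGraph
#'
#' @param graph a \linkS4class{MixedGraph}.
#' @param from,to node names or indices.
#' @param markFrom,markTo endpoint marks at the \code{from} / \code{to} end
#'   (\code{"tail"}, \code{"arrow"}, \code{"circle"}); a directed edge
#'   \code{from -> to} is \code{markFrom = "tail", markTo = "arrow"}.
#' @return the updated graph.
#' @export
setEdge <- function(graph, from, to, markFrom = "tail", markTo = "arrow") {
  i <- nodeIndex(graph, from); j <- nodeIndex(graph, to)
  stopifnot(i != j)
  graph@amat[i, j] <- markCode(markTo)
  graph@amat[j, i] <- markCode(markFrom)
  graph
}

removeEdge <- function(graph, from, to) {
  i <- nodeIndex(graph, from); j <- nodeIndex(graph, to)
  graph@amat[i, j] <- 0L
  graph@amat[j, i] <- 0L
  graph
}

nodeIndex <- function(graph, x) {
  if (is.character(x)) match(x, graph@nodes) else as.integer(x)
}

## adjacency as a logical matrix (any mark)
adjMatrix <- function(graph) graph@amat != 0L

#' Edge class of a node pair
#'
#' CC for continuous-continuous, CD for mixed, DD for
#' categorical-categorical.
#' @param graph a \linkS4class{MixedGraph}.
#' @param i,j node names or indices.
#' @return \code{"CC"}, \code{"CD"} or \code{"DD"}.
#' @export
edgeClass <- function(graph, i, j) {
  ti <- graph@types[nodeIndex(graph, i)]
  tj <- graph@types[nodeIndex(graph, j)]
  ncont <- (ti == "continuous") + (tj == "continuous")
  c("DD", "CD", "CC")[ncont + 1L]
}

## parents/children for DAG-marked graphs (tail at parent, arrow at child)
dagParents <- function(graph, j) {
  j <- nodeIndex(graph, j)
  which(graph@amat[, j] == MARK_ARROW & graph@amat[j, ] == MARK_TAIL)
}

dagChildren <- function(graph, i) {
  i <- nodeIndex(graph, i)
  which(graph@amat[i, ] == MARK_ARROW & graph@amat[, i] == MARK_TAIL)
}

#' Test a graph for acyclicity of its directed part
#'
#' Kahn-style topological sort over the directed (tail-arrow) edges;
#' undirected or circle-marked edges are ignored.
#' @param graph a \linkS4class{MixedGraph}.
#' @return TRUE if the directed subgraph is acyclic.
#' @export
isAcyclic <- function(graph) {
  p <- length(graph@nodes)
  dir <- matrix(FALSE, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    if (graph@amat[i, j] == MARK_ARROW && graph@amat[j, i] == MARK_TAIL)
      dir[i, j] <- TRUE
  indeg <- colSums(dir)
  active <- rep(TRUE, p)
  repeat {
    src <- which(active & indeg == 0)
    if (!length(src)) break
    for (s in src) {
      active[s] <- FALSE
      indeg[dir[s, ]] <- indeg[dir[s, ]] - 1L
      dir[s, ] <- FALSE
    }
  }
  !any(active)
}

#' Moralized graph of a DAG
#'
#' Connects every node to its parents and marries co-parents, yielding the
#' undirected Markov-network structure of the DAG distribution.
#' @param graph a DAG-marked \linkS4class{TrueGraph} or
#'   \linkS4class{MixedGraph}.
#' @return an undirected \linkS4class{MixedGraph}.
#' @export
moralize <- function(graph) {
  p <- length(graph@nodes)
  m <- matrix(0L, p, p, dimnames = dimnames(graph@amat))
  m[adjMatrix(graph)] <- MARK_TAIL
  for (j in seq_len(p)) {
    pa <- dagParents(graph, j)
    if (length(pa) > 1) {
      cmb <- utils::combn(pa, 2)
      for (k in seq_len(ncol(cmb))) {
        m[cmb[1, k], cmb[2, k]] <- MARK_TAIL
        m[cmb[2, k], cmb[1, k]] <- MARK_TAIL
      }
    }
  }
  MixedGraph(graph@nodes, graph@types, amat = m,
             metadata = list(kind = "moralized graph"))
}

edgeString <- function(markFrom, markTo) {
  left <- c(tail = "-", arrow = "<", circle = "o")[markFrom]
  right <- c(tail = "-", arrow = ">", circle = "o")[markTo]
  paste0(left, "-", right)
}

#' Write a graph as an edge-list text file
#'
#' One edge per line in the form \code{A --> B}, \code{A <-> B},
#' \code{A o-> B}, \code{A o-o B} or \code{A --- B}; isolated nodes are
#' listed in a header line so the node set round-trips.
#' @param graph a \linkS4class{MixedGraph}.
#' @param path output file path.
#' @export
writeGraphTxt <- function(graph, path) {
  e <- graphEdges(graph)
  hdr <- c(paste("#nodes:", paste(graph@nodes, collapse = " ")),
           paste("#types:", paste(graph@types, collapse = " ")))
  lines <- if (nrow(e))
    paste(e$from, edgeString(e$markFrom, e$markTo), e$to) else character(0)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a graph from edge-list text
#' @param path file written by \code{\link{writeGraphTxt}}.
#' @return a \linkS4class{MixedGraph}.
#' @export
readGraphTxt <- function(path) {
  lines <- readLines(path)
  nodeLine <- grep("^#nodes:", lines, value = TRUE)
  typeLine <- grep("^#types:", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "[[:space:]]+")
  nodes <- if (length(nodeLine))
    strsplit(sub("^#nodes:\\s*", "", nodeLine[1]), " ")[[1]]
  else unique(unlist(lapply(parts, function(x) x[c(1, 3)])))
  types <- if (length(typeLine))
    strsplit(sub("^#types:\\s*", "", typeLine[1]), " ")[[1]]
  else rep("continuous", length(nodes))
  g <- MixedGraph(nodes, types)
  for (prt in parts) {
    stopifnot(length(prt) == 3)
    sym <- prt[2]
    left <- substr(sym, 1, 1); right <- substr(sym, 3, 3)
    mf <- c("-" = "tail", "<" = "arrow", "o" = "circle")[left]
    mt <- c("-" = "tail", ">" = "arrow", "o" = "circle")[right]
    g <- setEdge(g, prt[1], prt[3], mf, mt)
  }
  g
}

## undirected skeleton (all marks -> tail)
skeletonOf <- function(graph) {
  a <- graph@amat
  a[a != 0L] <- MARK_TAIL
  MixedGraph(graph@nodes, graph@types, amat = a,
             metadata = list(kind = "skeleton"))
}
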