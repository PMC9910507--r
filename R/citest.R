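#' @include AllClasses.R graph-utils.R
#' @useDynLib latentcausal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

varTypes <- function(data) {
  vapply(data, function(col)
    if (is.factor(col) || is.character(col)) "categorical" else "continuous",
    "")
}

## design matrix for a set of conditioning variables: intercept +
## continuous columns + reference-coded dummies (unused levels dropped)
buildDesign <- function(data, vars) {
  n <- nrow(data)
  M <- matrix(1, n, 1)
  for (v in vars) {
    col <- data[[v]]
    if (is.factor(col) || is.character(col)) {
      f <- droplevels(factor(col))
      if (nlevels(f) >= 2)
        M <- cbind(M, stats::model.matrix(~f)[, -1, drop = FALSE])
    } else {
      M <- cbind(M, as.numeric(col))
    }
  }
  M
}

gaussLoglik <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  rank <- fit$rank
  rss <- sum(fit$residuals^2)
  n <- length(y)
  list(ll = -n / 2 * (log(2 * pi * max(rss, 1e-300) / n) + 1), rank = rank)
}

multinomLoglik <- function(y, X) {
  f <- droplevels(factor(y))
  K <- nlevels(f)
  if (K < 2) return(list(ll = 0, rank = qr(X)$rank, K = K))
  qrX <- qr(X)
  Xr <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  ll <- mnLoglikCpp(Xr, as.integer(f) - 1L, K)
  list(ll = ll, rank = qrX$rank, K = K)
}

#' Conditional independence test for mixed data
#'
#' Tests x independent of y given S. When x, y and all of S are continuous
#' this is the Fisher-z test of the partial correlation. With any
#' categorical involvement a nested-model likelihood-ratio test is used:
#' the outcome (the categorical variable of the pair when exactly one is
#' categorical, otherwise the pair member later in column order, which makes
#' the test symmetric in its arguments) is regressed on S and on S plus the
#' other variable - by linear regression for a continuous outcome and
#' multinomial logistic regression for a categorical one - and twice the
#' log-likelihood gain is referred to a chi-square with the number of added
#' parameters as degrees of freedom.
#'
#' @param data data.frame; factor columns are categorical.
#' @param x,y column names or indices of the tested pair.
#' @param S conditioning set (names or indices; possibly empty).
#' @return list with \code{p}, \code{statistic}, \code{df} and a
#'   \code{degenerate} flag (singular design or absent contrast; the test
#'   then conservatively reports p = 1).
#' @export
ciTest <- function(data, x, y, S = character(0)) {
  nm <- names(data)
  xi <- if (is.character(x)) match(x, nm) else as.integer(x)
  yi <- if (is.character(y)) match(y, nm) else as.integer(y)
  Si <- if (is.character(S)) match(S, nm) else as.integer(S)
  stopifnot(xi != yi, !(xi %in% Si), !(yi %in% Si))
  types <- varTypes(data)
  ## all-continuous: Fisher-z partial correlation
  if (all(types[c(xi, yi, Si)] == "continuous")) {
    sub <- as.matrix(data[, c(xi, yi, Si), drop = FALSE])
    C <- suppressWarnings(stats::cor(sub))
    if (any(!is.finite(C)))
      return(list(p = 1, statistic = 0, df = 1L, degenerate = TRUE))
    p <- ciGaussCpp(C, nrow(sub), 1L, 2L,
                    if (length(Si)) as.integer(seq_along(Si) + 2L)
                    else integer(0))
    return(list(p = p, statistic = NA_real_, df = 1L, degenerate = FALSE))
  }
  ## likelihood-ratio construction; canonical outcome choice keeps the test
  ## symmetric in (x, y)
  cat_x <- types[xi] == "categorical"; cat_y <- types[yi] == "categorical"
  if (cat_x != cat_y) {
    out <- if (cat_x) xi else yi
  } else {
    out <- max(xi, yi)
  }
  oth <- if (out == xi) yi else xi
  X0 <- buildDesign(data, nm[Si])
  X1 <- cbind(X0, buildDesign(data, nm[oth])[, -1, drop = FALSE])
  if (types[out] == "continuous") {
    yv <- as.numeric(data[[out]])
    f0 <- gaussLoglik(yv, X0); f1 <- gaussLoglik(yv, X1)
    df <- f1$rank - f0$rank
    stat <- 2 * (f1$ll - f0$ll)
  } else {
    f0 <- multinomLoglik(data[[out]], X0)
    f1 <- multinomLoglik(data[[out]], X1)
    if (f0$K < 2)
      return(list(p = 1, statistic = 0, df = 0L, degenerate = TRUE))
    df <- (f1$K - 1) * (f1$rank - f0$rank)
    stat <- 2 * (f1$ll - f0$ll)
  }
  if (df <= 0)
    return(list(p = 1, statistic = 0, df = 0L, degenerate = TRUE))
  stat <- max(stat, 0)
  list(p = stats::pchisq(stat, df, lower.tail = FALSE), statistic = stat,
       df = as.integer(df), degenerate = FALSE)
}

## ---- tester abstraction -------------------------------------------------
##
## A tester is a list(p = function(xi, yi, Si) -> p-value, nodes, types,
## gauss = NULL or list(C, n)). Tests are memoized per (pair, sorted set).

#' Build a memoized CI tester from a mixed dataset
#'
#' Precomputes per-variable design blocks and the correlation matrix of
#' the continuous block, so repeated tests during structure search avoid
#' redundant work; results agree with \code{\link{ciTest}}.
#'
#' @param data data.frame; factor columns are categorical.
#' @return a tester object usable by \code{\link{pcMax}} and
#'   \code{\link{fci}}; when all columns are continuous a fast
#'   correlation-matrix path is enabled for the skeleton search.
#' @export
makeCiTester <- function(data) {
  nodes <- names(data)
  types <- varTypes(data)
  n <- nrow(data)
  cache <- new.env(parent = emptyenv())
  contIdx <- which(types == "continuous")
  Ccont <- if (length(contIdx)) {
    C <- suppressWarnings(stats::cor(as.matrix(data[contIdx])))
    C[!is.finite(C)] <- 0
    C
  }
  contPos <- match(seq_along(data), contIdx)
  blocks <- lapply(seq_along(data), function(j) {
    col <- data[[j]]
    if (types[j] == "categorical") {
      f <- droplevels(factor(col))
      if (nlevels(f) >= 2) stats::model.matrix(~f)[, -1, drop = FALSE]
      else matrix(0, n, 0)
    } else matrix(as.numeric(col), n, 1)
  })
  ycat <- lapply(seq_along(data), function(j) {
    if (types[j] != "categorical") return(NULL)
    f <- droplevels(factor(data[[j]]))
    list(codes = as.integer(f) - 1L, K = nlevels(f))
  })
  ones <- matrix(1, n, 1)
  testOne <- function(xi, yi, Si) {
    if (all(types[c(xi, yi, Si)] == "continuous"))
      return(ciGaussCpp(Ccont, n, contPos[xi], contPos[yi],
                        as.integer(contPos[Si])))
    cx <- types[xi] == "categorical"; cy <- types[yi] == "categorical"
    out <- if (cx != cy) { if (cx) xi else yi } else max(xi, yi)
    oth <- if (out == xi) yi else xi
    X0 <- do.call(cbind, c(list(ones), blocks[Si]))
    X1 <- cbind(X0, blocks[[oth]])
    if (types[out] == "continuous") {
      yv <- blocks[[out]][, 1]
      f0 <- gaussLoglik(yv, X0); f1 <- gaussLoglik(yv, X1)
      df <- f1$rank - f0$rank
      stat <- 2 * (f1$ll - f0$ll)
    } else {
      yc <- ycat[[out]]
      if (yc$K < 2) return(1)
      q0 <- qr(X0); q1 <- qr(X1)
      ll0 <- mnLoglikCpp(X0[, q0$pivot[seq_len(q0$rank)], drop = FALSE],
                         yc$codes, yc$K)
      ll1 <- mnLoglikCpp(X1[, q1$pivot[seq_len(q1$rank)], drop = FALSE],
                         yc$codes, yc$K)
      df <- (yc$K - 1) * (q1$rank - q0$rank)
      stat <- 2 * (ll1 - ll0)
    }
    if (df <= 0) return(1)
    stats::pchisq(max(stat, 0), df, lower.tail = FALSE)
  }
  pfun <- function(xi, yi, Si) {
    a <- min(xi, yi); b <- max(xi, yi)
    key <- paste(a, b, paste(sort(Si), collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    p <- testOne(a, b, Si)
    cache[[key]] <- p
    p
  }
  gauss <- if (all(types == "continuous")) list(C = Ccont, n = n)
  list(p = pfun, nodes = nodes, types = types, gauss = gauss, n = n)
}

#' Build a d-separation oracle tester from a DAG
#'
#' Returns p = 1 when x and y are d-separated given S in the graph and
#' p = 0 otherwise; used to study search algorithms free of sampling error.
#'
#' @param graph a DAG-marked \linkS4class{MixedGraph}.
#' @return a tester object.
#' @export
makeOracleTester <- function(graph) {
  nodes <- graph@nodes
  pfun <- function(xi, yi, Si) {
    if (dSeparated(graph, xi, yi, Si)) 1 else 0
  }
  list(p = pfun, nodes = nodes, types = graph@types, gauss = NULL,
       n = Inf)
}

#' Test d-separation in a DAG
#'
#' Ancestral-subgraph moralization: restrict to the ancestors of
#' \code{{x, y} union S}, moralize, delete S, and check connectivity.
#'
#' @param graph a DAG-marked \linkS4class{MixedGraph}.
#' @param x,y node names or indices.
#' @param S conditioning set.
#' @return TRUE when x and y are d-separated given S.
#' @export
dSeparated <- function(graph, x, y, S = integer(0)) {
  xi <- nodeIndex(graph, x); yi <- nodeIndex(graph, y)
  Si <- if (length(S)) vapply(S, function(s) nodeIndex(graph, s), 0L)
  else integer(0)
  p <- length(graph@nodes)
  ## ancestors of the involved set
  anc <- rep(FALSE, p)
  stack <- c(xi, yi, Si)
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (anc[v]) next
    anc[v] <- TRUE
    stack <- c(stack, dagParents(graph, v))
  }
  keep <- which(anc)
  ## moralized adjacency on the ancestral subgraph
  adj <- matrix(FALSE, p, p)
  for (j in keep) {
    pa <- intersect(dagParents(graph, j), keep)
    for (a in pa) { adj[a, j] <- TRUE; adj[j, a] <- TRUE }
    if (length(pa) > 1) {
      cmb <- utils::combn(pa, 2)
      for (k in seq_len(ncol(cmb))) {
        adj[cmb[1, k], cmb[2, k]] <- TRUE
        adj[cmb[2, k], cmb[1, k]] <- TRUE
      }
    }
  }
  ## remove S and test connectivity x -> y
  blocked <- rep(FALSE, p)
  blocked[Si] <- TRUE
  seen <- rep(FALSE, p)
  stack <- xi
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v] || blocked[v]) next
    seen[v] <- TRUE
    if (v == yi) return(FALSE)
    stack <- c(stack, which(adj[v, ] & !seen & !blocked))
  }
  TRUE
}
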