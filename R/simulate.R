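#' @include AllClasses.R graph-utils.R
NULL

## Run `expr` under a temporary RNG state derived from `seed`, restoring the
## caller's stream afterwards, so every generator is bit-reproducible and
## composable.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## signed uniform draw with |value| in [lo, hi]
runifSigned <- function(n, range) {
  stats::runif(n, range[1], range[2]) * sample(c(-1, 1), n, replace = TRUE)
}

#' Generate a sparse random DAG over mixed-type nodes
#'
#' Draws a uniformly random topological order over continuous and
#' categorical nodes (so both types mix as parents and children), then
#' places exactly \code{round(avgDegree * nNodes / 2)} edges uniformly at
#' random among the order-respecting pairs (Erdos-Renyi conditioned on the
#' edge count), guaranteeing acyclicity by construction.
#'
#' @param nContinuous number of continuous (latent factor) nodes.
#' @param nCategorical number of categorical (covariate) nodes.
#' @param avgDegree target average degree; edge count is
#'   \code{round(avgDegree * nNodes / 2)}.
#' @param levelRange integer range; each categorical node draws its number
#'   of levels uniformly from \code{levelRange[1]:levelRange[2]}.
#' @param seed integer seed.
#' @return a \linkS4class{TrueGraph} DAG; continuous nodes are named
#'   \code{Z1..}, categorical nodes \code{D1..}; the topological order is
#'   kept in \code{metadata$topoOrder}.
#' @export
generateRandomDag <- function(nContinuous, nCategorical, avgDegree,
                              levelRange = c(2L, 4L), seed = 1L) {
  p <- nContinuous + nCategorical
  if (p < 2) stop("need at least two nodes")
  if (avgDegree <= 0 || avgDegree >= p)
    stop("avgDegree must lie in (0, nNodes - 1)")
  m <- round(avgDegree * p / 2)
  if (m > choose(p, 2)) stop("average degree infeasible for node count")
  nodes <- c(if (nContinuous) paste0("Z", seq_len(nContinuous)),
             if (nCategorical) paste0("D", seq_len(nCategorical)))
  types <- c(rep("continuous", nContinuous), rep("categorical", nCategorical))
  withSeed(seed, {
    ord <- sample.int(p)                # topological order (node indices)
    nLevels <- rep(NA_integer_, p)
    if (nCategorical)
      nLevels[types == "categorical"] <-
        sample(seq(levelRange[1], levelRange[2]), nCategorical, replace = TRUE)
    amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
    ## order-respecting pairs: position a < b in ord means ord[a] -> ord[b]
    pairs <- utils::combn(p, 2)
    pick <- sample.int(ncol(pairs), m)
    for (k in pick) {
      i <- ord[pairs[1, k]]; j <- ord[pairs[2, k]]
      amat[i, j] <- MARK_ARROW
      amat[j, i] <- MARK_TAIL
    }
    new("TrueGraph", nodes = nodes, types = types, amat = amat,
        metadata = list(kind = "true DAG", topoOrder = ord,
                        avgDegree = avgDegree, seed = seed),
        nLevels = stats::setNames(nLevels, nodes))
  })
}

## Draw the structural-equation parameters for a TrueGraph. Coefficient
## magnitudes come from coefRange (the LC/HC regime knob). Returns a list
## keyed by child node.
parametrizeGraph <- function(graph, coefRange, model = c("LH", "CG"),
                             noiseSd = 1, sdRange = c(0.5, 1.5)) {
  model <- match.arg(model)
  p <- length(graph@nodes)
  params <- vector("list", p)
  names(params) <- graph@nodes
  for (j in seq_len(p)) {
    pa <- dagParents(graph, j)
    paCont <- pa[graph@types[pa] == "continuous"]
    paCat <- pa[graph@types[pa] == "categorical"]
    if (graph@types[j] == "continuous") {
      beta <- runifSigned(length(paCont), coefRange)
      shifts <- lapply(paCat, function(q) {
        L <- graph@nLevels[q]
        s <- runifSigned(L, coefRange)
        s - mean(s)                    # center so the marginal mean is ~0
      })
      names(shifts) <- graph@nodes[paCat]
      ## CG: the conditional distribution may change variance (and pick up a
      ## joint mean offset) with the configuration of the discrete parents.
      nConf <- if (length(paCat)) prod(graph@nLevels[paCat]) else 1L
      if (model == "CG" && length(paCat)) {
        confSd <- stats::runif(nConf, sdRange[1], sdRange[2])
        confMu <- runifSigned(nConf, coefRange)
        confMu <- confMu - mean(confMu)
      } else {
        confSd <- rep(noiseSd, nConf)
        confMu <- rep(0, nConf)
      }
      params[[j]] <- list(type = "continuous",
                          paCont = paCont, beta = beta,
                          paCat = paCat, shifts = shifts,
                          confSd = confSd, confMu = confMu)
    } else {
      L <- graph@nLevels[j]
      ## multinomial logistic in the parents; level 1 is the reference
      intercept <- stats::runif(L - 1, -0.5, 0.5)
      betaCont <- matrix(runifSigned(length(paCont) * (L - 1), coefRange),
                         nrow = max(length(paCont), 0))
      catCoef <- lapply(paCat, function(q) {
        Lq <- graph@nLevels[q]
        matrix(runifSigned(Lq * (L - 1), coefRange), nrow = Lq)
      })
      names(catCoef) <- graph@nodes[paCat]
      params[[j]] <- list(type = "categorical", nLevels = L,
                          paCont = paCont, betaCont = betaCont,
                          paCat = paCat, catCoef = catCoef,
                          intercept = intercept)
    }
  }
  params
}

## index of the joint configuration of the discrete parents (1-based,
## mixed-radix over the parents' levels)
confIndex <- function(Dlev, levels) {
  if (!length(levels)) return(rep(1L, if (is.matrix(Dlev)) nrow(Dlev) else 1L))
  idx <- rep(1L, nrow(Dlev))
  mult <- 1L
  for (k in seq_along(levels)) {
    idx <- idx + (Dlev[, k] - 1L) * mult
    mult <- mult * levels[k]
  }
  idx
}

sampleFromGraph <- function(graph, n, coefRange, seed, model,
                            noiseSd = 1, sdRange = c(0.5, 1.5)) {
  withSeed(seed, {
    params <- parametrizeGraph(graph, coefRange, model = model,
                               noiseSd = noiseSd, sdRange = sdRange)
    p <- length(graph@nodes)
    ord <- graph@metadata$topoOrder
    if (is.null(ord)) ord <- topoSort(graph)
    vals <- matrix(0, n, p, dimnames = list(NULL, graph@nodes))
    for (j in ord) {
      pj <- params[[j]]
      if (pj$type == "continuous") {
        mu <- rep(0, n)
        if (length(pj$paCont))
          mu <- mu + as.vector(vals[, pj$paCont, drop = FALSE] %*% pj$beta)
        for (qi in seq_along(pj$paCat))
          mu <- mu + pj$shifts[[qi]][vals[, pj$paCat[qi]]]
        ci <- confIndex(vals[, pj$paCat, drop = FALSE],
                        graph@nLevels[pj$paCat])
        vals[, j] <- mu + pj$confMu[ci] + stats::rnorm(n, 0, pj$confSd[ci])
      } else {
        L <- pj$nLevels
        eta <- matrix(0, n, L)          # level-1 reference: eta[,1] = 0
        eta[, -1] <- matrix(pj$intercept, n, L - 1, byrow = TRUE)
        if (length(pj$paCont))
          eta[, -1] <- eta[, -1] +
            vals[, pj$paCont, drop = FALSE] %*% pj$betaCont
        for (qi in seq_along(pj$paCat))
          eta[, -1] <- eta[, -1] + pj$catCoef[[qi]][vals[, pj$paCat[qi]], ,
                                                    drop = FALSE]
        pr <- exp(eta - apply(eta, 1, max))
        pr <- pr / rowSums(pr)
        u <- stats::runif(n)
        cum <- t(apply(pr, 1, cumsum))
        vals[, j] <- 1L + rowSums(u > cum[, -L, drop = FALSE])
      }
    }
    contIdx <- which(graph@types == "continuous")
    catIdx <- which(graph@types == "categorical")
    Z <- vals[, contIdx, drop = FALSE]
    D <- as.data.frame(lapply(catIdx, function(j)
      factor(vals[, j], levels = seq_len(graph@nLevels[j]))))
    names(D) <- graph@nodes[catIdx]
    list(Z = Z, D = D, params = params)
  })
}

topoSort <- function(graph) {
  p <- length(graph@nodes)
  indeg <- vapply(seq_len(p), function(j) length(dagParents(graph, j)), 0L)
  out <- integer(0)
  remaining <- seq_len(p)
  while (length(remaining)) {
    src <- remaining[indeg[remaining] == 0][1]
    if (is.na(src)) stop("graph has a cycle")
    out <- c(out, src)
    for (ch in dagChildren(graph, src)) indeg[ch] <- indeg[ch] - 1L
    indeg[src] <- NA_integer_
    remaining <- setdiff(remaining, src)
  }
  out
}

#' Sample mixed data under the Lee-Hastie model
#'
#' Continuous children are linear in their continuous parents with
#' level-specific mean shifts from categorical parents and homoscedastic
#' Gaussian noise, so the conditional covariance of the continuous block is
#' common across discrete configurations. Categorical children follow a
#' multinomial logistic model in their parents.
#'
#' @param graph a \linkS4class{TrueGraph}.
#' @param n number of samples.
#' @param coefRange magnitude range of the structural coefficients (the
#'   low/high correlation regime knob).
#' @param seed integer seed.
#' @param noiseSd residual standard deviation of continuous children.
#' @return list with \code{Z} (n x K matrix of continuous values), \code{D}
#'   (data.frame of factors) and \code{params} (the drawn structural
#'   parameters).
#' @export
sampleLh <- function(graph, n, coefRange = c(0.1, 0.5), seed = 1L,
                     noiseSd = 1) {
  sampleFromGraph(graph, n, coefRange, seed, model = "LH", noiseSd = noiseSd)
}

#' Sample mixed data under the conditional Gaussian model
#'
#' As \code{\link{sampleLh}}, but the conditional distribution of a
#' continuous child is a Gaussian mixture indexed by the joint configuration
#' of its own discrete parents: each configuration gets its own residual
#' standard deviation (drawn from \code{sdRange}) and mean offset, so the
#' common-covariance assumption of the Lee-Hastie model is violated whenever
#' component variances differ.
#'
#' @inheritParams sampleLh
#' @param sdRange range of per-configuration residual standard deviations.
#' @return as \code{\link{sampleLh}}.
#' @export
sampleCg <- function(graph, n, coefRange = c(0.1, 0.5), seed = 1L,
                     noiseSd = 1, sdRange = c(0.5, 1.5)) {
  sampleFromGraph(graph, n, coefRange, seed, model = "CG",
                  noiseSd = noiseSd, sdRange = sdRange)
}

#' Generate a sparse Gaussian loading matrix
#'
#' Draws a p x K matrix of i.i.d. standard normal weights and keeps only the
#' \code{ceiling(keepFraction * p * K)} entries of greatest absolute value
#' (global top-|value| rule), zeroing the rest. A column left with no
#' support gets its single largest-|value| entry restored so every latent
#' factor retains at least one observed proxy.
#'
#' @param p number of observed features.
#' @param K number of latent factors.
#' @param keepFraction fraction of entries kept (default 0.02, i.e. about
#'   \code{0.02 * p} features per factor).
#' @param seed integer seed.
#' @return p x K numeric matrix.
#' @export
generateLoadingMatrix <- function(p, K, keepFraction = 0.02, seed = 1L) {
  stopifnot(keepFraction > 0, keepFraction <= 1)
  withSeed(seed, {
    A <- matrix(stats::rnorm(p * K), p, K)
    nKeep <- ceiling(keepFraction * p * K)
    thr <- sort(abs(A), decreasing = TRUE)[nKeep]
    Asp <- A * (abs(A) >= thr)
    for (k in seq_len(K)) {
      if (all(Asp[, k] == 0)) {
        top <- which.max(abs(A[, k]))
        Asp[top, k] <- A[top, k]
      }
    }
    Asp
  })
}

#' Expand latent factors to observed features
#'
#' Computes \code{X = Z \%*\% t(A) + E} with E i.i.d. standard normal; the
#' noise can be switched off to verify the identity exactly.
#'
#' @param Z n x K latent factor matrix.
#' @param A p x K loading matrix.
#' @param seed integer seed for the noise draw.
#' @param noise logical; FALSE suppresses E (test hook).
#' @return n x p observed matrix.
#' @export
expandToObserved <- function(Z, A, seed = 1L, noise = TRUE) {
  if (ncol(Z) != ncol(A)) stop("Z and A must agree in the factor dimension")
  X <- Z %*% t(A)
  if (noise)
    X <- X + withSeed(seed, matrix(stats::rnorm(length(X)), nrow(X), ncol(X)))
  colnames(X) <- paste0("X", seq_len(ncol(X)))
  X
}

#' Draw row-subset datasets
#'
#' Draws \code{m} independent subsets of \code{nSub} rows, each sampled
#' without replacement, from an observed matrix and its covariate table.
#'
#' @param X n x p matrix.
#' @param D data.frame with n rows (may be NULL).
#' @param nSub rows per subset.
#' @param m number of subsets.
#' @param seed integer seed.
#' @return list of \code{m} lists with elements \code{X}, \code{D},
#'   \code{rows}.
#' @export
subsampleDatasets <- function(X, D = NULL, nSub, m = 5L, seed = 1L) {
  n <- nrow(X)
  if (nSub > n) stop("nSub exceeds the number of rows")
  withSeed(seed, {
    lapply(seq_len(m), function(i) {
      rows <- sample.int(n, nSub)
      list(X = X[rows, , drop = FALSE],
           D = if (!is.null(D)) D[rows, , drop = FALSE],
           rows = rows)
    })
  })
}

regimeCoefRange <- function(regime) {
  switch(toupper(regime), LC = c(0.1, 0.5), HC = c(0.5, 1.0),
         stop("regime must be 'LC' or 'HC'"))
}

#' Simulate a full latent-factor benchmark dataset
#'
#' Generates a sparse mixed-type DAG, samples latent continuous factors Z
#' and categorical covariates D under the chosen structural model, and
#' expands Z to observed features through a sparse Gaussian loading matrix.
#'
#' @param model structural model, \code{"CG"} or \code{"LH"}.
#' @param regime correlation regime: \code{"LC"} draws structural
#'   coefficient magnitudes from [0.1, 0.5], \code{"HC"} from [0.5, 1.0].
#' @param n number of samples.
#' @param nLatents number of continuous latent factors.
#' @param nCategorical number of categorical covariates.
#' @param pObserved number of observed features.
#' @param keepFrac loading sparsity (fraction of entries kept).
#' @param avgDegree average degree of the generating DAG.
#' @param levelRange range of categorical level counts.
#' @param seed integer seed.
#' @return a \linkS4class{SimulationTruth}.
#' @export
simulateBenchmark <- function(model = c("CG", "LH"), regime = c("LC", "HC"),
                              n = 10000L, nLatents = 50L, nCategorical = 25L,
                              pObserved = 2500L, keepFrac = 0.02,
                              avgDegree = 2.67, levelRange = c(2L, 4L),
                              seed = 1L) {
  model <- match.arg(model)
  regime <- match.arg(regime)
  coefRange <- regimeCoefRange(regime)
  graph <- generateRandomDag(nLatents, nCategorical, avgDegree,
                             levelRange = levelRange, seed = seed)
  draw <- if (model == "LH")
    sampleLh(graph, n, coefRange, seed = seed + 1L)
  else sampleCg(graph, n, coefRange, seed = seed + 1L)
  A <- generateLoadingMatrix(pObserved, nLatents, keepFrac, seed = seed + 2L)
  X <- expandToObserved(draw$Z, A, seed = seed + 3L)
  new("SimulationTruth", graph = graph, Z = draw$Z, D = draw$D, A = A,
      X = X, noiseSd = 1, regime = regime, model = model,
      seed = as.integer(seed),
      params = list(coefRange = coefRange, keepFrac = keepFrac,
                    avgDegree = avgDegree, levelRange = levelRange,
                    structural = draw$params))
}

#' Write a simulation to disk
#'
#' Writes X.tsv, covariates.tsv, Z.tsv, A.tsv (TSV with header, sample IDs
#' in column 1 where applicable), the generating DAG as edge-list text, and
#' truth.json with all generation parameters.
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param dir output directory (created if missing).
#' @export
writeSimulation <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrixTsv(truth@X, file.path(dir, "X.tsv"))
  writeMatrixTsv(truth@Z, file.path(dir, "Z.tsv"))
  writeMatrixTsv(truth@A, file.path(dir, "A.tsv"), rowIds = FALSE)
  dcov <- data.frame(sample = paste0("S", seq_len(nrow(truth@D))), truth@D)
  utils::write.table(dcov, file.path(dir, "covariates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeGraphTxt(truth@graph, file.path(dir, "graph.txt"))
  jsonlite::write_json(
    list(model = truth@model, regime = truth@regime, seed = truth@seed,
         n = nrow(truth@Z), nLatents = ncol(truth@Z),
         nCategorical = ncol(truth@D), pObserved = ncol(truth@X),
         noiseSd = truth@noiseSd,
         coefRange = truth@params$coefRange,
         keepFrac = truth@params$keepFrac,
         avgDegree = truth@params$avgDegree,
         levelRange = truth@params$levelRange),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

writeMatrixTsv <- function(M, path, rowIds = TRUE) {
  df <- as.data.frame(M)
  if (is.null(colnames(M)))
    names(df) <- paste0("V", seq_len(ncol(M)))
  if (rowIds)
    df <- data.frame(sample = paste0("S", seq_len(nrow(M))), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix from TSV
#'
#' @param path TSV with a header row; a first column named \code{sample} (or
#'   any non-numeric first column) is treated as row identifiers.
#' @return numeric matrix.
#' @export
readMatrixTsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) && !is.numeric(df[[1]])) {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
    M <- as.matrix(df)
    rownames(M) <- rn
  } else M <- as.matrix(df)
  M
}

#' Read a mixed-type covariate table from TSV
#'
#' Columns are typed by content: character columns or integer-valued columns
#' with at most \code{maxLevels} distinct values become factors; the rest
#' stay numeric.
#'
#' @param path TSV with header; a non-numeric first column named
#'   \code{sample} is dropped into row names.
#' @param maxLevels level cap for treating an integer column as categorical.
#' @return data.frame of numeric and factor columns.
#' @export
readCovariatesTsv <- function(path, maxLevels = 10L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) && (names(df)[1] == "sample" || !is.numeric(df[[1]]))) {
    rownames(df) <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  for (j in seq_along(df)) {
    x <- df[[j]]
    if (is.character(x) ||
        (is.numeric(x) && all(x == round(x)) &&
         length(unique(x)) <= maxLevels))
      df[[j]] <- factor(x)
  }
  df
}
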