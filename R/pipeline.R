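#' @include simulate.R factorize.R mgm.R pc.R fci.R stability.R mb.R evaluate.R
NULL

#' Default benchmark run configuration
#'
#' Returns the full configuration list for the benchmark pipelines:
#' generation sizes and regimes, factorization, skeleton, search and
#' stability-selection parameters, and the seeds of every stochastic stage.
#' Any entry can be overridden through \code{...}.
#'
#' @param ... named overrides.
#' @return named list.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(
    model = "CG", regime = "LC",
    n = 10000L, nLatents = 50L, nCategorical = 25L, pObserved = 2500L,
    keepFrac = 0.02, avgDegree = 2.67, levelRange = c(2L, 4L),
    nSub = 1000L, m = 5L,
    ebmfKmax = NULL, ebmfTol = 1e-7, backfit = TRUE,
    backfitSweeps = 100L, supportRel = 0.1,
    lambdaGrid = lambdaGridDefault(), stepsSubsamples = 20L,
    stepsThreshold = 0.05,
    alphaGrid = c(0.001, 0.01, 0.05, 0.1), starsSubsamples = 20L,
    starsThreshold = 0.05,
    alpha = 0.05, maxDepth = 3L,
    seed = 1L)
  utils::modifyList(cfg, list(...))
}

#' Write / read a run configuration
#' @param config named list from \code{\link{defaultRunConfig}}.
#' @param path JSON file path.
#' @return \code{readRunConfig} returns the configuration list.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(defaultRunConfig(), cfg)
}

#' Embed a learned graph into a reference node set
#'
#' Extra nodes are dropped and missing nodes become isolated, so a graph
#' learned over estimated (possibly renamed or partial) variables can be
#' scored against a generating graph.
#'
#' @param graph a \linkS4class{MixedGraph}.
#' @param nodes reference node names.
#' @param types reference node types.
#' @return a \linkS4class{MixedGraph} over \code{nodes}.
#' @export
restrictGraph <- function(graph, nodes, types) {
  p <- length(nodes)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  common <- intersect(graph@nodes, nodes)
  gi <- match(common, graph@nodes)
  ri <- match(common, nodes)
  amat[ri, ri] <- graph@amat[gi, gi]
  MixedGraph(nodes, types, amat = amat, metadata = graph@metadata)
}

## skeleton + search for one dataset: MGM with StEPS, then PC-Max with
## StARS restricted to the MGM skeleton
skeletonThenSearch <- function(d, cfg, seed) {
  st <- stepsSelect(d, lambdaGrid = cfg$lambdaGrid,
                    nSubsamples = cfg$stepsSubsamples,
                    threshold = cfg$stepsThreshold, seed = seed)
  sr <- starsSelect(d, alphaGrid = cfg$alphaGrid, initGraph = st$graph,
                    nSubsamples = cfg$starsSubsamples,
                    threshold = cfg$starsThreshold, seed = seed + 1L,
                    algorithm = "pcmax", maxDepth = cfg$maxDepth)
  list(steps = st, stars = sr, graph = sr$graph)
}

fitEbmfArm <- function(X, cfg) {
  fm <- ebmfGreedy(X, kMax = cfg$ebmfKmax, tol = cfg$ebmfTol)
  greedyK <- fm@K
  if (cfg$backfit && fm@K > 0)
    fm <- ebmfBackfit(fm, X, maxIter = cfg$backfitSweeps, tol = cfg$ebmfTol)
  fm <- normalizeFactors(fm)
  list(model = fm, greedyK = greedyK)
}

#' Run the full graph-recovery benchmark
#'
#' Simulates the benchmark (latent DAG, mixed sampling, expansion to
#' observed features), draws \code{m} row subsets, and on each one runs two
#' arms through MGM+StEPS and PC-Max+StARS: the true source factors plus
#' covariates (the best-case arm) and the EBMF greedy+backfit estimated
#' factors (matched to sources by the MCC assignment and relabeled) plus
#' covariates. A PCA eigenvalue-ratio baseline is fitted for factor
#' recovery. Reports per-subset and averaged factor-recovery and edge
#' metrics.
#'
#' @param config list from \code{\link{defaultRunConfig}}.
#' @param out optional directory for TSV reports.
#' @return list with \code{factorTable}, \code{edgeTable} (averages in
#'   rows with \code{subset == "mean"}), and the per-subset details.
#' @export
runBenchmark <- function(config = defaultRunConfig(), out = NULL) {
  cfg <- config
  truth <- simulateBenchmark(cfg$model, cfg$regime, cfg$n, cfg$nLatents,
                             cfg$nCategorical, cfg$pObserved, cfg$keepFrac,
                             cfg$avgDegree, cfg$levelRange, seed = cfg$seed)
  subs <- subsampleDatasets(truth@X, truth@D, cfg$nSub, cfg$m,
                            seed = cfg$seed + 10L)
  contNames <- truth@graph@nodes[truth@graph@types == "continuous"]
  factorRows <- NULL; edgeRows <- NULL
  for (i in seq_along(subs)) {
    sub <- subs[[i]]
    Zi <- truth@Z[sub$rows, , drop = FALSE]
    colnames(Zi) <- contNames
    seedI <- cfg$seed + 100L * i
    ## factor recovery arms
    ebmf <- fitEbmfArm(sub$X, cfg)
    pca <- pcaEigenvalueRatio(sub$X, kBar = min(100L, nrow(sub$X) - 2L))
    mccE <- if (ebmf$model@K > 0)
      matchFactorsMcc(Zi, loadings(ebmf$model))
    else list(mcc = NA_real_, kEst = 0L, assignment = integer(0))
    mccP <- matchFactorsMcc(Zi, pca@scores)
    factorRows <- rbind(factorRows,
      data.frame(subset = i, method = c("EBMF+BF", "PCA"),
                 k = c(ebmf$model@K, pca@kHat),
                 kGreedy = c(ebmf$greedyK, NA),
                 mcc = c(mccE$mcc, mccP$mcc)))
    ## source-factor arm
    dSrc <- data.frame(as.data.frame(Zi), sub$D, check.names = FALSE)
    gSrc <- skeletonThenSearch(dSrc, cfg, seedI)$graph
    emSrc <- edgeMetricTable(truth@graph,
                             restrictGraph(gSrc, truth@graph@nodes,
                                           truth@graph@types))
    emSrc$arm <- "Source"; emSrc$subset <- i
    ## estimated-factor arm: matched factors relabeled to source names
    emEst <- NULL
    if (ebmf$model@K > 0) {
      sc <- loadings(ebmf$model)
      asg <- mccE$assignment
      nmEst <- ifelse(is.na(asg), paste0("EF", seq_len(ncol(sc))),
                      contNames[asg])
      colnames(sc) <- nmEst
      dEst <- data.frame(as.data.frame(sc), sub$D, check.names = FALSE)
      gEst <- skeletonThenSearch(dEst, cfg, seedI + 7L)$graph
      emEst <- edgeMetricTable(truth@graph,
                               restrictGraph(gEst, truth@graph@nodes,
                                             truth@graph@types))
      emEst$arm <- "EBMF+BF"; emEst$subset <- i
    }
    edgeRows <- rbind(edgeRows, emSrc, emEst)
  }
  meanBy <- function(df, keys) {
    agg <- stats::aggregate(df[setdiff(names(df), c(keys, "subset"))],
                            df[keys], mean, na.rm = TRUE)
    agg$subset <- "mean"
    agg
  }
  factorTable <- rbind(
    data.frame(factorRows, stringsAsFactors = FALSE),
    cbind(meanBy(factorRows, "method")[
      c("method", "k", "kGreedy", "mcc", "subset")],
      row.names = NULL))
  edgeMean <- meanBy(edgeRows, c("arm", "class"))
  res <- list(factorTable = factorTable, edgeTable = edgeRows,
              edgeMean = edgeMean, truth = truth, config = cfg)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(factorTable, file.path(out, "factor_recovery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(edgeRows, file.path(out, "edge_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(edgeMean, file.path(out, "edge_metrics_mean.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}

#' Run the confounded-edge benchmark against FCI
#'
#' Simulates the small benchmark (10 latent factors, 200 observed
#' features), and on each row subset compares two ways of identifying
#' confounded feature pairs (pairs sharing a latent parent): the support of
#' the EBMF greedy+backfit loading matrix (whole-unit counting), and FCI
#' run directly on the observed features with fractional PAG scoring
#' (double-arrow = 1 TP; o-o = 1/3 TP + 2/3 FP; o-> = 1/2 TP + 1/2 FP
#' when the pair is expected, 1 FP otherwise). The expected adjacency is
#' derived from the source loading matrix support.
#'
#' @param config list from \code{\link{defaultRunConfig}}; sizes default to
#'   the small benchmark when not overridden.
#' @param out optional directory for a TSV report.
#' @param runFci set FALSE to skip the FCI arm.
#' @param runEbmf set FALSE to skip the EBMF arm.
#' @return list with the per-subset \code{table} and its \code{mean} row.
#' @export
runFciBenchmark <- function(config = NULL, out = NULL, runFci = TRUE,
                            runEbmf = TRUE) {
  ## loading sparsity follows the design invariant of ~50 regulated
  ## features per latent factor, which at p = 200 means keeping 25% of the
  ## loading entries
  cfg <- if (is.null(config))
    defaultRunConfig(nLatents = 10L, nCategorical = 5L, pObserved = 200L,
                     keepFrac = min(1, 50 / 200))
  else config
  truth <- simulateBenchmark(cfg$model, cfg$regime, cfg$n, cfg$nLatents,
                             cfg$nCategorical, cfg$pObserved, cfg$keepFrac,
                             cfg$avgDegree, cfg$levelRange, seed = cfg$seed)
  expected <- expectedConfounderAdjacency(truth@A)
  subs <- subsampleDatasets(truth@X, truth@D, cfg$nSub, cfg$m,
                            seed = cfg$seed + 10L)
  rows <- NULL
  for (i in seq_along(subs)) {
    sub <- subs[[i]]
    if (runEbmf) {
      ebmf <- fitEbmfArm(sub$X, cfg)
      if (ebmf$model@K > 0) {
        supp <- loadingSupport(factorMatrix(ebmf$model),
                               rel = cfg$supportRel)
        estAdj <- expectedConfounderAdjacency(supp)
        prE <- confoundedEdgePr(estAdj, expected)
      } else prE <- list(ap = NA_real_, ar = 0)
      rows <- rbind(rows, data.frame(subset = i, method = "EBMF",
                                     ap = prE$ap, ar = prE$ar))
    }
    if (runFci) {
      pag <- fci(as.data.frame(sub$X), alpha = cfg$alpha,
                 maxDepth = cfg$maxDepth)
      prF <- confoundedEdgePr(pag, expected)
      rows <- rbind(rows, data.frame(subset = i, method = "FCI",
                                     ap = prF$ap, ar = prF$ar))
    }
  }
  meanRows <- stats::aggregate(rows[c("ap", "ar")], rows["method"], mean,
                               na.rm = TRUE)
  meanRows$subset <- "mean"
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(rbind(rows, meanRows[names(rows)]),
                       file.path(out, "confounder_recovery.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(table = rows, mean = meanRows, truth = truth, config = cfg)
}

#' Applied workflow: factorize, merge covariates, search, Markov blankets
#'
#' Fits EBMF (greedy, optionally backfitted) to the expression block only,
#' merges the normalized per-sample factor scores with the covariate table,
#' learns an MGM skeleton (optional) and a causal graph over factors plus
#' covariates, and extracts the Markov blanket of each declared target.
#' Binary targets can additionally be scored by nested cross-validated
#' Markov-blanket logistic regression.
#'
#' @param X n x p expression-like matrix.
#' @param covariates data.frame of mixed covariates (never entered into the
#'   factorization).
#' @param targets character vector of covariate names of interest.
#' @param config pipeline knobs as in \code{\link{defaultRunConfig}};
#'   \code{useSteps} toggles StEPS (otherwise \code{mgmLambda} or no
#'   skeleton), \code{algorithm} is \code{"pcmax"} or \code{"fci"},
#'   \code{predictTargets} lists binary targets to cross-validate.
#' @return list with \code{model} (\linkS4class{FactorModel}),
#'   \code{graph}, \code{mb} (per target), and \code{auc} (per predicted
#'   target).
#' @export
runApplied <- function(X, covariates, targets = character(0),
                       config = list()) {
  cfg <- utils::modifyList(
    list(ebmfKmax = NULL, ebmfTol = 1e-7, backfit = TRUE,
         backfitSweeps = 100L, useSteps = FALSE, mgmLambda = NULL,
         lambdaGrid = lambdaGridDefault(), stepsSubsamples = 20L,
         stepsThreshold = 0.05, algorithm = "pcmax", alpha = 0.05,
         maxDepth = 3L, seed = 1L, predictTargets = character(0),
         folds = 5L), config)
  stopifnot(nrow(X) == nrow(covariates))
  arm <- fitEbmfArm(X, cfg)
  fm <- arm$model
  if (fm@K == 0) stop("EBMF found no factors in the expression block")
  sc <- loadings(fm)
  colnames(sc) <- paste0("LF", seq_len(ncol(sc)))
  merged <- data.frame(as.data.frame(sc), covariates, check.names = FALSE)
  init <- if (cfg$useSteps) {
    stepsSelect(merged, lambdaGrid = cfg$lambdaGrid,
                nSubsamples = cfg$stepsSubsamples,
                threshold = cfg$stepsThreshold, seed = cfg$seed)$graph
  } else if (!is.null(cfg$mgmLambda)) {
    fitMgm(merged, cfg$mgmLambda)$graph
  }
  graph <- if (cfg$algorithm == "fci")
    fci(merged, alpha = cfg$alpha, initGraph = init,
        maxDepth = cfg$maxDepth)
  else pcMax(merged, alpha = cfg$alpha, initGraph = init,
             maxDepth = cfg$maxDepth)
  mb <- lapply(stats::setNames(targets, targets),
               function(t) markovBlanket(graph, t))
  auc <- list()
  for (t in intersect(cfg$predictTargets, names(covariates))) {
    auc[[t]] <- predictFromMb(X, covariates, t, folds = cfg$folds,
                              seed = cfg$seed,
                              config = list(kMax = cfg$ebmfKmax,
                                            backfit = cfg$backfit,
                                            alpha = cfg$alpha,
                                            maxDepth = cfg$maxDepth,
                                            mgmLambda = cfg$mgmLambda,
                                            tol = cfg$ebmfTol))
  }
  list(model = fm, graph = graph, mb = mb, auc = auc, merged = merged)
}
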