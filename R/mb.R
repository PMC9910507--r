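#' @include graph-utils.R factorize.R mgm.R stability.R
NULL

#' Markov blanket of a target node
#'
#' For directed edges: parents, children, and co-parents of children. For
#' edges whose endpoint at the target is not fully oriented (undirected,
#' circle, or bidirected), the adjacent node is included, giving a
#' conservative superset in CPDAGs and PAGs. A co-parent is any node with
#' an arrowhead into a definite child of the target.
#'
#' @param graph a \linkS4class{MixedGraph} (CPDAG or PAG).
#' @param target node name or index.
#' @return character vector of node names (empty for an isolated target).
#' @export
markovBlanket <- function(graph, target) {
  t <- nodeIndex(graph, target)
  if (is.na(t)) stop("target not in graph")
  a <- graph@amat
  p <- nrow(a)
  mb <- rep(FALSE, p)
  mb[which(a[t, ] != 0L)] <- TRUE               # all adjacent nodes
  children <- which(a[t, ] == MARK_ARROW & a[, t] == MARK_TAIL)
  for (ch in children) {
    coparents <- which(a[, ch] == MARK_ARROW)
    mb[coparents] <- TRUE
  }
  mb[t] <- FALSE
  graph@nodes[mb]
}

#' Project new samples onto fitted factors
#'
#' Least-squares regression of new observations on the factor matrix,
#' giving factor scores for samples not used in the fit.
#'
#' @param model a \linkS4class{FactorModel}.
#' @param Xnew m x p matrix on the same features the model was fitted to.
#' @param ridge small ridge added for numerical stability.
#' @return m x K score matrix.
#' @export
projectFactors <- function(model, Xnew, ridge = 1e-8) {
  FF <- model@FF
  G <- crossprod(FF)
  diag(G) <- diag(G) + ridge * mean(diag(G))
  Xnew %*% FF %*% solve(G)
}

stratifiedFolds <- function(y, folds, seed) {
  withSeed(seed, {
    fold <- integer(length(y))
    for (lev in unique(y)) {
      idx <- sample(which(y == lev))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Markov-blanket prediction of a binary outcome by nested cross-validation
#'
#' Outer k-fold cross-validation in which, within each training fold, the
#' entire causal learning pipeline is rerun: EBMF factorization of the
#' expression block, merging of factor scores with covariates, structure
#' search, Markov-blanket feature selection for the target, and a logistic
#' regression on the selected features. Held-out samples are projected onto
#' the training-fold factors and scored; the pooled out-of-fold
#' predictions give the AUC. Selecting features inside each fold avoids the
#' optimistic bias of selecting on the full data.
#'
#' @param X n x p expression-like matrix (NULL to search covariates only).
#' @param covariates data.frame of mixed covariates including the target.
#' @param target name of a binary (2-level factor) column of
#'   \code{covariates}.
#' @param folds number of outer folds (stratified by the target).
#' @param seed integer seed.
#' @param config list of pipeline knobs: \code{kMax}, \code{backfit},
#'   \code{alpha}, \code{maxDepth}, \code{mgmLambda} (NULL skips the MGM
#'   skeleton; a single value fits it with that penalty for all classes).
#' @return list with pooled \code{auc}, the \code{roc} object, per-fold
#'   Markov blankets \code{mb}, out-of-fold \code{predictions} and the
#'   fold assignment.
#' @export
predictFromMb <- function(X, covariates, target, folds = 5L, seed = 1L,
                          config = list()) {
  cfg <- utils::modifyList(
    list(kMax = 20L, backfit = TRUE, alpha = 0.05, maxDepth = 3L,
         mgmLambda = NULL, tol = 1e-6), config)
  y <- covariates[[target]]
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(droplevels(y)) != 2) stop("target must be binary")
  y <- droplevels(y)
  n <- length(y)
  fold <- stratifiedFolds(y, folds, seed)
  pred <- rep(NA_real_, n)
  mbs <- vector("list", folds)
  for (k in seq_len(folds)) {
    tr <- fold != k; te <- !tr
    covTr <- covariates[tr, setdiff(names(covariates), target),
                        drop = FALSE]
    if (!is.null(X)) {
      fm <- ebmfGreedy(X[tr, , drop = FALSE], kMax = cfg$kMax,
                       tol = cfg$tol)
      if (cfg$backfit && fm@K > 0)
        fm <- ebmfBackfit(fm, X[tr, , drop = FALSE], tol = cfg$tol)
      fm <- normalizeFactors(fm)
      if (fm@K > 0) {
        sc <- loadings(fm)
        colnames(sc) <- paste0("LF", seq_len(ncol(sc)))
        scTe <- projectFactors(fm, X[te, , drop = FALSE])
        colnames(scTe) <- colnames(sc)
      } else sc <- scTe <- NULL
    } else sc <- scTe <- NULL
    dTr <- cbind(if (!is.null(sc)) as.data.frame(sc), covTr)
    dTr[[target]] <- y[tr]
    init <- if (!is.null(cfg$mgmLambda))
      fitMgm(dTr, cfg$mgmLambda)$graph
    g <- pcMax(dTr, alpha = cfg$alpha, initGraph = init,
               maxDepth = cfg$maxDepth)
    mb <- markovBlanket(g, target)
    mbs[[k]] <- mb
    trainDf <- dTr[c(mb, target)]
    fit <- stats::glm(stats::reformulate(if (length(mb)) mb else "1",
                                         response = target),
                      family = stats::binomial(), data = trainDf)
    teDf <- cbind(if (!is.null(scTe)) as.data.frame(scTe),
                  covariates[te, setdiff(names(covariates), target),
                             drop = FALSE])
    pred[te] <- stats::predict(fit, newdata = teDf, type = "response")
  }
  roc <- pROC::roc(response = y, predictor = pred, quiet = TRUE,
                   direction = "<", levels = levels(y))
  list(auc = as.numeric(pROC::auc(roc)), roc = roc, mb = mbs,
       predictions = pred, fold = fold)
}
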