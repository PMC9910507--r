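#' @include AllClasses.R graph-utils.R simulate.R
NULL

## Encode a mixed data.frame for the pseudolikelihood: z-scored continuous
## block and reference-coded (levels 2..L) indicators for the discrete
## block, with the column groups of each discrete variable.
mgmEncode <- function(data) {
  types <- varTypes(data)
  contNames <- names(data)[types == "continuous"]
  discNames <- names(data)[types == "categorical"]
  n <- nrow(data)
  Xc <- if (length(contNames)) {
    M <- as.matrix(data[contNames])
    M <- scale(M)
    M[!is.finite(M)] <- 0              # constant columns
    M
  } else matrix(0, n, 0)
  groups <- list(); Dind <- matrix(0, n, 0)
  for (s in discNames) {
    f <- factor(data[[s]])
    if (nlevels(f) < 2) stop("categorical column with a single level: ", s)
    ind <- stats::model.matrix(~ f)[, -1, drop = FALSE]
    groups[[s]] <- ncol(Dind) + seq_len(ncol(ind))
    Dind <- cbind(Dind, ind)
  }
  groupIndex <- rep(seq_along(groups), times = lengths(groups))
  list(Xc = Xc, Dind = Dind, contNames = contNames, discNames = discNames,
       groups = groups, groupIndex = groupIndex, n = n,
       nodes = c(contNames, discNames),
       types = c(rep("continuous", length(contNames)),
                 rep("categorical", length(discNames))))
}

mgmZeroParams <- function(enc) {
  pc <- ncol(enc$Xc); dTot <- ncol(enc$Dind)
  list(B = matrix(0, pc, pc), dB = rep(1, pc), alpha = rep(0, pc),
       Rho = matrix(0, dTot, pc), Phi = matrix(0, dTot, dTot),
       Psi = rep(0, dTot))
}

## smooth part of the negative log-pseudolikelihood (averaged over n) and
## its gradient
mgmSmooth <- function(theta, enc, gradient = TRUE) {
  n <- enc$n; Xc <- enc$Xc; Dind <- enc$Dind
  pc <- ncol(Xc); dTot <- ncol(Dind)
  ## continuous conditionals: x_j | rest ~ N(m_j / d_j, 1 / d_j), with m_j
  ## the linear natural parameter and d_j the free diagonal precision
  m <- matrix(rep(theta$alpha, each = n), n, pc)
  if (pc) m <- m + Xc %*% theta$B
  if (pc && dTot) m <- m + Dind %*% theta$Rho
  dB <- theta$dB
  f <- 0; e <- NULL
  if (pc) {
    mOverD <- sweep(m, 2, dB, `/`)
    e <- mOverD - Xc
    f <- sum(sweep(Xc^2, 2, dB, `*`)) / (2 * n) - sum(Xc * m) / n +
      sum(m * mOverD) / (2 * n) - 0.5 * sum(log(dB))
  }
  Delta <- matrix(0, n, dTot)
  if (dTot) {
    Eta <- matrix(rep(theta$Psi, each = n), n, dTot)
    if (pc) Eta <- Eta + Xc %*% t(theta$Rho)
    Eta <- Eta + Dind %*% theta$Phi
    for (s in names(enc$groups)) {
      g <- enc$groups[[s]]
      es <- Eta[, g, drop = FALSE]
      rmax <- es[, 1]
      for (col in seq_len(ncol(es))[-1]) rmax <- pmax(rmax, es[, col])
      rmax <- pmax(rmax, 0)
      ex <- exp(es - rmax)
      den <- exp(-rmax) + rowSums(ex)
      P <- ex / den
      Y <- Dind[, g, drop = FALSE]
      f <- f + (sum(log(den) + rmax) - sum(Y * es)) / n
      Delta[, g] <- P - Y
    }
  }
  if (!gradient) return(list(f = f))
  gB <- if (pc) { G <- crossprod(Xc, e) / n; G <- G + t(G); diag(G) <- 0; G }
        else matrix(0, 0, 0)
  gDB <- if (pc)
    colMeans(Xc^2) / 2 - colSums(m * m) / (2 * n * dB^2) - 1 / (2 * dB)
  else numeric(0)
  gAlpha <- if (pc) colSums(e) / n else numeric(0)
  gRho <- if (pc && dTot)
    crossprod(Dind, e) / n + crossprod(Delta, Xc) / n
  else matrix(0, dTot, pc)
  gPhi <- if (dTot) {
    G <- crossprod(Dind, Delta) / n
    G <- G + t(G)
    for (s in names(enc$groups)) {
      g <- enc$groups[[s]]
      G[g, g] <- 0
    }
    G
  } else matrix(0, 0, 0)
  gPsi <- if (dTot) colSums(Delta) / n else numeric(0)
  list(f = f, grad = list(B = gB, dB = gDB, alpha = gAlpha, Rho = gRho,
                          Phi = gPhi, Psi = gPsi))
}

## group-wise proximal operator of the penalties (vectorized with rowsum
## over the level-group index of each discrete variable)
mgmProx <- function(theta, enc, step, lambda) {
  pc <- ncol(enc$Xc)
  if (pc) {
    B <- theta$B
    thr <- step * lambda[["cc"]]
    B <- sign(B) * pmax(abs(B) - thr, 0)
    diag(B) <- 0
    theta$B <- B
  }
  gs <- enc$groups
  q <- length(gs)
  if (q && is.null(enc$groupIndex))
    stop("encoder missing group index")   # set in mgmEncode
  gi <- enc$groupIndex
  if (q && pc) {
    thr <- step * lambda[["cd"]]
    norms <- sqrt(rowsum(theta$Rho^2, gi, reorder = FALSE))   # q x pc
    scale <- ifelse(norms > thr, 1 - thr / pmax(norms, 1e-300), 0)
    theta$Rho <- theta$Rho * scale[gi, , drop = FALSE]
  }
  if (q >= 2) {
    thr <- step * lambda[["dd"]]
    bl <- t(rowsum(t(rowsum(theta$Phi^2, gi, reorder = FALSE)), gi,
                   reorder = FALSE))                           # q x q
    norms <- sqrt(bl)
    scale <- ifelse(norms > thr, 1 - thr / pmax(norms, 1e-300), 0)
    diag(scale) <- 0
    theta$Phi <- theta$Phi * scale[gi, gi, drop = FALSE]
  }
  theta
}

mgmPenalty <- function(theta, enc, lambda) {
  pen <- 0
  pc <- ncol(enc$Xc)
  if (pc) pen <- pen + lambda[["cc"]] * sum(abs(theta$B[upper.tri(theta$B)]))
  gi <- enc$groupIndex
  q <- length(enc$groups)
  if (q && pc)
    pen <- pen + lambda[["cd"]] *
      sum(sqrt(rowsum(theta$Rho^2, gi, reorder = FALSE)))
  if (q >= 2) {
    bl <- t(rowsum(t(rowsum(theta$Phi^2, gi, reorder = FALSE)), gi,
                   reorder = FALSE))
    pen <- pen + lambda[["dd"]] * sum(sqrt(bl[upper.tri(bl)]))
  }
  pen
}

## B and Phi store each symmetric pair twice (entry and transpose) while
## the true parameter is shared, so pair-wise inner products take half the
## full-matrix sums; Rho, alpha, Psi are stored once.
paramDiff2 <- function(a, b) {
  0.5 * sum((a$B - b$B)^2) + sum((a$dB - b$dB)^2) +
    sum((a$alpha - b$alpha)^2) + sum((a$Rho - b$Rho)^2) +
    0.5 * sum((a$Phi - b$Phi)^2) + sum((a$Psi - b$Psi)^2)
}

paramGradDot <- function(g, d) {
  0.5 * sum(g$B * d$B) + sum(g$dB * d$dB) + sum(g$alpha * d$alpha) +
    sum(g$Rho * d$Rho) + 0.5 * sum(g$Phi * d$Phi) + sum(g$Psi * d$Psi)
}

paramStep <- function(theta, grad, step) {
  list(B = theta$B - step * grad$B,
       dB = pmax(theta$dB - step * grad$dB, 1e-4),  # precision stays positive
       alpha = theta$alpha - step * grad$alpha,
       Rho = theta$Rho - step * grad$Rho,
       Phi = theta$Phi - step * grad$Phi,
       Psi = theta$Psi - step * grad$Psi)
}

paramMinus <- function(a, b) {
  list(B = a$B - b$B, dB = a$dB - b$dB, alpha = a$alpha - b$alpha,
       Rho = a$Rho - b$Rho, Phi = a$Phi - b$Phi, Psi = a$Psi - b$Psi)
}

## edge adjacency implied by the parameter groups
mgmAdjacency <- function(theta, enc, tol = 1e-8) {
  nodes <- enc$nodes
  p <- length(nodes)
  pc <- length(enc$contNames)
  adj <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  if (pc) {
    cc <- abs(theta$B) > tol
    adj[seq_len(pc), seq_len(pc)] <- cc
  }
  gs <- enc$groups
  for (si in seq_along(gs)) {
    rows <- gs[[si]]
    s <- pc + si
    if (pc) {
      nz <- sqrt(colSums(theta$Rho[rows, , drop = FALSE]^2)) > tol
      adj[s, seq_len(pc)] <- nz
      adj[seq_len(pc), s] <- nz
    }
    for (ti in seq_along(gs)) {
      if (ti <= si) next
      t <- pc + ti
      nz <- sqrt(sum(theta$Phi[rows, gs[[ti]]]^2)) > tol
      adj[s, t] <- nz; adj[t, s] <- nz
    }
  }
  diag(adj) <- FALSE
  adj
}

#' Fit a mixed graphical model skeleton
#'
#' Minimizes the Lee-Hastie negative log-pseudolikelihood over continuous
#' and categorical variables with class-specific sparsity penalties (lasso
#' on continuous-continuous coefficients, group lasso over level
#' coefficients for continuous-discrete pairs and over level-by-level
#' blocks for discrete-discrete pairs) by proximal gradient descent with
#' backtracking line search. An edge is present exactly when its parameter
#' group is nonzero.
#'
#' @param data data.frame; factor columns are categorical, continuous
#'   columns are z-scored internally.
#' @param lambdaCc,lambdaCd,lambdaDd penalties for the three edge classes
#'   (\code{lambdaCd}, \code{lambdaDd} default to \code{lambdaCc}).
#' @param maxIter iteration cap.
#' @param tol relative objective tolerance.
#' @param warm optional warm-start parameter list (from a previous fit).
#' @return list with the undirected \code{graph}
#'   (\linkS4class{MixedGraph}), the parameter list \code{params}, the
#'   objective \code{trace}, and \code{converged}.
#' @export
fitMgm <- function(data, lambdaCc, lambdaCd = lambdaCc,
                   lambdaDd = lambdaCc, maxIter = 1000L, tol = 1e-5,
                   warm = NULL) {
  enc <- mgmEncode(data)
  lambda <- c(cc = lambdaCc, cd = lambdaCd, dd = lambdaDd)
  theta <- if (is.null(warm)) mgmZeroParams(enc) else warm
  sm <- mgmSmooth(theta, enc)
  obj <- sm$f + mgmPenalty(theta, enc, lambda)
  trace <- obj
  step <- 1
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    ## backtracking proximal step
    repeat {
      cand <- mgmProx(paramStep(theta, sm$grad, step), enc, step, lambda)
      d <- paramMinus(cand, theta)
      fCand <- mgmSmooth(cand, enc, gradient = FALSE)$f
      if (fCand <= sm$f + paramGradDot(sm$grad, d) +
            paramDiff2(cand, theta) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    theta <- cand
    sm <- mgmSmooth(theta, enc)
    newObj <- sm$f + mgmPenalty(theta, enc, lambda)
    trace <- c(trace, newObj)
    if (abs(obj - newObj) <= tol * (abs(obj) + 1e-10)) {
      converged <- TRUE
      obj <- newObj
      break
    }
    obj <- newObj
    step <- min(step * 2, 1e3)          # cautious step growth
  }
  adj <- mgmAdjacency(theta, enc)
  amat <- matrix(0L, length(enc$nodes), length(enc$nodes))
  amat[adj] <- MARK_TAIL
  graph <- MixedGraph(enc$nodes, enc$types, amat = amat,
                      metadata = list(kind = "MGM skeleton",
                                      lambda = lambda,
                                      converged = converged))
  list(graph = graph, params = theta, trace = trace, converged = converged,
       enc = enc)
}

## fit a descending lambda path with warm starts; returns list of fits
mgmPath <- function(data, lambdaGrid, maxIter = 1000L, tol = 1e-5) {
  fits <- vector("list", length(lambdaGrid))
  warm <- NULL
  for (i in seq_along(lambdaGrid)) {
    fits[[i]] <- fitMgm(data, lambdaGrid[i], maxIter = maxIter, tol = tol,
                        warm = warm)
    warm <- fits[[i]]$params
  }
  fits
}

#' Default StEPS/StARS lambda grid
#' @param nLambda grid length.
#' @param from,to sparse and dense ends.
#' @return descending (sparse to dense) log-spaced grid.
#' @export
lambdaGridDefault <- function(nLambda = 30L, from = 0.8, to = 0.05) {
  exp(seq(log(from), log(to), length.out = nLambda))
}

#' StEPS stability selection of the MGM penalties
#'
#' Fits the lambda path on subsamples, measures per-edge appearance
#' instability 2 theta (1 - theta) averaged within each edge class, and for
#' each class selects the densest lambda whose monotonized class
#' instability stays at or below the threshold; the final model is refitted
#' on the full data with the selected per-class lambda triple.
#'
#' @param data mixed data.frame.
#' @param lambdaGrid descending (sparse to dense) penalty grid.
#' @param nSubsamples number of subsamples.
#' @param subsampleSize rows per subsample (default \code{floor(10*sqrt(n))},
#'   capped at n - 1).
#' @param threshold instability threshold.
#' @param seed integer seed.
#' @param jointLambda select a single lambda for all classes from the
#'   overall instability instead of per-class values.
#' @param maxIter,tol passed to the subsample fits.
#' @return list with \code{lambda} (named cc/cd/dd), the refitted
#'   \code{graph}, the per-class \code{instability} matrix and the grid.
#' @export
stepsSelect <- function(data, lambdaGrid = lambdaGridDefault(),
                        nSubsamples = 20L, subsampleSize = NULL,
                        threshold = 0.05, seed = 1L, jointLambda = FALSE,
                        maxIter = 500L, tol = 1e-4) {
  n <- nrow(data)
  if (is.null(subsampleSize)) subsampleSize <- min(floor(10 * sqrt(n)), n - 1)
  enc <- mgmEncode(data)
  p <- length(enc$nodes)
  pairClass <- outer(enc$types, enc$types, function(a, b)
    ifelse(a == "continuous" & b == "continuous", "CC",
           ifelse(a == "categorical" & b == "categorical", "DD", "CD")))
  up <- upper.tri(pairClass)
  counts <- array(0, dim = c(p, p, length(lambdaGrid)))
  subs <- withSeed(seed, lapply(seq_len(nSubsamples), function(i)
    sample.int(n, subsampleSize)))
  for (b in seq_len(nSubsamples)) {
    fits <- mgmPath(data[subs[[b]], , drop = FALSE], lambdaGrid,
                    maxIter = maxIter, tol = tol)
    for (i in seq_along(lambdaGrid)) {
      adj <- adjMatrix(fits[[i]]$graph)
      counts[, , i] <- counts[, , i] + adj
    }
  }
  classes <- c("CC", "CD", "DD")
  instab <- matrix(NA_real_, length(lambdaGrid), length(classes) + 1,
                   dimnames = list(NULL, c(classes, "all")))
  for (i in seq_along(lambdaGrid)) {
    theta <- counts[, , i] / nSubsamples
    xi <- 2 * theta * (1 - theta)
    for (cl in classes) {
      sel <- up & pairClass == cl
      instab[i, cl] <- if (any(sel)) mean(xi[sel]) else NA_real_
    }
    instab[i, "all"] <- mean(xi[up])
  }
  pickLambda <- function(col) {
    v <- instab[, col]
    if (all(is.na(v))) return(lambdaGrid[1])
    v <- cummax(ifelse(is.na(v), 0, v))   # monotonize from the sparse end
    ok <- which(v <= threshold)
    if (!length(ok)) {
      warning("no lambda meets the instability threshold for class ", col,
              "; using the sparsest")
      return(lambdaGrid[1])
    }
    lambdaGrid[max(ok)]                   # densest admissible
  }
  lambda <- if (jointLambda) {
    l <- pickLambda("all"); c(cc = l, cd = l, dd = l)
  } else {
    c(cc = pickLambda("CC"), cd = pickLambda("CD"), dd = pickLambda("DD"))
  }
  fit <- fitMgm(data, lambda[["cc"]], lambda[["cd"]], lambda[["dd"]],
                maxIter = 1000L, tol = tol / 10)
  list(lambda = lambda, graph = fit$graph, instability = instab,
       lambdaGrid = lambdaGrid, fit = fit)
}
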