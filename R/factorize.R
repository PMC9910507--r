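#' @include AllClasses.R
NULL

## ---- Empirical Bayes normal means with a point-normal prior -------------
##
## Observations x_i ~ N(theta_i, s2_i), prior theta_i ~ pi0 delta_0 +
## (1 - pi0) N(0, sa2). The prior (pi0, sa2) is fitted by marginal maximum
## likelihood; posterior first and second moments follow in closed form.

## negative marginal loglik and its gradient in (logit pi0, log sa2);
## x2 = x^2 and f0 (the null density) are precomputed by the caller
pnObjGrad <- function(par, x2, s2, f0) {
  pi0 <- stats::plogis(par[1])
  sa2 <- exp(par[2])
  v <- sa2 + s2
  f1 <- exp(-0.5 * log(2 * pi * v) - x2 / (2 * v))
  m <- pmax(pi0 * f0 + (1 - pi0) * f1, 1e-300)
  dPi0 <- sum((f0 - f1) / m) * pi0 * (1 - pi0)
  dA <- sum((1 - pi0) * f1 * 0.5 * (x2 / v^2 - 1 / v) / m) * sa2
  list(value = -sum(log(m)), gradient = c(-dPi0, -dA))
}

ebnmPointNormal <- function(x, s2, gInit = NULL) {
  s2 <- rep_len(s2, length(x))
  x2 <- x^2
  f0 <- exp(-0.5 * log(2 * pi * s2) - x2 / (2 * s2))
  ## moment-based starting value for the slab variance
  sa2Start <- max(mean(x2 - s2), mean(s2) * 0.1, 1e-8)
  start <- if (!is.null(gInit) && is.finite(gInit$s2) && gInit$s2 > 0)
    c(stats::qlogis(min(max(gInit$pi0, 1e-6), 1 - 1e-6)), log(gInit$s2))
  else c(0, log(sa2Start))
  opt <- stats::optim(start,
                      fn = function(p) pnObjGrad(p, x2, s2, f0)$value,
                      gr = function(p) pnObjGrad(p, x2, s2, f0)$gradient,
                      method = "L-BFGS-B",
                      lower = c(-15, -25), upper = c(15, 15),
                      control = list(maxit = 100, factr = 1e5))
  pi0 <- stats::plogis(opt$par[1])
  sa2 <- exp(opt$par[2])
  ## posterior moments
  v <- sa2 + s2
  f1 <- exp(-0.5 * log(2 * pi * v) - x2 / (2 * v))
  marg <- pi0 * f0 + (1 - pi0) * f1
  w1 <- ifelse(marg > 0, (1 - pi0) * f1 / marg, 0)
  shrink <- sa2 / (sa2 + s2)
  mu1 <- shrink * x
  v1 <- shrink * s2
  postMean <- w1 * mu1
  postMean2 <- w1 * (mu1^2 + v1)
  loglik <- sum(log(pmax(marg, 1e-300)))
  ## minus KL(q || g) plus E_q log p(x | theta), via the marginal-likelihood
  ## identity: equals loglik - E_q log N(x; theta, s2)
  eLogLikTilde <- sum(-0.5 * log(2 * pi * s2) -
                        (x^2 - 2 * x * postMean + postMean2) / (2 * s2))
  list(postMean = postMean, postMean2 = postMean2,
       g = list(pi0 = pi0, s2 = sa2),
       loglik = loglik, kl = loglik - eLogLikTilde)
}

## leading singular pair by power iteration (deterministic start)
leadingPair <- function(R, iter = 50) {
  v <- R[which.max(rowSums(R^2)), ]
  nv <- sqrt(sum(v^2))
  if (nv == 0) v <- rep(1, ncol(R)) else v <- v / nv
  u <- rep(0, nrow(R))
  for (it in seq_len(iter)) {
    u <- as.vector(R %*% v)
    nu <- sqrt(sum(u^2)); if (nu == 0) break
    u <- u / nu
    v <- as.vector(crossprod(R, u))
    nv <- sqrt(sum(v^2)); if (nv == 0) break
    v <- v / nv
  }
  d <- as.numeric(crossprod(u, R %*% v))
  list(u = u * sqrt(abs(d)), v = v * sqrt(abs(d)) * sign(d))
}

#' Fit a single EBMF factor on a residual matrix
#'
#' Coordinate-ascent variational fit of the rank-one model
#' \eqn{R = l f^T + E}, with point-normal priors on l and f estimated by
#' empirical Bayes and column-specific residual precisions tau updated each
#' iteration. May converge to the exact zero factor when shrinkage removes
#' all signal.
#'
#' @param R n x p residual matrix.
#' @param tau length-p residual precisions (initialized from the residual
#'   variance when NULL).
#' @param init optional list with starting values \code{l}, \code{f}.
#' @param extraSS length-p vector of additional expected squared residuals
#'   contributed by other factors' posterior variance (used by backfitting;
#'   0 for a standalone fit).
#' @param maxIter,tol inner iteration cap and relative objective tolerance.
#' @param zeroTol zero-factor declaration threshold relative to
#'   \code{normY} (Frobenius norm of the data).
#' @param normY Frobenius norm of the full data matrix (defaults to
#'   \code{norm(R, "F")}).
#' @return list with posterior moments \code{l}, \code{l2}, \code{f},
#'   \code{f2}, priors \code{gl}, \code{gf}, precisions \code{tau}, KL terms
#'   \code{klL}, \code{klF}, the \code{elbo} trace and \code{zero} flag.
#' @export
fitRankOne <- function(R, tau = NULL, init = NULL, extraSS = 0,
                       maxIter = 500L, tol = 1e-7, zeroTol = 1e-10,
                       normY = NULL) {
  if (!all(is.finite(R))) stop("residual matrix contains non-finite values")
  n <- nrow(R); p <- ncol(R)
  if (is.null(normY)) normY <- sqrt(sum(R^2))
  extraSS <- rep_len(extraSS, p)
  R2col <- colSums(R^2)
  if (is.null(tau)) tau <- n / pmax(R2col + extraSS, 1e-12)
  if (is.null(init)) init <- { lp <- leadingPair(R); list(l = lp$u, f = lp$v) }
  El <- init$l; El2 <- El^2
  Ef <- init$f; Ef2 <- Ef^2
  gl <- gf <- NULL
  klL <- klF <- 0
  elbo <- numeric(0)
  zero <- FALSE
  for (it in seq_len(maxIter)) {
    ## l update: normal means with common variance
    dl <- sum(tau * Ef2)
    if (dl < 1e-300) { zero <- TRUE; break }
    xl <- as.vector(R %*% (tau * Ef)) / dl
    ebl <- ebnmPointNormal(xl, 1 / dl, gl)
    El <- ebl$postMean; El2 <- ebl$postMean2
    gl <- ebl$g; klL <- ebl$kl
    sl2 <- sum(El2)
    if (sl2 < 1e-300) { zero <- TRUE; break }
    ## f update: normal means with per-feature variance
    Rl <- as.vector(crossprod(R, El))
    xf <- Rl / sl2
    ebf <- ebnmPointNormal(xf, 1 / (tau * sl2), gf)
    Ef <- ebf$postMean; Ef2 <- ebf$postMean2
    gf <- ebf$g; klF <- ebf$kl
    ## tau update and objective
    Rl <- as.vector(crossprod(R, El))
    erss <- R2col - 2 * Ef * Rl + Ef2 * sl2 + extraSS
    erss <- pmax(erss, 1e-12)
    tau <- n / erss
    obj <- sum(0.5 * n * log(tau / (2 * pi)) - 0.5 * tau * erss) + klL + klF
    elbo <- c(elbo, obj)
    if (sqrt(sum(El^2)) * sqrt(sum(Ef^2)) < zeroTol * normY) {
      zero <- TRUE; break
    }
    if (it > 1 && abs(obj - elbo[it - 1]) <=
          tol * (abs(elbo[it - 1]) + 1e-8)) break
  }
  ## null check: a fitted factor must beat the zero-factor objective,
  ## otherwise coordinate ascent has landed in a weak local optimum and the
  ## factor is discarded
  if (!zero && length(elbo)) {
    erss0 <- pmax(R2col + extraSS, 1e-12)
    tau0 <- n / erss0
    obj0 <- sum(0.5 * n * log(tau0 / (2 * pi)) - 0.5 * n)
    if (obj0 >= elbo[length(elbo)]) zero <- TRUE
  }
  if (zero || !length(elbo)) {
    El <- El2 <- rep(0, n); Ef <- Ef2 <- rep(0, p)
    klL <- klF <- 0
    erss <- pmax(R2col + extraSS, 1e-12)
    tau <- n / erss
    elbo <- c(elbo, sum(0.5 * n * log(tau / (2 * pi)) - 0.5 * tau * erss))
    zero <- TRUE
  }
  list(l = El, l2 = El2, f = Ef, f2 = Ef2, gl = gl, gf = gf, tau = tau,
       klL = klL, klF = klF, elbo = elbo, zero = zero)
}

## expected squared-residual correction contributed by factor k's posterior
## variance: for feature j, Ef2_jk * sum_i El2_ik - Ef_jk^2 * sum_i El_ik^2
factorSSCorrection <- function(L, L2, FF, F2, k) {
  F2[, k] * sum(L2[, k]) - FF[, k]^2 * sum(L[, k]^2)
}

fullObjective <- function(Y, L, L2, FF, F2, tau, klTotal) {
  n <- nrow(Y)
  Rfull <- Y - L %*% t(FF)
  erss <- colSums(Rfull^2)
  for (k in seq_len(ncol(L)))
    erss <- erss + factorSSCorrection(L, L2, FF, F2, k)
  sum(0.5 * n * log(tau / (2 * pi)) - 0.5 * pmax(tau, 1e-300) * erss) +
    klTotal
}

newFactorModel <- function(Y, L, L2, FF, F2, gl, gf, tau, objective) {
  K <- ncol(L)
  new("FactorModel", L = L, FF = FF, L2 = L2, F2 = F2,
      gl = gl, gf = gf, tau = tau, K = as.integer(K),
      objective = objective)
}

#' Greedy EBMF fit
#'
#' Adds factors one at a time: each new factor is fitted by
#' \code{\link{fitRankOne}} on the running residual, and the procedure stops
#' when a new factor optimizes to zero or \code{kMax} is reached, which
#' selects the number of factors automatically.
#'
#' @param Y n x p data matrix.
#' @param kMax maximum number of factors (default \code{min(n, p) / 5}
#'   capped at 200).
#' @param tol relative objective tolerance per rank-one fit.
#' @param maxIter inner iteration cap per factor.
#' @param seed integer seed (the fit is deterministic; kept for interface
#'   symmetry and future stochastic initializations).
#' @return a \linkS4class{FactorModel}; \code{K = 0} yields empty matrices.
#' @export
ebmfGreedy <- function(Y, kMax = NULL, tol = 1e-7, maxIter = 500L,
                       seed = 1L) {
  n <- nrow(Y); p <- ncol(Y)
  if (is.null(kMax)) kMax <- min(200L, max(1L, floor(min(n, p) / 5)))
  normY <- sqrt(sum(Y^2))
  R <- Y
  L <- matrix(0, n, 0); L2 <- matrix(0, n, 0)
  FF <- matrix(0, p, 0); F2 <- matrix(0, p, 0)
  gl <- list(); gf <- list(); kls <- numeric(0)
  tau <- NULL
  extraSS <- rep(0, p)
  objective <- numeric(0)
  for (k in seq_len(kMax)) {
    fit <- fitRankOne(R, tau = tau, extraSS = extraSS,
                      maxIter = maxIter, tol = tol, normY = normY)
    tau <- fit$tau
    if (fit$zero) break
    L <- cbind(L, fit$l); L2 <- cbind(L2, fit$l2)
    FF <- cbind(FF, fit$f); F2 <- cbind(F2, fit$f2)
    gl[[length(gl) + 1]] <- fit$gl
    gf[[length(gf) + 1]] <- fit$gf
    kls <- c(kls, fit$klL + fit$klF)
    R <- R - tcrossprod(fit$l, fit$f)
    extraSS <- extraSS + factorSSCorrection(L, L2, FF, F2, ncol(L))
    objective <- c(objective,
                   fullObjective(Y, L, L2, FF, F2, tau, sum(kls)))
  }
  newFactorModel(Y, L, L2, FF, F2, gl, gf,
                 if (is.null(tau)) n / pmax(colSums(Y^2), 1e-12) else tau,
                 objective)
}

#' Backfitting refinement of an EBMF model
#'
#' Cycles over the factors, refitting each against the residual that
#' excludes it (with all other factors held at their current posterior
#' moments), until the objective change over a sweep falls below \code{tol}.
#' Factors that shrink to zero are dropped.
#'
#' @param model a fitted \linkS4class{FactorModel}.
#' @param Y the data matrix the model was fitted on.
#' @param maxIter maximum number of backfit sweeps.
#' @param tol relative objective tolerance between sweeps.
#' @param innerIter iteration cap for each factor refit within a sweep.
#' @param rotate start the sweeps from an oblique (promax) rotation of the
#'   factor matrix. Greedy fitting explains correlated latent factors with
#'   a near-orthogonal basis, a stationary point coordinate ascent cannot
#'   leave; rotating toward sparse factors first lets the backfit converge
#'   to the correlated solution the sparsity priors favor. If the rotated
#'   start ends below the greedy objective, the plain backfit is used
#'   instead.
#' @return the refined \linkS4class{FactorModel}; its objective trace is
#'   appended to the input model's.
#' @export
ebmfBackfit <- function(model, Y, maxIter = 100L, tol = 1e-7,
                        innerIter = 10L, rotate = TRUE) {
  if (model@K == 0) return(model)
  if (rotate && model@K >= 2) {
    rotated <- promaxRotate(model)
    fit <- ebmfBackfit(rotated, Y, maxIter = maxIter, tol = tol,
                       innerIter = innerIter, rotate = FALSE)
    greedyObj <- if (length(model@objective))
      utils::tail(model@objective, 1) else -Inf
    if (utils::tail(fit@objective, 1) >=
          greedyObj - 1e-8 * (abs(greedyObj) + 1)) return(fit)
    ## rotation landed in a worse basin: fall through to the plain backfit
  }
  n <- nrow(Y); p <- ncol(Y)
  normY <- sqrt(sum(Y^2))
  L <- model@L; L2 <- model@L2; FF <- model@FF; F2 <- model@F2
  gl <- model@gl; gf <- model@gf; tau <- model@tau
  kls <- numeric(ncol(L))
  for (k in seq_len(ncol(L))) kls[k] <- 0   # refreshed on first sweep
  corr <- sapply(seq_len(ncol(L)), function(k)
    factorSSCorrection(L, L2, FF, F2, k))
  corr <- matrix(corr, nrow = p)
  Rfull <- Y - L %*% t(FF)
  objective <- model@objective
  prevObj <- if (length(objective)) utils::tail(objective, 1) else -Inf
  for (sweep in seq_len(maxIter)) {
    for (k in seq_len(ncol(L))) {
      Rk <- Rfull + tcrossprod(L[, k], FF[, k])
      extraSS <- rowSums(corr[, -k, drop = FALSE])
      fit <- fitRankOne(Rk, tau = tau,
                        init = list(l = L[, k], f = FF[, k]),
                        extraSS = extraSS, maxIter = innerIter, tol = tol,
                        normY = normY)
      tau <- fit$tau
      L[, k] <- fit$l; L2[, k] <- fit$l2
      FF[, k] <- fit$f; F2[, k] <- fit$f2
      gl[[k]] <- fit$gl; gf[[k]] <- fit$gf
      kls[k] <- fit$klL + fit$klF
      corr[, k] <- factorSSCorrection(L, L2, FF, F2, k)
      Rfull <- Rk - tcrossprod(L[, k], FF[, k])
    }
    obj <- fullObjective(Y, L, L2, FF, F2, tau, sum(kls))
    objective <- c(objective, obj)
    if (is.finite(prevObj) &&
        abs(obj - prevObj) <= tol * (abs(prevObj) + 1e-8)) break
    prevObj <- obj
  }
  keep <- colSums(L^2) > 0 & colSums(FF^2) > 0
  newFactorModel(Y, L[, keep, drop = FALSE], L2[, keep, drop = FALSE],
                 FF[, keep, drop = FALSE], F2[, keep, drop = FALSE],
                 gl[keep], gf[keep], tau, objective)
}

## oblique promax rotation of the factor side with the inverse applied to
## the loadings, preserving the reconstruction L F^T; posterior variances
## are carried over approximately (they are refreshed by the next sweep)
promaxRotate <- function(model) {
  rot <- tryCatch(stats::promax(model@FF), error = function(e) NULL)
  if (is.null(rot)) return(model)
  Fr <- unclass(rot$loadings)
  Rinv <- tryCatch(solve(t(rot$rotmat)), error = function(e) NULL)
  if (is.null(Rinv)) return(model)
  Lr <- model@L %*% Rinv
  out <- model
  out@F2 <- Fr^2 + pmax(model@F2 - model@FF^2, 0)
  out@L2 <- Lr^2 + pmax(model@L2 - model@L^2, 0)
  out@FF <- Fr
  out@L <- Lr
  out
}

#' Normalize an EBMF model to the unit-loading scale
#'
#' Each loading column l_k is scaled to unit Euclidean norm with the
#' reciprocal scale folded into f_k (the factorization is identifiable only
#' up to a multiplicative constant per factor), so the reconstruction
#' \code{L \%*\% t(F)} is unchanged. The sign is fixed so that the
#' largest-absolute entry of each f_k is positive. Zero-norm columns are
#' dropped.
#'
#' @param model a \linkS4class{FactorModel}.
#' @return the normalized model.
#' @export
normalizeFactors <- function(model) {
  if (model@K == 0) return(model)
  L <- model@L; L2 <- model@L2; FF <- model@FF; F2 <- model@F2
  keep <- rep(TRUE, ncol(L))
  for (k in seq_len(ncol(L))) {
    s <- sqrt(sum(L[, k]^2))
    if (s == 0 || sum(FF[, k]^2) == 0) { keep[k] <- FALSE; next }
    L[, k] <- L[, k] / s; L2[, k] <- L2[, k] / s^2
    FF[, k] <- FF[, k] * s; F2[, k] <- F2[, k] * s^2
    sgn <- sign(FF[, k][which.max(abs(FF[, k]))])
    if (sgn < 0) { FF[, k] <- -FF[, k]; L[, k] <- -L[, k] }
  }
  newFactorModel(NULL, L[, keep, drop = FALSE], L2[, keep, drop = FALSE],
                 FF[, keep, drop = FALSE], F2[, keep, drop = FALSE],
                 model@gl[keep], model@gf[keep], model@tau, model@objective)
}

#' PCA with factor-number selection by the eigenvalue ratio test
#'
#' Computes the eigenvalues of the centered covariance and selects the
#' number of components as the argmax over \code{k <= kBar} of the adjacent
#' eigenvalue ratio \eqn{\lambda_k / \lambda_{k+1}} (ties broken at the
#' smallest k); the search cap can never exceed min(n, p) - 1 and is
#' truncated further when the spectrum is rank deficient.
#'
#' @param Y n x p data matrix.
#' @param kBar search cap for the number of components.
#' @return a \linkS4class{PcaSelection}.
#' @export
pcaEigenvalueRatio <- function(Y, kBar = NULL) {
  n <- nrow(Y); p <- ncol(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sv <- svd(Yc, nu = min(n, p), nv = 0)
  lam <- sv$d^2 / (n - 1)
  maxK <- min(n, p) - 1L
  if (is.null(kBar)) kBar <- maxK
  kBar <- min(as.integer(kBar), maxK)
  ## truncate where eigenvalues vanish (rank deficiency)
  posK <- sum(lam > max(lam) * 1e-12)
  kSearch <- min(kBar, posK - 1L)
  if (kSearch < 1) stop("spectrum too degenerate for the ratio test")
  ratios <- lam[seq_len(kSearch)] / lam[seq_len(kSearch) + 1L]
  kHat <- which.max(ratios)            # ties: lowest k
  scores <- sv$u[, seq_len(kHat), drop = FALSE] %*%
    diag(sv$d[seq_len(kHat)], kHat)
  new("PcaSelection", eigenvalues = lam, kBar = as.integer(kBar),
      kHat = as.integer(kHat), scores = scores)
}
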