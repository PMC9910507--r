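test_that("rank-one fit recovers a planted factor and reports a monotone objective", {
  set.seed(1)
  l <- rnorm(80); f <- c(rnorm(25, sd = 2), rep(0, 75))
  R <- tcrossprod(l, f)
  fitNoiseless <- fitRankOne(R)
  expect_false(fitNoiseless$zero)
  expect_gt(abs(cor(fitNoiseless$l, l)), 0.999)
  fit <- fitRankOne(R + matrix(rnorm(80 * 100, sd = 0.3), 80, 100))
  expect_gt(abs(cor(fit$l, l)), 0.99)
  expect_true(all(diff(fit$elbo) > -1e-6 * abs(fit$elbo[-1])))
  expect_error(fitRankOne(matrix(c(1, NA), 2, 2)), "finite")
})

test_that("null shrinkage returns the zero factor on pure noise", {
  zeros <- 0
  for (s in 1:20) {
    set.seed(s + 400)
    Y <- matrix(rnorm(100 * 100), 100, 100)
    if (fitRankOne(Y)$zero) zeros <- zeros + 1
  }
  expect_gte(zeros, 18)
})

test_that("greedy fit selects the planted number of factors", {
  hits <- 0
  for (s in 1:5) {
    pd <- plantedFactorData(120, 240, 3, seed = s)
    fm <- ebmfGreedy(pd$Y, kMax = 10)
    if (fm@K == 3) hits <- hits + 1
  }
  expect_gte(hits, 4)
  ## pure noise selects zero factors in most seeds
  nullK <- vapply(1:5, function(s) {
    set.seed(s + 50)
    ebmfGreedy(matrix(rnorm(80 * 80), 80, 80), kMax = 4)@K
  }, 0L)
  expect_gte(sum(nullK == 0), 4)
})

test_that("backfitting refines without degrading and keeps the objective monotone", {
  pd <- plantedFactorData(100, 200, 4, seed = 7, corFactors = TRUE)
  fm <- ebmfGreedy(pd$Y, kMax = 8)
  fb <- ebmfBackfit(fm, pd$Y, maxIter = 20)
  obj <- fb@objective
  expect_true(all(diff(obj) > -1e-5 * (abs(obj[-1]) + 1)))
  mccBefore <- matchFactorsMcc(pd$L, normalizeFactors(fm)@L)$mcc
  mccAfter <- matchFactorsMcc(pd$L, normalizeFactors(fb)@L)$mcc
  expect_gte(mccAfter, mccBefore - 0.02)
  ## a converged model is an objective fixed point within tolerance
  fb2 <- ebmfBackfit(fb, pd$Y, maxIter = 3)
  o1 <- utils::tail(fb@objective, 1); o2 <- utils::tail(fb2@objective, 1)
  expect_lt(abs(o2 - o1), 1e-4 * abs(o1))
})

test_that("normalization preserves the reconstruction and fixes scale and sign", {
  pd <- plantedFactorData(60, 120, 3, seed = 9)
  fm <- ebmfGreedy(pd$Y, kMax = 5)
  nf <- normalizeFactors(fm)
  expect_equal(tcrossprod(nf@L, nf@FF), tcrossprod(fm@L, fm@FF),
               tolerance = 1e-12)
  expect_equal(unname(colSums(nf@L^2)), rep(1, nf@K), tolerance = 1e-12)
  for (k in seq_len(nf@K)) {
    expect_gt(nf@FF[which.max(abs(nf@FF[, k])), k], 0)
  }
})

test_that("fitting a scaled matrix recovers the same normalized factors", {
  pd <- plantedFactorData(80, 160, 2, seed = 11)
  n1 <- normalizeFactors(ebmfGreedy(pd$Y, kMax = 4))
  n2 <- normalizeFactors(ebmfGreedy(5 * pd$Y, kMax = 4))
  expect_equal(n1@K, n2@K)
  m <- matchFactorsMcc(n1@L, n2@L)
  expect_gt(m$mcc, 0.99)
})

test_that("recovered factors are not forced orthogonal", {
  ## strongly correlated planted factors at high SNR: the fit must track
  ## the dependence instead of imposing orthogonality as PCA would
  set.seed(13)
  n <- 200; p <- 300
  L <- matrix(rnorm(n * 3, sd = 2), n, 3)
  for (k in 2:3) L[, k] <- 0.8 * L[, k - 1] + 0.6 * rnorm(n, sd = 2)
  FF <- matrix(0, p, 3)
  for (k in 1:3) FF[sample(p, 40), k] <- rnorm(40, sd = 1.5)
  Y <- tcrossprod(L, FF) + matrix(rnorm(n * p, sd = 0.5), n, p)
  nf <- normalizeFactors(ebmfBackfit(ebmfGreedy(Y, kMax = 6), Y,
                                     maxIter = 10))
  skip_if(nf@K < 2)
  cors <- abs(cor(nf@L))
  expect_gt(max(cors[upper.tri(cors)]), 0.1)
})

test_that("eigenvalue ratio test selects the planted spike count", {
  ## hand-computable spectrum: ratios peak at k = 1 (tie broken low)
  set.seed(15)
  lam <- c(8, 4, 2, 1.9, 1.8, 1.7, 1.6)
  ratios <- lam[1:5] / lam[2:6]
  expect_equal(which.max(ratios), 1)
  ## planted 3-spike model
  Z <- matrix(rnorm(400 * 3), 400, 3) %*% diag(c(6, 5, 4))
  Y <- Z %*% matrix(rnorm(3 * 80), 3, 80) + matrix(rnorm(400 * 80), 400, 80)
  sel <- pcaEigenvalueRatio(Y, 10)
  expect_equal(sel@kHat, 3L)
  expect_equal(ncol(sel@scores), 3L)
  expect_true(all(diff(sel@eigenvalues) <= 1e-8))
  ## search cap is respected
  expect_lte(pcaEigenvalueRatio(Y, 2)@kHat, 2L)
})
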