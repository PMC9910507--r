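test_that("factor projection reproduces training scores on clean data", {
  pd <- plantedFactorData(100, 150, 3, seed = 61, noise = 0.2)
  fm <- normalizeFactors(ebmfGreedy(pd$Y, kMax = 6))
  skip_if(fm@K < 1)
  proj <- projectFactors(fm, pd$Y)
  for (k in seq_len(fm@K))
    expect_gt(abs(cor(proj[, k], loadings(fm)[, k])), 0.97)
})

test_that("null outcomes score near chance and planted signals score high", {
  set.seed(63)
  n <- 400; p <- 40
  L <- matrix(rnorm(n * 3, sd = 2), n, 3)
  FF <- matrix(0, p, 3)
  for (k in 1:3) FF[sample(p, 8), k] <- rnorm(8, sd = 1.5)
  X <- tcrossprod(L, FF) + matrix(rnorm(n * p), n, p)
  cfg <- list(kMax = 5, backfit = FALSE, alpha = 0.05, maxDepth = 2)
  ## independent target
  covNull <- data.frame(out = factor(sample(c("n", "y"), n, TRUE)))
  resNull <- predictFromMb(X, covNull, "out", folds = 5, seed = 1,
                           config = cfg)
  expect_lt(abs(resNull$auc - 0.5), 0.12)
  ## target driven by the first latent factor
  pr <- plogis(1.5 * scale(L[, 1]))
  covSig <- data.frame(out = factor(ifelse(runif(n) < pr, "y", "n")))
  resSig <- predictFromMb(X, covSig, "out", folds = 5, seed = 1,
                          config = cfg)
  expect_gt(resSig$auc, 0.8)
  ## fold assignment reproducible
  resSig2 <- predictFromMb(X, covSig, "out", folds = 5, seed = 1,
                           config = cfg)
  expect_identical(resSig$fold, resSig2$fold)
  expect_equal(resSig$auc, resSig2$auc)
  ## stratification: every fold sees both classes
  tab <- table(resSig$fold, covSig$out)
  expect_true(all(tab > 0))
})
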