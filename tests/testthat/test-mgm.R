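test_that("full shrinkage yields the empty graph", {
  set.seed(41)
  d <- data.frame(a = rnorm(300), b = rnorm(300),
                  f = factor(sample(1:3, 300, TRUE)))
  fit <- fitMgm(d, 0.9)
  expect_equal(numEdges(fit$graph), 0)
  expect_error(fitMgm(data.frame(a = rnorm(10), g = factor(rep(1, 10))),
                      0.1), "single level")
})

test_that("a continuous chain is recovered without the shielded edge", {
  hits <- 0
  for (s in 1:5) {
    set.seed(s + 500)
    n <- 1000
    x <- rnorm(n); y <- 0.8 * x + rnorm(n); z <- 0.8 * y + rnorm(n)
    fit <- fitMgm(data.frame(X = x, Y = y, Z = z), 0.15, tol = 1e-6)
    e <- graphEdges(fit$graph)
    keys <- paste(e$from, e$to)
    if (setequal(keys, c("X Y", "Y Z"))) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("the pseudolikelihood at lambda = 0 matches node-wise regressions", {
  set.seed(43)
  n <- 2000
  x <- rnorm(n); y <- 0.6 * x + rnorm(n)
  f <- factor(ifelse(y + rnorm(n) > 0, "a", "b"))
  d <- data.frame(X = x, Y = y, F = f)
  fit <- fitMgm(d, 0, maxIter = 3000, tol = 1e-9)
  enc <- latentcausal:::mgmEncode(d)
  sm <- latentcausal:::mgmSmooth(fit$params, enc, gradient = FALSE)
  ## per-observation log-pseudolikelihood of the fit (restore the Gaussian
  ## 2*pi constants the objective drops)
  llMgm <- -sm$f - log(2 * pi)
  ## node-wise oracle: each conditional maximized separately is an upper
  ## bound, and the two coincide for Markov-consistent truth at large n
  xs <- scale(cbind(x, y))
  r1 <- lm.fit(cbind(1, xs[, 2], model.matrix(~f)[, -1]), xs[, 1])$residuals
  r2 <- lm.fit(cbind(1, xs[, 1], model.matrix(~f)[, -1]), xs[, 2])$residuals
  gfit <- glm(f ~ xs, family = binomial())
  llNode <- -0.5 * (log(2 * pi * sum(r1^2) / n) + 1) -
    0.5 * (log(2 * pi * sum(r2^2) / n) + 1) +
    as.numeric(logLik(gfit)) / n
  expect_lte(llMgm, llNode + 1e-6)
  expect_gt(llMgm, llNode - 0.01)
})

test_that("objective decreases monotonically and the path is nested", {
  set.seed(45)
  n <- 400
  x <- rnorm(n); y <- 0.7 * x + rnorm(n)
  f <- factor(sample(1:2, n, TRUE, prob = c(0.5, 0.5)))
  z <- 0.5 * y + 0.8 * (f == "2") + rnorm(n)
  d <- data.frame(X = x, Y = y, Z = z, F = f)
  fit <- fitMgm(d, 0.2)
  expect_true(all(diff(fit$trace) <= 1e-10))
  grid <- lambdaGridDefault(12)
  fits <- latentcausal:::mgmPath(d, grid)
  counts <- vapply(fits, function(f) numEdges(f$graph), 0L)
  violations <- sum(diff(counts) < 0)   # descending lambda: counts grow
  expect_lte(violations, ceiling(0.05 * length(grid)))
})

test_that("MGM covers the moralized graph on oracle-scale data", {
  g <- generateRandomDag(6, 2, 2.5, seed = 91)
  draw <- sampleLh(g, 10000, coefRange = c(0.5, 1.0), seed = 92)
  d <- data.frame(as.data.frame(draw$Z), draw$D, check.names = FALSE)
  ## lambda scaled with sqrt(log p / n): a consistency-regime penalty so
  ## weak married-parent edges survive at oracle sample size
  fit <- fitMgm(d, 0.7 * sqrt(log(ncol(d)) / nrow(d)), tol = 1e-6)
  mg <- moralize(g)
  est <- adjacencyPr(mg, reorderGraph(fit$graph, g@nodes), "all")
  expect_gte(est$ar, 0.95)
})

test_that("StEPS instability selection behaves on noise and planted data", {
  set.seed(47)
  dNoise <- as.data.frame(matrix(rnorm(400 * 5), 400, 5))
  st <- stepsSelect(dNoise, lambdaGrid = lambdaGridDefault(8),
                    nSubsamples = 6, seed = 2)
  expect_lte(numEdges(st$graph), 1)
  ## empty-graph instability is zero at the sparse end
  expect_lt(st$instability[1, "CC"], 0.05)
  ## planted structure: instability at the densest lambda exceeds the
  ## sparsest across seeds
  worse <- 0
  for (s in 1:3) {
    set.seed(s + 600)
    n <- 300
    x <- rnorm(n); y <- 0.6 * x + rnorm(n); z <- rnorm(n)
    dd <- data.frame(X = x, Y = y, Z = z,
                     F = factor(sample(1:2, n, TRUE)))
    st2 <- stepsSelect(dd, lambdaGrid = lambdaGridDefault(8),
                       nSubsamples = 6, seed = s)
    ins <- st2$instability[, "all"]
    if (ins[length(ins)] >= ins[1]) worse <- worse + 1
  }
  expect_gte(worse, 2)
})
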