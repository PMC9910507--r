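test_that("random DAGs have the requested edge count and are acyclic", {
  for (s in 1:5) {
    g <- generateRandomDag(10, 5, 3.0, c(2, 3), seed = s)
    expect_equal(numEdges(g), round(3.0 * 15 / 2))
    expect_true(isAcyclic(g))
    ## independent acyclicity oracle
    am <- markMatrix(g)
    dir <- (am == 2) * 1
    ig <- igraph::graph_from_adjacency_matrix(t(dir) * 0 + (am == 2 &
      t(am) == 3), mode = "directed")
    expect_true(igraph::is_dag(ig))
    expect_true(all(g@nLevels[nodeTypes(g) == "categorical"] >= 2))
  }
  g <- generateRandomDag(50, 25, 2.67, seed = 1)
  expect_equal(numEdges(g), 100)
  g2 <- generateRandomDag(2, 0, 1.0, seed = 9)
  expect_equal(numEdges(g2), 1)
  expect_error(generateRandomDag(3, 0, 5), "avgDegree")
})

test_that("Lee-Hastie sampling matches closed forms", {
  ## root node: mean 0, sd = noiseSd
  g <- MixedGraph(c("A", "B"))
  g <- setEdge(g, "A", "B")
  tg <- new("TrueGraph", g, nLevels = c(A = NA_integer_, B = NA_integer_))
  d <- sampleLh(tg, 1e5, coefRange = c(0.6, 0.6), seed = 3)
  expect_lt(abs(mean(d$Z[, "A"])), 0.02)
  expect_lt(abs(sd(d$Z[, "A"]) - 1), 0.02)
  ## corr(A, B) = beta / sqrt(beta^2 + 1) for |beta| = 0.6
  expect_lt(abs(abs(cor(d$Z[, "A"], d$Z[, "B"])) - 0.6 / sqrt(1.36)), 0.02)
})

test_that("categorical parents shift continuous children by their level", {
  g <- MixedGraph(c("D1", "Z1"), types = c("categorical", "continuous"))
  g <- setEdge(g, "D1", "Z1")
  tg <- new("TrueGraph", g, nLevels = c(D1 = 2L, Z1 = NA_integer_))
  d <- sampleLh(tg, 1e5, coefRange = c(0.8, 0.8), seed = 5)
  sh <- d$params$Z1$shifts$D1
  grpMeans <- tapply(d$Z[, "Z1"], d$D$D1, mean)
  se <- 3 / sqrt(table(d$D$D1))
  expect_true(all(abs(grpMeans - sh) < se))
})

test_that("conditional Gaussian data violate common covariance, LH does not", {
  g <- MixedGraph(c("D1", "Z1"), types = c("categorical", "continuous"))
  g <- setEdge(g, "D1", "Z1")
  tg <- new("TrueGraph", g, nLevels = c(D1 = 2L, Z1 = NA_integer_))
  dCg <- sampleCg(tg, 1e5, coefRange = c(0.5, 0.5), seed = 2,
                  sdRange = c(0.5, 1.5))
  sds <- tapply(dCg$Z[, "Z1"], dCg$D$D1, sd)
  expTrue <- dCg$params$Z1$confSd
  expect_true(all(abs(sds - expTrue) < 0.03))
  ## the mixture of unequal components is non-Gaussian marginally
  if (abs(diff(expTrue)) > 0.3) {
    z <- scale(dCg$Z[, "Z1"])
    kurt <- mean(z^4)
    expect_gt(abs(kurt - 3), 0.05)
  }
  dLh <- sampleLh(tg, 1e5, coefRange = c(0.5, 0.5), seed = 2)
  sdsLh <- tapply(dLh$Z[, "Z1"], dLh$D$D1, sd)
  expect_lt(abs(diff(sdsLh)), 0.03)
})

test_that("loading matrix keeps the global top fraction by absolute value", {
  A <- generateLoadingMatrix(2500, 50, 0.02, seed = 3)
  expect_equal(sum(A != 0), 2500)
  expect_equal(mean(colSums(A != 0)), 50)
  expect_true(all(colSums(A != 0) >= 1))
  ## brute-force sort oracle at small size
  set.seed(4)
  A2 <- generateLoadingMatrix(10, 2, 0.5, seed = 4)
  full <- withr::with_seed(4, matrix(rnorm(20), 10, 2))
  kept <- abs(full) >= sort(abs(full), decreasing = TRUE)[10]
  expect_equal(A2 != 0, kept)
  expect_equal(A2[kept], full[kept])
  ## dense case
  expect_true(all(generateLoadingMatrix(20, 3, 1, seed = 1) != 0))
})

test_that("observed expansion follows X = Z A^T + E", {
  Z <- matrix(rnorm(50 * 4), 50, 4)
  A <- generateLoadingMatrix(30, 4, 0.2, seed = 7)
  X0 <- expandToObserved(Z, A, noise = FALSE)
  expect_equal(unname(X0), Z %*% t(A))
  X1 <- expandToObserved(Z, A, seed = 8)
  expect_false(isTRUE(all.equal(unname(X1), Z %*% t(A))))
  ## variance decomposition at large n
  Zb <- matrix(rnorm(1e5 * 2), 1e5, 2)
  Ab <- matrix(c(1.5, 0, 0.5, -1), 2, 2)
  Xb <- expandToObserved(Zb, Ab, seed = 9)
  expect_equal(unname(apply(Xb, 2, var)), rowSums(Ab^2) + 1,
               tolerance = 0.05)
  expect_error(expandToObserved(Z, A[, 1:3]), "factor dimension")
})

test_that("subsampling draws unique rows and honors bounds", {
  X <- matrix(rnorm(200 * 3), 200, 3)
  D <- data.frame(f = factor(sample(1:2, 200, TRUE)))
  subs <- subsampleDatasets(X, D, 50, 4, seed = 2)
  expect_length(subs, 4)
  for (s in subs) {
    expect_equal(nrow(s$X), 50)
    expect_equal(anyDuplicated(s$rows), 0)
    expect_equal(nrow(s$D), 50)
  }
  full <- subsampleDatasets(X, NULL, 200, 1, seed = 3)[[1]]
  expect_setequal(full$rows, 1:200)
  expect_error(subsampleDatasets(X, D, 201, 1), "exceeds")
})

test_that("generation is bit-reproducible under a fixed seed", {
  t1 <- simulateBenchmark("CG", "LC", n = 200, nLatents = 5,
                          nCategorical = 3, pObserved = 40, seed = 11)
  t2 <- simulateBenchmark("CG", "LC", n = 200, nLatents = 5,
                          nCategorical = 3, pObserved = 40, seed = 11)
  expect_identical(t1@X, t2@X)
  expect_identical(t1@Z, t2@Z)
  expect_identical(t1@D, t2@D)
  expect_identical(markMatrix(t1@graph), markMatrix(t2@graph))
})

test_that("simulation artifacts round-trip through disk", {
  truth <- simulateBenchmark("LH", "HC", n = 50, nLatents = 4,
                             nCategorical = 2, pObserved = 20, seed = 5)
  dir <- withr::local_tempdir()
  writeSimulation(truth, dir)
  X <- readMatrixTsv(file.path(dir, "X.tsv"))
  expect_equal(unname(X), unname(truth@X), tolerance = 1e-6)
  cov <- readCovariatesTsv(file.path(dir, "covariates.tsv"))
  expect_true(all(vapply(cov, is.factor, TRUE)))
  g <- readGraphTxt(file.path(dir, "graph.txt"))
  expect_identical(unname(markMatrix(g)), unname(markMatrix(truth@graph)))
  meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$seed, 5)
})
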