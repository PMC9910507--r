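test_that("StARS is deterministic under a fixed seed and sparse under noise", {
  set.seed(51)
  n <- 400
  x <- rnorm(n); y <- 0.8 * x + rnorm(n); z <- 0.8 * y + rnorm(n)
  d <- data.frame(X = x, Y = y, Z = z)
  s1 <- starsSelect(d, alphaGrid = c(0.01, 0.05, 0.1), nSubsamples = 8,
                    seed = 7)
  s2 <- starsSelect(d, alphaGrid = c(0.01, 0.05, 0.1), nSubsamples = 8,
                    seed = 7)
  expect_identical(s1$alpha, s2$alpha)
  expect_identical(markMatrix(s1$graph), markMatrix(s2$graph))
  ## pure noise: the sparse end is selected
  dN <- as.data.frame(matrix(rnorm(300 * 5), 300, 5))
  sN <- starsSelect(dN, alphaGrid = c(0.01, 0.05, 0.2), nSubsamples = 8,
                    seed = 3)
  expect_lte(sN$alpha, 0.05)
})

test_that("StARS instability equals an independent recount of edge frequencies", {
  set.seed(53)
  n <- 300
  x <- rnorm(n); y <- 0.7 * x + rnorm(n)
  d <- data.frame(X = x, Y = y, Z = rnorm(n))
  grid <- c(0.01, 0.1)
  st <- starsSelect(d, alphaGrid = grid, nSubsamples = 5, seed = 9)
  ## recount: reproduce the subsample indices and rerun the search
  subs <- latentcausal:::withSeed(9, lapply(1:5, function(i)
    sample.int(n, min(floor(10 * sqrt(n)), n - 1))))
  p <- ncol(d)
  recount <- vapply(seq_along(grid), function(gi) {
    freq <- matrix(0, p, p)
    for (b in 1:5) {
      g <- pcMax(d[subs[[b]], ], alpha = grid[gi], maxDepth = 3)
      freq <- freq + (markMatrix(g) != 0L)
    }
    theta <- freq / 5
    mean((2 * theta * (1 - theta))[upper.tri(theta)])
  }, 0)
  expect_equal(unname(st$instability), recount)
})

test_that("bootstrap ensembles keep strong edges and nest across thresholds", {
  set.seed(55)
  n <- 1200
  a <- rnorm(n); b <- 2 * a + rnorm(n)
  d <- data.frame(A = a, B = b, C = rnorm(n))
  alg <- function(dd) pcMax(dd, alpha = 0.05, maxDepth = 2)
  ens <- bootstrapEnsemble(d, alg, B = 20, keepThreshold = 0.5, seed = 4)
  expect_equal(ens@metadata$frequency[1, 2], 1)
  e <- graphEdges(ens)
  expect_true("A" %in% e$from & "B" %in% e$to)
  ensStrict <- bootstrapEnsemble(d, alg, B = 20, keepThreshold = 0.9,
                                 seed = 4)
  ## higher threshold keeps a subset of the edges
  expect_true(all(markMatrix(ensStrict) == 0L |
                    markMatrix(ens) != 0L))
  expect_error(bootstrapEnsemble(d, alg, B = 1), "at least 2")
})
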