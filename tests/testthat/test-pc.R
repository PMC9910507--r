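test_that("oracle search orients the canonical structures", {
  g <- MixedGraph(c("X", "Y", "Z"))
  collider <- setEdge(setEdge(g, "X", "Z"), "Y", "Z")
  cp <- pcMax(tester = makeOracleTester(collider), alpha = 0.5)
  e <- graphEdges(cp)
  expect_setequal(paste(e$from, e$markTo, e$to), c("X arrow Z", "Y arrow Z"))
  chain <- setEdge(setEdge(g, "X", "Y"), "Y", "Z")
  e2 <- graphEdges(pcMax(tester = makeOracleTester(chain), alpha = 0.5))
  expect_true(all(e2$markFrom == "tail" & e2$markTo == "tail"))
  expect_setequal(paste(e2$from, e2$to), c("X Y", "Y Z"))
})

test_that("sample-based search is near-empty under the null", {
  set.seed(10)
  d <- as.data.frame(matrix(rnorm(1000 * 6), 1000, 6))
  g <- pcMax(d, alpha = 0.01, maxDepth = 2)
  expect_lte(numEdges(g), 2)
})

test_that("the PC-stable skeleton is order independent", {
  set.seed(12)
  n <- 600
  x1 <- rnorm(n); x2 <- 0.7 * x1 + rnorm(n); x3 <- 0.7 * x2 + rnorm(n)
  x4 <- rnorm(n); x5 <- 0.6 * x4 + 0.6 * x3 + rnorm(n)
  d <- data.frame(x1, x2, x3, x4, x5)
  g1 <- pcMax(d, alpha = 0.05)
  perm <- c(4, 2, 5, 1, 3)
  g2 <- pcMax(d[, perm], alpha = 0.05)
  a1 <- adjacencyPr(skeletonFrom(g1), reorderGraph(skeletonFrom(g2),
                                                   g1@nodes), "all")
  expect_equal(a1$ap, 1)
  expect_equal(a1$ar, 1)
})

test_that("an initial graph restricts the output edge set", {
  set.seed(14)
  n <- 800
  a <- rnorm(n); b <- 0.8 * a + rnorm(n); cc <- 0.8 * b + rnorm(n)
  d <- data.frame(A = a, B = b, C = cc)
  init <- MixedGraph(c("A", "B", "C"))
  init <- setEdge(init, "A", "B", "tail", "tail")
  g <- pcMax(d, alpha = 0.05, initGraph = init)
  e <- graphEdges(g)
  expect_true(all(paste(e$from, e$to) %in% "A B"))
})

test_that("Markov blankets from the oracle CPDAG match brute-force d-separation", {
  for (s in 1:6) {
    g <- generateRandomDag(10, 0, 2.6, seed = s + 30)
    cp <- pcMax(tester = makeOracleTester(g), alpha = 0.5, maxDepth = 9)
    for (t in c(1, 5, 9)) {
      mb <- markovBlanket(cp, t)
      others <- setdiff(seq_len(10), t)
      mbTrue <- others[!vapply(others, function(v) {
        S <- setdiff(others, v)
        igraphDsep(g, t, v, S)
      }, TRUE)]
      expect_setequal(mb, g@nodes[mbTrue])
    }
  }
})

test_that("textbook Markov blanket and isolated targets", {
  g <- MixedGraph(c("X", "Y", "T", "Z", "W", "I"))
  g <- setEdge(g, "X", "T"); g <- setEdge(g, "Y", "T")
  g <- setEdge(g, "T", "Z"); g <- setEdge(g, "W", "Z")
  expect_setequal(markovBlanket(g, "T"), c("X", "Y", "Z", "W"))
  expect_length(markovBlanket(g, "I"), 0)
  expect_error(markovBlanket(g, "Q"), "target")
})
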