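## oracle tester over a marginalized DAG: observed nodes obs, tests use
## d-separation in the full graph but can only condition on observed nodes
marginalOracle <- function(graph, obs) {
  list(p = function(xi, yi, Si)
    if (dSeparated(graph, obs[xi], obs[yi], obs[Si])) 1 else 0,
    nodes = graph@nodes[obs], types = graph@types[obs], gauss = NULL,
    n = Inf)
}

test_that("a marginalized common cause yields a non-directed edge", {
  g <- MixedGraph(c("L", "X", "Y"))
  g <- setEdge(g, "L", "X"); g <- setEdge(g, "L", "Y")
  pag <- fci(tester = marginalOracle(g, c(2L, 3L)), alpha = 0.5)
  e <- graphEdges(pag)
  expect_equal(nrow(e), 1)
  expect_true(all(c(e$markFrom, e$markTo) %in% c("circle", "arrow")))
})

test_that("without latents the oracle PAG skeleton matches the CPDAG skeleton", {
  for (s in 1:5) {
    g <- generateRandomDag(7, 0, 2.2, seed = s + 70)
    pag <- fci(tester = makeOracleTester(g), alpha = 0.5, maxDepth = 6)
    cp <- pcMax(tester = makeOracleTester(g), alpha = 0.5, maxDepth = 6)
    expect_identical(markMatrix(pag) != 0L, markMatrix(cp) != 0L)
    ## no fully-tailed edge is produced by the orientation rules alone
    am <- markMatrix(pag)
    idx <- which(upper.tri(am) & am != 0L, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      marks <- c(am[idx[r, 2], idx[r, 1]], am[idx[r, 1], idx[r, 2]])
      expect_false(all(marks == 3L))
    }
  }
})

test_that("colliders among observed variables receive arrowheads", {
  g <- MixedGraph(c("X", "Y", "Z"))
  g <- setEdge(g, "X", "Z"); g <- setEdge(g, "Y", "Z")
  pag <- fci(tester = makeOracleTester(g), alpha = 0.5)
  am <- markMatrix(pag)
  expect_equal(am[1, 3], 2L)  # arrow at Z from X
  expect_equal(am[2, 3], 2L)  # arrow at Z from Y
})

test_that("sample-based FCI finds the confounded pair and spares the isolated one", {
  set.seed(31)
  n <- 1500
  L <- rnorm(n)
  d <- data.frame(X = L + 0.4 * rnorm(n), Y = L + 0.4 * rnorm(n),
                  W = rnorm(n))
  pag <- fci(d, alpha = 0.01)
  e <- graphEdges(pag)
  expect_equal(nrow(e), 1)
  expect_setequal(c(e$from, e$to), c("X", "Y"))
})

test_that("discriminating-path machinery orients into the sepset direction", {
  ## latent confounding between A and B, B -> C, A -> C: classic R4 setting
  ## built as an oracle over the marginalized graph
  g <- MixedGraph(c("H", "A", "B", "C", "D"))
  g <- setEdge(g, "H", "A"); g <- setEdge(g, "H", "B")
  g <- setEdge(g, "A", "C"); g <- setEdge(g, "B", "C")
  g <- setEdge(g, "D", "A")
  pag <- fci(tester = marginalOracle(g, 2:5), alpha = 0.5, maxDepth = 4)
  ## C must not be an ancestor of A or B: edges into C carry arrowheads
  am <- markMatrix(pag)
  nodes <- pag@nodes
  ci <- match("C", nodes)
  for (v in c("A", "B")) {
    vi <- match(v, nodes)
    if (am[vi, ci] != 0L) expect_equal(am[vi, ci], 2L)
  }
})
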