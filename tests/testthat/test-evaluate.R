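test_that("assignment solver attains the exhaustive-permutation maximum", {
  set.seed(21)
  for (r in 1:20) {
    k1 <- sample(2:6, 1); k2 <- sample(2:6, 1)
    C <- matrix(runif(k1 * k2), k1, k2)
    a <- solveAssignment(-C)
    got <- sum(C[cbind(which(!is.na(a)), a[!is.na(a)])])
    expect_equal(got, bruteAssignmentMax(C), tolerance = 1e-10)
    ## injectivity
    expect_equal(anyDuplicated(stats::na.omit(a)), 0)
  }
})

test_that("MCC is invariant to permutation, scaling and sign flips", {
  set.seed(3)
  Z <- matrix(rnorm(300 * 5), 300, 5)
  Ze <- Z[, c(4, 2, 5, 1, 3)] %*% diag(c(3, -0.5, 1, -2, 10))
  m <- matchFactorsMcc(Z, Ze)
  expect_equal(m$mcc, 1, tolerance = 1e-12)
  expect_equal(sort(m$assignment), 1:5)
  ## independent noise scores low
  mNull <- matchFactorsMcc(matrix(rnorm(1000 * 5), 1000, 5),
                           matrix(rnorm(1000 * 5), 1000, 5))
  expect_lt(mNull$mcc, 0.15)
  ## unequal factor counts reported separately
  m2 <- matchFactorsMcc(Z, Ze[, 1:3])
  expect_equal(m2$kTrue, 5)
  expect_equal(m2$kEst, 3)
  expect_length(m2$matched, 3)
  ## constant column handled as zero correlation
  Zc <- Ze; Zc[, 2] <- 1
  expect_true(is.finite(matchFactorsMcc(Z, Zc)$mcc))
})

test_that("adjacency and arrowhead metrics match brute-force enumeration", {
  for (s in 1:20) {
    p <- 8
    types <- sample(c("continuous", "categorical"), p, TRUE)
    gT <- MixedGraph(paste0("N", 1:p), types, amat = randomMarkGraph(p, 0.35, s))
    gE <- MixedGraph(paste0("N", 1:p), types,
                     amat = randomMarkGraph(p, 0.35, s + 100))
    for (cl in c("CC", "CD", "DD", "all")) {
      adj <- adjacencyPr(gT, gE, cl)
      bru <- bruteAdjacency(gT, gE, cl)
      expect_equal(adj$ap, bru$ap)
      expect_equal(adj$ar, bru$ar)
      arr <- arrowheadPr(gT, gE, cl)
      bru2 <- bruteArrowhead(gT, gE, cl)
      expect_equal(arr$ahp, bru2$ahp)
      expect_equal(arr$ahr, bru2$ahr)
    }
  }
})

test_that("hand-counted adjacency example reproduces", {
  g <- MixedGraph(c("A", "B", "C"))
  gT <- setEdge(setEdge(g, "A", "B", "tail", "tail"), "B", "C", "tail", "tail")
  gE <- setEdge(setEdge(g, "A", "B", "tail", "tail"), "A", "C", "tail", "tail")
  pr <- adjacencyPr(gT, gE, "all")
  expect_equal(pr$ap, 0.5)
  expect_equal(pr$ar, 0.5)
  prSame <- adjacencyPr(gT, gT, "all")
  expect_equal(prSame$ap, 1)
  expect_equal(prSame$ar, 1)
})

test_that("arrowhead endpoint table is scored per the orientation rules", {
  g <- MixedGraph(c("A", "B"))
  tDir <- setEdge(g, "A", "B")                  # A -> B
  tUnd <- setEdge(g, "A", "B", "tail", "tail")  # A -- B
  ## predicted A -> B on true A -> B: TP at B, TN at A
  s1 <- arrowheadPr(tDir, tDir, "all")
  expect_equal(c(s1$tp, s1$tn, s1$fp, s1$fn), c(1, 1, 0, 0))
  expect_equal(s1$ahp, 1); expect_equal(s1$ahr, 1)
  ## predicted A -- B on true A -> B: FN at B, TN at A
  s2 <- arrowheadPr(tDir, tUnd, "all")
  expect_equal(c(s2$tp, s2$tn, s2$fp, s2$fn), c(0, 1, 0, 1))
  expect_equal(s2$ahr, 0)
  expect_true(is.na(s2$ahp))
  ## predicted A -> B on true A -- B: FP at B, TN at A
  s3 <- arrowheadPr(tUnd, tDir, "all")
  expect_equal(c(s3$tp, s3$tn, s3$fp, s3$fn), c(0, 1, 1, 0))
  expect_equal(s3$ahp, 0)
})

test_that("expected confounder adjacency is the union of factor cliques", {
  A <- matrix(0, 6, 2)
  A[1:3, 1] <- c(1, -2, 0.5)
  A[4:6, 2] <- c(3, 1, -1)
  adj <- expectedConfounderAdjacency(A)
  expect_true(all(adj[1:3, 1:3][upper.tri(diag(3))]))
  expect_true(all(adj[4:6, 4:6][upper.tri(diag(3))]))
  expect_false(any(adj[1:3, 4:6]))
  expect_false(any(diag(adj)))
  ## random sparse A vs double-loop oracle
  set.seed(8)
  Ar <- matrix(rnorm(40) * rbinom(40, 1, 0.3), 10, 4)
  got <- expectedConfounderAdjacency(Ar)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(got[i, j], any(Ar[i, ] != 0 & Ar[j, ] != 0))
  }
})

test_that("fractional confounded-edge scoring reproduces hand tallies", {
  expected <- matrix(FALSE, 4, 4)
  expected[1, 2] <- expected[2, 1] <- TRUE
  g <- MixedGraph(paste0("X", 1:4))
  ## one expected pair predicted as a double arrow
  g1 <- setEdge(g, "X1", "X2", "arrow", "arrow")
  pr1 <- confoundedEdgePr(g1, expected)
  expect_equal(pr1$ap, 1); expect_equal(pr1$ar, 1)
  ## same pair as o-o: one third TP, two thirds FP
  g2 <- setEdge(g, "X1", "X2", "circle", "circle")
  pr2 <- confoundedEdgePr(g2, expected)
  expect_equal(pr2$ap, 1 / 3); expect_equal(pr2$ar, 1 / 3)
  ## o->: half TP, half FP
  g3 <- setEdge(g, "X1", "X2", "circle", "arrow")
  pr3 <- confoundedEdgePr(g3, expected)
  expect_equal(pr3$ap, 1 / 2); expect_equal(pr3$ar, 1 / 2)
  ## mixed toy: expected {12, 34}; predicted X1<->X2 and X1 o-> X3
  expected2 <- matrix(FALSE, 4, 4)
  expected2[1, 2] <- expected2[2, 1] <- TRUE
  expected2[3, 4] <- expected2[4, 3] <- TRUE
  g4 <- setEdge(setEdge(g, "X1", "X2", "arrow", "arrow"),
                "X1", "X3", "circle", "arrow")
  pr4 <- confoundedEdgePr(g4, expected2)
  expect_equal(pr4$tp, 1); expect_equal(pr4$fp, 1)
  expect_equal(pr4$ap, 0.5); expect_equal(pr4$ar, 0.5)
  ## directed and undirected edges claim no confounding
  g5 <- setEdge(g, "X1", "X2", "tail", "arrow")
  pr5 <- confoundedEdgePr(g5, expected)
  expect_equal(pr5$tp + pr5$fp, 0)
  ## boolean adjacency counts whole units
  pred <- matrix(FALSE, 4, 4); pred[1, 2] <- pred[2, 1] <- TRUE
  pred[1, 3] <- pred[3, 1] <- TRUE
  pr6 <- confoundedEdgePr(pred, expected)
  expect_equal(pr6$tp, 1); expect_equal(pr6$fp, 1)
  ## empty expected set leaves recall undefined
  pr7 <- confoundedEdgePr(pred, matrix(FALSE, 4, 4))
  expect_true(is.na(pr7$ar))
})
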