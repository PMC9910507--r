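test_that("continuous tests detect dependence and conditional independence", {
  set.seed(2)
  n <- 2000
  x <- rnorm(n); z <- 0.8 * x + rnorm(n); y <- 0.8 * z + rnorm(n)
  d <- data.frame(X = x, Y = y, Z = z)
  expect_lt(ciTest(d, "X", "Y")$p, 1e-10)
  expect_gt(ciTest(d, "X", "Y", "Z")$p, 0.01)
  ## identical variables are dependent at any n
  d2 <- data.frame(a = rnorm(200))
  d2$b <- d2$a
  expect_lt(ciTest(d2, "a", "b")$p, 1e-10)
})

test_that("collider conditioning induces dependence", {
  opens <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 2000
    x <- rnorm(n); y <- rnorm(n); z <- 0.8 * x + 0.8 * y + rnorm(n)
    d <- data.frame(X = x, Y = y, Z = z)
    if (ciTest(d, "X", "Y")$p > 0.05 && ciTest(d, "X", "Y", "Z")$p < 0.05)
      opens <- opens + 1
  }
  expect_gte(opens, 6)
})

test_that("mixed-type tests are symmetric and calibrated", {
  set.seed(4)
  n <- 1000
  f <- factor(sample(1:3, n, TRUE))
  w <- c(0, 1.2, -1)[f] + rnorm(n)
  d <- data.frame(F = f, W = w, U = rnorm(n),
                  G = factor(sample(1:2, n, TRUE)))
  expect_lt(ciTest(d, "F", "W")$p, 1e-10)
  expect_identical(ciTest(d, "F", "W")$p, ciTest(d, "W", "F")$p)
  expect_identical(ciTest(d, "F", "G")$p, ciTest(d, "G", "F")$p)
  expect_gt(ciTest(d, "F", "U")$p, 0.001)
  ## type-I calibration of the LRT branch (continuous-categorical pairs)
  ps <- vapply(1:300, function(s) {
    set.seed(s + 900)
    dd <- data.frame(a = rnorm(250),
                     g = factor(sample(1:3, 250, TRUE)),
                     h = factor(sample(1:2, 250, TRUE)))
    ciTest(dd, "a", "g", "h")$p
  }, 0)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
})

test_that("degenerate designs return p = 1 with a flag", {
  d <- data.frame(a = rnorm(50), b = rnorm(50),
                  g = factor(rep(1, 50)))
  r <- ciTest(d, "a", "g")
  expect_true(r$degenerate)
  expect_equal(r$p, 1)
})

test_that("the d-separation oracle matches an igraph-based check", {
  set.seed(6)
  for (s in 1:10) {
    g <- generateRandomDag(8, 0, 2.5, seed = s)
    for (r in 1:15) {
      nodes <- sample(8, sample(2:4, 1))
      x <- nodes[1]; y <- nodes[2]; S <- nodes[-(1:2)]
      expect_equal(dSeparated(g, x, y, S), igraphDsep(g, x, y, S),
                   info = sprintf("seed %d case %d", s, r))
    }
  }
})
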