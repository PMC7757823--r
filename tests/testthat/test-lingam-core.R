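test_that("entropy approximation matches the reference formula", {
  set.seed(1)
  for (x in list(scale(rnorm(500))[, 1], scale(runif(500))[, 1],
                 scale(std_laplace(500))[, 1])) {
    expect_equal(entropy_approx(x), ref_entropy(x), tolerance = 1e-12)
  }
  expect_error(entropy_approx(c(1, NA, 2)), "finite")
  expect_error(entropy_approx(c(1, Inf, 2)), "finite")
  # extreme standardized values must not overflow log cosh
  big <- scale(c(rnorm(100), 500))[, 1]
  expect_true(is.finite(entropy_approx(big)))
})

test_that("entropy approaches the Gaussian limit on normal samples", {
  h_gauss <- 0.5 * (1 + log(2 * pi))
  set.seed(2)
  n <- 1e5
  h <- entropy_approx(scale(rnorm(n))[, 1])
  expect_lt(abs(h - h_gauss), 3 / sqrt(n))
  expect_lte(h, h_gauss + 1e-12)   # penalty terms only subtract
})

test_that("Laplace samples score the analytic sub-Gaussian entropy", {
  # numerical integration of the two expectations under the standardized
  # Laplace density gives H = 1.314588 (vs the Gaussian 1.418939)
  set.seed(3)
  h <- entropy_approx(scale(std_laplace(1e5))[, 1])
  expect_equal(h, 1.314588, tolerance = 0.02)
  expect_lt(h, 0.5 * (1 + log(2 * pi)))
})

test_that("entropy is invariant under sign flip", {
  set.seed(4)
  x <- scale(std_laplace(1000))[, 1]
  expect_identical(entropy_approx(x), entropy_approx(-x))
})

test_that("residual_on is the least-squares residual", {
  set.seed(5)
  xj <- rnorm(200)
  expect_equal(residual_on(xj, xj), rep(0, 200), tolerance = 1e-14)
  xi <- rnorm(200)
  r <- residual_on(xi, xj)
  expect_lt(abs(cov(r, xj)), 1e-13)
  # independent inputs: slope near zero, residual near xi
  expect_gt(cor(r, xi), 0.95)
  expect_error(residual_on(xi, rep(1, 200)), "variance")
})

test_that("pairwise measure is exactly antisymmetric and matches the oracle", {
  set.seed(6)
  x <- std_laplace(2000)
  y <- 0.5 * x + std_laplace(2000)
  expect_identical(pairwise_measure(x, y), -pairwise_measure(y, x))
  expect_equal(pairwise_measure(x, y), ref_pairwise(x, y),
               tolerance = 1e-10)
  m <- pairwise_measure_matrix(cbind(a = x, b = y, c = std_laplace(2000)))
  expect_identical(m + t(m), matrix(0, 3, 3,
                                    dimnames = dimnames(m)))
  expect_identical(unname(diag(m)), rep(0, 3))
})

test_that("Gaussian pairs are unidentifiable, Laplace pairs are not", {
  n <- 50000
  set.seed(7)
  m_gauss <- replicate(5, {
    x <- rnorm(n)
    y <- 0.8 * x + 0.6 * rnorm(n)
    pairwise_measure(x, y)
  })
  expect_lt(max(abs(m_gauss)), 1e-3)
  set.seed(8)
  m_lap <- replicate(5, {
    x <- std_laplace(n)
    y <- 0.8 * x + 0.6 * std_laplace(n)
    pairwise_measure(x, y)
  })
  expect_gt(min(m_lap), 0.05)
})

test_that("the causal direction sign is right in 99+ of 100 seeds", {
  n <- 50000
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- std_laplace(n)
    y <- 0.8 * x + std_laplace(n)
    hits <- hits + (pairwise_measure(x, y) > 0)
  }
  expect_gte(hits, 99)
})

test_that("root scores match the exhaustive oracle and are nonpositive", {
  cfg <- chain3_config(n = 20000, seed = 9)
  tbl <- generate_standardized(cfg)
  scores <- root_scores(tbl)
  # brute force: recompute every pairwise measure independently
  vars <- c("x1", "x2", "x3")
  oracle <- sapply(vars, function(i) {
    -sum(sapply(setdiff(vars, i), function(j) {
      min(0, ref_pairwise(tbl[[i]], tbl[[j]]))^2
    }))
  })
  expect_equal(scores$m_score, unname(oracle), tolerance = 1e-10)
  expect_true(all(scores$m_score <= 0))
  expect_identical(scores$index[which.max(scores$m_score)], "x1")
  expect_identical(select_root(tbl), "x1")
})

test_that("root score is zero iff every measure favors the candidate", {
  m <- matrix(c(0, 0.2, 0.1,
                -0.2, 0, 0.3,
                -0.1, -0.3, 0), 3, 3, byrow = TRUE)
  score <- -rowSums(pmin(m, 0)^2)
  expect_identical(score[1], 0)
  expect_true(all(score[2:3] < 0))
})

test_that("select_root handles singletons and recovers planted roots", {
  single <- tibble::tibble(only = rnorm(10))
  expect_identical(select_root(single), "only")
  n <- 50000
  hits <- 0
  for (s in 1:100) {
    cfg <- pair_config(n = n, seed = 1000 + s, b21 = 0.8)
    tbl <- generate_standardized(cfg)
    hits <- hits + (select_root(tbl) == "x1")
  }
  expect_gte(hits, 99)
})

test_that("deflation removes the root and orthogonalizes", {
  cfg <- chain3_config(n = 5000, seed = 10)
  tbl <- generate_standardized(cfg)
  d <- deflate(tbl, "x1")
  expect_setequal(names(d), c("x2", "x3"))
  # residual before restandardization is orthogonal to the root: the
  # restandardized version stays uncorrelated
  expect_lt(abs(cor(d$x2, tbl$x1)), 1e-12)
  expect_lt(abs(cor(d$x3, tbl$x1)), 1e-12)
  expect_equal(sd(d$x2), 1, tolerance = 1e-12)
  # sequential deflation == joint residualization (Gram-Schmidt)
  d2 <- deflate(d, "x2")
  X <- as.matrix(tbl[c("x1", "x2", "x3")])
  Xs <- scale(X)
  q <- qr(Xs[, 1:2])
  joint <- qr.resid(q, Xs[, 3])
  joint <- (joint - mean(joint)) / sd(joint)
  expect_equal(abs(cor(d2$x3, joint)), 1, tolerance = 1e-10)
})

test_that("estimate_order recovers a planted chain in 99+ of 100 seeds", {
  hits <- 0
  for (s in 1:100) {
    cfg <- chain3_config(n = 50000, seed = 2000 + s)
    tbl <- generate_standardized(cfg)
    hits <- hits + identical(estimate_order(tbl), c("x1", "x2", "x3"))
  }
  expect_gte(hits, 99)
})

test_that("estimate_order always returns a permutation", {
  single <- tibble::tibble(only = rnorm(50))
  expect_identical(estimate_order(single), "only")
  set.seed(11)
  for (k in 1:5) {
    # adversarial inputs: heavy tails, near-Gaussian mixtures
    n <- 500
    X <- tibble::tibble(a = rcauchy(n), b = rnorm(n)^3,
                        c = rnorm(n), d = runif(n))
    expect_setequal(estimate_order(X), c("a", "b", "c", "d"))
  }
})

test_that("Gaussian data never reach planted-model order dominance", {
  n <- 5000
  orders_gauss <- character(20)
  orders_lap <- character(20)
  for (s in 1:20) {
    set.seed(3000 + s)
    e1 <- rnorm(n); e2 <- rnorm(n); e3 <- rnorm(n)
    x1 <- e1; x2 <- 0.6 * x1 + sqrt(1 - 0.36) * e2
    x3 <- 0.6 * x2 + sqrt(1 - 0.36) * e3
    orders_gauss[s] <- paste(estimate_order(cbind(x1 = x1, x2 = x2,
                                                  x3 = x3)), collapse = " ")
    cfg <- chain3_config(n = n, seed = 3000 + s, b21 = 0.6, b32 = 0.6)
    orders_lap[s] <- paste(estimate_order(generate_standardized(cfg)),
                           collapse = " ")
  }
  expect_lt(max(table(orders_gauss)), max(table(orders_lap)))
  expect_identical(names(which.max(table(orders_lap))), "x1 x2 x3")
})

test_that("estimate_order is invariant to affine rescaling", {
  cfg <- chain3_config(n = 5000, seed = 13)
  tbl <- generate_standardized(cfg)
  scaled <- dplyr::mutate(tbl, x1 = 1000 * x1 + 5, x2 = 0.001 * x2 + 7,
                          x3 = x3 - 100)
  expect_identical(estimate_order(scaled), estimate_order(tbl))
})
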