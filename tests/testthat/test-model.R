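test_that("sinusoidal embeddings have the standard structure", {
  b0 <- sinusoidalEmbedding(0, 8)
  expect_equal(b0, rep(c(0, 1), 4))
  expect_equal(sum(b0^2), 4)
  for (n in c(3, 17, 100)) {
    b <- sinusoidalEmbedding(n, 32)
    expect_true(all(abs(b) <= 1))
    ## consecutive (sin, cos) pairs lie on the unit circle
    expect_equal(b[c(TRUE, FALSE)]^2 + b[c(FALSE, TRUE)]^2, rep(1, 16))
  }
  expect_error(sinusoidalEmbedding(1, 7), "even")
})

test_that("multi-head attention matches a loop-over-heads oracle", {
  set.seed(41)
  d <- 12; h <- 3; dh <- d / h
  params <- list(WQ = matrix(rnorm(d * d), d), WK = matrix(rnorm(d * d), d),
                 WV = matrix(rnorm(d * d), d), WO = matrix(rnorm(d * d), d))
  Q <- matrix(rnorm(2 * d), 2); K <- matrix(rnorm(5 * d), 5)
  V <- matrix(rnorm(5 * d), 5)
  out <- multiHeadAttention(Q, K, V, params, h)
  oracle <- matrix(0, 2, d)
  for (i in 1:h) {
    blk <- ((i - 1) * dh + 1):(i * dh)
    S <- (Q %*% params$WQ[, blk]) %*% t(K %*% params$WK[, blk]) / sqrt(dh)
    W <- exp(S) / rowSums(exp(S))
    expect_equal(rowSums(W), rep(1, 2))
    oracle[, blk] <- W %*% (V %*% params$WV[, blk])
  }
  expect_equal(out, oracle %*% params$WO, tolerance = 1e-12)
  ## a single key/value row gets weight 1 regardless of the query
  o1 <- multiHeadAttention(Q, K[1, , drop = FALSE], V[1, , drop = FALSE],
                           params, h)
  expect_equal(o1[1, ], o1[2, ])
})

test_that("the model normalizes exactly over enumerable tree spaces", {
  for (N in 4:5) {
    taxa <- sprintf("t%d", seq_len(N))
    mod <- edgeModel(taxa, d = 8L, h = 2L, seed = N)
    lp <- logProb(mod, enumerateTopologies(taxa))
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-10)
    expect_true(all(is.finite(lp)))   # full support
  }
  ## N = 3: the unique topology has probability 1
  mod3 <- edgeModel(letters[1:3], d = 8L, h = 2L, seed = 1)
  expect_equal(logProb(mod3, enumerateTopologies(taxaOrder(letters[1:3]))), 0)
})

test_that("sampled log-probabilities match teacher-forced evaluation", {
  taxa <- sprintf("t%d", 1:6)
  mod <- edgeModel(taxa, d = 8L, h = 2L, seed = 5)
  s <- sampleTopologies(mod, 25, seed = 42)
  expect_equal(s$logProb, logProb(mod, decisions = s$decisions),
               tolerance = 1e-12)
  expect_equal(s$logProb, logProb(mod, s$topologies), tolerance = 1e-12)
  ## reproducible under the seed
  s2 <- sampleTopologies(mod, 25, seed = 42)
  expect_identical(s$decisions, s2$decisions)
  ## fresh models put mass everywhere: all 15 topologies hit at N = 5
  mod5 <- edgeModel(sprintf("t%d", 1:5), d = 8L, h = 2L, seed = 6)
  s5 <- sampleTopologies(mod5, 600, seed = 7)
  expect_equal(length(unique(vapply(s5$topologies, topoKey, ""))), 15L)
})

test_that("the graph representation is invariant to node order", {
  ## feeding a row-permuted copy of the node features through the pooling
  ## leaves the graph vector unchanged (attention over a set)
  set.seed(43)
  d <- 8; h <- 2
  mod <- edgeModel(sprintf("t%d", 1:5), d = d, h = h, seed = 44)
  p <- mod@params
  X <- matrix(rnorm(6 * d), 6)
  pool <- function(X) {
    at <- list(WQ = p$at.WQ, WK = p$at.WK, WV = p$at.WV, WO = p$at.WO)
    Xl <- PhyloAR:::.lnFwd(X, p$at.g, p$at.b)$Y
    multiHeadAttention(matrix(p$at.q, 1), Xl, Xl, at, h) + p$at.q
  }
  expect_equal(pool(X), pool(X[sample(6), ]), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  taxa <- sprintf("t%d", 1:5)
  mod <- edgeModel(taxa, d = 8L, h = 2L, seed = 9)
  set.seed(10)
  s <- sampleTopologies(mod, 3)
  dec <- s$decisions
  w <- c(0.7, -1.2, 0.4)
  run <- PhyloAR:::.runModel(mod, 3L, decisions = dec, keepCaches = TRUE)
  G <- PhyloAR:::.backwardCaches(mod, run$caches, dec, w)
  f <- function(m) sum(w * PhyloAR:::.runModel(m, 3L, decisions = dec)$logProb)
  eps <- 1e-5
  for (nm in names(mod@params)) {
    g <- G[[nm]]
    expect_false(is.null(g), info = nm)
    idx <- sample(length(mod@params[[nm]]), min(3, length(mod@params[[nm]])))
    for (i in idx) {
      mp <- mod; mp@params[[nm]][i] <- mod@params[[nm]][i] + eps
      mm <- mod; mm@params[[nm]][i] <- mod@params[[nm]][i] - eps
      fd <- (f(mp) - f(mm)) / (2 * eps)
      relErr <- abs(g[i] - fd) / max(1e-3, abs(g[i]) + abs(fd))
      expect_lt(relErr, 1e-3, label = sprintf("%s[%d] grad error", nm, i))
    }
  }
})

test_that("log-probabilities are invariant to the tree representation", {
  taxa <- sprintf("t%d", 1:6)
  mod <- edgeModel(taxa, d = 8L, h = 2L, seed = 11)
  tp <- randomTopology(taxa, seed = 12)
  ## rewrite through Newick (different internal node numbering)
  tp2 <- readNewick(writeNewick(tp))
  expect_equal(logProb(mod, list(tp)), logProb(mod, list(tp2)))
})
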