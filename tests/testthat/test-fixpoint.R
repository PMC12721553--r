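test_that("Dirichlet energy matches hand-computed values", {
  st3 <- initialTree(letters[1:3])
  ## one interior at the centroid of three one-hots: 3 * (4/9 + 1/9 + 1/9)
  expect_equal(dirichletEnergy(matrix(1 / 3, 1, 3), st3), 2)
  ## interior row placed on a leaf's one-hot: that pendant edge contributes 0
  st4 <- attachLeaf(initialTree(letters[1:4]), 3L)
  F <- exactEmbedding(st4, padded = FALSE)
  F2 <- F; F2[2, ] <- c(0, 0, 1, 0)      # interior 2 sits on leaf 3
  manual <- sum((diag(4)[1, ] - F2[1, ])^2) + sum((diag(4)[2, ] - F2[1, ])^2) +
    sum((F2[1, ] - F2[2, ])^2) + 0 + sum((diag(4)[4, ] - F2[2, ])^2)
  expect_equal(dirichletEnergy(F2, st4), manual)
  expect_error(dirichletEnergy(matrix(1 / 3, 2, 3), st3), "row")
})

test_that("the exact embedding solves the harmonic system", {
  st3 <- initialTree(letters[1:3])
  expect_equal(exactEmbedding(st3, padded = FALSE),
               matrix(1 / 3, 1, 3))
  ## 4-leaf tree with split {1,2}|{3,4}: rows (3/8,3/8,1/8,1/8) and mirror
  st4 <- attachLeaf(initialTree(letters[1:4]), 3L)
  F <- exactEmbedding(st4, padded = FALSE)
  expect_equal(sort(F[, 1]), c(1 / 8, 3 / 8))
  expect_equal(F[1, ] + F[2, ], rep(1 / 2, 4))
  set.seed(31)
  for (rep in 1:10) {
    st <- randomState(sample(5:30, 1))
    F <- exactEmbedding(st, padded = FALSE)
    n <- st@n
    expect_equal(rowSums(F), rep(1, n - 2))
    expect_true(all(F >= 0))
    ## residual of the fixed-point equation
    res <- F - interiorAdjacency(st) %*% F / 3 - crossAdjacency(st) / 3
    expect_lt(max(abs(res)), 1e-12)
  }
})

test_that("the exact solution is the energy minimizer", {
  set.seed(32)
  for (rep in 1:5) {
    st <- randomState(sample(5:15, 1))
    F <- exactEmbedding(st, padded = FALSE)
    e0 <- dirichletEnergy(F, st)
    for (k in 1:5) {
      pert <- F + matrix(rnorm(length(F), sd = 0.05), nrow(F))
      expect_gte(dirichletEnergy(pert, st), e0)
    }
  }
})

test_that("fixed-point iteration agrees with the direct solve", {
  st3 <- initialTree(letters[1:3])
  fe <- fixpointEmbedding(st3, fixpointControl(mode = "plain"))
  expect_equal(fe$embeddings[[1]][4, ], c(1 / 3, 1 / 3, 1 / 3))
  expect_equal(fe$iterations, 1L)
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(4:40, 1)
    st <- randomState(n)
    ex <- exactEmbedding(st)
    for (mode in c("plain", "power")) {
      fe <- fixpointEmbedding(st, fixpointControl(mode = mode))
      expect_lt(norm(fe$embeddings[[1]] - ex, "F"), 1e-5 * n)
    }
  }
  ## batched call matches per-state calls
  sts <- replicate(4, randomState(8), simplify = FALSE)
  fb <- fixpointEmbedding(sts)
  for (i in 1:4)
    expect_equal(fb$embeddings[[i]], fixpointEmbedding(sts[[i]])$embeddings[[1]])
  expect_error(fixpointEmbedding(list(randomState(5), randomState(6))),
               "same rank")
})

test_that("power mode equals plain mode at matched iteration counts", {
  set.seed(34)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    st <- randomState(n)
    fe <- fixpointEmbedding(st, fixpointControl(mode = "power"))
    F <- matrix(1 / n, n - 2L, n)
    A3 <- interiorAdjacency(st) / 3; C3 <- crossAdjacency(st) / 3
    for (i in seq_len(fe$iterations)) F <- A3 %*% F + C3
    expect_lt(max(abs(F - fe$embeddings[[1]][(n + 1):(2 * n - 2),
                                             seq_len(n)])), 1e-10)
  }
})

test_that("interior spectral radius has the known closed forms", {
  expect_equal(interiorSpectralRadius(initialTree(letters[1:3])), 0)
  st4 <- attachLeaf(initialTree(letters[1:4]), 1L)
  expect_equal(interiorSpectralRadius(st4), 1)   # single interior edge
  ## caterpillar: interior graph is a path of m nodes
  for (N in c(6, 9)) {
    st <- initialTree(sprintf("t%d", seq_len(N)))
    while (st@n < N) {
      e <- which(st@edges[, 1] == st@n)[1]       # pendant edge of newest leaf
      st <- attachLeaf(st, e)
    }
    m <- N - 2
    expect_equal(interiorSpectralRadius(st), 2 * cos(pi / (m + 1)),
                 tolerance = 1e-10)
    expect_equal(interiorSpectralRadius(asTopology(st)),
                 interiorSpectralRadius(st))
  }
})

test_that("the iteration bound is monotone and sufficient", {
  eps <- 10^seq(-8, -2)
  for (n in c(5, 20, 60)) {
    b <- vapply(eps, iterationBound, 1L, n = n)
    expect_true(all(diff(b) <= 0))
  }
  ## plugging the bound into plain iteration meets the exact-oracle test
  set.seed(35)
  for (rep in 1:10) {
    n <- sample(4:30, 1)
    st <- randomState(n)
    M <- iterationBound(1e-5, n)
    F <- matrix(1 / n, n - 2L, n)
    A3 <- interiorAdjacency(st) / 3; C3 <- crossAdjacency(st) / 3
    for (i in seq_len(M)) F <- A3 %*% F + C3
    err <- norm(F - exactEmbedding(st, padded = FALSE), "F")
    expect_lt(err, 1e-5 * n)
  }
  ## the power trick needs only ceiling(log2(M)) squarings
  st <- randomState(20)
  M <- iterationBound(1e-5, 20)
  fe <- fixpointEmbedding(st, fixpointControl())
  expect_lte(fe$iterations, 2^ceiling(log2(M)))
  expect_gte(fe$iterations, M)
})
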