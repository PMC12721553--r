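test_that("Fitch scores match brute force and phangorn on small trees", {
  t4 <- readNewick("((t1,t2),(t3,t4));")
  expect_equal(fitchScore(t4, siteMatrix(sprintf("t%d", 1:4), "AACC")), 1L)
  expect_equal(fitchScore(t4, siteMatrix(sprintf("t%d", 1:4), "ACAC")), 2L)
  expect_equal(fitchScore(t4, siteMatrix(sprintf("t%d", 1:4), "GGGG")), 0L)
  set.seed(51)
  for (rep in 1:5) {
    N <- sample(4:5, 1)
    tp <- randomTopology(N)
    aln <- simulateJCAlignment(tp, brlens = rexp(2 * N - 3, 5), M = 20)
    expect_equal(fitchScore(tp, aln), bruteFitch(tp, aln))
    pd <- phangorn::phyDat(aln, type = "DNA")
    expect_equal(fitchScore(tp, aln),
                 as.integer(phangorn::fitch(asPhylo(tp), pd)))
  }
  ## ambiguity codes are full-uncertainty: an all-N site costs nothing
  expect_equal(fitchScore(t4, siteMatrix(sprintf("t%d", 1:4), "NN-A")), 0L)
  expect_error(fitchScore(t4, siteMatrix(sprintf("t%d", 1:4), "AZAA")),
               "unknown character")
})

test_that("JC transition matrices behave at the limits", {
  expect_equal(jcTransition(0), diag(4), ignore_attr = TRUE)
  expect_equal(jcTransition(50), matrix(0.25, 4, 4), ignore_attr = TRUE,
               tolerance = 1e-10)
  for (q in c(0.01, 0.3, 2)) {
    P <- jcTransition(q)
    expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)
    expect_equal(P, t(P))
  }
  expect_error(jcTransition(-0.1), "non-negative")
})

test_that("pruning log-likelihood matches the exhaustive sum over
           internal assignments", {
  set.seed(52)
  for (rep in 1:4) {
    N <- sample(4:5, 1)
    tp <- randomTopology(N)
    q <- rexp(2 * N - 3, 10)
    aln <- simulateJCAlignment(tp, brlens = q, M = 10)
    expect_equal(pruningLogLik(tp, q, aln), bruteLogLik(tp, q, aln),
                 tolerance = 1e-10)
    ## root-placement invariance
    lls <- vapply((N + 1):(2 * N - 2), function(r)
      pruningLogLik(tp, q, aln, rootAt = r), 1)
    expect_lt(diff(range(lls)), 1e-8)
  }
  ## 3-leaf star with tiny branches and identical characters: log(1/4)/site
  t3 <- replayDecisions(integer(0), c("a", "b", "c"))
  a3 <- siteMatrix(c("a", "b", "c"), "AAA", "AAA")
  expect_equal(pruningLogLik(t3, rep(1e-9, 3), a3), 2 * log(1 / 4),
               tolerance = 1e-6)
  ## independent implementation: phangorn's pml on the same tree
  tp <- randomTopology(6, seed = 53)
  q <- rexp(9, 10)
  aln <- simulateJCAlignment(tp, brlens = q, M = 40)
  tp@edgeLength <- q
  expect_equal(pruningLogLik(tp, q, aln),
               as.numeric(phangorn::pml(asPhylo(tp),
                                        phangorn::phyDat(aln, type = "DNA"))$logLik),
               tolerance = 1e-8)
})

test_that("branch-length gradients of the log-likelihood are exact", {
  set.seed(54)
  tp <- randomTopology(6)
  q <- rexp(9, 10) + 0.01
  aln <- simulateJCAlignment(tp, brlens = q, M = 25)
  g <- pruningLogLik(tp, q, aln, grad = TRUE)
  expect_equal(g$logLik, pruningLogLik(tp, q, aln))
  for (i in seq_along(q)) {
    e <- 1e-6
    qp <- q; qp[i] <- q[i] + e
    qm <- q; qm[i] <- q[i] - e
    fd <- (pruningLogLik(tp, qp, aln) - pruningLogLik(tp, qm, aln)) / (2 * e)
    expect_equal(g$grad[i], fd, tolerance = 1e-5)
  }
})

test_that("the phylogenetic prior has the stated closed form", {
  tp <- randomTopology(5, seed = 55)
  expect_equal(logPriorPhylo(tp, rep(0, 7)), -log(15) + 7 * log(10))
  q <- rexp(7, 10)
  expect_equal(logPriorPhylo(tp, q),
               -log(15) + sum(dexp(q, 10, log = TRUE)))
  tp2 <- randomTopology(sprintf("t%d", 1:5))
  expect_equal(logPriorPhylo(tp, q) , logPriorPhylo(tp2, q))
  expect_error(logPriorPhylo(tp, c(q[-7], -1)), "non-negative")
})

test_that("the annealing schedule ramps linearly and caps at one", {
  expect_equal(annealBeta(0, 200000), 0.001)
  expect_equal(annealBeta(1e6, 200000), 1)
  H <- 1000
  expect_equal(annealBeta(ceiling(0.999 * H), H), 1)
  t <- seq(0, 2 * H, by = 7)
  expect_true(all(diff(annealBeta(t, H)) >= 0))
})

test_that("VIMCO signals have the baseline-difference structure", {
  expect_equal(vimcoSignals(rep(1.3, 6)), rep(0, 6))
  set.seed(56)
  lw <- rnorm(8)
  expect_equal(vimcoSignals(lw), vimcoSignals(lw + 11.7))
  expect_error(vimcoSignals(2), "at least 2")
  expect_error(vimcoSignals(c(1, Inf)), "finite")
})

test_that("the VIMCO gradient estimator is unbiased on an enumerable toy", {
  ## categorical proposal over two outcomes; exact K-sample bound and its
  ## gradient by enumeration of all outcomes
  theta <- c(0.3, -0.5); f <- c(2.0, 0.5); K <- 3
  qfun <- function(th) exp(th) / sum(exp(th))
  exactBound <- function(th) {
    q <- qfun(th)
    grid <- as.matrix(expand.grid(rep(list(1:2), K)))
    sum(apply(grid, 1, function(x)
      prod(q[x]) * log(mean(exp(log(f[x]) - log(q[x]))))))
  }
  eg <- vapply(1:2, function(i) {
    e <- 1e-6
    tp <- theta; tp[i] <- theta[i] + e
    tm <- theta; tm[i] <- theta[i] - e
    (exactBound(tp) - exactBound(tm)) / (2 * e)
  }, 1)
  set.seed(57)
  nrep <- 1e5
  q <- qfun(theta)
  X <- matrix(sample.int(2, nrep * K, TRUE, prob = q), nrep, K)
  LW <- matrix(log(f[X]) - log(q[X]), nrep, K)
  est <- matrix(0, nrep, 2)
  for (r in seq_len(nrep)) {
    sig <- vimcoSignals(LW[r, ])
    wt <- exp(LW[r, ] - max(LW[r, ])); wt <- wt / sum(wt)
    coef <- sig - wt
    for (i in seq_len(K))
      est[r, ] <- est[r, ] + coef[i] * ((X[r, i] == 1:2) - q)
  }
  mc <- colMeans(est)
  se <- apply(est, 2, sd) / sqrt(nrep)
  expect_true(all(abs(mc - eg) < 3 * se))
})

test_that("the parsimony bound behaves like a multi-sample ELBO", {
  taxa <- sprintf("t%d", 1:5)
  mod <- edgeModel(taxa, d = 8L, h = 2L, seed = 58)
  tp <- randomTopology(taxa, seed = 59)
  aln <- simulateJCAlignment(tp, M = 30, seed = 60)
  pe <- parsimonyElbo(mod, aln, K = 8, beta = 0.7, seed = 61)
  expect_equal(pe$bound,
               log(mean(exp(pe$logWeights - max(pe$logWeights)))) +
                 max(pe$logWeights))
  ## E[exp(bound)] <= Z_beta (Jensen on the unbiased weight average),
  ## with Z_beta exact by enumeration over the 15 topologies
  tops <- enumerateTopologies(taxa)
  sc <- vapply(tops, fitchScore, 1L, alignment = aln)
  Zb <- sum(exp(-0.7 * sc))
  bs <- vapply(1:60, function(s)
    exp(parsimonyElbo(mod, aln, K = 4, beta = 0.7, seed = 100 + s)$bound), 1)
  se <- sd(bs) / sqrt(length(bs))
  expect_lt(mean(bs), Zb + 3 * se)
})

test_that("TDE loss and KL evaluation agree with direct formulas", {
  taxa <- sprintf("t%d", 1:5)
  mod <- edgeModel(taxa, d = 8L, h = 2L, seed = 62)
  tp <- randomTopology(taxa, seed = 63)
  ts1 <- list(topologies = list(tp), weights = 1)
  expect_equal(tdeLoss(mod, ts1), -logProb(mod, list(tp)))
  expect_error(tdeLoss(mod, list(topologies = list(), weights = numeric(0))),
               "empty")
  ## KL(model || model) over its own exhaustive distribution is zero
  tops <- enumerateTopologies(taxa)
  lp <- logProb(mod, tops)
  self <- list(topologies = tops, weights = exp(lp))
  expect_equal(klToTarget(mod, self), 0, tolerance = 1e-6)
  ## uniform target: KL = -log(15) - mean log Q
  unif <- list(topologies = tops, weights = rep(1 / 15, 15))
  expect_equal(klToTarget(mod, unif), -log(15) - mean(lp))
  expect_gte(klToTarget(mod, unif), 0)
})

test_that("lognormal branch draws match their reported density", {
  taxa <- sprintf("t%d", 1:5)
  bm <- branchModel(taxa, hidden = 8L, seed = 64)
  tp <- randomTopology(taxa, seed = 65)
  s <- branchSample(bm, tp, seed = 66)
  expect_length(s$q, 7L)
  expect_true(all(s$q > 0))
  expect_equal(s$logDensity,
               sum(dlnorm(s$q, s$mu, s$sigma, log = TRUE)))
  expect_equal(s$q, exp(s$mu + s$sigma * s$z))
  ## the median of repeated draws per edge is exp(mu)
  qs <- replicate(4000, branchSample(bm, tp)$q)
  expect_equal(apply(qs, 1, median), exp(s$mu), tolerance = 0.05)
})

test_that("VBPI bound ingredients compose into a valid ELBO", {
  taxa <- sprintf("s%d", 1:4)
  tp <- randomTopology(taxa, seed = 67)
  aln <- simulateJCAlignment(tp, M = 20, seed = 68)
  mod <- edgeModel(taxa, d = 8L, h = 2L, seed = 69)
  bm <- branchModel(taxa, hidden = 8L, seed = 70)
  b1 <- vbpiBound(mod, bm, aln, K = 1, seed = 71)
  expect_equal(b1$bound, b1$logWeights)     # K = 1 is the plain ELBO
  bK <- vbpiBound(mod, bm, aln, K = 6, seed = 72)
  expect_equal(bK$bound,
               max(bK$logWeights) +
                 log(mean(exp(bK$logWeights - max(bK$logWeights)))))
})
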