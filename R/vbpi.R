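## Variational Bayesian phylogenetic inference: a diagonal lognormal
## branch-length family whose per-edge locations and scales are read off a
## small MLP over topological edge features, the annealed multi-sample
## bound with VIMCO (topology) + reparametrization (branch) gradients, and
## the importance-sampling marginal-likelihood estimator.

#' Lognormal branch-length model
#'
#' A diagonal lognormal conditional \code{Q(q | tau)}: for every edge of a
#' completed topology, an MLP maps the edge feature (elementwise maximum
#' of the two endpoint rows of the tree's topological node embedding) to
#' the lognormal location and log-scale of that edge's branch length.
#'
#' @param taxa taxa order the model is bound to
#' @param hidden hidden width of the 2-layer MLP
#' @param epsilon fixed-point tolerance for the tree embeddings
#' @param seed optional seed for initialization
#' @return a list of class \code{"branchModel"}
#' @export
branchModel <- function(taxa, hidden = 32L, epsilon = 1e-5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- length(taxa)
  rmat <- function(a, b) matrix(stats::rnorm(a * b, sd = 1 / sqrt(a)), a, b)
  params <- list(
    B.W1 = rmat(N, hidden), B.b1 = numeric(hidden),
    B.g1 = rep(1, hidden), B.be1 = numeric(hidden),
    B.W2 = rmat(hidden, 2L),
    ## start near Exp(10)-scale branch lengths: median 0.1, sigma ~ 0.5
    B.b2 = c(log(0.1), log(0.5)))
  structure(list(taxa = as.character(taxa), hidden = as.integer(hidden),
                 epsilon = epsilon, params = params),
            class = "branchModel")
}

## Dirichlet-energy embedding of a completed topology (padded 2N-2 x N);
## node keys index rows directly at full rank
.embedTopology <- function(topology, epsilon = 1e-5) {
  N <- nLeaves(topology)
  E <- topology@edge
  A <- matrix(0, N - 2L, N - 2L)
  Cx <- matrix(0, N - 2L, N)
  for (i in seq_len(nrow(E))) {
    a <- E[i, 1L]; b <- E[i, 2L]
    if (a <= N) Cx[b - N, a] <- 1
    else { A[a - N, b - N] <- 1; A[b - N, a - N] <- 1 }
  }
  M <- iterationBound(epsilon, N)
  k <- if (M <= 1L) 0L else as.integer(ceiling(log2(M)))
  Abar <- rbind(cbind(diag(N), matrix(0, N, N - 2L)),
                cbind(Cx / 3, A / 3))
  for (i in seq_len(k)) Abar <- Abar %*% Abar
  Abar %*% rbind(diag(N), matrix(1 / N, N - 2L, N))
}

## forward pass of the branch MLP: per-edge (mu, log sigma) + cache
.branchForward <- function(bm, topology) {
  emb <- .embedTopology(topology, bm$epsilon)
  E <- topology@edge
  Xe <- pmax(emb[E[, 1L], , drop = FALSE], emb[E[, 2L], , drop = FALSE])
  p <- bm$params
  Z1 <- sweep(Xe %*% p$B.W1, 2L, p$B.b1, "+")
  ln1 <- .lnFwd(Z1, p$B.g1, p$B.be1)
  H1 <- .elu(ln1$Y)
  out <- sweep(H1 %*% p$B.W2, 2L, p$B.b2, "+")
  list(mu = out[, 1L], logSigma = pmin(out[, 2L], 3),
       clamped = out[, 2L] > 3, Xe = Xe, ln1 = ln1, H1 = H1)
}

## gradient of sum_e (dmu[e] * mu_e + dls[e] * logSigma_e) into env G
.branchBackward <- function(bm, cache, dmu, dls, G) {
  p <- bm$params
  dOut <- cbind(dmu, dls)
  .gAdd(G, "B.W2", crossprod(cache$H1, dOut))
  .gAdd(G, "B.b2", colSums(dOut))
  dH1 <- tcrossprod(dOut, p$B.W2)
  dN1 <- dH1 * .eluGrad(cache$ln1$Y)
  l1 <- .lnBwd(dN1, cache$ln1, p$B.g1)
  .gAdd(G, "B.g1", l1$dg)
  .gAdd(G, "B.be1", l1$db)
  .gAdd(G, "B.W1", crossprod(cache$Xe, l1$dX))
  .gAdd(G, "B.b1", colSums(l1$dX))
  invisible(NULL)
}

#' Sample branch lengths and evaluate their log density
#'
#' Reparametrized draw \code{q_e = exp(mu_e + sigma_e z_e)} with standard
#' normal \code{z_e}, and the lognormal log density of the draw (including
#' the \code{-sum log q_e} Jacobian term).
#'
#' @param bm a \code{\link{branchModel}}
#' @param topology a completed \code{TreeTopology}
#' @param seed optional seed
#' @return list with \code{q} (canonical edge order), \code{z},
#'   \code{logDensity}, \code{mu}, \code{sigma}
#' @export
branchSample <- function(bm, topology, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fw <- .branchForward(bm, topology)
  sigma <- exp(fw$logSigma)
  z <- stats::rnorm(length(fw$mu))
  q <- exp(fw$mu + sigma * z)
  ld <- sum(stats::dlnorm(q, meanlog = fw$mu, sdlog = sigma, log = TRUE))
  list(q = q, z = z, logDensity = ld, mu = fw$mu, sigma = sigma)
}

## draw K (topology, branch) pairs and all log-weight ingredients
.vbpiDraw <- function(model, bm, alignment, K, beta, keepCaches = FALSE,
                      grad = FALSE) {
  run <- .runModel(model, as.integer(K), keepCaches = keepCaches)
  out <- vector("list", K)
  lw <- numeric(K)
  for (i in seq_len(K)) {
    tp <- run$topologies[[i]]
    bfw <- .branchForward(bm, tp)
    sigma <- exp(bfw$logSigma)
    z <- stats::rnorm(length(bfw$mu))
    q <- exp(bfw$mu + sigma * z)
    llk <- pruningLogLik(tp, q, alignment, grad = grad)
    ll <- if (grad) llk$logLik else llk
    lq <- sum(stats::dlnorm(q, bfw$mu, sigma, log = TRUE))
    lw[i] <- beta * ll + logPriorPhylo(tp, q) - run$logProb[i] - lq
    out[[i]] <- list(topology = tp, q = q, z = z, sigma = sigma,
                     bcache = bfw, logLik = ll,
                     llGrad = if (grad) llk$grad else NULL)
  }
  list(run = run, draws = out, logWeights = lw)
}

#' Annealed multi-sample VBPI lower bound
#'
#' Draws K (topology, branch-length) pairs from the variational family
#' and evaluates \code{log(1/K sum_i exp(l_i))} with
#' \code{l_i = beta * logLik + logPrior - log Q(tau_i) - log Q(q_i|tau_i)}.
#' At \code{beta = 1} this lower-bounds the log evidence.
#'
#' @param model an \code{EdgeModel}
#' @param bm a \code{\link{branchModel}}
#' @param alignment character matrix with taxon row names
#' @param K number of samples
#' @param beta annealing weight
#' @param seed optional seed
#' @return list with \code{bound} and \code{logWeights}
#' @export
vbpiBound <- function(model, bm, alignment, K, beta = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- .vbpiDraw(model, bm, alignment, as.integer(K), beta)
  list(bound = .logMeanExp(d$logWeights), logWeights = d$logWeights)
}

#' Importance-sampling estimate of the marginal likelihood
#'
#' Log-mean-exp of independent importance weights at \code{beta = 1},
#' repeated \code{reps} times to report run-to-run spread.
#'
#' @param model an \code{EdgeModel}
#' @param bm a \code{\link{branchModel}}
#' @param alignment character matrix
#' @param nParticles particles per estimate
#' @param reps number of independent estimates
#' @param seed optional seed
#' @return numeric vector of \code{reps} log marginal likelihood estimates
#' @export
marginalLikelihoodIS <- function(model, bm, alignment, nParticles,
                                 reps = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(reps), function(r) {
    lw <- numeric(0)
    left <- nParticles
    while (left > 0L) {                      # draw in manageable batches
      k <- min(left, 50L)
      lw <- c(lw, .vbpiDraw(model, bm, alignment, k, 1)$logWeights)
      left <- left - k
    }
    .logMeanExp(lw)
  }, 1)
}

#' Train the variational family on the annealed posterior
#'
#' Joint stochastic optimization of the topology model (VIMCO estimator)
#' and the lognormal branch model (reparametrization trick, with the exact
#' analytic branch-length gradient of the pruning log-likelihood) against
#' the annealed unnormalized posterior
#' \code{p(Y | tau, q)^beta_t p(tau, q)}.
#'
#' @param model an \code{EdgeModel}
#' @param bm a \code{\link{branchModel}}
#' @param alignment character matrix
#' @param steps parameter updates
#' @param K samples per update (>= 2)
#' @param H annealing period
#' @param lr Adam learning rate
#' @param rate exponential branch prior rate
#' @param seed optional seed
#' @param historyEvery record the bound every this many steps
#' @return list with trained \code{model}, \code{bm} and \code{history}
#' @export
trainVBPI <- function(model, bm, alignment, steps, K = 10L, H = 2000L,
                      lr = 1e-3, rate = 10, seed = NULL,
                      historyEvery = 50L) {
  if (!is.null(seed)) set.seed(seed)
  p <- model@params
  optT <- .adamInit(p)
  optB <- .adamInit(bm$params)
  hist <- list()
  for (t in seq_len(steps)) {
    beta <- annealBeta(t - 1, H)
    dr <- .vbpiDraw(model, bm, alignment, as.integer(K), beta,
                    keepCaches = TRUE, grad = TRUE)
    lw <- dr$logWeights
    sig <- vimcoSignals(lw)
    wt <- exp(lw - max(lw)); wt <- wt / sum(wt)
    Gt <- .backwardCaches(model, dr$run$caches, dr$run$decisions,
                          -(sig - wt))
    Gb <- new.env(parent = emptyenv())
    for (i in seq_len(as.integer(K))) {
      d <- dr$draws[[i]]
      base <- (beta * d$llGrad - rate) * d$q       # d l / d q * q
      dmu <- base + 1
      dls <- base * d$sigma * d$z + d$sigma * d$z + 1
      dls[d$bcache$clamped] <- 0                   # log-scale is capped
      .branchBackward(bm, d$bcache, -wt[i] * dmu, -wt[i] * dls, Gb)
    }
    upT <- .adamStep(p, Gt, optT, lr)
    p <- upT$p; optT <- upT$opt
    model@params <- p
    upB <- .adamStep(bm$params, Gb, optB, lr)
    bm$params <- upB$p; optB <- upB$opt
    if (t %% historyEvery == 0L || t == steps)
      hist[[length(hist) + 1L]] <- data.frame(
        step = t, beta = beta, bound = .logMeanExp(lw))
  }
  list(model = model, bm = bm, history = do.call(rbind, hist))
}
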