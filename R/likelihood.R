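## Jukes-Cantor likelihood machinery: transition probabilities,
## Felsenstein pruning (with analytic branch-length derivatives via an
## outside pass), phylogenetic priors, and an exhaustive small-tree
## evidence computation used as a ground-truth reference at N = 4.

#' Jukes-Cantor transition probability matrix
#'
#' \code{P_jj = 1/4 + 3/4 exp(-4q/3)}, \code{P_jk = 1/4 - 1/4 exp(-4q/3)}
#' for \code{j != k}; the stationary distribution is uniform.
#'
#' @param q non-negative branch length
#' @return 4 x 4 row-stochastic matrix (states A, C, G, T)
#' @export
jcTransition <- function(q) {
  if (q < 0) stop("branch length must be non-negative")
  e <- exp(-4 * q / 3)
  off <- (1 - e) / 4
  m <- matrix(off, 4L, 4L)
  diag(m) <- (1 + 3 * e) / 4
  dimnames(m) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  m
}

## d/dq of jcTransition
.jcTransitionDq <- function(q) {
  e <- exp(-4 * q / 3)
  m <- matrix(e / 3, 4L, 4L)
  diag(m) <- -e
  m
}

## leaf conditional likelihoods (4 x M) from characters; ambiguity codes
## become all-ones over their member states
.leafPartials <- function(chars) {
  masks <- .charMasks(chars)
  rbind(A = as.numeric(bitwAnd(masks, 1L) > 0L),
        C = as.numeric(bitwAnd(masks, 2L) > 0L),
        G = as.numeric(bitwAnd(masks, 4L) > 0L),
        T = as.numeric(bitwAnd(masks, 8L) > 0L))
}

#' Phylogenetic log-likelihood by Felsenstein pruning (JC model)
#'
#' Post-order dynamic programming over conditional likelihoods with
#' per-site rescaling, rooted (arbitrarily, the value is root-invariant
#' under the reversible JC model) at an interior node adjacent to leaf 1.
#' With \code{grad = TRUE} an additional outside pass returns the exact
#' derivative of the log-likelihood with respect to every branch length.
#'
#' @param topology a \code{TreeTopology}
#' @param brlens numeric vector of non-negative branch lengths in the
#'   topology's canonical edge order
#' @param alignment character matrix with taxon row names
#' @param grad also compute d logLik / d q per edge
#' @param rootAt optional node key of the interior root (for testing the
#'   root invariance)
#' @return the log-likelihood, or (with \code{grad}) a list with
#'   \code{logLik} and \code{grad}
#' @export
pruningLogLik <- function(topology, brlens, alignment, grad = FALSE,
                          rootAt = NULL) {
  N <- nLeaves(topology)
  E <- topology@edge
  if (length(brlens) != nrow(E)) stop("need one branch length per edge")
  if (any(brlens < 0)) stop("branch lengths must be non-negative")
  aln <- .alignForTopology(topology, alignment)
  M <- ncol(aln)
  adj <- .adjList(E, 2L * N - 2L)
  root <- if (is.null(rootAt)) adj[[1L]][1L] else as.integer(rootAt)
  if (root <= N) stop("root must be an interior node")
  ro <- .rootedOrder2(adj, root, 2L * N - 2L)
  eix <- .edgeIndexLookup(E)

  Pmats <- lapply(brlens, jcTransition)
  D <- vector("list", 2L * N - 2L)       # scaled conditionals, 4 x M
  logsc <- matrix(0, 2L * N - 2L, M)     # per-node accumulated log scale
  PD <- vector("list", 2L * N - 2L)      # P(q_v) %*% D[v] per child v
  for (v in ro$postorder) {
    if (v <= N) {
      D[[v]] <- .leafPartials(aln[v, ])
    } else {
      kids <- ro$children[[v]]
      prod <- 1
      ls <- 0
      for (k in kids) {
        PD[[k]] <- Pmats[[eix[k, v]]] %*% D[[k]]
        prod <- prod * PD[[k]]
        ls <- ls + logsc[k, ]
      }
      mx <- apply(prod, 2L, max)
      D[[v]] <- sweep(prod, 2L, mx, "/")
      logsc[v, ] <- ls + log(mx)
    }
    if (v == root) break
  }
  siteL <- colSums(D[[root]] * 0.25)
  ll <- sum(log(siteL) + logsc[root, ])
  if (!grad) return(ll)

  ## outside pass: Gq[[v]] is the outside partial at the parent end of the
  ## edge above v (scale-free because only ratios are used)
  dll <- numeric(nrow(E))
  Gq <- vector("list", 2L * N - 2L)
  for (v in ro$preorder) {
    if (v == root) {
      for (k in ro$children[[v]]) {
        out <- matrix(0.25, 4L, M)
        for (k2 in setdiff(ro$children[[v]], k)) out <- out * PD[[k2]]
        Gq[[k]] <- out
      }
      next
    }
    e <- eix[v, ro$parent[v]]
    num <- colSums(Gq[[v]] * (.jcTransitionDq(brlens[e]) %*% D[[v]]))
    den <- colSums(Gq[[v]] * (Pmats[[e]] %*% D[[v]]))
    dll[e] <- sum(num / den)
    if (v > N) {
      above <- crossprod(Pmats[[e]], Gq[[v]])   # JC is symmetric anyway
      for (k in ro$children[[v]]) {
        out <- above
        for (k2 in setdiff(ro$children[[v]], k)) out <- out * PD[[k2]]
        Gq[[k]] <- out
      }
    }
  }
  list(logLik = ll, grad = dll)
}

## rooted traversal from an interior root given an adjacency list
.rootedOrder2 <- function(adj, root, nNodes) {
  parent <- integer(nNodes)
  children <- vector("list", nNodes)
  order <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    kids <- setdiff(adj[[v]], parent[v])
    children[[v]] <- kids
    parent[kids] <- v
    stack <- c(stack, kids)
  }
  list(preorder = order, postorder = rev(order), parent = parent,
       children = children)
}

.edgeIndexLookup <- function(E) {
  n <- max(E)
  eix <- matrix(0L, n, n)
  for (i in seq_len(nrow(E))) {
    eix[E[i, 1L], E[i, 2L]] <- i
    eix[E[i, 2L], E[i, 1L]] <- i
  }
  eix
}

#' Log prior of a phylogenetic tree
#'
#' Uniform over the \code{(2N-5)!!} topologies and i.i.d. exponential
#' branch lengths with the given rate (default \code{Exp(10)}).
#'
#' @param topology a \code{TreeTopology}
#' @param brlens branch lengths in canonical edge order
#' @param rate exponential rate
#' @return log prior density
#' @export
logPriorPhylo <- function(topology, brlens, rate = 10) {
  if (any(brlens < 0)) stop("branch lengths must be non-negative")
  N <- nLeaves(topology)
  -log(nTopologies(N)) + sum(log(rate) - rate * brlens)
}

#' Exhaustive model evidence for four-taxon JC data
#'
#' Ground-truth marginal likelihood \code{p(Y)} for an \code{N = 4}
#' alignment under the uniform topology prior, Exp(rate) branch prior and
#' JC model: the sum over the three topologies of a 5-dimensional
#' Gauss-Legendre quadrature over branch lengths (sites compressed to
#' patterns).  Intended as a reference value for variational bounds and
#' importance-sampling estimates; doubling \code{gridSize} gives a
#' convergence check.
#'
#' @param alignment 4-row character matrix with taxon row names
#' @param gridSize quadrature nodes per branch dimension
#' @param qMax truncation of the branch-length integral (the Exp(rate)
#'   tail mass beyond it is negligible for the default)
#' @param rate exponential branch prior rate
#' @return log evidence
#' @export
exactEvidenceJC <- function(alignment, gridSize = 8L, qMax = 1.2,
                            rate = 10) {
  if (nrow(alignment) != 4L) stop("exact evidence is implemented for N = 4")
  taxa <- rownames(alignment)
  gl <- pracma::gaussLegendre(gridSize, 0, qMax)
  nodes <- gl$x
  logw <- log(gl$w) + log(rate) - rate * nodes   # quadrature x prior
  P <- lapply(nodes, jcTransition)
  tops <- enumerateTopologies(taxaOrder(taxa))
  G <- gridSize
  perTop <- vapply(tops, function(tp) {
    aln <- .alignForTopology(tp, alignment)
    ## leaves attached to each interior node (u = N+1, v = N+2)
    E <- tp@edge
    uLeaf <- E[E[, 2L] == 5L & E[, 1L] <= 4L, 1L]
    vLeaf <- E[E[, 2L] == 6L & E[, 1L] <= 4L, 1L]
    pat <- apply(aln, 2L, paste, collapse = "")
    tab <- table(pat)
    counts <- as.numeric(tab)
    reps <- match(names(tab), pat)
    leafP <- lapply(seq_len(4L), function(i)
      .leafPartials(aln[i, reps, drop = FALSE]))
    ## A-side: interior u with its two leaves; B-side: v with its two
    Aside <- array(0, dim = c(4L, length(reps), G, G))
    Bside <- array(0, dim = c(4L, length(reps), G, G))
    for (g1 in seq_len(G)) for (g2 in seq_len(G)) {
      Aside[, , g1, g2] <-
        (P[[g1]] %*% leafP[[uLeaf[1L]]]) * (P[[g2]] %*% leafP[[uLeaf[2L]]])
      Bside[, , g1, g2] <-
        (P[[g1]] %*% leafP[[vLeaf[1L]]]) * (P[[g2]] %*% leafP[[vLeaf[2L]]])
    }
    terms <- numeric(G^5)
    ti <- 0L
    for (g1 in seq_len(G)) for (g2 in seq_len(G)) {
      A <- Aside[, , g1, g2]
      for (g5 in seq_len(G)) {
        PA <- crossprod(P[[g5]], A)          # 4 x npat
        for (g3 in seq_len(G)) for (g4 in seq_len(G)) {
          Lpat <- 0.25 * colSums(PA * Bside[, , g3, g4])
          ti <- ti + 1L
          terms[ti] <-
            logw[g1] + logw[g2] + logw[g3] + logw[g4] + logw[g5] +
            sum(counts * log(Lpat))
        }
      }
    }
    mx <- max(terms)
    mx + log(sum(exp(terms - mx)))
  }, 1)
  mx <- max(perTop)
  -log(3) + mx + log(sum(exp(perTop - mx)))
}
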