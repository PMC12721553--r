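## Synthetic data generators: uniform and RF-kernel tree distributions
## standing in for posterior tree samples, and forward-simulated
## Jukes-Cantor alignments, so that every pipeline stage runs offline.

#' Uniform random topology
#'
#' Grows a tree with uniform edge choices at every rank.  Because decision
#' sequences are in bijection with topologies and the number of paths to
#' each topology is exactly one, the result is uniform over all
#' \code{(2N-5)!!} labeled topologies.
#'
#' @param taxa taxa order, or a single integer N (labels \code{t1..tN})
#' @param seed optional seed
#' @return a \code{TreeTopology}
#' @export
randomTopology <- function(taxa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(taxa) && length(taxa) == 1L)
    taxa <- sprintf("t%d", seq_len(taxa))
  N <- length(taxa)
  st <- initialTree(taxa)
  while (st@n < N) st <- attachLeaf(st, sample.int(2L * st@n - 3L, 1L))
  asTopology(st)
}

#' Robinson-Foulds kernel target distribution
#'
#' Tabulates \code{p(tau) proportional to exp(-lambda * RF(tau, anchor))}
#' over all topologies on the anchor's taxa by exhaustive enumeration.
#'
#' @param anchor a \code{TreeTopology} with at most 7 leaves
#' @param lambda non-negative concentration (0 gives the uniform
#'   distribution)
#' @return a \code{\linkS4class{ToyTarget}}
#' @export
toyTarget <- function(anchor, lambda = 1) {
  N <- nLeaves(anchor)
  if (N > 7L) stop("toy targets are tabulated exhaustively; need N <= 7")
  if (lambda < 0) stop("lambda must be non-negative")
  tops <- enumerateTopologies(taxaOrder(tipLabels(anchor)))
  rf <- vapply(tops, rfDistance, 1L, t2 = anchor)
  lw <- -lambda * rf
  p <- exp(lw - max(lw)); p <- p / sum(p)
  new("ToyTarget", topologies = tops, probs = p, anchor = anchor,
      lambda = lambda)
}

#' Draw a weighted tree multiset from a tabulated target
#'
#' I.i.d. draws from the probability table, returned as the unique drawn
#' trees with their empirical frequencies as weights (summing to 1).
#'
#' @param target a \code{ToyTarget}
#' @param size number of draws
#' @param seed optional seed
#' @return list with \code{topologies}, \code{weights}, and \code{counts}
#' @export
sampleTreeSet <- function(target, size, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(target@probs), size, replace = TRUE,
                    prob = target@probs)
  tab <- table(idx)
  sel <- as.integer(names(tab))
  list(topologies = target@topologies[sel],
       weights = as.numeric(tab) / size,
       counts = as.integer(tab))
}

#' Simulate an alignment under the Jukes-Cantor model
#'
#' Root states are drawn from the uniform stationary distribution at an
#' interior node and propagated edge by edge with
#' \code{\link{jcTransition}}; sites are i.i.d.
#'
#' @param topology a \code{TreeTopology}
#' @param brlens branch lengths in canonical edge order (default: i.i.d.
#'   Exp(10) draws, matching the prior)
#' @param M number of sites
#' @param seed optional seed
#' @return character matrix (taxa x sites) over A, C, G, T with taxon row
#'   names, with the branch lengths used attached as
#'   \code{attr(, "brlens")}
#' @export
simulateJCAlignment <- function(topology, brlens = NULL, M, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- nLeaves(topology)
  if (is.null(brlens)) brlens <- stats::rexp(2L * N - 3L, rate = 10)
  if (length(brlens) != 2L * N - 3L) stop("need one branch length per edge")
  adj <- .adjList(topology@edge, 2L * N - 2L)
  root <- adj[[1L]][1L]
  ro <- .rootedOrder2(adj, root, 2L * N - 2L)
  eix <- .edgeIndexLookup(topology@edge)
  states <- matrix(0L, 2L * N - 2L, M)
  states[root, ] <- sample.int(4L, M, replace = TRUE)
  for (v in ro$preorder) {
    if (v == root) next
    q <- brlens[eix[v, ro$parent[v]]]
    pSame <- 0.25 + 0.75 * exp(-4 * q / 3)
    par <- states[ro$parent[v], ]
    stay <- stats::runif(M) < pSame
    shift <- sample.int(3L, M, replace = TRUE)
    states[v, ] <- ifelse(stay, par, 1L + (par - 1L + shift) %% 4L)
  }
  out <- matrix(c("A", "C", "G", "T")[states[seq_len(N), ]], N, M)
  rownames(out) <- tipLabels(topology)
  attr(out, "brlens") <- brlens
  out
}
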