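## Fitch parsimony and the annealed variational parsimony objective.

## IUPAC nucleotide codes as 4-bit sets over (A, C, G, T); ambiguity codes
## and gaps map to the full-uncertainty set
.DNA_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
               R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
               B = 14L, D = 13L, H = 11L, V = 7L,
               N = 15L, X = 15L, "-" = 15L, "?" = 15L)

.charMasks <- function(chars) {
  m <- .DNA_MASK[toupper(chars)]
  if (anyNA(m)) stop("unknown character(s): ",
                     paste(unique(chars[is.na(m)]), collapse = " "))
  unname(m)
}

## rooted traversal of a topology: root at leaf `rootLeaf`, giving every
## internal node exactly two children; returns post-order node list with
## parent pointers and the parent edge row index
.rootedOrder <- function(topology, rootLeaf = 1L) {
  N <- nLeaves(topology)
  E <- topology@edge
  adj <- .adjList(E, 2L * N - 2L)
  eix <- matrix(0L, 2L * N - 2L, 2L * N - 2L)
  for (i in seq_len(nrow(E))) {
    eix[E[i, 1L], E[i, 2L]] <- i
    eix[E[i, 2L], E[i, 1L]] <- i
  }
  parent <- integer(2L * N - 2L)
  order <- integer(0)
  stack <- rootLeaf
  parent[rootLeaf] <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    for (nb in adj[[v]]) if (nb != parent[v]) {
      parent[nb] <- v
      stack <- c(stack, nb)
    }
  }
  list(preorder = order, postorder = rev(order), parent = parent,
       edgeIndex = eix, root = rootLeaf)
}

## order the alignment rows by the topology's leaf indexing
.alignForTopology <- function(topology, alignment) {
  if (is.null(rownames(alignment))) stop("alignment must have taxon row names")
  idx <- match(tipLabels(topology), rownames(alignment))
  if (anyNA(idx)) stop("alignment is missing taxa: ",
                       paste(tipLabels(topology)[is.na(idx)], collapse = " "))
  alignment[idx, , drop = FALSE]
}

#' Fitch parsimony score
#'
#' The minimum number of character-state changes over all assignments of
#' characters to the internal nodes, summed over sites, computed per site
#' by the set-intersection recursion on a rooted copy of the tree (rooted
#' at leaf 1, which leaves every internal node with two children; the
#' score does not depend on the rooting).  Ambiguity codes and gaps count
#' as full-uncertainty sets.
#'
#' @param topology a \code{TreeTopology}
#' @param alignment character matrix with taxon row names covering the
#'   topology's leaves
#' @param perSite return the per-site score vector instead of the total
#' @return integer score
#' @export
fitchScore <- function(topology, alignment, perSite = FALSE) {
  N <- nLeaves(topology)
  aln <- .alignForTopology(topology, alignment)
  M <- ncol(aln)
  ro <- .rootedOrder(topology)
  sets <- matrix(0L, 2L * N - 2L, M)
  for (i in seq_len(N)) sets[i, ] <- .charMasks(aln[i, ])
  changes <- integer(M)
  adj <- .adjList(topology@edge, 2L * N - 2L)
  for (v in ro$postorder) {
    if (v <= N) next
    kids <- setdiff(adj[[v]], ro$parent[v])
    s <- sets[kids[1L], ]
    for (k in kids[-1L]) {
      inter <- bitwAnd(s, sets[k, ])
      disjoint <- inter == 0L
      changes <- changes + disjoint
      s <- ifelse(disjoint, bitwOr(s, sets[k, ]), inter)
    }
    sets[v, ] <- s
  }
  ## the leaf root contributes a change if its state is outside its
  ## child's set
  rootChild <- setdiff(adj[[ro$root]], 0L)[1L]
  changes <- changes +
    (bitwAnd(sets[ro$root, ], sets[rootChild, ]) == 0L)
  if (perSite) return(as.integer(changes))
  as.integer(sum(changes))
}

#' Annealing schedule
#'
#' \code{beta_t = min(1, floor + t / H)}: a linear ramp from \code{floor}
#' reaching 1 after (slightly less than) \code{H} iterations and capped
#' there.
#'
#' @param t iteration index (>= 0)
#' @param H annealing period
#' @param floor starting inverse temperature (default 0.001)
#' @return annealing weight in (0, 1]
#' @export
annealBeta <- function(t, H, floor = 0.001) pmin(1, floor + t / H)

.logMeanExp <- function(l) {
  mx <- max(l)
  mx + log(mean(exp(l - mx)))
}

#' VIMCO leave-one-out learning signals
#'
#' For multi-sample bounds over discrete latent variables, the per-sample
#' signal is the bound minus the bound with that sample's log-weight
#' replaced by the arithmetic mean of the others (the geometric-mean
#' baseline of the original estimator).  The full gradient estimator of
#' the bound combines these signals with the pathwise term:
#' \code{sum_i (signal_i - wtilde_i) * grad log Q(tau_i)} where
#' \code{wtilde} are the normalized importance weights.
#'
#' @param logWeights numeric vector of K >= 2 finite log-weights
#' @return numeric vector of per-sample signals
#' @export
vimcoSignals <- function(logWeights) {
  K <- length(logWeights)
  if (K < 2L) stop("VIMCO needs at least 2 samples")
  if (any(!is.finite(logWeights))) stop("log-weights must be finite")
  lhat <- .logMeanExp(logWeights)
  vapply(seq_len(K), function(i) {
    held <- logWeights
    held[i] <- mean(logWeights[-i])
    lhat - .logMeanExp(held)
  }, 1)
}

#' Multi-sample annealed parsimony lower bound
#'
#' Draws K topologies from the model and evaluates the bound
#' \code{log(1/K sum_i exp(-beta * S(tau_i; Y) - log Q(tau_i)))} against
#' the annealed parsimony target.
#'
#' @param model an \code{EdgeModel}
#' @param alignment character matrix with taxon row names
#' @param K number of samples (>= 1)
#' @param beta annealing weight
#' @param seed optional seed
#' @return list with \code{bound}, \code{logWeights}, \code{scores},
#'   \code{topologies}
#' @export
parsimonyElbo <- function(model, alignment, K, beta = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- sampleTopologies(model, K)
  sc <- vapply(s$topologies, fitchScore, 1L, alignment = alignment)
  lw <- -beta * sc - s$logProb
  list(bound = .logMeanExp(lw), logWeights = lw, scores = sc,
       topologies = s$topologies)
}

#' Train the model on the annealed variational parsimony objective
#'
#' Stochastic gradient ascent on the K-sample annealed bound with the
#' VIMCO estimator and Adam.  The target at iteration t is
#' \code{P(tau) proportional to exp(-beta_t * S(tau; Y))} with
#' \code{beta_t = min(1, floor + t/H)}.
#'
#' @param model an \code{EdgeModel}
#' @param alignment character matrix with taxon row names
#' @param steps number of parameter updates
#' @param K samples per update (>= 2)
#' @param H annealing period
#' @param lr Adam learning rate
#' @param floor annealing floor
#' @param seed optional seed
#' @param historyEvery record the bound every this many steps
#' @return list with the trained \code{model} and a \code{history}
#'   data.frame (step, beta, bound, minScore)
#' @export
trainParsimony <- function(model, alignment, steps, K = 10L, H = 2000L,
                           lr = 1e-3, floor = 0.001, seed = NULL,
                           historyEvery = 50L) {
  if (!is.null(seed)) set.seed(seed)
  p <- model@params
  opt <- .adamInit(p)
  hist <- list()
  for (t in seq_len(steps)) {
    beta <- annealBeta(t - 1, H, floor)
    run <- .runModel(model, as.integer(K), keepCaches = TRUE)
    sc <- vapply(run$topologies, fitchScore, 1L, alignment = alignment)
    lw <- -beta * sc - run$logProb
    sig <- vimcoSignals(lw)
    wt <- exp(lw - max(lw)); wt <- wt / sum(wt)
    coef <- sig - wt
    G <- .backwardCaches(model, run$caches, run$decisions, -coef)
    up <- .adamStep(p, G, opt, lr)
    p <- up$p; opt <- up$opt
    model@params <- p
    if (t %% historyEvery == 0L || t == steps)
      hist[[length(hist) + 1L]] <- data.frame(
        step = t, beta = beta, bound = .logMeanExp(lw),
        minScore = min(sc))
  }
  list(model = model, history = do.call(rbind, hist))
}
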