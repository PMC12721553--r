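## Tree topology density estimation: maximum-likelihood fitting of the
## autoregressive model to a weighted collection of topologies, and exact
## KL evaluation against enumerable targets.

#' Negative weighted log-likelihood of a tree collection
#'
#' With \code{batch = NULL} the exact weighted mean
#' \code{-sum_i w_i log Q(tau_i)} over the whole collection; otherwise the
#' unweighted mean over a minibatch drawn with probability proportional to
#' the weights (the stochastic training loss).
#'
#' @param model an \code{EdgeModel}
#' @param treeSet list with \code{topologies} and normalized
#'   \code{weights} (as returned by \code{\link{readTreeSet}} or
#'   \code{\link{sampleTreeSet}})
#' @param batch optional minibatch size
#' @param seed optional seed for the minibatch draw
#' @return scalar loss
#' @export
tdeLoss <- function(model, treeSet, batch = NULL, seed = NULL) {
  if (!length(treeSet$topologies)) stop("empty training set")
  w <- treeSet$weights / sum(treeSet$weights)
  if (is.null(batch)) {
    lp <- logProb(model, treeSet$topologies)
    return(-sum(w * lp))
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(w), batch, replace = TRUE, prob = w)
  -mean(logProb(model, treeSet$topologies[idx]))
}

#' Exact KL divergence from a tabulated target to the model
#'
#' \code{sum_tau w(tau) (log w(tau) - log Q(tau))} over the support of the
#' target.  The model has full support over topology space, so the KL is
#' always finite.
#'
#' @param model an \code{EdgeModel}
#' @param target a \code{\linkS4class{ToyTarget}}, or a list with
#'   \code{topologies} and \code{weights} summing to 1
#' @return non-negative scalar
#' @export
klToTarget <- function(model, target) {
  if (is(target, "ToyTarget"))
    target <- list(topologies = target@topologies, weights = target@probs)
  w <- target$weights
  if (abs(sum(w) - 1) > 1e-6) stop("target weights must sum to 1")
  keep <- w > 0
  lp <- logProb(model, target$topologies[keep])
  sum(w[keep] * (log(w[keep]) - lp))
}

#' Fit the model to a tree collection by maximum likelihood
#'
#' Stochastic gradient ascent (Adam) on the weighted log-likelihood.
#' Decision sequences and fixed-point embeddings of the unique training
#' trees are precomputed once, so each update only runs the network.
#'
#' @param model an \code{EdgeModel}
#' @param treeSet list with \code{topologies} and \code{weights}
#' @param steps number of parameter updates
#' @param batch minibatch size (trees drawn by weight, with replacement)
#' @param lr Adam learning rate
#' @param seed optional seed
#' @param historyEvery record the minibatch loss every this many steps
#' @return list with trained \code{model} and \code{history}
#' @export
trainTDE <- function(model, treeSet, steps, batch = 10L, lr = 1e-3,
                     seed = NULL, historyEvery = 50L) {
  if (!is.null(seed)) set.seed(seed)
  w <- treeSet$weights / sum(treeSet$weights)
  taxa <- model@taxa
  decs <- vapply(treeSet$topologies,
                 function(t) decomposeTopology(t, taxa),
                 integer(length(taxa) - 3L))
  if (is.vector(decs)) decs <- matrix(decs, nrow = length(taxa) - 3L)
  traces <- lapply(seq_len(ncol(decs)),
                   function(i) .traceDecisions(model, decs[, i]))
  p <- model@params
  opt <- .adamInit(p)
  hist <- list()
  batch <- as.integer(batch)
  for (t in seq_len(steps)) {
    idx <- sample.int(length(w), batch, replace = TRUE, prob = w)
    run <- .runModel(model, batch, decisions = decs[, idx, drop = FALSE],
                     traces = traces[idx], keepCaches = TRUE)
    G <- .backwardCaches(model, run$caches, decs[, idx, drop = FALSE],
                         rep(-1 / batch, batch))
    up <- .adamStep(p, G, opt, lr)
    p <- up$p; opt <- up$opt
    model@params <- p
    if (t %% historyEvery == 0L || t == steps)
      hist[[length(hist) + 1L]] <- data.frame(
        step = t, loss = -mean(run$logProb))
  }
  list(model = model, history = do.call(rbind, hist))
}
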