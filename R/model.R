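## The attention-based edge-decision network and the batched autoregressive
## sampler / evaluator over tree topologies.
##
## At rank n every tree in a batch contributes m = 2n - 2 node rows
## (leaves 1..n, then interiors 1..n-2), stacked tree-major into one
## matrix, so all dense layers run as single matrix products across the
## whole batch.  The forward pass per rank is:
##   padded fixed-point embeddings -> embedding MLP L -> node features X
##   -> layer norm -> single-query multi-head attention + residual
##   -> graph readout MLP -> graph vector r
##   edge features p(e) = elementwise max of endpoint rows of X
##   scores = edge readout MLP(concat(p(e), r) + b_n) -> softmax -> alpha.

#' Construct an edge-decision model
#'
#' Initializes all learnable tensors with fan-in-scaled Gaussian weights.
#' The model is bound to a taxa order: leaf \code{i} of every generated
#' tree is \code{taxa[i]}.
#'
#' @param taxa taxa order (use \code{\link{taxaOrder}} for the default
#'   lexicographic order)
#' @param d node feature dimension (divisible by \code{h})
#' @param h number of attention heads
#' @param hidden width of the hidden layer of the three 2-layer MLPs
#'   (embedding map, graph readout, edge readout); defaults to \code{d}
#' @param epsilon stopping tolerance of the fixed-point embedding iteration
#' @param seed optional integer seed for the initialization draw
#' @return an \code{\linkS4class{EdgeModel}}
#' @export
edgeModel <- function(taxa, d = 100L, h = 4L, hidden = d, epsilon = 1e-5,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- length(taxa)
  d <- as.integer(d); h <- as.integer(h); hidden <- as.integer(hidden)
  rmat <- function(a, b) matrix(stats::rnorm(a * b, sd = 1 / sqrt(a)), a, b)
  mlp <- function(pre, ins, hid, outs) {
    p <- list(rmat(ins, hid), numeric(hid), rep(1, hid), numeric(hid),
              rmat(hid, outs), numeric(outs), rep(1, outs), numeric(outs))
    names(p) <- paste0(pre, c(".W1", ".b1", ".g1", ".be1",
                              ".W2", ".b2", ".g2", ".be2"))
    p
  }
  params <- c(
    mlp("L", N, hidden, d),
    list(at.g = rep(1, d), at.b = numeric(d),
         at.q = stats::rnorm(d, sd = 1 / sqrt(d)),
         at.WQ = rmat(d, d), at.WK = rmat(d, d),
         at.WV = rmat(d, d), at.WO = rmat(d, d)),
    mlp("Rg", d, hidden, d),
    mlp("Re", 2L * d, hidden, 1L))
  ## scalar head: drop the unused output layer norm parameters
  params$Re.g2 <- NULL; params$Re.be2 <- NULL
  new("EdgeModel", taxa = as.character(taxa), d = d, h = h,
      epsilon = epsilon, params = params)
}

## local node row of key k in a rank-n state (leaves first, then interiors)
.localRows <- function(keys, n, N) ifelse(keys <= N, keys, n + keys - N)

## per-state edge endpoint rows for the current rank
.stateGeometry <- function(state) {
  n <- state@n; N <- length(state@taxa)
  list(eu = .localRows(state@edges[, 1L], n, N),
       ev = .localRows(state@edges[, 2L], n, N))
}

## full forward pass for one rank over a stacked batch
.forwardRank <- function(p, d, h, X0, B, m, iu, iv, edgeTree, bn) {
  dh <- d %/% h
  sdh <- sqrt(dh)
  Lc <- .mlpFwd(X0, p, "L")
  X <- Lc$out
  aln <- .lnFwd(X, p$at.g, p$at.b)
  Xl <- aln$Y
  qW <- as.vector(p$at.q %*% p$at.WQ)
  K <- Xl %*% p$at.WK
  V <- Xl %*% p$at.WV
  grp <- rep(seq_len(B), each = m)
  att <- vector("list", h)
  O <- matrix(0, B, d)
  for (i in seq_len(h)) {
    blk <- ((i - 1L) * dh + 1L):(i * dh)
    sc <- as.vector(K[, blk, drop = FALSE] %*% qW[blk]) / sdh
    S <- matrix(sc, m, B)
    S <- exp(sweep(S, 2L, apply(S, 2L, max), "-"))
    A <- sweep(S, 2L, colSums(S), "/")
    att[[i]] <- A
    O[, blk] <- rowsum(V[, blk, drop = FALSE] * as.vector(A), grp)
  }
  Mt <- O %*% p$at.WO
  rbar <- sweep(Mt, 2L, p$at.q, "+")
  Rgc <- .mlpFwd(rbar, p, "Rg")
  r <- Rgc$out
  Xu <- X[iu, , drop = FALSE]; Xv <- X[iv, , drop = FALSE]
  maskU <- Xu >= Xv
  P <- pmax(Xu, Xv)
  Z <- sweep(cbind(P, r[edgeTree, , drop = FALSE]), 2L, bn, "+")
  Rec <- .mlpFwd(Z, p, "Re", outLN = FALSE)
  s <- matrix(Rec$out, ncol = B)            # E x B edge scores
  s <- exp(sweep(s, 2L, apply(s, 2L, max), "-"))
  alpha <- sweep(s, 2L, colSums(s), "/")
  list(alpha = alpha, Lc = Lc, aln = aln, K = K, V = V, att = att, O = O,
       Rgc = Rgc, Rec = Rec, maskU = maskU, qW = qW,
       B = B, m = m, iu = iu, iv = iv, edgeTree = edgeTree)
}

## backward pass for one rank; dS is the (B*E) vector of score gradients
.backwardRank <- function(dS, cc, p, d, h, G) {
  B <- cc$B; m <- cc$m
  dh <- d %/% h
  sdh <- sqrt(dh)
  dZ <- .mlpBwd(matrix(dS, ncol = 1L), cc$Rec, p, "Re", G, outLN = FALSE)
  dP <- dZ[, seq_len(d), drop = FALSE]
  drEdge <- rowsum(dZ[, d + seq_len(d), drop = FALSE], cc$edgeTree)
  dX <- matrix(0, B * m, d)
  acc <- rowsum(rbind(dP * cc$maskU, dP * !cc$maskU), c(cc$iu, cc$iv))
  ridx <- as.integer(rownames(acc))
  dX[ridx, ] <- dX[ridx, ] + acc
  drbar <- .mlpBwd(drEdge, cc$Rgc, p, "Rg", G)
  .gAdd(G, "at.q", colSums(drbar))
  .gAdd(G, "at.WO", crossprod(cc$O, drbar))
  dO <- tcrossprod(drbar, p$at.WO)
  grp <- rep(seq_len(B), each = m)
  dK <- matrix(0, B * m, d); dV <- matrix(0, B * m, d)
  dqW <- numeric(d)
  for (i in seq_len(h)) {
    blk <- ((i - 1L) * dh + 1L):(i * dh)
    A <- cc$att[[i]]
    dOr <- dO[grp, blk, drop = FALSE]
    dAv <- rowSums(cc$V[, blk, drop = FALSE] * dOr)
    dV[, blk] <- as.vector(A) * dOr
    dA <- matrix(dAv, m, B)
    dSc <- A * sweep(dA, 2L, colSums(A * dA), "-")
    dscv <- as.vector(dSc) / sdh
    dK[, blk] <- outer(dscv, cc$qW[blk])
    dqW[blk] <- colSums(cc$K[, blk, drop = FALSE] * dscv)
  }
  .gAdd(G, "at.WK", crossprod(cc$aln$Y, dK))
  .gAdd(G, "at.WV", crossprod(cc$aln$Y, dV))
  dXl <- tcrossprod(dK, p$at.WK) + tcrossprod(dV, p$at.WV)
  .gAdd(G, "at.q", as.vector(dqW %*% t(p$at.WQ)))
  .gAdd(G, "at.WQ", outer(p$at.q, dqW))
  l <- .lnBwd(dXl, cc$aln, p$at.g)
  .gAdd(G, "at.g", l$dg)
  .gAdd(G, "at.b", l$db)
  dX <- dX + l$dX
  .mlpBwd(dX, cc$Lc, p, "L", G)
  invisible(NULL)
}

## Run the autoregressive model over a batch.
##
## decisions: (N-3) x B integer matrix for teacher forcing, or NULL to
## sample.  traces: optional precomputed per-tree embedding traces (from
## .traceDecisions) to skip state replay and fixed-point solves.
## Returns logProb (B), decisions, topologies (sample mode), and when
## keepCaches the per-rank forward caches for a later .backwardCaches call.
.runModel <- function(model, B, decisions = NULL, traces = NULL,
                      keepCaches = FALSE) {
  p <- model@params; d <- model@d; h <- model@h
  taxa <- model@taxa; N <- length(taxa)
  sampling <- is.null(decisions)
  if (sampling) decisions <- matrix(0L, max(N - 3L, 0L), B)
  ctrl <- fixpointControl(epsilon = model@epsilon)
  states <- NULL
  if (is.null(traces))
    states <- replicate(B, initialTree(taxa), simplify = FALSE)
  logp <- numeric(B)
  caches <- if (keepCaches) vector("list", max(N - 3L, 0L)) else NULL
  if (N > 3L) for (n in 3L:(N - 1L)) {
    m <- 2L * n - 2L; E <- 2L * n - 3L
    if (is.null(traces)) {
      emb <- fixpointEmbedding(states, ctrl)$embeddings
      geo <- lapply(states, .stateGeometry)
    } else {
      emb <- lapply(traces, function(tr) tr[[n - 2L]]$emb)
      geo <- lapply(traces, function(tr) tr[[n - 2L]])
    }
    X0 <- do.call(rbind, emb)
    off <- rep((seq_len(B) - 1L) * m, each = E)
    iu <- unlist(lapply(geo, `[[`, "eu")) + off
    iv <- unlist(lapply(geo, `[[`, "ev")) + off
    edgeTree <- rep(seq_len(B), each = E)
    bn <- sinusoidalEmbedding(n, 2L * d)
    fw <- .forwardRank(p, d, h, X0, B, m, iu, iv, edgeTree, bn)
    if (sampling) {
      u <- stats::runif(B)
      cum <- apply(fw$alpha, 2L, cumsum)
      decisions[n - 2L, ] <- vapply(seq_len(B), function(b)
        min(which(cum[, b] >= u[b] * cum[E, b])), 1L)
    }
    sel <- decisions[n - 2L, ]
    logp <- logp + log(fw$alpha[cbind(sel, seq_len(B))])
    if (keepCaches) caches[[n - 2L]] <- fw
    if (is.null(traces))
      states <- mapply(attachLeaf, states, sel, SIMPLIFY = FALSE)
  }
  out <- list(logProb = logp, decisions = decisions, caches = caches)
  if (sampling && is.null(traces))
    out$topologies <- lapply(states, asTopology)
  out
}

## accumulate gradients of sum_b weights[b] * logProb[b] into a new env
.backwardCaches <- function(model, caches, decisions, weights) {
  p <- model@params; d <- model@d; h <- model@h
  G <- new.env(parent = emptyenv())
  for (k in seq_along(caches)) {
    cc <- caches[[k]]
    sel <- decisions[k, ]
    D <- sweep(cc$alpha, 2L, weights, "*") * -1
    D[cbind(sel, seq_len(cc$B))] <- D[cbind(sel, seq_len(cc$B))] + weights
    .backwardRank(as.vector(D), cc, p, d, h, G)
  }
  G
}

## precompute the per-rank embedding trace of one decision sequence
.traceDecisions <- function(model, decisions) {
  taxa <- model@taxa; N <- length(taxa)
  ctrl <- fixpointControl(epsilon = model@epsilon)
  st <- initialTree(taxa)
  tr <- vector("list", max(N - 3L, 0L))
  if (N > 3L) for (n in 3L:(N - 1L)) {
    geo <- .stateGeometry(st)
    tr[[n - 2L]] <- list(
      emb = fixpointEmbedding(st, ctrl)$embeddings[[1L]],
      eu = geo$eu, ev = geo$ev)
    st <- attachLeaf(st, decisions[n - 2L])
  }
  tr
}

#' Sample tree topologies from the model
#'
#' Grows \code{B} trees synchronously from rank 3 to \code{N}; at every
#' rank the edge-decision distribution is computed for the whole batch in
#' one vectorized forward pass and one edge per tree is drawn.
#'
#' @param model an \code{EdgeModel}
#' @param B number of trees
#' @param seed optional integer seed
#' @return list with \code{topologies} (list of \code{TreeTopology}),
#'   \code{logProb} (numeric B) and \code{decisions}
#'   (\code{(N-3) x B} integer matrix)
#' @export
sampleTopologies <- function(model, B, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- .runModel(model, B)
  out["caches"] <- NULL
  out
}

#' Log-probability of tree topologies under the model
#'
#' Decomposes each topology into its leaf-addition decisions and
#' teacher-forces them through the same forward pass used for sampling.
#' Accepts precomputed decision matrices to skip the decomposition.
#'
#' @param model an \code{EdgeModel}
#' @param topologies a list of \code{TreeTopology} objects (alternatively
#'   pass \code{decisions})
#' @param decisions optional \code{(N-3) x B} integer matrix of decision
#'   sequences replacing \code{topologies}
#' @param chunk evaluate at most this many trees per stacked batch
#' @return numeric vector of log-probabilities
#' @export
logProb <- function(model, topologies = NULL, decisions = NULL,
                    chunk = 128L) {
  if (is.null(decisions)) {
    taxa <- model@taxa
    bad <- !vapply(topologies, function(t)
      setequal(tipLabels(t), taxa), TRUE)
    if (any(bad)) stop("topology leaf set does not match the model's taxa")
    decisions <- vapply(topologies,
                        function(t) decomposeTopology(t, taxa),
                        integer(length(taxa) - 3L))
    if (is.vector(decisions))
      decisions <- matrix(decisions, nrow = length(taxa) - 3L)
  }
  B <- ncol(decisions)
  out <- numeric(B)
  for (start in seq(1L, B, by = chunk)) {
    idx <- start:min(B, start + chunk - 1L)
    out[idx] <- .runModel(model, length(idx),
                          decisions = decisions[, idx, drop = FALSE])$logProb
  }
  out
}
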