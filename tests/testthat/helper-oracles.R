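## Independent brute-force oracles and small fixture builders used across
## the suite.  These deliberately avoid the package's production code
## paths: parsimony and likelihood are computed by exhaustive enumeration
## over internal-state assignments, embeddings by a direct dense solve.

## exhaustive minimum-change parsimony over all internal assignments
bruteFitch <- function(topology, alignment) {
  N <- nLeaves(topology)
  aln <- alignment[match(tipLabels(topology), rownames(alignment)), ,
                   drop = FALSE]
  E <- edgeList(topology)
  lm <- match(toupper(aln), c("A", "C", "G", "T"))
  dim(lm) <- dim(aln)
  grid <- as.matrix(expand.grid(rep(list(1:4), N - 2)))
  total <- 0L
  for (s in seq_len(ncol(aln))) {
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      st <- c(lm[, s], grid[g, ])
      best <- min(best, sum(st[E[, 1]] != st[E[, 2]]))
    }
    total <- total + best
  }
  total
}

## exhaustive sum over internal-state extensions of the JC likelihood
bruteLogLik <- function(topology, brlens, alignment) {
  N <- nLeaves(topology)
  aln <- alignment[match(tipLabels(topology), rownames(alignment)), ,
                   drop = FALSE]
  E <- edgeList(topology)
  P <- lapply(brlens, jcTransition)
  lm <- match(toupper(aln), c("A", "C", "G", "T"))
  dim(lm) <- dim(aln)
  grid <- as.matrix(expand.grid(rep(list(1:4), N - 2)))
  ll <- 0
  for (s in seq_len(ncol(aln))) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      st <- c(lm[, s], grid[g, ])
      pr <- 0.25
      for (i in seq_len(nrow(E))) pr <- pr * P[[i]][st[E[i, 1]], st[E[i, 2]]]
      tot <- tot + pr
    }
    ll <- ll + log(tot)
  }
  ll
}

## random ordinal state of rank n (uniform decision path)
randomState <- function(n, N = n) {
  st <- initialTree(sprintf("t%02d", seq_len(N)))
  while (st@n < n) st <- attachLeaf(st, sample.int(2L * st@n - 3L, 1L))
  st
}

## canonical string identity of a topology
topoKey <- function(topology) paste(topologySplits(topology), collapse = ";")

## small alignment on given taxa with explicit characters (sites in rows)
siteMatrix <- function(taxa, ...) {
  sites <- list(...)
  m <- do.call(cbind, lapply(sites, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- taxa
  m
}
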