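## Ordinal (leaf-addition) construction of unrooted bifurcating topologies.
##
## Node keys: leaf i (taxa position) -> i; interior j (creation order)
## -> N + j.  Canonical edge order: rows sorted (min, max), edges sorted
## lexicographically by (min, max).  All decision indices are 1-based:
## d_n in 1..(2n - 3) selects an edge of the rank-n state.

.sortEdges <- function(E) {
  E <- cbind(pmin.int(E[, 1L], E[, 2L]), pmax.int(E[, 1L], E[, 2L]))
  E[order(E[, 1L], E[, 2L]), , drop = FALSE]
}

#' Default taxa order
#'
#' The leaf-addition order used throughout: lexicographic on the labels.
#' @param labels character vector of taxon names
#' @return sorted character vector
#' @export
taxaOrder <- function(labels) {
  if (anyDuplicated(labels)) stop("duplicate taxon labels")
  sort(as.character(labels), method = "radix")
}

#' Rank-3 starting state
#'
#' The unique topology on the first three taxa: one interior node (key
#' \code{N + 1}) adjacent to leaves 1, 2, 3.
#'
#' @param taxa full taxa order (all \code{N >= 3} labels, in leaf-addition
#'   order)
#' @return an \code{\linkS4class{OrdinalTree}} of rank 3
#' @examples
#' st <- initialTree(c("a", "b", "c", "d", "e"))
#' edgeList(st)
#' @export
initialTree <- function(taxa) {
  taxa <- as.character(taxa)
  N <- length(taxa)
  if (N < 3L) stop("need at least 3 taxa")
  w <- N + 1L
  new("OrdinalTree", taxa = taxa, n = 3L,
      intAdj = matrix(0, 1L, 1L), crossAdj = matrix(1, 1L, 3L),
      edges = .sortEdges(cbind(1:3, w)))
}

#' Attach the next leaf to a chosen edge
#'
#' Grows a rank-\code{n} state to rank \code{n + 1}: the chosen edge
#' \code{(a, b)} is subdivided by a new interior node \code{w} (interior
#' index \code{n - 1}, key \code{N + n - 1}), and the new leaf \code{n + 1}
#' is joined to \code{w}.  The adjacency update is local: the \code{a - b}
#' entry is cleared and one row/column is appended to both \code{A} and
#' \code{C}.
#'
#' @param state an \code{OrdinalTree} with \code{n < N}
#' @param edgeIndex 1-based canonical index of the edge to subdivide,
#'   in \code{1..(2n - 3)}
#' @return the rank-\code{n + 1} \code{OrdinalTree}
#' @export
attachLeaf <- function(state, edgeIndex) {
  n <- state@n; N <- length(state@taxa)
  if (n >= N) stop("state is already at full rank N")
  edgeIndex <- as.integer(edgeIndex)
  if (is.na(edgeIndex) || edgeIndex < 1L || edgeIndex > 2L * n - 3L)
    stop("edgeIndex out of range")
  a <- state@edges[edgeIndex, 1L]; b <- state@edges[edgeIndex, 2L]
  wIdx <- n - 1L            # interior index of the new node
  w <- N + wIdx
  leaf <- n + 1L

  A <- rbind(cbind(state@intAdj, 0), 0)
  Cx <- rbind(cbind(state@crossAdj, 0), 0)
  ## clear the old a-b adjacency, join w to a, b and the new leaf
  for (x in c(a, b)) {
    if (x > N) {                       # interior endpoint
      j <- x - N
      A[wIdx, j] <- A[j, wIdx] <- 1
    } else {
      Cx[wIdx, x] <- 1
    }
  }
  if (a > N && b > N) {
    A[a - N, b - N] <- A[b - N, a - N] <- 0
  } else if (b > N) {                  # a is a leaf (a < b always)
    Cx[b - N, a] <- 0
  }
  Cx[wIdx, leaf] <- 1

  keep <- state@edges[-edgeIndex, , drop = FALSE]
  edges <- .sortEdges(rbind(keep, c(a, w), c(b, w), c(leaf, w)))
  new("OrdinalTree", taxa = state@taxa, n = n + 1L, intAdj = A,
      crossAdj = Cx, edges = edges)
}

#' Creation steps of the interior nodes
#'
#' Interior index \code{j} was created when the state reached rank
#' \code{j + 2}; the map is implicit in the indexing and returned here for
#' convenience.
#' @param state an \code{OrdinalTree}
#' @return named integer vector: interior index -> creation rank
#' @export
interiorCreation <- function(state) {
  j <- seq_len(state@n - 2L)
  stats::setNames(j + 2L, j)
}

#' Finalize a full-rank state into an immutable topology
#' @param state an \code{OrdinalTree} with \code{n == N}
#' @return a \code{\linkS4class{TreeTopology}}
#' @export
asTopology <- function(state) {
  if (state@n != length(state@taxa)) stop("state has not reached full rank")
  new("TreeTopology", tipLabels = state@taxa, edge = state@edges)
}

#' Replay a decision sequence into a topology
#'
#' The inverse of \code{\link{decomposeTopology}}: starting from the rank-3
#' state, attach leaf \code{n + 1} to edge \code{decisions[n - 2]} of the
#' rank-\code{n} state for \code{n = 3, ..., N - 1}.  Decision sequences of
#' length \code{N - 3} are in bijection with the \code{(2N - 5)!!} labeled
#' topologies.
#'
#' @param decisions integer vector of 1-based edge choices, length
#'   \code{N - 3} (empty for \code{N = 3})
#' @param taxa full taxa order
#' @return a \code{TreeTopology}
#' @export
replayDecisions <- function(decisions, taxa) {
  st <- initialTree(taxa)
  for (d in decisions) st <- attachLeaf(st, d)
  asTopology(st)
}

## adjacency list keyed by node id (list of integer vectors)
.adjList <- function(edge, nNodes) {
  adj <- vector("list", nNodes)
  for (i in seq_len(nrow(edge))) {
    a <- edge[i, 1L]; b <- edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

## leaves (keys <= nLeaf) on the `u` side of edge (u, v)
.edgeSideLeaves <- function(adj, u, v, nLeaf) {
  seen <- integer(0)
  stack <- u
  visited <- c(v)                      # block crossing the edge
  while (length(stack)) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    visited <- c(visited, x)
    if (x <= nLeaf) seen <- c(seen, x)
    nb <- setdiff(adj[[x]], visited)
    stack <- c(stack, nb)
  }
  sort(seen)
}

## canonical key of the bipartition induced by edge (u, v): the sorted leaf
## indices of the side containing leaf 1
.splitKey <- function(adj, u, v, nLeaf) {
  side <- .edgeSideLeaves(adj, u, v, nLeaf)
  if (!(1L %in% side)) side <- setdiff(seq_len(nLeaf), side)
  paste(side, collapse = ",")
}

#' Non-trivial splits of a topology
#'
#' Each interior edge bipartitions the leaf set; the set of these
#' bipartitions identifies the topology.  Splits are returned as canonical
#' strings over the leaf \emph{labels} so that topologies with differently
#' ordered \code{tipLabels} compare correctly.
#'
#' @param topology a \code{TreeTopology}
#' @return character vector of canonical split keys (possibly empty for
#'   \code{N = 3})
#' @export
topologySplits <- function(topology) {
  N <- nLeaves(topology)
  E <- topology@edge
  adj <- .adjList(E, 2L * N - 2L)
  interior <- E[, 1L] > N & E[, 2L] > N
  labs <- topology@tipLabels
  anchor <- order(labs)[1L]            # lexicographically smallest label
  keys <- character(0)
  for (i in which(interior)) {
    side <- .edgeSideLeaves(adj, E[i, 1L], E[i, 2L], N)
    if (!(anchor %in% side)) side <- setdiff(seq_len(N), side)
    keys <- c(keys, paste(sort(labs[side]), collapse = "|"))
  }
  sort(keys)
}

#' Robinson-Foulds distance
#'
#' The number of non-trivial splits present in exactly one of the two
#' topologies (the symmetric difference of their split sets).
#'
#' @param t1,t2 \code{TreeTopology} objects on the same leaf label set
#' @return non-negative integer, at most \code{2 * (N - 3)}
#' @export
rfDistance <- function(t1, t2) {
  if (!setequal(t1@tipLabels, t2@tipLabels)) stop("leaf label sets differ")
  s1 <- topologySplits(t1); s2 <- topologySplits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Topology equality by split set
#' @param t1,t2 \code{TreeTopology} objects
#' @return logical
#' @export
sameTopology <- function(t1, t2) {
  setequal(t1@tipLabels, t2@tipLabels) && rfDistance(t1, t2) == 0L
}

#' Decompose a topology into its leaf-addition decisions
#'
#' Peels leaves in reverse taxa order: for \code{n = N, ..., 4} the
#' highest-indexed leaf is detached, its interior neighbor deleted, and the
#' neighbor's two remaining edges fused; the canonical index that the fused
#' edge occupies in the resulting rank-\code{n - 1} state is recorded.
#' Replaying the sequence through \code{\link{attachLeaf}} reconstructs a
#' topology with the same leaf-labeled split set.
#'
#' @param topology a \code{TreeTopology} whose labels are exactly
#'   \code{taxa}
#' @param taxa taxa order; defaults to the lexicographic order of the
#'   topology's own labels
#' @return integer vector of length \code{N - 3} (1-based edge indices)
#' @export
decomposeTopology <- function(topology, taxa = taxaOrder(tipLabels(topology))) {
  N <- nLeaves(topology)
  if (!setequal(topology@tipLabels, taxa)) stop("leaf labels do not match taxa")
  ## relabel leaves so that leaf key == taxa position
  perm <- match(topology@tipLabels, taxa)      # old leaf key -> new leaf key
  map <- c(perm, (N + 1L):(2L * N - 2L))
  E <- matrix(map[topology@edge], ncol = 2L)
  adj <- .adjList(.sortEdges(E), 2L * N - 2L)

  if (N == 3L) return(integer(0))
  fusedKeys <- character(N - 3L)               # fusedKeys[n - 3]: rank-n fuse
  for (n in N:4L) {
    leaf <- n
    w <- adj[[leaf]][1L]
    rest <- setdiff(adj[[w]], leaf)            # the two fused endpoints
    a <- rest[1L]; b <- rest[2L]
    adj[[leaf]] <- integer(0)
    adj[[w]] <- integer(0)
    adj[[a]] <- c(setdiff(adj[[a]], w), b)
    adj[[b]] <- c(setdiff(adj[[b]], w), a)
    fusedKeys[n - 3L] <- .splitKey(adj, a, b, n - 1L)
  }

  ## replay forward, matching fused edges by their leaf bipartitions
  st <- initialTree(taxa)
  decisions <- integer(N - 3L)
  for (n in 3L:(N - 1L)) {
    sadj <- .adjList(st@edges, 2L * N - 2L)
    keys <- vapply(seq_len(nrow(st@edges)), function(i)
      .splitKey(sadj, st@edges[i, 1L], st@edges[i, 2L], n), "")
    d <- match(fusedKeys[n - 2L], keys)
    if (is.na(d)) stop("internal error: fused edge not found during replay")
    decisions[n - 2L] <- d
    st <- attachLeaf(st, d)
  }
  decisions
}

#' Enumerate all topologies on a small taxon set
#'
#' Walks every decision sequence, yielding each of the \code{(2N - 5)!!}
#' distinct labeled topologies exactly once (the construction is a
#' bijection, so no deduplication is needed).
#'
#' @param taxa taxa order, or a single integer \code{N} (labels
#'   \code{t1..tN} are generated); \code{N <= 8} to guard against blow-up
#' @return list of \code{TreeTopology} objects
#' @examples
#' length(enumerateTopologies(5))  # 15
#' @export
enumerateTopologies <- function(taxa) {
  if (is.numeric(taxa) && length(taxa) == 1L)
    taxa <- sprintf("t%d", seq_len(taxa))
  N <- length(taxa)
  if (N < 3L) stop("need at least 3 taxa")
  if (N > 8L) stop("refusing to enumerate more than 8 taxa")
  states <- list(initialTree(taxa))
  for (n in 3L:max(3L, N - 1L)) {
    if (n == N) break
    states <- unlist(lapply(states, function(st)
      lapply(seq_len(2L * n - 3L), function(d) attachLeaf(st, d))),
      recursive = FALSE)
  }
  lapply(states, asTopology)
}

#' Number of unrooted bifurcating topologies
#' @param N leaf count
#' @return \code{(2N - 5)!!}
#' @export
nTopologies <- function(N) {
  if (N < 3) stop("N must be at least 3")
  if (N == 3) return(1)
  prod(seq(3, 2 * N - 5, by = 2))
}
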