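#' @import methods
NULL

#' Unrooted bifurcating leaf-labeled tree topology
#'
#' An immutable tree topology on \code{N >= 3} labeled leaves in which every
#' internal node has degree 3.  Nodes are keyed by integers: leaf \code{i}
#' (in the order of \code{tipLabels}) has key \code{i}, and the \code{N - 2}
#' internal nodes have keys \code{N + 1, ..., 2N - 2}.  Edges are stored as a
#' \code{(2N - 3) x 2} integer matrix of node keys with each row sorted
#' increasingly.  Branch lengths are optional (length 0 or one per edge row);
#' they are carried through Newick round trips but play no role in topology
#' identity, which is defined by the set of non-trivial splits (see
#' \code{\link{topologySplits}}).
#'
#' @slot tipLabels character vector of leaf labels, one per leaf.
#' @slot edge two-column integer matrix of node keys.
#' @slot edgeLength numeric vector of branch lengths (possibly empty).
#' @seealso \code{\link{readNewick}}, \code{\link{rfDistance}},
#'   \code{\link{decomposeTopology}}
#' @export
setClass("TreeTopology",
  representation(tipLabels = "character", edge = "matrix",
                 edgeLength = "numeric"),
  prototype(edgeLength = numeric(0)))

setValidity("TreeTopology", function(object) {
  N <- length(object@tipLabels)
  if (N < 3L) return("need at least 3 leaves")
  if (anyDuplicated(object@tipLabels)) return("duplicate leaf labels")
  E <- object@edge
  if (!is.numeric(E) || ncol(E) != 2L) return("edge must be a 2-column matrix")
  if (nrow(E) != 2L * N - 3L) return(sprintf("expected %d edges", 2L * N - 3L))
  keys <- c(E)
  if (any(keys < 1L | keys > 2L * N - 2L)) return("node key out of range")
  deg <- tabulate(keys, nbins = 2L * N - 2L)
  if (any(deg[seq_len(N)] != 1L)) return("every leaf must have degree 1")
  if (any(deg[(N + 1L):(2L * N - 2L)] != 3L))
    return("every internal node must have degree 3")
  if (length(object@edgeLength) &&
      length(object@edgeLength) != nrow(E))
    return("edgeLength must be empty or one per edge")
  ## connectivity follows from the degree sequence + edge count only if the
  ## graph is a single component; check it explicitly
  comp <- .reachableFrom(E, 1L, 2L * N - 2L)
  if (length(comp) != 2L * N - 2L) return("graph is not connected")
  TRUE
})

#' Ordinal tree topology under construction
#'
#' A rank-\code{n} intermediate state of the leaf-addition construction: the
#' subtree spanning the first \code{n} taxa of a fixed taxa order, destined to
#' grow to \code{N} leaves.  Leaves carry global keys \code{1..N} (their taxa
#' positions); the interior node created when the state reached rank
#' \code{j + 2} carries interior index \code{j} and key \code{N + j}, which
#' makes the interior adjacency matrix \code{A} and the leaf-interior cross
#' adjacency \code{C} grow append-only: attaching a leaf touches O(1) existing
#' entries plus one appended row/column.
#'
#' @slot taxa full taxa order (length \code{N}).
#' @slot n current leaf count, \code{3 <= n <= N}.
#' @slot intAdj binary symmetric \code{(n-2) x (n-2)} interior adjacency
#'   matrix with zero diagonal.
#' @slot crossAdj binary \code{(n-2) x n} leaf-interior cross adjacency.
#' @slot edges two-column integer matrix of the \code{2n - 3} edges in
#'   canonical order (rows sorted, then lexicographic by (min, max) key).
#' @seealso \code{\link{initialTree}}, \code{\link{attachLeaf}}
#' @export
setClass("OrdinalTree",
  representation(taxa = "character", n = "integer",
                 intAdj = "matrix", crossAdj = "matrix", edges = "matrix"))

setValidity("OrdinalTree", function(object) {
  n <- object@n; N <- length(object@taxa)
  A <- object@intAdj; Cx <- object@crossAdj
  if (n < 3L || n > N) return("rank n out of range")
  if (!identical(dim(A), c(n - 2L, n - 2L))) return("bad intAdj dimensions")
  if (!identical(dim(Cx), c(n - 2L, n))) return("bad crossAdj dimensions")
  if (any(A != t(A)) || any(diag(A) != 0))
    return("intAdj must be symmetric with zero diagonal")
  if (!all(A %in% c(0, 1)) || !all(Cx %in% c(0, 1)))
    return("adjacency matrices must be binary")
  if (any(rowSums(A) + rowSums(Cx) != 3))
    return("every interior node must have total degree 3")
  if (nrow(object@edges) != 2L * n - 3L)
    return(sprintf("expected %d edges", 2L * n - 3L))
  TRUE
})

#' Interior adjacency matrix of an ordinal tree state
#' @param state an \code{OrdinalTree}
#' @return binary symmetric \code{(n-2) x (n-2)} matrix
#' @export
interiorAdjacency <- function(state) state@intAdj

#' Leaf-interior cross adjacency matrix of an ordinal tree state
#' @param state an \code{OrdinalTree}
#' @return binary \code{(n-2) x n} matrix
#' @export
crossAdjacency <- function(state) state@crossAdj

#' Attention-based autoregressive edge-decision model
#'
#' Holds the full parameter set of the edge-decision network: the embedding
#' MLP from padded topological node embeddings to d-dimensional node
#' features, the single-query multi-head attention block that pools node
#' features into a graph representation, and the graph/edge readout MLPs.
#' Construct with \code{\link{edgeModel}}.
#'
#' @slot taxa taxa order the model is bound to (defines N and leaf indexing).
#' @slot d node feature dimension.
#' @slot h number of attention heads (must divide \code{d}).
#' @slot epsilon stopping tolerance of the fixed-point embedding iteration.
#' @slot params named list of parameter matrices/vectors.
#' @export
setClass("EdgeModel",
  representation(taxa = "character", d = "integer", h = "integer",
                 epsilon = "numeric", params = "list"))

setValidity("EdgeModel", function(object) {
  if (length(object@taxa) < 3L) return("need at least 3 taxa")
  if (object@d %% object@h != 0L) return("d must be divisible by h")
  if (object@epsilon <= 0) return("epsilon must be positive")
  TRUE
})

#' Enumerable toy target distribution over tree topologies
#'
#' A fully tabulated probability distribution over all \code{(2N-5)!!}
#' topologies on a small taxon set, with \code{p(tau) proportional to
#' exp(-lambda * RF(tau, anchor))}.  Serves as an exactly known stand-in for
#' posterior tree samples so that KL divergences can be computed in closed
#' form.
#'
#' @slot topologies list of all \code{TreeTopology} objects on the taxa.
#' @slot probs normalized probability for each topology.
#' @slot anchor the anchor topology (the unique mode when \code{lambda > 0}).
#' @slot lambda non-negative concentration; 0 gives the uniform distribution.
#' @export
setClass("ToyTarget",
  representation(topologies = "list", probs = "numeric",
                 anchor = "TreeTopology", lambda = "numeric"))

setValidity("ToyTarget", function(object) {
  if (length(object@topologies) != length(object@probs))
    return("one probability per topology")
  if (abs(sum(object@probs) - 1) > 1e-9) return("probabilities must sum to 1")
  if (object@lambda < 0) return("lambda must be non-negative")
  TRUE
})

## ---- generics -------------------------------------------------------------

#' Number of leaves
#' @param x a \code{TreeTopology} or \code{OrdinalTree}
#' @return integer leaf count
#' @export
setGeneric("nLeaves", function(x) standardGeneric("nLeaves"))

#' Leaf labels
#' @param x a \code{TreeTopology} or \code{OrdinalTree}
#' @return character vector of labels
#' @export
setGeneric("tipLabels", function(x) standardGeneric("tipLabels"))

#' Canonically ordered edge list
#' @param x a \code{TreeTopology} or \code{OrdinalTree}
#' @return two-column integer matrix of node keys
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' Largest absolute eigenvalue of the interior adjacency matrix
#'
#' The spectral radius of the subgraph induced by the internal nodes.  It is
#' bounded by \code{2 * sqrt(2)} for every bifurcating topology of any size,
#' which is what guarantees the uniform linear convergence (rate
#' \code{2 * sqrt(2) / 3}) of the fixed-point embedding iteration.
#'
#' @param x a \code{TreeTopology} or \code{OrdinalTree}
#' @return non-negative scalar; 0 when there are no interior edges
#' @export
setGeneric("interiorSpectralRadius",
           function(x) standardGeneric("interiorSpectralRadius"))

setMethod("nLeaves", "TreeTopology", function(x) length(x@tipLabels))
setMethod("nLeaves", "OrdinalTree", function(x) x@n)
setMethod("tipLabels", "TreeTopology", function(x) x@tipLabels)
setMethod("tipLabels", "OrdinalTree", function(x) x@taxa[seq_len(x@n)])
setMethod("edgeList", "TreeTopology", function(x) x@edge)
setMethod("edgeList", "OrdinalTree", function(x) x@edges)

setMethod("show", "TreeTopology", function(object) {
  N <- nLeaves(object)
  cat(sprintf("TreeTopology: %d leaves, %d internal nodes, %d edges\n",
              N, N - 2L, nrow(object@edge)))
  lab <- object@tipLabels
  if (N > 6L) lab <- c(lab[1:6], "...")
  cat("  leaves:", paste(lab, collapse = ", "), "\n")
  if (length(object@edgeLength))
    cat("  with branch lengths\n")
})

setMethod("show", "OrdinalTree", function(object) {
  cat(sprintf("OrdinalTree: rank %d of %d (%d edges, %d interior nodes)\n",
              object@n, length(object@taxa), nrow(object@edges),
              object@n - 2L))
})

setMethod("show", "EdgeModel", function(object) {
  np <- sum(vapply(object@params, length, 1L))
  cat(sprintf("EdgeModel: N = %d taxa, d = %d, h = %d heads, %d parameters\n",
              length(object@taxa), object@d, object@h, np))
})

setMethod("show", "ToyTarget", function(object) {
  cat(sprintf(
    "ToyTarget: %d topologies on %d taxa, lambda = %g, mode prob = %.4f\n",
    length(object@topologies), nLeaves(object@anchor), object@lambda,
    max(object@probs)))
})

## connected component reachable from `start` in an undirected edge list
.reachableFrom <- function(edge, start, nNodes) {
  adj <- vector("list", nNodes)
  for (i in seq_len(nrow(edge))) {
    a <- edge[i, 1L]; b <- edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(nNodes); seen[start] <- TRUE
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    stack <- c(stack, new)
  }
  which(seen)
}
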