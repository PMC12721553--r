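## Newick / alignment I/O.  Parsing and serialization are delegated to ape
## and phangorn; this layer only converts to and from the package's
## canonical node keying.

#' Convert to an ape \code{phylo} object
#'
#' The unrooted topology is emitted with a trifurcation at an arbitrary
#' interior node (the MrBayes-style representation).
#' @param topology a \code{TreeTopology}
#' @return an object of class \code{phylo}
#' @export
asPhylo <- function(topology) {
  N <- nLeaves(topology)
  adj <- .adjList(topology@edge, 2L * N - 2L)
  ql <- if (length(topology@edgeLength)) {
    key <- paste(topology@edge[, 1L], topology@edge[, 2L])
    stats::setNames(topology@edgeLength, key)
  } else NULL
  root <- N + 1L
  ## orient parent -> child by DFS; relabel interiors into preorder as ape
  ## likes root == N + 1
  newId <- integer(2L * N - 2L)
  newId[seq_len(N)] <- seq_len(N)
  nextInt <- N + 1L
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  stack <- list(c(root, 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[length(stack)] <- NULL
    v <- top[1L]; p <- top[2L]
    if (v > N) { newId[v] <- nextInt; nextInt <- nextInt + 1L }
    if (p != 0L) {
      parent <- c(parent, newId[p]); child <- c(child, v)
      if (!is.null(ql))
        elen <- c(elen, ql[[paste(min(v, p), max(v, p))]])
    }
    for (nb in adj[[v]]) if (nb != p) stack[[length(stack) + 1L]] <- c(nb, v)
  }
  child <- ifelse(child <= N, child, newId[child])
  tr <- list(edge = cbind(parent, child), tip.label = topology@tipLabels,
             Nnode = N - 2L)
  if (!is.null(ql)) tr$edge.length <- elen
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr
}

#' Convert an ape \code{phylo} object to a \code{TreeTopology}
#'
#' Rooted binary trees are coerced to unrooted form by suppressing the
#' degree-2 root; all remaining internal nodes must have degree 3.
#' @param phy a \code{phylo} object
#' @return a \code{TreeTopology}
#' @export
fromPhylo <- function(phy) {
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf labels")
  if (ape::is.rooted(phy)) phy <- ape::unroot(phy)
  phy <- ape::collapse.singles(phy)
  N <- length(phy$tip.label)
  if (N < 3L) stop("need at least 3 leaves")
  if (phy$Nnode != N - 2L)
    stop("tree is not an unrooted bifurcating topology")
  ## ape numbers tips 1..N and internals N+1..2N-2 already
  E <- .sortEdges(phy$edge)
  el <- numeric(0)
  if (!is.null(phy$edge.length)) {
    o <- order(pmin(phy$edge[, 1], phy$edge[, 2]),
               pmax(phy$edge[, 1], phy$edge[, 2]))
    el <- phy$edge.length[o]
  }
  new("TreeTopology", tipLabels = phy$tip.label, edge = E, edgeLength = el)
}

#' Read a tree topology from Newick
#' @param text a Newick string, or \code{NULL} to read from \code{file}
#' @param file path to a Newick file
#' @return a \code{TreeTopology} (branch lengths preserved when present)
#' @export
readNewick <- function(text = NULL, file = NULL) {
  phy <- if (!is.null(text)) ape::read.tree(text = text)
         else ape::read.tree(file = file)
  if (is.null(phy)) stop("malformed Newick")
  fromPhylo(phy)
}

#' Write a tree topology as Newick
#' @param topology a \code{TreeTopology}
#' @param file optional path; when \code{NULL} the string is returned
#' @return the Newick string, invisibly when writing to a file
#' @export
writeNewick <- function(topology, file = NULL) {
  s <- ape::write.tree(asPhylo(topology))
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read a training set of trees with optional weights
#'
#' Plain-text list of Newick strings, one per line, with an optional
#' tab-separated weight column after the Newick string.  Weights are
#' normalized to sum to 1; absent weights default to uniform.
#'
#' @param file path
#' @return list with elements \code{topologies} (list of
#'   \code{TreeTopology}) and \code{weights} (normalized numeric)
#' @export
readTreeSet <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  nwk <- vapply(parts, `[[`, "", 1L)
  w <- vapply(parts, function(p)
    if (length(p) > 1L) as.numeric(p[[2L]]) else 1, 1)
  if (any(!is.finite(w)) || any(w <= 0)) stop("invalid tree weights")
  list(topologies = lapply(nwk, function(s) readNewick(text = s)),
       weights = w / sum(w))
}

#' Write a set of trees (with optional weights) as Newick lines
#' @param topologies list of \code{TreeTopology}
#' @param file path
#' @param weights optional numeric weights (tab-separated second column)
#' @export
writeTreeSet <- function(topologies, file, weights = NULL) {
  s <- vapply(topologies, writeNewick, "")
  if (!is.null(weights)) s <- paste(s, format(weights, digits = 12), sep = "\t")
  writeLines(s, file)
  invisible(file)
}

#' Read a multiple sequence alignment
#'
#' Supports FASTA, NEXUS and (relaxed) PHYLIP through
#' \code{phangorn::read.phyDat}.  The result is the package's plain
#' alignment representation: an \code{N x M} character matrix of upper-case
#' symbols with taxon names as row names.
#'
#' @param file path
#' @param format "fasta", "nexus" or "phylip" (default guesses from the
#'   file extension)
#' @return character matrix
#' @export
readAlignment <- function(file, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(file))
    format <- switch(ext,
      fa = , fas = , fasta = "fasta",
      nex = , nexus = "nexus",
      "phylip")
  }
  pd <- phangorn::read.phyDat(file, format = format, type = "DNA")
  m <- toupper(as.character(pd))
  rownames(m) <- names(pd)
  m
}

#' Write an alignment as FASTA
#' @param alignment character matrix with taxon row names
#' @param file path
#' @export
writeAlignmentFasta <- function(alignment, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(alignment))) {
    writeLines(paste0(">", rownames(alignment)[i]), con)
    writeLines(paste(alignment[i, ], collapse = ""), con)
  }
  invisible(file)
}
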