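## Topological node embeddings by Dirichlet-energy minimization.
##
## For a rank-n state, the embedding of leaf i is the one-hot delta_i in
## R^n and the interior embeddings F in R^{(n-2) x n} solve the harmonic
## system F = A F / 3 + C / 3 (every interior node has degree 3).  The
## iteration F <- A F / 3 + C / 3 contracts at rate 2 sqrt(2) / 3 because
## the interior adjacency A has spectral radius at most 2 sqrt(2).

.CONTRACTION_RATE <- 2 * sqrt(2) / 3

#' Dirichlet energy of an embedding
#'
#' Sum over edges of the squared Euclidean distance between the endpoint
#' embedding rows.  Leaf rows are the fixed one-hot encodings; only the
#' interior rows are free.
#'
#' @param F interior embedding matrix, \code{(n-2) x n} (or the padded
#'   \code{(n-2) x N} form; trailing columns beyond \code{n} must be zero
#'   and are dropped)
#' @param state the \code{OrdinalTree} the embedding belongs to
#' @return non-negative scalar
#' @examples
#' st <- initialTree(c("a", "b", "c"))
#' dirichletEnergy(matrix(1/3, 1, 3), st)  # 2
#' @export
dirichletEnergy <- function(F, state) {
  n <- state@n; N <- length(state@taxa)
  F <- as.matrix(F)
  if (nrow(F) != n - 2L) stop("F must have one row per interior node")
  if (ncol(F) == N && N > n) F <- F[, seq_len(n), drop = FALSE]
  if (ncol(F) != n) stop("F must have n columns")
  Fbar <- rbind(diag(n), F)           # leaf block is the identity
  E <- state@edges
  key <- function(k) ifelse(k <= N, k, n + (k - N))
  du <- Fbar[key(E[, 1L]), , drop = FALSE] - Fbar[key(E[, 2L]), , drop = FALSE]
  sum(du * du)
}

#' Exact topological node embedding (direct linear solve)
#'
#' Solves \code{(I - A/3) F = C/3} directly.  The system is always
#' non-singular, and the interior rows of the solution are non-negative
#' and sum to one.  This is the reference oracle for
#' \code{\link{fixpointEmbedding}}; the production path is the fixed-point
#' iteration.
#'
#' @param state an \code{OrdinalTree}
#' @param padded when \code{TRUE} (default) return the stacked
#'   \code{(2n-2) x N} matrix (leaf one-hot block over the interior block,
#'   zero-padded to \code{N} columns); otherwise the native
#'   \code{(n-2) x n} interior matrix
#' @return embedding matrix
#' @export
exactEmbedding <- function(state, padded = TRUE) {
  n <- state@n
  A <- state@intAdj; Cx <- state@crossAdj
  F <- solve(diag(n - 2L) - A / 3, Cx / 3)
  if (!padded) return(F)
  .padEmbedding(F, state)
}

## stack leaf one-hots over interior rows and zero-pad to N columns
.padEmbedding <- function(F, state) {
  n <- state@n; N <- length(state@taxa)
  out <- matrix(0, 2L * n - 2L, N)
  out[cbind(seq_len(n), seq_len(n))] <- 1
  out[(n + 1L):(2L * n - 2L), seq_len(n)] <- F
  out
}

#' A-priori iteration count for the fixed-point embedding
#'
#' The smallest \code{m} such that \code{c^m * E0 <= epsilon * n}, where
#' \code{c = 2 sqrt(2) / 3} is the contraction rate and
#' \code{E0 = sqrt(2 (n - 2))} bounds the initial Frobenius error (each
#' interior row of the all-\code{1/n} start and of the fixed point is a
#' probability vector, so each row error is at most \code{sqrt(2)}).  The
#' bound depends only on \code{n}, never on the topology shape.
#'
#' @param epsilon stopping tolerance (> 0)
#' @param n leaf count (>= 3)
#' @return non-negative integer
#' @export
iterationBound <- function(epsilon, n) {
  if (epsilon <= 0) stop("epsilon must be positive")
  if (n < 3) stop("n must be at least 3")
  if (n == 3) return(1L)                       # A = 0: one step is exact
  E0 <- sqrt(2 * (n - 2))
  target <- epsilon * n
  if (E0 <= target) return(0L)
  as.integer(ceiling(log(target / E0) / log(.CONTRACTION_RATE)))
}

#' Fixed-point control parameters
#' @param epsilon stopping tolerance (default \code{1e-5})
#' @param mode \code{"power"} (repeated squaring of the augmented iteration
#'   matrix; the default) or \code{"plain"} (one multiply per iteration)
#' @param maxIters safety cap on effective iterations
#' @return a list of class \code{"fixpointControl"}
#' @export
fixpointControl <- function(epsilon = 1e-5, mode = c("power", "plain"),
                            maxIters = 10000L) {
  mode <- match.arg(mode)
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(epsilon = epsilon, mode = mode,
                 maxIters = as.integer(maxIters)),
            class = "fixpointControl")
}

#' Topological node embeddings by fixed-point iteration
#'
#' Computes the Dirichlet-energy minimizing embeddings for a batch of
#' equal-rank states.  The interior block starts from all entries
#' \code{1/n} and is iterated \code{F <- A F / 3 + C / 3}; the number of
#' iterations is the precomputed \code{\link{iterationBound}}, which
#' guarantees \code{||F^(m) - F*||_F / n < epsilon}.  In \code{"power"}
#' mode the same map is applied through repeated squaring of the augmented
#' matrix \code{rbind(cbind(I, 0), cbind(C/3, A/3))}, needing only
#' \code{ceiling(log2(M))} matrix squarings.
#'
#' @param states a single \code{OrdinalTree} or a list of them, all of the
#'   same rank
#' @param control a \code{\link{fixpointControl}} list
#' @return list with \code{embeddings} (list of padded \code{(2n-2) x N}
#'   matrices, one per state) and \code{iterations} (effective iteration
#'   count of the linear map)
#' @export
fixpointEmbedding <- function(states, control = fixpointControl()) {
  if (is(states, "OrdinalTree")) states <- list(states)
  n <- states[[1L]]@n
  if (!all(vapply(states, function(s) s@n, 1L) == n))
    stop("all states in a batch must share the same rank")
  M <- min(iterationBound(control$epsilon, n), control$maxIters)
  if (control$mode == "plain") {
    embs <- lapply(states, function(st) {
      F <- matrix(1 / n, n - 2L, n)
      A3 <- st@intAdj / 3; C3 <- st@crossAdj / 3
      for (m in seq_len(M)) F <- A3 %*% F + C3
      .padEmbedding(F, st)
    })
    return(list(embeddings = embs, iterations = M))
  }
  k <- if (M <= 1L) 0L else as.integer(ceiling(log2(M)))
  embs <- lapply(states, function(st) {
    Abar <- rbind(cbind(diag(n), matrix(0, n, n - 2L)),
                  cbind(st@crossAdj / 3, st@intAdj / 3))
    for (i in seq_len(k)) Abar <- Abar %*% Abar
    F0 <- rbind(diag(n), matrix(1 / n, n - 2L, n))
    Fbar <- Abar %*% F0
    .padEmbedding(Fbar[(n + 1L):(2L * n - 2L), , drop = FALSE], st)
  })
  list(embeddings = embs, iterations = 2L^k)
}

setMethod("interiorSpectralRadius", "OrdinalTree", function(x) {
  if (x@n == 3L) return(0)
  max(abs(eigen(x@intAdj, symmetric = TRUE, only.values = TRUE)$values))
})

setMethod("interiorSpectralRadius", "TreeTopology", function(x) {
  N <- nLeaves(x)
  E <- x@edge
  keep <- E[, 1L] > N & E[, 2L] > N
  if (!any(keep)) return(0)
  A <- matrix(0, N - 2L, N - 2L)
  for (i in which(keep)) {
    a <- E[i, 1L] - N; b <- E[i, 2L] - N
    A[a, b] <- A[b, a] <- 1
  }
  max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
})
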