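## Minimal neural-network layer kit (dense layers, layer normalization,
## ELU, single-query multi-head attention) with hand-written reverse-mode
## gradients, written in plain matrix code.  Everything operates on
## row-batched matrices; gradients are accumulated into an environment
## keyed like the parameter list.

.LN_EPS <- 1e-5

.elu <- function(x) ifelse(x > 0, x, expm1(x))
.eluGrad <- function(x) ifelse(x > 0, 1, exp(x))

.lnFwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + .LN_EPS)
  xhat <- xc * inv
  Y <- sweep(xhat, 2L, g, "*")
  Y <- sweep(Y, 2L, b, "+")
  list(Y = Y, xhat = xhat, inv = inv)
}

.lnBwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, g, "*")
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

## accumulate `val` into G[[name]] (environment of gradients)
.gAdd <- function(G, name, val) {
  cur <- G[[name]]
  G[[name]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

## 2-layer MLP: linear -> LN -> ELU -> linear [-> LN].  Layer norm follows
## every linear layer except a scalar output head (outLN = FALSE), where
## normalizing a single feature would be degenerate.
.mlpFwd <- function(X, p, pre, outLN = TRUE) {
  W1 <- p[[paste0(pre, ".W1")]]; b1 <- p[[paste0(pre, ".b1")]]
  W2 <- p[[paste0(pre, ".W2")]]; b2 <- p[[paste0(pre, ".b2")]]
  Z1 <- sweep(X %*% W1, 2L, b1, "+")
  ln1 <- .lnFwd(Z1, p[[paste0(pre, ".g1")]], p[[paste0(pre, ".be1")]])
  H1 <- .elu(ln1$Y)
  Z2 <- sweep(H1 %*% W2, 2L, b2, "+")
  if (outLN) {
    ln2 <- .lnFwd(Z2, p[[paste0(pre, ".g2")]], p[[paste0(pre, ".be2")]])
    out <- ln2$Y
  } else {
    ln2 <- NULL
    out <- Z2
  }
  list(out = out, X = X, ln1 = ln1, H1 = H1, ln2 = ln2)
}

.mlpBwd <- function(dOut, cache, p, pre, G, outLN = TRUE) {
  if (outLN) {
    l2 <- .lnBwd(dOut, cache$ln2, p[[paste0(pre, ".g2")]])
    .gAdd(G, paste0(pre, ".g2"), l2$dg)
    .gAdd(G, paste0(pre, ".be2"), l2$db)
    dZ2 <- l2$dX
  } else {
    dZ2 <- dOut
  }
  .gAdd(G, paste0(pre, ".W2"), crossprod(cache$H1, dZ2))
  .gAdd(G, paste0(pre, ".b2"), colSums(dZ2))
  dH1 <- tcrossprod(dZ2, p[[paste0(pre, ".W2")]])
  dN1 <- dH1 * .eluGrad(cache$ln1$Y)
  l1 <- .lnBwd(dN1, cache$ln1, p[[paste0(pre, ".g1")]])
  .gAdd(G, paste0(pre, ".g1"), l1$dg)
  .gAdd(G, paste0(pre, ".be1"), l1$db)
  .gAdd(G, paste0(pre, ".W1"), crossprod(cache$X, l1$dX))
  .gAdd(G, paste0(pre, ".b1"), colSums(l1$dX))
  tcrossprod(l1$dX, p[[paste0(pre, ".W1")]])
}

#' Sinusoidal positional embedding of a construction step
#'
#' The standard transformer sinusoid: component \code{2i + 1} is
#' \code{sin(n / 10000^(2i / dim))} and component \code{2i + 2} the matching
#' cosine, for \code{i = 0, ..., dim/2 - 1}.
#'
#' @param n step index (non-negative)
#' @param dim embedding dimension (even)
#' @return numeric vector of length \code{dim}
#' @export
sinusoidalEmbedding <- function(n, dim) {
  if (dim %% 2L != 0L) stop("dim must be even")
  i <- seq_len(dim %/% 2L) - 1L
  ang <- n / 10000^(2 * i / dim)
  out <- numeric(dim)
  out[2L * i + 1L] <- sin(ang)
  out[2L * i + 2L] <- cos(ang)
  out
}

#' Single-query multi-head attention (reference form)
#'
#' Scaled dot-product attention with \code{h} heads, written for an
#' explicit query matrix.  In the edge-decision network the query is a
#' single learnable row, which makes the pooling linear in the number of
#' nodes; this exported form exists mainly so that tests can compare the
#' batched production path against a direct implementation.
#'
#' @param Q query matrix (rows of dimension d)
#' @param K,V key/value matrix (equal row counts, dimension d)
#' @param params list with \code{WQ}, \code{WK}, \code{WV} (d x d, head
#'   blocks in columns) and \code{WO} (d x d)
#' @param h number of heads
#' @return matrix with \code{nrow(Q)} rows
#' @export
multiHeadAttention <- function(Q, K, V, params, h) {
  d <- ncol(Q)
  dh <- d %/% h
  Qp <- Q %*% params$WQ; Kp <- K %*% params$WK; Vp <- V %*% params$WV
  heads <- lapply(seq_len(h), function(i) {
    blk <- ((i - 1L) * dh + 1L):(i * dh)
    S <- Qp[, blk, drop = FALSE] %*% t(Kp[, blk, drop = FALSE]) / sqrt(dh)
    W <- exp(S - apply(S, 1L, max))
    W <- W / rowSums(W)
    W %*% Vp[, blk, drop = FALSE]
  })
  do.call(cbind, heads) %*% params$WO
}

## Adam optimizer over a named list of parameter arrays
.adamInit <- function(p) {
  zero <- lapply(p, function(x) x * 0)
  list(m = zero, v = zero, t = 0L)
}

.adamStep <- function(p, G, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(p)) {
    g <- G[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    p[[nm]] <- p[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(p = p, opt = opt)
}
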