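# Minimal vision-transformer building blocks with hand-written forward and
# backward passes on plain matrices (token sequences are N x D). Depth-0
# stacks degenerate to the identity, which several contract tests rely on.
#
# Parameter containers are nested named lists of numeric arrays; gradient
# containers mirror their structure exactly.

.ln_eps <- 1e-6

rmat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Initialize transformer encoder parameters
#'
#' @param D Token dimension. @param depth Number of blocks. @param heads
#'   Attention heads (`D %% heads == 0`). @param mlp_ratio Hidden widening
#'   of the token MLP.
#' @return Nested parameter list (`blocks`, `ln_f`). Draws from the active
#'   RNG stream.
#' @keywords internal
init_encoder <- function(D, depth, heads, mlp_ratio = 4) {
  if (depth > 0 && D %% heads != 0) stop("D must be divisible by heads")
  Dh <- as.integer(D * mlp_ratio)
  blocks <- lapply(seq_len(depth), function(i) list(
    ln1 = list(g = rep(1, D), b = rep(0, D)),
    attn = list(Wq = rmat(D, D), bq = rep(0, D),
                Wk = rmat(D, D), bk = rep(0, D),
                Wv = rmat(D, D), bv = rep(0, D),
                Wo = rmat(D, D), bo = rep(0, D)),
    ln2 = list(g = rep(1, D), b = rep(0, D)),
    mlp = list(W1 = rmat(D, Dh), b1 = rep(0, Dh),
               W2 = rmat(Dh, D), b2 = rep(0, D))
  ))
  list(blocks = blocks, ln_f = if (depth > 0)
    list(g = rep(1, D), b = rep(0, D)) else NULL,
    D = D, heads = heads)
}

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + .ln_eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, g, `*`), 2, b, `+`)
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g))
}

ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dy * xhat); db <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * inv
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(s) {
  m <- apply(s, 1, max)
  e <- exp(s - m)
  e / rowSums(e)
}

attn_fwd <- function(x, p, heads) {
  D <- ncol(x); Dh <- D %/% heads; N <- nrow(x)
  Q <- sweep(x %*% p$Wq, 2, p$bq, `+`)
  K <- sweep(x %*% p$Wk, 2, p$bk, `+`)
  V <- sweep(x %*% p$Wv, 2, p$bv, `+`)
  O <- matrix(0, N, D)
  A <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * Dh + 1):(h * Dh)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(Dh)
    A[[h]] <- softmax_rows(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  y <- sweep(O %*% p$Wo, 2, p$bo, `+`)
  list(y = y, cache = list(x = x, Q = Q, K = K, V = V, A = A, O = O,
                           heads = heads, Dh = Dh))
}

attn_bwd <- function(dy, cache, p) {
  x <- cache$x; Q <- cache$Q; K <- cache$K; V <- cache$V
  heads <- cache$heads; Dh <- cache$Dh
  dWo <- t(cache$O) %*% dy; dbo <- colSums(dy)
  dO <- dy %*% t(p$Wo)
  dQ <- matrix(0, nrow(x), ncol(x)); dK <- dQ; dV <- dQ
  for (h in seq_len(heads)) {
    idx <- ((h - 1) * Dh + 1):(h * Dh)
    A <- cache$A[[h]]
    dOh <- dO[, idx, drop = FALSE]
    dA <- dOh %*% t(V[, idx, drop = FALSE])
    dV[, idx] <- t(A) %*% dOh
    dS <- (dA - rowSums(dA * A)) * A
    dQ[, idx] <- (dS %*% K[, idx, drop = FALSE]) / sqrt(Dh)
    dK[, idx] <- (t(dS) %*% Q[, idx, drop = FALSE]) / sqrt(Dh)
  }
  dx <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  grads <- list(Wq = t(x) %*% dQ, bq = colSums(dQ),
                Wk = t(x) %*% dK, bk = colSums(dK),
                Wv = t(x) %*% dV, bv = colSums(dV),
                Wo = dWo, bo = dbo)
  list(dx = dx, grads = grads)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

mlp_fwd <- function(x, p) {
  h <- sweep(x %*% p$W1, 2, p$b1, `+`)
  a <- gelu(h)
  y <- sweep(a %*% p$W2, 2, p$b2, `+`)
  list(y = y, cache = list(x = x, h = h, a = a))
}

mlp_bwd <- function(dy, cache, p) {
  dW2 <- t(cache$a) %*% dy; db2 <- colSums(dy)
  da <- dy %*% t(p$W2)
  dh <- da * gelu_grad(cache$h)
  dW1 <- t(cache$x) %*% dh; db1 <- colSums(dh)
  dx <- dh %*% t(p$W1)
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

block_fwd <- function(x, blk, heads) {
  l1 <- ln_fwd(x, blk$ln1$g, blk$ln1$b)
  at <- attn_fwd(l1$y, blk$attn, heads)
  x2 <- x + at$y
  l2 <- ln_fwd(x2, blk$ln2$g, blk$ln2$b)
  ml <- mlp_fwd(l2$y, blk$mlp)
  list(y = x2 + ml$y, cache = list(l1 = l1$cache, at = at$cache,
                                   l2 = l2$cache, ml = ml$cache))
}

block_bwd <- function(dy, cache, blk, heads) {
  mb <- mlp_bwd(dy, cache$ml, blk$mlp)
  l2b <- ln_bwd(mb$dx, cache$l2)
  dx2 <- dy + l2b$dx
  ab <- attn_bwd(dx2, cache$at, blk$attn)
  l1b <- ln_bwd(ab$dx, cache$l1)
  dx <- dx2 + l1b$dx
  list(dx = dx,
       grads = list(ln1 = list(g = l1b$dg, b = l1b$db), attn = ab$grads,
                    ln2 = list(g = l2b$dg, b = l2b$db), mlp = mb$grads))
}

#' Forward pass of a transformer stack over a token sequence
#' @return list(y, caches); depth-0 stacks return the input unchanged.
#' @keywords internal
encoder_fwd <- function(x, enc) {
  caches <- vector("list", length(enc$blocks))
  for (i in seq_along(enc$blocks)) {
    r <- block_fwd(x, enc$blocks[[i]], enc$heads)
    x <- r$y; caches[[i]] <- r$cache
  }
  lnc <- NULL
  if (!is.null(enc$ln_f)) {
    r <- ln_fwd(x, enc$ln_f$g, enc$ln_f$b)
    x <- r$y; lnc <- r$cache
  }
  list(y = x, caches = caches, ln_cache = lnc)
}

#' Backward pass matching [encoder_fwd()]
#' @return list(dx, grads) with grads mirroring the parameter structure.
#' @keywords internal
encoder_bwd <- function(dy, fwd, enc) {
  grads <- list(blocks = vector("list", length(enc$blocks)), ln_f = NULL)
  if (!is.null(enc$ln_f)) {
    r <- ln_bwd(dy, fwd$ln_cache)
    dy <- r$dx; grads$ln_f <- list(g = r$dg, b = r$db)
  }
  for (i in rev(seq_along(enc$blocks))) {
    r <- block_bwd(dy, fwd$caches[[i]], enc$blocks[[i]], enc$heads)
    dy <- r$dx; grads$blocks[[i]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

# ---- generic parameter-tree utilities and AdamW -----------------------------

is_leaf <- function(x) is.numeric(x)

tree_map2 <- function(f, a, b) {
  if (is_leaf(a)) return(f(a, b))
  out <- a
  for (nm in names(a)) {
    if (is.null(a[[nm]]) || identical(nm, "D") || identical(nm, "heads")) next
    out[[nm]] <- tree_map2(f, a[[nm]], b[[nm]])
  }
  out
}

tree_zero <- function(p) tree_map2(function(a, b) a * 0, p, p)
tree_add <- function(a, b) tree_map2(`+`, a, b)
tree_scale <- function(p, s) tree_map2(function(a, b) a * s, p, p)

# Weight decay applies only to weight matrices (leaf names starting with "W");
# biases, layer-norm affine parameters and mask tokens are exempt.
.tree_walk <- function(p, path = character()) {
  if (is_leaf(p)) return(list(list(path = path, value = p)))
  out <- list()
  for (nm in names(p)) {
    if (is.null(p[[nm]]) || identical(nm, "D") || identical(nm, "heads")) next
    out <- c(out, .tree_walk(p[[nm]], c(path, nm)))
  }
  out
}

#' Create AdamW optimizer state for a parameter tree
#' @keywords internal
adamw_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

#' One AdamW update (decoupled weight decay on weight matrices only)
#'
#' @param params,grads Matching parameter and gradient trees.
#' @param state State from [adamw_init()].
#' @param lr,wd,beta1,beta2,eps Optimizer hyper-parameters.
#' @return list(params, state).
#' @keywords internal
adamw_step <- function(params, grads, state, lr, wd = 0.05,
                       beta1 = 0.9, beta2 = 0.95, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v, decay) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    p <- p - lr * mh / (sqrt(vh) + eps)
    if (decay) p <- p - lr * wd * p
    list(p = p, m = m, v = v)
  }
  rec <- function(p, g, m, v, path) {
    if (is_leaf(p)) {
      nm <- if (length(path)) path[length(path)] else ""
      return(upd(p, g, m, v, startsWith(nm, "W")))
    }
    out <- list(p = p, m = m, v = v)
    for (nm in names(p)) {
      if (is.null(p[[nm]]) || identical(nm, "D") || identical(nm, "heads")) next
      r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]], c(path, nm))
      out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
    }
    out
  }
  r <- rec(params, grads, state$m, state$v, character())
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
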