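# Low-level neural network layers with hand-written backward passes.
# All activations are plain base-R matrix algebra (BLAS); caches returned by
# the *_fwd functions carry exactly what the matching *_bwd needs.

init_linear <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  list(W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
       b = numeric(fan_out))
}

linear_fwd <- function(x, W, b) {
  y <- x %*% W
  y + rep(b, each = nrow(y))
}

# LayerNorm over features (per row), eps 1e-5
ln_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  y <- xhat * rep(g, each = nrow(x)) + rep(b, each = nrow(x))
  list(y = y, xhat = xhat, inv = inv, g = g)
}

ln_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  n <- nrow(dy)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(cache$g, each = n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  P <- exp(S - mx)
  P / rowSums(P)
}

# Multi-head scaled dot-product attention. xq: nq x h queries, xkv: nk x h
# keys/values. Returns output, per-head attention matrices, and cache.
mha_fwd <- function(xq, xkv, p, nh) {
  h <- ncol(xq)
  d <- h / nh
  Q <- linear_fwd(xq, p$Wq, p$bq)
  K <- linear_fwd(xkv, p$Wk, p$bk)
  V <- linear_fwd(xkv, p$Wv, p$bv)
  O <- matrix(0, nrow(xq), h)
  Ps <- vector("list", nh)
  for (a in seq_len(nh)) {
    idx <- ((a - 1) * d + 1):(a * d)
    Sa <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) / sqrt(d)
    Pa <- softmax_rows(Sa)
    O[, idx] <- Pa %*% V[, idx, drop = FALSE]
    Ps[[a]] <- Pa
  }
  y <- linear_fwd(O, p$Wo, p$bo)
  list(y = y, P = Ps,
       cache = list(xq = xq, xkv = xkv, Q = Q, K = K, V = V, O = O, nh = nh))
}

mha_bwd <- function(dy, fwd, p) {
  cc <- fwd$cache
  nh <- cc$nh
  h <- ncol(cc$Q)
  d <- h / nh
  dWo <- crossprod(cc$O, dy)
  dbo <- colSums(dy)
  dO <- tcrossprod(dy, p$Wo)
  dQ <- matrix(0, nrow(cc$Q), h)
  dK <- matrix(0, nrow(cc$K), h)
  dV <- matrix(0, nrow(cc$V), h)
  for (a in seq_len(nh)) {
    idx <- ((a - 1) * d + 1):(a * d)
    Pa <- fwd$P[[a]]
    dOa <- dO[, idx, drop = FALSE]
    dPa <- tcrossprod(dOa, cc$V[, idx, drop = FALSE])
    dV[, idx] <- crossprod(Pa, dOa)
    dSa <- Pa * (dPa - rowSums(dPa * Pa))
    dQ[, idx] <- dSa %*% cc$K[, idx, drop = FALSE] / sqrt(d)
    dK[, idx] <- crossprod(dSa, cc$Q[, idx, drop = FALSE]) / sqrt(d)
  }
  dxq <- tcrossprod(dQ, p$Wq)
  dxkv <- tcrossprod(dK, p$Wk) + tcrossprod(dV, p$Wv)
  # element order must match init_mha
  grads <- list(Wq = crossprod(cc$xq, dQ), Wk = crossprod(cc$xkv, dK),
                Wv = crossprod(cc$xkv, dV), Wo = dWo,
                bq = colSums(dQ), bk = colSums(dK), bv = colSums(dV),
                bo = dbo)
  list(dxq = dxq, dxkv = dxkv, grads = grads)
}

# Position-wise two-layer feed-forward with ReLU
ffn_fwd <- function(x, p) {
  pre <- linear_fwd(x, p$W1, p$b1)
  hmid <- pre * (pre > 0)
  y <- linear_fwd(hmid, p$W2, p$b2)
  list(y = y, cache = list(x = x, pre = pre, hmid = hmid))
}

ffn_bwd <- function(dy, fwd, p) {
  cc <- fwd$cache
  dW2 <- crossprod(cc$hmid, dy)
  db2 <- colSums(dy)
  dh <- tcrossprod(dy, p$W2) * (cc$pre > 0)
  dW1 <- crossprod(cc$x, dh)
  db1 <- colSums(dh)
  dx <- tcrossprod(dh, p$W1)
  list(dx = dx, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

init_mha <- function(h) {
  c(setNames(lapply(1:4, function(i) init_linear(h, h)$W),
             c("Wq", "Wk", "Wv", "Wo")),
    list(bq = numeric(h), bk = numeric(h), bv = numeric(h), bo = numeric(h)))
}

init_ffn <- function(h, mult) {
  l1 <- init_linear(h, h * mult)
  l2 <- init_linear(h * mult, h)
  list(W1 = l1$W, b1 = l1$b, W2 = l2$W, b2 = l2$b)
}

init_block <- function(h, mult) {
  list(ln1_g = rep(1, h), ln1_b = numeric(h), attn = init_mha(h),
       ln2_g = rep(1, h), ln2_b = numeric(h), ffn = init_ffn(h, mult))
}

# Inverted dropout on a residual branch: active only when pdrop > 0 (training
# mode); evaluation mode always passes through.
drop_fwd <- function(y, pdrop) {
  if (pdrop <= 0) return(list(y = y, mask = NULL))
  mask <- matrix(rbinom(length(y), 1, 1 - pdrop), nrow(y)) / (1 - pdrop)
  list(y = y * mask, mask = mask)
}

drop_bwd <- function(dy, mask) if (is.null(mask)) dy else dy * mask

# Pre-LN self-attention encoder block: x + MHA(LN(x)) then x + FFN(LN(x))
enc_block_fwd <- function(x, p, nh, pdrop = 0) {
  l1 <- ln_fwd(x, p$ln1_g, p$ln1_b)
  at <- mha_fwd(l1$y, l1$y, p$attn, nh)
  d1 <- drop_fwd(at$y, pdrop)
  x1 <- x + d1$y
  l2 <- ln_fwd(x1, p$ln2_g, p$ln2_b)
  ff <- ffn_fwd(l2$y, p$ffn)
  d2 <- drop_fwd(ff$y, pdrop)
  list(y = x1 + d2$y,
       cache = list(l1 = l1, at = at, l2 = l2, ff = ff,
                    m1 = d1$mask, m2 = d2$mask))
}

enc_block_bwd <- function(dy, fwd, p, nh) {
  cc <- fwd$cache
  fb <- ffn_bwd(drop_bwd(dy, cc$m2), cc$ff, p$ffn)
  l2b <- ln_bwd(fb$dx, cc$l2)
  dx1 <- dy + l2b$dx
  ab <- mha_bwd(drop_bwd(dx1, cc$m1), cc$at, p$attn)
  l1b <- ln_bwd(ab$dxq + ab$dxkv, cc$l1)
  dx <- dx1 + l1b$dx
  grads <- list(ln1_g = l1b$dg, ln1_b = l1b$db, attn = ab$grads,
                ln2_g = l2b$dg, ln2_b = l2b$db, ffn = fb$grads)
  list(dx = dx, grads = grads)
}

# Pre-LN cross-attention decoder block: the query token attends over the cell
# latents z; no query self-attention (vacuous with a single token).
dec_block_fwd <- function(q, z, p, nh, pdrop = 0) {
  l1 <- ln_fwd(q, p$ln1_g, p$ln1_b)
  at <- mha_fwd(l1$y, z, p$attn, nh)
  d1 <- drop_fwd(at$y, pdrop)
  q1 <- q + d1$y
  l2 <- ln_fwd(q1, p$ln2_g, p$ln2_b)
  ff <- ffn_fwd(l2$y, p$ffn)
  d2 <- drop_fwd(ff$y, pdrop)
  list(y = q1 + d2$y, attn = at$P,
       cache = list(l1 = l1, at = at, l2 = l2, ff = ff,
                    m1 = d1$mask, m2 = d2$mask))
}

dec_block_bwd <- function(dy, fwd, p, nh) {
  cc <- fwd$cache
  fb <- ffn_bwd(drop_bwd(dy, cc$m2), cc$ff, p$ffn)
  l2b <- ln_bwd(fb$dx, cc$l2)
  dq1 <- dy + l2b$dx
  ab <- mha_bwd(drop_bwd(dq1, cc$m1), cc$at, p$attn)
  l1b <- ln_bwd(ab$dxq, cc$l1)
  dq <- dq1 + l1b$dx
  grads <- list(ln1_g = l1b$dg, ln1_b = l1b$db, attn = ab$grads,
                ln2_g = l2b$dg, ln2_b = l2b$db, ffn = fb$grads)
  list(dq = dq, dz = ab$dxkv, grads = grads)
}

# ---- parameter-tree utilities ----------------------------------------------

tree_map <- function(f, tree) {
  if (is.list(tree)) lapply(tree, function(t) tree_map(f, t)) else f(tree)
}

# name-aware where names exist, positional otherwise
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
    mapply(function(x, y) tree_map2(f, x, y), a, b, SIMPLIFY = FALSE)
  } else f(a, b)
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_add <- function(a, b) tree_map2(`+`, a, b)

tree_sum_sq <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_sum_sq, numeric(1)))
  else sum(tree^2)
}

tree_identical <- function(a, b) {
  if (is.list(a)) all(mapply(tree_identical, a, b))
  else identical(as.numeric(a), as.numeric(b))
}
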