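# AdamW with cosine learning-rate decay and global-norm gradient clipping.
# Decoupled weight decay applies to 2-D weight matrices only (never to biases,
# LayerNorm parameters, the mask bank or the prediction token).

adamw_init <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

cosine_lr <- function(base_lr, step, total_steps, warmup = 0L) {
  if (warmup > 0 && step <= warmup) return(base_lr * step / warmup)
  prog <- min(1, (step - warmup) / max(1, total_steps - warmup))
  base_lr * 0.5 * (1 + cos(pi * prog))
}

clip_global_norm <- function(grads, max_norm) {
  gn <- sqrt(tree_sum_sq(grads))
  if (is.finite(gn) && gn > max_norm)
    grads <- tree_map(function(g) g * (max_norm / gn), grads)
  grads
}

# One AdamW step. params/grads/state trees must be structurally identical.
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 0.01) {
  state$t <- state$t + 1L
  t <- state$t
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    if (is.matrix(p) && weight_decay > 0) upd <- upd + weight_decay * p
    list(p = p - lr * upd, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
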