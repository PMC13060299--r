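#' Model configuration
#'
#' Architecture hyperparameters of the encoder-decoder. Defaults mirror the
#' reference setting: hidden size 128, 4 encoder and 4 decoder layers, 4
#' attention heads, feed-forward inner dimension `4 * hidden_size`.
#'
#' @param hidden_size transformer hidden size `h`; must be divisible by
#'   `heads`.
#' @param encoder_layers,decoder_layers number of Pre-LN blocks in each stack.
#' @param heads attention heads per layer.
#' @param feedforward_multiplier inner FFN width as a multiple of `h`.
#' @param dropout residual-branch dropout probability in `[0, 1)`, applied in
#'   training mode only.
#' @param variance_floor lower clamp for predicted variances.
#' @return an object of class `cytoformer_config`.
#' @export
model_config <- function(hidden_size = 128L, encoder_layers = 4L,
                         decoder_layers = 4L, heads = 4L,
                         feedforward_multiplier = 4L, dropout = 0,
                         variance_floor = 1e-6) {
  if (hidden_size %% heads != 0)
    stop_cf("hidden_size must be divisible by heads",
            class = "cytoformer_parameter_error")
  if (dropout < 0 || dropout >= 1)
    stop_cf("dropout must be in [0, 1)", class = "cytoformer_parameter_error")
  structure(list(hidden_size = as.integer(hidden_size),
                 encoder_layers = as.integer(encoder_layers),
                 decoder_layers = as.integer(decoder_layers),
                 heads = as.integer(heads),
                 feedforward_multiplier = as.integer(feedforward_multiplier),
                 dropout = dropout, variance_floor = variance_floor),
            class = "cytoformer_config")
}

#' Initialise a cytoformer model
#'
#' Creates an untrained model: the learnable mask bank (zeros), the input
#' projection, the self-attention encoder stack, the heteroscedastic
#' pretraining heads over the full vocabulary, and the cross-attention decoder
#' with its learnable prediction token and task head.
#'
#' @param vocabulary a [marker_vocabulary].
#' @param config a [model_config()].
#' @param task `"classification"` or `"regression"`.
#' @param classes character vector of class labels (classification only).
#' @param seed integer seed for weight initialisation.
#' @return an object of class `cytoformer`.
#' @export
init_cytoformer <- function(vocabulary, config = model_config(),
                            task = "classification", classes = NULL,
                            seed = 1L) {
  V <- vocabulary$size
  h <- config$hidden_size
  mult <- config$feedforward_multiplier
  n_out <- if (task == "classification") max(2L, length(classes)) else 1L
  params <- with_seed(derive_seed(seed, "init"), {
    list(
      mu = numeric(V),
      proj = init_linear(2 * V, h),
      enc = lapply(seq_len(config$encoder_layers),
                   function(i) init_block(h, mult)),
      enc_ln = list(g = rep(1, h), b = numeric(h)),
      heads = list(X = init_head(h, V), P = init_head(h, V),
                   D = init_head(h, V)),
      token = rnorm(h, sd = 0.02),
      dec = lapply(seq_len(config$decoder_layers),
                   function(i) init_block(h, mult)),
      dec_ln = list(g = rep(1, h), b = numeric(h)),
      task = init_linear(h, n_out)
    )
  })
  structure(list(vocabulary = vocabulary, config = config, params = params,
                 task = task, classes = classes, pretrained = FALSE,
                 finetuned = FALSE, history = list()),
            class = "cytoformer")
}

init_head <- function(h, V) {
  m <- init_linear(h, V)
  l <- init_linear(h, V)
  list(Wm = m$W, bm = m$b, Wl = l$W, bl = l$b)
}

#' Encode a sample's cells into the latent space
#'
#' Runs the panel-augmented embedding, input projection and Pre-LN
#' self-attention encoder stack. The map is permutation-equivariant over
#' cells: no positional encoding is used, and each output row is aligned with
#' its input cell.
#'
#' @param model a [cytoformer] object.
#' @param sample a [cyto_sample], or a pre-embedded `n x 2|M|` matrix.
#' @return numeric matrix `n x h` of latent cell states.
#' @export
encode <- function(model, sample) {
  cells <- if (inherits(sample, "cyto_sample"))
    embed_sample(sample, model$vocabulary, model$params$mu) else sample
  fw <- encoder_fwd(cells, model$params, model$config, pdrop = 0)
  fw$z
}

# full encoder forward with caches; pdrop > 0 only in training mode
encoder_fwd <- function(cells, params, config, pdrop = 0, final_ln = TRUE) {
  pj <- project_fwd(cells, params$proj)
  x <- pj$y
  blocks <- vector("list", config$encoder_layers)
  for (l in seq_len(config$encoder_layers)) {
    bf <- enc_block_fwd(x, params$enc[[l]], config$heads, pdrop)
    if (!all(is.finite(bf$y)))
      stop_cf("non-finite activations in encoder layer ", l,
              class = "cytoformer_numeric_error")
    blocks[[l]] <- bf
    x <- bf$y
  }
  lnf <- NULL
  if (final_ln) {
    lnf <- ln_fwd(x, params$enc_ln$g, params$enc_ln$b)
    x <- lnf$y
  }
  list(z = x, proj = pj, blocks = blocks, final = lnf)
}

encoder_bwd <- function(dz, fwd, params, config) {
  grads <- list()
  if (!is.null(fwd$final)) {
    lb <- ln_bwd(dz, fwd$final)
    grads$enc_ln <- list(g = lb$dg, b = lb$db)
    dz <- lb$dx
  } else {
    grads$enc_ln <- list(g = numeric(config$hidden_size),
                         b = numeric(config$hidden_size))
  }
  grads$enc <- vector("list", config$encoder_layers)
  for (l in rev(seq_len(config$encoder_layers))) {
    bb <- enc_block_bwd(dz, fwd$blocks[[l]], params$enc[[l]], config$heads)
    grads$enc[[l]] <- bb$grads
    dz <- bb$dx
  }
  pb <- project_bwd(dz, fwd$proj, params$proj)
  grads$proj <- pb$grads
  list(dcells = pb$dcells, grads = grads)
}

#' Pretraining heads: heteroscedastic per-cell predictions
#'
#' Maps each latent cell state to a predicted mean and strictly positive
#' variance for all three self-supervision targets (expression, percentile,
#' log-density), over every vocabulary slot. Cells are independent
#' (position-wise map). Variances are `exp(logvar)` clamped below at the
#' configured floor.
#'
#' @param model a [cytoformer].
#' @param latent `n x h` matrix from [encode()].
#' @return list with elements `X`, `P`, `D`, each holding `mean` and `var`
#'   matrices of shape `n x |M|`, plus `n_clamped` counting floor hits.
#' @export
pretrain_heads <- function(model, latent) {
  hf <- heads_fwd(latent, model$params$heads, model$config$variance_floor)
  out <- lapply(hf$out, function(o) o[c("mean", "var")])
  out$n_clamped <- hf$n_clamped
  out
}

heads_fwd <- function(z, hp, floor) {
  n_clamped <- 0L
  out <- lapply(hp, function(p) {
    mean <- linear_fwd(z, p$Wm, p$bm)
    logvar <- linear_fwd(z, p$Wl, p$bl)
    var <- exp(logvar)
    clamped <- var < floor
    n_clamped <<- n_clamped + sum(clamped)
    var[clamped] <- floor
    list(mean = mean, logvar = logvar, var = var, clamped = clamped)
  })
  list(out = out, n_clamped = n_clamped)
}

# dmean/dvar given per target; returns dz and head grads. Gradient wrt logvar
# is zero where the floor clamp was active.
heads_bwd <- function(dout, fwd, z, hp) {
  dz <- matrix(0, nrow(z), ncol(z))
  grads <- list()
  for (t in names(hp)) {
    o <- fwd$out[[t]]
    dmean <- dout[[t]]$dmean
    dlogvar <- dout[[t]]$dvar * o$var
    dlogvar[o$clamped] <- 0
    dz <- dz + tcrossprod(dmean, hp[[t]]$Wm) + tcrossprod(dlogvar, hp[[t]]$Wl)
    grads[[t]] <- list(Wm = crossprod(z, dmean), bm = colSums(dmean),
                       Wl = crossprod(z, dlogvar), bl = colSums(dlogvar))
  }
  list(dz = dz, grads = grads)
}

#' Decode: cross-attention pooling to a sample-level prediction
#'
#' A single learnable prediction token is refined through the decoder's
#' cross-attention blocks over all cell latents, and the final token state
#' feeds the task head. The prediction is permutation-invariant over cells;
#' the attention weights are permutation-equivariant and, per layer and head,
#' sum to one over cells.
#'
#' @param model a [cytoformer].
#' @param latent `n x h` matrix from [encode()].
#' @return list with `prediction` (class scores named by class, or a scalar
#'   for regression), `probabilities` (classification only) and `attention`
#'   (an `attention_map`: `weights` array `layers x heads x n` and
#'   `per_layer_mean` matrix `layers x n`).
#' @export
decode_predict <- function(model, latent) {
  latent <- standardize_latent(model, latent)
  fw <- decoder_fwd(latent, model$params, model$config, pdrop = 0)
  pred <- drop(fw$logits)
  out <- list(attention = fw$attention)
  if (model$task == "classification") {
    names(pred) <- model$classes
    out$prediction <- pred
    out$probabilities <- softmax_vec(pred)
  } else {
    out$prediction <- unname(pred[1])
  }
  out
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Fixed per-dimension affine standardisation of encoder latents, computed on
# the downstream training corpus (mean/sd over all training cells) and stored
# in the checkpoint. Pure preconditioning of the decoder's in-projections:
# mathematically absorbable into Wq/Wk/Wv and their biases, but it makes the
# scale of the pooled features independent of the pretrained latent geometry,
# which conditions decoder optimisation at small problem sizes.
standardize_latent <- function(model, z) {
  st <- model$latent_stats
  if (is.null(st)) return(z)
  sweep(sweep(z, 2, st$mean), 2, st$sd, "/")
}

decoder_fwd <- function(z, params, config, pdrop = 0) {
  q <- matrix(params$token, 1)
  blocks <- vector("list", config$decoder_layers)
  L <- config$decoder_layers
  nh <- config$heads
  n <- nrow(z)
  weights <- array(0, c(L, nh, n))
  for (l in seq_len(L)) {
    bf <- dec_block_fwd(q, z, params$dec[[l]], nh, pdrop)
    if (!all(is.finite(bf$y)))
      stop_cf("non-finite activations in decoder layer ", l,
              class = "cytoformer_numeric_error")
    for (a in seq_len(nh)) weights[l, a, ] <- bf$attn[[a]][1, ]
    blocks[[l]] <- bf
    q <- bf$y
  }
  lnf <- ln_fwd(q, params$dec_ln$g, params$dec_ln$b)
  logits <- linear_fwd(lnf$y, params$task$W, params$task$b)
  per_layer_mean <- matrix(0, L, n)
  for (l in seq_len(L)) per_layer_mean[l, ] <- colMeans(matrix(weights[l, , ],
                                                               nh, n))
  attention <- structure(list(weights = weights,
                              per_layer_mean = per_layer_mean),
                         class = "attention_map")
  list(logits = logits, attention = attention,
       blocks = blocks, final = lnf, token_state = lnf$y, z = z)
}

# returns grads for token/dec/dec_ln/task and dz for optional encoder unfreeze
decoder_bwd <- function(dlogits, fwd, params, config) {
  grads <- list()
  dlogits <- matrix(dlogits, 1)
  grads$task <- list(W = crossprod(fwd$final$y, dlogits),
                     b = colSums(dlogits))
  dq <- tcrossprod(dlogits, params$task$W)
  lb <- ln_bwd(dq, fwd$final)
  grads$dec_ln <- list(g = lb$dg, b = lb$db)
  dq <- lb$dx
  dz <- matrix(0, nrow(fwd$z), ncol(fwd$z))
  grads$dec <- vector("list", config$decoder_layers)
  for (l in rev(seq_len(config$decoder_layers))) {
    bb <- dec_block_bwd(dq, fwd$blocks[[l]], params$dec[[l]], config$heads)
    grads$dec[[l]] <- bb$grads
    dz <- dz + bb$dz
    dq <- bb$dq
  }
  grads$token <- as.numeric(dq)
  list(dz = dz, grads = grads)
}
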