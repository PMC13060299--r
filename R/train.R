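#' Downstream training configuration
#'
#' @param marker_dropout_rate fixed marker-wise input dropout rate applied at
#'   training time only (default 0.1).
#' @param freeze_encoder keep embedding, mask bank and encoder bitwise frozen
#'   (default TRUE; unfreezing can help in data-rich regimes).
#' @param loss `"cross-entropy"` (classification) or `"mse"` (regression).
#' @param validation_fraction held-out fraction for early stopping (default
#'   0.1, i.e. a 90-10 split).
#' @param patience early-stopping patience in epochs on validation loss.
#' @param epochs maximum training epochs.
#' @param lr,batch_size,weight_decay,clip AdamW settings (cosine-decayed lr).
#' @param max_cells per-sample cell cap during downstream training (default
#'   7000).
#' @return an object of class `downstream_config`.
#' @export
downstream_config <- function(marker_dropout_rate = 0.1,
                              freeze_encoder = TRUE, loss = "cross-entropy",
                              validation_fraction = 0.1, patience = 10L,
                              epochs = 60L, lr = 1e-4, batch_size = 4L,
                              weight_decay = 0.01, clip = 1.0,
                              max_cells = 7000L) {
  if (marker_dropout_rate < 0 || marker_dropout_rate >= 1 ||
      validation_fraction < 0 || validation_fraction >= 1)
    stop_cf("rates must be in [0, 1)", class = "cytoformer_parameter_error")
  structure(as.list(environment()), class = "downstream_config")
}

#' Pretraining configuration
#'
#' @param epochs,lr,batch_size,weight_decay,clip AdamW settings
#'   (cosine-decayed lr, gradient clipping by global norm).
#' @param max_cells per-sample cell cap per pretraining epoch (default 5000).
#' @param sigma KDE bandwidth for the density target.
#' @param target_cells cap for target precomputation (default 50000).
#' @param validation_fraction sample fraction held out for checkpoint
#'   selection.
#' @param patience early-stopping patience in epochs.
#' @return an object of class `pretrain_config`.
#' @export
pretrain_config <- function(epochs = 30L, lr = 1e-3, batch_size = 4L,
                            weight_decay = 0.01, clip = 1.0,
                            max_cells = 5000L, sigma = 0.05,
                            target_cells = 50000L,
                            validation_fraction = 0.1, patience = 10L) {
  structure(as.list(environment()), class = "pretrain_config")
}

subtree_names_pretrain <- c("mu", "proj", "enc", "enc_ln", "heads")
subtree_names_decoder <- c("token", "dec", "dec_ln", "task")
subtree_names_encoder <- c("mu", "proj", "enc", "enc_ln")

# one pretraining forward/backward for a (sub)sample under both masked views;
# returns loss value and gradients over the pretraining subtree
pretrain_sample_grad <- function(events, markers, tg_rows, model, mask_cfg,
                                 loss_cfg, view_seeds, pdrop = 0) {
  params <- model$params
  config <- model$config
  V <- model$vocabulary$size
  slots <- vocab_slots(model$vocabulary, markers)
  grads <- tree_zeros_like(params[subtree_names_pretrain])
  total <- 0
  patterns <- c("uniform_random", "marker_wise")
  for (k in 1:2) {
    view <- if (patterns[k] == "uniform_random")
      mask_uniform_random(events, mask_cfg, seed = view_seeds[k])
    else mask_marker_wise(events, mask_cfg, seed = view_seeds[k])
    wk <- if (k == 1) loss_cfg$w_uniform else loss_cfg$w_markerwise
    au <- augment_cells(events, markers, model$vocabulary, params$mu,
                        per_cell_mask = view$mask,
                        dropped = view$dropped_markers)
    cells <- cbind(au$avail, au$expr)
    ef <- encoder_fwd(cells, params, config, pdrop = pdrop)
    hf <- heads_fwd(ef$z, params$heads, config$variance_floor)
    head_out <- lapply(hf$out, function(o) o[c("mean", "var")])
    pl <- suppressWarnings(
      pretrain_loss(tg_rows, list(view), list(head_out), loss_cfg, slots))
    total <- total + sum_view_loss(pl$components, loss_cfg, wk)
    dout <- pretrain_loss_grad(tg_rows, view, head_out, loss_cfg, slots, V, wk)
    hb <- heads_bwd(dout, hf, ef$z, params$heads)
    eb <- encoder_bwd(hb$dz, ef, params, config)
    dE <- eb$dcells[, V + seq_len(V), drop = FALSE]
    dmu <- colSums(dE * (1 - au$avail))
    grads <- tree_add(grads, c(list(mu = dmu), eb$grads[c("proj", "enc",
                                                          "enc_ln")],
                               list(heads = hb$grads)))
  }
  list(loss = total, grads = grads)
}

# weighted sum of one view's six components (names "<pattern>.<t>.<set>")
sum_view_loss <- function(components, loss_cfg, wk) {
  wt <- c(X = loss_cfg$w_x, P = loss_cfg$w_p, D = loss_cfg$w_d)
  pattern <- strsplit(names(components)[1], ".", fixed = TRUE)[[1]][1]
  s <- 0
  for (t in names(wt)) {
    lm <- components[[paste(pattern, t, "masked", sep = ".")]]
    lu <- components[[paste(pattern, t, "unmasked", sep = ".")]]
    s <- s + wk * wt[[t]] * (lm + loss_cfg$beta_unmasked * lu)
  }
  unname(s)
}

#' Self-supervised pretraining
#'
#' Trains the mask bank, input projection, encoder and the three
#' heteroscedastic prediction heads by dual-masking masked prediction of
#' expression, percentile-rank and log-density targets. Decoder and task head
#' are untouched. Fully seeded: two runs with the same seed and data produce
#' identical loss trajectories.
#'
#' @param model a [cytoformer] from [init_cytoformer()].
#' @param corpus list of [cyto_sample] objects (labels not used).
#' @param config a [pretrain_config()].
#' @param mask_cfg a [mask_config()].
#' @param loss_cfg a [pretrain_loss_config()].
#' @param seed integer master seed.
#' @param cache_dir optional target-cache directory.
#' @param verbose print per-epoch losses.
#' @return the model with updated parameters, `pretrained = TRUE` and a
#'   training history (`history$pretrain`: epoch, train_loss, val_loss, lr).
#' @export
pretrain <- function(model, corpus, config = pretrain_config(),
                     mask_cfg = mask_config(),
                     loss_cfg = pretrain_loss_config(), seed = 1L,
                     cache_dir = NULL, verbose = FALSE) {
  stopifnot(length(corpus) >= 1)
  targets <- lapply(corpus, function(s)
    precompute_targets(s, sigma = config$sigma,
                       max_cells = config$target_cells, seed = seed,
                       cache_dir = cache_dir))
  n <- length(corpus)
  n_val <- floor(n * config$validation_fraction)
  val_idx <- if (n_val >= 1)
    with_seed(derive_seed(seed, "valsplit"), sample.int(n, n_val))
    else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)

  tp <- model$params[subtree_names_pretrain]
  opt <- adamw_init(tp)
  steps_per_epoch <- ceiling(length(train_idx) / config$batch_size)
  total_steps <- steps_per_epoch * config$epochs
  step <- 0L
  best_val <- Inf; best_params <- tp; wait <- 0L
  hist <- NULL

  epoch_loss_of <- function(idx, epoch, params_now, pdrop) {
    model$params[subtree_names_pretrain] <- params_now
    losses <- vapply(idx, function(i) {
      tg <- targets[[i]]
      rows <- epoch_rows(nrow(tg$expression), config$max_cells, seed,
                         tg$sample_id, epoch)
      tg_rows <- list(expression = tg$expression[rows, , drop = FALSE],
                      percentile = tg$percentile[rows, , drop = FALSE],
                      density = tg$density[rows, , drop = FALSE])
      vs <- c(derive_seed(seed, tg$sample_id, epoch, "uniform_random"),
              derive_seed(seed, tg$sample_id, epoch, "marker_wise"))
      with_seed(derive_seed(seed, tg$sample_id, epoch, "fwd"),
                pretrain_sample_grad(tg_rows$expression, tg$markers, tg_rows,
                                     model, mask_cfg, loss_cfg, vs,
                                     pdrop = pdrop)$loss)
    }, numeric(1))
    mean(losses)
  }

  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(seed, "shuffle", epoch),
                     sample(train_idx))
    ep_losses <- c()
    for (b in seq(1, length(ord), by = config$batch_size)) {
      bidx <- ord[b:min(b + config$batch_size - 1, length(ord))]
      acc <- tree_zeros_like(tp)
      bl <- 0
      model$params[subtree_names_pretrain] <- tp
      for (i in bidx) {
        tg <- targets[[i]]
        rows <- epoch_rows(nrow(tg$expression), config$max_cells, seed,
                           tg$sample_id, epoch)
        tg_rows <- list(expression = tg$expression[rows, , drop = FALSE],
                        percentile = tg$percentile[rows, , drop = FALSE],
                        density = tg$density[rows, , drop = FALSE])
        vs <- c(derive_seed(seed, tg$sample_id, epoch, "uniform_random"),
                derive_seed(seed, tg$sample_id, epoch, "marker_wise"))
        r <- with_seed(derive_seed(seed, tg$sample_id, epoch, "fwd"),
                       pretrain_sample_grad(tg_rows$expression, tg$markers,
                                            tg_rows, model, mask_cfg,
                                            loss_cfg, vs,
                                            pdrop = model$config$dropout))
        if (!is.finite(r$loss))
          stop_cf("pretraining diverged (non-finite loss) on sample ",
                  tg$sample_id, class = "cytoformer_numeric_error")
        acc <- tree_add(acc, r$grads)
        bl <- bl + r$loss
      }
      acc <- tree_map(function(g) g / length(bidx), acc)
      acc <- clip_global_norm(acc, config$clip)
      step <- step + 1L
      lr <- cosine_lr(config$lr, step, total_steps)
      st <- adamw_step(tp, acc, opt, lr, weight_decay = config$weight_decay)
      tp <- st$params; opt <- st$state
      ep_losses <- c(ep_losses, bl / length(bidx))
    }
    val_loss <- if (length(val_idx))
      epoch_loss_of(val_idx, epoch, tp, pdrop = 0) else mean(ep_losses)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(ep_losses),
                                   val_loss = val_loss,
                                   lr = cosine_lr(config$lr, step,
                                                  total_steps)))
    if (verbose)
      message(sprintf("pretrain epoch %d: train %.4f val %.4f", epoch,
                      mean(ep_losses), val_loss))
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss; best_params <- tp; wait <- 0L
    } else {
      wait <- wait + 1L
      if (length(val_idx) && wait >= config$patience) break
    }
  }
  model$params[subtree_names_pretrain] <- best_params
  model$pretrained <- TRUE
  model$history$pretrain <- hist
  model
}

epoch_rows <- function(n, max_cells, seed, id, epoch) {
  if (n <= max_cells) seq_len(n)
  else with_seed(derive_seed(seed, id, epoch, "cells"),
                 sample.int(n, max_cells))
}

# forward pass for downstream loss on one sample; returns loss, grads on the
# requested subtrees, by backprop through decoder (and encoder if unfrozen)
downstream_sample_grad <- function(sample, model, y, cfg, epoch, seed,
                                   train = TRUE) {
  params <- model$params
  config <- model$config
  events <- sample$events
  keep_mask <- NULL
  if (train && cfg$marker_dropout_rate > 0) {
    view <- mask_marker_wise(events, seed = derive_seed(seed,
                                                        sample$sample_id,
                                                        epoch, "mdrop"),
                             rate = cfg$marker_dropout_rate)
    keep_mask <- view$mask
  }
  au <- augment_cells(events, sample$markers, model$vocabulary, params$mu,
                      per_cell_mask = keep_mask)
  cells <- cbind(au$avail, au$expr)
  pdrop <- if (train) config$dropout else 0
  ef <- encoder_fwd(cells, params, config, pdrop = pdrop)
  zs <- standardize_latent(model, ef$z)
  df <- decoder_fwd(zs, params, config, pdrop = pdrop)
  if (model$task == "classification") {
    ce <- cross_entropy(df$logits, y)
    loss <- ce$loss; dlogits <- ce$dlogits
  } else {
    pred <- df$logits[1, 1]
    loss <- (pred - y)^2
    dlogits <- 2 * (pred - y)
  }
  db <- decoder_bwd(dlogits, df, params, config)
  grads <- db$grads[subtree_names_decoder]
  if (!cfg$freeze_encoder) {
    dz <- db$dz
    if (!is.null(model$latent_stats))
      dz <- sweep(dz, 2, model$latent_stats$sd, "/")
    eb <- encoder_bwd(dz, ef, params, config)
    dE <- eb$dcells[, model$vocabulary$size + seq_len(model$vocabulary$size),
                    drop = FALSE]
    grads <- c(grads, list(mu = colSums(dE * (1 - au$avail))),
               eb$grads[c("proj", "enc", "enc_ln")])
  }
  list(loss = loss, grads = grads)
}

#' Downstream task training
#'
#' Trains the decoder (prediction token, cross-attention stack and task head)
#' on labelled samples with the embedding, mask bank and encoder frozen
#' (bitwise unchanged) unless `freeze_encoder = FALSE`. Marker-wise input
#' dropout at the fixed configured rate is applied at training time only; a
#' 90-10 train/validation split drives early stopping on validation loss.
#'
#' @param model a pretrained (or freshly initialised) [cytoformer].
#' @param corpus list of labelled [cyto_sample] objects.
#' @param config a [downstream_config()].
#' @param seed integer master seed.
#' @param verbose print per-epoch losses.
#' @return the model with trained decoder, `finetuned = TRUE`, `classes` set,
#'   and `history$downstream`.
#' @export
finetune <- function(model, corpus, config = downstream_config(), seed = 1L,
                     verbose = FALSE) {
  labels <- vapply(corpus, function(s) as.character(s$label), character(1))
  if (anyNA(labels) || any(labels == "NA"))
    stop_cf("all samples need labels for downstream training",
            class = "cytoformer_configuration_error")
  if (model$task == "classification") {
    classes <- model$classes %||% sort(unique(labels))
    if (length(unique(labels)) < 2)
      stop_cf("classification needs at least two classes in the corpus",
              class = "cytoformer_configuration_error")
    if (length(classes) != ncol(model$params$task$W)) {
      # task head sized at init for max(2, length(classes)); re-check
      if (length(classes) > ncol(model$params$task$W))
        stop_cf("more classes than task-head outputs",
                class = "cytoformer_configuration_error")
    }
    model$classes <- classes
    ys <- match(labels, classes)
  } else {
    ys <- as.numeric(labels)
  }

  corpus <- lapply(corpus, subsample_cells, max_cells = config$max_cells,
                   seed = seed)
  # fixed latent standardisation from the training corpus (see
  # standardize_latent); computed once, stored in the checkpoint
  if (is.null(model$latent_stats)) {
    allz <- do.call(rbind, lapply(corpus, function(s) {
      cells <- embed_sample(s, model$vocabulary, model$params$mu)
      encoder_fwd(cells, model$params, model$config, pdrop = 0)$z
    }))
    sdv <- apply(allz, 2, stats::sd)
    sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
    model$latent_stats <- list(mean = colMeans(allz), sd = sdv)
  }
  n <- length(corpus)
  n_val <- floor(n * config$validation_fraction)
  val_idx <- if (n_val >= 1) with_seed(derive_seed(seed, "dsval"),
                                       stratified_pick(ys, n_val))
             else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)

  tnames <- subtree_names_decoder
  if (!config$freeze_encoder) tnames <- c(tnames, subtree_names_encoder)
  tp <- model$params[tnames]
  opt <- adamw_init(tp)
  steps_per_epoch <- ceiling(length(train_idx) / config$batch_size)
  total_steps <- steps_per_epoch * config$epochs
  step <- 0L
  best_val <- Inf; best_params <- tp; wait <- 0L
  hist <- NULL

  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(seed, "dshuffle", epoch), sample(train_idx))
    ep_losses <- c()
    for (b in seq(1, length(ord), by = config$batch_size)) {
      bidx <- ord[b:min(b + config$batch_size - 1, length(ord))]
      acc <- tree_zeros_like(tp)
      bl <- 0
      model$params[tnames] <- tp
      for (i in bidx) {
        r <- with_seed(derive_seed(seed, corpus[[i]]$sample_id, epoch, "dfwd"),
                       downstream_sample_grad(corpus[[i]], model, ys[i],
                                              config, epoch, seed))
        if (!is.finite(r$loss))
          stop_cf("downstream training diverged on sample ",
                  corpus[[i]]$sample_id, class = "cytoformer_numeric_error")
        acc <- tree_add(acc, r$grads)
        bl <- bl + r$loss
      }
      acc <- tree_map(function(g) g / length(bidx), acc)
      acc <- clip_global_norm(acc, config$clip)
      step <- step + 1L
      lr <- cosine_lr(config$lr, step, total_steps)
      st <- adamw_step(tp, acc, opt, lr, weight_decay = config$weight_decay)
      tp <- st$params; opt <- st$state
      ep_losses <- c(ep_losses, bl / length(bidx))
    }
    model$params[tnames] <- tp
    val_loss <- if (length(val_idx)) {
      mean(vapply(val_idx, function(i)
        downstream_sample_grad(corpus[[i]], model, ys[i], config, epoch,
                               seed, train = FALSE)$loss, numeric(1)))
    } else mean(ep_losses)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = mean(ep_losses),
                                   val_loss = val_loss))
    if (verbose)
      message(sprintf("downstream epoch %d: train %.4f val %.4f", epoch,
                      mean(ep_losses), val_loss))
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss; best_params <- tp; wait <- 0L
    } else {
      wait <- wait + 1L
      if (length(val_idx) && wait >= config$patience) break
    }
  }
  model$params[tnames] <- best_params
  model$finetuned <- TRUE
  model$history$downstream <- hist
  model
}

# pick ~n_val indices spread across classes
stratified_pick <- function(ys, n_val) {
  picked <- integer(0)
  by_class <- split(seq_along(ys), ys)
  while (length(picked) < n_val) {
    for (cl in by_class) {
      remaining <- setdiff(cl, picked)
      if (length(remaining) && length(picked) < n_val)
        picked <- c(picked, sample(remaining, 1))
    }
    if (all(seq_along(ys) %in% picked)) break
  }
  picked
}
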