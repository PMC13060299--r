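#' Gaussian negative log-likelihood
#'
#' Mean over entries of the full Gaussian negative log density:
#' `0.5 * (log(variance) + (target - mean)^2 / variance + log(2*pi))`.
#' The additive constant is included, so a perfect prediction with unit
#' variance scores `0.5 * log(2*pi)` per entry.
#'
#' @param target,mean numeric arrays of equal shape.
#' @param variance strictly positive array of the same shape.
#' @return scalar mean loss.
#' @export
gnll <- function(target, mean, variance) {
  if (length(target) != length(mean) || length(mean) != length(variance))
    stop_cf("gnll: shape mismatch", class = "cytoformer_dimension_error")
  if (length(target) == 0) return(0)
  if (any(variance <= 0))
    stop_cf("gnll: non-positive variance", class = "cytoformer_numeric_error")
  mean(0.5 * (log(variance) + (target - mean)^2 / variance + log(2 * pi)))
}

#' Pretraining loss configuration
#'
#' Weights of the dual-masking objective. `beta_unmasked` (< 1) keeps a
#' reduced supervision signal on visible entries so the model cannot ignore
#' observed marker values; target weights default to 1 and the two masking
#' patterns are averaged with weight 0.5 each.
#'
#' @param beta_unmasked weight on unmasked measured entries, in `[0, 1)`.
#' @param w_x,w_p,w_d weights of the expression / percentile / density
#'   targets.
#' @param w_uniform,w_markerwise weights of the two masking patterns.
#' @return an object of class `pretrain_loss_config`.
#' @export
pretrain_loss_config <- function(beta_unmasked = 0.5, w_x = 1, w_p = 1,
                                 w_d = 1, w_uniform = 0.5,
                                 w_markerwise = 0.5) {
  if (beta_unmasked < 0 || beta_unmasked >= 1)
    stop_cf("beta_unmasked must be in [0, 1)",
            class = "cytoformer_parameter_error")
  if (any(c(w_x, w_p, w_d, w_uniform, w_markerwise) < 0))
    stop_cf("weights must be >= 0", class = "cytoformer_parameter_error")
  structure(list(beta_unmasked = beta_unmasked, w_x = w_x, w_p = w_p,
                 w_d = w_d, w_uniform = w_uniform,
                 w_markerwise = w_markerwise),
            class = "pretrain_loss_config")
}

#' Dual-masking pretraining loss
#'
#' Combines, for each masked view and each target (expression, percentile,
#' log-density), the GNLL on masked entries plus `beta_unmasked` times the
#' GNLL on unmasked measured entries. Dropped markers and unmeasured
#' vocabulary slots contribute nothing. Returns the scalar total and the
#' 12-component breakdown (2 patterns x 3 targets x masked/unmasked); the
#' total equals the weighted sum of the components exactly.
#'
#' @param targets a `pretrain_targets` object ([precompute_targets()]).
#' @param views list of two `masked_view` objects, one per pattern.
#' @param head_outputs list parallel to `views`; each element as returned by
#'   [pretrain_heads()] (matrices `n x |M|`).
#' @param config a [pretrain_loss_config()].
#' @param measured_slots vocabulary slot index for each measured marker
#'   column.
#' @return list with `total` (scalar) and `components` (named numeric vector
#'   of the 12 unweighted GNLL terms).
#' @export
pretrain_loss <- function(targets, views, head_outputs, config,
                          measured_slots) {
  tgt <- list(X = targets$expression, P = targets$percentile,
              D = targets$density)
  wt <- c(X = config$w_x, P = config$w_p, D = config$w_d)
  comps <- c()
  total <- 0
  for (k in seq_along(views)) {
    view <- views[[k]]
    wk <- if (view$pattern == "uniform_random") config$w_uniform
          else config$w_markerwise
    cls <- entry_classes(view)
    if (!any(cls$masked))
      warning("view ", view$pattern, ": no masked entries; masked terms are 0")
    for (t in names(tgt)) {
      ho <- head_outputs[[k]][[t]]
      mh <- ho$mean[, measured_slots, drop = FALSE]
      vh <- ho$var[, measured_slots, drop = FALSE]
      lm <- if (any(cls$masked))
        gnll(tgt[[t]][cls$masked], mh[cls$masked], vh[cls$masked]) else 0
      lu <- if (any(cls$unmasked))
        gnll(tgt[[t]][cls$unmasked], mh[cls$unmasked], vh[cls$unmasked])
        else 0
      comps[paste(view$pattern, t, "masked", sep = ".")] <- lm
      comps[paste(view$pattern, t, "unmasked", sep = ".")] <- lu
      total <- total + wk * wt[[t]] * (lm + config$beta_unmasked * lu)
    }
  }
  list(total = total, components = comps)
}

# gradient of the per-view target loss wrt head mean/var, on the n x |M|
# grid. Entry weights: coef/N_set on each included set, zero elsewhere.
pretrain_loss_grad <- function(targets, view, head_out, config,
                               measured_slots, V, pattern_weight) {
  tgt <- list(X = targets$expression, P = targets$percentile,
              D = targets$density)
  wt <- c(X = config$w_x, P = config$w_p, D = config$w_d)
  cls <- entry_classes(view)
  n <- nrow(view$mask)
  dout <- list()
  for (t in names(tgt)) {
    ho <- head_out[[t]]
    dmean <- matrix(0, n, V)
    dvar <- matrix(0, n, V)
    mh <- ho$mean[, measured_slots, drop = FALSE]
    vh <- ho$var[, measured_slots, drop = FALSE]
    diff <- mh - tgt[[t]]
    dm_meas <- matrix(0, n, length(measured_slots))
    dv_meas <- matrix(0, n, length(measured_slots))
    for (set in c("masked", "unmasked")) {
      sel <- cls[[set]]
      nset <- sum(sel)
      if (nset == 0) next
      coef <- pattern_weight * wt[[t]] *
        (if (set == "masked") 1 else config$beta_unmasked) / nset
      dm_meas[sel] <- dm_meas[sel] + coef * diff[sel] / vh[sel]
      dv_meas[sel] <- dv_meas[sel] +
        coef * 0.5 * (1 / vh[sel] - diff[sel]^2 / vh[sel]^2)
    }
    dmean[, measured_slots] <- dm_meas
    dvar[, measured_slots] <- dv_meas
    dout[[t]] <- list(dmean = dmean, dvar = dvar)
  }
  dout
}

# cross-entropy on logits; y is a 1-based class index
cross_entropy <- function(logits, y) {
  p <- softmax_vec(as.numeric(logits))
  loss <- -log(max(p[y], 1e-12))
  dlogits <- p
  dlogits[y] <- dlogits[y] - 1
  list(loss = loss, dlogits = dlogits)
}
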