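#' @export
print.cytoformer <- function(x, ...) {
  cfg <- x$config
  cat("cytoformer model\n")
  cat(sprintf("  vocabulary: %d markers | hidden %d | %d enc + %d dec layers, %d heads\n",
              x$vocabulary$size, cfg$hidden_size, cfg$encoder_layers,
              cfg$decoder_layers, cfg$heads))
  cat("  task:", x$task,
      if (!is.null(x$classes)) paste0("(", paste(x$classes, collapse = "/"),
                                      ")") else "", "\n")
  cat("  stage:",
      if (x$finetuned) "task-trained"
      else if (x$pretrained) "pretrained (encoder only)"
      else "initialised (untrained)", "\n")
  invisible(x)
}

#' @export
summary.cytoformer <- function(object, ...) {
  np <- count_params(object$params)
  cat("cytoformer model summary\n")
  print(object)
  cat(sprintf("  parameters: %s total\n", format(np, big.mark = ",")))
  for (st in names(object$history)) {
    h <- object$history[[st]]
    cat(sprintf("  %s: %d epochs, final train loss %.4f, best val loss %.4f\n",
                st, nrow(h), h$train_loss[nrow(h)], min(h$val_loss)))
  }
  invisible(list(n_parameters = np, history = object$history))
}

count_params <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, count_params, numeric(1)))
  else length(tree)
}

#' @export
coef.cytoformer <- function(object, ...) object$params

#' Plot training history
#'
#' Training and validation loss per epoch for whichever stages have been
#' run (pretraining and/or downstream).
#'
#' @param x a [cytoformer] with a training history.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cytoformer <- function(x, ...) {
  if (!length(x$history)) {
    warning("model has no training history to plot")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, length(x$history)))
  on.exit(graphics::par(old))
  for (st in names(x$history)) {
    h <- x$history[[st]]
    graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                      lty = c(1, 2), col = c("black", "firebrick"),
                      xlab = "epoch", ylab = "loss", main = st, ...)
    graphics::legend("topright", c("train", "validation"), lty = c(1, 2),
                     col = c("black", "firebrick"), bty = "n")
  }
  invisible(x)
}

#' @export
print.attention_map <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("attention map: %d layers x %d heads x %d cells\n",
              d[1], d[2], d[3]))
  cat("  head-averaged layer maxima:",
      paste(signif(apply(x$per_layer_mean, 1, max), 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.attribution_record <- function(x, ...) {
  cat("attribution record for", x$sample_id, "-",
      ncol(x$per_layer_weights), "cells,",
      nrow(x$per_layer_weights), "decoder layers\n")
  cat("  max weight per layer:",
      paste(signif(x$max_weight_per_layer, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS archive holding the vocabulary, mask bank,
#' all weights and the full configuration, versioned.
#'
#' @param model a [cytoformer].
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$format_version) || is.null(ck$model))
    stop_cf("not a cytoformer checkpoint: ", path,
            class = "cytoformer_state_error")
  ck$model
}
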