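#' Extract per-cell attention attribution
#'
#' Runs inference in evaluation mode and captures the prediction token's
#' cross-attention over cells at every decoder layer, averaged across heads
#' per layer (head-level weights are retained for power users). Extraction is
#' a pure read-out: the returned prediction is identical to [predict()]'s.
#'
#' @param model a task-trained [cytoformer].
#' @param sample a [cyto_sample].
#' @param clip_fraction winsorisation fraction for the display-ready weights
#'   (default 0.002, i.e. top and bottom 0.2%).
#' @return an object of class `attribution_record`: `sample_id`,
#'   `per_layer_weights` (layers x n, head-averaged, each row sums to 1),
#'   `head_weights` (layers x heads x n), `max_weight_per_layer`,
#'   `clipped_weights`, `cell_index`, `prediction`.
#' @export
extract_attention <- function(model, sample, clip_fraction = 0.002) {
  if (!model$finetuned && !model$pretrained)
    stop_cf("model has not been trained", class = "cytoformer_state_error")
  z <- encode(model, sample)
  dp <- decode_predict(model, z)
  plw <- dp$attention$per_layer_mean
  clipped <- t(apply(plw, 1, clip_for_display, clip_fraction = clip_fraction))
  structure(list(sample_id = sample$sample_id,
                 per_layer_weights = plw,
                 head_weights = dp$attention$weights,
                 max_weight_per_layer = apply(plw, 1, max),
                 clipped_weights = clipped,
                 cell_index = seq_len(nrow(sample$events)),
                 prediction = dp$prediction),
            class = "attribution_record")
}

#' Winsorise attention weights for display
#'
#' Clips values at the `clip_fraction` and `1 - clip_fraction` empirical
#' quantiles (type-7), preserving order among unclipped entries; intended as
#' input to power-scaled colour mapping.
#'
#' @param weights numeric vector.
#' @param clip_fraction in `[0, 0.5)`; 0 is the identity.
#' @return winsorised numeric vector.
#' @export
clip_for_display <- function(weights, clip_fraction = 0.002) {
  if (clip_fraction < 0 || clip_fraction >= 0.5)
    stop_cf("clip_fraction must be in [0, 0.5)",
            class = "cytoformer_parameter_error")
  if (clip_fraction == 0) return(weights)
  q <- stats::quantile(weights, c(clip_fraction, 1 - clip_fraction),
                       names = FALSE)
  pmin(pmax(weights, q[1]), q[2])
}

#' Export per-cell attribution to TSV
#'
#' One row per cell: cell index, all measured marker values, per-layer
#' head-averaged attention and the clipped display values. Suitable for
#' external embedding/plotting tools. Deterministic: re-export is
#' byte-identical.
#'
#' @param record an `attribution_record` from [extract_attention()].
#' @param sample the matching [cyto_sample].
#' @param path output file path.
#' @param reducer optional function mapping the event matrix to an `n x 2`
#'   coordinate matrix (any dimensionality reducer can be plugged in); when
#'   given, `embed_1`/`embed_2` columns are appended for plotting.
#' @return the path, invisibly.
#' @export
export_attribution <- function(record, sample, path, reducer = NULL) {
  L <- nrow(record$per_layer_weights)
  att <- t(record$per_layer_weights)
  colnames(att) <- paste0("attention_layer", seq_len(L))
  clip <- t(record$clipped_weights)
  colnames(clip) <- paste0("clipped_layer", seq_len(L))
  df <- data.frame(cell_index = record$cell_index,
                   sample$events, att, clip, check.names = FALSE)
  if (!is.null(reducer)) {
    coords <- reducer(sample$events)
    stopifnot(nrow(coords) == nrow(df), ncol(coords) == 2)
    df$embed_1 <- coords[, 1]
    df$embed_2 <- coords[, 2]
  }
  ok <- tryCatch({
    suppressWarnings(
      utils::write.table(format(df, digits = 12, trim = TRUE), path,
                         sep = "\t", quote = FALSE, row.names = FALSE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_cf("cannot write attribution to ", path,
                   class = "cytoformer_io_error")
  invisible(path)
}

#' Attention enrichment of a cell population
#'
#' Hypergeometric test of whether the top-`top_fraction` attended cells
#' (head-averaged weights of one decoder layer) are enriched for a given
#' population, against the population's base frequency in the sample.
#'
#' @param record an `attribution_record`.
#' @param cell_populations character vector of per-cell population labels
#'   aligned with the sample's rows.
#' @param population population name to test.
#' @param layer decoder layer to use (default: last).
#' @param top_fraction fraction of cells considered "attended" (default
#'   0.05).
#' @return list with `p_value` (upper-tail hypergeometric), `overlap`,
#'   `expected`, `top_n`.
#' @export
attention_enrichment <- function(record, cell_populations, population,
                                 layer = nrow(record$per_layer_weights),
                                 top_fraction = 0.05) {
  w <- record$per_layer_weights[layer, ]
  n <- length(w)
  top_n <- max(1L, floor(n * top_fraction))
  top <- order(w, decreasing = TRUE)[seq_len(top_n)]
  in_pop <- cell_populations == population
  overlap <- sum(in_pop[top])
  p <- stats::phyper(overlap - 1, sum(in_pop), n - sum(in_pop), top_n,
                     lower.tail = FALSE)
  list(p_value = p, overlap = overlap,
       expected = top_n * mean(in_pop), top_n = top_n)
}
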