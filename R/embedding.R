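#' Panel-augmented cell embedding
#'
#' Builds the fixed-size augmented representation for every cell of a sample:
#' a binary marker-availability indicator `a` over the full vocabulary,
#' concatenated with a sparse expression vector `e` that carries the measured
#' value where a marker is available and the learnable per-marker mask value
#' `mu_j` everywhere else. Masked-but-measured entries are indistinguishable
#' here from truly unmeasured entries (both get availability 0 and `mu_j`);
#' the distinction lives in the loss bookkeeping, not the embedding. A
#' measured value of 0 and an unmeasured marker always differ, because the
#' availability bit differs.
#'
#' @param sample a [cyto_sample].
#' @param vocabulary a [marker_vocabulary]; every measured marker must be in
#'   it.
#' @param mask_bank numeric vector of length `vocabulary$size`: the learnable
#'   mask values `mu` (zeros before pretraining).
#' @param per_cell_mask optional binary matrix `n_cells x n_measured_markers`
#'   (1 = keep, 0 = treat as unmeasured for this cell).
#' @param dropped_markers optional indices (into the sample's marker list) of
#'   markers removed sample-wide.
#' @return numeric matrix `n_cells x 2|M|`: columns `1..|M|` availability,
#'   columns `|M|+1..2|M|` expression.
#' @export
embed_sample <- function(sample, vocabulary, mask_bank = numeric(vocabulary$size),
                         per_cell_mask = NULL, dropped_markers = integer(0)) {
  au <- augment_cells(sample$events, sample$markers, vocabulary, mask_bank,
                      per_cell_mask, dropped_markers)
  cbind(au$avail, au$expr)
}

# internal: returns availability and expression parts separately plus slot map
augment_cells <- function(events, markers, vocabulary, mu,
                          per_cell_mask = NULL, dropped = integer(0)) {
  n <- nrow(events)
  V <- vocabulary$size
  slots <- vocab_slots(vocabulary, markers)
  keep <- if (is.null(per_cell_mask)) matrix(1, n, length(markers))
          else as.matrix(per_cell_mask)
  if (length(dropped)) keep[, dropped] <- 0
  avail <- matrix(0, n, V)
  expr <- matrix(mu, n, V, byrow = TRUE)
  avail[, slots] <- keep
  expr[, slots] <- keep * events + (1 - keep) * matrix(mu[slots], n,
                                                       length(slots),
                                                       byrow = TRUE)
  list(avail = avail, expr = expr, slots = slots)
}

#' Project augmented cells to the model hidden size
#'
#' Row-wise affine map plus ReLU from the `2|M|`-dimensional augmented vectors
#' to the transformer hidden size; cells are independent, so permuting input
#' rows permutes output rows identically.
#'
#' @param cells numeric matrix `n x 2|M|` from [embed_sample()].
#' @param params list with `W` (`2|M| x h`) and `b` (length `h`).
#' @return numeric matrix `n x h`.
#' @export
project_cells <- function(cells, params) {
  if (ncol(cells) != nrow(params$W))
    stop_cf("projection expects ", nrow(params$W), " input features, got ",
            ncol(cells), class = "cytoformer_dimension_error")
  pre <- linear_fwd(cells, params$W, params$b)
  pre * (pre > 0)
}

# forward with cache for training
project_fwd <- function(cells, params) {
  pre <- linear_fwd(cells, params$W, params$b)
  list(y = pre * (pre > 0), cache = list(cells = cells, pre = pre))
}

# returns gradient wrt cells and projection params
project_bwd <- function(dy, fwd, params) {
  cc <- fwd$cache
  dpre <- dy * (cc$pre > 0)
  list(dcells = tcrossprod(dpre, params$W),
       grads = list(W = crossprod(cc$cells, dpre), b = colSums(dpre)))
}
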