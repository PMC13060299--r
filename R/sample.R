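#' Marker vocabulary
#'
#' The ordered global set of marker names a model knows about. The ordering is
#' fixed for the lifetime of a trained model: each marker owns one embedding
#' slot, so two models built on differently ordered vocabularies are not
#' interchangeable.
#'
#' @param markers character vector of unique marker names.
#' @return an object of class `marker_vocabulary`.
#' @export
marker_vocabulary <- function(markers) {
  markers <- as.character(markers)
  if (anyDuplicated(markers)) stop_cf("duplicate marker names in vocabulary",
                                      class = "cytoformer_vocabulary_error")
  if (length(markers) < 1) stop_cf("empty vocabulary",
                                   class = "cytoformer_vocabulary_error")
  structure(list(markers = markers, size = length(markers)),
            class = "marker_vocabulary")
}

#' @export
print.marker_vocabulary <- function(x, ...) {
  cat("Marker vocabulary:", x$size, "markers\n ",
      paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

# vocabulary slot indices for a set of marker names; errors on unknown markers
vocab_slots <- function(vocabulary, markers) {
  idx <- match(markers, vocabulary$markers)
  if (anyNA(idx)) {
    bad <- markers[is.na(idx)]
    stop_cf("marker(s) not in vocabulary: ", paste(bad, collapse = ", "),
            class = "cytoformer_vocabulary_error")
  }
  idx
}

#' A single cytometry sample
#'
#' One sample's event matrix (cells x measured markers, already on the
#' transformed scale) plus its measured-marker list and metadata. Row order
#' carries no meaning: permuting rows yields an equivalent sample.
#'
#' @param events numeric matrix, one row per cell, one column per measured
#'   marker, column order matching `markers`.
#' @param markers character vector of measured marker names (no duplicates).
#' @param sample_id opaque identifier.
#' @param label optional sample-level label (factor level or numeric).
#' @param batch_id optional batch identifier.
#' @return an object of class `cyto_sample`.
#' @export
cyto_sample <- function(events, markers, sample_id = "sample",
                        label = NA, batch_id = NA) {
  events <- as.matrix(events)
  storage.mode(events) <- "double"
  if (nrow(events) < 1) stop_cf("sample must contain at least one cell",
                                class = "cytoformer_sample_error")
  if (ncol(events) != length(markers))
    stop_cf("events has ", ncol(events), " columns but ", length(markers),
            " marker names given", class = "cytoformer_sample_error")
  if (anyDuplicated(markers))
    stop_cf("duplicate measured markers", class = "cytoformer_sample_error")
  colnames(events) <- markers
  structure(list(events = events, markers = as.character(markers),
                 sample_id = as.character(sample_id), label = label,
                 batch_id = batch_id),
            class = "cyto_sample")
}

#' @export
print.cyto_sample <- function(x, ...) {
  cat("cyto_sample", x$sample_id, ":", nrow(x$events), "cells x",
      length(x$markers), "markers\n")
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  if (!is.na(x$label[1])) cat("  label:", as.character(x$label), "\n")
  if (!is.na(x$batch_id[1])) cat("  batch:", as.character(x$batch_id), "\n")
  invisible(x)
}

#' Subsample cells from a sample
#'
#' Uniform subsampling without replacement, reproducible from the seed. The
#' seed is combined with the sample id so corpus-level results do not depend on
#' iteration order. Samples at or below `max_cells` are returned unchanged.
#'
#' @param sample a [cyto_sample].
#' @param max_cells keep at most this many cells.
#' @param seed integer seed.
#' @return a [cyto_sample] with at most `max_cells` rows.
#' @export
subsample_cells <- function(sample, max_cells, seed = 1L) {
  stopifnot(max_cells >= 1)
  n <- nrow(sample$events)
  if (n <= max_cells) return(sample)
  keep <- with_seed(derive_seed(seed, sample$sample_id, "subsample"),
                    sample.int(n, max_cells))
  out <- sample
  out$events <- sample$events[keep, , drop = FALSE]
  pops <- attr(sample, "cell_populations")
  if (!is.null(pops)) attr(out, "cell_populations") <- pops[keep]
  out
}
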