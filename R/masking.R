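#' Masking-ratio distribution configuration
#'
#' Beta-distribution parameters for the three stochastic ratios used during
#' masked pretraining: the sample-wide marker dropout ratio `r_drop` and the
#' per-pattern masking ratios `r_mask`. Defaults give mean dropout 0.1 and
#' mean masking 0.25 for both patterns; all are recorded in checkpoints.
#'
#' @param drop_alpha,drop_beta Beta parameters for `r_drop`.
#' @param uniform_alpha,uniform_beta Beta parameters for the uniform-random
#'   pattern's `r_mask`.
#' @param markerwise_alpha,markerwise_beta Beta parameters for the marker-wise
#'   pattern's `r_mask`.
#' @return an object of class `mask_config`.
#' @export
mask_config <- function(drop_alpha = 1, drop_beta = 9,
                        uniform_alpha = 2, uniform_beta = 6,
                        markerwise_alpha = 2, markerwise_beta = 6) {
  cfg <- list(drop_alpha = drop_alpha, drop_beta = drop_beta,
              uniform_alpha = uniform_alpha, uniform_beta = uniform_beta,
              markerwise_alpha = markerwise_alpha,
              markerwise_beta = markerwise_beta)
  if (any(unlist(cfg) <= 0))
    stop_cf("all Beta parameters must be > 0",
            class = "cytoformer_parameter_error")
  structure(cfg, class = "mask_config")
}

new_masked_view <- function(events, mask, pattern, dropped) {
  structure(list(masked_events = events * mask, mask = mask,
                 pattern = pattern, dropped_markers = dropped),
            class = "masked_view")
}

#' Uniform-random masking with sample-wide marker dropout
#'
#' First draws a dropout ratio `r_drop ~ Beta(drop_alpha, drop_beta)` and
#' removes `round(m * r_drop)` uniformly chosen markers from the measured set
#' entirely (they become unmeasured, not masked). Then draws
#' `r_mask ~ Beta(uniform_alpha, uniform_beta)` and masks each remaining entry
#' independently with probability `r_mask`. At least one marker always
#' survives the dropout stage. Rounding of marker counts is half away from
#' zero.
#'
#' @param events numeric matrix, cells x measured markers.
#' @param config a [mask_config()].
#' @param seed integer seed; identical seeds give identical views.
#' @return an object of class `masked_view`: `masked_events` (events with
#'   masked entries zeroed), `mask` (1 = retained, 0 = masked; dropped columns
#'   are all zero but tracked separately), `pattern`, `dropped_markers`
#'   (column indices removed sample-wide).
#' @export
mask_uniform_random <- function(events, config = mask_config(), seed = 1L) {
  events <- as.matrix(events)
  m <- ncol(events)
  stopifnot(m >= 1)
  with_seed(seed, {
    r_drop <- rbeta(1, config$drop_alpha, config$drop_beta)
    n_drop <- min(round_half_up(m * r_drop), m - 1)   # keep >= 1 marker
    dropped <- if (n_drop > 0) sort(sample.int(m, n_drop)) else integer(0)
    r_mask <- rbeta(1, config$uniform_alpha, config$uniform_beta)
    mask <- matrix(rbinom(length(events), 1, 1 - r_mask),
                   nrow(events), m)
    mask[, dropped] <- 0
    new_masked_view(events, mask, "uniform_random", dropped)
  })
}

#' Marker-wise masking
#'
#' Draws `r_mask ~ Beta(markerwise_alpha, markerwise_beta)` and masks
#' `round(m * r_mask)` uniformly chosen markers across all cells, so every
#' mask column is constant 0 or constant 1 and the masked matrix mimics the
#' distribution of a sample measured on a smaller panel. At least one marker
#' always remains unmasked. Rounding is half away from zero.
#'
#' @inheritParams mask_uniform_random
#' @param rate optional fixed masking rate overriding the Beta draw (used for
#'   downstream marker-wise input dropout, where the rate is fixed).
#' @return a `masked_view` with `pattern = "marker_wise"` and empty
#'   `dropped_markers`.
#' @export
mask_marker_wise <- function(events, config = mask_config(), seed = 1L,
                             rate = NULL) {
  events <- as.matrix(events)
  m <- ncol(events)
  stopifnot(m >= 1)
  with_seed(seed, {
    r_mask <- if (is.null(rate)) rbeta(1, config$markerwise_alpha,
                                       config$markerwise_beta) else rate
    n_mask <- min(round_half_up(m * r_mask), m - 1)   # keep >= 1 marker
    cols <- if (n_mask > 0) sort(sample.int(m, n_mask)) else integer(0)
    mask <- matrix(1, nrow(events), m)
    mask[, cols] <- 0
    new_masked_view(events, mask, "marker_wise", integer(0))
  })
}

# The three disjoint entry classes over the n x m measured grid that the
# pretraining loss distinguishes: "masked" (measured, hidden from the
# embedding, supervised at full weight), "unmasked" (measured and visible,
# supervised at weight beta) and "dropped" (removed sample-wide; treated as
# unmeasured, never supervised). Unmeasured vocabulary slots are outside this
# grid and also never supervised.
entry_classes <- function(view) {
  m <- ncol(view$mask)
  dropped_col <- matrix(FALSE, nrow(view$mask), m)
  if (length(view$dropped_markers))
    dropped_col[, view$dropped_markers] <- TRUE
  list(masked = view$mask == 0 & !dropped_col,
       unmasked = view$mask == 1 & !dropped_col,
       dropped = dropped_col)
}
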