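#' @keywords internal
#' @importFrom stats rnorm rbeta rbinom runif uniroot predict coef
"_PACKAGE"

# Deterministic 31-bit seed derivation from a global seed plus arbitrary
# string/integer tags, so per-sample / per-epoch RNG streams do not depend on
# iteration order. Simple polynomial rolling hash mod (2^31 - 1).
derive_seed <- function(seed, ...) {
  tags <- list(...)
  mod <- 2147483647
  h <- as.double(seed %% mod)
  for (tag in tags) {
    chars <- utf8ToInt(paste0("|", as.character(tag)))
    for (ch in chars) h <- (h * 131 + ch) %% mod
  }
  as.integer(h %% (mod - 1L) + 1)
}

# Evaluate expr under a temporary RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round half away from zero (R's round() is half-to-even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cf <- function(..., class) {
  stop(structure(class = c(class, "cytoformer_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
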