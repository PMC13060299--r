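# Independent oracle implementations used to validate the package's
# vectorised code paths. Deliberately written as straight-line loops from the
# defining formulas; they share no code with the implementation.

# percentile ranks by explicit counting: average rank of ties
oracle_percentile <- function(x) {
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (j in seq_len(ncol(x))) {
    for (i in seq_len(n)) {
      less <- 0; ties <- 0
      for (k in seq_len(n)) {
        if (x[k, j] < x[i, j]) less <- less + 1
        if (x[k, j] == x[i, j]) ties <- ties + 1
      }
      out[i, j] <- (less + (ties + 1) / 2) / n
    }
  }
  out
}

# log Gaussian-kernel KDE by double loop
oracle_density <- function(x, sigma) {
  n <- nrow(x)
  out <- matrix(0, n, ncol(x))
  for (j in seq_len(ncol(x))) {
    for (i in seq_len(n)) {
      s <- 0
      for (k in seq_len(n))
        s <- s + exp(-0.5 * ((x[i, j] - x[k, j]) / sigma)^2) / sqrt(2 * pi)
      out[i, j] <- log(s / (n * sigma))
    }
  }
  out
}

# scaled dot-product multi-head attention by explicit loops over heads,
# queries and keys (no matrix algebra beyond dot products)
oracle_mha <- function(xq, xkv, p, nh) {
  h <- ncol(xq)
  d <- h / nh
  nq <- nrow(xq); nk <- nrow(xkv)
  lin <- function(x, W, b) {
    out <- matrix(0, nrow(x), ncol(W))
    for (i in seq_len(nrow(x)))
      for (j in seq_len(ncol(W)))
        out[i, j] <- sum(x[i, ] * W[, j]) + b[j]
    out
  }
  Q <- lin(xq, p$Wq, p$bq); K <- lin(xkv, p$Wk, p$bk); V <- lin(xkv, p$Wv, p$bv)
  O <- matrix(0, nq, h)
  for (a in seq_len(nh)) {
    idx <- ((a - 1) * d + 1):(a * d)
    for (i in seq_len(nq)) {
      sc <- numeric(nk)
      for (k in seq_len(nk)) sc[k] <- sum(Q[i, idx] * K[k, idx]) / sqrt(d)
      w <- exp(sc - max(sc)); w <- w / sum(w)
      for (jj in idx) O[i, jj] <- sum(w * V[, jj])
    }
  }
  lin(O, p$Wo, p$bo)
}

# tiny corpora / models shared across tests --------------------------------

tiny_vocab <- function() marker_vocabulary(paste0("m", 1:4))

tiny_model <- function(classes = c("a", "b"), seed = 3, V = 4) {
  init_cytoformer(marker_vocabulary(paste0("m", seq_len(V))),
                  model_config(hidden_size = 8L, encoder_layers = 2L,
                               decoder_layers = 2L, heads = 2L,
                               feedforward_multiplier = 2L),
                  classes = classes, seed = seed)
}

tiny_sample <- function(n = 6, markers = c("m1", "m3", "m4"), seed = 1,
                        label = "a", id = "t1") {
  ev <- matrix(with_seed_test(seed, runif(n * length(markers))), n,
               length(markers))
  cyto_sample(ev, markers, sample_id = id, label = label)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# write a minimal FCS 3.0 file (float32, little-endian) for reader tests
write_fcs_fixture <- function(path, data, pnn, pns) {
  n_par <- ncol(data); n_tot <- nrow(data)
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot),
          "$NEXTDATA", "0")
  for (i in seq_len(n_par)) {
    kw <- c(kw, sprintf("$P%dN", i), pnn[i], sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0", sprintf("$P%dR", i), "262144")
    if (!is.na(pns[i])) kw <- c(kw, sprintf("$P%dS", i), pns[i])
  }
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  text_start <- 58L
  text_end <- text_start + nchar(text) - 1L
  data_start <- text_end + 1L
  data_len <- 4L * n_par * n_tot
  data_end <- data_start + data_len - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d", text_start, text_end,
                    data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(data)), con, size = 4, endian = "little")
  invisible(path)
}
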