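#' Read an FCS 3.0 / 3.1 file
#'
#' Minimal list-mode FCS reader: parses the TEXT segment, reads float, double
#' or integer DATA in either byte order, resolves fluorescence channels to
#' marker names, applies the logicle transformation, and drops channels with
#' no marker annotation.
#'
#' Channel resolution: if `channel_map` is given, it maps `$PnN` channel names
#' to marker names (`NA` or `""` discards the channel); otherwise the `$PnS`
#' stain keyword is used and channels lacking one are discarded.
#'
#' @param path path to the FCS file.
#' @param channel_map optional named character vector, names = `$PnN` channel
#'   names, values = marker names (or `NA` to discard).
#' @param transform logicle parameters ([logicle_params()]), or `NULL` to skip
#'   transformation (input declared pre-transformed).
#' @param vocabulary optional [marker_vocabulary]; resolved markers absent from
#'   it raise an error naming the marker.
#' @param sample_id,label,batch_id sample metadata.
#' @return a [cyto_sample] with logicle-transformed events.
#' @export
read_fcs <- function(path, channel_map = NULL, transform = logicle_params(),
                     vocabulary = NULL, sample_id = basename(path),
                     label = NA, batch_id = NA) {
  raw <- parse_fcs(path)
  markers <- resolve_channels(raw$pnn, raw$pns, channel_map)
  keep <- !is.na(markers) & nzchar(markers)
  if (!any(keep))
    stop_cf("no annotated channels in ", path, class = "cytoformer_format_error")
  events <- raw$data[, keep, drop = FALSE]
  markers <- markers[keep]
  if (!is.null(vocabulary)) vocab_slots(vocabulary, markers)
  if (!is.null(transform)) events <- logicle(events, transform)
  cyto_sample(events, markers, sample_id = sample_id,
              label = label, batch_id = batch_id)
}

resolve_channels <- function(pnn, pns, channel_map) {
  if (is.null(channel_map)) return(pns)
  out <- unname(channel_map[pnn])
  out[is.na(pnn)] <- NA_character_
  out
}

parse_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop_cf("not an FCS 3.x file: ", path, class = "cytoformer_format_error")
  off <- function(i, j) suppressWarnings(as.numeric(trimws(substr(header, i, j))))
  text_start <- off(11, 18); text_end <- off(19, 26)
  data_start <- off(27, 34); data_end <- off(35, 42)
  if (is.na(text_start) || is.na(text_end) || text_end <= text_start)
    stop_cf("corrupt FCS header in ", path, class = "cytoformer_format_error")
  seek(con, text_start)
  text <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- parts[seq(2, length(parts), by = 2)]
  names(kw) <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  get_kw <- function(k) if (k %in% names(kw)) kw[[k]] else NA_character_

  n_par <- as.integer(get_kw("$PAR"))
  n_tot <- as.integer(get_kw("$TOT"))
  dtype <- toupper(get_kw("$DATATYPE"))
  byteord <- get_kw("$BYTEORD")
  mode <- toupper(get_kw("$MODE"))
  if (is.na(n_par) || is.na(n_tot) || is.na(dtype))
    stop_cf("missing required FCS keywords in ", path,
            class = "cytoformer_format_error")
  if (!is.na(mode) && mode != "L")
    stop_cf("only list-mode ($MODE L) FCS supported",
            class = "cytoformer_format_error")
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"
  if (is.na(data_start) || data_start == 0)
    data_start <- as.numeric(get_kw("$BEGINDATA"))
  bits <- vapply(seq_len(n_par), function(i)
    as.integer(get_kw(sprintf("$P%dB", i))), integer(1))
  pnn <- vapply(seq_len(n_par), function(i)
    as.character(get_kw(sprintf("$P%dN", i))), character(1))
  pns <- vapply(seq_len(n_par), function(i)
    as.character(get_kw(sprintf("$P%dS", i))), character(1))

  seek(con, data_start)
  nvals <- n_par * n_tot
  data <- switch(dtype,
    "F" = readBin(con, "numeric", n = nvals, size = 4, endian = endian),
    "D" = readBin(con, "numeric", n = nvals, size = 8, endian = endian),
    "I" = {
      sz <- unique(bits) / 8
      if (length(sz) != 1 || !sz %in% c(2, 4))
        stop_cf("unsupported integer width in ", path,
                class = "cytoformer_format_error")
      readBin(con, "integer", n = nvals, size = sz, endian = endian,
              signed = sz > 2)
    },
    stop_cf("unsupported $DATATYPE ", dtype, class = "cytoformer_format_error"))
  if (length(data) < nvals)
    stop_cf("truncated DATA segment in ", path,
            class = "cytoformer_format_error")
  mat <- matrix(data, nrow = n_tot, ncol = n_par, byrow = TRUE)
  list(data = mat, pnn = pnn, pns = pns, keywords = kw)
}

#' Read a plain event matrix (CSV/TSV)
#'
#' Alternative input path for pre-exported or synthetic data: a delimited file
#' whose header row holds marker names. Values are taken as-is unless
#' `transform` is supplied.
#'
#' @inheritParams read_fcs
#' @export
read_events_csv <- function(path, transform = NULL, vocabulary = NULL,
                            sample_id = basename(path), label = NA,
                            batch_id = NA) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  events <- as.matrix(df)
  if (!is.null(vocabulary)) vocab_slots(vocabulary, colnames(events))
  if (!is.null(transform)) events <- logicle(events, transform)
  cyto_sample(events, colnames(events), sample_id = sample_id,
              label = label, batch_id = batch_id)
}

# ---- on-disk sample store ---------------------------------------------------

#' Sample store input/output
#'
#' The package's on-disk corpus form: one TSV event matrix plus one JSON
#' metadata sidecar per sample, and a `manifest.tsv` (sample_id, path, label,
#' batch_id, panel fingerprint). Events round-trip exactly (written at full
#' double precision).
#'
#' @param samples list of [cyto_sample] objects.
#' @param dir store directory (created if absent).
#' @return `write_sample_store` returns the manifest data frame invisibly;
#'   `read_sample_store` returns a named list of [cyto_sample] objects.
#' @export
write_sample_store <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(samples, function(s) {
    fn <- paste0(s$sample_id, ".tsv")
    df <- as.data.frame(format(s$events, digits = 17, trim = TRUE,
                               scientific = TRUE))
    colnames(df) <- s$markers
    utils::write.table(df, file.path(dir, fn), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    meta <- list(sample_id = s$sample_id, markers = s$markers,
                 n_cells = nrow(s$events),
                 label = if (is.na(s$label[1])) NULL else as.character(s$label),
                 batch_id = if (is.na(s$batch_id[1])) NULL
                            else as.character(s$batch_id),
                 transformed = TRUE)
    pops <- attr(s, "cell_populations")
    if (!is.null(pops)) meta$cell_populations <- as.character(pops)
    jsonlite::write_json(meta, file.path(dir, paste0(s$sample_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(sample_id = s$sample_id, path = fn,
               label = as.character(s$label),
               batch_id = as.character(s$batch_id),
               panel = paste(sort(s$markers), collapse = "+"),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_sample_store
#' @param ids optional subset of sample ids to load.
#' @export
read_sample_store <- function(dir, ids = NULL) {
  mf <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!is.null(ids)) mf <- mf[mf$sample_id %in% ids, , drop = FALSE]
  out <- lapply(seq_len(nrow(mf)), function(i) {
    meta <- jsonlite::read_json(
      file.path(dir, paste0(mf$sample_id[i], ".json")), simplifyVector = TRUE)
    df <- utils::read.table(file.path(dir, mf$path[i]), header = TRUE,
                            sep = "\t", check.names = FALSE)
    s <- cyto_sample(as.matrix(df), meta$markers,
                     sample_id = meta$sample_id,
                     label = meta$label %||% NA,
                     batch_id = meta$batch_id %||% NA)
    if (!is.null(meta$cell_populations))
      attr(s, "cell_populations") <- meta$cell_populations
    s
  })
  names(out) <- mf$sample_id
  out
}

#' Corpus-level rare-marker filter
#'
#' Flags markers measured in exactly one sample of the corpus and removes only
#' those from the affected samples (extremely rare markers carry no
#' transferable signal and would waste vocabulary slots).
#'
#' @param samples list of [cyto_sample] objects.
#' @return list with `samples` (filtered) and `removed` (character vector of
#'   dropped marker names).
#' @export
filter_rare_markers <- function(samples) {
  counts <- table(unlist(lapply(samples, function(s) unique(s$markers))))
  rare <- names(counts)[counts == 1]
  out <- lapply(samples, function(s) {
    keep <- !(s$markers %in% rare)
    if (all(keep)) return(s)
    if (!any(keep))
      stop_cf("rare-marker filter would empty sample ", s$sample_id,
              class = "cytoformer_sample_error")
    s2 <- cyto_sample(s$events[, keep, drop = FALSE], s$markers[keep],
                      sample_id = s$sample_id, label = s$label,
                      batch_id = s$batch_id)
    attr(s2, "cell_populations") <- attr(s, "cell_populations")
    s2
  })
  names(out) <- names(samples)
  list(samples = out, removed = rare)
}
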