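# Dataset-level feature assembly: NMBAC | PSSM-DCT | PSSM-DWT.

#' Encode a set of proteins into the concatenated feature matrix
#'
#' Runs the requested encoders on every record and stacks the results
#' into one matrix, blocks concatenated in the fixed order
#' NMBAC, DCT, DWT (200 + 100 + 1040 = 1340 columns at defaults).
#'
#' @param records list of curated protein records.
#' @param pssms list of `pssm` objects matched to `records` by
#'   position or by `protein_id` == record id; required when `dct` or
#'   `dwt` is requested.
#' @param features subset of `c("nmbac", "dct", "dwt")`.
#' @param lg,include_aac NMBAC settings, see [encode_nmbac()].
#' @param m,scan DCT settings, see [encode_pssm_dct()].
#' @param wavelet,levels,mode,n_dct DWT settings, see
#'   [encode_pssm_dwt()].
#' @return numeric matrix, one row per record (row names = ids), with
#'   attributes `block_map` (data.frame block/start/end) and `labels`
#'   (+1/-1/NA per record, taken from the records).
#' @export
encode_features <- function(records, pssms = NULL,
                            features = c("nmbac", "dct", "dwt"),
                            lg = 30, include_aac = TRUE,
                            m = 100, scan = "zigzag",
                            wavelet = "db2", levels = 4,
                            mode = "symmetric", n_dct = 5) {
  features <- match.arg(features, several.ok = TRUE)
  features <- intersect(c("nmbac", "dct", "dwt"), features)  # fixed order
  if (length(records) == 0) stop("no records to encode")
  needs_pssm <- any(c("dct", "dwt") %in% features)
  if (needs_pssm) {
    if (is.null(pssms)) stop("dct/dwt features need PSSM profiles")
    pid <- vapply(pssms, `[[`, "", "protein_id")
    rid <- vapply(records, `[[`, "", "id")
    ord <- match(rid, pid)
    if (anyNA(ord)) {
      if (length(pssms) == length(records)) ord <- seq_along(records)
      else stop("no PSSM for record(s): ",
                paste(rid[is.na(ord)], collapse = ", "))
    }
    pssms <- pssms[ord]
  }
  rows <- lapply(seq_along(records), function(i) {
    parts <- list()
    if ("nmbac" %in% features) {
      parts$nmbac <- encode_nmbac(records[[i]], lg = lg,
                                  include_aac = include_aac)
    }
    if ("dct" %in% features) {
      parts$dct <- encode_pssm_dct(pssms[[i]], m = m, scan = scan)
    }
    if ("dwt" %in% features) {
      parts$dwt <- encode_pssm_dwt(pssms[[i]], wavelet = wavelet,
                                   levels = levels, mode = mode,
                                   n_dct = n_dct)
    }
    unlist(unname(lapply(parts, as.vector)), use.names = FALSE)
  })
  lens <- vapply(rows, length, 0L)
  if (length(unique(lens)) != 1) stop("inconsistent feature lengths")
  x <- do.call(rbind, rows)
  rownames(x) <- vapply(records, `[[`, "", "id")
  # column names + block map from a single prototype row
  proto <- list()
  if ("nmbac" %in% features) {
    proto$nmbac <- encode_nmbac(records[[1]], lg = lg,
                                include_aac = include_aac)
  }
  if ("dct" %in% features) proto$dct <- encode_pssm_dct(pssms[[1]], m = m,
                                                        scan = scan)
  if ("dwt" %in% features) {
    proto$dwt <- encode_pssm_dwt(pssms[[1]], wavelet = wavelet,
                                 levels = levels, mode = mode, n_dct = n_dct)
  }
  colnames(x) <- unlist(lapply(proto, names), use.names = FALSE)
  blens <- vapply(proto, length, 0L)
  ends <- cumsum(blens)
  attr(x, "block_map") <- data.frame(
    block = names(blens),
    start = as.integer(c(1L, utils::head(ends, -1) + 1L)),
    end = as.integer(ends), stringsAsFactors = FALSE)
  attr(x, "labels") <- vapply(records, function(r) {
    if (is.null(r$label) || is.na(r$label)) NA_integer_ else r$label
  }, 0L)
  x
}

#' Block membership of feature columns
#'
#' Maps column indices of an encoded matrix to their block
#' (`nmbac`/`dct`/`dwt`) via the matrix's `block_map` attribute.
#'
#' @param x encoded feature matrix (or anything carrying a
#'   `block_map` attribute).
#' @param idx column indices; default all columns.
#' @return character vector of block names.
#' @export
feature_blocks <- function(x, idx = seq_len(ncol(x))) {
  bm <- attr(x, "block_map")
  if (is.null(bm)) return(rep("feat", length(idx)))
  out <- rep(NA_character_, length(idx))
  for (b in seq_len(nrow(bm))) {
    hit <- idx >= bm$start[b] & idx <= bm$end[b]
    out[hit] <- bm$block[b]
  }
  out
}
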