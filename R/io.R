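# Readers and writers: FASTA, PSI-BLAST ASCII PSSM, labeled feature matrices.

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased; no residue validation is performed here —
#' curation is a separate, explicit step ([curate_records()]).
#'
#' @param path path to a FASTA file; multi-line sequences are allowed.
#' @return a list of protein records, each a list with elements `id`
#'   (character), `sequence` (character) and `label` (NA until set).
#' @seealso [write_fasta()], [curate_records()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(list())
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path,
                                           ": ", conditionMessage(e)))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  recs <- vector("list", length(set))
  for (i in seq_along(set)) {
    if (!nzchar(seqs[[i]])) {
      stop("empty sequence for record '", ids[[i]], "' in ", path)
    }
    if (!nzchar(ids[[i]])) stop("record ", i, " in ", path, " has an empty id")
    recs[[i]] <- protein_record(ids[[i]], seqs[[i]])
  }
  recs
}

#' Construct a protein record
#'
#' @param id identifier string.
#' @param sequence amino-acid sequence (uppercased on construction).
#' @param label optional class label; accepts +1/-1 or 1/0 (0 is mapped
#'   to -1, the internal negative-class code).
#' @export
protein_record <- function(id, sequence, label = NA) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence for record '", id, "'")
  if (!is.na(label)) {
    if (!label %in% c(-1, 0, 1)) stop("label must be +1/-1 (or 1/0)")
    if (label == 0) label <- -1
  }
  structure(list(id = id, sequence = toupper(sequence),
                 label = as.integer(label)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s  (%d aa%s)\n", x$id, nchar(x$sequence),
              if (is.na(x$label)) "" else sprintf(", label %+d", x$label)))
  invisible(x)
}

#' Write protein records to FASTA
#'
#' @param records list of protein records (see [protein_record()]).
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  seqs <- vapply(records, `[[`, "", "sequence")
  ids <- vapply(records, `[[`, "", "id")
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Curate protein records by length and alphabet
#'
#' Removes records shorter than `min_len` residues and records that
#' contain any character outside the 20-letter standard alphabet.
#' Ambiguity and non-standard codes (X, B, Z, U, O, ...) all cause
#' removal: neither the property table nor profile columns cover them.
#' Order of the retained records is preserved and the operation is
#' idempotent.
#'
#' @param records list of protein records.
#' @param min_len minimum retained sequence length (default 50).
#' @return the retained records, with a `"removed"` attribute: a
#'   data.frame of `id` and `reason` for every record dropped.
#' @export
curate_records <- function(records, min_len = 50) {
  keep <- logical(length(records))
  why <- character(0); who <- character(0)
  ok_re <- sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = ""))
  for (i in seq_along(records)) {
    r <- records[[i]]
    if (nchar(r$sequence) < min_len) {
      who <- c(who, r$id)
      why <- c(why, sprintf("length %d < %d", nchar(r$sequence), min_len))
    } else if (!grepl(ok_re, r$sequence)) {
      bad <- setdiff(unique(strsplit(r$sequence, "")[[1]]), AA_ALPHABET)
      who <- c(who, r$id)
      why <- c(why, paste0("non-standard residue(s): ",
                           paste(bad, collapse = "")))
    } else keep[i] <- TRUE
  }
  out <- records[keep]
  attr(out, "removed") <- data.frame(id = who, reason = why,
                                     stringsAsFactors = FALSE)
  out
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Accepts two dialects, auto-detected per line by token count:
#' \itemize{
#'   \item the classic PSI-BLAST layout: header lines, then one row per
#'     position holding the position index, the query residue, 20
#'     integer log-odds scores, 20 percentage columns and two trailing
#'     floats (42+ numeric-ish tokens);
#'   \item a bare whitespace-separated L x 20 matrix (exactly 20
#'     numeric tokens per line), for pre-stripped files.
#' }
#' Only the first 20 (log-odds) columns are kept, unscaled.
#'
#' @param path path to the PSSM file.
#' @return a `pssm` object: list with `protein_id` (file stem),
#'   `matrix` (L x 20, columns named in PSI-BLAST order) and
#'   `residues` (length-L residue string; all-`"X"` for the bare
#'   dialect, which carries no residue column).
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list(); res <- character(0); lnos <- integer(0)
  bare <- NA
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[ln]]), "\\s+")[[1]]
    if (length(tok) == 0 || !nzchar(tok[[1]])) next
    num1 <- suppressWarnings(as.numeric(tok[[1]]))
    if (length(tok) == 20 && !anyNA(suppressWarnings(as.numeric(tok)))) {
      # bare dialect row
      if (isFALSE(bare)) stop("mixed PSSM dialects at line ", ln, " of ", path)
      bare <- TRUE
      rows[[length(rows) + 1L]] <- as.numeric(tok)
      lnos <- c(lnos, ln)
    } else if (!is.na(num1) && length(tok) >= 3 &&
               grepl("^[A-Za-z]$", tok[[2]])) {
      # classic data row: index, residue, then numeric columns
      if (isTRUE(bare)) stop("mixed PSSM dialects at line ", ln, " of ", path)
      bare <- FALSE
      vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
      if (anyNA(vals) || length(vals) < 40) {
        stop("PSSM row with ", length(vals),
             " numeric columns (need >= 40) at line ", ln, " of ", path)
      }
      rows[[length(rows) + 1L]] <- vals[1:20]
      res <- c(res, toupper(tok[[2]]))
      lnos <- c(lnos, ln)
    }
    # anything else: header / footer / statistics line -> skipped
  }
  if (length(rows) == 0) stop("no PSSM data rows found in ", path)
  m <- do.call(rbind, rows)
  if (!all(is.finite(m))) stop("non-finite PSSM entries in ", path)
  colnames(m) <- PSSM_ALPHABET
  if (isTRUE(bare)) res <- rep("X", nrow(m))
  pssm(sub("\\.[^.]*$", "", basename(path)), m, paste(res, collapse = ""))
}

#' Construct a `pssm` profile object
#'
#' @param protein_id identifier.
#' @param matrix L x 20 numeric matrix, rows = positions, columns = the
#'   20 amino-acid types in PSI-BLAST column order.
#' @param residues length-L string of query residues aligned to rows.
#' @export
pssm <- function(protein_id, matrix, residues) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 20) stop("PSSM must have exactly 20 columns")
  if (nrow(matrix) < 1) stop("empty PSSM matrix")
  if (!all(is.finite(matrix))) stop("PSSM entries must be finite")
  if (nchar(residues) != nrow(matrix)) {
    stop("residue string length (", nchar(residues),
         ") != row count (", nrow(matrix), ")")
  }
  if (is.null(colnames(matrix))) colnames(matrix) <- PSSM_ALPHABET
  structure(list(protein_id = protein_id, matrix = matrix,
                 residues = residues),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %s  %d x 20 profile\n", x$protein_id, nrow(x$matrix)))
  invisible(x)
}

#' Write a profile in the classic PSI-BLAST ASCII layout
#'
#' Integer matrices round-trip exactly through [read_pssm()]; the 20
#' percentage columns are written as zeros and the two trailing floats
#' as placeholders, as only the log-odds block is ever consumed.
#'
#' @param x a `pssm` object.
#' @param path output path.
#' @export
write_pssm <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  res <- strsplit(x$residues, "")[[1]]
  hdr <- c("", paste("Last position-specific scoring matrix computed,",
                     "weighted observed percentages rounded down"),
           paste(" ", paste(sprintf("%3s", c(PSSM_ALPHABET, PSSM_ALPHABET)),
                            collapse = "")))
  body <- vapply(seq_len(nrow(x$matrix)), function(i) {
    paste0(sprintf("%5d %s ", i, res[[i]]),
           paste(sprintf("%3s", format(x$matrix[i, ], trim = TRUE,
                                       digits = 15)), collapse = " "),
           "  ", paste(rep("0", 20), collapse = "   "),
           "  0.00 0.00")
  }, "")
  writeLines(c(hdr, body, ""), path)
  invisible(path)
}

#' Write a labeled feature matrix as TSV
#'
#' Header names each feature column `block:name`; the final column is
#' the integer class label (+1/-1). Values are written at full double
#' precision so the round trip through [read_feature_matrix()] is
#' lossless.
#'
#' @param x numeric feature matrix (rows = proteins) carrying a
#'   `block_map` attribute (see [encode_features()]); plain matrices
#'   are written under a single `feat` block.
#' @param labels integer vector of +1/-1 (or 1/0) labels, one per row.
#' @param path output path.
#' @export
write_feature_matrix <- function(x, labels, path) {
  x <- as.matrix(x)
  if (nrow(x) == 0 || ncol(x) == 0) stop("empty feature matrix")
  if (length(labels) != nrow(x)) stop("one label per row required")
  labels <- ifelse(labels == 0, -1L, as.integer(labels))
  if (!all(labels %in% c(-1L, 1L))) stop("labels must be +1/-1 (or 1/0)")
  if (is.null(colnames(x))) colnames(x) <- paste0("feat:", seq_len(ncol(x)))
  df <- data.frame(x, check.names = FALSE)
  df$label <- labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(colnames(x), "label"), collapse = "\t"), con)
  mat_chr <- vapply(seq_len(nrow(df)), function(i) {
    paste(c(sprintf("%.17g", x[i, ]), labels[i]), collapse = "\t")
  }, "")
  writeLines(mat_chr, con)
  invisible(path)
}

#' Read a labeled feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return list with `matrix` (numeric, named columns), `labels`
#'   (+1/-1 integer vector) and `block_map` (data.frame of block name,
#'   start and end column, reconstructed from the header prefixes).
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!"label" %in% names(tab)) stop("no 'label' column in ", path)
  labels <- as.integer(tab$label)
  labels <- ifelse(labels == 0L, -1L, labels)
  m <- as.matrix(tab[names(tab) != "label"])
  blocks <- sub(":.*$", "", colnames(m))
  rl <- rle(blocks)
  ends <- cumsum(rl$lengths)
  bm <- data.frame(block = rl$values,
                   start = c(1L, utils::head(ends, -1) + 1L),
                   end = ends, stringsAsFactors = FALSE)
  attr(m, "block_map") <- bm
  list(matrix = m, labels = labels, block_map = bm)
}
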