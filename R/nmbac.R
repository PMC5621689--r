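# Normalized Moreau-Broto autocorrelation (NMBAC) + amino-acid composition.

#' Encode a sequence as normalized Moreau-Broto autocorrelation features
#'
#' Each residue is replaced by its six standardized physicochemical
#' property values (see [aa_properties()]). For property j and lag d
#' the descriptor is the average product of property values at
#' sequence positions i and i + d:
#' \deqn{A_{d,j} = \frac{1}{n-d}\sum_{i=1}^{n-d} X'_{i,j}\,X'_{i+d,j}}
#' computed for d = 1..`lg`. With the default `lg = 30` this yields a
#' 30 x 6 = 180-value autocorrelation block; the 20 amino-acid
#' frequencies (composition) are appended, giving 200 features.
#'
#' Ordering is property-major (all lags of H, then VSC, P1, P2, SASA,
#' NCISC), composition last in alphabetical residue order. The
#' encoding depends only on the sequence, never on id or label, and is
#' invariant under sequence reversal (the defining sum is palindromic).
#'
#' @param record a protein record (see [protein_record()]) or a plain
#'   sequence string.
#' @param lg maximum lag; the sequence must be longer than `lg`.
#' @param include_aac append the 20 composition frequencies (default
#'   `TRUE`).
#' @param table property matrix to use; defaults to the standardized
#'   six-property table. Override for sensitivity studies.
#' @return named numeric vector of length `6 * lg + 20` (or `6 * lg`
#'   without composition), with a `block_map` attribute tagging it as
#'   the `nmbac` block.
#' @examples
#' v <- encode_nmbac(strrep("ACDEFGHIKLMNPQRSTVWY", 3))
#' length(v)  # 200
#' @export
encode_nmbac <- function(record, lg = 30, include_aac = TRUE,
                         table = aa_properties()) {
  seq <- if (inherits(record, "protein_record")) record$sequence else record
  id <- if (inherits(record, "protein_record")) record$id else "<sequence>"
  stopifnot(is.character(seq), length(seq) == 1L, lg >= 1)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  idx <- match(chars, rownames(table))
  if (anyNA(idx)) {
    stop("record '", id, "' contains non-standard residue(s): ",
         paste(unique(chars[is.na(idx)]), collapse = ""))
  }
  if (n <= lg) {
    stop("record '", id, "' has length ", n,
         " but the maximum lag is ", lg, "; need length > lg")
  }
  X <- table[idx, , drop = FALSE]              # n x 6
  ac <- matrix(0, nrow = lg, ncol = ncol(X))   # lag x property
  for (d in seq_len(lg)) {
    ac[d, ] <- colSums(X[1:(n - d), , drop = FALSE] *
                       X[(1 + d):n, , drop = FALSE]) / (n - d)
  }
  out <- as.vector(ac)                         # property-major
  names(out) <- paste0("nmbac:", rep(colnames(table), each = lg),
                       ".lag", rep(seq_len(lg), ncol(X)))
  if (include_aac) {
    freq <- tabulate(idx, nbins = nrow(table)) / n
    names(freq) <- paste0("nmbac:aac.", rownames(table))
    out <- c(out, freq)
  }
  attr(out, "block_map") <- data.frame(block = "nmbac", start = 1L,
                                       end = length(out),
                                       stringsAsFactors = FALSE)
  out
}
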