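# Orthonormal discrete cosine transform and the PSSM-DCT encoder.

# Orthonormal DCT-II basis matrix: row i (0-based) holds
# a_i * cos(pi * (2m + 1) * i / (2n)), a_0 = sqrt(1/n), else sqrt(2/n).
dct_matrix <- function(n) {
  i <- 0:(n - 1)
  m <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(i, 2 * m + 1) / (2 * n))
  D[1, ] <- sqrt(1 / n)
  D
}

#' Two-dimensional orthonormal type-II discrete cosine transform
#'
#' `DCT(i, j) = a_i a_j sum_{m,n} X(m, n) cos(pi (2m+1) i / 2M)
#' cos(pi (2n+1) j / 2N)` with `a_0 = sqrt(1/M)` and
#' `a_i = sqrt(2/M)` otherwise (likewise over columns). The transform
#' is orthonormal: it preserves the Frobenius norm and [idct2()] is
#' its exact inverse.
#'
#' @param x numeric matrix.
#' @return matrix of DCT coefficients, same shape as `x`; low spatial
#'   frequencies sit in the upper-left corner.
#' @export
dct2 <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 0) stop("empty matrix")
  stopifnot(all(is.finite(x)))
  dct_matrix(nrow(x)) %*% x %*% t(dct_matrix(ncol(x)))
}

#' Inverse of [dct2()]
#' @param x coefficient matrix.
#' @export
idct2 <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 0) stop("empty matrix")
  t(dct_matrix(nrow(x))) %*% x %*% dct_matrix(ncol(x))
}

# One-dimensional orthonormal DCT-II (used for approximation-band
# cosine coefficients in the wavelet encoder).
dct1 <- function(x) as.vector(dct_matrix(length(x)) %*% x)

#' Zigzag traversal order of an M x N grid
#'
#' JPEG-style scan: anti-diagonals from the (1,1) corner outward,
#' alternating direction, so coefficients come out in order of
#' increasing spatial frequency.
#'
#' @param nrow,ncol grid dimensions.
#' @return two-column integer matrix of (row, col) positions covering
#'   the grid exactly once.
#' @export
zigzag_indices <- function(nrow, ncol) {
  out <- matrix(0L, nrow * ncol, 2)
  k <- 0L
  for (s in 0:(nrow + ncol - 2)) {
    i <- max(0L, s - ncol + 1L):min(s, nrow - 1L)
    if (s %% 2 == 0) i <- rev(i)   # even diagonals run bottom-left -> top-right
    j <- s - i
    out[k + seq_along(i), 1] <- i + 1L
    out[k + seq_along(i), 2] <- j + 1L
    k <- k + length(i)
  }
  out
}

#' PSSM-DCT feature block
#'
#' Compresses an L x 20 profile with the 2-D DCT and keeps the first
#' `m` coefficients, where "first" means lowest spatial frequency: the
#' default zigzag scan walks anti-diagonals out of the upper-left
#' (DC) corner. A `block` scan is available instead, which takes a
#' row-major `ceiling(m/20) x 20` upper submatrix prefix.
#'
#' @param x a `pssm` object or a plain L x 20 matrix.
#' @param m number of retained coefficients (default 100).
#' @param scan `"zigzag"` (default) or `"block"`.
#' @return named numeric vector of length `m` with a `block_map`
#'   attribute tagging the `dct` block.
#' @export
encode_pssm_dct <- function(x, m = 100, scan = c("zigzag", "block")) {
  scan <- match.arg(scan)
  mat <- if (inherits(x, "pssm")) x$matrix else as.matrix(x)
  if (m < 1 || m > length(mat)) {
    stop("m = ", m, " out of range for a ", nrow(mat), " x ", ncol(mat),
         " profile")
  }
  co <- dct2(mat)
  idx <- switch(scan,
    zigzag = zigzag_indices(nrow(co), ncol(co))[seq_len(m), , drop = FALSE],
    block = {
      r <- ceiling(m / ncol(co))
      cbind(rep(seq_len(r), each = ncol(co)),
            rep(seq_len(ncol(co)), r))[seq_len(m), , drop = FALSE]
    })
  out <- co[idx]
  names(out) <- paste0("dct:", idx[, 1] - 1L, ".", idx[, 2] - 1L)
  attr(out, "block_map") <- data.frame(block = "dct", start = 1L,
                                       end = m, stringsAsFactors = FALSE)
  out
}
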