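# Cascade discrete wavelet transform and the PSSM-DWT encoder.

#' Decomposition filter pairs for the supported wavelets
#'
#' `haar` is the 2-tap Haar pair; `db2` (default elsewhere) is the
#' 4-tap Daubechies orthogonal pair. Both satisfy the quadrature
#' mirror conditions, so single-level analysis under periodized
#' boundaries is an orthogonal transform.
#'
#' @param wavelet `"haar"` or `"db2"`.
#' @return list with numeric `lo` (low-pass) and `hi` (high-pass)
#'   decomposition filters.
#' @export
wavelet_filters <- function(wavelet = c("db2", "haar")) {
  wavelet <- match.arg(wavelet)
  s3 <- sqrt(3)
  switch(wavelet,
    haar = list(lo = c(1, 1) / sqrt(2), hi = c(-1, 1) / sqrt(2)),
    db2 = list(lo = c(1 - s3, 3 - s3, 3 + s3, 1 + s3) / (4 * sqrt(2)),
               hi = c(-(1 + s3), 3 + s3, -(3 - s3), 1 - s3) / (4 * sqrt(2))))
}

# One analysis level: convolve with the filter and keep even positions.
# mode "symmetric": half-point reflection by (f - 1) samples each side,
# then the stride-2 subsequence of the fully-overlapping convolution,
# giving floor((n + f - 1) / 2) coefficients per band.
# mode "periodic": circular convolution at even phases (the signal is
# first extended to even length by repeating its last sample); gives
# n/2 coefficients per band and preserves energy for orthogonal filters.
dwt_step <- function(x, filt, mode) {
  f <- length(filt)
  n <- length(x)
  if (n < f) {
    stop("signal of length ", n, " too short for a ", f, "-tap filter; ",
         "need length >= ", f)
  }
  if (mode == "periodic") {
    if (n %% 2 == 1) { x <- c(x, x[n]); n <- n + 1 }
    half <- n / 2
    y <- numeric(half)
    pos <- 2 * seq_len(half)                     # convolution at even samples
    for (j in seq_len(f)) {
      y <- y + filt[j] * x[((pos - j) %% n) + 1]
    }
    y
  } else {
    e <- c(x[(f - 1):1], x, x[n:(n - f + 2)])
    nv <- n + f - 1
    v <- numeric(nv)
    for (j in seq_len(f)) {
      v <- v + filt[j] * e[seq_len(nv) + f - j]  # conv, fully-overlapping part
    }
    v[seq(2, nv, by = 2)]
  }
}

#' Multi-level one-dimensional discrete wavelet decomposition
#'
#' Classic Mallat cascade: at every level the current approximation is
#' convolved with the low- and high-pass decomposition filters and
#' downsampled by two; the low-pass output (approximation) feeds the
#' next level, the high-pass output (detail) is kept as is.
#'
#' @param x numeric signal.
#' @param wavelet filter pair name, see [wavelet_filters()].
#' @param levels decomposition depth (default 4).
#' @param mode boundary handling: `"symmetric"` (half-point
#'   reflection, default) or `"periodic"` (periodization; energy
#'   preserving for these orthogonal filters).
#' @return list with `approx` and `detail`, each a list of `levels`
#'   coefficient vectors (level 1 first), plus the resolved
#'   `wavelet`, `levels`, `mode`.
#' @export
dwt_1d <- function(x, wavelet = "db2", levels = 4,
                   mode = c("symmetric", "periodic")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(x), levels >= 1)
  filt <- wavelet_filters(wavelet)
  approx <- vector("list", levels)
  detail <- vector("list", levels)
  cur <- as.numeric(x)
  for (lev in seq_len(levels)) {
    approx[[lev]] <- dwt_step(cur, filt$lo, mode)
    detail[[lev]] <- dwt_step(cur, filt$hi, mode)
    cur <- approx[[lev]]
  }
  list(approx = approx, detail = detail, wavelet = wavelet,
       levels = levels, mode = mode)
}

# population SD; length-1 bands have SD 0
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' PSSM-DWT feature block
#'
#' Treats each of the 20 profile columns as a length-L signal and runs
#' a `levels`-deep wavelet decomposition on it. Per column the block
#' holds, for every level, the maximum, minimum, mean and population
#' standard deviation of both the approximation and the detail
#' coefficients (`levels * 8` values), followed by the first
#' `n_dct` one-dimensional DCT coefficients of every level's
#' approximation band (`levels * n_dct` values, the low-frequency
#' bands being the informative ones). Columns are concatenated in
#' profile column order: at the defaults (4 levels, 5 cosine
#' coefficients) that is 52 values per column, 1040 in total.
#'
#' @param x a `pssm` object or plain L x 20 matrix; L must support
#'   `levels` halvings with at least `n_dct` approximation
#'   coefficients left (any curated sequence of length >= 50 does).
#' @param wavelet,levels,mode passed to [dwt_1d()].
#' @param n_dct cosine coefficients kept per approximation band.
#' @return named numeric vector (length 1040 at defaults) with a
#'   `block_map` attribute tagging the `dwt` block.
#' @export
encode_pssm_dwt <- function(x, wavelet = "db2", levels = 4,
                            mode = "symmetric", n_dct = 5) {
  mat <- if (inherits(x, "pssm")) x$matrix else as.matrix(x)
  if (ncol(mat) != 20) stop("profile must have 20 columns")
  per_col <- levels * 8 + levels * n_dct
  out <- numeric(per_col * 20)
  nm <- character(per_col * 20)
  for (cc in seq_len(20)) {
    dec <- dwt_1d(mat[, cc], wavelet = wavelet, levels = levels, mode = mode)
    if (length(dec$approx[[levels]]) < n_dct) {
      stop("profile with ", nrow(mat), " rows leaves only ",
           length(dec$approx[[levels]]), " level-", levels,
           " approximation coefficients; need >= ", n_dct)
    }
    vals <- numeric(per_col)
    vnm <- character(per_col)
    k <- 0L
    for (lev in seq_len(levels)) {
      for (band in c("approx", "detail")) {
        b <- dec[[band]][[lev]]
        vals[k + 1:4] <- c(max(b), min(b), mean(b), sd_pop(b))
        vnm[k + 1:4] <- paste0("l", lev, ".", substr(band, 1, 1), ".",
                               c("max", "min", "mean", "sd"))
        k <- k + 4L
      }
    }
    for (lev in seq_len(levels)) {
      vals[k + seq_len(n_dct)] <- dct1(dec$approx[[lev]])[seq_len(n_dct)]
      vnm[k + seq_len(n_dct)] <- paste0("l", lev, ".a.dct", seq_len(n_dct))
      k <- k + n_dct
    }
    span <- (cc - 1L) * per_col + seq_len(per_col)
    out[span] <- vals
    nm[span] <- paste0("dwt:c", cc, ".", vnm)
  }
  names(out) <- nm
  attr(out, "block_map") <- data.frame(block = "dwt", start = 1L,
                                       end = length(out),
                                       stringsAsFactors = FALSE)
  out
}
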