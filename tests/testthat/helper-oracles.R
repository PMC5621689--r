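# Independent oracles and small generators shared across the suite.
# Each oracle is a deliberately naive re-derivation of the defining
# formula, written without reference to the package internals.

rand_seq <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                              collapse = "")

rand_records <- function(k, len_range = c(50, 80)) {
  lapply(seq_len(k), function(i) {
    protein_record(sprintf("r%03d", i),
                   rand_seq(sample(len_range[1]:len_range[2], 1)),
                   sample(c(1, -1), 1))
  })
}

# Eq-by-eq double loop over positions: autocorrelation of standardized
# property values, then residue frequencies.
brute_nmbac <- function(seq, lg, include_aac = TRUE) {
  tab <- aa_properties()
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  out <- c()
  for (j in seq_len(ncol(tab))) {
    for (d in seq_len(lg)) {
      s <- 0
      for (i in seq_len(n - d)) {
        s <- s + tab[ch[i], j] * tab[ch[i + d], j]
      }
      out <- c(out, s / (n - d))
    }
  }
  if (include_aac) {
    for (a in rownames(tab)) out <- c(out, sum(ch == a) / n)
  }
  out
}

# Direct quadruple-loop evaluation of the 2-D cosine transform.
brute_dct2 <- function(mat) {
  M <- nrow(mat); N <- ncol(mat)
  out <- matrix(0, M, N)
  for (i in 0:(M - 1)) {
    ai <- if (i == 0) sqrt(1 / M) else sqrt(2 / M)
    for (j in 0:(N - 1)) {
      aj <- if (j == 0) sqrt(1 / N) else sqrt(2 / N)
      s <- 0
      for (m in 0:(M - 1)) {
        for (nn in 0:(N - 1)) {
          s <- s + mat[m + 1, nn + 1] *
            cos(pi * (2 * m + 1) * i / (2 * M)) *
            cos(pi * (2 * nn + 1) * j / (2 * N))
        }
      }
      out[i + 1, j + 1] <- ai * aj * s
    }
  }
  out
}

# One analysis level by explicit convolution of the boundary-extended
# signal with the filter, keeping every second fully-overlapping
# window (half-point symmetric extension by f - 1 samples each side).
brute_dwt_step <- function(x, filt) {
  f <- length(filt); n <- length(x)
  e <- c(x[(f - 1):1], x, x[n:(n - f + 2)])
  conv <- numeric(length(e) + f - 1)
  for (a in seq_along(e)) {
    for (b in seq_len(f)) {
      conv[a + b - 1] <- conv[a + b - 1] + e[a] * filt[b]
    }
  }
  valid <- conv[f:length(e)]
  valid[seq(2, length(valid), by = 2)]
}

# AUROC as the fraction of correctly ordered (positive, negative)
# score pairs, ties counting one half.
brute_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == -1]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# two well-separated 2-D Gaussian blobs for classifier tests
toy_blobs <- function(n = 100, sep = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, -1), length.out = n)
  x <- matrix(rnorm(2 * n), n)
  x[y == 1, ] <- x[y == 1, ] + sep
  list(x = x, y = y)
}
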