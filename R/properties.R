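# Physicochemical property table and its normalization.

#' The 20 standard amino acids, alphabetical one-letter order
#'
#' This is the row order of [aa_properties()] and the order in which
#' amino-acid composition features are reported.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Amino-acid column order of PSI-BLAST profile matrices
#' @export
PSSM_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Physicochemical properties of the 20 standard amino acids
#'
#' Six properties per residue: hydrophobicity (`H`), volume of side
#' chain (`VSC`), polarity (`P1`), polarizability (`P2`),
#' solvent-accessible surface area (`SASA`) and net charge index of
#' side chain (`NCISC`). Rows are the 20 standard amino acids in
#' alphabetical one-letter order.
#'
#' @param normalized if `TRUE` (default), each property column is
#'   standardized to zero mean and unit population standard deviation
#'   over the 20 residues (see [normalize_properties()]); if `FALSE`
#'   the raw literature values are returned.
#' @return a 20 x 6 numeric matrix with residue row names and property
#'   column names.
#' @examples
#' aa_properties()["A", "H"]
#' @export
aa_properties <- function(normalized = TRUE) {
  raw <- .aa_property_raw
  if (normalized) normalize_properties(raw) else raw
}

.aa_property_raw <- local({
  vals <- c(
    # H      VSC     P1    P2     SASA   NCISC
    0.62,   27.5,   8.1,  0.046, 1.181,  0.007187, # A
    0.29,   44.6,   5.5,  0.128, 1.461, -0.03661,  # C
   -0.90,   40.0,  13.0,  0.105, 1.587, -0.02382,  # D
   -0.74,   62.0,  12.3,  0.151, 1.862,  0.006802, # E
    1.19,  115.5,   5.2,  0.290, 2.228,  0.037552, # F
    0.48,    0.0,   9.0,  0.000, 0.881,  0.179052, # G
   -0.40,   79.0,  10.4,  0.230, 2.025, -0.01069,  # H
    1.38,   93.5,   5.2,  0.186, 1.810,  0.021631, # I
   -1.50,  100.0,  11.3,  0.219, 2.258,  0.017708, # K
    1.06,   93.5,   4.9,  0.186, 1.931,  0.051672, # L
    0.64,   94.1,   5.7,  0.221, 2.034,  0.002683, # M
   -0.78,   58.7,  11.6,  0.134, 1.655,  0.005392, # N
    0.12,   41.9,   8.0,  0.131, 1.468,  0.239531, # P
   -0.85,   80.7,  10.5,  0.180, 1.932,  0.049211, # Q
   -2.53,  105.0,  10.5,  0.291, 2.560,  0.043587, # R
   -0.18,   29.3,   9.2,  0.062, 1.298,  0.004627, # S
   -0.05,   51.3,   8.6,  0.108, 1.525,  0.003352, # T
    1.08,   71.5,   5.9,  0.140, 1.645,  0.057004, # V
    0.81,  145.5,   5.4,  0.409, 2.663,  0.037977, # W
    0.26,  117.3,   6.2,  0.298, 2.368,  0.023599  # Y
  )
  m <- matrix(vals, nrow = 20, ncol = 6, byrow = TRUE,
              dimnames = list(AA_ALPHABET,
                              c("H", "VSC", "P1", "P2", "SASA", "NCISC")))
  m
})

#' Standardize a property table to zero mean and unit SD per column
#'
#' Each column is centred on its mean over the 20 amino acids and
#' divided by its standard deviation. The SD is the population SD
#' (divisor 20): the 20 residue values constitute the whole population
#' of amino-acid types, not a sample from one.
#'
#' @param raw a 20 x 6 (more generally n x p) finite numeric matrix.
#' @param population use the population SD (default); set `FALSE` for
#'   the sample SD (divisor n - 1) for sensitivity analyses.
#' @return matrix of the same shape; every column has mean 0 and the
#'   requested SD equal to 1.
#' @export
normalize_properties <- function(raw, population = TRUE) {
  raw <- as.matrix(raw)
  stopifnot(is.numeric(raw), all(is.finite(raw)))
  mu <- colMeans(raw)
  n <- nrow(raw)
  ss <- colMeans(raw^2) - mu^2
  sdv <- if (population) sqrt(ss) else sqrt(ss * n / (n - 1))
  if (any(sdv <= 0)) {
    stop("constant property column(s): ",
         paste(colnames(raw)[sdv <= 0], collapse = ", "))
  }
  sweep(sweep(raw, 2, mu, "-"), 2, sdv, "/")
}
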