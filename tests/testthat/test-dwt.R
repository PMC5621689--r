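test_that("constant signals have vanishing detail at every level", {
  for (w in c("haar", "db2")) {
    dec <- dwt_1d(rep(5, 48), wavelet = w, levels = 4)
    expect_equal(max(abs(unlist(dec$detail))), 0, tolerance = 1e-12)
  }
})

test_that("one analysis level equals direct convolve-then-downsample", {
  filt <- wavelet_filters("db2")
  imp <- c(1, rep(0, 15))
  dec <- dwt_1d(imp, "db2", levels = 1)
  expect_equal(dec$approx[[1]], brute_dwt_step(imp, filt$lo),
               tolerance = 1e-9)
  expect_equal(dec$detail[[1]], brute_dwt_step(imp, filt$hi),
               tolerance = 1e-9)
  set.seed(31)
  for (n in c(17, 24, 50)) {
    x <- rnorm(n)
    dec <- dwt_1d(x, "db2", levels = 1)
    expect_equal(dec$approx[[1]], brute_dwt_step(x, filt$lo),
                 tolerance = 1e-9)
    expect_equal(dec$detail[[1]], brute_dwt_step(x, filt$hi),
                 tolerance = 1e-9)
  }
})

test_that("periodized analysis preserves energy for orthogonal filters", {
  set.seed(32)
  for (w in c("haar", "db2")) {
    x <- rnorm(64)
    dec <- dwt_1d(x, w, levels = 1, mode = "periodic")
    expect_equal(sum(x^2),
                 sum(dec$approx[[1]]^2) + sum(dec$detail[[1]]^2),
                 tolerance = 1e-9)
    # cascading keeps total energy too
    dec4 <- dwt_1d(x, w, levels = 4, mode = "periodic")
    expect_equal(sum(x^2),
                 sum(dec4$approx[[4]]^2) + sum(unlist(dec4$detail)^2),
                 tolerance = 1e-9)
  }
})

test_that("db2 symmetric-mode coefficients match an external reference", {
  # frozen from an independent wavelet implementation (PyWavelets,
  # dwt(x, 'db2', mode = 'symmetric')) on this fixed signal
  x <- c(-2, -1, 1, -2, 0, 0, 0, 2, -2, 3, -1, -2, -1, 1, 0, -1, -2,
         -1, 2, 0, -1, -2, 0)
  ref_a <- c(-2.47487373, -1.31947922, -1.19006969, -0.25881905,
             0.83651630, 1.57829826, -2.50954891, 0.48296291,
             -1.15539452, -1.35415439, 1.00060100, -2.15599552,
             -0.31887821)
  ref_d <- c(-0.61237244, 2.28540504, 0.31887821, -0.96592583,
             -3.57020908, -0.28420304, -0.74178196, 0.38822857,
             -0.96592583, 2.15599552, -0.12940952, 0.57769726,
             -1.19006969)
  dec <- dwt_1d(x, "db2", levels = 1, mode = "symmetric")
  expect_equal(dec$approx[[1]], ref_a, tolerance = 1e-8)
  expect_equal(dec$detail[[1]], ref_d, tolerance = 1e-8)
})

test_that("signals too short for the filter are rejected with the minimum", {
  expect_error(dwt_1d(c(1, 2, 3), "db2", levels = 1), "length >= 4")
  expect_error(dwt_1d(rnorm(8), "db2", levels = 4), "too short")
})

test_that("DWT block is 1040-dimensional with sane per-band statistics", {
  b <- gen_dataset(n_pos = 1, n_neg = 1, length_range = c(50, 60), seed = 41)
  p <- b$pssms[[1]]
  v <- encode_pssm_dwt(p)
  expect_length(v, 1040)
  # min <= mean <= max and sd >= 0 for every (column, level, band)
  for (col in c(1, 7, 20)) {
    base <- (col - 1) * 52
    for (lev in 1:4) {
      for (band in 0:1) {
        st <- v[base + (lev - 1) * 8 + band * 4 + 1:4]  # max,min,mean,sd
        expect_gte(st[1], st[3]); expect_gte(st[3], st[2])
        expect_gte(st[4], 0)
      }
    }
  }
  expect_equal(as.vector(encode_pssm_dwt(matrix(0, 60, 20))), rep(0, 1040))
})

test_that("DWT block equals chaining dwt_1d with summary statistics", {
  b <- gen_dataset(n_pos = 1, n_neg = 1, length_range = c(55, 65), seed = 42)
  p <- b$pssms[[1]]
  v <- encode_pssm_dwt(p)
  sdp <- function(z) sqrt(mean((z - mean(z))^2))
  for (col in c(3, 20)) {
    dec <- dwt_1d(p$matrix[, col], "db2", levels = 4, mode = "symmetric")
    expected <- c()
    for (lev in 1:4) {
      for (band in list(dec$approx[[lev]], dec$detail[[lev]])) {
        expected <- c(expected, max(band), min(band), mean(band),
                      sdp(band))
      }
    }
    for (lev in 1:4) {
      a <- dec$approx[[lev]]
      n <- length(a)
      dctm <- sqrt(2 / n) *
        cos(pi * outer(0:(n - 1), 2 * (0:(n - 1)) + 1) / (2 * n))
      dctm[1, ] <- sqrt(1 / n)
      expected <- c(expected, (dctm %*% a)[1:5])
    }
    got <- v[(col - 1) * 52 + 1:52]
    expect_equal(unname(got), expected, tolerance = 1e-9)
  }
  expect_identical(encode_pssm_dwt(p), encode_pssm_dwt(p))
})
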