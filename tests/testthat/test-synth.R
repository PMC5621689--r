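test_that("generation is deterministic per seed and varies across seeds", {
  b1 <- gen_dataset(n_pos = 5, n_neg = 5, length_range = c(50, 70), seed = 3)
  b2 <- gen_dataset(n_pos = 5, n_neg = 5, length_range = c(50, 70), seed = 3)
  expect_identical(b1, b2)
  b3 <- gen_dataset(n_pos = 5, n_neg = 5, length_range = c(50, 70), seed = 4)
  expect_false(identical(b1$records, b3$records))
  expect_false(identical(b1$pssms[[1]]$matrix, b3$pssms[[1]]$matrix))
  # manifest replay regenerates the bundle bit-identically
  expect_identical(do.call(gen_dataset, b1$manifest), b1)
})

test_that("generated records pass curation unchanged and profiles align", {
  b <- gen_dataset(n_pos = 10, n_neg = 10, seed = 5)
  kept <- curate_records(b$records)
  expect_length(kept, 20)
  expect_equal(nrow(attr(kept, "removed")), 0)
  for (i in c(1, 20)) {
    expect_equal(nrow(b$pssms[[i]]$matrix), nchar(b$records[[i]]$sequence))
    expect_equal(b$pssms[[i]]$protein_id, b$records[[i]]$id)
    expect_true(all(b$pssms[[i]]$matrix >= -10 & b$pssms[[i]]$matrix <= 10))
    expect_true(all(b$pssms[[i]]$matrix == round(b$pssms[[i]]$matrix)))
  }
})

test_that("effect zero makes residue composition class-exchangeable", {
  b <- gen_dataset(n_pos = 40, n_neg = 40, length_range = c(120, 160),
                   effect = 0, seed = 6)
  counts <- function(recs) {
    ch <- unlist(strsplit(vapply(recs, `[[`, "", "sequence"), ""))
    table(factor(ch, levels = AA_ALPHABET))
  }
  pos <- counts(b$records[1:40])
  neg <- counts(b$records[41:80])
  p <- suppressWarnings(stats::chisq.test(rbind(pos, neg))$p.value)
  expect_gt(p, 0.01)
})

test_that("generated profiles survive the disk round trip", {
  b <- gen_dataset(n_pos = 2, n_neg = 2, length_range = c(50, 60), seed = 7)
  f <- withr::local_tempfile(fileext = ".pssm")
  write_pssm(b$pssms[[1]], f)
  back <- read_pssm(f)
  expect_equal(unname(back$matrix), unname(b$pssms[[1]]$matrix))
  expect_equal(back$residues, b$records[[1]]$sequence)
})

test_that("bundles write out as FASTA + profiles + labels", {
  b <- gen_dataset(n_pos = 3, n_neg = 3, length_range = c(50, 60), seed = 8)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  recs <- read_fasta(file.path(dir, "sequences.fasta"))
  expect_length(recs, 6)
  expect_length(list.files(file.path(dir, "pssm")), 6)
  lab <- utils::read.delim(file.path(dir, "labels.tsv"))
  expect_equal(lab$label, b$labels)
})

test_that("composition signal at effect 3 is recoverable by the pipeline", {
  b <- gen_dataset(n_pos = 100, n_neg = 100, effect = 3, seed = 11)
  x <- encode_features(b$records, features = "nmbac")
  ev <- jackknife_eval(x, b$labels)
  expect_gte(ev$metrics$ACC, 0.85)
})

test_that("profile signal at effect 4 is recoverable from DCT features", {
  b <- gen_dataset(n_pos = 100, n_neg = 100, effect = 4, seed = 12)
  x <- encode_features(b$records, b$pssms, features = "dct")
  ev <- jackknife_eval(x, b$labels)
  expect_gte(ev$metrics$ACC, 0.85)
})

test_that("classification accuracy is non-decreasing in the effect size", {
  mean_acc <- vapply(c(0, 1, 2, 4), function(eff) {
    mean(vapply(1:10, function(s) {
      b <- gen_dataset(n_pos = 30, n_neg = 30, effect = eff,
                       length_range = c(50, 150), seed = 400 + 37 * s)
      x <- encode_features(b$records, features = "nmbac")
      jackknife_eval(x, b$labels)$metrics$ACC
    }, 0))
  }, 0)
  expect_true(all(diff(mean_acc) >= -0.03))
})

test_that("the lag channel plants autocorrelation signal", {
  b <- gen_dataset(n_pos = 40, n_neg = 40, effect = 3,
                   channels = "lag", length_range = c(80, 150), seed = 13)
  x <- encode_features(b$records, features = "nmbac", include_aac = FALSE)
  ev <- jackknife_eval(x, b$labels)
  expect_gte(ev$metrics$ACC, 0.7)
})
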