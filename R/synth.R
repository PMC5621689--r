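# Synthetic sequences and profile matrices with controllable class
# signal, so every pipeline stage is testable without database
# searches.

# Frozen generator constants (see the methods vignette): tilt per unit
# of `effect` for the composition and lag channels, profile noise SD,
# log-odds clip range, and the conservation self-score bump.
.synth <- list(tilt_comp = 0.2, tilt_lag = 0.25, noise_sd = 2,
               clip = c(-10, 10), self_bump = 2)

#' Generate labeled synthetic protein sequences
#'
#' Negative-class residues are drawn uniformly over the 20 standard
#' amino acids. Positive-class draws are tilted according to the
#' requested signal channels:
#' \itemize{
#'   \item `composition`: residue weights proportional to
#'     `exp(0.2 * effect * |H'|)` where `H'` is standardized
#'     hydrophobicity — binding-class sequences are enriched for
#'     residues of extreme hydrophobicity, which the
#'     composition/autocorrelation features can detect;
#'   \item `lag`: an alternating positional bias of strength
#'     `0.25 * effect` toward hydrophobic residues at even and
#'     hydrophilic at odd positions, planting signal specifically in
#'     the short-lag autocorrelation terms.
#' }
#' `effect = 0` makes the classes exchangeable. All sequences respect
#' the curation rules (standard alphabet, length >= 50 under the
#' default range).
#'
#' @param n_pos,n_neg class sizes.
#' @param length_range inclusive sequence-length interval.
#' @param effect class-signal strength, in SD-like units (>= 0).
#' @param channels subset of `c("composition", "profile", "lag")`;
#'   `profile` is used by [gen_pssm()], not here.
#' @param seed RNG seed; same seed, same records.
#' @return list of labeled protein records (+1 first, then -1).
#' @export
gen_sequences <- function(n_pos = 100, n_neg = 100,
                          length_range = c(50, 300), effect = 2,
                          channels = c("composition", "profile"),
                          seed = 1) {
  stopifnot(effect >= 0, length_range[1] >= 50,
            all(channels %in% c("composition", "profile", "lag")))
  set.seed(seed)
  hn <- aa_properties()[, "H"]
  w_base <- if ("composition" %in% channels) {
    exp(.synth$tilt_comp * effect * abs(hn))
  } else rep(1, 20)
  lag_tilt <- if ("lag" %in% channels) .synth$tilt_lag * effect else 0
  draw <- function(n, positive) {
    if (!positive) {
      paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
    } else if (lag_tilt == 0) {
      paste(sample(AA_ALPHABET, n, replace = TRUE,
                   prob = w_base / sum(w_base)), collapse = "")
    } else {
      even <- w_base * exp(lag_tilt * hn)
      odd <- w_base * exp(-lag_tilt * hn)
      ch <- character(n)
      pe <- even / sum(even); po <- odd / sum(odd)
      for (i in seq_len(n)) {
        ch[i] <- sample(AA_ALPHABET, 1,
                        prob = if (i %% 2 == 0) pe else po)
      }
      paste(ch, collapse = "")
    }
  }
  lens <- sample(length_range[1]:length_range[2], n_pos + n_neg,
                 replace = TRUE)
  recs <- vector("list", n_pos + n_neg)
  for (i in seq_len(n_pos)) {
    recs[[i]] <- protein_record(sprintf("pos_%03d", i),
                                draw(lens[i], TRUE), 1)
  }
  for (i in seq_len(n_neg)) {
    recs[[n_pos + i]] <- protein_record(sprintf("neg_%03d", i),
                                        draw(lens[n_pos + i], FALSE), -1)
  }
  recs
}

#' Generate a synthetic profile matrix for a record
#'
#' Emulates the integer L x 20 log-odds structure of a real profile:
#' discretized Gaussian noise (SD 2) clipped to \[-10, 10\], plus a
#' +2 self-score bump in each row's own residue column (mimicking
#' conservation). For positive-class records with the `profile`
#' channel active, a smooth separable cosine pattern of amplitude
#' `effect` is added before rounding, so the class signal lives in the
#' low-frequency profile coefficients that the DCT/DWT encoders
#' retain.
#'
#' @param record a labeled protein record.
#' @param effect signal amplitude (log-odds units).
#' @param channels as in [gen_sequences()].
#' @param seed optional seed; `NULL` (default) continues the current
#'   RNG stream, which is what [gen_dataset()] relies on.
#' @return a `pssm` object with integer entries.
#' @export
gen_pssm <- function(record, effect = 2,
                     channels = c("composition", "profile"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(record$sequence)
  m <- matrix(stats::rnorm(L * 20, 0, .synth$noise_sd), L, 20)
  if ("profile" %in% channels && !is.na(record$label) &&
      record$label == 1) {
    m <- m + effect * outer(cos(pi * (seq_len(L) - 0.5) / L),
                            cos(pi * (seq_len(20) - 0.5) / 20))
  }
  m <- round(m)
  cols <- match(strsplit(record$sequence, "")[[1]], PSSM_ALPHABET)
  m[cbind(seq_len(L), cols)] <- m[cbind(seq_len(L), cols)] +
    .synth$self_bump
  m <- pmin(pmax(m, .synth$clip[1]), .synth$clip[2])
  colnames(m) <- PSSM_ALPHABET
  pssm(record$id, m, record$sequence)
}

#' Generate a complete labeled dataset bundle
#'
#' Composes [gen_sequences()] and [gen_pssm()] under one seed and
#' records the generating configuration, so any bundle can be
#' regenerated bit-identically from its manifest.
#'
#' @inheritParams gen_sequences
#' @return list with `records`, `pssms` (one per record), `labels`
#'   (+1/-1 vector) and `manifest` (the full configuration).
#' @examples
#' b <- gen_dataset(n_pos = 5, n_neg = 5, length_range = c(50, 80))
#' identical(do.call(gen_dataset, b$manifest), b)
#' @export
gen_dataset <- function(n_pos = 100, n_neg = 100,
                        length_range = c(50, 300), effect = 2,
                        channels = c("composition", "profile"),
                        seed = 1) {
  records <- gen_sequences(n_pos, n_neg, length_range, effect, channels,
                           seed)
  # gen_sequences seeded the stream; profiles continue it deterministically
  pssms <- lapply(records, gen_pssm, effect = effect, channels = channels)
  list(records = records, pssms = pssms,
       labels = vapply(records, `[[`, 0L, "label"),
       manifest = list(n_pos = n_pos, n_neg = n_neg,
                       length_range = length_range, effect = effect,
                       channels = channels, seed = seed))
}

#' Write a dataset bundle as FASTA + profile files + label table
#'
#' Produces the on-disk layout the command-line interface consumes:
#' `sequences.fasta`, one `pssm/<id>.pssm` per record (classic ASCII
#' layout) and `labels.tsv` (id, label).
#'
#' @param bundle a [gen_dataset()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$records, file.path(dir, "sequences.fasta"))
  for (p in bundle$pssms) {
    write_pssm(p, file.path(dir, "pssm", paste0(p$protein_id, ".pssm")))
  }
  utils::write.table(
    data.frame(id = vapply(bundle$records, `[[`, "", "id"),
               label = bundle$labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
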