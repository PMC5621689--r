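---
title: "Methods: sequence- and profile-based prediction of DNA-binding proteins"
author: "dbpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence- and profile-based prediction of DNA-binding proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbpred)
```

## The problem and the model

Whether a protein binds DNA can often be read off its sequence and its
evolutionary history. `dbpred` implements a classical machine-learning
pipeline for this binary decision: three fixed-length descriptor
blocks are computed per protein, concatenated, optionally pruned by
margin-based recursive feature elimination, and classified by an
RBF-kernel support vector machine, with leave-one-out (jackknife) or
k-fold cross-validation producing ACC, SN, SP, MCC and ROC/AUROC.

The inputs are a curated amino-acid sequence and, for the profile
blocks, an $L \times 20$ position-specific scoring matrix (PSSM): row
$i$ holds log-odds conservation scores of the 20 amino-acid types at
sequence position $i$, as produced by iterative database search
(e.g. PSI-BLAST). The package never runs the database search itself;
it consumes the standard ASCII profile format (and a bare $L \times
20$ numeric dialect, auto-detected by column count).

### Curation

Records shorter than 50 residues, or containing any character outside
the 20-letter standard alphabet, are removed before encoding.
Ambiguity codes (X, B, Z) and rare residues (U, O) are all treated as
non-standard: neither the physicochemical table nor the 20 profile
columns describe them. The length floor also guarantees that every
curated sequence supports the default lag depth and the four wavelet
halvings below.

## The three feature blocks

### Normalized Moreau–Broto autocorrelation (NMBAC), 200 features

Six physicochemical properties describe each residue: hydrophobicity
(H), side-chain volume (VSC), polarity (P1), polarizability (P2),
solvent-accessible surface area (SASA) and the net charge index of
the side chain (NCISC). Each property column is standardized to zero
mean and unit standard deviation over the 20 amino-acid types before
use; the SD divisor is 20 (population form) because the twenty values
are the complete population of residue types, not a sample. The table
ships with the package (`aa_properties()`) and can be replaced for
sensitivity studies.

For property $j$ and lag $d$ the descriptor is

$$A_{d,j} = \frac{1}{n-d} \sum_{i=1}^{n-d} X'_{i,j} X'_{i+d,j},$$

where $X'_{i,j}$ is the standardized property value of the residue at
position $i$. Lags run from 1 to `lg` (default 30, fixed by
cross-validated accuracy sweeps; see `param_sweep()`), giving
$30 \times 6 = 180$ autocorrelation values; the 20 residue
frequencies are appended for a 200-dimensional block.

Two layout choices are underdetermined by the formula and fixed here
once, because downstream selection indices depend on them: ordering
is property-major (all lags of H first), and composition comes last.
The encoder depends only on the sequence — never on identifier or
label — and is exactly invariant under sequence reversal, both of
which are asserted in the test suite.

### PSSM-DCT, 100 features

The profile is compressed with the orthonormal two-dimensional
type-II discrete cosine transform

$$C_{ij} = \alpha_i \alpha_j \sum_{m=0}^{M-1}\sum_{n=0}^{N-1}
  P_{mn} \cos\frac{\pi(2m+1)i}{2M} \cos\frac{\pi(2n+1)j}{2N},$$

with $\alpha_0 = \sqrt{1/M}$ and $\alpha_i = \sqrt{2/M}$ otherwise
(likewise over columns). Smooth structure concentrates in the
upper-left (low-frequency) corner, so the block keeps the *first* `m`
coefficients (default 100, fixed by the same sweep protocol as `lg`).
"First" is implemented as the JPEG-style zigzag traversal from the
corner, which orders coefficients by increasing spatial frequency —
the natural reading of "keep the low-frequency part". A row-major
block scan (`scan = "block"`) is available as an alternative, since
descriptor implementations differ here and the choice is not
derivable from the dimension alone. Profile values enter raw: no
sigmoid or min-max rescaling is applied (none is standard for this
descriptor family; per-matrix standardization would discard the
overall conservation level).

### PSSM-DWT, 1040 features

Each of the 20 profile columns is treated as a length-$L$ signal and
decomposed by a four-level Mallat cascade: at every level the current
approximation is convolved with a low-pass/high-pass quadrature
mirror pair and downsampled by two; the low-pass output feeds the
next level. Per column the block stores, for each level, the maximum,
minimum, mean and population SD of both the approximation and the
detail band ($4 \times 8 = 32$ values), plus the first five 1-D DCT
coefficients of each level's approximation band ($4 \times 5 = 20$) —
the high-frequency bands are noisier, so only the smooth bands
contribute cosine coefficients. That is 52 values per column, 1040 in
total, and this per-level reading of "five cosine coefficients" is
the only one consistent with that printed total.

Defaults that the dimensionality does not pin down:

* **Wavelet**: the 4-tap Daubechies orthogonal pair (`db2`) — short
  support, one vanishing moment beyond Haar, and standard in the
  protein-descriptor literature, which rarely names its filter. Haar
  is available; dimensions are filter-independent.
* **Boundary**: half-point symmetric extension (the common default;
  avoids wrap-around artifacts on profiles). A periodization mode
  exists chiefly because orthogonal filters then preserve energy
  exactly, which the tests exploit as a Parseval check. Symmetric-mode
  coefficients are cross-checked in the suite against values frozen
  from an independent wavelet implementation (PyWavelets).
* **SD**: population form, matching the property-table convention.

A length-50 signal leaves five level-4 approximation coefficients
under symmetric extension — exactly enough for the five cosine
coefficients, which is another reason the curation floor sits at 50.

## Feature selection: SVM-RFE with correlation-bias reduction

The concatenated space (order NMBAC, DCT, DWT; 1340 columns) is
ranked by recursive feature elimination: repeatedly fit a linear
maximum-margin classifier on the surviving (internally z-scored)
features, score each feature by its squared weight $w_f^2$, and
eliminate the lowest-scoring 10% (`step_fraction`). Features
eliminated later rank better.

Plain RFE is biased against correlated features: the weight that a
group of near-duplicates shares is split among them, so each member
looks individually weak even when the group is strong. The
correlation-bias reduction used here groups survivors into connected
components of the $|r| \ge 0.9$ correlation graph
(`corr_threshold`), scores every group by its *strongest* member,
and eliminates whole groups in ascending group score until the
round's quota is met. A group is thus never split: either its
evidence is bottom-ranked and the group leaves together, or all its
members are protected for that round. (If the single weakest group
alone exceeds the quota, its weakest members fill the quota so a
round always progresses.) With no correlated pairs every component is
a singleton and the procedure reduces exactly to plain SVM-RFE — an
identity the tests assert. Setting `cbr = FALSE` forces plain RFE.

Ranking hyper-parameters (10% steps, $|r| \ge 0.9$, linear cost
$C = 1$) are conventional rather than derived; all are exposed in
`rfe_control()`. Ties in scores break by original column index, so
ranking is deterministic. Constant columns cannot carry class
information and are ranked last with a warning.

Selection takes the best `k` ranked features. When a ranked list is
only needed down to some `k`, `rank_features(..., stop_at = k)` stops
eliminating there — the surviving set equals the top-`k` prefix of a
full ranking, at roughly half the fits. `sweep_k()` tabulates
accuracy against `k` for a given ranking; ties in the best `k` break
toward the smaller model.

Whether ranking is run once on all data or re-run inside every
cross-validation fold is a genuine design fork: once-on-all-data is
common practice but lets test samples influence the ranking.
`jackknife_eval()`/`cv_eval()` therefore default to within-fold
re-ranking (`selection = "within-fold"`), with
`selection = "whole"` available for comparability with the optimistic
protocol.

## Classification and evaluation

The classifier is a soft-margin SVM with RBF kernel
$K(x, x') = \exp(-\gamma\|x - x'\|^2)$, delegated to LIBSVM via
e1071. Features are standardized with training-fold statistics only;
the statistics travel with the model. Defaults are $C = 1$ and
$\gamma = 1/p$; `svm_control()` accepts log-spaced grids (the
conventional wide ranges are $C \in 2^{-5..15}$,
$\gamma \in 2^{-15..3}$) tuned by stratified inner cross-validation,
ties to the smaller $C$ then smaller $\gamma$. Inside resampling
protocols a supplied grid is resolved once on the training data and
then held fixed across folds — per-fold re-tuning is supported by
calling `train_svm()` in an outer loop, but is not the default, for
tractability.

Jackknife evaluation holds out each sample once and accumulates the
$n$ held-out predictions into one confusion matrix:

$$ACC = \frac{TP+TN}{n}, \quad SN = \frac{TP}{TP+FN}, \quad
SP = \frac{TN}{TN+FP},$$
$$MCC = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FN)(TN+FP)(TP+FP)(TN+FN)}},$$

with $MCC = 0$ by convention when any denominator factor vanishes.
ROC curves sweep a threshold over the signed SVM margins (the natural
score; class probabilities are never calibrated) and AUROC is the
trapezoidal area, which equals the Mann–Whitney pair-counting
statistic — asserted against a brute-force pair count and against
pROC in the tests.

## The synthetic data generator

Real benchmarks for this task are PDB-derived sets whose profiles
require large database searches; building and testing the package
cannot depend on those. `gen_dataset()` therefore produces labeled
bundles with controllable class signal:

* **Sequences**: negatives draw residues uniformly; positives are
  tilted by `effect` through up to two channels. The *composition*
  channel weights residues by $\exp(0.2\,e\,|H'|)$ ($H'$ =
  standardized hydrophobicity), enriching extreme-hydrophobicity
  residues — detectable by the composition and autocorrelation
  features. The *lag* channel alternates hydrophobic/hydrophilic bias
  along positions (strength $0.25\,e$), planting signal specifically
  in short-lag autocorrelation.
* **Profiles**: integer matrices of discretized Gaussian noise
  (SD 2) clipped to $[-10, 10]$ — the typical range and granularity
  of log-odds profiles — plus a $+2$ bump in each row's own residue
  column to mimic self-conservation. The *profile* channel adds a
  smooth separable cosine pattern of amplitude `effect` to positives,
  so the signal lives exactly where the DCT/DWT encoders look: in the
  low spatial frequencies.

The tilt constants (0.2, 0.25) were calibrated once so that
`effect = 2` is a moderate problem (composition-only jackknife
accuracy near 0.8 at $n = 200$) and `effect = 3` a strong one
(≥ 0.85), then frozen; tests never adjust them. `effect = 0` makes
the classes exchangeable by construction.

What the generator does *not* emulate: homology structure between
records, realistic binding motifs, the coupling between a real
sequence and its evolutionary profile, and database-search artifacts.
Passing tests therefore demonstrate that the machinery recovers
signal of the kinds the encoders target and reports chance under the
null — not that any particular accuracy will be attained on real
benchmark sets.

## Numerical and scale choices in the test suite

The suite verifies the end-to-end property — encode, select within
fold, jackknife — at sizes chosen to keep a full run in minutes on
one core: the signal case uses 120 proteins at `effect = 2`
(accuracy ≥ 0.9 expected; larger n only makes this easier) and the
null band uses ten reseeds of 60 proteins (mean accuracy in
[0.4, 0.6]). Leave-one-out with within-fold selection is the
costliest protocol in the package — each of $n$ folds re-runs the
full elimination ladder — which is why the null replicates use the
smaller $n$; well below $n \approx 50$ the protocol itself becomes
anti-conservative (with $p \gg n$ the held-out sample is always the
training minority class's complement, pushing null accuracy below
chance), so 60 is about as small as an honest null check can go.

Other conventions: degenerate inputs error early with the offending
record or line named; all generators and protocols are deterministic
given their seeds; encoders are pure functions of their inputs
(bit-identical on repeat calls).

## Known limitations

* Sequence-identity de-duplication of datasets (e.g. a 25% identity
  ceiling) is out of scope; it requires external clustering tools.
* Profiles must be precomputed; the package does not drive PSI-BLAST.
* Only binary classification; no probability calibration.
* The wavelet filter and DCT coefficient ordering used by other
  implementations of these descriptors vary and are rarely reported;
  results are comparable across this package's runs, not necessarily
  across implementations.
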