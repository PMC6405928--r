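---
title: "premirscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{premirscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Mature microRNAs (20–24 nt) are excised from ~70–120 nt stem-loop
precursors (pre-miRNAs).  Because miRNA expression is tissue- and
time-specific, sequencing-based discovery under-samples the repertoire, and
conservation-based prediction misses both very old and very young miRNA
genes — a particular problem in allopolyploid genomes such as bread wheat,
whose A, B and D subgenomes diverged on very different time scales.  The
species-specific alternative is to train a classifier on the target
species' own miRNAs and scan the genome for precursor-like hairpins.
`premirscan` implements that workflow end to end: homology-seeded candidate
generation, hairpin screening, structural/thermodynamic feature extraction,
class-weighted kernel SVM classification, cross-validated evaluation, and
computational validation operators (miRNA* detection, exact read-library
matching, homology lookup).

# Pipeline and parameters

1. **Homology seeding** (`scan_homology`).  Known mature miRNAs are matched
   against the genome with an exact-word index (word length 7) and ungapped
   full-coverage extension.  Placements with at most 4 mismatches are kept
   — i.e. "fewer than 5" — and at most the 10 best hits per query are
   retained, ordered by (mismatches, −score, coordinate).  The permissive
   E-value cutoff of the original BLASTN stage (E ≤ 10) is honoured by
   construction: at word length 7 and ≤4 mismatches over a 17–30-nt query,
   every retained hit is far below that threshold, so no Karlin–Altschul
   statistics are computed.  A seed word can in principle be destroyed by
   ≥3 mismatches in a 21-mer (pigeonhole guarantees survival only up to 2);
   `exhaustive = TRUE` scans every offset instead.
2. **Windows** (`extract_flanked_locus`, `fragment_locus`).  500 nt of 5′
   and 3′ flank are taken around each hit (clipped at contig ends), then
   fragmented into sliding windows of 90/100/110/120 nt at step 10.  The
   published description says both "no overlap" and "step of 10"; only the
   sliding reading reproduces the window-count arithmetic
   ((L − w)/step + 1), so that is what is implemented.
3. **Folding and screening** (`fold_rna`, `hairpin_metrics`,
   `passes_filter`).  Windows are folded (see below) and kept when the
   longest bridged stem carries 20–50 base pairs, GC content is 24–82 %,
   the folding energy is between −60 and −20 kcal/mol (all inclusive — the
   only non-empty reading of the published ranges), and the structure forms
   a single hairpin.  "Stem length" is interpreted as base pairs in the
   longest chain of helices whose interruptions are at most 3 nt on either
   strand: under a nucleotide reading, 20–50 could not be satisfied
   together with a terminal loop inside a 90-nt window.
4. **Features** (`feature_catalog`, `compute_features`).  133 features in
   five families: mono-/di-/tri-nucleotide frequencies and GC% (COMP),
   32 paired/unpaired triplet elements (TRIPLET), MFE with AMFE =
   100·MFE/L and MFEI1–4 (MFE_DERIVED), hairpin topology counts
   (TOPOLOGY), and per-length topology (NORMALIZED).  The original tool
   computed 152 features whose exact list is not printed; this catalog is
   an explicit, documented reconstruction of the same families, and a user
   holding the original list can register it instead (the catalog is
   ordinary data with a hash that models verify before scoring).
5. **Feature selection** (`select_features`).  The published pipeline kept
   the 107 of 152 features "found to be significant" without naming the
   test; a two-sided Mann–Whitney U per feature with Benjamini–Hochberg
   control at FDR 0.05 is used by default (distribution-free, matches the
   mixed continuous/discrete feature types); Welch's t is available.
6. **Classification** (`svm_train`, `svm_decision`).  Soft-margin kernel
   SVM with the published SVMlight settings mapped as g→γ = 1e−4, c→C = 5,
   j→positive-class cost factor = 3, t = 2→RBF.  The dual QP (box
   constraints 0 ≤ α ≤ C·j for positives, C for negatives; Σαy = 0) is
   solved with `quadprog`; kernels, weighting, scaling, the positive-score
   decision rule and JSON persistence are owned by the package.  Windows
   with strictly positive decision value are reported.

# The folding backend

ViennaRNA is not a dependency.  `fold_rna` exposes four backends:

* **reference** (default): a dynamic program over nested structures with
  canonical pairs (GC/AU/GU), minimum hairpin loop 3 nt and no lonely pairs
  (helices carry ≥ 2 stacked pairs), minimising a simple stacking energy.
  Each stack contributes minus the mean of its two pair weights (GC 1.8,
  AU 1.0, GU 0.6 kcal/mol) and each hairpin loop costs +3 kcal/mol
  (a Turner-scale initiation penalty).  Two calibration points anchor the
  scale: a 30-bp, 50 %-GC stem scores ≈ −38 kcal/mol, the magnitude
  thermodynamic folding reports for plant precursors, and the +3 loop
  penalty means an isolated 2-stack hairpin in random flank sequence is
  usually unfavourable — without it, maximum-pairing-style structures
  sprout marginal side hairpins that no physical model would predict.
* **maxpair**: the same DP maximising raw base-pair count (the classical
  Nussinov objective), kept as an oracle surface for tests.
* **rnafold**: shells out to an `RNAfold` binary when one is on the PATH;
  otherwise it raises an error that points at fixture mode.
* **fixture**: looks sequences up in a recorded (id, seq, dot-bracket,
  mfe) table, for tests that need exact recorded energies.

The reference backend is deterministic, and its traceback prefers the
outermost, longest helix so that equal-score structures resolve to the
nested single-hairpin form.

# Feature scaling

Features are min–max scaled **to [0, 100]** on the training fold only (the
scaler is stored in the model and applied, never refitted, to new data).
[0, 1] scaling was tried first and rejected for cause: with γ = 1e−4 every
RBF kernel entry on [0, 1]-scaled inputs equals 1 − O(1e−4), the Gram
matrix is numerically constant, and with the positive-class cost factor
j = 3 the dual optimum collapses to an all-positive classifier.  An RBF
kernel needs squared distances of order 1/γ; the [0, 100] (percent-like)
range restores that while preserving the boundedness rationale.

# The synthetic world

`make_genome` plants `n_precursors = 20` perfect-duplex hairpins (arms
20–40 bp, loops 4–15 nt, GC target 40–60 %) and 10 decoys (alternating
dinucleotide-shuffled hairpins and ORF-like stretches) in 50 kb of uniform
iid background, with 150-nt clearance between inserts.  Each precursor's
21-nt 5′-arm mature is emitted as the known-miRNA query set, so the
homology stage is exercised honestly.  Negative training examples come from
synthetic coding sequence (ATG + random sense codons) with embedded
*pseudo-hairpins*: inverted repeats whose 3′ arm carries ~12 % scattered
substitutions (spaced ≥ 5 nt so single mismatches stay bridgeable) — they
pass the stem/GC/MFE screen the way the published CDS-derived negative set
does, but are imperfect duplexes.

What the generator does **not** emulate: genomic base composition and
repeat structure (background is uniform iid; a 2nd-order option would give
harder negatives), sequencing error, multi-locus miRNA families,
polyploid homoeologs, and real thermodynamic energies (the reference
backend is a calibrated stand-in).  A green end-to-end test therefore
establishes that the pipeline machinery recovers planted signal under its
own stated world — not that wheat-scale accuracy transfers.

# Numerical and procedural choices

* Coordinates are 0-based half-open everywhere internally; GFF3 (1-based
  inclusive) and BED (0-based half-open) conversion happens only in the
  writers.
* Ties in ROC curves are grouped per distinct score, yielding diagonal
  segments — exactly the mid-rank Mann–Whitney convention, which the tests
  verify to 1e−12.
* 0/0 metric ratios are reported as 0 with an `undefined` flag instead of
  erroring, so batch reports stay total.
* Cross-validation folds are stratified (the published "randomly divided"
  on a balanced 439/439 design is near-stratified anyway, and
  stratification prevents degenerate single-class folds at small n); the
  "±" in summaries is the across-fold standard deviation, labelled as
  such.
* Scaling of held-out data never updates the scaler; models refuse to
  score feature vectors whose catalog hash differs from training.
* The mature/star duplex rule quantifies "permissible gap and penalty" as
  at most 4 unpaired positions inside the duplex and a fixed 2-nt 3′
  overhang (the Dicer convention); both are arguments of `find_star`.
* The dual QP adds a 1e−6-scale ridge to the Gram diagonal (duplicate
  training rows make kernel matrices singular) and escalates it only if
  the Cholesky fails; the bias is taken from free support vectors when any
  exist, otherwise as the midpoint of the KKT-feasible interval.

# Known limitations

* The homology engine is ungapped by design; indel-containing homologs are
  out of reach (the published mismatch rule is only well-defined ungapped).
* The reference folding backend is a calibrated toy: adequate for
  screening logic and planted-truth recovery, not for publication-grade
  energies.  Use the `rnafold` backend where ViennaRNA is installed.
* The 152-feature list and the significance procedure of the original
  pipeline are not public; the reconstruction here preserves the families
  and the 152→107-style selection shape, not the exact list.
* Genome-scale wheat runs (17 Gb) and the published prediction counts are
  out of scope; the toolkit targets contig-scale scans and synthetic
  validation.
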