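---
title: "Peptide-centric DIA analysis with deep chromatogram representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peptide-centric DIA analysis with deep chromatogram representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Data-independent acquisition (DIA) fragments everything inside wide
precursor isolation windows on every cycle, so MS2 spectra are highly
multiplexed and cannot be interpreted spectrum by spectrum. Peptide-centric
scoring inverts the problem: for every precursor in a spectral library, the
engine extracts ion chromatograms (XICs) around its expected fragment and
precursor masses, asks whether a coherent co-eluting peak group exists, and
controls errors with in-silico decoys. `diasense` implements this workflow
end to end — library handling, decoy generation, XIC extraction, a
recurrent neural scoring model, retention-time (RT) calibration,
positive-unlabeled (PU) rescoring, target-decoy FDR control and
correlation-weighted quantification — together with a synthetic DIA
generator that provides ground truth for every stage.

# The representative spectral matrix

The unit of evidence is the representative spectral matrix (RSM): 170 XICs
over a 12-cycle window centered on a candidate RT location, in eight row
blocks.

| block | rows | contents |
|---|---|---|
| `library_r` | 20 | top-20 library fragments by library intensity, extracted at the basic resolution `r` |
| `library_02r` | 20 | same fragments at `0.2 r` |
| `library_045r` | 20 | same fragments at `0.45 r` |
| `self` | 50 | all theoretical b/y ions of the precursor |
| `qt3` | 10 | unfragmented precursor and its M+1..M+4 isotopes in MS2 |
| `ms1` | 10 | precursor at all three resolutions, M+1..M+4 and M-1 in MS1 |
| `iso` | 20 | (M+1)/q isotope of each library fragment |
| `light` | 20 | (M-1)/q light isotopologue of each library fragment |

Rows at the basic resolution are sorted by the sum of their Pearson
correlations with the other library rows (computed over the window,
self-pairing excluded); the narrower resolutions, `iso` and `light` follow
that order row for row, so row *i* of each aligned block always refers to
the same fragment. `self` rows are sorted by correlation with the first
library row. Zero-variance rows take correlation 0 by convention, which
parks zero-filled padding rows deterministically at the end of each sort;
remaining ties keep the original index order. Windows clipped at the run
edge are zero-padded rather than re-centered, so a peak apex always sits at
the same column.

Two quiet constants deserve a note. The theoretical b/y enumeration uses
fragment charge {1} for precursors of charge ≤ 2 and {1, 2} above, with
monoisotopic residue masses and a proton of 1.007276 Da. Isotope spacing is
implemented as the ¹³C–¹²C mass difference (1.0033548 Da) divided by
charge; the synthetic generator emits its isotope envelopes with the same
constant, so extraction and simulation agree to within the ppm tolerance.

The `qt3` and `ms1` blocks enumerate 5 and 8 chromatograms respectively and
are zero-padded to 10 rows each. This is the only reading under which the
block total reaches 170 and stepwise part exclusion reproduces the row
series 150/130/120/110/60/40/20; the padded rows carry no information and
the model learns to ignore them.

The basic resolution defaults to 30 ppm, a realistic half-width for
TOF-class centroided data; the two extra "resolutions" are implemented as
narrower windows (6 and 13.5 ppm) at the same centers, which is what makes
the narrow rows a strict subset of the wide rows' intensity.

# The representation model

The RSM is consumed along its cycle axis by two stacked LSTM layers (128
and 64 units, input dropout 0.4, recurrent dropout 0.3 — one mask per
sequence, shared across time steps) followed by a 16-unit ReLU layer and a
single sigmoid unit. The 16 penultimate activations are the *deep
representation features*; the sigmoid output is the *deep discriminant
score* (dds), a probability-like score that the window contains a real
co-eluting peak group. Training minimizes binary cross-entropy between
targets (1) and decoys (0).

No deep-learning framework is a dependency: the network, including
backpropagation through time and Adam, is implemented in vectorized base R
(gradients are verified against finite differences in the test suite), with
an Rcpp/Armadillo fast path for inference that is bit-identical to the R
reference. Choices the architecture left open, decided here once:

* optimizer Adam, learning rate `1e-3`, batch 256, early stopping on
  validation loss with patience 10;
* the train/validation split is 7:3 *by precursor*, so no precursor
  contributes windows to both sides;
* each RSM is normalized by its global maximum before entering the model
  (idempotent, all-zero matrices pass through unchanged);
* inputs are oriented time-major: 12 steps of 170 channels.

The shipped workflow trains this model on synthetic experiments
(`generate_rsm_training_set` assembles balanced target/decoy RSMs through
the real extraction code, never by shortcut synthesis). At the study sizes
used in the tests — 2,000 RSMs, 10 epochs — training takes well under a
minute on one CPU and reaches held-out AUC above 0.99.

# RT calibration

A seeded sample of library targets (default 500) is scanned across the
whole gradient at stride 1; each precursor's anchor is the cycle with
maximal dds, and anchors below dds 0.5 are discarded as likely absent. The
anchor set then fits either a linear model by RANSAC (minimal two-point
samples, 100 iterations, inlier threshold 2.5 × MAD of a preliminary
least-squares fit, followed by up to three rounds of refit-and-reselect
refinement, final OLS refit on the consensus set) or a nonlinear LOWESS
curve (span 0.3, two robustness iterations, points beyond 3 × MAD of the
smoothed curve removed before a refit). Linear models extrapolate beyond
the anchor range; LOWESS predictions clamp at the boundaries. Predictions
map library RT to seconds and then to the nearest cycle.

# Candidates, PU rescoring and FDR

Every library precursor (and its decoy) is scanned over ±25 cycles around
its predicted RT; windows with dds ≥ 0.5 become candidates, and a
precursor whose windows all fail the threshold keeps its single max-dds
window so that every precursor remains scoreable. Each candidate carries
the dds, the 16 deep features, and six auxiliary features: precursor m/z,
charge, peptide length, |candidate − predicted RT| in cycles, log library
block intensity, and the count of non-zero library rows.

A run-specific classifier — XGBoost (depth 6) by default, or a
200-tree random forest of depth 12 — is trained with decoys as confirmed
negatives and targets as the unlabeled positive class. By default the
candidates are split into two folds by precursor and each fold is scored
by the model trained on the other; this removes the self-scoring optimism
a single-pass scheme shows on small runs. The best-scoring candidate per
precursor (ties: smaller RT deviation, then earlier cycle) enters FDR
estimation.

FDR at cutoff c is estimated as π₀ · #{decoys ≥ c} / #{targets ≥ c},
monotonized into q-values. The π₀ factor corrects for the fact that the
library contains one decoy per *target* while only the absent fraction of
targets can generate false identifications; it is estimated as the
target/decoy count ratio below the 90th percentile of the decoy score
distribution — a region covering nearly the whole decoy null while staying
under genuine identifications, so that any leakage of true positives
inflates π₀ and errs conservative — and clamped to [0.01, 1]. Setting `pi0 = 1`
recovers the plain (conservative) decoys/targets estimator. Protein-level
q-values group results by protein, score each protein by its best member
and reuse the same estimator.

On synthetic experiments with 2,000 library precursors of which 30% are
planted absentees, the realized false-target fraction tracks the reported
q-value within the ±50% relative band at q = 0.01, 0.05 and 0.10 (three
seeds). The residual tail anti-conservatism (~1.2× at q = 0.1) has a real
cause worth knowing about: absent targets are genuine tryptic sequences
that share low-index y-ion masses with co-eluting peptides far more often
than shuffled decoys do, so decoys slightly understate the false-target
tail. This is a property of sequence-shuffled decoys generally, not of the
synthetic data.

# Quantification

A precursor quantity is the correlation-weighted area of its top library
fragments (at most six, taken in the correlation-sum order of the library
block): Q = Σᵢ Σⱼ Corr(Cᵢ, Cⱼ) · Area(Cᵢ), with the self-pair (i = j,
Corr = 1) included and negative weights allowed — the double sum is
implemented exactly as stated, not with the self-pair excluded, and is
checked against a literal double-loop oracle to 10⁻⁹ relative error.
Areas are trapezoidal integrals over the fixed 12-cycle window using
per-cycle RT spacing in seconds; no peak-boundary detection is attempted.
An optional mode adds the top 3–15 self fragments, each weighted by its
correlation with the first library row. Protein quantities are the sum of
the top three precursor quantities.

# The synthetic generator

`generate_experiment` emulates what the scoring model assumes about real
DIA data: cycle-structured MS1 + 64 fixed-width isolation windows over
400–1200 Th; Gaussian elution peaks (σ = 4 s ± 20% per precursor,
3 s cycles, 120 cycles) whose apexes follow a known linear library-RT map
(seconds = 3 × RT + 30); fragment heights proportional to library
intensities times a log-normal abundance; MS1 isotope envelopes; fragment
M+1 isotopes at 30%; co-eluting interference peptides (10% of the library
size) with independent apexes; a sparse exponential noise floor (~1% of
the median fragment apex — a high-SNR regime); and 2 ppm centroid jitter.
A configurable fraction of library precursors is simply never emitted.
Runs are written as standard mzML or mzXML through `mzR` and read back by
the same loader used for real files.

What it deliberately does not emulate: detector saturation, charge-state
cross-talk, profile-mode peak shapes, dynamic exclusion artifacts, or
retention-time drift nonlinearity. Passing tests therefore demonstrate
that the machinery is correct and calibrated under the stated statistical
structure, not that identification rates on real instrument data will
match.

Two-condition mode reuses identical peptides, presence and base abundances
across two runs and multiplies per-group fold changes into condition 2,
which is what makes exact ratio-recovery tests possible.

# Benchmarks

The two-species utilities reproduce the proxy-FDR validation design:
foreign precursors filtered for sequence overlap, spiked in at exactly the
sample-library count, all entries truncated to their six most intense
fragments; the proxy FDR at a cutoff is foreign-above / all-above. In the
calibration tests the generator's planted absentees play the role of the
foreign species — the estimator only needs the labels.

The deamidation confidence test analyzes one run twice with identical
settings: once with the true deamidation shift (0.9840 Da) and once with a
pseudo-shift library in which every deamidation-bearing ion is moved by
N × (1.0227 − 0.9840)/C. Counts at matched q ≤ 0.01 barely separate the
two analyses here, for a structural reason: a pseudo-shifted entry keeps
every fragment that does not span the modified residue, plus most of its
MS1 evidence, so it still outranks all decoys. The representation score
exposes the difference sharply — confident elution profiles (dds ≥ 0.8)
are at least five-fold rarer under the pseudo shift — so the benchmark
reports both the q-level counts and the per-precursor dds of both
analyses.

# Problem sizes and numerical choices

The test suite trains the full 128/64 architecture on 2,000 RSMs for 10
epochs, runs three independent 2,000-precursor calibration analyses, and
recovers planted log2 ratios {0, 1, −2} on a 600-precursor two-condition
experiment — sizes chosen so the whole suite exercises study-scale
statistics in minutes on a single CPU. Degenerate inputs are defined, not
special-cased: all-zero RSMs normalize to themselves and embed to finite
features; all-zero fragment sets quantify to Q = 0 with a warning;
homopolymer sequences that cannot be shuffled into a distinct decoy are
skipped with a warning after 10 re-draws. Extraction sums all centroid
peaks inside the tolerance window (robust to centroid splitting, and
required for the conservation property that disjoint bins sum to the
spectrum total).

# Known limitations

* Decoys inherit their target's precursor m/z (composition-preserving
  transforms), so their MS1 evidence is not a perfect null for absent
  targets; see the FDR section.
* Only b/y series are enumerated for the self block; a/x ions and neutral
  losses are out of scope.
* Quantities are single-run; no cross-run normalization or alignment.
* The bundled modification table covers carbamidomethyl, oxidation,
  deamidation and N-terminal acetyl; other UniMod accessions raise an
  error naming the tag.
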