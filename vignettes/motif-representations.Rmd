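---
title: "How max-pooling geometry shapes the motifs CNN filters learn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How max-pooling geometry shapes the motifs CNN filters learn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Convolutional networks trained on regulatory DNA are routinely
"interpreted" by converting first-layer filters into sequence logos and
comparing them against motif databases. Whether that is meaningful
depends on *where* in the network motif representations live. If the
architecture lets deeper layers assemble partial patterns into whole
motifs (a *distributed* representation), first-layer filters have no
reason to contain complete motifs, and their logos are uninformative.
If the architecture makes that assembly impossible — most directly by
max-pooling away the spatial information that assembly requires — whole
motifs must be learned by single first-layer filters (a *localist*
representation) for the classifier to work at all.

`motifrep` provides a controlled test bed for this question: a
synthetic multi-label classification task with exact ground truth, a
family of CNNs that differ only in max-pool and filter geometry, an
activation-alignment procedure that turns trained filters into
position probability matrices (PPMs), and a Tomtom-style comparison
that scores each PPM against the ground-truth motifs.

## The synthetic task

`generate_dataset()` draws sequences of 200 nt with i.i.d. uniform
background. For each sequence, `k` motif sites (`k` uniform on 1–5) are
sampled *with replacement* from a pool of 24 strand-motifs (12
transcription factors and their reverse complements) and embedded with
at least 1 nt of clearance from each other and from the sequence ends.
Each site is itself sampled column-by-column from the motif's PWM, so
sites carry realistic variability. The label is a 12-bit vector, one
bit per TF, set when that TF's motif was embedded on either strand.
Motif-like strings arising by chance in the background are *not*
labelled; as in real ChIP-derived data this introduces a small
false-negative label noise. Sequences are split 0.7/0.1/0.2 into
train/validation/test by a seeded permutation.

The 12 bundled PWMs (`default_motif_pool()`) are constructed stand-ins,
not database downloads: their names, widths (6–16 nt) and consensus
sequences mirror the JASPAR vertebrate entries for Arid3, CEBPB, FOSL1,
Gabpa, MEF2A, MAFK, MAX, NFYB, SP1, SRF, STAT1 and YY1, with
information content tapering toward the edges (core positions ~1.6
bits, soft flanks ~0.2 bits) as in curated PFMs. The width distribution
matters scientifically: several motifs (15–16 nt) approach the 19-nt
first-layer filter size, so capturing a whole motif in one filter is
genuinely demanding, and partial-motif strategies are competitive —
the regime the architecture contrast probes. Motif count per sequence,
background composition and split fractions are fixed study conditions,
not tuning knobs.

```{r}
library(motifrep)
pool <- default_motif_pool()
dataset <- generate_dataset(pool, n_sequences = 10000, seed = 0)
autoplot(pool$motifs[[1]])   # logo of the first ground-truth motif
```

## The model family

Every network shares one backbone: one-hot DNA in; convolution blocks
of cross-correlation (stride 1, "same" zero-padding) → batch
normalization → ReLU → max-pool → dropout 0.1; a 512-unit dense ReLU
layer with dropout 0.5; 12 sigmoid outputs. The base geometry is 30
filters of size 19 in layer 1 and 128 of size 5 in layer 2. Variants
(`cnn_variant()`) alter only pooling and filter sizes:

* **Coupled pools** `CNN-1` … `CNN-100`: pool sizes multiply to 100,
  so the dense layer always sees 2 × 128 inputs and every coupled
  variant has exactly the same parameter count (asserted in the test
  suite). `CNN-25` (pools 25/4) is the prototypical localist design;
  `CNN-1`/`CNN-2` are the distributed designs.
* `CNN_9-4`, `CNN_9-25`, `CNN_3-2`, `CNN_3-50`: smaller first-layer
  filters (9 or 3 nt).
* `CNN-50-2`: pool window 50 with stride 2 — overlapping receptive
  fields with large spatial uncertainty.
* `CNN_19-1_-2`: second-layer filter size 1, removing assembly
  capacity without touching pooling.
* `CNN-1-1-100`: three conv layers with the only pooling (size 100)
  after layer 3, pushing the spatial bottleneck one layer deeper.

Training (`train_cnn()`) follows a fixed protocol: Adam with constant
learning rate 3e-4 and default moment parameters, mini-batches of 100,
binary cross-entropy, L2 strength 1e-6 on weight matrices, He
initialization, and early stopping by checkpoint selection — the
returned parameters are those of the epoch with the lowest validation
loss. Training is exactly reproducible from a seed on a fixed BLAS.

The numerical engine is the package's own RcppArmadillo code. The
convolutions run in single precision as shifted GEMMs over a
zero-padded slab (each sequence occupies `L + 2·pad` columns with
zeroed borders, so shifted column ranges implement "same" padding
without an im2col copy), with a specialized gather/scatter path for the
one-hot first layer. Gradients of the fused blocks agree with a
double-precision reference implementation to single-precision rounding,
and that reference was itself verified against central finite
differences. One analytic consequence of the architecture: the
convolution bias is followed immediately by batch normalization, which
subtracts any constant — its gradient is exactly zero and the bias
stays at its initialization. Batch-norm uses eps 1e-5 and
running-statistics momentum 0.9; pooling windows are clipped at the
right edge (output length `ceil(L / stride)`); pooling ties take the
leftmost position.

## From filters to motifs

`scan_activations()` runs the network in evaluation mode and records,
per filter and sequence, the maximum post-ReLU activation and its
position. `build_ppm()` implements the alignment procedure: sequences
whose maximum is below 70% of the filter's maximum achievable
activation are discarded; from each survivor the receptive-field-sized
subsequence aligned at the maximum is extracted (windows overrunning a
sequence end are dropped); base counts are normalized into a PPM.
"Maximum achievable" is by default the empirical maximum over the
scanned set; an analytic mode (batch-norm folded into the weights, sum
of per-position maxima over one-hot inputs) is selectable and gives an
upper bound. Logos use letter heights `p · IC` with
`IC = 2 + Σ p log2 p` bits per column.

Deeper layers can be visualized the same way *only* when no pooling
precedes them, because pooling breaks the correspondence between
feature-map position and sequence position; `scan_activations()`
refuses otherwise. For `CNN-1` the second layer (receptive field 23 nt)
and for `CNN-1-1-100` the third (27 nt) are valid.

`match_report()` scores each non-empty PPM against all 24 strand-motifs
by sliding it over each target (minimum overlap 4 columns) and summing
column-wise Pearson correlations; zero-variance columns contribute
nothing. Significance comes from a permutation null — by default 1,000
column-shuffles of the query, best-over-offsets — scaled into an
E-value and thresholded at 0.1. The scaling factor is the
multiple-testing burden of the search the E-value is meant to mimic:
by default the size of the pool actually scored (24), but the
headline match fractions of the original study were determined by a
Tomtom search of the full JASPAR 2016 vertebrate collection, so the
experiment pipeline and the acceptance script set `n_database = 519`
(with 20,000 shuffles so the permutation p-values can resolve
`0.1 / 519`). The choice matters scientifically: at pool-size scaling
a clean five-column partial motif reaches significance, while at
database scaling only near-complete motifs do — the stringency under
which "distributed" first-layer filters score near zero. Under the
database-scale configuration the matcher is well calibrated on
filter-width inputs: an exact whole-motif copy centered in a 19-column
PPM matches its source for all 24 strand-motifs, and none of 200
column-shuffled decoys reaches significance. A second null
(`null_model = "database"`, columns drawn from the pool's own column
collection, the analogue of Tomtom's database-derived null) is
available for bare, short, repetitive motifs — e.g. the 6-bp AT-rich
Arid3 matrix, whose column shuffles are near-automorphic and therefore
invisible to the shuffle null. This is a deliberate
stand-in for Tomtom (which is available through `run_tomtom()` when the
MEME suite is installed): on this 24-target pool it has unit
sensitivity for exact motif copies and a decoy false-positive rate
below 5% (asserted in the tests). Two behaviours deserve note. First,
a *clean* sub-motif of five or more informative columns generally
reaches E ≤ 0.1 — partial representations are only "unmatchable" when
they are noisy mixtures, which is exactly what converged distributed
filters look like. Second, because surviving subsequences come from
real motif instances, the PPM of a partial-motif filter can absorb
consistent flanking motif context and appear more complete than the
filter's weights; the match fraction is therefore a property of the
alignment-PPM pipeline, as in the original procedure, not of the raw
weights. Ties between targets break by smaller E-value, then larger
overlap, then name.

## Desk-scale protocol and what it shows

Full replication — 25,000 sequences, 100 epochs (17,500 Adam steps),
five trials for each of 16 variants — is days of single-core CPU time.
The package therefore fixes two reduced protocols, chosen by compute
budget:

* The test suite's contrast check trains CNN-2, CNN-25, CNN_3-2 and
  CNN_3-50 on 10,000 sequences for 30 epochs each.
* `scripts/acceptance.R` trains one model per reported quantity on
  10,000 sequences, each within a wall-clock budget proportioned to its
  per-step cost (220 s for CNN-25, capped at the protocol's 100 epochs,
  down to 70–90 s for the heaviest variants) so the full set fits a
  single desktop-CPU session; on faster hardware the same budgets buy
  more epochs.

Under this training protocol the optimization has a long
plateau: filters discover motifs gradually, and both classification
AU-ROC and the matched-filter fraction rise steadily toward their
full-protocol values over roughly the full 17,500-step budget (the
effective learning rate of a batch-normalized layer scales inversely
with its weight norm, so He-initialized layers move slowly at a
constant 3e-4). A 2,000–10,000-step budget therefore lands *en route*:
the localist designs already show high ground-truth match fractions,
while AU-ROC and the match fractions of expensive variants remain
below their converged values. Reduced-scale numbers are best read as
lower bounds with the correct ordering between architectures, not as
estimates of the full-protocol values.

What passing desk-scale tests do show: the generator's ground truth and
invariants; exact agreement of the metrics and the information-content
formula with closed forms; the matcher's calibration; and the
directional architecture effects. What they cannot show: the converged
magnitudes of slowly-converging quantities, agreement with a real
Tomtom/JASPAR-database comparison (no database is bundled), or anything
about in vivo sequence complexity — the generator has uniform base
composition, no repeats, no GC structure and a single PWM per TF.

## Known limitations

* The bundled PWMs are synthetic stand-ins; identity-level conclusions
  about specific TFs should use real JASPAR matrices via
  `load_motifs()`.
* The permutation-null matcher is not Tomtom; E-values are comparable
  in spirit, not in value. Database-wide match fractions (the "any
  JASPAR motif" column of the original study) require the external
  Tomtom pathway.
* Single-precision training is deterministic for a fixed seed and
  BLAS, but bitwise results may differ across BLAS builds.
* The reduced budgets truncate optimization; quantities reported at
  desk scale systematically undershoot full-protocol values for the
  expensive variants.
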