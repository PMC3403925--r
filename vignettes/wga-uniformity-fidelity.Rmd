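---
title: "Assessing uniformity and fidelity of whole-genome-amplified DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing uniformity and fidelity of whole-genome-amplified DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multiple displacement amplification (MDA) turns nanograms of genomic DNA
into micrograms by isothermal strand displacement with Φ29 polymerase.
Before such material can stand in for the native DNA -- in array analyses,
copy-number assays, or mutation testing -- two questions must be answered:

* **Uniformity**: does every genomic locus come out at (close to) its input
  copy number, or are some regions systematically over- or under-amplified?
* **Fidelity**: does the polymerase introduce detectable point mutations?

`mdaqc` implements the analysis stack for answering both with two-channel
array-CGH probe ratios, qPCR copy-number assays, and bidirectional Sanger
concordance, plus a synthetic-data generator so that the entire pipeline is
testable without array data.

## The measurement model

A hybridization compares amplified (test) against unamplified (reference)
DNA.  For probe $i$ the readout is the log ratio
$r_i = \log_2(T_i / R_i)$, zero when amplification preserved copy number.
After a single global (median) normalization -- the stand-in for linear dye
normalization; no spatial or intensity-dependent correction is attempted --
the analysis proceeds on four axes:

1. **Per-array noise.** The derivative log-ratio spread (DLRS) estimates the
   per-probe noise sd from consecutive-probe differences within
   chromosomes.  The estimator is the IQR of those differences divided by
   $1.349\sqrt 2$: 1.349 converts an IQR to an sd under normality, and
   $\sqrt 2$ undoes the variance doubling of differencing.  The quantity is
   standard; the robust estimator is this package's choice, since only the
   name and magnitude (self-self floor $\approx 0.165$) are fixed by
   convention.
2. **Segmentation.** Circular binary segmentation (CBS) partitions each
   chromosome into constant-mean segments.  The arc of probes maximizing
   the standardized mean difference against its circular complement is
   found (exhaustively up to `max_exact` probes, by arc sampling above);
   the split is kept when a within-window permutation p-value falls below
   `alpha`.  Defaults: `alpha = 0.01`, `n_permutations = 1000` in
   `cbs_segment()` (studies default to 200 to keep 28-array runs fast),
   `min_width = 2`, undo threshold 1 noise-sd.  None of these are fixed by
   convention upstream; they are chosen so that small exhaustive searches
   are exact and pure-noise profiles split at about the nominal rate (both
   properties are tested).  Ties in the maximizing arc break toward the
   leftmost start, then the shortest arc, for reproducibility.
3. **Consistency statistics.** The Kolmogorov distance
   $\sup_x |F_a(x) - F_b(x)|$ between two arrays' ratio distributions (the
   two-sample KS statistic, no p-value; right-continuous ECDFs, supremum
   attained at pooled sample points) measures how alike two amplifications
   are overall.  The Phi correlation of two binary CNV-location vectors --
   probes whose *smoothed* fold change $2^{|r|}$ exceeds 2 -- measures
   whether copy-number changes sit in the same places; it equals the
   Pearson correlation of the 0/1 vectors.  Within a replicate group of 4,
   the group median is taken over the 6 unique unordered pairs; between two
   groups, over all 16 ordered cells.  Both conventions were validated
   against independently published pairwise tables (one published
   within-group median, 0.085 where the printed cells give 0.0635, is
   inconsistent with its own cells under any ordering convention and is
   treated as a typesetting artifact; the other seven blocks validate).
4. **Threshold and region reporting.**  "Ratio > k" is read
   direction-agnostically as $2^{|r|} > k$, because over- and
   under-amplification are counted together; `threshold_table()` has a
   `one_sided` switch for the alternative reading.  Threshold tables are
   computed on raw per-probe ratios by default (the smoothed variant is a
   flag away): the published Phi tables say "after CBS smoothing" while the
   threshold tables do not.  Aberrant regions are maximal runs of at least
   3 consecutive probes beyond 3-fold on the segment-smoothed profile;
   replicates are combined before reporting with weights proportional to
   $1/\mathrm{DLRS}^2$ (the quality metric behind published
   "weight proportional to quality" combination is unstated; inverse
   variance from the array's own noise estimate is this package's
   stand-in).  Consistently under-amplified regions are the base-pair
   intersection of per-group region sets across all samples and kits;
   `genome_fraction()` takes chromosome lengths as explicit input rather
   than assuming a genome build.

The qPCR arm uses the comparative-Ct model with efficiency fixed at 2
(perfect doubling, the assumption behind vendor copy-number callers;
configurable for sensitivity analysis): $CN = 2 \cdot 2^{-\Delta\Delta
C_t}$ against the unamplified calibrator, replicates summarized at the CN
scale (mean with min/max bars), and a flag when any replicate deviates more
than 2-fold from the calibrator.

The fidelity arm classifies each pre-aligned position of a
forward/reverse Sanger call pair against the unamplified reference:
no-call ('N' on either strand) and strand-discordant positions are
excluded -- no-call tested first, so an 'N' is never counted as discordant
-- and a concordant non-reference call is a mutation.  With zero mutations
in $N$ examined bases the report prints the explicit detection bound
$1/N$ ("fewer than one per $N$"), with the one-sided 95% rule-of-three
bound $3/N$ alongside; published reports print an opaque "<0.01" whose
rounding is unstated, so the explicit bound is reported instead.
Primer-table coordinates follow the 1-based inclusive convention of such
tables; everything else in the package is 0-based half-open, converted
only at I/O boundaries (BED is native).

## What the generator emulates

`simulate_genome()` draws a genome whose base composition is a first-order
Markov chain over strong/weak base classes with a block-wise GC target
(about 41% genome-wide, with a 15% admixture of ~55%-GC blocks) -- the
simplest process that produces the GC-clustered regions on which MDA bias
acts -- and lays probes at 1--2 kb spacing.  The probe "GC window" defaults
to 500 bp (probe plus local context) so that GC bias acts regionally, as it
does on real arrays, instead of as per-probe jitter.

`simulate_hybridization()` adds, on the log2 scale:

* a linear GC term, `gc_coefficient` log2 units per unit GC deviation from
  the genome mean (negative: GC-rich DNA resists strand displacement);
* an exponential chromosome-end depression
  $-d_{\max} e^{-d/\lambda}$ ($d$ = distance to the nearest end), matching
  the qualitative end-of-chromosome under-amplification of amplified
  arrays;
* injected CNV segments (shared "under-amplified loci" picked from the
  highest-GC windows by `underamplified_loci()`); and
* iid Gaussian noise.

The two kits are parameter presets of this one model, not separate code
paths: GenomiPhi (GC coefficient -4, end depression 2 log2, noise sd 0.33)
is deliberately noisier and more biased than REPLI-g (-3, 1.5, 0.25),
echoing the consistently higher outlier fractions of that chemistry, and
the unamplified preset is bias-free at the self-self DLRS floor of 0.165.
The injected locus depth defaults to -2.5 log2: median normalization
re-centers a biased profile by a few tenths of a log2 unit, and the loci
are meant to emulate regions *more than 3-fold* under-amplified after
normalization -- at -2.0 a mid-GC locus realizes only ~2.8-fold and would
contradict its own definition.

Randomness descends from a single root seed through stable string-hashed
child seeds per (sample, kit, replicate) cell, so any cell can be
regenerated in isolation and a whole study is byte-reproducible.

What the generator does **not** emulate: intensity-dependent (loess-shaped)
dye bias, spatial array artifacts, probe-sequence response differences,
segmental duplications or polymorphic CNVs of the donors, and
amplicon-level PCR failure in the sequencing arm.  A green end-to-end test
therefore establishes that the statistics and their orderings behave
correctly under the stated bias model -- not that a particular scanner's
data would reproduce any published coordinates.

## Numerical choices and degenerate inputs

* ECDFs are right-continuous; KS suprema are evaluated at pooled sample
  points (exact for step functions).
* Phi with identical vectors returns 1 even when both are all-zero -- the
  self-self case with no CNVs anywhere must correlate perfectly; differing
  vectors with a degenerate 2x2 marginal return 0 with a warning.
* Flat CBS windows (range < 1e-12) are never split; windows shorter than
  `2 * min_width` probes form a single segment.
* Even-count medians are midpoints of the central order statistics
  (`stats::median`).
* Zero-intensity probe rows are rejected at read time with a warning; a
  DLRS of zero (noiseless replicate) switches replicate combination to
  equal weights.
* Reports round to 3 decimals; all internal computation is full precision.

## Limitations

* The CBS variant matches the original arc statistic with permutation
  significance and sd-undo; vendor implementations differ in speedups and
  defaults, so only qualitative agreement can be expected on real data.
* Published genome-scale percentages (threshold tables, the 2.1% genome
  fraction, region coordinates) derive from ~970,000-probe human arrays
  with no deposited raw data; they are covered by direction and ordering
  properties on synthetic data, not by numeric reproduction.
* The sequencing module consumes pre-aligned call strings; chromatogram
  parsing and base-quality modeling are out of scope (a global aligner
  utility co-registers offset reads, dropping indel columns).

## A worked run

```{r}
library(mdaqc)
bundle <- run_study(study_config(), seed = 1)
print(bundle)
```

The printed medians show the expected structure: within-group Kolmogorov
medians a few hundredths; amplified-vs-self-self distances an order of
magnitude larger; Phi medians high; GenomiPhi above REPLI-g in every
threshold column; recovered common regions GC-rich relative to the genome;
no qPCR flags; zero mutations with an explicit detection bound.
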