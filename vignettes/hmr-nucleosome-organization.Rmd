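---
title: "Nucleosome organization at HMR boundaries: models and methods"
author: "hmrnuc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome organization at HMR boundaries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmrnuc)
```

## The scientific question

Vertebrate genomes are pervasively CpG-methylated, punctuated by
hypomethylated regions (HMRs) that mark promoters, enhancers and other
regulatory elements. Where exactly an HMR "ends" — the methylation
transition at its boundary — is also where nucleosome organization
changes: nucleosomes pile up at the boundary CG and phase outward into
the methylated flank with a regular spacing. `hmrnuc` implements the
analysis chain needed to study this interplay from primary data:

1. **MNase-seq processing** — paired-end fragments are size-selected to
   the mononucleosome band, midpoints (dyad proxies) counted per bp, and
   the counts Gaussian-smoothed into a continuous occupancy track.
2. **HMR calling** — a two-state hidden Markov model over per-CpG
   methylated/total read counts segments the methylome into
   hypomethylated and methylated states.
3. **Intrinsic nucleosome occupancy (INOS)** — a sequence-only Lasso
   model over k-mer content of 147-bp windows, scoring every base pair.
4. **Boundary-anchored quantification** — metaprofiles, length-sorted
   heatmap matrices, phasing-period estimation, cross-tissue HMR classes,
   6-mer/E-box enrichment at boundary CGs, and ROC/AUC comparison of
   nucleosome predictors.
5. **Synthetic data** — a fully seeded generator that plants every signal
   the pipeline is supposed to recover, with complete ground truth.

All coordinates are 0-based half-open (BED-native) everywhere inside the
package. Methylome tables are read as 0-based by default; a `one_based`
flag converts 1-based dialects. CpG records on the minus strand are
collapsed onto the plus-strand C position by summing counts, treating the
CG dinucleotide symmetrically.

## Nucleosome occupancy tracks

Fragments are filtered to inclusive insert lengths 100–160 bp (the
mononucleosome band). Each fragment adds one count at
`floor((start + end - 1) / 2)`; for even lengths the tie breaks leftward,
a documented deterministic choice. Smoothing convolves the counts with a
Gaussian kernel truncated at ±4σ and renormalized to unit mass, so an
interior impulse conserves mass exactly. The bandwidth is not dictated by
the underlying protocol; the default σ = 20 bp preserves ~165-bp phasing
structure while suppressing single-bp noise, and is exposed as a
parameter. Kernel mass falling off a chromosome end is dropped rather
than reflected — the simplest contract — and downstream metaprofiles mask
(rather than zero-fill) positions beyond the ends so averages near edges
stay unbiased. Tracks are normalized to genome-wide mean 1 for
cross-sample comparison.

## The two-state methylation HMM

Emissions are beta-binomial: in state *s*, a CpG with total count *n*
has methylated count *m* with probability
\(\binom{n}{m} B(m+\alpha_s,\, n-m+\beta_s) / B(\alpha_s, \beta_s)\),
allowing the overdispersion real WGBS data show. Fitting is Baum–Welch
with each chromosome an independent sequence. The transition M-step is
the standard closed form. For the emission M-step we first moment-match
(α, β) from posterior-weighted level moments, discounting the expected
binomial sampling variance, then refine numerically over
(logit mean, log concentration) and accept the update only if it does
not decrease the expected emission log-likelihood. The refinement step
exists because plain moment matching is not an ascent step, while this
hybrid is a generalized EM: the observed log-likelihood is
non-decreasing every iteration, which the tests assert on dozens of
random data sets.

Two numerical guards: the concentration α+β is bounded to
[0.05, 1000] (a floor of overdispersion, so a state cannot shave off
near-duplicate slices of a single methylation regime), and a safety net
reverts to the previous parameters if floating-point effects ever
produce a likelihood decrease.

Decoding is posterior-based: maximal runs of CpGs with P(HYPO) > 0.5,
rather than Viterbi — posterior runs are less brittle at boundary CpGs
and the per-site probabilities are needed anyway. Runs with fewer than
`min_cpgs = 4` CpGs are discarded and runs are split across inter-CpG
gaps larger than 10 kb, preventing spurious mega-HMRs across
unsequenced deserts. Transitions are distance-independent (no decay with
inter-CpG gap); that is the simplest model consistent with a two-state
chain and is a known limitation for very irregular CpG spacing.

Boundary conventions: `first_unmeth` (outermost HMR CpG),
`second_unmeth` (next inward) and `adjacent_meth` (nearest CpG outside
the HMR) on either side, any of which can be undefined at chromosome
ends or single-CpG HMRs.

## INOS: sequence-intrinsic occupancy

Features of a 147-bp window (one nucleosomal DNA length) are the counts
of all reverse-complement-collapsed k-mers for k = 1..4, each normalized
by the number of window positions for that k, plus the window GC
fraction (feature `GC_frac`). Collapsing makes featurization — and hence
every score — exactly strand-symmetric. The model is a Lasso linear
model fit by cyclic coordinate descent with soft thresholding; features
are standardized internally (population SD) and the inverse transform is
folded into the stored weights, so the serialized model acts on raw
features. The penalized objective is asserted non-increasing per sweep,
and the fit is deterministic given the fixed feature order.

The published coefficient set of the original intrinsic-occupancy model
is not restated in the source material, so the package ships the model
*form* plus a training operation (`train_on_track()`) that fits it to
any occupancy track, including synthetic ones; tests train on tracks
constructed as known functions of sequence. Scoring assigns the model
value of the window centered at each bp (the central position of the
147-mer); the first/last 73 bp and N-containing windows are `NA`.
Scoring is O(genome length): each k-mer weight becomes a per-position
contribution and the window sum is a cumulative-sum difference. A
brute-force per-position oracle (re-featurize and dot product) checks
this path to 1e-9 in the tests; the reverse-complement symmetry of the
score track is exact up to floating-point summation order (asserted at
1e-12; the featurization itself is bit-identical under reverse
complement).

## Boundary profiles and periodicity

`metaprofile()` averages track signal over offsets around anchor
positions, with per-offset counts so chromosome-end truncation masks
rather than biases. 3′-side anchors are mirrored by default so "into the
methylated flank" is one consistent direction and both boundaries pool;
the unmirrored mode is exposed. The heatmap matrix anchors one row per
interval and sorts rows by interval length. Flank width defaults to
±2000 bp, a declared choice.

The phasing period is the lag of the maximum of the mean-subtracted
autocorrelation within a 120–260 bp search window — robust at the
profile lengths used here, where a spectral fit would have very few
informative frequencies. A permutation null (`periodicity_null()`)
calibrates how large a prominence chance alone produces.

## Cross-tissue comparison and motif analysis

Two HMR sets are compared with a reciprocal-overlap rule: a pair is
*common* when each interval covers at least 50% of the other, matched
one-to-one in order of decreasing reciprocal overlap (ties to the
leftmost partner); everything unmatched is tissue-specific. The 50%
threshold is a package default exposed as a flag — the comparison is
robust over a range of sensible values, and no canonical threshold
exists for this taxonomy. CGI overlap uses ≥1 bp sharing. Extended pairs
are overlapping HMRs sharing exactly one first-unmethylated-CG boundary
(exact by default; a bp tolerance is exposed because methylome noise can
shift the first CG), with boundary 1 the shared position, boundary 2 the
end of the shorter HMR and boundary 3 the end of the longer one.

Boundary nucleosome scores are the mean track value over ±73 bp (one
nucleosome half-length; "peak at the boundary" has no canonical numeric
definition, so the footprint window is the declared one), stratified
into bottom 20% / middle / top 20% with deterministic tie-breaking by
position. 6-mers are read centered on the boundary CG (positions 3–4 of
the 6-mer), reverse-complemented on the 3′ side so CG orientation is
consistent; enrichment is the log2 ratio of pseudocounted frequencies
(pseudocount 1). Observed/expected positional ratios index CG sites
outward/inward from the boundary CG; the expected rate is the
genome-wide fraction of CG-centered windows equal to the pattern —
genome-wide rather than flank-local or composition-matched, the simplest
defensible baseline, with the alternatives reachable by passing a
different boundary set.

AUC uses the rank (Mann–Whitney) formulation with midranks, checked
against explicit pair counting. For predictor comparisons the positive
label is "boundary score above the median" over all boundaries, or
top-20% vs bottom-20% for the stratified analysis; both are exposed
because the labeling is an analysis choice. The single-CG-dinucleotide
predictor is the binary presence of CG at the evaluated position — at
HMR boundaries, which essentially always carry a CG, it is
uninformative by construction, which is the point of the comparison.

## The synthetic data generator

The generator is first-class, tested code; every stage of the pipeline
is validated by recovering what it plants.

* `simulate_genome()`: i.i.d. bases at background GC 0.42 with CpG
  depletion (each background CG destroyed with probability 0.75,
  emulating mammalian CpG depletion and giving ~1 CpG per ~100 bp), and
  non-overlapping CpG islands at GC 0.65 without depletion.
* `simulate_methylome()`: plants common, tissue-specific and extended
  HMRs. Boundary CpGs are written into the sequence at exact positions;
  a CpG-free moat is carved outside each boundary and the adjacent
  methylated CG planted at a gap drawn uniform 100–200 bp (mean
  150 bp), making the boundary-gap statistic a planted, recoverable
  parameter. Extended pairs share one boundary CG exactly; the extension
  is lognormal(meanlog = log 170, sdlog = 1), which has median 170 bp
  and mean ≈ 280 bp, clamped to [100, 2000] bp. Emissions are
  beta-binomial with hypo mean 0.05, methylated mean 0.85, dispersion
  0.1 for both states, and Poisson coverage with mean 20 — typical WGBS
  working depth. 35% of common HMRs are placed inside CGIs.
* `simulate_fragments()`: midpoints from a mixture of uniform background
  and Gaussian-positioned nucleosomes at `boundary + k·period`
  (period 165 bp, k = 0..2) propagating into the methylated flank,
  amplitude decaying 0.7 per nucleosome — one to three phased
  nucleosomes, positional jitter SD 20 bp. `fold` is the k = 0 peak
  height in background units (default 8); `fold = 0` is the uniform
  null. Insert lengths are rounded normal (147 ± 10), truncated to
  [50, 300], optionally clipped to [100, 160].
* `plant_motifs()`: writes a motif (default the E-box CACGTG) centered
  on the CG of a target share of boundary CGs (default 20%) and of
  non-boundary CG sites (default 10%), discounting natural occurrences
  so realized rates match the targets. A site is planted only when its
  context contains no CG other than the central one before and after
  writing, so the genome's CpG set — and any methylome generated from
  it — is unchanged; ineligible sites are skipped and reported.

Sub-generators are seeded deterministically from one master seed;
identical seeds give byte-identical genomes, methylomes and fragment
sets.

What the generator does *not* emulate: MNase sequence bias, replicate
structure, chromatin beyond the planted phasing, distance-dependent
methylation transitions, and realistic k-mer composition beyond GC/CpG
structure. Passing tests therefore demonstrate that the implementation
recovers the signals it models, not that those signals dominate real
tissues.

## Problem sizes and numerical choices

The full-scale preset is a 5 Mb genome, ~50k CpGs, ~500 HMRs and 500k
fragments per cell. The test suite and the acceptance script run scaled
versions — typically `scale = 0.04`–`0.06` (200–300 kb, ~3k CpGs,
~16–25 HMRs, 20–30k fragments), a 3 Mb genome for the motif analyses
(≈2000 boundaries per stratum), and 10k-CpG chains for HMM parameter
recovery — sizes at which every planted parameter is comfortably
identifiable while the whole suite runs in minutes on one CPU.

Other numerical choices: EM stops on a log-likelihood increment below
`tol` or at `max_iter` with a flag; state labels are fixed post-fit so
HYPO has the lower expected level; Lasso convergence is the largest
coefficient change in a sweep below 1e-8; zero-variance features get
weight 0; `round(level × coverage)` uses round-half-away-from-zero for
platform determinism; midrank ties in AUC and position-order ties in
stratification keep every result deterministic.

## Known limitations

* The HMM has distance-independent transitions and no permutation-based
  size filtering; `min_cpgs` is the only size guard.
* The INOS default is trained on synthetic tracks; absolute score scales
  are not comparable to any published coefficient set, which is why
  outputs are meaningful raw or z-scored but cross-study comparisons
  need retraining.
* BAM/CRAM input is out of scope; fragments are consumed as BED/BEDPE.
* Single-chromosome tracks: multi-chromosome analyses loop over
  per-chromosome tracks.
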