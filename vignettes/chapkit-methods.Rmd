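---
title: "Kernel-convolution peak calling for bacterial ChAP-Seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-convolution peak calling for bacterial ChAP-Seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chapkit)
```

## The problem

Chromatin affinity purification sequencing (ChAP-Seq) maps the genome-wide
binding sites of a tagged DNA-binding protein — here, bacterial
transcription factors such as the iron-responsive repressor DtxR or the
heme-responsive regulator HrrA of *Corynebacterium glutamicum*. After
crosslinking, pull-down and sequencing, the analyst is left with aligned
reads on a small circular chromosome and must answer: where does the
protein bind, how strongly, how reproducibly across replicates and growth
conditions, which genes do the sites regulate, and is a known binding
motif present under the peaks?

chapkit implements that analysis as a chain of small, testable steps, each
of which can be exercised on synthetic data with planted ground truth.

## The detection model

Binding sites appear in coverage as roughly Gaussian bumps of a
characteristic width sitting on a noisy but locally flat background. The
caller exploits that shape with a matched band-pass filter: the coverage
track is convolved with the negated second derivative of a Gaussian
density (a "Mexican hat"). This kernel has a positive center flanked by
negative lobes and zero total mass, so

* constant background convolves to exactly zero,
* linear trends cancel,
* bumps whose width matches the kernel scale produce strong positive
  maxima at their centers.

The processing chain for one sample:

1. **Expected width** `w`. Provisional peaks are the maximal runs of
   positions whose depth exceeds three times the genome-wide mean `mu`.
   For each, the coverage is walked outward from the local maximum until
   it drops below half that maximum; the distance between the outermost
   positions still at or above half-maximum is the peak's FWHM. `w` is
   the median FWHM (lower-middle element for even counts, so the result
   is always an observed width). If no position exceeds `3 mu` the sample
   has no detectable peaks and the caller stops with an informative error.
2. **Kernel**. `sigma = w / 8`, so the truncated support (plus/minus
   4 sigma) spans exactly the expected width. Discrete truncation breaks
   the analytic zero integral of the second derivative, so the weights
   are mean-shifted to sum to zero exactly.
3. **Convolution**. Circular convolution for circular chromosomes
   (coordinates wrap modulo the genome length), zero-padding for linear
   sequences. The implementation rides on `stats::filter`; tests compare
   it against a naive direct sum at relative error below 1e-9.
4. **Summits**. Candidate summits are positions where the discrete first
   difference of the convolution profile changes sign from positive to
   negative; flat plateaus report their center, rounded down. Candidates
   with non-positive profile values are discarded — only bump-like
   features qualify.
5. **Score and filter**. A peak's score is the convolution value at its
   summit; its raw height is the coverage there. Peaks are kept when the
   raw height reaches `min_fold * mu` (default 3, reusing the detection
   threshold) and the score is positive. Extents are `summit ± w/2`;
   overlapping extents merge, keeping the higher-scoring summit.
6. **Normalization**. The normalization coefficient `B` is the background
   mass: total coverage minus the coverage inside all peak extents. Each
   peak's comparable intensity is `score / B * 1e6` (the `1e6` purely for
   readability). Score and `B` both scale linearly with sequencing depth,
   so intensities are invariant under depth rescaling — the property that
   makes intensities comparable across samples; tests assert it at
   scaling factors 0.1, 10 and 137.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `min_fold` | 3 | multiples of mean depth | detection and filter threshold |
| `sigma_ratio` | 1/8 | – | kernel scale relative to `w` |
| `merge_distance` | `w/2` | bp | replicate clustering linkage |
| `upstream_window` | 500 | bp | promoter window for annotation |
| `p_threshold` | 1e-5 | – | motif hit cutoff (exact p) |

Design points that were genuinely open, and the choices made:

* **Kernel sign.** Summit detection scans for positive-to-negative
  derivative changes, which presumes summits are *maxima* of the profile;
  the second-derivative kernel is therefore negated. This is the only
  reading under which the derivative rule detects anything.
* **`sigma = w/8`.** "Expanding the kernel to the expected width" is read
  as: the truncated support `2 * 4 sigma` equals `w`. Other mappings
  (e.g. FWHM of the kernel's central lobe equal to `w`) are accessible
  via `sigma_ratio`.
* **Filter rule.** Which candidate peaks survive filtering is
  under-determined; the package reuses the only stated threshold
  (`3 mu`, applied to summit raw coverage) plus positivity of the score.
  Both are configurable.
* **Normalization direction.** `score / B`, not `B / score`: intensities
  must grow with binding strength for any of the downstream
  figures (distance-intensity trends, replicate correlation on
  intensities) to make sense. A literal "coefficient divided by
  intensities" would invert the ranking.
* **Peak extent for background subtraction** is `summit ± w/2`.
* **`mu` includes peak regions.** The mean is over the whole genome; with
  tens of peaks on a 100 kb to multi-Mb genome the difference is small,
  and it keeps the statistic assumption-free.
* **Even-count medians** take the lower middle element; plateau summits
  round down. Both choices keep integer outputs and bitwise
  reproducibility.

### FWHM convention

The width of a provisional peak is measured between the outermost
positions still at or above half-maximum (not the first positions below
it). On a symmetric triangle rising linearly over 100 bp this yields
exactly 100; measuring to the first sub-half positions would give 102 and
systematically overestimate every width by 2 bp.

## Consolidation and downstream analyses

**Replicate merging.** Summits from all samples are clustered by single
linkage with threshold `merge_distance` (circular distance; default
`w/2`). Sorting makes this exact in 1-D: cut where neighbour gaps exceed
the threshold, then re-join the first and last cluster if the wrap-around
gap is small. Each cluster becomes one consolidated target with an
intensity-weighted mean locus, a support count (`n`, the number of
replicates contributing a significant peak — significance meaning
presence in that replicate's filtered peak set; the method defines no
per-replicate test beyond the filter), per-sample intensities (0 when
absent — dropping loci absent anywhere would erase condition-specific
binding, which is exactly the signal of interest), and per-condition
presence flags.

**Reproducibility.** Samples become vectors of intensities over the union
loci; the Pearson matrix of those vectors summarizes replicate agreement.
Zero-variance vectors yield `NA` rows rather than errors.

**Annotation.** A summit inside exactly one gene body is intragenic, with
a positive oriented distance from that gene's TSS. Otherwise the nearest
TSS downstream of the summit (in the gene's own orientation) within the
upstream window claims it, at a negative distance. The 500 bp default
window is a field convention, not a derived quantity; upstream/intragenic
splits depend on it and it is prominently configurable. Divergent
promoters resolve to the nearest TSS, ties to the lexicographically
smaller gene id.

**Correlations.** Distance-to-TSS vs intensity and intensity vs
differential-expression-magnitude use Spearman (or Pearson) coefficients
with permutation p-values (default 10^4 label permutations, seeded,
add-one corrected). Permutation rather than parametric tests because the
target counts are small and nothing guarantees normality. Expression is
paired by magnitude `|log2 ratio|`, since binding may activate or repress
and the question is strength, not direction.

**Motif scanning.** A PWM (built from aligned sites, a MEME minimal file,
or an IUPAC consensus such as `TAGGTTAGSCTAACCTAA`) is scanned over both
strands with exact p-values: the score distribution under a 0-order
background model is computed by dynamic programming over integer-binned
per-position scores (bin width `granularity = 0.001`; the binning can
displace the effective threshold by at most `length * granularity`).
Tests compare the DP tail to exhaustive enumeration of all `4^5` windows
for length-5 PWMs. The background defaults to the scanned sequence's own
mononucleotide frequencies; hits are reported where `p < 1e-5`, all
overlaps included, with no FDR layer on top — the scan is used as a
presence filter, not a discovery procedure.

## The synthetic-data generator

`generate_genome()`, `plant_peaks()`, `simulate_coverage()`,
`plant_motif()` and `simulate_expression()` produce a complete miniature
study: a circular chromosome (default 100 kb, GC 0.54 in the demo,
matching a high-GC actinobacterium), 40 non-overlapping genes on both
strands, 20–60 Gaussian binding sites (FWHM 40–120 bp — the field's
typical protected-fragment scale; the real width distribution is not
published, so this range is a configurable default), heights 30–300 on a
background of mean 10, per-base Poisson noise, three replicates per
condition, and condition-specific peak subsets. Peaks are parameterized
by FWHM (`sigma = width / 2.355`) so that the planted width is exactly
what the width estimator measures. Summits stay at least twice the
larger pair width apart, making recovery matching unambiguous.

What the generator *does not* emulate: read-level artifacts (mapping
bias, GC bias of library prep, adapter chimeras), fragment-size
distributions, crosslinking chemistry, copy-number structure near the
origin of replication, and low-complexity regions. Passing recovery tests
therefore demonstrates correctness of the algorithmic chain under the
stated noise model, not robustness to every artifact of real libraries —
for real data the blacklist argument exists precisely because artifact
peaks (e.g. cryptic technical peaks) are best removed by hand.

Every generator is a pure function of its integer seed; truth bundles
(FASTA + GFF3 + bedGraph + JSON sidecar) are byte-identical across
re-runs.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run at desk scale, chosen so a
complete check is comfortable on a laptop: 100 kb genomes, 20–31 planted
peaks, 3 replicates, 10 simulation seeds for recovery, 200 random
instances for each oracle-equivalence property, 50 seeds for p-value
calibration with 2 000 permutations each, and exhaustive enumeration for
length-5 PWMs. These sizes are statistically meaningful for the
properties tested (binomial confidence at n = 900 called peaks is about
±1.5 %) while keeping the full run in minutes.

## Worked example

```{r demo, eval = FALSE}
out <- chap_demo(tempfile("chapdemo"), seed = 1)
glance(out$peaksets[[1]])
out$condition_sets$demoTF
autoplot(out$peaksets[[1]])
```

## Known limitations

* One chromosome per run; multi-replicon genomes need per-replicon calls.
* No input/control-sample subtraction and no FDR for peaks — filtering is
  threshold-based, as in the underlying method.
* The upstream/intragenic split is sensitive to `upstream_window`; report
  it alongside any counts.
* The PWM scanner assumes a 0-order background; repeat-rich genomes may
  warrant a higher-order model it does not provide.
* `support` counts replicates with a surviving peak; it is a presence
  count, not a statistical significance measure.
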