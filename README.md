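# chapkit

Peak calling and regulon analysis for bacterial ChAP-Seq (chromatin
affinity purification sequencing) — the assay that maps where a tagged
transcription factor, such as the iron regulator DtxR or the heme
regulator HrrA of *Corynebacterium glutamicum*, binds its circular
chromosome under different growth conditions.

## What it computes

The caller is a matched band-pass detector. For a per-base coverage track
$c(x)$ on a circular genome:

1. estimate the expected peak width $w$ as the median FWHM of all
   provisional peaks (maximal runs with $c(x) > 3\bar{c}$; FWHM measured
   between the outermost positions still at or above half of the local
   maximum);
2. build a Mexican-hat kernel $k(i) = -g''(i;\sigma)$ with
   $\sigma = w/8$, truncated at $\pm 4\sigma$ and mean-shifted so
   $\sum_i k(i) = 0$;
3. convolve: $s(x) = \sum_i k(i)\, c(x - i \bmod L)$;
4. report a summit wherever the first difference of $s$ changes sign from
   positive to negative (plateau centers rounded down), keep summits with
   raw coverage $\ge 3\bar{c}$ and $s > 0$, and merge overlapping extents
   $[x - w/2,\; x + w/2)$;
5. normalize by the background mass
   $B = \sum_x c(x) - \sum_{\text{peaks}} \sum_{x \in \text{extent}} c(x)$:
   each peak's comparable intensity is $s(\text{summit})/B \times 10^6$,
   invariant under sequencing-depth rescaling.

Around the caller: PCR-duplicate collapsing and coverage computation from
BED/SAM alignments, bedGraph I/O, replicate consolidation with support
counts and Pearson reproducibility matrices, regulon comparison between
two regulators, peak-to-TSS annotation (upstream vs intragenic), PWM
scanning with exact dynamic-programming p-values at the $p < 10^{-5}$
threshold, binding-vs-expression correlation with permutation p-values,
the $2^{-\Delta\Delta Ct}$ qPCR fold change, and a seeded synthetic-data
generator that plants ground-truth binding sites so the whole chain is
testable offline.

## Worked example

```r
library(chapkit)

g     <- generate_genome(100000, gc_fraction = 0.54, n_genes = 40, seed = 1)
truth <- plant_peaks(g$genome, g$genes, n_peaks = 30,
                     height_range = c(100, 100), background_mean = 10,
                     seed = 101, condition_pattern = rep("iron", 30))
trk   <- simulate_coverage(truth, "iron", replicate = 1,
                           noise = "poisson", seed = 1001)
peaks <- call_peaks(trk)
peaks
#> <peak_set> 30 peaks on synthetic_chr (100000 bp), expected width 138 bp, mean depth 12.66
#>   normalization coefficient B = 9.805e+05
head(tidy(peaks), 3)
#> # A tibble: 3 x 10
#>   summit start   end raw_height  score norm_intensity chrom         sample    condition replicate
#>    <int> <int> <int>      <dbl>  <dbl>          <dbl> <chr>         <chr>     <chr>         <int>
#> 1   4250  4181  4319        120 0.0369         0.0376 synthetic_chr iron_rep1 iron              1
#> 2   6314  6245  6383        120 0.0485         0.0494 synthetic_chr iron_rep1 iron              1
#> 3   7933  7864  8002        114 0.0524         0.0535 synthetic_chr iron_rep1 iron              1
```

Thirty peaks were planted at height 100 over a Poisson background of mean
10, and all thirty are recovered with summits at the planted positions.
The estimated width (138 bp) exceeds the planted FWHM range because the
half-maximum crossings are measured on signal plus background; the kernel
only needs the right scale, not the exact value. `norm_intensity` is the
depth-independent score each downstream analysis (replicate correlation,
TSS-distance trend, expression correlation) consumes. `chap_demo(outdir,
seed = 1)` runs the full pipeline — six replicate tracks across two
conditions, consolidation, annotation, motif scan, correlations — and
writes every table plus a reproducibility manifest.

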