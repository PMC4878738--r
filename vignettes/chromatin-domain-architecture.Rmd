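---
title: "Methods: co-occupancy, repressive domains and boundary analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occupancy, repressive domains and boundary analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chrombound)
```

## Scope and model

chrombound analyzes the interval-level architecture of transcription-factor
occupancy and repressive chromatin. Its inputs are ChIP-seq peak calls
(BED/narrowPeak), SICER-style enriched-window tables for the Polycomb mark
H3K27me3, gene models, chromosome sizes with assembly gaps, and RNA-seq
count tables. Every coordinate is 0-based half-open (the BED convention);
every user-facing function takes a plain data frame and returns a tibble, so
stages compose with the pipe.

The analyses are:

1. **Factor co-occupancy** (`classify_cooccupancy()`): a CTCF peak is
   co-occupied by cohesin when it overlaps at least one cohesin peak. Each
   peak is counted once however many partners it touches, so the co-occupied
   count of A against B is not symmetric in A and B; both directions are
   reported.
2. **Cross-cell-type sharing** (`classify_cross_cell()`): against K
   reference peak sets, a site shared with none is *cell-type specific*,
   shared with all K *invariant*, otherwise *intermediate*. The three
   classes partition the target set exactly.
3. **Genome bins** (`build_bins()`, `peak_bin_distribution()`): every
   non-gap base is assigned to one bin by the fixed precedence
   promoter > downstream > genic > 5′ distal > 3′ distal > intergenic, with
   promoter = TSS ± 1 kb, downstream = TES ± 1 kb, distal = 1–50 kb beyond on
   the strand-aware side, and assembly gaps as a residual seventh bin. Peaks
   are assigned by a single point (summit when available, else midpoint) so
   bin fractions sum to one.
4. **Repressive domains** (`call_domains()`): windows with fold enrichment
   strictly above 3 are merged transitively when separated by at most
   2000 bases, and merged regions strictly larger than 2000 bases become
   domains. Both inequalities are strict readings of "more than"; merging is
   transitive because chains of nearby enriched windows form one continuous
   domain, the behaviour of a coordinate-sorted merge.
5. **Boundary marking** (`extract_boundaries()`, `mark_boundaries()`): each
   domain contributes a left and a right boundary; a binding site within
   1 kb of a boundary position marks it. Two tallies are kept — unique
   marking peaks and marked boundaries — because a peak near both edges of a
   short domain counts once as a site but twice as a marked edge.
6. **Randomization null** (`randomize_intervals()`,
   `colocalization_test()`): the null for any co-localization count re-places
   the query intervals uniformly in the gap-masked genome, preserving
   lengths exactly, and recomputes the statistic per iteration.
7. **Expression integration**: detection (median CPM > 1), the
   CPM > 1-in-≥3-samples filter, 2-fold classification on pseudocounted mean
   CPM, TSS-proximity linkage of peaks to genes, and two-sided Wilcoxon
   rank-sum comparisons of log2(mean CPM + 1) between gene classes.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `min_bp` | 1 | bases | overlap needed for "shared"/"co-occupied" |
| `min_fold` (windows) | 3 | ratio | enrichment floor for domain windows (strict) |
| `merge_gap` | 2000 | bases | maximum gap bridged when merging windows |
| `min_length` | 2000 | bases | minimum domain length (strict) |
| `boundary_d` | 1000 | bases | distance defining a boundary-marking site |
| `tss_d` | 1000 | bases | distance defining a peak-linked gene |
| `promoter_d` / `distal_d` | 1000 / 50000 | bases | bin geometry |
| `cpm_threshold` / `min_samples` | 1 / 3 | CPM / samples | detection and filtering |
| `min_fold_change` / `pseudocount` | 2 / 0.5 | ratio / CPM | expression classes |
| `n_iterations` | 1000 | — | randomization depth; p floor 1/(n+1) |

A 1 bp overlap is the field's default notion of a shared site (the behaviour
of `bedtools intersect`); no published threshold overrides it here, so it is
exposed as a knob rather than hard-coded. Peak-level quality filtering
(`filter_peaks()`) uses strict inequalities — fold enrichment above the
cutoff, p-value below it — matching how peak callers report thresholds.

## Distance and d = 0 semantics

Distance between disjoint intervals is the count of intervening bases, so a
peak ending at 5200 is 800 bases from a boundary at position 6000, and any
overlap has distance 0. Bookended intervals (zero intervening bases, no
shared base) are a genuine edge case: we define `d = 0` to require an actual
overlap, while bookended pairs match any `d >= 1`. This keeps
`within_distance(d = 0)` exactly equivalent to a 1 bp overlap test — a
property the test suite asserts — at the cost of a documented special case
for touching intervals.

## The randomization null

`randomize_intervals()` places each interval independently and uniformly
over every genome-wide position whose containing non-gap segment fully
holds it: segments are weighted by capacity (segment length − interval
length + 1), then an offset is drawn uniformly within the chosen segment.
Placement is genome-wide rather than per-chromosome because the masked
genome, not the chromosome of origin, is the stated reference space; a
per-chromosome variant would only require restricting the segment pool.
Placed intervals may overlap one another — no exclusion constraint is
imposed, matching the independence assumption of the count statistic.

Empirical p-values use the add-one rule
$p = (1 + \#\{T_{null} \ge T_{obs}\}) / (1 + n)$ for enrichment and the
mirrored rule for depletion. p is therefore never zero and is floored at
$1/(n+1)$ — with 1000 iterations the strongest reportable enrichment is
just below 0.001. Both directions are always computed; `direction` labels
the smaller. The test suite verifies placement uniformity (chi-square over
equal-capacity strata), bit-identical nulls under a fixed seed, and that
p-values are uniform when the query set is itself drawn from the null
(Kolmogorov–Smirnov, 200 replicate tests of 200 iterations).

## What the synthetic generator emulates — and what it does not

The generator plants known structure so every stage can be scored against
recorded truth:

- `sim_genome()`: equal-length chromosomes with non-overlapping random gaps
  totalling a requested fraction (within 1%).
- `sim_peak_panel()`: log-normal peak lengths (median ≈ 300 bp, the scale of
  point-source ChIP-seq peaks); an exact planted fraction of target peaks
  receives an overlapping partner peak; exact planted fractions are present
  in all, none, or a random proper subset of K reference sets.
- `sim_h3k27me3_track()`: fixed-width windows (200 bp) tiling the non-gap
  genome; log-normal background fold (median 1, sd 0.25 on the log scale)
  against log-normal domain fold (median 5, sd 0.2); planted domains are
  window-aligned, log-normal in length (median 10 kb, echoing the reported
  8–12 kb scale), and separated by ≥ 4 kb so the merge rule cannot fuse
  them; boundary peaks are planted at each edge with a configurable rate and
  ≤ 500 bp jitter.
- `sim_expression()`: negative-binomial counts (the standard RNA-seq noise
  model; dispersion 0.1), gene baselines normal in log2 CPM, class-specific
  log2 shifts, library sizes uniform ±20%.

Recovery behaves as designed: planted co-occupancy and sharing fractions
come back within 2 percentage points at 5000 peaks on a sparse
(500 Mb) genome; domain edges come back within one window; a 2 log2-unit
expression shift comes back within 0.2 at 500 genes per class. Those
tolerances are driven by real, quantifiable noise — accidental overlaps at
the planted peak density, single edge windows dropping below the fold
threshold (probability ≈ 0.5% per edge at the default fold
distributions), and count noise.

What the generator deliberately does not model: read-level artefacts
(mappability, duplicates, fragment-size effects), GC or accessibility bias
in where peaks and domains sit, correlated peak positions (clustering,
CpG-island promoters), isoform structure, or edgeR-style dispersion
shrinkage. Passing the planted-recovery suite therefore demonstrates the
*rules* are implemented correctly, not that the pipeline is robust to every
bias in real ChIP-seq; on real data the quality filters and the published
thresholds carry that weight.

## Numerical and design choices

- **Strictness**: "fold enrichment > 3", "larger than 2000 bases", "more
  than 2 fold", "median CPM > 1" are all strict; printed integer percents
  use round-half-away-from-zero.
- **Genome-fraction denominator**: total gap-inclusive assembly length by
  default (`exclude_gaps = TRUE` switches to sequenced length); the
  shipped `hg19_assembly_length` constant (3,137,161,264 bp) is the full
  hg19 scaffold total.
- **Sharing-table denominators**: where a shared-site count admits two
  denominators (either cell type's total), both are computable and nothing
  is guessed; `percent_common()` always reports the denominator alongside
  the percent.
- **Conflict rule for gene linkage**: a gene near peaks of several classes
  resolves by specific > invariant > alphabetical, and all linked classes
  are kept in a list-column.
- **Peak-to-TSS distance** is measured from the peak edge (not summit or
  midpoint); the summit is used only for bin assignment, where a unique
  point per peak is required.
- **Empty/degenerate inputs**: empty peak sets classify cleanly (all
  "alone"), empty domain sets give count 0 with an NA mean, a comparison
  class with fewer than two genes is skipped with a warning rather than
  fabricating a p-value.
- **Backends**: interval overlap, merge and complement run on
  IRanges/GenomicRanges; CPM on edgeR; rank-sum on `stats::wilcox.test`.
  Test-suite oracles are independent brute-force implementations (all-pairs
  scans, per-base bitmaps, exhaustive permutation).

## Problem sizes in the shipped tests

The suite exercises the oracles on ≥ 120 randomized toy instances (≤ 100 kb
chromosomes), calibrates the null over 200 replicate tests of 200 iterations
on a 1 Mb masked genome, and runs recovery at 5000 peaks / 500 Mb, 150
domains / 20 Mb, and 1000 genes. These sizes give stable statistics while
keeping a full run of the suite inside a few minutes on one core; all of
them scale up by changing generator arguments only.

## Known limitations

- The seventh genome bin is the assembly-gap residual; finer inventories
  (exons, UTRs, enhancers) are out of scope.
- The randomization offers no GC-, chromosome- or annotation-matched
  shuffling modes.
- Fold-change classification implements the stated CPM ratio rule; it is
  not a substitute for a dispersion-modelled differential test when
  replicates warrant one.
- `run_all()` on file inputs expects narrowPeak peaks and a refFlat-like
  gene table; other layouts should go through the reader functions
  directly.
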