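# chrombound

Interval genomics of CTCF/cohesin occupancy and repressive chromatin
architecture, for analysts working with ChIP-seq peak calls and RNA-seq
count tables from hematopoietic (or any other) cell types.

During differentiation, the insulator protein CTCF and the cohesin complex
(its SA-1/STAG1 variant) redistribute across the genome, and broad domains
of Polycomb-repressed chromatin — marked by H3K27me3 — expand. chrombound
implements the interval-level analyses that quantify this:

- **Co-occupancy**: peak $a_i$ of factor A is co-occupied by factor B iff
  $\exists\, b_j : |a_i \cap b_j| \ge \text{min\_bp}$ (default 1 bp).
- **Cell-type specificity**: against $K$ reference peak sets, a site's
  shared count $s \in \{0,\dots,K\}$ classifies it *specific* ($s = 0$),
  *invariant* ($s = K$) or *intermediate*.
- **Genome bins**: a seven-bin partition of the genome relative to gene
  models (promoter = TSS ± 1 kb, downstream = TES ± 1 kb, 5′/3′ distal =
  1–50 kb, intergenic, assembly gaps), with peak fractions vs genome
  composition.
- **Repressive domains**: from windowed H3K27me3 enrichment, keep windows
  with fold $> 3$, merge across gaps $\le 2000$ bp, keep merged regions
  $> 2000$ bp.
- **Boundary marking**: a binding site within 1 kb of a domain start/end
  marks that boundary.
- **Randomization null**: query intervals are re-placed uniformly in the
  gap-masked genome (lengths preserved) and the co-localization count is
  recomputed per iteration; the empirical p-value is
  $p = (1 + \#\{T_{null} \ge T_{obs}\})/(1 + n)$, floored at $1/(n+1)$.
- **Expression linkage**: CPM detection (median $> 1$), the
  $>1$-CPM-in-$\ge 3$-samples filter, 2-fold classification on
  pseudocounted mean CPM, peak-to-TSS linkage within 1 kb, and Wilcoxon
  rank-sum comparison of $\log_2(\text{CPM}+1)$ between gene classes.

A synthetic-data module plants known co-occupancy fractions, sharing
classes, domains with boundary peaks, and expression shifts, so the entire
pipeline is testable against recorded truth without external downloads.

## Worked example

Simulate a masked genome with planted repressive domains, rebuild the
domains from the windowed track, and test boundary co-localization against
the randomization null:

```r
library(chrombound)

asm <- sim_genome(n_chrom = 2, chrom_length = 1e7, gap_fraction = 0.02, seed = 42)
asm
#> <genome_assembly> 2 chromosome(s), 20,000,000 bp total, 9 gap(s) (402,000 bp)

track   <- sim_h3k27me3_track(asm, n_domains = 120, boundary_peak_rate = 0.7, seed = 43)
domains <- call_domains(track$windows, min_fold = 3, merge_gap = 2000, min_length = 2000)
domain_stats(domains, assembly = asm)
#> # A tibble: 1 × 5
#>   n_domains mean_length total_domain_bp genome_fraction genome_percent
#>       <int>       <dbl>           <int>           <dbl>          <dbl>
#> 1       120      11263.         1351600          0.0676           6.76

marking <- mark_boundaries(track$boundary_peaks, extract_boundaries(domains), d = 1000)
marking
#> <boundary_marking> 177 of 177 peaks mark 177 of 240 boundaries

ct <- colocalization_test(
  marking_peaks(marking),
  transform(extract_boundaries(domains), start = pos, end = pos + 1),
  asm, statistic = "within_d", d = 1000, n_iterations = 1000, seed = 44)
ct
#> <coloc_test> statistic 'within_d': observed 177 of 177 (null mean 4.8 over 1000 iterations)
#>   p[enrichment] = 0.000999, p[depletion] = 1 (enrichment)
```

All 120 planted domains are recovered (mean length ≈ 11.3 kb, 6.8% of the
genome); the 177 planted boundary peaks mark 177 of 240 boundaries (the
0.7 planting rate), and their proximity to boundaries is maximally
significant under 1000 randomizations (p at the 1/1001 floor). Printed
sharing percentages follow the integer convention of published tables:

```r
percent_common(2602, 4832)
#> # A tibble: 1 × 4
#>   n_common n_total percent percent_rounded
#>      <dbl>   <dbl>   <dbl>           <dbl>
#> 1     2602    4832    53.8              54
```

`run_all(default_config(seed = 1))` chains every stage (simulation or file
inputs via `config$inputs`) and returns a JSON-serializable summary;
`tidy()`, `glance()`, `autoplot()` and the `plot_*()` functions cover the
result objects. The methods vignette
(`vignettes/chromatin-domain-architecture.Rmd`) documents the model,
parameter choices and limitations.

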