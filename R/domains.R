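# H3K27me3 repressive-domain construction from enriched windows.

#' Call repressive chromatin domains from enriched windows
#'
#' Applies the filter-merge-filter rule for building broad repressive
#' domains from windowed H3K27me3 enrichment: keep windows with fold
#' enrichment strictly above `min_fold` (default 3), merge surviving windows
#' separated by at most `merge_gap` bases (default 2000, transitive — chains
#' of nearby windows form one domain, as BEDTools merge behaves), and keep
#' merged regions strictly larger than `min_length` bases (default 2000).
#'
#' @param windows Interval table with a `fold_enrichment` column (e.g. from
#'   `read_bed(dialect = "sicer_window")`).
#' @param min_fold Fold-enrichment threshold, strict `>` (default 3).
#' @param merge_gap Maximum merge gap in bases (default 2000).
#' @param min_length Minimum domain length in bases, strict `>` (default 2000).
#' @return Sorted, non-overlapping tibble of domains with `domain_id`,
#'   `length` and `source_window_count` columns.
#' @examples
#' w <- data.frame(chrom = "chr1", start = c(0, 2500), end = c(1000, 3500),
#'                 fold_enrichment = c(4, 5))
#' call_domains(w)  # one domain chr1:0-3500
#' @export
call_domains <- function(windows, min_fold = 3, merge_gap = 2000L, min_length = 2000L) {
  if (min_fold < 0 || merge_gap < 0 || min_length < 0) {
    abort("min_fold, merge_gap and min_length must be >= 0")
  }
  windows <- as_intervals(windows)
  if (!"fold_enrichment" %in% names(windows)) {
    abort("windows must carry a fold_enrichment column")
  }
  enriched <- windows[windows$fold_enrichment > min_fold, , drop = FALSE]
  merged <- merge_within(enriched, max_gap = merge_gap)
  merged$length <- merged$end - merged$start
  out <- merged[merged$length > min_length, , drop = FALSE]
  out <- dplyr::rename(out, source_window_count = "n_merged")
  out$domain_id <- if (nrow(out) > 0) paste0("domain_", seq_len(nrow(out))) else character(0)
  out[, c("chrom", "start", "end", "domain_id", "length", "source_window_count")]
}

#' Summary statistics for a domain set
#'
#' Count, arithmetic mean length, and the fraction of the genome covered.
#' The denominator is the total (gap-inclusive) assembly length by default;
#' set `exclude_gaps = TRUE` to use sequenced length only. Either an
#' assembly or an explicit `total_length` may supply the denominator.
#'
#' @param domains Interval table of domains.
#' @param assembly Optional [genome_assembly()].
#' @param total_length Optional explicit genome length in bases (used when
#'   `assembly` is `NULL`).
#' @param exclude_gaps Use non-gap length as denominator (default `FALSE`).
#' @return One-row tibble: `n_domains`, `mean_length` (NA when empty),
#'   `total_domain_bp`, `genome_fraction` (NA without a denominator) and
#'   `genome_percent`.
#' @export
domain_stats <- function(domains, assembly = NULL, total_length = NULL,
                         exclude_gaps = FALSE) {
  domains <- as_intervals(domains)
  n <- nrow(domains)
  lens <- domains$end - domains$start
  denom <- if (!is.null(assembly)) {
    assembly_length(assembly, exclude_gaps = exclude_gaps)
  } else {
    total_length
  }
  frac <- if (is.null(denom)) NA_real_ else sum(lens) / denom
  tibble::tibble(
    n_domains = n,
    mean_length = if (n > 0) mean(lens) else NA_real_,
    total_domain_bp = sum(lens),
    genome_fraction = frac,
    genome_percent = 100 * frac
  )
}

#' Domains specific to one cell type
#'
#' Returns the domains of `a` with no overlap (of at least `min_bp` bases)
#' against any domain of `b` — e.g. erythroid domains absent from HSPCs.
#'
#' @param a,b Interval tables of domains from two cell types.
#' @param min_bp Minimum overlap in bases that disqualifies a domain.
#' @return The specific subset of `a`, sorted.
#' @export
celltype_specific_domains <- function(a, b, min_bp = 1L) {
  a <- as_intervals(a)
  b <- as_intervals(b)
  a[!overlaps_any(a, b, min_bp), , drop = FALSE]
}

#' Total hg19 assembly length in bases
#'
#' The gap-inclusive length of the hg19/GRCh37 human reference assembly
#' (all scaffolds), used as the default denominator for genome-fraction
#' statistics on human data.
#' @export
hg19_assembly_length <- 3137161264
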