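# Partition of the genome into feature bins relative to gene models.

bin_levels <- c("promoter", "downstream", "genic", "five_prime_distal",
                "three_prime_distal", "intergenic", "unassigned_gap")

#' Validate a gene model table
#'
#' Gene models are strand-resolved: `tss` is the transcription start and
#' `tes` the transcription end, so `tss < tes` on the `+` strand and
#' `tss > tes` on the `-` strand.
#'
#' @param x Data frame with columns `chrom`, `strand` (`+`/`-`), `tss`,
#'   `tes`, `gene_id`.
#' @return A tibble.
#' @export
as_gene_models <- function(x) {
  x <- as_tibble(x)
  req <- c("chrom", "strand", "tss", "tes", "gene_id")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("gene table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(x$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  plus_bad <- x$strand == "+" & x$tss >= x$tes
  minus_bad <- x$strand == "-" & x$tss <= x$tes
  if (any(plus_bad | minus_bad)) {
    abort(paste0("tss/tes not strand-consistent for gene ",
                 x$gene_id[which(plus_bad | minus_bad)[1]]))
  }
  x
}

#' Read gene models from BED6 or a refFlat-like table
#'
#' For BED6, `tss` is `start` on the `+` strand and `end` on the `-` strand
#' (`tes` the opposite end). A refFlat-like TSV must already carry
#' `chrom`, `strand`, `tss`, `tes`, `gene_id` columns (header required).
#'
#' @param path File path.
#' @param format `"bed6"` or `"tsv"`.
#' @return A gene model tibble (see [as_gene_models()]).
#' @export
read_genes <- function(path, format = c("bed6", "tsv")) {
  format <- match.arg(format)
  if (format == "bed6") {
    x <- read_bed(path, "bed6")
    as_gene_models(tibble(
      chrom = x$chrom,
      strand = x$strand,
      tss = ifelse(x$strand == "+", x$start, x$end),
      tes = ifelse(x$strand == "+", x$end, x$start),
      gene_id = x$name
    ))
  } else {
    as_gene_models(readr::read_tsv(path, show_col_types = FALSE))
  }
}

# strand-resolved candidate windows for one bin type, clipped later
gene_windows <- function(genes, which, promoter_d, distal_d) {
  up <- ifelse(genes$strand == "+", -1L, 1L)  # direction towards 5'
  switch(
    which,
    promoter = tibble(chrom = genes$chrom,
                      start = genes$tss - promoter_d, end = genes$tss + promoter_d),
    downstream = tibble(chrom = genes$chrom,
                        start = genes$tes - promoter_d, end = genes$tes + promoter_d),
    genic = tibble(chrom = genes$chrom,
                   start = pmin(genes$tss, genes$tes), end = pmax(genes$tss, genes$tes)),
    five_prime_distal = tibble(
      chrom = genes$chrom,
      start = ifelse(genes$strand == "+", genes$tss - distal_d, genes$tss + promoter_d),
      end = ifelse(genes$strand == "+", genes$tss - promoter_d, genes$tss + distal_d)),
    three_prime_distal = tibble(
      chrom = genes$chrom,
      start = ifelse(genes$strand == "+", genes$tes + promoter_d, genes$tes - distal_d),
      end = ifelse(genes$strand == "+", genes$tes + distal_d, genes$tes - promoter_d))
  )
}

#' Partition a genome into feature bins relative to gene models
#'
#' Assigns every non-gap base to exactly one bin by fixed precedence
#' `promoter > downstream > genic > five_prime_distal > three_prime_distal >
#' intergenic`; assembly gaps form the residual `unassigned_gap` bin, so the
#' bins partition the whole genome. Definitions (all distances configurable):
#' promoter = within `promoter_d` (1 kb) of the TSS; downstream = within
#' `promoter_d` of the TES; genic = the TSS-to-TES gene body; 5'/3' distal =
#' `promoter_d` to `distal_d` (50 kb) beyond the TSS/TES on the strand-aware
#' side; intergenic = everything further than `distal_d` from any gene.
#'
#' @param genes Gene model table (see [as_gene_models()]).
#' @param assembly A [genome_assembly()].
#' @param promoter_d Promoter/downstream half-width in bases (default 1000).
#' @param distal_d Distal reach in bases (default 50000).
#' @return Tibble of disjoint intervals with a `bin` factor column covering
#'   every base of the assembly.
#' @export
build_bins <- function(genes, assembly, promoter_d = 1000L, distal_d = 50000L) {
  stopifnot(inherits(assembly, "genome_assembly"))
  if (promoter_d <= 0 || distal_d <= promoter_d) {
    abort("need 0 < promoter_d < distal_d")
  }
  if (nrow(as_tibble(genes)) > 0) {
    genes <- as_gene_models(genes)
    unknown <- setdiff(genes$chrom, assembly$chrom_sizes$chrom)
    if (length(unknown) > 0) {
      bad <- genes$gene_id[genes$chrom %in% unknown][1]
      abort(paste0("gene off assembly: ", bad))
    }
    sizes <- assembly$chrom_sizes$size[match(genes$chrom, assembly$chrom_sizes$chrom)]
    off <- pmax(genes$tss, genes$tes) > sizes | pmin(genes$tss, genes$tes) < 0
    if (any(off)) abort(paste0("gene off chromosome bounds: ", genes$gene_id[which(off)[1]]))
  }
  remaining <- as_granges0(subtract_gaps(assembly))
  sizes <- assembly$chrom_sizes$size
  names(sizes) <- assembly$chrom_sizes$chrom
  clip <- function(w) {
    w$start <- pmax(w$start, 0L)
    w$end <- pmin(w$end, sizes[as.character(w$chrom)])
    w[w$start < w$end, , drop = FALSE]
  }
  pieces <- list()
  assignable <- c("promoter", "downstream", "genic", "five_prime_distal",
                  "three_prime_distal")
  for (bn in assignable) {
    if (nrow(as_tibble(genes)) == 0) break
    cand <- clip(gene_windows(genes, bn, promoter_d, distal_d))
    if (nrow(cand) == 0) next
    cgr <- GenomicRanges::reduce(as_granges0(cand))
    got <- GenomicRanges::intersect(remaining, cgr)
    remaining <- GenomicRanges::setdiff(remaining, cgr)
    if (length(got) > 0) {
      piece <- granges_as_tibble(got)
      piece$bin <- bn
      pieces[[bn]] <- piece
    }
  }
  if (length(remaining) > 0) {
    inter <- granges_as_tibble(remaining)
    inter$bin <- "intergenic"
    pieces[["intergenic"]] <- inter
  }
  if (nrow(assembly$gaps) > 0) {
    g <- assembly$gaps
    g$bin <- "unassigned_gap"
    pieces[["unassigned_gap"]] <- g
  }
  out <- dplyr::bind_rows(pieces)
  out$bin <- factor(out$bin, levels = bin_levels)
  as_intervals(out)
}

#' Distribution of peaks across genome bins
#'
#' Assigns each peak to exactly one bin via a single point — its `summit`
#' when present, otherwise its midpoint — and tabulates the fraction of
#' peaks per bin against the fraction of the genome each bin occupies, plus
#' their ratio (enrichment over genome composition). Peak fractions sum
#' to 1.
#'
#' @param peaks Interval table (optional `summit` column).
#' @param bins Output of [build_bins()].
#' @return Tibble with one row per bin: `n_peaks`, `peak_fraction`,
#'   `genome_bp`, `genome_fraction`, `enrichment`.
#' @export
peak_bin_distribution <- function(peaks, bins) {
  peaks <- as_intervals(peaks)
  point <- if ("summit" %in% names(peaks)) {
    ifelse(is.na(peaks$summit), (peaks$start + peaks$end) %/% 2L, peaks$summit)
  } else {
    (peaks$start + peaks$end) %/% 2L
  }
  pts <- tibble(chrom = peaks$chrom, start = point, end = point + 1L)
  hits <- overlap_pairs(pts, bins)
  lab <- rep(NA_character_, nrow(peaks))
  lab[hits$query] <- as.character(bins$bin[hits$subject])
  lab[is.na(lab)] <- "unassigned_gap"  # points off every bin (outside assembly)
  genome <- bins |>
    dplyr::group_by(bin = .data$bin) |>
    dplyr::summarise(genome_bp = sum(.data$end - .data$start), .groups = "drop") |>
    tidyr::complete(bin, fill = list(genome_bp = 0)) |>
    dplyr::mutate(genome_fraction = .data$genome_bp / sum(.data$genome_bp))
  tibble(bin = factor(lab, levels = bin_levels)) |>
    dplyr::count(.data$bin, name = "n_peaks") |>
    tidyr::complete(bin, fill = list(n_peaks = 0L)) |>
    dplyr::mutate(peak_fraction = .data$n_peaks / sum(.data$n_peaks)) |>
    dplyr::left_join(genome, by = "bin") |>
    dplyr::mutate(enrichment = ifelse(.data$genome_fraction > 0,
                                      .data$peak_fraction / .data$genome_fraction, NA_real_))
}
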