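# CPM-based expression detection/filtering, fold-change rules, and linkage
# of peaks and repressive domains to gene expression.

counts_matrix <- function(counts) {
  counts <- as_tibble(counts)
  if (!"gene_id" %in% names(counts)) abort("counts must carry a gene_id column")
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  if (!is.numeric(m)) abort("count columns must be numeric")
  if (any(m < 0)) abort("counts must be non-negative")
  rownames(m) <- counts$gene_id
  m
}

#' Counts per million
#'
#' Library-size normalization of a raw count table (columns sum to one
#' million after scaling).
#'
#' @param counts Tibble with a `gene_id` column and one numeric column per
#'   sample.
#' @return Tibble of the same shape holding CPM values.
#' @export
compute_cpm <- function(counts) {
  m <- counts_matrix(counts)
  if (any(colSums(m) == 0)) abort("library sizes must be > 0")
  cpm <- edgeR::cpm(m)
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(cpm))
}

cpm_matrix <- function(counts) counts_matrix(compute_cpm(counts))

#' Detected transcripts (median CPM rule)
#'
#' A transcript counts as detected when its median CPM across samples is
#' strictly greater than `cpm_threshold`.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param cpm_threshold CPM threshold, strict `>` (default 1).
#' @param samples Optional character vector of sample columns to use.
#' @return Tibble of detected genes with their `median_cpm`.
#' @export
detect_transcripts <- function(counts, cpm_threshold = 1, samples = NULL) {
  cpm <- cpm_matrix(counts)
  if (!is.null(samples)) cpm <- cpm[, samples, drop = FALSE]
  med <- apply(cpm, 1, stats::median)
  tibble(gene_id = rownames(cpm), median_cpm = unname(med)) |>
    dplyr::filter(.data$median_cpm > cpm_threshold)
}

#' Filter transcripts (CPM in enough samples)
#'
#' Keeps transcripts with CPM strictly greater than `cpm_threshold` in at
#' least `min_samples` samples.
#'
#' @inheritParams detect_transcripts
#' @param min_samples Minimum number of qualifying samples (default 3).
#' @return Tibble of passing genes with `n_pass`, the number of samples
#'   above threshold.
#' @export
filter_transcripts <- function(counts, cpm_threshold = 1, min_samples = 3L,
                               samples = NULL) {
  cpm <- cpm_matrix(counts)
  if (!is.null(samples)) cpm <- cpm[, samples, drop = FALSE]
  if (min_samples > ncol(cpm)) abort("min_samples exceeds the number of samples")
  n_pass <- rowSums(cpm > cpm_threshold)
  tibble(gene_id = rownames(cpm), n_pass = as.integer(n_pass)) |>
    dplyr::filter(.data$n_pass >= min_samples)
}

#' Classify genes by fold change between two sample groups
#'
#' The ratio `(mean CPM in B + pseudocount) / (mean CPM in A + pseudocount)`
#' classifies a gene `up` (in B relative to A) when it exceeds `min_fold`,
#' `down` when below `1/min_fold`, otherwise `unchanged`.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param group_a,group_b Disjoint character vectors of sample column names.
#' @param min_fold Fold-change threshold, strict (default 2).
#' @param pseudocount CPM pseudocount stabilizing low expressors (default 0.5).
#' @return Tibble with per-gene `mean_cpm_a`, `mean_cpm_b`, `ratio`, `class`.
#' @export
fold_change_classify <- function(counts, group_a, group_b, min_fold = 2,
                                 pseudocount = 0.5) {
  if (length(intersect(group_a, group_b)) > 0) abort("groups must be disjoint")
  if (length(group_a) == 0 || length(group_b) == 0) abort("groups must be non-empty")
  if (min_fold <= 0) abort("min_fold must be > 0")
  cpm <- cpm_matrix(counts)
  missing_s <- setdiff(c(group_a, group_b), colnames(cpm))
  if (length(missing_s) > 0) abort(paste0("unknown sample: ", missing_s[1]))
  ma <- rowMeans(cpm[, group_a, drop = FALSE])
  mb <- rowMeans(cpm[, group_b, drop = FALSE])
  ratio <- (mb + pseudocount) / (ma + pseudocount)
  tibble(
    gene_id = rownames(cpm), mean_cpm_a = unname(ma), mean_cpm_b = unname(mb),
    ratio = unname(ratio),
    class = dplyr::case_when(ratio > min_fold ~ "up",
                             ratio < 1 / min_fold ~ "down",
                             TRUE ~ "unchanged")
  )
}

#' Link peaks to genes by TSS proximity
#'
#' A gene is linked to a peak when the peak interval lies within `d` bases
#' of the gene's TSS (edge distance; a peak covering the TSS has distance
#' 0). When a gene links to peaks of several classes, its resolved class
#' follows the precedence `specific > invariant > others`; all linked
#' classes are also reported.
#'
#' @param peaks Interval table with a `class` column (e.g. from
#'   [classify_cross_cell()]).
#' @param genes Gene model table (see [as_gene_models()]).
#' @param d Maximum TSS distance in bases (default 1000).
#' @param precedence Class precedence for conflict resolution.
#' @return Tibble with one row per gene: `n_linked_peaks`, `classes`
#'   (list-column of all linked classes) and `class` (resolved; `NA` when
#'   unlinked).
#' @export
link_peaks_to_genes <- function(peaks, genes, d = 1000L,
                                precedence = c("specific", "invariant")) {
  if (d < 0) abort("d must be >= 0")
  peaks <- as_intervals(peaks)
  if (!"class" %in% names(peaks)) abort("peaks must carry a class column")
  genes <- as_gene_models(genes)
  anchors <- tibble(chrom = genes$chrom, pos = genes$tss)
  res <- within_distance(peaks, anchors, d = d)
  linked <- res$pairs |>
    dplyr::mutate(peak_class = peaks$class[.data$query]) |>
    dplyr::group_by(anchor = .data$anchor) |>
    dplyr::summarise(n_linked_peaks = dplyr::n(),
                     classes = list(unique(.data$peak_class)), .groups = "drop")
  resolve <- function(cls) {
    for (p in precedence) if (p %in% cls) return(p)
    sort(cls)[1]
  }
  out <- tibble(gene_id = genes$gene_id, n_linked_peaks = 0L,
                classes = list(character(0)), class = NA_character_)
  if (nrow(linked) > 0) {
    out$n_linked_peaks[linked$anchor] <- linked$n_linked_peaks
    out$classes[linked$anchor] <- linked$classes
    out$class[linked$anchor] <- vapply(linked$classes, resolve, character(1))
  }
  out
}

#' Compare gene expression between two classes of genes
#'
#' Expression per gene is `log2(mean CPM over the designated samples + 1)`;
#' the two classes are compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param gene_classes Tibble with `gene_id` and `class` columns (e.g. from
#'   [link_peaks_to_genes()]).
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param class_a,class_b The two class labels to compare.
#' @param samples Optional sample columns over which to average CPM
#'   (default: all).
#' @param exact Passed to [stats::wilcox.test()] (default `NULL`: exact for
#'   small samples without ties).
#' @return An object of class `expr_class_comparison` with per-gene values,
#'   class medians, the rank-sum statistic and two-sided p-value; or, when a
#'   class has fewer than 2 genes, `NULL` with a warning. Supports
#'   [tidy()][generics::tidy] and [glance()][generics::glance].
#' @export
compare_expression_by_class <- function(gene_classes, counts, class_a, class_b,
                                        samples = NULL, exact = NULL) {
  gene_classes <- as_tibble(gene_classes)
  cpm <- cpm_matrix(counts)
  if (!is.null(samples)) cpm <- cpm[, samples, drop = FALSE]
  expr <- log2(rowMeans(cpm) + 1)
  values <- gene_classes |>
    dplyr::filter(.data$class %in% c(class_a, class_b),
                  .data$gene_id %in% names(expr)) |>
    dplyr::mutate(expression = expr[.data$gene_id])
  na <- sum(values$class == class_a); nb <- sum(values$class == class_b)
  if (na < 2 || nb < 2) {
    warn(sprintf("fewer than 2 genes in a class (%s: %d, %s: %d); comparison skipped",
                 class_a, na, class_b, nb))
    return(NULL)
  }
  xa <- values$expression[values$class == class_a]
  xb <- values$expression[values$class == class_b]
  wt <- stats::wilcox.test(xa, xb, alternative = "two.sided", exact = exact)
  structure(
    list(values = values, class_a = class_a, class_b = class_b,
         n_a = na, n_b = nb,
         median_a = stats::median(xa), median_b = stats::median(xb),
         statistic = unname(wt$statistic), p_value = wt$p.value),
    class = "expr_class_comparison"
  )
}

#' @export
print.expr_class_comparison <- function(x, ...) {
  cat(sprintf(
    "<expr_class_comparison> %s (n=%d, median %.2f) vs %s (n=%d, median %.2f)\n  rank-sum W = %.0f, two-sided p = %.3g\n",
    x$class_a, x$n_a, x$median_a, x$class_b, x$n_b, x$median_b,
    x$statistic, x$p_value))
  invisible(x)
}

#' Tidy an expression class comparison
#'
#' @param x An `expr_class_comparison` object.
#' @param ... Unused.
#' @method tidy expr_class_comparison
#' @export
tidy.expr_class_comparison <- function(x, ...) {
  tibble::tibble(class = c(x$class_a, x$class_b), n = c(x$n_a, x$n_b),
                 median_expression = c(x$median_a, x$median_b))
}

#' @rdname tidy.expr_class_comparison
#' @method glance expr_class_comparison
#' @export
glance.expr_class_comparison <- function(x, ...) {
  tibble::tibble(class_a = x$class_a, class_b = x$class_b,
                 n_a = x$n_a, n_b = x$n_b,
                 median_a = x$median_a, median_b = x$median_b,
                 median_difference = x$median_b - x$median_a,
                 statistic = x$statistic, p_value = x$p_value)
}

#' Association between repressive domains and gene expression
#'
#' Classifies genes by whether their TSS lies inside a repressive domain and
#' compares expression between the `in_domain` and `outside` classes (see
#' [compare_expression_by_class()]).
#'
#' @param domains Interval table of repressive domains.
#' @param genes Gene model table.
#' @param counts Count tibble.
#' @param samples Optional sample columns over which to average CPM.
#' @return An `expr_class_comparison` (classes `in_domain` vs `outside`),
#'   with the per-gene classification attached as attribute
#'   `gene_classes`; `NULL` (with a warning) when a class has < 2 genes.
#' @export
domain_expression_association <- function(domains, genes, counts, samples = NULL) {
  genes <- as_gene_models(genes)
  domains <- as_intervals(domains)
  tss <- tibble(chrom = genes$chrom, start = genes$tss, end = genes$tss + 1L)
  inside <- overlaps_any(tss, domains)
  gene_classes <- tibble(gene_id = genes$gene_id,
                         class = ifelse(inside, "in_domain", "outside"))
  cmp <- compare_expression_by_class(gene_classes, counts,
                                     class_a = "outside", class_b = "in_domain",
                                     samples = samples)
  if (!is.null(cmp)) attr(cmp, "gene_classes") <- gene_classes
  cmp
}
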