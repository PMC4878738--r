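# Peak co-occupancy and cross-cell-type classification.

#' Classify peaks of two factors by co-occupancy
#'
#' Labels every peak of set A as `both` (overlapping at least one peak of B
#' by `min_bp` bases) or `a_only`, and symmetrically for B. Each peak is
#' counted once regardless of how many partners it overlaps, so
#' `n_both(A, B)` counts A peaks and need not equal `n_both(B, A)`; both
#' directions are reported by the returned object.
#'
#' @param a,b Interval tables of peaks for the two factors.
#' @param min_bp Minimum overlap in bases defining co-occupancy (default 1).
#' @return An object of class `cooccupancy_result`: a list with `a` and `b`
#'   (the input tibbles plus a `class` column), and counts `n_both_a`
#'   (A peaks co-occupied), `n_both_b`, `n_a_only`, `n_b_only`.
#' @examples
#' a <- data.frame(chrom = "chr1", start = c(0, 200), end = c(100, 300))
#' b <- data.frame(chrom = "chr1", start = 50, end = 150)
#' classify_cooccupancy(a, b)
#' @export
classify_cooccupancy <- function(a, b, min_bp = 1L) {
  a <- as_intervals(a)
  b <- as_intervals(b)
  a_hit <- overlaps_any(a, b, min_bp)
  b_hit <- overlaps_any(b, a, min_bp)
  a$class <- ifelse(a_hit, "both", "a_only")
  b$class <- ifelse(b_hit, "both", "b_only")
  structure(
    list(a = a, b = b,
         n_both_a = sum(a_hit), n_a_only = sum(!a_hit),
         n_both_b = sum(b_hit), n_b_only = sum(!b_hit)),
    class = "cooccupancy_result"
  )
}

#' @export
print.cooccupancy_result <- function(x, ...) {
  cat(sprintf("<cooccupancy_result> A: %d co-occupied / %d alone; B: %d co-occupied / %d alone\n",
              x$n_both_a, x$n_a_only, x$n_both_b, x$n_b_only))
  invisible(x)
}

#' @rdname classify_cooccupancy
#' @param x A `cooccupancy_result`.
#' @param ... Unused.
#' @method tidy cooccupancy_result
#' @export
tidy.cooccupancy_result <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$a, set = "a", .before = 1),
    dplyr::mutate(x$b, set = "b", .before = 1)
  )
}

#' @rdname classify_cooccupancy
#' @method glance cooccupancy_result
#' @export
glance.cooccupancy_result <- function(x, ...) {
  tibble::tibble(
    n_a = x$n_both_a + x$n_a_only, n_b = x$n_both_b + x$n_b_only,
    n_both_a = x$n_both_a, n_a_only = x$n_a_only,
    n_both_b = x$n_both_b, n_b_only = x$n_b_only,
    pct_both_a = percent_common(x$n_both_a, x$n_both_a + x$n_a_only)$percent,
    pct_both_b = percent_common(x$n_both_b, x$n_both_b + x$n_b_only)$percent
  )
}

#' Classify peaks as cell-type specific, invariant or intermediate
#'
#' For each target peak, counts how many of `references` (peak sets from K
#' other cell types) contain at least one overlapping interval. A peak shared
#' with none is `specific`, with all K is `invariant`, otherwise
#' `intermediate`.
#'
#' @param target Interval table of peaks to classify.
#' @param references A list of K interval tables.
#' @param min_bp Minimum overlap in bases.
#' @return The target tibble with `shared_count` (0..K) and `class` columns.
#' @export
classify_cross_cell <- function(target, references, min_bp = 1L) {
  if (!is.list(references) || length(references) == 0 ||
      inherits(references, "data.frame")) {
    abort("references must be a non-empty list of interval tables")
  }
  target <- as_intervals(target)
  k <- length(references)
  hits <- vapply(references, function(r) overlaps_any(target, as_intervals(r), min_bp),
                 logical(nrow(target)))
  shared <- if (nrow(target) == 1) sum(hits) else rowSums(matrix(hits, nrow = nrow(target)))
  target$shared_count <- as.integer(shared)
  target$class <- dplyr::case_when(
    shared == 0 ~ "specific",
    shared == k ~ "invariant",
    TRUE ~ "intermediate"
  )
  attr(target, "n_references") <- k
  target
}

#' Summarize a cross-cell classification
#'
#' @param classified Output of [classify_cross_cell()].
#' @return Tibble with one row per class: count, fraction and integer percent.
#' @export
cross_cell_summary <- function(classified) {
  n <- nrow(classified)
  classified |>
    dplyr::count(class = factor(.data$class,
                                levels = c("specific", "intermediate", "invariant"))) |>
    tidyr::complete(class, fill = list(n = 0L)) |>
    dplyr::mutate(fraction = .data$n / !!n,
                  percent = round_half_up(100 * .data$n / !!n))
}

# round half away from zero, the convention of printed integer percents
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percent of common sites
#'
#' The fraction of common (shared) sites over a total, times 100, reported
#' raw and rounded half-away-from-zero to the nearest integer — the
#' convention used for printed percentages in peak-sharing tables.
#'
#' @param n_common,n_total Counts; `0 <= n_common <= n_total`, `n_total > 0`.
#' @return Tibble with `n_common`, `n_total`, `percent` (raw) and
#'   `percent_rounded` (integer).
#' @examples
#' percent_common(24867, 49417)  # 50%
#' @export
percent_common <- function(n_common, n_total) {
  if (any(n_total <= 0)) abort("n_total must be > 0")
  if (any(n_common < 0) || any(n_common > n_total)) {
    abort("n_common must lie in [0, n_total]")
  }
  pct <- 100 * n_common / n_total
  tibble::tibble(n_common = n_common, n_total = n_total,
                 percent = pct, percent_rounded = round_half_up(pct))
}

#' Filter peaks on fold enrichment and p-value
#'
#' Keeps peaks with `fold_enrichment` strictly greater than `min_fold` and,
#' when `max_p` is given, p-value strictly below `max_p` (peaks carry
#' `neg_log10_p`, so the test is `neg_log10_p > -log10(max_p)`). When
#' `max_p` is `NULL` no p-value condition is applied.
#'
#' @param peaks Interval table with a `fold_enrichment` column (and
#'   `neg_log10_p` if `max_p` is used).
#' @param min_fold Fold-enrichment threshold (strict `>`); must be >= 0.
#' @param max_p Optional p-value ceiling (strict `<`).
#' @return The surviving rows, sorted.
#' @export
filter_peaks <- function(peaks, min_fold, max_p = NULL) {
  if (min_fold < 0) abort("min_fold must be >= 0")
  peaks <- as_intervals(peaks)
  if (!"fold_enrichment" %in% names(peaks)) {
    abort("peaks must carry a fold_enrichment column")
  }
  keep <- peaks$fold_enrichment > min_fold
  if (!is.null(max_p)) {
    if (max_p <= 0 || max_p > 1) abort("max_p must be in (0, 1]")
    if (!"neg_log10_p" %in% names(peaks)) {
      warn("no neg_log10_p column; p-value filter skipped")
    } else {
      keep <- keep & !is.na(peaks$neg_log10_p) & peaks$neg_log10_p > -log10(max_p)
    }
  }
  peaks[keep, , drop = FALSE]
}
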