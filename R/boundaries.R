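# Domain boundaries and the 1 kb boundary-marking rule.

#' Extract the boundaries of repressive domains
#'
#' Each domain contributes exactly two boundaries: its start (`left`) and
#' its end (`right`).
#'
#' @param domains Interval table of non-overlapping domains (a `domain_id`
#'   column is used if present, otherwise row numbers).
#' @return Tibble with `chrom`, `pos`, `side` (`left`/`right`), `domain_id`;
#'   `2 * nrow(domains)` rows.
#' @export
extract_boundaries <- function(domains) {
  domains <- as_intervals(domains)
  ids <- if ("domain_id" %in% names(domains)) domains$domain_id else
    paste0("domain_", seq_len(nrow(domains)))
  out <- dplyr::bind_rows(
    tibble(chrom = domains$chrom, pos = domains$start, side = "left", domain_id = ids),
    tibble(chrom = domains$chrom, pos = domains$end, side = "right", domain_id = ids)
  )
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Peaks marking domain boundaries
#'
#' A peak marks a boundary when it lies within `d` bases of the boundary
#' position (default 1 kb; a peak overlapping the position has distance 0).
#' Both tallies are reported: unique marking peaks (a peak near two
#' boundaries of a short domain counts once) and marked boundaries (that
#' same peak counts at each boundary).
#'
#' @param peaks Interval table of binding sites.
#' @param boundaries Output of [extract_boundaries()].
#' @param d Maximum distance in bases (default 1000).
#' @return An object of class `boundary_marking`: a list with `peaks` and
#'   `boundaries` tibbles (each gaining a logical `marks`/`marked` column),
#'   `pairs` (peak/boundary index pairs with distances), and counts
#'   `n_marking_peaks`, `n_marked_boundaries`.
#' @export
mark_boundaries <- function(peaks, boundaries, d = 1000L) {
  if (d < 0) abort("d must be >= 0")
  peaks <- as_intervals(peaks)
  res <- within_distance(peaks, boundaries, d = d)
  peaks$marks <- res$query_hit
  boundaries$marked <- res$anchor_hit
  structure(
    list(peaks = peaks, boundaries = boundaries, pairs = res$pairs,
         n_marking_peaks = sum(res$query_hit),
         n_marked_boundaries = sum(res$anchor_hit)),
    class = "boundary_marking"
  )
}

#' @export
print.boundary_marking <- function(x, ...) {
  cat(sprintf("<boundary_marking> %d of %d peaks mark %d of %d boundaries\n",
              x$n_marking_peaks, nrow(x$peaks),
              x$n_marked_boundaries, nrow(x$boundaries)))
  invisible(x)
}

#' Marking peaks from a boundary-marking result
#'
#' @param marking A `boundary_marking` object.
#' @return The subset of peaks that mark at least one boundary.
#' @export
marking_peaks <- function(marking) {
  stopifnot(inherits(marking, "boundary_marking"))
  marking$peaks[marking$peaks$marks, , drop = FALSE]
}

#' Co-localization of two factors at domain boundaries
#'
#' Given the boundary-marking peak sets of two factors (e.g. CTCF and
#' cohesin), counts the A-marking peaks that overlap at least one B-marking
#' peak, as a count, fraction of A-marking peaks, and rounded integer
#' percent.
#'
#' @param a_marking,b_marking Interval tables of boundary-marking peaks.
#' @param min_bp Minimum overlap in bases.
#' @return One-row tibble: `n_coloc`, `n_a_marking`, `fraction`,
#'   `percent_rounded` (all NA-fraction when `a_marking` is empty).
#' @export
boundary_colocalization <- function(a_marking, b_marking, min_bp = 1L) {
  a_marking <- as_intervals(a_marking)
  b_marking <- as_intervals(b_marking)
  n_a <- nrow(a_marking)
  n <- sum(overlaps_any(a_marking, b_marking, min_bp))
  frac <- if (n_a > 0) n / n_a else NA_real_
  tibble::tibble(
    n_coloc = n, n_a_marking = n_a, fraction = frac,
    percent_rounded = if (n_a > 0) round_half_up(100 * frac) else NA_real_
  )
}

#' Boundary sites shared between two cell types
#'
#' Counts the boundary-marking peaks of cell type A that overlap at least
#' one boundary-marking peak of cell type B.
#'
#' @param a_cell,b_cell Interval tables of boundary-marking peaks from two
#'   cell types.
#' @param min_bp Minimum overlap in bases.
#' @return Integer count.
#' @export
shared_boundary_sites <- function(a_cell, b_cell, min_bp = 1L) {
  sum(overlaps_any(as_intervals(a_cell), as_intervals(b_cell), min_bp))
}
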