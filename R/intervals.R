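#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Coordinate convention: 0-based half-open [start, end), BED-native.
# All interval tables are plain tibbles with at least chrom/start/end.

#' Validate and normalize an interval table
#'
#' Checks the coordinate invariants (`0 <= start < end`, non-empty `chrom`)
#' and returns the table sorted by `(chrom, start, end)`. All other columns
#' are carried along untouched. Coordinates are 0-based half-open, the BED
#' convention used throughout the package.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param flag_duplicates If `TRUE`, adds a logical `duplicated_interval`
#'   column marking rows whose coordinates repeat an earlier row.
#' @return A tibble sorted by `(chrom, start, end)`.
#' @examples
#' as_intervals(data.frame(chrom = "chr1", start = c(500, 0), end = c(600, 100)))
#' @export
as_intervals <- function(x, flag_duplicates = FALSE) {
  x <- as_tibble(x)
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("interval table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
      abort("chrom must be non-empty")
    }
    if (any(is.na(x$start)) || any(is.na(x$end))) abort("start/end must not be NA")
    if (any(x$start < 0)) abort("start must be >= 0")
    bad <- which(x$start >= x$end)
    if (length(bad) > 0) {
      abort(sprintf("start >= end at row %d (%s:%d-%d)",
                    bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
    }
  }
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  if (flag_duplicates) {
    x$duplicated_interval <- duplicated(x[, req])
  }
  x
}

# tibble (0-based half-open) -> GRanges (1-based closed); internal
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# GRanges -> tibble (0-based half-open); internal
granges_as_tibble <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Construct a genome assembly description
#'
#' Bundles chromosome sizes with (optional) assembly gaps — runs of
#' unsequenced bases excluded from binning and randomization. Gaps are
#' normalized (sorted, overlapping gaps merged) and checked to lie within
#' their chromosome.
#'
#' @param chrom_sizes A data frame with columns `chrom` and `size`, or a
#'   named numeric vector of chromosome lengths.
#' @param gaps Optional interval table of assembly gaps.
#' @return An object of class `genome_assembly`: a list with tibbles
#'   `chrom_sizes` and `gaps`.
#' @examples
#' genome_assembly(c(chr1 = 1000), gaps = data.frame(chrom = "chr1", start = 200, end = 300))
#' @export
genome_assembly <- function(chrom_sizes, gaps = NULL) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- tibble(chrom = names(chrom_sizes), size = unname(chrom_sizes))
  }
  chrom_sizes <- as_tibble(chrom_sizes)
  stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)))
  if (any(chrom_sizes$size <= 0)) abort("chromosome sizes must be positive")
  if (anyDuplicated(chrom_sizes$chrom)) abort("duplicate chromosome names")
  if (is.null(gaps) || nrow(as_tibble(gaps)) == 0) {
    gaps <- tibble(chrom = character(), start = integer(), end = integer())
  } else {
    gaps <- as_intervals(gaps)[, c("chrom", "start", "end")]
    unknown <- setdiff(gaps$chrom, chrom_sizes$chrom)
    if (length(unknown) > 0) {
      abort(paste0("gap on unknown chromosome: ", unknown[1]))
    }
    sizes <- chrom_sizes$size[match(gaps$chrom, chrom_sizes$chrom)]
    if (any(gaps$end > sizes)) abort("gap extends beyond chromosome end")
    gaps <- merge_within(gaps, max_gap = 0)
  }
  structure(list(chrom_sizes = chrom_sizes, gaps = gaps), class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %d chromosome(s), %s bp total, %d gap(s) (%s bp)\n",
              nrow(x$chrom_sizes),
              format(sum(x$chrom_sizes$size), big.mark = ","),
              nrow(x$gaps),
              format(sum(x$gaps$end - x$gaps$start), big.mark = ",")))
  invisible(x)
}

#' Total assembly length
#'
#' @param assembly A [genome_assembly()].
#' @param exclude_gaps If `TRUE`, subtract the total gap length.
#' @return Length in bases.
#' @export
assembly_length <- function(assembly, exclude_gaps = FALSE) {
  tot <- sum(assembly$chrom_sizes$size)
  if (exclude_gaps) tot <- tot - sum(assembly$gaps$end - assembly$gaps$start)
  tot
}

#' Read a BED-family peak or interval file
#'
#' Parses BED3/BED6, ENCODE narrowPeak (10-column) and SICER-style enriched
#' window tables into a normalized (sorted) interval tibble. narrowPeak
#' summits are converted from the column-10 offset to an absolute `summit`
#' position (a `-1` offset, the conventional sentinel, yields `NA`). The
#' SICER dialect maps a configurable score column onto `fold_enrichment`.
#'
#' @param path File path.
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowPeak"`, `"sicer_window"`.
#' @param fold_col For `sicer_window`: 1-based index of the fold-enrichment
#'   column (default 7, the SICER island fold-change column).
#' @return A sorted tibble with `chrom`, `start`, `end` plus dialect-specific
#'   columns (`name`, `score`, `strand`, `fold_enrichment`, `neg_log10_p`,
#'   `summit`).
#' @export
read_bed <- function(path, dialect = c("bed3", "bed6", "narrowPeak", "sicer_window"),
                     fold_col = 7L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  min_cols <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowPeak = 10L,
                     sicer_window = max(3L, fold_col))
  ncols <- lengths(fields)
  if (any(ncols < min_cols)) {
    abort(sprintf("line %d of %s has %d field(s); dialect '%s' needs >= %d",
                  which(ncols < min_cols)[1], path, min(ncols), dialect, min_cols))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  x <- tibble(
    chrom = col(1),
    start = suppressWarnings(as.integer(col(2))),
    end = suppressWarnings(as.integer(col(3)))
  )
  bad <- which(is.na(x$start) | is.na(x$end))
  if (length(bad) > 0) {
    abort(sprintf("malformed coordinates at line %d of %s", bad[1], path))
  }
  bad <- which(x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf("start >= end at line %d of %s", bad[1], path))
  }
  if (dialect %in% c("bed6", "narrowPeak")) {
    x$name <- col(4)
    x$score <- suppressWarnings(as.numeric(col(5)))
    x$strand <- col(6)
  }
  if (dialect == "narrowPeak") {
    x$fold_enrichment <- suppressWarnings(as.numeric(col(7)))
    x$neg_log10_p <- suppressWarnings(as.numeric(col(8)))
    offset <- suppressWarnings(as.integer(col(10)))
    x$summit <- ifelse(offset >= 0, x$start + offset, NA_integer_)
  }
  if (dialect == "sicer_window") {
    x$fold_enrichment <- suppressWarnings(as.numeric(col(fold_col)))
    if (any(is.na(x$fold_enrichment))) {
      abort(sprintf("non-numeric fold enrichment at line %d of %s",
                    which(is.na(x$fold_enrichment))[1], path))
    }
  }
  as_intervals(x)
}

#' Write an interval table as BED
#'
#' Writes `chrom`, `start`, `end` plus optional `name` and `score` columns as
#' tab-separated BED with no header.
#'
#' @param x Interval table.
#' @param path Output path.
#' @param name_col,score_col Optional column names to place in BED columns 4-5.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, name_col = NULL, score_col = NULL) {
  x <- as_intervals(x)
  out <- x[, c("chrom", "start", "end")]
  if (!is.null(name_col)) out$name <- x[[name_col]]
  if (!is.null(score_col)) {
    if (is.null(name_col)) out$name <- "."
    out$score <- x[[score_col]]
  }
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Pairwise interval overlap test
#'
#' Tests whether paired intervals overlap by at least `min_bp` bases. Rows of
#' `a` are matched to rows of `b` positionally (either may have one row, which
#' is recycled). Intervals on different chromosomes never overlap; half-open
#' adjacency (`end == start`) is not an overlap.
#'
#' @param a,b Interval tables (or single-row tibbles).
#' @param min_bp Minimum overlap in bases (default 1).
#' @return Logical vector.
#' @examples
#' overlaps(data.frame(chrom = "chr1", start = 0, end = 10),
#'          data.frame(chrom = "chr1", start = 9, end = 20))
#' @export
overlaps <- function(a, b, min_bp = 1L) {
  if (min_bp < 1) abort("min_bp must be >= 1")
  a <- as_tibble(a); b <- as_tibble(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1) a <- a[rep(1, n), ]
  if (nrow(b) == 1) b <- b[rep(1, n), ]
  if (nrow(a) != nrow(b)) abort("a and b must have matching (or recyclable) row counts")
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  as.character(a$chrom) == as.character(b$chrom) & ov >= min_bp
}

#' Which query intervals overlap any subject interval?
#'
#' @param queries,subjects Interval tables.
#' @param min_bp Minimum overlap in bases.
#' @return Logical vector, one element per row of `queries`.
#' @export
overlaps_any <- function(queries, subjects, min_bp = 1L) {
  if (min_bp < 1) abort("min_bp must be >= 1")
  queries <- as_tibble(queries); subjects <- as_tibble(subjects)
  if (nrow(queries) == 0) return(logical(0))
  if (nrow(subjects) == 0) return(rep(FALSE, nrow(queries)))
  # no shared chromosomes is a legitimate "no overlap", not a warning
  suppressWarnings(
    IRanges::overlapsAny(as_granges0(queries), as_granges0(subjects),
                         minoverlap = as.integer(min_bp))
  )
}

#' All overlapping query/subject pairs
#'
#' @inheritParams overlaps_any
#' @return Tibble with `query` and `subject` row indices.
#' @export
overlap_pairs <- function(queries, subjects, min_bp = 1L) {
  if (min_bp < 1) abort("min_bp must be >= 1")
  queries <- as_tibble(queries); subjects <- as_tibble(subjects)
  if (nrow(queries) == 0 || nrow(subjects) == 0) {
    return(tibble(query = integer(), subject = integer()))
  }
  h <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges0(queries), as_granges0(subjects),
                                minoverlap = as.integer(min_bp))
  )
  tibble(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

#' Merge intervals separated by at most a given gap
#'
#' Transitive-closure merge: two intervals on the same chromosome join when
#' the gap between them (`start_j - end_i`) is at most `max_gap`; chains of
#' such intervals collapse into one. With `max_gap = 0` this is a plain union
#' of overlapping/adjacent intervals. The result is sorted, non-overlapping
#' and idempotent under re-application.
#'
#' @param x Interval table.
#' @param max_gap Maximum gap in bases (>= 0).
#' @return Tibble of merged intervals with an `n_merged` column counting the
#'   input intervals absorbed into each output interval.
#' @examples
#' merge_within(data.frame(chrom = "chr1", start = c(0, 2500), end = c(1000, 3000)),
#'              max_gap = 2000)
#' @export
merge_within <- function(x, max_gap = 0L) {
  if (max_gap < 0) abort("max_gap must be >= 0")
  x <- as_intervals(x)
  if (nrow(x) == 0) return(tibble(chrom = character(), start = integer(),
                                  end = integer(), n_merged = integer()))
  gr <- as_granges0(x)
  red <- GenomicRanges::reduce(gr, min.gapwidth = as.integer(max_gap) + 1L)
  out <- granges_as_tibble(red)
  out$n_merged <- GenomicRanges::countOverlaps(red, gr)
  as_intervals(out)
}

# normalize anchors: accepts interval table, or table with chrom+pos,
# representing positions as 1-bp intervals [pos, pos+1)
normalize_anchors <- function(anchors) {
  anchors <- as_tibble(anchors)
  if (!"start" %in% names(anchors)) {
    pos_col <- intersect(c("pos", "position"), names(anchors))
    if (length(pos_col) == 0) abort("anchors need start/end or a pos/position column")
    anchors$start <- anchors[[pos_col[1]]]
    anchors$end <- anchors$start + 1L
  }
  anchors
}

#' Proximity matching between intervals and anchors
#'
#' A query matches an anchor when they overlap, or when they are within `d`
#' intervening bases of each other on the same chromosome. Anchors may be
#' intervals (`start`/`end`) or point positions (a `pos` column, treated as
#' the 1-bp interval `[pos, pos + 1)`). Distance is the count of bases
#' strictly between the two intervals, so an overlap has distance 0. With
#' `d = 0` a genuine overlap is required: bookended intervals (zero
#' intervening bases but no shared base) match only for `d >= 1`.
#'
#' @param queries Interval table.
#' @param anchors Interval table or position table (`chrom` + `pos`).
#' @param d Maximum distance in bases (>= 0).
#' @return A list with `query_hit` (logical per query), `anchor_hit` (logical
#'   per anchor) and `pairs` (tibble of matching `query`/`anchor` indices with
#'   the `distance` between them).
#' @examples
#' within_distance(data.frame(chrom = "chr1", start = 5000, end = 5200),
#'                 data.frame(chrom = "chr1", pos = 6000), d = 1000)
#' @export
within_distance <- function(queries, anchors, d = 1000L) {
  if (d < 0) abort("d must be >= 0")
  queries <- as_tibble(queries)
  anchors <- normalize_anchors(anchors)
  empty <- list(query_hit = rep(FALSE, nrow(queries)),
                anchor_hit = rep(FALSE, nrow(anchors)),
                pairs = tibble(query = integer(), anchor = integer(),
                               distance = integer()))
  if (nrow(queries) == 0 || nrow(anchors) == 0) return(empty)
  # candidate pairs: expand anchors by d + 1 so every pair with gap <= d
  # (including bookended, gap 0) produces an overlap hit, then filter exactly
  expanded <- tibble(chrom = anchors$chrom,
                     start = anchors$start - (as.integer(d) + 1L),
                     end = anchors$end + (as.integer(d) + 1L))
  qgr <- as_granges0(queries)
  agr <- GenomicRanges::GRanges(as.character(expanded$chrom),
                                IRanges::IRanges(expanded$start + 1L, expanded$end))
  h <- suppressWarnings(GenomicRanges::findOverlaps(qgr, agr))
  qi <- S4Vectors::queryHits(h); ai <- S4Vectors::subjectHits(h)
  gap <- pmax(anchors$start[ai] - queries$end[qi],
              queries$start[qi] - anchors$end[ai])
  is_overlap <- pmin(queries$end[qi], anchors$end[ai]) -
    pmax(queries$start[qi], anchors$start[ai]) >= 1
  keep <- is_overlap | (d >= 1 & gap >= 0 & gap <= d)
  qi <- qi[keep]; ai <- ai[keep]
  dist <- ifelse(is_overlap[keep], 0L, pmax(gap[keep], 0L))
  list(
    query_hit = seq_len(nrow(queries)) %in% qi,
    anchor_hit = seq_len(nrow(anchors)) %in% ai,
    pairs = tibble(query = qi, anchor = ai, distance = as.integer(dist))
  )
}

#' Complement of assembly gaps
#'
#' Returns, per chromosome, the sorted disjoint intervals of sequenced
#' (non-gap) genome: the complement of the gap set within `[0, size)`.
#'
#' @param assembly A [genome_assembly()].
#' @return Tibble of non-gap intervals (`chrom`, `start`, `end`) covering
#'   every chromosome.
#' @export
subtract_gaps <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  full <- tibble(chrom = assembly$chrom_sizes$chrom,
                 start = 0L, end = assembly$chrom_sizes$size)
  if (nrow(assembly$gaps) == 0) return(as_intervals(full))
  res <- GenomicRanges::setdiff(as_granges0(full), as_granges0(assembly$gaps))
  as_intervals(granges_as_tibble(res))
}
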