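test_that("read_bed parses dialects and normalizes order", {
  p <- write_temp_bed(c("chr2\t500\t900", "chr1\t100\t200", "chr1\t50\t80"))
  x <- read_bed(p, "bed3")
  expect_equal(x$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(x$start, c(50, 100, 500))
  # matches a naive sort of the raw rows
  raw <- data.frame(chrom = c("chr2", "chr1", "chr1"),
                    start = c(500, 100, 50), end = c(900, 200, 80))
  expect_equal(as.data.frame(x), raw[order(raw$chrom, raw$start), ],
               ignore_attr = TRUE)

  np <- write_temp_bed(c(
    "chr1\t100\t400\tpeak1\t60\t.\t8.5\t6.2\t4.1\t150",
    "chr1\t600\t800\tpeak2\t50\t.\t5.0\t5.5\t3.0\t-1"
  ))
  pk <- read_bed(np, "narrowPeak")
  expect_equal(pk$summit, c(250, NA))
  expect_equal(pk$fold_enrichment, c(8.5, 5.0))
  expect_equal(pk$neg_log10_p, c(6.2, 5.5))

  si <- write_temp_bed(c("chr1\t0\t200\t55\t10\t0.001\t4.5\t0.01"))
  sw <- read_bed(si, "sicer_window")
  expect_equal(sw$fold_enrichment, 4.5)
})

test_that("read_bed reports malformed lines by number", {
  p <- write_temp_bed(c("chr1\t100\t200", "chr1\t300"))
  expect_error(read_bed(p, "bed3"), "line 2")
  p2 <- write_temp_bed(c("chr1\t100\t200", "chr1\t500\t400"))
  expect_error(read_bed(p2, "bed3"), "line 2")
  expect_error(read_bed(tempfile(), "bed3"), "not found")
})

test_that("interval tables round-trip through write_bed/read_bed", {
  withr::local_seed(71)
  x <- as_intervals(random_interval_set(40))
  p <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, p)
  expect_equal(read_bed(p, "bed3"), x[, c("chrom", "start", "end")])
})

test_that("pairwise overlaps follows half-open convention", {
  i1 <- data.frame(chrom = "chr1", start = 0, end = 10)
  expect_true(overlaps(i1, data.frame(chrom = "chr1", start = 9, end = 20)))
  expect_false(overlaps(i1, data.frame(chrom = "chr1", start = 10, end = 20)))
  expect_false(overlaps(i1, data.frame(chrom = "chr2", start = 0, end = 10)))
  expect_error(overlaps(i1, i1, min_bp = 0))
})

test_that("overlap detection equals all-pairs brute force on random sets", {
  withr::local_seed(4001)
  for (rep in 1:5) {
    a <- random_interval_set(200)
    b <- random_interval_set(200)
    for (min_bp in c(1, 50)) {
      expected <- oracle_overlap_pairs(a, b, min_bp)
      got <- overlap_pairs(as_intervals(a), as_intervals(b), min_bp)
      # brute force indexes raw rows; re-sort both against sorted tables
      a_s <- as_intervals(a); b_s <- as_intervals(b)
      exp_pairs <- oracle_overlap_pairs(a_s, b_s, min_bp)
      expect_equal(
        got[order(got$query, got$subject), ],
        tibble::tibble(query = exp_pairs[, 1], subject = exp_pairs[, 2]) |>
          dplyr::arrange(query, subject)
      )
      expect_equal(overlaps_any(a_s, b_s, min_bp),
                   seq_len(nrow(a_s)) %in% exp_pairs[, 1])
    }
  }
})

test_that("overlaps is symmetric", {
  withr::local_seed(90)
  a <- random_interval_set(100)
  b <- random_interval_set(100)
  expect_equal(overlaps(a, b), overlaps(b, a))
})

test_that("merge_within applies the gap rule transitively", {
  x <- data.frame(chrom = "chr1", start = c(0, 2500), end = c(1000, 3000))
  m <- merge_within(x, max_gap = 2000)
  expect_equal(m[, c("start", "end")], tibble::tibble(start = 0L, end = 3000L))
  x2 <- data.frame(chrom = "chr1", start = c(0, 3500), end = c(1000, 4000))
  expect_equal(nrow(merge_within(x2, max_gap = 2000)), 2L)  # gap 2500 stays split
  # chain: each link <= gap, whole chain collapses
  chain <- data.frame(chrom = "chr1", start = c(0, 150, 300), end = c(100, 250, 400))
  expect_equal(nrow(merge_within(chain, max_gap = 50)), 1L)
})

test_that("merge_within matches the scan oracle and is idempotent and order-independent", {
  withr::local_seed(4002)
  for (rep in 1:5) {
    x <- random_interval_set(500)
    for (gap in c(0, 100, 2000)) {
      m <- merge_within(x, max_gap = gap)
      o <- oracle_merge(x, max_gap = gap)
      expect_equal(as.data.frame(m[, c("chrom", "start", "end")]), o,
                   ignore_attr = TRUE)
      expect_equal(merge_within(m, max_gap = gap)[, c("chrom", "start", "end")],
                   m[, c("chrom", "start", "end")])
      shuffled <- x[sample(nrow(x)), ]
      expect_equal(merge_within(shuffled, max_gap = gap), m)
    }
  }
})

test_that("merged coverage never shrinks and equals union coverage", {
  withr::local_seed(4003)
  x <- random_interval_set(300, chroms = "chrT", max_pos = 5e4)
  cover <- rep(FALSE, 5e4)
  for (i in seq_len(nrow(x))) cover[(x$start[i] + 1):x$end[i]] <- TRUE
  m0 <- merge_within(x, max_gap = 0)
  expect_equal(sum(m0$end - m0$start), sum(cover))
  m2 <- merge_within(x, max_gap = 200)
  expect_gte(sum(m2$end - m2$start), sum(cover))
})

test_that("within_distance handles the 1 kb rule and point anchors", {
  peak <- data.frame(chrom = "chr1", start = 5000, end = 5200)
  hit <- within_distance(peak, data.frame(chrom = "chr1", pos = 6000), d = 1000)
  expect_true(hit$query_hit)
  expect_equal(hit$pairs$distance, 800L)
  miss <- within_distance(peak, data.frame(chrom = "chr1", pos = 6500), d = 1000)
  expect_false(miss$query_hit)
  # overlap means distance zero
  ov <- within_distance(data.frame(chrom = "chr1", start = 4800, end = 5100),
                        data.frame(chrom = "chr1", pos = 5000), d = 0)
  expect_true(ov$query_hit)
  expect_equal(ov$pairs$distance, 0L)
  # exact boundary distance d still matches
  edge <- within_distance(data.frame(chrom = "chr1", start = 4000, end = 5000),
                          data.frame(chrom = "chr1", pos = 6000), d = 1000)
  expect_true(edge$query_hit)
})

test_that("within_distance equals the brute-force predicate on random instances", {
  withr::local_seed(4004)
  for (rep in 1:5) {
    q <- as_intervals(random_interval_set(120))
    a <- as_intervals(random_interval_set(80))
    for (d in c(0, 1, 250, 1000)) {
      res <- within_distance(q, a, d = d)
      mat <- oracle_within(q, a, d)
      expect_equal(res$query_hit, apply(mat, 1, any))
      expect_equal(res$anchor_hit, apply(mat, 2, any))
    }
  }
})

test_that("within_distance at d = 0 coincides with 1 bp overlap", {
  withr::local_seed(4005)
  q <- as_intervals(random_interval_set(150))
  a <- as_intervals(random_interval_set(150))
  expect_equal(within_distance(q, a, d = 0)$query_hit, overlaps_any(q, a, 1))
})

test_that("subtract_gaps complements gaps exactly", {
  asm <- toy_assembly(1000, gaps = data.frame(chrom = "chrT", start = 200, end = 300))
  ng <- subtract_gaps(asm)
  expect_equal(ng$start, c(0, 300))
  expect_equal(ng$end, c(200, 1000))
  expect_equal(sum(ng$end - ng$start), 900)
  # no gaps: identity
  ng0 <- subtract_gaps(toy_assembly(1000))
  expect_equal(ng0, tibble::tibble(chrom = "chrT", start = 0L, end = 1000L),
               ignore_attr = TRUE)
})

test_that("non-gap length conserves total minus gap bases for random gaps", {
  withr::local_seed(4006)
  for (rep in 1:5) {
    g <- random_interval_set(20, chroms = "chrT", max_pos = 9e4, max_len = 400)
    asm <- toy_assembly(1e5, gaps = g)
    merged_gap <- sum(asm$gaps$end - asm$gaps$start)
    ng <- subtract_gaps(asm)
    expect_equal(sum(ng$end - ng$start), 1e5 - merged_gap)
    # disjoint and sorted
    expect_true(all(ng$start[-1] >= ng$end[-nrow(ng)]))
  }
})

test_that("assembly validation rejects out-of-bounds gaps", {
  expect_error(toy_assembly(1000, gaps = data.frame(chrom = "chrT", start = 900, end = 1100)),
               "beyond")
  expect_error(genome_assembly(c(chrT = 500),
                               gaps = data.frame(chrom = "chrX", start = 0, end = 10)),
               "unknown")
  expect_error(as_intervals(data.frame(chrom = "chr1", start = 10, end = 10)),
               "start >= end")
})
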