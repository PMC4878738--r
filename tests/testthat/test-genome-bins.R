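test_that("single-gene partition matches the per-base oracle", {
  asm <- genome_assembly(c(chr1 = 3e5))
  genes <- data.frame(chrom = "chr1", strand = "+", tss = 1e5, tes = 1.2e5,
                      gene_id = "g1")
  bins <- build_bins(genes, asm)
  # hand-checkable pieces under precedence promoter > downstream > genic
  prom <- bins[bins$bin == "promoter", ]
  expect_equal(c(prom$start, prom$end), c(99000, 101000))
  genic <- bins[bins$bin == "genic", ]
  expect_equal(c(genic$start, genic$end), c(101000, 119000))
  down <- bins[bins$bin == "downstream", ]
  expect_equal(c(down$start, down$end), c(119000, 121000))
  expect_equal(sum(bins$end - bins$start), 3e5)
})

test_that("bin partition is total, disjoint and oracle-identical on toy genomes", {
  withr::local_seed(4201)
  for (rep in 1:4) {
    size <- 1e5
    gaps <- random_interval_set(3, chroms = "chrT", max_pos = 9e4, max_len = 2000)
    asm <- toy_assembly(size, gaps = gaps)
    n_genes <- sample(2:5, 1)
    tss <- floor(runif(n_genes, 5000, 90000))
    len <- floor(runif(n_genes, 3000, 20000))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- data.frame(
      chrom = "chrT", strand = strand,
      tss = tss,
      tes = ifelse(strand == "+", pmin(tss + len, size), pmax(tss - len, 0)),
      gene_id = paste0("g", seq_len(n_genes))
    )
    genes <- genes[genes$strand == "+" | genes$tes < genes$tss, , drop = FALSE]
    genes <- genes[genes$strand == "-" | genes$tes > genes$tss, , drop = FALSE]
    bins <- build_bins(genes, asm, promoter_d = 1000, distal_d = 20000)
    expect_equal(sum(bins$end - bins$start), size)  # total
    got <- bins_to_labels(bins, "chrT", size)
    expect_false(anyNA(got))                         # disjoint & covering
    want <- oracle_bin_labels(genes, "chrT", size, gaps = asm$gaps,
                              promoter_d = 1000, distal_d = 20000)
    expect_equal(got, want)
  }
})

test_that("gene-free genome is entirely intergenic", {
  asm <- toy_assembly(5e4)
  bins <- build_bins(data.frame(chrom = character(), strand = character(),
                                tss = numeric(), tes = numeric(),
                                gene_id = character()), asm)
  expect_equal(as.character(bins$bin), "intergenic")
  expect_equal(sum(bins$end - bins$start), 5e4)
})

test_that("genes off the assembly are rejected by id", {
  asm <- toy_assembly(1e4)
  genes <- data.frame(chrom = "chrT", strand = "+", tss = 9000, tes = 12000,
                      gene_id = "runaway")
  expect_error(build_bins(genes, asm), "runaway")
})

test_that("peak assignment uses summit else midpoint and fractions sum to one", {
  asm <- genome_assembly(c(chr1 = 3e5))
  genes <- data.frame(chrom = "chr1", strand = "+", tss = 1e5, tes = 1.2e5,
                      gene_id = "g1")
  bins <- build_bins(genes, asm)
  peaks <- data.frame(chrom = "chr1",
                      start = c(99400, 99400), end = c(99600, 99600),
                      summit = c(NA, 130000))  # midpoint in promoter; summit in 3' distal
  d <- peak_bin_distribution(peaks, bins)
  expect_equal(d$n_peaks[d$bin == "promoter"], 1L)
  expect_equal(d$n_peaks[d$bin == "three_prime_distal"], 1L)
  expect_equal(sum(d$peak_fraction), 1)
  expect_equal(sum(d$genome_fraction), 1)
})

test_that("per-peak bin assignment equals a point-lookup oracle", {
  withr::local_seed(4202)
  asm <- toy_assembly(1e5)
  genes <- data.frame(chrom = "chrT", strand = c("+", "-"),
                      tss = c(20000, 80000), tes = c(35000, 62000),
                      gene_id = c("g1", "g2"))
  bins <- build_bins(genes, asm, promoter_d = 1000, distal_d = 20000)
  labels <- bins_to_labels(bins, "chrT", 1e5)
  peaks <- random_interval_set(500, chroms = "chrT", max_pos = 1e5 - 600)
  d <- peak_bin_distribution(peaks, bins)
  mid <- (peaks$start + peaks$end) %/% 2
  want <- table(factor(labels[mid + 1],
                       levels = levels(d$bin)))
  expect_equal(d$n_peaks, as.integer(want))
  expect_equal(sum(d$n_peaks), 500L)
})

test_that("promoter-planted peaks show promoter enrichment over genome share", {
  withr::local_seed(4203)
  asm <- toy_assembly(1e5)
  genes <- data.frame(chrom = "chrT", strand = "+", tss = 50000, tes = 70000,
                      gene_id = "g")
  bins <- build_bins(genes, asm, promoter_d = 1000, distal_d = 20000)
  # half the peaks hug the TSS, half are uniform
  near <- tibble::tibble(chrom = "chrT",
                         start = floor(runif(100, 49200, 50600)))
  near$end <- near$start + 200
  unif <- random_interval_set(100, chroms = "chrT", max_pos = 99000, max_len = 200)
  d <- peak_bin_distribution(dplyr::bind_rows(near, unif), bins)
  expect_gt(d$enrichment[d$bin == "promoter"], 1)
})
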