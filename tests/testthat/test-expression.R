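# counts built so each column sums to 1e6: CPM values equal raw counts,
# making thresholds exactly checkable
counts_with_filler <- function(m) {
  filler <- 1e6 - colSums(m)
  stopifnot(all(filler >= 0))
  out <- rbind(m, filler = filler)
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(out)),
                   tibble::as_tibble(out))
}

test_that("CPM columns are conserved at one million", {
  withr::local_seed(4601)
  counts <- tibble::tibble(gene_id = paste0("g", 1:50)) |>
    dplyr::bind_cols(tibble::as_tibble(matrix(rpois(200, 40), 50,
                                              dimnames = list(NULL, paste0("s", 1:4)))))
  cpm <- compute_cpm(counts)
  expect_equal(unname(colSums(as.matrix(cpm[, -1]))), rep(1e6, 4))
})

test_that("detection uses a strict median-CPM rule", {
  m <- rbind(g1 = c(0.5, 2, 3), g2 = c(0, 0, 0), g3 = c(1, 1, 1))
  colnames(m) <- paste0("s", 1:3)
  counts <- counts_with_filler(m)
  det <- detect_transcripts(counts, cpm_threshold = 1)
  expect_equal(det$gene_id[det$gene_id != "filler"], "g1")  # median 2 > 1; 1 fails strict
})

test_that("detection and filtering match per-gene oracles on random tables", {
  withr::local_seed(4602)
  m <- matrix(rpois(2000, 15), 500, 4, dimnames = list(paste0("g", 1:500), paste0("s", 1:4)))
  counts <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), tibble::as_tibble(m))
  cpm <- t(t(m) / colSums(m)) * 1e6
  det <- detect_transcripts(counts)
  expect_setequal(det$gene_id, rownames(m)[apply(cpm, 1, stats::median) > 1])
  filt <- filter_transcripts(counts, cpm_threshold = 1, min_samples = 3)
  expect_setequal(filt$gene_id, rownames(m)[rowSums(cpm > 1) >= 3])
  # monotone in thresholds
  expect_lte(nrow(detect_transcripts(counts, cpm_threshold = 2)), nrow(det))
  expect_lte(nrow(filter_transcripts(counts, min_samples = 4)), nrow(filt))
})

test_that("the sample-count filter applies the 3-of-n rule", {
  m <- rbind(keep = c(1.5, 1.2, 0.3, 2.0), drop = c(1.5, 0.2, 0.3, 0.4))
  colnames(m) <- paste0("s", 1:4)
  counts <- counts_with_filler(m * 100)  # scale preserved: CPM = 100 * value
  got <- filter_transcripts(counts, cpm_threshold = 100, min_samples = 3)
  expect_true("keep" %in% got$gene_id)
  expect_false("drop" %in% got$gene_id)
})

test_that("fold-change classification follows the pseudocounted ratio", {
  m <- rbind(up = c(10, 10, 25, 25), flat = c(20, 20, 20, 20), down = c(40, 40, 8, 8))
  colnames(m) <- c("a1", "a2", "b1", "b2")
  counts <- counts_with_filler(m * 1000)
  fc <- fold_change_classify(counts, c("a1", "a2"), c("b1", "b2"),
                             min_fold = 2, pseudocount = 0.5)
  expect_equal(fc$class[fc$gene_id == "up"], "up")       # 25000.5/10000.5 = 2.5
  expect_equal(fc$class[fc$gene_id == "flat"], "unchanged")
  expect_equal(fc$class[fc$gene_id == "down"], "down")
  expect_error(fold_change_classify(counts, "a1", "a1"))
  # random table equals direct arithmetic
  withr::local_seed(4603)
  m2 <- matrix(rpois(400, 30), 100, 4,
               dimnames = list(paste0("g", 1:100), c("a1", "a2", "b1", "b2")))
  counts2 <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m2)), tibble::as_tibble(m2))
  cpm2 <- t(t(m2) / colSums(m2)) * 1e6
  ratio <- (rowMeans(cpm2[, 3:4]) + 0.5) / (rowMeans(cpm2[, 1:2]) + 0.5)
  want <- ifelse(ratio > 2, "up", ifelse(ratio < 0.5, "down", "unchanged"))
  got <- fold_change_classify(counts2, c("a1", "a2"), c("b1", "b2"))
  expect_equal(got$class, unname(want[got$gene_id]))
})

test_that("peaks link to genes within 1 kb of the TSS", {
  genes <- data.frame(chrom = "chr1", strand = "+", tss = 2100, tes = 9000,
                      gene_id = "g1")
  pk <- data.frame(chrom = "chr1", start = 990, end = 1200, class = "invariant")
  linked <- link_peaks_to_genes(pk, genes, d = 1000)
  expect_equal(linked$class, "invariant")  # distance 900
  far <- link_peaks_to_genes(dplyr::mutate(pk, start = 100, end = 300), genes, d = 1000)
  expect_true(is.na(far$class))
  # class precedence: specific wins over invariant
  two <- data.frame(chrom = "chr1", start = c(1500, 2500), end = c(1700, 2700),
                    class = c("invariant", "specific"))
  expect_equal(link_peaks_to_genes(two, genes)$class, "specific")
  expect_equal(link_peaks_to_genes(two, genes)$n_linked_peaks, 2L)
})

test_that("peak-gene linkage equals the brute-force TSS-distance oracle", {
  withr::local_seed(4604)
  peaks <- as_intervals(random_interval_set(150))
  peaks$class <- sample(c("specific", "invariant", "intermediate"), 150, replace = TRUE)
  tss <- floor(runif(60, 0, 1e5))
  genes <- data.frame(chrom = sample(c("chrA", "chrB"), 60, replace = TRUE),
                      strand = "+", tss = tss, tes = tss + 500,
                      gene_id = paste0("g", 1:60))
  linked <- link_peaks_to_genes(peaks, genes, d = 1000)
  anchors <- data.frame(chrom = genes$chrom, start = genes$tss, end = genes$tss + 1)
  mat <- oracle_within(peaks, anchors, 1000)
  expect_equal(linked$n_linked_peaks, unname(colSums(mat)))
})

test_that("identical class distributions give a null rank-sum comparison", {
  vals <- c(5, 8, 11, 14, 17, 20)
  m <- matrix(rep(vals, 2), ncol = 1,
              dimnames = list(paste0("g", 1:12), "s1"))
  counts <- counts_with_filler(m * 1000)
  # both classes hold the same multiset of values (rows 1-6 repeat as 7-12)
  classes <- tibble::tibble(gene_id = paste0("g", 1:12),
                            class = rep(c("x", "y"), each = 6))
  cmp <- compare_expression_by_class(classes, counts, "x", "y", exact = FALSE)
  expect_equal(cmp$median_a, cmp$median_b)
  expect_gt(cmp$p_value, 0.9)
})

test_that("small-sample rank-sum p equals the exhaustive-permutation oracle", {
  withr::local_seed(4605)
  for (rep in 1:3) {
    vals <- round(runif(8, 10, 500))  # distinct with prob ~1; re-draw collisions
    while (anyDuplicated(vals)) vals <- round(runif(8, 10, 500))
    m <- matrix(vals, ncol = 1, dimnames = list(paste0("g", 1:8), "s1"))
    counts <- counts_with_filler(m * 100)
    classes <- tibble::tibble(gene_id = paste0("g", 1:8),
                              class = rep(c("x", "y"), each = 4))
    cmp <- compare_expression_by_class(classes, counts, "x", "y", exact = TRUE)
    expr <- log2(vals * 100 + 1)  # CPM equals the scaled count here
    expect_equal(cmp$p_value, oracle_ranksum_p(expr[1:4], expr[5:8]))
  }
})

test_that("a comparison with a near-empty class is skipped with a warning", {
  m <- matrix(1:6 * 10, ncol = 1, dimnames = list(paste0("g", 1:6), "s1"))
  counts <- counts_with_filler(m * 1000)
  classes <- tibble::tibble(gene_id = paste0("g", 1:6),
                            class = c("x", rep("y", 5)))
  expect_warning(out <- compare_expression_by_class(classes, counts, "x", "y"),
                 "skipped")
  expect_null(out)
})

test_that("a planted expression shift is recovered in direction and size", {
  asm <- sim_genome(1, 1e6, 0, seed = 4606)
  genes <- sim_genes(asm, n_genes = 400, seed = 4607)
  genes$class <- rep(c("lo", "hi"), 200)
  sim <- sim_expression(genes, class_shifts = c(lo = 0, hi = 2),
                        n_samples = 4, seed = 4608)
  cmp <- compare_expression_by_class(
    tibble::tibble(gene_id = genes$gene_id, class = genes$class),
    sim$counts, "lo", "hi")
  expect_lt(abs((cmp$median_b - cmp$median_a) - 2), 0.3)
  expect_lt(cmp$p_value, 1e-10)
})

test_that("domain-expression association classifies TSS membership exactly", {
  withr::local_seed(4609)
  asm <- sim_genome(1, 1e6, 0, seed = 4610)
  genes <- sim_genes(asm, n_genes = 300, seed = 4611)
  domains <- as_intervals(random_interval_set(30, chroms = "chr1",
                                              max_pos = 9e5, max_len = 20000))
  # membership equals the point-in-interval oracle
  in_dom <- vapply(seq_len(nrow(genes)), function(i) {
    any(domains$start <= genes$tss[i] & genes$tss[i] < domains$end)
  }, logical(1))
  genes$class <- ifelse(in_dom, "in_domain", "outside")
  sim <- sim_expression(genes, class_shifts = c(in_domain = -2, outside = 0),
                        n_samples = 4, seed = 4612)
  cmp <- domain_expression_association(domains, genes, sim$counts)
  gc <- attr(cmp, "gene_classes")
  expect_equal(gc$class, genes$class)
  expect_lt(cmp$median_b, cmp$median_a)  # repression inside domains
  expect_lt(cmp$p_value, 1e-6)
  # all genes outside: skipped
  expect_warning(
    expect_null(domain_expression_association(
      data.frame(chrom = "chrZ", start = 0, end = 10), genes, sim$counts)),
    "skipped")
})
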