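# Small generators used across test files; all take an explicit seed so
# every test is deterministic.

random_interval_set <- function(n, chroms = c("chrA", "chrB"), max_pos = 1e5,
                                max_len = 500) {
  start <- floor(runif(n, 0, max_pos - max_len))
  len <- pmax(1, floor(runif(n, 1, max_len)))
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + len)
}

toy_assembly <- function(size = 1e5, gaps = NULL) {
  genome_assembly(c(chrT = size), gaps = gaps)
}

write_temp_bed <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
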