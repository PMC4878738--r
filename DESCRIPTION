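Package: chrombound
Title: CTCF and Cohesin Co-Occupancy, Repressive Chromatin Domains, and
    Domain-Boundary Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interval-genomics toolkit for studying CTCF and cohesin(SA-1)
    occupancy and repressive chromatin architecture from ChIP-seq peak calls.
    Classifies peaks by factor co-occupancy and by sharing across cell-type
    panels (invariant versus cell-type-specific sites), partitions a genome
    into feature bins relative to gene models, builds H3K27me3 repressive
    domains from enriched windows by a filter-merge-filter rule, identifies
    peaks marking domain boundaries under a 1 kb proximity rule, tests
    co-localization against a gap-masked length-preserving randomization null
    with empirical p-values, and links peaks and domains to gene expression
    via CPM-based detection, filtering and fold-change rules. A synthetic-data
    generator with planted truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
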