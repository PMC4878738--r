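# Synthetic genomes, peak panels, H3K27me3 window tracks and expression
# tables with planted (known) structure, so every pipeline stage can be
# tested against recorded truth without any external data.

#' Simulate a genome assembly with random gaps
#'
#' Chromosomes of equal length with non-overlapping random gaps totalling
#' approximately `gap_fraction` of each chromosome (within 1%).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param gap_fraction Fraction of each chromosome covered by gaps, in
#'   `[0, 0.5)`.
#' @param seed Optional integer seed (placement is deterministic per seed).
#' @return A [genome_assembly()].
#' @export
sim_genome <- function(n_chrom = 2L, chrom_length = 1e6, gap_fraction = 0.05,
                       seed = NULL) {
  if (gap_fraction < 0 || gap_fraction >= 0.5) abort("gap_fraction must be in [0, 0.5)")
  if (!is.null(seed)) withr::local_seed(seed)
  chroms <- paste0("chr", seq_len(n_chrom))
  sizes <- tibble(chrom = chroms, size = as.integer(chrom_length))
  gaps <- list()
  for (ch in chroms) {
    target <- round(gap_fraction * chrom_length)
    if (target < 1) next
    placed <- tibble(start = numeric(0), end = numeric(0))
    total <- 0
    attempts <- 0
    while (total < target * 0.99 && attempts < 5000) {
      attempts <- attempts + 1
      len <- min(target - total + round(0.005 * target),
                 round(stats::runif(1, 0.05, 0.35) * target))
      len <- max(len, 1)
      s <- floor(stats::runif(1, 0, chrom_length - len))
      if (nrow(placed) == 0 || all(s >= placed$end | s + len <= placed$start)) {
        placed <- dplyr::bind_rows(placed, tibble(start = s, end = s + len))
        total <- total + len
      }
    }
    if (total < target * 0.99) abort("could not place gaps; lower gap_fraction")
    gaps[[ch]] <- dplyr::mutate(placed, chrom = ch, .before = 1)
  }
  genome_assembly(sizes, gaps = dplyr::bind_rows(gaps))
}

# place n intervals of given lengths uniformly in the non-gap genome
place_random <- function(lengths, assembly) {
  pl <- make_placement(lengths, subtract_gaps(assembly))
  d <- draw_placement(pl)
  tibble(chrom = d$chrom, start = d$start, end = d$end)
}

# jittered partner peak guaranteed to overlap its template
partner_peaks <- function(peaks, length_draw) {
  n <- nrow(peaks)
  len <- length_draw(n)
  centre <- (peaks$start + peaks$end) / 2
  shift <- floor(stats::runif(n, -0.3, 0.3) * (peaks$end - peaks$start))
  start <- pmax(floor(centre + shift - len / 2), 0)
  tibble(chrom = peaks$chrom, start = start, end = start + len)
}

#' Simulate a peak panel with planted co-occupancy and cell-type sharing
#'
#' Generates a target-cell CTCF-like peak set with (a) a planted fraction of
#' peaks co-occupied by an overlapping partner-factor (cohesin-like) peak
#' and (b) planted fractions of peaks present in all of `n_references`
#' reference cell types (invariant), in none (specific), or in a random
#' proper subset (intermediate). Peak lengths are log-normal (median
#' ~300 bp, echoing ChIP-seq point-source peaks). Truth labels are recorded
#' per peak.
#'
#' @param assembly A [genome_assembly()]; peaks are placed uniformly in its
#'   non-gap segments.
#' @param n_peaks Number of target peaks.
#' @param cooccupancy_fraction Fraction of target peaks receiving an
#'   overlapping partner peak.
#' @param invariant_fraction,specific_fraction Fractions of target peaks
#'   planted as invariant / specific (their sum must be <= 1).
#' @param n_references Number of reference cell types K.
#' @param extra_partner_fraction Extra partner-only peaks, as a fraction of
#'   `n_peaks`, placed at random (not tied to target peaks).
#' @param peak_meanlog,peak_sdlog Log-normal peak length parameters.
#' @param seed Optional integer seed.
#' @return A list: `target` (peak tibble with `peak_id`), `partner`,
#'   `references` (list of K tibbles), `truth` (per-peak planted
#'   `cooccupied` flag, `share_class` and `shared_count`), and `params`.
#' @export
sim_peak_panel <- function(assembly, n_peaks = 5000L,
                           cooccupancy_fraction = 0.5,
                           invariant_fraction = 0.3, specific_fraction = 0.4,
                           n_references = 7L, extra_partner_fraction = 0.3,
                           peak_meanlog = log(300), peak_sdlog = 0.35,
                           seed = NULL) {
  stopifnot(cooccupancy_fraction >= 0, cooccupancy_fraction <= 1,
            invariant_fraction >= 0, specific_fraction >= 0,
            invariant_fraction + specific_fraction <= 1, n_references >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  length_draw <- function(n) pmax(round(stats::rlnorm(n, peak_meanlog, peak_sdlog)), 50)
  target <- place_random(length_draw(n_peaks), assembly)
  target$peak_id <- paste0("peak_", seq_len(n_peaks))

  # planted co-occupancy: exact count, random subset
  n_co <- round(cooccupancy_fraction * n_peaks)
  co_idx <- sample.int(n_peaks, n_co)
  partner <- partner_peaks(target[co_idx, , drop = FALSE], length_draw)
  n_extra <- round(extra_partner_fraction * n_peaks)
  if (n_extra > 0) {
    partner <- dplyr::bind_rows(partner, place_random(length_draw(n_extra), assembly))
  }

  # planted sharing classes: exact counts
  n_inv <- round(invariant_fraction * n_peaks)
  n_spec <- round(specific_fraction * n_peaks)
  cls <- sample(rep(c("invariant", "specific", "intermediate"),
                    c(n_inv, n_spec, n_peaks - n_inv - n_spec)))
  shared_count <- integer(n_peaks)
  shared_count[cls == "invariant"] <- n_references
  inter_idx <- which(cls == "intermediate")
  if (n_references >= 2) {
    shared_count[inter_idx] <- sample(seq_len(n_references - 1),
                                      length(inter_idx), replace = TRUE)
  } else {
    cls[inter_idx] <- "specific"  # K = 1 admits no intermediate class
  }
  # fixed random subsets for intermediates (exactly shared_count references each)
  membership <- matrix(FALSE, n_peaks, n_references)
  membership[cls == "invariant", ] <- TRUE
  for (i in inter_idx) {
    membership[i, sample.int(n_references, shared_count[i])] <- TRUE
  }
  references <- lapply(seq_len(n_references), function(k) {
    tmpl <- target[membership[, k], , drop = FALSE]
    as_intervals(partner_peaks(tmpl, length_draw))
  })
  list(
    target = as_intervals(target),
    partner = as_intervals(partner),
    references = references,
    truth = tibble(peak_id = target$peak_id,
                   cooccupied = seq_len(n_peaks) %in% co_idx,
                   share_class = cls, shared_count = shared_count),
    params = list(n_peaks = n_peaks, cooccupancy_fraction = cooccupancy_fraction,
                  invariant_fraction = invariant_fraction,
                  specific_fraction = specific_fraction,
                  n_references = n_references, seed = seed)
  )
}

# non-overlapping window-aligned domain placement with minimum spacing
place_domains <- function(lengths, assembly, window_size, min_spacing) {
  segs <- subtract_gaps(assembly)
  segs <- segs[segs$end - segs$start >= max(lengths) + 2 * window_size, , drop = FALSE]
  if (nrow(segs) == 0) abort("no non-gap segment can hold the planted domains")
  placed <- vector("list", length(lengths))
  occupied <- tibble(chrom = character(0), start = numeric(0), end = numeric(0))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    ok <- FALSE
    for (attempt in 1:200) {
      j <- sample.int(nrow(segs), 1, prob = segs$end - segs$start)
      lo <- segs$start[j]; hi <- segs$end[j] - len
      s <- lo + floor(stats::runif(1, 0, (hi - lo) / window_size)) * window_size
      sel <- occupied$chrom == segs$chrom[j]
      if (!any(sel) || all(s >= occupied$end[sel] + min_spacing |
                           s + len <= occupied$start[sel] - min_spacing)) {
        placed[[i]] <- tibble(chrom = segs$chrom[j], start = s, end = s + len)
        occupied <- dplyr::bind_rows(occupied, placed[[i]])
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("could not place planted domains; genome too crowded")
  }
  dplyr::bind_rows(placed)
}

#' Simulate a windowed H3K27me3 enrichment track with planted domains
#'
#' Tiles the non-gap genome with fixed-size windows and assigns each a fold
#' enrichment: log-normal background (median 1) outside planted domains,
#' log-normal domain signal (median `domain_fold`) inside. Planted domains
#' are window-aligned, non-overlapping and separated by at least
#' `min_spacing` bases, so the filter-merge-filter rule can recover their
#' edges to within one window. A boundary-proximal peak is planted at each
#' domain edge independently with probability `boundary_peak_rate`, centred
#' within `boundary_jitter` bases of the edge.
#'
#' @param assembly A [genome_assembly()].
#' @param n_domains Number of planted domains.
#' @param domain_meanlog,domain_sdlog Log-normal planted domain length
#'   parameters (default median 10 kb).
#' @param window_size Window width in bases (default 200).
#' @param background_sdlog Log-normal sd of background fold (meanlog 0).
#' @param domain_fold Median fold enrichment inside domains (default 5).
#' @param domain_fold_sdlog Log-normal sd of domain fold.
#' @param boundary_peak_rate Probability a domain edge receives a planted
#'   boundary peak.
#' @param boundary_jitter Maximum distance (bases) of a planted boundary
#'   peak centre from its edge.
#' @param min_spacing Minimum separation between planted domains (bases).
#' @param seed Optional integer seed.
#' @return A list: `windows` (tibble with `fold_enrichment`),
#'   `boundary_peaks`, `domains` (planted truth with `domain_id`),
#'   `boundary_truth` (per edge: position, side, whether a peak was
#'   planted), and `params`.
#' @export
sim_h3k27me3_track <- function(assembly, n_domains = 200L,
                               domain_meanlog = log(10000), domain_sdlog = 0.4,
                               window_size = 200L, background_sdlog = 0.25,
                               domain_fold = 5, domain_fold_sdlog = 0.2,
                               boundary_peak_rate = 0.8, boundary_jitter = 500L,
                               min_spacing = 4000L, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  lengths <- round(stats::rlnorm(n_domains, domain_meanlog, domain_sdlog))
  lengths <- pmax(ceiling(lengths / window_size), 12) * window_size  # > 2000 bp
  domains <- as_intervals(place_domains(lengths, assembly, window_size, min_spacing))
  domains$domain_id <- paste0("planted_", seq_len(n_domains))

  segs <- subtract_gaps(assembly)
  windows <- purrr::pmap_dfr(segs, function(chrom, start, end, ...) {
    n <- (end - start) %/% window_size
    if (n == 0) return(NULL)
    s <- start + window_size * (seq_len(n) - 1)
    tibble(chrom = chrom, start = s, end = s + window_size)
  })
  mid <- tibble(chrom = windows$chrom,
                start = windows$start + window_size %/% 2,
                end = windows$start + window_size %/% 2 + 1)
  in_dom <- overlaps_any(mid, domains)
  nw <- nrow(windows)
  windows$fold_enrichment <- ifelse(
    in_dom,
    stats::rlnorm(nw, log(domain_fold), domain_fold_sdlog),
    stats::rlnorm(nw, 0, background_sdlog)
  )

  edges <- extract_boundaries(domains)
  has_peak <- stats::runif(nrow(edges)) < boundary_peak_rate
  centre <- edges$pos + round(stats::runif(nrow(edges), -boundary_jitter, boundary_jitter))
  peaks <- tibble(chrom = edges$chrom,
                  start = pmax(centre - 100L, 0), end = pmax(centre - 100L, 0) + 200L)
  list(
    windows = as_intervals(windows),
    boundary_peaks = as_intervals(peaks[has_peak, , drop = FALSE]),
    domains = domains,
    boundary_truth = dplyr::mutate(edges, peak_planted = has_peak),
    params = list(n_domains = n_domains, window_size = window_size,
                  domain_fold = domain_fold,
                  boundary_peak_rate = boundary_peak_rate,
                  boundary_jitter = boundary_jitter, seed = seed)
  )
}

#' Simulate an expression count table with planted class shifts
#'
#' Negative-binomial counts per gene and sample. Each gene's expected CPM is
#' `2^(baseline + shift)` where the baseline is normal (`base_mean_log2`,
#' `base_sd_log2`) and the shift is looked up from `class_shifts` by the
#' gene's `class` column (genes of unlisted classes shift 0). Library sizes
#' vary uniformly ±20% around `lib_size`.
#'
#' @param genes Tibble with `gene_id` and optionally `class`.
#' @param class_shifts Named numeric vector of log2 shifts per class.
#' @param n_samples Number of samples.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson-free deterministic means.
#' @param lib_size Mean library size in reads.
#' @param base_mean_log2,base_sd_log2 Baseline log2-CPM distribution.
#' @param seed Optional integer seed.
#' @return A list: `counts` (tibble `gene_id` + `sample_1..n`), `truth`
#'   (per-gene baseline, shift and expected CPM), and `params`.
#' @export
sim_expression <- function(genes, class_shifts = c(specific = 2, invariant = 0),
                           n_samples = 4L, dispersion = 0.1, lib_size = 2e6,
                           base_mean_log2 = 5, base_sd_log2 = 1,
                           seed = NULL) {
  genes <- as_tibble(genes)
  stopifnot("gene_id" %in% names(genes), n_samples >= 1, dispersion >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  ng <- nrow(genes)
  base <- stats::rnorm(ng, base_mean_log2, base_sd_log2)
  shift <- if ("class" %in% names(genes)) {
    s <- class_shifts[genes$class]
    ifelse(is.na(s), 0, s)
  } else {
    rep(0, ng)
  }
  mu_cpm <- 2^(base + shift)
  libs <- round(lib_size * stats::runif(n_samples, 0.8, 1.2))
  counts <- vapply(seq_len(n_samples), function(j) {
    mu <- mu_cpm / 1e6 * libs[j]
    if (dispersion == 0) round(mu) else stats::rnbinom(ng, mu = mu, size = 1 / dispersion)
  }, numeric(ng))
  colnames(counts) <- paste0("sample_", seq_len(n_samples))
  list(
    counts = dplyr::bind_cols(tibble(gene_id = genes$gene_id), as_tibble(counts)),
    truth = tibble(gene_id = genes$gene_id, base_log2_cpm = base,
                   shift_log2 = unname(shift), expected_cpm = mu_cpm),
    params = list(n_samples = n_samples, dispersion = dispersion,
                  lib_size = lib_size, class_shifts = class_shifts, seed = seed)
  )
}

#' Simulate gene models on an assembly
#'
#' Random non-overlapping gene bodies with strand, for bin-partition and
#' TSS-linkage testing.
#'
#' @param assembly A [genome_assembly()].
#' @param n_genes Number of genes.
#' @param gene_length_mean Mean gene length (exponential, floor 2 kb).
#' @param seed Optional integer seed.
#' @return A gene model tibble (see [as_gene_models()]).
#' @export
sim_genes <- function(assembly, n_genes = 100L, gene_length_mean = 20000,
                      seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  lens <- pmax(round(stats::rexp(n_genes, 1 / gene_length_mean)), 2000)
  body <- place_random(lens, assembly)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  as_gene_models(tibble(
    chrom = body$chrom,
    strand = strand,
    tss = ifelse(strand == "+", body$start, body$end),
    tes = ifelse(strand == "+", body$end, body$start),
    gene_id = paste0("gene_", seq_len(n_genes))
  ))
}
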