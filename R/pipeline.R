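# End-to-end orchestration: config validation, stage sequencing, and
# machine-readable summaries.

#' Read a chrom.sizes file
#'
#' @param path Two-column tab-separated file: chromosome name, length.
#' @return Tibble with `chrom` and `size`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "size"),
                       col_types = "ci", progress = FALSE)
  if (any(is.na(x$size))) abort(paste0("malformed chrom.sizes: ", path))
  x
}

#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_all()], populated for a
#' synthetic run: genome, planted peak panel, planted H3K27me3 track,
#' planted expression, plus every analysis threshold (1 bp overlap, fold
#' enrichment > 3, 2 kb merge gap and minimum domain length, 1 kb boundary
#' and TSS distances, CPM > 1 in >= 3 samples, 2-fold change). Any element
#' can be overridden before calling [run_all()]; set `inputs` to a list of
#' file paths to analyze real data instead of simulating.
#'
#' @param seed Integer seed controlling every stochastic stage.
#' @return A named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome = list(n_chrom = 3L, chrom_length = 2e6, gap_fraction = 0.05),
    peaks = list(n_peaks = 800L, cooccupancy_fraction = 0.5,
                 invariant_fraction = 0.3, specific_fraction = 0.4,
                 n_references = 7L),
    domains = list(n_domains = 60L, window_size = 200L, domain_fold = 5,
                   boundary_peak_rate = 0.8, min_fold = 3,
                   merge_gap = 2000L, min_length = 2000L),
    genes = list(n_genes = 300L),
    expression = list(n_samples = 4L, dispersion = 0.1,
                      cpm_threshold = 1, min_samples = 3L,
                      min_fold_change = 2, pseudocount = 0.5),
    thresholds = list(min_bp = 1L, boundary_d = 1000L, tss_d = 1000L,
                      promoter_d = 1000L, distal_d = 50000L),
    randomization = list(n_iterations = 200L, statistic = "overlap"),
    inputs = NULL,
    output_dir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Checks threshold signs, the planted-fraction budget, that a seed is
#' present whenever a stochastic stage is enabled, and — in file mode —
#' that every referenced input exists and that chromosome sizes and gaps
#' are supplied when randomization is enabled.
#'
#' @param config A configuration list (see [default_config()]).
#' @return The config, invisibly; errors describe the offending entry.
#' @export
validate_config <- function(config) {
  th <- config$thresholds
  if (any(unlist(th) < 0)) abort("all thresholds must be >= 0")
  stochastic <- is.null(config$inputs) || config$randomization$n_iterations > 0
  if (stochastic && is.null(config$seed)) {
    abort("config$seed is required when any stochastic stage is enabled")
  }
  if (is.null(config$inputs)) {
    pk <- config$peaks
    if (pk$invariant_fraction + pk$specific_fraction > 1) {
      abort("invariant_fraction + specific_fraction must be <= 1")
    }
  } else {
    inp <- config$inputs
    for (nm in names(inp)) {
      for (p in inp[[nm]]) {
        if (!file.exists(p)) abort(paste0("input file missing (", nm, "): ", p))
      }
    }
    if (config$randomization$n_iterations > 0) {
      if (is.null(inp$chrom_sizes)) {
        abort("randomization enabled but inputs$chrom_sizes is missing")
      }
      if (is.null(inp$gaps)) {
        abort("randomization enabled but inputs$gaps is missing")
      }
    }
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- utils::modifyList(default_config(), user)
  validate_config(config)
  config
}

# assemble stage inputs, simulated or loaded from files
gather_inputs <- function(config) {
  th <- config$thresholds
  if (is.null(config$inputs)) {
    seed <- config$seed
    assembly <- sim_genome(config$genome$n_chrom, config$genome$chrom_length,
                           config$genome$gap_fraction, seed = seed)
    panel <- sim_peak_panel(
      assembly, n_peaks = config$peaks$n_peaks,
      cooccupancy_fraction = config$peaks$cooccupancy_fraction,
      invariant_fraction = config$peaks$invariant_fraction,
      specific_fraction = config$peaks$specific_fraction,
      n_references = config$peaks$n_references, seed = seed + 1L)
    genes <- sim_genes(assembly, n_genes = config$genes$n_genes, seed = seed + 2L)
    track <- sim_h3k27me3_track(
      assembly, n_domains = config$domains$n_domains,
      window_size = config$domains$window_size,
      domain_fold = config$domains$domain_fold,
      boundary_peak_rate = config$domains$boundary_peak_rate, seed = seed + 3L)
    # planted expression: genes repressed in domains, activated near
    # cell-type-specific sites
    tss <- tibble(chrom = genes$chrom, start = genes$tss, end = genes$tss + 1L)
    in_dom <- overlaps_any(tss, track$domains)
    crosscell <- classify_cross_cell(panel$target, panel$references, th$min_bp)
    linked <- link_peaks_to_genes(crosscell, genes, d = th$tss_d)
    sim_class <- dplyr::case_when(in_dom ~ "in_domain",
                                  !is.na(linked$class) ~ linked$class,
                                  TRUE ~ "background")
    expr <- sim_expression(
      dplyr::mutate(genes, class = sim_class),
      class_shifts = c(specific = 2, invariant = 0, in_domain = -2, background = 0),
      n_samples = config$expression$n_samples,
      dispersion = config$expression$dispersion, seed = seed + 4L)
    list(assembly = assembly, peaks_a = panel$target, peaks_b = panel$partner,
         references = panel$references, genes = genes, windows = track$windows,
         boundary_peaks = track$boundary_peaks, counts = expr$counts,
         truth = list(panel = panel$truth, domains = track$domains,
                      boundaries = track$boundary_truth, expression = expr$truth))
  } else {
    inp <- config$inputs
    assembly <- if (!is.null(inp$chrom_sizes)) {
      gaps <- if (!is.null(inp$gaps)) read_bed(inp$gaps, "bed3")
      genome_assembly(read_chrom_sizes(inp$chrom_sizes), gaps = gaps)
    }
    list(
      assembly = assembly,
      peaks_a = if (!is.null(inp$peaks_a)) read_bed(inp$peaks_a, "narrowPeak"),
      peaks_b = if (!is.null(inp$peaks_b)) read_bed(inp$peaks_b, "narrowPeak"),
      references = if (!is.null(inp$references)) {
        lapply(inp$references, read_bed, dialect = "bed3")
      },
      genes = if (!is.null(inp$genes)) read_genes(inp$genes, "tsv"),
      windows = if (!is.null(inp$windows)) read_bed(inp$windows, "sicer_window"),
      boundary_peaks = NULL,
      counts = if (!is.null(inp$counts)) {
        readr::read_tsv(inp$counts, show_col_types = FALSE)
      },
      truth = NULL
    )
  }
}

#' Run the full analysis pipeline
#'
#' Executes every stage in dependency order on either simulated data with
#' planted truth (the default) or user-supplied files (`config$inputs`):
#' factor co-occupancy, cross-cell-type classification, genome-bin peak
#' distribution, repressive-domain construction and statistics, boundary
#' marking and co-localization, the randomization null, and the expression
#' analyses. Identical configs (seed included) yield identical summaries.
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file.
#' @return An object of class `chrombound_run`: a list with `summary` (a
#'   JSON-serializable list of per-stage results, thresholds and seed),
#'   `objects` (the intermediate tibbles and result objects) and `config`.
#'   When `config$output_dir` is set the summary and key tables are also
#'   written there.
#' @export
run_all <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  config <- utils::modifyList(default_config(), config)
  validate_config(config)
  th <- config$thresholds
  data <- gather_inputs(config)
  objects <- list(data = data)
  summary <- list(schema_version = "1.0", seed = config$seed, thresholds = th)

  if (!is.null(data$peaks_a) && !is.null(data$peaks_b)) {
    co <- classify_cooccupancy(data$peaks_a, data$peaks_b, th$min_bp)
    objects$cooccupancy <- co
    summary$cooccupancy <- as.list(glance.cooccupancy_result(co))
  }
  if (!is.null(data$peaks_a) && !is.null(data$references)) {
    cc <- classify_cross_cell(data$peaks_a, data$references, th$min_bp)
    objects$crosscell <- cc
    summary$crosscell <- as.data.frame(cross_cell_summary(cc))
  }
  if (!is.null(data$genes) && !is.null(data$assembly)) {
    bins <- build_bins(data$genes, data$assembly, th$promoter_d, th$distal_d)
    objects$bins <- bins
    if (!is.null(data$peaks_a)) {
      dist <- peak_bin_distribution(data$peaks_a, bins)
      objects$bin_distribution <- dist
      summary$bin_distribution <- as.data.frame(dist)
    }
  }
  if (!is.null(data$windows)) {
    dom <- call_domains(data$windows, config$domains$min_fold,
                        config$domains$merge_gap, config$domains$min_length)
    objects$domains <- dom
    summary$domains <- as.list(domain_stats(dom, assembly = data$assembly))
    bounds <- extract_boundaries(dom)
    bpeaks <- data$boundary_peaks %||% data$peaks_a
    if (!is.null(bpeaks)) {
      marking <- mark_boundaries(bpeaks, bounds, d = th$boundary_d)
      objects$boundary_marking <- marking
      summary$boundaries <- list(
        n_boundaries = nrow(bounds),
        n_marking_peaks = marking$n_marking_peaks,
        n_marked_boundaries = marking$n_marked_boundaries,
        marked_boundary_rate = marking$n_marked_boundaries / max(nrow(bounds), 1))
      if (!is.null(data$peaks_b)) {
        b_marking <- mark_boundaries(data$peaks_b, bounds, d = th$boundary_d)
        coloc <- boundary_colocalization(marking_peaks(marking),
                                         marking_peaks(b_marking), th$min_bp)
        summary$boundary_colocalization <- as.list(coloc)
      }
      if (config$randomization$n_iterations > 0 && !is.null(data$assembly) &&
          marking$n_marking_peaks > 0) {
        ct <- colocalization_test(
          marking_peaks(marking),
          tibble(chrom = bounds$chrom, start = bounds$pos, end = bounds$pos + 1L),
          data$assembly, statistic = "within_d", d = th$boundary_d,
          n_iterations = config$randomization$n_iterations,
          seed = config$seed + 5L)
        objects$coloc_test <- ct
        summary$randomization <- as.list(glance.coloc_test(ct))
      }
    }
  }
  if (!is.null(data$counts)) {
    ex <- config$expression
    detected <- detect_transcripts(data$counts, ex$cpm_threshold)
    filtered <- filter_transcripts(data$counts, ex$cpm_threshold, ex$min_samples)
    summary$expression <- list(n_detected = nrow(detected),
                               n_filtered = nrow(filtered))
    samp <- setdiff(names(data$counts), "gene_id")
    if (length(samp) >= 2) {
      half <- length(samp) %/% 2
      fc <- fold_change_classify(data$counts, samp[seq_len(half)],
                                 samp[-seq_len(half)], ex$min_fold_change,
                                 ex$pseudocount)
      objects$fold_change <- fc
      summary$expression$fold_change <- as.list(table(fc$class))
    }
    if (!is.null(data$genes) && !is.null(objects$domains)) {
      dea <- suppressWarnings(
        domain_expression_association(objects$domains, data$genes, data$counts))
      if (!is.null(dea)) {
        objects$domain_expression <- dea
        summary$domain_expression <- as.list(glance.expr_class_comparison(dea))
      }
    }
    if (!is.null(data$genes) && !is.null(objects$crosscell)) {
      linked <- link_peaks_to_genes(objects$crosscell, data$genes, d = th$tss_d)
      objects$linked_genes <- linked
      cmp <- suppressWarnings(
        compare_expression_by_class(linked, data$counts, "specific", "invariant"))
      if (!is.null(cmp)) {
        objects$class_expression <- cmp
        summary$class_expression <- as.list(glance.expr_class_comparison(cmp))
      }
    }
  }
  run <- structure(list(summary = summary, objects = objects, config = config),
                   class = "chrombound_run")
  if (!is.null(config$output_dir)) write_run(run, config$output_dir)
  run
}

#' @export
print.chrombound_run <- function(x, ...) {
  cat("<chrombound_run> stages:",
      paste(setdiff(names(x$summary), c("schema_version", "seed", "thresholds")),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits `summary.json` plus TSV/BED files for the per-stage tables.
#'
#' @param run A `chrombound_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ob <- run$objects
  if (!is.null(ob$crosscell)) {
    readr::write_tsv(dplyr::select(ob$crosscell, -dplyr::any_of("classes")),
                     file.path(dir, "crosscell.tsv"))
  }
  if (!is.null(ob$bin_distribution)) {
    readr::write_tsv(ob$bin_distribution, file.path(dir, "bin_distribution.tsv"))
  }
  if (!is.null(ob$domains)) {
    write_bed(ob$domains, file.path(dir, "domains.bed"), name_col = "domain_id")
  }
  if (!is.null(ob$boundary_marking)) {
    write_bed(marking_peaks(ob$boundary_marking),
              file.path(dir, "boundary_marking_peaks.bed"))
  }
  invisible(dir)
}
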