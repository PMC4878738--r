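# Independent brute-force oracles. These deliberately avoid the package's
# interval machinery (no GenomicRanges): plain double loops and per-base
# label vectors, so they can arbitrate the optimized implementations.

# all-pairs overlap: list of hit pairs (i, j) with >= min_bp shared bases
oracle_overlap_pairs <- function(a, b, min_bp = 1) {
  hits <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_bp) hits[[length(hits) + 1]] <- c(i, j)
    }
  }
  if (length(hits) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

# union-then-scan merge with gap tolerance
oracle_merge <- function(x, max_gap = 0) {
  out <- NULL
  for (ch in sort(unique(x$chrom))) {
    xs <- x[x$chrom == ch, , drop = FALSE]
    xs <- xs[order(xs$start, xs$end), , drop = FALSE]
    cur_s <- xs$start[1]; cur_e <- xs$end[1]
    for (i in seq_len(nrow(xs))[-1]) {
      if (xs$start[i] - cur_e <= max_gap) {
        cur_e <- max(cur_e, xs$end[i])
      } else {
        out <- rbind(out, data.frame(chrom = ch, start = cur_s, end = cur_e))
        cur_s <- xs$start[i]; cur_e <- xs$end[i]
      }
    }
    out <- rbind(out, data.frame(chrom = ch, start = cur_s, end = cur_e))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

# per-pair proximity predicate: overlap, or 0 <= gap <= d when d >= 1
oracle_within <- function(q, a, d) {
  n <- nrow(q); m <- nrow(a)
  mat <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (q$chrom[i] != a$chrom[j]) next
      ov <- min(q$end[i], a$end[j]) - max(q$start[i], a$start[j])
      gap <- max(a$start[j] - q$end[i], q$start[i] - a$end[j])
      mat[i, j] <- (ov >= 1) || (d >= 1 && gap >= 0 && gap <= d)
    }
  }
  mat
}

# per-base bin labels for a single toy chromosome (<= 1e5 bp)
oracle_bin_labels <- function(genes, chrom, size, gaps = NULL,
                              promoter_d = 1000, distal_d = 50000) {
  lab <- rep("intergenic", size)  # base i is position i - 1
  paint <- function(s, e, value) {
    s <- max(s, 0); e <- min(e, size)
    if (s < e) lab[(s + 1):e] <<- value
  }
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  # lowest precedence first, higher bins overwrite
  for (i in seq_len(nrow(g))) {
    if (g$strand[i] == "+") paint(g$tes[i] + promoter_d, g$tes[i] + distal_d, "three_prime_distal")
    else paint(g$tes[i] - distal_d, g$tes[i] - promoter_d, "three_prime_distal")
  }
  for (i in seq_len(nrow(g))) {
    if (g$strand[i] == "+") paint(g$tss[i] - distal_d, g$tss[i] - promoter_d, "five_prime_distal")
    else paint(g$tss[i] + promoter_d, g$tss[i] + distal_d, "five_prime_distal")
  }
  for (i in seq_len(nrow(g))) paint(min(g$tss[i], g$tes[i]), max(g$tss[i], g$tes[i]), "genic")
  for (i in seq_len(nrow(g))) paint(g$tes[i] - promoter_d, g$tes[i] + promoter_d, "downstream")
  for (i in seq_len(nrow(g))) paint(g$tss[i] - promoter_d, g$tss[i] + promoter_d, "promoter")
  if (!is.null(gaps)) {
    gp <- gaps[gaps$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(gp))) paint(gp$start[i], gp$end[i], "unassigned_gap")
  }
  lab
}

# expand a bins table into per-base labels for one chromosome
bins_to_labels <- function(bins, chrom, size) {
  lab <- rep(NA_character_, size)
  b <- bins[bins$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(b))) lab[(b$start[i] + 1):b$end[i]] <- as.character(b$bin[i])
  lab
}

# filter > min_fold, scan-merge, drop length <= min_length
oracle_domains <- function(windows, min_fold = 3, merge_gap = 2000, min_length = 2000) {
  keep <- windows[windows$fold_enrichment > min_fold, , drop = FALSE]
  if (nrow(keep) == 0) return(keep[, c("chrom", "start", "end")])
  m <- oracle_merge(keep, max_gap = merge_gap)
  m[m$end - m$start > min_length, , drop = FALSE]
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  w_null <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_low <- mean(w_null <= w_obs)
  p_high <- mean(w_null >= w_obs)
  min(1, 2 * min(p_low, p_high))
}
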