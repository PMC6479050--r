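# Fixture builders and independent brute-force oracles.  Every oracle takes
# the naive route (all-pairs loops, per-base expansion, Kahan-compensated
# sums, label permutation) so it shares no code path with the implementation
# it checks.

iv <- function(chrom, start, end, ...) {
  data.frame(chrom = chrom, start = start, end = end, ...,
             stringsAsFactors = FALSE)
}

gene_row <- function(gene_id, chrom, strand, tx_start, tx_end,
                     cds_start = tx_start, cds_end = tx_end,
                     exon_starts = as.list(tx_start),
                     exon_ends = as.list(tx_end)) {
  g <- data.frame(gene_id = gene_id, tx_name = paste0(gene_id, ".1"),
                  chrom = chrom, strand = strand,
                  tx_start = tx_start, tx_end = tx_end,
                  cds_start = cds_start, cds_end = cds_end,
                  stringsAsFactors = FALSE)
  g$exon_starts <- exon_starts
  g$exon_ends <- exon_ends
  g
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 1e5,
                             max_width = 500) {
  start <- floor(runif(n, 0, span))
  width <- 1 + floor(runif(n, 0, max_width))
  iv(sample(chroms, n, replace = TRUE), start, start + width,
     name = sprintf("p%04d", seq_len(n)))
}

random_genes <- function(n, chroms = c("chr1", "chr2"), span = 1e5) {
  tx_start <- floor(runif(n, 0, span))
  gene_row(sprintf("g%04d", sample(n)), sample(chroms, n, replace = TRUE),
           sample(c("+", "-"), n, replace = TRUE),
           tx_start, tx_start + 1000 + floor(runif(n, 0, 4000)))
}

random_track <- function(n_steps, chrom = "chr1", span = 1e5) {
  # non-overlapping sorted steps with gaps
  edges <- sort(sample.int(span, 2 * n_steps))
  as_signal_track(data.frame(
    chrom = chrom,
    start = edges[seq(1, 2 * n_steps, by = 2)],
    end = edges[seq(2, 2 * n_steps, by = 2)],
    value = round(runif(n_steps, 0, 10), 4),
    stringsAsFactors = FALSE))
}

random_dense_track <- function(n_steps, chrom = "chr1", span = 1e5) {
  # gap-free cover of [0, span)
  breaks <- sort(c(0, sample.int(span - 1, n_steps - 1), span))
  as_signal_track(data.frame(
    chrom = chrom, start = breaks[-length(breaks)], end = breaks[-1],
    value = round(runif(n_steps, 0, 10), 4), stringsAsFactors = FALSE))
}

# all-pairs overlap classification (exhaustive scan, one row at a time)
bf_classify <- function(focal, partner) {
  fc <- rep("II", nrow(focal))
  pc <- rep("III", nrow(partner))
  for (i in seq_len(nrow(focal))) {
    hit <- focal$chrom[i] == partner$chrom &
      focal$start[i] < partner$end & partner$start < focal$end[i]
    if (any(hit)) {
      fc[i] <- "I"
      pc[hit] <- "I-partner"
    }
  }
  list(focal = fc, partner = pc)
}

# exhaustive nearest-gene scan with lexicographic tie-break
bf_nearest <- function(peaks, genes) {
  mid <- floor((peaks$start + peaks$end) / 2)
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1)
  out_id <- character(nrow(peaks))
  out_d <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    d <- abs(mid[i] - tss)
    d[peaks$chrom[i] != genes$chrom] <- Inf
    best <- min(d)
    if (is.finite(best)) {
      out_id[i] <- min(genes$gene_id[d == best])   # lexicographic tie-break
      out_d[i] <- best
    } else {
      out_id[i] <- NA_character_
      out_d[i] <- NA_real_
    }
  }
  data.frame(gene_id = out_id, distance = out_d, stringsAsFactors = FALSE)
}

# naive per-gene regulatory potential with Kahan-compensated summation
bf_rp <- function(peaks, genes, window = 1e5, offset = 0.5, scale = 4) {
  mid <- floor((peaks$start + peaks$end) / 2)
  tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1)
  S <- numeric(nrow(genes)); k <- integer(nrow(genes))
  for (j in seq_len(nrow(genes))) {
    s <- 0; c_comp <- 0
    for (i in seq_len(nrow(peaks))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      d <- abs(mid[i] - tss[j])
      if (d > window) next
      k[j] <- k[j] + 1L
      term <- exp(-(offset + scale * d / window))
      y <- term - c_comp
      t <- s + y
      c_comp <- (t - s) - y
      s <- t
    }
    S[j] <- s
  }
  data.frame(gene_id = genes$gene_id, score = S, k = k,
             stringsAsFactors = FALSE)
}

# per-base expansion of a binned window mean
bf_bin_means <- function(track, chrom, mid, flank, bin) {
  base_val <- function(pos) {   # value of track at single base [pos, pos+1)
    hit <- which(track$chrom == chrom & track$start <= pos & pos < track$end)
    if (length(hit)) track$value[hit[1]] else 0
  }
  nb <- 2 * flank / bin
  vapply(seq_len(nb), function(b) {
    lo <- mid - flank + (b - 1) * bin
    mean(vapply(lo:(lo + bin - 1), function(p)
      if (p < 0) 0 else base_val(p), numeric(1)))
  }, numeric(1))
}

# Monte-Carlo permutation p-value for rank-sum "x smaller than y"
perm_ranksum_p <- function(x, y, B = 2000) {
  all_v <- c(x, y)
  r <- rank(all_v)
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  stat <- vapply(seq_len(B), function(b)
    sum(r[sample.int(length(all_v), n1)]), numeric(1))
  (1 + sum(stat <= obs)) / (B + 1)
}

# Monte-Carlo permutation p-value for the one-sided KS alternative
# "group scores stochastically greater than static" (D- of group vs static)
perm_ks_p <- function(x, y, B = 2000) {
  dminus <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(stats::ecdf(b)(v) - stats::ecdf(a)(v))
  }
  obs <- dminus(x, y)
  all_v <- c(x, y)
  n1 <- length(x)
  stat <- vapply(seq_len(B), function(b) {
    idx <- sample.int(length(all_v), n1)
    dminus(all_v[idx], all_v[-idx])
  }, numeric(1))
  (1 + sum(stat >= obs)) / (B + 1)
}

small_config <- function(seed = 7L, ...) {
  defaults <- list(seed = seed, n_chroms = 2L, chrom_length = 5e6,
                   n_genes = 200L, n_target_genes_up = 30L,
                   n_target_genes_down = 30L, n_focal_peaks = 150L,
                   n_partner_peaks = 150L, peak_width_mean = 300)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}
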