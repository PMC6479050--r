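# Peak co-occupancy classification and genomic-feature annotation.
#
# Class labels follow the three-way partition used for paired cistromes:
# focal peaks that overlap (>= min_overlap bp, half-open) at least one
# partner peak are Class I, the rest Class II; partner peaks that overlap no
# focal peak are Class III (partner peaks of Class I pairs are "I-partner").

#' Classify peaks by co-occupancy of a partner factor
#'
#' @param focal interval data.frame of the focal factor's peaks.
#' @param partner interval data.frame of the partner factor's peaks.
#' @param min_overlap minimum shared bases to count as overlap (default 1).
#' @return object of class `"peak_classification"`: list with `focal`
#'   (input + `class` in I/II), `partner` (input + `class` in
#'   I-partner/III), and `pairs` (data.frame of overlapping
#'   `focal_idx`/`partner_idx`).
#' @export
classify_peaks <- function(focal, partner, min_overlap = 1L) {
  validate_intervals(focal, "focal")
  validate_intervals(partner, "partner")
  if (nrow(focal) && nrow(partner)) {
    hits <- GenomicRanges::findOverlaps(as_granges0(focal), as_granges0(partner),
                                        minoverlap = min_overlap)
    pairs <- data.frame(focal_idx = S4Vectors::queryHits(hits),
                        partner_idx = S4Vectors::subjectHits(hits))
  } else {
    pairs <- data.frame(focal_idx = integer(), partner_idx = integer())
  }
  focal$class <- ifelse(seq_len(nrow(focal)) %in% pairs$focal_idx, "I", "II")
  partner$class <- ifelse(seq_len(nrow(partner)) %in% pairs$partner_idx,
                          "I-partner", "III")
  structure(list(focal = focal, partner = partner, pairs = pairs),
            class = "peak_classification")
}

#' @export
print.peak_classification <- function(x, ...) {
  cat("Peak classification\n")
  cat(sprintf("  focal:   %d peaks (Class I: %d, Class II: %d)\n",
              nrow(x$focal), sum(x$focal$class == "I"),
              sum(x$focal$class == "II")))
  cat(sprintf("  partner: %d peaks (I-partner: %d, Class III: %d)\n",
              nrow(x$partner), sum(x$partner$class == "I-partner"),
              sum(x$partner$class == "III")))
  invisible(x)
}

GENOMIC_CATEGORIES <- c("promoter", "5utr", "3utr", "coding_exon", "intron",
                        "distal_intergenic")

# Feature spans for one transcript as 0-based half-open intervals with a
# precedence (1 = promoter wins).  5'/3' UTRs are the transcript-end segments
# outside the CDS, mirrored on the minus strand.
transcript_features <- function(g, promoter_halfwidth) {
  tss <- if (g$strand == "+") g$tx_start else g$tx_end - 1
  feats <- list(
    data.frame(start = max(0, tss - promoter_halfwidth),
               end = tss + promoter_halfwidth + 1, prec = 1)
  )
  utr_left <- data.frame(start = g$tx_start, end = g$cds_start,
                         prec = if (g$strand == "+") 2 else 3)
  utr_right <- data.frame(start = g$cds_end, end = g$tx_end,
                          prec = if (g$strand == "+") 3 else 2)
  feats <- c(feats, list(utr_left, utr_right))
  es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
  cds_ex <- data.frame(start = pmax(es, g$cds_start),
                       end = pmin(ee, g$cds_end), prec = 4)
  feats <- c(feats, list(cds_ex))
  feats <- c(feats, list(data.frame(start = g$tx_start, end = g$tx_end, prec = 5)))
  out <- do.call(rbind, feats)
  out <- out[out$start < out$end, , drop = FALSE]
  # intron = transcript body minus exons: exons outrank the body via the
  # coding-exon/UTR spans, so the residual body hit means intron
  out
}

#' Genomic distribution of peaks over gene features
#'
#' Each peak is assigned a single category by its midpoint, with precedence
#' promoter > 5utr > 3utr > coding_exon > intron > distal_intergenic applied
#' jointly across all transcripts covering the midpoint.  Promoter is
#' `TSS +/- promoter_halfwidth`; UTRs are the transcript-end segments outside
#' the CDS; coding_exon is exon intersected with the CDS; intron is the
#' transcript body outside exons.
#'
#' @param peaks interval data.frame.
#' @param genes gene-model data.frame ([read_gene_models()] shape).
#' @param promoter_halfwidth promoter half-width in bp (default 1000).
#' @return list with `per_peak` (data.frame: midpoint, category) and
#'   `fractions` (named vector over all six categories, summing to 1).
#' @export
annotate_distribution <- function(peaks, genes, promoter_halfwidth = 1000) {
  validate_intervals(peaks, "peaks")
  mid <- interval_midpoint(peaks$start, peaks$end)
  prec <- rep(6L, nrow(peaks))
  if (nrow(genes)) {
    feat_list <- vector("list", nrow(genes))
    for (i in seq_len(nrow(genes))) {
      f <- transcript_features(genes[i, ], promoter_halfwidth)
      f$chrom <- genes$chrom[i]
      feat_list[[i]] <- f
    }
    feats <- do.call(rbind, feat_list)
    pts <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid + 1, mid + 1))
    fr <- GenomicRanges::GRanges(feats$chrom,
                                 IRanges::IRanges(feats$start + 1, feats$end))
    hits <- GenomicRanges::findOverlaps(pts, fr)
    if (length(hits)) {
      best <- tapply(feats$prec[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits), min)
      prec[as.integer(names(best))] <- as.integer(best)
    }
  }
  category <- factor(GENOMIC_CATEGORIES[prec], levels = GENOMIC_CATEGORIES)
  fractions <- if (length(category)) {
    as.vector(table(category)) / length(category)
  } else rep(NA_real_, length(GENOMIC_CATEGORIES))
  names(fractions) <- GENOMIC_CATEGORIES
  list(per_peak = data.frame(midpoint = mid, category = as.character(category),
                             stringsAsFactors = FALSE),
       fractions = fractions)
}

#' Peak-width summaries per class
#'
#' Widths (`end - start`) summarised per class, plus a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test of Class I vs Class II focal-peak
#' widths.  The test is marked not applicable (`NA`) when either class has
#' fewer than 2 peaks.
#'
#' @param classification a [classify_peaks()] result.
#' @return list with `summary` (data.frame: class, n, mean, median, q25, q75)
#'   and `test` (list: statistic, p_value, applicable).
#' @export
width_stats <- function(classification) {
  stopifnot(inherits(classification, "peak_classification"))
  grab <- function(df, cl) {
    w <- df$end[df$class == cl] - df$start[df$class == cl]
    data.frame(class = cl, n = length(w),
               mean = if (length(w)) mean(w) else NA_real_,
               median = if (length(w)) median(w) else NA_real_,
               q25 = if (length(w)) unname(quantile(w, 0.25)) else NA_real_,
               q75 = if (length(w)) unname(quantile(w, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }
  summary <- rbind(grab(classification$focal, "I"),
                   grab(classification$focal, "II"),
                   grab(classification$partner, "III"))
  w1 <- with(classification$focal, end[class == "I"] - start[class == "I"])
  w2 <- with(classification$focal, end[class == "II"] - start[class == "II"])
  test <- if (length(w1) >= 2 && length(w2) >= 2) {
    wt <- suppressWarnings(wilcox.test(w1, w2, alternative = "two.sided"))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         applicable = TRUE)
  } else {
    list(statistic = NA_real_, p_value = NA_real_, applicable = FALSE)
  }
  list(summary = summary, test = test)
}
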