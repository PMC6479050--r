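# Coordinate conventions: all intervals are 0-based half-open [start, end),
# the BED on-disk convention, held in plain data.frames with columns
# chrom, start, end and optionally name, score, strand.

#' Validate a data.frame of genomic intervals
#'
#' Checks the structural invariants of an interval table: required columns,
#' integer-valued non-negative coordinates, and `start < end` for every row.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (0-based half-open).
#' @param what label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) stop(what, ": expected a data.frame")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop(what, ": missing column(s) ", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(!is.finite(x$start)) || any(!is.finite(x$end)))
      stop(what, ": non-finite coordinates")
    if (any(x$start != floor(x$start)) || any(x$end != floor(x$end)))
      stop(what, ": non-integer coordinates")
    if (any(x$start < 0)) stop(what, ": negative start")
    bad <- which(x$start >= x$end)
    if (length(bad))
      stop(what, ": start >= end at row ", bad[1])
  }
  invisible(x)
}

#' Interval midpoint
#'
#' The representative anchor point of an interval, `floor((start + end) / 2)`,
#' guaranteed to lie inside `[start, end)`.
#'
#' @param start,end 0-based half-open coordinates (vectorised).
#' @return integer-valued midpoint vector.
#' @export
interval_midpoint <- function(start, end) {
  floor((start + end) / 2)
}

#' Do two intervals overlap?
#'
#' Half-open overlap: at least one shared base.  Abutting intervals
#' (`a$end == b$start`) do not overlap.  Vectorised with recycling.
#'
#' @param chrom_a,start_a,end_a first interval(s).
#' @param chrom_b,start_b,end_b second interval(s).
#' @return logical vector.
#' @export
overlaps <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  chrom_a == chrom_b & start_a < end_b & start_b < end_a
}

#' Strand-aware transcription start sites
#'
#' TSS is `tx_start` for `+` strand transcripts and `tx_end - 1` (the last
#' covered base) for `-` strand transcripts, so the TSS is always a genomic
#' point inside the transcript.
#'
#' @param genes gene-model data.frame (see [read_gene_models()]).
#' @return numeric vector of TSS positions (0-based).
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$tx_start, genes$tx_end - 1)
}

#' Signed distance from peak midpoints to a gene's TSS
#'
#' Distance is measured from the peak midpoint to the strand-aware TSS;
#' positive values are downstream of the gene (in the direction of
#' transcription), negative upstream.  Peaks on a different chromosome get
#' `NA` ("no distance defined"; callers treat this as beyond any window).
#'
#' @param peaks interval data.frame.
#' @param gene a single gene model (one-row data.frame or list with fields
#'   `chrom`, `strand`, `tx_start`, `tx_end`).
#' @return numeric vector, one signed distance per peak (`NA` off-chromosome).
#' @export
distance_to_tss <- function(peaks, gene) {
  stopifnot(length(gene$chrom) == 1L)
  tss <- if (gene$strand == "+") gene$tx_start else gene$tx_end - 1
  mid <- interval_midpoint(peaks$start, peaks$end)
  d <- if (gene$strand == "+") mid - tss else tss - mid
  d[peaks$chrom != gene$chrom] <- NA_real_
  d
}

#' Nearest gene (by TSS) for each peak
#'
#' Assigns every peak the gene whose TSS is closest to the peak midpoint
#' (absolute distance).  Exact ties are broken by lexicographically smallest
#' `gene_id`.  Peaks on chromosomes carrying no gene are unassigned (`NA`).
#'
#' @param peaks interval data.frame.
#' @param genes gene-model data.frame with `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`.
#' @return data.frame with one row per peak: `gene_id`, `distance`
#'   (absolute bp), `signed_distance` (strand-aware, positive = downstream).
#' @export
nearest_gene <- function(peaks, genes) {
  validate_intervals(peaks, "peaks")
  if (nrow(genes) == 0L) stop("nearest_gene: empty gene list")
  mid <- interval_midpoint(peaks$start, peaks$end)
  tss <- gene_tss(genes)
  out <- data.frame(
    gene_id = rep(NA_character_, nrow(peaks)),
    distance = rep(NA_real_, nrow(peaks)),
    signed_distance = rep(NA_real_, nrow(peaks)),
    stringsAsFactors = FALSE
  )
  for (ch in unique(peaks$chrom)) {
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    pi <- which(peaks$chrom == ch)
    # columns ordered by gene_id so which.min's first-minimum rule
    # implements the lexicographic tie-break
    gi <- gi[order(genes$gene_id[gi])]
    d <- abs(outer(mid[pi], tss[gi], "-"))
    j <- apply(d, 1L, which.min)
    hit <- gi[j]
    out$gene_id[pi] <- genes$gene_id[hit]
    out$distance[pi] <- d[cbind(seq_along(pi), j)]
    sgn <- ifelse(genes$strand[hit] == "+",
                  mid[pi] - tss[hit],
                  tss[hit] - mid[pi])
    out$signed_distance[pi] <- sgn
  }
  out
}

# GRanges view of a 0-based half-open interval table (internal overlap engine)
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}
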