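# Signal profiling: binned matrices around peak centres, per-class average
# profiles, per-site signal changes between conditions, and the
# proximal/distal correlation of signal change with expression change.

# Per-chromosome cumulative-integral index of a piecewise-constant track.
# F(x) = integral of the track over (-inf, x); bin means follow from
# differences of F at bin edges, which makes binning exact (no per-base
# expansion) and O(log n) per query.
track_index <- function(track) {
  split(track[c("start", "end", "value")], track$chrom)
}

track_cumF <- function(steps, x) {
  if (!nrow(steps)) return(numeric(length(x)))
  w <- (steps$end - steps$start) * steps$value
  before <- c(0, cumsum(w))[seq_len(nrow(steps))]
  i <- findInterval(x, steps$start)
  out <- numeric(length(x))
  inside <- i >= 1L
  ii <- i[inside]
  out[inside] <- before[ii] +
    steps$value[ii] * pmax(0, pmin(x[inside], steps$end[ii]) - steps$start[ii])
  out
}

# integral of track over [from, to) for query vectors on one chromosome
track_integral_chrom <- function(steps, from, to) {
  track_cumF(steps, to) - track_cumF(steps, from)
}

#' Mean signal over arbitrary windows
#'
#' Base-pair-weighted mean of a piecewise-constant track over `[from, to)`;
#' uncovered bases (including windows truncated below position 0) count as 0
#' and the full window width is the denominator.
#'
#' @param track signal track.
#' @param chrom,from,to query windows (vectorised, equal length).
#' @return numeric vector of window means.
#' @export
window_mean_signal <- function(track, chrom, from, to) {
  stopifnot(length(chrom) == length(from), length(from) == length(to),
            all(to > from))
  idx <- track_index(track)
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    q <- which(chrom == ch)
    steps <- idx[[ch]]
    if (is.null(steps)) next
    out[q] <- track_integral_chrom(steps, pmax(from[q], 0), pmax(to[q], 0)) /
      (to[q] - from[q])
  }
  out
}

#' Binned signal matrix around peak centres
#'
#' For each peak, a window of `2 * flank` bp centred on the peak midpoint is
#' cut into `bin`-bp bins; each cell is the base-pair-weighted mean of the
#' track over that bin (implicit zeros where the track is uncovered, windows
#' running off the chromosome start contribute zeros).
#'
#' @param track signal track.
#' @param peaks interval data.frame.
#' @param flank half-window in bp (default 5000, i.e. 5 kb up- and downstream).
#' @param bin bin width in bp; must divide `flank`.
#' @return numeric matrix, `nrow(peaks)` x `2 * flank / bin`, with attributes
#'   `flank` and `bin`; column names give the bin-start offset from the centre.
#' @export
binned_matrix <- function(track, peaks, flank = 5000, bin = 50) {
  if (flank <= 0 || bin <= 0 || flank %% bin != 0)
    stop("flank must be a positive multiple of bin")
  validate_intervals(peaks, "peaks")
  nb <- as.integer(2 * flank / bin)
  mid <- interval_midpoint(peaks$start, peaks$end)
  mat <- matrix(0, nrow = nrow(peaks), ncol = nb)
  idx <- track_index(track)
  offsets <- seq(-flank, flank, by = bin)   # nb + 1 edges
  for (ch in unique(peaks$chrom)) {
    p <- which(peaks$chrom == ch)
    steps <- idx[[ch]]
    if (is.null(steps)) next
    edges <- outer(mid[p], offsets, "+")    # length(p) x (nb + 1)
    Fv <- matrix(track_cumF(steps, pmax(as.numeric(edges), 0)), nrow = length(p))
    mat[p, ] <- (Fv[, -1, drop = FALSE] - Fv[, -(nb + 1), drop = FALSE]) / bin
  }
  rownames(mat) <- if (!is.null(peaks$name)) peaks$name else NULL
  colnames(mat) <- sprintf("%d", offsets[-(nb + 1)])
  attr(mat, "flank") <- flank
  attr(mat, "bin") <- bin
  mat
}

#' Per-class average signal profile
#'
#' Column means of a binned matrix within each class of rows; the average
#' enrichment profile over each peak class.
#'
#' @param mat matrix from [binned_matrix()].
#' @param classes character vector of class labels, one per row of `mat`.
#' @return matrix with one row per class (row name = class); an empty class
#'   yields a row of `NA`.
#' @export
average_profile <- function(mat, classes) {
  stopifnot(length(classes) == nrow(mat))
  lv <- sort(unique(classes))
  out <- matrix(NA_real_, nrow = length(lv), ncol = ncol(mat),
                dimnames = list(lv, colnames(mat)))
  for (cl in lv) {
    rows <- which(classes == cl)
    if (length(rows))
      out[cl, ] <- colMeans(mat[rows, , drop = FALSE])
  }
  out
}

#' Per-site signal change between two conditions
#'
#' Mean signal over `midpoint +/- window` in each track and the pseudocounted
#' log2 ratio `log2((mean_b + pc) / (mean_a + pc))`; the pseudocount keeps
#' the ratio finite at empty sites (0 signal in both tracks gives change 0).
#' When `genes` is supplied, each site also carries its nearest gene and the
#' absolute midpoint-to-TSS distance.
#'
#' @param track_a,track_b signal tracks for the two conditions.
#' @param sites interval data.frame (the same site list for both tracks).
#' @param window half-window in bp for the site mean (default 1000).
#' @param pseudocount added to both means before the ratio (default 1).
#' @param genes optional gene models for nearest-gene assignment.
#' @return data.frame: `name`, `chrom`, `midpoint`, `mean_a`, `mean_b`,
#'   `log2_change`, and if `genes` given `gene_id`, `distance`.
#' @export
site_signal_change <- function(track_a, track_b, sites, window = 1000,
                               pseudocount = 1.0, genes = NULL) {
  validate_intervals(sites, "sites")
  mid <- interval_midpoint(sites$start, sites$end)
  from <- mid - window
  to <- mid + window
  ma <- window_mean_signal(track_a, sites$chrom, from, to)
  mb <- window_mean_signal(track_b, sites$chrom, from, to)
  out <- data.frame(
    name = if (!is.null(sites$name)) sites$name else sprintf("site_%d", seq_len(nrow(sites))),
    chrom = sites$chrom,
    midpoint = mid,
    mean_a = ma,
    mean_b = mb,
    log2_change = log2((mb + pseudocount) / (ma + pseudocount)),
    stringsAsFactors = FALSE
  )
  if (!is.null(genes)) {
    ng <- nearest_gene(sites, genes)
    out$gene_id <- ng$gene_id
    out$distance <- ng$distance
  }
  out
}

#' Correlation of signal change with expression change, by TSS distance
#'
#' Sites are stratified into TSS-proximal (`|distance| <= proximal_cutoff`)
#' and TSS-distal; within each stratum the site's log2 signal change is
#' rank-correlated (Spearman by default) with the log2 fold change of its
#' nearest gene.  Sites whose nearest gene is absent from the expression
#' table are dropped and counted.
#'
#' @param site_table output of [site_signal_change()] with `gene_id`,
#'   `distance` columns.
#' @param expression expression data.frame (`gene_id`, `log2fc`).
#' @param proximal_cutoff bp threshold splitting proximal from distal
#'   (default 2000).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return list with `strata` (data.frame: stratum, n, rho, p_value; `NA`
#'   when n < 3), `pairs` (per-site paired records), `n_dropped`.
#' @export
proximal_distal_correlation <- function(site_table, expression,
                                        proximal_cutoff = 2000,
                                        method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(all(c("gene_id", "distance", "log2_change") %in% names(site_table)))
  m <- match(site_table$gene_id, expression$gene_id)
  keep <- !is.na(m) & !is.na(site_table$distance)
  n_dropped <- sum(!keep)
  pairs <- data.frame(
    name = site_table$name[keep],
    gene_id = site_table$gene_id[keep],
    distance = site_table$distance[keep],
    stratum = ifelse(site_table$distance[keep] <= proximal_cutoff,
                     "proximal", "distal"),
    signal_log2_change = site_table$log2_change[keep],
    gene_log2fc = expression$log2fc[m[keep]],
    stringsAsFactors = FALSE
  )
  one <- function(stratum) {
    sub <- pairs[pairs$stratum == stratum, , drop = FALSE]
    if (nrow(sub) < 3)
      return(data.frame(stratum = stratum, n = nrow(sub), rho = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    ct <- suppressWarnings(cor.test(sub$signal_log2_change, sub$gene_log2fc,
                                    method = method, exact = FALSE))
    data.frame(stratum = stratum, n = nrow(sub),
               rho = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  }
  list(strata = rbind(one("proximal"), one("distal")),
       pairs = pairs, n_dropped = n_dropped)
}
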