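# Binding-and-expression target inference.
#
# A gene's regulatory potential sums exponentially distance-decayed
# contributions of all peaks whose midpoint lies within a fixed window of the
# TSS:
#
#   S_g = sum_{i=1}^{k} exp(-(offset + scale * Delta_i)),   Delta_i = |d_i| / window
#
# with offset 0.5, scale 4 and window 100 kb, so a peak sitting on the TSS
# contributes exp(-0.5) and one at 10 kb (Delta = 0.1) contributes exp(-0.9).
# Activating/repressive function is inferred by comparing the S_g
# distributions of up- and down-regulated gene groups against static
# (non-differential) genes with a Kolmogorov-Smirnov test.

#' Regulatory-potential configuration
#'
#' @param window TSS-centred radius in bp within which peaks count
#'   (default 100000); the boundary is closed (a peak at exactly `window`
#'   is included with Delta = 1).
#' @param offset,scale constants of the exponential decay
#'   `exp(-(offset + scale * Delta))` (defaults 0.5 and 4).
#' @param da number of differential genes kept per direction when grouping
#'   (default 500).
#' @return list of class `"rp_config"`.
#' @export
rp_config <- function(window = 100000, offset = 0.5, scale = 4.0, da = 500L) {
  stopifnot(window > 0, da >= 1)
  structure(list(window = window, offset = offset, scale = scale,
                 da = as.integer(da)), class = "rp_config")
}

#' Regulatory potential of every gene
#'
#' For each transcript, `k` is the number of peaks with
#' `|midpoint - TSS| <= window` and `S = sum(exp(-(offset + scale * |d|/window)))`.
#' Genes with multiple transcripts are credited with their best-scoring
#' transcript (maximum S).  Genes are ranked by descending score, ties broken
#' by `gene_id`.
#'
#' @param peaks interval data.frame.
#' @param genes gene-model data.frame.
#' @param cfg an [rp_config()].
#' @return data.frame of class `"rp_table"`: `gene_id`, `score`, `k`, `rank`,
#'   ordered by rank.
#' @export
regulatory_potential <- function(peaks, genes, cfg = rp_config()) {
  stopifnot(inherits(cfg, "rp_config"))
  validate_intervals(peaks, "peaks")
  mid <- interval_midpoint(peaks$start, peaks$end)
  tss <- gene_tss(genes)
  S <- numeric(nrow(genes))
  k <- integer(nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(pi)) next
    d <- abs(outer(tss[gi], mid[pi], "-"))
    within <- d <= cfg$window
    wgt <- exp(-(cfg$offset + cfg$scale * d / cfg$window)) * within
    S[gi] <- rowSums(wgt)
    k[gi] <- rowSums(within)
  }
  # best transcript per gene
  agg <- data.frame(gene_id = genes$gene_id, score = S, k = k,
                    stringsAsFactors = FALSE)
  agg <- agg[order(agg$gene_id, -agg$score), , drop = FALSE]
  agg <- agg[!duplicated(agg$gene_id), , drop = FALSE]
  agg <- agg[order(-agg$score, agg$gene_id), , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  class(agg) <- c("rp_table", class(agg))
  agg
}

#' Partition expressed genes into up / down / static groups
#'
#' Up = the `cfg$da` most significant genes with `log2fc > min_abs_lfc`
#' (ordered by ascending p-value, then descending |log2fc|, then gene_id);
#' down is symmetric.  Static = every gene in neither group with
#' `pvalue >= static_p_floor`, i.e. the non-differential background with
#' near-significant genes excluded.
#'
#' @param expression expression data.frame (`gene_id`, `log2fc`, `pvalue`).
#' @param cfg an [rp_config()] (supplies `da`).
#' @param static_p_floor minimum p-value for a gene to enter the static
#'   background (default 0.1).
#' @param min_abs_lfc minimum |log2fc| for a gene to be considered
#'   differential (default 0).
#' @return list of class `"gene_groups"` with character vectors `up`, `down`,
#'   `static` (pairwise disjoint).
#' @export
group_genes <- function(expression, cfg = rp_config(), static_p_floor = 0.1,
                        min_abs_lfc = 0.0) {
  stopifnot(nrow(expression) > 0)
  ord <- function(sub) {
    sub[order(sub$pvalue, -abs(sub$log2fc), sub$gene_id), , drop = FALSE]
  }
  up_pool <- ord(expression[expression$log2fc > min_abs_lfc, , drop = FALSE])
  down_pool <- ord(expression[expression$log2fc < -min_abs_lfc, , drop = FALSE])
  up <- head(up_pool$gene_id, cfg$da)
  down <- head(down_pool$gene_id, cfg$da)
  rest <- !(expression$gene_id %in% c(up, down))
  static <- expression$gene_id[rest & expression$pvalue >= static_p_floor]
  if (!length(static))
    stop("group_genes: static background is empty; cannot form a null group")
  structure(list(up = up, down = down, static = static),
            class = "gene_groups")
}

#' Activating/repressive inference by Kolmogorov-Smirnov test
#'
#' Compares the regulatory-potential distribution of the up- and of the
#' down-regulated group against the static background with a two-sample KS
#' test.  The headline p-value is one-sided for the alternative "the group's
#' scores are stochastically greater than static" (binding enriched near the
#' group); the two-sided p is co-reported.  Cumulative rank curves sweep all
#' scored genes from highest to lowest regulatory potential and record the
#' fraction of each group accumulated.
#'
#' @param rp an [regulatory_potential()] table.
#' @param groups a [group_genes()] result.
#' @param label optional label for the peak subset the rp table was computed
#'   from (e.g. `"all"`, `"I"`, `"II"`).
#' @return list of class `"beta_result"`: `stats` (data.frame: group, n,
#'   n_static, D, p_one_sided, p_two_sided; `NA` when the group has < 3
#'   scored genes), `curves` (data.frame: rank, gene_id, score, cum_up,
#'   cum_down, cum_static), `label`.
#' @export
ks_activating_repressive <- function(rp, groups, label = NULL) {
  stopifnot(inherits(groups, "gene_groups"))
  s_static <- rp$score[rp$gene_id %in% groups$static]
  one <- function(group_name) {
    s_grp <- rp$score[rp$gene_id %in% groups[[group_name]]]
    if (length(s_grp) < 3 || length(s_static) < 3)
      return(data.frame(group = group_name, n = length(s_grp),
                        n_static = length(s_static), D = NA_real_,
                        p_one_sided = NA_real_, p_two_sided = NA_real_,
                        stringsAsFactors = FALSE))
    # alternative "less": the CDF of x lies below that of y, i.e. the group
    # scores are stochastically greater than the static scores
    k1 <- suppressWarnings(ks.test(s_grp, s_static, alternative = "less"))
    k2 <- suppressWarnings(ks.test(s_grp, s_static, alternative = "two.sided"))
    data.frame(group = group_name, n = length(s_grp),
               n_static = length(s_static), D = unname(k2$statistic),
               p_one_sided = k1$p.value, p_two_sided = k2$p.value,
               stringsAsFactors = FALSE)
  }
  stats <- rbind(one("up"), one("down"))
  ord <- rp[order(-rp$score, rp$gene_id), , drop = FALSE]
  # genes tied on score accumulate jointly: the curve is the group ECDF
  # evaluated at score thresholds, not a function of the arbitrary
  # within-tie gene order
  n_ord <- nrow(ord)
  ends <- which(c(ord$score[-1] != ord$score[-n_ord], TRUE))
  block_end <- rep(ends, diff(c(0, ends)))
  cum_frac <- function(set) {
    if (!length(set)) return(rep(NA_real_, nrow(ord)))
    cs <- cumsum(ord$gene_id %in% set)
    cs[block_end] / length(intersect(ord$gene_id, set))
  }
  curves <- data.frame(
    rank = seq_len(nrow(ord)),
    gene_id = ord$gene_id,
    score = ord$score,
    cum_up = cum_frac(groups$up),
    cum_down = cum_frac(groups$down),
    cum_static = cum_frac(groups$static),
    stringsAsFactors = FALSE
  )
  structure(list(stats = stats, curves = curves, label = label),
            class = "beta_result")
}

#' @export
print.beta_result <- function(x, ...) {
  cat("Binding/expression target inference",
      if (!is.null(x$label)) sprintf("(peaks: %s)", x$label), "\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Call direct target genes
#'
#' Direct targets carry both binding (regulatory potential > 0) and
#' differential expression (membership in the up or down group).  Candidates
#' are scored by the rank product of their regulatory-potential rank (among
#' candidates, descending score) and their differential-expression rank
#' (ascending p-value, then descending |log2fc|); smaller is stronger.
#'
#' @param rp a [regulatory_potential()] table.
#' @param groups a [group_genes()] result.
#' @param expression expression data.frame.
#' @return list with data.frames `up` and `down`, each `gene_id`, `score`,
#'   `k`, `log2fc`, `pvalue`, `rp_rank`, `de_rank`, `rank_product`, sorted by
#'   ascending rank product.
#' @export
direct_targets <- function(rp, groups, expression) {
  one <- function(group_name) {
    ids <- intersect(groups[[group_name]], rp$gene_id[rp$score > 0])
    if (!length(ids))
      return(data.frame(gene_id = character(), score = numeric(),
                        k = integer(), log2fc = numeric(), pvalue = numeric(),
                        rp_rank = integer(), de_rank = integer(),
                        rank_product = numeric(), stringsAsFactors = FALSE))
    ri <- rp[match(ids, rp$gene_id), , drop = FALSE]
    ei <- expression[match(ids, expression$gene_id), , drop = FALSE]
    out <- data.frame(gene_id = ids, score = ri$score, k = ri$k,
                      log2fc = ei$log2fc, pvalue = ei$pvalue,
                      stringsAsFactors = FALSE)
    out$rp_rank <- rank_by(list(-out$score, out$gene_id))
    out$de_rank <- rank_by(list(out$pvalue, -abs(out$log2fc), out$gene_id))
    out$rank_product <- out$rp_rank * out$de_rank
    out <- out[order(out$rank_product, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(up = one("up"), down = one("down"))
}

# dense 1..n ranking by successive keys (no ties remain once gene_id is a key)
rank_by <- function(keys) {
  ord <- do.call(order, keys)
  r <- integer(length(ord))
  r[ord] <- seq_along(ord)
  r
}

#' Nearest-peak distances of gene groups versus static background
#'
#' For every gene, the distance to its nearest peak
#' (`min |midpoint - TSS|` over all peaks; genes on peak-free chromosomes are
#' dropped and counted).  Group distances are summarised and compared to the
#' static group with a one-sided Mann-Whitney test for the alternative
#' "group distances are smaller than static" (binding closer to regulated
#' genes).
#'
#' @param peaks interval data.frame.
#' @param genes gene-model data.frame.
#' @param groups a [group_genes()] result.
#' @return list with `summary` (data.frame: group, n, median, q25, q75,
#'   p_vs_static; p `NA` when a group is empty or static unusable) and
#'   `distances` (named list of per-group distance vectors).
#' @export
distance_comparison <- function(peaks, genes, groups) {
  stopifnot(inherits(groups, "gene_groups"))
  mid <- interval_midpoint(peaks$start, peaks$end)
  tss <- gene_tss(genes)
  d_gene <- rep(NA_real_, nrow(genes))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(pi)) next
    d <- abs(outer(tss[gi], mid[pi], "-"))
    d_gene[gi] <- apply(d, 1L, min)
  }
  # multiple transcripts: credit the gene with its closest transcript
  per_gene <- tapply(d_gene, genes$gene_id, function(v)
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  dist_of <- function(ids) {
    v <- per_gene[names(per_gene) %in% ids]
    as.numeric(v[!is.na(v)])
  }
  dists <- list(up = dist_of(groups$up), down = dist_of(groups$down),
                static = dist_of(groups$static))
  one <- function(group_name) {
    v <- dists[[group_name]]
    p <- if (group_name != "static" && length(v) >= 1 &&
             length(dists$static) >= 1) {
      suppressWarnings(wilcox.test(v, dists$static,
                                   alternative = "less")$p.value)
    } else NA_real_
    data.frame(group = group_name, n = length(v),
               median = if (length(v)) median(v) else NA_real_,
               q25 = if (length(v)) unname(quantile(v, 0.25)) else NA_real_,
               q75 = if (length(v)) unname(quantile(v, 0.75)) else NA_real_,
               p_vs_static = p, stringsAsFactors = FALSE)
  }
  list(summary = rbind(one("up"), one("down"), one("static")),
       distances = dists)
}
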