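# Seeded generator of a paired cistrome + transcriptome study with planted
# direct-target structure: gene models on a synthetic genome, a focal and a
# partner peak set with partial co-occupancy, piecewise-constant signal
# tracks in two conditions, and a differential-expression table in which
# planted target genes move and every other gene is static.
#
# Each stage draws from its own RNG substream derived from the master seed,
# so changing e.g. the peak count never perturbs the expression draws.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is exercised under:
#' a 100 Mb genome (4 x 25 Mb), 2000 genes of which 200 are planted
#' up-targets and 200 down-targets, 1000 focal and 1000 partner peaks with
#' half the focal peaks co-occupied, planted peaks at an exponential 5 kb
#' distance scale from their target TSS, and a +/-2 log2 fold-change effect
#' over a 0.25-sd static background.
#'
#' @param seed master seed (integer).
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes total gene count.
#' @param n_target_genes_up,n_target_genes_down planted direct targets.
#' @param n_focal_peaks,n_partner_peaks peak counts for the two factors.
#' @param frac_cooccupied probability a focal peak receives an overlapping
#'   partner peak (expected Class I fraction).
#' @param target_distance_scale exponential scale (bp) of planted
#'   peak-to-TSS distances.
#' @param peak_width_mean,peak_width_sdlog log-normal peak widths (bp).
#' @param cooccupied_width_factor width multiplier for co-occupied peaks
#'   (Class I peaks run wider than the other classes).
#' @param effect_size_log2fc planted |log2 fold change|.
#' @param static_sd_log2fc log2fc standard deviation of static genes.
#' @param signal_baseline,signal_peak_height,signal_noise_sd signal-track
#'   baseline level, enrichment height over peaks, and relative Gaussian
#'   noise on both.
#' @param frac_signal_up,frac_signal_down fractions of target-linked peaks
#'   whose enrichment is scaled up / down in the second condition.
#' @param signal_change_factor the scaling factor applied to those peaks.
#' @param baseline_step step width (bp) of the baseline signal grid.
#' @return list of class `"sim_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chroms = 4L, chrom_length = 2.5e7,
                              n_genes = 2000L,
                              n_target_genes_up = 200L,
                              n_target_genes_down = 200L,
                              n_focal_peaks = 1000L, n_partner_peaks = 1000L,
                              frac_cooccupied = 0.5,
                              target_distance_scale = 5000,
                              peak_width_mean = 500, peak_width_sdlog = 0.35,
                              cooccupied_width_factor = 1.5,
                              effect_size_log2fc = 2.0,
                              static_sd_log2fc = 0.25,
                              signal_baseline = 1.0,
                              signal_peak_height = 10.0,
                              signal_noise_sd = 0.1,
                              frac_signal_up = 0.3, frac_signal_down = 0.3,
                              signal_change_factor = 2.0,
                              baseline_step = 1000) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_chroms >= 1, chrom_length > 0, n_genes >= 1,
              n_target_genes_up >= 0, n_target_genes_down >= 0,
              n_target_genes_up + n_target_genes_down <= n_genes,
              n_focal_peaks >= n_target_genes_up + n_target_genes_down,
              frac_cooccupied >= 0, frac_cooccupied <= 1,
              target_distance_scale > 0, peak_width_mean > 0,
              static_sd_log2fc > 0)
  })
  structure(cfg, class = "sim_config")
}

# sample() without the length-1 surprise
sample_n <- function(x, n) x[sample.int(length(x), n)]

# substream seed for a named stage; kept below 2^31
stage_seed <- function(seed, stage) {
  (abs(as.integer(seed)) %% 100000L) * 20011L + sum(utf8ToInt(stage))
}

#' Simulate gene models
#'
#' Places TSSs on a jittered grid so pairwise spacing is at least half the
#' grid cell; strands are drawn 50/50; every gene is a 2-exon transcript
#' with 5'/3' UTRs so all annotation categories are populated.
#'
#' @param config a [simulation_config()].
#' @return gene-model data.frame (ids `g0001...`) in genomic order.
#' @export
simulate_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  cell <- config$chrom_length / max(per_chrom)
  if (cell < 20 * config$peak_width_mean)
    stop("infeasible spacing: chrom_length / genes-per-chromosome must be ",
         ">= 20 * peak_width_mean")
  tx_len <- 5000
  withr::with_seed(stage_seed(config$seed, "genes"), {
    rows <- list()
    for (ci in seq_len(config$n_chroms)) {
      n_c <- per_chrom[ci]
      if (!n_c) next
      cell_c <- config$chrom_length / n_c
      pos <- (seq_len(n_c) - 1) * cell_c + cell_c / 4 +
        runif(n_c) * cell_c / 2
      pos <- round(pmin(pmax(pos, tx_len), config$chrom_length - tx_len))
      strand <- sample(c("+", "-"), n_c, replace = TRUE)
      tx_start <- ifelse(strand == "+", pos, pos + 1 - tx_len)
      tx_end <- tx_start + tx_len
      rows[[ci]] <- data.frame(chrom = sprintf("chr%d", ci), strand = strand,
                               tx_start = tx_start, tx_end = tx_end,
                               stringsAsFactors = FALSE)
    }
    g <- do.call(rbind, rows)
    nd <- max(4, nchar(as.character(config$n_genes)))
    g$gene_id <- sprintf(paste0("g%0", nd, "d"), seq_len(nrow(g)))
    g$tx_name <- paste0(g$gene_id, ".1")
    # relative 2-exon layout, mirrored on the minus strand so the 5' UTR
    # always sits at the TSS end; the 5' UTR (1.4 kb) outreaches the default
    # 1 kb promoter half-width so the category is observable under the
    # promoter-first precedence
    plus <- g$strand == "+"
    g$cds_start <- ifelse(plus, g$tx_start + 1400, g$tx_start + 600)
    g$cds_end <- ifelse(plus, g$tx_end - 600, g$tx_end - 1400)
    e1_end <- ifelse(plus, g$tx_start + 1200, g$tx_start + 1500)
    e2_start <- ifelse(plus, g$tx_end - 1500, g$tx_end - 1200)
    g$exon_starts <- mapply(function(s, e2) c(s, e2), g$tx_start, e2_start,
                            SIMPLIFY = FALSE)
    g$exon_ends <- mapply(function(e1, e) c(e1, e), e1_end, g$tx_end,
                          SIMPLIFY = FALSE)
    g[c("gene_id", "tx_name", "chrom", "strand", "tx_start", "tx_end",
        "cds_start", "cds_end", "exon_starts", "exon_ends")]
  })
}

draw_widths <- function(n, mean_w, sdlog) {
  w <- rlnorm(n, meanlog = log(mean_w) - sdlog^2 / 2, sdlog = sdlog)
  pmax(50, round(w))
}

#' Simulate focal and partner peak sets with planted targets
#'
#' One focal peak is planted near the TSS of every target gene at a signed
#' exponential distance; remaining focal peaks fall uniformly over the
#' genome.  A `frac_cooccupied` fraction of focal peaks receive an
#' overlapping partner peak (midpoint offset under half the smaller width);
#' remaining partner peaks are placed uniformly away from focal peaks.
#' Co-occupied peaks draw wider widths (`cooccupied_width_factor`).
#'
#' @param config a [simulation_config()].
#' @param genes output of [simulate_genes()].
#' @return list: `focal` and `partner` interval data.frames (with `name`),
#'   `truth_genes` (data.frame gene_id, label in planted_up / planted_down /
#'   static), `truth_peaks` (data.frame name, label in target-linked /
#'   background, target_gene).
#' @export
simulate_peaks <- function(config, genes) {
  stopifnot(inherits(config, "sim_config"))
  n_up <- config$n_target_genes_up
  n_down <- config$n_target_genes_down
  n_planted <- n_up + n_down
  glen <- config$chrom_length
  withr::with_seed(stage_seed(config$seed, "peaks"), {
    tgt_idx <- sample(nrow(genes), n_planted)
    up_ids <- genes$gene_id[tgt_idx[seq_len(n_up)]]
    down_ids <- genes$gene_id[tgt_idx[n_up + seq_len(n_down)]]
    truth_genes <- data.frame(
      gene_id = genes$gene_id,
      label = ifelse(genes$gene_id %in% up_ids, "planted_up",
                     ifelse(genes$gene_id %in% down_ids, "planted_down",
                            "static")),
      stringsAsFactors = FALSE)

    # planted focal peaks near target TSSs (distance capped inside the
    # regulatory window so every planted target is scoreable)
    tss <- gene_tss(genes)
    d <- pmin(rexp(n_planted, rate = 1 / config$target_distance_scale), 95000)
    sgn <- sample(c(-1, 1), n_planted, replace = TRUE)
    planted_mid <- round(tss[tgt_idx] + sgn * d)

    n_bg <- config$n_focal_peaks - n_planted
    bg_chrom <- sample(config$n_chroms, n_bg, replace = TRUE)
    bg_mid <- round(runif(n_bg, 0, glen))
    focal_mid <- c(planted_mid, bg_mid)
    focal_chrom <- c(genes$chrom[tgt_idx], sprintf("chr%d", bg_chrom))

    cooc <- runif(config$n_focal_peaks) < config$frac_cooccupied
    wf <- draw_widths(config$n_focal_peaks, config$peak_width_mean,
                      config$peak_width_sdlog)
    wf[cooc] <- draw_widths(sum(cooc),
                            config$peak_width_mean * config$cooccupied_width_factor,
                            config$peak_width_sdlog)
    focal_mid <- pmin(pmax(focal_mid, ceiling(wf / 2)), glen - ceiling(wf / 2))
    focal <- data.frame(
      chrom = focal_chrom,
      start = focal_mid - floor(wf / 2),
      end = focal_mid - floor(wf / 2) + wf,
      name = sprintf("focal_%04d", seq_len(config$n_focal_peaks)),
      strand = ".",
      stringsAsFactors = FALSE)

    truth_peaks <- data.frame(
      name = focal$name,
      label = c(rep("target-linked", n_planted), rep("background", n_bg)),
      target_gene = c(genes$gene_id[tgt_idx], rep(NA_character_, n_bg)),
      stringsAsFactors = FALSE)

    # partner peaks: overlapping mates for co-occupied focal peaks
    n_cooc <- sum(cooc)
    if (n_cooc > config$n_partner_peaks)
      stop("n_partner_peaks too small for frac_cooccupied")
    wp_mate <- draw_widths(n_cooc,
                           config$peak_width_mean * config$cooccupied_width_factor,
                           config$peak_width_sdlog)
    offset <- round(runif(n_cooc, -0.4, 0.4) * pmin(wf[cooc], wp_mate))
    mate_mid <- focal_mid[cooc] + offset
    mate_mid <- pmin(pmax(mate_mid, ceiling(wp_mate / 2)), glen - ceiling(wp_mate / 2))

    n_free <- config$n_partner_peaks - n_cooc
    wp_free <- draw_widths(n_free, config$peak_width_mean, config$peak_width_sdlog)
    free_chrom <- sprintf("chr%d", sample(config$n_chroms, n_free, replace = TRUE))
    free_mid <- round(runif(n_free, 0, glen))
    # keep background partner peaks clear of focal peaks (they are Class III)
    for (iter in 1:25) {
      cand <- data.frame(chrom = free_chrom,
                         start = pmax(0, free_mid - floor(wp_free / 2)),
                         end = pmax(1, free_mid - floor(wp_free / 2) + wp_free),
                         stringsAsFactors = FALSE)
      hit <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(as_granges0(cand), as_granges0(focal))))
      if (!length(hit)) break
      free_chrom[hit] <- sprintf("chr%d", sample(config$n_chroms, length(hit),
                                                 replace = TRUE))
      free_mid[hit] <- round(runif(length(hit), 0, glen))
    }
    partner <- data.frame(
      chrom = c(focal$chrom[cooc], free_chrom),
      start = c(mate_mid - floor(wp_mate / 2),
                pmax(0, free_mid - floor(wp_free / 2))),
      end = c(mate_mid - floor(wp_mate / 2) + wp_mate,
              pmax(0, free_mid - floor(wp_free / 2)) + wp_free),
      name = sprintf("partner_%04d", seq_len(config$n_partner_peaks)),
      strand = ".",
      stringsAsFactors = FALSE)
    list(focal = focal, partner = partner, truth_genes = truth_genes,
         truth_peaks = truth_peaks)
  })
}

# trapezoidal enrichment steps over one peak: quarter-width ramps (4 steps
# each side) flanking a half-width plateau at the full height
trapezoid_steps <- function(start, end, height) {
  w <- end - start
  ramp <- max(4, floor(w / 4))
  nstep <- 4L
  up_edges <- round(seq(start, start + ramp, length.out = nstep + 1))
  down_edges <- round(seq(end - ramp, end, length.out = nstep + 1))
  lev_up <- height * (seq_len(nstep) - 0.5) / nstep
  data.frame(
    start = c(up_edges[-(nstep + 1)], start + ramp, down_edges[-(nstep + 1)]),
    end = c(up_edges[-1], end - ramp, down_edges[-1]),
    value = c(lev_up, height, rev(lev_up))
  )
}

#' Simulate a pair of condition signal tracks
#'
#' A baseline of Gaussian-perturbed constant steps carries a trapezoidal
#' enrichment plateau over every focal peak.  In the second (knockout-like)
#' condition a subset of target-linked peaks changes enrichment, aligned
#' with the expression direction of the linked gene: a `frac_signal_up`
#' fraction of peaks linked to up-regulated targets is scaled up by
#' `signal_change_factor` and a `frac_signal_down` fraction of peaks linked
#' to down-regulated targets is scaled down by the same factor, so mark
#' changes and expression changes are positively coupled in both
#' directions.  All other peaks keep their height; baseline noise is drawn
#' independently per condition.
#'
#' @param config a [simulation_config()].
#' @param peaks a [simulate_peaks()] result (uses `focal`, `truth_peaks` and
#'   `truth_genes`).
#' @return list: signal tracks `wt` and `ko`, plus `signal_truth`
#'   (data.frame name, direction in up / down / unchanged).
#' @export
simulate_signal <- function(config, peaks) {
  focal <- peaks$focal
  tgt_label <- peaks$truth_genes$label[match(peaks$truth_peaks$target_gene,
                                             peaks$truth_genes$gene_id)]
  up_linked <- which(peaks$truth_peaks$label == "target-linked" &
                       tgt_label == "planted_up")
  down_linked <- which(peaks$truth_peaks$label == "target-linked" &
                         tgt_label == "planted_down")
  withr::with_seed(stage_seed(config$seed, "signal"), {
    n_up <- round(config$frac_signal_up * length(up_linked))
    n_down <- round(config$frac_signal_down * length(down_linked))
    dir <- rep("unchanged", nrow(focal))
    dir[sample_n(up_linked, n_up)] <- "up"
    dir[sample_n(down_linked, n_down)] <- "down"
    heights <- config$signal_peak_height *
      pmax(0, 1 + rnorm(nrow(focal), 0, config$signal_noise_sd))
    h_ko <- heights
    h_ko[dir == "up"] <- heights[dir == "up"] * config$signal_change_factor
    h_ko[dir == "down"] <- heights[dir == "down"] / config$signal_change_factor

    one_track <- function(h) {
      segs <- list()
      for (ci in seq_len(config$n_chroms)) {
        ch <- sprintf("chr%d", ci)
        edges_base <- seq(0, config$chrom_length, by = config$baseline_step)
        if (edges_base[length(edges_base)] < config$chrom_length)
          edges_base <- c(edges_base, config$chrom_length)
        p <- which(focal$chrom == ch)
        contrib <- if (length(p)) {
          do.call(rbind, lapply(p, function(i)
            trapezoid_steps(focal$start[i], focal$end[i], h[i])))
        } else data.frame(start = numeric(), end = numeric(), value = numeric())
        contrib <- contrib[contrib$start < contrib$end, , drop = FALSE]
        edges <- sort(unique(c(edges_base, contrib$start, contrib$end)))
        s <- edges[-length(edges)]
        e <- edges[-1]
        base_val <- pmax(0, rnorm(length(s), config$signal_baseline,
                                  config$signal_noise_sd * config$signal_baseline))
        v <- base_val
        if (nrow(contrib)) {
          m <- interval_midpoint(s, e)
          hits <- GenomicRanges::findOverlaps(
            GenomicRanges::GRanges(ch, IRanges::IRanges(m + 1, m + 1)),
            GenomicRanges::GRanges(ch, IRanges::IRanges(contrib$start + 1,
                                                        contrib$end)))
          if (length(hits)) {
            add <- tapply(contrib$value[S4Vectors::subjectHits(hits)],
                          S4Vectors::queryHits(hits), sum)
            v[as.integer(names(add))] <- v[as.integer(names(add))] + as.numeric(add)
          }
        }
        segs[[ci]] <- data.frame(chrom = ch, start = s, end = e, value = v,
                                 stringsAsFactors = FALSE)
      }
      as_signal_track(do.call(rbind, segs))
    }
    wt <- one_track(heights)
    ko <- one_track(h_ko)
    list(wt = wt, ko = ko,
         signal_truth = data.frame(name = focal$name, direction = dir,
                                   stringsAsFactors = FALSE))
  })
}

#' Simulate a differential-expression table
#'
#' Planted up/down genes draw `log2fc ~ Normal(+/- effect, static_sd)`;
#' static genes draw `Normal(0, static_sd)`.  P-values come from the normal
#' tail of the simulated log2fc (`2 * pnorm(-|log2fc| / static_sd)`), which
#' makes static p-values exactly Uniform(0,1) and planted p-values small, and
#' keeps the differential ranking coherent with effect size.  `padj` is BH.
#'
#' @param config a [simulation_config()].
#' @param truth_genes truth labels from [simulate_peaks()].
#' @return expression data.frame (`gene_id`, `log2fc`, `pvalue`, `padj`).
#' @export
simulate_expression <- function(config, truth_genes) {
  withr::with_seed(stage_seed(config$seed, "expression"), {
    n <- nrow(truth_genes)
    mu <- ifelse(truth_genes$label == "planted_up", config$effect_size_log2fc,
                 ifelse(truth_genes$label == "planted_down",
                        -config$effect_size_log2fc, 0))
    lfc <- rnorm(n, mu, config$static_sd_log2fc)
    p <- 2 * pnorm(-abs(lfc) / config$static_sd_log2fc)
    p <- pmin(pmax(p, 1e-300), 1)
    data.frame(gene_id = truth_genes$gene_id, log2fc = lfc, pvalue = p,
               padj = p.adjust(p, method = "BH"), stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic study
#'
#' Chains the four generator stages and optionally writes every artifact to
#' disk in its standard format (refFlat, narrowPeak, bedGraph, TSV) so the
#' readers can re-ingest them.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory.
#' @param include_signal simulate the signal tracks (the slowest stage);
#'   set `FALSE` when only peaks/expression are needed.
#' @return list of class `"synthetic_study"`: `genes`, `focal`, `partner`,
#'   `truth_genes`, `truth_peaks`, `expression`, `signal_wt`, `signal_ko`,
#'   `signal_truth`, `config`.
#' @export
simulate_study <- function(config = simulation_config(), out_dir = NULL,
                           include_signal = TRUE) {
  genes <- simulate_genes(config)
  pk <- simulate_peaks(config, genes)
  expression <- simulate_expression(config, pk$truth_genes)
  sig <- if (include_signal) simulate_signal(config, pk) else NULL
  study <- structure(list(
    genes = genes, focal = pk$focal, partner = pk$partner,
    truth_genes = pk$truth_genes, truth_peaks = pk$truth_peaks,
    expression = expression,
    signal_wt = sig$wt, signal_ko = sig$ko, signal_truth = sig$signal_truth,
    config = config), class = "synthetic_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_gene_models(genes, file.path(out_dir, "genes.refflat"))
    np <- function(x) { x$score <- 0; x$signal_value <- 0; x }
    write_intervals(np(pk$focal), file.path(out_dir, "focal.narrowPeak"),
                    "narrowpeak")
    write_intervals(np(pk$partner), file.path(out_dir, "partner.narrowPeak"),
                    "narrowpeak")
    write_expression(expression, file.path(out_dir, "expression.tsv"))
    write_tsv_table(pk$truth_genes, file.path(out_dir, "truth_genes.tsv"))
    write_tsv_table(pk$truth_peaks, file.path(out_dir, "truth_peaks.tsv"))
    if (include_signal) {
      write_bedgraph(sig$wt, file.path(out_dir, "mark.wt.bedGraph"))
      write_bedgraph(sig$ko, file.path(out_dir, "mark.ko.bedGraph"))
      write_tsv_table(sig$signal_truth, file.path(out_dir, "truth_signal.tsv"))
    }
    write_run_metadata(file.path(out_dir, "config.json"),
                       params = unclass(config), seed = config$seed)
  }
  study
}
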