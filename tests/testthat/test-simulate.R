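test_that("all generator stages are deterministic under a fixed seed", {
  cfg <- small_config(seed = 42)
  s1 <- simulate_study(cfg, include_signal = TRUE)
  s2 <- simulate_study(cfg, include_signal = TRUE)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$focal, s2$focal)
  expect_identical(s1$partner, s2$partner)
  expect_identical(s1$expression, s2$expression)
  expect_identical(as.data.frame(s1$signal_wt), as.data.frame(s2$signal_wt))
  expect_identical(as.data.frame(s1$signal_ko), as.data.frame(s2$signal_ko))
})

test_that("gene placement respects counts, ids and pairwise spacing", {
  cfg <- small_config(seed = 3)
  g <- simulate_genes(cfg)
  expect_equal(nrow(g), 200)
  expect_equal(g$gene_id[1], "g0001")
  expect_equal(g$gene_id[200], "g0200")
  tss <- gene_tss(g)
  for (ch in unique(g$chrom)) {
    d <- diff(sort(tss[g$chrom == ch]))
    # jittered-grid guard: half a grid cell
    expect_true(all(d >= (cfg$chrom_length / sum(g$chrom == ch)) / 2 - 5000))
  }
  # every annotation category is populated by construction: probe the
  # feature boundaries of one plus- and one minus-strand gene
  probe <- function(gene, offset)
    annotate_distribution(iv(gene$chrom, gene$tx_start + offset,
                             gene$tx_start + offset + 2), g)$per_peak$category
  gp <- g[g$strand == "+", ][1, ]
  expect_equal(probe(gp, 0), "promoter")
  expect_equal(probe(gp, 1100), "5utr")         # past the promoter, before CDS
  expect_equal(probe(gp, 2000), "intron")
  expect_equal(probe(gp, 3600), "coding_exon")  # exon2 within the CDS
})

test_that("co-occupancy fraction follows the configured binomial rate", {
  cfg <- small_config(seed = 10, n_focal_peaks = 200L, n_partner_peaks = 200L,
                      frac_cooccupied = 0.5)
  pk <- simulate_peaks(cfg, simulate_genes(cfg))
  cls <- classify_peaks(pk$focal, pk$partner)
  n1 <- sum(cls$focal$class == "I")
  expect_lt(abs(n1 - 100), 3 * sqrt(200 * 0.25) + 3)  # binomial 3-sigma + slack
})

test_that("full co-occupancy leaves no Class II peaks", {
  cfg <- small_config(seed = 5, frac_cooccupied = 1)
  pk <- simulate_peaks(cfg, simulate_genes(cfg))
  cls <- classify_peaks(pk$focal, pk$partner)
  expect_equal(sum(cls$focal$class == "II"), 0)
})

test_that("planted peaks sit closer to TSSs than background peaks", {
  cfg <- small_config(seed = 8, target_distance_scale = 5000,
                      n_target_genes_up = 100L, n_target_genes_down = 100L,
                      n_focal_peaks = 400L, n_partner_peaks = 400L)
  genes <- simulate_genes(cfg)
  pk <- simulate_peaks(cfg, genes)
  ng <- nearest_gene(pk$focal, genes)
  planted <- pk$truth_peaks$label == "target-linked"
  expect_lt(median(ng$distance[planted]), median(ng$distance[!planted]))
  # every planted target gene has a focal peak within the 100 kb window
  rp <- regulatory_potential(pk$focal, genes)
  tgt <- pk$truth_genes$gene_id[pk$truth_genes$label != "static"]
  expect_true(all(rp$k[rp$gene_id %in% tgt] >= 1))
})

test_that("truth labels partition genes", {
  cfg <- small_config(seed = 2)
  pk <- simulate_peaks(cfg, simulate_genes(cfg))
  expect_equal(sort(table(pk$truth_genes$label)[c("planted_up", "planted_down")]),
               sort(c(planted_up = 30L, planted_down = 30L)),
               ignore_attr = TRUE)
  expect_equal(nrow(pk$truth_genes), 200)
  expect_true(all(pk$truth_genes$label %in%
                    c("planted_up", "planted_down", "static")))
})

test_that("noise-free signal equals the configured enrichment exactly", {
  cfg <- small_config(seed = 4, signal_noise_sd = 0, signal_baseline = 0,
                      signal_peak_height = 7)
  genes <- simulate_genes(cfg)
  pk <- simulate_peaks(cfg, genes)
  sig <- simulate_signal(cfg, pk)
  p1 <- pk$focal[1, ]
  mid <- interval_midpoint(p1$start, p1$end)
  # plateau value at the peak centre is exactly the configured height
  v <- window_mean_signal(sig$wt, p1$chrom, mid, mid + 1)
  expect_equal(v, 7, tolerance = 1e-12)
})

test_that("site signal change recovers planted directions at moderate noise", {
  cfg <- small_config(seed = 6, signal_noise_sd = 0.1)
  genes <- simulate_genes(cfg)
  pk <- simulate_peaks(cfg, genes)
  sig <- simulate_signal(cfg, pk)
  sc <- site_signal_change(sig$wt, sig$ko, pk$focal)
  chg <- sig$signal_truth$direction != "unchanged"
  expect_gt(sum(chg), 10)
  hit <- sign(sc$log2_change[chg]) ==
    ifelse(sig$signal_truth$direction[chg] == "up", 1, -1)
  expect_gte(mean(hit), 0.95)
})

test_that("planted expression moves by the configured effect", {
  cfg <- small_config(seed = 9)
  pk <- simulate_peaks(cfg, simulate_genes(cfg))
  ex <- simulate_expression(cfg, pk$truth_genes)
  up <- pk$truth_genes$label == "planted_up"
  stat <- pk$truth_genes$label == "static"
  expect_gt(mean(ex$log2fc[up]), 1.5)
  expect_lt(abs(mean(ex$log2fc[stat])), 0.1)
  # p-values of static genes are uniform: mean near 0.5
  expect_lt(abs(mean(ex$pvalue[stat]) - 0.5), 0.1)
})

test_that("generated files re-ingest through every reader without error", {
  cfg <- small_config(seed = 12)
  dir <- withr::local_tempdir()
  st <- simulate_study(cfg, out_dir = dir, include_signal = TRUE)
  genes <- read_gene_models(file.path(dir, "genes.refflat"))
  expect_equal(genes$gene_id, st$genes$gene_id)
  expect_equal(genes$tx_start, st$genes$tx_start)
  focal <- read_intervals(file.path(dir, "focal.narrowPeak"), "narrowpeak")
  expect_equal(focal$start, st$focal$start)
  wt <- read_bedgraph(file.path(dir, "mark.wt.bedGraph"))
  expect_equal(nrow(wt), nrow(st$signal_wt))
  ex <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(ex$gene_id, st$expression$gene_id)
  expect_equal(ex$log2fc, st$expression$log2fc, tolerance = 1e-12)
})

test_that("stronger planted effects never weaken the up-group KS signal", {
  p_at_effect <- function(effect) {
    cfg <- small_config(seed = 31, effect_size_log2fc = effect)
    genes <- simulate_genes(cfg)
    pk <- simulate_peaks(cfg, genes)
    ex <- simulate_expression(cfg, pk$truth_genes)
    rp <- regulatory_potential(pk$focal, genes)
    g <- group_genes(ex, rp_config(da = 50))
    ks_activating_repressive(rp, g)$stats$p_one_sided[1]
  }
  ps <- vapply(c(0.5, 1.5, 3), p_at_effect, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("infeasible gene spacing is a configuration error", {
  cfg <- small_config(seed = 1)
  cfg$chrom_length <- 1e5   # 100 genes/chrom in 100 kb: too dense
  expect_error(simulate_genes(cfg), "infeasible spacing")
})
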