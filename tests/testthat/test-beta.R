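# The decay constants give closed-form single-peak scores: a peak on the TSS
# contributes exp(-0.5), one at 10 kb (Delta = 0.1) exp(-0.9), etc.

test_that("regulatory potential reproduces the closed-form decay", {
  gene <- gene_row("g1", "chr1", "+", 500000, 505000)  # TSS 500000
  peak_at <- function(d) iv("chr1", 500000 + d - 100, 500000 + d + 100)

  rp <- regulatory_potential(peak_at(0), gene)
  expect_equal(rp$score, exp(-0.5), tolerance = 1e-9)
  expect_equal(rp$score, 0.606531, tolerance = 1e-6)

  # peaks at 10 kb and 50 kb: exp(-0.9) + exp(-2.5)
  rp <- regulatory_potential(rbind(peak_at(10000), peak_at(50000)), gene)
  expect_equal(rp$score, exp(-0.9) + exp(-2.5), tolerance = 1e-12)
  expect_equal(rp$score, 0.4886547, tolerance = 1e-6)  # mpmath 30-digit oracle
  expect_equal(rp$k, 2L)

  # closed boundary: exactly 100 kb counts with weight exp(-4.5); 100,001 not
  rp_in <- regulatory_potential(iv("chr1", 599900, 600100), gene)   # mid 600000
  expect_equal(rp_in$score, exp(-4.5), tolerance = 1e-12)
  rp_out <- regulatory_potential(iv("chr1", 599901, 600101), gene)  # mid 600001
  expect_equal(rp_out$score, 0)
  expect_equal(rp_out$k, 0L)
})

test_that("genes without nearby peaks score zero, and zero iff k is zero", {
  withr::with_seed(79, {
    genes <- random_genes(100, span = 1e6)
    peaks <- random_intervals(60, span = 1e6, max_width = 400)
    rp <- regulatory_potential(peaks, genes)
    expect_equal(rp$score == 0, rp$k == 0)
    expect_true(all(rp$score <= rp$k * exp(-0.5) + 1e-12))
  })
})

test_that("regulatory potential matches the compensated brute-force oracle", {
  withr::with_seed(83, {
    for (rep in 1:3) {
      peaks <- random_intervals(500, span = 8e5)
      genes <- random_genes(200, span = 8e5)
      rp <- regulatory_potential(peaks, genes)
      bf <- bf_rp(peaks, genes)
      m <- match(rp$gene_id, bf$gene_id)
      expect_equal(rp$score, bf$score[m], tolerance = 1e-12)
      expect_equal(rp$k, bf$k[m])
    }
  })
})

test_that("adding peaks inside the window never lowers scores; outside changes nothing", {
  withr::with_seed(89, {
    genes <- random_genes(50, span = 5e5, chroms = "chr1")
    peaks <- random_intervals(100, span = 5e5, chroms = "chr1")
    base <- regulatory_potential(peaks, genes)
    extra_in <- iv("chr1", 250000, 250400, name = "extra")
    inside <- regulatory_potential(rbind(peaks, extra_in), genes)
    expect_true(all(inside$score[match(base$gene_id, inside$gene_id)] >=
                      base$score - 1e-12))
    extra_out <- iv("chr9", 0, 400, name = "far")
    outside <- regulatory_potential(rbind(peaks, extra_out), genes)
    expect_equal(outside$score[match(base$gene_id, outside$gene_id)],
                 base$score)
  })
})

test_that("k identical-distance peaks score k times the single-peak weight", {
  gene <- gene_row("g1", "chr1", "+", 500000, 505000)
  one <- iv("chr1", 489900, 490100)
  k <- 7
  rp1 <- regulatory_potential(one, gene)
  rpk <- regulatory_potential(one[rep(1, k), ], gene)
  expect_equal(rpk$score, k * rp1$score, tolerance = 1e-12)
})

test_that("a multi-transcript gene is credited with its best transcript", {
  genes <- rbind(gene_row("g1", "chr1", "+", 500000, 505000),
                 gene_row("g1", "chr1", "+", 560000, 565000))
  peak <- iv("chr1", 499900, 500100)  # on the first transcript's TSS
  rp <- regulatory_potential(peak, genes)
  expect_equal(nrow(rp), 1)
  expect_equal(rp$score, exp(-0.5), tolerance = 1e-12)
})

test_that("gene grouping honours direction, da cap and the static floor", {
  withr::with_seed(97, {
    n <- 2000
    ex <- data.frame(gene_id = sprintf("g%04d", 1:n),
                     log2fc = rnorm(n, 0, 0.1),
                     pvalue = runif(n), stringsAsFactors = FALSE)
    sig <- sample(n, 300)
    ex$log2fc[sig] <- abs(rnorm(300, 2, 0.2))
    ex$pvalue[sig] <- runif(300, 0, 1e-4)
    g <- group_genes(ex, rp_config(da = 500))
    # only 300 clearly-significant up genes exist, but positive-lfc nulls
    # fill the quota: the 300 significant ones must all be included
    expect_true(all(ex$gene_id[sig] %in% g$up))
    expect_lte(length(g$up), 500)
    expect_true(all(ex$pvalue[match(g$static, ex$gene_id)] >= 0.1))
    expect_length(intersect(g$up, g$down), 0)
    expect_length(intersect(g$up, g$static), 0)

    # with 800 significant up genes, exactly the 500 smallest-p are kept
    ex2 <- ex
    sig2 <- sample(n, 800)
    ex2$log2fc[] <- abs(rnorm(n, 0, 0.1))
    ex2$log2fc[sig2] <- 2
    ex2$pvalue[] <- runif(n, 0.2, 1)
    ex2$pvalue[sig2] <- runif(800, 0, 1e-3)
    g2 <- group_genes(ex2, rp_config(da = 500))
    expect_length(g2$up, 500)
    expect_setequal(g2$up, ex2$gene_id[order(ex2$pvalue)][1:500])
  })
})

test_that("grouping fails loudly when no static background remains", {
  ex <- data.frame(gene_id = c("g1", "g2"), log2fc = c(2, -2),
                   pvalue = c(1e-5, 1e-5), stringsAsFactors = FALSE)
  expect_error(group_genes(ex, rp_config(da = 5)), "static")
})

test_that("KS inference: identical distributions give D = 0, p = 1", {
  rp <- data.frame(gene_id = sprintf("g%03d", 1:300),
                   score = rep(seq(0.1, 1, length.out = 100), 3),
                   k = 1L, stringsAsFactors = FALSE)
  rp$rank <- rank(-rp$score, ties.method = "first")
  groups <- structure(list(up = rp$gene_id[1:100], down = character(0),
                           static = rp$gene_id[101:300]),
                      class = "gene_groups")
  res <- ks_activating_repressive(rp, groups)
  up <- res$stats[res$stats$group == "up", ]
  expect_equal(up$D, 0)
  expect_equal(up$p_one_sided, 1)
  expect_true(is.na(res$stats$D[res$stats$group == "down"]))  # empty group
})

test_that("a shifted group is detected one-sided, matching a permutation oracle", {
  withr::with_seed(101, {
    s_static <- runif(100, 0, 2)
    s_up <- s_static + 1.0
    rp <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     score = c(s_up, s_static), k = 1L,
                     stringsAsFactors = FALSE)
    rp$rank <- rank(-rp$score, ties.method = "first")
    groups <- structure(list(up = rp$gene_id[1:100], down = character(0),
                             static = rp$gene_id[101:200]),
                        class = "gene_groups")
    res <- ks_activating_repressive(rp, groups)
    p <- res$stats$p_one_sided[res$stats$group == "up"]
    expect_lt(p, 1e-3)
    expect_lt(perm_ks_p(s_up, s_static, B = 2000), 2 / 2001 + 1e-12)

    # moderate shift: analytic one-sided p agrees with the permutation oracle
    s_up2 <- s_static + 0.25
    p2 <- suppressWarnings(ks.test(s_up2, s_static,
                                   alternative = "less")$p.value)
    pp2 <- perm_ks_p(s_up2, s_static, B = 4000)
    expect_lt(abs(p2 - pp2), 4 * sqrt(pp2 * (1 - pp2) / 4000) + 1 / 4000 + 0.01)
  })
})

test_that("swapping group and static maps the one-sided p to the mirror alternative", {
  withr::with_seed(103, {
    x <- rnorm(80, 0.3)
    y <- rnorm(90)
    p_xy <- suppressWarnings(ks.test(x, y, alternative = "less")$p.value)
    p_yx <- suppressWarnings(ks.test(y, x, alternative = "greater")$p.value)
    expect_equal(p_xy, p_yx, tolerance = 1e-12)
  })
})

test_that("cumulative curves are nondecreasing from ~0 to 1", {
  cfg <- small_config(seed = 107)
  genes <- simulate_genes(cfg)
  pk <- simulate_peaks(cfg, genes)
  ex <- simulate_expression(cfg, pk$truth_genes)
  rp <- regulatory_potential(pk$focal, genes)
  g <- group_genes(ex, rp_config(da = 50))
  res <- ks_activating_repressive(rp, g)
  for (cv in list(res$curves$cum_up, res$curves$cum_down,
                  res$curves$cum_static)) {
    expect_false(is.unsorted(cv))
    expect_equal(cv[length(cv)], 1)
    expect_true(all(cv >= 0 & cv <= 1))
  }
  expect_true(all(res$stats$D >= 0 & res$stats$D <= 1))
})

test_that("direct targets require both binding and expression change", {
  rp <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                   score = c(0.9, 0, 0.5, 0.2), k = c(2L, 0L, 1L, 1L),
                   rank = 1:4, stringsAsFactors = FALSE)
  ex <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                   log2fc = c(2, 1.5, -1, 0.01),
                   pvalue = c(1e-6, 1e-5, 1e-4, 0.9), stringsAsFactors = FALSE)
  groups <- structure(list(up = c("gA", "gB"), down = "gC", static = "gD"),
                      class = "gene_groups")
  tg <- direct_targets(rp, groups, ex)
  expect_equal(tg$up$gene_id, "gA")     # gB bound nowhere (k = 0): excluded
  expect_equal(tg$down$gene_id, "gC")

  all_static <- structure(list(up = character(0), down = character(0),
                               static = c("gA", "gB", "gC", "gD")),
                          class = "gene_groups")
  tg0 <- direct_targets(rp, all_static, ex)
  expect_equal(nrow(tg0$up), 0)
  expect_equal(nrow(tg0$down), 0)
})

test_that("rank-product ordering favours jointly strong candidates", {
  rp <- data.frame(gene_id = c("g1", "g2", "g3"), score = c(1, 0.5, 0.1),
                   k = 1L, rank = 1:3, stringsAsFactors = FALSE)
  ex <- data.frame(gene_id = c("g1", "g2", "g3"), log2fc = c(2, 2, 2),
                   pvalue = c(1e-8, 1e-6, 1e-4), stringsAsFactors = FALSE)
  groups <- structure(list(up = c("g1", "g2", "g3"), down = character(0),
                           static = character(0)), class = "gene_groups")
  tg <- direct_targets(rp, groups, ex)
  expect_equal(tg$up$gene_id, c("g1", "g2", "g3"))
  expect_equal(tg$up$rank_product, c(1, 4, 9))
})

test_that("distance comparison summarises groups and flags empties", {
  genes <- rbind(gene_row("g1", "chr1", "+", 10000, 15000),
                 gene_row("g2", "chr1", "+", 200000, 205000))
  peaks <- iv("chr1", 9900, 10100)   # midpoint exactly at g1's TSS
  groups <- structure(list(up = "g1", down = character(0), static = "g2"),
                      class = "gene_groups")
  dc <- distance_comparison(peaks, genes, groups)
  expect_equal(dc$summary$median[dc$summary$group == "up"], 0)
  expect_true(is.na(dc$summary$p_vs_static[dc$summary$group == "down"]))
})

test_that("null distance p-values are roughly uniform over replicates", {
  withr::with_seed(109, {
    ps <- vapply(1:200, function(i) {
      tss <- runif(60, 0, 1e6)
      genes <- gene_row(sprintf("g%03d", 1:60), "chr1", "+", tss, tss + 5000)
      peaks <- random_intervals(40, chroms = "chr1", span = 1e6)
      groups <- structure(list(up = genes$gene_id[1:20], down = character(0),
                               static = genes$gene_id[21:60]),
                          class = "gene_groups")
      distance_comparison(peaks, genes, groups)$summary$p_vs_static[1]
    }, numeric(1))
    ks <- suppressWarnings(ks.test(ps, "punif"))
    expect_gt(ks$p.value, 0.001)
    expect_lt(abs(mean(ps) - 0.5), 0.1)
  })
})
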