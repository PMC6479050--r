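# End-to-end driver: simulate a study, classify peaks, annotate, profile
# signal, score regulatory potential, infer activating/repressive function,
# call direct targets, and compare binding distances — writing every result
# table under one output directory.  Fully deterministic under the config
# seed: two runs on the same config produce byte-identical files.

#' Run the full binding/expression integration pipeline
#'
#' Simulates a study from `config` (or uses a supplied one), then runs every
#' analysis stage and writes TSV/JSON results under `out_dir`.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param study optional pre-simulated [simulate_study()] result; when given,
#'   `config` is taken from it.
#' @param flank,bin profile window half-width and bin size in bp.
#' @param site_window half-window for per-site signal means.
#' @param proximal_cutoff TSS-proximal/-distal split in bp.
#' @param promoter_halfwidth promoter half-width for annotation.
#' @param rp [rp_config()] for the target inference.
#' @return (invisibly) a named list of all in-memory results.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         study = NULL, flank = 5000, bin = 50,
                         site_window = 1000, proximal_cutoff = 2000,
                         promoter_halfwidth = 1000, rp = rp_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(study)) {
    study <- simulate_study(config, out_dir = file.path(out_dir, "inputs"))
  } else {
    config <- study$config
  }

  # --- peak classification + annotation -------------------------------------
  cls <- classify_peaks(study$focal, study$partner)
  write_tsv_table(cls$focal[c("chrom", "start", "end", "name", "class")],
                  file.path(out_dir, "classes_focal.tsv"))
  write_tsv_table(cls$partner[c("chrom", "start", "end", "name", "class")],
                  file.path(out_dir, "classes_partner.tsv"))

  dist_all <- annotate_distribution(study$focal, study$genes, promoter_halfwidth)
  by_class <- lapply(c(I = "I", II = "II"), function(cl)
    annotate_distribution(cls$focal[cls$focal$class == cl, ], study$genes,
                          promoter_halfwidth))
  distribution <- data.frame(
    category = GENOMIC_CATEGORIES,
    all = unname(dist_all$fractions),
    class_I = unname(by_class$I$fractions),
    class_II = unname(by_class$II$fractions),
    stringsAsFactors = FALSE)
  write_tsv_table(distribution, file.path(out_dir, "distribution.tsv"))

  widths <- width_stats(cls)
  wtab <- widths$summary
  wtab$mw_p_I_vs_II <- widths$test$p_value
  write_tsv_table(wtab, file.path(out_dir, "widths.tsv"))

  # --- signal profiles ------------------------------------------------------
  profiles <- site_changes <- correlation <- NULL
  if (!is.null(study$signal_wt)) {
    mat <- binned_matrix(study$signal_wt, cls$focal, flank = flank, bin = bin)
    prof <- average_profile(mat, cls$focal$class)
    ptab <- data.frame(class = rownames(prof), prof, check.names = FALSE)
    write_tsv_table(ptab, file.path(out_dir, "profiles.tsv"))
    profiles <- prof

    site_changes <- site_signal_change(study$signal_wt, study$signal_ko,
                                       cls$focal, window = site_window,
                                       genes = study$genes)
    write_tsv_table(site_changes, file.path(out_dir, "site_changes.tsv"))

    correlation <- proximal_distal_correlation(site_changes, study$expression,
                                               proximal_cutoff)
    jsonlite::write_json(
      list(strata = correlation$strata, n_dropped = correlation$n_dropped),
      file.path(out_dir, "correlation.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  }

  # --- regulatory potential + target inference ------------------------------
  groups <- group_genes(study$expression, rp)
  sel <- list(all = study$focal,
              I = cls$focal[cls$focal$class == "I", ],
              II = cls$focal[cls$focal$class == "II", ])
  beta <- list()
  for (lab in names(sel)) {
    rpt <- regulatory_potential(sel[[lab]], study$genes, rp)
    res <- ks_activating_repressive(rpt, groups, label = lab)
    beta[[lab]] <- list(rp = rpt, result = res)
    write_tsv_table(rpt, file.path(out_dir, sprintf("rp_%s.tsv", lab)))
    write_tsv_table(res$curves, file.path(out_dir, sprintf("curves_%s.tsv", lab)))
  }
  ks_tab <- do.call(rbind, lapply(names(beta), function(lab) {
    s <- beta[[lab]]$result$stats
    s$peaks <- lab
    s[c("peaks", setdiff(names(s), "peaks"))]
  }))
  write_tsv_table(ks_tab, file.path(out_dir, "beta_stats.tsv"))
  jsonlite::write_json(ks_tab, file.path(out_dir, "beta_result.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)

  groups_tab <- data.frame(
    gene_id = c(groups$up, groups$down, groups$static),
    group = rep(c("up", "down", "static"),
                c(length(groups$up), length(groups$down), length(groups$static))),
    stringsAsFactors = FALSE)
  write_tsv_table(groups_tab, file.path(out_dir, "groups.tsv"))

  targets <- direct_targets(beta$all$rp, groups, study$expression)
  write_tsv_table(targets$up, file.path(out_dir, "targets_up.tsv"))
  write_tsv_table(targets$down, file.path(out_dir, "targets_down.tsv"))

  dists <- distance_comparison(study$focal, study$genes, groups)
  write_tsv_table(dists$summary, file.path(out_dir, "distances.tsv"))

  write_run_metadata(
    file.path(out_dir, "run_metadata.json"),
    params = list(config = unclass(config), flank = flank, bin = bin,
                  site_window = site_window, proximal_cutoff = proximal_cutoff,
                  promoter_halfwidth = promoter_halfwidth, rp = unclass(rp)),
    seed = config$seed)

  invisible(list(study = study, classification = cls,
                 distribution = distribution, widths = widths,
                 profiles = profiles, site_changes = site_changes,
                 correlation = correlation, groups = groups, beta = beta,
                 targets = targets, distances = dists))
}
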