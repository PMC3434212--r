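# End-to-end orchestration: simulate -> preprocess -> normalize -> DE
# (baseline + paired) -> threshold grids -> clustering -> heterogeneity ->
# qPCR, with a reproducibility manifest.

#' Run the full pipeline on a synthetic cohort
#'
#' Executes every stage with the configured parameters and writes all
#' artifacts as tab-separated tables under `outdir`, together with a
#' `manifest.tsv` recording per-artifact row counts and MD5 hashes and the
#' configuration hash. Two runs with the same configuration (including the
#' simulation seed) produce identical manifests.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @param write_beads also serialize the bead-level tables (large); default
#'   FALSE.
#' @return invisibly, a list with the in-memory stage results (`cohort`,
#'   `em`, `de_baseline`, `grid_baseline`, `de_paired`, `grid_paired`,
#'   `crp`, `cluster`, `adjacency`, `heterogeneity`, `stability`, `ddct`)
#'   and the `manifest` data frame.
#' @export
run_pipeline <- function(config = run_config(), outdir, write_beads = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  log_art <- function(name, df, path) {
    write_tabular(df, path)
    artifacts[[name]] <<- data.frame(
      stage = name, artifact = basename(path), rows = nrow(df),
      md5 = unname(tools::md5sum(path)), stringsAsFactors = FALSE)
  }

  # simulate
  cohort <- generate_cohort(config$sim)
  if (write_beads) write_cohort(cohort, file.path(outdir, "cohort"))
  log_art("simulate", cohort$meta, file.path(outdir, "samples.tsv"))

  # preprocess
  em <- build_expression_matrix(cohort$arrays, cohort$meta,
                                mad_multiplier = config$mad_multiplier,
                                alpha = config$detection_alpha,
                                mad_zero_policy = config$mad_zero_policy)
  calls <- do.call(rbind, lapply(names(em$probe_calls), function(s) {
    cbind(sample_id = s, em$probe_calls[[s]])
  }))
  log_art("preprocess", calls, file.path(outdir, "probe_calls.tsv"))
  message("preprocess: ", length(em$assessed), " of ", nrow(em$values),
          " probes assessed")

  # normalize
  em <- log2_quantile_normalize(em)
  expr_df <- data.frame(probe_id = rownames(em$values), em$values,
                        check.names = FALSE, stringsAsFactors = FALSE)
  log_art("normalize", expr_df, file.path(outdir, "expression_log2q.tsv"))

  cfg_ct <- cybert_config(config$window_size, config$confidence)
  groups <- em$groups
  meta <- em$sample_meta

  # baseline contrast: patients vs controls
  de_base <- grid_base <- NULL
  if (all(c("control.baseline", "patient.baseline") %in% names(groups))) {
    genes_base <- assessed_probes(em, c("control.baseline",
                                        "patient.baseline"))
    de_base <- cybert_contrast(em, groups$patient.baseline,
                               groups$control.baseline, genes_base, cfg_ct)
    de_base <- de_base[order(de_base$p_value), ]
    log_art("de_baseline", de_base, file.path(outdir, "de_baseline.tsv"))
    grid_base <- threshold_count_table(de_base)
    log_art("grid_baseline",
            data.frame(cell = names(grid_base), count = as.integer(grid_base)),
            file.path(outdir, "grid_baseline.tsv"))
  }

  # paired contrast: treated patients pre vs post
  de_pair <- grid_pair <- clus <- adj <- NULL
  if (all(c("treated.pre", "treated.post") %in% names(groups)) &&
      length(groups$treated.post) >= 2) {
    de_pair <- paired_contrast(em, groups$treated.pre, groups$treated.post)
    de_pair <- de_pair[order(de_pair$p_value), ]
    log_art("de_paired", de_pair, file.path(outdir, "de_paired.tsv"))
    grid_pair <- threshold_count_table(de_pair)
    log_art("grid_paired",
            data.frame(cell = names(grid_pair), count = as.integer(grid_pair)),
            file.path(outdir, "grid_paired.tsv"))

    # clustering of pre/post samples on the significantly modulated genes
    sig <- de_pair$gene_id[de_pair$p_value < 0.05]
    if (length(sig) >= 2) {
      rm_ <- build_ratio_matrix(em, groups$treated.pre, sig)
      clus <- hierarchical_cluster(rm_, c(groups$treated.pre,
                                          groups$treated.post))
      post_meta <- meta[meta$timepoint == "post", , drop = FALSE]
      pairs <- data.frame(subject_id = post_meta$subject_id,
                          pre = groups$treated.pre,
                          post = groups$treated.post,
                          stringsAsFactors = FALSE)
      adj <- adjacency_score(clus, pairs)
      log_art("cluster",
              data.frame(position = seq_along(clus$leaf_order),
                         sample_id = clus$leaf_order),
              file.path(outdir, "leaf_order.tsv"))
      log_art("cluster_merges", clus$merges,
              file.path(outdir, "merges.tsv"))
      log_art("adjacency",
              data.frame(subject_id = names(adj$per_subject),
                         adjacent = as.integer(adj$per_subject)),
              file.path(outdir, "adjacency.tsv"))
      message("cluster: adjacency fraction ",
              format(adj$adjacency_fraction, digits = 3))
    }
  }

  # CRP tertile subanalysis
  crp <- NULL
  pats <- meta[meta$group == "patient" & meta$timepoint == "baseline", ]
  if (nrow(pats) >= 6 && !anyNA(pats$crp)) {
    crp <- crp_tertile_contrast(em, cfg_ct)
    log_art("crp_grids",
            data.frame(cell = names(crp$grid_low),
                       low = as.integer(crp$grid_low),
                       high = as.integer(crp$grid_high)),
            file.path(outdir, "grid_crp.tsv"))
  }

  # per-sample heterogeneity (baseline)
  het <- NULL
  if (length(groups$control.baseline) >= 3 &&
      length(groups$patient.baseline) >= 1) {
    het_genes <- assessed_probes(em, c("control.baseline",
                                       "patient.baseline"),
                                 rule = "intersection")
    het <- per_sample_heterogeneity(em, groups$control.baseline,
                                    groups$patient.baseline,
                                    flag_k = config$flag_k,
                                    genes = het_genes)
    log_art("heterogeneity", het$sample_sd,
            file.path(outdir, "heterogeneity.tsv"))
  }

  # qPCR validation arm
  stab <- NULL
  ddct_rows <- NULL
  if (config$sim$n_de_genes > 0 && config$sim$qpcr_n_targets > 0 &&
      length(groups$control.baseline) >= 2) {
    study <- generate_qpcr(config$sim, cohort)
    agg <- qc_and_aggregate(study, config$quality_threshold)
    base_ids <- meta$sample_id[meta$timepoint == "baseline"]
    agg_base <- agg[agg$sample_id %in% base_ids, , drop = FALSE]
    for (a in c("housekeeping_candidates", "designed_stable", "targets")) {
      attr(agg_base, a) <- attr(study, a)
    }
    attr(agg_base, "meta") <- meta[meta$timepoint == "baseline", ]
    stab <- suppressWarnings(stability_ranking(agg_base))
    log_art("qpcr_stability", stab$table,
            file.path(outdir, "qpcr_stability.tsv"))
    ddct_rows <- do.call(rbind, lapply(attr(study, "targets"), function(g) {
      r <- ddct(agg_base, g, stab$selected_reference,
                groups$patient.baseline, groups$control.baseline)
      data.frame(gene = g, ddct = r$ddct, fold_change = r$fold_change,
                 p_value = r$p_value,
                 low_confidence = as.integer(r$low_confidence),
                 stringsAsFactors = FALSE)
    }))
    log_art("qpcr_ddct", ddct_rows, file.path(outdir, "qpcr_ddct.tsv"))
  }

  # manifest
  cfg_file <- file.path(outdir, "run_config.txt")
  write_run_config(config, cfg_file)
  manifest <- do.call(rbind, artifacts)
  manifest <- rbind(manifest, data.frame(
    stage = "config", artifact = basename(cfg_file), rows = NA_integer_,
    md5 = unname(tools::md5sum(cfg_file)), stringsAsFactors = FALSE))
  write_tabular(manifest, file.path(outdir, "manifest.tsv"))

  invisible(list(cohort = cohort, em = em, de_baseline = de_base,
                 grid_baseline = grid_base, de_paired = de_pair,
                 grid_paired = grid_pair, crp = crp, cluster = clus,
                 adjacency = adj, heterogeneity = het, stability = stab,
                 ddct = ddct_rows, manifest = manifest))
}
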