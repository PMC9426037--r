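#' Run the full analysis pipeline on a synthetic or provided cohort
#'
#' Orchestrates the stages end to end: cohort input (synthetic generation or
#' files), per-sample mutation statistics (TMB, MSI, frequency table,
#' signature refit), matched-cohort differential-mutation comparison,
#' covariate-adjusted differential expression with gene-set scores, consensus
#' NMF class discovery with rank selection, and actionability annotation.
#' All stage outputs are written under `out_dir` together with a
#' `manifest.json` recording the package version, seeds and a config hash;
#' rerunning with the same config reproduces the outputs bit for bit.
#'
#' @param config list with entries: `seed` (integer), `out_dir` (path),
#'   optional `cohort` (a [generate_cohort()] result; generated from
#'   `cohort_config(seed = seed)` when absent), `stages` (character subset of
#'   `c("variant_stats", "comparison", "expression", "class_discovery",
#'   "actionability")`; all by default), `control_pool_n` (default 2000),
#'   `match_target` (default 200), `thresholds` (list: `alpha`, `msi`,
#'   `tmb_high`, `overlap_ari`), and `nmf` (list: `k_range`, `n_runs`).
#' @return invisible list of stage results (also serialized under `out_dir`).
#' @export
run_pipeline <- function(config) {
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stop("config$out_dir is required",
                                      call. = FALSE)
  stages <- config$stages %||% c("variant_stats", "comparison", "expression",
                                 "class_discovery", "actionability")
  th <- config$thresholds %||% list()
  alpha <- th$alpha %||% 0.05
  msi_thr <- th$msi %||% 0.20
  tmb_high <- th$tmb_high %||% 10
  overlap_ari <- th$overlap_ari %||% 0.6
  nmf_cfg <- config$nmf %||% list()
  k_range <- nmf_cfg$k_range %||% 2:6
  n_runs <- nmf_cfg$n_runs %||% 30

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- config$cohort %||% generate_cohort(cohort_config(seed = seed))
  results <- list()

  write_maf(cohort$variants, file.path(out_dir, "variants.maf.tsv"))
  write_clinical(cohort$samples, file.path(out_dir, "clinical.tsv"))
  write_expression(cohort$expression, file.path(out_dir, "expression.csv"))

  if ("variant_stats" %in% stages) {
    tmb <- compute_tmb(cohort$variants, cohort$panel,
                       sample_ids = cohort$samples$sample_id)
    msi <- msi_score(cohort$msi, threshold = msi_thr)
    freq <- mutation_frequency_table(cohort$variants, cohort$samples)
    catalog <- build_96_catalog(cohort$variants)
    sig_fit <- if (sum(catalog) > 0) fit_signatures(catalog) else NULL
    results$variant_stats <- list(tmb = tmb, msi = msi, freq = freq$table,
                                  signature_fit = sig_fit)
    write_tsv_exact(tmb, file.path(out_dir, "tmb.tsv"))
    write_tsv_exact(freq$table, file.path(out_dir, "mutation_frequency.tsv"))
  }

  if ("comparison" %in% stages) {
    pool <- generate_control_pool(config$control_pool_n %||% 2000,
                                  seed = derive_seed(seed, 11))
    matched <- build_matched_cohort(
      pool, match_spec(target_size = config$match_target %||% 200,
                       seed = derive_seed(seed, 13)))
    genes <- setdiff(names(pool), c("sample_id", "er_status", "grade",
                                    "her2_score"))
    onc <- mutation_frequency_table(cohort$variants, cohort$samples,
                                    genes = genes)$oncoprint
    ref <- as.data.frame(t(onc))
    cmp <- differential_mutation_test(ref, matched, genes = genes,
                                      alpha = alpha)
    results$comparison <- cmp
    write_tsv_exact(cmp$table, file.path(out_dir, "differential_mutation.tsv"))
    jsonlite::write_json(as.list(cmp$spider),
                         file.path(out_dir, "spider_summary.json"),
                         auto_unbox = TRUE)
  }

  norm <- normalize_expression(cohort$expression, cohort$housekeeping)
  if ("expression" %in% stages) {
    grp <- factor(ifelse(cohort$samples$her2_class == "HLBC-1",
                         "HLBC-1", "HLBC-2"), levels = c("HLBC-2", "HLBC-1"))
    d <- dge(norm, grp,
             covariates = cohort$samples[, c("er_status", "grade")])
    gtab <- gss(d, cohort$gene_sets)
    results$expression <- list(dge = d, gss = gtab)
    write_tsv_exact(as.data.frame(d), file.path(out_dir, "dge.tsv"))
    write_tsv_exact(gtab, file.path(out_dir, "gss.tsv"))
  }

  if ("class_discovery" %in% stages) {
    vg <- select_variable_genes(norm)
    V <- norm$values[vg, , drop = FALSE]
    cons <- consensus_nmf(V, k_range = k_range, n_runs = n_runs,
                          seed = derive_seed(seed, 17))
    sel <- select_rank(cons, cohort$samples$pam50,
                       overlap_threshold = overlap_ari)
    chosen <- cons[[as.character(sel$chosen_k)]]
    reports <- characterize_clusters(
      setNames(sel$labels, cohort$samples$sample_id), cohort$samples,
      cohort$variants,
      compute_tmb(cohort$variants, cohort$panel,
                  sample_ids = cohort$samples$sample_id),
      cn = cohort$cn, expr = norm)
    results$class_discovery <- list(selection = sel, reports = reports)
    write_tsv_exact(data.frame(sample_id = cohort$samples$sample_id,
                               cluster = sel$labels),
                    file.path(out_dir, "cluster_labels.tsv"))
    write_expression(chosen$consensus,
                     file.path(out_dir, "consensus_matrix.csv"))
    jsonlite::write_json(sel$candidates,
                         file.path(out_dir, "rank_selection.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("actionability" %in% stages) {
    rep_act <- annotate_actionability(cohort$variants, cohort$cn)
    tmb <- results$variant_stats$tmb %||%
      compute_tmb(cohort$variants, cohort$panel,
                  sample_ids = cohort$samples$sample_id)
    msi <- results$variant_stats$msi %||% msi_score(cohort$msi,
                                                    threshold = msi_thr)
    summ <- summarize_actionability(rep_act, tmb, msi,
                                    tmb_high_threshold = tmb_high)
    results$actionability <- list(report = rep_act, summary = summ)
    write_tsv_exact(rep_act$alterations,
                    file.path(out_dir, "actionability.tsv"))
    write_tsv_exact(summ, file.path(out_dir, "actionability_summary.tsv"))
  }

  cfg_path <- file.path(out_dir, "config.json")
  # the hashable config excludes the output location and any in-memory cohort
  cfg_serializable <- config[setdiff(names(config), c("cohort", "out_dir"))]
  jsonlite::write_json(cfg_serializable, cfg_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest <- list(
    package = "hlbc",
    version = as.character(utils::packageVersion("hlbc")),
    seed = seed,
    stages = stages,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = sort(setdiff(list.files(out_dir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
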