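#' Load and validate a level-of-evidence rule table
#'
#' The table maps alteration patterns to OncoKB levels and ESCAT tiers.
#' Pattern types, in matching-precedence order: `exact` (exact protein
#' change, e.g. `"p.H1047R"`), `range` (amino-acid position interval,
#' `"542-546"`), `class` (`any_oncogenic_mutation`, `amplification`,
#' `deletion`). Every record must carry at least one non-none level.
#'
#' @param path TSV with columns `gene`, `pattern`, `pattern_type`,
#'   `oncokb_level`, `escat_tier`. Defaults to the illustrative synthetic
#'   table shipped with the package.
#' @return validated data frame of class `loe_table`.
#' @export
read_loe_table <- function(path = system.file("extdata",
                                              "loe_table_synthetic.tsv",
                                              package = "hlbc")) {
  df <- read_tsv_checked(path, c("gene", "pattern", "pattern_type",
                                 "oncokb_level", "escat_tier"))
  ok_levels <- c("1", "2", "3A", "3B", "4", "none")
  ok_tiers <- c("IA", "IB", "IC", "IIA", "IIB", "IIIA", "IV", "none")
  bad <- which(!(df$pattern_type %in% c("exact", "range", "class")) |
                 !(df$oncokb_level %in% ok_levels) |
                 !(df$escat_tier %in% ok_tiers) |
                 (df$oncokb_level == "none" & df$escat_tier == "none"))
  if (length(bad) > 0)
    stop(sprintf("malformed level-of-evidence record(s): %s",
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  rng <- df$pattern_type == "range"
  if (any(rng & !grepl("^[0-9]+-[0-9]+$", df$pattern)))
    stop("malformed range pattern in level-of-evidence table", call. = FALSE)
  cls <- df$pattern_type == "class"
  if (any(cls & !(df$pattern %in% c("any_oncogenic_mutation",
                                    "amplification", "deletion"))))
    stop("malformed class pattern in level-of-evidence table", call. = FALSE)
  class(df) <- c("loe_table", "data.frame")
  df
}

# first integer in a protein-change string, NA when absent
protein_position <- function(protein_change) {
  suppressWarnings(as.integer(sub("^[^0-9]*([0-9]+).*$", "\\1",
                                  protein_change)))
}

match_loe_variant <- function(gene, protein_change, loe) {
  sub <- loe[loe$gene == gene & loe$pattern_type != "class" |
               (loe$gene == gene & loe$pattern == "any_oncogenic_mutation"), ,
             drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  exact <- sub[sub$pattern_type == "exact" & sub$pattern == protein_change, ,
               drop = FALSE]
  if (nrow(exact) > 0) return(exact[1, ])
  pos <- protein_position(protein_change)
  if (!is.na(pos)) {
    rng <- sub[sub$pattern_type == "range", , drop = FALSE]
    if (nrow(rng) > 0) {
      bounds <- do.call(rbind, strsplit(rng$pattern, "-", fixed = TRUE))
      hit <- which(pos >= as.integer(bounds[, 1]) &
                     pos <= as.integer(bounds[, 2]))
      if (length(hit) > 0) return(rng[hit[1], ])
    }
  }
  cls <- sub[sub$pattern_type == "class", , drop = FALSE]
  if (nrow(cls) > 0) return(cls[1, ])
  NULL
}

#' Annotate alterations with levels of evidence
#'
#' Matches somatic variants and copy-number alterations against a
#' level-of-evidence rule table. Matching precedence per variant: exact
#' protein change, then positional range, then alteration class; CN gains
#' match `amplification` records and losses `deletion` records. Unmatched
#' alterations carry level none. A patient is flagged actionable when at
#' least one alteration carries a non-none OncoKB level or ESCAT tier.
#'
#' @param variants variant-call data frame (somatic calls are annotated).
#' @param cn_calls optional copy-number table with `call` column.
#' @param loe_table a [read_loe_table()] result.
#' @return object of class `actionability_report`: `alterations` (one row per
#'   annotated alteration), `patients` (`sample_id`, `any_actionable`),
#'   `n_actionable`.
#' @export
annotate_actionability <- function(variants, cn_calls = NULL,
                                   loe_table = read_loe_table()) {
  som <- variants[variants$origin == "somatic", , drop = FALSE]
  ann <- do.call(rbind, lapply(seq_len(nrow(som)), function(i) {
    hit <- match_loe_variant(som$gene[i], som$protein_change[i], loe_table)
    data.frame(sample_id = som$sample_id[i], gene = som$gene[i],
               alteration = som$protein_change[i], kind = "mutation",
               oncokb_level = if (is.null(hit)) "none" else hit$oncokb_level,
               escat_tier = if (is.null(hit)) "none" else hit$escat_tier,
               matched_pattern = if (is.null(hit)) NA_character_
                                 else hit$pattern,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(cn_calls)) {
    altered <- cn_calls[cn_calls$call %in% c("gain", "loss"), , drop = FALSE]
    cn_ann <- do.call(rbind, lapply(seq_len(nrow(altered)), function(i) {
      want <- if (altered$call[i] == "gain") "amplification" else "deletion"
      hit <- loe_table[loe_table$gene == altered$gene[i] &
                         loe_table$pattern_type == "class" &
                         loe_table$pattern == want, , drop = FALSE]
      data.frame(sample_id = altered$sample_id[i], gene = altered$gene[i],
                 alteration = want, kind = "cna",
                 oncokb_level = if (nrow(hit) == 0) "none"
                                else hit$oncokb_level[1],
                 escat_tier = if (nrow(hit) == 0) "none"
                              else hit$escat_tier[1],
                 matched_pattern = if (nrow(hit) == 0) NA_character_
                                   else hit$pattern[1],
                 stringsAsFactors = FALSE)
    }))
    ann <- rbind(ann, cn_ann)
  }
  if (is.null(ann))
    ann <- data.frame(sample_id = character(0), gene = character(0),
                      alteration = character(0), kind = character(0),
                      oncokb_level = character(0), escat_tier = character(0),
                      matched_pattern = character(0),
                      stringsAsFactors = FALSE)
  ann <- ann[order(ann$sample_id, ann$gene, ann$alteration,
                   method = "radix"), , drop = FALSE]
  rownames(ann) <- NULL
  actionable <- ann$oncokb_level != "none" | ann$escat_tier != "none"
  ids <- sort(unique(ann$sample_id))
  patients <- data.frame(
    sample_id = ids,
    any_actionable = ids %in% ann$sample_id[actionable],
    stringsAsFactors = FALSE)
  structure(list(alterations = ann, patients = patients,
                 n_actionable = sum(patients$any_actionable)),
            class = "actionability_report")
}

#' Cohort-level actionability summary
#'
#' Counts and fractions of patients with at least one actionable alteration,
#' with TMB at or above the TMB-high threshold, and flagged MSI-high.
#'
#' @param report an [annotate_actionability()] result.
#' @param tmb_results [compute_tmb()] output.
#' @param msi_results [msi_score()] output.
#' @param tmb_high_threshold TMB-high cutoff in mut/Mb (default 10,
#'   inclusive).
#' @return one-row data frame with counts and fractions; denominators are the
#'   TMB table's sample set.
#' @export
summarize_actionability <- function(report, tmb_results, msi_results = NULL,
                                    tmb_high_threshold = 10) {
  ids <- tmb_results$sample_id
  extra <- setdiff(report$patients$sample_id, ids)
  if (length(extra) > 0)
    stop(sprintf("report sample(s) missing from TMB table: %s",
                 paste(head(extra, 5), collapse = ", ")), call. = FALSE)
  n <- length(ids)
  n_act <- sum(report$patients$any_actionable)
  n_tmb <- sum(tmb_results$tmb >= tmb_high_threshold)
  n_msi <- if (is.null(msi_results)) NA_integer_
           else sum(msi_results$msi_flag[match(ids, msi_results$sample_id)],
                    na.rm = TRUE)
  data.frame(n_samples = n,
             n_actionable = n_act, frac_actionable = n_act / n,
             n_tmb_high = n_tmb, frac_tmb_high = n_tmb / n,
             n_msi_high = n_msi,
             frac_msi_high = if (is.na(n_msi)) NA_real_ else n_msi / n)
}
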