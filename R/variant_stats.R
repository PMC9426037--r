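#' Tumor mutational burden from a targeted panel
#'
#' TMB per sample is the number of somatic, non-synonymous variants with
#' variant allele frequency strictly above `vaf_min`, divided by the panel's
#' sequenced megabases. The non-synonymous set is {missense, nonsense,
#' frameshift, inframe_indel, splice}, so small indels count; synonymous
#' variants, germline calls and sub-threshold VAF calls do not. Samples with
#' no qualifying variants are reported with TMB 0, not dropped.
#'
#' @param variants variant-call data frame.
#' @param panel a [panel_spec()].
#' @param sample_ids optional character vector fixing the set (and order) of
#'   reported samples; defaults to the samples present in `variants`.
#' @param vaf_min strict VAF threshold (default 0.05).
#' @return data frame with `sample_id`, `n_qualifying_variants`, `tmb`.
#' @export
compute_tmb <- function(variants, panel = panel_spec(), sample_ids = NULL,
                        vaf_min = 0.05) {
  if (panel$panel_mb <= 0) stop("panel_mb must be > 0", call. = FALSE)
  unknown <- which(!(variants$variant_classification %in% .VC_LEVELS))
  if (length(unknown) > 0)
    stop(sprintf("unknown variant_classification in rows: %s",
                 paste(head(unknown, 10), collapse = ", ")), call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- unique(variants$sample_id)
  qual <- variants[variants$origin == "somatic" &
                     variants$variant_classification %in% .NONSYN &
                     variants$vaf > vaf_min, , drop = FALSE]
  counts <- table(factor(qual$sample_id, levels = sample_ids))
  data.frame(sample_id = sample_ids,
             n_qualifying_variants = as.integer(counts),
             tmb = as.numeric(counts) / panel$panel_mb,
             stringsAsFactors = FALSE)
}

#' Microsatellite-instability fraction per sample
#'
#' The MSI score is the fraction of scored microsatellite loci called
#' unstable; a sample is flagged MSI-high when the fraction is greater than
#' or equal to `threshold` (inclusive).
#'
#' @param msi_table data frame with `sample_id`, `locus`, `call` in
#'   {stable, unstable}.
#' @param threshold MSI-high cutoff on the unstable fraction (default 0.20).
#' @return data frame with `sample_id`, `n_loci`, `n_unstable`,
#'   `msi_fraction`, `msi_flag`.
#' @export
msi_score <- function(msi_table, threshold = 0.20) {
  if (nrow(msi_table) == 0) stop("empty microsatellite call set",
                                 call. = FALSE)
  bad <- which(!(msi_table$call %in% c("stable", "unstable")))
  if (length(bad) > 0)
    stop(sprintf("invalid locus call in rows: %s",
                 paste(head(bad, 10), collapse = ", ")), call. = FALSE)
  ids <- unique(msi_table$sample_id)
  n <- as.integer(table(factor(msi_table$sample_id, levels = ids)))
  un <- as.integer(table(factor(
    msi_table$sample_id[msi_table$call == "unstable"], levels = ids)))
  frac <- un / n
  data.frame(sample_id = ids, n_loci = n, n_unstable = un,
             msi_fraction = frac, msi_flag = frac >= threshold,
             stringsAsFactors = FALSE)
}

#' Per-gene mutation frequencies and oncoprint matrix
#'
#' Collapses the variant table to per-sample mutated/not-mutated status per
#' gene (a sample counts once per gene regardless of how many variants it
#' carries there) and tabulates counts and fractions per group. Genes are
#' ranked by overall mutated-sample frequency; ties break lexicographically
#' by symbol.
#'
#' @param variants variant-call data frame.
#' @param samples clinical data frame with `sample_id`.
#' @param group_by name of the grouping column in `samples` (default
#'   `"her2_class"`), or `NULL` for a single overall group.
#' @param genes gene universe for the table; defaults to the genes observed
#'   in `variants`.
#' @return list with `table` (data frame: gene, per-group `n_<group>` counts
#'   and `frac_<group>` fractions, `n_total`, `frac_total`) and `oncoprint`
#'   (gene x sample 0/1 matrix).
#' @export
mutation_frequency_table <- function(variants, samples,
                                     group_by = "her2_class", genes = NULL) {
  orphan <- setdiff(unique(variants$sample_id), samples$sample_id)
  if (length(orphan) > 0)
    stop(sprintf("variant sample_id absent from clinical table: %s",
                 paste(head(orphan, 5), collapse = ", ")), call. = FALSE)
  if (is.null(genes)) genes <- sort(unique(variants$gene))
  ids <- samples$sample_id
  mat <- matrix(0L, length(genes), length(ids),
                dimnames = list(genes, ids))
  keep <- variants$gene %in% genes
  if (any(keep))
    mat[cbind(match(variants$gene[keep], genes),
              match(variants$sample_id[keep], ids))] <- 1L
  group <- if (is.null(group_by)) rep("all", length(ids))
           else samples[[group_by]]
  levs <- unique(group)
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (lv in levs) {
    cols <- group == lv
    tab[[paste0("n_", lv)]] <- as.integer(rowSums(mat[, cols, drop = FALSE]))
    tab[[paste0("frac_", lv)]] <- tab[[paste0("n_", lv)]] / sum(cols)
  }
  tab$n_total <- as.integer(rowSums(mat))
  tab$frac_total <- tab$n_total / length(ids)
  ord <- order(-tab$frac_total, tab$gene, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, oncoprint = mat[tab$gene, , drop = FALSE])
}

# Welch two-sample t in closed form; returns t, df, p (two-sided).
# Degenerate zero-variance pairs: equal means -> t = 0, p = 1; unequal
# means with zero pooled SE -> p = 0.
welch_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  d <- mean(x) - mean(y)
  if (se2 == 0)
    return(list(t = if (d == 0) 0 else sign(d) * Inf, df = n1 + n2 - 2,
                p = if (d == 0) 1 else 0))
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t <- d / sqrt(se2)
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Pairwise group-mean comparison by Welch's unpaired t-test
#'
#' For every pair of groups, reports group means with 95 percent confidence
#' intervals (mean +/- t(0.975, n-1) * SE) and the two-sided Welch
#' (unequal-variance) t-test p-value, Benjamini-Hochberg adjusted across the
#' pairs.
#'
#' @param values numeric vector of per-sample values.
#' @param groups grouping vector, same length.
#' @return list with `groups` (per-group mean, CI, n) and `pairs` (per-pair
#'   t, df, p, p_adj).
#' @export
group_mean_test <- function(values, groups) {
  groups <- as.character(groups)
  levs <- unique(groups)
  sizes <- table(factor(groups, levels = levs))
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0)
    stop(sprintf("group(s) with fewer than 2 values: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  gstats <- do.call(rbind, lapply(levs, function(lv) {
    x <- values[groups == lv]
    se <- sd(x) / sqrt(length(x))
    hw <- qt(0.975, length(x) - 1) * se
    data.frame(group = lv, n = length(x), mean = mean(x),
               ci_lo = mean(x) - hw, ci_hi = mean(x) + hw,
               stringsAsFactors = FALSE)
  }))
  cmb <- utils::combn(levs, 2)
  pairs <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    a <- cmb[1, j]; b <- cmb[2, j]
    w <- welch_t(values[groups == a], values[groups == b])
    data.frame(group_a = a, group_b = b, mean_diff = gstats$mean[
                 gstats$group == a] - gstats$mean[gstats$group == b],
               t = w$t, df = w$df, p = w$p, stringsAsFactors = FALSE)
  }))
  pairs$p_adj <- p.adjust(pairs$p, method = "BH")
  list(groups = gstats, pairs = pairs)
}
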