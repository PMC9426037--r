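#' Matching specification for control-cohort assembly
#'
#' Defaults reproduce the stated matching strata: the matched control cohort
#' is 90 percent ER-positive, its ER-positive stratum contains 55 percent
#' high-grade (G3) tumors and its ER-negative stratum 80 percent G3 tumors.
#'
#' @param er_pos_fraction ER-positive fraction of the matched cohort.
#' @param g3_fraction_in_er_pos G3 fraction within the ER-positive stratum.
#' @param g3_fraction_in_er_neg G3 fraction within the ER-negative stratum.
#' @param target_size matched-cohort size.
#' @param seed integer RNG seed for the stratified draw.
#' @return object of class `match_spec`.
#' @export
match_spec <- function(er_pos_fraction = 0.90,
                       g3_fraction_in_er_pos = 0.55,
                       g3_fraction_in_er_neg = 0.80,
                       target_size = 545L, seed = 1L) {
  check_prob(c(er_pos_fraction, g3_fraction_in_er_pos,
               g3_fraction_in_er_neg), "match fractions")
  if (target_size <= 0) stop_config("target_size", "must be > 0")
  structure(list(er_pos_fraction = er_pos_fraction,
                 g3_fraction_in_er_pos = g3_fraction_in_er_pos,
                 g3_fraction_in_er_neg = g3_fraction_in_er_neg,
                 target_size = as.integer(target_size),
                 seed = as.integer(seed)),
            class = "match_spec")
}

#' Build a matched control cohort by stratified sampling
#'
#' Draws, without replacement and deterministically given the seed, a cohort
#' of `spec$target_size` rows from `pool` whose ER x grade strata follow the
#' matching fractions. Stratum counts are the largest-remainder rounding of
#' `target_size` times the stratum fractions, so the total is exact and each
#' realized stratum deviates from its quota by at most one sample.
#'
#' @param pool data frame with `er_status` ("pos"/"neg") and `grade`
#'   ("G1"/"G2"/"G3") columns, e.g. from [generate_control_pool()].
#' @param spec a [match_spec()].
#' @return the matched subset of `pool`, with a `stratum` column appended.
#' @export
build_matched_cohort <- function(pool, spec = match_spec()) {
  if (!all(c("er_status", "grade") %in% names(pool)))
    stop("pool must have er_status and grade columns", call. = FALSE)
  fr <- c(er_pos_g3   = spec$er_pos_fraction * spec$g3_fraction_in_er_pos,
          er_pos_nong3 = spec$er_pos_fraction *
            (1 - spec$g3_fraction_in_er_pos),
          er_neg_g3   = (1 - spec$er_pos_fraction) *
            spec$g3_fraction_in_er_neg,
          er_neg_nong3 = (1 - spec$er_pos_fraction) *
            (1 - spec$g3_fraction_in_er_neg))
  counts <- setNames(largest_remainder(spec$target_size, fr), names(fr))
  stratum <- paste0("er_", ifelse(pool$er_status == "pos", "pos", "neg"),
                    ifelse(pool$grade == "G3", "_g3", "_nong3"))
  set.seed(spec$seed)
  picked <- integer(0)
  for (st in names(counts)) {
    idx <- which(stratum == st)
    if (length(idx) < counts[[st]])
      stop(sprintf(
        "insufficient pool in stratum '%s': need %d, have %d (deficit %d)",
        st, counts[[st]], length(idx), counts[[st]] - length(idx)),
        call. = FALSE)
    picked <- c(picked, if (counts[[st]] > 0) idx[sample.int(length(idx),
                                                             counts[[st]])])
  }
  out <- pool[sort(picked), , drop = FALSE]
  out$stratum <- stratum[sort(picked)]
  rownames(out) <- NULL
  out
}

#' Per-gene differential-mutation test between two cohorts
#'
#' Two-sided Fisher's exact test on the mutated/wild-type 2x2 table per gene
#' (R's point-probability method), Benjamini-Hochberg adjusted across the
#' tested genes. Genes with zero mutations in both cohorts have a degenerate
#' table and are excluded from the test family. The "spider" counts report
#' how many genes fall below `alpha` on the raw and on the adjusted scale.
#'
#' @param cohort_a,cohort_b data frames carrying 0/1 mutation-flag columns
#'   named by gene (pool layout).
#' @param genes genes to test; defaults to the flag columns shared by both
#'   cohorts.
#' @param alpha significance threshold for the spider counts (default 0.05).
#' @return list of class `comparison_result`: `table` (gene, a_mut, a_wt,
#'   b_mut, b_wt, p, p_adj), `spider` (n_raw, n_adj), `n_a`, `n_b`.
#' @export
differential_mutation_test <- function(cohort_a, cohort_b, genes = NULL,
                                       alpha = 0.05) {
  if (nrow(cohort_a) == 0 || nrow(cohort_b) == 0)
    stop("both cohorts must be nonempty", call. = FALSE)
  flag_cols <- function(df) names(df)[vapply(df, function(x)
    is.numeric(x) && all(x %in% c(0, 1)), logical(1))]
  if (is.null(genes)) genes <- intersect(flag_cols(cohort_a),
                                         flag_cols(cohort_b))
  absent <- c(setdiff(genes, names(cohort_a)), setdiff(genes, names(cohort_b)))
  if (length(absent) > 0)
    stop(sprintf("gene(s) absent from a cohort: %s",
                 paste(unique(absent), collapse = ", ")), call. = FALSE)
  n_a <- nrow(cohort_a); n_b <- nrow(cohort_b)
  tab <- data.frame(gene = genes,
                    a_mut = vapply(genes, function(g) sum(cohort_a[[g]]),
                                   numeric(1)),
                    b_mut = vapply(genes, function(g) sum(cohort_b[[g]]),
                                   numeric(1)),
                    stringsAsFactors = FALSE)
  tab$a_wt <- n_a - tab$a_mut
  tab$b_wt <- n_b - tab$b_mut
  tab <- tab[tab$a_mut + tab$b_mut > 0, , drop = FALSE]
  tab$p <- vapply(seq_len(nrow(tab)), function(i)
    fisher.test(matrix(c(tab$a_mut[i], tab$a_wt[i],
                         tab$b_mut[i], tab$b_wt[i]), 2))$p.value,
    numeric(1))
  tab$p_adj <- p.adjust(tab$p, method = "BH")
  tab <- tab[, c("gene", "a_mut", "a_wt", "b_mut", "b_wt", "p", "p_adj")]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 spider = c(n_raw = sum(tab$p < alpha),
                            n_adj = sum(tab$p_adj < alpha)),
                 n_a = n_a, n_b = n_b),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Differential-mutation comparison (%d vs %d samples, %d genes)\n",
              x$n_a, x$n_b, nrow(x$table)))
  cat(sprintf("  genes with raw p < 0.05: %d; BH-adjusted p < 0.05: %d\n",
              x$spider[["n_raw"]], x$spider[["n_adj"]]))
  invisible(x)
}

#' Compare variant spectra between two cohorts
#'
#' Pearson chi-square test (no continuity correction) on the category-by-
#' cohort contingency table for a chosen dimension of the variant calls, with
#' Bonferroni correction for the number of cohort-pair comparisons in the
#' family.
#'
#' @param variants_a,variants_b variant-call data frames.
#' @param dimension `"VT"` (variant type), `"VC"` (variant classification) or
#'   `"pathogenicity"`.
#' @param n_comparisons Bonferroni family size (default 1).
#' @return list with `statistic`, `df`, `p`, `p_bonferroni` (capped at 1) and
#'   the contingency `table`.
#' @export
compare_variant_spectra <- function(variants_a, variants_b,
                                    dimension = c("VC", "VT",
                                                  "pathogenicity"),
                                    n_comparisons = 1) {
  dimension <- match.arg(dimension)
  col <- switch(dimension, VT = "variant_type",
                VC = "variant_classification",
                pathogenicity = "pathogenicity")
  if (nrow(variants_a) == 0 || nrow(variants_b) == 0)
    stop("degenerate comparison: a cohort has zero variants", call. = FALSE)
  levs <- switch(dimension, VT = .VT_LEVELS, VC = .VC_LEVELS,
                 pathogenicity = .PATHOGENICITY)
  tab <- cbind(a = table(factor(variants_a[[col]], levels = levs)),
               b = table(factor(variants_b[[col]], levels = levs)))
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2)
    stop("need at least two categories with nonzero totals", call. = FALSE)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value,
       p_bonferroni = min(1, ct$p.value * n_comparisons), table = tab)
}

#' Compare copy-number alteration prevalence for one gene
#'
#' Two-sided Fisher's exact test on the 2x2 table of samples with a gain (or
#' loss) call for `gene` versus the rest, between two cohorts.
#'
#' @param cn_a,cn_b copy-number call data frames (`sample_id`, `gene`,
#'   `call` in {gain, loss, neutral}).
#' @param gene gene symbol.
#' @param event `"gain"` or `"loss"`.
#' @return list with the 2x2 `counts` and the Fisher `p`.
#' @export
compare_cn_rates <- function(cn_a, cn_b, gene, event = c("gain", "loss")) {
  event <- match.arg(event)
  for (nm in list(a = cn_a, b = cn_b))
    if (!(gene %in% nm$gene))
      stop(sprintf("gene '%s' not in the CN panel of a cohort", gene),
           call. = FALSE)
  count <- function(cn) {
    sub <- cn[cn$gene == gene, , drop = FALSE]
    c(evt = sum(sub$call == event), other = sum(sub$call != event))
  }
  ca <- count(cn_a); cb <- count(cn_b)
  m <- matrix(c(ca, cb), 2, byrow = FALSE,
              dimnames = list(c(event, "other"), c("a", "b")))
  list(counts = m, p = fisher.test(m)$p.value)
}
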