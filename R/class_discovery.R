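#' Select the most variable genes
#'
#' Keeps the top `floor(fraction * n_genes)` genes by variance across
#' samples; ties break lexicographically by gene symbol.
#'
#' @param expr normalized expression (see [dge()]).
#' @param fraction fraction of genes to keep, in (0, 1] (default 0.33).
#' @return character vector of selected gene names.
#' @export
select_variable_genes <- function(expr, fraction = 0.33) {
  values <- as_expr_matrix(expr)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  if (nrow(values) < 3) stop("need at least 3 genes", call. = FALSE)
  n_keep <- floor(fraction * nrow(values))
  if (n_keep < 1) stop("fraction selects no genes", call. = FALSE)
  v <- apply(values, 1, var)
  ord <- order(-v, rownames(values), method = "radix")
  rownames(values)[ord][seq_len(n_keep)]
}

#' Single NMF factorization under the KL divergence
#'
#' Factorizes a nonnegative matrix `V ~ W %*% H` (W: genes x K, H: K x
#' samples) by multiplicative updates for the generalized Kullback-Leibler
#' divergence with seeded random-uniform initialization. The objective is
#' nonincreasing across iterations; the run stops when the relative KL change
#' between checks falls below `tol` or at `max_iter`.
#'
#' @param V nonnegative matrix with no all-zero rows or columns.
#' @param k factorization rank, `2 <= k < min(dim(V))`.
#' @param seed integer RNG seed for the initialization.
#' @param max_iter maximum number of update sweeps (default 2000).
#' @param tol relative KL-change convergence tolerance (default 1e-6).
#' @param check_every sweep interval between convergence checks.
#' @return object of class `nmf_fit`: `W`, `H`, `kl` (final divergence),
#'   `trace` (KL at each check), `iterations`, `k`, `seed`.
#' @export
nmf_factorize <- function(V, k, seed = 1L, max_iter = 2000, tol = 1e-6,
                          check_every = 10L) {
  if (any(V < 0)) stop("V must be nonnegative", call. = FALSE)
  if (any(rowSums(V) == 0) || any(colSums(V) == 0))
    stop("V has all-zero rows or columns; filter them before factorizing",
         call. = FALSE)
  if (k < 2 || k >= min(dim(V)))
    stop("k must satisfy 2 <= k < min(dim(V))", call. = FALSE)
  set.seed(seed)
  scale0 <- sqrt(mean(V) / k)
  W0 <- matrix(runif(nrow(V) * k, 1e-4, 1), nrow(V), k) * scale0
  H0 <- matrix(runif(k * ncol(V), 1e-4, 1), k, ncol(V)) * scale0
  fit <- nmf_kl_cpp(V, W0, H0, as.integer(max_iter), tol,
                    as.integer(check_every))
  dimnames(fit$W) <- list(rownames(V), NULL)
  dimnames(fit$H) <- list(NULL, colnames(V))
  fit$k <- k
  fit$seed <- seed
  class(fit) <- "nmf_fit"
  fit
}

#' Consensus NMF over random restarts
#'
#' Runs `n_runs` seeded NMF factorizations per rank. Each run assigns every
#' sample to its argmax metagene; the consensus matrix entry (i, j) is the
#' fraction of runs co-clustering samples i and j. Final labels come from
#' average-linkage hierarchical clustering of `1 - consensus` cut at K; the
#' cophenetic coefficient is the Pearson correlation between the
#' `1 - consensus` distances and the dendrogram's cophenetic distances, and
#' the mean silhouette width is computed on the same distances.
#'
#' @param V nonnegative matrix (genes x samples).
#' @param k_range ranks to evaluate (default 2:6).
#' @param n_runs random restarts per rank (default 30).
#' @param seed base seed; per-run seeds are derived deterministically.
#' @param ... passed to [nmf_factorize()].
#' @return named list (one element per K) of `consensus_nmf_result` objects:
#'   `k`, `consensus`, `labels`, `cophenetic`, `silhouette`, `best_fit` (the
#'   restart with lowest KL), `n_runs`.
#' @export
consensus_nmf <- function(V, k_range = 2:6, n_runs = 30, seed = 1L, ...) {
  if (n_runs < 2) stop("n_runs must be >= 2", call. = FALSE)
  n <- ncol(V)
  if (max(k_range) >= n)
    stop("k_range exceeds the number of samples", call. = FALSE)
  results <- list()
  for (k in k_range) {
    co <- matrix(0, n, n)
    best <- NULL
    for (r in seq_len(n_runs)) {
      fit <- nmf_factorize(V, k, seed = derive_seed(seed, 7919 * k + r), ...)
      lab <- max.col(t(fit$H), ties.method = "first")
      co <- co + outer(lab, lab, "==")
      if (is.null(best) || fit$kl < best$kl) best <- fit
    }
    consensus <- co / n_runs
    dimnames(consensus) <- list(colnames(V), colnames(V))
    d <- as.dist(1 - consensus)
    hc <- hclust(d, method = "average")
    labels <- cutree(hc, k)
    coph <- suppressWarnings(cor(d, cophenetic(hc)))
    if (!is.finite(coph)) coph <- 1  # zero-spread distances: perfectly stable
    sil <- if (length(unique(labels)) > 1)
      mean(cluster::silhouette(labels, d)[, "sil_width"]) else NA_real_
    results[[as.character(k)]] <- structure(
      list(k = k, consensus = consensus, labels = labels,
           cophenetic = coph, silhouette = sil, best_fit = best,
           n_runs = n_runs),
      class = "consensus_nmf_result")
  }
  results
}

#' Rank selection: cophenetic ranking with external-label exclusion
#'
#' Implements the two-step selection rule for the number of expression
#' classes: (i) rank candidate K by consensus cophenetic coefficient and
#' (ii) discard candidates whose clustering overlaps the external (PAM50)
#' labels, so that the retained clustering describes structure not already
#' captured by intrinsic subtype. Overlap is quantified by the adjusted Rand
#' index; candidates with ARI above `overlap_threshold` are discarded. The
#' chosen K maximizes the cophenetic coefficient among survivors.
#'
#' @param results list of `consensus_nmf_result` from [consensus_nmf()].
#' @param external_labels per-sample external labels (e.g. PAM50), covering
#'   all samples.
#' @param overlap_threshold ARI above which a clustering is considered to
#'   recapitulate the external labels (default 0.6).
#' @param min_k optional minimum number of groups a candidate must reach.
#' @return object of class `rank_selection`: `candidates` (data frame with
#'   k, cophenetic, silhouette, ari, discarded), `chosen_k`, the chosen
#'   result's `labels`.
#' @export
select_rank <- function(results, external_labels, overlap_threshold = 0.6,
                        min_k = NULL) {
  n <- length(results[[1]]$labels)
  if (length(external_labels) != n)
    stop("external labels must cover all samples", call. = FALSE)
  cand <- do.call(rbind, lapply(results, function(r) {
    data.frame(k = r$k, cophenetic = r$cophenetic,
               silhouette = r$silhouette,
               ari = mclust::adjustedRandIndex(r$labels, external_labels),
               stringsAsFactors = FALSE)
  }))
  cand$discarded <- cand$ari > overlap_threshold
  if (!is.null(min_k)) cand$discarded <- cand$discarded | cand$k < min_k
  rownames(cand) <- NULL
  surv <- cand[!cand$discarded, , drop = FALSE]
  if (nrow(surv) == 0)
    stop(paste("no novel clustering: every candidate K overlaps the",
               "external labels (or violates min_k)"), call. = FALSE)
  chosen <- surv$k[which.max(surv$cophenetic)]
  structure(list(candidates = cand, chosen_k = chosen,
                 labels = results[[as.character(chosen)]]$labels),
            class = "rank_selection")
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("Consensus-NMF rank selection\n")
  print(x$candidates, row.names = FALSE)
  cat("chosen K:", x$chosen_k, "\n")
  invisible(x)
}

#' Characterize discovered expression clusters
#'
#' For every cluster, reports: per-gene mutation prevalence versus the rest
#' (two-sided Fisher, BH-adjusted across genes), TMB and Ki67 mean contrasts
#' versus the rest (Welch t), PAM50 and grade composition, mean ERBB2
#' copy-number fold change, and differential expression versus the rest.
#' Singleton clusters trigger a warning and are reported with tests skipped.
#'
#' @param labels named (by sample id) or ordered per-sample cluster labels.
#' @param clinical clinical data frame (must cover the labelled samples).
#' @param variants variant-call data frame.
#' @param tmb [compute_tmb()] result.
#' @param cn copy-number table (with `log10_fc`).
#' @param expr optional normalized expression for cluster-vs-rest DGE.
#' @param genes genes to test for mutation enrichment; defaults to genes with
#'   at least 3 mutated samples.
#' @return list of per-cluster reports (class `cluster_report`): each has
#'   `n`, `mutation_tests`, `tmb_test`, `ki67_test`, `pam50_composition`,
#'   `grade_composition`, `mean_erbb2_fc`, `dge_vs_rest`.
#' @export
characterize_clusters <- function(labels, clinical, variants, tmb, cn = NULL,
                                  expr = NULL, genes = NULL) {
  ids <- names(labels) %||% clinical$sample_id[seq_along(labels)]
  if (is.null(names(labels))) names(labels) <- ids
  missing_cl <- setdiff(ids, clinical$sample_id)
  if (length(missing_cl) > 0)
    stop(sprintf("labelled sample(s) missing from clinical table: %s",
                 paste(head(missing_cl, 5), collapse = ", ")), call. = FALSE)
  clin <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  mut <- mutation_frequency_table(
    variants[variants$sample_id %in% ids, , drop = FALSE],
    clin, group_by = NULL)$oncoprint
  if (is.null(genes)) genes <- rownames(mut)[rowSums(mut) >= 3]
  tmb_v <- tmb$tmb[match(ids, tmb$sample_id)]
  out <- list()
  for (cl in sort(unique(labels))) {
    inside <- labels == cl
    rep_cl <- list(cluster = cl, n = sum(inside))
    if (sum(inside) < 2) {
      warning(sprintf("cluster %s is a singleton; tests skipped", cl),
              call. = FALSE)
      out[[as.character(cl)]] <- structure(rep_cl, class = "cluster_report")
      next
    }
    mt <- do.call(rbind, lapply(genes, function(g) {
      a <- sum(mut[g, inside]); b <- sum(mut[g, !inside])
      p <- fisher.test(matrix(c(a, sum(inside) - a,
                                b, sum(!inside) - b), 2))$p.value
      data.frame(gene = g, n_in = a, n_out = b,
                 frac_in = a / sum(inside), frac_out = b / sum(!inside),
                 p = p, stringsAsFactors = FALSE)
    }))
    if (!is.null(mt)) {
      mt$p_adj <- p.adjust(mt$p, method = "BH")
      rownames(mt) <- NULL
    }
    side <- ifelse(inside, "cluster", "rest")
    rep_cl$mutation_tests <- mt
    if (sum(!inside) >= 2) {
      rep_cl$tmb_test <- group_mean_test(tmb_v, side)
      rep_cl$ki67_test <- if ("ki67_pct" %in% names(clin))
        group_mean_test(clin$ki67_pct, side) else NULL
    }
    rep_cl$pam50_composition <- table(clin$pam50[inside])
    rep_cl$grade_composition <- table(clin$grade[inside])
    if (!is.null(cn)) {
      erbb2 <- cn[cn$gene == "ERBB2" & cn$sample_id %in% ids[inside], ,
                  drop = FALSE]
      rep_cl$mean_erbb2_fc <- if (nrow(erbb2) > 0)
        mean(10^erbb2$log10_fc) else NA_real_
    }
    if (!is.null(expr)) {
      values <- as_expr_matrix(expr)
      common <- intersect(colnames(values), ids)
      side_e <- factor(ifelse(labels[common] == cl, "cluster", "rest"),
                       levels = c("rest", "cluster"))
      if (nlevels(droplevels(side_e)) == 2)
        rep_cl$dge_vs_rest <- dge(values[, common, drop = FALSE], side_e)
    }
    out[[as.character(cl)]] <- structure(rep_cl, class = "cluster_report")
  }
  out
}
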