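#' Housekeeping normalization of a raw expression matrix
#'
#' Each sample's scale factor is the geometric mean of its housekeeping-gene
#' counts divided by a cohort-wide reference (the arithmetic mean of those
#' per-sample geometric means); counts are divided by the factor and
#' log2(x + 1)-transformed. Passing a fixed `ref_mean` makes normalization of
#' a sample independent of which other samples are present.
#'
#' @param raw nonnegative genes x samples matrix.
#' @param housekeeping character vector of housekeeping gene names, all
#'   present in `raw`.
#' @param ref_mean optional fixed reference (cohort-wide mean of housekeeping
#'   geometric means); computed from `raw` when `NULL`.
#' @return list of class `normalized_expression`: `values` (log2 matrix),
#'   `scale_factors`, `ref_mean`, `housekeeping`.
#' @export
normalize_expression <- function(raw, housekeeping, ref_mean = NULL) {
  missing_hk <- setdiff(housekeeping, rownames(raw))
  if (length(missing_hk) > 0)
    stop(sprintf("housekeeping gene(s) missing from matrix: %s",
                 paste(missing_hk, collapse = ", ")), call. = FALSE)
  if (any(raw < 0)) stop("raw expression must be nonnegative", call. = FALSE)
  hk <- raw[housekeeping, , drop = FALSE]
  zero <- colnames(raw)[apply(hk <= 0, 2, any)]
  if (length(zero) > 0)
    stop(sprintf("housekeeping count of zero in sample(s): %s",
                 paste(head(zero, 5), collapse = ", ")), call. = FALSE)
  gm <- exp(colMeans(log(hk)))
  if (is.null(ref_mean)) ref_mean <- mean(gm)
  sf <- gm / ref_mean
  values <- log2(sweep(raw, 2, sf, "/") + 1)
  structure(list(values = values, scale_factors = sf, ref_mean = ref_mean,
                 housekeeping = housekeeping),
            class = "normalized_expression")
}

as_expr_matrix <- function(expr) {
  if (inherits(expr, "normalized_expression")) expr$values
  else if (is.matrix(expr)) expr
  else stop("expected a matrix or normalized_expression", call. = FALSE)
}

#' Covariate-adjusted differential gene expression
#'
#' Fits, per gene, an ordinary least-squares linear model of log2 expression
#' on a two-level group indicator plus covariates, and reports the group
#' coefficient (log2 fold change target vs reference), its plain
#' (unmoderated) t-statistic, two-sided p-value and Benjamini-Hochberg
#' adjusted p-value.
#'
#' @param expr normalized expression ([normalize_expression()] result or a
#'   log2 genes x samples matrix).
#' @param group two-level factor or character vector over samples; the first
#'   level is the reference.
#' @param covariates optional data frame of per-sample covariates (e.g. ER
#'   status, grade) entering the design additively.
#' @return data frame of class `dge_result` with `gene`, `log2fc`, `t`, `p`,
#'   `p_adj`; attributes record the group levels and covariate names.
#' @export
dge <- function(expr, group, covariates = NULL) {
  values <- as_expr_matrix(expr)
  group <- as.factor(group)
  if (nlevels(group) != 2)
    stop("group must have exactly two levels", call. = FALSE)
  if (length(group) != ncol(values))
    stop("group length must equal the number of samples", call. = FALSE)
  dat <- data.frame(.group = group)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  X <- model.matrix(~ ., data = dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design; aliased term(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  fit <- lm.fit(X, t(values))
  coefs <- fit$coefficients
  res <- as.matrix(fit$residuals)
  df_res <- nrow(X) - ncol(X)
  if (df_res <= 0) stop("no residual degrees of freedom", call. = FALSE)
  sigma2 <- colSums(res^2) / df_res
  xtx_inv <- solve(crossprod(X))
  j <- match(paste0(".group", levels(group)[2]), colnames(X))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  log2fc <- coefs[j, ]
  t_stat <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pt(-abs(t_stat), df_res)
  out <- data.frame(gene = rownames(values), log2fc = log2fc, t = t_stat,
                    p = p, p_adj = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reference") <- levels(group)[1]
  attr(out, "target") <- levels(group)[2]
  attr(out, "covariates") <- if (is.null(covariates)) character(0)
                             else names(covariates)
  class(out) <- c("dge_result", "data.frame")
  out
}

#' Pathway score: first principal component of a gene set
#'
#' The per-sample score is the first principal component of the gene-centered
#' expression submatrix of the set. The eigenvector sign ambiguity is
#' resolved deterministically: the score is flipped so it correlates
#' nonnegatively with the set's per-sample mean expression (falling back to a
#' nonnegative loading sum when that correlation is zero).
#'
#' @param expr normalized expression (see [dge()]).
#' @param gene_set character vector of gene symbols.
#' @return named numeric vector of per-sample scores; attributes carry the
#'   `loadings` and the `var_explained` fraction of PC1.
#' @export
pathway_score <- function(expr, gene_set) {
  values <- as_expr_matrix(expr)
  present <- intersect(gene_set, rownames(values))
  if (length(present) == 0)
    stop("gene set has empty intersection with the expression matrix",
         call. = FALSE)
  sub <- values[present, , drop = FALSE]
  centered <- sub - rowMeans(sub)
  pc <- prcomp(t(centered), center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  loadings <- pc$rotation[, 1]
  means <- colMeans(sub)
  eps <- 1e-9
  orient <- suppressWarnings(cor(score, means))
  if (!is.finite(orient) || abs(orient) < eps) orient <- sum(loadings)
  if (abs(orient) < eps) {
    # e.g. a perfectly anti-correlated pair: orient on the first sample
    # with a non-negligible score, which is robust to rounding in the
    # eigenvector itself
    idx <- which(abs(score) > eps)[1]
    orient <- if (is.na(idx)) 1 else score[idx]
  }
  if (orient < 0) {
    score <- -score
    loadings <- -loadings
  }
  names(score) <- colnames(values)
  attr(score, "loadings") <- loadings
  attr(score, "var_explained") <-
    pc$sdev[1]^2 / sum(pc$sdev^2)
  score
}

#' Cell-type score: mean marker expression per sample
#'
#' @param expr normalized expression (see [dge()]).
#' @param marker_sets named list of marker gene vectors.
#' @return samples x cell-types matrix of mean log2 marker expression.
#' @export
cell_type_score <- function(expr, marker_sets) {
  values <- as_expr_matrix(expr)
  if (length(marker_sets) == 0) stop("empty marker set list", call. = FALSE)
  out <- vapply(names(marker_sets), function(nm) {
    markers <- intersect(marker_sets[[nm]], rownames(values))
    if (length(markers) == 0)
      stop(sprintf("empty marker set after intersection: %s", nm),
           call. = FALSE)
    colMeans(values[markers, , drop = FALSE])
  }, numeric(ncol(values)))
  rownames(out) <- colnames(values)
  out
}

#' Gene-set global significance scores (GSS and directed GSS)
#'
#' For a gene set S with member t-statistics t_g from a differential
#' expression comparison, the global significance score is the
#' root-mean-square `GSS = sqrt(mean(t^2))`; the directed variant keeps the
#' dominant direction of regulation:
#' `dGSS = sign(sum(sign(t) * t^2)) * sqrt(abs(mean(sign(t) * t^2)))`.
#' Always `|dGSS| <= GSS`, with equality exactly when all member t share one
#' sign.
#'
#' @param dge_result a [dge()] result (or any data frame with `gene` and `t`).
#' @param gene_sets named list of gene vectors; each must intersect the gene
#'   universe.
#' @return data frame with `set`, `n_genes`, `gss`, `dgss`.
#' @export
gss <- function(dge_result, gene_sets) {
  t_by_gene <- setNames(dge_result$t, dge_result$gene)
  out <- do.call(rbind, lapply(names(gene_sets), function(nm) {
    members <- intersect(gene_sets[[nm]], names(t_by_gene))
    if (length(members) == 0)
      stop(sprintf("gene set '%s' has empty intersection with the DGE genes",
                   nm), call. = FALSE)
    t <- t_by_gene[members]
    signed <- sign(t) * t^2
    data.frame(set = nm, n_genes = length(members),
               gss = sqrt(mean(t^2)),
               dgss = sign(sum(signed)) * sqrt(abs(mean(signed))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
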