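#' Canonical 96 trinucleotide substitution contexts
#'
#' Returns the standard ordering of the 96 single-base-substitution contexts:
#' the six pyrimidine substitutions (C>A, C>G, C>T, T>A, T>C, T>G), each in
#' the 16 possible 5'/3' flanking-base combinations, written as e.g.
#' `"A[C>T]G"`.
#'
#' @return character vector of length 96.
#' @export
contexts_96 <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs)
    for (five in bases)
      for (three in bases)
        out <- c(out, paste0(five, "[", s, "]", three))
  out
}

#' Synthetic reference mutational signatures
#'
#' Builds a deterministic, synthetic basis of single-base-substitution
#' signatures over the 96 trinucleotide contexts. Each signature is a smooth
#' peaked profile centered on a different region of the context axis with a
#' small uniform floor, column-normalized to sum to one. These are synthetic
#' stand-ins with the same shape contract as curated catalogs (96 rows,
#' nonnegative, unit column sums); they carry no biological identity.
#'
#' @param n number of signatures (1..12).
#' @return 96 x `n` numeric matrix; rownames are [contexts_96()], colnames
#'   `"S1"..`.
#' @export
synthetic_signatures <- function(n = 8) {
  if (n < 1 || n > 12) stop("n must be in 1..12", call. = FALSE)
  ctx <- contexts_96()
  idx <- seq_len(96)
  centers <- seq(4, 92, length.out = 12)[seq_len(n)]
  widths <- rep(c(5, 9, 14), length.out = n)
  S <- vapply(seq_len(n), function(k) {
    prof <- exp(-(idx - centers[k])^2 / (2 * widths[k]^2)) + 0.002
    # a small secondary peak gives each profile minor support elsewhere,
    # as real substitution signatures have, without making columns collinear
    prof <- prof + 0.1 * exp(-(idx - ((centers[k] + 41) %% 96 + 1))^2 / 20)
    prof / sum(prof)
  }, numeric(96))
  dimnames(S) <- list(ctx, paste0("S", seq_len(n)))
  S
}

#' Bin qualifying SNVs into the 96-context catalog
#'
#' Counts single-nucleotide variants with VAF strictly above `vaf_min` into
#' the 96 trinucleotide substitution classes. Non-SNV variants are ignored.
#'
#' @param variants variant-call data frame (see [generate_cohort()]).
#' @param vaf_min strict lower VAF bound for inclusion (default 0.1).
#' @return named integer vector of length 96 (names = [contexts_96()]); sums
#'   to the number of qualifying SNVs.
#' @export
build_96_catalog <- function(variants, vaf_min = 0.1) {
  ctx <- contexts_96()
  counts <- setNames(integer(96), ctx)
  if (nrow(variants) == 0) return(counts)
  snv <- variants[variants$variant_type == "SNV" & variants$vaf > vaf_min, ,
                  drop = FALSE]
  if (nrow(snv) == 0) return(counts)
  bad <- which(!(snv$context96 %in% ctx))
  if (length(bad) > 0)
    stop(sprintf("malformed context96 in SNV rows: %s (e.g. '%s')",
                 paste(head(bad, 5), collapse = ", "), snv$context96[bad[1]]),
         call. = FALSE)
  tab <- table(factor(snv$context96, levels = ctx))
  counts[] <- as.integer(tab)
  counts
}

#' Refit a mutation catalog against reference signatures
#'
#' Expresses a 96-context substitution catalog as a nonnegative mixture of
#' reference signatures by non-negative least squares on the frequency-scaled
#' catalog, then renormalizes the mixture weights to sum to one.
#'
#' @param catalog numeric 96-vector of context counts (or frequencies).
#' @param reference 96 x S nonnegative matrix with unit column sums.
#' @return object of class `signature_fit`: list with `weights` (named, sums
#'   to 1), `residual` (Euclidean norm of the NNLS residual on the frequency
#'   scale) and `catalog_n` (total count supplied).
#' @export
fit_signatures <- function(catalog, reference = synthetic_signatures()) {
  if (length(catalog) != nrow(reference))
    stop("catalog length must match reference rows", call. = FALSE)
  if (any(catalog < 0) || any(reference < 0))
    stop("catalog and reference must be nonnegative", call. = FALSE)
  n <- sum(catalog)
  if (n == 0) stop("empty catalog", call. = FALSE)
  y <- catalog / n
  fit <- pracma::lsqnonneg(reference, as.numeric(y))
  w <- fit$x
  if (sum(w) > 0) w <- w / sum(w)
  structure(list(weights = setNames(w, colnames(reference)),
                 residual = sqrt(fit$resid.norm),
                 catalog_n = n),
            class = "signature_fit")
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Signature refit on", x$catalog_n, "substitutions\n")
  top <- sort(x$weights[x$weights > 1e-3], decreasing = TRUE)
  for (nm in names(top)) cat(sprintf("  %-6s %.3f\n", nm, top[[nm]]))
  cat(sprintf("  residual (L2, frequency scale): %.4g\n", x$residual))
  invisible(x)
}
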