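# Plain-text fixture readers and writers.
#
# Dialect: TSV with header, UTF-8, "." decimal; the expression matrix is CSV
# with genes as rows. Numeric columns are written with %.17g so that
# write-then-read is the identity on doubles.

.MAF_COLUMNS <- c(Tumor_Sample_Barcode = "sample_id",
                  Hugo_Symbol = "gene",
                  HGVSp_Short = "protein_change",
                  Variant_Type = "variant_type",
                  Variant_Classification = "variant_classification",
                  t_VAF = "vaf",
                  origin = "origin",
                  pathogenicity = "pathogenicity",
                  context96 = "context96")

format_numeric_cols <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

write_tsv_exact <- function(df, path) {
  write.table(format_numeric_cols(df), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "", fileEncoding = "UTF-8")
}

read_tsv_checked <- function(path, mandatory, numeric_cols = character(0)) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "", fileEncoding = "UTF-8",
                   colClasses = "character")
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s: missing mandatory column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in numeric_cols) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !is.na(df[[col]]))
    if (length(bad) > 0)
      stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                   basename(path), col, bad[1] + 1L), call. = FALSE)
    df[[col]] <- x
  }
  df
}

#' Write / read a variant table as MAF-like TSV
#'
#' Columns follow cBioPortal MAF conventions (`Tumor_Sample_Barcode`,
#' `Hugo_Symbol`, `HGVSp_Short`, `Variant_Type`, `Variant_Classification`,
#' `t_VAF`, `origin`, `pathogenicity`, `context96`).
#'
#' @param variants variant-call data frame (see [generate_cohort()]).
#' @param path file path.
#' @return `write_maf` returns `path` invisibly; `read_maf` returns the
#'   variant data frame with package-internal column names.
#' @export
write_maf <- function(variants, path) {
  out <- variants[, unname(.MAF_COLUMNS)]
  names(out) <- names(.MAF_COLUMNS)
  write_tsv_exact(out, path)
  invisible(path)
}

#' @rdname write_maf
#' @export
read_maf <- function(path) {
  df <- read_tsv_checked(path, names(.MAF_COLUMNS), numeric_cols = "t_VAF")
  df <- df[, names(.MAF_COLUMNS)]
  names(df) <- unname(.MAF_COLUMNS)
  bad <- which(!is.na(df$vaf) & (df$vaf <= 0 | df$vaf > 1))
  if (length(bad) > 0)
    stop(sprintf("%s: t_VAF out of (0, 1] at line %d", basename(path),
                 bad[1] + 1L), call. = FALSE)
  df
}

#' Write / read clinical, copy-number, microsatellite and pool tables (TSV)
#'
#' @param df the table to write.
#' @param path file path.
#' @return writers return `path` invisibly; readers return the table.
#' @export
write_clinical <- function(df, path) {
  write_tsv_exact(df, path); invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "er_status", "grade",
                                 "her2_class", "pam50"))
  for (col in intersect(c("pgr_pct", "ki67_pct"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  df
}

#' @rdname write_clinical
#' @export
write_cn <- function(df, path) {
  write_tsv_exact(df, path); invisible(path)
}

#' @rdname write_clinical
#' @export
read_cn <- function(path) {
  read_tsv_checked(path, c("sample_id", "gene", "log10_fc", "call"),
                   numeric_cols = "log10_fc")
}

#' @rdname write_clinical
#' @export
write_msi <- function(df, path) {
  write_tsv_exact(df, path); invisible(path)
}

#' @rdname write_clinical
#' @export
read_msi <- function(path) {
  read_tsv_checked(path, c("sample_id", "locus", "call"))
}

#' @rdname write_clinical
#' @export
write_pool <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.integer(out[[j]])) out[[j]] <- as.integer(out[[j]])
  write_tsv_exact(out, path); invisible(path)
}

#' @rdname write_clinical
#' @export
read_pool <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "er_status", "grade"))
  genes <- setdiff(names(df), c("sample_id", "er_status", "grade",
                                "her2_score"))
  for (g in genes) df[[g]] <- as.integer(df[[g]])
  df
}

#' Write / read an expression matrix as CSV (genes as rows)
#'
#' @param mat numeric genes x samples matrix with dimnames.
#' @param path file path.
#' @return `write_expression` returns `path` invisibly; `read_expression`
#'   returns the matrix.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- mat[, j]
  write.table(format_numeric_cols(df), path, sep = ",", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene")
    stop(sprintf("%s: first column must be 'gene'", basename(path)),
         call. = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene
  storage.mode(mat) <- "double"
  mat
}

#' Write / read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @return `write_gmt` returns `path` invisibly; `read_gmt` a named list.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop(sprintf("%s: malformed GMT record at line %d", basename(path), i),
           call. = FALSE)
    out[[parts[1]]] <- parts[-(1:2)]
  }
  out
}

#' Write / read the planted-truth record as JSON
#'
#' @param truth list as returned in `generate_cohort()$truth`.
#' @param path file path.
#' @return `write_truth` returns `path` invisibly; `read_truth` the list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
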