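#' Construct an expression matrix
#'
#' Gene-by-sample abundance matrix with a declared unit and per-sample
#' metadata (condition, patient, specimen order).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All values must be non-negative.
#' @param unit One of `"FPKM"`, `"TPM"`, `"counts"`.
#' @param sample_meta Optional data.frame with columns `sample`, `condition`,
#'   and optionally `patient_id`, `specimen_order`. Defaults to one condition
#'   `"all"`, one patient per sample, specimen order 1.
#'
#' @return An object of class `expr_matrix` with elements `values`, `unit`,
#'   `sample_meta`.
#' @export
expression_matrix <- function(values, unit = c("FPKM", "TPM", "counts"),
                              sample_meta = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and sample colnames")
  }
  if (anyNA(values) || any(values < 0)) {
    stop("expression values must be non-negative and non-missing")
  }
  samples <- colnames(values)
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample = samples, condition = "all",
                              stringsAsFactors = FALSE)
  }
  if (!all(c("sample", "condition") %in% names(sample_meta))) {
    stop("sample_meta needs columns 'sample' and 'condition'")
  }
  if (is.null(sample_meta$patient_id)) sample_meta$patient_id <- sample_meta$sample
  if (is.null(sample_meta$specimen_order)) sample_meta$specimen_order <- 1L
  if (!setequal(sample_meta$sample, samples)) {
    stop("sample_meta does not cover the matrix columns")
  }
  sample_meta <- sample_meta[match(samples, sample_meta$sample), , drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values, unit = unit, sample_meta = sample_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples [", x$unit, "], conditions: ",
      paste(unique(x$sample_meta$condition), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Write / read a gene-by-sample matrix as GCT v1.2
#'
#' The GCT v1.2 dialect: line 1 `#1.2`, line 2 `<n_genes>\t<n_samples>`, then
#' a header row `Name`, `Description`, sample ids, followed by one row per
#' gene. Descriptions are written as the gene id when none are supplied.
#'
#' @param x An `expr_matrix`.
#' @param path File path.
#' @param descriptions Optional character vector of gene descriptions.
#' @return `path` invisibly (`write_gct`); an `expr_matrix` (`read_gct`).
#' @export
write_gct <- function(x, path, descriptions = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (is.null(descriptions)) descriptions <- rownames(v)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(paste(nrow(v), ncol(v), sep = "\t"), con)
  writeLines(paste(c("Name", "Description", colnames(v)), collapse = "\t"), con)
  body <- cbind(rownames(v), descriptions,
                format(v, trim = TRUE, scientific = FALSE))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_gct
#' @param unit Unit to declare on the matrix read from `path`.
#' @export
read_gct <- function(path, unit = "TPM") {
  header <- readLines(path, n = 2L)
  if (!startsWith(header[1L], "#1.2")) stop("not a GCT v1.2 file: ", path)
  dims <- as.integer(strsplit(header[2L], "\t")[[1L]][1:2])
  tab <- utils::read.table(path, sep = "\t", skip = 2L, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "")
  if (nrow(tab) != dims[1L] || ncol(tab) != dims[2L] + 2L) {
    stop("GCT dimension line disagrees with the table body")
  }
  v <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(v) <- tab[[1L]]
  expression_matrix(v, unit = unit)
}

#' Write / read an expression matrix as TSV (genes x samples)
#'
#' @param x An `expr_matrix`.
#' @param path File path.
#' @return `path` invisibly (`write_expression_tsv`); an `expr_matrix`
#'   (`read_expression_tsv`).
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  utils::write.table(data.frame(gene_id = rownames(x$values), x$values,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param unit Unit to declare on the matrix read from `path`.
#' @param sample_meta Optional sample metadata, see [expression_matrix()].
#' @export
read_expression_tsv <- function(path, unit = "FPKM", sample_meta = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  v <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(v) <- tab[[1L]]
  expression_matrix(v, unit = unit, sample_meta = sample_meta)
}
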