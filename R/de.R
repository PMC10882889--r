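#' Per-gene comparison of two conditions
#'
#' Computes condition means and log2 fold changes for every gene, flagging
#' genes that fall below the expression floor in both conditions as not
#' expressed (these are discarded by downstream selection).
#'
#' @param expr An `expr_matrix`.
#' @param cond_a,cond_b Condition labels present in `expr$sample_meta`;
#'   fold changes are B relative to A.
#' @param floor Expression floor: a gene is called expressed unless its mean
#'   is below `floor` in both conditions (default 0.2 FPKM).
#' @param eps Pseudo-count added to both means before the log ratio. The
#'   default 0 propagates infinite fold changes when one mean is zero;
#'   infinite fold changes pass any finite cut in [select_de()].
#' @return data.frame with `gene_id`, `mean_a`, `mean_b`, `log2fc`,
#'   `expressed`.
#' @export
compare_conditions <- function(expr, cond_a, cond_b, floor = 0.2, eps = 0) {
  stopifnot(inherits(expr, "expr_matrix"))
  meta <- expr$sample_meta
  for (cond in c(cond_a, cond_b)) {
    if (!cond %in% meta$condition) stop("unknown condition: ", cond)
  }
  a_cols <- meta$sample[meta$condition == cond_a]
  b_cols <- meta$sample[meta$condition == cond_b]
  mean_a <- rowMeans(expr$values[, a_cols, drop = FALSE])
  mean_b <- rowMeans(expr$values[, b_cols, drop = FALSE])
  data.frame(
    gene_id = rownames(expr$values),
    mean_a = mean_a, mean_b = mean_b,
    log2fc = log2((mean_b + eps) / (mean_a + eps)),
    expressed = !(mean_a < floor & mean_b < floor),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Select differentially expressed genes from a comparison
#'
#' @param results data.frame from [compare_conditions()].
#' @param cut Log2 fold-change cutoff (strict: `log2fc > cut` is up,
#'   `log2fc < -cut` is down). Must be positive.
#' @return A `de_gene_set`: list with character sets `up` and `down` and the
#'   thresholds used.
#' @export
select_de <- function(results, cut = 1) {
  if (!is.numeric(cut) || cut <= 0) stop("cut must be positive")
  expressed <- results$expressed & !is.nan(results$log2fc)
  up <- results$gene_id[expressed & results$log2fc > cut]
  down <- results$gene_id[expressed & results$log2fc < -cut]
  structure(list(up = up, down = down, thresholds = c(log2fc_cut = cut)),
            class = "de_gene_set")
}

#' @export
print.de_gene_set <- function(x, ...) {
  cat("<de_gene_set> up:", length(x$up), " down:", length(x$down), "\n")
  invisible(x)
}

#' Sign-consistent intersection of DE gene sets
#'
#' A gene is conserved differentially expressed only if it is up in every
#' comparison, or down in every comparison; mixed signs disqualify it.
#'
#' @param sets A list of two or more `de_gene_set` objects.
#' @return A `de_gene_set` with the intersected `up` and `down` sets.
#' @export
intersect_conserved <- function(sets) {
  if (length(sets) < 2L) stop("need at least two DE gene sets")
  stopifnot(all(vapply(sets, inherits, logical(1L), "de_gene_set")))
  up <- Reduce(intersect, lapply(sets, `[[`, "up"))
  down <- Reduce(intersect, lapply(sets, `[[`, "down"))
  structure(list(up = up, down = down, thresholds = sets[[1L]]$thresholds),
            class = "de_gene_set")
}

#' Rank genes by cohort prevalence and average expression
#'
#' For each gene, computes the fraction of cohort samples in which it is
#' expressed (value strictly above `min_expr`) and its average expression;
#' genes expressed in strictly more than `min_frac` of samples are returned,
#' ranked from lowest to highest average expression.
#'
#' @param cohort An `expr_matrix` (FPKM or TPM).
#' @param gene_ids Genes to evaluate (must be non-empty).
#' @param min_expr Expression call threshold (strict `>`; default 0.2).
#' @param min_frac Prevalence threshold (strict `>`; default 0.9).
#' @return data.frame `gene_id`, `frac_expressed`, `mean_expr`, `rank`
#'   (1 = lowest average expression), restricted to prevalent genes.
#' @export
prevalence_rank <- function(cohort, gene_ids, min_expr = 0.2, min_frac = 0.9) {
  stopifnot(inherits(cohort, "expr_matrix"))
  if (length(gene_ids) == 0L) stop("empty gene set")
  if (!cohort$unit %in% c("FPKM", "TPM")) {
    stop("prevalence ranking expects FPKM or TPM")
  }
  missing <- setdiff(gene_ids, rownames(cohort$values))
  if (length(missing)) stop("genes absent from cohort: ",
                            paste(utils::head(missing, 3L), collapse = ", "))
  v <- cohort$values[gene_ids, , drop = FALSE]
  frac <- rowMeans(v > min_expr)
  avg <- rowMeans(v)
  keep <- frac > min_frac
  out <- data.frame(gene_id = gene_ids[keep], frac_expressed = frac[keep],
                    mean_expr = avg[keep], row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_expr), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Threshold a differential-expression statistics table
#'
#' Applies the fold-change and FDR filter to a supplied per-gene statistics
#' table (e.g. from a count-based DE model). When no FDR column is present,
#' Benjamini-Hochberg adjusted p-values are computed.
#'
#' @param stats data.frame with columns `gene_id` (or `gene`), `log2fc`,
#'   `pvalue`, and optionally `fdr`.
#' @param log2_cut Absolute log2 fold-change cutoff (strict `>`; default 0.58,
#'   i.e. 1.5-fold).
#' @param fdr_cut FDR cutoff (strict `<`; default 0.05).
#' @return A `de_gene_set`.
#' @export
threshold_de_table <- function(stats, log2_cut = 0.58, fdr_cut = 0.05) {
  gene_col <- if ("gene_id" %in% names(stats)) "gene_id" else "gene"
  stopifnot(gene_col %in% names(stats), "log2fc" %in% names(stats))
  if (is.null(stats$fdr)) {
    if (is.null(stats$pvalue)) stop("need a pvalue or fdr column")
    p <- stats$pvalue
    if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values outside [0,1]")
    stats$fdr <- stats::p.adjust(p, method = "BH")
  }
  sig <- abs(stats$log2fc) > log2_cut & stats$fdr < fdr_cut
  structure(list(
    up = stats[[gene_col]][sig & stats$log2fc > 0],
    down = stats[[gene_col]][sig & stats$log2fc < 0],
    thresholds = c(log2fc_cut = log2_cut, fdr_cut = fdr_cut)
  ), class = "de_gene_set")
}
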