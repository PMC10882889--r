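#' Convert FPKM to TPM
#'
#' Divides each FPKM value by the per-sample FPKM total and multiplies by
#' 10^6, so every sample column sums to one million. Applying the conversion
#' to a matrix that is already TPM-normalized is a no-op (idempotence).
#'
#' @param expr An `expr_matrix` with unit `"FPKM"` or `"TPM"`.
#' @return An `expr_matrix` with unit `"TPM"`.
#' @export
fpkm_to_tpm <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!expr$unit %in% c("FPKM", "TPM")) {
    stop("fpkm_to_tpm expects FPKM (or TPM) input, got ", expr$unit)
  }
  totals <- colSums(expr$values)
  if (any(totals <= 0)) {
    stop("sample(s) with all-zero expression: ",
         paste(colnames(expr$values)[totals <= 0], collapse = ", "))
  }
  v <- sweep(expr$values, 2L, totals, "/") * 1e6
  expression_matrix(v, unit = "TPM", sample_meta = expr$sample_meta)
}

#' Preprocess a cohort expression matrix
#'
#' Standard cohort hygiene before tumor-vs-normal statistics: gene version
#' suffixes are stripped (text after the first `.` dropped, turning versioned
#' ids into plain Ensembl gene ids), duplicated gene ids are removed (first
#' occurrence kept by default), and when a patient contributed multiple
#' specimens only the first (lowest specimen order) is retained.
#'
#' @param expr An `expr_matrix` whose `sample_meta` carries `patient_id` and
#'   `specimen_order`.
#' @param dedup_genes `"first"` (keep first occurrence) or `"drop"` (remove
#'   all copies of a duplicated id).
#' @return An `expr_matrix` restricted to one specimen per patient with
#'   unique, version-stripped gene ids.
#' @export
preprocess_cohort <- function(expr, dedup_genes = c("first", "drop")) {
  stopifnot(inherits(expr, "expr_matrix"))
  dedup_genes <- match.arg(dedup_genes)
  v <- expr$values
  genes <- sub("\\..*$", "", rownames(v))
  if (dedup_genes == "first") {
    keep <- !duplicated(genes)
  } else {
    keep <- !(genes %in% genes[duplicated(genes)])
  }
  v <- v[keep, , drop = FALSE]
  rownames(v) <- genes[keep]
  meta <- expr$sample_meta
  if (anyNA(meta$patient_id)) stop("patient map missing for some samples")
  ord <- order(meta$patient_id, meta$specimen_order)
  first <- !duplicated(meta$patient_id[ord])
  keep_samples <- meta$sample[ord][first]
  keep_samples <- keep_samples[order(match(keep_samples, meta$sample))]
  expression_matrix(v[, keep_samples, drop = FALSE], unit = expr$unit,
                    sample_meta = meta[match(keep_samples, meta$sample), ,
                                       drop = FALSE])
}

#' Compare one gene's expression between two cohorts
#'
#' Summarizes each cohort with box-plot statistics (median, quartiles,
#' whiskers at the furthest observation within 1.5 interquartile ranges of
#' the quartiles) plus the mean, and tests the group difference with a
#' two-sample Student's t-test (classical equal-variance form by default;
#' Welch via `equal_var = FALSE`).
#'
#' @param tumor,normal `expr_matrix` objects containing `gene`.
#' @param gene Gene id.
#' @param equal_var Use the pooled-variance t-test (default `TRUE`).
#' @return A list with per-group summaries (`tumor`, `normal`) and `t`, `p`.
#' @export
group_compare <- function(tumor, normal, gene, equal_var = TRUE) {
  grab <- function(cohort, label) {
    stopifnot(inherits(cohort, "expr_matrix"))
    if (!gene %in% rownames(cohort$values)) {
      stop("gene ", gene, " absent from the ", label, " cohort")
    }
    x <- as.numeric(cohort$values[gene, ])
    if (length(x) < 2L) stop(label, " cohort has fewer than 2 samples")
    x
  }
  x <- grab(tumor, "tumor")
  y <- grab(normal, "normal")
  box_stats <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    list(mean = mean(v), median = q[2L], q1 = q[1L], q3 = q[3L],
         whisker_low = min(v[v >= q[1L] - 1.5 * iqr]),
         whisker_high = max(v[v <= q[3L] + 1.5 * iqr]),
         n = length(v))
  }
  tt <- two_sample_test(x, y, equal_var = equal_var)
  list(gene = gene, tumor = box_stats(x), normal = box_stats(y),
       t = tt$t, p = tt$p)
}

#' Random-gene-set correlation null for a focal gene pair
#'
#' Measures the Spearman rank correlation of a focal gene pair and situates
#' it against an empirical null built from random genes: `n_random` genes are
#' sampled without replacement (excluding the focal pair and constant genes)
#' and divided into `n_sets` disjoint sets. Within each set, the correlations
#' of each focal gene with every random gene give a null distribution; the
#' focal-pair correlation is expressed as a Z-score against that
#' distribution's mean and spread, and as a rank (1 = highest correlation)
#' among the set's correlations. Mean ranks and mean Z-scores across sets are
#' reported.
#'
#' @param cohort An `expr_matrix` (one cohort, unique genes).
#' @param gene_a,gene_b Focal gene ids.
#' @param n_random Total number of random genes (default 2000). Reduced with
#'   a warning when the cohort has fewer usable genes.
#' @param n_sets Number of disjoint sets (default 10).
#' @param seed Optional integer seed for the gene sampling.
#' @param sd_mode `"per_set"` (Z uses each set's own sd; default) or
#'   `"pooled"` (sd of all `n_random` correlations).
#' @param rank_ties `"count"` (rank = 1 + number of strictly larger null
#'   correlations; default) or `"average"` (average rank among ties).
#' @return A list of class `correlation_null`: `rho_pair`, per-set table
#'   `per_set` (`mean_rho_a`, `sd_rho_a`, `z_a`, `rank_a`, likewise for b),
#'   `z_a`, `z_b` (means across sets), `mean_rank_a`, `mean_rank_b`.
#' @export
correlation_null <- function(cohort, gene_a, gene_b, n_random = 2000L,
                             n_sets = 10L, seed = NULL,
                             sd_mode = c("per_set", "pooled"),
                             rank_ties = c("count", "average")) {
  stopifnot(inherits(cohort, "expr_matrix"))
  sd_mode <- match.arg(sd_mode)
  rank_ties <- match.arg(rank_ties)
  v <- cohort$values
  for (g in c(gene_a, gene_b)) {
    if (!g %in% rownames(v)) stop("gene ", g, " absent from cohort")
  }
  if (!is.null(seed)) set.seed(seed)
  # Spearman via Pearson on average ranks; samples in rows after transpose
  rk <- apply(t(v), 2L, rank)            # samples x genes
  ra <- rk[, gene_a]; rb <- rk[, gene_b]
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    stop("focal gene with constant expression: correlation undefined")
  }
  rho_pair <- stats::cor(ra, rb)
  pool <- setdiff(rownames(v), c(gene_a, gene_b))
  sds <- apply(rk[, pool, drop = FALSE], 2L, stats::sd)
  if (any(sds == 0)) {
    message("excluding ", sum(sds == 0), " constant gene(s) from the null pool")
    pool <- pool[sds > 0]
  }
  if (length(pool) < n_random) {
    warning("only ", length(pool), " usable genes; reducing n_random")
    n_random <- length(pool) - length(pool) %% n_sets
  }
  picked <- sample(pool, n_random, replace = FALSE)
  set_id <- rep(seq_len(n_sets), each = n_random %/% n_sets,
                length.out = n_random)
  cors_a <- as.numeric(stats::cor(ra, rk[, picked, drop = FALSE]))
  cors_b <- as.numeric(stats::cor(rb, rk[, picked, drop = FALSE]))
  pooled_sd_a <- stats::sd(cors_a)
  pooled_sd_b <- stats::sd(cors_b)
  rank_fun <- function(null_cors) {
    if (rank_ties == "count") {
      1 + sum(null_cors > rho_pair)
    } else {
      # average rank of rho_pair inserted into the null correlations
      mean(rank(-c(rho_pair, null_cors), ties.method = "average")[1L])
    }
  }
  per_set <- do.call(rbind, lapply(seq_len(n_sets), function(s) {
    ca <- cors_a[set_id == s]; cb <- cors_b[set_id == s]
    sd_a <- if (sd_mode == "per_set") stats::sd(ca) else pooled_sd_a
    sd_b <- if (sd_mode == "per_set") stats::sd(cb) else pooled_sd_b
    data.frame(set = s,
               mean_rho_a = mean(ca), sd_rho_a = sd_a,
               z_a = (rho_pair - mean(ca)) / sd_a, rank_a = rank_fun(ca),
               mean_rho_b = mean(cb), sd_rho_b = sd_b,
               z_b = (rho_pair - mean(cb)) / sd_b, rank_b = rank_fun(cb))
  }))
  structure(list(
    gene_a = gene_a, gene_b = gene_b, rho_pair = rho_pair, per_set = per_set,
    z_a = mean(per_set$z_a), z_b = mean(per_set$z_b),
    mean_rank_a = mean(per_set$rank_a), mean_rank_b = mean(per_set$rank_b),
    random_genes = split(picked, set_id)
  ), class = "correlation_null")
}

#' @export
print.correlation_null <- function(x, ...) {
  cat("<correlation_null> rho(", x$gene_a, ",", x$gene_b, ") = ",
      signif(x$rho_pair, 3L), "; mean z = ",
      signif(mean(c(x$z_a, x$z_b)), 3L), "; mean rank a/b = ",
      signif(x$mean_rank_a, 3L), "/", signif(x$mean_rank_b, 3L), "\n",
      sep = "")
  invisible(x)
}
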