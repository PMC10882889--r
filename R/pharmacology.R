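#' Construct a viability grid
#'
#' Dose-pair fractional effects relative to untreated control. The zero-dose
#' row and column carry the single-agent effects; `effect[1, 1]` (both doses
#' zero) is the untreated control and must be 1.
#'
#' @param doses_a,doses_b Numeric dose vectors (must include 0 for the
#'   single-agent margins).
#' @param effect Matrix of surviving fractions in (0, 1], `length(doses_a)`
#'   rows by `length(doses_b)` columns.
#' @return An object of class `viability_grid`.
#' @export
viability_grid <- function(doses_a, doses_b, effect) {
  effect <- as.matrix(effect)
  if (nrow(effect) != length(doses_a) || ncol(effect) != length(doses_b)) {
    stop("effect matrix dimensions do not match the dose vectors")
  }
  if (!(0 %in% doses_a) || !(0 %in% doses_b)) {
    stop("dose vectors must include 0 (single-agent margins)")
  }
  if (any(effect <= 0) || any(effect > 1)) {
    stop("surviving fractions must lie in (0, 1]")
  }
  ia <- match(0, doses_a); ib <- match(0, doses_b)
  if (abs(effect[ia, ib] - 1) > 1e-9) {
    stop("untreated control (dose 0/0) must have effect 1")
  }
  dimnames(effect) <- list(doses_a, doses_b)
  structure(list(doses_a = doses_a, doses_b = doses_b, effect = effect),
            class = "viability_grid")
}

#' Bliss-model combination index
#'
#' For each dose pair with both doses positive, the combination index is the
#' log2 ratio of the observed combined surviving fraction to the Bliss
#' independence expectation (the product of the single-agent fractions):
#' `CI = log2(E_ab / (E_a * E_b))`. CI < 0 indicates synergy (more kill than
#' independence predicts), CI > 0 antagonism; the mean over all dose pairs is
#' reported. The printed formula in some protocols carries a minus sign in
#' the denominator; with E as a positive surviving fraction that form has no
#' real logarithm, so it is exposed only behind `strict_sign = TRUE`.
#'
#' @param grid A `viability_grid`.
#' @param strict_sign If `TRUE`, uses the literal `-E_a * E_b` denominator
#'   (NaN for positive survivals; retained to document the sign convention).
#' @return A list of class `ci_result`: `ci_matrix` (positive-dose pairs) and
#'   `mean_ci`.
#' @export
combination_index <- function(grid, strict_sign = FALSE) {
  stopifnot(inherits(grid, "viability_grid"))
  ia <- match(0, grid$doses_a); ib <- match(0, grid$doses_b)
  e_a <- grid$effect[, ib]
  e_b <- grid$effect[ia, ]
  rows <- which(grid$doses_a > 0); cols <- which(grid$doses_b > 0)
  denom_sign <- if (strict_sign) -1 else 1
  ci <- log2(grid$effect[rows, cols, drop = FALSE] /
               (denom_sign * outer(e_a[rows], e_b[cols])))
  dimnames(ci) <- list(grid$doses_a[rows], grid$doses_b[cols])
  structure(list(ci_matrix = ci, mean_ci = mean(ci)), class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat("<ci_result> mean CI =", signif(x$mean_ci, 4L),
      if (x$mean_ci < 0) "(synergy)" else if (x$mean_ci > 0) "(antagonism)"
      else "(independence)", "\n")
  invisible(x)
}

#' Relative expression by the comparative Ct method
#'
#' Per sample, `dCt = Ct_target - Ct_housekeeping`; `ddCt` is the difference
#' of group-mean dCt (treated minus control); relative expression is
#' `2^(-ddCt)`, assuming an amplification efficiency of exactly 2 per cycle.
#'
#' @param ct data.frame with columns `sample`, `group`, `gene`, `ct`.
#' @param target Target gene id.
#' @param housekeeping Housekeeping gene id (must be measured in every sample
#'   that carries the target).
#' @param treated_group,control_group Group labels in `ct$group`.
#' @return A list: `fold` (relative expression), `ddct`, per-group mean dCt.
#' @export
relative_expression <- function(ct, target, housekeeping, treated_group,
                                control_group) {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  dct_for <- function(group) {
    sub <- ct[ct$group == group, , drop = FALSE]
    if (nrow(sub) == 0L) stop("no rows for group ", group)
    tgt <- sub[sub$gene == target, , drop = FALSE]
    hk <- sub[sub$gene == housekeeping, , drop = FALSE]
    if (nrow(tgt) == 0L) stop("target ", target, " absent in group ", group)
    hk_ct <- hk$ct[match(tgt$sample, hk$sample)]
    if (anyNA(hk_ct)) stop("housekeeping gene missing for sample(s) in group ",
                           group)
    mean(tgt$ct - hk_ct)
  }
  dct_t <- dct_for(treated_group)
  dct_c <- dct_for(control_group)
  ddct <- dct_t - dct_c
  list(fold = 2^(-ddct), ddct = ddct,
       dct_treated = dct_t, dct_control = dct_c)
}

#' Nuclear-to-cytoplasmic enrichment ratio
#'
#' The raw nuclear/cytoplasmic abundance ratio of a transcript is
#' `2^(Ct_cytoplasmic - Ct_nuclear)` (one Ct cycle = 2-fold); the ratio is
#' then normalized to the raw ratio of a nuclear-enriched control transcript
#' so that fraction-specific recovery differences cancel. Ct values from
#' replicate samples are averaged per gene and fraction.
#'
#' @param fracs data.frame with columns `gene`, `group` (`"nuclear"` /
#'   `"cytoplasmic"`) and `ct` (plus optionally `sample`).
#' @param gene Gene of interest.
#' @param control_gene Nuclear-enriched reference transcript.
#' @return A list: `ratio` (normalized), `raw_gene`, `raw_control`.
#' @export
nc_ratio <- function(fracs, gene, control_gene) {
  stopifnot(all(c("gene", "group", "ct") %in% names(fracs)))
  raw_for <- function(g) {
    sub <- fracs[fracs$gene == g, , drop = FALSE]
    if (nrow(sub) == 0L) stop("gene ", g, " absent from the fraction table")
    ct_n <- sub$ct[sub$group == "nuclear"]
    ct_c <- sub$ct[sub$group == "cytoplasmic"]
    if (length(ct_n) == 0L || length(ct_c) == 0L) {
      stop("both fractions required for gene ", g)
    }
    2^(mean(ct_c) - mean(ct_n))
  }
  raw_g <- raw_for(gene)
  raw_c <- raw_for(control_gene)
  list(ratio = raw_g / raw_c, raw_gene = raw_g, raw_control = raw_c)
}

#' Normalize cell growth to control treatment
#'
#' @param lum Named numeric vector of viability readings (e.g. RLU) per
#'   sample.
#' @param control_samples Names of the control-treated samples (their mean is
#'   the denominator; must be non-empty with positive mean).
#' @return Named numeric vector of growth fractions.
#' @export
growth_normalize <- function(lum, control_samples) {
  if (length(control_samples) == 0L) stop("empty control set")
  missing <- setdiff(control_samples, names(lum))
  if (length(missing)) stop("control sample(s) absent: ",
                            paste(missing, collapse = ", "))
  ctrl_mean <- mean(lum[control_samples])
  if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
    stop("control mean must be positive")
  }
  lum / ctrl_mean
}

#' Caliper-based tumor volume
#'
#' `V = 0.5 * length * width^2` (mm^3). By convention length is the larger
#' dimension; measurements supplied the other way round are swapped (with a
#' warning) unless `swap_axes = FALSE`.
#'
#' @param length,width Caliper measurements in mm (vectors recycled to a
#'   common length; all values must be positive).
#' @param swap_axes Swap pairs where width exceeds length (default `TRUE`).
#' @return Numeric vector of volumes in mm^3.
#' @export
tumor_volume <- function(length, width, swap_axes = TRUE) {
  if (any(length <= 0) || any(width <= 0)) {
    stop("dimensions must be positive")
  }
  n <- max(base::length(length), base::length(width))
  length <- rep_len(length, n); width <- rep_len(width, n)
  flipped <- width > length
  if (any(flipped)) {
    warning("width > length for ", sum(flipped),
            " measurement(s); ",
            if (swap_axes) "axes swapped by convention" else "kept as given")
    if (swap_axes) {
      tmp <- length[flipped]
      length[flipped] <- width[flipped]
      width[flipped] <- tmp
    }
  }
  0.5 * length * width^2
}

#' Two-sample Student's t-test
#'
#' Classical two-sided two-sample t-test, pooled-variance by default (Welch
#' with `equal_var = FALSE`). When both groups have zero variance the t
#' statistic is undefined for equal means (reported as `NaN` with p `NaN`)
#' and infinite for different means (p = 0).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param equal_var Pooled-variance form (default `TRUE`).
#' @return A list with `t` and `p`.
#' @export
two_sample_test <- function(x, y, equal_var = TRUE) {
  if (base::length(x) < 2L || base::length(y) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = NaN, p = NaN))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  res <- stats::t.test(x, y, var.equal = equal_var)
  list(t = unname(res$statistic), p = res$p.value)
}
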