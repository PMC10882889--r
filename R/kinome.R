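#' Construct a plate layout
#'
#' Well-level description of a kinase-activity plate: experimental wells
#' (one peptide sensor, one sample), the three control classes (no-ATP,
#' no-peptide, no-sample) and ATP standards.
#'
#' @param wells data.frame with columns `well`, `class` (one of
#'   `experimental`, `no_ATP`, `no_peptide`, `no_sample`, `ATP_standard`),
#'   `peptide`, `sample`, `replicate`, `standard_conc` (nM, standards only).
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(wells) {
  required <- c("well", "class", "peptide", "sample", "replicate",
                "standard_conc")
  for (col in setdiff(required, names(wells))) {
    wells[[col]] <- if (col == "replicate") 1L else NA
  }
  wells <- as.data.frame(wells)[required]
  classes <- c("experimental", "no_ATP", "no_peptide", "no_sample",
               "ATP_standard")
  if (!all(wells$class %in% classes)) {
    stop("unknown well class: ",
         paste(setdiff(wells$class, classes), collapse = ", "))
  }
  if (anyDuplicated(wells$well)) stop("duplicated well ids")
  exp_rows <- wells$class == "experimental"
  if (any(exp_rows & (is.na(wells$peptide) | is.na(wells$sample)))) {
    stop("experimental wells need both peptide and sample")
  }
  std <- wells$class == "ATP_standard"
  if (any(std & is.na(wells$standard_conc))) {
    stop("ATP standards need a concentration")
  }
  structure(wells, class = c("plate_layout", "data.frame"))
}

#' Assemble a 384-well layout for a sample/peptide panel
#'
#' Lays out `samples` x `peptides` x `n_replicates` experimental wells,
#' one no-peptide control per sample, plus no-sample, no-ATP and
#' ATP-standard wells, filling a 16 x 24 grid row-wise.
#'
#' @param peptides Character vector of peptide ids.
#' @param samples Character vector of sample ids.
#' @param n_replicates Experimental replicates per sample/peptide.
#' @param standard_concs ATP standard concentrations in nM (>= 3 wells at
#'   distinct concentrations recommended; >= 2 required for calibration).
#' @param n_no_sample,n_no_atp Number of wells of each control class.
#' @return A `plate_layout`.
#' @export
default_plate_layout <- function(peptides, samples, n_replicates = 1L,
                                 standard_concs = c(0, 62.5, 125, 250),
                                 n_no_sample = 2L, n_no_atp = 2L) {
  rows <- expand.grid(replicate = seq_len(n_replicates), peptide = peptides,
                      sample = samples, stringsAsFactors = FALSE)
  wells <- data.frame(
    class = "experimental", peptide = rows$peptide, sample = rows$sample,
    replicate = rows$replicate, standard_conc = NA_real_,
    stringsAsFactors = FALSE
  )
  add <- function(df, class, n, sample = NA, conc = NA_real_) {
    rbind(df, data.frame(class = class, peptide = NA, sample = sample,
                         replicate = seq_len(n), standard_conc = conc,
                         stringsAsFactors = FALSE))
  }
  for (s in samples) wells <- add(wells, "no_peptide", 1L, sample = s)
  wells <- add(wells, "no_sample", n_no_sample)
  wells <- add(wells, "no_ATP", n_no_atp)
  wells <- rbind(wells, data.frame(class = "ATP_standard", peptide = NA,
                                   sample = NA, replicate = 1L,
                                   standard_conc = standard_concs,
                                   stringsAsFactors = FALSE))
  if (nrow(wells) > 384L) {
    stop("layout needs ", nrow(wells), " wells; a 384-well plate has 384")
  }
  idx <- seq_len(nrow(wells)) - 1L
  wells$well <- paste0(LETTERS[idx %/% 24L + 1L],
                       sprintf("%02d", idx %% 24L + 1L))
  plate_layout(wells)
}

#' Construct a plate assay
#'
#' @param layout A `plate_layout`.
#' @param luminescence Named numeric vector of RLU keyed by well id (all
#'   wells of the layout must be present; values >= 0).
#' @param atp_start Starting ATP concentration in nM (default 250).
#' @return An object of class `plate_assay`.
#' @export
plate_assay <- function(layout, luminescence, atp_start = 250) {
  stopifnot(inherits(layout, "plate_layout"))
  missing <- setdiff(layout$well, names(luminescence))
  if (length(missing)) stop("luminescence missing for wells: ",
                            paste(utils::head(missing, 3L), collapse = ", "))
  if (any(luminescence < 0)) stop("luminescence must be non-negative")
  structure(list(layout = layout,
                 luminescence = luminescence[layout$well],
                 atp_start = atp_start),
            class = "plate_assay")
}

#' Calibrate luminescence against the ATP standards
#'
#' Least-squares line `RLU = slope * [ATP] + intercept` over the plate's ATP
#' standard wells. The inverse map `[ATP] = (RLU - intercept)/slope` converts
#' any well's signal to remaining ATP.
#'
#' @param assay A `plate_assay` whose layout contains standards at >= 2
#'   distinct concentrations.
#' @return List with `slope` (RLU per nM, required positive), `intercept`,
#'   `r_squared`, `n`.
#' @export
calibrate_atp <- function(assay) {
  stopifnot(inherits(assay, "plate_assay"))
  std <- assay$layout$class == "ATP_standard"
  conc <- assay$layout$standard_conc[std]
  if (length(unique(conc)) < 2L) {
    stop("need ATP standards at >= 2 distinct concentrations")
  }
  lum <- assay$luminescence[assay$layout$well[std]]
  fit <- stats::lm(lum ~ conc)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0) {
    stop("non-positive calibration slope: failed plate")
  }
  ss_tot <- sum((lum - mean(lum))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2, n = length(conc))
}

#' Peptide-level phosphorylation activity from a plate assay
#'
#' Converts each experimental well to consumed ATP via the calibration
#' (consumed = starting ATP minus remaining ATP), averages replicate wells,
#' and subtracts the matched no-peptide consumption of the same sample so
#' that sample-autonomous ATP use is removed. The result is the
#' peptide-dependent ATP consumption in nM — the phosphorylation activity
#' sensed by that peptide.
#'
#' @param assay A `plate_assay`.
#' @param calibration Output of [calibrate_atp()].
#' @return data.frame of class `activity_profiles`: `sample`, `peptide`,
#'   `activity` (nM ATP, background-corrected). The pre-correction consumed
#'   ATP is kept in column `consumed`.
#' @export
peptide_activity <- function(assay, calibration) {
  stopifnot(inherits(assay, "plate_assay"))
  lay <- assay$layout
  to_consumed <- function(wells) {
    remaining <- (assay$luminescence[wells] - calibration$intercept) /
      calibration$slope
    assay$atp_start - remaining
  }
  bg_rows <- lay$class == "no_peptide"
  bg <- tapply(to_consumed(lay$well[bg_rows]), lay$sample[bg_rows], mean)
  exp_rows <- lay[lay$class == "experimental", , drop = FALSE]
  missing_bg <- setdiff(unique(exp_rows$sample), names(bg))
  if (length(missing_bg)) {
    stop("no matched no-peptide control for sample(s): ",
         paste(missing_bg, collapse = ", "))
  }
  consumed <- to_consumed(exp_rows$well)
  agg <- stats::aggregate(consumed,
                          by = list(sample = exp_rows$sample,
                                    peptide = exp_rows$peptide),
                          FUN = mean)
  names(agg)[3L] <- "consumed"
  agg$activity <- agg$consumed - as.numeric(bg[agg$sample])
  agg <- agg[order(agg$sample, agg$peptide), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("activity_profiles", "data.frame"))
}

#' Wide peptide x sample matrix of activities
#'
#' @param profiles An `activity_profiles` data.frame.
#' @return Numeric matrix, peptides in rows, samples in columns.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(inherits(profiles, "activity_profiles") ||
              all(c("sample", "peptide", "activity") %in% names(profiles)))
  peptides <- sort(unique(profiles$peptide))
  samples <- sort(unique(profiles$sample))
  m <- matrix(NA_real_, length(peptides), length(samples),
              dimnames = list(peptides, samples))
  m[cbind(match(profiles$peptide, peptides),
          match(profiles$sample, samples))] <- profiles$activity
  m
}

#' Derive per-kinase activity signatures
#'
#' The activity of a kinase is the aggregate (mean by default) of the
#' activities of its biological peptide targets. Kinases with fewer than
#' `min_peptides` mapped-and-measured peptides are omitted.
#'
#' @param profiles An `activity_profiles` data.frame.
#' @param kinase_map data.frame with columns `kinase`, `peptide`.
#' @param min_peptides Minimum number of measured peptides per kinase
#'   (default 3).
#' @param agg `"mean"` (default) or `"median"`.
#' @return data.frame of class `kinase_signatures`: `sample`, `kinase`,
#'   `activity`, `n_peptides`.
#' @export
kinase_signature <- function(profiles, kinase_map, min_peptides = 3L,
                             agg = c("mean", "median")) {
  agg <- match.arg(agg)
  if (is.null(kinase_map) || nrow(kinase_map) == 0L) stop("empty kinase map")
  stopifnot(all(c("kinase", "peptide") %in% names(kinase_map)))
  agg_fun <- if (agg == "mean") mean else stats::median
  out <- list()
  for (s in unique(profiles$sample)) {
    sub <- profiles[profiles$sample == s, , drop = FALSE]
    for (k in unique(kinase_map$kinase)) {
      peps <- kinase_map$peptide[kinase_map$kinase == k]
      vals <- sub$activity[sub$peptide %in% peps]
      if (length(vals) >= min_peptides) {
        out[[length(out) + 1L]] <- data.frame(
          sample = s, kinase = k, activity = agg_fun(vals),
          n_peptides = length(vals), stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(sample = character(0), kinase = character(0),
                      activity = numeric(0), n_peptides = integer(0))
  }
  structure(res, class = c("kinase_signatures", "data.frame"))
}

#' Wide kinase x sample matrix of signature activities
#'
#' @param signatures A `kinase_signatures` data.frame.
#' @return Numeric matrix, kinases in rows, samples in columns.
#' @export
signature_matrix <- function(signatures) {
  kinases <- sort(unique(signatures$kinase))
  samples <- sort(unique(signatures$sample))
  m <- matrix(NA_real_, length(kinases), length(samples),
              dimnames = list(kinases, samples))
  m[cbind(match(signatures$kinase, kinases),
          match(signatures$sample, samples))] <- signatures$activity
  m
}

#' Uncentered-correlation distance matrix
#'
#' `d(x, y) = 1 - sum(x*y) / sqrt(sum(x^2) * sum(y^2))` — the cosine-type
#' similarity used in classical expression clustering; invariant to positive
#' scaling but, unlike Pearson, not to shifts. Zero vectors have undefined
#' similarity and are assigned the maximal distance 1 to every other item
#' (with a warning).
#'
#' @param mat Numeric matrix; distances are computed between columns.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
uncentered_cor_dist <- function(mat) {
  mat <- as.matrix(mat)
  norms <- sqrt(colSums(mat^2))
  zero <- norms == 0
  if (any(zero)) {
    warning("zero vector(s) in clustering input; assigned maximal distance")
    norms[zero] <- 1
  }
  sim <- crossprod(mat) / tcrossprod(norms)
  d <- 1 - sim
  if (any(zero)) {
    d[zero, ] <- 1
    d[, zero] <- 1
  }
  diag(d) <- 0
  # clamp tiny negative values from floating-point round-off
  d[d < 0] <- 0
  d
}

#' Cluster activity profiles
#'
#' Agglomerative clustering with uncentered-correlation distance and average
#' linkage (UPGMA), the classical combination for phospho-activity and
#' expression heat maps.
#'
#' @param mat Numeric feature x sample matrix.
#' @param axis `"columns"` (cluster samples; default) or `"rows"` (cluster
#'   features).
#' @return An `hclust` object.
#' @export
cluster_profiles <- function(mat, axis = c("columns", "rows")) {
  axis <- match.arg(axis)
  m <- as.matrix(mat)
  if (axis == "rows") m <- t(m)
  if (ncol(m) < 2L) stop("need at least two items to cluster")
  d <- uncentered_cor_dist(m)
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Two-group split at the top of a dendrogram
#'
#' @param hc An `hclust` object.
#' @return Named integer vector of cluster memberships (1/2) from cutting
#'   the tree into two clusters.
#' @export
top_split <- function(hc) stats::cutree(hc, k = 2L)

#' Compare two treatment signatures after control normalization
#'
#' Expresses each signature as a log2 ratio to the matched control signature
#' over the shared kinase set, then reports the Pearson correlation of the
#' two ratio profiles. Low correlation indicates treatment-specific kinome
#' reprogramming.
#'
#' @param sig_a,sig_b,control Named numeric vectors of kinase activities
#'   (e.g. columns of [signature_matrix()]); activities must be positive on
#'   the shared kinase set.
#' @return List with `r` (Pearson), `n_kinases`, and the two ratio profiles.
#' @export
compare_signatures <- function(sig_a, sig_b, control) {
  shared <- Reduce(intersect, list(names(sig_a), names(sig_b), names(control)))
  if (length(shared) == 0L) stop("no shared kinases")
  if (any(c(sig_a[shared], sig_b[shared], control[shared]) <= 0)) {
    stop("activities must be positive for log-ratio normalization")
  }
  la <- log2(sig_a[shared] / control[shared])
  lb <- log2(sig_b[shared] / control[shared])
  if (stats::sd(la) == 0 || stats::sd(lb) == 0) {
    stop("constant signature after control normalization")
  }
  list(r = stats::cor(la, lb), n_kinases = length(shared),
       log2_ratio_a = la, log2_ratio_b = lb)
}

#' Write a dendrogram in Newick format
#'
#' @param hc An `hclust` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  build <- function(i) {
    if (i < 0) return(hc$labels[-i])
    left <- build(hc$merge[i, 1L])
    right <- build(hc$merge[i, 2L])
    paste0("(", left, ",", right, "):", format(hc$height[i], digits = 10L))
  }
  writeLines(paste0(sub(":[^:]*$", "", build(nrow(hc$merge))), ";"), path)
  invisible(path)
}

#' Read / write a plate assay as CSV
#'
#' Columns: `well,row,col,class,peptide,sample,replicate,standard_conc,luminescence`.
#'
#' @param assay A `plate_assay`.
#' @param path File path.
#' @return `path` invisibly (`write_plate_csv`); a `plate_assay`
#'   (`read_plate_csv`).
#' @export
write_plate_csv <- function(assay, path) {
  stopifnot(inherits(assay, "plate_assay"))
  lay <- assay$layout
  df <- data.frame(
    well = lay$well,
    row = substr(lay$well, 1L, 1L),
    col = as.integer(substring(lay$well, 2L)),
    class = lay$class, peptide = lay$peptide, sample = lay$sample,
    replicate = lay$replicate, standard_conc = lay$standard_conc,
    luminescence = as.numeric(assay$luminescence[lay$well])
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @param atp_start Starting ATP concentration (nM) for the assay read back.
#' @export
read_plate_csv <- function(path, atp_start = 250) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lay <- plate_layout(df[c("well", "class", "peptide", "sample", "replicate",
                           "standard_conc")])
  lum <- stats::setNames(df$luminescence, df$well)
  plate_assay(lay, lum, atp_start = atp_start)
}
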