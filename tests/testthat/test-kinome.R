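exact_standards_assay <- function() {
  lay <- plate_layout(data.frame(
    well = c("A01", "A02", "A03", "B01", "B02"),
    class = c(rep("ATP_standard", 3), "experimental", "no_peptide"),
    peptide = c(NA, NA, NA, "P1", NA),
    sample = c(NA, NA, NA, "s1", "s1"),
    replicate = 1L,
    standard_conc = c(0, 125, 250, NA, NA)))
  plate_assay(lay, c(A01 = 100, A02 = 600, A03 = 1100, B01 = 500, B02 = 900))
}

test_that("ATP calibration recovers an exact line and rejects bad standards", {
  assay <- exact_standards_assay()
  cal <- calibrate_atp(assay)
  expect_equal(cal$slope, 4)
  expect_equal(cal$intercept, 100)
  one_conc <- plate_layout(data.frame(
    well = c("A01", "A02"), class = "ATP_standard", peptide = NA, sample = NA,
    replicate = 1L, standard_conc = c(125, 125)))
  expect_error(calibrate_atp(plate_assay(one_conc, c(A01 = 1, A02 = 2))),
               "distinct")
  # noisy standards equal the normal-equations closed form
  set.seed(121)
  conc <- c(0, 50, 100, 150, 250)
  lum <- 100 + 4 * conc + rnorm(5, sd = 10)
  lay <- plate_layout(data.frame(
    well = sprintf("A%02d", 1:5), class = "ATP_standard", peptide = NA,
    sample = NA, replicate = 1L, standard_conc = conc))
  cal2 <- calibrate_atp(plate_assay(lay, setNames(lum, lay$well)))
  sxx <- sum((conc - mean(conc))^2)
  slope_oracle <- sum((conc - mean(conc)) * (lum - mean(lum))) / sxx
  expect_equal(cal2$slope, slope_oracle)
  expect_equal(cal2$intercept, mean(lum) - slope_oracle * mean(conc))
})

test_that("peptide activity subtracts the matched no-peptide background", {
  assay <- exact_standards_assay()
  cal <- calibrate_atp(assay)
  prof <- peptide_activity(assay, cal)
  # well B01: remaining = (500-100)/4 = 100, consumed 150; background
  # (900-100)/4 = 200 remaining -> consumed 50; activity 100
  expect_equal(prof$activity[prof$peptide == "P1"], 100)
  # a well reading exactly its sample's no-peptide RLU has zero activity
  assay$luminescence["B01"] <- assay$luminescence["B02"]
  expect_equal(peptide_activity(assay, cal)$activity, 0)
  # missing control errors
  lay_nobg <- assay$layout[assay$layout$class != "no_peptide", ]
  assay2 <- plate_assay(plate_layout(lay_nobg),
                        assay$luminescence[lay_nobg$well])
  expect_error(peptide_activity(assay2, cal), "no-peptide")
})

test_that("ATP conservation holds per well before background correction", {
  assay <- gen_kinase_plate(sim_config(seed = 15, plate_cv = 0))
  cal <- calibrate_atp(assay)
  prof <- peptide_activity(assay, cal)
  lay <- assay$layout
  exp_wells <- lay[lay$class == "experimental" & lay$replicate == 1, ]
  remaining <- (assay$luminescence[exp_wells$well] - cal$intercept) / cal$slope
  consumed <- prof$consumed[match(paste(exp_wells$sample, exp_wells$peptide),
                                  paste(prof$sample, prof$peptide))]
  expect_equal(unname(consumed + remaining), rep(250, nrow(exp_wells)),
               tolerance = 1e-9)
})

test_that("kinase signatures aggregate peptides and enforce the minimum", {
  prof <- structure(data.frame(
    sample = "s1",
    peptide = c("P1", "P2", "P3", "P4", "P5"),
    consumed = 0,
    activity = c(1, 2, 3, 10, 20)), class = c("activity_profiles", "data.frame"))
  map <- data.frame(kinase = c("KA", "KA", "KA", "KB", "KB"),
                    peptide = c("P1", "P2", "P3", "P4", "P5"))
  sig <- kinase_signature(prof, map)
  expect_equal(sig$activity[sig$kinase == "KA"], 2)   # mean of 1,2,3
  expect_false("KB" %in% sig$kinase)                  # only 2 peptides
  sig2 <- kinase_signature(prof, map, min_peptides = 2)
  expect_equal(sig2$activity[sig2$kinase == "KB"], 15)
  expect_error(kinase_signature(prof, map[0, ]), "empty")
})

test_that("planted kinase effects are recovered through the full kinome stage", {
  cfg <- sim_config(seed = 16, plate_effect = c(K1 = 0.5, K3 = 1.6),
                    plate_cv = 0)
  assay <- gen_kinase_plate(cfg)
  sm <- signature_matrix(kinase_signature(
    peptide_activity(assay, calibrate_atp(assay)), default_kinase_map()))
  ratio <- sm[, "treated_1"] / sm[, "control_1"]
  expect_equal(unname(ratio["K1"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(ratio["K3"]), 1.6, tolerance = 1e-9)
  expect_equal(unname(ratio["K2"]), 1, tolerance = 1e-9)
})

test_that("uncentered correlation distance is scale-invariant with protected zeros", {
  x <- c(1, 2, 3); m <- cbind(a = x, b = 2 * x, c = c(3, -1, 2))
  d <- uncentered_cor_dist(m)
  expect_equal(d["a", "b"], 0)            # positive scaling: distance 0
  expect_gt(d["a", "c"], 0)
  # affine shift changes uncentered distance (unlike Pearson)
  m2 <- cbind(a = x, b = x + 10)
  expect_gt(uncentered_cor_dist(m2)["a", "b"], 0)
  expect_warning(dz <- uncentered_cor_dist(cbind(a = x, z = c(0, 0, 0))),
                 "zero vector")
  expect_equal(dz["a", "z"], 1)
})

test_that("average-linkage clustering matches the brute-force UPGMA oracle", {
  set.seed(131)
  for (rep in 1:20) {
    m <- matrix(rnorm(6 * 5), 6, dimnames = list(NULL, sprintf("i%d", 1:5)))
    hc <- cluster_profiles(m)
    d <- uncentered_cor_dist(m)
    coph_oracle <- brute_upgma_cophenetic(d)
    dimnames(coph_oracle) <- dimnames(d)
    coph_hc <- as.matrix(stats::cophenetic(hc))
    expect_equal(unname(coph_hc[hc$labels, hc$labels]),
                 unname(coph_oracle[hc$labels, hc$labels]),
                 tolerance = 1e-10)
  }
})

test_that("treated and control samples split at the top of the dendrogram", {
  cfg <- sim_config(seed = 17, plate_effect = c(K1 = 0.4, K2 = 0.5, K3 = 1.7),
                    plate_cv = 0.02)
  assay <- gen_kinase_plate(cfg)
  prof <- peptide_activity(assay, calibrate_atp(assay))
  split <- top_split(cluster_profiles(profile_matrix(prof)))
  treated <- grepl("^treated", names(split))
  expect_equal(length(unique(split[treated])), 1L)
  expect_equal(length(unique(split[!treated])), 1L)
  expect_false(split[treated][1] == split[!treated][1])
})

test_that("signature comparison normalizes to control and detects degeneracy", {
  a <- c(K1 = 2, K2 = 4, K3 = 1)
  ctrl <- c(K1 = 1, K2 = 1, K3 = 1)
  expect_equal(compare_signatures(a, a, ctrl)$r, 1)
  expect_error(compare_signatures(a, ctrl, ctrl), "constant")
  expect_error(compare_signatures(a, c(X = 1), ctrl), "shared")
  # independent effects on disjoint kinase sets decorrelate on average
  set.seed(141)
  rs <- replicate(100, {
    ctrl <- setNames(runif(12, 10, 20), sprintf("K%02d", 1:12))
    a <- ctrl; b <- ctrl
    a[1:6] <- a[1:6] * 2^rnorm(6, sd = 1)
    b[7:12] <- b[7:12] * 2^rnorm(6, sd = 1)
    a <- a * 2^rnorm(12, sd = 0.05); b <- b * 2^rnorm(12, sd = 0.05)
    compare_signatures(a, b, ctrl)$r
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("dendrograms round-trip to Newick leaf sets", {
  m <- matrix(rnorm(5 * 4), 5, dimnames = list(NULL, c("w", "x", "y", "z")))
  hc <- cluster_profiles(m)
  path <- tempfile(fileext = ".nwk")
  write_newick(hc, path)
  nwk <- readLines(path)
  expect_true(grepl(";$", nwk))
  for (lab in hc$labels) expect_true(grepl(lab, nwk, fixed = TRUE))
})
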