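toy_expr <- function(values, conditions) {
  samples <- sprintf("s%02d", seq_len(ncol(values)))
  colnames(values) <- samples
  expression_matrix(values, unit = "FPKM",
                    sample_meta = data.frame(sample = samples,
                                             condition = conditions))
}

test_that("condition comparison floors, means and fold changes behave", {
  v <- rbind(low = c(0.1, 0.1, 0.1, 0.1),
             flat = c(5, 5, 5, 5),
             up4 = c(1, 1, 4, 4))
  expr <- toy_expr(v, rep(c("a", "b"), each = 2))
  res <- compare_conditions(expr, "a", "b")
  expect_false(res$expressed[res$gene_id == "low"])
  expect_true(all(res$expressed[res$gene_id != "low"]))
  expect_equal(res$log2fc[res$gene_id == "flat"], 0)
  expect_equal(res$log2fc[res$gene_id == "up4"], 2)
  expect_error(compare_conditions(expr, "a", "nope"), "unknown condition")
})

test_that("DE selection uses strict cutoffs and drops unexpressed genes", {
  res <- data.frame(gene_id = c("exact", "just", "down", "dead"),
                    mean_a = c(1, 1, 4, 0.1), mean_b = c(2, 2.02, 1, 0.19),
                    log2fc = c(1, log2(2.02), -2, 1.5),
                    expressed = c(TRUE, TRUE, TRUE, FALSE))
  de <- select_de(res, cut = 1)
  expect_setequal(de$up, "just")
  expect_setequal(de$down, "down")
  expect_error(select_de(res, cut = 0), "positive")
})

test_that("conserved intersection requires the same sign everywhere", {
  mk <- function(up, down) structure(list(up = up, down = down,
                                          thresholds = c(log2fc_cut = 1)),
                                     class = "de_gene_set")
  s1 <- mk(c("a", "b", "c"), c("x"))
  s2 <- mk(c("a", "b"), c("x", "y"))
  s3 <- mk(c("a"), c("x", "b"))
  iv <- intersect_conserved(list(s1, s2, s3))
  expect_setequal(iv$up, "a")     # b flips sign in s3 -> excluded
  expect_setequal(iv$down, "x")
  expect_identical(intersect_conserved(list(s1, s1))[c("up", "down")],
                   s1[c("up", "down")])
  expect_error(intersect_conserved(list(s1)), "at least two")
  # brute-force tally oracle on random small sets
  set.seed(51)
  genes <- sprintf("g%02d", 1:30)
  for (rep in 1:20) {
    sets <- lapply(1:3, function(i) {
      labs <- sample(c("up", "down", "none"), 30, replace = TRUE)
      mk(genes[labs == "up"], genes[labs == "down"])
    })
    iv <- intersect_conserved(sets)
    tally_up <- genes[vapply(genes, function(g)
      all(vapply(sets, function(s) g %in% s$up, logical(1))), logical(1))]
    tally_down <- genes[vapply(genes, function(g)
      all(vapply(sets, function(s) g %in% s$down, logical(1))), logical(1))]
    expect_setequal(iv$up, tally_up)
    expect_setequal(iv$down, tally_down)
  }
})

test_that("zero-noise planted cohorts are recovered exactly", {
  ec <- gen_expression_cohorts(sim_config(seed = 8, noise_sd = 0))
  base <- names(ec$cohorts)[1]
  sets <- lapply(names(ec$cohorts)[-1], function(cond) {
    m <- combine_cohorts(ec$cohorts[[base]], ec$cohorts[[cond]])
    select_de(compare_conditions(m, base, cond))
  })
  iv <- intersect_conserved(sets)
  expect_setequal(iv$up, ec$truth$planted_de_ids_by_direction$up)
  expect_setequal(iv$down, ec$truth$planted_de_ids_by_direction$down)
})

test_that("null planted effect yields an (almost) empty intersection", {
  ec <- gen_expression_cohorts(sim_config(seed = 12, planted_log2fc = 0))
  base <- names(ec$cohorts)[1]
  sets <- lapply(names(ec$cohorts)[-1], function(cond) {
    m <- combine_cohorts(ec$cohorts[[base]], ec$cohorts[[cond]])
    select_de(compare_conditions(m, base, cond))
  })
  iv <- intersect_conserved(sets)
  expect_lte(length(iv$up) + length(iv$down), 2L)
})

test_that("prevalence ranking uses strict thresholds and counts correctly", {
  v <- rbind(at_floor = rep(0.2, 10),
             at_90pct = c(rep(1, 9), 0.1),
             common = c(rep(2, 10)),
             rich = rep(30, 10))
  expr <- toy_expr(v, rep("t", 10))
  expect_error(prevalence_rank(expr, character(0)), "empty")
  pr <- prevalence_rank(expr, rownames(v))
  # value == 0.2 is not an expression call; 90% exactly fails the > 90% rule
  expect_false("at_floor" %in% pr$gene_id)
  expect_false("at_90pct" %in% pr$gene_id)
  expect_equal(pr$gene_id, c("common", "rich"))  # ascending mean expression
  expect_equal(pr$rank, 1:2)
  # counting oracle on a random dropout pattern
  set.seed(61)
  v2 <- matrix(rexp(50 * 20), 50, dimnames = list(sprintf("g%02d", 1:50),
                                                  sprintf("s%02d", 1:20)))
  v2[sample(length(v2), 300)] <- 0
  expr2 <- toy_expr(v2, rep("t", 20))
  pr2 <- prevalence_rank(expr2, rownames(v2), min_frac = 0.5)
  direct <- apply(v2 > 0.2, 1L, mean)
  expect_equal(pr2$frac_expressed,
               unname(direct[pr2$gene_id]))
  expect_setequal(pr2$gene_id, names(direct)[direct > 0.5])
})

test_that("statistics-table thresholding applies BH and strict cuts", {
  stats_tab <- data.frame(gene_id = c("a", "b", "c"),
                          log2fc = c(0.58, 2, -2),
                          pvalue = c(1e-5, 1e-5, 1e-5))
  de <- threshold_de_table(stats_tab)
  expect_false("a" %in% de$up)   # 0.58 exactly fails the strict cut
  expect_setequal(de$up, "b")
  expect_setequal(de$down, "c")
  all_null <- data.frame(gene_id = letters[1:5], log2fc = rep(3, 5),
                         pvalue = rep(1, 5))
  de0 <- threshold_de_table(all_null)
  expect_length(de0$up, 0)
  expect_error(threshold_de_table(data.frame(gene_id = "a", log2fc = 1,
                                             pvalue = 1.4)), "\\[0,1\\]")
  # BH agrees with the textbook step-up on hand-set p-values
  set.seed(71)
  p <- round(runif(100), 3)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:100), log2fc = 1, pvalue = p)
  for (fc in c(0.2, 0.1, 0.05)) {
    got <- threshold_de_table(tab, log2_cut = 0.5, fdr_cut = fc)
    oracle <- tab$gene_id[brute_bh(p) < fc]
    expect_setequal(got$up, oracle)
  }
  # discoveries non-increasing in fdr_cut; at fdr_cut > 1 only the fc filter
  n_disc <- vapply(c(0.01, 0.05, 0.2, 1), function(fc)
    length(threshold_de_table(tab, log2_cut = 0.5, fdr_cut = fc)$up),
    numeric(1))
  expect_true(all(diff(n_disc) >= 0))
  expect_equal(length(threshold_de_table(tab, log2_cut = 0.5,
                                         fdr_cut = 1.0001)$up),
               sum(abs(tab$log2fc) > 0.5))
})
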