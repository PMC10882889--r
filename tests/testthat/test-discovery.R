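make_tx <- function(id, gene, starts, ends, strand = "+", chrom = "chr1") {
  data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
             strand = strand, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

test_that("annotation_set enforces its invariants", {
  expect_error(annotation_set(make_tx("t1", "g1", 10, 5)), "end < start")
  expect_error(annotation_set(make_tx("t1", "g1", c(1, 50), c(60, 100))),
               "overlapping exons")
  aset <- annotation_set(make_tx("t1", "g1", c(100, 300), c(200, 400)))
  tt <- transcript_table(aset)
  expect_equal(tt$length, 202L)
  expect_equal(tt$max_intron, 99L)
})

test_that("reference-overlap exclusion follows the >= 1 bp span rule", {
  ref <- annotation_set(make_tx("rt1", "rg1", 1000, 2000))
  inside <- make_tx("a_in", "x1", c(1200, 1500), c(1300, 1600))
  touching <- make_tx("a_touch", "x2", c(2000, 2300), c(2100, 2400))
  clear <- make_tx("a_clear", "x3", c(2001, 2300), c(2100, 2400))
  asm <- annotation_set(rbind(inside, touching, clear))
  kept <- exclude_known(asm, ref)
  expect_setequal(unique(kept$exons$transcript_id), "a_clear")
})

test_that("exclusion is strand-agnostic by default and stranded on request", {
  ref <- annotation_set(make_tx("rt1", "rg1", 1000, 2000, strand = "+"))
  asm <- annotation_set(make_tx("a1", "x1", c(1100, 1500), c(1200, 1700),
                                strand = "-"))
  expect_equal(nrow(exclude_known(asm, ref)$exons), 0L)
  expect_equal(unique(exclude_known(asm, ref, stranded = TRUE)$exons$transcript_id),
               "a1")
})

test_that("exclusion is idempotent and matches the pairwise brute force", {
  ann <- gen_annotation(sim_config(seed = 21))
  once <- exclude_known(ann$assembled, ann$reference)
  twice <- exclude_known(once, ann$reference)
  expect_identical(once, twice)
  excluded_oracle <- brute_overlapping_transcripts(ann$assembled, ann$reference)
  survivors_oracle <- setdiff(unique(ann$assembled$exons$transcript_id),
                              excluded_oracle)
  expect_setequal(unique(once$exons$transcript_id), survivors_oracle)
})

test_that("structural filter applies strict boundaries", {
  mono <- make_tx("mono", "g1", 100, 5099)                    # 5000 nt, 1 exon
  at200 <- make_tx("at200", "g2", c(100, 300), c(199, 399))   # exactly 200 nt
  minimal <- make_tx("pass", "g3", c(100, 212), c(200, 311))  # 201 nt, intron 11
  aset <- annotation_set(rbind(mono, at200, minimal))
  kept <- filter_structure(aset)
  expect_setequal(unique(kept$exons$transcript_id), "pass")
  # raising min_len never adds transcripts (monotonicity)
  for (cut in c(150, 250, 400)) {
    expect_true(all(unique(filter_structure(aset, min_len = cut)$exons$transcript_id)
                    %in% unique(filter_structure(aset, min_len = 100)$exons$transcript_id)))
  }
})

test_that("isoform merging equals connected components of the exon-overlap graph", {
  # two sharing an exon region, one disjoint
  t1 <- make_tx("t1", "g1", c(100, 500), c(300, 800))
  t2 <- make_tx("t2", "g2", c(250, 900), c(400, 1000))
  t3 <- make_tx("t3", "g3", c(5000, 5500), c(5200, 5800))
  aset <- annotation_set(rbind(t1, t2, t3))
  mg <- merge_isoforms(aset)
  expect_equal(length(unique(mg$members$locus_id)), 2L)
  expect_equal(mg$members$locus_id[mg$members$transcript_id == "t1"],
               mg$members$locus_id[mg$members$transcript_id == "t2"])
  # identical transcripts collapse to one locus with the same exon structure
  dup <- annotation_set(rbind(make_tx("a", "g1", c(10, 100), c(50, 200)),
                              make_tx("b", "g2", c(10, 100), c(50, 200))))
  mdup <- merge_isoforms(dup)
  expect_equal(length(unique(mdup$members$locus_id)), 1L)
  expect_equal(mdup$merged$exons$start, c(10L, 100L))
  expect_equal(mdup$merged$exons$end, c(50L, 200L))

  # randomized sets against the BFS oracle
  set.seed(17)
  for (rep in 1:5) {
    n <- 20L
    rows <- lapply(seq_len(n), function(i) {
      s <- sample.int(5000L, 1L)
      w1 <- sample(50:200, 1L); gap <- sample(20:200, 1L); w2 <- sample(50:200, 1L)
      make_tx(sprintf("tx%02d", i), sprintf("g%02d", i),
              c(s, s + w1 + gap), c(s + w1, s + w1 + gap + w2),
              strand = sample(c("+", "-", "*"), 1L))
    })
    aset <- annotation_set(do.call(rbind, rows))
    mg <- merge_isoforms(aset)
    oracle <- brute_locus_partition(aset)
    got <- mg$members$locus_id[match(names(oracle), mg$members$transcript_id)]
    # same partition: equal label co-membership
    expect_true(all((outer(got, got, "==") ==
                       outer(oracle, oracle, "=="))))
  }
})

test_that("unknown strand links transcripts on either strand into one locus", {
  plus <- make_tx("p", "g1", c(100, 300), c(200, 400), strand = "+")
  star <- make_tx("s", "g2", c(150, 350), c(250, 450), strand = "*")
  minus <- make_tx("m", "g3", c(160, 360), c(260, 460), strand = "-")
  mg <- merge_isoforms(annotation_set(rbind(plus, star, minus)))
  expect_equal(length(unique(mg$members$locus_id)), 1L)
  # without the unknown-strand bridge, opposite strands stay separate
  mg2 <- merge_isoforms(annotation_set(rbind(plus, minus)))
  expect_equal(length(unique(mg2$members$locus_id)), 2L)
})

test_that("ORF finding matches an independent six-frame scanner", {
  expect_equal(longest_orf("ATGAAATAA"), 9L)
  expect_equal(longest_orf("CCCCCCCCC"), 0L)
  expect_equal(longest_orf("ATGANATAA"), 0L)  # N breaks the ORF
  # reverse strand ORF: revcomp of ATGAAATAA
  expect_equal(longest_orf("TTATTTCAT"), 9L)
  set.seed(23)
  for (i in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 120, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                 collapse = "")
    expect_equal(longest_orf(seq), brute_longest_orf(seq), info = seq)
  }
})

test_that("coding-potential labels partition by the two evidence channels", {
  # no ATG anywhere: ncRNA with zero ORF
  rep_nc <- coding_potential(strrep("C", 600))
  expect_equal(rep_nc$orf_length, 0L)
  expect_identical(rep_nc$class_label, "ncRNA")
  # a 900-nt single ORF with a matching motif in frame 1: coding
  body <- strrep("GCT", 298)                      # alanine repeat
  seq <- paste0("ATG", body, "TAA")
  prot_motif <- "AAAAA"                           # poly-alanine
  rep_cod <- coding_potential(seq, motifs = prot_motif)
  expect_equal(rep_cod$orf_length, nchar(seq))
  expect_equal(rep_cod$orf_coverage, 1)
  expect_true(rep_cod$motif_hit)
  expect_identical(rep_cod$class_label, "coding")
  # ORF evidence without motif evidence: TUCP
  rep_tucp <- coding_potential(seq)
  expect_identical(rep_tucp$class_label, "TUCP")
  # motif without ORF evidence: TUCP from the other side
  rep_tucp2 <- coding_potential(strrep("GCT", 60), motifs = prot_motif)
  expect_identical(rep_tucp2$class_label, "TUCP")
  expect_error(coding_potential(""), "empty")
})

test_that("classification frequencies match a re-derivation of the rules", {
  set.seed(31)
  for (i in 1:40) {
    seq <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                 collapse = "")
    rep <- coding_potential(seq)
    orf <- brute_longest_orf(seq)
    orf_rule <- orf >= 300 || (orf / 1000 >= 0.5 && rep$fickett_score >= 0.95)
    expected <- if (orf_rule) "TUCP" else "ncRNA"   # no motifs supplied
    expect_identical(rep$class_label, expected)
    expect_equal(rep$orf_length, orf)
  }
})

test_that("every candidate receives exactly one class label", {
  ann <- gen_annotation(sim_config(seed = 33))
  disc <- discover_lncrna(ann$assembled, ann$reference)
  set.seed(33)
  seqs <- vapply(disc$candidates$transcript_id, function(id) {
    paste(sample(c("A", "C", "G", "T"),
                 disc$candidates$length[disc$candidates$transcript_id == id],
                 replace = TRUE), collapse = "")
  }, character(1))
  disc2 <- discover_lncrna(ann$assembled, ann$reference, sequences = seqs)
  expect_true(all(disc2$candidates$class_label %in%
                    c("coding", "ncRNA", "TUCP")))
})
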