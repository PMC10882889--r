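# Independent oracles used to check the package implementations. These are
# deliberately written with different algorithms/data structures than the
# package code paths they verify.

# Brute-force UPGMA: cluster distance = mean pairwise distance between the
# original items (O(n^3)); returns the cophenetic distance matrix.
brute_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best_d) { best_d <- avg; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1L]]]; b <- clusters[[best[2L]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1L]]] <- c(a, b)
    clusters[[best[2L]]] <- NULL
  }
  coph
}

# Interval-overlap brute force: transcripts (by span) overlapping any gene
# span by >= 1 bp, checked pair by pair.
brute_overlapping_transcripts <- function(assembled, reference) {
  tt <- transcript_table(assembled)
  gs <- gene_spans(reference)
  hit <- logical(nrow(tt))
  for (i in seq_len(nrow(tt))) {
    for (j in seq_len(nrow(gs))) {
      if (tt$chrom[i] == gs$chrom[j] &&
          tt$start[i] <= gs$end[j] && gs$start[j] <= tt$end[i]) {
        hit[i] <- TRUE
        break
      }
    }
  }
  tt$transcript_id[hit]
}

# Independent six-frame ORF scan: for every ATG, walk forward codon by codon
# to the first stop (N-containing codons kill the walk).
brute_longest_orf <- function(seq) {
  seq <- toupper(seq)
  revcomp <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
                   collapse = "")
  best <- 0L
  for (s in c(seq, revcomp)) {
    n <- nchar(s)
    for (start in seq_len(max(n - 2L, 0L))) {
      if (substr(s, start, start + 2L) != "ATG") next
      pos <- start
      while (pos + 2L <= n) {
        cod <- substr(s, pos, pos + 2L)
        if (grepl("N", cod)) break
        if (cod %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, pos + 3L - start)
          break
        }
        pos <- pos + 3L
      }
    }
  }
  best
}

# Connected components of the same-strand exonic-overlap graph, by BFS over
# an explicit adjacency matrix.
brute_locus_partition <- function(candidates) {
  tt <- transcript_table(candidates)
  ex <- candidates$exons
  ids <- tt$transcript_id
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  strands_ok <- function(s1, s2) s1 == "*" || s2 == "*" || s1 == s2
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { adj[i, j] <- TRUE; next }
      ei <- ex[ex$transcript_id == ids[i], ]
      ej <- ex[ex$transcript_id == ids[j], ]
      if (!strands_ok(tt$strand[i], tt$strand[j])) next
      for (a in seq_len(nrow(ei))) {
        for (b in seq_len(nrow(ej))) {
          if (ei$chrom[a] == ej$chrom[b] &&
              ei$start[a] <= ej$end[b] && ej$start[b] <= ei$end[a]) {
            adj[i, j] <- TRUE
          }
        }
      }
    }
  }
  comp <- integer(n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  stats::setNames(comp, ids)
}

# Textbook Benjamini-Hochberg step-up.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Merge two single-condition expression matrices into one.
combine_cohorts <- function(...) {
  mats <- list(...)
  expression_matrix(do.call(cbind, lapply(mats, `[[`, "values")),
                    unit = mats[[1]]$unit,
                    sample_meta = do.call(rbind, lapply(mats, `[[`, "sample_meta")))
}

# Vectorized global-null DE stats table: per gene, two groups of n normal
# observations; pooled-variance t-test computed from closed forms.
null_de_stats <- function(n_genes, n_per_group = 3L, sd = 1) {
  a <- matrix(rnorm(n_genes * n_per_group, sd = sd), n_genes)
  b <- matrix(rnorm(n_genes * n_per_group, sd = sd), n_genes)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, var); vb <- apply(b, 1L, var)
  sp <- sqrt(((n_per_group - 1) * (va + vb)) / (2 * n_per_group - 2))
  t_stat <- (mb - ma) / (sp * sqrt(2 / n_per_group))
  data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
             log2fc = mb - ma,
             pvalue = 2 * pt(-abs(t_stat), df = 2 * n_per_group - 2))
}
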