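#' Exclude assembled transcripts that overlap known genes
#'
#' First step of the candidate-lncRNA discovery cascade: any assembled
#' transcript whose genomic footprint overlaps a reference gene interval by
#' at least 1 bp is removed as "known". By default the gene interval is the
#' union hull of the gene's transcripts (span) and overlap is strand-agnostic
#' — the most conservative, most-excluding reading; both choices are
#' configurable.
#'
#' @param assembled,reference `annotation_set` objects sharing a coordinate
#'   system.
#' @param overlap `"span"` (assembled transcript span vs reference gene span)
#'   or `"exon"` (assembled exons vs reference gene span).
#' @param stranded If `TRUE`, only same-strand overlap excludes; transcripts
#'   of unknown strand (`"*"`) match either strand.
#' @return An `annotation_set` with the surviving assembled transcripts;
#'   the inputs are not modified.
#' @export
exclude_known <- function(assembled, reference,
                          overlap = c("span", "exon"), stranded = FALSE) {
  overlap <- match.arg(overlap)
  stopifnot(inherits(assembled, "annotation_set"),
            inherits(reference, "annotation_set"))
  ref_gr <- gene_granges(reference)
  qry <- if (overlap == "span") span_granges(assembled) else exon_granges(assembled)
  hits <- GenomicRanges::findOverlaps(qry, ref_gr, minoverlap = 1L,
                                      ignore.strand = !stranded)
  hit_tx <- unique(qry$transcript_id[S4Vectors::queryHits(hits)])
  keep <- !(assembled$exons$transcript_id %in% hit_tx)
  annotation_set(assembled$exons[keep, , drop = FALSE])
}

#' Structural filter for candidate lncRNAs
#'
#' Keeps multi-exonic transcripts (>= 2 exons) whose summed exon length is
#' strictly greater than `min_len` and which have at least one intron
#' strictly longer than `min_intron`. Mono-exonic models and short or
#' intron-less fragments are treated as transcriptional noise.
#'
#' @param candidates An `annotation_set`.
#' @param min_len Minimum transcript length in nt (exclusive; default 200).
#' @param min_intron Minimum intron length in nt (exclusive; default 10).
#' @return A filtered `annotation_set`.
#' @export
filter_structure <- function(candidates, min_len = 200L, min_intron = 10L) {
  stopifnot(inherits(candidates, "annotation_set"))
  tt <- transcript_table(candidates)
  keep_ids <- tt$transcript_id[tt$n_exons >= 2L &
                               tt$length > min_len &
                               tt$max_intron > min_intron]
  keep <- candidates$exons$transcript_id %in% keep_ids
  annotation_set(candidates$exons[keep, , drop = FALSE])
}

#' Merge isoforms into loci
#'
#' Groups transcripts into loci by single linkage on exonic overlap on the
#' same strand (unknown strand `"*"` matches either), i.e. the connected
#' components of the exon-overlap graph. Each locus is reported as one merged
#' model whose exon set is the union of the member exons (overlapping exons
#' coalesced), under a new locus id assigned in genomic order.
#'
#' @param candidates An `annotation_set` (normally after [filter_structure()]).
#' @return A list with `merged` (an `annotation_set` of one model per locus)
#'   and `members` (data.frame mapping `transcript_id` to `locus_id`).
#' @export
merge_isoforms <- function(candidates) {
  stopifnot(inherits(candidates, "annotation_set"))
  ex <- candidates$exons
  tx_ids <- unique(ex$transcript_id)
  if (length(tx_ids) == 0L) {
    return(list(merged = annotation_set(ex),
                members = data.frame(transcript_id = character(0),
                                     locus_id = character(0))))
  }
  exgr <- exon_granges(candidates)
  # '*' strands are compatible with both '+' and '-' under stranded overlap
  hits <- GenomicRanges::findOverlaps(exgr, ignore.strand = FALSE,
                                      drop.self = FALSE, drop.redundant = TRUE)
  from <- match(exgr$transcript_id[S4Vectors::queryHits(hits)], tx_ids)
  to <- match(exgr$transcript_id[S4Vectors::subjectHits(hits)], tx_ids)
  g <- igraph::make_graph(rbind(from, to), n = length(tx_ids), directed = FALSE)
  comp <- igraph::components(g)$membership
  # locus ids in genomic order of each component's leftmost exon
  tt <- transcript_table(candidates)
  tt <- tt[match(tx_ids, tt$transcript_id), ]
  comp_start <- tapply(tt$start, comp, min)
  comp_chrom <- tapply(tt$chrom, comp, function(ch) sort(ch)[1L])
  ord <- order(comp_chrom, comp_start)
  locus_of_comp <- integer(length(ord))
  locus_of_comp[ord] <- seq_along(ord)
  locus_ids <- sprintf("LOC_%06d", locus_of_comp[comp])
  members <- data.frame(transcript_id = tx_ids, locus_id = locus_ids,
                        stringsAsFactors = FALSE)
  merged_ex <- do.call(rbind, lapply(split(tx_ids, locus_ids), function(ids) {
    sub <- ex[ex$transcript_id %in% ids, , drop = FALSE]
    red <- GenomicRanges::reduce(
      GenomicRanges::GRanges(sub$chrom,
                             IRanges::IRanges(sub$start, sub$end)),
      ignore.strand = TRUE)
    strands <- setdiff(unique(sub$strand), "*")
    data.frame(
      transcript_id = NA_character_,
      gene_id = NA_character_,
      chrom = as.character(GenomicRanges::seqnames(red)),
      strand = if (length(strands) == 1L) strands else "*",
      start = GenomicRanges::start(red),
      end = GenomicRanges::end(red),
      stringsAsFactors = FALSE
    )
  }))
  locus_levels <- sort(unique(locus_ids))
  n_per <- vapply(split(tx_ids, locus_ids), function(ids) {
    sub <- ex[ex$transcript_id %in% ids, , drop = FALSE]
    length(GenomicRanges::reduce(
      GenomicRanges::GRanges(sub$chrom, IRanges::IRanges(sub$start, sub$end)),
      ignore.strand = TRUE))
  }, integer(1L))
  merged_ex$transcript_id <- rep(locus_levels, n_per)
  merged_ex$gene_id <- merged_ex$transcript_id
  list(merged = annotation_set(merged_ex), members = members)
}

# ---- coding potential -------------------------------------------------------

# Fickett TESTCODE lookup tables (position and composition parameters), as
# published for the original TESTCODE statistic. Thresholds are descending;
# a parameter value maps to the probability at the first threshold it meets.
.fickett_pos_thresholds <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0)
.fickett_cont_thresholds <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0)
.fickett_pos_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
.fickett_cont_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.58, 0.44, 0.51, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
.fickett_pos_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
.fickett_cont_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

#' Fickett TESTCODE score of a nucleotide sequence
#'
#' Combines, for each base, a position parameter (periodicity of the base
#' across the three codon positions, max/(min+1)) and a composition parameter
#' (base frequency), each converted to a coding probability by the published
#' lookup tables and combined with the published weights. Higher scores
#' indicate protein-coding-like periodicity; the classical coding call is
#' score >= 0.95.
#'
#' @param seq Character scalar over A/C/G/T/N (N is ignored in the counts).
#' @return Numeric score.
#' @export
fickett_score <- function(seq) {
  seq <- toupper(as.character(seq))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  chars <- chars[chars %in% c("A", "C", "G", "T")]
  if (length(chars) == 0L) return(0)
  pos <- (seq_along(chars) - 1L) %% 3L
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    counts <- vapply(0:2, function(p) sum(chars[pos == p] == b), numeric(1L))
    pos_par <- max(counts) / (min(counts) + 1)
    cont_par <- sum(counts) / length(chars)
    pi <- which(pos_par >= .fickett_pos_thresholds)[1L]
    ci <- which(cont_par >= .fickett_cont_thresholds)[1L]
    score <- score + .fickett_pos_prob[[b]][pi] * .fickett_pos_weight[[b]] +
      .fickett_cont_prob[[b]][ci] * .fickett_cont_weight[[b]]
  }
  score
}

# Longest complete ORF (ATG..stop, inclusive of the stop codon, in nt) in one
# reading frame given as a codon character vector. Codons containing N break
# any open ORF without completing it.
.longest_orf_in_frame <- function(codons) {
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  open_at <- NA_integer_
  for (i in seq_along(codons)) {
    cod <- codons[i]
    if (grepl("N", cod, fixed = TRUE)) {
      open_at <- NA_integer_
      next
    }
    if (is.na(open_at)) {
      if (cod == "ATG") open_at <- i
    } else if (cod %in% stops) {
      best <- max(best, (i - open_at + 1L) * 3L)
      open_at <- NA_integer_
    }
  }
  best
}

.frame_codons <- function(seq_chars, offset) {
  n <- length(seq_chars)
  usable <- n - offset
  n_cod <- usable %/% 3L
  if (n_cod == 0L) return(character(0))
  idx <- offset + seq_len(n_cod * 3L)
  m <- matrix(seq_chars[idx], nrow = 3L)
  paste0(m[1L, ], m[2L, ], m[3L, ])
}

#' Longest complete ORF over all six reading frames
#'
#' @param seq Character scalar or `DNAString` over A/C/G/T/N.
#' @return Length in nt (ATG through stop codon inclusive) of the longest
#'   complete ORF; 0 if none. N bases break ORFs.
#' @export
longest_orf <- function(seq) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) stop("empty sequence")
  fwd <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (!all(fwd %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence must be over A/C/G/T/N")
  }
  rev <- rev(chartr("ACGT", "TGCA", fwd))
  best <- 0L
  for (chars in list(fwd, rev)) {
    for (off in 0:2) {
      best <- max(best, .longest_orf_in_frame(.frame_codons(chars, off)))
    }
  }
  best
}

# six-frame translations (stop = '*', fuzzy codons = 'X')
.six_frame_proteins <- function(seq) {
  d <- Biostrings::DNAString(seq)
  r <- Biostrings::reverseComplement(d)
  out <- character(0)
  for (s in list(d, r)) {
    for (off in 0:2) {
      n <- length(s) - off
      n <- n - n %% 3L
      if (n < 3L) next
      sub <- Biostrings::subseq(s, start = off + 1L, width = n)
      out <- c(out, as.character(
        Biostrings::translate(sub, if.fuzzy.codon = "X")))
    }
  }
  out
}

#' Rule-based coding-potential classification of a transcript sequence
#'
#' A transparent two-channel classifier. Channel 1 (ORF evidence) fires when
#' the longest complete ORF is at least `orf_min` nt, or when the ORF covers
#' at least `cov_min` of the transcript and the Fickett TESTCODE score is at
#' least `fickett_min`. Channel 2 (domain evidence) fires when any supplied
#' protein motif matches any of the six translated frames. Labels: `coding`
#' when both channels fire, `ncRNA` when neither does, `TUCP` (transcript of
#' unknown coding potential) when exactly one does.
#'
#' @param seq Character scalar or `DNAString` over A/C/G/T/N.
#' @param motifs Character vector of amino-acid motifs (exact substrings of a
#'   translated frame); may be empty.
#' @param orf_min,cov_min,fickett_min Classifier thresholds (nt, fraction,
#'   score).
#' @return A one-row data.frame: `orf_length`, `orf_coverage`,
#'   `fickett_score`, `motif_hit`, `class_label`.
#' @export
coding_potential <- function(seq, motifs = character(0), orf_min = 300L,
                             cov_min = 0.5, fickett_min = 0.95) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) == 0L) stop("empty sequence")
  orf_len <- longest_orf(seq)
  cov <- orf_len / nchar(seq)
  fick <- fickett_score(seq)
  hit <- FALSE
  if (length(motifs) > 0L) {
    prots <- .six_frame_proteins(seq)
    hit <- any(vapply(motifs, function(m) any(grepl(m, prots, fixed = TRUE)),
                      logical(1L)))
  }
  orf_rule <- (orf_len >= orf_min) || (cov >= cov_min && fick >= fickett_min)
  label <- if (orf_rule && hit) "coding" else if (!orf_rule && !hit) "ncRNA" else "TUCP"
  data.frame(orf_length = orf_len, orf_coverage = cov, fickett_score = fick,
             motif_hit = hit, class_label = label, stringsAsFactors = FALSE)
}

#' Run the full candidate-lncRNA discovery cascade
#'
#' Reference-overlap exclusion, structural filtering, isoform merging and —
#' when transcript sequences are supplied — coding-potential classification.
#'
#' @param assembled,reference `annotation_set` objects.
#' @param sequences Optional named character vector (or `DNAStringSet`) of
#'   transcript sequences keyed by transcript id.
#' @param motifs Protein motifs for the domain channel of
#'   [coding_potential()].
#' @inheritParams exclude_known
#' @inheritParams filter_structure
#' @return A list of class `lnc_discovery`: `candidates` (per-transcript
#'   table with locus assignment, structure metrics and, if classified,
#'   `class_label`), `merged` and `members` from [merge_isoforms()].
#' @export
discover_lncrna <- function(assembled, reference, sequences = NULL,
                            motifs = character(0), min_len = 200L,
                            min_intron = 10L, overlap = "span",
                            stranded = FALSE) {
  novel <- exclude_known(assembled, reference, overlap = overlap,
                         stranded = stranded)
  kept <- filter_structure(novel, min_len = min_len, min_intron = min_intron)
  mg <- merge_isoforms(kept)
  cand <- transcript_table(kept)
  cand$locus_id <- mg$members$locus_id[match(cand$transcript_id,
                                             mg$members$transcript_id)]
  if (!is.null(sequences) && nrow(cand) > 0L) {
    seqs <- stats::setNames(as.character(sequences), names(sequences))
    rep_list <- lapply(cand$transcript_id, function(id) {
      if (is.na(seqs[id])) stop("no sequence supplied for ", id)
      coding_potential(seqs[[id]], motifs = motifs)
    })
    cand <- cbind(cand, do.call(rbind, rep_list))
  } else {
    cand$class_label <- rep(NA_character_, nrow(cand))
  }
  structure(list(candidates = cand, merged = mg$merged, members = mg$members),
            class = "lnc_discovery")
}

#' @export
print.lnc_discovery <- function(x, ...) {
  cat("<lnc_discovery> ", nrow(x$candidates), " candidate transcripts in ",
      length(unique(x$candidates$locus_id)), " loci\n", sep = "")
  invisible(x)
}
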