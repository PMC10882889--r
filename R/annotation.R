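#' Construct an annotation set
#'
#' An annotation set is the package's container for exon-structured transcript
#' models: one row per exon, grouped by transcript, in GTF convention
#' (1-based, inclusive coordinates). It is the substrate of the lncRNA
#' discovery cascade.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` (`"+"`, `"-"` or `"*"` for unknown), `start`, `end`. Exons of a
#'   transcript must be non-overlapping; they are sorted by `start` on
#'   construction.
#'
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(exons) {
  required <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0L) {
    stop("exon table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  exons <- as.data.frame(exons)[required]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(is.na(exons$start)) || any(is.na(exons$end))) {
    stop("exon coordinates must be integer and non-missing")
  }
  if (any(exons$end < exons$start)) {
    bad <- exons$transcript_id[exons$end < exons$start][1L]
    stop("exon with end < start in transcript ", bad)
  }
  if (!all(exons$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  # per-transcript sanity: one chrom/strand, non-overlapping exons
  by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (idx in by_tx) {
    if (length(unique(exons$chrom[idx])) != 1L ||
        length(unique(exons$strand[idx])) != 1L) {
      stop("transcript ", exons$transcript_id[idx[1L]],
           " spans multiple chromosomes or strands")
    }
    if (length(idx) > 1L) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (any(s[-1L] <= e[-length(e)])) {
        stop("overlapping exons in transcript ", exons$transcript_id[idx[1L]])
      }
    }
  }
  structure(list(exons = exons), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  n_tx <- length(unique(x$exons$transcript_id))
  cat("<annotation_set> ", n_tx, " transcripts, ",
      length(unique(x$exons$gene_id)), " genes, ",
      nrow(x$exons), " exons\n", sep = "")
  invisible(x)
}

#' Per-transcript summary of an annotation set
#'
#' @param x An `annotation_set`.
#' @return data.frame with one row per transcript: span (`start`, `end`),
#'   `n_exons`, summed exonic `length`, and `max_intron` (0 for mono-exonic
#'   transcripts). Intron length between consecutive exons i, i+1 is
#'   `start[i+1] - end[i] - 1`.
#' @export
transcript_table <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  ex <- x$exons
  by_tx <- split(seq_len(nrow(ex)), ex$transcript_id)
  ids <- names(by_tx)
  res <- lapply(by_tx, function(idx) {
    s <- ex$start[idx]; e <- ex$end[idx]
    introns <- if (length(idx) > 1L) s[-1L] - e[-length(e)] - 1L else integer(0)
    data.frame(
      gene_id = ex$gene_id[idx[1L]],
      chrom = ex$chrom[idx[1L]],
      strand = ex$strand[idx[1L]],
      start = min(s), end = max(e),
      n_exons = length(idx),
      length = sum(e - s + 1L),
      max_intron = if (length(introns)) max(introns) else 0L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(transcript_id = ids, stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Gene spans (union hull of each gene's transcripts)
#'
#' @param x An `annotation_set`.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`.
#' @export
gene_spans <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  ex <- x$exons
  by_gene <- split(seq_len(nrow(ex)), ex$gene_id)
  out <- do.call(rbind, lapply(by_gene, function(idx) {
    data.frame(
      chrom = ex$chrom[idx[1L]],
      strand = if (length(unique(ex$strand[idx])) == 1L) ex$strand[idx[1L]] else "*",
      start = min(ex$start[idx]),
      end = max(ex$end[idx]),
      stringsAsFactors = FALSE
    )
  }))
  out <- cbind(data.frame(gene_id = names(by_gene), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

# GRanges views of an annotation set; used by the discovery stage.
exon_granges <- function(x) {
  ex <- x$exons
  GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start, end = ex$end),
    strand = ex$strand,
    transcript_id = ex$transcript_id,
    gene_id = ex$gene_id
  )
}

span_granges <- function(x) {
  tt <- transcript_table(x)
  GenomicRanges::GRanges(
    seqnames = tt$chrom,
    ranges = IRanges::IRanges(start = tt$start, end = tt$end),
    strand = tt$strand,
    transcript_id = tt$transcript_id,
    gene_id = tt$gene_id
  )
}

gene_granges <- function(x) {
  gs <- gene_spans(x)
  GenomicRanges::GRanges(
    seqnames = gs$chrom,
    ranges = IRanges::IRanges(start = gs$start, end = gs$end),
    strand = gs$strand,
    gene_id = gs$gene_id
  )
}

#' Write an annotation set to GTF
#'
#' Exon features only, 1-based inclusive coordinates, attributes `gene_id`
#' and `transcript_id`. Output is deterministic (fixed row order), so
#' identical inputs give byte-identical files.
#'
#' @param x An `annotation_set`.
#' @param path Output file path.
#' @param source Value of the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(x, path, source = "lncscreen") {
  stopifnot(inherits(x, "annotation_set"))
  ex <- x$exons
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";', ex$gene_id, ex$transcript_id)
  lines <- paste(ex$chrom, source, "exon", ex$start, ex$end, ".",
                 ex$strand, ".", attrs, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF file into an annotation set
#'
#' Uses \pkg{rtracklayer} when available, otherwise a minimal reader for the
#' exon rows this package writes.
#'
#' @param path GTF file path.
#' @return An `annotation_set` built from the exon features.
#' @export
read_gtf <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[as.character(gr$type) == "exon"]
    ex <- data.frame(
      transcript_id = as.character(gr$transcript_id),
      gene_id = as.character(gr$gene_id),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = sub("^\\.$", "*", as.character(GenomicRanges::strand(gr))),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
    return(annotation_set(ex))
  }
  raw <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                           stringsAsFactors = FALSE)
  raw <- raw[raw[[3L]] == "exon", , drop = FALSE]
  get_attr <- function(a, key) {
    m <- regmatches(a, regexpr(paste0(key, ' "[^"]+"'), a))
    sub(paste0(key, ' "([^"]+)"'), "\\1", m)
  }
  annotation_set(data.frame(
    transcript_id = get_attr(raw[[9L]], "transcript_id"),
    gene_id = get_attr(raw[[9L]], "gene_id"),
    chrom = raw[[1L]],
    strand = ifelse(raw[[7L]] %in% c("+", "-"), raw[[7L]], "*"),
    start = raw[[4L]],
    end = raw[[5L]],
    stringsAsFactors = FALSE
  ))
}
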