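#' Genome coordinate model
#'
#' A `genome_annotation` holds the replicon sequences and a flat table of
#' stranded gene features in 1-based inclusive coordinates (GFF3 convention).
#' It is the coordinate frame for every downstream stage: TSS classification,
#' 5'-UTR extraction and promoter windows are all computed against it.
#'
#' @name genome_model
NULL

FEATURE_CLASSES <- c("CDS", "tRNA", "rRNA", "sRNA", "other_ncRNA")
NCRNA_CLASSES <- c("tRNA", "rRNA", "sRNA", "other_ncRNA")

# GFF3 `type` column -> internal feature class
gff3_type_map <- c(
  CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", sRNA = "sRNA",
  ncRNA = "other_ncRNA", antisense_RNA = "other_ncRNA",
  tmRNA = "other_ncRNA", RNase_P_RNA = "other_ncRNA", SRP_RNA = "other_ncRNA"
)

#' Construct a genome annotation object
#'
#' Low-level constructor used by [parse_genome_annotation()] and the synthetic
#' generator. Validates the invariants: unique replicon ids, features within
#' replicon bounds, `start <= end`.
#'
#' @param replicons data.frame with columns `replicon_id`, `length`,
#'   `sequence` (upper-case DNA string, may be `NA` when only coordinates are
#'   needed).
#' @param genes data.frame with columns `gene_id`, `replicon_id`, `start`,
#'   `end`, `strand`, `feature_class`.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(replicons, genes) {
  replicons <- as.data.frame(replicons, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  stopifnot(all(c("replicon_id", "length") %in% names(replicons)))
  if (is.null(replicons$sequence)) replicons$sequence <- NA_character_
  if (anyDuplicated(replicons$replicon_id)) {
    stop("replicon ids must be unique", call. = FALSE)
  }
  need <- c("gene_id", "replicon_id", "start", "end", "strand", "feature_class")
  if (nrow(genes) > 0) {
    stopifnot(all(need %in% names(genes)))
    check_strand(genes$strand)
    if (!all(genes$feature_class %in% FEATURE_CLASSES)) {
      stop("unknown feature_class: ",
           paste(setdiff(genes$feature_class, FEATURE_CLASSES), collapse = ", "),
           call. = FALSE)
    }
    bad <- setdiff(genes$replicon_id, replicons$replicon_id)
    if (length(bad) > 0) {
      stop("gene replicon id not in genome: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(genes$start > genes$end)) {
      stop("gene start > end", call. = FALSE)
    }
    len <- replicons$length[match(genes$replicon_id, replicons$replicon_id)]
    if (any(genes$start < 1) || any(genes$end > len)) {
      i <- which(genes$start < 1 | genes$end > len)[1]
      stop(sprintf("gene '%s' extends outside replicon '%s' (1..%d)",
                   genes$gene_id[i], genes$replicon_id[i], len[i]),
           call. = FALSE)
    }
  } else {
    genes <- data.frame(gene_id = character(), replicon_id = character(),
                        start = integer(), end = integer(),
                        strand = character(), feature_class = character(),
                        stringsAsFactors = FALSE)
  }
  structure(list(replicons = replicons, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d replicon(s), %d gene feature(s)\n",
              nrow(x$replicons), nrow(x$genes)))
  for (i in seq_len(nrow(x$replicons))) {
    cat(sprintf("  %s  %d bp\n", x$replicons$replicon_id[i],
                x$replicons$length[i]))
  }
  invisible(x)
}

#' Parse genome FASTA and GFF3 annotation
#'
#' Reads a (multi-record) FASTA and a GFF3 file into a [genome_annotation].
#' One feature is kept per annotated gene; the feature class is inferred from
#' the GFF3 `type` column (`CDS`, `tRNA`, `rRNA`, `sRNA`, `ncRNA`, ...).
#' `gene` container rows are ignored in favour of their typed children.
#'
#' @param fasta_path path to the genome FASTA; record ids must match the GFF3
#'   seqid column.
#' @param gff3_path path to the GFF3 annotation.
#' @return A [genome_annotation].
#' @export
parse_genome_annotation <- function(fasta_path, gff3_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  replicons <- data.frame(
    replicon_id = ids,
    length = Biostrings::width(seqs),
    sequence = toupper(as.character(seqs)),
    stringsAsFactors = FALSE
  )
  validate_gff3_lines(gff3_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  keep <- as.character(gr$type) %in% names(gff3_type_map)
  gr <- gr[keep]
  seqid <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(seqid), replicons$replicon_id)
  if (length(bad) > 0) {
    stop("GFF3 seqid not present in FASTA: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  gene_id <- gff3_feature_id(gr)
  genes <- data.frame(
    gene_id = gene_id,
    replicon_id = seqid,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_class = unname(gff3_type_map[as.character(gr$type)]),
    stringsAsFactors = FALSE
  )
  genome_annotation(replicons, genes)
}

gff3_feature_id <- function(gr) {
  meta <- S4Vectors::mcols(gr)
  pick <- function(col) {
    if (col %in% names(meta)) as.character(meta[[col]]) else
      rep(NA_character_, length(gr))
  }
  id <- pick("locus_tag")
  for (col in c("ID", "Name", "gene")) {
    alt <- pick(col)
    id <- ifelse(is.na(id) | id == "", alt, id)
  }
  miss <- is.na(id) | id == ""
  id[miss] <- sprintf("feature_%05d", which(miss))
  id
}

# Structural pre-check so coordinate errors can name the offending line;
# rtracklayer's parser does the real work afterwards.
validate_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 8) {
      stop(sprintf("malformed GFF3 line %d: fewer than 8 fields", i),
           call. = FALSE)
    }
    if (is.na(suppressWarnings(as.integer(fields[4]))) ||
        is.na(suppressWarnings(as.integer(fields[5])))) {
      stop(sprintf("malformed coordinate on GFF3 line %d", i), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a genome annotation back to FASTA/GFF3
#'
#' @param annotation a [genome_annotation].
#' @param gff3_path output GFF3 path.
#' @param fasta_path optional output FASTA path.
#' @export
write_genome_annotation <- function(annotation, gff3_path, fasta_path = NULL) {
  g <- annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$replicon_id,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand
  )
  # emit the GFF3 type that maps back onto the same feature class
  inv <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", sRNA = "sRNA",
           other_ncRNA = "ncRNA")
  gr$type <- unname(inv[g$feature_class])
  gr$phase <- ifelse(g$feature_class == "CDS", 0L, NA_integer_)
  gr$ID <- g$gene_id
  gr$locus_tag <- g$gene_id
  rtracklayer::export(gr, gff3_path, format = "gff3")
  if (!is.null(fasta_path)) {
    ss <- Biostrings::DNAStringSet(annotation$replicons$sequence)
    names(ss) <- annotation$replicons$replicon_id
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  invisible(gff3_path)
}

replicon_sequence <- function(annotation, replicon_id) {
  i <- match(replicon_id, annotation$replicons$replicon_id)
  if (is.na(i)) stop("unknown replicon: ", replicon_id, call. = FALSE)
  annotation$replicons$sequence[i]
}

replicon_length <- function(annotation, replicon_id) {
  i <- match(replicon_id, annotation$replicons$replicon_id)
  if (is.na(i)) stop("unknown replicon: ", replicon_id, call. = FALSE)
  annotation$replicons$length[i]
}

# strand-aware gene start (first transcribed base of the feature)
gene_start_pos <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end)
}

#' Extract a 5'-UTR sequence
#'
#' Returns the transcribed-strand sequence between a TSS and the base before
#' the start codon of its gene, plus its length in nt. A TSS at the start
#' codon gives a zero-length (leaderless) UTR.
#'
#' @param annotation a [genome_annotation].
#' @param gene_id gene identifier in the annotation.
#' @param tss_position 1-based TSS position; must not lie downstream of the
#'   gene start on the gene's strand.
#' @return list with `sequence` (character) and `length` (integer, nt).
#' @export
extract_five_prime_utr <- function(annotation, gene_id, tss_position) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0) stop("unknown gene: ", gene_id, call. = FALSE)
  g <- g[1, ]
  seq <- replicon_sequence(annotation, g$replicon_id)
  if (g$strand == "+") {
    len <- g$start - tss_position
    if (len < 0) stop("TSS lies downstream of the start codon", call. = FALSE)
    s <- if (len == 0) "" else substr(seq, tss_position, g$start - 1L)
  } else {
    len <- tss_position - g$end
    if (len < 0) stop("TSS lies downstream of the start codon", call. = FALSE)
    s <- if (len == 0) "" else revcomp(substr(seq, g$end + 1L, tss_position))
  }
  list(sequence = s, length = as.integer(len))
}

#' Extract a promoter region upstream of a TSS
#'
#' Returns `window` nt of transcribed-strand sequence ending at the base
#' immediately upstream of the TSS (TSS - 1 on its strand). Windows running
#' past the replicon edge are truncated and flagged.
#'
#' @param annotation a [genome_annotation].
#' @param replicon_id replicon holding the TSS.
#' @param tss_position 1-based TSS position (must lie inside the replicon).
#' @param strand `"+"` or `"-"`.
#' @param window upstream window size in nt (default 200).
#' @return list with `sequence` and logical `truncated`.
#' @export
extract_promoter_region <- function(annotation, replicon_id, tss_position,
                                    strand, window = 200L) {
  stopifnot(window >= 1)
  check_strand(strand)
  len <- replicon_length(annotation, replicon_id)
  if (tss_position < 1 || tss_position > len) {
    stop("TSS outside replicon bounds", call. = FALSE)
  }
  seq <- replicon_sequence(annotation, replicon_id)
  if (strand == "+") {
    from <- max(1L, tss_position - window)
    to <- tss_position - 1L
    truncated <- from > tss_position - window
    s <- if (to < from) "" else substr(seq, from, to)
  } else {
    from <- tss_position + 1L
    to <- min(len, tss_position + window)
    truncated <- to < tss_position + window
    s <- if (to < from) "" else revcomp(substr(seq, from, to))
  }
  list(sequence = s, truncated = truncated)
}
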