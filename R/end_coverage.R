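#' Strand-specific 5'-end count tracks
#'
#' dRNA-seq TSS calling consumes read 5'-end counts: one count at the first
#' sequenced base of each read, not full read coverage. Tracks are stored as
#' sparse per-position maps per replicon and strand, with the library's
#' metadata (condition, replicate, TEX/MINUS/RNASEQ treatment) attached.
#'
#' @name end_coverage
NULL

TREATMENTS <- c("TEX", "MINUS", "RNASEQ")

#' Library metadata
#'
#' @param library_id unique library identifier, e.g. `"A1_TEX"`.
#' @param condition `"A"` or `"B"` (the two growth conditions; in the original
#'   study design, 37 and 43 ppt salinity).
#' @param replicate integer replicate number (>= 1).
#' @param treatment `"TEX"` (5'PPP-enriched), `"MINUS"` (processed-end
#'   background) or `"RNASEQ"` (pooled conventional coverage).
#' @return list of class `library_meta`.
#' @export
library_meta <- function(library_id, condition, replicate, treatment) {
  stopifnot(condition %in% c("A", "B") || treatment == "RNASEQ",
            treatment %in% TREATMENTS,
            is.numeric(replicate), replicate >= 1)
  structure(list(library_id = library_id, condition = condition,
                 replicate = as.integer(replicate), treatment = treatment),
            class = "library_meta")
}

new_end_count_track <- function(counts, meta) {
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  if (nrow(counts) == 0) {
    counts <- data.frame(replicon = character(), strand = character(),
                         pos = integer(), count = numeric(),
                         stringsAsFactors = FALSE)
  }
  counts <- counts[counts$count != 0, , drop = FALSE]
  o <- order(counts$replicon, counts$strand, counts$pos)
  counts <- counts[o, , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(meta = meta, counts = counts,
                 total_count = sum(counts$count)),
            class = "end_count_track")
}

#' @export
print.end_count_track <- function(x, ...) {
  cat(sprintf("end_count_track '%s' (%s, rep %d, %s): %d positions, %g counts\n",
              x$meta$library_id, x$meta$condition, x$meta$replicate,
              x$meta$treatment, nrow(x$counts), x$total_count))
  invisible(x)
}

#' Read a strand-specific 5'-end count track from bedGraph files
#'
#' bedGraph has no strand column, so each library is a pair of files
#' (plus/minus strand). Intervals are standard 0-based half-open and are
#' expanded to per-position counts in the 1-based internal frame; zero-valued
#' intervals are dropped.
#'
#' @param bedgraph_plus path to the plus-strand bedGraph.
#' @param bedgraph_minus path to the minus-strand bedGraph.
#' @param meta a [library_meta()].
#' @param annotation optional [genome_annotation] for bounds checking.
#' @return An `end_count_track`.
#' @export
read_end_count_track <- function(bedgraph_plus, bedgraph_minus, meta,
                                 annotation = NULL) {
  parts <- list(`+` = read_bedgraph_positions(bedgraph_plus),
                `-` = read_bedgraph_positions(bedgraph_minus))
  counts <- do.call(rbind, lapply(names(parts), function(s) {
    p <- parts[[s]]
    if (nrow(p) == 0) return(NULL)
    p$strand <- s
    p
  }))
  if (is.null(counts)) {
    counts <- data.frame(replicon = character(), pos = integer(),
                         count = numeric(), strand = character())
  }
  if (!is.null(annotation) && nrow(counts) > 0) {
    len <- annotation$replicons$length[
      match(counts$replicon, annotation$replicons$replicon_id)]
    if (anyNA(len) || any(counts$pos < 1) || any(counts$pos > len)) {
      stop("track positions outside annotated replicon bounds", call. = FALSE)
    }
  }
  new_end_count_track(counts[, c("replicon", "strand", "pos", "count")], meta)
}

read_bedgraph_positions <- function(path) {
  empty <- data.frame(replicon = character(), pos = integer(),
                      count = numeric(), stringsAsFactors = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) return(empty)
  tab <- read.delim(text = lines, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("bedGraph needs 4 columns: ", path, call. = FALSE)
  names(tab)[1:4] <- c("chrom", "start0", "end0", "value")
  if (any(tab$value < 0)) {
    stop("negative value in bedGraph: ", path, call. = FALSE)
  }
  if (any(tab$value != round(tab$value))) {
    stop("non-integer 5'-end count in bedGraph: ", path, call. = FALSE)
  }
  # overlapping intervals on one strand are ambiguous counts
  for (chrom in unique(tab$chrom)) {
    sub <- tab[tab$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$start0), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start0[-1] < sub$end0[-nrow(sub)])) {
      stop("overlapping bedGraph intervals on ", chrom, " in ", path,
           call. = FALSE)
    }
  }
  widths <- tab$end0 - tab$start0
  if (any(widths <= 0)) stop("empty/negative bedGraph interval in ", path,
                             call. = FALSE)
  data.frame(
    replicon = rep(tab$chrom, widths),
    pos = unlist(lapply(seq_len(nrow(tab)),
                        function(i) seq.int(tab$start0[i] + 1L, tab$end0[i]))),
    count = rep(tab$value, widths),
    stringsAsFactors = FALSE
  )
}

#' Write a track back to a pair of bedGraph files
#'
#' Runs of equal counts are collapsed to single intervals (0-based
#' half-open), the exact inverse of [read_end_count_track()].
#'
#' @param track an `end_count_track`.
#' @param bedgraph_plus,bedgraph_minus output paths.
#' @export
write_end_count_track <- function(track, bedgraph_plus, bedgraph_minus) {
  for (s in c("+", "-")) {
    path <- if (s == "+") bedgraph_plus else bedgraph_minus
    sub <- track$counts[track$counts$strand == s, , drop = FALSE]
    con <- file(path, "w")
    if (nrow(sub) > 0) {
      sub <- sub[order(sub$replicon, sub$pos), , drop = FALSE]
      # break runs at replicon change, non-adjacent position or value change
      brk <- c(TRUE, sub$replicon[-1] != sub$replicon[-nrow(sub)] |
                 sub$pos[-1] != sub$pos[-nrow(sub)] + 1L |
                 sub$count[-1] != sub$count[-nrow(sub)])
      run <- cumsum(brk)
      first <- !duplicated(run)
      starts <- sub$pos[first] - 1L
      ends <- tapply(sub$pos, run, max)
      writeLines(sprintf("%s\t%d\t%d\t%g", sub$replicon[first], starts,
                         as.integer(ends), sub$count[first]), con)
    }
    close(con)
  }
  invisible(c(bedgraph_plus, bedgraph_minus))
}

#' Depth-scaling factors across libraries
#'
#' Library-size scaling: `factor_i = geometric mean of totals / total_i`.
#' Multiplying each library's counts by its factor equalises effective
#' sequencing depth across libraries.
#'
#' @param tracks named list of `end_count_track`s (>= 2).
#' @return named numeric vector of scale factors, one per `library_id`.
#' @export
scale_to_common_depth <- function(tracks) {
  stopifnot(length(tracks) >= 2)
  totals <- vapply(tracks, function(t) t$total_count, numeric(1))
  ids <- vapply(tracks, function(t) t$meta$library_id, character(1))
  if (any(totals == 0)) {
    stop("library has zero total count: ",
         paste(ids[totals == 0], collapse = ", "), call. = FALSE)
  }
  setNames(geometric_mean(totals) / totals, ids)
}

# fast per-(replicon, strand) lookup: position -> count
track_counts_for <- function(track, replicon, strand) {
  c0 <- track$counts
  sub <- c0[c0$replicon == replicon & c0$strand == strand, , drop = FALSE]
  sub[, c("pos", "count")]
}

#' Convert a BAM file to a 5'-end count track
#'
#' Optional ingestion utility: counts the 5'-most template base of every
#' primary alignment (leftmost base on `+`, rightmost on `-`).
#'
#' @param bam_path path to a coordinate-sorted BAM with index.
#' @param meta a [library_meta()].
#' @return An `end_count_track`.
#' @export
bam_to_end_count_track <- function(bam_path, meta) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required for BAM ingestion", call. = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "strand", "pos", "qwidth", "cigar"))
  b <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  if (length(b$pos) == 0) return(new_end_count_track(NULL, meta))
  width <- GenomicRanges::width(
    GenomicRanges::GRanges(b$rname, IRanges::IRanges(b$pos, width = 1),
                           strand = b$strand))
  aln_width <- vapply(b$cigar, cigar_ref_width, integer(1), USE.NAMES = FALSE)
  end5 <- ifelse(b$strand == "+", b$pos, b$pos + aln_width - 1L)
  tab <- stats::aggregate(
    list(count = rep(1L, length(end5))),
    by = list(replicon = as.character(b$rname),
              strand = as.character(b$strand), pos = end5), FUN = sum)
  new_end_count_track(tab, meta)
}

cigar_ref_width <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^\\d+", "", toks)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}
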