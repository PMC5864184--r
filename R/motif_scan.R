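#' CsrA-binding-site and IUPAC motif scanning
#'
#' CsrA/Rsm proteins recognise exposed GGA/ANGGA motifs; a candidate target
#' 5'-UTR carries two GGA cores with a 4-70 nt spacer, the second core
#' followed by 2-12 nt running to the end of the UTR (the base before the
#' start codon), i.e. positioned to occlude the ribosome-binding region.
#'
#' @name motif_scan
NULL

#' CsrA scan parameters
#'
#' Defaults encode the anchored pattern `GGA[ACGT]{4,70}GGA[ACGT]{2,12}$`.
#'
#' @param spacer1_min,spacer1_max inner spacer between the two GGA cores
#'   (default 4-70 nt).
#' @param tail_min,tail_max distance from the second GGA to the sequence end
#'   (default 2-12 nt).
#' @param cds_extension nt of coding sequence appended to each UTR before
#'   scanning (default 0: UTR only).
#' @return list of class `csra_scan_config`.
#' @export
csra_scan_config <- function(spacer1_min = 4, spacer1_max = 70,
                             tail_min = 2, tail_max = 12,
                             cds_extension = 0) {
  stopifnot(spacer1_min >= 0, spacer1_max >= spacer1_min,
            tail_min >= 0, tail_max >= tail_min, cds_extension >= 0)
  structure(list(spacer1_min = spacer1_min, spacer1_max = spacer1_max,
                 tail_min = tail_min, tail_max = tail_max,
                 cds_extension = cds_extension),
            class = "csra_scan_config")
}

csra_pattern <- function(config) {
  sprintf("GGA[ACGT]{%d,%d}GGA[ACGT]{%d,%d}$",
          config$spacer1_min, config$spacer1_max,
          config$tail_min, config$tail_max)
}

#' Scan 5'-UTR sequences for CsrA-binding sites
#'
#' Reports at most one hit per sequence: the leftmost suffix matching the
#' anchored two-GGA pattern. All valid decompositions into (spacer, tail)
#' are enumerated in the `decompositions` attribute column, and the number
#' of additional `A(N)GGA` occurrences anywhere in the sequence is counted
#' as supporting evidence.
#'
#' @param sequences named character vector of upper-case A/C/G/T sequences
#'   (sequences with other letters are skipped with a warning).
#' @param config a [csra_scan_config()].
#' @return data.frame with one row per hit: `seq_id`, `match_start`,
#'   `match_end`, `spacer1`, `tail` (greedy decomposition),
#'   `n_decompositions`, `anga_count`.
#' @export
scan_csra_sites <- function(sequences, config = csra_scan_config()) {
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq_%d", seq_along(sequences))
  }
  ok <- grepl("^[ACGT]*$", sequences)
  if (any(!ok)) {
    warning(sum(!ok), " sequence(s) with non-ACGT letters skipped")
  }
  pat <- csra_pattern(config)
  rows <- list()
  for (id in names(sequences)[ok]) {
    s <- sequences[[id]]
    if (nchar(s) == 0) next
    m <- regexec(sprintf("GGA([ACGT]{%d,%d})GGA([ACGT]{%d,%d})$",
                         config$spacer1_min, config$spacer1_max,
                         config$tail_min, config$tail_max), s, perl = TRUE)[[1]]
    if (m[1] == -1) next
    start <- m[1]
    spacer1 <- attr(m, "match.length")[2]
    tail_len <- attr(m, "match.length")[3]
    dec <- csra_decompositions(s, start, config)
    anga <- length(gregexpr("(?=A[ACGT]GGA)", s, perl = TRUE)[[1]])
    if (gregexpr("(?=A[ACGT]GGA)", s, perl = TRUE)[[1]][1] == -1) anga <- 0
    rows[[length(rows) + 1]] <- data.frame(
      seq_id = id, match_start = start, match_end = nchar(s),
      spacer1 = spacer1, tail = tail_len,
      n_decompositions = nrow(dec), anga_count = anga,
      stringsAsFactors = FALSE)
  }
  res <- if (length(rows) == 0) {
    data.frame(seq_id = character(), match_start = integer(),
               match_end = integer(), spacer1 = integer(), tail = integer(),
               n_decompositions = integer(), anga_count = integer(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# all (spacer1, tail) splits compatible with a match starting at `start`
csra_decompositions <- function(s, start, config) {
  len <- nchar(s)
  ggas <- unlist(gregexpr("(?=GGA)", s, perl = TRUE))
  ggas <- ggas[ggas > 0]
  second <- ggas[ggas > start]
  spacer1 <- second - (start + 3L)
  tail_len <- len - (second + 2L)
  keep <- spacer1 >= config$spacer1_min & spacer1 <= config$spacer1_max &
    tail_len >= config$tail_min & tail_len <= config$tail_max
  data.frame(spacer1 = spacer1[keep], tail = tail_len[keep])
}

#' Scan sequences for an IUPAC motif
#'
#' Finds all windows on both strands matching an IUPAC pattern with at most
#' `max_mismatches` mismatches. Positions are reported both 1-based from the
#' sequence start and relative to the sequence end, so that a promoter
#' window ending at TSS-1 yields TSS-anchored offsets (a match starting
#' 40 nt upstream of the TSS is reported at `rel_start = -40`).
#'
#' @param sequences named character vector (A/C/G/T).
#' @param iupac_pattern motif in IUPAC one-letter codes.
#' @param max_mismatches allowed mismatches (default 0).
#' @return data.frame: `seq_id`, `start`, `end`, `strand`, `rel_start`.
#' @export
scan_iupac_motif <- function(sequences, iupac_pattern, max_mismatches = 0) {
  stopifnot(max_mismatches >= 0)
  iupac_pattern <- toupper(iupac_pattern)
  valid <- names(Biostrings::IUPAC_CODE_MAP)
  letters_in <- strsplit(iupac_pattern, "")[[1]]
  if (!all(letters_in %in% valid)) {
    stop("invalid IUPAC code in pattern: ",
         paste(setdiff(letters_in, valid), collapse = ", "), call. = FALSE)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq_%d", seq_along(sequences))
  }
  pat_f <- Biostrings::DNAString(iupac_pattern)
  pat_r <- Biostrings::reverseComplement(pat_f)
  rows <- list()
  for (id in names(sequences)) {
    s <- sequences[[id]]
    if (nchar(s) < length(pat_f)) next
    subj <- Biostrings::DNAString(s)
    for (st in c("+", "-")) {
      pat <- if (st == "+") pat_f else pat_r
      hits <- Biostrings::matchPattern(pat, subj,
                                       max.mismatch = max_mismatches,
                                       fixed = FALSE)
      if (length(hits) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        seq_id = id,
        start = Biostrings::start(hits), end = Biostrings::end(hits),
        strand = st,
        rel_start = Biostrings::start(hits) - nchar(s) - 1L,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows) == 0) {
    data.frame(seq_id = character(), start = integer(), end = integer(),
               strand = character(), rel_start = integer(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  res <- res[order(res$seq_id, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Ingest an externally computed CsrA target table
#'
#' Hook for results of external target-prediction algorithms (e.g. scans of
#' intergenic regions and gene 5' ends): reads a tab-separated table with at
#' least a `gene_id` column and returns it with a `source` label, so
#' external predictions can be merged with [scan_csra_sites()] output.
#'
#' @param path TSV with header; must contain `gene_id`.
#' @param source label stored alongside (default `"external"`).
#' @return data.frame.
#' @export
read_external_csra_targets <- function(path, source = "external") {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) {
    stop("external target table needs a 'gene_id' column", call. = FALSE)
  }
  tab$source <- source
  tab
}
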