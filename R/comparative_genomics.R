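#' Flexible genomic islands and conserved proteins
#'
#' Related genomes in a genus with a conserved core show long-range synteny;
#' flexible genomic islands (fGIs) are the >= 10 kb stretches of a query
#' genome not covered by any collinear alignment anchor against a reference
#' genome. Conservation of individual proteins is decided by fixed BLAST
#' thresholds on the best hit.
#'
#' @name comparative_genomics
NULL

#' Read BLAST tabular output (outfmt 6)
#'
#' Standard 12 columns, with an optional 13th query-coverage column
#' (`qcovs`).
#'
#' @param path path to the tabular file.
#' @return data.frame of hit records.
#' @export
read_blast_hits <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
            "mismatches", "gap_opens", "query_start", "query_end",
            "subject_start", "subject_end", "e_value", "bit_score")
  if (ncol(tab) == 13) cols <- c(cols, "query_coverage")
  if (ncol(tab) < 12) stop("expected >= 12 BLAST tabular columns",
                           call. = FALSE)
  names(tab)[seq_along(cols)] <- cols
  tab
}

#' Conserved-protein thresholds
#'
#' All three comparisons are strict: e-value below `max_evalue`, query
#' coverage above `min_query_coverage` percent, identity above
#' `min_identity` percent.
#'
#' @param max_evalue default `1e-5`.
#' @param min_query_coverage default 80 (percent, strict `>`).
#' @param min_identity default 30 (percent, strict `>`).
#' @return list of class `conservation_thresholds`.
#' @export
conservation_thresholds <- function(max_evalue = 1e-5,
                                    min_query_coverage = 80,
                                    min_identity = 30) {
  structure(list(max_evalue = max_evalue,
                 min_query_coverage = min_query_coverage,
                 min_identity = min_identity),
            class = "conservation_thresholds")
}

#' Flag genes as conserved or flexible
#'
#' Takes a per-gene hit table (best hit per query), applies the strict
#' thresholds, and marks genes without any hit as flexible.
#'
#' @param hits data.frame with `query_id`, `percent_identity`, `e_value`
#'   and `query_coverage` (percent).
#' @param thresholds a [conservation_thresholds()].
#' @param all_genes optional character vector of gene ids; ids absent from
#'   `hits` are reported as flexible.
#' @return data.frame `gene_id`, `conserved` (logical).
#' @export
filter_conserved_hits <- function(hits, thresholds = conservation_thresholds(),
                                  all_genes = NULL) {
  hits <- as.data.frame(hits)
  if (nrow(hits) > 0) {
    if (is.null(hits$query_coverage)) {
      stop("hits need a query_coverage column (percent)", call. = FALSE)
    }
    if (any(hits$query_coverage > 100)) {
      stop("query coverage above 100%", call. = FALSE)
    }
    # best hit per gene: lowest e-value, then highest bit score
    o <- order(hits$query_id, hits$e_value,
               -(hits$bit_score %||% rep(0, nrow(hits))))
    hits <- hits[o, , drop = FALSE]
    hits <- hits[!duplicated(hits$query_id), , drop = FALSE]
    conserved <- hits$e_value < thresholds$max_evalue &
      hits$query_coverage > thresholds$min_query_coverage &
      hits$percent_identity > thresholds$min_identity
    res <- data.frame(gene_id = hits$query_id, conserved = conserved,
                      stringsAsFactors = FALSE)
  } else {
    res <- data.frame(gene_id = character(), conserved = logical(),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(all_genes)) {
    missing <- setdiff(all_genes, res$gene_id)
    if (length(missing) > 0) {
      res <- rbind(res, data.frame(gene_id = missing, conserved = FALSE,
                                   stringsAsFactors = FALSE))
    }
    res <- res[match(all_genes, res$gene_id), , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

#' fGI calling parameters
#'
#' @param min_island_length minimal anchor-free stretch reported as an fGI
#'   (default 10000 bp).
#' @param anchor_min_length minimal alignment length of a synteny anchor
#'   (default 1000 bp).
#' @param anchor_min_identity minimal percent identity of an anchor
#'   (default 70).
#' @param collinear require a consistent subject order along the query
#'   (longest collinear chain; default `TRUE`).
#' @return list of class `fgi_config`.
#' @export
fgi_config <- function(min_island_length = 10000, anchor_min_length = 1000,
                       anchor_min_identity = 70, collinear = TRUE) {
  stopifnot(min_island_length > 0, anchor_min_length > 0)
  structure(list(min_island_length = min_island_length,
                 anchor_min_length = anchor_min_length,
                 anchor_min_identity = anchor_min_identity,
                 collinear = collinear),
            class = "fgi_config")
}

#' Call flexible genomic islands from pairwise alignment hits
#'
#' Anchors are hits of at least `anchor_min_length` bp and
#' `anchor_min_identity` percent identity; when `collinear`, they are chained
#' by the longest subject-collinear subsequence along the query (either
#' orientation), so off-diagonal repeats cannot rescue synteny. Every maximal
#' query interval of at least `min_island_length` bp containing no anchored
#' base is an fGI; intervals are clipped to `[1, query_genome_length]`.
#'
#' @param hits data.frame as from [read_blast_hits()] for one query replicon
#'   against one reference genome.
#' @param query_genome_length length of the query replicon in bp.
#' @param config an [fgi_config()].
#' @param annotation optional [genome_annotation]; contained genes (fully
#'   inside the island) are then listed.
#' @param replicon_id replicon of the query in `annotation`.
#' @return data.frame `start`, `end`, `length`, `n_genes`, `genes`
#'   (comma-separated).
#' @export
call_flexible_islands <- function(hits, query_genome_length,
                                  config = fgi_config(), annotation = NULL,
                                  replicon_id = NULL) {
  hits <- as.data.frame(hits)
  anchors <- hits[hits$alignment_length >= config$anchor_min_length &
                    hits$percent_identity >= config$anchor_min_identity, ,
                  drop = FALSE]
  if (nrow(anchors) > 0 && config$collinear) {
    anchors <- chain_collinear(anchors)
  }
  covered <- if (nrow(anchors) == 0) {
    IRanges::IRanges()
  } else {
    IRanges::reduce(IRanges::IRanges(
      start = pmax(1L, pmin(anchors$query_start, anchors$query_end)),
      end = pmin(query_genome_length,
                 pmax(anchors$query_start, anchors$query_end))))
  }
  gaps <- IRanges::setdiff(IRanges::IRanges(1L, query_genome_length), covered)
  keep <- IRanges::width(gaps) >= config$min_island_length
  gaps <- gaps[keep]
  res <- data.frame(start = IRanges::start(gaps), end = IRanges::end(gaps),
                    length = IRanges::width(gaps),
                    n_genes = rep(NA_integer_, length(gaps)),
                    genes = rep(NA_character_, length(gaps)),
                    stringsAsFactors = FALSE)
  if (!is.null(annotation) && nrow(res) > 0) {
    g <- annotation$genes
    if (!is.null(replicon_id)) g <- g[g$replicon_id == replicon_id, ,
                                      drop = FALSE]
    for (i in seq_len(nrow(res))) {
      inside <- g$start >= res$start[i] & g$end <= res$end[i]
      res$n_genes[i] <- sum(inside)
      res$genes[i] <- paste(g$gene_id[inside], collapse = ",")
    }
  }
  res
}

# longest chain of anchors whose subject coordinates are monotone along the
# query (tries both orientations, keeps the longer chain, length-weighted)
chain_collinear <- function(anchors) {
  o <- order(pmin(anchors$query_start, anchors$query_end))
  anchors <- anchors[o, , drop = FALSE]
  smid <- (anchors$subject_start + anchors$subject_end) / 2
  w <- anchors$alignment_length
  best_chain <- function(val) {
    n <- length(val)
    score <- w
    prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1)) {
        if (val[j] < val[i] && score[j] + w[i] > score[i]) {
          score[i] <- score[j] + w[i]
          prev[i] <- j
        }
      }
    }
    i <- which.max(score)
    chain <- integer(0)
    while (!is.na(i)) {
      chain <- c(i, chain)
      i <- prev[i]
    }
    list(score = max(score), chain = chain)
  }
  fwd <- best_chain(smid)
  rev_ <- best_chain(-smid)
  pick <- if (fwd$score >= rev_$score) fwd$chain else rev_$chain
  anchors[pick, , drop = FALSE]
}
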