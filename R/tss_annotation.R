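#' TSS classification and 5'-UTR statistics
#'
#' Each TSS receives every category whose rule fires (the multi-label set is
#' kept) and is reported under the single highest-precedence category:
#'
#' * gTSS — same strand, 1..`gtss_window` nt upstream of a protein-coding
#'   gene's start codon (optionally any distance when continuous RNA-seq
#'   coverage connects the TSS to the start codon);
#' * iTSS — same strand, inside an annotated gene body;
#' * aTSS — opposite strand, inside a gene body extended by `atss_flank` nt
#'   on both sides;
#' * nTSS — upstream of a non-coding RNA gene on the same strand, or in an
#'   intergenic region where no other rule fires.
#'
#' @name tss_annotation
NULL

TSS_CATEGORIES <- c("gTSS", "iTSS", "aTSS", "nTSS")

#' Classification parameters
#'
#' @param gtss_window upstream window for gene-leading TSSs, inclusive
#'   (default 200 nt).
#' @param atss_flank antisense flank around gene bodies (default 50 nt).
#' @param leaderless_max maximal 5'-UTR length still counted as leaderless
#'   (default 10 nt).
#' @param long_utr_min 5'-UTRs strictly longer than this are "long"
#'   (default 200 nt).
#' @param precedence order in which multi-label categories collapse to the
#'   single reported one (default gTSS > iTSS > aTSS > nTSS).
#' @param use_coverage_extension allow gTSS assignment beyond `gtss_window`
#'   when RNA-seq coverage is continuous from the TSS to the start codon
#'   (default `FALSE`).
#' @param coverage_floor minimum per-base coverage for the extension
#'   (default 5).
#' @return list of class `classification_config`.
#' @export
classification_config <- function(gtss_window = 200, atss_flank = 50,
                                  leaderless_max = 10, long_utr_min = 200,
                                  precedence = c("gTSS", "iTSS", "aTSS", "nTSS"),
                                  use_coverage_extension = FALSE,
                                  coverage_floor = 5) {
  stopifnot(gtss_window >= 0, atss_flank >= 0, leaderless_max >= 0,
            long_utr_min >= 0,
            setequal(precedence, TSS_CATEGORIES), length(precedence) == 4)
  structure(list(gtss_window = gtss_window, atss_flank = atss_flank,
                 leaderless_max = leaderless_max, long_utr_min = long_utr_min,
                 precedence = precedence,
                 use_coverage_extension = use_coverage_extension,
                 coverage_floor = coverage_floor),
            class = "classification_config")
}

#' Classify TSS calls against an annotation
#'
#' @param tss_calls data.frame with `replicon`, `pos`, `strand` (as produced
#'   by [detect_tss()]; extra columns such as condition activity are carried
#'   through).
#' @param annotation a [genome_annotation].
#' @param config a [classification_config()].
#' @param rnaseq_track optional pooled RNA-seq coverage `end_count_track`,
#'   used only when `use_coverage_extension` is on.
#' @return the input with columns `category`, `all_categories`
#'   (comma-separated multi-label set), `associated_gene_id`, `utr_length`
#'   (gTSS only, else `NA`) and `leaderless`.
#' @export
classify_tss <- function(tss_calls, annotation,
                         config = classification_config(),
                         rnaseq_track = NULL) {
  tss_calls <- as.data.frame(tss_calls, stringsAsFactors = FALSE)
  n <- nrow(tss_calls)
  genes <- annotation$genes
  category <- character(n)
  all_cats <- character(n)
  assoc <- rep(NA_character_, n)
  utr <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- classify_one_tss(tss_calls$replicon[i], tss_calls$pos[i],
                          tss_calls$strand[i], genes, config, rnaseq_track)
    category[i] <- r$category
    all_cats[i] <- paste(r$all_categories, collapse = ",")
    assoc[i] <- r$associated_gene_id
    utr[i] <- r$utr_length
  }
  tss_calls$category <- category
  tss_calls$all_categories <- all_cats
  tss_calls$associated_gene_id <- assoc
  tss_calls$utr_length <- utr
  tss_calls$leaderless <- !is.na(utr) & utr <= config$leaderless_max
  class(tss_calls) <- c("tss_records", class(tss_calls))
  tss_calls
}

classify_one_tss <- function(replicon, pos, strand, genes, config,
                             rnaseq_track = NULL) {
  g <- genes[genes$replicon_id == replicon, , drop = FALSE]
  same <- g$strand == strand
  cds <- g$feature_class == "CDS"
  # strand-aware distance from TSS to the gene's first base (positive when
  # the TSS lies upstream)
  d <- ifelse(g$strand == "+", g$start - pos, pos - g$end)

  gtss_hit <- same & cds & d >= 1 & d <= config$gtss_window
  if (config$use_coverage_extension && !is.null(rnaseq_track)) {
    far <- which(same & cds & d > config$gtss_window)
    for (j in far) {
      span <- if (g$strand[j] == "+") c(pos, g$start[j]) else c(g$end[j], pos)
      if (coverage_continuous(rnaseq_track, replicon, strand, span[1], span[2],
                              config$coverage_floor)) {
        gtss_hit[j] <- TRUE
      }
    }
  }
  itss_hit <- same & pos >= g$start & pos <= g$end
  atss_hit <- !same & pos >= g$start - config$atss_flank &
    pos <= g$end + config$atss_flank
  ntss_hit <- same & !cds & d >= 1 & d <= config$gtss_window

  cats <- character(0)
  if (any(gtss_hit)) cats <- c(cats, "gTSS")
  if (any(itss_hit)) cats <- c(cats, "iTSS")
  if (any(atss_hit)) cats <- c(cats, "aTSS")
  if (any(ntss_hit) || length(cats) == 0) cats <- c(cats, "nTSS")
  cats <- intersect(config$precedence, cats)
  category <- cats[1]

  pick_nearest <- function(hit, dist) {
    idx <- which(hit)
    if (length(idx) == 0) return(NA_character_)
    dd <- dist[idx]
    best <- idx[dd == min(dd)]
    if (length(best) > 1) best <- best[which.min(g$start[best])]
    g$gene_id[best]
  }
  assoc <- switch(category,
    gTSS = pick_nearest(gtss_hit, d),
    iTSS = pick_nearest(itss_hit, pmin(abs(pos - g$start), abs(pos - g$end))),
    aTSS = pick_nearest(atss_hit, pmin(abs(pos - g$start), abs(pos - g$end))),
    nTSS = if (any(ntss_hit)) pick_nearest(ntss_hit, d) else NA_character_
  )
  utr <- NA_integer_
  if (category == "gTSS") {
    j <- match(assoc, g$gene_id)
    utr <- as.integer(d[j])
  }
  list(category = category, all_categories = cats,
       associated_gene_id = assoc, utr_length = utr)
}

coverage_continuous <- function(track, replicon, strand, from, to, floor) {
  sub <- track_counts_for(track, replicon, strand)
  need <- seq.int(from, to)
  cov <- sub$count[match(need, sub$pos)]
  !anyNA(cov) && all(cov >= floor)
}

#' Summarise 5'-UTR architecture
#'
#' Statistics over the gene-leading (gTSS) records only: median UTR length,
#' leaderless count (`utr_length <= leaderless_max`), long-UTR count
#' (`utr_length > long_utr_min`) and a length histogram.
#'
#' @param records output of [classify_tss()].
#' @param config a [classification_config()].
#' @return list with `n_gtss`, `median_utr`, `leaderless_count`,
#'   `long_utr_count` and `histogram` (table over 25-nt bins).
#' @export
compute_utr_statistics <- function(records, config = classification_config()) {
  u <- records$utr_length[records$category == "gTSS"]
  u <- u[!is.na(u)]
  if (length(u) == 0) {
    warning("no gTSS records; empty UTR summary")
    return(list(n_gtss = 0L, median_utr = NA_real_, leaderless_count = 0L,
                long_utr_count = 0L, histogram = table(integer(0))))
  }
  breaks <- seq(0, max(u) + 25, by = 25)
  list(
    n_gtss = length(u),
    median_utr = median(u),
    leaderless_count = sum(u <= config$leaderless_max),
    long_utr_count = sum(u > config$long_utr_min),
    histogram = table(cut(u, breaks = breaks, right = TRUE,
                          include.lowest = TRUE))
  )
}

#' Census of TSS categories per replicon and condition
#'
#' Builds the census table of the primary transcriptome: for every replicon
#' and for the union plus each per-condition subset, the count per category
#' and its percentage of the subset total (rounded to 2 decimals; blank when
#' the total is zero), followed by grand totals across replicons.
#'
#' @param records output of [classify_tss()]. Condition activity is read
#'   from logical `active_a`/`active_b` columns when present; otherwise all
#'   records count only towards the union.
#' @return data.frame with columns `replicon`, `subset`
#'   (`union`/`condition_A`/`condition_B`), `category` (the four categories
#'   plus `total`), `count` and `percent`.
#' @export
summarize_tss_counts <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  has_cond <- all(c("active_a", "active_b") %in% names(records))
  subsets <- list(union = rep(TRUE, nrow(records)))
  if (has_cond) {
    subsets$condition_A <- records$active_a
    subsets$condition_B <- records$active_b
  }
  replicons <- unique(records$replicon)
  rows <- list()
  emit <- function(replicon, subset_name, cats) {
    counts <- vapply(TSS_CATEGORIES, function(k) sum(cats == k), numeric(1))
    total <- sum(counts)
    pct <- if (total > 0) round(100 * counts / total, 2) else
      rep(NA_real_, length(counts))
    rows[[length(rows) + 1]] <<- data.frame(
      replicon = replicon, subset = subset_name,
      category = c(TSS_CATEGORIES, "total"),
      count = c(counts, total),
      percent = c(pct, if (total > 0) 100 else NA_real_),
      stringsAsFactors = FALSE)
  }
  for (rep_id in replicons) {
    in_rep <- records$replicon == rep_id
    for (s in names(subsets)) {
      emit(rep_id, s, records$category[in_rep & subsets[[s]]])
    }
  }
  for (s in names(subsets)) {
    emit("all_replicons", s, records$category[subsets[[s]]])
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Build TSS records directly from category counts
#'
#' Utility for census arithmetic: expands a named count vector (and optional
#' replicon/condition labels) into a minimal records table that
#' [summarize_tss_counts()] accepts. Used to reproduce published census
#' tables from their printed per-category counts.
#'
#' @param counts named vector/list, names among `gTSS`, `iTSS`, `aTSS`,
#'   `nTSS`.
#' @param replicon replicon label (default `"chromosome"`).
#' @return minimal `tss_records`-shaped data.frame.
#' @export
records_from_census_counts <- function(counts, replicon = "chromosome") {
  counts <- unlist(counts)
  stopifnot(all(names(counts) %in% TSS_CATEGORIES))
  category <- rep(names(counts), counts)
  data.frame(replicon = rep_len(replicon, length(category)),
             pos = seq_along(category),
             strand = rep_len("+", length(category)),
             category = category, stringsAsFactors = FALSE)
}
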