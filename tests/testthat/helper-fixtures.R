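# Fixture builders shared across test files. Everything is generated in code;
# no fixture touches the file system except through tempfile().

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal two-replicon annotation with explicit sequence
toy_annotation <- function(seq_len = 10000, genes = NULL) {
  if (is.null(genes)) {
    genes <- data.frame(
      gene_id = c("geneA", "geneB"),
      replicon_id = "chr",
      start = c(1001, 5001), end = c(2000, 6000),
      strand = c("+", "-"),
      feature_class = "CDS", stringsAsFactors = FALSE)
  }
  genome_annotation(
    data.frame(replicon_id = "chr", length = seq_len,
               sequence = random_dna(seq_len), stringsAsFactors = FALSE),
    genes)
}

write_toy_fasta <- function(annotation, path = tempfile(fileext = ".fasta")) {
  ss <- Biostrings::DNAStringSet(annotation$replicons$sequence)
  names(ss) <- annotation$replicons$replicon_id
  Biostrings::writeXStringSet(ss, path)
  path
}

write_gff3_lines <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff3_line <- function(seqid, type, start, end, strand, id) {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s",
          seqid, type, start, end, strand, id, id)
}

# build an end_count_track directly from a position/count table
make_track <- function(df, library_id = "X", condition = "A", replicate = 1,
                       treatment = "TEX") {
  plus <- tempfile(fileext = ".bedgraph")
  minus <- tempfile(fileext = ".bedgraph")
  for (s in c("+", "-")) {
    path <- if (s == "+") plus else minus
    sub <- df[df$strand == s, , drop = FALSE]
    if (nrow(sub) > 0) {
      writeLines(sprintf("%s\t%d\t%d\t%g", sub$replicon, sub$pos - 1L,
                         sub$pos, sub$count), path)
    } else {
      writeLines(character(0), path)
    }
  }
  read_end_count_track(plus, minus,
                       library_meta(library_id, condition, replicate,
                                    treatment))
}

track_df <- function(pos, count, strand = "+", replicon = "chr") {
  data.frame(replicon = rep_len(replicon, length(pos)),
             strand = rep_len(strand, length(pos)),
             pos = pos, count = rep_len(count, length(pos)),
             stringsAsFactors = FALSE)
}

# brute-force TSS classifier: tests every gene against every rule, used as
# the oracle for classify_tss
brute_force_classify <- function(replicon, pos, strand, genes,
                                 config = classification_config()) {
  cats <- character(0)
  gtss_genes <- character(0)
  gtss_d <- integer(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$replicon_id != replicon) next
    d <- if (g$strand == "+") g$start - pos else pos - g$end
    same <- g$strand == strand
    if (same && g$feature_class == "CDS" && d >= 1 && d <= config$gtss_window) {
      cats <- c(cats, "gTSS")
      gtss_genes <- c(gtss_genes, g$gene_id)
      gtss_d <- c(gtss_d, d)
    }
    if (same && pos >= g$start && pos <= g$end) cats <- c(cats, "iTSS")
    if (!same && pos >= g$start - config$atss_flank &&
        pos <= g$end + config$atss_flank) cats <- c(cats, "aTSS")
    if (same && g$feature_class != "CDS" && d >= 1 && d <= config$gtss_window) {
      cats <- c(cats, "nTSS")
    }
  }
  if (length(cats) == 0) cats <- "nTSS"
  cats <- intersect(config$precedence, unique(cats))
  category <- cats[1]
  utr <- NA_integer_
  if (category == "gTSS") utr <- min(gtss_d)
  list(category = category, all_categories = cats, utr_length = utr)
}

# brute-force CsrA suffix scanner: oracle for scan_csra_sites
brute_force_csra_hit <- function(seq, config = csra_scan_config()) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  is_gga <- function(i) i >= 1 && i + 2 <= n &&
    chars[i] == "G" && chars[i + 1] == "G" && chars[i + 2] == "A"
  for (i in seq_len(max(0, n - 5))) {
    if (!is_gga(i)) next
    for (j in (i + 3):(n - 2)) {
      if (!is_gga(j)) next
      spacer <- j - (i + 3)
      tail_len <- n - (j + 2)
      if (spacer >= config$spacer1_min && spacer <= config$spacer1_max &&
          tail_len >= config$tail_min && tail_len <= config$tail_max) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# conditional NB enumeration oracle built on dnbinom (independent of the
# package's lgamma route)
oracle_exact_p <- function(a_counts, b_counts, phi) {
  n_a <- length(a_counts); n_b <- length(b_counts)
  a <- sum(a_counts); s <- a + sum(b_counts)
  if (s == 0) return(1)
  x <- 0:s
  if (phi == 0) {
    probs <- dbinom(x, s, n_a / (n_a + n_b))
  } else {
    r_a <- n_a / phi; r_b <- n_b / phi
    # equal per-sample mean mu; any mu > 0 gives the same conditional law
    probs <- dnbinom(x, size = r_a, mu = r_a) *
      dnbinom(s - x, size = r_b, mu = r_b)
    probs <- probs / sum(probs)
  }
  p_obs <- probs[a + 1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# synthetic BLAST outfmt-6-like hit table
mk_hits <- function(qstart, qend, sstart = qstart, send = qend,
                    pident = 95, evalue = 0) {
  n <- length(qstart)
  data.frame(query_id = sprintf("h%d", seq_len(n)), subject_id = "ref",
             percent_identity = rep_len(pident, n),
             alignment_length = abs(qend - qstart) + 1,
             mismatches = 0, gap_opens = 0,
             query_start = qstart, query_end = qend,
             subject_start = sstart, subject_end = send,
             e_value = rep_len(evalue, n), bit_score = 100,
             stringsAsFactors = FALSE)
}

# straight-from-the-formula TMM oracle (unweighted path shares nothing with
# the package's vectorised implementation beyond the published definitions)
oracle_tmm_factors <- function(mat, logratio_trim = 0.3, abs_expr_trim = 0.05) {
  lib <- colSums(mat)
  f75 <- sapply(seq_len(ncol(mat)), function(k) {
    quantile(mat[, k] / lib[k], 0.75)
  })
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- sapply(seq_len(ncol(mat)), function(k) {
    o <- mat[, k]; r <- mat[, ref]
    keep <- o > 0 & r > 0
    o <- o[keep]; r <- r[keep]
    m <- log2((o / lib[k]) / (r / lib[ref]))
    a <- 0.5 * log2((o / lib[k]) * (r / lib[ref]))
    if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * abs_expr_trim) + 1; hi_a <- n + 1 - lo_a
    keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    w <- (lib[k] - o[keep2]) / (lib[k] * o[keep2]) +
      (lib[ref] - r[keep2]) / (lib[ref] * r[keep2])
    2^(sum(m[keep2] / w) / sum(1 / w))
  })
  fac / exp(mean(log(fac)))
}
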