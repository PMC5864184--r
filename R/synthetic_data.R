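#' Synthetic dRNA-seq fixture generator
#'
#' Generates an annotated genome, a planted TSS truth set and the matching
#' TEX/MINUS/RNA-seq 5'-end count tracks with the statistical structure the
#' analysis assumes: negative-binomial tag counts with a common dispersion,
#' positional jitter of read 5' ends, TEX leakage into the processed-end
#' background, Poisson processed-site background, and planted per-condition
#' fold changes. Every pipeline stage is thereby testable without any
#' external data, and recovery of the planted truth quantifies detection,
#' classification and differential-activity performance.
#'
#' @name synthetic_data
NULL

#' Simulation parameters
#'
#' Defaults mirror the architecture of a typical bacterial primary
#' transcriptome scaled to desk size: a 200 kb replicon, 150 genes, a TSS
#' category mix of 59/27/6/8 percent (gTSS/iTSS/aTSS/nTSS), lognormal 5'-UTR
#' lengths with median 63 nt, lognormal per-TSS expression with median
#' 50 tags, and NB dispersion 0.2.
#'
#' @param seed integer RNG seed; the whole bundle is deterministic in it.
#' @param genome_length replicon length in bp (default 200000).
#' @param n_genes number of gene features (default 150).
#' @param ncrna_fraction fraction of genes drawn as ncRNA classes
#'   (default 0.05).
#' @param n_tss number of planted TSSs (default 200).
#' @param category_mix named probabilities over the four TSS categories,
#'   summing to 1.
#' @param utr_meanlog,utr_sdlog lognormal parameters of the 5'-UTR length
#'   (median `exp(utr_meanlog)` = 63 nt).
#' @param utr_cap upper cap on sampled UTR lengths (default 400 nt; sampled
#'   gTSS UTRs are additionally resampled to stay within the gTSS window so
#'   planted categories are self-consistent under default classification).
#' @param expr_meanlog,expr_sdlog lognormal parameters of the per-TSS mean
#'   expression (median 50 tags, sdlog 0.5 for a realistic 19-133 tag
#'   central range).
#' @param nb_dispersion common NB dispersion of tag counts (default 0.2).
#' @param tex_leakage fraction of the TSS signal leaking into the MINUS
#'   background (default 0.1).
#' @param processed_site_rate_per_kb Poisson rate of processed 5' ends in
#'   the MINUS background (default 2 per kb).
#' @param processed_site_meanlog lognormal meanlog of the per-site
#'   background intensity (default `log(15)`).
#' @param jitter_probs probabilities of a tag landing 0, +/-1, +/-2 nt from
#'   its TSS (default 0.8/0.15/0.05, the +/- mass split evenly).
#' @param fraction_differential fraction of TSSs with a planted fold change
#'   (default 0.15).
#' @param logfc_magnitudes planted |log2 fold changes|, drawn uniformly with
#'   random sign (default 1, 2, 3).
#' @param min_tss_separation minimal same-strand spacing of planted TSSs in
#'   nt (default 25, keeping jittered clusters separable).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 42L,
                              genome_length = 200000L,
                              n_genes = 150L,
                              ncrna_fraction = 0.05,
                              n_tss = 200L,
                              category_mix = c(gTSS = 0.59, iTSS = 0.27,
                                               aTSS = 0.06, nTSS = 0.08),
                              utr_meanlog = log(63),
                              utr_sdlog = 0.7,
                              utr_cap = 400L,
                              expr_meanlog = log(50),
                              expr_sdlog = 0.5,
                              nb_dispersion = 0.2,
                              tex_leakage = 0.1,
                              processed_site_rate_per_kb = 2,
                              processed_site_meanlog = log(15),
                              jitter_probs = c(`0` = 0.8, `1` = 0.15,
                                               `2` = 0.05),
                              fraction_differential = 0.15,
                              logfc_magnitudes = c(1, 2, 3),
                              min_tss_separation = 25L) {
  stopifnot(abs(sum(category_mix) - 1) < 1e-8,
            setequal(names(category_mix), TSS_CATEGORIES),
            nb_dispersion >= 0, tex_leakage >= 0, tex_leakage <= 1,
            abs(sum(jitter_probs) - 1) < 1e-8,
            fraction_differential >= 0, fraction_differential <= 1)
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes), ncrna_fraction = ncrna_fraction,
                 n_tss = as.integer(n_tss),
                 category_mix = category_mix[TSS_CATEGORIES],
                 utr_meanlog = utr_meanlog, utr_sdlog = utr_sdlog,
                 utr_cap = as.integer(utr_cap),
                 expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
                 nb_dispersion = nb_dispersion, tex_leakage = tex_leakage,
                 processed_site_rate_per_kb = processed_site_rate_per_kb,
                 processed_site_meanlog = processed_site_meanlog,
                 jitter_probs = jitter_probs,
                 fraction_differential = fraction_differential,
                 logfc_magnitudes = logfc_magnitudes,
                 min_tss_separation = as.integer(min_tss_separation)),
            class = "simulation_config")
}

SYNTH_REPLICON <- "chr_synth"

#' Generate a random annotated genome
#'
#' Uniform i.i.d. base composition; non-overlapping genes with lengths
#' ~ N(900, 200) clipped at 150 bp on random strands, separated by random
#' intergenic gaps; an `ncrna_fraction` of the genes is assigned ncRNA
#' feature classes.
#'
#' @param config a [simulation_config()].
#' @return a [genome_annotation].
#' @export
generate_annotated_genome <- function(config = simulation_config()) {
  set.seed(config$seed)
  seq <- paste(sample(c("A", "C", "G", "T"), config$genome_length,
                      replace = TRUE), collapse = "")
  replicons <- data.frame(replicon_id = SYNTH_REPLICON,
                          length = config$genome_length, sequence = seq,
                          stringsAsFactors = FALSE)
  n <- config$n_genes
  if (n == 0) return(genome_annotation(replicons, NULL))
  lens <- pmax(150L, as.integer(round(rnorm(n, 900, 200))))
  free <- config$genome_length - sum(lens)
  if (free < 10L * (n + 1L)) {
    stop("cannot pack ", n, " genes into ", config$genome_length,
         " bp; reduce n_genes", call. = FALSE)
  }
  # split the intergenic space into n+1 random gaps (min 10 bp each)
  cut <- sort(runif(n))
  gaps <- 10L + as.integer(round((free - 10L * (n + 1L)) *
                                   diff(c(0, cut, 1))))
  starts <- integer(n)
  pos <- 1L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  ends <- starts + lens - 1L
  stopifnot(max(ends) <= config$genome_length)
  n_nc <- round(n * config$ncrna_fraction)
  classes <- rep("CDS", n)
  if (n_nc > 0) {
    nc_idx <- sample(n, n_nc)
    classes[nc_idx] <- sample(NCRNA_CLASSES, n_nc, replace = TRUE)
  }
  genes <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n)),
    replicon_id = SYNTH_REPLICON,
    start = starts, end = ends,
    strand = sample(c("+", "-"), n, replace = TRUE),
    feature_class = classes, stringsAsFactors = FALSE)
  genome_annotation(replicons, genes)
}

#' Plant a TSS truth set on an annotated genome
#'
#' Samples categories from the configured mix and places each TSS so that
#' the classifier (at default settings) assigns exactly the intended
#' category; infeasible placements are resampled up to 1000 times. Assigns
#' per-condition mean expressions and planted log2 fold changes.
#'
#' @param annotation output of [generate_annotated_genome()].
#' @param config a [simulation_config()].
#' @return data.frame of class `synthetic_truth`: `tss_id`, `replicon`,
#'   `pos`, `strand`, `category`, `gene_id`, `utr_length`, `mean_a`,
#'   `mean_b`, `logfc`.
#' @export
plant_tss_truth <- function(annotation, config = simulation_config()) {
  set.seed(config$seed + 1L)
  genes <- annotation$genes
  cds <- genes[genes$feature_class == "CDS", , drop = FALSE]
  len <- annotation$replicons$length[1]
  cls_cfg <- classification_config()
  cats <- sample(TSS_CATEGORIES, config$n_tss, replace = TRUE,
                 prob = config$category_mix)
  used <- list(`+` = integer(0), `-` = integer(0))
  ok_spacing <- function(pos, strand) {
    length(used[[strand]]) == 0 ||
      min(abs(used[[strand]] - pos)) >= config$min_tss_separation
  }
  out <- vector("list", config$n_tss)
  for (i in seq_len(config$n_tss)) {
    placed <- FALSE
    for (try in seq_len(1000)) {
      prop <- switch(cats[i],
        gTSS = {
          if (nrow(cds) == 0) break
          g <- cds[sample(nrow(cds), 1), ]
          utr <- min(config$utr_cap,
                     max(1L, as.integer(round(rlnorm(1, config$utr_meanlog,
                                                     config$utr_sdlog)))))
          if (utr > cls_cfg$gtss_window) next  # keep self-consistent
          pos <- if (g$strand == "+") g$start - utr else g$end + utr
          list(pos = pos, strand = g$strand, gene = g$gene_id, utr = utr)
        },
        iTSS = {
          g <- genes[sample(nrow(genes), 1), ]
          list(pos = sample(g$start:g$end, 1), strand = g$strand,
               gene = g$gene_id, utr = NA_integer_)
        },
        aTSS = {
          g <- genes[sample(nrow(genes), 1), ]
          lo <- max(1L, g$start - cls_cfg$atss_flank)
          hi <- min(len, g$end + cls_cfg$atss_flank)
          list(pos = sample(lo:hi, 1),
               strand = if (g$strand == "+") "-" else "+",
               gene = g$gene_id, utr = NA_integer_)
        },
        nTSS = {
          list(pos = sample(len, 1), strand = sample(c("+", "-"), 1),
               gene = NA_character_, utr = NA_integer_)
        })
      if (is.null(prop) || prop$pos < 1 || prop$pos > len) next
      if (!ok_spacing(prop$pos, prop$strand)) next
      got <- classify_one_tss(SYNTH_REPLICON, prop$pos, prop$strand, genes,
                              cls_cfg)
      if (got$category != cats[i]) next
      if (cats[i] == "gTSS" && got$utr_length != prop$utr) next
      used[[prop$strand]] <- c(used[[prop$strand]], prop$pos)
      out[[i]] <- data.frame(
        replicon = SYNTH_REPLICON, pos = prop$pos, strand = prop$strand,
        category = cats[i],
        gene_id = if (cats[i] == "nTSS") got$associated_gene_id else prop$gene,
        utr_length = prop$utr, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place a ", cats[i],
           " TSS after 1000 tries; layout infeasible", call. = FALSE)
    }
  }
  truth <- do.call(rbind, out)
  n <- nrow(truth)
  truth$tss_id <- sprintf("planted_%03d", seq_len(n))
  base <- rlnorm(n, config$expr_meanlog, config$expr_sdlog)
  lfc <- rep(0, n)
  n_de <- round(config$fraction_differential * n)
  if (n_de > 0) {
    de_idx <- sample(n, n_de)
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      sample(config$logfc_magnitudes, n_de, replace = TRUE)
  }
  truth$mean_a <- base
  truth$mean_b <- base * 2^lfc
  truth$logfc <- lfc
  class(truth) <- c("synthetic_truth", class(truth))
  truth
}

# spread `n` tags around `pos` with the jitter kernel; returns data.frame
jitter_tags <- function(pos, n, jitter_probs, len) {
  if (n == 0) return(NULL)
  p <- jitter_probs
  probs <- c(p[["2"]] / 2, p[["1"]] / 2, p[["0"]], p[["1"]] / 2, p[["2"]] / 2)
  cnt <- as.vector(rmultinom(1, n, probs))
  off <- -2:2
  keep <- cnt > 0
  at <- pos + off[keep]
  ok <- at >= 1 & at <= len
  if (!any(ok)) return(NULL)
  data.frame(pos = at[ok], count = cnt[keep][ok])
}

#' Simulate 5'-end count tracks from a planted truth set
#'
#' For each condition (A, B) and replicate (1, 2), TEX tag counts per TSS
#' are NB(mean, dispersion) spread by the jitter kernel; the matched MINUS
#' library receives the configured leakage fraction of the TSS signal plus a
#' Poisson processed-site background (site positions shared across
#' libraries, per-library counts Poisson around each site's intensity). A
#' pooled RNA-seq track adds plateau coverage from every gene-leading TSS to
#' its gene's end, supporting coverage-extension classification.
#'
#' @param truth output of [plant_tss_truth()].
#' @param annotation the matching [genome_annotation].
#' @param config a [simulation_config()].
#' @return named list of `end_count_track`s: `A1_TEX`, `A1_MINUS`, ...,
#'   `B2_MINUS`, `RNASEQ`.
#' @export
simulate_end_counts <- function(truth, annotation,
                                config = simulation_config()) {
  set.seed(config$seed + 2L)
  len <- annotation$replicons$length[1]
  n_sites <- rpois(1, config$processed_site_rate_per_kb * len / 1000)
  proc <- data.frame(
    pos = if (n_sites > 0) sample(len, n_sites, replace = TRUE) else integer(0),
    strand = if (n_sites > 0) sample(c("+", "-"), n_sites, replace = TRUE)
             else character(0),
    intensity = if (n_sites > 0) rlnorm(n_sites, config$processed_site_meanlog,
                                        0.8) else numeric(0),
    stringsAsFactors = FALSE)
  size <- if (config$nb_dispersion > 0) 1 / config$nb_dispersion else Inf
  draw_counts <- function(mu) {
    if (is.finite(size)) rnbinom(length(mu), size = size, mu = mu)
    else rpois(length(mu), mu)
  }
  tracks <- list()
  for (cond in c("A", "B")) {
    mu <- if (cond == "A") truth$mean_a else truth$mean_b
    for (rep_i in 1:2) {
      tex_rows <- list()
      minus_rows <- list()
      tags <- draw_counts(mu)
      leak <- draw_counts(config$tex_leakage * mu)
      for (k in seq_len(nrow(truth))) {
        t1 <- jitter_tags(truth$pos[k], tags[k], config$jitter_probs, len)
        if (!is.null(t1)) {
          t1$strand <- truth$strand[k]
          tex_rows[[length(tex_rows) + 1]] <- t1
        }
        m1 <- jitter_tags(truth$pos[k], leak[k], config$jitter_probs, len)
        if (!is.null(m1)) {
          m1$strand <- truth$strand[k]
          minus_rows[[length(minus_rows) + 1]] <- m1
        }
      }
      if (n_sites > 0) {
        bg <- rpois(n_sites, proc$intensity)
        nz <- bg > 0
        if (any(nz)) {
          minus_rows[[length(minus_rows) + 1]] <- data.frame(
            pos = proc$pos[nz], count = bg[nz], strand = proc$strand[nz])
        }
      }
      mk <- function(rows, treatment) {
        id <- sprintf("%s%d_%s", cond, rep_i, treatment)
        if (length(rows) == 0) {
          return(new_end_count_track(NULL, library_meta(id, cond, rep_i,
                                                        treatment)))
        }
        tab <- do.call(rbind, rows)
        agg <- stats::aggregate(count ~ pos + strand, tab, sum)
        agg$replicon <- SYNTH_REPLICON
        new_end_count_track(agg[, c("replicon", "strand", "pos", "count")],
                            library_meta(id, cond, rep_i, treatment))
      }
      tracks[[sprintf("%s%d_TEX", cond, rep_i)]] <- mk(tex_rows, "TEX")
      tracks[[sprintf("%s%d_MINUS", cond, rep_i)]] <- mk(minus_rows, "MINUS")
    }
  }
  # pooled conventional RNA-seq: plateau from each gene-leading TSS to the
  # gene 3' end, height scaled to the pooled mean
  genes <- annotation$genes
  cov_rows <- list()
  gt <- truth[truth$category == "gTSS", , drop = FALSE]
  for (k in seq_len(nrow(gt))) {
    g <- genes[genes$gene_id == gt$gene_id[k], ]
    span <- if (g$strand == "+") seq.int(gt$pos[k], g$end) else
      seq.int(g$start, gt$pos[k])
    h <- max(5, round((gt$mean_a[k] + gt$mean_b[k]) / 10))
    cov_rows[[length(cov_rows) + 1]] <- data.frame(
      pos = span, count = h, strand = g$strand)
  }
  rn_meta <- library_meta("RNASEQ", "A", 1, "RNASEQ")
  if (length(cov_rows) > 0) {
    tab <- do.call(rbind, cov_rows)
    agg <- stats::aggregate(count ~ pos + strand, tab, max)
    agg$replicon <- SYNTH_REPLICON
    tracks$RNASEQ <- new_end_count_track(
      agg[, c("replicon", "strand", "pos", "count")], rn_meta)
  } else {
    tracks$RNASEQ <- new_end_count_track(NULL, rn_meta)
  }
  tracks
}

#' Generate a complete synthetic fixture
#'
#' @param config a [simulation_config()].
#' @return list with `annotation`, `truth`, `tracks`, `config`.
#' @export
simulate_fixture <- function(config = simulation_config()) {
  annotation <- generate_annotated_genome(config)
  truth <- plant_tss_truth(annotation, config)
  tracks <- simulate_end_counts(truth, annotation, config)
  list(annotation = annotation, truth = truth, tracks = tracks,
       config = config)
}

#' Write a fixture bundle to disk
#'
#' Emits the genome FASTA, the GFF3 annotation, one bedGraph pair per
#' library, the truth table as TSV and a JSON manifest recording the seed, a
#' hash of the configuration and per-library totals.
#'
#' @param fixture output of [simulate_fixture()] (or a list with the same
#'   elements).
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty directory (default `FALSE`).
#' @return `out_dir`, invisibly.
#' @export
write_fixture_bundle <- function(fixture, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("output directory exists and is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_annotation(fixture$annotation,
                          gff3_path = file.path(out_dir, "annotation.gff3"),
                          fasta_path = file.path(out_dir, "genome.fasta"))
  totals <- list()
  for (id in names(fixture$tracks)) {
    tr <- fixture$tracks[[id]]
    write_end_count_track(tr,
                          file.path(out_dir, paste0(id, ".plus.bedgraph")),
                          file.path(out_dir, paste0(id, ".minus.bedgraph")))
    totals[[id]] <- tr$total_count
  }
  truth <- as.data.frame(fixture$truth)
  write.table(truth, file.path(out_dir, "truth_tss.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(seed = fixture$config$seed,
                   config_hash = config_hash(fixture$config),
                   library_totals = totals)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Match detected TSS calls to a planted truth set
#'
#' Greedy one-to-one matching within a position tolerance on the same
#' replicon and strand; reports recall (matched truth / truth) and precision
#' (matched calls / calls).
#'
#' @param calls detection output with `replicon`, `pos`, `strand`.
#' @param truth a `synthetic_truth` table.
#' @param tolerance maximal |distance| in nt (default 5).
#' @return list with `recall`, `precision`, `n_matched`, `n_calls`,
#'   `n_truth` and the logical `truth_matched` vector.
#' @export
evaluate_detection <- function(calls, truth, tolerance = 5) {
  calls <- as.data.frame(calls)
  truth <- as.data.frame(truth)
  matched_truth <- rep(FALSE, nrow(truth))
  matched_call <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    cand <- which(!matched_truth &
                    truth$replicon == calls$replicon[i] &
                    truth$strand == calls$strand[i] &
                    abs(truth$pos - calls$pos[i]) <= tolerance)
    if (length(cand) > 0) {
      j <- cand[which.min(abs(truth$pos[cand] - calls$pos[i]))]
      matched_truth[j] <- TRUE
      matched_call[i] <- TRUE
    }
  }
  list(recall = if (nrow(truth) > 0) mean(matched_truth) else NA_real_,
       precision = if (nrow(calls) > 0) mean(matched_call) else NA_real_,
       n_matched = sum(matched_call), n_calls = nrow(calls),
       n_truth = nrow(truth), truth_matched = matched_truth)
}
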