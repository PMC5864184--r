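two_gene_ann <- function() {
  genes <- data.frame(
    gene_id = c("cds1", "cds2", "trna1"),
    replicon_id = "chr",
    start = c(1000, 3000, 6000), end = c(2000, 4000, 6075),
    strand = c("+", "+", "+"),
    feature_class = c("CDS", "CDS", "tRNA"), stringsAsFactors = FALSE)
  toy_annotation(genes = genes)
}

classify_at <- function(ann, pos, strand, config = classification_config(),
                        rnaseq_track = NULL) {
  classify_tss(data.frame(replicon = "chr", pos = pos, strand = strand),
               ann, config, rnaseq_track)
}

test_that("the four category rules fire as defined", {
  set.seed(41)
  ann <- two_gene_ann()
  expect_equal(classify_at(ann, 850, "+")$category, "gTSS")   # 150 nt upstream
  expect_equal(classify_at(ann, 800, "+")$category, "gTSS")   # exactly 200, inclusive
  expect_equal(classify_at(ann, 799, "+")$category, "nTSS")   # 201 nt: outside
  expect_equal(classify_at(ann, 2500, "+")$category, "nTSS")  # intergenic, 500 from cds2
  expect_equal(classify_at(ann, 1500, "+")$category, "iTSS")  # inside cds1, sense
  expect_equal(classify_at(ann, 2030, "-")$category, "aTSS")  # 30 nt past 3' end, antisense
  expect_equal(classify_at(ann, 5900, "+")$category, "nTSS")  # 100 nt upstream of tRNA
})

test_that("precedence collapses multi-label sets and keeps them reportable", {
  set.seed(42)
  genes <- data.frame(
    gene_id = c("up", "down"), replicon_id = "chr",
    start = c(1000, 2120), end = c(2050, 3000), strand = "+",
    feature_class = "CDS", stringsAsFactors = FALSE)
  ann <- toy_annotation(genes = genes)
  rec <- classify_at(ann, 2000, "+")  # inside 'up', 120 nt upstream of 'down'
  expect_equal(rec$category, "gTSS")
  expect_setequal(strsplit(rec$all_categories, ",")[[1]], c("gTSS", "iTSS"))
  expect_equal(rec$associated_gene_id, "down")
  expect_equal(rec$utr_length, 120L)
})

test_that("coverage extension rescues distant gTSSs only with continuous coverage", {
  set.seed(43)
  genes <- data.frame(gene_id = "g", replicon_id = "chr", start = 2000,
                      end = 3000, strand = "+", feature_class = "CDS",
                      stringsAsFactors = FALSE)
  ann <- toy_annotation(genes = genes)
  cfg <- classification_config(use_coverage_extension = TRUE)
  tss_pos <- 1700  # 300 nt upstream, beyond the window
  covered <- make_track(track_df(1700:2000, rep(6, 301)), treatment = "RNASEQ")
  gapped <- make_track(track_df(c(1700:1800, 1900:2000), rep(6, 203)),
                       treatment = "RNASEQ")
  expect_equal(classify_at(ann, tss_pos, "+", cfg, covered)$category, "gTSS")
  expect_equal(classify_at(ann, tss_pos, "+", cfg, covered)$utr_length, 300L)
  expect_equal(classify_at(ann, tss_pos, "+", cfg, gapped)$category, "nTSS")
  # off by default
  expect_equal(classify_at(ann, tss_pos, "+",
                           rnaseq_track = covered)$category, "nTSS")
})

test_that("classification equals brute-force rule evaluation on random fixtures", {
  set.seed(44)
  for (k in 1:1000) {
    n_genes <- sample(2:6, 1)
    starts <- sort(sample(seq(100, 4500, by = 50), n_genes))
    genes <- data.frame(
      gene_id = sprintf("g%d", seq_len(n_genes)),
      replicon_id = "chr",
      start = starts,
      end = pmin(4999, starts + sample(100:700, n_genes, replace = TRUE)),
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      feature_class = sample(c("CDS", "CDS", "CDS", "tRNA", "sRNA"),
                             n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
    ann <- genome_annotation(
      data.frame(replicon_id = "chr", length = 5000, sequence = NA),
      genes)
    pos <- sample(5000, 3)
    strand <- sample(c("+", "-"), 3, replace = TRUE)
    rec <- classify_tss(data.frame(replicon = "chr", pos = pos,
                                   strand = strand), ann)
    for (i in 1:3) {
      oracle <- brute_force_classify("chr", pos[i], strand[i], genes)
      expect_equal(rec$category[i], oracle$category,
                   label = sprintf("fixture %d pos %d %s", k, pos[i], strand[i]))
      expect_setequal(strsplit(rec$all_categories[i], ",")[[1]],
                      oracle$all_categories)
      if (oracle$category == "gTSS") {
        expect_equal(rec$utr_length[i], as.integer(oracle$utr_length))
      }
    }
  }
})

test_that("every record gets exactly one category and counts sum to totals", {
  fx <- simulate_fixture(simulation_config(seed = 5, n_tss = 120))
  calls <- detect_tss(fx$tracks)
  rec <- classify_tss(calls, fx$annotation)
  expect_true(all(rec$category %in% c("gTSS", "iTSS", "aTSS", "nTSS")))
  expect_true(all(mapply(function(cat, all) cat %in% strsplit(all, ",")[[1]],
                         rec$category, rec$all_categories)))
  census <- summarize_tss_counts(rec)
  for (sub in unique(census$subset)) {
    s <- census[census$replicon == "chr_synth" & census$subset == sub, ]
    expect_equal(s$count[s$category == "total"],
                 sum(s$count[s$category != "total"]))
  }
})

test_that("UTR statistics report median, leaderless and long counts", {
  rec <- data.frame(category = "gTSS", utr_length = c(0L, 5L, 63L, 250L))
  s <- compute_utr_statistics(rec)
  expect_equal(s$median_utr, 34)
  expect_equal(s$leaderless_count, 2)
  expect_equal(s$long_utr_count, 1)

  s1 <- compute_utr_statistics(data.frame(category = "gTSS",
                                          utr_length = 63L))
  expect_equal(s1$median_utr, 63)

  expect_warning(
    empty <- compute_utr_statistics(data.frame(category = "iTSS",
                                               utr_length = NA_integer_)),
    "no gTSS")
  expect_equal(empty$n_gtss, 0)
})

test_that("planted UTR median is recovered by the pipeline", {
  fx <- simulate_fixture(simulation_config())
  calls <- detect_tss(fx$tracks)
  rec <- classify_tss(calls, fx$annotation)
  s <- compute_utr_statistics(rec)
  planted_median <- median(fx$truth$utr_length[fx$truth$category == "gTSS"])
  expect_lte(abs(s$median_utr - planted_median), 2)
})

test_that("planted categories are recovered at defaults on a noise-free fixture", {
  cfg <- simulation_config(seed = 8, nb_dispersion = 1e-9, tex_leakage = 0,
                           processed_site_rate_per_kb = 0,
                           expr_meanlog = log(200), expr_sdlog = 0.1,
                           jitter_probs = c(`0` = 1, `1` = 0, `2` = 0),
                           n_tss = 150)
  fx <- simulate_fixture(cfg)
  calls <- detect_tss(fx$tracks)
  rec <- classify_tss(calls, fx$annotation)
  truth <- as.data.frame(fx$truth)
  key_t <- paste(truth$pos, truth$strand)
  key_c <- paste(rec$pos, rec$strand)
  m <- match(key_c, key_t)
  expect_true(all(!is.na(m)))
  agree <- mean(rec$category == truth$category[m])
  expect_gte(agree, 0.98)
})

test_that("census arithmetic reproduces printed totals and percentages", {
  rec <- records_from_census_counts(
    c(gTSS = 1282, aTSS = 130, iTSS = 595, nTSS = 174), "chromosome")
  census <- summarize_tss_counts(rec)
  chr <- census[census$replicon == "chromosome", ]
  expect_equal(chr$count[chr$category == "total"], 2181)
  expect_equal(chr$percent[chr$category == "gTSS"], 58.78)
  expect_equal(chr$percent[chr$category == "aTSS"], 5.96)
  expect_equal(chr$percent[chr$category == "iTSS"], 27.28)
  expect_equal(chr$percent[chr$category == "nTSS"], 7.98)

  pl <- summarize_tss_counts(records_from_census_counts(
    c(gTSS = 33, aTSS = 16, iTSS = 35, nTSS = 15), "plasmid"))
  expect_equal(pl$count[pl$category == "total" & pl$replicon == "plasmid"], 99)
  expect_equal(pl$percent[pl$category == "iTSS" & pl$replicon == "plasmid"],
               35.35)

  empty <- summarize_tss_counts(records_from_census_counts(
    c(gTSS = 0, aTSS = 0, iTSS = 0, nTSS = 0), "none"))
  expect_equal(empty$count[empty$category == "total"], 0)
  expect_true(all(is.na(empty$percent[empty$category != "total"])))
})
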