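unit_factors <- c(TEX = 1, MIN = 1)

enr_tracks <- function(tex_df, minus_df) {
  list(tex = make_track(tex_df, "TEX", treatment = "TEX"),
       minus = make_track(minus_df, "MIN", treatment = "MINUS"))
}

test_that("position enrichment follows scaled_tex / (scaled_minus + pseudocount)", {
  tr <- enr_tracks(track_df(100, 20), track_df(100, 5))
  cand <- compute_position_enrichment(tr$tex, tr$minus, unit_factors)
  expect_equal(cand$enrichment, 20 / 6, tolerance = 1e-12)
  expect_equal(cand$signal, 15)

  tr2 <- enr_tracks(track_df(100, 20), track_df(999, 1))
  cand2 <- compute_position_enrichment(tr2$tex, tr2$minus, unit_factors)
  expect_equal(cand2$enrichment, 20)

  tr3 <- enr_tracks(track_df(100, 5), track_df(100, 0))
  cand3 <- compute_position_enrichment(tr3$tex, tr3$minus, unit_factors)
  expect_equal(nrow(cand3), 0)  # below min_height
})

test_that("replicate agreement rules behave as the rule table dictates", {
  cand_at <- function(enr, tex = 50) {
    data.frame(replicon = "chr", strand = "+", pos = 100, tex_raw = tex,
               tex_scaled = tex, minus_scaled = tex / enr - 1,
               enrichment = enr, signal = tex, stringsAsFactors = FALSE)
  }
  rule_cases <- list(
    list(enr = c(3.0, 2.5), rule = "both", pass = TRUE),
    list(enr = c(3.0, 1.2), rule = "both", pass = FALSE),
    list(enr = c(3.0, 1.2), rule = "any_strong", pass = FALSE),
    list(enr = c(6.0, 1.2), rule = "any_strong", pass = TRUE),
    list(enr = c(3.0, 1.2), rule = "any", pass = TRUE),
    list(enr = c(1.5, 1.5), rule = "both", pass = FALSE),
    list(enr = c(1.5, 1.5), rule = "any", pass = FALSE),
    list(enr = c(1.5, 1.5), rule = "any_strong", pass = FALSE)
  )
  for (cs in rule_cases) {
    cfg <- detection_config(replicate_rule = cs$rule)
    got <- call_candidates(list(cand_at(cs$enr[1]), cand_at(cs$enr[2])), cfg)
    expect_equal(nrow(got) == 1, cs$pass,
                 label = sprintf("enr=(%s) rule=%s", paste(cs$enr, collapse = ","),
                                 cs$rule))
  }
})

test_that("a missing replicate errors unless the rule is 'any'", {
  one <- data.frame(replicon = "chr", strand = "+", pos = 1, tex_raw = 50,
                    tex_scaled = 50, minus_scaled = 0, enrichment = 10,
                    signal = 50)
  expect_error(call_candidates(list(one), detection_config()), "replicate")
  expect_silent(call_candidates(list(one),
                                detection_config(replicate_rule = "any")))
})

test_that("clustering matches a brute-force chain-and-argmax oracle", {
  passing <- function(pos, tex, strand = "+") {
    data.frame(replicon = "chr", strand = strand, pos = pos, tex_total = tex,
               stringsAsFactors = FALSE)
  }
  got <- cluster_candidates(passing(c(100, 102, 103), c(50, 80, 30)))
  expect_equal(nrow(got), 1)
  expect_equal(got$pos, 102)
  expect_equal(got$tex_total, 160)

  got2 <- cluster_candidates(passing(c(100, 110), c(10, 10)))
  expect_equal(got2$pos, c(100, 110))

  got3 <- cluster_candidates(passing(c(100, 101), c(30, 30)))
  expect_equal(got3$pos, 100)
  got4 <- cluster_candidates(passing(c(100, 101), c(30, 30), strand = "-"))
  expect_equal(got4$pos, 101)

  # randomized oracle: chain by gap, representative = max count, tie 5'-most
  set.seed(31)
  for (k in 1:50) {
    pos <- sort(sample(1:300, sample(3:25, 1)))
    tex <- sample(1:5, length(pos), replace = TRUE) * 10
    strand <- sample(c("+", "-"), 1)
    got <- cluster_candidates(passing(pos, tex, strand))
    cl <- cumsum(c(TRUE, diff(pos) > 5))
    exp_pos <- vapply(split(seq_along(pos), cl), function(idx) {
      best <- idx[tex[idx] == max(tex[idx])]
      if (strand == "+") pos[min(best)] else pos[max(best)]
    }, numeric(1))
    expect_equal(got$pos, unname(sort(exp_pos)))
    expect_equal(sum(got$tex_total), sum(tex))
  }
})

test_that("condition consolidation unions and merges nearby calls", {
  clustered <- function(pos, tex, strand = "+") {
    data.frame(replicon = rep_len("chr", length(pos)),
               strand = rep_len(strand, length(pos)), pos = pos,
               cluster_start = pos, cluster_end = pos, tex_total = tex,
               n_members = rep_len(1L, length(pos)), stringsAsFactors = FALSE)
  }
  only_a <- consolidate_condition_tss(clustered(100, 50), clustered(integer(0), numeric(0))[0, ])
  expect_true(only_a$active_a)
  expect_false(only_a$active_b)

  merged <- consolidate_condition_tss(clustered(100, 50), clustered(102, 80))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$pos, 102)  # higher-count condition wins
  expect_true(merged$active_a && merged$active_b)

  disjoint <- consolidate_condition_tss(clustered(c(100, 200, 300), rep(10, 3)),
                                        clustered(c(500, 600, 700, 800), rep(10, 4)))
  expect_equal(nrow(disjoint), 7)
  expect_equal(sum(disjoint$active_a), 3)
  expect_equal(sum(disjoint$active_b), 4)
})

test_that("the union never exceeds the sum of per-condition calls", {
  set.seed(32)
  for (k in 1:20) {
    mk <- function() {
      pos <- sort(sample(seq(1, 2000, by = 8), sample(5:30, 1)))
      data.frame(replicon = "chr", strand = "+", pos = pos,
                 cluster_start = pos, cluster_end = pos,
                 tex_total = sample(10:100, length(pos), replace = TRUE),
                 n_members = 1L, stringsAsFactors = FALSE)
    }
    a <- mk(); b <- mk()
    u <- consolidate_condition_tss(a, b)
    expect_lte(nrow(u), nrow(a) + nrow(b))
    expect_equal(sum(u$tex_total_a), sum(a$tex_total))
    expect_equal(sum(u$tex_total_b), sum(b$tex_total))
  }
})

test_that("noise-free planted tracks are recovered perfectly", {
  cfg <- simulation_config(seed = 7, nb_dispersion = 1e-9, tex_leakage = 0,
                           processed_site_rate_per_kb = 0,
                           expr_meanlog = log(200), expr_sdlog = 0.1,
                           jitter_probs = c(`0` = 1, `1` = 0, `2` = 0),
                           n_tss = 60)
  fx <- simulate_fixture(cfg)
  calls <- detect_tss(fx$tracks)
  ev <- evaluate_detection(calls, fx$truth, tolerance = 0)
  expect_equal(ev$recall, 1.0)
  expect_equal(ev$precision, 1.0)
})

test_that("raising min_enrichment never increases the number of calls", {
  fx <- simulate_fixture(simulation_config(seed = 9, n_tss = 80))
  n_calls <- vapply(c(1.5, 2, 3, 5, 8), function(me) {
    nrow(detect_tss(fx$tracks, detection_config(min_enrichment = me)))
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})
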