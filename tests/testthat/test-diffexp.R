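test_that("tag counting sums a strand-aware window around each TSS", {
  tr <- make_track(track_df(98:102, c(3, 0, 10, 2, 1)), "L1")
  tss <- data.frame(tss_id = "t1", replicon = "chr", pos = 100, strand = "+")
  mat <- count_tss_tags(tss, list(tr), count_window = 5)
  expect_equal(unname(mat[1, 1]), 16)

  empty <- make_track(track_df(integer(0), numeric(0)), "L2")
  mat0 <- count_tss_tags(tss, list(empty), count_window = 5)
  expect_equal(unname(mat0[1, 1]), 0)

  # counts on the other strand are invisible
  tr_minus <- make_track(track_df(98:102, rep(5, 5), strand = "-"), "L3")
  mat_m <- count_tss_tags(tss, list(tr_minus), count_window = 5)
  expect_equal(unname(mat_m[1, 1]), 0)
})

test_that("overlapping TSS windows never double count", {
  set.seed(51)
  for (k in 1:20) {
    pos <- sort(sample(100:150, 2))
    counts <- track_df(96:154, sample(0:20, 59, replace = TRUE))
    tr <- make_track(counts, "L")
    tss <- data.frame(tss_id = c("a", "b"), replicon = "chr", pos = pos,
                      strand = "+")
    mat <- count_tss_tags(tss, list(tr), count_window = 5)
    # conservation: all positions within 5 of either TSS counted exactly once
    in_win <- abs(counts$pos - pos[1]) <= 5 | abs(counts$pos - pos[2]) <= 5
    expect_equal(sum(mat), sum(counts$count[in_win]))
  }
})

test_that("TMM factors are 1 on identical or purely depth-shifted libraries", {
  set.seed(52)
  y <- rnbinom(500, mu = 50, size = 5)
  same <- cbind(a = y, b = y)
  expect_equal(unname(tmm_normalization_factors(same)), c(1, 1))

  doubled <- cbind(a = y, b = 2L * y)
  f <- tmm_normalization_factors(doubled)
  # pure depth change: all M-values are zero, so the factors stay at 1 and the
  # doubling is absorbed entirely by the effective library sizes
  expect_equal(unname(f), c(1, 1))
  eff <- colSums(doubled) * f
  norm <- sweep(doubled, 2, eff / exp(mean(log(eff))), `/`)
  expect_equal(norm[, 1], norm[, 2], tolerance = 1e-12)
})

test_that("TMM matches a straight-from-the-formula oracle on random NB matrices", {
  set.seed(53)
  for (k in 1:10) {
    mu <- rlnorm(800, log(40), 1)
    mat <- sapply(1:4, function(j) rnbinom(800, mu = mu * runif(1, 0.5, 2),
                                           size = 5))
    keep <- rowSums(mat) > 0
    mat <- mat[keep, ]
    got <- tmm_normalization_factors(mat)
    expect_equal(unname(got), unname(oracle_tmm_factors(mat)),
                 tolerance = 1e-8)
  }
})

test_that("TMM agrees with edgeR's calcNormFactors", {
  skip_if_not_installed("edgeR")
  set.seed(54)
  mu <- rlnorm(1000, log(30), 1)
  mat <- sapply(1:4, function(j) rnbinom(1000, mu = mu * runif(1, 0.5, 2),
                                         size = 5))
  mat <- mat[rowSums(mat) > 0, ]
  got <- tmm_normalization_factors(mat)
  ref <- edgeR::calcNormFactors(mat, method = "TMM")
  expect_equal(unname(got), unname(ref), tolerance = 1e-6)
})

test_that("all-zero libraries are rejected", {
  mat <- cbind(a = c(1, 2, 3), b = c(0, 0, 0))
  expect_error(tmm_normalization_factors(mat), "zero")
})

test_that("dispersion estimation recovers Poisson and degenerate limits", {
  set.seed(55)
  pois <- sapply(1:4, function(j) rpois(2000, rlnorm(2000, log(50), 0.5)))
  mu <- rlnorm(2000, log(50), 0.5)
  pois <- sapply(1:4, function(j) rpois(2000, mu))
  expect_lte(estimate_common_dispersion(pois), 0.01)

  flat <- matrix(7, nrow = 1, ncol = 4)
  expect_lte(estimate_common_dispersion(flat), 2e-6)  # at the lower clip

  expect_error(estimate_common_dispersion(matrix(0, 5, 4)), "zero")
})

test_that("balanced counts give p = 1 and label swap is symmetric", {
  expect_equal(nb_exact_test(c(10, 10), c(10, 10), phi = 0.1), 1)
  set.seed(56)
  for (k in 1:20) {
    a <- rnbinom(2, mu = 40, size = 5)
    b <- rnbinom(2, mu = 80, size = 5)
    p_ab <- nb_exact_test(a, b, phi = 0.2)
    p_ba <- nb_exact_test(b, a, phi = 0.2)
    expect_equal(p_ab, p_ba, tolerance = 1e-12)
  }
})

test_that("exact test equals conditional NB enumeration for totals <= 200", {
  set.seed(57)
  for (k in 1:200) {
    s_target <- sample(1:200, 1)
    a <- sample(0:s_target, 1)
    splits <- c(sample(0:a, 1))
    a_counts <- c(splits, a - splits)
    b <- s_target - a
    sb <- sample(0:b, 1)
    b_counts <- c(sb, b - sb)
    phi <- sample(c(0, 0.05, 0.2, 1), 1)
    got <- nb_exact_test(a_counts, b_counts, phi = phi)
    expect_equal(got, oracle_exact_p(a_counts, b_counts, phi),
                 tolerance = 1e-10,
                 label = sprintf("a=(%s) b=(%s) phi=%g",
                                 paste(a_counts, collapse = ","),
                                 paste(b_counts, collapse = ","), phi))
  }
})

test_that("phi = 0 reduces to the binomial closed form", {
  # all 20 counts in group B: two equally extreme tails of 0.5^20 each
  p <- nb_exact_test(c(0, 0), c(10, 10), phi = 0)
  expect_equal(p, 2 * 0.5^20, tolerance = 1e-12)
})

test_that("exact test agrees with edgeR's small-p convention", {
  skip_if_not_installed("edgeR")
  set.seed(58)
  for (k in 1:50) {
    a <- rnbinom(2, mu = 30, size = 5)
    b <- rnbinom(2, mu = 60, size = 5)
    phi <- runif(1, 0.01, 0.5)
    got <- nb_exact_test(a, b, phi = phi)
    ref <- edgeR::exactTestBySmallP(matrix(a, nrow = 1),
                                    matrix(b, nrow = 1), dispersion = phi)
    expect_equal(got, as.numeric(ref), tolerance = 1e-8)
  }
})

test_that("fold-change floor and FDR cutoff gate the calls", {
  res <- data.frame(p_value = c(1e-6, 1e-6, 0.9),
                    mean_norm_a = c(100, 100, 100),
                    mean_norm_b = c(100 * 2^0.8, 400, 100))
  out <- call_differential_tss(res)
  expect_equal(out$call, c("unchanged", "up", "unchanged"))
  expect_lt(out$logfc[1], 1)

  # BH adjustment matches the step-up hand computation
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  res2 <- data.frame(p_value = p, mean_norm_a = 1, mean_norm_b = 1)
  out2 <- call_differential_tss(res2)
  hand <- rev(cummin(rev(p * 10 / seq_along(p))))
  expect_equal(out2$fdr, pmin(1, hand))
})

test_that("swapping condition labels negates logFC and keeps p-values", {
  fx <- simulate_fixture(simulation_config(seed = 6, n_tss = 60))
  tex <- fx$tracks[grep("_TEX$", names(fx$tracks))]
  rec <- detect_tss(fx$tracks)
  de1 <- test_differential_activity(rec, tex, dispersion = 0.2)
  swapped <- lapply(tex, function(t) {
    t$meta$condition <- if (t$meta$condition == "A") "B" else "A"
    t
  })
  de2 <- test_differential_activity(rec, swapped, dispersion = 0.2)
  expect_equal(de2$logfc, -de1$logfc, tolerance = 1e-9)
  expect_equal(de2$p_value, de1$p_value, tolerance = 1e-9)
})

test_that("planted fold changes are recovered in the correct direction", {
  fx <- simulate_fixture(simulation_config())
  calls <- detect_tss(fx$tracks)
  tex <- fx$tracks[grep("_TEX$", names(fx$tracks))]
  de <- test_differential_activity(calls, tex)
  truth <- as.data.frame(fx$truth)
  # map each detected call to its planted TSS; four-fold or larger planted
  # changes must have their sign recovered, and every significant call on a
  # planted-change TSS must point the right way
  hits <- 0; total <- 0; sig_ok <- TRUE
  for (i in seq_len(nrow(truth))) {
    if (abs(truth$logfc[i]) < 2) next
    j <- which(de$tss_id %in% calls$tss_id[
      calls$strand == truth$strand[i] & abs(calls$pos - truth$pos[i]) <= 5])
    if (length(j) == 0) next
    total <- total + 1
    if (sign(de$logfc[j[1]]) == sign(truth$logfc[i])) hits <- hits + 1
    if (de$call[j[1]] == "up" && truth$logfc[i] < 0) sig_ok <- FALSE
    if (de$call[j[1]] == "down" && truth$logfc[i] > 0) sig_ok <- FALSE
  }
  expect_gte(hits / total, 0.9)
  expect_true(sig_ok)
})
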