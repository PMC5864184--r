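#' Differential promoter activity at TSS resolution
#'
#' Per-TSS tag counts are taken from the TEX libraries, normalised between
#' libraries with the trimmed mean of M-values (TMM), a single
#' negative-binomial dispersion is estimated by conditional maximum
#' likelihood on counts mean-scaled to a common effective library size, and
#' each TSS is tested between conditions with an exact negative-binomial
#' test conditioning on its total count. Calls combine a fold-change floor
#' with a Benjamini-Hochberg FDR cutoff.
#'
#' @name differential_promoter_activity
NULL

#' TMM normalisation parameters
#'
#' @param logratio_trim two-sided trim fraction on M-values (default 0.30).
#' @param abs_expr_trim two-sided trim fraction on A-values (default 0.05).
#' @param weighting use inverse asymptotic-variance weights (default `TRUE`).
#' @return list of class `tmm_config`.
#' @export
tmm_config <- function(logratio_trim = 0.30, abs_expr_trim = 0.05,
                       weighting = TRUE) {
  stopifnot(logratio_trim >= 0, logratio_trim < 0.5,
            abs_expr_trim >= 0, abs_expr_trim < 0.5)
  structure(list(logratio_trim = logratio_trim,
                 abs_expr_trim = abs_expr_trim, weighting = weighting),
            class = "tmm_config")
}

#' Differential-call parameters
#'
#' @param fdr_cutoff Benjamini-Hochberg FDR threshold (default 0.05).
#' @param min_abs_logfc minimal |log2 fold change| to call a change
#'   (default 1).
#' @param prior_count added to normalised means before the log-ratio
#'   (default 0.5).
#' @param count_window half-width in nt of the tag-counting window around
#'   each TSS (default 5, matching the detection cluster distance).
#' @return list of class `diffexp_config`.
#' @export
diffexp_config <- function(fdr_cutoff = 0.05, min_abs_logfc = 1,
                           prior_count = 0.5, count_window = 5) {
  stopifnot(fdr_cutoff > 0, fdr_cutoff < 1, min_abs_logfc >= 0,
            prior_count >= 0, count_window >= 0)
  structure(list(fdr_cutoff = fdr_cutoff, min_abs_logfc = min_abs_logfc,
                 prior_count = prior_count,
                 count_window = as.integer(count_window)),
            class = "diffexp_config")
}

#' Per-TSS tag counts from TEX libraries
#'
#' Sums raw TEX 5'-end counts within `count_window` nt of each TSS on its
#' strand. Where the windows of two TSSs overlap, every position is assigned
#' to the nearer TSS (ties to the upstream, i.e. 5'-most, TSS), so no tag is
#' counted twice.
#'
#' @param tss_records data.frame with `tss_id`, `replicon`, `pos`, `strand`.
#' @param tex_tracks named list of TEX `end_count_track`s.
#' @param count_window window half-width in nt (default 5).
#' @return integer matrix, TSSs x libraries.
#' @export
count_tss_tags <- function(tss_records, tex_tracks, count_window = 5) {
  tss_records <- as.data.frame(tss_records)
  if (is.null(tss_records$tss_id)) {
    tss_records$tss_id <- sprintf("TSS_%s_%s_%d", tss_records$replicon,
                                  ifelse(tss_records$strand == "+", "p", "m"),
                                  tss_records$pos)
  }
  ids <- vapply(tex_tracks, function(t) t$meta$library_id, character(1))
  mat <- matrix(0L, nrow = nrow(tss_records), ncol = length(tex_tracks),
                dimnames = list(tss_records$tss_id, ids))
  for (j in seq_along(tex_tracks)) {
    cnt <- tex_tracks[[j]]$counts
    for (key in unique(paste(tss_records$replicon, tss_records$strand,
                             sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      t_idx <- which(tss_records$replicon == parts[1] &
                       tss_records$strand == parts[2])
      sub <- cnt[cnt$replicon == parts[1] & cnt$strand == parts[2], ,
                 drop = FALSE]
      if (nrow(sub) == 0 || length(t_idx) == 0) next
      tpos <- tss_records$pos[t_idx]
      o <- order(tpos)
      tpos_s <- tpos[o]
      # nearest TSS per position; ties resolved to the 5'-most TSS
      iv <- findInterval(sub$pos, tpos_s)
      lo <- pmax(iv, 1L)
      hi <- pmin(iv + 1L, length(tpos_s))
      d_lo <- abs(sub$pos - tpos_s[lo])
      d_hi <- abs(sub$pos - tpos_s[hi])
      upstream_first <- parts[2] == "+"
      use_lo <- if (upstream_first) d_lo <= d_hi else d_lo < d_hi
      near <- ifelse(use_lo, lo, hi)
      dist <- pmin(d_lo, d_hi)
      keep <- dist <= count_window
      if (!any(keep)) next
      add <- tapply(sub$count[keep], near[keep], sum)
      rows <- t_idx[o][as.integer(names(add))]
      mat[rows, j] <- mat[rows, j] + as.integer(add)
    }
  }
  mat
}

#' Trimmed mean of M-values normalisation factors
#'
#' Direct implementation of the published TMM estimator: per-gene log-ratios
#' (M) and average log-expressions (A) against a reference library (the one
#' whose upper quartile of scaled counts is closest to the mean upper
#' quartile), double trimming (30% on M, 5% on A by default), and a
#' precision-weighted mean of the retained M-values. Factors are rescaled to
#' geometric mean 1.
#'
#' @param count_matrix genes x libraries count matrix.
#' @param config a [tmm_config()].
#' @return named numeric factors, geometric mean 1.
#' @export
tmm_normalization_factors <- function(count_matrix, config = tmm_config()) {
  mat <- as.matrix(count_matrix)
  stopifnot(ncol(mat) >= 2)
  lib_size <- colSums(mat)
  if (any(lib_size == 0)) stop("library with all-zero counts", call. = FALSE)
  f75 <- apply(mat, 2, function(y) quantile(y / sum(y), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(mat)), function(k) {
    tmm_pair_factor(mat[, k], mat[, ref], lib_size[k], lib_size[ref], config)
  }, numeric(1))
  f <- f / geometric_mean(f)
  setNames(f, colnames(mat))
}

tmm_pair_factor <- function(obs, ref, n_obs, n_ref, config) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0) return(1)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * config$logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * config$abs_expr_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(1)
  if (config$weighting) {
    w <- (n_obs - obs[keep2]) / (n_obs * obs[keep2]) +
      (n_ref - ref[keep2]) / (n_ref * ref[keep2])
    tmm <- sum(m[keep2] / w) / sum(1 / w)
  } else {
    tmm <- mean(m[keep2])
  }
  2^tmm
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Counts are first mean-scaled to a common effective library size (the
#' geometric mean of `effective_sizes`); the common dispersion then maximises
#' the negative-binomial conditional log-likelihood given each feature's
#' total within each replicate group. Supplying a single pooled group treats
#' all samples as replicates.
#'
#' @param count_matrix features x libraries.
#' @param groups factor/character of group membership per library; default a
#'   single pooled group.
#' @param effective_sizes effective library sizes; default `colSums` of the
#'   matrix (multiply by TMM factors for normalised sizes).
#' @return dispersion estimate, clipped to `[1e-6, 10]`.
#' @export
estimate_common_dispersion <- function(count_matrix, groups = NULL,
                                       effective_sizes = NULL) {
  mat <- as.matrix(count_matrix)
  if (all(mat == 0)) stop("all counts are zero", call. = FALSE)
  if (is.null(groups)) groups <- rep("pooled", ncol(mat))
  if (is.null(effective_sizes)) effective_sizes <- colSums(mat)
  scaled <- sweep(mat, 2, geometric_mean(effective_sizes) / effective_sizes,
                  `*`)
  group_idx <- split(seq_len(ncol(mat)), groups)
  group_idx <- group_idx[vapply(group_idx, length, integer(1)) >= 2]
  if (length(group_idx) == 0) {
    stop("need at least one group with >= 2 samples", call. = FALSE)
  }
  neg_cll <- function(log_phi) {
    r <- 1 / exp(log_phi)
    ll <- 0
    for (idx in group_idx) {
      y <- scaled[, idx, drop = FALSE]
      z <- rowSums(y)
      n <- length(idx)
      ll <- ll + sum(rowSums(lgamma(y + r))) - nrow(y) * n * lgamma(r) +
        nrow(y) * lgamma(n * r) - sum(lgamma(z + n * r))
    }
    -ll
  }
  opt <- optimize(neg_cll, interval = log(c(1e-6, 10)))
  min(10, max(1e-6, exp(opt$minimum)))
}

#' Exact negative-binomial test for one feature
#'
#' Conditions on the total count after mean-scaling to equalised effective
#' sizes: the two group sums are negative-binomial with sizes
#' `n_A/phi` and `n_B/phi`, and the two-sided p-value sums the conditional
#' probabilities of all splits no more likely than the observed one
#' (small-probabilities convention), capped at 1. `phi = 0` reduces to a
#' binomial exact test.
#'
#' @param count_a,count_b raw counts of the feature in the two groups.
#' @param effective_sizes sizes for `c(count_a, count_b)` in that order;
#'   default all equal.
#' @param phi common NB dispersion (>= 0).
#' @return two-sided p-value.
#' @export
nb_exact_test <- function(count_a, count_b, effective_sizes = NULL, phi = 0) {
  stopifnot(all(count_a >= 0), all(count_b >= 0), phi >= 0)
  n_a <- length(count_a); n_b <- length(count_b)
  counts <- c(count_a, count_b)
  if (is.null(effective_sizes)) effective_sizes <- rep(1, n_a + n_b)
  stopifnot(length(effective_sizes) == n_a + n_b)
  scaled <- counts * geometric_mean(effective_sizes) / effective_sizes
  a <- round(sum(scaled[seq_len(n_a)]))
  s <- a + round(sum(scaled[-seq_len(n_a)]))
  if (s == 0) return(1)
  x <- 0:s
  if (phi <= 1e-12) {
    logp <- dbinom(x, s, n_a / (n_a + n_b), log = TRUE)
  } else {
    r_a <- n_a / phi
    r_b <- n_b / phi
    logp <- lgamma(x + r_a) - lgamma(x + 1) +
      lgamma(s - x + r_b) - lgamma(s - x + 1)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  p_obs <- logp[a + 1]
  min(1, sum(exp(logp[logp <= p_obs + 1e-12])))
}

#' Apply fold-change and FDR thresholds
#'
#' Benjamini-Hochberg adjusts the p-values across all tested TSSs and calls
#' each TSS `up` (logFC >= `min_abs_logfc` and FDR < `fdr_cutoff`), `down`
#' (logFC <= -`min_abs_logfc` and FDR < cutoff) or `unchanged`. The logFC is
#' `log2((mean_norm_b + prior) / (mean_norm_a + prior))`, i.e. condition B
#' relative to A.
#'
#' @param results data.frame with `p_value`, `mean_norm_a`, `mean_norm_b`.
#' @param config a [diffexp_config()].
#' @return the input plus `logfc`, `fdr` and `call`.
#' @export
call_differential_tss <- function(results, config = diffexp_config()) {
  results <- as.data.frame(results)
  results$logfc <- log2((results$mean_norm_b + config$prior_count) /
                          (results$mean_norm_a + config$prior_count))
  results$fdr <- p.adjust(results$p_value, method = "BH")
  results$call <- "unchanged"
  sig <- results$fdr < config$fdr_cutoff
  results$call[sig & results$logfc >= config$min_abs_logfc] <- "up"
  results$call[sig & results$logfc <= -config$min_abs_logfc] <- "down"
  results
}

#' Full differential promoter activity analysis
#'
#' Counts tags per TSS, computes TMM factors and effective sizes, estimates
#' the pooled common dispersion, runs the exact test per TSS and applies the
#' thresholds.
#'
#' @param tss_records classified or raw TSS calls (needs `tss_id`,
#'   `replicon`, `pos`, `strand`).
#' @param tex_tracks named list of the four TEX `end_count_track`s.
#' @param de_config a [diffexp_config()].
#' @param tmm_cfg a [tmm_config()].
#' @param dispersion optional fixed dispersion; estimated from the data when
#'   `NULL` by pooling all libraries as replicates.
#' @return data.frame: `tss_id`, per-library counts, `mean_norm_a/b`,
#'   `logfc`, `p_value`, `fdr`, `call`; dispersion and factors as attributes.
#' @export
test_differential_activity <- function(tss_records, tex_tracks,
                                       de_config = diffexp_config(),
                                       tmm_cfg = tmm_config(),
                                       dispersion = NULL) {
  conds <- vapply(tex_tracks, function(t) t$meta$condition, character(1))
  stopifnot(all(conds %in% c("A", "B")), sum(conds == "A") >= 1,
            sum(conds == "B") >= 1)
  mat <- count_tss_tags(tss_records, tex_tracks, de_config$count_window)
  keep <- rowSums(mat) > 0
  factors <- tmm_normalization_factors(mat[keep, , drop = FALSE], tmm_cfg)
  eff <- colSums(mat) * factors
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(mat[keep, , drop = FALSE],
                                             groups = NULL,
                                             effective_sizes = eff)
  }
  norm <- sweep(mat, 2, eff / geometric_mean(eff), `/`)
  ia <- which(conds == "A"); ib <- which(conds == "B")
  p <- vapply(seq_len(nrow(mat)), function(i) {
    nb_exact_test(mat[i, ia], mat[i, ib], effective_sizes = eff[c(ia, ib)],
                  phi = dispersion)
  }, numeric(1))
  res <- data.frame(tss_id = rownames(mat), mat, check.names = FALSE,
                    mean_norm_a = rowMeans(norm[, ia, drop = FALSE]),
                    mean_norm_b = rowMeans(norm[, ib, drop = FALSE]),
                    p_value = p, stringsAsFactors = FALSE)
  res <- call_differential_tss(res, de_config)
  attr(res, "dispersion") <- dispersion
  attr(res, "tmm_factors") <- factors
  res
}
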