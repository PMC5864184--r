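#' TSS detection from TEX+/MINUS contrast
#'
#' A position is a TSS candidate when its depth-scaled TEX+ 5'-end signal is
#' enriched over the depth-scaled processed-end (MINUS) background of the
#' same replicate; replicate agreement then suppresses spurious single-library
#' sites ("replicate-assisted background subtraction"). Candidates within a
#' few nt are collapsed to one representative, and per-condition calls are
#' merged into a global TSS set that records which conditions each TSS was
#' active in.
#'
#' @name tss_detection
NULL

#' Detection parameters
#'
#' @param min_height minimum raw TEX 5'-end count at a position before it is
#'   considered at all (default 10 reads).
#' @param min_enrichment minimum TEX/background enrichment per replicate
#'   (default 2).
#' @param pseudocount added to the scaled background before dividing
#'   (default 1).
#' @param cluster_distance positions within this many nt join one TSS
#'   cluster (default 5).
#' @param replicate_rule `"both"` (enrichment required in both replicates,
#'   the default), `"any"` (one suffices), or `"any_strong"` (both, or a
#'   single replicate at `strong_enrichment`).
#' @param strong_enrichment single-replicate rescue threshold for
#'   `"any_strong"` (default 5).
#' @return list of class `detection_config`.
#' @export
detection_config <- function(min_height = 10, min_enrichment = 2,
                             pseudocount = 1, cluster_distance = 5,
                             replicate_rule = c("both", "any", "any_strong"),
                             strong_enrichment = 5) {
  replicate_rule <- match.arg(replicate_rule)
  stopifnot(min_height >= 1, min_enrichment > 1, cluster_distance >= 0,
            pseudocount >= 0)
  structure(list(min_height = min_height, min_enrichment = min_enrichment,
                 pseudocount = pseudocount,
                 cluster_distance = as.integer(cluster_distance),
                 replicate_rule = replicate_rule,
                 strong_enrichment = strong_enrichment),
            class = "detection_config")
}

#' Per-position TEX enrichment over background
#'
#' For every position whose raw TEX count reaches `min_height`, computes
#' `enrichment = scaled_tex / (scaled_minus + pseudocount)` and the
#' background-subtracted signal `max(0, scaled_tex - scaled_minus)`, where
#' scaling uses the common-depth factors of [scale_to_common_depth()].
#'
#' @param tex_track,minus_track `end_count_track`s of one replicate.
#' @param scale_factors named factors covering both library ids.
#' @param config a [detection_config()].
#' @return data.frame of candidate positions with raw/scaled counts,
#'   enrichment and signal.
#' @export
compute_position_enrichment <- function(tex_track, minus_track, scale_factors,
                                        config = detection_config()) {
  f_tex <- scale_factors[[tex_track$meta$library_id]]
  f_min <- scale_factors[[minus_track$meta$library_id]]
  if (is.null(f_tex) || is.null(f_min)) {
    stop("scale factor missing for a library", call. = FALSE)
  }
  tex <- tex_track$counts
  tex <- tex[tex$count >= config$min_height, , drop = FALSE]
  if (nrow(tex) == 0) {
    return(data.frame(replicon = character(), strand = character(),
                      pos = integer(), tex_raw = numeric(),
                      tex_scaled = numeric(), minus_scaled = numeric(),
                      enrichment = numeric(), signal = numeric()))
  }
  mn <- minus_track$counts
  key_t <- paste(tex$replicon, tex$strand, tex$pos)
  key_m <- paste(mn$replicon, mn$strand, mn$pos)
  minus_raw <- mn$count[match(key_t, key_m)]
  minus_raw[is.na(minus_raw)] <- 0
  tex_scaled <- tex$count * f_tex
  minus_scaled <- minus_raw * f_min
  data.frame(
    replicon = tex$replicon, strand = tex$strand, pos = tex$pos,
    tex_raw = tex$count, tex_scaled = tex_scaled,
    minus_scaled = minus_scaled,
    enrichment = tex_scaled / (minus_scaled + config$pseudocount),
    signal = pmax(0, tex_scaled - minus_scaled),
    stringsAsFactors = FALSE
  )
}

#' Apply the replicate agreement rule
#'
#' Joins the candidate streams of one condition's replicates on position and
#' keeps positions passing the configured rule: `both` needs
#' `enrichment >= min_enrichment` in every replicate; `any` in at least one;
#' `any_strong` in every replicate, or in a single replicate at
#' `strong_enrichment`.
#'
#' @param candidates list of per-replicate data.frames from
#'   [compute_position_enrichment()].
#' @param config a [detection_config()].
#' @return data.frame of passing positions with `tex_total` (summed raw TEX
#'   counts over replicates present) and per-replicate enrichments.
#' @export
call_candidates <- function(candidates, config = detection_config()) {
  if (!is.list(candidates) || length(candidates) == 0) {
    stop("no candidate streams supplied", call. = FALSE)
  }
  if (length(candidates) < 2 && config$replicate_rule != "any") {
    stop("replicate missing: rule '", config$replicate_rule,
         "' needs both replicates", call. = FALSE)
  }
  n_rep <- length(candidates)
  all_pos <- unique(do.call(rbind, lapply(candidates, function(d)
    d[, c("replicon", "strand", "pos")])))
  if (nrow(all_pos) == 0) {
    return(cbind(all_pos, data.frame(tex_total = numeric(0), n_pass = integer(0))))
  }
  key <- paste(all_pos$replicon, all_pos$strand, all_pos$pos)
  enr <- matrix(NA_real_, nrow = nrow(all_pos), ncol = n_rep)
  tex <- matrix(0, nrow = nrow(all_pos), ncol = n_rep)
  for (j in seq_len(n_rep)) {
    d <- candidates[[j]]
    m <- match(paste(d$replicon, d$strand, d$pos), key)
    enr[m, j] <- d$enrichment
    tex[m, j] <- d$tex_raw
  }
  pass_rep <- !is.na(enr) & enr >= config$min_enrichment
  n_pass <- rowSums(pass_rep)
  keep <- switch(config$replicate_rule,
    both = n_pass == n_rep,
    any = n_pass >= 1,
    any_strong = n_pass == n_rep |
      rowSums(!is.na(enr) & enr >= config$strong_enrichment) >= 1
  )
  out <- all_pos[keep, , drop = FALSE]
  out$tex_total <- rowSums(tex)[keep]
  out$n_pass <- n_pass[keep]
  for (j in seq_len(n_rep)) out[[paste0("enrichment_rep", j)]] <- enr[keep, j]
  rownames(out) <- NULL
  out
}

#' Collapse jittered candidate positions into TSS clusters
#'
#' Positions within `cluster_distance` nt of the previous cluster member join
#' that cluster. The representative is the member with the maximal summed TEX
#' count over replicates; ties go to the 5'-most member (smallest coordinate
#' on `+`, largest on `-`).
#'
#' @param passing data.frame from [call_candidates()] (needs `replicon`,
#'   `strand`, `pos`, `tex_total`).
#' @param config a [detection_config()].
#' @return data.frame with one row per cluster: representative `pos`,
#'   `cluster_start`, `cluster_end`, `tex_total` (cluster sum), `n_members`.
#' @export
cluster_candidates <- function(passing, config = detection_config()) {
  empty <- data.frame(replicon = character(), strand = character(),
                      pos = integer(), cluster_start = integer(),
                      cluster_end = integer(), tex_total = numeric(),
                      n_members = integer(), stringsAsFactors = FALSE)
  if (nrow(passing) == 0) return(empty)
  out <- list()
  for (grp in split(passing,
                    paste(passing$replicon, passing$strand, sep = "\r"))) {
    grp <- grp[order(grp$pos), , drop = FALSE]
    gap <- c(Inf, diff(grp$pos))
    cl <- cumsum(gap > config$cluster_distance)
    for (sub in split(grp, cl)) {
      best <- which(sub$tex_total == max(sub$tex_total))
      rep_i <- if (sub$strand[1] == "+") min(best) else max(best)
      out[[length(out) + 1]] <- data.frame(
        replicon = sub$replicon[1], strand = sub$strand[1],
        pos = sub$pos[rep_i],
        cluster_start = min(sub$pos), cluster_end = max(sub$pos),
        tex_total = sum(sub$tex_total), n_members = nrow(sub),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$replicon, res$strand, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge per-condition TSS sets into global TSS calls
#'
#' Takes the clustered calls of the two conditions and forms their union;
#' calls from different conditions within `cluster_distance` nt are merged
#' into a single TSS whose representative position comes from the
#' higher-count condition. `active_conditions` records which conditions
#' contributed.
#'
#' @param clustered_a,clustered_b data.frames from [cluster_candidates()]
#'   for conditions A and B.
#' @param config a [detection_config()].
#' @return data.frame of TSS calls: `replicon`, `pos`, `strand`,
#'   `active_a`/`active_b`, `tex_total_a`/`tex_total_b`.
#' @export
consolidate_condition_tss <- function(clustered_a, clustered_b,
                                      config = detection_config()) {
  tag <- function(d, cond) {
    if (nrow(d) == 0) {
      return(data.frame(replicon = character(), strand = character(),
                        pos = integer(), tex_total = numeric(),
                        condition = character(), stringsAsFactors = FALSE))
    }
    data.frame(replicon = d$replicon, strand = d$strand, pos = d$pos,
               tex_total = d$tex_total, condition = cond,
               stringsAsFactors = FALSE)
  }
  both <- rbind(tag(clustered_a, "A"), tag(clustered_b, "B"))
  empty <- data.frame(replicon = character(), pos = integer(),
                      strand = character(), active_a = logical(),
                      active_b = logical(), tex_total_a = numeric(),
                      tex_total_b = numeric(), stringsAsFactors = FALSE)
  if (nrow(both) == 0) return(empty)
  out <- list()
  for (grp in split(both, paste(both$replicon, both$strand, sep = "\r"))) {
    grp <- grp[order(grp$pos), , drop = FALSE]
    gap <- c(Inf, diff(grp$pos))
    cl <- cumsum(gap > config$cluster_distance)
    for (sub in split(grp, cl)) {
      best <- which(sub$tex_total == max(sub$tex_total))
      rep_i <- if (sub$strand[1] == "+") min(best) else max(best)
      ta <- sum(sub$tex_total[sub$condition == "A"])
      tb <- sum(sub$tex_total[sub$condition == "B"])
      out[[length(out) + 1]] <- data.frame(
        replicon = sub$replicon[1], pos = sub$pos[rep_i],
        strand = sub$strand[1],
        active_a = any(sub$condition == "A"),
        active_b = any(sub$condition == "B"),
        tex_total_a = ta, tex_total_b = tb, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$replicon, res$strand, res$pos), , drop = FALSE]
  res$tss_id <- sprintf("TSS_%s_%s_%d", res$replicon,
                        ifelse(res$strand == "+", "p", "m"), res$pos)
  rownames(res) <- NULL
  res
}

#' Run the full TSS detection stage
#'
#' Convenience wrapper: computes common-depth scale factors over all TEX and
#' MINUS libraries, per-replicate enrichment, replicate-agreed candidates per
#' condition, clusters them and consolidates the two conditions.
#'
#' @param tracks named list of `end_count_track`s for the four TEX and four
#'   MINUS libraries (an `RNASEQ` track, if present, is ignored here).
#' @param config a [detection_config()].
#' @return TSS call data.frame as from [consolidate_condition_tss()].
#' @export
detect_tss <- function(tracks, config = detection_config()) {
  is_de <- vapply(tracks, function(t) t$meta$treatment %in% c("TEX", "MINUS"),
                  logical(1))
  tracks <- tracks[is_de]
  # empty background libraries (no processed 5' ends at all) contribute no
  # counts wherever scaled, so they take a neutral factor of 1
  totals <- vapply(tracks, function(t) t$total_count, numeric(1))
  factors <- scale_to_common_depth(tracks[totals > 0])
  if (any(totals == 0)) {
    ids0 <- vapply(tracks[totals == 0], function(t) t$meta$library_id,
                   character(1))
    factors <- c(factors, setNames(rep(1, length(ids0)), ids0))
  }
  clustered <- list()
  for (cond in c("A", "B")) {
    texs <- Filter(function(t) t$meta$treatment == "TEX" &&
                     t$meta$condition == cond, tracks)
    cand <- lapply(texs, function(tex) {
      minus <- Filter(function(t) t$meta$treatment == "MINUS" &&
                        t$meta$condition == cond &&
                        t$meta$replicate == tex$meta$replicate, tracks)
      if (length(minus) != 1) {
        stop("no matched MINUS library for ", tex$meta$library_id,
             call. = FALSE)
      }
      compute_position_enrichment(tex, minus[[1]], factors, config)
    })
    passing <- call_candidates(unname(cand), config)
    clustered[[cond]] <- cluster_candidates(passing, config)
  }
  consolidate_condition_tss(clustered$A, clustered$B, config)
}
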