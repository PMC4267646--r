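# Peak proximity scores and target classification.
#
# The proximity score of gene j for a transcription factor is
#   a_j = sum_k g_k * exp(-d_k / d0)
# over the factor's peaks k within a window around the gene's TSS, where
# g_k is the peak's fold enrichment over input and d_k the unsigned
# summit-to-TSS distance. Genes scoring above a factor-specific cutoff
# are treated as likely direct targets of that factor.

#' Peak proximity scores around gene TSSs
#'
#' Computes, per gene, the fold-enrichment-weighted exponential distance
#' decay sum over all peaks whose summit lies within `window` bp of the
#' gene's TSS. Distance is unsigned and strand-independent; a gene on a
#' chromosome without peaks scores 0.
#'
#' @param genes Annotation data.frame (`gene_id`, `chrom`, `tss`; see
#'   [read_gene_annotation()]).
#' @param peaks data.frame with columns `chrom`, `summit` and the column
#'   named by `fe_col` (a peak table or a consensus summit set).
#' @param d0 Decay length in bp; a peak at distance `d0` contributes
#'   `exp(-1)` of its enrichment. Default 5000.
#' @param window Hard half-window around the TSS in bp; default 500000
#'   (peaks within +/-500 kb of the TSS).
#' @param fe_col Name of the enrichment column to use as `g_k`; default
#'   `"fold_enrichment"`. For consensus input pass e.g. `"fe.tf1_scr"`
#'   to score binding in the unperturbed condition.
#' @return data.frame with `gene_id`, `score`, `n_peaks_in_window`.
#' @export
proximity_scores <- function(genes, peaks, d0 = 5000, window = 500000,
                             fe_col = "fold_enrichment") {
  stopifnot(d0 > 0, window > 0)
  if (!fe_col %in% names(peaks)) stop("no column '", fe_col, "' in peaks")
  score <- numeric(nrow(genes))
  npk <- integer(nrow(genes))
  by_chr <- split(seq_len(nrow(peaks)), peaks$chrom)
  for (chr in intersect(unique(genes$chrom), names(by_chr))) {
    idx <- by_chr[[chr]]
    ord <- order(peaks$summit[idx])
    spos <- peaks$summit[idx][ord]
    sfe <- peaks[[fe_col]][idx][ord]
    gi <- which(genes$chrom == chr)
    for (g in gi) {
      tss <- genes$tss[g]
      lo <- findInterval(tss - window - 0.5, spos) + 1L
      hi <- findInterval(tss + window + 0.5, spos)
      if (hi < lo) next
      d <- abs(spos[lo:hi] - tss)
      score[g] <- sum(sfe[lo:hi] * exp(-d / d0))
      npk[g] <- hi - lo + 1L
    }
  }
  data.frame(gene_id = genes$gene_id, score = score,
             n_peaks_in_window = npk, stringsAsFactors = FALSE)
}

#' Classify genes into two-factor target quadrants
#'
#' Assigns each gene to a quadrant of the (factor-1 score, factor-2
#' score) plane using strict cutoffs: above both cutoffs is a dual
#' target, above exactly one an exclusive target, above neither no direct
#' target. A gene missing from one score table is treated as scoring 0
#' for that factor. When `cumulative` is supplied, quadrant counts are
#' additionally split by regulation direction (sign of the cumulative
#' fold change).
#'
#' @param scores_tf1,scores_tf2 data.frames `gene_id`, `score` (see
#'   [proximity_scores()]).
#' @param cut1,cut2 Strict score cutoffs for the two factors; defaults 10
#'   and 5.
#' @param cumulative Optional data.frame `gene_id`, `cumulative_fc` (see
#'   [cumulative_fc()]) used to attach directions.
#' @return A list with `profiles` (per gene: scores, `target_class` in
#'   tf1-exclusive/tf2-exclusive/dual/none, and direction columns when
#'   available) and `quadrant_counts` (counts per class, by direction
#'   when available).
#' @export
classify_targets <- function(scores_tf1, scores_tf2, cut1 = 10, cut2 = 5,
                             cumulative = NULL) {
  genes <- sort(union(scores_tf1$gene_id, scores_tf2$gene_id))
  s1 <- scores_tf1$score[match(genes, scores_tf1$gene_id)]
  s2 <- scores_tf2$score[match(genes, scores_tf2$gene_id)]
  s1[is.na(s1)] <- 0
  s2[is.na(s2)] <- 0
  t1 <- s1 > cut1
  t2 <- s2 > cut2
  target_class <- ifelse(t1 & t2, "dual",
                  ifelse(t1, "tf1-exclusive",
                  ifelse(t2, "tf2-exclusive", "none")))
  profiles <- data.frame(gene_id = genes, score_tf1 = s1, score_tf2 = s2,
                         target_class = target_class,
                         stringsAsFactors = FALSE)
  class_levels <- c("tf1-exclusive", "tf2-exclusive", "dual", "none")
  if (!is.null(cumulative)) {
    cfc <- cumulative$cumulative_fc[match(genes, cumulative$gene_id)]
    profiles$cumulative_fc <- cfc
    profiles$direction <- ifelse(is.na(cfc) | cfc == 0, "none",
                                 ifelse(cfc > 0, "up", "down"))
    tab <- table(factor(profiles$target_class, levels = class_levels),
                 factor(profiles$direction, levels = c("down", "up", "none")))
    quadrant_counts <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(quadrant_counts) <- c("target_class", "direction", "n")
  } else {
    tab <- table(factor(profiles$target_class, levels = class_levels))
    quadrant_counts <- data.frame(target_class = names(tab),
                                  n = as.integer(tab),
                                  stringsAsFactors = FALSE)
  }
  list(profiles = profiles, quadrant_counts = quadrant_counts)
}

#' Fraction of direct targets per response phase
#'
#' For the early, late-only and all-DEG phase groups, counts how many
#' genes carry a proximity score above the cutoff (likely direct targets)
#' and reports the percentage to one decimal.
#'
#' @param phases Phase table from [classify_phases()]`$phases`.
#' @param scores Score table from [proximity_scores()].
#' @param cutoff Strict score cutoff defining a direct target; default 10.
#' @return data.frame with `phase`, `n_genes`, `n_direct`, `fraction_pct`
#'   (`NA` for an empty phase group).
#' @export
direct_fraction_by_phase <- function(phases, scores, cutoff = 10) {
  direct_ids <- scores$gene_id[scores$score > cutoff]
  groups <- list(
    early = phases$gene_id[phases$is_early],
    `late-only` = phases$gene_id[phases$phase_label == "late-only"],
    `all-deg` = phases$gene_id[phases$is_early | phases$is_late])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    ids <- groups[[g]]
    n <- length(ids)
    nd <- sum(ids %in% direct_ids)
    data.frame(phase = g, n_genes = n, n_direct = nd,
               fraction_pct = if (n > 0) format_pct(nd, n) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# percentage of num/den rounded for report display
format_pct <- function(num, den, digits = 1) {
  round(100 * num / den, digits)
}

#' Running mean of proximity scores along the fold-change order
#'
#' Orders genes by their log2 fold change at one time point and averages
#' the proximity score over consecutive non-overlapping windows of
#' `window_n` genes, tracing how binding strength varies from the most
#' down- to the most up-regulated genes. A trailing partial window is
#' kept (and flagged) when it holds at least `window_n / 2` genes and
#' dropped otherwise; fewer genes than `window_n` yield a single window
#' over all of them.
#'
#' @param profiles data.frame with `gene_id`, `log2fc`, `score`.
#' @param window_n Genes per window; default 100.
#' @return data.frame with `window`, `n_genes`, `mean_log2fc`,
#'   `mean_score`, `partial`.
#' @export
running_mean_by_fc <- function(profiles, window_n = 100) {
  stopifnot(window_n >= 1)
  ord <- order(profiles$log2fc, profiles$gene_id)
  fc <- profiles$log2fc[ord]
  sc <- profiles$score[ord]
  n <- length(fc)
  if (n == 0L) {
    return(data.frame(window = integer(0), n_genes = integer(0),
                      mean_log2fc = numeric(0), mean_score = numeric(0),
                      partial = logical(0)))
  }
  if (n < window_n) {
    bounds <- data.frame(from = 1L, to = n, partial = TRUE)
  } else {
    k <- n %/% window_n
    r <- n %% window_n
    from <- (seq_len(k) - 1L) * window_n + 1L
    to <- seq_len(k) * window_n
    bounds <- data.frame(from = from, to = to, partial = FALSE)
    if (r >= window_n / 2) {
      bounds <- rbind(bounds,
                      data.frame(from = k * window_n + 1L, to = n,
                                 partial = TRUE))
    }
  }
  out <- do.call(rbind, lapply(seq_len(nrow(bounds)), function(w) {
    i <- seq(bounds$from[w], bounds$to[w])
    data.frame(window = w, n_genes = length(i),
               mean_log2fc = mean(fc[i]), mean_score = mean(sc[i]),
               partial = bounds$partial[w])
  }))
  rownames(out) <- NULL
  out
}

#' Compare proximity scores of down- vs up-regulated direct targets
#'
#' Restricts to likely direct targets (score strictly above `cutoff`),
#' splits them by regulation direction (sign of the cumulative fold
#' change) and compares the score distributions with a Welch t-test on
#' log2-transformed scores; means and SDs are reported on the raw score
#' scale.
#'
#' @param profiles data.frame with `gene_id`, `score`, `cumulative_fc`.
#' @param cutoff Direct-target score cutoff; default 10.
#' @param pseudo Pseudo-count for the Welch log transform; default 0.1.
#' @return A list with `n_down`, `n_up`, `mean_down`, `sd_down`,
#'   `mean_up`, `sd_up`, `welch_p` and `flagged` (`TRUE` with `NA` p when
#'   either group has fewer than two members).
#' @export
compare_down_vs_up <- function(profiles, cutoff = 10, pseudo = 0.1) {
  direct <- profiles[profiles$score > cutoff, , drop = FALSE]
  down <- direct$score[direct$cumulative_fc < 0]
  up <- direct$score[direct$cumulative_fc > 0]
  flagged <- length(down) < 2L || length(up) < 2L
  p <- if (flagged) NA_real_ else welch_log2(down, up, pseudo)$p
  list(n_down = length(down), n_up = length(up),
       mean_down = if (length(down)) mean(down) else NA_real_,
       sd_down = if (length(down) > 1) stats::sd(down) else NA_real_,
       mean_up = if (length(up)) mean(up) else NA_real_,
       sd_up = if (length(up) > 1) stats::sd(up) else NA_real_,
       welch_p = p, flagged = flagged)
}

#' Flag consensus summits carrying a binding motif
#'
#' Joins an external motif hit table (e.g. from a de novo motif scan)
#' onto a consensus summit set: a summit carries the motif when at least
#' one hit with a score strictly above `threshold` lies within `flank`
#' bp of the summit (window boundary inclusive).
#'
#' @param consensus Consensus summit set (see
#'   [build_consensus_summits()]).
#' @param hits data.frame with columns `chrom`, `position`, `score`.
#' @param threshold Strict motif score threshold; default 8.005008.
#' @param flank Half-window around the summit in bp; default 100.
#' @return A list with `summits` (the consensus table plus a `has_motif`
#'   column), `n_with_motif` and `fraction_pct` (to one decimal).
#' @export
join_motif_hits <- function(consensus, hits, threshold = 8.005008,
                            flank = 100) {
  good <- hits[hits$score > threshold, , drop = FALSE]
  has <- logical(nrow(consensus))
  by_chr <- split(good$position, good$chrom)
  for (chr in intersect(unique(consensus$chrom), names(by_chr))) {
    pos <- sort(by_chr[[chr]])
    ci <- which(consensus$chrom == chr)
    lo <- findInterval(consensus$summit[ci] - flank - 0.5, pos)
    hi <- findInterval(consensus$summit[ci] + flank + 0.5, pos)
    has[ci] <- hi > lo
  }
  consensus$has_motif <- has
  list(summits = consensus, n_with_motif = sum(has),
       fraction_pct = if (nrow(consensus) > 0)
         format_pct(sum(has), nrow(consensus)) else NA_real_)
}
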