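# Consensus peak-summit construction and peak-set comparisons.
#
# Two peaks overlap only when the intersection covers at least half of the
# shorter peak ("50%-of-shorter" rule); replicate concordance is judged
# against the ENCODE criterion that 75% of either replicate's peaks be
# shared. Consensus summit sets quantify each sample's binding at every
# location where at least one sample had a peak.

#' 50%-of-shorter interval overlap rule
#'
#' Two genomic intervals overlap only if the length of their intersection
#' is at least `min_frac` times the length of the shorter interval
#' (boundary inclusive). The rule is symmetric; intervals on different
#' chromosomes never overlap.
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end` (0-based,
#'   half-open). Rows are compared pairwise; one argument may have a
#'   single row, which is recycled.
#' @param min_frac Required fraction of the shorter interval; default 0.5.
#' @return Logical vector.
#' @export
overlaps_50pct <- function(a, b, min_frac = 0.5) {
  stopifnot(min_frac > 0, min_frac <= 1)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep(seq_len(nrow(a)), length.out = n), , drop = FALSE]
  if (nrow(b) != n) b <- b[rep(seq_len(nrow(b)), length.out = n), , drop = FALSE]
  inter <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  shorter <- pmin(a$end - a$start, b$end - b$start)
  a$chrom == b$chrom & inter >= min_frac * shorter
}

# interval-tree search for all pairs (i in a, j in b) passing the
# 50%-of-shorter rule; coordinates converted to 1-based closed for IRanges
overlap_pairs_50pct <- function(a, b, min_frac = 0.5) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1, a$end))
  gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1, b$end))
  hits <- GenomicRanges::findOverlaps(ga, gb)
  qi <- S4Vectors::queryHits(hits)
  sj <- S4Vectors::subjectHits(hits)
  iw <- IRanges::width(IRanges::pintersect(IRanges::ranges(ga)[qi],
                                           IRanges::ranges(gb)[sj]))
  shorter <- pmin(a$end[qi] - a$start[qi], b$end[sj] - b$start[sj])
  ok <- iw >= min_frac * shorter
  data.frame(i = qi[ok], j = sj[ok])
}

#' Replicate concordance under the 50%-of-shorter rule
#'
#' Reports, for each replicate, the percentage of its peaks that have at
#' least one 50%-rule match in the other replicate, and whether both
#' fractions meet the ENCODE sharing criterion.
#'
#' @param rep_a,rep_b Peak data.frames (see [read_narrowpeak()]).
#' @param min_frac Overlap-rule fraction; default 0.5.
#' @param encode_threshold Required shared percentage; default 75.
#' @return A list of class `concordance_report` with `n_a`, `n_b`,
#'   `shared_frac_a`, `shared_frac_b` (percent) and `passes_encode`.
#'   An empty replicate yields 0% fractions and a failing report.
#' @export
replicate_concordance <- function(rep_a, rep_b, min_frac = 0.5,
                                  encode_threshold = 75) {
  n_a <- nrow(rep_a)
  n_b <- nrow(rep_b)
  if (n_a == 0L || n_b == 0L) {
    return(structure(list(n_a = n_a, n_b = n_b, shared_frac_a = 0,
                          shared_frac_b = 0, passes_encode = FALSE),
                     class = "concordance_report"))
  }
  pairs <- overlap_pairs_50pct(rep_a, rep_b, min_frac)
  fa <- 100 * length(unique(pairs$i)) / n_a
  fb <- 100 * length(unique(pairs$j)) / n_b
  structure(list(n_a = n_a, n_b = n_b, shared_frac_a = fa,
                 shared_frac_b = fb,
                 passes_encode = min(fa, fb) >= encode_threshold),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("Replicate concordance: %.1f%% of %d / %.1f%% of %d shared; ENCODE criterion %s\n",
              x$shared_frac_a, x$n_a, x$shared_frac_b, x$n_b,
              if (x$passes_encode) "met" else "not met"))
  invisible(x)
}

#' Build a consensus summit set across samples
#'
#' Pools the peak summits of all samples and groups them so that every
#' input summit belongs to exactly one consensus location: summits are
#' visited in decreasing fold-enrichment order (ties broken by leftmost
#' summit, then lexicographic sample id, then peak name) and each
#' still-unassigned summit within `merge_dist` of the current seed joins
#' its consensus. The consensus summit is therefore the summit of the
#' strongest contributing peak, and all members lie within `merge_dist`
#' of it. Each sample's enrichment at a consensus is the fold enrichment
#' of its strongest contributing peak, or 0 when the sample has no peak
#' there, giving a dense location x sample enrichment matrix.
#'
#' @param peak_sets Named list of peak data.frames, one per sample.
#' @param merge_dist Maximum summit distance to the consensus summit in
#'   bp; default 100 (the +/-100 bp summit-window convention).
#' @return data.frame with columns `chrom`, `summit`, `start`, `end`
#'   (merged interval), `source_count` and one `fe.<sample>` column per
#'   sample; the sample names are kept in the `"samples"` attribute.
#' @export
build_consensus_summits <- function(peak_sets, merge_dist = 100) {
  stopifnot(is.list(peak_sets), merge_dist >= 0)
  samples <- names(peak_sets)
  if (is.null(samples) || any(!nzchar(samples)) || anyDuplicated(samples)) {
    stop("peak_sets must be a named list with unique, non-empty names")
  }
  pool <- do.call(rbind, lapply(samples, function(s) {
    p <- peak_sets[[s]]
    if (nrow(p) == 0L) return(NULL)
    data.frame(sample = s, chrom = p$chrom, start = p$start, end = p$end,
               summit = p$summit, fold_enrichment = p$fold_enrichment,
               name = p$name, stringsAsFactors = FALSE)
  }))
  fe_cols <- paste0("fe.", samples)
  if (is.null(pool) || nrow(pool) == 0L) {
    out <- data.frame(chrom = character(0), summit = numeric(0),
                      start = numeric(0), end = numeric(0),
                      source_count = integer(0))
    for (col in fe_cols) out[[col]] <- numeric(0)
    attr(out, "samples") <- samples
    return(out)
  }

  res <- list()
  for (chr in sort(unique(pool$chrom))) {
    sub <- pool[pool$chrom == chr, , drop = FALSE]
    # deterministic seed order: strongest first
    seed_order <- order(-sub$fold_enrichment, sub$summit, sub$sample, sub$name)
    pos_order <- order(sub$summit)
    pos_sorted <- sub$summit[pos_order]
    assigned <- logical(nrow(sub))
    clusters <- vector("list", nrow(sub))
    k <- 0L
    for (i in seed_order) {
      if (assigned[i]) next
      s <- sub$summit[i]
      lo <- findInterval(s - merge_dist - 0.5, pos_sorted) + 1L
      hi <- findInterval(s + merge_dist + 0.5, pos_sorted)
      members <- pos_order[lo:hi]
      members <- members[!assigned[members]]
      assigned[members] <- TRUE
      k <- k + 1L
      mem <- sub[members, , drop = FALSE]
      fe_by_sample <- tapply(mem$fold_enrichment,
                             factor(mem$sample, levels = samples),
                             max)
      row <- data.frame(chrom = chr, summit = s,
                        start = min(mem$start), end = max(mem$end),
                        source_count = length(members),
                        stringsAsFactors = FALSE)
      row[fe_cols] <- as.list(ifelse(is.na(fe_by_sample), 0, fe_by_sample))
      clusters[[k]] <- row
    }
    res[[chr]] <- do.call(rbind, clusters[seq_len(k)])
  }
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$summit), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  out
}

#' Cross-condition change in consensus peak enrichment
#'
#' Compares per-summit mean fold enrichment between two sample groups of
#' a consensus summit set: the percent change of the group mean and a
#' Welch t-test (via [welch_log2()]) on the two per-summit enrichment
#' vectors.
#'
#' Each group's per-summit enrichment vector is taken over the summits
#' at which that group has a peak (enrichment > 0), so the statistic
#' measures the change in binding strength among observed peaks and is
#' not conflated with the separate change in peak *count* (see
#' [peak_count_reduction()]).
#'
#' @param consensus Output of [build_consensus_summits()].
#' @param group_a,group_b Character vectors of sample ids (reference
#'   first: the change is reported as b relative to a).
#' @param pseudo Pseudo-count for the log transform; default 0.1.
#' @return A list with `percent_change`
#'   (`100 * (mean_b - mean_a) / mean_a`), `welch_p`, `mean_a`, `mean_b`,
#'   `n_summits` and `flagged` (`TRUE` with `NA` p when group b has no
#'   enrichment anywhere, in which case the change is exactly -100).
#' @export
enrichment_change <- function(consensus, group_a, group_b, pseudo = 0.1) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  cols_a <- paste0("fe.", group_a)
  cols_b <- paste0("fe.", group_b)
  miss <- setdiff(c(cols_a, cols_b), names(consensus))
  if (length(miss)) stop("unknown sample(s): ",
                         paste(sub("^fe\\.", "", miss), collapse = ", "))
  ma <- rowMeans(consensus[, cols_a, drop = FALSE])
  mb <- rowMeans(consensus[, cols_b, drop = FALSE])
  if (length(ma) == 0L) stop("empty consensus set")
  ma <- ma[ma > 0]
  mb <- mb[mb > 0]
  if (length(ma) == 0L) stop("reference group has zero enrichment everywhere")
  if (length(mb) == 0L) {
    return(list(percent_change = -100, welch_p = NA_real_,
                mean_a = mean(ma), mean_b = 0,
                n_summits = nrow(consensus), flagged = TRUE))
  }
  pct <- 100 * (mean(mb) - mean(ma)) / mean(ma)
  p <- welch_log2(ma, mb, pseudo)$p
  list(percent_change = pct, welch_p = p, mean_a = mean(ma),
       mean_b = mean(mb), n_summits = nrow(consensus), flagged = FALSE)
}

#' Percent reduction in peak count
#'
#' @param n_a Reference peak count.
#' @param n_b Comparison peak count.
#' @return `100 * (n_a - n_b) / n_a`.
#' @export
peak_count_reduction <- function(n_a, n_b) {
  stopifnot(n_a > 0)
  100 * (n_a - n_b) / n_a
}
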