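# Temporal differential-expression calls and early/late phase accounting.
# A gene is a DEG at a time point when its q-value is strictly below alpha;
# the early phase covers 3-18 h after silencing and the late phase 48/96 h.

#' Call differentially expressed genes per time point
#'
#' Applies the strict q-value threshold (`qvalue < alpha`; a q-value
#' exactly equal to `alpha` is not significant) to every gene x time-point
#' record and assigns a direction from the sign of the recalculated log2
#' fold change.
#'
#' @param records Expression data.frame with columns `gene_id`, `time_h`,
#'   `log2fc`, `qvalue` (see [read_expression_table()]).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return data.frame with columns `gene_id`, `time_h`, `log2fc`,
#'   `qvalue`, `significant`, `direction` (`"up"`, `"down"` or `"none"`).
#' @export
call_degs <- function(records, alpha = 0.05) {
  stopifnot(is.data.frame(records), length(alpha) == 1L,
            alpha > 0, alpha < 1)
  need <- c("gene_id", "time_h", "log2fc", "qvalue")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  sig <- records$qvalue < alpha
  data.frame(
    gene_id = records$gene_id,
    time_h = records$time_h,
    log2fc = records$log2fc,
    qvalue = records$qvalue,
    significant = sig,
    direction = ifelse(!sig, "none", ifelse(records$log2fc > 0, "up", "down")),
    stringsAsFactors = FALSE)
}

# Shared accounting arithmetic: cumulative counts are the running sum of
# first-ever-significant ("new") counts, and phase totals satisfy
# early + late - both = total. Used both on real call sets and on printed
# count vectors (verify_paper_arithmetic).
build_accounting <- function(new_counts, time_points, early_times,
                             late_times, n_both) {
  stopifnot(length(new_counts) == length(time_points))
  is_early <- time_points %in% early_times
  per_time <- data.frame(
    time_h = time_points,
    phase = ifelse(is_early, "early", "late"),
    new_degs = as.integer(new_counts),
    cumulative_degs = as.integer(cumsum(new_counts)),
    stringsAsFactors = FALSE)
  total <- sum(new_counts)
  early_total <- sum(new_counts[is_early])
  late_total <- sum(new_counts[!is_early]) + n_both
  list(per_time = per_time,
       totals = list(early = as.integer(early_total),
                     late = as.integer(late_total),
                     both = as.integer(n_both),
                     total = as.integer(total)))
}

#' Classify genes into early/late response phases
#'
#' A gene is an early responder when it is significant at any early time
#' point (default 3-18 h) and a late responder when significant at any
#' late time point (default 48 or 96 h); the two are not exclusive. The
#' accompanying accounting attributes each DEG to the time point at which
#' it first becomes significant ("new per time point") and reports the
#' running cumulative count together with phase totals satisfying
#' `early + late - both = total`.
#'
#' @param calls Output of [call_degs()].
#' @param early_times,late_times Time points (hours) defining the two
#'   phases; every time point present in `calls` must belong to one of
#'   them.
#' @return A list with `phases` (data.frame: `gene_id`, `is_early`,
#'   `is_late`, `phase_label` in early-only/late-only/both/never) and
#'   `accounting` (list with `per_time` data.frame and `totals`).
#' @export
classify_phases <- function(calls, early_times = c(3, 6, 9, 12, 15, 18),
                            late_times = c(48, 96)) {
  stopifnot(is.data.frame(calls))
  all_times <- sort(c(early_times, late_times))
  if (anyDuplicated(all_times)) {
    stop("early and late time-point sets overlap")
  }
  extra <- setdiff(unique(calls$time_h), all_times)
  if (length(extra)) {
    stop("time point(s) not assigned to either phase: ",
         paste(extra, collapse = ", "))
  }

  genes <- sort(unique(calls$gene_id))
  sig <- calls[calls$significant, , drop = FALSE]
  early_ids <- unique(sig$gene_id[sig$time_h %in% early_times])
  late_ids <- unique(sig$gene_id[sig$time_h %in% late_times])
  is_early <- genes %in% early_ids
  is_late <- genes %in% late_ids
  phase_label <- ifelse(is_early & is_late, "both",
                 ifelse(is_early, "early-only",
                 ifelse(is_late, "late-only", "never")))
  phases <- data.frame(gene_id = genes, is_early = is_early,
                       is_late = is_late, phase_label = phase_label,
                       stringsAsFactors = FALSE)

  first_time <- if (nrow(sig)) {
    tapply(sig$time_h, sig$gene_id, min)
  } else {
    numeric(0)
  }
  new_counts <- as.integer(table(factor(first_time, levels = all_times)))
  n_both <- sum(is_early & is_late)
  accounting <- build_accounting(new_counts, all_times, early_times,
                                 late_times, n_both)
  list(phases = phases, accounting = accounting)
}

#' Cumulative fold change over significant time points
#'
#' Summarises each gene's response as the sum of its log2 fold changes
#' over the time points at which it was significant; genes never
#' significant get a cumulative fold change of 0 and are flagged with
#' `is_deg = FALSE`. The sign of the cumulative fold change is the
#' direction used for all per-direction summaries.
#'
#' @param calls Output of [call_degs()] (any number of genes).
#' @return data.frame with `gene_id`, `cumulative_fc`, `is_deg`.
#' @export
cumulative_fc <- function(calls) {
  stopifnot(is.data.frame(calls))
  genes <- sort(unique(calls$gene_id))
  sig <- calls[calls$significant, , drop = FALSE]
  sums <- tapply(sig$log2fc, factor(sig$gene_id, levels = genes), sum)
  out <- data.frame(
    gene_id = genes,
    cumulative_fc = as.numeric(ifelse(is.na(sums), 0, sums)),
    is_deg = genes %in% sig$gene_id,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select the top-n genes per direction at one time point
#'
#' Selects, irrespective of statistical significance, the `n` most
#' significantly altered genes (ascending q-value) separately among up-
#' and down-regulated genes at a single time point, for downstream
#' enrichment analyses. Ties in q-value are broken by descending
#' `|log2fc|` and then by gene id for determinism; genes with a log2 fold
#' change of exactly zero belong to neither direction.
#'
#' @param records Expression records (`gene_id`, `log2fc`, `qvalue`) for
#'   exactly one time point.
#' @param n Genes to keep per direction; default 150 (300 in total when
#'   both directions are fully populated).
#' @return data.frame of the selected records with a `direction` column,
#'   up-regulated first, each direction in ranking order.
#' @export
select_top_n <- function(records, n = 150) {
  stopifnot(is.data.frame(records), n >= 1)
  if ("time_h" %in% names(records) &&
      length(unique(records$time_h)) > 1L) {
    stop("select_top_n expects records from a single time point")
  }
  pick <- function(dir) {
    sub <- if (dir == "up") records[records$log2fc > 0, , drop = FALSE]
           else records[records$log2fc < 0, , drop = FALSE]
    sub <- sub[order(sub$qvalue, -abs(sub$log2fc), sub$gene_id), , drop = FALSE]
    sub <- utils::head(sub, n)
    sub$direction <- rep(dir, nrow(sub))
    sub
  }
  up <- pick("up")
  down <- pick("down")
  out <- rbind(up, down)
  rownames(out) <- NULL
  out
}
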