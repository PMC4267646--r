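#!/usr/bin/env Rscript

# Step 4 - proximity scoring and direct/indirect target classification.
#
# Scores every gene for proximal binding of each factor (exponential
# distance decay of fold enrichment around the TSS, scramble-condition
# consensus enrichments), classifies DEGs into target quadrants at the
# cutoffs 10 (silenced factor) and 5 (partner), and summarises the
# binding-vs-regulation relationship: direct fractions per phase,
# running-mean score profiles along the fold-change order, and the
# down- vs up-regulated score contrast.

suppressPackageStartupMessages(library(tftargets))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
ann <- read_gene_annotation("results/sim/annotation.tsv")
cons1 <- read.delim("results/tables/consensus_summits_tf1.tsv")
cons2 <- read.delim("results/tables/consensus_summits_tf2.tsv")
calls <- read.delim("results/tables/deg_calls.tsv")
phases <- read.delim("results/tables/gene_phases.tsv")
cfc <- read.delim("results/tables/cumulative_fc.tsv")

sc1 <- proximity_scores(ann, cons1, d0 = 5000, window = 5e5, "fe.tf1_scr")
sc2 <- proximity_scores(ann, cons2, d0 = 5000, window = 5e5, "fe.tf2_scr")
deg_ids <- cfc$gene_id[cfc$is_deg]

cls <- classify_targets(sc1[sc1$gene_id %in% deg_ids, ],
                        sc2[sc2$gene_id %in% deg_ids, ],
                        cut1 = 10, cut2 = 5, cumulative = cfc)
write.table(cls$profiles, "results/tables/target_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cls$quadrant_counts, "results/tables/quadrant_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Target quadrants among DEGs (by regulation direction):\n")
qc <- cls$quadrant_counts
print(qc[qc$n > 0, ], row.names = FALSE)

frac <- direct_fraction_by_phase(phases, sc1, cutoff = 10)
write.table(frac, "results/tables/direct_fractions_tf1.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Fraction of DEGs with strong proximal silenced-factor binding:\n")
print(frac, row.names = FALSE)

prof <- merge(sc1, cfc, by = "gene_id")
prof <- prof[prof$is_deg, ]
for (ph in c("early", "late-only")) {
  ids <- if (ph == "early") phases$gene_id[phases$is_early]
         else phases$gene_id[phases$phase_label == "late-only"]
  dvu <- compare_down_vs_up(prof[prof$gene_id %in% ids, ], cutoff = 10)
  cat(sprintf("%s direct targets: down %.1f +/- %.1f (n=%d) vs up %.1f +/- %.1f (n=%d), Welch p = %.2g\n",
              ph, dvu$mean_down, dvu$sd_down, dvu$n_down,
              dvu$mean_up, dvu$sd_up, dvu$n_up, dvu$welch_p))
}

rmeans <- do.call(rbind, lapply(split(calls, calls$time_h), function(ct) {
  ct <- ct[ct$gene_id %in% deg_ids, ]
  ct$score <- sc1$score[match(ct$gene_id, sc1$gene_id)]
  rm <- running_mean_by_fc(ct, window_n = 100)
  if (nrow(rm)) rm$time_h <- ct$time_h[1]
  rm
}))
write.table(rmeans, "results/tables/running_means.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# quadrant scatter in the style of a two-factor score plot
if (requireNamespace("ggplot2", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
  library(ggplot2)
  p <- ggplot(cls$profiles,
              aes(x = pmax(score_tf1, 0.05), y = pmax(score_tf2, 0.05),
                  colour = direction)) +
    geom_point(alpha = 0.7, size = 1.4) +
    geom_vline(xintercept = 10, linetype = "dashed", colour = "grey40") +
    geom_hline(yintercept = 5, linetype = "dashed", colour = "grey40") +
    scale_x_log10() + scale_y_log10() +
    scale_colour_manual(values = c(down = "#2166ac", up = "#b2182b",
                                   none = "grey70")) +
    labs(x = "silenced-factor proximity score",
         y = "partner-factor proximity score",
         colour = "regulation") +
    theme_bw()
  ggsave("results/figures/target_quadrants.png", p,
         width = 5.5, height = 4.5, dpi = 150)
  cat("Wrote results/figures/target_quadrants.png\n")
}
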