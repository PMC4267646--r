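#!/usr/bin/env Rscript

# Step 3 - consensus binding locations and knock-down effects on binding.
#
# Checks replicate concordance under the 50%-of-shorter rule against the
# ENCODE 75% criterion, merges each factor's scramble and knock-down
# peaks into a consensus summit set, and quantifies the knock-down effect
# as both a peak-count reduction and an enrichment reduction among
# surviving peaks.

suppressPackageStartupMessages(library(tftargets))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
read_pk <- function(name) read_narrowpeak(sprintf("results/sim/%s.narrowPeak", name))

for (cond in c("tf1_scr", "tf1_kd")) {
  conc <- replicate_concordance(read_pk(paste0(cond, "_r1")),
                                read_pk(paste0(cond, "_r2")))
  cat(sprintf("%s replicates: %.1f%% / %.1f%% shared, ENCODE criterion %s\n",
              cond, conc$shared_frac_a, conc$shared_frac_b,
              if (conc$passes_encode) "met" else "NOT met"))
}

peaks <- lapply(c(tf1_scr = "tf1_scr", tf1_kd = "tf1_kd",
                  tf2_scr = "tf2_scr", tf2_kd = "tf2_kd"), read_pk)

cons1 <- build_consensus_summits(peaks[c("tf1_scr", "tf1_kd")])
cons2 <- build_consensus_summits(peaks[c("tf2_scr", "tf2_kd")])
write.table(cons1, "results/tables/consensus_summits_tf1.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cons2, "results/tables/consensus_summits_tf2.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

red <- peak_count_reduction(nrow(peaks$tf1_scr), nrow(peaks$tf1_kd))
cat(sprintf("Silenced factor: %d -> %d peaks on knock-down (%.1f%% reduction)\n",
            nrow(peaks$tf1_scr), nrow(peaks$tf1_kd), red))
ech <- enrichment_change(cons1, "tf1_scr", "tf1_kd")
cat(sprintf("Enrichment among surviving peaks changed %.1f%% (Welch p = %.3g)\n",
            ech$percent_change, ech$welch_p))
gain <- -peak_count_reduction(nrow(peaks$tf2_scr), nrow(peaks$tf2_kd))
cat(sprintf("Partner factor: %d -> %d peaks (%.1f%% gain)\n",
            nrow(peaks$tf2_scr), nrow(peaks$tf2_kd), gain))
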