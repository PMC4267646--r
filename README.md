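# tftargets

Classify the direct and indirect targets of a transcription factor by
integrating an siRNA knock-down expression time course with ChIP-seq of
the silenced factor and a partner factor.

When a factor is silenced, its direct targets change expression early
and carry strong binding of the factor near their transcription start
sites (TSS); indirect targets respond late, through intermediate
regulators such as other transcription factors whose own expression and
chromatin occupancy shift after the knock-down. This package provides
the full analysis for that design - built for researchers in regulatory
genomics who have per-time-point differential-expression tables and
narrowPeak files and want a tested, deterministic path from those
inputs to a target classification:

* **Temporal DEG phasing** - strict `q < 0.05` calls per time point on
  pseudo-count-recalculated fold changes
  (`log2((T + 0.1)/(C + 0.1))`), early (3-18 h) vs late (48/96 h)
  phases, first-significant-time accounting, cumulative fold changes.
* **Consensus peak summits** - one merged location set per factor with
  each sample's fold enrichment quantified everywhere any sample has a
  peak; replicate concordance under the 50%-of-shorter overlap rule
  against the ENCODE 75% criterion; knock-down effects reported
  separately as peak-count reduction and enrichment reduction.
* **Peak proximity scores** - the TF association strength of Ouyang et
  al.: for gene *j*, `a_j = Σ_k g_k · exp(−d_k/d0)` over peaks within
  ±500 kb of the TSS, with `g_k` the fold enrichment over input and
  `d_k` the unsigned summit-to-TSS distance (`d0` = 5 kb by default).
* **Target quadrants** - genes scoring `> 10` for the silenced factor
  and/or `> 5` for the partner are classified factor-1-exclusive /
  factor-2-exclusive / dual / none, split by regulation direction.
* **A synthetic-data generator** - plants direct/indirect/null genes,
  knock-down peak thinning (19% retention, 0.4× enrichment), partner
  occupancy gain (1.5×) and shared sites (9%), so the whole pipeline is
  testable against known ground truth without any external data.

## Worked example

The `analysis/` scripts run the workflow end to end on a generated
study (2,000 genes, 160 planted direct targets, 90 indirect late
responders):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_consensus_peaks.R
Rscript analysis/04_target_classification.R
Rscript analysis/05_report.R
```

Step 3 prints the knock-down effect on binding:

```
tf1_scr replicates: 93.3% / 95.8% shared, ENCODE criterion met
Silenced factor: 784 -> 130 peaks on knock-down (83.4% reduction)
Enrichment among surviving peaks changed -62.0% (Welch p = 3.12e-29)
Partner factor: 553 -> 829 peaks (49.9% gain)
```

i.e. silencing removed ~83% of the factor's peaks, the surviving peaks
lost ~62% of their enrichment, and the partner factor *gained* ~50%
more sites. Step 4 classifies the detected DEGs and contrasts binding
by regulation direction:

```
Fraction of DEGs with strong proximal silenced-factor binding:
     phase n_genes n_direct fraction_pct
     early     172      151         87.8
 late-only     114        2          1.8
early direct targets: down 38.2 +/- 14.9 (n=99) vs up 24.4 +/- 9.1 (n=52), Welch p = 1.4e-09
```

Early responders are overwhelmingly bound (direct targets) while
late-only responders almost never are (indirect targets), and
down-regulated direct targets carry significantly stronger proximal
binding than up-regulated ones - the signature of a factor that mainly
activates its direct targets. The same run, orchestrated as a single
call with a JSON report, is `run_pipeline(run_config(...))` (step 5).

The same functions work on real data: point `run_config()` at your
expression TSV (`gene_id, time_h, fpkm_control, fpkm_treated, qvalue`),
a gene annotation (TSV or GTF) and narrowPeak files per factor and
condition.

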