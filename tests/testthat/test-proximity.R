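gene1 <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                    tss = 100000, stringsAsFactors = FALSE)

test_that("proximity score evaluates the exponential decay sum", {
  # peak at the TSS contributes its full enrichment
  at_tss <- peak_df("chr1", 99900, 100100, summit = 100000, fe = 5)
  expect_equal(proximity_scores(gene1, at_tss)$score, 5)
  # one decay length away contributes exp(-1)
  at_d0 <- peak_df("chr1", 104900, 105100, summit = 105000, fe = 10)
  expect_equal(proximity_scores(gene1, at_d0, d0 = 5000)$score,
               10 * exp(-1), tolerance = 1e-12)
  # beyond the window contributes nothing
  far <- peak_df("chr1", 700000, 700200, summit = 700100, fe = 50)
  expect_equal(proximity_scores(gene1, far)$score, 0)
  # distance is unsigned: upstream and downstream are equivalent
  up <- peak_df("chr1", 97900, 98100, summit = 98000, fe = 7)
  dn <- peak_df("chr1", 101900, 102100, summit = 102000, fe = 7)
  expect_equal(proximity_scores(gene1, up)$score,
               proximity_scores(gene1, dn)$score)
  # absent chromosome scores zero
  other <- data.frame(gene_id = "g2", chrom = "chrX", strand = "-",
                      tss = 5000, stringsAsFactors = FALSE)
  expect_equal(proximity_scores(other, at_tss)$score, 0)
})

test_that("proximity scores equal the brute-force loop oracle", {
  set.seed(71)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20),
                      chrom = sample(c("chr1", "chr2"), 20, TRUE),
                      strand = "+",
                      tss = sample.int(2e6, 20), stringsAsFactors = FALSE)
  peaks <- random_peaks(50, chroms = c("chr1", "chr2"), max_pos = 2e6)
  got <- proximity_scores(genes, peaks, d0 = 5000, window = 5e5)
  for (i in seq_len(nrow(genes))) {
    expect_equal(got$score[i],
                 oracle_proximity(genes[i, ], peaks, d0 = 5000,
                                  window = 5e5),
                 tolerance = 1e-12)
  }
})

test_that("proximity score is additive, decay-monotone and has the right limits", {
  set.seed(72)
  pk1 <- random_peaks(30, chroms = "chr1", max_pos = 6e5)
  pk2 <- random_peaks(30, chroms = "chr1", max_pos = 6e5)
  g <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                  tss = 300000, stringsAsFactors = FALSE)
  s_union <- proximity_scores(g, rbind(pk1, pk2))$score
  expect_equal(s_union, proximity_scores(g, pk1)$score +
                 proximity_scores(g, pk2)$score, tolerance = 1e-12)

  # moving a peak farther from the TSS never increases the score
  near <- peak_df("chr1", 300900, 301100, summit = 301000, fe = 4)
  farther <- peak_df("chr1", 305900, 306100, summit = 306000, fe = 4)
  expect_gt(proximity_scores(g, near)$score,
            proximity_scores(g, farther)$score)
  # increasing enrichment never decreases the score
  stronger <- near
  stronger$fold_enrichment <- 8
  expect_gt(proximity_scores(g, stronger)$score,
            proximity_scores(g, near)$score)

  # d0 -> Inf: sum of enrichments in the window; d0 -> 0: only TSS peaks
  within <- pk1[abs(pk1$summit - 300000) <= 5e5, ]
  expect_equal(proximity_scores(g, pk1, d0 = 1e12)$score,
               sum(within$fold_enrichment), tolerance = 1e-6)
  at_tss <- peak_df("chr1", 299900, 300100, summit = 300000, fe = 3)
  expect_equal(proximity_scores(g, rbind(pk1, at_tss), d0 = 1e-9)$score, 3)
})

test_that("target quadrants use strict cutoffs", {
  sc <- function(g, s) data.frame(gene_id = g, score = s,
                                  stringsAsFactors = FALSE)
  s1 <- sc(c("a", "b", "c", "d"), c(10, 11, 3, 11))
  s2 <- sc(c("a", "b", "c", "d"), c(5, 2, 6, 6))
  cls <- classify_targets(s1, s2, cut1 = 10, cut2 = 5)
  got <- setNames(cls$profiles$target_class, cls$profiles$gene_id)
  expect_equal(got[["a"]], "none")         # boundary: strict inequality
  expect_equal(got[["b"]], "tf1-exclusive")
  expect_equal(got[["c"]], "tf2-exclusive")
  expect_equal(got[["d"]], "dual")

  # a gene missing from one table scores zero for that factor
  cls2 <- classify_targets(sc("a", 20), sc("b", 20))
  prof <- cls2$profiles
  expect_equal(prof$score_tf2[prof$gene_id == "a"], 0)
  expect_equal(prof$target_class[prof$gene_id == "a"], "tf1-exclusive")
  expect_equal(prof$target_class[prof$gene_id == "b"], "tf2-exclusive")
})

test_that("planted quadrant memberships are recovered exactly", {
  set.seed(73)
  n <- 200
  classes <- sample(c("tf1-exclusive", "tf2-exclusive", "dual", "none"),
                    n, replace = TRUE)
  s1 <- ifelse(classes %in% c("tf1-exclusive", "dual"),
               runif(n, 15, 40), runif(n, 0, 8))
  s2 <- ifelse(classes %in% c("tf2-exclusive", "dual"),
               runif(n, 8, 30), runif(n, 0, 4))
  ids <- sprintf("g%03d", 1:n)
  cls <- classify_targets(
    data.frame(gene_id = ids, score = s1, stringsAsFactors = FALSE),
    data.frame(gene_id = ids, score = s2, stringsAsFactors = FALSE))
  expect_equal(cls$profiles$target_class[match(ids, cls$profiles$gene_id)],
               classes)
})

test_that("direct fractions per phase reproduce the published percentages", {
  # 276 early genes of which 149 direct; 130 late-only of which 51 direct
  phases <- data.frame(
    gene_id = sprintf("g%03d", 1:406),
    is_early = c(rep(TRUE, 276), rep(FALSE, 130)),
    is_late = c(rep(FALSE, 198), rep(TRUE, 78), rep(TRUE, 130)),
    stringsAsFactors = FALSE)
  phases$phase_label <- ifelse(phases$is_early & phases$is_late, "both",
                        ifelse(phases$is_early, "early-only", "late-only"))
  direct <- c(sprintf("g%03d", 1:149), sprintf("g%03d", 277:327))
  scores <- data.frame(gene_id = phases$gene_id,
                       score = ifelse(phases$gene_id %in% direct, 20, 1),
                       stringsAsFactors = FALSE)
  frac <- direct_fraction_by_phase(phases, scores, cutoff = 10)
  expect_equal(frac$fraction_pct[frac$phase == "early"], 54.0)
  expect_equal(frac$n_direct[frac$phase == "early"], 149)
  expect_equal(frac$fraction_pct[frac$phase == "late-only"], 39.2)
  expect_equal(frac$n_genes[frac$phase == "late-only"], 130)

  none <- direct_fraction_by_phase(phases, scores, cutoff = 1e6)
  expect_equal(none$fraction_pct[none$phase == "early"], 0)
})

test_that("running means average scores over consecutive fold-change windows", {
  n <- 300
  prof <- data.frame(gene_id = sprintf("g%03d", 1:n),
                     log2fc = seq(-3, 3, length.out = n),
                     score = 7, stringsAsFactors = FALSE)
  rm1 <- running_mean_by_fc(prof, window_n = 100)
  expect_equal(nrow(rm1), 3)
  expect_equal(rm1$mean_score, rep(7, 3))
  expect_false(any(rm1$partial))

  # monotone scores give monotone window means
  prof$score <- seq_len(n)
  rm2 <- running_mean_by_fc(prof, window_n = 100)
  expect_true(all(diff(rm2$mean_score) > 0))

  # windows equal the arithmetic mean oracle over their members
  set.seed(74)
  prof$score <- runif(n)
  prof <- prof[sample(n), ]
  rm3 <- running_mean_by_fc(prof, window_n = 100)
  ord <- prof[order(prof$log2fc, prof$gene_id), ]
  for (w in 1:3) {
    expect_equal(rm3$mean_score[w],
                 mean(ord$score[((w - 1) * 100 + 1):(w * 100)]))
  }

  # trailing window kept when >= half-full, dropped otherwise
  rm_keep <- running_mean_by_fc(prof[1:260, ], window_n = 100)
  expect_equal(nrow(rm_keep), 3)
  expect_true(rm_keep$partial[3])
  expect_equal(rm_keep$n_genes[3], 60)
  rm_drop <- running_mean_by_fc(prof[1:240, ], window_n = 100)
  expect_equal(nrow(rm_drop), 2)
  # fewer genes than one window: a single window over all genes
  rm_small <- running_mean_by_fc(prof[1:30, ], window_n = 100)
  expect_equal(nrow(rm_small), 1)
  expect_equal(rm_small$n_genes, 30)
})

test_that("down- vs up-regulated direct targets compare via Welch on scores", {
  prof <- data.frame(gene_id = sprintf("g%02d", 1:40),
                     score = c(rep(c(20, 25, 30, 35), 5),
                               rep(c(20, 25, 30, 35), 5)),
                     cumulative_fc = rep(c(-1, 1), each = 20),
                     stringsAsFactors = FALSE)
  same <- compare_down_vs_up(prof)
  expect_equal(same$mean_down, same$mean_up)
  expect_gt(same$welch_p, 0.9)

  prof2 <- prof
  prof2$score[prof2$cumulative_fc < 0] <-
    2 * prof2$score[prof2$cumulative_fc < 0]
  doubled <- compare_down_vs_up(prof2)
  expect_equal(doubled$mean_down / doubled$mean_up, 2)
  expect_lt(doubled$welch_p, same$welch_p)

  # sub-cutoff genes are not part of the comparison
  prof3 <- rbind(prof, data.frame(gene_id = "weak", score = 2,
                                  cumulative_fc = -5))
  expect_equal(compare_down_vs_up(prof3)$n_down, 20)

  few <- compare_down_vs_up(prof[c(1, 2), ])
  expect_true(few$flagged)
  expect_true(is.na(few$welch_p))
})

test_that("planted binding asymmetry yields a significant down-vs-up contrast", {
  # down-regulated direct targets receive 1.6x the mean enrichment of
  # up-regulated ones; the contrast should be detected in >= 95% of seeds
  hits <- 0L
  n_seeds <- 100
  for (seed in seq_len(n_seeds)) {
    set.seed(seed + 7500)
    n <- 80
    down <- rgamma(n, shape = 4, scale = 1.6 * 2.5) *
      2.5 * exp(-rexp(n, 1 / 2000) / 5000)
    up <- rgamma(n, shape = 4, scale = 2.5) *
      2.5 * exp(-rexp(n, 1 / 2000) / 5000)
    prof <- data.frame(gene_id = sprintf("g%03d", 1:(2 * n)),
                       score = c(down, up),
                       cumulative_fc = rep(c(-1, 1), each = n),
                       stringsAsFactors = FALSE)
    res <- compare_down_vs_up(prof, cutoff = 0)
    if (!is.na(res$welch_p) && res$welch_p < 0.01 &&
        res$mean_down > res$mean_up) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("motif hits are joined within an inclusive summit window", {
  s <- c(1000, 5000, 9000)
  cons <- data.frame(chrom = "chr1", summit = s, start = s - 100,
                     end = s + 100, source_count = 1L,
                     stringsAsFactors = FALSE)
  hits <- data.frame(chrom = "chr1",
                     position = c(1100, 5101, 9000),
                     score = c(9, 9, 5), stringsAsFactors = FALSE)
  res <- join_motif_hits(cons, hits, threshold = 8.005008, flank = 100)
  # summit+100 with a passing score: flagged (inclusive window)
  expect_true(res$summits$has_motif[1])
  # summit+101: outside the window
  expect_false(res$summits$has_motif[2])
  # hit score below threshold: not flagged
  expect_false(res$summits$has_motif[3])
  expect_equal(res$n_with_motif, 1L)

  # the published fraction arithmetic: 3706 of 8533 is 43.4%
  big <- data.frame(chrom = "chr1", summit = seq_len(8533) * 1000,
                    start = seq_len(8533) * 1000 - 100,
                    end = seq_len(8533) * 1000 + 100,
                    source_count = 1L, stringsAsFactors = FALSE)
  bhits <- data.frame(chrom = "chr1", position = seq_len(3706) * 1000,
                      score = 9, stringsAsFactors = FALSE)
  expect_equal(join_motif_hits(big, bhits)$fraction_pct, 43.4)
})
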