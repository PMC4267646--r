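iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("the 50%-of-shorter rule is boundary-inclusive and symmetric", {
  a <- iv("chr1", 100, 200)
  b <- iv("chr1", 150, 400)
  # intersection 50 = 0.5 * 100 exactly: inclusive boundary
  expect_true(overlaps_50pct(a, b))
  expect_true(overlaps_50pct(b, a))
  # abutting half-open intervals do not intersect
  expect_false(overlaps_50pct(iv("chr1", 0, 100), iv("chr1", 100, 200)))
  # different chromosomes are false, not an error
  expect_false(overlaps_50pct(iv("chr1", 0, 100), iv("chr2", 0, 100)))
  # reflexive on any interval
  expect_true(overlaps_50pct(a, a))
  # boundary becomes exclusive-like when min_frac is raised
  expect_false(overlaps_50pct(a, b, min_frac = 0.51))
})

test_that("the overlap rule agrees with the per-bp intersection oracle", {
  set.seed(61)
  n <- 1000
  a <- iv(sample(c("chr1", "chr2"), n, TRUE),
          start = sample(0:400, n, TRUE), end = 0)
  a$end <- a$start + sample(1:100, n, TRUE)
  b <- iv(sample(c("chr1", "chr2"), n, TRUE),
          start = sample(0:400, n, TRUE), end = 0)
  b$end <- b$start + sample(1:100, n, TRUE)
  got <- overlaps_50pct(a, b)
  want <- vapply(seq_len(n), function(i) {
    oracle_overlap_50pct(a[i, ], b[i, ])
  }, logical(1))
  expect_equal(got, want)
})

test_that("interval-tree concordance search equals the all-pairs oracle", {
  set.seed(62)
  pa <- random_peaks(300)
  pb <- random_peaks(300)
  rep_ab <- replicate_concordance(pa, pb)
  # quadratic oracle: fraction of a-peaks with any 50%-rule match in b
  match_a <- vapply(seq_len(nrow(pa)), function(i) {
    any(vapply(seq_len(nrow(pb)), function(j) {
      overlaps_50pct(pa[i, ], pb[j, ])
    }, logical(1)))
  }, logical(1))
  expect_equal(rep_ab$shared_frac_a, 100 * mean(match_a))
})

test_that("replicate concordance reports identity, disjointness and planted sharing", {
  pk <- random_peaks(200, seed = 63)
  same <- replicate_concordance(pk, pk)
  expect_equal(same$shared_frac_a, 100)
  expect_equal(same$shared_frac_b, 100)
  expect_true(same$passes_encode)

  far <- pk
  far$start <- far$start + 1e7
  far$end <- far$end + 1e7
  far$summit <- far$summit + 1e7
  disj <- replicate_concordance(pk, far)
  expect_equal(disj$shared_frac_a, 0)
  expect_false(disj$passes_encode)

  empty <- replicate_concordance(pk[0, ], pk)
  expect_equal(empty$shared_frac_a, 0)
  expect_false(empty$passes_encode)

  # replicates generated with 90% of sites shared recover ~90%
  set.seed(64)
  n <- 2000
  start <- sample.int(5e7, n)
  truth <- peak_df("chr1", start, start + 300)
  keep_b <- runif(n) < 0.9
  extra_start <- sample.int(5e7, n - sum(keep_b)) # rep-b-only sites
  rep_b <- rbind(truth[keep_b, ],
                 peak_df("chr2", extra_start, extra_start + 300))
  conc <- replicate_concordance(truth, rep_b)
  expect_lt(abs(conc$shared_frac_a - 90), 3)
  expect_lt(abs(conc$shared_frac_b - 90), 3)
})

test_that("consensus summits merge nearby summits with per-sample enrichment", {
  one <- peak_df("chr1", c(900, 4900), c(1100, 5100),
                 summit = c(1000, 5000), fe = c(5, 8))
  cons <- build_consensus_summits(list(s1 = one))
  expect_equal(nrow(cons), 2L)
  expect_equal(cons$fe.s1, c(5, 8))
  expect_equal(cons$source_count, c(1L, 1L))

  two_a <- peak_df("chr1", 900, 1100, summit = 1000, fe = 5)
  two_b <- peak_df("chr1", 950, 1150, summit = 1050, fe = 9)
  cons <- build_consensus_summits(list(sa = two_a, sb = two_b),
                                  merge_dist = 100)
  expect_equal(nrow(cons), 1L)
  # consensus summit is the strongest member's summit
  expect_equal(cons$summit, 1050)
  expect_equal(cons$fe.sa, 5)
  expect_equal(cons$fe.sb, 9)
  expect_equal(cons$source_count, 2L)

  empty <- build_consensus_summits(list(sa = two_a[0, ], sb = two_b[0, ]))
  expect_equal(nrow(empty), 0L)
})

test_that("consensus clustering matches the quadratic oracle and conserves peaks", {
  set.seed(65)
  mk <- function(n) {
    s <- sample.int(20000, n, replace = TRUE)
    peak_df("chr1", s - 100, s + 100, summit = s,
            fe = round(runif(n, 1, 50), 3))
  }
  sets <- list(cond_a = mk(200), cond_b = mk(200))
  cons <- build_consensus_summits(sets, merge_dist = 100)

  pool <- do.call(rbind, lapply(names(sets), function(s) {
    cbind(sets[[s]], sample = s, stringsAsFactors = FALSE)
  }))
  oracle <- oracle_consensus(pool, merge_dist = 100)
  expect_equal(nrow(cons), length(oracle))
  osum <- sort(vapply(oracle, `[[`, numeric(1), "summit"))
  expect_equal(sort(cons$summit), osum)
  expect_equal(sum(cons$source_count), nrow(pool))
  # every member summit lies within merge_dist of its consensus summit
  # (guaranteed by construction; checked via the oracle's counts)
  expect_equal(sort(cons$source_count),
               sort(vapply(oracle, `[[`, numeric(1), "n")))
})

test_that("consensus construction is invariant to sample order", {
  set.seed(66)
  a <- random_peaks(150, chroms = "chr1", max_pos = 1e5)
  b <- random_peaks(150, chroms = "chr1", max_pos = 1e5)
  c1 <- build_consensus_summits(list(x = a, y = b))
  c2 <- build_consensus_summits(list(y = b, x = a))
  expect_equal(c1[c("chrom", "summit", "start", "end", "source_count",
                    "fe.x", "fe.y")],
               c2[c("chrom", "summit", "start", "end", "source_count",
                    "fe.x", "fe.y")])
})

test_that("enrichment change recovers scaling, identity and degenerate cases", {
  set.seed(67)
  n <- 400
  s <- sort(sample.int(1e6, n))
  fe_a <- round(runif(n, 2, 30), 3)
  cons <- data.frame(chrom = "chr1", summit = s, start = s - 100,
                     end = s + 100, source_count = 2L,
                     fe.a = fe_a, fe.b = fe_a / 2)
  half <- enrichment_change(cons, "a", "b")
  expect_equal(half$percent_change, -50, tolerance = 1e-9)

  cons$fe.b <- cons$fe.a
  ident <- enrichment_change(cons, "a", "b")
  expect_equal(ident$percent_change, 0)
  expect_gt(ident$welch_p, 0.99)

  cons$fe.b <- 0
  gone <- enrichment_change(cons, "a", "b")
  expect_equal(gone$percent_change, -100)
  expect_true(gone$flagged)

  expect_equal(peak_count_reduction(8446, 1573), 100 * (8446 - 1573) / 8446)
})

test_that("simulated knockdown reproduces the planted enrichment reduction", {
  sim <- simulate_study(sim_config(seed = 68),
                        include_expression = FALSE)
  cons <- build_consensus_summits(sim$condition_peaks[c("tf1_scr", "tf1_kd")])
  ech <- enrichment_change(cons, "tf1_scr", "tf1_kd")
  expect_lt(abs(ech$percent_change - (-60)), 5)
  expect_lt(ech$welch_p, 1e-6)
})
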