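# In-code fixtures shared across the suite.

# minimal peak table from parallel vectors (0-based half-open)
peak_df <- function(chrom, start, end, summit = NULL, fe = 10,
                    name = NULL) {
  n <- length(start)
  if (is.null(summit)) summit <- start + floor((end - start) / 2)
  data.frame(
    chrom = rep_len(chrom, n), start = start, end = end,
    name = if (is.null(name)) sprintf("p%03d", seq_len(n)) else name,
    score = rep_len(0, n), strand = rep_len(".", n),
    fold_enrichment = rep_len(fe, n),
    pvalue_log10 = rep_len(5, n), qvalue_log10 = rep_len(3, n),
    summit = summit, qvalue = rep_len(1e-3, n),
    stringsAsFactors = FALSE)
}

# random valid peaks for round-trip / oracle properties
random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(50:500, n, replace = TRUE)
  off <- floor(width * runif(n))
  peak_df(chrom = sample(chroms, n, replace = TRUE),
          start = start, end = start + width, summit = start + off,
          fe = round(rgamma(n, 2, scale = 5) + 0.1, 5))
}

# expression records for a single gene x time grid
expr_df <- function(gene_id, time_h, log2fc, qvalue) {
  data.frame(gene_id = gene_id, time_h = time_h, log2fc = log2fc,
             qvalue = qvalue, significant = NA, stringsAsFactors = FALSE)
}

# small, fast simulation for module tests
small_sim_config <- function(seed = 7, ...) {
  sim_config(seed = seed, n_chroms = 2, chrom_length = 5e6, n_genes = 300,
             n_direct_down = 25, n_direct_up = 15, n_indirect_late = 15,
             ...)
}

# brute-force proximity score: explicit loop over peaks
oracle_proximity <- function(gene, peaks, d0 = 5000, window = 5e5,
                             fe_col = "fold_enrichment") {
  total <- 0
  for (k in seq_len(nrow(peaks))) {
    if (peaks$chrom[k] != gene$chrom) next
    d <- abs(peaks$summit[k] - gene$tss)
    if (d > window) next
    total <- total + peaks[[fe_col]][k] * exp(-d / d0)
  }
  total
}

# per-bp set-intersection overlap oracle (small coordinates only)
oracle_overlap_50pct <- function(a, b, min_frac = 0.5) {
  if (a$chrom != b$chrom) return(FALSE)
  bp_a <- seq(a$start, a$end - 1)
  bp_b <- seq(b$start, b$end - 1)
  inter <- length(intersect(bp_a, bp_b))
  inter >= min_frac * min(length(bp_a), length(bp_b))
}

# naive quadratic consensus clustering: strongest unassigned summit
# absorbs all unassigned summits within merge_dist, written as plain
# double loops for independence from the package implementation
oracle_consensus <- function(pool, merge_dist = 100) {
  pool <- pool[order(-pool$fold_enrichment, pool$summit, pool$sample,
                     pool$name), ]
  assigned <- rep(FALSE, nrow(pool))
  clusters <- list()
  for (i in seq_len(nrow(pool))) {
    if (assigned[i]) next
    members <- integer(0)
    for (j in seq_len(nrow(pool))) {
      if (assigned[j]) next
      if (pool$chrom[j] == pool$chrom[i] &&
          abs(pool$summit[j] - pool$summit[i]) <= merge_dist) {
        members <- c(members, j)
      }
    }
    assigned[members] <- TRUE
    clusters[[length(clusters) + 1]] <-
      list(chrom = pool$chrom[i], summit = pool$summit[i],
           n = length(members))
  }
  clusters
}
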