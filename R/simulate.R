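# Synthetic study generator.
#
# Emulates the statistical structure of a two-factor, two-condition
# ChIP-seq experiment combined with an 8-point knock-down expression
# time course: planted direct targets with strong proximal binding of
# the silenced factor, indirect late responders bound by the partner
# factor, null genes with background binding only, knock-down thinning
# of the silenced factor's peaks, and a partner factor whose occupancy
# rises on knock-down. Every downstream contract of the pipeline is
# testable against the planted ground truth.

#' Default knock-down trajectory of the silenced factor
#'
#' The silenced gene's own log2 fold change over the 3-96 h time course:
#' already -0.9 at 3 h, deepest at 15 h (-1.28), and recovered to about
#' 70% of basal expression by 96 h (log2(0.7) = -0.51). All values are
#' non-positive - silencing never increases the target.
#'
#' @return Named numeric vector over the default time points (hours).
#' @export
kd_trajectory_default <- function() {
  c(`3` = -0.9, `6` = -1.0, `9` = -1.1, `12` = -1.2,
    `15` = -1.28, `18` = -1.2, `48` = -0.8, `96` = -0.51)
}

#' Simulation configuration
#'
#' Bundles all generator parameters with defaults matching the study
#' conditions the pipeline is designed for. Gene classes
#' (`n_direct_down`, `n_direct_up`, `n_indirect_late`, the silenced
#' factor's own gene, and nulls) partition `n_genes`.
#'
#' @param seed Integer RNG seed; the simulation is deterministic given
#'   the seed.
#' @param n_chroms,chrom_length Synthetic genome shape.
#' @param n_genes Total genes.
#' @param time_points Expression sampling times in hours.
#' @param n_direct_down,n_direct_up Direct targets of the silenced
#'   factor (early responders with planted proximal peaks), by response
#'   direction.
#' @param n_indirect_late Indirect targets: significant only at the late
#'   time points, bound by the partner factor but not the silenced one.
#' @param effect_size_log2,effect_sd_log2,effect_min_log2 Planted
#'   per-gene peak |log2 fold change|: normal with this mean and sd,
#'   truncated below.
#' @param noise_sd_log2 Replicate-to-replicate noise sd on the log2 FPKM
#'   scale.
#' @param n_replicates Expression replicates per condition.
#' @param kd_trajectory Per-time-point log2 fold change of the silenced
#'   factor's own gene; must be non-positive, one value per time point.
#' @param peak_bg_rate Background peaks per Mb for the silenced factor.
#' @param peaks_per_target Inclusive range of planted peaks per direct
#'   target gene.
#' @param fe_background,fe_target Gamma parameters (`shape`, `scale`,
#'   lower truncation `min`) of fold-enrichment draws for background and
#'   planted target peaks.
#' @param down_fe_factor Multiplier on planted peak enrichment at
#'   down-regulated targets relative to up-regulated ones (the silenced
#'   factor binds its activated targets more strongly).
#' @param kd_peak_retention Probability that a silenced-factor peak
#'   survives knock-down; default 0.19.
#' @param kd_fe_multiplier Fold-enrichment scaling of surviving peaks on
#'   knock-down; default 0.4.
#' @param partner_gain Partner-factor peak count multiplier on
#'   knock-down; default 1.5.
#' @param shared_site_frac Fraction of silenced-factor sites co-bound by
#'   the partner factor (within 50 bp); default 0.09.
#' @param tf2_bg_rate Background peaks per Mb for the partner factor.
#' @param tf2_dual_frac Fraction of up-regulated direct targets that are
#'   also bound by the partner factor (dual targets).
#' @param n_chip_replicates ChIP replicates emitted per condition.
#' @param rep_retain Probability a condition-level peak appears in a
#'   given replicate.
#' @param summit_jitter_sd Replicate summit jitter sd in bp.
#' @param pseudo Pseudo-count (FPKM) used when computing the q-value
#'   column of the emitted expression table.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L,
                       chrom_length = 25e6,
                       n_genes = 2000L,
                       time_points = c(3, 6, 9, 12, 15, 18, 48, 96),
                       n_direct_down = 100L,
                       n_direct_up = 60L,
                       n_indirect_late = 90L,
                       effect_size_log2 = 1.2,
                       effect_sd_log2 = 0.3,
                       effect_min_log2 = 0.6,
                       noise_sd_log2 = 0.15,
                       n_replicates = 3L,
                       kd_trajectory = kd_trajectory_default(),
                       peak_bg_rate = 3,
                       peaks_per_target = c(2L, 4L),
                       fe_background = list(shape = 2, scale = 5, min = 1),
                       fe_target = list(shape = 4, scale = 2.5, min = 1),
                       down_fe_factor = 1.6,
                       kd_peak_retention = 0.19,
                       kd_fe_multiplier = 0.4,
                       partner_gain = 1.5,
                       shared_site_frac = 0.09,
                       tf2_bg_rate = 1,
                       tf2_dual_frac = 0.5,
                       n_chip_replicates = 2L,
                       rep_retain = 0.95,
                       summit_jitter_sd = 5,
                       pseudo = 0.1) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, n_genes = as.integer(n_genes),
              time_points = time_points,
              n_direct_down = as.integer(n_direct_down),
              n_direct_up = as.integer(n_direct_up),
              n_indirect_late = as.integer(n_indirect_late),
              effect_size_log2 = effect_size_log2,
              effect_sd_log2 = effect_sd_log2,
              effect_min_log2 = effect_min_log2,
              noise_sd_log2 = noise_sd_log2,
              n_replicates = as.integer(n_replicates),
              kd_trajectory = kd_trajectory,
              peak_bg_rate = peak_bg_rate,
              peaks_per_target = as.integer(peaks_per_target),
              fe_background = fe_background, fe_target = fe_target,
              down_fe_factor = down_fe_factor,
              kd_peak_retention = kd_peak_retention,
              kd_fe_multiplier = kd_fe_multiplier,
              partner_gain = partner_gain,
              shared_site_frac = shared_site_frac,
              tf2_bg_rate = tf2_bg_rate, tf2_dual_frac = tf2_dual_frac,
              n_chip_replicates = as.integer(n_chip_replicates),
              rep_retain = rep_retain,
              summit_jitter_sd = summit_jitter_sd,
              pseudo = pseudo)
  n_special <- cfg$n_direct_down + cfg$n_direct_up + cfg$n_indirect_late + 1L
  if (n_special > cfg$n_genes) {
    stop("infeasible configuration: more target genes (",
         n_special, ") than genes (", cfg$n_genes, ")")
  }
  cfg$n_null <- cfg$n_genes - n_special
  probs <- c(cfg$kd_peak_retention, cfg$shared_site_frac, cfg$rep_retain,
             cfg$tf2_dual_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (length(cfg$kd_trajectory) != length(cfg$time_points)) {
    stop("kd_trajectory must have one value per time point")
  }
  if (any(cfg$kd_trajectory > 0)) {
    stop("kd_trajectory must be non-positive (silencing never increases the target)")
  }
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length > 2e5, cfg$n_genes >= 10,
            cfg$n_replicates >= 2, cfg$kd_fe_multiplier > 0,
            cfg$partner_gain >= 1, length(cfg$peaks_per_target) == 2L,
            cfg$peaks_per_target[1] >= 1,
            cfg$peaks_per_target[2] >= cfg$peaks_per_target[1])
  structure(cfg, class = "sim_config")
}

# truncated-gamma fold enrichment
draw_fe <- function(n, par, scale_mult = 1) {
  pmax(par$min, stats::rgamma(n, shape = par$shape,
                              scale = par$scale * scale_mult))
}

# summit-to-TSS distance: exponential, mean 2 kb, truncated at 10 kb
draw_target_distance <- function(n, mean_bp = 2000, max_bp = 10000) {
  u <- stats::runif(n) * stats::pexp(max_bp, rate = 1 / mean_bp)
  round(stats::qexp(u, rate = 1 / mean_bp))
}

# assemble a peak table around given summits
make_peak_table <- function(chrom, summit, fe, chrom_length, prefix) {
  n <- length(summit)
  if (n == 0L) return(empty_peak_table())
  w <- round(stats::runif(n, 150, 400))
  off <- floor(w * stats::runif(n, 0.25, 0.75))
  start <- summit - off
  end <- start + w
  shift <- pmax(0, -start) - pmax(0, end - chrom_length)
  start <- start + shift
  end <- end + shift
  summit <- pmin(pmax(summit, start), end - 1)
  fe <- round(fe, 5)
  data.frame(chrom = chrom, start = start, end = end,
             name = sprintf("%s_%05d", prefix, seq_len(n)),
             score = round(10 * fe), strand = ".",
             fold_enrichment = fe,
             pvalue_log10 = round(fe + 4, 5),
             qvalue_log10 = round(fe + 2, 5),
             summit = summit,
             qvalue = 10^(-round(fe + 2, 5)),
             stringsAsFactors = FALSE)
}

# response-shape profiles over configurable time points (hours)
direct_shape <- function(time_points) {
  stats::approx(x = c(0, 9, 12, 15, 18, 48, 96),
                y = c(0, 0, 0.25, 1, 1, 0.75, 0.5),
                xout = time_points, rule = 2)$y
}

indirect_shape <- function(time_points) {
  stats::approx(x = c(0, 18, 48, 96), y = c(0, 0, 1, 1),
                xout = time_points, rule = 2)$y
}

#' Simulate a two-factor knock-down study with planted ground truth
#'
#' Generates a gene annotation, condition-level and replicate peak sets
#' for the silenced factor (tf1) and its partner (tf2) in scramble (scr)
#' and knock-down (kd) conditions, a time-course expression table with
#' q-values from per-gene Welch tests on simulated log2 FPKM replicates
#' followed by Benjamini-Hochberg adjustment, and the planted truth
#' labels needed for recovery tests. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @param include_expression Generate the expression table (the slowest
#'   component); set `FALSE` for peak-only studies.
#' @return A list of class `tf_sim` with elements `config`, `annotation`,
#'   `condition_peaks` (named list: `tf1_scr`, `tf1_kd`, `tf2_scr`,
#'   `tf2_kd`), `replicate_peaks` (named list, two per condition),
#'   `expression` (or `NULL`) and `truth` (list with `genes`,
#'   `planted_fc` and planted peak tables).
#' @export
simulate_study <- function(config = sim_config(),
                           include_expression = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  L <- config$chrom_length
  n <- config$n_genes
  tp <- config$time_points
  margin <- 1e5

  ## --- genes -------------------------------------------------------
  gene_id <- sprintf("g%04d", seq_len(n))
  gchrom <- sample(chroms, n, replace = TRUE)
  gtss <- floor(stats::runif(n, margin, L - margin))
  gstrand <- sample(c("+", "-"), n, replace = TRUE)
  class <- rep("null", n)
  class[1] <- "silenced_tf"
  idx <- 1L
  class[idx + seq_len(config$n_direct_down)] <- "direct-down"
  idx <- idx + config$n_direct_down
  class[idx + seq_len(config$n_direct_up)] <- "direct-up"
  idx <- idx + config$n_direct_up
  class[idx + seq_len(config$n_indirect_late)] <- "indirect-late"
  annotation <- data.frame(gene_id = gene_id, chrom = gchrom,
                           strand = gstrand, tss = gtss,
                           stringsAsFactors = FALSE)

  sign <- rep(0, n)
  sign[class == "direct-down"] <- -1
  sign[class == "direct-up"] <- 1
  ind <- class == "indirect-late"
  sign[ind] <- sample(c(-1, 1), sum(ind), replace = TRUE)
  magnitude <- rep(0, n)
  eff <- class %in% c("direct-down", "direct-up", "indirect-late")
  magnitude[eff] <- pmax(config$effect_min_log2,
                         stats::rnorm(sum(eff), config$effect_size_log2,
                                      config$effect_sd_log2))

  shp_direct <- direct_shape(tp)
  shp_ind <- indirect_shape(tp)
  fc <- matrix(0, n, length(tp), dimnames = list(gene_id, tp))
  fc[class == "silenced_tf", ] <- config$kd_trajectory
  dd <- class %in% c("direct-down", "direct-up")
  fc[dd, ] <- outer(sign[dd] * magnitude[dd], shp_direct)
  fc[ind, ] <- outer(sign[ind] * magnitude[ind], shp_ind)

  truth_genes <- data.frame(gene_id = gene_id, class = class,
                            sign = sign, magnitude = magnitude,
                            stringsAsFactors = FALSE)
  planted_fc <- data.frame(
    gene_id = rep(gene_id, times = length(tp)),
    time_h = rep(tp, each = n),
    planted_log2fc = as.vector(fc),
    stringsAsFactors = FALSE)

  ## --- tf1 peaks, scramble condition -------------------------------
  n_bg1 <- stats::rpois(config$n_chroms, config$peak_bg_rate * L / 1e6)
  bg1 <- make_peak_table(
    chrom = rep(chroms, n_bg1),
    summit = floor(stats::runif(sum(n_bg1), 0, L)),
    fe = draw_fe(sum(n_bg1), config$fe_background),
    chrom_length = L, prefix = "tf1bg")

  target_idx <- which(dd)
  k_per <- sample(seq(config$peaks_per_target[1],
                      config$peaks_per_target[2]),
                  length(target_idx), replace = TRUE)
  owner <- rep(target_idx, k_per)
  d <- draw_target_distance(length(owner))
  side <- sample(c(-1, 1), length(owner), replace = TRUE)
  fe_scale <- ifelse(class[owner] == "direct-down", config$down_fe_factor, 1)
  planted1 <- make_peak_table(
    chrom = gchrom[owner],
    summit = pmin(pmax(gtss[owner] + side * d, 0), L - 1),
    fe = draw_fe(length(owner), config$fe_target) * fe_scale,
    chrom_length = L, prefix = "tf1tg")
  planted1$gene_id <- gene_id[owner]

  tf1_scr <- rbind(bg1, planted1[, names(bg1)])

  ## --- tf1 peaks, knock-down condition ------------------------------
  keep <- stats::runif(nrow(tf1_scr)) < config$kd_peak_retention
  tf1_kd <- tf1_scr[keep, , drop = FALSE]
  tf1_kd$fold_enrichment <- round(
    tf1_kd$fold_enrichment * config$kd_fe_multiplier *
      exp(stats::rnorm(nrow(tf1_kd), 0, 0.05)), 5)
  tf1_kd$name <- sub("^tf1", "tf1kd", tf1_kd$name)
  rownames(tf1_kd) <- NULL

  ## --- tf2 peaks ----------------------------------------------------
  n_bg2 <- stats::rpois(config$n_chroms, config$tf2_bg_rate * L / 1e6)
  bg2 <- make_peak_table(
    chrom = rep(chroms, n_bg2),
    summit = floor(stats::runif(sum(n_bg2), 0, L)),
    fe = draw_fe(sum(n_bg2), config$fe_background),
    chrom_length = L, prefix = "tf2bg")

  # shared sites: partner co-binds a fraction of tf1 sites within 50 bp
  n_shared <- round(config$shared_site_frac * nrow(tf1_scr))
  shared_i <- sample.int(nrow(tf1_scr), n_shared)
  shared2 <- make_peak_table(
    chrom = tf1_scr$chrom[shared_i],
    summit = pmin(pmax(tf1_scr$summit[shared_i] +
                         round(stats::runif(n_shared, -50, 50)), 0), L - 1),
    fe = draw_fe(n_shared, config$fe_background),
    chrom_length = L, prefix = "tf2sh")

  # planted partner binding: all indirect-late genes plus a fraction of
  # up-regulated direct targets (dual targets)
  up_idx <- which(class == "direct-up")
  dual_idx <- up_idx[seq_len(round(config$tf2_dual_frac * length(up_idx)))]
  tf2_target_idx <- c(which(ind), dual_idx)
  k2 <- sample(seq(config$peaks_per_target[1], config$peaks_per_target[2]),
               length(tf2_target_idx), replace = TRUE)
  owner2 <- rep(tf2_target_idx, k2)
  d2 <- draw_target_distance(length(owner2))
  side2 <- sample(c(-1, 1), length(owner2), replace = TRUE)
  planted2 <- make_peak_table(
    chrom = gchrom[owner2],
    summit = pmin(pmax(gtss[owner2] + side2 * d2, 0), L - 1),
    fe = draw_fe(length(owner2), config$fe_target),
    chrom_length = L, prefix = "tf2tg")
  planted2$gene_id <- gene_id[owner2]

  tf2_scr <- rbind(bg2, shared2, planted2[, names(bg2)])

  # knock-down: partner occupancy rises; extra sites preferentially near
  # up-regulated genes
  tf2_kd <- tf2_scr
  tf2_kd$fold_enrichment <- round(
    tf2_kd$fold_enrichment * exp(stats::rnorm(nrow(tf2_kd), 0, 0.05)), 5)
  n_extra <- round((config$partner_gain - 1) * nrow(tf2_scr))
  up_genes <- which(sign > 0)
  near_up <- stats::runif(n_extra) < 0.7 & length(up_genes) > 0
  host <- if (length(up_genes)) sample(up_genes, n_extra, replace = TRUE)
          else rep(1L, n_extra)
  extra_summit <- ifelse(
    near_up,
    pmin(pmax(gtss[host] + sample(c(-1, 1), n_extra, replace = TRUE) *
                draw_target_distance(n_extra), 0), L - 1),
    floor(stats::runif(n_extra, 0, L)))
  extra2 <- make_peak_table(
    chrom = ifelse(near_up, gchrom[host],
                   sample(chroms, n_extra, replace = TRUE)),
    summit = extra_summit,
    fe = draw_fe(n_extra, config$fe_target),
    chrom_length = L, prefix = "tf2kd")
  tf2_kd$name <- sub("^tf2", "tf2kd", tf2_kd$name)
  tf2_kd <- rbind(tf2_kd, extra2)
  rownames(tf2_kd) <- NULL

  condition_peaks <- list(tf1_scr = tf1_scr, tf1_kd = tf1_kd,
                          tf2_scr = tf2_scr, tf2_kd = tf2_kd)

  ## --- ChIP replicates ---------------------------------------------
  replicate_peaks <- list()
  for (cond in names(condition_peaks)) {
    pk <- condition_peaks[[cond]]
    for (r in seq_len(config$n_chip_replicates)) {
      keep <- stats::runif(nrow(pk)) < config$rep_retain
      rp <- pk[keep, , drop = FALSE]
      jit <- round(stats::rnorm(nrow(rp), 0, config$summit_jitter_sd))
      rp$start <- pmax(0, rp$start + jit)
      rp$end <- rp$end + jit
      rp$summit <- pmin(pmax(rp$summit + jit, rp$start), rp$end - 1)
      rp$name <- sprintf("%s_r%d", rp$name, r)
      rownames(rp) <- NULL
      replicate_peaks[[sprintf("%s_r%d", cond, r)]] <- rp
    }
  }

  ## --- expression ---------------------------------------------------
  expression <- NULL
  if (include_expression) {
    R <- config$n_replicates
    base <- stats::rnorm(n, mean = log2(20), sd = 1.5)
    tabs <- vector("list", length(tp))
    for (ti in seq_along(tp)) {
      ctrl <- matrix(stats::rnorm(n * R, base, config$noise_sd_log2), n, R)
      trt <- matrix(stats::rnorm(n * R, base + fc[, ti],
                                 config$noise_sd_log2), n, R)
      fpkm_c <- 2^ctrl
      fpkm_t <- 2^trt
      lc <- log2(fpkm_c + config$pseudo)
      lt <- log2(fpkm_t + config$pseudo)
      mc <- rowMeans(lc)
      mt <- rowMeans(lt)
      vc <- rowSums((lc - mc)^2) / (R - 1)
      vt <- rowSums((lt - mt)^2) / (R - 1)
      # replicate noise is homoscedastic across genes by construction, so
      # the per-gene test pools the variance estimate genome-wide (the
      # moderation count-based differential tools achieve by dispersion
      # sharing); df is then effectively unbounded
      pooled <- mean((vc + vt) / 2)
      tstat <- (mt - mc) / sqrt(2 * pooled / R)
      df <- 2 * n * (R - 1)
      p <- 2 * stats::pt(-abs(tstat), df)
      q <- bh_adjust(p)
      tabs[[ti]] <- data.frame(
        gene_id = gene_id, time_h = tp[ti],
        fpkm_control = round(rowMeans(fpkm_c), 4),
        fpkm_treated = round(rowMeans(fpkm_t), 4),
        qvalue = q, stringsAsFactors = FALSE)
    }
    expression <- do.call(rbind, tabs)
    expression$log2fc <- compute_log2fc(expression$fpkm_treated,
                                        expression$fpkm_control,
                                        config$pseudo)
    rownames(expression) <- NULL
  }

  structure(list(config = config, annotation = annotation,
                 condition_peaks = condition_peaks,
                 replicate_peaks = replicate_peaks,
                 expression = expression,
                 truth = list(genes = truth_genes,
                              planted_fc = planted_fc,
                              tf1_planted = planted1,
                              tf2_planted = planted2)),
            class = "tf_sim")
}

#' Write a simulated study to disk
#'
#' Emits the exact file formats the readers consume: a gene annotation
#' TSV, one narrowPeak file per condition and per replicate, the
#' expression TSV, the planted truth table and the configuration as
#' JSON. Byte-identical across runs with the same configuration.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "tf_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  for (cond in names(sim$condition_peaks)) {
    write_narrowpeak(sim$condition_peaks[[cond]],
                     file.path(dir, paste0(cond, ".narrowPeak")))
  }
  for (rep in names(sim$replicate_peaks)) {
    write_narrowpeak(sim$replicate_peaks[[rep]],
                     file.path(dir, paste0(rep, ".narrowPeak")))
  }
  if (!is.null(sim$expression)) {
    write_expression_table(sim$expression, file.path(dir, "expression.tsv"))
  }
  utils::write.table(sim$truth$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$planted_fc,
                     file.path(dir, "truth_planted_fc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
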