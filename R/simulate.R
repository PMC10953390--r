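# Seeded synthetic-data generator.
#
# Emulates every processed table the pipeline consumes: distance-decaying
# interaction scores with planted cell-type-specific loops, binomially
# distributed per-allele read counts with planted imbalance, LD blocks around
# GWAS leads, enhancer intervals with controllable SNP overlap, and
# negative-binomial expression counts whose planted effects are coupled to the
# planted interaction differences. Every generator is a pure function of its
# configuration: identical config (including seed) gives identical output.

#' Simulation configuration
#'
#' Defaults encode the emulated study design: two immune cell types, 10
#' patients and 5 controls, a CHiCAGO-style score-5 significance convention,
#' and 23 GWAS loci.
#'
#' @param seed integer RNG seed.
#' @param n_baits number of baited promoter fragments.
#' @param n_other_ends_per_bait candidate other ends per bait.
#' @param n_samples_patient,n_samples_control samples per disease state
#'   (defaults 10 and 5).
#' @param cell_types two cell-type labels (default `c("CD4", "CD14")`);
#'   positive differential log2 fold changes mean higher in the first.
#' @param frac_celltype_specific_loops fraction of bait/other-end pairs with a
#'   planted cell-type-specific loop.
#' @param allelic_effect true reference-haplotype read fraction for planted
#'   imbalanced pairs (default 0.75; 0.5 is the null).
#' @param frac_imbalanced_pairs fraction of (SNP, loop) pairs with planted
#'   allelic imbalance.
#' @param reads_per_het_sample Poisson mean of total reads per heterozygous
#'   sample and loop (default 20).
#' @param n_gwas_loci number of GWAS lead signals (default 23).
#' @param n_proxies_per_lead LD proxies simulated per lead.
#' @param ld_block_span_bp half-width of the LD block around each lead.
#' @param maf minor allele frequency for loop SNP genotypes (Hardy-Weinberg).
#' @param frac_r2_high fraction of proxies drawn with r2 > 0.8.
#' @param enhancer_density fraction of passing GWAS SNPs covered by an
#'   enhancer, per cell type.
#' @param n_candidate_snps number of GWAS leads planted inside other ends of
#'   significant interactions (creating known candidate genes).
#' @param de_effect_log2fc mean planted expression log2 fold-change magnitude.
#' @param coupling_rate probability that a planted cell-type-specific loop's
#'   bait gene receives a planted expression effect in the same direction.
#' @param couple_magnitude if TRUE (default) the planted expression magnitude
#'   is proportional to the loop's interaction |log2FC| (scaled so its mean is
#'   `de_effect_log2fc`); if FALSE the magnitude is exactly
#'   `de_effect_log2fc`.
#' @param n_genes total gene universe for the expression simulation.
#' @param frac_shared_baits fraction of baits capturing two promoters.
#' @param nb_dispersion negative-binomial dispersion of expression counts.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_baits = 100,
                       n_other_ends_per_bait = 10,
                       n_samples_patient = 10,
                       n_samples_control = 5,
                       cell_types = c("CD4", "CD14"),
                       frac_celltype_specific_loops = 0.1,
                       allelic_effect = 0.75,
                       frac_imbalanced_pairs = 0.1,
                       reads_per_het_sample = 20,
                       n_gwas_loci = 23,
                       n_proxies_per_lead = 20,
                       ld_block_span_bp = 100000,
                       maf = 0.3,
                       frac_r2_high = 0.8,
                       enhancer_density = 0.25,
                       n_candidate_snps = 8,
                       de_effect_log2fc = 3,
                       coupling_rate = 0.8,
                       couple_magnitude = TRUE,
                       n_genes = 2000,
                       frac_shared_baits = 0.05,
                       nb_dispersion = 0.1) {
  cfg <- list(seed = as.integer(seed), n_baits = as.integer(n_baits),
              n_other_ends_per_bait = as.integer(n_other_ends_per_bait),
              n_samples_patient = as.integer(n_samples_patient),
              n_samples_control = as.integer(n_samples_control),
              cell_types = as.character(cell_types),
              frac_celltype_specific_loops = frac_celltype_specific_loops,
              allelic_effect = allelic_effect,
              frac_imbalanced_pairs = frac_imbalanced_pairs,
              reads_per_het_sample = reads_per_het_sample,
              n_gwas_loci = as.integer(n_gwas_loci),
              n_proxies_per_lead = as.integer(n_proxies_per_lead),
              ld_block_span_bp = as.integer(ld_block_span_bp),
              maf = maf, frac_r2_high = frac_r2_high,
              enhancer_density = enhancer_density,
              n_candidate_snps = as.integer(n_candidate_snps),
              de_effect_log2fc = de_effect_log2fc,
              coupling_rate = coupling_rate,
              couple_magnitude = isTRUE(couple_magnitude),
              n_genes = as.integer(n_genes),
              frac_shared_baits = frac_shared_baits,
              nb_dispersion = nb_dispersion)
  fracs <- c("frac_celltype_specific_loops", "frac_imbalanced_pairs", "maf",
             "frac_r2_high", "enhancer_density", "coupling_rate",
             "frac_shared_baits")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (cfg$allelic_effect < 0 || cfg$allelic_effect > 1)
    stop("allelic_effect must lie in [0, 1]")
  if (length(cfg$cell_types) != 2) stop("exactly two cell types expected")
  pos <- c("n_other_ends_per_bait", "n_samples_patient", "n_samples_control",
           "reads_per_het_sample", "n_genes")
  for (f in pos) if (cfg[[f]] <= 0) stop(f, " must be positive")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  for (f in names(x)) {
    cat(sprintf("  %-28s: %s\n", f, paste(x[[f]], collapse = ", ")))
  }
  invisible(x)
}

.seed_for <- function(config, offset) {
  set.seed((config$seed + offset) %% 2147483587L)
}

.FRAG_W <- 5000  # restriction-fragment-scale width of baits and other ends

#' Simulate per-cell-type interaction calls and a differential table
#'
#' Baseline scores decay with bait/other-end distance; planted
#' cell-type-specific loops receive a score above 5 in one cell type and below
#' 5 in the other. The differential table covers every pair significant
#' (score > 5) in at least one cell type; planted pairs get a sign-correct
#' log2 fold change (positive = higher in the first cell type) and a weighted
#' adjusted p below 0.05, background pairs a uniform weighted adjusted p and
#' near-zero log2 fold change.
#'
#' @param config a [sim_config()].
#' @return list with `interactions` (all cell type x condition calls, internal
#'   convention), `differential` (schema `differential_interactions`) and
#'   `truth` (schema `truth_interactions`).
#' @export
simulate_interactions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_baits <= 0) stop("zero baits")
  .seed_for(config, 101L)

  n_b <- config$n_baits
  n_oe <- config$n_other_ends_per_bait
  chroms <- paste0("chr", (seq_len(n_b) - 1) %% 4 + 1)
  bait_start <- 1e6 + ((seq_len(n_b) - 1) %/% 4) * 8e5
  bait_end <- bait_start + .FRAG_W

  genes <- sprintf("gene_%04d", seq_len(n_b))
  n_shared <- floor(config$frac_shared_baits * n_b)
  shared_idx <- if (n_shared > 0) sort(sample.int(n_b, n_shared)) else integer(0)
  bait_genes <- genes
  if (n_shared > 0)
    bait_genes[shared_idx] <- paste0(genes[shared_idx], ";",
                                     sprintf("gene_%04d",
                                             n_b + seq_len(n_shared)))

  bi <- rep(seq_len(n_b), each = n_oe)
  dist <- round(10 ^ runif(n_b * n_oe, log10(2e4), log10(2e6)))
  sgn <- sample(c(-1, 1), n_b * n_oe, replace = TRUE)
  oe_start <- bait_start[bi] + sgn * dist
  flip <- oe_start < 0
  oe_start[flip] <- bait_start[bi][flip] + dist[flip]
  oe_end <- oe_start + .FRAG_W

  pairs <- data.frame(bait_chrom = chroms[bi], bait_start = bait_start[bi],
                      bait_end = bait_end[bi], bait_genes = bait_genes[bi],
                      oe_chrom = chroms[bi], oe_start = oe_start,
                      oe_end = oe_end, n_reads = NA_integer_,
                      stringsAsFactors = FALSE)
  pairs$loop_id <- interaction_key(pairs)

  n_pairs <- nrow(pairs)
  n_planted <- round(config$frac_celltype_specific_loops * n_pairs)
  planted <- if (n_planted > 0) sort(sample.int(n_pairs, n_planted)) else
    integer(0)
  # the "on" cell type is a bait-level property: a promoter's planted loops
  # all gain interactivity in the same cell type
  bait_ct <- sample(config$cell_types, n_b, replace = TRUE)
  on_ct <- rep(NA_character_, n_pairs)
  if (n_planted > 0) on_ct[planted] <- bait_ct[bi[planted]]

  mu <- 1 + 12 * exp(-dist / 2e5)
  base <- pmax(0, mu + rnorm(n_pairs, sd = 1.5))
  score <- list()
  for (ct in config$cell_types) {
    s <- pmax(0, base + rnorm(n_pairs, sd = 0.8))
    s[planted] <- ifelse(on_ct[planted] == ct,
                         runif(n_planted, 6, 15),
                         runif(n_planted, 0.5, 4.5))
    score[[ct]] <- s
  }

  tabs <- list()
  for (ct in config$cell_types) {
    for (cond in c("pooled", "patient", "control")) {
      t <- pairs
      t$score <- if (cond == "pooled") score[[ct]] else
        pmax(0, score[[ct]] + rnorm(n_pairs, sd = 0.5))
      t$cell_type <- ct
      t$condition <- cond
      tabs[[paste(ct, cond, sep = "_")]] <- t
    }
  }
  interactions <- do.call(rbind, tabs)
  rownames(interactions) <- NULL

  s1 <- score[[config$cell_types[1]]]
  s2 <- score[[config$cell_types[2]]]
  in_diff <- s1 > 5 | s2 > 5
  log2fc <- rnorm(n_pairs, sd = 0.3)
  wadj_p <- runif(n_pairs)
  if (n_planted > 0) {
    # a cell-type-specific promoter's interactome shifts coherently: its
    # non-planted loops drift in the same direction (moderate magnitude,
    # significance rate unchanged), its planted loops are strong and
    # significant
    planted_baits <- unique(bi[planted])
    cobait <- setdiff(which(bi %in% planted_baits), planted)
    if (length(cobait) > 0) {
      drift_sign <- ifelse(bait_ct[bi[cobait]] == config$cell_types[1], 1, -1)
      log2fc[cobait] <- drift_sign * abs(rnorm(length(cobait), 1.2, 0.6))
    }
    dir_sign <- ifelse(on_ct[planted] == config$cell_types[1], 1, -1)
    log2fc[planted] <- dir_sign * runif(n_planted, 2.2, 6)
    wadj_p[planted] <- 10 ^ runif(n_planted, -12, log10(0.049))
  }
  differential <- data.frame(bait_genes = pairs$bait_genes,
                             bait_chrom = pairs$bait_chrom,
                             bait_start = as.integer(pairs$bait_start),
                             bait_end = as.integer(pairs$bait_end),
                             oe_chrom = pairs$oe_chrom,
                             oe_start = as.integer(pairs$oe_start),
                             oe_end = as.integer(pairs$oe_end),
                             log2fc = log2fc, wadj_p = wadj_p,
                             stringsAsFactors = FALSE)[in_diff, , drop = FALSE]
  rownames(differential) <- NULL

  truth <- data.frame(loop_id = pairs$loop_id[planted],
                      bait_genes = pairs$bait_genes[planted],
                      on_cell_type = on_ct[planted],
                      log2fc = log2fc[planted],
                      stringsAsFactors = FALSE)
  list(interactions = interactions, differential = differential,
       truth = truth)
}

#' Simulate phased genotypes and per-allele loop read counts
#'
#' One SNP is placed at the midpoint of each loop's other end. Genotypes are
#' drawn per sample under Hardy-Weinberg at the configured minor allele
#' frequency. For each heterozygous sample the total read count is Poisson
#' with mean `reads_per_het_sample` and the reference-haplotype count is
#' binomial with success probability 0.5 (null pairs) or `allelic_effect`
#' toward a pair-level direction shared across samples (planted pairs).
#'
#' @param config a [sim_config()].
#' @param loops interaction calls for one cell type (pooled), one row per
#'   loop; the `cell_type` column prefixes SNP ids.
#' @return list with `genotypes` (schema `phased_genotypes`), `counts`
#'   (schema `allele_counts`) and `truth` (schema `truth_allelic`).
#' @export
simulate_allelic_counts <- function(config, loops) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(loops) == 0) stop("loops must be non-empty")
  if (config$allelic_effect <= 0 || config$allelic_effect >= 1)
    stop("allelic_effect of 0 or 1 gives a degenerate binomial")
  ct <- if ("cell_type" %in% names(loops) && !is.na(loops$cell_type[1]))
    loops$cell_type[1] else "NA"
  .seed_for(config, 211L + sum(utf8ToInt(ct)) %% 997L)

  n_loops <- nrow(loops)
  snp_id <- sprintf("%s_snp_%05d", ct, seq_len(n_loops))
  mid0 <- floor((loops$oe_start + loops$oe_end) / 2)  # 0-based, inside [s, e)
  pos <- mid0 + 1                                     # 1-based
  chrom <- loops$oe_chrom

  samples <- c(sprintf("P%02d", seq_len(config$n_samples_patient)),
               sprintf("C%02d", seq_len(config$n_samples_control)))
  n_s <- length(samples)

  maf <- config$maf
  gt_levels <- c("hom_ref", "het", "hom_alt")
  gt_prob <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  gt_class <- matrix(sample(gt_levels, n_loops * n_s, replace = TRUE,
                            prob = gt_prob),
                     nrow = n_loops)
  phase <- matrix(sample(c("0|1", "1|0"), n_loops * n_s, replace = TRUE),
                  nrow = n_loops)
  gt <- ifelse(gt_class == "hom_ref", "0|0",
               ifelse(gt_class == "hom_alt", "1|1", phase))

  genotypes <- data.frame(sample_id = rep(samples, each = n_loops),
                          snp_id = rep(snp_id, n_s),
                          chrom = rep(chrom, n_s),
                          pos = rep(as.integer(pos), n_s),
                          ref = "A", alt = "G",
                          gt = as.vector(gt),
                          stringsAsFactors = FALSE)

  n_planted <- round(config$frac_imbalanced_pairs * n_loops)
  planted <- if (n_planted > 0) sort(sample.int(n_loops, n_planted)) else
    integer(0)
  direction <- rep(NA_character_, n_loops)
  p_ref <- rep(0.5, n_loops)
  if (n_planted > 0) {
    direction[planted] <- sample(c("ref_up", "alt_up"), n_planted,
                                 replace = TRUE)
    p_ref[planted] <- ifelse(direction[planted] == "ref_up",
                             config$allelic_effect,
                             1 - config$allelic_effect)
  }

  het <- which(gt == "0|1" | gt == "1|0", arr.ind = TRUE)
  if (nrow(het) > 0) {
    li <- het[, 1]; si <- het[, 2]
    tot <- rpois(nrow(het), config$reads_per_het_sample)
    keep <- tot > 0
    li <- li[keep]; si <- si[keep]; tot <- tot[keep]
    ref_n <- rbinom(length(tot), tot, p_ref[li])
    counts <- data.frame(sample_id = samples[si],
                         snp_id = snp_id[li],
                         loop_id = loops$loop_id[li],
                         ref_count = as.integer(ref_n),
                         alt_count = as.integer(tot - ref_n),
                         stringsAsFactors = FALSE)
    counts <- counts[order(counts$snp_id, counts$sample_id), , drop = FALSE]
    rownames(counts) <- NULL
  } else {
    counts <- data.frame(sample_id = character(0), snp_id = character(0),
                         loop_id = character(0), ref_count = integer(0),
                         alt_count = integer(0), stringsAsFactors = FALSE)
  }

  truth <- data.frame(snp_id = snp_id[planted],
                      loop_id = loops$loop_id[planted],
                      direction = direction[planted],
                      p_ref = p_ref[planted],
                      stringsAsFactors = FALSE)
  list(genotypes = genotypes, counts = counts, truth = truth)
}

#' Internal differential-expression summary (Welch t on log2 CPM)
#'
#' A deliberately simple test standing in for a full count-model analysis to
#' give the concordance stage realistically distributed inputs: per gene, a
#' Welch t-test on `log2(CPM + 1)` between the two groups, with
#' Benjamini-Hochberg adjustment. It is not equivalent to edgeR/DESeq2-style
#' dispersion modelling.
#'
#' @param counts genes x samples count matrix (rownames = gene ids).
#' @param group factor/character vector of length `ncol(counts)` with exactly
#'   two levels; the first level is condition A.
#' @return data.frame in the `expression_results` schema.
#' @export
de_summary <- function(counts, group) {
  group <- as.character(group)
  levels_ <- unique(group)
  if (length(levels_) != 2) stop("exactly two groups expected")
  a <- group == levels_[1]; b <- group == levels_[2]
  if (sum(a) < 2 || sum(b) < 2) stop("fewer than 2 samples per group")
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  lg <- log2(cpm + 1)
  ma <- rowMeans(lg[, a, drop = FALSE]); mb <- rowMeans(lg[, b, drop = FALSE])
  va <- apply(lg[, a, drop = FALSE], 1, stats::var)
  vb <- apply(lg[, b, drop = FALSE], 1, stats::var)
  na <- sum(a); nb <- sum(b)
  se2 <- va / na + vb / nb
  tstat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(gene_id = rownames(counts),
             log2fc = ma - mb,
             adj_p = bh_adjust(p),
             p_value = p,  # raw per-gene p, kept for calibration checks
             mean_expr_a = rowMeans(cpm[, a, drop = FALSE]),
             mean_expr_b = rowMeans(cpm[, b, drop = FALSE]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate expression counts coupled to planted interaction differences
#'
#' Counts are negative-binomial per gene and sample across the two cell types.
#' Bait genes of planted cell-type-specific loops receive, with probability
#' `coupling_rate`, a planted expression log2 fold change whose sign matches
#' the loop's cell-type direction; with `couple_magnitude = TRUE` the
#' magnitude is proportional to the loop's interaction |log2FC| (scaled so its
#' expectation equals `de_effect_log2fc`).
#'
#' @param config a [sim_config()].
#' @param loop_truth truth table from [simulate_interactions()].
#' @param genes optional gene universe; defaults to the truth genes padded
#'   with background genes up to `config$n_genes`.
#' @return list with `counts` (matrix), `group` (cell-type label per column),
#'   `expression` (schema `expression_results` via [de_summary()]) and `truth`
#'   (schema `truth_expression`).
#' @export
simulate_expression_counts <- function(config, loop_truth, genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples_patient + config$n_samples_control < 2)
    stop("fewer than 2 samples per group")
  .seed_for(config, 307L)

  truth_genes <- if (nrow(loop_truth) > 0)
    unlist(strsplit(loop_truth$bait_genes, ";", fixed = TRUE)) else character(0)
  if (is.null(genes)) {
    n_bg <- max(0, config$n_genes - length(unique(truth_genes)))
    genes <- c(unique(truth_genes), sprintf("bg_gene_%05d", seq_len(n_bg)))
  } else {
    genes <- unique(genes)
    if (length(genes) < config$n_genes)
      genes <- c(genes,
                 sprintf("bg_gene_%05d",
                         seq_len(config$n_genes - length(genes))))
  }
  n_g <- length(genes)

  # planted expression effects coupled to planted loops
  lfc <- stats::setNames(rep(0, n_g), genes)
  truth_rows <- list()
  if (nrow(loop_truth) > 0) {
    mean_di <- (2.2 + 6) / 2  # mean planted interaction |log2FC|
    # gene-level coupling: the expression effect tracks the gene's median
    # planted interaction effect (dosage relationship), not a single loop
    fan <- fan_out_genes(loop_truth)
    for (g in unique(fan$gene_id)) {
      if (!g %in% genes) next
      if (runif(1) > config$coupling_rate) next
      rows <- fan[fan$gene_id == g, , drop = FALSE]
      med <- stats::median(rows$log2fc)
      mag <- if (config$couple_magnitude)
        config$de_effect_log2fc * abs(med) / mean_di
      else config$de_effect_log2fc
      lfc[[g]] <- sign(med) * mag
      truth_rows[[length(truth_rows) + 1]] <-
        data.frame(gene_id = g, true_log2fc = lfc[[g]],
                   loop_id = paste(rows$loop_id, collapse = ";"),
                   stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth_rows) > 0) do.call(rbind, truth_rows) else
    data.frame(gene_id = character(0), true_log2fc = numeric(0),
               loop_id = character(0), stringsAsFactors = FALSE)

  n_per_ct <- config$n_samples_patient + config$n_samples_control
  group <- rep(config$cell_types, each = n_per_ct)
  base_mu <- stats::rlnorm(n_g, meanlog = log(200), sdlog = 1)
  mu_a <- base_mu * 2 ^ (lfc / 2)
  mu_b <- base_mu * 2 ^ (-lfc / 2)
  size <- 1 / config$nb_dispersion
  counts <- cbind(
    matrix(rnbinom(n_g * n_per_ct, mu = rep(mu_a, n_per_ct), size = size),
           nrow = n_g),
    matrix(rnbinom(n_g * n_per_ct, mu = rep(mu_b, n_per_ct), size = size),
           nrow = n_g))
  rownames(counts) <- genes
  colnames(counts) <- paste0(group, "_", c(seq_len(n_per_ct),
                                           seq_len(n_per_ct)))

  list(counts = counts, group = group,
       expression = de_summary(counts, group), truth = truth)
}

#' Simulate GWAS leads, LD proxies and enhancer segmentations
#'
#' Each lead receives proxies within `ld_block_span_bp`, with r2 drawn so that
#' `frac_r2_high` of them exceed 0.8. Enhancer intervals are placed so that
#' `enhancer_density` of the significance-passing SNPs fall inside enhancers
#' of each cell type. When `interactions` are supplied, `n_candidate_snps`
#' leads are planted at the midpoints of other ends of significant
#' (score > 5) interactions, creating known candidate genes; the returned
#' truth table is a brute-force containment scan of the emitted bundle
#' (independent of the package's interval machinery).
#'
#' @param config a [sim_config()].
#' @param interactions optional interaction calls (pooled per cell type) used
#'   to plant candidate genes.
#' @return list with `leads`, `proxies`, `enhancers` and `truth` (schema
#'   `truth_candidate_genes`).
#' @export
simulate_gwas_annotation <- function(config, interactions = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_gwas_loci == 0) stop("n_gwas_loci must be positive")
  .seed_for(config, 401L)

  n_lead <- config$n_gwas_loci
  lead_id <- sprintf("lead_%02d", seq_len(n_lead))
  # far zone, on chromosomes never used by interactions
  chrom <- paste0("chr", 21 + (seq_len(n_lead) - 1) %% 2)
  pos <- 5e6 + ((seq_len(n_lead) - 1) %/% 2) * 3e6

  # plant candidate leads inside other ends of significant interactions
  sig <- if (!is.null(interactions))
    interactions[interactions$score > 5, , drop = FALSE] else NULL
  n_cand <- if (is.null(sig) || nrow(sig) == 0) 0 else
    min(config$n_candidate_snps, n_lead)
  cand_ct <- character(0)
  if (n_cand > 0) {
    pick_loops <- sample(unique(sig$loop_id), min(n_cand,
                                                  length(unique(sig$loop_id))))
    n_cand <- length(pick_loops)
    for (k in seq_len(n_cand)) {
      rows <- sig[sig$loop_id == pick_loops[k], , drop = FALSE]
      r <- rows[sample.int(nrow(rows), 1), ]
      chrom[k] <- r$oe_chrom
      pos[k] <- floor((r$oe_start + r$oe_end) / 2) + 1
      cand_ct[k] <- r$cell_type
    }
  }
  leads <- data.frame(snp_id = lead_id, chrom = chrom, pos = as.integer(pos),
                      gwas_p = 10 ^ -runif(n_lead, 8.05, 40),
                      stringsAsFactors = FALSE)

  n_p <- config$n_proxies_per_lead
  li <- rep(seq_len(n_lead), each = n_p)
  offset <- round(runif(n_lead * n_p, -config$ld_block_span_bp,
                        config$ld_block_span_bp))
  offset[offset == 0] <- 1
  high <- runif(n_lead * n_p) < config$frac_r2_high
  proxies <- data.frame(
    snp_id = sprintf("%s_p%03d", lead_id[li], rep(seq_len(n_p), n_lead)),
    chrom = leads$chrom[li],
    pos = as.integer(pmax(1, leads$pos[li] + offset)),
    lead_id = lead_id[li],
    r2 = ifelse(high, runif(n_lead * n_p, 0.8001, 1),
                runif(n_lead * n_p, 0, 0.8)),
    stringsAsFactors = FALSE)

  # significance-passing SNP set, generator-side (leads + high-LD proxies)
  passing <- rbind(
    data.frame(snp_id = leads$snp_id, chrom = leads$chrom, pos = leads$pos,
               lead_id = leads$snp_id, stringsAsFactors = FALSE),
    data.frame(snp_id = proxies$snp_id[proxies$r2 > 0.8],
               chrom = proxies$chrom[proxies$r2 > 0.8],
               pos = proxies$pos[proxies$r2 > 0.8],
               lead_id = proxies$lead_id[proxies$r2 > 0.8],
               stringsAsFactors = FALSE))

  enh <- list()
  for (ct in config$cell_types) {
    n_cov <- round(config$enhancer_density * nrow(passing))
    cover <- if (n_cov > 0) sample.int(nrow(passing), n_cov) else integer(0)
    # candidate leads must carry an enhancer in their interaction's cell type
    force_idx <- which(passing$snp_id %in% lead_id[seq_len(n_cand)][
      cand_ct[seq_len(n_cand)] == ct])
    cover <- union(cover, force_idx)
    e <- if (length(cover) > 0)
      data.frame(chrom = passing$chrom[cover],
                 start = pmax(0, passing$pos[cover] - 1 - 100),
                 end = passing$pos[cover] + 100,
                 cell_type = ct, stringsAsFactors = FALSE)
    else data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0), cell_type = character(0),
                    stringsAsFactors = FALSE)
    # background enhancers away from all simulated SNPs
    bg <- data.frame(chrom = paste0("chr", 21 + seq_len(30) %% 2),
                     start = 6e7 + seq_len(30) * 5e4,
                     end = 6e7 + seq_len(30) * 5e4 + 1000,
                     cell_type = ct, stringsAsFactors = FALSE)
    enh[[ct]] <- rbind(e, bg)
  }
  enhancers <- do.call(rbind, enh)
  rownames(enhancers) <- NULL

  truth <- .scan_candidate_truth(passing, enhancers, interactions,
                                 config$cell_types)
  list(leads = leads, proxies = proxies, enhancers = enhancers, truth = truth)
}

# Brute-force truth scan: for every passing SNP and cell type, is the SNP
# inside an enhancer of that cell type AND inside the other end of a
# significant (score > 5) interaction of that cell type? Plain arithmetic,
# independent of the GRanges-based pipeline path.
.scan_candidate_truth <- function(passing, enhancers, interactions,
                                  cell_types) {
  empty <- data.frame(lead_id = character(0), snp_id = character(0),
                      gene_id = character(0), cell_type = character(0),
                      loop_id = character(0), stringsAsFactors = FALSE)
  if (is.null(interactions) || nrow(passing) == 0) return(empty)
  rows <- list()
  for (ct in cell_types) {
    e <- enhancers[enhancers$cell_type == ct, , drop = FALSE]
    ints <- interactions[interactions$cell_type == ct &
                           interactions$score > 5, , drop = FALSE]
    if (nrow(e) == 0 || nrow(ints) == 0) next
    for (i in seq_len(nrow(passing))) {
      p0 <- passing$pos[i] - 1
      in_enh <- any(e$chrom == passing$chrom[i] & e$start <= p0 & p0 < e$end)
      if (!in_enh) next
      hit <- which(ints$oe_chrom == passing$chrom[i] &
                     ints$oe_start <= p0 & p0 < ints$oe_end)
      for (h in hit) {
        for (g in strsplit(ints$bait_genes[h], ";", fixed = TRUE)[[1]]) {
          rows[[length(rows) + 1]] <-
            data.frame(lead_id = passing$lead_id[i],
                       snp_id = passing$snp_id[i], gene_id = g,
                       cell_type = ct, loop_id = ints$loop_id[h],
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$lead_id, out$snp_id, out$gene_id, out$cell_type), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate the complete in-memory fixture bundle
#'
#' Runs all four generators with consistent cross-references: allelic counts
#' are drawn on each cell type's pooled loops, expression effects are coupled
#' to the planted interaction truth, and GWAS candidate SNPs are planted
#' inside significant other ends.
#'
#' @param config a [sim_config()].
#' @return list with elements `config`, `interactions`, `differential`,
#'   `allelic` (per cell type: `genotypes`, `counts`), `expression` (counts,
#'   group, summary table) and `gwas` (leads, proxies, enhancers), plus
#'   `truth` (interactions, allelic per cell type, expression,
#'   candidate_genes).
#' @export
simulate_bundle <- function(config) {
  ints <- simulate_interactions(config)
  pooled <- ints$interactions[ints$interactions$condition == "pooled", ,
                              drop = FALSE]
  allelic <- lapply(stats::setNames(config$cell_types, config$cell_types),
                    function(ct) {
                      simulate_allelic_counts(
                        config, pooled[pooled$cell_type == ct, , drop = FALSE])
                    })
  all_genes <- unique(unlist(strsplit(pooled$bait_genes, ";", fixed = TRUE)))
  expr <- simulate_expression_counts(config, ints$truth, genes = all_genes)
  gwas <- simulate_gwas_annotation(config, interactions = pooled)
  list(config = config,
       interactions = ints$interactions,
       differential = ints$differential,
       allelic = lapply(allelic, function(a) a[c("genotypes", "counts")]),
       expression = expr[c("counts", "group", "expression")],
       gwas = gwas[c("leads", "proxies", "enhancers")],
       truth = list(interactions = ints$truth,
                    allelic = lapply(allelic, `[[`, "truth"),
                    expression = expr$truth,
                    candidate_genes = gwas$truth))
}

#' Write a fixture bundle to disk
#'
#' Writes every table through the package's format writers and emits a
#' `manifest.json` with per-file MD5 checksums and a hash of the
#' configuration, making the bundle self-describing. A failed write removes
#' any partially written files before erroring.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
simulate_fixture_bundle <- function(config, out_dir) {
  bundle <- simulate_bundle(config)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  written <- character(0)
  emit <- function(fname, writer) {
    path <- file.path(out_dir, fname)
    writer(path)
    if (!file.exists(path)) stop("write failed: ", path)
    written <<- c(written, path)
    path
  }
  on_fail <- function(e) {
    unlink(written)
    stop("bundle write failed (partial files removed): ",
         conditionMessage(e), call. = FALSE)
  }

  tryCatch({
    ints <- bundle$interactions
    for (ct in config$cell_types) {
      for (cond in c("pooled", "patient", "control")) {
        sub <- ints[ints$cell_type == ct & ints$condition == cond, ,
                    drop = FALSE]
        emit(sprintf("interactions_%s_%s.ibed", ct, cond),
             function(p) write_interaction_table(sub, p))
      }
      emit(sprintf("genotypes_%s.tsv", ct), function(p)
        write_results(bundle$allelic[[ct]]$genotypes, p, "phased_genotypes"))
      emit(sprintf("allele_counts_%s.tsv", ct), function(p)
        write_results(bundle$allelic[[ct]]$counts, p, "allele_counts"))
      emit(sprintf("truth_allelic_%s.tsv", ct), function(p)
        write_results(bundle$truth$allelic[[ct]], p, "truth_allelic"))
      enh <- bundle$gwas$enhancers
      emit(sprintf("enhancers_%s.bed", ct), function(p)
        write_region_bed(enh[enh$cell_type == ct, , drop = FALSE], p))
    }
    emit("differential_interactions.tsv", function(p)
      write_results(bundle$differential, p, "differential_interactions"))
    emit("expression_results.tsv", function(p)
      write_results(bundle$expression$expression, p, "expression_results"))
    emit("expression_counts.tsv", function(p) {
      m <- data.frame(gene_id = rownames(bundle$expression$counts),
                      bundle$expression$counts, check.names = FALSE)
      utils::write.table(m, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    emit("gwas_leads.tsv", function(p)
      write_results(bundle$gwas$leads, p, "gwas_leads"))
    emit("ld_proxies.tsv", function(p)
      write_results(bundle$gwas$proxies, p, "ld_proxies"))
    emit("truth_interactions.tsv", function(p)
      write_results(bundle$truth$interactions, p, "truth_interactions"))
    emit("truth_expression.tsv", function(p)
      write_results(bundle$truth$expression, p, "truth_expression"))
    emit("truth_candidate_genes.tsv", function(p)
      write_results(bundle$truth$candidate_genes, p, "truth_candidate_genes"))

    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA)
    tmp <- tempfile(); writeLines(cfg_json, tmp)
    cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
    files <- stats::setNames(as.list(unname(tools::md5sum(written))),
                             basename(written))
    manifest <- list(package = "varloops", config = unclass(config),
                     config_hash = cfg_hash, files = files)
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, manifest_path)
    invisible(manifest)
  }, error = on_fail)
}

#' Load a fixture bundle written by [simulate_fixture_bundle()]
#'
#' @param dir bundle directory containing `manifest.json`.
#' @return in-memory bundle in the shape of [simulate_bundle()] (without
#'   expression counts and truth-less fields absent from disk).
#' @export
load_fixture_bundle <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(manifest_path)
  cts <- unlist(manifest$config$cell_types)
  ints <- list(); allelic <- list(); truth_allelic <- list(); enh <- list()
  for (ct in cts) {
    for (cond in c("pooled", "patient", "control")) {
      f <- file.path(dir, sprintf("interactions_%s_%s.ibed", ct, cond))
      ints[[paste(ct, cond)]] <- load_interaction_table(
        f, "ibed", cell_type = ct, condition = cond)
    }
    allelic[[ct]] <- list(
      genotypes = load_results(file.path(dir, sprintf("genotypes_%s.tsv", ct)),
                               "phased_genotypes"),
      counts = load_results(file.path(dir,
                                      sprintf("allele_counts_%s.tsv", ct)),
                            "allele_counts"))
    truth_allelic[[ct]] <- load_results(
      file.path(dir, sprintf("truth_allelic_%s.tsv", ct)), "truth_allelic")
    enh[[ct]] <- load_region_bed(file.path(dir,
                                           sprintf("enhancers_%s.bed", ct)))
  }
  enhancers <- do.call(rbind, enh); rownames(enhancers) <- NULL
  list(config = manifest$config,
       interactions = do.call(rbind, ints),
       differential = load_results(
         file.path(dir, "differential_interactions.tsv"),
         "differential_interactions"),
       allelic = allelic,
       expression = list(expression = load_results(
         file.path(dir, "expression_results.tsv"), "expression_results")),
       gwas = list(
         leads = load_results(file.path(dir, "gwas_leads.tsv"), "gwas_leads"),
         proxies = load_results(file.path(dir, "ld_proxies.tsv"),
                                "ld_proxies"),
         enhancers = enhancers),
       truth = list(
         interactions = load_results(file.path(dir, "truth_interactions.tsv"),
                                     "truth_interactions"),
         allelic = truth_allelic,
         expression = load_results(file.path(dir, "truth_expression.tsv"),
                                   "truth_expression"),
         candidate_genes = load_results(
           file.path(dir, "truth_candidate_genes.tsv"),
           "truth_candidate_genes")))
}
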