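# Synthetic-data generator: determinism, planted structure, null construction.

test_that("configs validate their fields", {
  expect_error(sim_config(maf = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(n_genes = 0), "positive")
  expect_s3_class(sim_config(), "sim_config")
  expect_output(print(sim_config()), "seed")
})

test_that("interaction counts and planted scores follow the construction", {
  cfg <- sim_config(seed = 2, n_baits = 100, n_other_ends_per_bait = 10)
  sim <- simulate_interactions(cfg)
  pooled <- sim$interactions[sim$interactions$condition == "pooled", ]
  # exactly 1,000 candidate pairs per cell type
  expect_equal(sum(pooled$cell_type == "CD4"), 1000)
  expect_equal(sum(pooled$cell_type == "CD14"), 1000)

  # every planted loop scores > 5 in its cell type and < 5 in the other
  for (i in seq_len(nrow(sim$truth))) {
    on <- sim$truth$on_cell_type[i]
    off <- setdiff(cfg$cell_types, on)
    s_on <- pooled$score[pooled$loop_id == sim$truth$loop_id[i] &
                           pooled$cell_type == on]
    s_off <- pooled$score[pooled$loop_id == sim$truth$loop_id[i] &
                            pooled$cell_type == off]
    expect_gt(s_on, 5)
    expect_lt(s_off, 5)
  }
  # planted loops are significant in the differential table with correct sign
  dk <- interaction_key(sim$differential)
  for (i in seq_len(nrow(sim$truth))) {
    row <- sim$differential[dk == sim$truth$loop_id[i], ]
    expect_equal(nrow(row), 1)
    expect_lt(row$wadj_p, 0.05)
    expect_equal(sign(row$log2fc),
                 if (sim$truth$on_cell_type[i] == "CD4") 1 else -1)
  }
  expect_error(simulate_interactions(sim_config(n_baits = 0)), "zero baits")
})

test_that("null interaction bundle has no truth and ~5% chance significance", {
  cfg <- sim_config(seed = 3, n_baits = 200,
                    frac_celltype_specific_loops = 0)
  sim <- simulate_interactions(cfg)
  expect_equal(nrow(sim$truth), 0)
  frac_sig <- mean(sim$differential$wadj_p < 0.05)
  expect_lt(abs(frac_sig - 0.05), 0.025)
})

test_that("generators are deterministic in the config", {
  cfg <- sim_config(seed = 9, n_baits = 30)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$interactions, b2$interactions)
  expect_identical(b1$allelic, b2$allelic)
  expect_identical(b1$expression$counts, b2$expression$counts)
  expect_identical(b1$gwas, b2$gwas)
  b3 <- simulate_bundle(sim_config(seed = 10, n_baits = 30))
  expect_false(identical(b1$interactions$score, b3$interactions$score))
})

test_that("allelic counts follow Hardy-Weinberg structure and planted effects", {
  cfg <- sim_config(seed = 5, n_baits = 60)
  loops <- simulate_interactions(cfg)$interactions
  loops <- loops[loops$cell_type == "CD4" & loops$condition == "pooled", ]

  # MAF 0: no heterozygotes, empty count table
  cfg0 <- sim_config(seed = 5, maf = 0)
  a0 <- simulate_allelic_counts(cfg0, loops)
  expect_equal(nrow(a0$counts), 0)
  expect_true(all(a0$genotypes$gt == "0|0"))

  # degenerate allelic_effect rejected
  expect_error(simulate_allelic_counts(sim_config(allelic_effect = 0), loops),
               "degenerate")
  expect_error(simulate_allelic_counts(sim_config(allelic_effect = 1), loops),
               "degenerate")

  # allelic_effect 0.5 with everything "planted" is indistinguishable from null
  cfg5 <- sim_config(seed = 6, allelic_effect = 0.5,
                     frac_imbalanced_pairs = 1)
  a5 <- simulate_allelic_counts(cfg5, loops)
  tot <- sum(a5$counts$ref_count) + sum(a5$counts$alt_count)
  expect_gt(tot, 10000)
  expect_lt(abs(sum(a5$counts$ref_count) / tot - 0.5), 0.02)

  # planted pairs push the pooled reference fraction toward the effect
  cfg75 <- sim_config(seed = 6, frac_imbalanced_pairs = 1)
  a75 <- simulate_allelic_counts(cfg75, loops)
  dir <- a75$truth$direction[match(a75$counts$snp_id, a75$truth$snp_id)]
  up <- a75$counts[dir == "ref_up", ]
  frac <- sum(up$ref_count) / (sum(up$ref_count) + sum(up$alt_count))
  expect_lt(abs(frac - 0.75), 0.03)
})

test_that("expression nulls are calibrated and planted effects recovered", {
  # null: uniform raw p, empty truth
  cfg0 <- sim_config(seed = 7, de_effect_log2fc = 0, coupling_rate = 0,
                     n_genes = 1000)
  b0 <- simulate_bundle(cfg0)
  expect_equal(nrow(b0$truth$expression), 0)
  pv <- b0$expression$expression$p_value
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(pv < 0.1) - 0.1), 0.04)

  # planted constant effect of 3 recovered within +/- 0.5 on average
  est <- unlist(lapply(1:3, function(s) {
    cfg <- sim_config(seed = s, coupling_rate = 1, couple_magnitude = FALSE,
                      de_effect_log2fc = 3)
    b <- simulate_bundle(cfg)
    tr <- b$truth$expression
    e <- b$expression$expression
    e$log2fc[match(tr$gene_id, e$gene_id)] * sign(tr$true_log2fc)
  }))
  expect_gt(length(est), 100)
  expect_lt(abs(mean(est) - 3), 0.5)

  # coupling_rate 1: every planted loop's gene is in the DE truth with
  # matching sign
  b1 <- simulate_bundle(sim_config(seed = 8, coupling_rate = 1))
  fan <- fan_out_genes(b1$truth$interactions)
  for (g in unique(fan$gene_id)) {
    tr <- b1$truth$expression[b1$truth$expression$gene_id == g, ]
    expect_equal(nrow(tr), 1)
    expect_equal(sign(tr$true_log2fc),
                 sign(stats::median(fan$log2fc[fan$gene_id == g])))
  }

  # the group-size guard (bypassing the constructor's own validation)
  tiny <- sim_config()
  tiny$n_samples_patient <- 1L
  tiny$n_samples_control <- 0L
  expect_error(simulate_expression_counts(tiny, data.frame()),
               "fewer than 2")
})

test_that("GWAS annotation honors r2 fractions and enhancer density", {
  cfg <- sim_config(seed = 11, frac_r2_high = 1)
  g <- simulate_gwas_annotation(cfg)
  # every proxy exceeds 0.8, so LD expansion returns all of them
  snp_set <- expand_ld(g$leads, g$proxies)
  expect_equal(nrow(snp_set), nrow(g$leads) + nrow(g$proxies))

  # enhancer_density 0 and no planted candidates -> no overlapping SNPs
  cfg0 <- sim_config(seed = 11, enhancer_density = 0, n_candidate_snps = 0)
  g0 <- simulate_gwas_annotation(cfg0)
  snp0 <- expand_ld(g0$leads, g0$proxies)
  ann <- annotate_snp_overlaps(snp0, g0$enhancers)
  expect_true(all(ann$summary$n_overlap == 0))
  expect_equal(nrow(g0$truth), 0)

  expect_error(simulate_gwas_annotation(sim_config(n_gwas_loci = 0)),
               "positive")
})

test_that("truth tables reference only emitted entities, exactly once", {
  b <- simulate_bundle(sim_config(seed = 13))
  pooled <- b$interactions[b$interactions$condition == "pooled", ]
  expect_true(all(b$truth$interactions$loop_id %in% pooled$loop_id))
  expect_false(any(duplicated(b$truth$interactions$loop_id)))
  for (ct in c("CD4", "CD14")) {
    tr <- b$truth$allelic[[ct]]
    expect_false(any(duplicated(paste(tr$snp_id, tr$loop_id))))
    expect_true(all(tr$snp_id %in% b$allelic[[ct]]$genotypes$snp_id))
    expect_true(all(tr$loop_id %in% pooled$loop_id[pooled$cell_type == ct]))
  }
  expect_false(any(duplicated(b$truth$expression$gene_id)))
  expect_true(all(b$truth$expression$gene_id %in%
                    rownames(b$expression$counts)))
  snp_ids <- c(b$gwas$leads$snp_id, b$gwas$proxies$snp_id)
  expect_true(all(b$truth$candidate_genes$snp_id %in% snp_ids))
})

test_that("fixture bundles are self-describing and reproducible on disk", {
  cfg <- sim_config(seed = 15, n_baits = 20)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- simulate_fixture_bundle(cfg, d1)
  m2 <- simulate_fixture_bundle(cfg, d2)
  expect_identical(m1$config_hash, m2$config_hash)
  expect_identical(m1$files, m2$files)  # byte-identical tables
  # manifest lists an interaction table per cell type and condition
  expect_true(all(sprintf("interactions_%s_%s.ibed",
                          rep(c("CD4", "CD14"), each = 3),
                          c("pooled", "patient", "control")) %in%
                    names(m1$files)))

  # bundles round-trip through the loaders
  back <- load_fixture_bundle(d1)
  mem <- simulate_bundle(cfg)
  pooled_mem <- mem$interactions[mem$interactions$condition == "pooled" &
                                   mem$interactions$cell_type == "CD4", ]
  pooled_disk <- back$interactions[back$interactions$condition == "pooled" &
                                     back$interactions$cell_type == "CD4", ]
  expect_equal(pooled_disk$loop_id, pooled_mem$loop_id)
  expect_equal(pooled_disk$score, pooled_mem$score, tolerance = 1e-5)
  expect_equal(back$truth$candidate_genes, mem$truth$candidate_genes)

  # an uncreatable target directory errors before writing anything
  blocker <- withr::local_tempfile()
  writeLines("x", blocker)  # a regular file cannot be a parent directory
  expect_error(simulate_fixture_bundle(cfg, file.path(blocker, "sub")),
               "cannot create")

  # a failure midway through the bundle removes already-written files
  broken <- withr::local_tempdir()
  dir.create(file.path(broken, "differential_interactions.tsv"))  # blocks one write
  suppressWarnings(
    expect_error(simulate_fixture_bundle(cfg, broken),
                 "partial files removed"))
  expect_equal(setdiff(list.files(broken), "differential_interactions.tsv"),
               character(0))
})
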