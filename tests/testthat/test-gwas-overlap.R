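# GWAS locus definition, enhancer unions, overlap statistics and the
# candidate-gene assignment rule.

make_leads <- function(n, chrom = "chr1", spacing = 1e6, p = 1e-10) {
  data.frame(snp_id = sprintf("lead_%02d", seq_len(n)), chrom = chrom,
             pos = as.integer(seq_len(n) * spacing), gwas_p = p,
             stringsAsFactors = FALSE)
}

test_that("LD expansion applies strict significance and r2 boundaries", {
  leads <- data.frame(snp_id = c("l1", "l2"), chrom = "chr1",
                      pos = c(100L, 1000L), gwas_p = c(5e-8, 4.9e-8),
                      stringsAsFactors = FALSE)
  prox <- data.frame(snp_id = c("p1", "p2"), chrom = "chr1",
                     pos = c(150L, 1050L), lead_id = c("l2", "l2"),
                     r2 = c(0.8, 0.81), stringsAsFactors = FALSE)
  out <- expand_ld(leads, prox)
  # l1 at exactly 5e-8 excluded (strict <); p1 at exactly 0.8 excluded
  expect_setequal(out$snp_id, c("l2", "p2"))
  expect_equal(out$r2[out$snp_id == "l2"], 1)

  prox$lead_id[1] <- "nobody"
  expect_error(expand_ld(leads, prox), "unknown lead")
})

test_that("LD expansion counts leads plus passing proxies", {
  leads <- make_leads(3)
  prox <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(snp_id = sprintf("l%d_p%02d", i, 1:10), chrom = "chr1",
               pos = as.integer(i * 1e6 + 1:10 * 100),
               lead_id = sprintf("lead_%02d", i), r2 = 0.9,
               stringsAsFactors = FALSE)
  }))
  expect_equal(nrow(expand_ld(leads, prox)), 33)
})

test_that("locus definition spans members and merges nearby leads", {
  leads <- make_leads(1)
  snp <- expand_ld(leads, empty_proxies())
  # single lead, no proxies: length-1 region at the lead position
  snp1 <- data.frame(snp_id = "lead_01", chrom = "chr1", pos = 500L,
                     lead_id = "lead_01", r2 = 1, gwas_p = 1e-10,
                     stringsAsFactors = FALSE)
  loci <- define_loci(snp1)
  expect_equal(loci$start, 499)
  expect_equal(loci$end, 500)

  # two leads 10 kb apart merge at 250 kb distance
  snp2 <- data.frame(snp_id = c("a", "b"), chrom = "chr1",
                     pos = c(1000L, 11000L), lead_id = c("a", "b"),
                     r2 = 1, gwas_p = 1e-10, stringsAsFactors = FALSE)
  loci2 <- define_loci(snp2)
  expect_equal(nrow(loci2), 1)
  expect_equal(loci2$lead_ids, "a;b")
  expect_equal(nrow(define_loci(snp2, merge_distance_bp = 5000)), 2)
})

test_that("locus merging matches a transitive-closure oracle and partitions SNPs", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 50
    leads <- data.frame(snp_id = sprintf("L%02d", 1:n),
                        chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                        pos = as.integer(sample.int(5e6, n)),
                        gwas_p = 1e-10, stringsAsFactors = FALSE)
    prox <- data.frame(snp_id = sprintf("L%02d_p", 1:n),
                       chrom = leads$chrom,
                       pos = as.integer(pmax(1, leads$pos +
                                               sample(-5e4:5e4, n))),
                       lead_id = leads$snp_id, r2 = 0.95,
                       stringsAsFactors = FALSE)
    snp_set <- expand_ld(leads, prox)
    d <- sample(c(1e4, 1e5, 2.5e5), 1)
    loci <- define_loci(snp_set, merge_distance_bp = d)

    per_lead <- do.call(rbind, lapply(split(snp_set, snp_set$lead_id),
                                      function(s) data.frame(
                                        chrom = s$chrom[1],
                                        start = min(s$pos) - 1,
                                        end = max(s$pos))))
    oracle <- oracle_merge_regions(per_lead, d)
    expect_equal(nrow(loci), nrow(oracle))
    expect_equal(loci$start, oracle$start)
    expect_equal(loci$end, oracle$end)

    # every SNP belongs to exactly one locus
    membership <- unlist(strsplit(loci$snp_ids, ";", fixed = TRUE))
    expect_equal(sort(membership), sort(unique(snp_set$snp_id)))
    # and each region contains its member SNP positions
    for (i in seq_len(nrow(loci))) {
      ids <- strsplit(loci$snp_ids[i], ";", fixed = TRUE)[[1]]
      pos <- snp_set$pos[match(ids, snp_set$snp_id)]
      expect_true(all(pos - 1 >= loci$start[i] & pos - 1 < loci$end[i]))
    }
  }
})

test_that("enhancer union merges states present in any sample per cell type", {
  seg <- data.frame(
    sample_id = c("s1", "s1", "s2", "s2"),
    cell_type = c("CD4", "CD4", "CD4", "CD14"),
    chrom = "chr1",
    start = c(0, 50, 300, 500),
    end = c(100, 150, 400, 600),
    state = c("E7", "E7", "E7", "E9"),
    stringsAsFactors = FALSE)
  enh <- build_enhancer_union(seg, enhancer_states = c("E7", "E9"))
  cd4 <- enh[enh$cell_type == "CD4", ]
  expect_equal(cd4$start, c(0, 300))  # [0,100) + [50,150) merge to [0,150)
  expect_equal(cd4$end, c(150, 400))
  # enhancer present only in one sample still counts (>= 1 rule)
  expect_equal(enh$start[enh$cell_type == "CD14"], 500)
  # no enhancer states anywhere -> empty set; unknown labels ignored
  expect_equal(nrow(build_enhancer_union(seg, "E99")), 0)
})

test_that("interval union and containment agree with brute-force scans", {
  for (seed in 1:4) {
    iv <- random_intervals(200, seed = seed)
    merged <- merge_intervals(iv)
    expect_equal(oracle_union_coverage(merged, 0, 2200),
                 oracle_union_coverage(iv, 0, 2200))
    # merged intervals are disjoint and sorted
    by_chr <- split(merged, merged$chrom)
    for (m in by_chr)
      if (nrow(m) > 1) expect_true(all(m$start[-1] > m$end[-nrow(m)]))

    pos <- sample.int(2200, 200, replace = TRUE)
    chrom <- sample(c("chr1", "chr2"), 200, replace = TRUE)
    expect_equal(points_in_intervals(chrom, pos, iv),
                 oracle_points_in(chrom, pos, iv))
  }
})

test_that("SNP/enhancer overlap respects the half-open convention", {
  enh <- data.frame(chrom = "chr1", start = c(99, 100), end = c(100, 200),
                    cell_type = c("CD4", "CD14"), stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = "s", chrom = "chr1", pos = 100L,
                     stringsAsFactors = FALSE)
  ann <- annotate_snp_overlaps(snps, enh)
  expect_true(ann$snps$in_enhancer_CD4)    # pos 100 is offset 99, in [99,100)
  expect_false(ann$snps$in_enhancer_CD14)  # not in [100,200)

  snps3 <- data.frame(snp_id = c("a", "b", "c"), chrom = "chr1",
                      pos = c(100L, 100L, 500L), stringsAsFactors = FALSE)
  ann3 <- annotate_snp_overlaps(snps3, enh[1, ])
  expect_equal(ann3$summary$proportion, 2 / 3)
})

test_that("two-proportion z-test matches the pooled-variance normal form", {
  sym <- two_proportion_test(15, 15, 60)
  expect_equal(sym$z, 0)
  expect_equal(sym$p, 1)

  t1 <- two_proportion_test(20, 10, 100)
  # closed-form pooled-variance oracle
  z_expect <- (0.2 - 0.1) / sqrt(0.15 * 0.85 * 2 / 100)
  expect_equal(t1$z, z_expect, tolerance = 1e-12)
  expect_equal(t1$z, 1.9803, tolerance = 1e-4)
  expect_equal(t1$p, 2 * pnorm(-z_expect), tolerance = 1e-12)
  expect_equal(t1$p, 0.0477, tolerance = 1e-3)

  ext <- two_proportion_test(50, 0, 50)
  expect_gt(abs(ext$z), abs(two_proportion_test(40, 10, 50)$z))
  expect_lt(ext$p, 1e-10)
  expect_error(two_proportion_test(1, 1, 0), "positive")
})

test_that("enhancer enrichment equals the hypergeometric tail", {
  # table [[10, 10], [10, 70]]: 20 foreground (10 in), 80 background (10 in)
  enh <- data.frame(chrom = "chr1", start = 0, end = 1000, cell_type = "CD4",
                    stringsAsFactors = FALSE)
  fg <- data.frame(snp_id = sprintf("f%d", 1:20), chrom = "chr1",
                   pos = c(1:10 * 10L, 2000L + 1:10),
                   stringsAsFactors = FALSE)
  bg <- data.frame(snp_id = sprintf("b%d", 1:80), chrom = "chr1",
                   pos = c(500L + 1:10, 3000L + 1:70),
                   stringsAsFactors = FALSE)
  res <- enhancer_enrichment(fg, bg, enh)
  expect_equal(res$odds_ratio, 7)
  expect_equal(res$p, oracle_fisher_exact_greater(10, 10, 10, 70),
               tolerance = 1e-12)

  # extreme table: all foreground in, all background out
  fg2 <- fg; fg2$pos <- 1:20 * 10L
  bg2 <- bg; bg2$pos <- 3000L + 1:80
  res2 <- enhancer_enrichment(fg2, bg2, enh)
  expect_equal(res2$odds_ratio, Inf)
  expect_equal(res2$p, oracle_fisher_exact_greater(20, 0, 0, 80),
               tolerance = 1e-12)

  expect_error(enhancer_enrichment(fg, fg, enh), "empty background")
})

test_that("candidate assignment needs the same SNP in enhancer and PIR", {
  loops <- toy_loops()  # loop 1: score 8, oe [10000, 11000) on chr1
  snps <- data.frame(snp_id = "rs1", chrom = "chr1", pos = 10500L,
                     lead_id = "rs1", r2 = 1, gwas_p = 1e-10,
                     stringsAsFactors = FALSE)
  enh_in <- data.frame(chrom = "chr1", start = 10400, end = 10600,
                       cell_type = "CD4", stringsAsFactors = FALSE)
  res <- map_snps_to_genes(snps, enh_in, loops)
  expect_equal(res$candidates$gene_id, "GENE_A")
  expect_equal(res$candidates$cell_types, "CD4")
  expect_equal(unname(res$interaction_counts["CD4"]), 1L)

  # same SNP outside all enhancers -> nothing
  enh_out <- data.frame(chrom = "chr1", start = 90000, end = 91000,
                        cell_type = "CD4", stringsAsFactors = FALSE)
  expect_equal(nrow(map_snps_to_genes(snps, enh_out, loops)$candidates), 0)

  # sub-threshold interaction score -> nothing
  low <- loops; low$score <- 4
  expect_equal(nrow(map_snps_to_genes(snps, enh_in, low)$candidates), 0)

  # shared baits fan out to one candidate row per gene
  snps2 <- data.frame(snp_id = "rs2", chrom = "chr2", pos = 70500L,
                      lead_id = "rs2", r2 = 1, gwas_p = 1e-10,
                      stringsAsFactors = FALSE)
  enh2 <- data.frame(chrom = "chr2", start = 70000, end = 71000,
                     cell_type = "CD4", stringsAsFactors = FALSE)
  res2 <- map_snps_to_genes(snps2, enh2, loops)
  expect_setequal(res2$candidates$gene_id, c("GENE_B", "GENE_C"))
})

test_that("candidate evidence re-validates against the raw inputs", {
  b <- simulate_bundle(sim_config(seed = 17))
  snp_set <- expand_ld(b$gwas$leads, b$gwas$proxies)
  pooled <- b$interactions[b$interactions$condition == "pooled", ]
  res <- map_snps_to_genes(snp_set, b$gwas$enhancers, pooled)
  ev <- res$evidence
  expect_gt(nrow(ev), 0)
  for (i in seq_len(nrow(ev))) {
    snp <- snp_set[snp_set$snp_id == ev$snp_id[i], ]
    int <- pooled[pooled$loop_id == ev$loop_id[i] &
                    pooled$cell_type == ev$cell_type[i], ]
    expect_gt(int$score[1], 5)
    p0 <- snp$pos - 1
    expect_true(p0 >= int$oe_start[1] && p0 < int$oe_end[1])
    expect_true(p0 >= ev$enh_start[i] && p0 < ev$enh_end[i])
    expect_true(ev$gene_id[i] %in%
                  strsplit(int$bait_genes[1], ";", fixed = TRUE)[[1]])
  }
})

test_that("removing a cell type's enhancers can only shrink its candidates", {
  b <- simulate_bundle(sim_config(seed = 19))
  snp_set <- expand_ld(b$gwas$leads, b$gwas$proxies)
  pooled <- b$interactions[b$interactions$condition == "pooled", ]
  full <- map_snps_to_genes(snp_set, b$gwas$enhancers, pooled)
  no_cd4 <- map_snps_to_genes(
    snp_set, b$gwas$enhancers[b$gwas$enhancers$cell_type != "CD4", ], pooled)
  in_ct <- function(res, ct) {
    cand <- res$candidates
    out <- cand[grepl(ct, cand$cell_types), c("locus_id", "gene_id")]
    rownames(out) <- NULL
    out
  }
  expect_equal(nrow(in_ct(no_cd4, "CD4")), 0)
  # CD14 candidates are unchanged
  expect_equal(in_ct(no_cd4, "CD14"), in_ct(full, "CD14"))
})

test_that("planted candidate genes are recovered exactly end to end", {
  for (seed in c(23, 29)) {
    b <- simulate_bundle(sim_config(seed = seed))
    snp_set <- expand_ld(b$gwas$leads, b$gwas$proxies)
    pooled <- b$interactions[b$interactions$condition == "pooled", ]
    res <- map_snps_to_genes(snp_set, b$gwas$enhancers, pooled)
    got <- unique(with(res$evidence,
                       paste(locus_id, snp_id, gene_id, cell_type, loop_id)))
    want <- unique(with(b$truth$candidate_genes,
                        paste(lead_id, snp_id, gene_id, cell_type, loop_id)))
    expect_setequal(got, want)
    expect_gt(length(want), 0)
  }
})
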