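# Small in-code fixtures shared across test files.

# a minimal interaction table (internal 0-based convention)
toy_loops <- function() {
  df <- data.frame(
    bait_chrom = c("chr1", "chr1", "chr2"),
    bait_start = c(1000, 1000, 5000),
    bait_end = c(2000, 2000, 6000),
    bait_genes = c("GENE_A", "GENE_A", "GENE_B;GENE_C"),
    oe_chrom = c("chr1", "chr1", "chr2"),
    oe_start = c(10000, 50000, 70000),
    oe_end = c(11000, 51000, 71000),
    n_reads = NA_integer_,
    score = c(8, 3, 6.5),
    cell_type = "CD4",
    condition = "pooled",
    stringsAsFactors = FALSE)
  df$loop_id <- interaction_key(df)
  df
}

# genotypes for two samples at a SNP inside toy_loops()[1, ] other end
toy_genotypes <- function() {
  data.frame(sample_id = c("S1", "S2", "S1", "S2"),
             snp_id = c("rs1", "rs1", "rs2", "rs2"),
             chrom = c("chr1", "chr1", "chr2", "chr2"),
             pos = c(10500L, 10500L, 70500L, 70500L),
             ref = "A", alt = "G",
             gt = c("0|1", "1|1", "1|0", "0|1"),
             stringsAsFactors = FALSE)
}

random_allele_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    sample_id = sample(sprintf("S%02d", 1:8), n, replace = TRUE),
    snp_id = sample(sprintf("rs%03d", 1:40), n, replace = TRUE),
    loop_id = sample(sprintf("L%03d", 1:30), n, replace = TRUE),
    ref_count = rpois(n, 8),
    alt_count = rpois(n, 8),
    stringsAsFactors = FALSE)
}

empty_proxies <- function() {
  data.frame(snp_id = character(0), chrom = character(0), pos = integer(0),
             lead_id = character(0), r2 = numeric(0), stringsAsFactors = FALSE)
}

random_intervals <- function(n, seed, chroms = c("chr1", "chr2"),
                             max_pos = 2000, max_w = 120) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_w, n, replace = TRUE),
             stringsAsFactors = FALSE)
}
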