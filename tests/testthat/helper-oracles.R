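# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and GenomicRanges): plain enumeration and arithmetic only.

# exact two-sided binomial p at p0 = 0.5: sum of probabilities of all
# outcomes no more likely than the observed count
oracle_binom_p <- function(k, n) {
  d <- vapply(0:n, function(i) choose(n, i) * 0.5^n, numeric(1))
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# naive O(n^2) Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    ri <- which(ord == i)  # rank of element i
    vals <- vapply(ri:n, function(j) p[ord[j]] * n / j, numeric(1))
    q[i] <- min(1, min(vals))
  }
  q
}

# chi-square survival oracle for Fisher's method via numerical integration
oracle_fisher_combined <- function(p_values) {
  chi2 <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  f <- function(x) x^(df / 2 - 1) * exp(-x / 2) / (2^(df / 2) * gamma(df / 2))
  list(chi2 = chi2, p = stats::integrate(f, chi2, Inf, rel.tol = 1e-12)$value)
}

# one-sided (greater) Fisher exact p by hypergeometric enumeration over the
# 2x2 table [[a, b], [c, d]]
oracle_fisher_exact_greater <- function(a, b, c_, d) {
  m <- a + b          # foreground size
  n_total <- a + b + c_ + d
  k_in <- a + c_      # total "in" column
  amax <- min(m, k_in)
  probs <- vapply(0:amax, function(x) {
    choose(k_in, x) * choose(n_total - k_in, m - x) / choose(n_total, m)
  }, numeric(1))
  sum(probs[(a:amax) + 1])
}

# Spearman rho by rank-then-Pearson with average ranks
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# brute-force interval union: boolean scan over unit positions (small ranges)
oracle_union_coverage <- function(df, lo, hi) {
  cov <- rep(FALSE, hi - lo)
  for (i in seq_len(nrow(df))) {
    s <- max(df$start[i], lo); e <- min(df$end[i], hi)
    if (e > s) cov[(s - lo + 1):(e - lo)] <- TRUE
  }
  cov
}

# brute-force point-in-intervals scan
oracle_points_in <- function(chrom, pos, intervals) {
  vapply(seq_along(pos), function(i) {
    any(intervals$chrom == chrom[i] &
          intervals$start <= pos[i] - 1 & pos[i] - 1 < intervals$end)
  }, logical(1))
}

# transitive-closure merge oracle for locus regions: merge any two regions on
# the same chromosome with gap <= d until a fixed point
oracle_merge_regions <- function(regions, d) {
  repeat {
    merged <- FALSE
    i <- 1
    while (i <= nrow(regions)) {
      j <- i + 1
      while (j <= nrow(regions)) {
        if (regions$chrom[i] == regions$chrom[j]) {
          gap <- max(regions$start[i], regions$start[j]) -
            min(regions$end[i], regions$end[j])
          if (gap <= d) {
            regions$start[i] <- min(regions$start[i], regions$start[j])
            regions$end[i] <- max(regions$end[i], regions$end[j])
            regions <- regions[-j, , drop = FALSE]
            merged <- TRUE
            next
          }
        }
        j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  regions[order(regions$chrom, regions$start), , drop = FALSE]
}

# group-and-sum oracle for allele count aggregation
oracle_aggregate_counts <- function(records) {
  key <- paste(records$sample_id, records$snp_id, records$loop_id, sep = "|")
  out <- lapply(split(seq_len(nrow(records)), key), function(i) {
    data.frame(sample_id = records$sample_id[i[1]],
               snp_id = records$snp_id[i[1]],
               loop_id = records$loop_id[i[1]],
               ref_count = sum(records$ref_count[i]),
               alt_count = sum(records$alt_count[i]),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df <- df[order(df$snp_id, df$loop_id, df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
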