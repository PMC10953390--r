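# Allele-associated loop calling.
#
# Chain: aggregate per-allele read counts -> QC filter (heterozygous samples,
# read floor, SNP-in-anchor) -> per-sample exact binomial test against 0.5 ->
# directionality check -> Fisher's-method meta-analysis -> Benjamini-Hochberg
# FDR across (SNP, loop) pairs.

#' QC thresholds for allelic-imbalance testing
#'
#' The exact QC rules behind published allele-specific loop calls are usually
#' study-specific; these conservative defaults (a 10-read floor per sample,
#' at least one informative heterozygote, SNP inside a loop anchor) are
#' exposed as configuration.
#'
#' @param min_reads_per_sample minimum `ref + alt` reads for a sample to be
#'   informative (default 10; stabilizes the exact test).
#' @param min_het_samples minimum surviving heterozygous samples per
#'   (SNP, loop) pair (default 1).
#' @param require_snp_in_anchor drop pairs whose SNP lies outside both the
#'   bait and the other-end fragment of the loop (default TRUE).
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_reads_per_sample = 10, min_het_samples = 1,
                          require_snp_in_anchor = TRUE) {
  if (min_reads_per_sample < 1) stop("min_reads_per_sample must be >= 1")
  if (min_het_samples < 1) stop("min_het_samples must be >= 1")
  structure(list(min_reads_per_sample = as.integer(min_reads_per_sample),
                 min_het_samples = as.integer(min_het_samples),
                 require_snp_in_anchor = isTRUE(require_snp_in_anchor)),
            class = "qc_thresholds")
}

#' Aggregate per-allele read counts to unique (sample, SNP, loop) triples
#'
#' Duplicate records for the same triple are summed.
#'
#' @param records data.frame with `sample_id, snp_id, loop_id, ref_count,
#'   alt_count`.
#' @return data.frame keyed uniquely by the triple.
#' @export
aggregate_allele_counts <- function(records) {
  need <- c("sample_id", "snp_id", "loop_id", "ref_count", "alt_count")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0)
    stop("allele count records missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(records$ref_count < 0) || any(records$alt_count < 0))
    stop("negative allele counts")
  if (nrow(records) == 0)
    return(records[, need])
  agg <- stats::aggregate(cbind(ref_count, alt_count) ~
                            sample_id + snp_id + loop_id,
                          data = records[, need], FUN = sum)
  agg <- agg[order(agg$snp_id, agg$loop_id, agg$sample_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, need]
}

#' QC-filter (SNP, loop) pairs for allelic-imbalance testing
#'
#' Keeps, per pair, only samples that are heterozygous for the SNP and reach
#' the read floor; drops pairs with fewer than `min_het_samples` surviving
#' samples; optionally drops pairs whose SNP falls outside both loop anchors.
#'
#' @param counts aggregated allele counts ([aggregate_allele_counts()]).
#' @param genotypes phased genotypes ([load_phased_genotypes()]).
#' @param loops interaction calls ([load_interaction_table()]); must contain
#'   every `loop_id` referenced by `counts`.
#' @param thresholds a [qc_thresholds()] object.
#' @return data.frame of testable per-sample counts
#'   (`snp_id, loop_id, sample_id, ref_count, alt_count`).
#' @export
qc_filter_pairs <- function(counts, genotypes, loops,
                            thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  missing_loops <- setdiff(unique(counts$loop_id), loops$loop_id)
  if (length(missing_loops) > 0)
    stop("loop_id not found in interaction calls: ", missing_loops[1])
  if (nrow(counts) == 0)
    return(counts[, c("snp_id", "loop_id", "sample_id",
                      "ref_count", "alt_count")])

  gkey <- paste(genotypes$sample_id, genotypes$snp_id, sep = "\r")
  gt <- genotypes$gt[match(paste(counts$sample_id, counts$snp_id, sep = "\r"),
                           gkey)]
  keep <- !is.na(gt) & is_het(gt) &
    (counts$ref_count + counts$alt_count) >= thresholds$min_reads_per_sample
  out <- counts[keep, , drop = FALSE]

  if (thresholds$require_snp_in_anchor && nrow(out) > 0) {
    snp_pos <- genotypes[!duplicated(genotypes$snp_id),
                         c("snp_id", "chrom", "pos")]
    pairs <- unique(out[, c("snp_id", "loop_id")])
    li <- match(pairs$loop_id, loops$loop_id)
    si <- match(pairs$snp_id, snp_pos$snp_id)
    if (anyNA(si)) stop("SNP without genotype record: ",
                        pairs$snp_id[which(is.na(si))[1]])
    p0 <- snp_pos$pos[si] - 1  # 0-based offset of the 1-based SNP position
    in_bait <- snp_pos$chrom[si] == loops$bait_chrom[li] &
      p0 >= loops$bait_start[li] & p0 < loops$bait_end[li]
    in_oe <- snp_pos$chrom[si] == loops$oe_chrom[li] &
      p0 >= loops$oe_start[li] & p0 < loops$oe_end[li]
    ok_pairs <- paste(pairs$snp_id, pairs$loop_id, sep = "\r")[in_bait | in_oe]
    out <- out[paste(out$snp_id, out$loop_id, sep = "\r") %in% ok_pairs, ,
               drop = FALSE]
  }

  if (nrow(out) > 0) {
    pk <- paste(out$snp_id, out$loop_id, sep = "\r")
    n_by_pair <- table(pk)
    out <- out[pk %in% names(n_by_pair)[n_by_pair >= thresholds$min_het_samples],
               , drop = FALSE]
  }
  rownames(out) <- NULL
  out[, c("snp_id", "loop_id", "sample_id", "ref_count", "alt_count")]
}

#' Exact binomial test for allelic imbalance in one sample
#'
#' Two-sided exact binomial test of `ref_count` out of `ref_count + alt_count`
#' reads against 0.5 (the two-sided p is the sum of the probabilities of all
#' outcomes no more likely than the observed one). Direction is `ref_up` when
#' the reference haplotype carries more reads, `alt_up` when fewer; a tie
#' yields `ref_up` with p = 1, which the meta-analysis treats as
#' direction-neutral.
#'
#' @param ref_count,alt_count non-negative read counts; total must be >= 1.
#' @return list with `p` and `direction`.
#' @export
binomial_imbalance_test <- function(ref_count, alt_count) {
  if (length(ref_count) != 1 || length(alt_count) != 1)
    stop("scalar counts expected; use the driver for vectors")
  if (ref_count < 0 || alt_count < 0) stop("negative allele counts")
  if (ref_count + alt_count < 1) stop("both counts are zero")
  p <- stats::binom.test(ref_count, ref_count + alt_count, 0.5)$p.value
  direction <- if (alt_count > ref_count) "alt_up" else "ref_up"
  list(p = p, direction = direction)
}

# vectorized version used by the driver
.binom_imbalance_vec <- function(ref, alt) {
  n <- ref + alt
  if (any(n < 1)) stop("both counts are zero for some record")
  p <- vapply(seq_along(ref),
              function(i) stats::binom.test(ref[i], n[i], 0.5)$p.value,
              numeric(1))
  list(p = pmin(p, 1), direction = ifelse(alt > ref, "alt_up", "ref_up"))
}

#' Combine per-sample imbalance tests with a directionality check
#'
#' Fisher's method for meta-analysis: `chi2 = -2 * sum(log(p))` over the `m`
#' samples used, referred to a chi-square distribution with `2m` degrees of
#' freedom. Ties (p = 1) are direction-neutral and compatible with any
#' direction. Two directionality modes:
#' \describe{
#'   \item{`concordance`}{(default) all non-tie samples must share one
#'     direction; if they conflict the pair is flagged `discordant` and gets
#'     `combined_p = 1` (retained, auditable, never significant).}
#'   \item{`pooled`}{one-sided meta-analysis toward the majority direction:
#'     each two-sided p is converted to a one-sided p for that direction
#'     (`p/2` if the sample agrees, `1 - p/2` otherwise) before combining.}
#' }
#'
#' @param p numeric vector of per-sample p-values in (0, 1].
#' @param direction character vector (`ref_up`/`alt_up`) parallel to `p`.
#' @param mode `"concordance"` or `"pooled"`.
#' @return list with `chi2`, `df`, `combined_p`, `direction`.
#' @export
combine_directional_fisher <- function(p, direction,
                                       mode = c("concordance", "pooled")) {
  mode <- match.arg(mode)
  if (length(p) == 0) stop("empty p-value list")
  if (length(direction) != length(p)) stop("p and direction lengths differ")
  if (any(p <= 0)) stop("p = 0 cannot arise from the exact test")
  if (any(p > 1)) stop("p-values must lie in (0, 1]")

  neutral <- p >= 1 - 1e-12
  dirs <- unique(direction[!neutral])
  m <- length(p)

  if (mode == "concordance") {
    if (length(dirs) > 1) {
      return(list(chi2 = -2 * sum(log(p)), df = 2L * m,
                  combined_p = 1, direction = "discordant"))
    }
    chi2 <- -2 * sum(log(p))
    dir_out <- if (length(dirs) == 1) dirs else "ref_up"
    list(chi2 = chi2, df = 2L * m,
         combined_p = stats::pchisq(chi2, df = 2 * m, lower.tail = FALSE),
         direction = dir_out)
  } else {
    # pooled one-sided meta-analysis
    if (length(dirs) == 0) {
      pooled <- "ref_up"
    } else {
      tab <- table(direction[!neutral])
      pooled <- names(tab)[which.max(tab)]
    }
    p1 <- ifelse(direction == pooled, p / 2, 1 - p / 2)
    p1[neutral] <- 0.5
    chi2 <- -2 * sum(log(p1))
    list(chi2 = chi2, df = 2L * m,
         combined_p = stats::pchisq(chi2, df = 2 * m, lower.tail = FALSE),
         direction = pooled)
  }
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`; q-values are
#' returned in input order and satisfy `q >= p` elementwise.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call allele-associated loops
#'
#' Runs the full chain (aggregation, QC, per-sample exact binomial tests,
#' directionality check, Fisher's-method combination, BH adjustment) and
#' returns per-(SNP, loop) imbalance calls plus a roll-up summary. BH is
#' applied across the pairs in `counts`, i.e. within whatever cell type the
#' caller passes (run once per cell type to mirror per-cell-type reporting).
#'
#' @param counts allele count records.
#' @param genotypes phased genotypes.
#' @param loops interaction calls containing every referenced `loop_id`.
#' @param thresholds a [qc_thresholds()] object.
#' @param fdr significance level on the BH q-value (default 0.05).
#' @param direction_mode see [combine_directional_fisher()].
#' @return object of class `imbalance_calls`: list with `calls` (data.frame in
#'   the `imbalance_calls` schema), `summary` (named list of roll-up counts),
#'   `thresholds`, `fdr`.
#' @export
call_imbalanced_loops <- function(counts, genotypes, loops,
                                  thresholds = qc_thresholds(), fdr = 0.05,
                                  direction_mode = c("concordance", "pooled")) {
  direction_mode <- match.arg(direction_mode)
  counts <- aggregate_allele_counts(counts)
  testable <- qc_filter_pairs(counts, genotypes, loops, thresholds)

  empty <- data.frame(snp_id = character(0), loop_id = character(0),
                      n_samples_used = integer(0),
                      per_sample_p = character(0), direction = character(0),
                      fisher_chi2 = numeric(0), fisher_df = integer(0),
                      combined_p = numeric(0), q_value = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(testable) == 0) {
    res <- structure(list(calls = empty,
                          summary = list(n_pairs_tested = 0L,
                                         n_significant = 0L, n_loops = 0L,
                                         n_snps = 0L, n_genes = 0L,
                                         fdr = fdr),
                          thresholds = thresholds, fdr = fdr),
                     class = "imbalance_calls")
    return(res)
  }

  bt <- .binom_imbalance_vec(testable$ref_count, testable$alt_count)
  testable$p <- bt$p
  testable$direction <- bt$direction

  pk <- paste(testable$snp_id, testable$loop_id, sep = "\r")
  idx <- split(seq_len(nrow(testable)), pk)
  calls <- do.call(rbind, lapply(idx, function(i) {
    comb <- combine_directional_fisher(testable$p[i], testable$direction[i],
                                       mode = direction_mode)
    data.frame(snp_id = testable$snp_id[i[1]],
               loop_id = testable$loop_id[i[1]],
               n_samples_used = length(i),
               per_sample_p = paste(sprintf("%.6g", testable$p[i]),
                                    collapse = ";"),
               direction = comb$direction,
               fisher_chi2 = comb$chi2,
               fisher_df = comb$df,
               combined_p = comb$combined_p,
               stringsAsFactors = FALSE)
  }))
  rownames(calls) <- NULL
  calls <- calls[order(calls$combined_p, calls$snp_id, calls$loop_id), ,
                 drop = FALSE]
  calls$q_value <- bh_adjust(calls$combined_p)

  sig <- calls[calls$q_value < fdr, , drop = FALSE]
  sig_genes <- if (nrow(sig) > 0) {
    unique(unlist(strsplit(
      loops$bait_genes[match(sig$loop_id, loops$loop_id)], ";", fixed = TRUE)))
  } else character(0)
  structure(list(
    calls = calls,
    summary = list(n_pairs_tested = nrow(calls),
                   n_significant = nrow(sig),
                   n_loops = length(unique(sig$loop_id)),
                   n_snps = length(unique(sig$snp_id)),
                   n_genes = length(sig_genes),
                   fdr = fdr),
    thresholds = thresholds, fdr = fdr),
    class = "imbalance_calls")
}

#' @export
print.imbalance_calls <- function(x, ...) {
  s <- x$summary
  cat("Allele-associated loop calls\n")
  cat(sprintf("  (SNP, loop) pairs tested : %d\n", s$n_pairs_tested))
  cat(sprintf("  significant at q < %-4.3g : %d\n", s$fdr, s$n_significant))
  cat(sprintf("  distinct loops / SNPs    : %d / %d\n", s$n_loops, s$n_snps))
  cat(sprintf("  distinct bait genes      : %d\n", s$n_genes))
  invisible(x)
}

#' @export
summary.imbalance_calls <- function(object, ...) object$summary
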