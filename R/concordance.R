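# Concordance between differential chromatin interactions and differential
# expression: set enrichment (one-sided Fisher), rank correlation of effect
# sizes, and the stringent-cutoff sign-concordance exact binomial test.
#
# Sign convention: positive log2 fold change = higher in condition A (the
# first cell type) for both tables.

#' Select significantly differentially expressed genes
#'
#' Strict thresholds: `adj_p < adj_p_max` and `|log2fc| > abs_lfc_min`.
#'
#' @param expression_results data.frame in the `expression_results` schema.
#' @param adj_p_max FDR cutoff.
#' @param abs_lfc_min absolute log2 fold-change cutoff.
#' @return character vector of gene ids.
#' @export
select_significant_de <- function(expression_results, adj_p_max = 0.05,
                                  abs_lfc_min = 2) {
  if (adj_p_max <= 0) stop("adj_p_max must be positive")
  if (abs_lfc_min < 0) stop("abs_lfc_min must be non-negative")
  keep <- expression_results$adj_p < adj_p_max &
    abs(expression_results$log2fc) > abs_lfc_min
  unique(expression_results$gene_id[keep])
}

#' Summarize significant differential interactions per gene
#'
#' Keeps interactions with `wadj_p < wadj_p_max`, fans multi-promoter baits
#' out to genes, and reports per gene the median log2 fold change over its
#' significant interactions, their count and the minimum weighted adjusted p.
#'
#' @param differential_interactions data.frame in the
#'   `differential_interactions` schema.
#' @param wadj_p_max weighted adjusted p cutoff (default 0.05, strict `<`).
#' @return data.frame `gene_id, di_median_log2fc, n_interactions,
#'   di_min_wadj_p`.
#' @export
select_significant_di <- function(differential_interactions,
                                  wadj_p_max = 0.05) {
  sig <- differential_interactions[
    differential_interactions$wadj_p < wadj_p_max, , drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(gene_id = character(0), di_median_log2fc = numeric(0),
                      n_interactions = integer(0), di_min_wadj_p = numeric(0),
                      stringsAsFactors = FALSE))
  sig <- fan_out_genes(sig)
  idx <- split(seq_len(nrow(sig)), sig$gene_id)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(gene_id = sig$gene_id[i[1]],
               di_median_log2fc = stats::median(sig$log2fc[i]),
               n_interactions = length(i),
               di_min_wadj_p = min(sig$wadj_p[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Enrichment of differentially interacting genes among differentially expressed
#'
#' One-sided (greater) Fisher exact test on the 2x2 table defined over a gene
#' universe. Reports the sample odds ratio (`ad/bc`) and the overlap size.
#'
#' @param de_genes,di_genes character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe character vector of all genes considered.
#' @return list with `odds_ratio`, `p`, `overlap_count`, `table`.
#' @export
overlap_enrichment <- function(de_genes, di_genes, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  de_genes <- intersect(unique(de_genes), universe)
  di_genes <- intersect(unique(di_genes), universe)
  a <- length(intersect(de_genes, di_genes))
  b <- length(de_genes) - a
  c_ <- length(di_genes) - a
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("de", "not_de"), c("di", "not_di")))
  or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(odds_ratio = or, p = p, overlap_count = a, table = tab)
}

#' Spearman rank correlation of per-gene effect sizes
#'
#' Correlates differential-expression log2 fold changes with per-gene median
#' differential-interaction log2 fold changes, using average ranks for ties
#' and the large-sample t approximation for the p-value.
#'
#' @param pairs data.frame with `de_log2fc` and `di_median_log2fc`.
#' @return list with `rho` and `p`.
#' @export
lfc_correlation <- function(pairs) {
  if (nrow(pairs) < 3) stop("need at least 3 gene pairs")
  x <- pairs$de_log2fc; y <- pairs$di_median_log2fc
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in an effect-size vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Sign-concordance exact binomial test under a stringent effect cutoff
#'
#' Restricts to genes whose absolute median differential-interaction log2 fold
#' change exceeds `abs_median_lfc_min` (strict), counts genes whose expression
#' and interaction effects share a sign, and tests the concordant count
#' against 0.5 with a two-sided exact binomial test (sum of probabilities of
#' outcomes no more likely than the observed one). A zero effect counts as
#' non-concordant.
#'
#' @param pairs data.frame with `de_log2fc` and `di_median_log2fc`.
#' @param abs_median_lfc_min stringent cutoff (default 2).
#' @return list with `n`, `k_concordant`, `p`, `success_fraction`.
#' @export
concordance_binomial <- function(pairs, abs_median_lfc_min = 2) {
  sub <- pairs[abs(pairs$di_median_log2fc) > abs_median_lfc_min, ,
               drop = FALSE]
  n <- nrow(sub)
  if (n == 0) stop("no gene pairs pass the stringent cutoff")
  concordant <- sign(sub$de_log2fc) == sign(sub$di_median_log2fc) &
    sign(sub$de_log2fc) != 0
  k <- sum(concordant)
  list(n = n, k_concordant = k,
       p = stats::binom.test(k, n, 0.5)$p.value,
       success_fraction = k / n)
}

#' Full differential interaction / differential expression concordance analysis
#'
#' Runs the three concordance statistics in sequence: selects significant
#' differentially expressed genes and per-gene differential-interaction
#' summaries, tests the enrichment of differentially interacting genes among
#' differentially expressed ones (one-sided Fisher over a gene universe),
#' rank-correlates the paired log2 fold changes across the overlapping genes,
#' and applies the stringent-cutoff sign-concordance binomial test. Empty
#' significant sets are handled gracefully (statistics reported as `NA`).
#'
#' @param expression_results expression summary table.
#' @param differential_interactions differential-interaction table.
#' @param de_adj_p_max,de_abs_lfc_min differential-expression thresholds
#'   (defaults 0.05 and 2).
#' @param di_wadj_p_max differential-interaction threshold (default 0.05).
#' @param stringent_lfc stringent cutoff on the per-gene median interaction
#'   log2 fold change (default 2).
#' @param universe gene universe for the Fisher test; defaults to all genes in
#'   the expression table.
#' @return object of class `concordance_result`: list with `n_de`, `n_di`,
#'   `enrichment`, `correlation`, `binomial`, `pairs`.
#' @export
concordance_analysis <- function(expression_results,
                                 differential_interactions,
                                 de_adj_p_max = 0.05, de_abs_lfc_min = 2,
                                 di_wadj_p_max = 0.05, stringent_lfc = 2,
                                 universe = NULL) {
  if (is.null(universe)) universe <- unique(expression_results$gene_id)
  de <- select_significant_de(expression_results, de_adj_p_max, de_abs_lfc_min)
  di <- select_significant_di(differential_interactions, di_wadj_p_max)

  enrichment <- if (length(de) > 0 || nrow(di) > 0) {
    overlap_enrichment(de, di$gene_id, universe)
  } else list(odds_ratio = NA_real_, p = NA_real_, overlap_count = 0L,
              table = NULL)

  overlap_genes <- intersect(de, di$gene_id)
  pairs <- data.frame(
    gene_id = overlap_genes,
    de_log2fc = expression_results$log2fc[
      match(overlap_genes, expression_results$gene_id)],
    de_adj_p = expression_results$adj_p[
      match(overlap_genes, expression_results$gene_id)],
    di_median_log2fc = di$di_median_log2fc[match(overlap_genes, di$gene_id)],
    di_min_wadj_p = di$di_min_wadj_p[match(overlap_genes, di$gene_id)],
    stringsAsFactors = FALSE)

  correlation <- if (nrow(pairs) >= 3 &&
                     stats::var(pairs$de_log2fc) > 0 &&
                     stats::var(pairs$di_median_log2fc) > 0) {
    lfc_correlation(pairs)
  } else list(rho = NA_real_, p = NA_real_)

  binomial <- if (any(abs(pairs$di_median_log2fc) > stringent_lfc)) {
    concordance_binomial(pairs, stringent_lfc)
  } else list(n = 0L, k_concordant = 0L, p = NA_real_,
              success_fraction = NA_real_)

  structure(list(n_de = length(de), n_di = nrow(di),
                 enrichment = enrichment, correlation = correlation,
                 binomial = binomial, pairs = pairs,
                 thresholds = list(de_adj_p_max = de_adj_p_max,
                                   de_abs_lfc_min = de_abs_lfc_min,
                                   di_wadj_p_max = di_wadj_p_max,
                                   stringent_lfc = stringent_lfc)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("Differential interaction / expression concordance\n")
  cat(sprintf("  significant DE genes       : %d\n", x$n_de))
  cat(sprintf("  differentially interacting : %d\n", x$n_di))
  cat(sprintf("  overlap                    : %d\n",
              x$enrichment$overlap_count))
  cat(sprintf("  Fisher enrichment OR, p    : %.3g, %.3g\n",
              x$enrichment$odds_ratio, x$enrichment$p))
  cat(sprintf("  Spearman rho, p            : %.3g, %.3g\n",
              x$correlation$rho, x$correlation$p))
  cat(sprintf("  sign concordance           : %d/%d (p = %.3g)\n",
              x$binomial$k_concordant, x$binomial$n, x$binomial$p))
  invisible(x)
}
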