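# GWAS locus definition and SNP -> enhancer -> promoter-interacting-region
# gene assignment.

#' Expand GWAS lead SNPs with their LD proxies
#'
#' Returns genome-wide-significant leads (`gwas_p < p_threshold`, strict) plus
#' proxies in high LD (`r2 > r2_threshold`, strict) with a retained lead.
#'
#' @param leads data.frame `snp_id, chrom, pos, gwas_p`.
#' @param proxy_table data.frame `snp_id, chrom, pos, lead_id, r2`; every
#'   `lead_id` must reference a known lead.
#' @param r2_threshold LD threshold (default 0.8).
#' @param p_threshold genome-wide significance threshold (default 5e-8).
#' @return data.frame `snp_id, chrom, pos, lead_id, r2, gwas_p` (leads carry
#'   `r2 = 1` and `lead_id = snp_id`; proxies carry `gwas_p = NA`).
#' @export
expand_ld <- function(leads, proxy_table, r2_threshold = 0.8,
                      p_threshold = 5e-8) {
  orphan <- setdiff(unique(proxy_table$lead_id), leads$snp_id)
  if (length(orphan) > 0)
    stop("proxy references unknown lead: ", orphan[1])
  keep_leads <- leads[leads$gwas_p < p_threshold, , drop = FALSE]
  lead_rows <- data.frame(snp_id = keep_leads$snp_id,
                          chrom = keep_leads$chrom,
                          pos = keep_leads$pos,
                          lead_id = keep_leads$snp_id,
                          r2 = 1,
                          gwas_p = keep_leads$gwas_p,
                          stringsAsFactors = FALSE)
  keep_prox <- proxy_table[proxy_table$r2 > r2_threshold &
                             proxy_table$lead_id %in% keep_leads$snp_id, ,
                           drop = FALSE]
  prox_rows <- data.frame(snp_id = keep_prox$snp_id,
                          chrom = keep_prox$chrom,
                          pos = keep_prox$pos,
                          lead_id = keep_prox$lead_id,
                          r2 = keep_prox$r2,
                          gwas_p = rep(NA_real_, nrow(keep_prox)),
                          stringsAsFactors = FALSE)
  out <- rbind(lead_rows, prox_rows)
  out <- out[!duplicated(out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define GWAS loci from an expanded SNP set
#'
#' Per lead, the locus region spans the lead and its proxies
#' (`[min(pos) - 1, max(pos))`, half-open); regions on the same chromosome
#' separated by at most `merge_distance_bp` are merged transitively,
#' concatenating lead and SNP memberships. Loci are sorted by coordinate with
#' deterministic ids.
#'
#' @param snp_set output of [expand_ld()].
#' @param merge_distance_bp maximum gap merged (default 250000).
#' @return data.frame `locus_id, chrom, start, end, lead_ids, snp_ids, n_snps`
#'   (`lead_ids`/`snp_ids` are `";"`-joined).
#' @export
define_loci <- function(snp_set, merge_distance_bp = 250000) {
  if (nrow(snp_set) == 0) stop("empty SNP set")
  by_lead <- split(snp_set, snp_set$lead_id)
  regions <- do.call(rbind, lapply(by_lead, function(s) {
    if (length(unique(s$chrom)) != 1)
      stop("lead ", s$lead_id[1], ": members on several chromosomes")
    data.frame(chrom = s$chrom[1],
               start = min(s$pos) - 1, end = max(s$pos),
               lead_ids = s$lead_id[1],
               snp_ids = paste(sort(unique(s$snp_id)), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  regions <- regions[order(regions$chrom, regions$start, regions$end), ,
                     drop = FALSE]
  merged <- list()
  cur <- NULL
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    if (!is.null(cur) && r$chrom == cur$chrom &&
        r$start - cur$end <= merge_distance_bp) {
      cur$end <- max(cur$end, r$end)
      cur$lead_ids <- paste(cur$lead_ids, r$lead_ids, sep = ";")
      cur$snp_ids <- paste(cur$snp_ids, r$snp_ids, sep = ";")
    } else {
      if (!is.null(cur)) merged[[length(merged) + 1]] <- cur
      cur <- r
    }
  }
  merged[[length(merged) + 1]] <- cur
  out <- do.call(rbind, merged)
  out$snp_ids <- vapply(strsplit(out$snp_ids, ";", fixed = TRUE),
                        function(x) paste(sort(unique(x)), collapse = ";"),
                        character(1))
  out$n_snps <- lengths(strsplit(out$snp_ids, ";", fixed = TRUE))
  out$locus_id <- sprintf("locus_%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("locus_id", "chrom", "start", "end", "lead_ids", "snp_ids",
          "n_snps")]
}

#' Build per-cell-type enhancer unions from chromatin-state segmentations
#'
#' For each cell type, takes the union (interval merge) of all segments whose
#' state label denotes enhancer activity in at least one sample of that cell
#' type. Unknown state labels are ignored.
#'
#' @param segmentations data.frame `sample_id, cell_type, chrom, start, end,
#'   state` (BED-convention coordinates).
#' @param enhancer_states character vector of state labels counted as
#'   enhancers (e.g. `c("E7", "E8")`).
#' @return data.frame `chrom, start, end, cell_type` of merged enhancer
#'   intervals.
#' @export
build_enhancer_union <- function(segmentations, enhancer_states) {
  need <- c("cell_type", "chrom", "start", "end", "state")
  missing_cols <- setdiff(need, names(segmentations))
  if (length(missing_cols) > 0)
    stop("segmentations missing column(s): ",
         paste(missing_cols, collapse = ", "))
  enh <- segmentations[segmentations$state %in% enhancer_states, , drop = FALSE]
  out <- do.call(rbind, lapply(split(enh, enh$cell_type), function(e) {
    m <- merge_intervals(e[, c("chrom", "start", "end")])
    if (nrow(m) == 0) return(NULL)
    m$cell_type <- e$cell_type[1]
    m
  }))
  if (is.null(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), cell_type = character(0),
                      stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Flag SNPs overlapping enhancer regions, per cell type
#'
#' A SNP at 1-based position `p` overlaps a 0-based half-open enhancer
#' `[s, e)` iff `s <= p - 1 < e`.
#'
#' @param snp_set data.frame with `snp_id, chrom, pos`.
#' @param enhancers data.frame `chrom, start, end, cell_type`.
#' @return list with `snps` (input plus one logical `in_enhancer_<cell type>`
#'   column per cell type) and `summary` (data.frame `cell_type, n_overlap,
#'   n_total, proportion`).
#' @export
annotate_snp_overlaps <- function(snp_set, enhancers) {
  cts <- sort(unique(enhancers$cell_type))
  snps <- snp_set
  summ <- data.frame(cell_type = cts, n_overlap = 0L,
                     n_total = nrow(snp_set), proportion = 0,
                     stringsAsFactors = FALSE)
  for (i in seq_along(cts)) {
    e <- enhancers[enhancers$cell_type == cts[i], , drop = FALSE]
    flag <- points_in_intervals(snps$chrom, snps$pos, e)
    snps[[paste0("in_enhancer_", cts[i])]] <- flag
    summ$n_overlap[i] <- sum(flag)
    summ$proportion[i] <- if (nrow(snps) > 0) sum(flag) / nrow(snps) else NA
  }
  list(snps = snps, summary = summ)
}

#' Pooled two-proportion z-test
#'
#' Tests whether two overlap counts `k1`, `k2` out of the same total `n`
#' differ, using the pooled-variance normal approximation with a two-sided p.
#'
#' @param k1,k2 counts in \[0, n\].
#' @param n common total (> 0).
#' @return list with `z` and `p`.
#' @export
two_proportion_test <- function(k1, k2, n) {
  if (n <= 0) stop("n must be positive")
  if (k1 < 0 || k2 < 0 || k1 > n || k2 > n)
    stop("counts must lie in [0, n]")
  p1 <- k1 / n; p2 <- k2 / n
  pooled <- (k1 + k2) / (2 * n)
  se <- sqrt(pooled * (1 - pooled) * 2 / n)
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Fisher-exact enhancer enrichment of a SNP set (GARFIELD substitute)
#'
#' Plain one-sided (greater) Fisher exact test on the 2x2 table of
#' in/out-enhancer by foreground/background SNPs. This is an explicitly
#' labelled substitute for LD- and distance-matched enrichment methods such as
#' GARFIELD: it performs no matching, so its odds ratio is not comparable to
#' matched-permutation enrichment estimates. The background may be a superset
#' of the foreground; foreground SNPs are removed from it first.
#'
#' @param snp_set foreground data.frame `snp_id, chrom, pos`.
#' @param background_snps background data.frame `snp_id, chrom, pos`.
#' @param enhancers enhancer intervals for one cell type.
#' @return list with `odds_ratio` (sample OR, `ad/bc`), `p` and `table`.
#' @export
enhancer_enrichment <- function(snp_set, background_snps, enhancers) {
  bg <- background_snps[!background_snps$snp_id %in% snp_set$snp_id, ,
                        drop = FALSE]
  if (nrow(bg) == 0) stop("empty background after removing foreground SNPs")
  fg_in <- sum(points_in_intervals(snp_set$chrom, snp_set$pos, enhancers))
  bg_in <- sum(points_in_intervals(bg$chrom, bg$pos, enhancers))
  a <- fg_in; b <- nrow(snp_set) - fg_in
  c_ <- bg_in; d <- nrow(bg) - bg_in
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("foreground", "background"),
                                c("in_enhancer", "out_enhancer")))
  or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(odds_ratio = or, p = p, table = tab)
}

#' Assign candidate genes by SNP x enhancer x promoter-interacting-region overlap
#'
#' Per cell type, keeps interactions with `score > score_threshold` whose
#' other-end (promoter-interacting region) contains at least one SNP that also
#' overlaps an enhancer of the same cell type; the baited promoter gene(s) of
#' such interactions become candidate genes. The same SNP must satisfy both
#' the enhancer overlap and the PIR containment. Multi-promoter baits fan out
#' to one candidate row per gene.
#'
#' @param snp_set expanded SNP set ([expand_ld()]).
#' @param enhancers enhancer intervals `chrom, start, end, cell_type`.
#' @param interactions interaction calls with `cell_type` labels (pooled calls
#'   per cell type).
#' @param score_threshold significance cutoff on the interaction score
#'   (default 5, strict `>`).
#' @param loci optional [define_loci()] output used to label candidates with
#'   locus ids; without it the SNP's `lead_id` serves as the locus label.
#' @return object of class `candidate_genes`: list with `candidates`
#'   (data.frame `locus_id, gene_id, cell_types, n_support`), `evidence`
#'   (one row per supporting (SNP, interaction, enhancer) triple) and
#'   `interaction_counts` (qualifying interactions per cell type).
#' @export
map_snps_to_genes <- function(snp_set, enhancers, interactions,
                              score_threshold = 5, loci = NULL) {
  cts <- sort(unique(interactions$cell_type))
  locus_of <- .locus_lookup(snp_set, loci)

  evidence <- list()
  counts <- stats::setNames(integer(length(cts)), cts)
  for (ct in cts) {
    enh <- enhancers[enhancers$cell_type == ct, , drop = FALSE]
    ints <- interactions[interactions$cell_type == ct &
                           interactions$score > score_threshold, ,
                         drop = FALSE]
    if (nrow(enh) == 0 || nrow(ints) == 0 || nrow(snp_set) == 0) next
    enh_hits <- .point_interval_hits(snp_set$chrom, snp_set$pos, enh)
    if (nrow(enh_hits) == 0) next
    oe <- data.frame(chrom = ints$oe_chrom, start = ints$oe_start,
                     end = ints$oe_end, stringsAsFactors = FALSE)
    oe_hits <- .point_interval_hits(snp_set$chrom, snp_set$pos, oe)
    if (nrow(oe_hits) == 0) next
    j <- merge(oe_hits, enh_hits, by = "point_idx",
               suffixes = c("_int", "_enh"))
    if (nrow(j) == 0) next
    counts[ct] <- length(unique(j$interval_idx_int))
    ev <- data.frame(
      cell_type = ct,
      snp_id = snp_set$snp_id[j$point_idx],
      locus_id = locus_of[snp_set$snp_id[j$point_idx]],
      loop_id = ints$loop_id[j$interval_idx_int],
      bait_genes = ints$bait_genes[j$interval_idx_int],
      score = ints$score[j$interval_idx_int],
      enh_chrom = enh$chrom[j$interval_idx_enh],
      enh_start = enh$start[j$interval_idx_enh],
      enh_end = enh$end[j$interval_idx_enh],
      stringsAsFactors = FALSE)
    evidence[[ct]] <- fan_out_genes(ev)
  }
  evidence <- if (length(evidence) > 0) do.call(rbind, evidence) else
    data.frame(cell_type = character(0), snp_id = character(0),
               locus_id = character(0), loop_id = character(0),
               score = numeric(0), enh_chrom = character(0),
               enh_start = numeric(0), enh_end = numeric(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  rownames(evidence) <- NULL

  if (nrow(evidence) > 0) {
    key <- paste(evidence$locus_id, evidence$gene_id, sep = "\r")
    idx <- split(seq_len(nrow(evidence)), key)
    candidates <- do.call(rbind, lapply(idx, function(i) {
      data.frame(locus_id = evidence$locus_id[i[1]],
                 gene_id = evidence$gene_id[i[1]],
                 cell_types = paste(sort(unique(evidence$cell_type[i])),
                                    collapse = ";"),
                 n_support = length(i),
                 stringsAsFactors = FALSE)
    }))
    candidates <- candidates[order(candidates$locus_id, candidates$gene_id), ,
                             drop = FALSE]
    rownames(candidates) <- NULL
  } else {
    candidates <- data.frame(locus_id = character(0), gene_id = character(0),
                             cell_types = character(0), n_support = integer(0),
                             stringsAsFactors = FALSE)
  }
  structure(list(candidates = candidates, evidence = evidence,
                 interaction_counts = counts,
                 score_threshold = score_threshold),
            class = "candidate_genes")
}

.locus_lookup <- function(snp_set, loci) {
  if (is.null(loci)) {
    return(stats::setNames(snp_set$lead_id, snp_set$snp_id))
  }
  lookup <- character(0)
  for (i in seq_len(nrow(loci))) {
    ids <- strsplit(loci$snp_ids[i], ";", fixed = TRUE)[[1]]
    lookup[ids] <- loci$locus_id[i]
  }
  out <- lookup[snp_set$snp_id]
  names(out) <- snp_set$snp_id
  out
}

#' @export
print.candidate_genes <- function(x, ...) {
  cat("Candidate interacting genes (SNP x enhancer x PIR overlap)\n")
  cat(sprintf("  score threshold          : > %g\n", x$score_threshold))
  for (ct in names(x$interaction_counts))
    cat(sprintf("  qualifying interactions, %s: %d\n", ct,
                x$interaction_counts[[ct]]))
  cat(sprintf("  candidate (locus, gene) rows: %d\n", nrow(x$candidates)))
  if (nrow(x$candidates) > 0)
    print(utils::head(x$candidates, 10))
  invisible(x)
}
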