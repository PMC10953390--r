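# Config-driven orchestration: simulate (optional) -> allelic imbalance per
# cell type -> GWAS locus mapping -> differential interaction/expression
# concordance -> consolidated report.

#' Pipeline configuration
#'
#' Either a `simulate` block (a [sim_config()]) or a set of input paths must
#' be provided. All thresholds the stages use are explicit here and echoed in
#' the report, so no stage runs with a silent default.
#'
#' @param simulate optional [sim_config()]; when present the fixture bundle is
#'   generated in memory and `paths` must be absent.
#' @param paths optional named list of input files: `interactions` (named list
#'   `cell type -> ibed path`, pooled calls), `differential`, `genotypes` and
#'   `allele_counts` (named lists per cell type), `expression`, `gwas_leads`,
#'   `ld_proxies`, `enhancers` (named list `cell type -> BED path`).
#' @param cell_types cell-type labels (default `c("CD4", "CD14")`).
#' @param chicago_score interaction significance score threshold (default 5).
#' @param wadj_p differential-interaction significance threshold (default 0.05).
#' @param de_adj_p,de_abs_lfc differential-expression thresholds for the
#'   cell-type contrast (defaults 0.05 and 2).
#' @param r2 LD threshold for proxy expansion (default 0.8).
#' @param gwas_p genome-wide significance threshold (default 5e-8).
#' @param merge_kb locus merge distance in kb (default 250).
#' @param stringent_lfc stringent per-gene median interaction cutoff
#'   (default 2).
#' @param imbalance_qc a [qc_thresholds()] object.
#' @param fdr FDR level for allelic-imbalance calls (default 0.05).
#' @param seed integer seed (used when `simulate` is present).
#' @param out_dir optional directory for the report files.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            cell_types = c("CD4", "CD14"),
                            chicago_score = 5, wadj_p = 0.05,
                            de_adj_p = 0.05, de_abs_lfc = 2,
                            r2 = 0.8, gwas_p = 5e-8, merge_kb = 250,
                            stringent_lfc = 2,
                            imbalance_qc = qc_thresholds(), fdr = 0.05,
                            seed = 1L, out_dir = NULL) {
  if (is.null(simulate) && is.null(paths))
    stop("pipeline_config needs either a simulate block or input paths")
  if (!is.null(simulate) && !is.null(paths))
    stop("provide either a simulate block or input paths, not both")
  if (!is.null(simulate) && !inherits(simulate, "sim_config"))
    stop("simulate must be a sim_config object")
  for (thr in c(wadj_p, de_adj_p, fdr))
    if (thr <= 0 || thr > 1) stop("probability thresholds must lie in (0, 1]")
  if (r2 < 0 || r2 > 1) stop("r2 must lie in [0, 1]")
  if (chicago_score < 0) stop("chicago_score must be non-negative")
  stopifnot(inherits(imbalance_qc, "qc_thresholds"))
  structure(list(simulate = simulate, paths = paths,
                 cell_types = as.character(cell_types),
                 chicago_score = chicago_score, wadj_p = wadj_p,
                 de_adj_p = de_adj_p, de_abs_lfc = de_abs_lfc, r2 = r2,
                 gwas_p = gwas_p, merge_kb = merge_kb,
                 stringent_lfc = stringent_lfc, imbalance_qc = imbalance_qc,
                 fdr = fdr, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()]'s arguments; a `simulate:` mapping is
#' passed to [sim_config()], an `imbalance_qc:` mapping to [qc_thresholds()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  if (!is.null(y$imbalance_qc))
    y$imbalance_qc <- do.call(qc_thresholds, y$imbalance_qc)
  do.call(pipeline_config, y)
}

.load_inputs <- function(config) {
  p <- config$paths
  need <- c("interactions", "differential", "genotypes", "allele_counts",
            "expression", "gwas_leads", "ld_proxies", "enhancers")
  missing_inputs <- setdiff(need, names(p))
  if (length(missing_inputs) > 0)
    stop("pipeline config missing input path(s): ",
         paste(missing_inputs, collapse = ", "))
  ints <- do.call(rbind, lapply(config$cell_types, function(ct) {
    load_interaction_table(p$interactions[[ct]], "ibed", cell_type = ct,
                           condition = "pooled")
  }))
  enh <- do.call(rbind, lapply(config$cell_types, function(ct) {
    e <- load_region_bed(p$enhancers[[ct]])
    e$cell_type <- ct
    e
  }))
  list(interactions = ints,
       differential = load_results(p$differential,
                                   "differential_interactions"),
       allelic = stats::setNames(lapply(config$cell_types, function(ct) {
         list(genotypes = load_phased_genotypes(p$genotypes[[ct]]),
              counts = load_results(p$allele_counts[[ct]], "allele_counts"))
       }), config$cell_types),
       expression = list(expression = load_results(p$expression,
                                                   "expression_results")),
       gwas = list(leads = load_results(p$gwas_leads, "gwas_leads"),
                   proxies = load_results(p$ld_proxies, "ld_proxies"),
                   enhancers = enh),
       truth = NULL)
}

#' Run the full pipeline
#'
#' Stages, in order: acquire inputs (simulate the fixture bundle or load the
#' configured paths), call allele-associated loops per cell type, define GWAS
#' loci and assign candidate genes, and compute differential
#' interaction/expression concordance. Per-stage record counts are logged;
#' identical config (and seed) gives an identical report.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress logging to stderr.
#' @return object of class `pipeline_report` (see [generate_report()]); if
#'   `config$out_dir` is set, `report.md`, `report.json` and `pipeline.log`
#'   are written there.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    log_lines <<- c(log_lines, msg)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  say("stage 1/4: inputs")
  bundle <- stage("inputs", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- config$seed
      simulate_bundle(sim)
    } else {
      .load_inputs(config)
    }
  })
  pooled <- bundle$interactions[
    is.na(bundle$interactions$condition) |
      bundle$interactions$condition == "pooled", , drop = FALSE]
  say("  interactions: %d rows (%d pooled), differential: %d rows",
      nrow(bundle$interactions), nrow(pooled), nrow(bundle$differential))

  say("stage 2/4: allelic imbalance")
  imbalance <- stage("allelic_imbalance", {
    stats::setNames(lapply(config$cell_types, function(ct) {
      a <- bundle$allelic[[ct]]
      loops <- pooled[pooled$cell_type == ct, , drop = FALSE]
      call_imbalanced_loops(a$counts, a$genotypes, loops,
                            thresholds = config$imbalance_qc,
                            fdr = config$fdr)
    }), config$cell_types)
  })
  for (ct in config$cell_types)
    say("  %s: %d pairs tested, %d significant (q < %g)", ct,
        imbalance[[ct]]$summary$n_pairs_tested,
        imbalance[[ct]]$summary$n_significant, config$fdr)

  say("stage 3/4: GWAS locus mapping")
  mapping <- stage("gwas_overlap", {
    snp_set <- expand_ld(bundle$gwas$leads, bundle$gwas$proxies,
                         r2_threshold = config$r2,
                         p_threshold = config$gwas_p)
    loci <- define_loci(snp_set, merge_distance_bp = config$merge_kb * 1000)
    overlaps <- annotate_snp_overlaps(snp_set, bundle$gwas$enhancers)
    prop_test <- if (nrow(overlaps$summary) == 2) {
      two_proportion_test(overlaps$summary$n_overlap[1],
                          overlaps$summary$n_overlap[2],
                          overlaps$summary$n_total[1])
    } else NULL
    background <- rbind(
      bundle$gwas$proxies[, c("snp_id", "chrom", "pos")],
      data.frame(snp_id = bundle$gwas$leads$snp_id,
                 chrom = bundle$gwas$leads$chrom,
                 pos = bundle$gwas$leads$pos, stringsAsFactors = FALSE))
    enrichment <- stats::setNames(lapply(config$cell_types, function(ct) {
      enhancer_enrichment(
        snp_set, background,
        bundle$gwas$enhancers[bundle$gwas$enhancers$cell_type == ct, ,
                              drop = FALSE])
    }), config$cell_types)
    candidates <- map_snps_to_genes(snp_set, bundle$gwas$enhancers, pooled,
                                    score_threshold = config$chicago_score,
                                    loci = loci)
    list(snp_set = snp_set, loci = loci, overlaps = overlaps,
         prop_test = prop_test, enrichment = enrichment,
         candidates = candidates)
  })
  say("  %d SNPs in %d loci; %d candidate (locus, gene) rows",
      nrow(mapping$snp_set), nrow(mapping$loci),
      nrow(mapping$candidates$candidates))

  say("stage 4/4: concordance")
  concordance <- stage("concordance", {
    concordance_analysis(bundle$expression$expression, bundle$differential,
                         de_adj_p_max = config$de_adj_p,
                         de_abs_lfc_min = config$de_abs_lfc,
                         di_wadj_p_max = config$wadj_p,
                         stringent_lfc = config$stringent_lfc)
  })
  say("  DE genes: %d, DI genes: %d, overlap: %d",
      concordance$n_de, concordance$n_di,
      concordance$enrichment$overlap_count)

  report <- generate_report(list(config = config, bundle = bundle,
                                 imbalance = imbalance, mapping = mapping,
                                 concordance = concordance))
  report$log <- log_lines

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(report$markdown, file.path(config$out_dir, "report.md"))
    jsonlite::write_json(report$json,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
  }
  report
}

#' Build the consolidated report from stage outputs
#'
#' Produces a human-readable markdown summary and a machine-readable JSON
#' mirror; every number in the markdown is present in the JSON. The
#' candidate-gene matrix has one column per cell type; genes from shared baits
#' keep their own rows, and shared-bait promoters remain `";"`-joined in the
#' supporting loop ids.
#'
#' @param stage_outputs list with `config`, `bundle`, `imbalance`, `mapping`,
#'   `concordance` as assembled by [run_pipeline()].
#' @return object of class `pipeline_report`: list with `markdown` (character
#'   vector of lines), `json` (list) and the stage outputs.
#' @export
generate_report <- function(stage_outputs) {
  cfg <- stage_outputs$config
  imb <- stage_outputs$imbalance
  map <- stage_outputs$mapping
  conc <- stage_outputs$concordance
  cts <- cfg$cell_types

  json <- list(
    thresholds = list(chicago_score = cfg$chicago_score,
                      wadj_p = cfg$wadj_p, de_adj_p = cfg$de_adj_p,
                      de_abs_lfc = cfg$de_abs_lfc, r2 = cfg$r2,
                      gwas_p = cfg$gwas_p, merge_kb = cfg$merge_kb,
                      stringent_lfc = cfg$stringent_lfc, fdr = cfg$fdr,
                      min_reads_per_sample =
                        cfg$imbalance_qc$min_reads_per_sample,
                      min_het_samples = cfg$imbalance_qc$min_het_samples),
    seed = cfg$seed,
    imbalance = lapply(imb, function(x) x$summary),
    gwas = list(
      n_snps = nrow(map$snp_set), n_loci = nrow(map$loci),
      snp_enhancer_overlap = map$overlaps$summary,
      two_proportion = if (!is.null(map$prop_test))
        list(z = map$prop_test$z, p = map$prop_test$p) else NULL,
      enrichment = lapply(map$enrichment, function(e)
        list(odds_ratio = e$odds_ratio, p = e$p)),
      interaction_counts = as.list(map$candidates$interaction_counts),
      n_candidate_rows = nrow(map$candidates$candidates)),
    concordance = list(
      n_de = conc$n_de, n_di = conc$n_di,
      overlap_count = conc$enrichment$overlap_count,
      enrichment_or = conc$enrichment$odds_ratio,
      enrichment_p = conc$enrichment$p,
      spearman_rho = conc$correlation$rho,
      spearman_p = conc$correlation$p,
      binomial_n = conc$binomial$n,
      binomial_k = conc$binomial$k_concordant,
      binomial_p = conc$binomial$p,
      success_fraction = conc$binomial$success_fraction),
    candidate_genes = map$candidates$candidates)

  md <- c("# Pipeline report", "",
          "## Thresholds",
          sprintf("- interaction score > %g; weighted adjusted p < %g",
                  cfg$chicago_score, cfg$wadj_p),
          sprintf("- DE: adjusted p < %g, |log2FC| > %g; stringent DI |median log2FC| > %g",
                  cfg$de_adj_p, cfg$de_abs_lfc, cfg$stringent_lfc),
          sprintf("- LD r2 > %g; GWAS p < %g; locus merge %g kb",
                  cfg$r2, cfg$gwas_p, cfg$merge_kb),
          sprintf("- imbalance: >= %d reads/sample, >= %d het samples, FDR %g",
                  cfg$imbalance_qc$min_reads_per_sample,
                  cfg$imbalance_qc$min_het_samples, cfg$fdr),
          sprintf("- seed %d", cfg$seed), "",
          "## Allele-associated loops")
  for (ct in cts) {
    s <- imb[[ct]]$summary
    md <- c(md, sprintf(
      "- %s: %d pairs tested, %d significant (q < %g), %d loops, %d SNPs, %d genes",
      ct, s$n_pairs_tested, s$n_significant, s$fdr, s$n_loops, s$n_snps,
      s$n_genes))
  }
  md <- c(md, "", "## GWAS loci and candidate genes",
          sprintf("- %d SNPs passing filters in %d loci",
                  nrow(map$snp_set), nrow(map$loci)))
  for (i in seq_len(nrow(map$overlaps$summary))) {
    s <- map$overlaps$summary[i, ]
    md <- c(md, sprintf("- %s enhancer overlap: %d/%d SNPs (%.1f%%)",
                        s$cell_type, s$n_overlap, s$n_total,
                        100 * s$proportion))
  }
  if (!is.null(map$prop_test))
    md <- c(md, sprintf("- two-proportion z = %.3f, p = %.3g",
                        map$prop_test$z, map$prop_test$p))
  for (ct in cts)
    md <- c(md, sprintf(
      "- %s enhancer enrichment (Fisher substitute): OR = %.3g, p = %.3g",
      ct, map$enrichment[[ct]]$odds_ratio, map$enrichment[[ct]]$p))
  for (ct in names(map$candidates$interaction_counts))
    md <- c(md, sprintf("- %s qualifying interactions: %d", ct,
                        map$candidates$interaction_counts[[ct]]))

  cand <- map$candidates$candidates
  md <- c(md, "", "### Candidate-gene matrix")
  if (nrow(cand) == 0) {
    md <- c(md, "no candidates")
  } else {
    md <- c(md, paste0("| locus | gene | ",
                       paste(cts, collapse = " | "), " |"),
            paste0("|", paste(rep("---", length(cts) + 2), collapse = "|"),
                   "|"))
    for (i in seq_len(nrow(cand))) {
      in_ct <- vapply(cts, function(ct)
        ct %in% strsplit(cand$cell_types[i], ";", fixed = TRUE)[[1]],
        logical(1))
      md <- c(md, paste0("| ", cand$locus_id[i], " | ", cand$gene_id[i],
                         " | ", paste(ifelse(in_ct, "yes", "-"),
                                      collapse = " | "), " |"))
    }
  }

  md <- c(md, "", "## Differential interaction / expression concordance",
          sprintf("- %d DE genes, %d DI genes, overlap %d",
                  conc$n_de, conc$n_di, conc$enrichment$overlap_count),
          sprintf("- enrichment OR = %.3g, one-sided Fisher p = %.3g",
                  conc$enrichment$odds_ratio, conc$enrichment$p),
          sprintf("- Spearman rho = %.3g (p = %.3g)",
                  conc$correlation$rho, conc$correlation$p),
          sprintf("- sign concordance %d/%d, exact binomial p = %.3g",
                  conc$binomial$k_concordant, conc$binomial$n,
                  conc$binomial$p))

  structure(list(markdown = md, json = json,
                 imbalance = imb, mapping = map, concordance = conc,
                 config = cfg),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(paste(x$markdown, collapse = "\n"), "\n")
  invisible(x)
}
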