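# Readers and writers for every table the pipeline touches.
#
# Conventions:
#  * ibed/tsv interaction tables and SNP positions arrive 1-based inclusive and
#    are converted to the internal 0-based half-open convention on read.
#  * BED files are already 0-based half-open; no conversion.
#  * schema TSVs written by write_results() store the internal representation
#    directly (coordinates 0-based half-open) and round-trip exactly through
#    load_results().

# -- schema registry ---------------------------------------------------------

.schemas <- list(
  imbalance_calls = c(snp_id = "character", loop_id = "character",
                      n_samples_used = "integer", per_sample_p = "character",
                      direction = "character", fisher_chi2 = "double",
                      fisher_df = "integer", combined_p = "double",
                      q_value = "double"),
  candidate_genes = c(locus_id = "character", gene_id = "character",
                      cell_types = "character", n_support = "integer"),
  concordance_summary = c(metric = "character", value = "double"),
  phased_genotypes = c(sample_id = "character", snp_id = "character",
                       chrom = "character", pos = "integer",
                       ref = "character", alt = "character", gt = "character"),
  allele_counts = c(sample_id = "character", snp_id = "character",
                    loop_id = "character", ref_count = "integer",
                    alt_count = "integer"),
  expression_results = c(gene_id = "character", log2fc = "double",
                         adj_p = "double", mean_expr_a = "double",
                         mean_expr_b = "double"),
  differential_interactions = c(bait_genes = "character",
                                bait_chrom = "character",
                                bait_start = "integer", bait_end = "integer",
                                oe_chrom = "character", oe_start = "integer",
                                oe_end = "integer", log2fc = "double",
                                wadj_p = "double"),
  gwas_leads = c(snp_id = "character", chrom = "character", pos = "integer",
                 gwas_p = "double"),
  ld_proxies = c(snp_id = "character", chrom = "character", pos = "integer",
                 lead_id = "character", r2 = "double"),
  gwas_snps = c(snp_id = "character", chrom = "character", pos = "integer",
                lead_id = "character", r2 = "double", gwas_p = "double"),
  truth_interactions = c(loop_id = "character", bait_genes = "character",
                         on_cell_type = "character", log2fc = "double"),
  truth_allelic = c(snp_id = "character", loop_id = "character",
                    direction = "character", p_ref = "double"),
  truth_expression = c(gene_id = "character", true_log2fc = "double",
                       loop_id = "character"),
  truth_candidate_genes = c(lead_id = "character", snp_id = "character",
                            gene_id = "character", cell_type = "character",
                            loop_id = "character")
)

#' Names of the table schemas known to [write_results()]
#' @return character vector of schema names.
#' @export
result_schemas <- function() names(.schemas)

.get_schema <- function(schema) {
  if (!is.character(schema) || length(schema) != 1 || !schema %in% names(.schemas))
    stop("unknown schema: ", paste(schema, collapse = ", "),
         " (known: ", paste(names(.schemas), collapse = ", "), ")")
  .schemas[[schema]]
}

# columns whose values must lie in [0, 1]
.unit_interval_cols <- c("wadj_p", "adj_p", "combined_p", "q_value", "r2",
                         "gwas_p", "p_ref")

.validate_schema_df <- function(df, schema) {
  cols <- .get_schema(schema)
  missing_cols <- setdiff(names(cols), names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("records missing schema column(s) for '%s': %s",
                 schema, paste(missing_cols, collapse = ", ")))
  for (cn in intersect(names(cols), .unit_interval_cols)) {
    v <- df[[cn]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad) > 0)
      stop(sprintf("column '%s' outside [0, 1] at row %d", cn, bad[1]))
  }
  for (cn in intersect(c("ref_count", "alt_count"), names(cols))) {
    bad <- which(df[[cn]] < 0)
    if (length(bad) > 0)
      stop(sprintf("column '%s' negative at row %d", cn, bad[1]))
  }
  invisible(df)
}

#' Write a result table under a named schema
#'
#' Columns are emitted in the schema's canonical order; doubles are rendered
#' with 6 significant digits; the output round-trips through [load_results()]
#' up to that rendering precision. An empty record set yields a header-only
#' file.
#'
#' @param records data.frame conforming to the schema.
#' @param path output file path.
#' @param schema one of [result_schemas()].
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, schema) {
  cols <- .get_schema(schema)
  .validate_schema_df(records, schema)
  out <- records[, names(cols), drop = FALSE]
  for (cn in names(cols)) {
    if (cols[[cn]] == "double") {
      out[[cn]] <- ifelse(is.na(out[[cn]]), "NA",
                          sprintf("%.6g", as.numeric(out[[cn]])))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Load a table previously written by [write_results()]
#'
#' @param path file path.
#' @param schema one of [result_schemas()].
#' @return validated data.frame with schema column types.
#' @export
load_results <- function(path, schema) {
  cols <- .get_schema(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(names(cols), names(df))
  if (length(missing_cols) > 0)
    stop(sprintf("file %s missing schema column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  df <- df[, names(cols), drop = FALSE]
  for (cn in names(cols)) {
    df[[cn]] <- switch(cols[[cn]],
                       character = as.character(df[[cn]]),
                       integer = .parse_int(df[[cn]], path, cn),
                       double = .parse_num(df[[cn]], path, cn))
  }
  .validate_schema_df(df, schema)
  df
}

.parse_num <- function(x, path, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & x != "NA")
  if (length(bad) > 0)
    stop(sprintf("%s: malformed row %d, column '%s': not numeric ('%s')",
                 path, bad[1], col, x[bad[1]]))
  out
}

.parse_int <- function(x, path, col) {
  out <- .parse_num(x, path, col)
  bad <- which(!is.na(out) & out != round(out))
  if (length(bad) > 0)
    stop(sprintf("%s: malformed row %d, column '%s': not an integer ('%s')",
                 path, bad[1], col, x[bad[1]]))
  as.integer(out)
}

# -- interaction tables ------------------------------------------------------

#' Canonical key identifying one bait/other-end interaction
#'
#' Built from internal 0-based coordinates; stable across write/read cycles.
#'
#' @param df interaction data.frame.
#' @return character vector of keys.
#' @export
interaction_key <- function(df) {
  sprintf("%s:%d-%d>%s:%d-%d",
          df$bait_chrom, as.integer(df$bait_start), as.integer(df$bait_end),
          df$oe_chrom, as.integer(df$oe_start), as.integer(df$oe_end))
}

.IBED_COLS <- c("bait_chr", "bait_start", "bait_end", "bait_name",
                "oe_chr", "oe_start", "oe_end", "oe_name", "N_reads", "score")

#' Load a table of chromatin interaction calls
#'
#' Two dialects are supported, both tab-separated with a header row and
#' 1-based inclusive coordinates (converted to the internal 0-based half-open
#' convention on read):
#' \describe{
#'   \item{`ibed`}{columns `bait_chr, bait_start, bait_end, bait_name, oe_chr,
#'     oe_start, oe_end, oe_name, N_reads (optional), score`. `bait_name`
#'     carries the promoter gene symbol(s); promoters sharing a bait are
#'     `";"`-separated.}
#'   \item{`tsv`}{columns `bait_chrom, bait_start, bait_end, bait_genes,
#'     oe_chrom, oe_start, oe_end, score` plus optional `cell_type`,
#'     `condition`, `n_reads`.}
#' }
#'
#' @param path file path.
#' @param dialect `"ibed"` or `"tsv"`.
#' @param cell_type,condition labels attached to every record when the file
#'   does not carry them.
#' @return data.frame with columns `bait_chrom, bait_start, bait_end,
#'   bait_genes, oe_chrom, oe_start, oe_end, n_reads, score, cell_type,
#'   condition, loop_id`.
#' @export
load_interaction_table <- function(path, dialect = c("ibed", "tsv"),
                                   cell_type = NA_character_,
                                   condition = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  cell_type <- rep(cell_type, nrow(raw))
  condition <- rep(condition, nrow(raw))
  if (dialect == "ibed") {
    need <- setdiff(.IBED_COLS, c("N_reads"))
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols) > 0)
      stop(path, ": ibed file missing column(s): ",
           paste(missing_cols, collapse = ", "))
    df <- data.frame(
      bait_chrom = raw$bait_chr,
      bait_start = .parse_int(raw$bait_start, path, "bait_start"),
      bait_end = .parse_int(raw$bait_end, path, "bait_end"),
      bait_genes = raw$bait_name,
      oe_chrom = raw$oe_chr,
      oe_start = .parse_int(raw$oe_start, path, "oe_start"),
      oe_end = .parse_int(raw$oe_end, path, "oe_end"),
      n_reads = if ("N_reads" %in% names(raw))
        .parse_int(raw$N_reads, path, "N_reads") else
          rep(NA_integer_, nrow(raw)),
      score = .parse_num(raw$score, path, "score"),
      cell_type = if ("cell_type" %in% names(raw)) raw$cell_type else cell_type,
      condition = if ("condition" %in% names(raw)) raw$condition else condition,
      stringsAsFactors = FALSE)
  } else {
    need <- c("bait_chrom", "bait_start", "bait_end", "bait_genes",
              "oe_chrom", "oe_start", "oe_end", "score")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols) > 0)
      stop(path, ": tsv interaction file missing column(s): ",
           paste(missing_cols, collapse = ", "))
    df <- data.frame(
      bait_chrom = raw$bait_chrom,
      bait_start = .parse_int(raw$bait_start, path, "bait_start"),
      bait_end = .parse_int(raw$bait_end, path, "bait_end"),
      bait_genes = raw$bait_genes,
      oe_chrom = raw$oe_chrom,
      oe_start = .parse_int(raw$oe_start, path, "oe_start"),
      oe_end = .parse_int(raw$oe_end, path, "oe_end"),
      n_reads = if ("n_reads" %in% names(raw))
        .parse_int(raw$n_reads, path, "n_reads") else
          rep(NA_integer_, nrow(raw)),
      score = .parse_num(raw$score, path, "score"),
      cell_type = if ("cell_type" %in% names(raw)) raw$cell_type else cell_type,
      condition = if ("condition" %in% names(raw)) raw$condition else condition,
      stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0) {
    df$loop_id <- character(0)
    return(df)
  }
  # 1-based inclusive -> 0-based half-open
  b <- coords_1based_to_0based(df$bait_start, df$bait_end)
  o <- coords_1based_to_0based(df$oe_start, df$oe_end)
  df$bait_start <- b$start; df$bait_end <- b$end
  df$oe_start <- o$start; df$oe_end <- o$end
  bad <- which(is.na(df$bait_genes) | !nzchar(df$bait_genes))
  if (length(bad) > 0)
    stop(sprintf("%s: malformed row %d, column 'bait_name': empty gene list",
                 path, bad[1]))
  bad <- which(df$score < 0)
  if (length(bad) > 0)
    stop(sprintf("%s: malformed row %d, column 'score': negative score (%s)",
                 path, bad[1], df$score[bad[1]]))
  validate_intervals(df, prefix = "bait_", what = paste0(path, " bait"))
  validate_intervals(df, prefix = "oe_", what = paste0(path, " other end"))
  df$loop_id <- interaction_key(df)
  df
}

#' Write interaction calls in the ibed dialect
#'
#' Inverse of [load_interaction_table()]: internal 0-based half-open
#' coordinates are rendered 1-based inclusive.
#'
#' @param df interaction data.frame (internal representation).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(df, path) {
  b <- coords_0based_to_1based(df$bait_start, df$bait_end)
  o <- coords_0based_to_1based(df$oe_start, df$oe_end)
  out <- data.frame(bait_chr = df$bait_chrom,
                    bait_start = as.integer(b$start),
                    bait_end = as.integer(b$end),
                    bait_name = df$bait_genes,
                    oe_chr = df$oe_chrom,
                    oe_start = as.integer(o$start),
                    oe_end = as.integer(o$end),
                    oe_name = ".",
                    N_reads = ifelse(is.na(df$n_reads), 0L,
                                     as.integer(df$n_reads)),
                    score = sprintf("%.6g", df$score),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Split multi-promoter bait gene strings into one row per gene
#'
#' Baits capturing several promoters carry `";"`-separated gene symbols; every
#' gene-level statement downstream fans out over the list.
#'
#' @param df data.frame with a `bait_genes` column.
#' @return `df` with `bait_genes` replaced by a single `gene_id` per row.
#' @export
fan_out_genes <- function(df) {
  genes <- strsplit(df$bait_genes, ";", fixed = TRUE)
  n <- lengths(genes)
  out <- df[rep(seq_len(nrow(df)), n), , drop = FALSE]
  out$gene_id <- trimws(unlist(genes))
  out$bait_genes <- NULL
  rownames(out) <- NULL
  out
}

# -- BED ---------------------------------------------------------------------

#' Load a BED3+ file of genomic regions
#'
#' Tab-separated, no header, already 0-based half-open (no conversion). An
#' optional 4th column is returned as `cell_type` (the tag used for enhancer
#' segmentations); an optional 5th column as `name`.
#'
#' @param path file path.
#' @return interval data.frame.
#' @export
load_region_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 3)
    stop(path, ": BED file needs at least 3 tab-separated columns")
  df <- data.frame(chrom = raw[[1]],
                   start = .parse_int(raw[[2]], path, "start"),
                   end = .parse_int(raw[[3]], path, "end"),
                   stringsAsFactors = FALSE)
  if (ncol(raw) >= 4) df$cell_type <- raw[[4]]
  if (ncol(raw) >= 5) df$name <- raw[[5]]
  validate_intervals(df, what = path)
  df
}

#' Write genomic regions as BED
#' @param df interval data.frame (optionally with `cell_type`, `name`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(df, path) {
  out <- df[, c("chrom", "start", "end"), drop = FALSE]
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  if ("cell_type" %in% names(df)) out$cell_type <- df$cell_type
  if ("name" %in% names(df)) out$name <- df$name
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# -- phased genotypes --------------------------------------------------------

.VALID_GT <- c("0|0", "0|1", "1|0", "1|1")

#' Load phased genotypes
#'
#' Headered TSV with columns `sample_id, snp_id, chrom, pos, ref, alt, GT`
#' (VCF-style 1-based positions, kept 1-based for SNPs internally). Only
#' phased genotype strings (`0|0`, `0|1`, `1|0`, `1|1`) are accepted; an
#' unphased `0/1` is an error. Non-heterozygous records are accepted here and
#' excluded later by QC.
#'
#' @param path file path.
#' @return data.frame `sample_id, snp_id, chrom, pos, ref, alt, gt`.
#' @export
load_phased_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  gt_col <- if ("GT" %in% names(raw)) "GT" else "gt"
  need <- c("sample_id", "snp_id", "chrom", "pos", "ref", "alt", gt_col)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop(path, ": genotype file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- data.frame(sample_id = raw$sample_id, snp_id = raw$snp_id,
                   chrom = raw$chrom,
                   pos = .parse_int(raw$pos, path, "pos"),
                   ref = raw$ref, alt = raw$alt, gt = raw[[gt_col]],
                   stringsAsFactors = FALSE)
  bad <- which(!df$gt %in% .VALID_GT)
  if (length(bad) > 0)
    stop(sprintf(
      "%s: record %d (sample %s, SNP %s): genotype '%s' is not a phased GT",
      path, bad[1], df$sample_id[bad[1]], df$snp_id[bad[1]], df$gt[bad[1]]))
  bad <- which(df$pos < 1)
  if (length(bad) > 0)
    stop(sprintf("%s: record %d: pos < 1", path, bad[1]))
  bad <- which(!nzchar(df$ref) | !nzchar(df$alt))
  if (length(bad) > 0)
    stop(sprintf("%s: record %d: empty allele string", path, bad[1]))
  df
}

#' Is a phased genotype heterozygous?
#' @param gt character vector of phased GT strings.
#' @return logical vector.
#' @export
is_het <- function(gt) gt %in% c("0|1", "1|0")
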