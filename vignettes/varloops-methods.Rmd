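---
title: "Methods: models, parameters and design choices in varloops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in varloops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`varloops` analyses processed promoter capture Hi-C (PCHi-C) outputs in two
cell types: it calls allele-associated chromatin loops, assigns GWAS risk
variants to candidate target genes through enhancer and
promoter-interacting-region (PIR) overlap, and quantifies the concordance
between differential interactions and differential expression. This vignette
documents the statistical models, every tunable parameter, the synthetic-data
generator, and the numerical and design choices behind them.

## Coordinate and data conventions

All intervals inside the package are 0-based half-open (`[start, end)`, the
BED convention). ibed-style interaction tables arrive 1-based inclusive and
are converted once at the I/O boundary; SNP positions are VCF-style 1-based
and treated as width-1 intervals for overlap (`pos` overlaps `[s, e)` iff
`s <= pos - 1 < e`). Strand is ignored throughout: the overlap logic is
strand-free. Baits capturing several promoters carry `";"`-separated gene
symbols, and every gene-level statement fans out over the list, so each gene
of a shared bait gets its own row downstream. Interval union, containment and
merging are delegated to GenomicRanges/IRanges; the test suite checks them
against brute-force positional scans.

## Allele-associated loop calling

For each (SNP, loop) pair and each sample that is heterozygous for the SNP,
the reference-haplotype read count `r` out of `n = r + a` loop-supporting
reads is tested against Binomial(n, 0.5) with the exact two-sided rule: the
p-value is the total probability of all outcomes no more likely than the one
observed. Per-sample results are then combined per pair with Fisher's method,

> chi² = −2 Σᵢ ln pᵢ,  df = 2m,  combined p = P(χ²₍₂ₘ₎ ≥ chi²),

after a directionality check, and the combined p-values are
Benjamini–Hochberg adjusted within each cell type (mirroring per-cell-type
reporting).

**QC thresholds** (class `qc_thresholds`). Published allele-specific analyses
apply study-specific filters whose exact values are rarely stated; the
defaults here are deliberately conservative and fully exposed:

| parameter | default | rationale |
|---|---|---|
| `min_reads_per_sample` | 10 reads | below ~10 reads the exact test has essentially no power and contributes mostly discreteness |
| `min_het_samples` | 1 | a single informative heterozygote is admissible; the Fisher combination handles m = 1 as the identity |
| `require_snp_in_anchor` | TRUE | the question is loop-level: the SNP should sit in the bait or other-end fragment whose contact it putatively modulates |

**Directionality.** Two readings of "checked for directionality" are
implemented behind `direction_mode`:

* `"concordance"` (default): ties (p = 1, i.e. r = a) are direction-neutral;
  all non-tie samples must share a direction, otherwise the pair is flagged
  `discordant` and assigned combined p = 1 — retained in the output rather
  than silently dropped, so row counts stay auditable.
* `"pooled"`: a one-sided meta-analysis toward the majority direction
  (two-sided p converted to p/2 for agreeing samples, 1 − p/2 otherwise,
  then Fisher-combined).

The concordance gate is the default because it is the simplest reading and
makes the direction of every significant call unambiguous; the pooled mode is
kept because the phrasing is genuinely ambiguous.

**Calibration of the combined p-value.** The exact binomial test is discrete:
with ~20 reads per sample its two-sided p has an atom at 1 (probability ≈ 0.18
of a perfect tie at n = 20) and E[−2 ln p] ≈ 1.47 < 2. Fisher's method assumes
continuous uniform p-values, so the combined p under the null is
**stochastically conservative, not uniform** — the directionality gate
(discordant null pairs get p = 1) strengthens this further. Consequently the
suite asserts the property that actually holds and matters: under the null,
P(combined p ≤ α) ≤ α at every α, and significant calls at q < 0.05 among
5,000 null pairs number at most 5 (observed: 0). A Kolmogorov–Smirnov
uniformity check on the combined p necessarily rejects; this is a property of
discrete exact tests, not an implementation defect, and false-positive
control is what the conservativeness guarantees.

## GWAS loci and candidate-gene assignment

`expand_ld()` keeps genome-wide-significant leads (p < 5×10⁻⁸, strict) and
proxies in high LD (r² > 0.8, strict) with a retained lead. `define_loci()`
spans each lead and its proxies (`[min pos − 1, max pos)`) and merges regions
on the same chromosome separated by at most `merge_distance_bp` (default
250 kb) transitively. Published locus windows are usually curated by hand;
the span-plus-merge rule is a deterministic stand-in that reproduces the
qualitative behaviour of nearby independent signals collapsing into one
region, and the merge distance is exposed.

`build_enhancer_union()` takes, per cell type, the interval union of all
segments whose chromatin-state label denotes enhancer activity in at least
one sample of that cell type (the "≥ 1 sample" rule).

`map_snps_to_genes()` applies the strict intersection reading of the
assignment rule: the **same SNP** must overlap an enhancer of the cell type
*and* fall inside the other end of an interaction with score above the
threshold (default 5, strict `>`), using per-cell-type pooled interaction
calls. Candidates are reported per (locus, gene) with all supporting
(SNP, interaction, enhancer) evidence triples; the suite re-validates every
triple against the raw inputs and checks that removing a cell type's
enhancers can only shrink that cell type's candidates.

Two overlap statistics accompany the mapping: a pooled two-proportion z-test
comparing the per-cell-type SNP/enhancer overlap counts, and a plain
one-sided Fisher exact enrichment of the SNP set against a background SNP set
(foreground removed from the background first). The Fisher enrichment is an
explicitly labelled substitute for matched-permutation methods such as
GARFIELD: it performs no LD- or distance-matching, so its odds ratio is not
comparable to matched enrichment estimates. The reported odds ratio is the
sample OR (ad/bc) throughout, not the conditional MLE.

## Differential interaction / expression concordance

With positive log₂ fold changes meaning "higher in the first cell type" in
both tables:

* `select_significant_de()`: adjusted p < 0.05 and |log₂FC| > 2 (strict).
* `select_significant_di()`: weighted adjusted p < 0.05; multi-promoter baits
  fan out; per gene the **median** log₂FC over its significant interactions
  is the effect summary.
* `overlap_enrichment()`: one-sided Fisher exact on the 2×2 table over a gene
  universe. The universe defaults to all genes present in the expression
  table — the least arbitrary choice, and configurable.
* `lfc_correlation()`: Spearman rank correlation (average ranks for ties,
  large-sample t approximation), on the per-gene median pairing for
  consistency with the stringent step.
* `concordance_binomial()`: restricted to genes with |median interaction
  log₂FC| > 2 (strict), counts sign agreement between the expression and
  interaction effects, and applies the exact two-sided binomial test against
  0.5. A zero effect counts as non-concordant; with strict cutoffs upstream
  it cannot occur, but the policy is fixed.

All stages tolerate empty significant sets (statistics reported as `NA`
rather than failing), since real between-state contrasts can legitimately
yield none.

## The synthetic-data generator

`sim_config()` fixes the emulated study design; every generator is a pure
function of the configuration, and identical configs give byte-identical
bundles. Defaults:

| parameter | default | meaning |
|---|---|---|
| `n_samples_patient`, `n_samples_control` | 10, 5 | the emulated cohort |
| `cell_types` | CD4, CD14 | two immune cell types; positive log₂FC = higher in the first |
| `n_baits`, `n_other_ends_per_bait` | 100, 10 | interaction universe (1,000 pairs/cell type) |
| `frac_celltype_specific_loops` | 0.10 | planted cell-type-specific loops |
| `allelic_effect` | 0.75 | true reference read fraction for imbalanced pairs |
| `frac_imbalanced_pairs` | 0.10 | planted allelic imbalance |
| `reads_per_het_sample` | 20 | Poisson mean of loop reads per heterozygote |
| `maf` | 0.30 | Hardy–Weinberg genotype draws (common regulatory variants) |
| `n_gwas_loci` | 23 | lead signals |
| `n_proxies_per_lead`, `ld_block_span_bp` | 20, 100 kb | LD block structure |
| `frac_r2_high` | 0.8 | proxies drawn with r² > 0.8 |
| `enhancer_density` | 0.25 | fraction of passing SNPs inside enhancers per cell type |
| `n_candidate_snps` | 8 | leads planted inside significant other ends |
| `de_effect_log2fc`, `coupling_rate` | 3, 0.8 | planted expression effects coupled to planted loops |
| `n_genes` | 2,000 | expression universe |
| `nb_dispersion` | 0.1 | negative-binomial dispersion |

Interaction scores decay with bait/other-end distance
(mean 1 + 12·e^(−d/200 kb) plus Gaussian noise), so short-range contacts are
mostly significant and long-range ones mostly not, as in CHiCAGO-style
calls. Planted loops score uniformly in (6, 15) in their cell type and
(0.5, 4.5) in the other. The differential table covers pairs significant in
at least one cell type; planted pairs get |log₂FC| in (2.2, 6) with the
correct sign and weighted adjusted p below 0.05, background pairs a uniform
weighted adjusted p (so ~5% are chance-significant) and N(0, 0.3) log₂FC.

Three coupling choices model the gene-level phenomenon the pipeline is meant
to detect — that a gene overexpressed in one cell type has coherently more
chromatin interactions there:

1. the planted "on" cell type is a **bait-level** property (all planted loops
   of one promoter share direction);
2. the remaining loops of a planted bait drift in the same direction
   (|N(1.2, 0.6)| log₂FC, significance rates untouched), emulating a coherent
   interactome shift rather than an isolated loop;
3. a coupled gene's planted expression log₂FC tracks the **median** of its
   planted interaction effects, with magnitude proportional to it (scaled so
   the mean equals `de_effect_log2fc`; `couple_magnitude = FALSE` gives a
   constant magnitude instead).

Without these, per-gene median interaction effects are scrambled by
direction-random co-bait loops and the observable rank correlation saturates
well below the planted signal. With `frac_celltype_specific_loops = 0` no
bait is planted and every pair is a pure null draw.

Allele counts are simulated directly at the (sample, SNP, loop) level — one
SNP at each other-end midpoint, genotypes under Hardy–Weinberg, totals
Poisson, reference counts Binomial(total, 0.5 or `allelic_effect` with a
pair-level direction shared across samples). Read-level haplotype assignment
is out of scope; the binomial count model is exactly what the downstream test
consumes. Expression counts are negative-binomial; the internal
differential-expression summary (`de_summary()`) is a deliberately simple
Welch t-test on log₂(CPM + 1) with BH adjustment — it stands in for a full
count-model analysis (edgeR/DESeq2-style dispersion shrinkage) only to give
the concordance stage realistically distributed inputs, and is not equivalent
to one.

**What the generator does not emulate** — and hence what passing tests do not
show about real data: reference-mapping bias and read-level allele
assignment errors; LD correlation *structure* (r² values are drawn, not
derived from haplotypes); FDR-adjusted behaviour of the background weighted
adjusted p (kept uniform by design, which slightly overstates background
contamination); restriction-fragment geometry; trans-chromosomal contacts;
and covariate structure (age, sex, batch). Truth-recovery results bound what
the pipeline can do under its own assumptions, not its field performance.

## Numerical choices

* Every published threshold is applied with the strict inequality as printed
  (score > 5, r² > 0.8, p < 5×10⁻⁸, weighted adjusted p < 0.05,
  |log₂FC| > 2).
* Exact binomial ties (r = a) give p = 1 and never create discordance;
  p = 0 is rejected as impossible for the exact test.
* Discordant pairs keep their chi² but are assigned combined p = 1.
* Fisher-exact p-values come from `fisher.test`; reported odds ratios are
  sample ORs (ad/bc), matching the 2×2 arithmetic, with `Inf` for empty
  off-diagonals.
* `write_results()` renders doubles with 6 significant digits; round-trips
  are exact to that rendering.
* Test problem sizes: oracle equivalence sweeps all binomial totals ≤ 25 and
  2×2 tables with n ≤ 60; null calibration uses 5,000 (SNP, loop) pairs and
  2,000 genes; power and concordance checks average 10 seeded replicates of
  the default 1,000-pair bundle. These sizes give stable Monte-Carlo
  estimates (binomial SE ≤ ~1.5 percentage points on the recovery rates)
  while keeping the default test run fast.

## Known limitations

* The combined allelic-imbalance p-value is conservative (see above); power
  at low read depth is correspondingly pessimistic.
* Locus definition is a deterministic stand-in for curated locus windows.
* The enhancer enrichment is unmatched and not comparable to
  LD-/distance-matched permutation methods.
* The per-gene pairing for the rank correlation (median over significant
  interactions) is one of several defensible choices; per-interaction
  pairing would weight promiscuous promoters more heavily.
* eQTL evidence is consumed as optional annotation only and never computed.
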