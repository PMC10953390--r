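# varloops

Linking GWAS risk variants to their candidate target genes with promoter
capture Hi-C (PCHi-C), in the cell types where the regulation actually
happens.

Most disease-associated variants found by GWAS sit in non-coding regions —
typically enhancers — and the gene they regulate is often not the nearest
one. PCHi-C maps which distal regions physically contact each baited gene
promoter, so a risk variant can be tied to a gene by asking whether it falls
inside a **promoter-interacting region** (PIR, the "other end" of a
significant promoter contact) that is also an enhancer in that cell type.
`varloops` implements this integrative analysis for processed PCHi-C outputs
in two immune cell types (CD4+ T cells and CD14+ monocytes by default),
together with two companion analyses:

1. **Allele-associated loops.** For phased heterozygous SNPs, per-allele read
   counts within each significant loop are tested per sample with an exact
   two-sided binomial test against 0.5; per-sample p-values are checked for a
   shared direction and combined with Fisher's method
   (chi² = −2 Σ ln pᵢ on 2m degrees of freedom), then FDR-controlled with
   Benjamini–Hochberg across (SNP, loop) pairs.
2. **Variant-to-gene assignment.** GWAS leads (p < 5×10⁻⁸) are expanded with
   LD proxies (r² > 0.8) and merged into loci; a candidate gene is a baited
   promoter whose PIR contains a risk SNP that also overlaps an enhancer of
   the same cell type, among interactions with CHiCAGO-style score > 5.
3. **Interaction/expression concordance.** Between cell types, genes with
   significant differential interactions (weighted adjusted p < 0.05) are
   tested for enrichment among differentially expressed genes (one-sided
   Fisher exact), their log₂ fold changes are rank-correlated (Spearman),
   and under a stringent cutoff (per-gene |median interaction log₂FC| > 2)
   sign concordance is tested with an exact binomial test against 0.5.

A seeded synthetic-data generator emulates every processed table the
pipeline consumes — interaction calls with distance-decaying scores and
planted cell-type-specific loops, binomial allele counts with planted
imbalance, LD blocks, enhancer segmentations, and negative-binomial
expression counts coupled to the planted loops — so the whole analysis is
testable end to end without any external download.

## Worked example

```r
library(varloops)

cfg <- sim_config(seed = 42)          # 10 patients + 5 controls, 2 cell types
bundle <- simulate_bundle(cfg)        # all tables, with planted truth

# allele-associated loops in CD4+ T cells
loops <- subset(bundle$interactions, cell_type == "CD4" & condition == "pooled")
calls <- call_imbalanced_loops(bundle$allelic$CD4$counts,
                               bundle$allelic$CD4$genotypes, loops)
print(calls)
#> Allele-associated loop calls
#>   (SNP, loop) pairs tested : 1000
#>   significant at q < 0.05 : 87
#>   distinct loops / SNPs    : 87 / 87
#>   distinct bait genes      : 64
```

Of the 1,000 testable SNP–loop pairs, 100 carry a planted allelic imbalance
(reference-allele read fraction 0.75); 87 reach q < 0.05, essentially all of
them planted (the acceptance run reports recall ≈ 0.86 at empirical
FDR < 0.01).

```r
# GWAS locus definition and candidate-gene assignment
snps <- expand_ld(bundle$gwas$leads, bundle$gwas$proxies)   # p<5e-8, r2>0.8
loci <- define_loci(snps)                                   # merge within 250 kb
cand <- map_snps_to_genes(snps, bundle$gwas$enhancers,
                          subset(bundle$interactions, condition == "pooled"),
                          loci = loci)
print(cand)
#> Candidate interacting genes (SNP x enhancer x PIR overlap)
#>   score threshold          : > 5
#>   qualifying interactions, CD14: 9
#>   qualifying interactions, CD4: 5
#>   candidate (locus, gene) rows: 9
```

Each candidate row names a locus, a gene and the cell types in which the
full SNP × enhancer × PIR rule holds; `cand$evidence` holds every supporting
(SNP, interaction, enhancer) triple, which re-validates against the raw
inputs.

```r
# concordance between differential interactions and differential expression
conc <- concordance_analysis(bundle$expression$expression, bundle$differential)
print(conc)
#> Differential interaction / expression concordance
#>   significant DE genes       : 49
#>   differentially interacting : 81
#>   overlap                    : 49
#>   Fisher enrichment OR, p    : Inf, 7.08e-77
#>   Spearman rho, p            : 0.959, 2.4e-27
#>   sign concordance           : 49/49 (p = 3.55e-15)
```

Genes overexpressed in one cell type show more chromatin interactions in
that cell type: here all 49 overlapping genes are sign-concordant, with a
rank correlation of 0.96 between the two effect sizes.

The full pipeline (all four stages plus a consolidated markdown/JSON report)
runs from one configuration object or YAML file:

```r
report <- run_pipeline(pipeline_config(simulate = cfg, seed = 42))
```

A thin command-line wrapper lives at `inst/cli/varloops.R`
(`Rscript varloops.R run --config config.yaml`).

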