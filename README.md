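# wingqtl

Multi-layer omics analysis of organ-size variation in panels of fully
inbred lines, modeled on the *Drosophila* wing and the DGRP design.

## The problem and who this is for

Wing size in flies varies in two distinct ways: between the sexes (females
are larger) and between genetically distinct lines within each sex. These
two axes can be driven by different regulatory systems, and telling them
apart requires jointly analysing genotypes, expression and phenotypes.
`wingqtl` is for quantitative geneticists working with inbred panels
(binary homozygous genotypes, replicated bulk RNA-seq per line and sex,
line-level size phenotypes) who want a tested, reusable implementation of
that analysis chain — plus a ground-truth cohort simulator to validate
every stage.

## What it computes

1. **Preprocessing** — library/count filtering, log2-CPM with
   mean-variance precision weights, principal-component batch removal
   (batch directions estimated from replicate residuals so line-level
   biology is untouched), replicate averaging, and replicate/cross-layer
   concordance QC.
2. **Trait–expression association** of three types, per gene, by weighted
   least squares with Benjamini–Hochberg FDR:
   - type 1: `expr ~ absCS` (both sexes pooled),
   - type 2: `expr ~ sex + absCS|relCS` (parallel-slopes ANCOVA — the
     between-line, within-sex signal),
   - type 3: `expr ~ sex` (sexual dimorphism),
   and the set logic classifying *exclusive type 1* / *confirmed type 3*
   genes.
3. **cis-eQTL mapping** per sex: MAF ≥ 10%, cis = same chromosome within
   ±100 kb of the gene body, per-pair regression on the allele indicator,
   gene-level permutation minimum-p correction (one shared label shuffle
   per round; corrected p = k/n_perm), empirical FDR
   `FDR(t) = t·G / #{p_corr ≤ t}`, TSS/TES density profiles and
   between-sex overlap summaries.
4. **Mediator genes and the unit-sign flow model** — genes passing both
   20% FDR criteria (type-2 association and eQTL mapping) whose variants
   also associate with the trait (p < 0.05) enter a model where each
   mediator-linked eQTL contributes `sign(beta_eqtl) × sign(slope)` per
   alternate allele; a line's **net score** is the plain sum. Scores are
   evaluated by rank correlation in-sample and by calibrated linear
   prediction (with 50/95% prediction intervals) on held-out lines.
5. **Synthetic cohorts** (`simulate_cohort()`) — inbred genotypes with
   blockwise LD, sexually dimorphic phenotypes, extreme-line selection
   from a measured pool, negative-binomial counts with batch structure,
   planted association types / cis-eQTLs / mediator loci, and a weakly
   coupled protein layer, all bitwise reproducible from one master seed.

## Worked example

```r
library(wingqtl)

co <- simulate_cohort(seed = 42)   # study-design defaults
co
#> wing_cohort (seed 42):
#>   pool: 160 lines; 32 selected, 128 holdout
#>   genome: 600 genes, 1500 variants
#>   counts: 600 genes x 128 samples
#>   planted: type1 = 30 type2 = 30 type3 = 60 eQTL = 60 mediators = 8

pl <- run_wing_pipeline(co, sex = "F", trait = "absCS",
                        n_perm = 200, seed = 1)
pl
#> wing_pipeline (F, absCS)
#>   type-2 genes at FDR < 0.2: 137
#>   cis eGenes: 82
#>   mediator genes: 11
#>   in-sample Spearman rho = 0.822 (p = 7.8e-09, n = 32)
#>   holdout Pearson r = 0.355 (p = 3.9e-05, n = 128)

head(pl$model$entries, 3)
#>          variant      gene eqtl_sign trait_sign net_sign
#> 1 2L_2162064_SNP gene_0049        -1          1       -1
#> 2 2L_2537107_SNP gene_0065         1          1        1
#> 3  2R_397897_SNP gene_0152        -1          1       -1
```

Reading the output: of the 600 simulated genes, 82 have a cis-eQTL at 20%
empirical FDR in females and 137 associate with female/male between-line
size at 20% BH FDR; 11 genes pass both criteria *and* the SNP-level trait
screen, so their linked eQTLs enter the flow model. Each model entry is one
eQTL reduced to a unit sign (e.g. the first row: the alternate allele
lowers expression of `gene_0049`, which is positively associated with
size, so carrying that allele contributes −1 to a line's predicted size).
Summing entries per line gives integer net scores whose ranking matches
observed wing size closely in the 32 profiled extreme lines (ρ = 0.82) and
still predicts size significantly in 128 unseen medium-size lines
(r = 0.36) — genotype alone, via mediator expression, carries real
information about organ size.

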