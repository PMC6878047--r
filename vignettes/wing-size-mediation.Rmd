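---
title: "From genotype to organ size: methods behind wingqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From genotype to organ size: methods behind wingqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingqtl)
```

# The scientific problem

Organ size in natural populations is polygenic, and in *Drosophila* it is
also strongly sexually dimorphic: females carry larger wings than males.
`wingqtl` implements a multi-layer analysis that separates the two kinds of
size variation — between sexes and between genetically distinct inbred
lines within a sex — and then asks whether the between-line component can be
predicted from genotype alone through *mediator genes*: genes whose
expression is under local genetic control (a cis-eQTL) **and** associated
with the size trait, with the eQTL alleles themselves associated with size.

The intended data are panels of fully inbred, fully sequenced lines (a
DGRP-style design): genotypes are homozygous and therefore binary per line,
expression is bulk RNA-seq of the larval wing imaginal disc measured per
line and sex with replicates, and the phenotypes are wing centroid size
(absCS) and a body-size-adjusted version (relCS, using the interocular
distance IOD as the body-size reference).

Because the full-design data are large and external, the package ships a
complete synthetic cohort generator with known ground truth. Every claim
the test-suite makes about power, calibration or recovery is made against
that generator.

# The analysis chain

## Preprocessing

Counts pass a sample filter (library size at least a fraction, default
0.25, of the median library — shallow failed libraries are removed and
logged) and then a gene filter: a gene is kept iff its total count reaches
70% of the number of samples. Expression is `log2 CPM` with a 0.5 count
offset and a `library + 1` denominator, so zeros stay finite.

**Precision weights.** Count data have strongly mean-dependent variance on
the log scale. We regress each gene on the line-by-sex design, smooth the
square root of the residual SD against the average log2 count with
`lowess`, evaluate the trend at each observation's fitted log2 count, and
use the fourth inverse power of the predicted value — an inverse-variance
weight — clipped to `[1e-3, 1e3]`. A unit-weight mode exists for ablation.
The weights behave like the familiar RNA-seq precision-weighting approach
(the test suite cross-checks the ranking of gene weights against an
independent `limma::voom` fit), but the implementation is self-contained.

**Batch removal.** Technical structure is removed by regressing every gene
on the leading sample-space principal components (default `k = 2`),
restoring gene means; the residual matrix is exactly orthogonal to the
removed scores. One design choice matters here and was made deliberately:
at the scale of the synthetic cohorts (hundreds of genes, a sixth of them
carrying planted effects), the dominant principal components of the *total*
expression matrix are the sex axis and the within-sex size axis, i.e. the
biology itself, and projecting them out destroys the signal the rest of the
pipeline is supposed to find. `remove_batch_pcs()` therefore estimates the
batch directions from the *replicate residual* matrix — expression minus
its line-by-sex mean — by default. Replicate disagreement contains library
and batch structure but cannot contain line-level biology, so the estimated
directions are safe to remove at any planted-effect density. The
total-matrix variant remains available via `protect_design = FALSE` for
data where technical variance clearly dominates.

Replicates are then averaged per line and sex; combined weights are the sum
of the replicate weights, the inverse variance of a mean of independent
observations.

**QC.** `concordance_report()` reproduces the standard reproducibility
diagnostics: pairwise Spearman correlations grouped into biological
replicates, same-line-other-sex pairs and non-replicates, and (cross-layer
mode) per-gene Spearman correlation between RNA and protein abundance
across shared line-by-sex units with a large-sample p-value.

## Three association types

All models are per-gene weighted least squares at line-by-sex resolution:

* **type 1** — `expr ~ absCS`, pooling sexes: genes tracking the whole size
  range, which is dominated by the sex difference;
* **type 2** — `expr ~ sex + trait` (parallel-slopes ANCOVA, trait = absCS
  or relCS): genes tracking between-line size variation *within* sexes;
* **type 3** — `expr ~ sex`: sexually dimorphic expression.

The reported p-value tests the size term (types 1, 2) or the sex term
(type 3). FDR is Benjamini–Hochberg, computed within each
(layer, model, trait) family over testable genes only, so undefined tests
do not deflate the adjusted values. `classify_association_types()` encodes
the set logic: genes significant for type 1 but neither type-2 family are
*exclusive type 1*, and those with a significant type-3 test as well are
*confirmed type 3* — the signature of genes whose apparent size association
is purely the sexual dimorphism.

The sex-by-trait interaction is off by default (the parallel-slopes model
is the stated analysis); an interaction mode exists for exploration.

## cis-eQTL mapping with permutation min-p correction

Mapping is per sex on line-level expression. Variants need MAF ≥ 0.10
(computed over non-missing lines, boundary kept). A variant is *cis* to a
gene iff it lies on the same chromosome within ±100 kb of the gene body,
inclusive; everything else is *trans* (implemented, chunked, and off by
default — at 32 lines the multiple-testing burden makes trans discoveries
implausible, and the scan exists mainly for completeness).

The nominal scan is a simple regression of expression on the 0/1 allele
indicator; missing calls drop the line from that pair only (inbred calls
are either confident or absent — no imputation). Internally variants are
grouped by missingness pattern so the scan runs as dense matrix products,
and the per-gene minimum p is obtained from the maximum squared correlation
within each pattern group, which is orders of magnitude faster than
materializing every p-value during permutations.

Gene-level correction follows the permutation min-p scheme: the line
labels of the whole expression matrix are shuffled once per round — the
same shuffle for every gene, preserving gene–gene correlation — and each
gene's observed minimum p is compared with its permutation minima. The
corrected p is the plain ratio `k / n_perm` (number of permutation minima
strictly smaller, over rounds). The ratio can be exactly zero; a
positively biased `(k + 1) / (n_perm + 1)` variant is available behind
`count_adjust = TRUE`, but the plain ratio is the default because it is
the stated procedure of the analysis this package reproduces.

The empirical FDR at threshold `t` is `t * G / #{corrected p <= t}` with
`G` the family size; the reported threshold is the largest grid value at or
under the target (default 20%). Variant-level reporting follows the min-p
convention: for each significant gene, all tested variants whose nominal p
does not exceed the gene's permutation-derived nominal threshold (the
`floor(t * n_perm)`-th smallest permutation minimum) are reported, and the
top variant always is. Whether a study should report all sub-threshold
variants or only the top SNP per gene is genuinely ambiguous; this
convention is the switchable default and the per-gene counts are visible
in the output either way.

With 200 permutations the corrected-p resolution is 0.005, adequate for a
20% FDR target; the function warns when `n_perm` is too small for the
requested resolution.

## Mediators and the unit-sign flow model

For one condition (sex × trait), mediator candidates are genes passing
**both** 20% FDR criteria — the type-2 association and the gene-level eQTL
mapping — with their supporting variants carried forward. The variants are
then screened directly against the trait (per-sex regression of the line
trait on the allele indicator, retain p < 0.05, R² reported). Since a gene
can qualify for both absCS and relCS, both screens are computed; each
condition keeps its own mediator set.

The flow model reduces every retained (variant, gene) pair to unit-strength
signs: `eqtl_sign = sign(beta_eqtl)`, `trait_sign = sign(type-2 slope)`,
`net_sign` their product — the expected direction of the alternate allele's
effect on size. A line's **net score** sums `net_sign` over entries whose
alternate allele it carries; reference calls contribute zero, missing calls
contribute zero and are counted. All linked eQTLs of a gene enter the sum
(the model sums eQTL effects, not gene effects); a one-top-SNP-per-gene
restriction can be emulated by pre-filtering the selection table.

Evaluation is rank-based in-sample (Spearman ρ of net score vs the observed
trait — raw scores, no calibration, since ranks are invariant to any
monotone calibration) and linear for holdout prediction: a univariate least
squares calibration `trait ~ net_score` fitted on the training lines,
applied to unseen lines, with 50% and 95% prediction intervals from the
residual variance. Training/holdout disjointness is enforced.

# The synthetic cohort generator

`simulate_cohort()` emulates the extreme-line design end to end:

* a measured pool of lines (default 160) with homozygous genotypes, target
  MAF uniform in [0.1, 0.5], blockwise LD (variants within a 20 kb block
  copy a block haplotype with flip probability `(1 - 0.9)/2`; the block
  anchor meets its target MAF exactly) and 2% missing calls;
* phenotypes `absCS = 180 + 15·[female] + Σ mediator-SNP effects +
  line effect (SD 4) + noise (SD 1)` in centroid-size units, IOD partially
  coupled to absCS (within-sex correlation ≈ 0.5), and relCS as the
  per-sex residual of absCS on IOD plus the per-sex mean — a stand-in
  convention chosen to keep relCS in centroid-size units, and flagged as
  such in the written `config.yaml`;
* selection of the 16 largest and 16 smallest lines by sex-centred mean
  absCS as the expression cohort; the remaining medium lines form the
  holdout panel;
* negative binomial counts (gene-wise dispersion log-normal around 0.15,
  two replicates per line and sex split across two library batches, batch
  shift SD 0.3 log2) on top of an additive log2 latent structure: baseline
  uniform in [3, 9], sex effects (types 1, 3; magnitude 0.8–1.5 log2),
  size slopes (types 1, 2; 0.06–0.12 log2 per CS unit), cis-eQTL allele
  effects (1.2–1.8 log2) planted on common variants weighted towards the
  transcript start/end, and 8 mediator loci whose alleles shift absCS by
  3.5 CS units in the direction consistent with their eQTL and slope signs;
* a protein layer generated directly on the abundance scale, weakly
  coupled (attenuation 0.4 against unit-SD noise) to the same latent
  structure, reproducing the weak RNA–protein concordance regime.

Two parameter choices deserve their rationale spelled out. First,
**extreme-line selection is part of the design**, not an optimisation:
profiling the phenotypic tails of a larger measured pool is what makes a
per-sex SNP–trait screen at n = 32 workable at all, because selection on
the phenotype inflates the genotype–phenotype R² of causal loci roughly in
proportion to the variance inflation of the selected tails. Consequently
in-sample rank correlations are high (≈ 0.7–0.9) while holdout correlations
on the medium-size lines are much lower (≈ 0.2–0.35) — exactly the pattern
such designs produce in practice. Second, the **8 mediator loci jointly
explain roughly half of the between-line trait variance**
(8 × 3.5² × mean p(1−p) ≈ 21 CS² against a non-genetic line variance of
16 CS²), a broad-sense heritability in the range reported for fly wing
traits; weaker planted effects would make the screen step the power
bottleneck, which is a property of the n = 32 design, not of the code.

A master seed drives everything; submodule seeds are derived by hashing a
fixed label with the seed (`derive_seed`), so cohorts are bitwise
reproducible and components can be regenerated independently.

What the generator does **not** emulate: read-level artefacts (alignment,
UMI structure, barcode bleed), dominance or epistasis, population
structure/relatedness among lines, trans-regulatory hubs, and
compositional effects beyond the mechanical one (planted shifts do change
library totals, so log-CPM of null genes acquires a small common
size-correlated component — visible in planted cohorts as mild inflation
of null type-2 tests, and absent in null cohorts, which is where type-I
calibration is asserted). Passing tests therefore demonstrate the
statistical machinery is correct under an idealized bulk RNA-seq noise
model, not that real wing-disc data meet these assumptions.

# Numerical choices and degenerate inputs

* All single-coefficient tests convert a squared correlation and residual
  df to p via the F(1, df) tail, which is algebraically the two-sided t
  test; exact fits give p = 0 rather than NaN.
* Genes with constant expression, traits with no variance, or fewer than 4
  units are flagged untestable (`NA`) and excluded from their FDR family.
* Monomorphic variants (after missing-call removal) are skipped and
  counted, never imputed.
* Spearman statistics use average ranks for ties and a large-sample t
  approximation for p.
* The lowess weight trend is clipped to `[1e-3, 1e3]` to keep a single
  all-but-constant gene from dominating a weighted fit.
* BH adjustment is delegated to `stats::p.adjust`; note the step-up is
  *not* idempotent in general (re-adjusting adjusted values changes them),
  so adjusted values are computed exactly once per family.
* `empirical_fdr` skips grid points with zero passers rather than
  reporting a 0/0 FDR.

# Problem sizes used by the shipped studies

The test suite and `scripts/acceptance.R` run cohorts of 80–2,000 genes,
300–1,500 variants, pools of 24–160 lines with 32-line expression cohorts,
and 100–200 permutation rounds. These sizes were chosen so that every
statistical property under test (type-I error in [0.04, 0.06], KS of
corrected p < 0.07, FDP/sensitivity at 20% FDR, mediator recovery across
seeds) is measured with meaningful resolution on a single desk-class CPU;
scaling any of them up is a matter of the corresponding arguments, not of
code changes.

# Known limitations

* The permutation machinery assumes exchangeable lines under the null;
  related lines or shared environment blocks would need a restricted
  permutation scheme that is not implemented.
* The verbatim `k / n_perm` corrected p can be zero, which makes the
  empirical FDR threshold grid-dependent at the low end; the
  `count_adjust` mode avoids zeros at the cost of a positive bias.
* The unit-sign score deliberately discards effect magnitudes; it is a
  reproduction of the flow-model idea, not a tuned polygenic score, and
  regularized multi-SNP prediction is explicitly out of scope.
* relCS uses a residual-based stand-in convention; analyses that depend on
  the precise body-size adjustment of a given study should substitute
  their own definition before comparing numbers.
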