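# Synthetic cohort generator: genome annotation, inbred genotypes, phenotypes,
# RNA-seq counts and a protein layer, with a ground-truth table for
# parameter-recovery studies. The generator emulates the statistical structure
# of an extreme-line inbred panel design: homozygous binary genotypes with
# blockwise LD, sexually dimorphic size phenotypes (female > male), negative
# binomial counts with batch structure, planted trait-expression associations
# of three types, cis-eQTLs concentrated near transcript ends, and mediator
# loci whose alleles shift both a transcript and the size trait.

#' Generate a scaled-down genome annotation and variant positions
#'
#' Places `n_genes` non-overlapping gene intervals and `n_variants` uniform
#' SNP positions on a small set of chromosomes. Genes and variants are
#' apportioned to chromosomes proportionally to length.
#'
#' @param n_genes,n_variants number of genes / biallelic SNPs (both >= 1).
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param gene_length_range range (bp) from which gene lengths are drawn.
#' @param seed master seed; the genome stream is derived from it.
#' @return a list with elements `genes` (data.frame: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`) and `variants` (data.frame: `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `maf`; `maf` is `NA` until genotypes are
#'   drawn). Intervals are 1-based inclusive.
#' @export
generate_genome <- function(n_genes, n_variants,
                            chrom_lengths = c("2L" = 5e6, "2R" = 5e6,
                                              "3L" = 5e6, "3R" = 5e6,
                                              "X" = 5e6),
                            gene_length_range = c(1000, 8000),
                            seed = 1L) {
  if (!is.numeric(n_genes) || n_genes < 1) stop("n_genes must be >= 1")
  if (!is.numeric(n_variants) || n_variants < 1) stop("n_variants must be >= 1")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  set.seed(derive_seed(seed, "genome"))

  share <- chrom_lengths / sum(chrom_lengths)
  n_per <- drop(stats::rmultinom(1, n_genes, share))
  v_per <- drop(stats::rmultinom(1, n_variants, share))

  genes <- vector("list", length(chrom_lengths))
  for (i in seq_along(chrom_lengths)) {
    k <- n_per[i]
    if (k == 0) next
    cname <- names(chrom_lengths)[i]
    L <- chrom_lengths[i]
    len <- round(stats::runif(k, gene_length_range[1], gene_length_range[2]))
    slack <- L - sum(len) - (k + 1)      # >= 1 bp gap flanking every gene
    if (slack < 0)
      stop("chromosome ", cname, " (", L, " bp) is too short to place ", k,
           " genes of total length ", sum(len), " bp")
    w <- stats::rexp(k + 1)
    gaps <- 1 + floor(slack * w / sum(w))
    # cumulative layout: gap1 gene1 gap2 gene2 ...
    start <- numeric(k)
    pos <- 0
    for (g in seq_len(k)) {
      pos <- pos + gaps[g]
      start[g] <- pos + 1
      pos <- pos + len[g]
    }
    genes[[i]] <- data.frame(
      gene_id = character(k), chrom = cname,
      start = start, end = start + len - 1,
      strand = sample(c("+", "-"), k, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  genes <- do.call(rbind, genes[!vapply(genes, is.null, logical(1))])
  rownames(genes) <- NULL
  genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))

  vars <- vector("list", length(chrom_lengths))
  for (i in seq_along(chrom_lengths)) {
    k <- v_per[i]
    if (k == 0) next
    cname <- names(chrom_lengths)[i]
    pos <- sort(sample.int(chrom_lengths[i], k))
    ref <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    vars[[i]] <- data.frame(
      variant_id = paste(cname, pos, "SNP", sep = "_"),
      chrom = cname, pos = pos, ref = ref, alt = alt, maf = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  vars <- do.call(rbind, vars[!vapply(vars, is.null, logical(1))])
  rownames(vars) <- NULL

  list(genes = genes, variants = vars)
}

#' Draw homozygous inbred genotypes with blockwise linkage disequilibrium
#'
#' Each variant is coded 0 (homozygous reference) / 1 (homozygous alternate)
#' per line, with `NA` for missing calls, emulating fully inbred panel lines.
#' Variants falling in the same `ld_block` window share a block haplotype that
#' each variant copies with a per-line flip probability `(1 - ld_corr) / 2`,
#' reproducing the tight local linkage seen in natural inbred panels;
#' `ld_corr = 1` makes variants in a block identical, `ld_block = 0` makes all
#' variants independent.
#'
#' @param variants variant table from [generate_genome()].
#' @param n_lines number of inbred lines (>= 2).
#' @param maf_range interval within (0, 0.5] from which each variant's target
#'   minor allele frequency is drawn.
#' @param ld_block LD block width in bp (0 = independent variants).
#' @param ld_corr within-block haplotype fidelity in `[0, 1]`.
#' @param missing_rate per-call missingness probability in `[0, 1)`.
#' @param seed master seed.
#' @return an object of class `genotype_set`: list with `lines` (ids),
#'   `calls` (lines x variants integer matrix, 0/1/NA) and `variants`
#'   (the variant table with realized `maf` over non-missing lines).
#' @export
generate_genotypes <- function(variants, n_lines, maf_range = c(0.1, 0.5),
                               ld_block = 20000, ld_corr = 0.9,
                               missing_rate = 0.02, seed = 1L) {
  if (n_lines < 2) stop("n_lines must be >= 2")
  .assert_frac(missing_rate, "missing_rate")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  .assert_frac(ld_corr, "ld_corr", hi_open = FALSE)
  set.seed(derive_seed(seed, "genotypes"))

  nv <- nrow(variants)
  calls <- matrix(NA_integer_, n_lines, nv)
  flip_p <- (1 - ld_corr) / 2
  block <- if (ld_block > 0) {
    paste(variants$chrom, variants$pos %/% ld_block)
  } else {
    as.character(seq_len(nv))
  }
  for (idx in split(seq_len(nv), block)) {
    p0 <- stats::runif(1, maf_range[1], maf_range[2])
    anchor <- stats::rbinom(n_lines, 1, p0)
    calls[, idx[1]] <- as.integer(anchor)   # the anchor meets its target MAF
    for (j in idx[-1]) {
      if (flip_p > 0) {
        flips <- stats::rbinom(n_lines, 1, flip_p)
        calls[, j] <- as.integer((anchor + flips) %% 2L)
      } else {
        calls[, j] <- as.integer(anchor)
      }
    }
  }
  if (missing_rate > 0) {
    calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
  }
  lines <- sprintf("line_%03d", seq_len(n_lines))
  dimnames(calls) <- list(lines, variants$variant_id)

  f <- colMeans(calls, na.rm = TRUE)
  variants$maf <- pmin(f, 1 - f)

  structure(list(lines = lines, calls = calls, variants = variants),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("genotype_set:", length(x$lines), "inbred lines x",
      ncol(x$calls), "biallelic variants\n")
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Subset a genotype_set by variants and/or lines
#'
#' @param geno a `genotype_set`.
#' @param variants logical/integer/character selector of variants.
#' @param lines character vector of line ids to keep.
#' @return the subset `genotype_set` (MAF recomputed).
#' @export
subset_genotypes <- function(geno, variants = NULL, lines = NULL) {
  calls <- geno$calls
  vtab <- geno$variants
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, vtab$variant_id)
    calls <- calls[, variants, drop = FALSE]
    vtab <- vtab[variants, , drop = FALSE]
    rownames(vtab) <- NULL
  }
  line_ids <- geno$lines
  if (!is.null(lines)) {
    calls <- calls[lines, , drop = FALSE]
    line_ids <- rownames(calls)
  }
  f <- colMeans(calls, na.rm = TRUE)
  vtab$maf <- pmin(f, 1 - f)
  structure(list(lines = line_ids, calls = calls, variants = vtab),
            class = "genotype_set")
}

#' Build the ground-truth table of planted effects
#'
#' Assigns association types to genes, plants cis-eQTLs near transcript start
#' or end sites, and designates mediator loci: genes carrying both a planted
#' within-sex size association (type 2) and a planted cis-eQTL whose variant
#' additionally shifts the size trait. The direction of the planted phenotype
#' effect is `sign(eQTL beta) * sign(expression-size slope)`, so that the
#' triangular association is causally coherent and the expected unit-sign net
#' effect of the alternate allele is known.
#'
#' @param genome output of [generate_genome()].
#' @param geno `genotype_set`; used to pick common planted variants.
#' @param n_type1,n_type2,n_type3 planted gene counts for the three
#'   association types (disjoint sets; mediator genes count towards
#'   `n_type2`).
#' @param n_eqtl planted cis-eQTL genes (includes mediator genes).
#' @param n_mediators number of mediator loci.
#' @param slope_range absolute within-sex slope range, log2 expression units
#'   per centroid-size unit.
#' @param sex_effect_range absolute sex effect range, log2 units.
#' @param beta_eqtl_range absolute eQTL allele effect range, log2 units.
#' @param beta_pheno absolute phenotype effect of each mediator allele,
#'   centroid-size units.
#' @param cis_window bp window around the gene within which planted eQTL
#'   variants are placed.
#' @param min_planted_maf minimum MAF of planted variants.
#' @param seed master seed.
#' @return an object of class `truth_table`: list with data.frames `genes`
#'   (`gene_id`, `assoc_type` in `{1,2,3,none}`, `sex_effect`, `slope`),
#'   `eqtls` (`gene_id`, `variant_id`, `beta`) and `mediators` (`gene_id`,
#'   `variant_id`, `beta_pheno`, `net_sign`).
#' @export
make_truth_table <- function(genome, geno,
                             n_type1 = 0, n_type2 = 0, n_type3 = 0,
                             n_eqtl = 0, n_mediators = 0,
                             slope_range = c(0.06, 0.12),
                             sex_effect_range = c(0.8, 1.5),
                             beta_eqtl_range = c(1.2, 1.8),
                             beta_pheno = 3.5,
                             cis_window = 1e5,
                             min_planted_maf = 0.2,
                             seed = 1L) {
  set.seed(derive_seed(seed, "truth"))
  genes <- genome$genes
  vtab <- geno$variants
  G <- nrow(genes)
  if (n_mediators > n_type2) stop("n_mediators cannot exceed n_type2")
  if (n_mediators > n_eqtl) stop("n_mediators cannot exceed n_eqtl")
  if (n_type1 + n_type2 + n_type3 > G)
    stop("more planted genes than genes in the genome")

  # candidate planted variant per gene: common SNP near TSS/TES, weighted
  # towards the transcript ends to emulate the observed eQTL density
  pick_cis_variant <- function(gi) {
    g <- genes[gi, ]
    cand <- which(vtab$chrom == g$chrom &
                    vtab$pos >= g$start - cis_window &
                    vtab$pos <= g$end + cis_window &
                    !is.na(vtab$maf) & vtab$maf >= min_planted_maf)
    if (!length(cand)) return(NA_integer_)
    d <- pmin(abs(vtab$pos[cand] - g$start), abs(vtab$pos[cand] - g$end))
    w <- exp(-d / 2e4)
    cand[sample.int(length(cand), 1, prob = w)]
  }

  eligible <- which(vapply(seq_len(G), function(gi) {
    g <- genes[gi, ]
    any(vtab$chrom == g$chrom &
          vtab$pos >= g$start - cis_window & vtab$pos <= g$end + cis_window &
          !is.na(vtab$maf) & vtab$maf >= min_planted_maf)
  }, logical(1)))
  if (n_eqtl > length(eligible))
    stop("not enough genes with a common cis variant to plant ", n_eqtl,
         " eQTLs")

  eqtl_genes <- sample(eligible, n_eqtl)
  med_genes <- if (n_mediators > 0) sample(eqtl_genes, n_mediators) else integer(0)
  rest <- setdiff(seq_len(G), med_genes)
  type2_extra <- sample(rest, n_type2 - n_mediators)
  rest <- setdiff(rest, type2_extra)
  type1_genes <- sample(rest, min(n_type1, length(rest)))
  rest <- setdiff(rest, type1_genes)
  type3_genes <- sample(rest, min(n_type3, length(rest)))
  type2_genes <- c(med_genes, type2_extra)

  assoc_type <- rep("none", G)
  assoc_type[type1_genes] <- "1"
  assoc_type[type2_genes] <- "2"
  assoc_type[type3_genes] <- "3"

  rsign <- function(n) sample(c(-1, 1), n, replace = TRUE)
  slope <- numeric(G)
  sex_effect <- numeric(G)
  has_slope <- assoc_type %in% c("1", "2")
  has_sex <- assoc_type %in% c("1", "3")
  slope[has_slope] <- rsign(sum(has_slope)) *
    stats::runif(sum(has_slope), slope_range[1], slope_range[2])
  sex_effect[has_sex] <- rsign(sum(has_sex)) *
    stats::runif(sum(has_sex), sex_effect_range[1], sex_effect_range[2])

  eqtl_variant <- vapply(eqtl_genes, pick_cis_variant, integer(1))
  ok <- !is.na(eqtl_variant)
  eqtl_genes <- eqtl_genes[ok]
  eqtl_variant <- eqtl_variant[ok]
  beta <- rsign(length(eqtl_genes)) *
    stats::runif(length(eqtl_genes), beta_eqtl_range[1], beta_eqtl_range[2])
  eqtls <- data.frame(
    gene_id = genes$gene_id[eqtl_genes],
    variant_id = vtab$variant_id[eqtl_variant],
    beta = beta, stringsAsFactors = FALSE
  )

  med_idx <- match(genes$gene_id[med_genes], eqtls$gene_id)
  if (anyNA(med_idx))
    stop("internal error: a mediator gene lost its planted eQTL")
  net_sign <- sign(eqtls$beta[med_idx]) *
    sign(slope[med_genes])
  mediators <- data.frame(
    gene_id = eqtls$gene_id[med_idx],
    variant_id = eqtls$variant_id[med_idx],
    beta_pheno = beta_pheno * net_sign,
    net_sign = net_sign, stringsAsFactors = FALSE
  )

  out <- structure(list(
    genes = data.frame(gene_id = genes$gene_id, assoc_type = assoc_type,
                       sex_effect = sex_effect, slope = slope,
                       stringsAsFactors = FALSE),
    eqtls = eqtls, mediators = mediators
  ), class = "truth_table")
  validate_truth_table(out)
  out
}

#' @rdname make_truth_table
#' @param truth a `truth_table` to validate.
#' @export
validate_truth_table <- function(truth) {
  med <- truth$mediators
  if (nrow(med)) {
    t2 <- truth$genes$gene_id[truth$genes$assoc_type == "2"]
    if (!all(med$gene_id %in% t2))
      stop("every mediator gene must carry a planted type-2 association")
    key <- paste(med$gene_id, med$variant_id)
    ekey <- paste(truth$eqtls$gene_id, truth$eqtls$variant_id)
    if (!all(key %in% ekey))
      stop("every mediator must be backed by a planted cis-eQTL")
  }
  invisible(truth)
}

#' Generate sexually dimorphic size phenotypes for a line panel
#'
#' Absolute centroid size is built additively: a baseline, a positive female
#' offset (`sex_dimorphism`), planted mediator SNP effects, a Gaussian
#' between-line effect and residual noise. The interocular distance (IOD) is
#' partially coupled to absCS, and relative centroid size (relCS) is computed
#' as the per-sex residual of absCS regressed on IOD plus the per-sex mean,
#' which keeps relCS on the centroid-size scale while adjusting for body size
#' (see [adjust_relative_size()]).
#'
#' @param lines character vector of line ids.
#' @param sex_dimorphism female minus male mean absCS, centroid-size units.
#' @param line_sd SD of the Gaussian between-line effect (>= 0).
#' @param mediator_truth `truth_table` (or `NULL`) providing planted SNP
#'   effects on the trait.
#' @param geno `genotype_set` covering `lines` (required when mediator
#'   effects are planted). Missing calls contribute no effect.
#' @param seed master seed.
#' @param baseline intercept absCS.
#' @param noise_sd residual (within line x sex) noise SD.
#' @param iod_base,iod_sex,iod_coupling,iod_noise_sd IOD model: baseline,
#'   female offset, coupling to sex-centred absCS, and noise SD.
#' @return a `data.frame` (class `phenotype_table`) with one row per
#'   line x sex and columns `line`, `sex`, `absCS`, `IOD`, `relCS`.
#' @export
generate_phenotypes <- function(lines, sex_dimorphism = 15, line_sd = 4,
                                mediator_truth = NULL, geno = NULL, seed = 1L,
                                baseline = 180, noise_sd = 1,
                                iod_base = 30, iod_sex = 2,
                                iod_coupling = 0.15, iod_noise_sd = 0.8) {
  if (line_sd < 0) stop("line_sd must be >= 0")
  set.seed(derive_seed(seed, "phenotypes"))
  n <- length(lines)
  line_eff <- stats::rnorm(n, 0, line_sd)

  snp_eff <- numeric(n)
  med <- if (!is.null(mediator_truth)) mediator_truth$mediators else NULL
  if (!is.null(med) && nrow(med)) {
    if (is.null(geno)) stop("geno is required when mediator effects are planted")
    miss <- setdiff(med$variant_id, colnames(geno$calls))
    if (length(miss))
      stop("mediator variants absent from genotypes: ",
           paste(miss, collapse = ", "))
    calls <- geno$calls[lines, med$variant_id, drop = FALSE]
    calls[is.na(calls)] <- 0L
    snp_eff <- drop(calls %*% med$beta_pheno)
  }

  ph <- expand.grid(line = lines, sex = c("F", "M"), stringsAsFactors = FALSE)
  ph <- ph[order(ph$line, ph$sex), ]
  rownames(ph) <- NULL
  i <- match(ph$line, lines)
  is_f <- ph$sex == "F"
  ph$absCS <- baseline + sex_dimorphism * is_f + line_eff[i] + snp_eff[i] +
    stats::rnorm(nrow(ph), 0, noise_sd)
  sex_mean <- stats::ave(ph$absCS, ph$sex)
  ph$IOD <- iod_base + iod_sex * is_f + iod_coupling * (ph$absCS - sex_mean) +
    stats::rnorm(nrow(ph), 0, iod_noise_sd)
  ph <- adjust_relative_size(ph)
  class(ph) <- c("phenotype_table", "data.frame")
  ph
}

#' Compute relative size adjusted for body size
#'
#' Relative centroid size is defined here as the per-sex residual of absCS
#' regressed on the interocular distance (IOD), shifted back by the per-sex
#' mean absCS. This keeps relCS in centroid-size units and preserves the sex
#' offset while removing the component of wing size explained by body size.
#'
#' @param pheno data.frame with `sex`, `absCS`, `IOD` columns.
#' @return the input with a `relCS` column (re)computed.
#' @export
adjust_relative_size <- function(pheno) {
  stopifnot(all(c("sex", "absCS", "IOD") %in% names(pheno)))
  pheno$relCS <- NA_real_
  for (s in unique(pheno$sex)) {
    i <- pheno$sex == s & is.finite(pheno$absCS) & is.finite(pheno$IOD)
    fit <- stats::lm(absCS ~ IOD, data = pheno[i, ])
    pheno$relCS[i] <- stats::residuals(fit) + mean(pheno$absCS[i])
  }
  pheno
}

#' Generate an RNA-seq count matrix from planted truth
#'
#' Per-gene latent log2 expression is additive: a baseline drawn per gene, a
#' sex term (association types 1 and 3), a slope times the line x sex size
#' trait (types 1 and 2), planted eQTL allele effects, a per-gene batch shift
#' applied to the second library batch, and an optional clonal (between-line)
#' expression effect. Counts are drawn negative binomially with a gene-wise
#' dispersion around `dispersion`, with library sizes jittered per sample.
#'
#' @param truth `truth_table` covering all genes to simulate.
#' @param pheno `phenotype_table` covering the simulated lines.
#' @param geno `genotype_set` holding the planted eQTL variants.
#' @param n_replicates biological replicates per line x sex (>= 1). Replicate
#'   r is assigned to library batch `((r - 1) %% 2) + 1`.
#' @param batch_effect SD of the per-gene log2 shift of batch 2.
#' @param dispersion central NB dispersion (gene-wise, log-normal spread).
#' @param seed master seed.
#' @param lines lines to simulate (default: all lines in `geno`).
#' @param lib_size mean library size; per-sample sizes are jittered.
#' @param base_range range of per-gene baseline log2 expression.
#' @param line_effect_sd SD of an optional clonal expression effect shared by
#'   replicates and sexes of a line (default 0: between-line expression
#'   variation arises only from planted genetic effects).
#' @return an object of class `count_set`: list with `counts` (genes x
#'   samples integer matrix) and `samples` (data.frame: `sample_id`, `line`,
#'   `sex`, `replicate`, `batch`).
#' @export
generate_expression <- function(truth, pheno, geno, n_replicates = 2,
                                batch_effect = 0.3, dispersion = 0.15,
                                seed = 1L, lines = NULL, lib_size = 1.5e6,
                                base_range = c(3, 9), line_effect_sd = 0) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  set.seed(derive_seed(seed, "expression"))
  lines <- lines %||% geno$lines
  if (!all(lines %in% geno$lines)) stop("unknown lines requested")
  tg <- truth$genes
  G <- nrow(tg)

  miss_v <- setdiff(truth$eqtls$variant_id, colnames(geno$calls))
  if (length(miss_v))
    stop("truth references variants absent from genotypes: ",
         paste(miss_v, collapse = ", "))
  if (!all(truth$eqtls$gene_id %in% tg$gene_id))
    stop("truth eQTL table references unknown genes")

  samples <- expand.grid(replicate = seq_len(n_replicates),
                         sex = c("F", "M"), line = lines,
                         stringsAsFactors = FALSE)[, 3:1]
  samples$batch <- ((samples$replicate - 1L) %% 2L) + 1L
  samples$sample_id <- paste(samples$line, samples$sex, samples$replicate,
                             sep = "_")
  S <- nrow(samples)

  mu0 <- stats::runif(G, base_range[1], base_range[2])
  disp <- dispersion * exp(stats::rnorm(G, 0, 0.3))
  b_batch <- stats::rnorm(G, 0, batch_effect)

  key <- paste(pheno$line, pheno$sex)
  abs_cs <- pheno$absCS[match(paste(samples$line, samples$sex), key)]
  if (anyNA(abs_cs)) stop("phenotypes missing for some simulated line x sex")
  abs_c <- abs_cs - mean(abs_cs)
  is_f <- samples$sex == "F"

  lat <- matrix(mu0, G, S)
  lat <- lat + tg$sex_effect %o% as.numeric(is_f)
  lat <- lat + tg$slope %o% abs_c
  lat <- lat + b_batch %o% as.numeric(samples$batch == 2L)
  if (line_effect_sd > 0) {
    le <- matrix(stats::rnorm(G * length(lines), 0, line_effect_sd),
                 G, length(lines), dimnames = list(NULL, lines))
    lat <- lat + le[, samples$line, drop = FALSE]
  }
  if (nrow(truth$eqtls)) {
    gi <- match(truth$eqtls$gene_id, tg$gene_id)
    calls <- geno$calls[samples$line, truth$eqtls$variant_id, drop = FALSE]
    calls[is.na(calls)] <- 0L
    for (k in seq_len(nrow(truth$eqtls))) {
      lat[gi[k], ] <- lat[gi[k], ] + truth$eqtls$beta[k] * calls[, k]
    }
  }

  rel <- 2^lat
  frac <- sweep(rel, 2, colSums(rel), "/")
  libs <- lib_size * stats::runif(S, 0.7, 1.3)
  mu <- sweep(frac, 2, libs, "*")
  counts <- matrix(stats::rnbinom(G * S, mu = mu, size = rep(1 / disp, S)),
                   G, S)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(tg$gene_id, samples$sample_id)

  structure(list(counts = counts,
                 samples = samples[, c("sample_id", "line", "sex",
                                       "replicate", "batch")]),
            class = "count_set")
}

#' @export
print.count_set <- function(x, ...) {
  cat("count_set:", nrow(x$counts), "genes x", ncol(x$counts), "samples (",
      length(unique(x$samples$line)), "lines,",
      length(unique(x$samples$batch)), "batches )\n")
  invisible(x)
}

#' Generate a protein abundance layer coupled to the planted truth
#'
#' Protein abundances are generated directly on the (log) abundance scale at
#' line x sex resolution for a random subset of genes: the planted genetic
#' structure (sex effects, size slopes, eQTL alleles) enters attenuated by
#' `coupling`, on top of dominant independent noise. With the defaults the
#' per-gene RNA-protein correlation is weak, emulating the modest concordance
#' observed between transcript and protein layers.
#'
#' @param truth,pheno,geno as in [generate_expression()].
#' @param lines lines to cover (default all in `geno`).
#' @param frac fraction of genes quantified at the protein level.
#' @param coupling attenuation of the shared genetic signal in `[0, 1]`.
#' @param noise_sd SD of the independent protein noise.
#' @param seed master seed.
#' @return matrix genes x (line_sex) of log2 protein abundance.
#' @export
generate_protein <- function(truth, pheno, geno, lines = NULL, frac = 0.25,
                             coupling = 0.4, noise_sd = 1, seed = 1L) {
  set.seed(derive_seed(seed, "protein"))
  lines <- lines %||% geno$lines
  tg <- truth$genes
  keep <- sort(sample.int(nrow(tg), max(2, round(frac * nrow(tg)))))

  units <- expand.grid(sex = c("F", "M"), line = lines,
                       stringsAsFactors = FALSE)[, 2:1]
  key <- paste(pheno$line, pheno$sex)
  abs_cs <- pheno$absCS[match(paste(units$line, units$sex), key)]
  abs_c <- abs_cs - mean(abs_cs)
  is_f <- units$sex == "F"

  sig <- tg$sex_effect[keep] %o% as.numeric(is_f) + tg$slope[keep] %o% abs_c
  eq <- truth$eqtls[truth$eqtls$gene_id %in% tg$gene_id[keep], , drop = FALSE]
  if (nrow(eq)) {
    gi <- match(eq$gene_id, tg$gene_id[keep])
    calls <- geno$calls[units$line, eq$variant_id, drop = FALSE]
    calls[is.na(calls)] <- 0L
    for (k in seq_len(nrow(eq))) sig[gi[k], ] <- sig[gi[k], ] + eq$beta[k] * calls[, k]
  }
  base <- stats::runif(length(keep), 10, 16)
  out <- base + coupling * sig +
    matrix(stats::rnorm(length(sig), 0, noise_sd), nrow(sig), ncol(sig))
  dimnames(out) <- list(tg$gene_id[keep], paste(units$line, units$sex, sep = "_"))
  out
}

#' Select extreme-size lines from a measured pool
#'
#' Ranks lines by their sex-centred mean absCS and returns the
#' `n_select / 2` smallest and largest lines (the expression cohort) together
#' with the remaining medium-size lines (the holdout set), mirroring an
#' extreme-phenotype sequencing design.
#'
#' @param pheno `phenotype_table` for the pool.
#' @param n_select even number of lines to select.
#' @return list with `selected` and `holdout` character vectors of line ids
#'   and the ranking data.frame `ranking`.
#' @export
select_extreme_lines <- function(pheno, n_select = 32) {
  lines <- unique(pheno$line)
  if (n_select %% 2 != 0) stop("n_select must be even")
  if (n_select > length(lines)) stop("n_select exceeds pool size")
  dev <- pheno$absCS - stats::ave(pheno$absCS, pheno$sex)
  score <- tapply(dev, pheno$line, mean)[lines]
  ord <- order(score)
  half <- n_select / 2
  sel <- lines[c(ord[seq_len(half)], ord[seq(length(lines) - half + 1,
                                             length(lines))])]
  list(selected = sort(sel), holdout = sort(setdiff(lines, sel)),
       ranking = data.frame(line = lines[ord], score = sort(score),
                            row.names = NULL))
}

#' Simulate a complete wing-size omics cohort
#'
#' Orchestrates the full generative model: genome annotation, pool genotypes,
#' ground truth, pool phenotypes, extreme-line selection, RNA-seq counts for
#' the selected lines and a coupled protein layer. The defaults emulate the
#' design of an extreme-line inbred study: a measured pool of 160 lines from
#' which the 16 largest and 16 smallest are profiled, two replicates per
#' line x sex split over two library batches, and 8 mediator loci jointly
#' explaining roughly half of the between-line trait variance.
#'
#' @param seed master seed; all component seeds derive from it.
#' @param n_pool,n_select pool size and number of extreme lines profiled.
#'   Setting `n_select = n_pool` disables selection.
#' @param n_genes,n_variants genome size.
#' @param n_type1,n_type2,n_type3,n_eqtl,n_mediators planted effect counts
#'   (see [make_truth_table()]; `n_type2 >= n_mediators`,
#'   `n_eqtl >= n_mediators`).
#' @param n_replicates replicates per line x sex.
#' @param protein logical: generate the protein layer?
#' @param ... further arguments to component generators:
#'   [generate_genotypes()] (`maf_range`, `ld_block`, `ld_corr`,
#'   `missing_rate`), [generate_phenotypes()] (`sex_dimorphism`, `line_sd`,
#'   `noise_sd`, ...), [generate_expression()] (`batch_effect`, `dispersion`,
#'   `line_effect_sd`, ...), [make_truth_table()] (`beta_pheno`, ...).
#' @return object of class `wing_cohort`: list with `genome`, `geno` (pool),
#'   `pheno` (pool), `truth`, `counts` (selected lines), `protein`,
#'   `selected`, `holdout`, `params`.
#' @export
simulate_cohort <- function(seed = 1L, n_pool = 160, n_select = 32,
                            n_genes = 600, n_variants = 1500,
                            n_type1 = 30, n_type2 = 30, n_type3 = 60,
                            n_eqtl = 60, n_mediators = 8,
                            n_replicates = 2, protein = TRUE, ...) {
  dots <- list(...)
  grab <- function(f, fixed) {
    nm <- intersect(names(dots), setdiff(names(formals(f)), names(fixed)))
    c(fixed, dots[nm])
  }
  genome <- do.call(generate_genome, grab(generate_genome, list(
    n_genes = n_genes, n_variants = n_variants, seed = seed)))
  geno <- do.call(generate_genotypes, grab(generate_genotypes, list(
    variants = genome$variants, n_lines = n_pool, seed = seed)))
  genome$variants <- geno$variants
  truth <- do.call(make_truth_table, grab(make_truth_table, list(
    genome = genome, geno = geno, n_type1 = n_type1, n_type2 = n_type2,
    n_type3 = n_type3, n_eqtl = n_eqtl, n_mediators = n_mediators,
    seed = seed)))
  pheno <- do.call(generate_phenotypes, grab(generate_phenotypes, list(
    lines = geno$lines, mediator_truth = truth, geno = geno, seed = seed)))
  sel <- select_extreme_lines(pheno, n_select)
  counts <- do.call(generate_expression, grab(generate_expression, list(
    truth = truth, pheno = pheno, geno = geno, n_replicates = n_replicates,
    lines = sel$selected, seed = seed)))
  prot <- if (protein) {
    do.call(generate_protein, grab(generate_protein, list(
      truth = truth, pheno = pheno, geno = geno, lines = sel$selected,
      seed = seed)))
  } else NULL

  structure(list(genome = genome, geno = geno, pheno = pheno, truth = truth,
                 counts = counts, protein = prot,
                 selected = sel$selected, holdout = sel$holdout,
                 params = c(list(seed = seed, n_pool = n_pool,
                                 n_select = n_select, n_genes = n_genes,
                                 n_variants = n_variants, n_type1 = n_type1,
                                 n_type2 = n_type2, n_type3 = n_type3,
                                 n_eqtl = n_eqtl, n_mediators = n_mediators,
                                 n_replicates = n_replicates), dots)),
            class = "wing_cohort")
}

#' @export
print.wing_cohort <- function(x, ...) {
  cat("wing_cohort (seed ", x$params$seed, "):\n", sep = "")
  cat("  pool:", length(x$geno$lines), "lines;",
      length(x$selected), "selected,", length(x$holdout), "holdout\n")
  cat("  genome:", nrow(x$genome$genes), "genes,",
      nrow(x$genome$variants), "variants\n")
  cat("  counts:", nrow(x$counts$counts), "genes x",
      ncol(x$counts$counts), "samples\n")
  cat("  planted: type1 =", x$params$n_type1, "type2 =", x$params$n_type2,
      "type3 =", x$params$n_type3, "eQTL =", x$params$n_eqtl,
      "mediators =", x$params$n_mediators, "\n")
  invisible(x)
}
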