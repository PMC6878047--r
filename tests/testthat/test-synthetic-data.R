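test_that("genome construction yields disjoint genes and valid variants", {
  gen <- generate_genome(10, 100, chrom_lengths = c(chr1 = 1e6), seed = 1)
  expect_equal(nrow(gen$genes), 10)
  expect_equal(nrow(gen$variants), 100)
  expect_true(all(gen$genes$start <= gen$genes$end))
  o <- gen$genes[order(gen$genes$start), ]
  expect_true(all(o$start[-1] > o$end[-nrow(o)]))     # non-overlapping
  expect_false(anyDuplicated(gen$genes$gene_id) > 0)
  expect_false(anyDuplicated(gen$variants$variant_id) > 0)
  expect_true(all(gen$variants$ref != gen$variants$alt))
  expect_true(all(gen$variants$pos >= 1 & gen$variants$pos <= 1e6))
})

test_that("genome generation is deterministic and validates inputs", {
  a <- generate_genome(10, 100, chrom_lengths = c(chr1 = 1e6), seed = 1)
  b <- generate_genome(10, 100, chrom_lengths = c(chr1 = 1e6), seed = 1)
  expect_identical(a, b)
  expect_error(generate_genome(0, 10), "n_genes")
  expect_error(generate_genome(200, 10, chrom_lengths = c(chr1 = 1e5)),
               "too short")
})

test_that("genotypes honour missingness, LD limit and homozygous coding", {
  gen <- generate_genome(5, 60, chrom_lengths = c(chr1 = 1e6), seed = 2)
  g0 <- generate_genotypes(gen$variants, 32, missing_rate = 0, seed = 2)
  expect_false(anyNA(g0$calls))
  expect_true(all(g0$calls %in% c(0L, 1L)))
  expect_equal(dim(g0$calls), c(32, 60))

  # perfect LD: all variants in one block are identical
  g1 <- generate_genotypes(gen$variants, 32, ld_block = 2e6, ld_corr = 1,
                           missing_rate = 0, seed = 3)
  expect_true(all(apply(g1$calls, 1, function(r) length(unique(r)) == 1)))

  expect_error(generate_genotypes(gen$variants, 1), "n_lines")
})

test_that("independent-variant MAF matches a binomial sampling oracle", {
  gen <- generate_genome(5, 1000, chrom_lengths = c(chr1 = 5e6), seed = 4)
  n <- 200
  g <- generate_genotypes(gen$variants, n, maf_range = c(0.2, 0.4),
                          ld_block = 0, missing_rate = 0, seed = 4)
  cnt <- colSums(g$calls)
  # alt counts are Binomial(n, p) with p ~ U(0.2, 0.4): nearly all counts
  # must fall inside the envelope of the extreme targets +/- 4 binomial SDs
  lo <- n * 0.2 - 4 * sqrt(n * 0.2 * 0.8)
  hi <- n * 0.4 + 4 * sqrt(n * 0.4 * 0.6)
  expect_gt(mean(cnt >= lo & cnt <= hi), 0.99)
  # and the realized mean frequency matches the mid-target
  expect_lt(abs(mean(cnt / n) - 0.3), 0.02)
})

test_that("phenotypes carry dimorphism, noise limits and SNP effects", {
  lines <- sprintf("line_%03d", 1:32)
  ph <- generate_phenotypes(lines, sex_dimorphism = 15, line_sd = 4, seed = 5)
  expect_equal(nrow(ph), 64)
  expect_false(anyDuplicated(paste(ph$line, ph$sex)) > 0)
  dF <- ph$absCS[ph$sex == "F"]
  dM <- ph$absCS[ph$sex == "M"]
  # F > M checked at 3 sigma of the difference of means
  se <- sqrt(var(dF) / 32 + var(dM) / 32)
  expect_gt(mean(dF) - mean(dM), 3 * se)
  expect_true(all(ph$absCS > 0))

  ph0 <- generate_phenotypes(lines, sex_dimorphism = 0, line_sd = 0,
                             noise_sd = 0, seed = 5)
  expect_equal(var(ph0$absCS), 0)

  # planted SNP effect on 16/32 alt lines recovers beta within its CI
  calls <- matrix(rep(c(0L, 1L), each = 16), 32, 1,
                  dimnames = list(lines, "chr1_100_SNP"))
  geno <- list(lines = lines, calls = calls)
  truth <- list(mediators = data.frame(gene_id = "g", variant_id = "chr1_100_SNP",
                                       beta_pheno = 6, net_sign = 1))
  ph2 <- generate_phenotypes(lines, sex_dimorphism = 0, line_sd = 1,
                             noise_sd = 0.5, mediator_truth = truth,
                             geno = geno, seed = 6)
  alt <- ph2$line %in% lines[17:32]
  d <- mean(ph2$absCS[alt]) - mean(ph2$absCS[!alt])
  se <- sqrt(var(ph2$absCS[alt]) / 32 + var(ph2$absCS[!alt]) / 32)
  expect_lt(abs(d - 6), 3 * se)
})

test_that("expression counts are integer, dimensioned and type-3 structured", {
  co <- tiny_cohort(seed = 7)
  y <- co$counts$counts
  expect_true(is.integer(y) || all(y == round(y)))
  expect_true(all(y >= 0))
  expect_equal(ncol(y), 24 * 2 * 2)      # lines x sexes x replicates
  expect_equal(nrow(y), 80)

  # near the zero-noise limit a planted type-3 gene separates by sex and is
  # flat across lines within sex
  gen <- generate_genome(20, 50, chrom_lengths = c(chr1 = 1e6), seed = 8)
  geno <- generate_genotypes(gen$variants, 16, missing_rate = 0, seed = 8)
  truth <- make_truth_table(gen, geno, n_type3 = 5, seed = 8)
  ph <- generate_phenotypes(geno$lines, seed = 8)
  cs <- generate_expression(truth, ph, geno, n_replicates = 4,
                            dispersion = 1e-4, batch_effect = 0,
                            lib_size = 5e6, base_range = c(7, 9), seed = 8)
  expr <- summarize_line_sex(log_cpm_weights(cs, weights = "unit"))
  g3 <- truth$genes$gene_id[truth$genes$assoc_type == "3"][1]
  eff <- truth$genes$sex_effect[truth$genes$gene_id == g3]
  sexdiff <- rowMeans(expr$E[, expr$samples$sex == "F"]) -
    rowMeans(expr$E[, expr$samples$sex == "M"])
  # CPM normalization shifts all genes by a common compositional offset;
  # net of it, the planted sex effect is recovered
  offset <- median(sexdiff[truth$genes$assoc_type == "none"])
  expect_lt(abs((sexdiff[g3] - offset) - eff), 0.1)
  vF <- expr$E[g3, expr$samples$sex == "F"]
  vM <- expr$E[g3, expr$samples$sex == "M"]
  expect_lt(sd(vF), 0.1)
  expect_lt(sd(vM), 0.1)
})

test_that("a planted eQTL of known effect is recovered on the log-CPM scale", {
  gen <- generate_genome(30, 80, chrom_lengths = c(chr1 = 2e6), seed = 9)
  geno <- generate_genotypes(gen$variants, 24, missing_rate = 0,
                             maf_range = c(0.3, 0.5), seed = 9)
  truth <- make_truth_table(gen, geno, n_eqtl = 3,
                            beta_eqtl_range = c(1, 1), seed = 9)
  ph <- generate_phenotypes(geno$lines, seed = 9)
  cs <- generate_expression(truth, ph, geno, n_replicates = 8,
                            dispersion = 0.01, batch_effect = 0,
                            lib_size = 4e6, base_range = c(6, 9), seed = 9)
  expr <- summarize_line_sex(log_cpm_weights(cs, weights = "unit"))
  E <- expr_sex_matrix(expr, "F")
  for (k in seq_len(nrow(truth$eqtls))) {
    x <- geno$calls[colnames(E), truth$eqtls$variant_id[k]]
    d <- mean(E[truth$eqtls$gene_id[k], x == 1]) -
      mean(E[truth$eqtls$gene_id[k], x == 0])
    # group-mean oracle: allele effect of 1 log2 unit up to composition
    expect_lt(abs(d - truth$eqtls$beta[k]), 0.25)
  }
})

test_that("truth table enforces the mediator invariant and errors propagate", {
  co <- tiny_cohort(seed = 10)
  med <- co$truth$mediators
  expect_equal(nrow(med), 3)
  t2 <- co$truth$genes$gene_id[co$truth$genes$assoc_type == "2"]
  expect_true(all(med$gene_id %in% t2))
  expect_true(all(paste(med$gene_id, med$variant_id) %in%
                    paste(co$truth$eqtls$gene_id, co$truth$eqtls$variant_id)))
  expect_equal(med$net_sign, sign(med$beta_pheno))

  bad <- co$truth
  bad$eqtls$variant_id[1] <- "nope_1_SNP"
  expect_error(generate_expression(bad, co$pheno, co$geno, seed = 1),
               "absent")
})

test_that("cohorts are bitwise reproducible under a fixed master seed", {
  a <- tiny_cohort(seed = 11)
  b <- tiny_cohort(seed = 11)
  expect_identical(a$geno$calls, b$geno$calls)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$truth, b$truth)
  expect_identical(a$protein, b$protein)
  c2 <- tiny_cohort(seed = 12)
  expect_false(identical(a$counts$counts, c2$counts$counts))
})

test_that("extreme-line selection takes the tails and keeps the middle", {
  lines <- sprintf("line_%03d", 1:40)
  ph <- generate_phenotypes(lines, line_sd = 5, seed = 13)
  sel <- select_extreme_lines(ph, 10)
  expect_length(sel$selected, 10)
  expect_length(sel$holdout, 30)
  expect_length(intersect(sel$selected, sel$holdout), 0)
  dev <- tapply(ph$absCS - ave(ph$absCS, ph$sex), ph$line, mean)
  expect_true(all(rank(dev)[sel$selected] %in% c(1:5, 36:40)))
})
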