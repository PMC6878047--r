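test_that("MAF filter applies the boundary rule over non-missing lines", {
  calls <- cbind(
    v1 = c(rep(1L, 3), rep(0L, 29)),                 # 3/32  = 0.094 -> out
    v2 = c(rep(1L, 4), rep(0L, 28)),                 # 4/32  = 0.125 -> kept
    v3 = c(rep(1L, 4), rep(0L, 26), NA, NA))         # 4/30  = 0.133 -> kept
  g <- manual_geno(calls)
  out <- maf_filter(g, 0.10)
  expect_setequal(out$variants$variant_id, g$variants$variant_id[2:3])
  # exact boundary is kept: 16/32 = 0.5 >= 0.5
  gb <- manual_geno(cbind(v = rep(c(0L, 1L), 16)))
  expect_equal(ncol(maf_filter(gb, 0.5)$calls), 1)
})

test_that("cis/trans classification uses the inclusive +/- 100 kb window", {
  genes <- data.frame(gene_id = "g1", chrom = "2L", start = 1000000,
                      end = 1005000, strand = "+")
  variants <- data.frame(
    variant_id = c("a", "b", "c", "d"),
    chrom = c("2L", "2L", "2L", "2L"),
    pos = c(900000, 1105000, 1105001, 50000))
  map <- classify_cis_trans(variants, genes, window = 1e5)
  expect_equal(pair_scope(map, "g1", "a"), "cis")    # boundary inclusive
  expect_equal(pair_scope(map, "g1", "b"), "cis")
  expect_equal(pair_scope(map, "g1", "c"), "trans")
  expect_equal(pair_scope(map, "g1", "d"), "trans")
  # another chromosome is always trans; unknown chromosomes error
  genes2 <- rbind(genes, data.frame(gene_id = "g2", chrom = "3R",
                                    start = 1, end = 10, strand = "-"))
  v2 <- rbind(variants, data.frame(variant_id = "e", chrom = "3R", pos = 5))
  map2 <- classify_cis_trans(v2, genes2, window = 1e5)
  expect_equal(pair_scope(map2, "g1", "e"), "trans")
  expect_error(classify_cis_trans(
    data.frame(variant_id = "x", chrom = "4", pos = 1), genes),
    "unknown")
})

test_that("maf_filter and classify_cis_trans commute", {
  co <- tiny_cohort(seed = 50)
  g <- subset_genotypes(co$geno, lines = co$selected)
  a <- classify_cis_trans(maf_filter(g, 0.1)$variants, co$genome$genes)
  b_full <- classify_cis_trans(g$variants, co$genome$genes)
  keep <- g$variants$variant_id[!is.na(g$variants$maf) &
                                  g$variants$maf >= 0.1]
  for (gene in sample(a$gene_ids, 20)) {
    va <- a$variant_ids[a$cis[[gene]]]
    vb <- intersect(b_full$variant_ids[b_full$cis[[gene]]], keep)
    expect_setequal(va, vb)
  }
})

test_that("nominal scan matches a per-pair least-squares oracle to 1e-10", {
  co <- tiny_cohort(seed = 51)
  counts <- filter_genes(filter_samples(co$counts, 0.25))
  ls <- summarize_line_sex(log_cpm_weights(counts, weights = "unit"))
  E <- expr_sex_matrix(ls, "F")
  geno <- maf_filter(subset_genotypes(co$geno, lines = colnames(E)), 0.1)
  map <- classify_cis_trans(geno$variants, co$genome$genes)
  rec <- nominal_scan(E, geno, map, scope = "cis")
  expect_gt(nrow(rec), 50)
  set.seed(51)
  for (i in sample(nrow(rec), 100, replace = TRUE)) {
    y <- E[rec$gene[i], ]
    x <- geno$calls[colnames(E), rec$variant[i]]
    ok <- !is.na(x)
    fit <- summary(lm(y[ok] ~ x[ok]))
    expect_equal(rec$beta[i], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(rec$p[i], fit$coefficients[2, 4], tolerance = 1e-10)
  }
})

test_that("a perfectly separating variant gives beta 1 and a floor p", {
  calls <- cbind(v = rep(c(0L, 1L), each = 8))
  g <- manual_geno(calls, chrom = "2L", pos = 1000)
  genes <- data.frame(gene_id = "g1", chrom = "2L", start = 500, end = 600,
                      strand = "+")
  E <- matrix(rep(c(0, 1), each = 8), 1, dimnames = list("g1", g$lines))
  map <- classify_cis_trans(g$variants, genes)
  rec <- nominal_scan(E, g, map, scope = "cis")
  expect_equal(rec$beta, 1)
  expect_lt(rec$p, 1e-300)
})

test_that("permutation correction implements the counting formula", {
  # the corrected p is the fraction of permutation minima strictly below the
  # observed minimum; reproduce it against hand-built distributions
  co <- tiny_cohort(seed = 52, n_genes = 40)
  counts <- filter_genes(filter_samples(co$counts, 0.25))
  ls <- summarize_line_sex(log_cpm_weights(counts, weights = "unit"))
  E <- expr_sex_matrix(ls, "F")
  geno <- maf_filter(subset_genotypes(co$geno, lines = colnames(E)), 0.1)
  map <- classify_cis_trans(geno$variants, co$genome$genes)
  perm <- permutation_adjust(E, geno, map, n_perm = 100, seed = 1)
  k <- rowSums(perm$perm_min < perm$min_p)
  expect_equal(perm$corrected_p, k / 100)
  expect_true(any(perm$corrected_p == 0))    # verbatim ratio can reach zero
  perm2 <- permutation_adjust(E, geno, map, n_perm = 100, seed = 1,
                              count_adjust = TRUE)
  expect_equal(perm2$corrected_p, (k + 1) / 101)
  # observed minimum agrees with the nominal records
  for (g in sample(perm$gene, 10)) {
    sub <- perm$records[perm$records$gene == g, ]
    if (!nrow(sub)) next
    expect_equal(perm$min_p[match(g, perm$gene)], min(sub$p),
                 tolerance = 1e-12)
  }
  expect_warning(permutation_adjust(E, geno, map, n_perm = 10, seed = 1),
                 "resolution")
})

test_that("the empirical FDR follows t * G / passers and picks the largest t", {
  cp <- c(rep(0.01, 25), seq(0.5, 1, length.out = 75))   # G = 100
  names(cp) <- paste0("g", 1:100)
  res <- empirical_fdr(cp, target = 0.2, grid = c(0.05, 0.3))
  # at t = 0.05: 25 passers -> FDR = 0.05 * 100 / 25 = 0.2
  expect_equal(res$curve$fdr[res$curve$t == 0.05], 0.2)
  expect_equal(res$threshold, 0.05)
  expect_length(res$genes, 25)
  # a grid point with zero passers is skipped (NA), not treated as zero
  res2 <- suppressWarnings(
    empirical_fdr(c(0.5, 0.9), target = 0.2, grid = c(0.1, 0.9)))
  expect_true(is.na(res2$curve$fdr[1]))
  expect_warning(empirical_fdr(c(0.5, 0.9), target = 0.01,
                               grid = c(0.5, 0.9)), "no corrected-p")
})

test_that("density profile conserves assignments and spikes where planted", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "2L",
                      start = c(1e6, 2e6), end = c(1.01e6, 2.02e6),
                      strand = c("+", "-"))
  variants <- data.frame(variant_id = c("v1", "v2"), chrom = "2L",
                         pos = c(1e6, 2.02e6))
  qtls <- data.frame(gene = c("gp", "gm"), variant = c("v1", "v2"))
  prof <- qtl_density_profile(qtls, genes, variants, bin = 1000, span = 5e4)
  # v1 sits exactly on the TSS of gp; v2 on the TSS of gm (minus strand)
  tss <- prof[prof$anchor == "TSS", ]
  expect_equal(sum(tss$count), 2)
  expect_equal(tss$mid[tss$count == 2], 0)
  expect_equal(sum(prof$count), attr(prof, "n_assigned"))
  expect_equal(prof$per_kb, prof$count / 1)   # 1 kb bins

  # uniformly placed variants give a flat TSS profile within Poisson error
  set.seed(53)
  n <- 4000
  up <- data.frame(variant_id = paste0("u", 1:n), chrom = "2L",
                   pos = sample(9e5:11e5, n, replace = TRUE))
  uq <- data.frame(gene = "gp", variant = up$variant_id)
  pr <- qtl_density_profile(uq, genes, up, bin = 1e4, span = 5e4)
  cnt <- pr$count[pr$anchor == "TSS"]
  cnt <- cnt[-c(1, length(cnt))]      # edge bins are only half-covered
  expect_lt(max(abs(cnt - mean(cnt))) / sqrt(mean(cnt)), 4)
})

test_that("sex overlap reports shared counts and per-sex fractions", {
  f <- list(genes = c("a", "b", "c", "d"), variants = c("v1", "v2"))
  m <- list(genes = c("c", "d"), variants = c("v3", "v4"))
  ov <- sex_overlap(f, m)
  g <- ov[ov$item == "gene", ]
  expect_equal(g$n_shared, 2)
  expect_equal(g$frac_f, 0.5)
  expect_equal(g$frac_m, 1.0)
  v <- ov[ov$item == "variant", ]
  expect_equal(v$n_shared, 0)
  expect_equal(v$frac_f, 0)
  ident <- sex_overlap(f, f)
  expect_true(all(ident$frac_f == 1 & ident$frac_m == 1))
})

test_that("permuted expression yields uniform nominal p-values", {
  co <- null_cohort(seed = 54, n_genes = 150, n_lines = 32,
                    n_variants = 600, ld_block = 0)
  ls <- summarize_line_sex(log_cpm_weights(co$counts, weights = "unit"))
  E <- expr_sex_matrix(ls, "M")
  set.seed(54)
  E <- E[, sample(ncol(E))]
  colnames(E) <- sort(colnames(E))
  geno <- maf_filter(subset_genotypes(co$geno, lines = colnames(E)), 0.1)
  map <- classify_cis_trans(geno$variants, co$genome$genes)
  rec <- nominal_scan(E, geno, map, scope = "cis")
  ks <- suppressWarnings(ks.test(rec$p, "punif"))$statistic
  expect_lt(ks, 0.05)
})
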