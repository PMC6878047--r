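test_that("library-size filter removes shallow samples only", {
  y <- matrix(c(50, 50, 50, 2,
                50, 50, 50, 2), nrow = 2, byrow = TRUE)
  cs <- manual_counts(y, line = paste0("l", 1:4), sex = rep("F", 4))
  expect_message(out <- filter_samples(cs, 0.25), "removed 1")
  expect_equal(ncol(out$counts), 3)          # library 4 < 0.25 * 100
  expect_equal(ncol(filter_samples(cs, 0)$counts), 4)
  expect_error(filter_samples(cs, 1), "min_library_frac")

  # planted shallow samples in a generated cohort are exactly the removals
  co <- null_cohort(seed = 20, n_genes = 100)
  y <- co$counts$counts
  shallow <- c(3, 10, 25)
  y[, shallow] <- matrix(rbinom(nrow(y) * 3, 1, 0.02), ncol = 3)
  cs <- structure(list(counts = y, samples = co$counts$samples),
                  class = "count_set")
  kept <- suppressMessages(filter_samples(cs, 0.25))
  expect_setequal(setdiff(cs$samples$sample_id, kept$samples$sample_id),
                  cs$samples$sample_id[shallow])
})

test_that("gene filter keeps totals >= 70% of sample size, exactly", {
  n <- 100
  y <- matrix(0L, 3, n)
  y[1, seq_len(69)] <- 1L       # total 69 -> removed
  y[2, seq_len(70)] <- 1L       # total 70 -> kept
  cs <- manual_counts(y, line = paste0("l", seq_len(n)), sex = rep("F", n))
  out <- filter_genes(cs)
  expect_setequal(rownames(out$counts), "g002")   # all-zero gene also gone

  # independent row-sum oracle on a random matrix
  co <- null_cohort(seed = 21, n_genes = 300)
  out <- filter_genes(co$counts)
  oracle <- rownames(co$counts$counts)[
    rowSums(co$counts$counts) >= 0.7 * ncol(co$counts$counts)]
  expect_identical(rownames(out$counts), oracle)
})

test_that("log-CPM is finite, scale-invariant and weight trend is sane", {
  co <- null_cohort(seed = 22, n_genes = 200)
  cs <- co$counts
  cs$counts[1, 1] <- 0L
  expr <- log_cpm_weights(cs)
  expect_true(all(is.finite(expr$E)))
  expect_equal(dim(expr$E), dim(cs$counts))
  expect_equal(dim(expr$weights), dim(cs$counts))
  expect_true(all(expr$weights > 0))

  # doubling a sample's counts leaves well-expressed genes nearly unchanged
  cs2 <- cs
  cs2$counts[, 1] <- cs2$counts[, 1] * 2L
  e2 <- log_cpm_weights(cs2, weights = "unit")
  big <- cs$counts[, 1] >= 50
  expect_lt(max(abs(e2$E[big, 1] - expr$E[big, 1])), 0.01)

  # precision increases with abundance where counting noise dominates:
  # at shallow depth low-count genes must get clearly lower weights
  lo <- null_cohort(seed = 29, n_genes = 300, lib_size = 3e4)
  elo <- log_cpm_weights(lo$counts)
  abar <- rowMeans(log2(lo$counts$counts + 0.5))
  w <- rowMeans(elo$weights)
  half <- abar <= median(abar)
  expect_gt(cor(abar[half], w[half], method = "spearman"), 0.5)
  qs <- cut(abar, quantile(abar, 0:4 / 4), include.lowest = TRUE)
  mw <- tapply(w, qs, mean)
  expect_gt(mw[2], mw[1])
})

test_that("weight trend agrees with an independent voom fit", {
  skip_if_not_installed("limma")
  co <- null_cohort(seed = 23, n_genes = 400)
  expr <- log_cpm_weights(co$counts)
  grp <- factor(paste(co$counts$samples$line, co$counts$samples$sex))
  v <- limma::voom(co$counts$counts, design = model.matrix(~ 0 + grp))
  # same inverse-variance logic: per-gene mean weights strongly co-ranked
  expect_gt(cor(rowMeans(expr$weights), rowMeans(v$weights),
                method = "spearman"), 0.9)
})

test_that("PC removal strips a planted batch axis and is a projection", {
  co <- null_cohort(seed = 24, n_genes = 300)
  expr <- log_cpm_weights(co$counts, weights = "unit")
  batch <- as.numeric(co$counts$samples$batch == 2)
  shift <- rnorm(nrow(expr$E), 0, 1)
  expr$E <- expr$E + shift %o% batch
  out <- remove_batch_pcs(expr, 2)
  expect_equal(dim(out$E), dim(expr$E))
  cors <- abs(apply(out$E, 1, cor, y = batch))
  expect_gt(mean(cors < 0.1), 0.95)
  expect_lt(max(abs((out$E - rowMeans(out$E)) %*% out$pc_scores)), 1e-8)
  expect_warning(idem <- remove_batch_pcs(expr, 0), "no components")
  expect_identical(idem$E, expr$E)
})

test_that("PC removal spares line-level biology when replicates exist", {
  co <- tiny_cohort(seed = 25)
  expr <- log_cpm_weights(co$counts, weights = "unit")
  out <- remove_batch_pcs(expr, 2)
  ls0 <- summarize_line_sex(expr)
  ls1 <- summarize_line_sex(out)
  g2 <- co$truth$genes$assoc_type == "2"
  key <- paste(ls1$samples$line, ls1$samples$sex)
  cs <- co$pheno$absCS[match(key, paste(co$pheno$line, co$pheno$sex))]
  r0 <- apply(ls0$E[g2, ], 1, function(y) cor(y, cs))
  r1 <- apply(ls1$E[g2, ], 1, function(y) cor(y, cs))
  # the planted within-sex associations survive batch removal
  expect_gt(cor(r0, r1), 0.95)
})

test_that("replicate averaging follows the mean and sum-of-weights rules", {
  E <- matrix(c(1, 3, 5), 1, 3)
  W <- matrix(c(2, 2, 7), 1, 3)
  cs <- manual_counts(matrix(1L, 1, 3), line = c("a", "a", "b"),
                      sex = c("F", "F", "F"), replicate = c(1, 2, 1))
  expr <- structure(list(E = E, weights = W, samples = cs$samples),
                    class = "expr_set")
  rownames(expr$E) <- rownames(expr$weights) <- "g1"
  out <- summarize_line_sex(expr)
  expect_equal(out$E[1, "a_F"], 2)            # mean(1, 3)
  expect_equal(out$E[1, "b_F"], 5)            # single replicate passthrough
  expect_equal(out$weights[1, "a_F"], 4)      # summed replicate weights
  expect_equal(out$weights[1, "b_F"], 7)
  expect_warning(summarize_line_sex(expr, lines = c("a", "b", "c")),
                 "without samples")
})

test_that("within-layer concordance separates replicates from non-replicates", {
  co <- tiny_cohort(seed = 26, line_effect_sd = 0.6)
  expr <- log_cpm_weights(co$counts, weights = "unit")
  rep_dup <- expr
  rep_dup$E <- cbind(expr$E, dup = expr$E[, 1])
  rep_dup$samples <- rbind(expr$samples, expr$samples[1, ])
  rep_dup$samples$sample_id[nrow(rep_dup$samples)] <- "dup"
  rep <- concordance_report(rep_dup)
  dup_rho <- rep$pairs$rho[rep$pairs$a == colnames(expr$E)[1] &
                             rep$pairs$b == "dup"]
  expect_equal(dup_rho, 1)

  # clonal variation above replicate noise: replicates agree better
  rep2 <- concordance_report(expr)
  med <- setNames(rep2$summary$median_rho, rep2$summary$relation)
  expect_gt(med["replicate"], med["non-replicate"])
})

test_that("cross-layer concordance is near zero for independent layers", {
  co <- null_cohort(seed = 27, n_genes = 500)
  ls <- summarize_line_sex(log_cpm_weights(co$counts, weights = "unit"))
  noise <- matrix(rnorm(length(ls$E)), nrow(ls$E),
                  dimnames = dimnames(ls$E))
  rep <- concordance_report(ls, other = noise)
  expect_lt(abs(rep$summary$median_rho), 0.1)
  expect_true(all(rep$genes$rho >= -1 & rep$genes$rho <= 1, na.rm = TRUE))

  # the generated protein layer is weakly positively coupled
  co2 <- tiny_cohort(seed = 28)
  ls2 <- summarize_line_sex(log_cpm_weights(co2$counts, weights = "unit"))
  rep2 <- concordance_report(ls2, other = co2$protein)
  expect_true(is.finite(rep2$summary$median_rho))
  expect_error(concordance_report(ls2, other = ls2$E[, 1:2, drop = FALSE]),
               "shared units")
})
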