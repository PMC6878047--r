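# Shared fixture builders. Everything is generated in code; cohorts are kept
# small so the whole suite stays fast.

# a tiny fully-planted cohort without extreme-line selection
tiny_cohort <- function(seed = 1, ...) {
  args <- list(seed = seed, n_pool = 24, n_select = 24, n_genes = 80,
               n_variants = 300, n_type1 = 5, n_type2 = 6, n_type3 = 10,
               n_eqtl = 10, n_mediators = 3, protein = TRUE)
  args[names(list(...))] <- list(...)
  do.call(simulate_cohort, args)
}

# a null cohort: no planted effects at all
null_cohort <- function(seed = 1, n_genes = 200, n_lines = 24,
                        n_variants = 300, ...) {
  simulate_cohort(seed = seed, n_pool = n_lines, n_select = n_lines,
                  n_genes = n_genes, n_variants = n_variants,
                  n_type1 = 0, n_type2 = 0, n_type3 = 0, n_eqtl = 0,
                  n_mediators = 0, protein = FALSE, ...)
}

# a hand-built count_set for exact filter arithmetic
manual_counts <- function(counts, line, sex, replicate = NULL,
                          batch = NULL) {
  n <- ncol(counts)
  replicate <- replicate %||% rep(1L, n)
  batch <- batch %||% rep(1L, n)
  samples <- data.frame(
    sample_id = colnames(counts) %||% paste0("s", seq_len(n)),
    line = line, sex = sex, replicate = replicate, batch = batch,
    stringsAsFactors = FALSE)
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  structure(list(counts = counts, samples = samples), class = "count_set")
}

# hand-built expr_set at line x sex resolution
manual_expr_ls <- function(E, line, sex, weights = NULL) {
  units <- paste(line, sex, sep = "_")
  colnames(E) <- units
  if (is.null(rownames(E))) rownames(E) <- sprintf("g%03d", seq_len(nrow(E)))
  if (!is.null(weights)) dimnames(weights) <- dimnames(E)
  structure(list(E = E, weights = weights,
                 samples = data.frame(unit = units, line = line, sex = sex,
                                      stringsAsFactors = FALSE)),
            class = "expr_set")
}

# hand-built genotype_set
manual_geno <- function(calls, chrom = NULL, pos = NULL) {
  nv <- ncol(calls)
  chrom <- chrom %||% rep("2L", nv)
  pos <- pos %||% seq(1e5, by = 5e4, length.out = nv)
  vid <- paste(chrom, pos, "SNP", sep = "_")
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("line_%03d", seq_len(nrow(calls)))
  colnames(calls) <- vid
  f <- colMeans(calls, na.rm = TRUE)
  structure(list(lines = rownames(calls), calls = calls,
                 variants = data.frame(variant_id = vid, chrom = chrom,
                                       pos = pos, ref = "A", alt = "G",
                                       maf = pmin(f, 1 - f),
                                       stringsAsFactors = FALSE)),
            class = "genotype_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent step-up BH oracle, written from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}
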