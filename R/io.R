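# Plain-text persistence: TSV tables for counts, phenotypes, annotation and
# genotypes (panel-style), VCF for genotypes, and a YAML config tying a
# written cohort together.

#' Write genotypes as a minimal VCF
#'
#' Homozygous calls are encoded as `0/0` (reference), `1/1` (alternate) and
#' `./.` (missing) in per-line GT columns.
#'
#' @param geno a `genotype_set`.
#' @param path output file.
#' @export
write_genotypes_vcf <- function(geno, path) {
  v <- geno$variants
  gt <- t(geno$calls)
  gt_chr <- matrix("./.", nrow(gt), ncol(gt))
  gt_chr[!is.na(gt) & gt == 0L] <- "0/0"
  gt_chr[!is.na(gt) & gt == 1L] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##source=wingqtl",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", geno$lines), collapse = "\t"))
  body <- cbind(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", ".", ".",
                "GT", gt_chr)
  lines <- c(header, apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a VCF with homozygous GT calls
#'
#' Uses the `vcfR` parser; `0/0` or `0|0` maps to 0, `1/1` or `1|1` to 1 and
#' anything else (including heterozygous calls, which inbred panels should
#' not contain) to missing.
#'
#' @param path VCF file.
#' @return a `genotype_set`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf)
  calls <- matrix(NA_integer_, ncol(gt), nrow(gt))
  calls[t(gt) %in% c("0/0", "0|0")] <- 0L
  calls[t(gt) %in% c("1/1", "1|1")] <- 1L
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  variants <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, maf = NA_real_,
                         stringsAsFactors = FALSE)
  dimnames(calls) <- list(colnames(gt), variants$variant_id)
  f <- colMeans(calls, na.rm = TRUE)
  variants$maf <- pmin(f, 1 - f)
  structure(list(lines = colnames(gt), calls = calls, variants = variants),
            class = "genotype_set")
}

#' Write genotypes as a panel-style TSV
#'
#' One row per variant: `chrom`, `pos`, `ref`, `alt`, then one 0/1/NA column
#' per line.
#'
#' @param geno a `genotype_set`.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(geno, path) {
  v <- geno$variants
  tab <- cbind(v[, c("chrom", "pos", "ref", "alt")],
               as.data.frame(t(geno$calls)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  fixed <- c("chrom", "pos", "ref", "alt")
  lines <- setdiff(names(tab), fixed)
  calls <- t(as.matrix(tab[, lines, drop = FALSE]))
  storage.mode(calls) <- "integer"
  variants <- data.frame(
    variant_id = paste(tab$chrom, tab$pos, "SNP", sep = "_"),
    chrom = tab$chrom, pos = tab$pos, ref = tab$ref, alt = tab$alt,
    maf = NA_real_, stringsAsFactors = FALSE)
  dimnames(calls) <- list(lines, variants$variant_id)
  f <- colMeans(calls, na.rm = TRUE)
  variants$maf <- pmin(f, 1 - f)
  structure(list(lines = lines, calls = calls, variants = variants),
            class = "genotype_set")
}

#' Read/write count matrices with sample metadata
#'
#' Counts are stored genes x samples with a `gene_id` first column; sample
#' metadata (`sample_id`, `line`, `sex`, `replicate`, `batch`) in a second
#' TSV.
#'
#' @param counts a `count_set`.
#' @param counts_path,samples_path file paths.
#' @export
write_counts_tsv <- function(counts, counts_path, samples_path) {
  utils::write.table(data.frame(gene_id = rownames(counts$counts),
                                counts$counts, check.names = FALSE),
                     counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(counts$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  storage.mode(m) <- "integer"
  samples <- utils::read.delim(samples_path,
                               colClasses = c(sex = "character"))
  structure(list(counts = m, samples = samples), class = "count_set")
}

#' Read/write phenotype and annotation tables
#' @param x the table to write.
#' @param path file path.
#' @export
write_phenotypes_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  ph <- utils::read.delim(path, colClasses = c(sex = "character"))
  class(ph) <- c("phenotype_table", "data.frame")
  ph
}

#' @rdname write_phenotypes_tsv
#' @export
read_annotation_tsv <- function(path) {
  utils::read.delim(path, colClasses = c(chrom = "character",
                                         strand = "character"))
}

#' Write a complete cohort to a directory
#'
#' Writes annotation, variants, genotypes (VCF and TSV), counts, samples,
#' phenotypes, protein matrix and the truth tables as plain-text files, plus
#' a `config.yaml` recording the paths and generator parameters.
#'
#' @param cohort a `wing_cohort`.
#' @param dir output directory (created if needed).
#' @return the config file path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.table(cohort$genome$genes, p("annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$geno$variants, p("variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_genotypes_vcf(cohort$geno, p("genotypes.vcf"))
  write_genotypes_tsv(cohort$geno, p("genotypes.tsv"))
  write_counts_tsv(cohort$counts, p("counts.tsv"), p("samples.tsv"))
  write_phenotypes_tsv(cohort$pheno, p("phenotypes.tsv"))
  if (!is.null(cohort$protein))
    utils::write.table(data.frame(gene_id = rownames(cohort$protein),
                                  cohort$protein, check.names = FALSE),
                       p("protein.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  utils::write.table(cohort$truth$genes, p("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$eqtls, p("truth_eqtls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$mediators, p("truth_mediators.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- list(
    files = list(annotation = "annotation.tsv", variants = "variants.tsv",
                 genotypes_vcf = "genotypes.vcf",
                 genotypes_tsv = "genotypes.tsv",
                 counts = "counts.tsv", samples = "samples.tsv",
                 phenotypes = "phenotypes.tsv",
                 protein = if (!is.null(cohort$protein)) "protein.tsv",
                 truth_genes = "truth_genes.tsv",
                 truth_eqtls = "truth_eqtls.tsv",
                 truth_mediators = "truth_mediators.tsv"),
    selected = cohort$selected,
    holdout = cohort$holdout,
    params = cohort$params,
    notes = list(relCS = paste("per-sex residual of absCS on IOD plus the",
                               "per-sex mean (stand-in convention)"))
  )
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(p("config.yaml"))
}
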