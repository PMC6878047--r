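# cis/trans eQTL mapping on line-level expression of one sex: MAF filtering,
# window-based cis/trans classification, vectorized nominal scans, the
# permutation minimum-p multiple-testing correction and the empirical FDR,
# plus the density and sex-overlap summaries.

#' Filter variants by minor allele frequency
#'
#' MAF is computed over non-missing lines; variants at exactly the boundary
#' are kept (`>=`).
#'
#' @param geno a `genotype_set`.
#' @param min_maf threshold in `[0, 0.5]`.
#' @return the filtered `genotype_set` (maf column refreshed).
#' @export
maf_filter <- function(geno, min_maf = 0.10) {
  .assert_frac(min_maf, "min_maf", hi = 0.5, hi_open = FALSE)
  f <- colMeans(geno$calls, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  subset_genotypes(geno, which(!is.na(maf) & maf >= min_maf))
}

#' Classify gene-variant pairs as cis or trans
#'
#' A variant is cis to a gene iff it lies on the same chromosome with
#' position inside `[start - window, end + window]` (inclusive); every other
#' pair, including pairs on distinct chromosomes, is trans.
#'
#' @param variants variant table (`variant_id`, `chrom`, `pos`).
#' @param genes gene annotation (`gene_id`, `chrom`, `start`, `end`).
#' @param window flanking window in bp (default 100 kb).
#' @return an object of class `cis_map`: list with `gene_ids`,
#'   `variant_ids`, `window` and `cis`, a per-gene list of integer indices
#'   into `variant_ids`.
#' @export
classify_cis_trans <- function(variants, genes, window = 1e5) {
  unknown <- setdiff(unique(variants$chrom), unique(genes$chrom))
  if (length(unknown))
    stop("variants on chromosome(s) unknown to the annotation: ",
         paste(unknown, collapse = ", "))
  by_chr <- split(seq_len(nrow(variants)), variants$chrom)
  cis <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    idx <- by_chr[[genes$chrom[g]]]
    if (is.null(idx)) {
      cis[[g]] <- integer(0)
      next
    }
    pos <- variants$pos[idx]
    cis[[g]] <- idx[pos >= genes$start[g] - window &
                      pos <= genes$end[g] + window]
  }
  names(cis) <- genes$gene_id
  structure(list(gene_ids = genes$gene_id, variant_ids = variants$variant_id,
                 window = window, cis = cis),
            class = "cis_map")
}

#' Scope of a single gene-variant pair
#' @param map a `cis_map`.
#' @param gene,variant ids.
#' @return `"cis"` or `"trans"`.
#' @export
pair_scope <- function(map, gene, variant) {
  vi <- match(variant, map$variant_ids)
  if (is.na(vi)) stop("unknown variant: ", variant)
  if (!gene %in% map$gene_ids) stop("unknown gene: ", gene)
  if (vi %in% map$cis[[gene]]) "cis" else "trans"
}

# group variants by identical missing-call patterns so that scans can run as
# dense matrix products per group; returns list(variants, lines) per pattern
.geno_groups <- function(calls) {
  na <- is.na(calls)
  key <- apply(na, 2, function(z) paste(which(z), collapse = ","))
  lapply(split(seq_len(ncol(calls)), key), function(vi) {
    list(variants = vi, lines = which(!na[, vi[1]]))
  })
}

# per-group scan core: centred genotype columns, sums of squares, and the
# genes x variants cross-product; E is genes x lines (full panel)
.group_stats <- function(E, calls, grp) {
  X <- calls[grp$lines, grp$variants, drop = FALSE]
  xc <- sweep(X, 2, colMeans(X), check.margin = FALSE)
  sxx <- colSums(xc^2)
  Eg <- E[, grp$lines, drop = FALSE]
  Ec <- Eg - rowMeans(Eg)
  syy <- rowSums(Ec^2)
  S <- Ec %*% xc
  list(S = S, sxx = sxx, syy = syy, n = length(grp$lines))
}

#' Nominal eQTL scan
#'
#' Per (gene, variant) pair, a simple linear regression of line-level
#' expression on the homozygous alternate-allele indicator over lines with a
#' non-missing call, returning the allele effect `beta` and a two-sided
#' p-value. The scan is restricted to cis pairs, trans pairs (processed in
#' variant chunks) or all pairs.
#'
#' @param expr numeric matrix genes x lines (one sex), or an `expr_set`
#'   whose units are the lines of one sex.
#' @param geno a `genotype_set` aligned to (a superset of) the expression
#'   lines.
#' @param map a `cis_map` from [classify_cis_trans()] (required for scopes
#'   `"cis"` and `"trans"`).
#' @param scope `"cis"`, `"trans"` or `"both"`.
#' @param chunk variant chunk size for the trans scan.
#' @return data.frame (class `qtl_records`) with `gene`, `variant`, `beta`,
#'   `p`, `n`; monomorphic pairs are skipped and counted in
#'   `attr(, "n_skipped")`.
#' @export
nominal_scan <- function(expr, geno, map = NULL,
                         scope = c("cis", "trans", "both"), chunk = 2000) {
  scope <- match.arg(scope)
  E <- .as_line_matrix(expr)
  lines <- colnames(E)
  if (!all(lines %in% geno$lines))
    stop("expression lines missing from genotypes")
  calls <- geno$calls[lines, , drop = FALSE]
  G <- nrow(E)
  V <- ncol(calls)
  if (scope != "both") {
    if (is.null(map)) stop("a cis_map is required for scope '", scope, "'")
    mask <- .cis_mask(map, rownames(E), colnames(calls))
    if (scope == "trans") mask <- !mask
  } else {
    mask <- matrix(TRUE, G, V)
  }

  groups <- .geno_groups(calls)
  res <- vector("list", length(groups))
  skipped <- 0L
  for (k in seq_along(groups)) {
    grp <- groups[[k]]
    st <- .group_stats(E, calls, grp)
    n <- st$n
    if (n < 4) {
      skipped <- skipped + sum(mask[, grp$variants])
      next
    }
    poly <- st$sxx > 0
    skipped <- skipped + sum(mask[, grp$variants[!poly], drop = FALSE])
    vkeep <- which(poly)
    if (!length(vkeep)) next
    S <- st$S[, vkeep, drop = FALSE]
    sxx <- st$sxx[vkeep]
    beta <- sweep(S, 2, sxx, "/")
    r2 <- S^2 / outer(st$syy, sxx)
    p <- .p_from_r2(r2, n - 2)
    m <- mask[, grp$variants[vkeep], drop = FALSE] & is.finite(p)
    idx <- which(m, arr.ind = TRUE)
    if (!nrow(idx)) next
    res[[k]] <- data.frame(
      gene = rownames(E)[idx[, 1]],
      variant = colnames(calls)[grp$variants[vkeep]][idx[, 2]],
      beta = beta[idx], p = p[idx], n = n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene = character(), variant = character(),
                      beta = numeric(), p = numeric(), n = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  class(out) <- c("qtl_records", "data.frame")
  out
}

.as_line_matrix <- function(expr) {
  if (inherits(expr, "expr_set")) {
    E <- expr$E
    colnames(E) <- expr$samples$line
    E
  } else {
    stopifnot(is.matrix(expr), !is.null(colnames(expr)))
    expr
  }
}

.cis_mask <- function(map, gene_ids, variant_ids) {
  mask <- matrix(FALSE, length(gene_ids), length(variant_ids))
  vi <- match(map$variant_ids, variant_ids)     # map index -> column
  for (g in seq_along(gene_ids)) {
    m <- map$cis[[gene_ids[g]]]
    if (is.null(m)) stop("gene absent from cis_map: ", gene_ids[g])
    cols <- vi[m]
    cols <- cols[!is.na(cols)]
    if (length(cols)) mask[g, cols] <- TRUE
  }
  mask
}

# masked per-gene minimum p for a given expression matrix; groups carry
# precomputed genotype pieces. Returns a vector of length nrow(E) (NA for
# genes with no testable variant).
.masked_min_p <- function(E, calls, groups, mask) {
  G <- nrow(E)
  minp <- rep(NA_real_, G)
  for (grp in groups) {
    n <- length(grp$lines)
    if (n < 4) next
    st <- .group_stats(E, calls, grp)
    poly <- st$sxx > 0
    if (!any(poly)) next
    vk <- grp$variants[poly]
    r2 <- st$S[, poly, drop = FALSE]^2 / outer(st$syy, st$sxx[poly])
    r2[!mask[, vk, drop = FALSE]] <- -1
    r2[!is.finite(r2)] <- -1
    best <- max.col(r2, ties.method = "first")
    val <- r2[cbind(seq_len(G), best)]
    has <- val >= 0
    if (!any(has)) next
    pg <- rep(NA_real_, G)
    pg[has] <- .p_from_r2(val[has], n - 2)
    minp <- pmin(minp, pg, na.rm = TRUE)
  }
  minp
}

#' Permutation minimum-p correction for gene-level eQTL significance
#'
#' For each gene, the minimum nominal p-value over its tested variants is
#' compared with the distribution of minima obtained by permuting the line
#' labels of the whole expression matrix: one shared permutation per round
#' for all genes, which preserves gene-gene correlation. The corrected
#' p-value is the fraction of permutation minima strictly smaller than the
#' observed minimum (`k / n_perm`); `count_adjust = TRUE` switches to the
#' positively biased `(k + 1) / (n_perm + 1)` variant.
#'
#' @inheritParams nominal_scan
#' @param n_perm number of permutation rounds (>= 1).
#' @param seed seed for the permutation stream.
#' @param count_adjust use `(k + 1) / (n_perm + 1)` instead of the plain
#'   ratio.
#' @param min_resolution warn when `1 / n_perm` is coarser than this.
#' @return an object of class `qtl_perm`: list with `gene` (ids), `min_p`,
#'   `corrected_p`, `perm_min` (genes x n_perm matrix), `n_perm`,
#'   `records` (the observed nominal cis records) and `map`.
#' @export
permutation_adjust <- function(expr, geno, map, n_perm = 200, seed = 1L,
                               scope = c("cis", "trans", "both"),
                               count_adjust = FALSE, min_resolution = 0.01) {
  scope <- match.arg(scope)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (1 / n_perm > min_resolution)
    warning("n_perm = ", n_perm, " gives corrected-p resolution ",
            signif(1 / n_perm, 3), ", coarser than ", min_resolution)
  E <- .as_line_matrix(expr)
  lines <- colnames(E)
  calls <- geno$calls[lines, , drop = FALSE]
  mask <- .cis_mask(map, rownames(E), colnames(calls))
  if (scope == "trans") mask <- !mask
  if (scope == "both") mask[] <- TRUE
  groups <- .geno_groups(calls)

  obs <- .masked_min_p(E, calls, groups, mask)
  perm_min <- matrix(NA_real_, nrow(E), n_perm)
  set.seed(derive_seed(seed, "permutation"))
  for (b in seq_len(n_perm)) {
    pi <- sample.int(ncol(E))
    perm_min[, b] <- .masked_min_p(E[, pi, drop = FALSE], calls, groups, mask)
  }
  k <- rowSums(perm_min < obs)
  corrected <- if (count_adjust) (k + 1) / (n_perm + 1) else k / n_perm
  corrected[is.na(obs)] <- NA_real_

  records <- nominal_scan(E, geno, map = map, scope = scope)
  structure(list(gene = rownames(E), min_p = obs, corrected_p = corrected,
                 perm_min = perm_min, n_perm = n_perm, records = records,
                 map = map, scope = scope),
            class = "qtl_perm")
}

#' @export
print.qtl_perm <- function(x, ...) {
  cat("qtl_perm:", length(x$gene), "genes,", x$n_perm, "permutations (",
      x$scope, ")\n")
  cat("  corrected p: ",
      paste(names(summary(x$corrected_p)), signif(summary(x$corrected_p), 3),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Empirical FDR over permutation-corrected p-values
#'
#' At a corrected-p threshold t the expected number of genes passing by
#' chance is `t * G` (G = family size), so `FDR(t) = t * G / #\{p_corr <= t\}`.
#' The reported threshold is the largest grid value whose FDR does not exceed
#' `target`.
#'
#' @param x a `qtl_perm` object, or a numeric vector of corrected p-values.
#' @param target FDR target (default 0.20).
#' @param grid threshold grid; defaults to the achievable values
#'   `0, 1/n_perm, ..., 1` (or the sorted unique corrected p for a vector
#'   input).
#' @return list (class `fdr_result`) with `curve` (data.frame `t`, `n_pass`,
#'   `fdr`), `threshold`, `target`, `genes` (ids passing at the threshold,
#'   when gene ids are available) and `G`.
#' @export
empirical_fdr <- function(x, target = 0.20, grid = NULL) {
  if (inherits(x, "qtl_perm")) {
    cp <- x$corrected_p
    genes <- x$gene
    grid <- grid %||% seq(0, 1, by = 1 / x$n_perm)
  } else {
    cp <- x
    genes <- names(x)
    grid <- grid %||% sort(unique(cp[!is.na(cp)]))
  }
  ok <- !is.na(cp)
  cp <- cp[ok]
  genes <- if (!is.null(genes)) genes[ok]
  G <- length(cp)
  n_pass <- vapply(grid, function(t) sum(cp <= t), integer(1))
  fdr <- ifelse(n_pass > 0, grid * G / n_pass, NA_real_)
  curve <- data.frame(t = grid, n_pass = n_pass, fdr = fdr)
  pass_ok <- which(n_pass > 0 & fdr <= target)
  if (!length(pass_ok)) {
    warning("no corrected-p threshold attains FDR <= ", target)
    threshold <- NA_real_
    sig <- character(0)
  } else {
    threshold <- max(grid[pass_ok])
    sig <- if (!is.null(genes)) genes[cp <= threshold] else character(0)
  }
  structure(list(curve = curve, threshold = threshold, target = target,
                 genes = sig, G = G),
            class = "fdr_result")
}

#' Variants supporting each significant gene
#'
#' For every gene significant at the empirical-FDR threshold, reports all of
#' its tested variants whose nominal p-value does not exceed the gene's
#' permutation-derived nominal threshold: the k-th smallest permutation
#' minimum p of that gene, with `k = floor(t * n_perm)` at the corrected-p
#' cutoff `t` (when `k` is zero the observed minimum p itself is used, so
#' the top variant is always reported).
#'
#' @param perm a `qtl_perm` object.
#' @param fdr an `fdr_result` from [empirical_fdr()].
#' @return data.frame with `gene`, `variant`, `beta`, `p` restricted to
#'   supporting variants of significant genes.
#' @export
significant_qtl_variants <- function(perm, fdr) {
  if (is.na(fdr$threshold) || !length(fdr$genes))
    return(data.frame(gene = character(), variant = character(),
                      beta = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  k <- floor(fdr$threshold * perm$n_perm)
  rec <- perm$records
  out <- vector("list", length(fdr$genes))
  for (i in seq_along(fdr$genes)) {
    g <- fdr$genes[i]
    gi <- match(g, perm$gene)
    thr <- if (k >= 1) sort(perm$perm_min[gi, ], partial = k)[k]
           else perm$min_p[gi]
    thr <- max(thr, perm$min_p[gi])   # the top variant is always reported
    r <- rec[rec$gene == g & rec$p <= thr, c("gene", "variant", "beta", "p")]
    out[[i]] <- r
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Map eQTLs for one sex: scan, permutation correction, FDR, variants
#'
#' Convenience wrapper chaining [maf_filter()], [classify_cis_trans()],
#' [permutation_adjust()], [empirical_fdr()] and
#' [significant_qtl_variants()].
#'
#' @param expr genes x lines matrix (one sex) or `expr_set`.
#' @param geno a `genotype_set` for (a superset of) those lines.
#' @param genes gene annotation covering the expression genes.
#' @param window cis window (bp).
#' @param min_maf MAF threshold.
#' @param n_perm permutation rounds.
#' @param fdr_target empirical FDR target.
#' @param seed permutation seed.
#' @param ... passed to [permutation_adjust()].
#' @return list (class `eqtl_result`): `perm`, `fdr`, `egenes`,
#'   `variants` (data.frame of supporting variants), `records`.
#' @export
map_eqtls <- function(expr, geno, genes, window = 1e5, min_maf = 0.10,
                      n_perm = 200, fdr_target = 0.20, seed = 1L, ...) {
  E <- .as_line_matrix(expr)
  genes <- genes[match(rownames(E), genes$gene_id), , drop = FALSE]
  if (anyNA(genes$gene_id)) stop("annotation missing for some genes")
  geno <- maf_filter(subset_genotypes(geno, lines = colnames(E)), min_maf)
  map <- classify_cis_trans(geno$variants, genes, window)
  perm <- permutation_adjust(E, geno, map, n_perm = n_perm, seed = seed, ...)
  fdr <- empirical_fdr(perm, target = fdr_target)
  variants <- significant_qtl_variants(perm, fdr)
  structure(list(perm = perm, fdr = fdr, egenes = fdr$genes,
                 variants = variants, records = perm$records),
            class = "eqtl_result")
}

#' @export
print.eqtl_result <- function(x, ...) {
  cat("eqtl_result:", length(x$egenes), "significant genes,",
      length(unique(x$variants$variant)), "supporting variants at FDR <=",
      x$fdr$target, "\n")
  invisible(x)
}

#' eQTL density around transcript start and end sites
#'
#' Each significant (gene, variant) pair contributes one assignment per
#' anchor (TSS and TES). Distances are measured in the direction of
#' transcription (negative = upstream of the anchor), using the annotated
#' strand, and binned; the profile reports eQTLs per kb per bin.
#'
#' @param qtls data.frame with `gene`, `variant` columns.
#' @param genes gene annotation with `strand`.
#' @param variants variant table with positions.
#' @param bin bin width (bp).
#' @param span half-width of the profiled window around each anchor (bp).
#' @return data.frame with `anchor` (`TSS`/`TES`), `lower`, `mid`, `count`,
#'   `per_kb`; `attr(, "n_assigned")` is the total number of in-window
#'   assignments (equal to the sum of `count`).
#' @export
qtl_density_profile <- function(qtls, genes, variants, bin = 1000,
                                span = 1e5) {
  if (!nrow(qtls)) stop("qtls is empty")
  gi <- match(qtls$gene, genes$gene_id)
  vi <- match(qtls$variant, variants$variant_id)
  if (anyNA(gi) || anyNA(vi)) stop("unmatched gene or variant ids")
  sgn <- ifelse(genes$strand[gi] == "+", 1, -1)
  tss <- ifelse(sgn > 0, genes$start[gi], genes$end[gi])
  tes <- ifelse(sgn > 0, genes$end[gi], genes$start[gi])
  pos <- variants$pos[vi]
  d <- data.frame(anchor = rep(c("TSS", "TES"), each = nrow(qtls)),
                  dist = c((pos - tss) * sgn, (pos - tes) * sgn))
  d <- d[abs(d$dist) <= span, ]
  breaks <- seq(-span - bin / 2, span + bin / 2, by = bin)
  out <- do.call(rbind, lapply(split(d, d$anchor), function(dd) {
    h <- hist(dd$dist, breaks = breaks, plot = FALSE)
    data.frame(anchor = dd$anchor[1], lower = h$breaks[-length(h$breaks)],
               mid = h$mids, count = h$counts,
               per_kb = h$counts / (bin / 1000))
  }))
  rownames(out) <- NULL
  attr(out, "n_assigned") <- nrow(d)
  out
}

#' Overlap of eQTL discoveries between the sexes
#'
#' @param f,m per-sex results: `eqtl_result` objects or lists with `genes`
#'   and `variants` character vectors.
#' @return data.frame with one row per item (`gene`, `variant`): totals per
#'   sex, shared count, and the shared fraction relative to each sex.
#' @export
sex_overlap <- function(f, m) {
  pick <- function(x) {
    if (inherits(x, "eqtl_result"))
      list(genes = x$egenes, variants = unique(x$variants$variant))
    else list(genes = unique(x$genes), variants = unique(x$variants))
  }
  f <- pick(f); m <- pick(m)
  row <- function(item, a, b) {
    sh <- length(intersect(a, b))
    data.frame(item = item, n_f = length(a), n_m = length(b), n_shared = sh,
               frac_f = if (length(a)) sh / length(a) else NA_real_,
               frac_m = if (length(b)) sh / length(b) else NA_real_)
  }
  out <- rbind(row("gene", f$genes, m$genes),
               row("variant", f$variants, m$variants))
  rownames(out) <- NULL
  out
}
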