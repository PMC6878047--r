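# Trait-expression association: the three association types, BH correction
# and the association-type classification.
#
# Type 1: expression regressed on absolute size across both sexes pooled.
# Type 2: sex-adjusted ANCOVA (parallel slopes) on absolute or relative size,
#         capturing between-line size variation within sexes.
# Type 3: one-way ANOVA on sex alone, capturing sexually dimorphic expression.

#' Fit a trait-expression association model per gene
#'
#' Fits, gene by gene, a weighted least squares model of expression at
#' line x sex resolution on the size trait and/or sex:
#' type 1 `expr ~ trait`, type 2 `expr ~ sex + trait` (parallel-slopes
#' ANCOVA), type 3 `expr ~ sex`. The reported p-value tests the size term
#' (types 1 and 2) or the sex term (type 3). Precision weights carried by the
#' `expr_set` are used when present. FDR is computed within the family of
#' testable genes of this (layer, type, trait) analysis by [bh_adjust()].
#'
#' @param expr an `expr_set` at line x sex resolution (see
#'   [summarize_line_sex()]).
#' @param pheno a `phenotype_table` covering the expression units.
#' @param model_type 1, 2 or 3.
#' @param trait `"absCS"` or `"relCS"` (ignored, and recorded as `NA`, for
#'   type 3).
#' @param layer label stored in the output (`"RNA"` or `"protein"`).
#' @param interaction logical: for type 2, add a sex x trait interaction
#'   (off by default; the reported size p-value is then for the main effect).
#' @return a `data.frame` (class `assoc_records`) with columns `gene`,
#'   `layer`, `model_type`, `trait`, `slope`, `sex_effect`, `p`, `fdr`.
#'   Genes that cannot be tested (fewer than 4 units or constant trait) get
#'   `NA` statistics and are excluded from the FDR family.
#' @export
fit_trait_model <- function(expr, pheno, model_type, trait = c("absCS", "relCS"),
                            layer = "RNA", interaction = FALSE) {
  stopifnot(model_type %in% 1:3)
  trait <- match.arg(trait)
  meta <- expr$samples
  key <- paste(meta$line, meta$sex, sep = "_")
  pk <- paste(pheno$line, pheno$sex, sep = "_")
  i <- match(key, pk)
  if (anyNA(i)) stop("phenotypes missing for units: ",
                     paste(key[is.na(i)], collapse = ", "))
  tr <- pheno[[trait]][i]
  sexM <- as.numeric(pheno$sex[i] == "M")

  n <- ncol(expr$E)
  X <- switch(as.character(model_type),
    "1" = cbind(intercept = 1, trait = tr),
    "2" = if (interaction) {
      cbind(intercept = 1, sexM = sexM, trait = tr, sex_trait = sexM * tr)
    } else {
      cbind(intercept = 1, sexM = sexM, trait = tr)
    },
    "3" = cbind(intercept = 1, sexM = sexM))
  term <- if (model_type == 3) "sexM" else "trait"
  untestable <- n < 4 || (model_type != 3 && stats::sd(tr) == 0) ||
    length(unique(sexM)) < (if (model_type == 1) 1 else 2)

  G <- nrow(expr$E)
  slope <- sex_eff <- p <- rep(NA_real_, G)
  if (!untestable) {
    ti <- match(term, colnames(X))
    si <- match("sexM", colnames(X))
    for (g in seq_len(G)) {
      y <- expr$E[g, ]
      w <- if (is.null(expr$weights)) rep(1, n) else expr$weights[g, ]
      fit <- stats::lm.wfit(X, y, w)
      df <- n - fit$rank
      if (df < 1 || is.na(fit$coefficients[ti])) next
      rss <- sum(w * fit$residuals^2)
      XtWXi <- chol2inv(chol(crossprod(X * sqrt(w))))
      se <- sqrt(XtWXi[ti, ti] * rss / df)
      b <- fit$coefficients[ti]
      if (se == 0) {
        p[g] <- if (b == 0) 1 else 0
      } else {
        p[g] <- 2 * stats::pt(-abs(b / se), df)
      }
      if (model_type != 3) slope[g] <- b
      if (!is.na(si)) sex_eff[g] <- -fit$coefficients[si]  # female minus male
    }
  }

  rec <- data.frame(
    gene = rownames(expr$E) %||% as.character(seq_len(G)),
    layer = layer,
    model_type = as.integer(model_type),
    trait = if (model_type == 3) NA_character_ else trait,
    slope = slope, sex_effect = sex_eff, p = p,
    fdr = NA_real_, stringsAsFactors = FALSE
  )
  ok <- !is.na(rec$p)
  rec$fdr[ok] <- bh_adjust(rec$p[ok])
  class(rec) <- c("assoc_records", "data.frame")
  rec
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p vector of p-values in `[0, 1]` (no `NA`).
#' @return adjusted values (monotone in rank order, capped at 1).
#' @export
bh_adjust <- function(p) {
  .assert_prob(p, "p-values")
  stats::p.adjust(p, method = "BH")
}

#' Classify genes by association-type membership
#'
#' Given the association records of the four analyses (type 1 on absCS,
#' type 2 on absCS, type 2 on relCS, type 3), flags membership at an FDR
#' threshold and derives: `exclusive_type1` (type 1 member that belongs to
#' neither type-2 set — the signature of expression tracking size only
#' through its sex difference) and `confirmed_type3` (exclusive type 1 and a
#' significant type-3 sex effect, the ANOVA confirmation).
#'
#' @param records a single `assoc_records` data.frame (rbind of the four
#'   analyses) or a list of them.
#' @param fdr_threshold membership threshold on FDR (default 0.20).
#' @return data.frame (class `type_classification`) with logical columns
#'   `type1`, `type2_abs`, `type2_rel`, `type3`, `exclusive_type1`,
#'   `confirmed_type3` per gene.
#' @export
classify_association_types <- function(records, fdr_threshold = 0.20) {
  .assert_frac(fdr_threshold, "fdr_threshold", hi_open = FALSE)
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  pick <- function(type, trait) {
    r <- records[records$model_type == type &
                   (if (is.na(trait)) is.na(records$trait)
                    else !is.na(records$trait) & records$trait == trait), ]
    stats::setNames(r$fdr, r$gene)
  }
  f1 <- pick(1, "absCS")
  f2a <- pick(2, "absCS")
  f2r <- pick(2, "relCS")
  f3 <- pick(3, NA)
  genes <- unique(records$gene)
  complete <- genes %in% names(f1) & genes %in% names(f2a) &
    genes %in% names(f2r) & genes %in% names(f3)
  if (any(!complete)) {
    warning(sum(!complete), " gene(s) lack one of the four analyses; skipped")
    genes <- genes[complete]
  }
  sig <- function(f) !is.na(f[genes]) & f[genes] < fdr_threshold
  out <- data.frame(
    gene = genes,
    type1 = sig(f1), type2_abs = sig(f2a), type2_rel = sig(f2r),
    type3 = sig(f3), stringsAsFactors = FALSE
  )
  out$exclusive_type1 <- out$type1 & !out$type2_abs & !out$type2_rel
  out$confirmed_type3 <- out$exclusive_type1 & out$type3
  rownames(out) <- NULL
  class(out) <- c("type_classification", "data.frame")
  out
}

#' Per-gene Spearman correlation between expression and a size trait
#'
#' Rank correlation of each gene's expression with the trait, pooled across
#' sexes, with a large-sample (t approximation) p-value.
#'
#' @param expr an `expr_set` at line x sex resolution.
#' @param pheno a `phenotype_table`.
#' @param trait `"absCS"` or `"relCS"`.
#' @return data.frame with `gene`, `rho`, `p`, `n`; constant genes get `NA`.
#' @export
spearman_size_correlation <- function(expr, pheno, trait = c("absCS", "relCS")) {
  trait <- match.arg(trait)
  meta <- expr$samples
  i <- match(paste(meta$line, meta$sex), paste(pheno$line, pheno$sex))
  if (anyNA(i)) stop("phenotypes missing for some units")
  tr <- pheno[[trait]][i]
  n <- length(tr)
  if (n < 4) stop("need at least 4 units")
  rt <- rank(tr)
  G <- nrow(expr$E)
  rho <- p <- rep(NA_real_, G)
  for (g in seq_len(G)) {
    y <- expr$E[g, ]
    if (stats::sd(y) == 0) next
    r <- stats::cor(rank(y), rt)
    rho[g] <- r
    p[g] <- .p_from_r2(r^2, n - 2)
  }
  data.frame(gene = rownames(expr$E) %||% as.character(seq_len(G)),
             rho = rho, p = p, n = n, stringsAsFactors = FALSE)
}
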