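# Mediator-gene selection by triangular association and the additive
# unit-sign flow model: each mediator-linked eQTL contributes +1 or -1
# (eQTL effect sign times trait-slope sign) to a line's predicted size when
# the line carries the alternate allele.

#' Extract one sex's line-level expression matrix
#'
#' @param expr an `expr_set` at line x sex resolution.
#' @param sex `"F"` or `"M"`.
#' @return genes x lines numeric matrix (colnames = line ids).
#' @export
expr_sex_matrix <- function(expr, sex = c("F", "M")) {
  sex <- match.arg(sex)
  keep <- expr$samples$sex == sex
  E <- expr$E[, keep, drop = FALSE]
  colnames(E) <- expr$samples$line[keep]
  E
}

#' Select mediator candidates by triangular association
#'
#' A mediator candidate is a gene whose within-sex (type 2) trait
#' association and gene-level eQTL mapping are both significant at the FDR
#' threshold; its supporting eQTL variants are carried forward.
#'
#' @param assoc `assoc_records` from [fit_trait_model()] with
#'   `model_type == 2` for the matching trait.
#' @param eqtl an `eqtl_result` for the matching sex.
#' @param fdr FDR threshold applied to both criteria (default 0.20).
#' @return data.frame with `gene`, `variant`, `beta_eqtl`, `slope`,
#'   `p_eqtl`, `fdr_assoc`: one row per candidate gene x linked variant.
#' @export
select_mediators <- function(assoc, eqtl, fdr = 0.20) {
  stopifnot(all(assoc$model_type == 2))
  sig_genes <- assoc$gene[!is.na(assoc$fdr) & assoc$fdr < fdr]
  genes <- intersect(sig_genes, eqtl$egenes)
  v <- eqtl$variants[eqtl$variants$gene %in% genes, , drop = FALSE]
  if (!nrow(v)) {
    warning("no gene passes both FDR criteria: empty mediator set")
    return(data.frame(gene = character(), variant = character(),
                      beta_eqtl = numeric(), slope = numeric(),
                      p_eqtl = numeric(), fdr_assoc = numeric(),
                      stringsAsFactors = FALSE))
  }
  ai <- match(v$gene, assoc$gene)
  out <- data.frame(gene = v$gene, variant = v$variant, beta_eqtl = v$beta,
                    slope = assoc$slope[ai], p_eqtl = v$p,
                    fdr_assoc = assoc$fdr[ai], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Screen variants for direct association with the size trait
#'
#' Per-variant simple regression of the per-sex line trait on the alternate
#' allele indicator; variants with p below `alpha` are retained. The
#' R-squared quantifies the single-locus predictability of the trait.
#'
#' @param geno a `genotype_set`.
#' @param pheno a `phenotype_table`.
#' @param variants character vector of variant ids to screen.
#' @param trait `"absCS"` or `"relCS"`.
#' @param sex `"F"` or `"M"`.
#' @param alpha retention threshold on p (default 0.05).
#' @param lines optional subset of lines to use (default: all genotype lines
#'   with a phenotype).
#' @return data.frame with `variant`, `beta`, `p`, `r2`, `n`, `retained`;
#'   monomorphic variants are dropped.
#' @export
snp_trait_screen <- function(geno, pheno, variants, trait = c("absCS", "relCS"),
                             sex = c("F", "M"), alpha = 0.05, lines = NULL) {
  trait <- match.arg(trait)
  sex <- match.arg(sex)
  .assert_frac(alpha, "alpha", hi_open = FALSE)
  ph <- pheno[pheno$sex == sex, ]
  lines <- lines %||% intersect(geno$lines, ph$line)
  y <- ph[[trait]][match(lines, ph$line)]
  miss <- setdiff(variants, colnames(geno$calls))
  if (length(miss)) stop("variants absent from genotypes: ",
                         paste(miss, collapse = ", "))
  out <- lapply(variants, function(v) {
    x <- geno$calls[lines, v]
    ok <- !is.na(x) & !is.na(y)
    xv <- x[ok]; yv <- y[ok]
    n <- length(xv)
    if (n < 4 || min(sum(xv == 0), sum(xv == 1)) < 1) return(NULL)
    xc <- xv - mean(xv); yc <- yv - mean(yv)
    sxx <- sum(xc^2)
    beta <- sum(xc * yc) / sxx
    r2 <- sum(xc * yc)^2 / (sxx * sum(yc^2))
    data.frame(variant = v, beta = beta, p = .p_from_r2(r2, n - 2),
               r2 = r2, n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(variant = character(), beta = numeric(), p = numeric(),
                      r2 = numeric(), n = integer(), retained = logical(),
                      stringsAsFactors = FALSE))
  out$retained <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Build the unit-sign genetic information flow model
#'
#' Each retained (variant, gene) entry is reduced to unit-strength signed
#' effects: `eqtl_sign = sign(beta_eqtl)` (direction of the allele's effect
#' on the transcript), `trait_sign = sign(type-2 slope)` (direction of the
#' transcript's association with size), and
#' `net_sign = eqtl_sign * trait_sign`, the expected direction of the
#' allele's effect on size.
#'
#' @param selected mediator candidates from [select_mediators()].
#' @param screen screen results from [snp_trait_screen()]; only retained
#'   variants enter the model (pass `NULL` to skip the screen).
#' @param trait,sex labels recorded in the model.
#' @return object of class `mediator_model`: list with `trait`, `sex` and
#'   `entries` (data.frame `variant`, `gene`, `eqtl_sign`, `trait_sign`,
#'   `net_sign`). Entries with a zero effect or slope are rejected with a
#'   message.
#' @export
build_flow_model <- function(selected, screen = NULL, trait = "absCS",
                             sex = "F") {
  e <- selected
  if (!is.null(screen)) {
    keep <- e$variant %in% screen$variant[screen$retained]
    e <- e[keep, , drop = FALSE]
  }
  zero <- e$beta_eqtl == 0 | e$slope == 0
  if (any(zero)) {
    message("build_flow_model: rejecting ", sum(zero),
            " entr(ies) with zero effect or slope")
    e <- e[!zero, , drop = FALSE]
  }
  entries <- data.frame(
    variant = e$variant, gene = e$gene,
    eqtl_sign = sign(e$beta_eqtl), trait_sign = sign(e$slope),
    stringsAsFactors = FALSE)
  entries$net_sign <- entries$eqtl_sign * entries$trait_sign
  if (!nrow(entries)) warning("flow model has no entries")
  rownames(entries) <- NULL
  structure(list(trait = trait, sex = sex, entries = entries),
            class = "mediator_model")
}

#' @export
print.mediator_model <- function(x, ...) {
  cat("mediator_model (", x$sex, ", ", x$trait, "): ",
      nrow(x$entries), " eQTL entries over ",
      length(unique(x$entries$gene)), " mediator gene(s)\n", sep = "")
  invisible(x)
}

#' Score lines by summed unit-sign eQTL effects
#'
#' A line's net score adds `net_sign` over all model entries whose alternate
#' allele the line carries; reference calls contribute 0 and missing calls
#' contribute 0 while incrementing `n_missing`.
#'
#' @param model a `mediator_model` with at least one entry.
#' @param geno a `genotype_set` containing every model variant.
#' @param lines optional subset of lines to score.
#' @return data.frame (class `line_scores`) with `line`, `net_score`,
#'   `n_missing`.
#' @export
score_lines <- function(model, geno, lines = NULL) {
  e <- model$entries
  if (!nrow(e)) stop("flow model has no entries")
  missing <- setdiff(e$variant, colnames(geno$calls))
  if (length(missing))
    stop("model variants absent from genotypes: ",
         paste(missing, collapse = ", "))
  lines <- lines %||% geno$lines
  calls <- geno$calls[lines, e$variant, drop = FALSE]
  na <- is.na(calls)
  calls[na] <- 0L
  out <- data.frame(line = lines,
                    net_score = drop(calls %*% e$net_sign),
                    n_missing = rowSums(na),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("line_scores", "data.frame")
  out
}

#' Evaluate net-score prediction of the size trait
#'
#' Rank mode reports the Spearman correlation (with a large-sample p)
#' between net scores and the observed per-sex trait; linear mode fits the
#' least-squares calibration `trait ~ net_score` and reports Pearson r,
#' R-squared and 50\% / 95\% prediction intervals from the residual
#' variance.
#'
#' @param scores `line_scores` from [score_lines()].
#' @param pheno a `phenotype_table`.
#' @param trait,sex condition to evaluate.
#' @param mode `"rank"` or `"linear"`.
#' @return rank mode: list with `rho`, `p`, `n`. Linear mode: list with
#'   `fit` (the `lm`), `r`, `r2`, `p`, `n`, `intervals` (data.frame with
#'   fitted values and 50/95\% prediction bounds) and `lines` (training
#'   line ids, used by [predict_holdout()]).
#' @export
evaluate_prediction <- function(scores, pheno, trait = c("absCS", "relCS"),
                                sex = c("F", "M"),
                                mode = c("rank", "linear")) {
  trait <- match.arg(trait)
  sex <- match.arg(sex)
  mode <- match.arg(mode)
  ph <- pheno[pheno$sex == sex, ]
  i <- match(scores$line, ph$line)
  ok <- !is.na(i)
  y <- ph[[trait]][i[ok]]
  s <- scores$net_score[ok]
  n <- length(s)
  if (n < 4) stop("need at least 4 scored lines with a phenotype")
  if (stats::sd(s) == 0) {
    message("constant net scores: prediction undefined")
    return(list(rho = NA_real_, r = NA_real_, p = NA_real_, n = n))
  }
  if (mode == "rank") {
    rho <- stats::cor(s, y, method = "spearman")
    list(rho = rho, p = .p_from_r2(rho^2, n - 2), n = n)
  } else {
    d <- data.frame(net_score = s, y = y)
    fit <- stats::lm(y ~ net_score, data = d)
    r <- stats::cor(s, y)
    pi50 <- suppressWarnings(
      stats::predict(fit, interval = "prediction", level = 0.50))
    pi95 <- suppressWarnings(
      stats::predict(fit, interval = "prediction", level = 0.95))
    list(fit = fit, r = r, r2 = r^2, p = .p_from_r2(r^2, n - 2), n = n,
         intervals = data.frame(line = scores$line[ok], net_score = s,
                                observed = y, fit = pi50[, "fit"],
                                lwr50 = pi50[, "lwr"], upr50 = pi50[, "upr"],
                                lwr95 = pi95[, "lwr"], upr95 = pi95[, "upr"]),
         lines = scores$line[ok])
  }
}

#' Predict the trait for held-out lines from genotype alone
#'
#' Applies the training calibration (linear fit of trait on net score) to
#' the net scores of unseen lines and evaluates the predictions against the
#' observed phenotypes. Training and holdout line sets must be disjoint.
#'
#' @param model a `mediator_model`.
#' @param calibration linear-mode output of [evaluate_prediction()] (must
#'   carry `fit` and `lines`).
#' @param holdout_geno genotypes covering the holdout lines.
#' @param holdout_pheno phenotypes for the holdout lines.
#' @param lines holdout line ids (default: all lines of `holdout_geno` that
#'   are not training lines and have a phenotype).
#' @return list with `scores`, `predicted` (data.frame `line`, `net_score`,
#'   `predicted`, `observed`), `r`, `p`, `n`.
#' @export
predict_holdout <- function(model, calibration, holdout_geno, holdout_pheno,
                            lines = NULL) {
  if (is.null(calibration$fit) || is.null(calibration$lines))
    stop("calibration must be the linear-mode output of evaluate_prediction()")
  ph <- holdout_pheno[holdout_pheno$sex == model$sex, ]
  lines <- lines %||% setdiff(intersect(holdout_geno$lines, ph$line),
                              calibration$lines)
  overlap <- intersect(lines, calibration$lines)
  if (length(overlap))
    stop("holdout overlaps training lines: ", paste(overlap, collapse = ", "))
  sc <- score_lines(model, holdout_geno, lines = lines)
  obs <- ph[[model$trait]][match(sc$line, ph$line)]
  pred <- stats::predict(calibration$fit,
                         newdata = data.frame(net_score = sc$net_score))
  ok <- !is.na(obs)
  n <- sum(ok)
  r <- if (n >= 3 && stats::sd(sc$net_score[ok]) > 0 && stats::sd(obs[ok]) > 0)
    stats::cor(pred[ok], obs[ok]) else NA_real_
  list(scores = sc,
       predicted = data.frame(line = sc$line, net_score = sc$net_score,
                              predicted = pred, observed = obs,
                              stringsAsFactors = FALSE),
       r = r, p = if (is.na(r)) NA_real_ else .p_from_r2(r^2, n - 2), n = n)
}
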