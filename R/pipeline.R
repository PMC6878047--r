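# End-to-end driver: counts -> preprocessing -> trait association ->
# eQTL mapping -> mediator selection -> unit-sign scoring -> in-sample and
# holdout evaluation, for one (sex, trait) condition.

#' Run the full wing-size analysis pipeline on a cohort
#'
#' Chains all modules for one biological condition (sex x trait): sample and
#' gene filtering, log-CPM with precision weights, principal-component batch
#' removal, replicate averaging, within-sex trait association (type 2),
#' permutation-corrected cis-eQTL mapping, triangular mediator selection
#' with the SNP-trait screen, the unit-sign flow model, line scoring, and
#' in-sample rank evaluation plus linear calibration; when holdout lines are
#' available their phenotypes are predicted from genotype alone.
#'
#' @param cohort a `wing_cohort` from [simulate_cohort()], or any list with
#'   the same components (`counts`, `pheno`, `geno`, `genome`, `selected`,
#'   `holdout`).
#' @param sex `"F"` or `"M"`.
#' @param trait `"absCS"` or `"relCS"`.
#' @param fdr FDR threshold for both mediator criteria (default 0.20).
#' @param alpha SNP-trait screen threshold (default 0.05).
#' @param n_perm permutation rounds for the eQTL correction.
#' @param pcs number of principal components removed.
#' @param min_lib_frac library-size filter fraction.
#' @param min_maf MAF threshold for the eQTL scan.
#' @param window cis window (bp).
#' @param weights `"trend"` or `"unit"` precision weights.
#' @param seed seed for the permutation stream.
#' @return list (class `wing_pipeline`) with components `expr` (line x sex
#'   `expr_set`), `assoc` (type-2 records), `eqtl` (`eqtl_result`),
#'   `mediators`, `screen`, `model`, `scores`, `insample` (rank mode),
#'   `calibration` (linear mode) and `holdout` (or `NULL`).
#' @export
run_wing_pipeline <- function(cohort, sex = c("F", "M"),
                              trait = c("absCS", "relCS"),
                              fdr = 0.20, alpha = 0.05, n_perm = 200,
                              pcs = 2, min_lib_frac = 0.25, min_maf = 0.10,
                              window = 1e5, weights = "trend", seed = 1L) {
  sex <- match.arg(sex)
  trait <- match.arg(trait)

  counts <- filter_genes(filter_samples(cohort$counts, min_lib_frac))
  expr <- log_cpm_weights(counts, weights = weights)
  if (pcs > 0) expr <- remove_batch_pcs(expr, k = pcs)
  expr_ls <- summarize_line_sex(expr)

  assoc <- fit_trait_model(expr_ls, cohort$pheno, model_type = 2,
                           trait = trait)

  E_sex <- expr_sex_matrix(expr_ls, sex)
  eqtl <- map_eqtls(E_sex, cohort$geno, cohort$genome$genes,
                    window = window, min_maf = min_maf, n_perm = n_perm,
                    fdr_target = fdr, seed = seed)

  med <- select_mediators(assoc, eqtl, fdr = fdr)
  screen <- model <- scores <- insample <- calibration <- holdout <- NULL
  if (nrow(med)) {
    train_lines <- colnames(E_sex)
    screen <- snp_trait_screen(cohort$geno, cohort$pheno,
                               unique(med$variant), trait = trait, sex = sex,
                               lines = train_lines, alpha = alpha)
    model <- build_flow_model(med, screen, trait = trait, sex = sex)
    if (nrow(model$entries)) {
      scores <- score_lines(model, cohort$geno, lines = train_lines)
      insample <- evaluate_prediction(scores, cohort$pheno, trait, sex,
                                      mode = "rank")
      calibration <- evaluate_prediction(scores, cohort$pheno, trait, sex,
                                         mode = "linear")
      if (length(cohort$holdout)) {
        holdout <- predict_holdout(model, calibration, cohort$geno,
                                   cohort$pheno, lines = cohort$holdout)
      }
    }
  }

  structure(list(sex = sex, trait = trait, expr = expr_ls, assoc = assoc,
                 eqtl = eqtl, mediators = med, screen = screen,
                 model = model, scores = scores, insample = insample,
                 calibration = calibration, holdout = holdout),
            class = "wing_pipeline")
}

#' @export
print.wing_pipeline <- function(x, ...) {
  cat("wing_pipeline (", x$sex, ", ", x$trait, ")\n", sep = "")
  cat("  type-2 genes at FDR < 0.2:",
      sum(x$assoc$fdr < 0.2, na.rm = TRUE), "\n")
  cat("  cis eGenes:", length(x$eqtl$egenes), "\n")
  cat("  mediator genes:",
      if (is.null(x$model)) 0 else length(unique(x$model$entries$gene)), "\n")
  if (!is.null(x$insample))
    cat(sprintf("  in-sample Spearman rho = %.3f (p = %.2g, n = %d)\n",
                x$insample$rho, x$insample$p, x$insample$n))
  if (!is.null(x$holdout))
    cat(sprintf("  holdout Pearson r = %.3f (p = %.2g, n = %d)\n",
                x$holdout$r, x$holdout$p, x$holdout$n))
  invisible(x)
}
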