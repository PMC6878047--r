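# Count preprocessing: sample/gene filtering, log-CPM with mean-variance
# precision weights, principal-component batch removal, replicate averaging
# and the QC concordance statistics.

#' Remove samples with abnormally shallow libraries
#'
#' Drops samples whose library size falls below `min_library_frac` times the
#' median library size and reports the removed ids.
#'
#' @param counts a `count_set`.
#' @param min_library_frac fraction of the median library size in `[0, 1)`;
#'   0 disables the filter.
#' @return the filtered `count_set`.
#' @export
filter_samples <- function(counts, min_library_frac = 0.25) {
  .assert_frac(min_library_frac, "min_library_frac")
  lib <- colSums(counts$counts)
  keep <- lib >= min_library_frac * stats::median(lib)
  if (!any(keep)) stop("all samples removed by the library-size filter")
  removed <- counts$samples$sample_id[!keep]
  if (length(removed))
    message("filter_samples: removed ", length(removed), " sample(s): ",
            paste(removed, collapse = ", "))
  structure(list(counts = counts$counts[, keep, drop = FALSE],
                 samples = counts$samples[keep, , drop = FALSE]),
            class = "count_set")
}

#' Remove genes with insufficient counts
#'
#' A gene is kept if and only if its total count across the retained samples
#' is at least `min_count_frac` times the number of samples (default 70\%),
#' i.e. genes averaging well under one read per sample are dropped.
#'
#' @param counts a `count_set`.
#' @param min_count_frac threshold as a fraction of the sample count.
#' @return the filtered `count_set`.
#' @export
filter_genes <- function(counts, min_count_frac = 0.7) {
  n <- ncol(counts$counts)
  if (n < 1) stop("no samples present")
  keep <- rowSums(counts$counts) >= min_count_frac * n
  structure(list(counts = counts$counts[keep, , drop = FALSE],
                 samples = counts$samples),
            class = "count_set")
}

#' Log-CPM transformation with mean-variance precision weights
#'
#' Converts counts to `log2((count + 0.5) / (library + 1) * 1e6)` and, for
#' `weights = "trend"`, attaches per-observation precision weights derived
#' from a mean-variance trend: expression is regressed on the line x sex
#' design, the square root of each gene's residual SD is smoothed (lowess)
#' against its average log2 count, the trend is evaluated at each
#' observation's fitted log2 count, and the weight is the predicted value to
#' the power -4 (an inverse-variance weight), clipped to `[1e-3, 1e3]`. This
#' down-weights observations from low-count genes whose log-CPM values are
#' intrinsically noisier. `weights = "unit"` skips the weighting for
#' ablation.
#'
#' @param counts a `count_set` with positive library sizes.
#' @param weights `"trend"` or `"unit"`.
#' @param span lowess span of the trend fit.
#' @return an object of class `expr_set`: list with `E` (genes x samples
#'   log-CPM), `weights` (same shape, or `NULL` for `"unit"`) and `samples`.
#' @export
log_cpm_weights <- function(counts, weights = c("trend", "unit"),
                            span = 0.5) {
  weights <- match.arg(weights)
  y <- counts$counts
  lib <- colSums(y)
  if (any(lib <= 0)) stop("library sizes must be positive")
  E <- log2(sweep(y + 0.5, 2, lib + 1, "/") * 1e6)
  dimnames(E) <- dimnames(y)

  W <- NULL
  if (weights == "trend") {
    grp <- factor(paste(counts$samples$line, counts$samples$sex))
    X <- stats::model.matrix(~ 0 + grp)
    fit <- stats::lm.fit(X, t(E))
    res <- t(fit$residuals)
    df <- ncol(E) - fit$rank
    if (df < 1) {
      warning("no residual degrees of freedom for the variance trend; ",
              "falling back to unit weights")
    } else {
      sd_g <- sqrt(rowSums(res^2) / df)
      abar <- rowMeans(log2(y + 0.5))
      lo <- stats::lowess(abar, sqrt(sd_g), f = span)
      fitted_E <- t(fit$fitted.values)
      fitted_count <- sweep(fitted_E, 2, log2(lib + 1) - log2(1e6), "+")
      pred <- stats::approx(lo$x, lo$y, xout = fitted_count, rule = 2,
                            ties = mean)$y
      W <- matrix(pmin(pmax(pred^-4, 1e-3), 1e3), nrow(E), ncol(E))
      dimnames(W) <- dimnames(E)
    }
  }
  structure(list(E = E, weights = W, samples = counts$samples),
            class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$E), "genes x", ncol(x$E), "units;",
      if (is.null(x$weights)) "unweighted" else "precision-weighted", "\n")
  invisible(x)
}

#' Regress out leading principal components (batch removal)
#'
#' Computes sample-space principal component scores and replaces each gene's
#' expression vector by the residual of its regression on the top `k`
#' scores, restoring the gene mean. The output is orthogonal to the removed
#' scores.
#'
#' By default (`protect_design = TRUE`) the scores are the principal
#' components of the gene-standardized *replicate residual* matrix, i.e.
#' expression after subtracting each line x sex mean. Replicate residuals
#' contain technical structure (library batch, processing day) but cannot
#' contain line-level biology, so batch directions are removed without
#' touching the sex or size axes even when those dominate the total
#' variance. `protect_design = FALSE` uses the plain gene-standardized
#' expression matrix instead, which is adequate when technical variance
#' dwarfs the biological axes.
#'
#' @param expr an `expr_set`.
#' @param k number of components to remove (`k <= 0` returns the input with a
#'   warning; `k` must be smaller than the number of samples).
#' @param protect_design estimate batch directions from replicate residuals
#'   (default) rather than from total expression.
#' @return the corrected `expr_set` (weights are passed through unchanged).
#' @export
remove_batch_pcs <- function(expr, k = 2, protect_design = TRUE) {
  if (k <= 0) {
    warning("k <= 0: no components removed")
    return(expr)
  }
  n <- ncol(expr$E)
  if (k >= n) stop("k must be smaller than the number of samples")
  Z <- expr$E
  if (protect_design) {
    grp <- factor(paste(expr$samples$line, expr$samples$sex))
    if (all(table(grp) < 2)) {
      warning("no replication: falling back to total-expression components")
    } else {
      mu <- t(apply(Z, 1, function(y) stats::ave(y, grp)))
      Z <- Z - mu
    }
  }
  Z <- Z - rowMeans(Z)
  s <- sqrt(rowSums(Z^2) / (n - 1))
  ok <- s > 0
  Z[ok, ] <- Z[ok, ] / s[ok]
  sv <- svd(Z[ok, , drop = FALSE], nu = 0, nv = k)
  scores <- sv$v

  X <- cbind(1, scores)
  fit <- stats::lm.fit(X, t(expr$E))
  out <- t(fit$residuals) + rowMeans(expr$E)
  dimnames(out) <- dimnames(expr$E)
  structure(list(E = out, weights = expr$weights, samples = expr$samples,
                 pc_scores = scores),
            class = "expr_set")
}

#' Average replicates into line x sex expression values
#'
#' Replaces replicate samples by their mean per line x sex. When precision
#' weights are present the combined weight is the sum of the replicate
#' weights (the inverse variance of a weighted mean under independent
#' observations).
#'
#' @param expr an `expr_set` at sample resolution.
#' @param lines optional character vector of expected lines; missing
#'   line x sex combinations are reported with a warning.
#' @return an `expr_set` whose units are line x sex; `samples` has columns
#'   `unit`, `line`, `sex`.
#' @export
summarize_line_sex <- function(expr, lines = NULL) {
  meta <- expr$samples
  grp <- paste(meta$line, meta$sex, sep = "_")
  units <- unique(grp)
  M <- outer(grp, units, "==") * 1           # samples x units indicator
  nrep <- colSums(M)
  E <- expr$E %*% sweep(M, 2, nrep, "/")
  W <- if (!is.null(expr$weights)) expr$weights %*% M else NULL
  u <- data.frame(unit = units,
                  line = sub("_(F|M)$", "", units),
                  sex = sub("^.*_", "", units),
                  stringsAsFactors = FALSE)
  colnames(E) <- units
  if (!is.null(W)) colnames(W) <- units
  if (!is.null(lines)) {
    want <- as.vector(outer(lines, c("F", "M"), paste, sep = "_"))
    absent <- setdiff(want, units)
    if (length(absent))
      warning("line x sex units without samples: ",
              paste(absent, collapse = ", "))
  }
  structure(list(E = E, weights = W, samples = u), class = "expr_set")
}

#' Replicate and cross-layer concordance statistics
#'
#' In within-layer mode, computes the Spearman correlation between every pair
#' of samples (across genes) and groups pairs as biological replicates (same
#' line and sex), same line but other sex, or non-replicates (different
#' lines). In cross-layer mode (`other` given, e.g. a protein matrix),
#' computes the per-gene Spearman correlation between the two layers across
#' shared line x sex units, with a large-sample p-value, plus summaries
#' (median rho; fraction of genes positively correlated at p < 0.05).
#'
#' @param expr an `expr_set` (sample level for within-layer mode, line x sex
#'   level for cross-layer mode).
#' @param other optional matrix genes x units (colnames `line_sex`) of the
#'   second layer.
#' @return an object of class `concordance_report`: within-layer mode has
#'   `pairs` (data.frame `a`, `b`, `relation`, `rho`) and `summary`;
#'   cross-layer mode has `genes` (data.frame `gene`, `rho`, `p`, `n`) and
#'   `summary` (`median_rho`, `frac_pos_sig`, `n_genes`).
#' @export
concordance_report <- function(expr, other = NULL) {
  if (is.null(other)) {
    if (ncol(expr$E) < 2) stop("need at least two samples")
    rho <- stats::cor(expr$E, method = "spearman")
    meta <- expr$samples
    idx <- which(upper.tri(rho), arr.ind = TRUE)
    same_line <- meta$line[idx[, 1]] == meta$line[idx[, 2]]
    same_sex <- meta$sex[idx[, 1]] == meta$sex[idx[, 2]]
    relation <- ifelse(same_line & same_sex, "replicate",
                       ifelse(same_line, "same-line-other-sex",
                              "non-replicate"))
    pairs <- data.frame(a = colnames(rho)[idx[, 1]],
                        b = colnames(rho)[idx[, 2]],
                        relation = relation, rho = rho[idx],
                        stringsAsFactors = FALSE)
    med <- tapply(pairs$rho, pairs$relation, stats::median)
    out <- list(mode = "within",
                pairs = pairs,
                summary = data.frame(relation = names(med),
                                     n = as.vector(table(pairs$relation)[names(med)]),
                                     median_rho = as.vector(med),
                                     row.names = NULL))
  } else {
    genes <- intersect(rownames(expr$E), rownames(other))
    units <- intersect(colnames(expr$E), colnames(other))
    if (length(units) < 3)
      stop("fewer than 3 shared units: per-gene correlation undefined")
    A <- expr$E[genes, units, drop = FALSE]
    B <- other[genes, units, drop = FALSE]
    n <- length(units)
    rho <- p <- rep(NA_real_, length(genes))
    for (i in seq_along(genes)) {
      if (stats::sd(A[i, ]) == 0 || stats::sd(B[i, ]) == 0) next
      r <- stats::cor(A[i, ], B[i, ], method = "spearman")
      rho[i] <- r
      p[i] <- .p_from_r2(r^2, n - 2)
    }
    gtab <- data.frame(gene = genes, rho = rho, p = p, n = n,
                       stringsAsFactors = FALSE)
    out <- list(mode = "cross",
                genes = gtab,
                summary = data.frame(
                  median_rho = stats::median(rho, na.rm = TRUE),
                  frac_pos_sig = mean(rho > 0 & p < 0.05, na.rm = TRUE),
                  n_genes = sum(!is.na(rho))))
  }
  structure(out, class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report (", x$mode, "-layer )\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
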