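# shared internal helpers

#' Derive a submodule seed from a master seed and a label
#'
#' All stochastic generators in the package draw their RNG state from a single
#' master seed combined with a fixed text label, so that partial reruns of a
#' cohort (e.g. regenerating phenotypes only) are reproducible without
#' coupling the RNG streams of unrelated components.
#'
#' @param seed master seed (single number).
#' @param label character label naming the consuming component.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_prob <- function(p, what = "p") {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
  invisible(p)
}

.assert_frac <- function(x, what, lo = 0, hi = 1, hi_open = TRUE) {
  bad <- !is.numeric(x) || length(x) != 1L || is.na(x) || x < lo ||
    (if (hi_open) x >= hi else x > hi)
  if (bad) stop(what, " must be in [", lo, ", ", hi, if (hi_open) ")" else "]",
                call. = FALSE)
  invisible(x)
}

# p-value of a two-sided test of a single regression slope, from r^2 and the
# residual df; identical to the square of the usual t test
.p_from_r2 <- function(r2, df) {
  r2 <- pmin(pmax(r2, 0), 1)
  stats::pf(r2 * df / pmax(1 - r2, .Machine$double.xmin), 1, df,
            lower.tail = FALSE)
}
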