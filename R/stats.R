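# Shared statistical primitives. Group comparisons throughout the package
# are Welch two-sample t-tests on log2-transformed values after adding a
# pseudo-count, and multiple testing is controlled with Benjamini-Hochberg.

#' Welch two-sample t-test on log2-transformed values
#'
#' Adds a pseudo-count, log2-transforms both samples, and runs a Welch
#' (unequal-variance) two-sample t-test with Welch-Satterthwaite degrees
#' of freedom and a two-sided p-value. The pseudo-count default of 0.1
#' mirrors the FPKM convention used for fold-change recalculation.
#'
#' @param x,y Numeric samples with at least two values each;
#'   `x + pseudo` and `y + pseudo` must be strictly positive.
#' @param pseudo Pseudo-count added before the log transform; default 0.1.
#' @return An object of class `welch_log2`: a list with `mean_x`, `mean_y`
#'   (log2 scale), `t`, `df` and two-sided `p`. When both groups are
#'   constant with equal means, `t = 0`, `p = 1` and `df = NA`; constant
#'   groups with unequal means give `t = +/-Inf`, `p = 0`.
#' @export
welch_log2 <- function(x, y, pseudo = 0.1) {
  stopifnot(is.numeric(x), is.numeric(y), length(pseudo) == 1L, pseudo >= 0)
  if (length(x) < 2L || length(y) < 2L) {
    stop("welch_log2 needs at least two values per group")
  }
  if (any(x + pseudo <= 0) || any(y + pseudo <= 0)) {
    stop("all values plus pseudo-count must be strictly positive")
  }
  lx <- log2(x + pseudo)
  ly <- log2(y + pseudo)
  if (stats::var(lx) == 0 && stats::var(ly) == 0) {
    d <- mean(lx) - mean(ly)
    res <- list(mean_x = mean(lx), mean_y = mean(ly),
                t = if (d == 0) 0 else sign(d) * Inf,
                df = NA_real_,
                p = if (d == 0) 1 else 0)
  } else {
    tt <- stats::t.test(lx, ly)
    res <- list(mean_x = mean(lx), mean_y = mean(ly),
                t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  structure(res, class = "welch_log2")
}

#' @export
print.welch_log2 <- function(x, ...) {
  cat(sprintf("Welch t-test on log2 values: t = %.4g, df = %.3g, p = %.4g\n",
              x$t, x$df, x$p))
  cat(sprintf("  group means (log2): %.4g vs %.4g\n", x$mean_x, x$mean_y))
  invisible(x)
}

#' Squared Pearson correlation with p-value
#'
#' @param a,b Numeric vectors of equal length (at least 3).
#' @return A list with `r2` (in `[0, 1]`), the two-sided `p` from the
#'   t transform of the correlation, and `degenerate` (`TRUE`, with
#'   `NA` estimates, when either vector has zero variance).
#' @export
pearson_r2 <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3L) stop("need at least 3 paired values")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r2 = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r2 = unname(ct$estimate)^2, p = ct$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate adjustment; the result is
#' returned in the input order and is element-wise at least as large as
#' the input after the ranking adjustment.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values of the same length.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(is.numeric(pvalues))
  if (length(pvalues) && (any(is.na(pvalues)) ||
                          any(pvalues < 0 | pvalues > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
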