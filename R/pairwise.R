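#' Hedges' g standardized mean difference
#'
#' Small-sample-corrected Cohen's d:
#' \deqn{g = J \cdot (\bar a - \bar b) / s_{pooled}, \quad
#'       J = 1 - 3 / (4(n_a + n_b - 2) - 1).}
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @return Scalar effect size; `|g| < |d|` always, since `J < 1`.
#' @export
hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("undefined-effect error: zero pooled variance", call. = FALSE)
  J <- 1 - 3 / (4 * (na + nb - 2) - 1)
  J * (mean(a) - mean(b)) / sqrt(sp2)
}

#' Normality-gated pairwise comparison with Bonferroni correction
#'
#' Tests each sample (and, when paired, the differences) for normality with
#' Shapiro-Wilk at alpha = 0.05. If nothing rejects, a t-test is used (paired,
#' or two-sample Welch by default); otherwise the Wilcoxon analogue
#' (signed-rank or rank-sum). The raw p-value is Bonferroni-corrected for
#' `m_comparisons` comparisons within the feature group:
#' `p_bonferroni = min(1, m * p_raw)`. Hedges' g is attached for the
#' parametric branch.
#'
#' @param a,b Numeric samples (n >= 3 for the normality gate).
#' @param paired Paired comparison? (default FALSE).
#' @param m_comparisons Number of comparisons in the feature group (default 1).
#' @param label Comparison label carried into the result.
#' @param pooled_t Use the pooled-variance two-sample t instead of Welch.
#' @return An object of class `pairwise_result`: list with `test` ("t" or
#'   "wilcoxon"), `statistic`, `p_raw`, `p_bonferroni`, `hedges_g`, `n`,
#'   `normality_p`.
#' @export
gated_pairwise <- function(a, b, paired = FALSE, m_comparisons = 1,
                           label = "a vs b", pooled_t = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stopifnot(length(a) >= 3, length(b) >= 3)
  if (paired && length(a) != length(b))
    stop("paired samples must have equal length", call. = FALSE)
  shap_p <- function(x) {
    if (length(unique(x)) < 3) return(0)   # degenerate: treat as non-normal
    stats::shapiro.test(x)$p.value
  }
  norm_p <- if (paired) c(a = shap_p(a), b = shap_p(b), diff = shap_p(a - b))
            else c(a = shap_p(a), b = shap_p(b))
  parametric <- all(norm_p > 0.05)
  if (parametric) {
    tt <- stats::t.test(a, b, paired = paired, var.equal = pooled_t)
    test <- "t"; statistic <- unname(tt$statistic); p_raw <- tt$p.value
    g <- tryCatch(hedges_g(a, b), error = function(e) NA_real_)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired, exact = FALSE))
    test <- "wilcoxon"; statistic <- unname(wt$statistic); p_raw <- wt$p.value
    g <- NA_real_
  }
  structure(list(label = label, test = test, statistic = statistic,
                 p_raw = p_raw,
                 p_bonferroni = min(1, m_comparisons * p_raw),
                 hedges_g = g, n = c(length(a), length(b)),
                 normality_p = norm_p, paired = paired),
            class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("<pairwise> %s: %s-test, stat=%.3f, p=%.4g (Bonferroni %.4g)%s\n",
              x$label, x$test, x$statistic, x$p_raw, x$p_bonferroni,
              if (is.finite(x$hedges_g)) sprintf(", g=%.2f", x$hedges_g) else ""))
  invisible(x)
}
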