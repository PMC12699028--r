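# F ratio with explicit degenerate handling: a zero error SS is tolerated
# when the effect SS is also zero (constant data along the effect -> F = 0);
# a positive effect with no error variance is a degenerate model.
f_ratio <- function(ss_e, df_e, ss_err, df_err, ss_total) {
  tol <- .Machine$double.eps^0.75 * max(ss_total, 1)
  if (ss_err <= tol) {
    if (ss_e <= tol) return(0)
    stop("degenerate-model error: zero error variance", call. = FALSE)
  }
  (ss_e / df_e) / (ss_err / df_err)
}

# Greenhouse-Geisser epsilon from the pooled within-subject covariance of a
# subjects x levels score matrix (pooled over groups when `group` is given).
gg_epsilon <- function(scores, group = NULL) {
  k <- ncol(scores)
  if (is.null(group)) group <- rep(1, nrow(scores))
  centered <- do.call(rbind, lapply(split.data.frame(scores, group), function(m)
    sweep(m, 2, colMeans(m))))
  S <- crossprod(centered) / (nrow(scores) - length(unique(group)))
  # double-center
  M <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) + mean(S)
  sum(diag(M))^2 / ((k - 1) * sum(M^2))
}

#' Mixed (split-plot) ANOVA
#'
#' Two-factor mixed design: one between-subject factor (group) and one
#' within-subject factor on which every participant has all levels. The
#' between effect is tested against subject-within-group error; the within and
#' interaction effects against the subject x within residual. Sums of squares
#' are sequential (group, then within, then interaction), which coincides with
#' the classical decomposition for balanced groups. Greenhouse-Geisser
#' epsilon and the epsilon-corrected p-values are reported alongside the
#' uncorrected ones for the within-subject effects.
#'
#' @param data Long-format data.frame.
#' @param dv,subject,within,between Column names of the dependent variable,
#'   subject id, within-subject factor and between-subject factor.
#' @return An object of class `anova_table`: a data.frame with one row per
#'   effect (`group`, `within`, `interaction`) giving `F`, `df1`, `df2`, `p`,
#'   `eta_p_sq`, `gg_epsilon`, `p_gg`.
#' @export
mixed_anova <- function(data, dv, subject, within, between) {
  y <- data[[dv]]
  s <- factor(data[[subject]]); w <- factor(data[[within]]); g <- factor(data[[between]])
  tab <- table(s, w)
  if (any(tab != 1))
    stop("unbalanced data: every subject must have exactly one value per within level",
         call. = FALSE)
  if (any(table(unique(data.frame(s, g))$g) < 2))
    stop("need at least 2 subjects per group", call. = FALSE)
  k <- nlevels(w); G <- nlevels(g); N <- nlevels(s)
  grand <- mean(y)
  ms <- tapply(y, s, mean)                       # subject means
  subj_group <- tapply(as.character(g), s, `[`, 1)
  mg <- tapply(y, g, mean); ng <- table(subj_group)
  mw <- tapply(y, w, mean)
  mcell <- tapply(y, list(g, w), mean)

  ss_subjects <- k * sum((ms - grand)^2)
  ss_group <- k * sum(ng * (mg[names(ng)] - grand)^2)
  ss_subj_err <- ss_subjects - ss_group
  ss_within <- N * sum((mw - grand)^2)
  ss_cells <- sum(sweep((mcell - grand)^2, 1, as.numeric(ng[rownames(mcell)]), `*`))
  ss_inter <- ss_cells - ss_group - ss_within
  ss_total <- sum((y - grand)^2)
  ss_resid <- ss_total - ss_subjects - ss_within - ss_inter

  df_group <- G - 1; df_subj <- N - G
  df_within <- k - 1; df_inter <- (G - 1) * (k - 1); df_resid <- (N - G) * (k - 1)

  scores <- do.call(rbind, lapply(levels(s), function(si)
    y[s == si][order(w[s == si])]))
  eps <- gg_epsilon(scores, group = subj_group[levels(s)])

  row <- function(effect, ss_e, df_e, ss_err, df_err, use_eps) {
    Fv <- f_ratio(ss_e, df_e, ss_err, df_err, ss_total)
    p <- stats::pf(Fv, df_e, df_err, lower.tail = FALSE)
    p_gg <- if (use_eps && is.finite(eps))
      stats::pf(Fv, eps * df_e, eps * df_err, lower.tail = FALSE) else NA_real_
    data.frame(effect = effect, F = Fv, df1 = df_e, df2 = df_err, p = p,
               eta_p_sq = if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err) else 0,
               gg_epsilon = if (use_eps) eps else NA_real_, p_gg = p_gg,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("group", ss_group, df_group, ss_subj_err, df_subj, FALSE),
    row("within", ss_within, df_within, ss_resid, df_resid, TRUE),
    row("interaction", ss_inter, df_inter, ss_resid, df_resid, TRUE))
  attr(out, "ss") <- c(group = ss_group, subject_error = ss_subj_err,
                       within = ss_within, interaction = ss_inter,
                       residual = ss_resid, total = ss_total)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject factor only (e.g. questionnaire scores over timepoints in a
#' single group). With two levels, F equals the squared paired t statistic.
#'
#' @param data Long-format data.frame.
#' @param dv,subject,within Column names.
#' @return An `anova_table` with a single `within` row.
#' @export
rm_anova <- function(data, dv, subject, within) {
  y <- data[[dv]]
  s <- factor(data[[subject]]); w <- factor(data[[within]])
  if (any(table(s, w) != 1))
    stop("unbalanced data: every subject must have exactly one value per level",
         call. = FALSE)
  k <- nlevels(w); n <- nlevels(s)
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  ss_subj <- k * sum((tapply(y, s, mean) - grand)^2)
  ss_within <- n * sum((tapply(y, w, mean) - grand)^2)
  ss_err <- ss_total - ss_subj - ss_within
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  Fv <- f_ratio(ss_within, df1, ss_err, df2, ss_total)
  scores <- do.call(rbind, lapply(levels(s), function(si)
    y[s == si][order(w[s == si])]))
  eps <- gg_epsilon(scores)
  out <- data.frame(effect = "within", F = Fv, df1 = df1, df2 = df2,
                    p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
                    eta_p_sq = if (ss_within + ss_err > 0)
                      ss_within / (ss_within + ss_err) else 0,
                    gg_epsilon = eps,
                    p_gg = if (is.finite(eps))
                      stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
                    else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "ss") <- c(subject = ss_subj, within = ss_within,
                       residual = ss_err, total = ss_total)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$F <- round(df$F, 3); df$p <- signif(df$p, 3)
  df$eta_p_sq <- round(df$eta_p_sq, 3)
  df$gg_epsilon <- round(df$gg_epsilon, 3); df$p_gg <- signif(df$p_gg, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
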