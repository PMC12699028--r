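# Smoothness (FWHM, in nodes) of a 1D field, estimated from the gradients of
# the normalized residuals (Kiebel-style estimator).
estimate_fwhm <- function(residuals) {
  ssq <- colSums(residuals^2)
  dx <- residuals[, -1, drop = FALSE] - residuals[, -ncol(residuals), drop = FALSE]
  v <- colSums(dx^2) / (sqrt(ssq[-length(ssq)] * ssq[-1]) + .Machine$double.eps)
  rpn <- sqrt(v / (4 * log(2)))            # resels per node
  1 / mean(rpn)
}

# Expected Euler characteristic of a 1D t field of `df` degrees of freedom
# thresholded at u, over `resels` resolution elements.
ec_expected_t <- function(u, df, resels) {
  p0 <- stats::pt(u, df, lower.tail = FALSE)
  p1 <- resels * sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
  p0 + p1
}

# Random-field-theory critical threshold for a 1D t field: solves
# alpha = 1 - exp(-E[EC]) for the threshold u.
rft_threshold_t <- function(alpha, df, resels) {
  f <- function(u) 1 - exp(-ec_expected_t(u, df, resels)) - alpha
  lo <- stats::qt(1 - alpha, df)
  hi <- 50
  while (f(hi) > 0 && hi < 1e8) hi <- hi * 10   # heavy EC tail at tiny df
  if (f(hi) > 0) return(Inf)                    # level unattainable
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Two-sample SPM\{t\} over a 101-node waveform
#'
#' Statistical parametric mapping of a group difference along the gait cycle:
#' a node-wise two-sample t statistic (pooled variance,
#' `df = nA + nB - 2`), a family-wise critical threshold from 1D
#' random field theory (expected Euler characteristic of the t field at the
#' smoothness estimated from the normalized residual gradients), and the
#' suprathreshold clusters. Inference is two-sided on `|t|` (the RFT
#' threshold is taken at `alpha/2` per tail), with each cluster annotated by
#' its direction. A permutation threshold (the `1 - alpha` quantile of the
#' max-`|t|` null distribution over group-label permutations) is computed as
#' a cross-check; labels are enumerated exhaustively when there are at most
#' 20,000 distinct assignments, otherwise `permutations` random draws are
#' used.
#'
#' @param group_a,group_b Numeric matrices, one row per participant
#'   (that participant's mean waveform), 101 columns.
#' @param alpha Family-wise error level (default 0.05).
#' @param permutations Random permutation count when not enumerating
#'   (default 10000); `0` skips the permutation cross-check entirely.
#' @param seed Seed for the permutation draw (default 1).
#' @return An object of class `spm_result`: `t_field` (101 values),
#'   `critical_threshold`, `clusters` (data.frame start_node, end_node,
#'   extent_pct, direction), `fwhm_estimate`, `resels`, `df`, `alpha`,
#'   `perm_threshold`.
#' @export
spm_ttest2 <- function(group_a, group_b, alpha = 0.05, permutations = 10000,
                       seed = 1) {
  A <- as.matrix(group_a); B <- as.matrix(group_b)
  stopifnot(ncol(A) == 101, ncol(B) == 101, nrow(A) >= 2, nrow(B) >= 2)
  nA <- nrow(A); nB <- nrow(B); df <- nA + nB - 2
  tfield_of <- function(A, B) {
    mA <- colMeans(A); mB <- colMeans(B)
    sp2 <- (colSums(sweep(A, 2, mA)^2) + colSums(sweep(B, 2, mB)^2)) / df
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    tt <- (mA - mB) / se
    tt[se == 0] <- NA_real_
    tt
  }
  t_field <- tfield_of(A, B)
  if (anyNA(t_field)) warning("zero-variance nodes excluded from inference")
  resid <- rbind(sweep(A, 2, colMeans(A)), sweep(B, 2, colMeans(B)))
  fwhm <- estimate_fwhm(resid)
  resels <- (ncol(A) - 1) / fwhm
  tstar <- rft_threshold_t(alpha / 2, df, resels)

  # clusters: maximal runs with |t| above threshold
  over <- !is.na(t_field) & abs(t_field) > tstar
  clusters <- NULL
  if (any(over)) {
    r <- rle(over)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    idx <- which(r$values)
    clusters <- data.frame(
      start_node = starts[idx] - 1L, end_node = ends[idx] - 1L,
      extent_pct = 100 * r$lengths[idx] / 101,
      direction = vapply(idx, function(i)
        sign(mean(t_field[starts[i]:ends[i]])), numeric(1)))
  } else {
    clusters <- data.frame(start_node = integer(0), end_node = integer(0),
                           extent_pct = numeric(0), direction = numeric(0))
  }

  # permutation cross-check: max-|t| null distribution over label permutations
  perm_threshold <- NA_real_
  if (permutations > 0) {
  all_rows <- rbind(A, B)
  n <- nA + nB
  n_total <- choose(n, nA)
  max_abs_t <- function(labels) {
    tt <- tfield_of(all_rows[labels, , drop = FALSE],
                    all_rows[-labels, , drop = FALSE])
    max(abs(tt), na.rm = TRUE)
  }
  if (n_total <= 20000) {
    combs <- utils::combn(n, nA)
    maxima <- apply(combs, 2, max_abs_t)
    attainable_p <- 1 / n_total
  } else {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    maxima <- c(max_abs_t(seq_len(nA)),
                vapply(seq_len(permutations - 1), function(i)
                  max_abs_t(sample.int(n, nA)), numeric(1)))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    attainable_p <- 1 / permutations
  }
  if (attainable_p > alpha)
    warning("permutation resolution too coarse for alpha; attainable minimum p = ",
            attainable_p)
  perm_threshold <- unname(stats::quantile(maxima, 1 - alpha, type = 7))
  }

  structure(list(t_field = t_field, critical_threshold = tstar,
                 clusters = clusters, fwhm_estimate = fwhm, resels = resels,
                 df = df, alpha = alpha, perm_threshold = perm_threshold,
                 n = c(nA, nB)),
            class = "spm_result")
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf("<spm_result> two-sample SPM{t}, df=%d, FWHM=%.1f nodes, t*=%.3f (RFT), %.3f (perm)\n",
              x$df, x$fwhm_estimate, x$critical_threshold, x$perm_threshold))
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("  cluster: %d-%d%% of stride (%s)\n",
                  x$clusters$start_node[i], x$clusters$end_node[i],
                  if (x$clusters$direction[i] > 0) "A > B" else "A < B"))
  } else cat("  no suprathreshold clusters\n")
  invisible(x)
}

#' @export
plot.spm_result <- function(x, ...) {
  graphics::plot(0:100, x$t_field, type = "l", xlab = "% of stride",
                 ylab = "SPM{t}", ...)
  graphics::abline(h = c(-1, 1) * x$critical_threshold, lty = 2)
  graphics::abline(h = 0, col = "grey")
  if (nrow(x$clusters))
    for (i in seq_len(nrow(x$clusters))) {
      idx <- (x$clusters$start_node[i]:x$clusters$end_node[i]) + 1
      graphics::points(idx - 1, x$t_field[idx], col = "red", pch = 16, cex = 0.5)
    }
  invisible(x)
}

#' Smooth Gaussian 1D fields
#'
#' Generates zero-mean, unit-variance Gaussian random fields with a target
#' smoothness, for null simulations of waveform statistics: white noise is
#' convolved with a Gaussian kernel of the requested FWHM and rescaled to
#' unit marginal variance.
#'
#' @param n Number of fields (rows).
#' @param nodes Field length (default 101).
#' @param fwhm Full width at half maximum of the smoothing kernel, in nodes.
#' @return An `n x nodes` matrix.
#' @export
smooth_gaussian_fields <- function(n, nodes = 101, fwhm = 15) {
  sd_k <- fwhm / (2 * sqrt(2 * log(2)))
  half <- ceiling(3 * sd_k)
  kern <- stats::dnorm(-half:half, sd = sd_k)
  kern <- kern / sqrt(sum(kern^2))          # unit output variance
  pad <- nodes + 2 * half
  out <- matrix(0, n, nodes)
  for (i in seq_len(n)) {
    w <- stats::rnorm(pad)
    sm <- stats::convolve(w, rev(kern), type = "filter")
    out[i, ] <- sm[seq_len(nodes)]
  }
  out
}
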