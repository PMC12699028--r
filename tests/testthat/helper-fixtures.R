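# Shared fixture builders (all data generated in code).

# Minimal keypoint series: all keypoints at fixed positions unless overridden.
# `override` is a named list keypoint -> n x 2 matrix (x, y).
toy_keypoints <- function(n = 100, fps = 50, override = list(), conf = NULL) {
  kp <- keypoint_names()
  x <- matrix(100, n, 17, dimnames = list(NULL, kp))
  y <- matrix(200, n, 17, dimnames = list(NULL, kp))
  # spread defaults so segments are non-degenerate
  y[, "left_hip"] <- 300; y[, "left_knee"] <- 390; y[, "left_ankle"] <- 480
  y[, "left_shoulder"] <- 180; y[, "left_elbow"] <- 250; y[, "left_wrist"] <- 310
  for (nm in names(override)) {
    x[, nm] <- override[[nm]][, 1]
    y[, nm] <- override[[nm]][, 2]
  }
  keypoint_series(x, y, confidence = conf, fps = fps)
}

# Stride set built directly from a matrix of strides.
toy_strides <- function(m, stride_times = NULL) {
  m <- matrix(m, ncol = 101, byrow = FALSE)
  if (is.null(stride_times)) stride_times <- rep(1.2, nrow(m))
  stride_set(m, stride_times)
}

# Long-format mixed-design table from a subjects x levels matrix per group.
long_table <- function(mats) {
  rows <- list()
  sid <- 0
  for (g in names(mats)) {
    m <- mats[[g]]
    for (i in seq_len(nrow(m))) {
      sid <- sid + 1
      rows[[length(rows) + 1]] <- data.frame(
        subject = sprintf("S%02d", sid), group = g,
        level = paste0("L", seq_len(ncol(m))), y = m[i, ])
    }
  }
  do.call(rbind, rows)
}

# Independent brute-force split-plot sums-of-squares oracle (cell/group/
# subject means computed directly; no reuse of package internals).
split_plot_oracle <- function(d) {
  y <- d$y; s <- d$subject; w <- d$level; g <- d$group
  grand <- mean(y)
  k <- length(unique(w))
  subj_means <- tapply(y, s, mean)
  subj_grp <- tapply(as.character(g), s, unique)
  ss_subjects <- k * sum((subj_means - grand)^2)
  ng <- table(subj_grp)
  gm <- tapply(y, g, mean)
  ss_group <- k * sum(ng * (gm[names(ng)] - grand)^2)
  ss_time <- length(unique(s)) * sum((tapply(y, w, mean) - grand)^2)
  cell <- tapply(y, list(g, w), mean)
  ss_cells <- sum(sweep((cell - grand)^2, 1, as.numeric(ng[rownames(cell)]), `*`))
  ss_total <- sum((y - grand)^2)
  list(group = ss_group, subj_err = ss_subjects - ss_group, time = ss_time,
       inter = ss_cells - ss_group - ss_time,
       resid = ss_total - ss_subjects - ss_time - (ss_cells - ss_group - ss_time),
       total = ss_total)
}

# Exhaustive local-maxima scan (independent oracle for peak detection):
# every interior frame strictly above its predecessor and >= its successor.
bruteforce_maxima <- function(d) {
  n <- length(d)
  which(vapply(2:(n - 1), function(i) d[i] > d[i - 1] && d[i] >= d[i + 1],
               logical(1))) + 1L
}
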