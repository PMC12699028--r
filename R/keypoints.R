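#' The 17-keypoint controlled vocabulary
#'
#' Names of the anatomical keypoints expected in every frame of a
#' [keypoint_series], in canonical (COCO) order: nose, eyes, ears, shoulders,
#' elbows, wrists, hips, knees and ankles (left/right).
#'
#' @return Character vector of length 17.
#' @export
keypoint_names <- function() {
  c("nose",
    "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle")
}

#' Keypoint trajectory series
#'
#' Container for a sagittal-plane pose-estimation trial: per-frame x/y pixel
#' coordinates plus detection confidence for the 17 anatomical keypoints,
#' sampled at a fixed frame rate.
#'
#' Missing detections are represented by confidence 0 (coordinates may be NA);
#' they are never interpolated -- downstream stages flag affected frames and
#' drop affected strides instead.
#'
#' @param x,y Numeric matrices, frames x 17, with columns named by
#'   [keypoint_names()] (any order; they are reordered canonically).
#' @param confidence Numeric matrix like `x`, values in `[0, 1]`. Defaults to
#'   all ones.
#' @param fps Frames per second (default 50).
#' @param participant_id Participant label.
#' @param bout Walking bout label, `"slow"` or `"fast"`.
#' @return An object of class `keypoint_series`.
#' @export
keypoint_series <- function(x, y, confidence = NULL, fps = 50,
                            participant_id = "P00", bout = c("slow", "fast")) {
  bout <- match.arg(bout)
  x <- as.matrix(x); y <- as.matrix(y)
  if (is.null(confidence)) {
    confidence <- matrix(1, nrow(x), ncol(x), dimnames = dimnames(x))
  }
  confidence <- as.matrix(confidence)
  kp <- keypoint_names()
  for (m in list(x, y, confidence)) {
    if (is.null(colnames(m)) || !setequal(colnames(m), kp))
      stop("keypoint schema error: columns must be exactly the 17 keypoint names",
           call. = FALSE)
  }
  x <- x[, kp, drop = FALSE]
  y <- y[, kp, drop = FALSE]
  confidence <- confidence[, kp, drop = FALSE]
  if (nrow(x) < 1L) stop("keypoint series must contain at least one frame", call. = FALSE)
  if (!isTRUE(fps > 0)) stop("fps must be positive", call. = FALSE)
  ok <- confidence > 0
  if (any(!is.finite(x[ok])) || any(!is.finite(y[ok])))
    stop("non-finite coordinates at confident keypoints", call. = FALSE)
  structure(
    list(x = x, y = y, confidence = confidence, fps = fps,
         participant_id = participant_id, bout = bout),
    class = "keypoint_series")
}

#' @export
print.keypoint_series <- function(x, ...) {
  cat(sprintf("<keypoint_series> %s/%s: %d frames @ %g fps (%.1f s), 17 keypoints\n",
              x$participant_id, x$bout, n_frames(x), x$fps, n_frames(x) / x$fps))
  miss <- mean(x$confidence == 0)
  if (miss > 0) cat(sprintf("  missing detections: %.1f%% of keypoint-frames\n", 100 * miss))
  invisible(x)
}

#' Number of frames in a keypoint series
#' @param series A [keypoint_series].
#' @return Integer frame count.
#' @export
n_frames <- function(series) nrow(series$x)

#' Read keypoint trajectories from CSV or JSON
#'
#' Two dialects are supported. CSV is long-format with columns
#' `frame,keypoint,x,y,confidence` (one row per keypoint per frame). JSON is
#' pose-estimator style: an array of frames, each an object mapping keypoint
#' name to `[x, y, confidence]`.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @param fps,participant_id,bout Metadata not carried by the file formats.
#' @return A [keypoint_series].
#' @export
read_keypoints <- function(path, format = c("auto", "csv", "json"), fps = 50,
                           participant_id = "P00", bout = "slow") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("frame", "keypoint", "x", "y", "confidence")
    if (!all(need %in% names(d)))
      stop("keypoint CSV parse error: need columns ", paste(need, collapse = ","),
           call. = FALSE)
    frames <- sort(unique(d$frame))
    per_frame <- table(d$frame)
    if (any(per_frame != 17L))
      stop("keypoint schema error: frame ", names(per_frame)[per_frame != 17L][1],
           " has ", per_frame[per_frame != 17L][1], " keypoints, expected 17",
           call. = FALSE)
    kp <- keypoint_names()
    if (!setequal(unique(d$keypoint), kp))
      stop("keypoint schema error: keypoint names do not match the 17-name set",
           call. = FALSE)
    d <- d[order(d$frame, match(d$keypoint, kp)), ]
    nf <- length(frames)
    shape <- function(v) matrix(v, nf, 17, byrow = TRUE, dimnames = list(NULL, kp))
    keypoint_series(shape(d$x), shape(d$y), shape(d$confidence), fps = fps,
                    participant_id = participant_id, bout = bout)
  } else {
    fr <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (length(fr) == 0) stop("keypoint JSON parse error: empty frame list", call. = FALSE)
    kp <- keypoint_names()
    grab <- function(f, j) {
      if (!setequal(names(f), kp))
        stop("keypoint schema error: keypoint names do not match the 17-name set",
             call. = FALSE)
      vapply(kp, function(k) as.numeric(f[[k]][[j]]), numeric(1))
    }
    x <- t(vapply(fr, grab, numeric(17), j = 1))
    y <- t(vapply(fr, grab, numeric(17), j = 2))
    cf <- t(vapply(fr, grab, numeric(17), j = 3))
    colnames(x) <- colnames(y) <- colnames(cf) <- kp
    keypoint_series(x, y, cf, fps = fps, participant_id = participant_id, bout = bout)
  }
}

#' Write keypoint trajectories
#'
#' Inverse of [read_keypoints()]; round-trips all per-frame fields.
#'
#' @param series A [keypoint_series].
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(series, path, format = c("csv", "json")) {
  format <- match.arg(format)
  kp <- keypoint_names()
  nf <- n_frames(series)
  if (format == "csv") {
    d <- data.frame(
      frame = rep(seq_len(nf), each = 17),
      keypoint = rep(kp, nf),
      x = as.vector(t(series$x)),
      y = as.vector(t(series$y)),
      confidence = as.vector(t(series$confidence)))
    utils::write.csv(d, path, row.names = FALSE)
  } else {
    fr <- lapply(seq_len(nf), function(i) {
      f <- lapply(kp, function(k) c(series$x[i, k], series$y[i, k], series$confidence[i, k]))
      names(f) <- kp
      f
    })
    jsonlite::write_json(fr, path, auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Remove the treadmill familiarization period
#'
#' Drops the first `trim_seconds` of the trial (default 30 s) so the retained
#' frames reflect steady-state walking.
#'
#' @param series A [keypoint_series].
#' @param trim_seconds Seconds to drop from the start (default 30).
#' @return The trimmed [keypoint_series].
#' @export
trim_familiarization <- function(series, trim_seconds = 30) {
  stopifnot(trim_seconds >= 0)
  n_drop <- round(trim_seconds * series$fps)
  if (n_drop >= n_frames(series))
    stop("empty trial: duration (", n_frames(series) / series$fps,
         " s) does not exceed trim_seconds (", trim_seconds, " s)", call. = FALSE)
  if (n_drop == 0) return(series)
  keep <- (n_drop + 1):n_frames(series)
  series$x <- series$x[keep, , drop = FALSE]
  series$y <- series$y[keep, , drop = FALSE]
  series$confidence <- series$confidence[keep, , drop = FALSE]
  series
}

#' Low-pass filter keypoint trajectories
#'
#' Applies a zero-phase (forward-backward) Butterworth low-pass filter to every
#' x and y channel. The design order refers to the one-pass filter; the
#' forward-backward application squares the magnitude response, i.e. the
#' effective attenuation is that of a filter of twice the design order with no
#' phase lag. The confidence channel is untouched.
#'
#' @param series A [keypoint_series].
#' @param cutoff_hz Cutoff frequency in Hz (default 10); must be below Nyquist.
#' @param order Butterworth design order (default 2).
#' @return The filtered [keypoint_series].
#' @export
filter_trajectories <- function(series, cutoff_hz = 10, order = 2) {
  nyq <- series$fps / 2
  if (!(cutoff_hz > 0 && cutoff_hz < nyq))
    stop("cutoff_hz must lie in (0, Nyquist = ", nyq, " Hz)", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  # odd-symmetric reflection padding suppresses the start/end transients of
  # the forward-backward pass
  pad <- min(n_frames(series) - 1L, 50L)
  smooth <- function(m) apply(m, 2, function(col) {
    n <- length(col)
    ext <- c(2 * col[1] - col[(pad + 1):2], col, 2 * col[n] - col[(n - 1):(n - pad)])
    signal::filtfilt(bf, ext)[(pad + 1):(pad + n)]
  })
  series$x <- smooth(series$x)
  series$y <- smooth(series$y)
  colnames(series$x) <- colnames(series$y) <- keypoint_names()
  series
}
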