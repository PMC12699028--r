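#' Extract per-bout gait features from a keypoint trial
#'
#' Runs the single-trial gait chain: low-pass filter the trajectories, trim
#' the familiarization period, detect left heel strikes from the ankle-hip
#' distance, compute joint angles, segment every angle signal into
#' 101-node strides, apply the non-functional-arm-stride exclusion to the arm
#' signals, and compute stride time, coefficients of variation and upper-body
#' ROMs.
#'
#' @param series A raw [keypoint_series] for one walking bout.
#' @param cutoff_hz,filter_order Butterworth settings (defaults 10 Hz, 2).
#' @param trim_seconds Familiarization trim (default 30 s).
#' @param offset_frames Heel-strike offset after the distance maximum
#'   (default 1 frame).
#' @param min_period_s Peak separation; `NULL` self-tunes.
#' @param elbow_threshold_deg Interior elbow angle below which an arm stride
#'   is excluded (default 80).
#' @param stride_time_bounds Stride plausibility window (default 0.4--2.5 s).
#' @param forward Walking direction in the image, `"-x"` or `"+x"`.
#' @return A list with `features` (one-row data.frame of stride_time_s, cv_*
#'   and rom_*), `strides` (named list of [stride_set]s for hip_flexion,
#'   knee_flexion, shoulder_flexion, elbow_flexion, arm_swing), `events`, and
#'   `counts` (strides detected/dropped/arm-excluded).
#' @export
extract_gait_features <- function(series, cutoff_hz = 10, filter_order = 2,
                                  trim_seconds = 30, offset_frames = 1L,
                                  min_period_s = NULL, elbow_threshold_deg = 80,
                                  stride_time_bounds = c(0.4, 2.5),
                                  forward = "-x") {
  s <- filter_trajectories(series, cutoff_hz = cutoff_hz, order = filter_order)
  s <- trim_familiarization(s, trim_seconds)
  d <- ankle_hip_distance(s, side = "left")
  ev <- detect_heel_strikes(d, fps = s$fps, min_period_s = min_period_s,
                            offset_frames = offset_frames,
                            participant_id = s$participant_id, bout = s$bout)
  ja <- joint_angles(s, forward = forward)
  signals <- c("hip_flexion", "knee_flexion", "shoulder_flexion",
               "elbow_flexion", "arm_swing")
  strides <- lapply(signals, function(nm)
    segment_strides(ja[[nm]], ev, stride_time_bounds = stride_time_bounds,
                    signal_name = nm))
  names(strides) <- signals

  keep <- functional_arm_strides(strides$elbow_flexion, elbow_threshold_deg)
  arm_sigs <- c("shoulder_flexion", "elbow_flexion", "arm_swing")
  arm_ok <- any(keep)
  if (arm_ok && !all(keep))
    strides[arm_sigs] <- lapply(strides[arm_sigs], subset_strides, keep = keep)

  cv_or_na <- function(ss) if (is.null(ss) || nrow(ss$strides) < 2) NA_real_ else
    coefficient_of_variation(ss)
  feats <- data.frame(
    participant = series$participant_id, bout = series$bout,
    stride_time_s = mean(strides$hip_flexion$stride_times),
    cv_hip = cv_or_na(strides$hip_flexion),
    cv_knee = cv_or_na(strides$knee_flexion),
    cv_shoulder = if (arm_ok) cv_or_na(strides$shoulder_flexion) else NA_real_,
    cv_elbow = if (arm_ok) cv_or_na(strides$elbow_flexion) else NA_real_,
    cv_armswing = if (arm_ok) cv_or_na(strides$arm_swing) else NA_real_,
    rom_shoulder_deg = if (arm_ok) range_of_motion(strides$shoulder_flexion) else NA_real_,
    rom_elbow_deg = if (arm_ok) range_of_motion(strides$elbow_flexion) else NA_real_,
    rom_armswing_deg = if (arm_ok) range_of_motion(strides$arm_swing) else NA_real_,
    stringsAsFactors = FALSE)
  counts <- c(events = length(ev$heel_strike_frames),
              strides = nrow(strides$hip_flexion$strides),
              dropped = attr(strides$hip_flexion, "dropped"),
              arm_excluded = sum(!keep))
  list(features = feats, strides = strides, events = ev, counts = counts)
}

#' Per-participant gait feature table
#'
#' Averages per-bout discrete features (stride time, cv's, ROMs) over the two
#' walking bouts of each participant.
#'
#' @param bout_features A data.frame of per-bout feature rows as produced by
#'   [extract_gait_features()] (`$features`), several participants allowed.
#' @param require_both Require both bouts per participant (default TRUE).
#' @return A data.frame with one row per participant.
#' @export
build_feature_table <- function(bout_features, require_both = TRUE) {
  ids <- unique(bout_features$participant)
  num <- setdiff(names(bout_features), c("participant", "bout"))
  rows <- lapply(ids, function(id) {
    sub <- bout_features[bout_features$participant == id, , drop = FALSE]
    if (require_both && !all(c("slow", "fast") %in% sub$bout))
      stop("completeness error: participant ", id, " is missing a bout",
           call. = FALSE)
    out <- data.frame(participant = id, stringsAsFactors = FALSE)
    for (v in num) out[[v]] <- mean(sub[[v]])
    out
  })
  do.call(rbind, rows)
}

#' Mean stride waveform of a participant
#' @param strides A [stride_set].
#' @return Numeric vector of length 101 (mean over strides at each node).
#' @export
mean_waveform <- function(strides) colMeans(strides$strides)
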