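# Segment inclination from the downward vertical, in degrees.
# v is a (proximal -> distal) segment vector in image coordinates (y down);
# positive angles tilt toward the walking direction (`forward_sign` * x).
segment_angle <- function(vx, vy, forward_sign) {
  atan2(forward_sign * vx, vy) * 180 / pi
}

wrap180 <- function(a) ((a + 180) %% 360) - 180

#' Sagittal joint angles from keypoints
#'
#' Computes left-side segment and joint angles per frame from the keypoint
#' trajectories, using segment-angle differences. Conventions (recorded in the
#' `"convention"` attribute):
#' * image y-axis points down; the subject walks toward `forward = "-x"`
#'   (image left, the default) or `"+x"`;
#' * segment angles are measured from the downward vertical, positive forward;
#' * `hip_flexion` = thigh angle minus trunk angle (thigh forward of trunk
#'   positive); `knee_flexion` = thigh minus shank (0 at a straight leg,
#'   flexion positive); `shoulder_flexion` = upper-arm minus trunk;
#'   `elbow_flexion` = forearm minus upper arm (0 = fully extended; the
#'   interior elbow angle is 180 minus this); `arm_swing` = whole-arm
#'   (shoulder to wrist) angle from the downward vertical, forward positive.
#'
#' Frames with a missing keypoint or a degenerate (zero-length) segment get NA
#' angles and are flagged in the `bad_frame` column; strides containing them
#' are dropped later by [segment_strides()].
#'
#' @param series A [keypoint_series].
#' @param forward Walking direction in image coordinates, `"-x"` or `"+x"`.
#' @return A data.frame with one row per frame: `hip_flexion`, `knee_flexion`,
#'   `shoulder_flexion`, `elbow_flexion`, `arm_swing` (degrees) and
#'   `bad_frame`; class `joint_angle_set`.
#' @export
joint_angles <- function(series, forward = c("-x", "+x")) {
  forward <- match.arg(forward)
  f <- if (forward == "-x") -1 else 1
  X <- series$x; Y <- series$y; C <- series$confidence
  need <- c("left_shoulder", "left_elbow", "left_wrist",
            "left_hip", "left_knee", "left_ankle")
  bad <- rowSums(C[, need, drop = FALSE] == 0) > 0
  seg <- function(p, q) {     # angle of segment p -> q
    vx <- X[, q] - X[, p]; vy <- Y[, q] - Y[, p]
    deg <- segment_angle(vx, vy, f)
    deg[vx == 0 & vy == 0] <- NA_real_
    deg
  }
  trunk <- seg("left_shoulder", "left_hip")      # downward trunk axis
  thigh <- seg("left_hip", "left_knee")
  shank <- seg("left_knee", "left_ankle")
  uarm  <- seg("left_shoulder", "left_elbow")
  farm  <- seg("left_elbow", "left_wrist")
  warm  <- seg("left_shoulder", "left_wrist")
  out <- data.frame(
    hip_flexion      = wrap180(thigh - trunk),
    knee_flexion     = wrap180(thigh - shank),
    shoulder_flexion = wrap180(uarm - trunk),
    elbow_flexion    = wrap180(farm - uarm),
    arm_swing        = warm)
  out$bad_frame <- bad | rowSums(!is.finite(as.matrix(out))) > 0
  out[out$bad_frame, c("hip_flexion", "knee_flexion", "shoulder_flexion",
                       "elbow_flexion", "arm_swing")] <- NA_real_
  attr(out, "convention") <- list(
    y_axis = "down", forward = forward, zero = "straight-segment alignment",
    positive = "flexion / forward", arm_swing_reference = "downward vertical",
    elbow_interior = "180 - elbow_flexion")
  class(out) <- c("joint_angle_set", "data.frame")
  out
}

#' Exclude strides with non-functional arm movement
#'
#' Strides in which the arm was strongly bent (e.g. the hand raised to the
#' head) are not representative of arm swing. A stride is excluded when its
#' minimal interior elbow angle (180 minus the stored elbow flexion) drops
#' below `threshold_deg`. The same stride indices must then be removed from
#' every arm-signal stride set of the trial; leg signals are unaffected.
#'
#' @param elbow A [stride_set] of `elbow_flexion` (internal convention,
#'   0 = straight).
#' @param threshold_deg Interior-angle threshold in degrees (default 80;
#'   0 disables exclusion).
#' @return Logical vector, `TRUE` for strides to keep.
#' @export
functional_arm_strides <- function(elbow, threshold_deg = 80) {
  interior_min <- apply(180 - elbow$strides, 1, min)
  interior_min >= threshold_deg
}

#' Apply a stride filter to a stride set
#' @param strides A [stride_set].
#' @param keep Logical vector over strides.
#' @return The subset [stride_set]; errors if no stride remains.
#' @export
subset_strides <- function(strides, keep) {
  if (!any(keep))
    stop("empty-feature warning: all strides excluded for ",
         strides$signal_name, call. = FALSE)
  stride_set(strides$strides[keep, , drop = FALSE], strides$stride_times[keep],
             signal_name = strides$signal_name,
             participant_id = strides$participant_id, bout = strides$bout)
}

#' Waveform coefficient of variation
#'
#' Variability index of a stride-normalized waveform: the root of the mean
#' across-stride variance over the 101 nodes, divided by the mean absolute
#' across-stride mean,
#' \deqn{cv = \sqrt{\tfrac{1}{N}\sum_i \sigma_i^2} \; / \;
#'       \tfrac{1}{N}\sum_i |X_i|,}
#' where \eqn{\sigma_i} and \eqn{X_i} are the sample standard deviation
#' (denominator M-1) and mean over strides at node i. Scale-invariant under
#' positive rescaling; sensitive to additive offsets through the denominator.
#'
#' @param strides A [stride_set] with at least 2 strides.
#' @return Unitless non-negative scalar.
#' @export
coefficient_of_variation <- function(strides) {
  m <- strides$strides
  if (nrow(m) < 2) stop("cv requires at least 2 strides", call. = FALSE)
  sig2 <- apply(m, 2, stats::var)
  denom <- mean(abs(colMeans(m)))
  if (denom == 0) stop("undefined-cv error: mean waveform is identically zero",
                       call. = FALSE)
  sqrt(mean(sig2)) / denom
}

#' Range of motion of a stride set
#'
#' Per-stride max minus min, averaged over strides.
#'
#' @param strides A [stride_set].
#' @return Mean ROM in the signal's units (degrees for joint angles).
#' @export
range_of_motion <- function(strides) {
  mean(apply(strides$strides, 1, function(r) max(r) - min(r)))
}
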