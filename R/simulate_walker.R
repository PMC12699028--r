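# Default joint-angle waveforms (degrees) as truncated Fourier series of the
# gait-cycle phase, chosen to resemble normative treadmill gait: hip flexion
# ~ -10..30 deg single-peaked, knee flexion double-bumped (stance ~20 deg,
# swing ~60 deg), arms swinging in anti-phase with the ipsilateral leg, elbow
# held comfortably flexed (interior angle well above the 80 deg exclusion).
# Each entry: mean a0, then harmonics as (amplitude, phase) pairs;
# angle(phi) = a0 + sum_h A_h * cos(2*pi*h*phi - p_h).
default_joint_waveforms <- function() {
  list(
    hip_flexion      = list(a0 = 10, amp = c(20, 3),  phase = c(0, 0.5)),
    knee_flexion     = list(a0 = 30, amp = c(20, 10), phase = c(3.4, 2.0)),
    shoulder_flexion = list(a0 = -3, amp = c(10, 1),  phase = c(pi, 0)),
    elbow_flexion    = list(a0 = 35, amp = c(12, 2),  phase = c(pi, 0)),
    trunk_lean       = list(a0 = 3,  amp = c(1, 0.5), phase = c(0, 0)))
}

eval_waveform <- function(wf, phi, amp_scale = 1) {
  v <- rep(wf$a0, length(phi))
  for (h in seq_along(wf$amp))
    v <- v + amp_scale * wf$amp[h] * cos(2 * pi * h * phi - wf$phase[h])
  v
}

#' Walker simulation parameters
#'
#' Parameters of the planar kinematic walker. Defaults reflect the study
#' conditions: 50 Hz sagittal video, 240 s bouts, stride times near 1.2 s,
#' 2 px keypoint noise typical of 2D pose estimation on such footage.
#'
#' @param stride_time Stride duration in seconds (0.6--2.0).
#' @param fps Video frame rate (default 50).
#' @param duration Trial length in seconds (default 240).
#' @param segment_lengths Named vector of segment lengths in pixels: trunk,
#'   thigh, shank, upper_arm, forearm.
#' @param waveforms Joint-angle waveforms; see `default_joint_waveforms`
#'   structure (mean + harmonic amplitudes/phases, degrees).
#' @param noise_sd Gaussian pixel noise SD added to every keypoint coordinate
#'   (default 2).
#' @param clothing_bias Named list of per-keypoint constant `c(x, y)` pixel
#'   offsets emulating systematic clothing-related keypoint shifts (default
#'   none).
#' @param stride_jitter_sd Per-stride multiplicative jitter SD of the
#'   oscillatory waveform components (0 = perfectly repeated strides).
#' @param hip_osc_px Amplitude of the vertical hip oscillation at stride
#'   frequency (default 2 px).
#' @param seed RNG seed.
#' @return A list of class `walker_params`.
#' @export
walker_params <- function(stride_time = 1.2, fps = 50, duration = 240,
                          segment_lengths = c(trunk = 120, thigh = 90,
                                              shank = 90, upper_arm = 70,
                                              forearm = 60),
                          waveforms = default_joint_waveforms(),
                          noise_sd = 2, clothing_bias = list(),
                          stride_jitter_sd = 0, hip_osc_px = 2, seed = 1) {
  if (stride_time < 0.6 || stride_time > 2.0)
    stop("stride_time must lie in [0.6, 2.0] s", call. = FALSE)
  stopifnot(fps > 0, noise_sd >= 0, duration > 0)
  structure(list(stride_time = stride_time, fps = fps, duration = duration,
                 segment_lengths = segment_lengths, waveforms = waveforms,
                 noise_sd = noise_sd, clothing_bias = clothing_bias,
                 stride_jitter_sd = stride_jitter_sd, hip_osc_px = hip_osc_px,
                 seed = seed),
            class = "walker_params")
}

#' Simulate a planar walker
#'
#' Forward kinematics of a sagittal-plane walking figure in image coordinates
#' (y down, walking toward -x): the left hip oscillates vertically at stride
#' frequency; leg and arm keypoints are placed along the trunk-thigh-shank and
#' trunk-upper-arm-forearm chains driven by the joint-angle waveforms; the
#' right side runs half a cycle out of phase (arms anti-phase with the
#' ipsilateral leg). Vertical GRF is synthesized at 1000 Hz as a double-bump
#' profile over the stance phase (first 60% of each cycle after heel strike).
#' Independent Gaussian pixel noise and optional constant per-keypoint
#' clothing offsets are added last. The returned `truth` records the
#' generating quantities: heel-strike frames (at the ankle-hip distance
#' maxima, before the one-frame detection offset), 101-node joint-angle
#' waveforms, stride time and ROMs.
#'
#' @param params A [walker_params].
#' @param participant_id,bout Metadata labels.
#' @return A list: `keypoints` ([keypoint_series]), `grf` ([grf_series]),
#'   `truth` (list).
#' @export
simulate_walker <- function(params, participant_id = "P00", bout = "slow") {
  p <- params
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(p$seed)

  nf <- round(p$duration * p$fps)
  t_s <- (seq_len(nf) - 1) / p$fps
  phi_g <- t_s / p$stride_time               # global phase (cycles)
  stride_idx <- floor(phi_g)
  phi <- phi_g - stride_idx                  # within-cycle phase
  n_strides <- max(stride_idx) + 1L

  # per-stride amplitude jitter (1 = default waveform)
  jit <- if (p$stride_jitter_sd > 0)
    1 + stats::rnorm(n_strides, 0, p$stride_jitter_sd) else rep(1, n_strides)
  amp_scale <- jit[stride_idx + 1L]

  wf <- p$waveforms
  hip_fx  <- eval_waveform(wf$hip_flexion, phi, amp_scale)
  knee_fx <- eval_waveform(wf$knee_flexion, phi, amp_scale)
  sho_fx  <- eval_waveform(wf$shoulder_flexion, phi, amp_scale)
  elb_fx  <- eval_waveform(wf$elbow_flexion, phi, amp_scale)
  trunk   <- eval_waveform(wf$trunk_lean, phi, 1)
  # right side: half a cycle shifted; arms anti-phase with same-side legs
  phiR <- (phi + 0.5) %% 1
  hip_fx_R  <- eval_waveform(wf$hip_flexion, phiR, 1)
  knee_fx_R <- eval_waveform(wf$knee_flexion, phiR, 1)
  sho_fx_L  <- eval_waveform(wf$shoulder_flexion, phiR, amp_scale)  # left arm ~ right leg
  elb_fx_L  <- eval_waveform(wf$elbow_flexion, phiR, amp_scale)
  sho_fx_R  <- eval_waveform(wf$shoulder_flexion, phi, 1)
  elb_fx_R  <- eval_waveform(wf$elbow_flexion, phi, 1)

  knee_band <- range(knee_fx)
  if (knee_band[1] < -20 || knee_band[2] > 180)
    stop("parameter error: knee flexion waveform outside [-20, 180] deg",
         call. = FALSE)

  L <- p$segment_lengths
  f <- -1                                    # walking toward -x
  uvec <- function(deg) {                    # unit vector at inclination deg
    r <- deg * pi / 180
    cbind(f * sin(r), cos(r))
  }
  hip <- cbind(400, 400 + p$hip_osc_px * sin(2 * pi * phi_g))
  chain <- function(origin, deg, len) origin + len * uvec(deg)
  place_side <- function(hipxy, hipdeg, kneedeg, shodeg, elbdeg) {
    knee <- chain(hipxy, trunk + hipdeg, L[["thigh"]])
    ankle <- chain(knee, trunk + hipdeg - kneedeg, L[["shank"]])
    shoulder <- hipxy - L[["trunk"]] * uvec(trunk)
    elbow <- chain(shoulder, trunk + shodeg, L[["upper_arm"]])
    wrist <- chain(elbow, trunk + shodeg + elbdeg, L[["forearm"]])
    list(knee = knee, ankle = ankle, shoulder = shoulder,
         elbow = elbow, wrist = wrist)
  }
  hipR <- hip + cbind(rep(4, nf), 0)         # slight depth offset
  Lside <- place_side(hip, hip_fx, knee_fx, sho_fx_L, elb_fx_L)
  Rside <- place_side(hipR, hip_fx_R, knee_fx_R, sho_fx_R, elb_fx_R)

  neck <- Lside$shoulder - 0.25 * L[["trunk"]] * uvec(trunk)
  nose <- neck + cbind(rep(f * 12, nf), -8)
  kp <- keypoint_names()
  X <- matrix(NA_real_, nf, 17, dimnames = list(NULL, kp))
  Y <- matrix(NA_real_, nf, 17, dimnames = list(NULL, kp))
  setkp <- function(name, xy) { X[, name] <<- xy[, 1]; Y[, name] <<- xy[, 2] }
  setkp("nose", nose)
  setkp("left_ear", nose + cbind(rep(-f * 6, nf), -2))
  setkp("right_ear", nose + cbind(rep(-f * 8, nf), -2))
  setkp("left_eye", nose + cbind(rep(0, nf), -5))
  setkp("right_eye", nose + cbind(rep(-f * 3, nf), -5))
  setkp("left_shoulder", Lside$shoulder); setkp("right_shoulder", Rside$shoulder)
  setkp("left_elbow", Lside$elbow); setkp("right_elbow", Rside$elbow)
  setkp("left_wrist", Lside$wrist); setkp("right_wrist", Rside$wrist)
  setkp("left_hip", hip); setkp("right_hip", hipR)
  setkp("left_knee", Lside$knee); setkp("right_knee", Rside$knee)
  setkp("left_ankle", Lside$ankle); setkp("right_ankle", Rside$ankle)

  # ground truth: heel strike at the maximum of the noiseless ankle-hip
  # distance. |ankle - hip|^2 = Lt^2 + Ls^2 + 2*Lt*Ls*cos(knee_flexion), so
  # the distance depends only on the knee angle and peaks where the knee is
  # straightest. The truth is the discrete per-cycle argmax of the sampled
  # noiseless distance (pre-offset), exactly what an ideal detector sees.
  Lt <- L[["thigh"]]; Ls <- L[["shank"]]
  chain_dist <- function(knee_deg)
    sqrt(Lt^2 + Ls^2 + 2 * Lt * Ls * cos(knee_deg * pi / 180))
  fine <- seq(0, 1, length.out = 4001)[-4001]
  dist_fine <- chain_dist(eval_waveform(wf$knee_flexion, fine, 1))
  phi_hs <- fine[which.max(dist_fine)]       # continuous heel-strike phase
  # sampled distance from the actual (pre-noise) keypoint positions so that
  # the truth argmax matches a noiseless detector bit-for-bit even at
  # floating-point near-ties between adjacent frames
  d_frames <- sqrt((X[, "left_ankle"] - X[, "left_hip"])^2 +
                   (Y[, "left_ankle"] - Y[, "left_hip"])^2)
  cycle_frames <- split(seq_len(nf), stride_idx)
  full <- lengths(cycle_frames) >= floor(p$stride_time * p$fps) - 1  # complete cycles
  hs_frames <- as.integer(vapply(cycle_frames[full], function(ix)
    ix[which.max(d_frames[ix])], numeric(1)))
  # a true heel strike must be an interior local maximum near the global
  # peak height (guards partial edge cycles whose argmax is a secondary peak)
  is_peak <- hs_frames > 1 & hs_frames < nf &
    d_frames[pmax(hs_frames - 1, 1)] < d_frames[hs_frames] &
    d_frames[hs_frames] >= d_frames[pmin(hs_frames + 1, nf)] &
    d_frames[hs_frames] >= max(d_frames) - 0.25 * diff(range(d_frames))
  hs_frames <- sort(hs_frames[is_peak])

  # truth waveforms are laid out as the pipeline measures them: a stride
  # starts at the heel strike, i.e. one frame after the distance maximum.
  # Left-arm signals run half a cycle out of phase with the left leg.
  phi0 <- if (length(hs_frames)) hs_frames[1] / (p$stride_time * p$fps) else phi_hs
  node_grid <- phi0 + seq(0, 1, length.out = 101)
  truth_wave <- function(w, shift = 0) eval_waveform(wf[[w]], node_grid + shift, 1)
  truth_waveforms <- list(
    hip_flexion = truth_wave("hip_flexion"),
    knee_flexion = truth_wave("knee_flexion"),
    shoulder_flexion = truth_wave("shoulder_flexion", shift = 0.5),
    elbow_flexion = truth_wave("elbow_flexion", shift = 0.5))

  # vertical GRF at 1000 Hz: double-bump over the first 60% of each cycle
  sr <- 1000; W <- 700
  tg <- seq(0, p$duration - 1 / sr, by = 1 / sr)
  grf_for <- function(phase_cycles) {
    ph <- (phase_cycles - phi_hs) %% 1       # 0 at heel strike
    u <- ph / 0.6
    ifelse(ph < 0.6, W * (1.1 * sin(pi * u) + 0.15 * sin(3 * pi * u)), 0)
  }
  f_left <- grf_for(tg / p$stride_time)
  f_right <- grf_for(tg / p$stride_time + 0.5)

  # measurement artifacts
  if (p$noise_sd > 0) {
    X <- X + matrix(stats::rnorm(nf * 17, 0, p$noise_sd), nf, 17)
    Y <- Y + matrix(stats::rnorm(nf * 17, 0, p$noise_sd), nf, 17)
  }
  for (nm in names(p$clothing_bias)) {
    X[, nm] <- X[, nm] + p$clothing_bias[[nm]][1]
    Y[, nm] <- Y[, nm] + p$clothing_bias[[nm]][2]
  }

  series <- keypoint_series(X, Y, fps = p$fps, participant_id = participant_id,
                            bout = bout)
  grf <- grf_series(f_left, f_right, sample_rate = sr,
                    participant_id = participant_id, bout = bout)
  truth <- list(
    heel_strike_frames = hs_frames, heel_strike_phase = phi_hs,
    stride_time = p$stride_time,
    waveforms = truth_waveforms,
    arm_swing_rom = {
      # left arm runs half a cycle out of phase with the (left-leg) cycle
      ph <- seq(0, 1, length.out = 4001)
      sf <- eval_waveform(wf$shoulder_flexion, ph + 0.5, 1)
      ef <- eval_waveform(wf$elbow_flexion, ph + 0.5, 1)
      tlph <- eval_waveform(wf$trunk_lean, ph, 1)
      ua <- L[["upper_arm"]]; fa <- L[["forearm"]]
      wvx <- ua * sin((tlph + sf) * pi / 180) + fa * sin((tlph + sf + ef) * pi / 180)
      wvy <- ua * cos((tlph + sf) * pi / 180) + fa * cos((tlph + sf + ef) * pi / 180)
      aw <- atan2(wvx, wvy) * 180 / pi
      max(aw) - min(aw)
    },
    cv = stats::setNames(rep(0, 4), names(truth_waveforms)),
    params = p)
  list(keypoints = series, grf = grf, truth = truth)
}
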