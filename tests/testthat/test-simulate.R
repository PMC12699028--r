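test_that("walker simulation is bit-identical under the same seed", {
  p <- walker_params(stride_time = 1.2, duration = 10, noise_sd = 2, seed = 42)
  w1 <- simulate_walker(p)
  w2 <- simulate_walker(p)
  expect_identical(w1$keypoints$x, w2$keypoints$x)
  expect_identical(w1$grf$f_left, w2$grf$f_left)
  expect_identical(w1$truth, w2$truth)
  w3 <- simulate_walker(walker_params(stride_time = 1.2, duration = 10,
                                      noise_sd = 2, seed = 43))
  expect_false(identical(w1$keypoints$x, w3$keypoints$x))
})

test_that("noiseless pipeline recovers stride time to within one frame", {
  p <- walker_params(stride_time = 1.1, duration = 14, noise_sd = 0, seed = 1)
  w <- simulate_walker(p)
  d <- ankle_hip_distance(w$keypoints)
  ev <- detect_heel_strikes(d, fps = 50)
  ss <- segment_strides(d, ev)
  expect_lte(mean(abs(ss$stride_times - 1.1)), 1 / 50)
})

test_that("detected events equal true events shifted by exactly the offset", {
  for (T in c(1.1, 1.2)) {
    p <- walker_params(stride_time = T, duration = 14, noise_sd = 0, seed = 2)
    w <- simulate_walker(p)
    ev <- detect_heel_strikes(ankle_hip_distance(w$keypoints), fps = 50)
    expect_true(all(ev$heel_strike_frames %in% (w$truth$heel_strike_frames + 1L)))
    expect_gte(length(ev$heel_strike_frames),
               length(w$truth$heel_strike_frames) - 2)
  }
})

test_that("tiled identical strides give cv = 0 for every signal", {
  p <- walker_params(stride_time = 1.2, duration = 20, noise_sd = 0,
                     stride_jitter_sd = 0, seed = 3)
  w <- simulate_walker(p)
  ev <- detect_heel_strikes(ankle_hip_distance(w$keypoints), fps = 50)
  ja <- joint_angles(w$keypoints)
  for (sig in c("hip_flexion", "knee_flexion", "arm_swing")) {
    ss <- segment_strides(ja[[sig]], ev, signal_name = sig)
    expect_lt(coefficient_of_variation(ss), 1e-6)
  }
})

test_that("keypoint- and GRF-derived heel strikes agree within 2 frames", {
  p <- walker_params(stride_time = 1.2, duration = 20, noise_sd = 0, seed = 4)
  w <- simulate_walker(p)
  ev_kp <- detect_heel_strikes(ankle_hip_distance(w$keypoints), fps = 50)
  ev_grf <- detect_heel_strikes_grf(w$grf, fps = 50)
  for (e in ev_kp$heel_strike_frames) {
    gap <- min(abs(ev_grf$heel_strike_frames - e))
    expect_lte(gap, 2)
  }
})

test_that("an ankle clothing bias shifts knee flexion but spares the hip", {
  # a constant shank-endpoint offset distorts the knee angle systematically
  # while the hip angle (trunk/thigh only) is untouched
  base <- walker_params(stride_time = 1.2, duration = 20, noise_sd = 0, seed = 5)
  biased <- walker_params(stride_time = 1.2, duration = 20, noise_sd = 0,
                          clothing_bias = list(left_ankle = c(8, 6)), seed = 5)
  wave <- function(p, sig) {
    w <- simulate_walker(p)
    # identical true events in both runs isolate the pure angle distortion
    ev <- gait_events(w$truth$heel_strike_frames + 1L, fps = 50)
    ja <- joint_angles(w$keypoints)
    mean_waveform(segment_strides(ja[[sig]], ev, signal_name = sig))
  }
  knee_shift <- max(abs(wave(biased, "knee_flexion") - wave(base, "knee_flexion")))
  hip_shift <- max(abs(wave(biased, "hip_flexion") - wave(base, "hip_flexion")))
  expect_gt(knee_shift, 2)
  expect_lt(hip_shift, 0.5)
})

test_that("cortisol simulator: amplitude 0 is flat; peak sampling recovers it", {
  flat <- simulate_cortisol(3, 0, group = "control")
  expect_true(all(flat$series$concentrations == 3))
  expect_false(cortisol_features(flat$series)$responder)
  # sample exactly at the peak: S1 at onset + peak_delay
  clk <- c(S0 = 0, S1 = 27, S2 = 40, S3 = 50, S4 = 65, S5 = 75)
  at_peak <- simulate_cortisol(3, 3, onset = 10, peak_delay = 17,
                               sample_clock = clk)
  cf <- cortisol_features(at_peak$series)
  expect_equal(cf$max_increase, 3, tolerance = 1e-12)
  expect_true(cf$responder)
  # peak between samples: sampled max strictly below the true amplitude
  off_peak <- simulate_cortisol(3, 3, onset = 10, peak_delay = 17,
                                sample_clock = c(S0 = 0, S1 = 15, S2 = 45,
                                                 S3 = 55, S4 = 70, S5 = 80))
  expect_lt(cortisol_features(off_peak$series)$max_increase, 3)
  expect_gt(cortisol_features(off_peak$series)$max_increase, 0)
})

test_that("cortisol pulse peaks at onset + peak_delay with value amplitude", {
  tt <- seq(0, 120, by = 0.01)
  curve <- 3 + 2.5 * gaitstress:::cortisol_pulse(tt, onset = 10, peak_delay = 17,
                                                 decay = 25)
  expect_equal(tt[which.max(curve)], 27, tolerance = 0.02)
  expect_equal(max(curve), 5.5, tolerance = 1e-6)
  expect_true(all(curve[tt <= 10] == 3))   # nothing before onset
})

test_that("cohort simulation is reproducible and respects the protocol", {
  c1 <- simulate_cohort(n_per_group = c(OMC = 2, control = 2), duration = 8,
                        seed = 7)
  c2 <- simulate_cohort(n_per_group = c(OMC = 2, control = 2), duration = 8,
                        seed = 7)
  expect_identical(c1$participants$P01$bouts$slow$keypoints$x,
                   c2$participants$P01$bouts$slow$keypoints$x)
  expect_identical(c1$truth, c2$truth)
  # OMC has Q-marker, controls do not
  omc_tp <- vapply(c1$participants$P01$questionnaires, `[[`, "", "timepoint")
  ctl_tp <- vapply(c1$participants$P03$questionnaires, `[[`, "", "timepoint")
  expect_true("Q-marker" %in% omc_tp)
  expect_false("Q-marker" %in% ctl_tp)
  expect_equal(c1$participants$P03$group, "control")
  # both bouts present per participant
  expect_named(c1$participants$P01$bouts, c("slow", "fast"))
})

test_that("constructed cortisol amplitudes control the responder count", {
  # noiseless curves sampled at the peak: responders by construction
  eff <- list(cortisol = list(baseline_meanlog = log(3), baseline_sdlog = 0,
                              amplitude_mean = c(OMC = 3, control = 0.2),
                              amplitude_sd = c(OMC = 0, control = 0),
                              onset = c(OMC = 23, control = 0.99),
                              noise_cv = 0))
  co <- simulate_cohort(n_per_group = c(OMC = 3, control = 3), duration = 8,
                        effects = eff, seed = 8)
  resp <- vapply(co$participants, function(p)
    cortisol_features(p$cortisol)$responder, logical(1))
  grp <- vapply(co$participants, `[[`, "", "group")
  expect_equal(sum(resp[grp == "OMC"]), 3)
  expect_equal(sum(resp[grp == "control"]), 0)
})
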