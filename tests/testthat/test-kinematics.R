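test_that("straight vertical posture gives zero hip and knee flexion", {
  n <- 10
  s <- toy_keypoints(n, override = list(
    left_shoulder = cbind(rep(50, n), rep(100, n)),
    left_hip = cbind(rep(50, n), rep(220, n)),
    left_knee = cbind(rep(50, n), rep(310, n)),
    left_ankle = cbind(rep(50, n), rep(400, n))))
  ja <- joint_angles(s)
  expect_equal(ja$hip_flexion, rep(0, n))
  expect_equal(ja$knee_flexion, rep(0, n))
})

test_that("right-angle shank gives 90 degree knee flexion (y-down image)", {
  n <- 5
  s <- toy_keypoints(n, override = list(
    left_hip = cbind(rep(0, n), rep(0, n)),
    left_knee = cbind(rep(0, n), rep(50, n)),
    left_ankle = cbind(rep(50, n), rep(50, n))))
  # oracle: thigh points straight down (0 deg), shank points +x which is
  # backward under the forward = -x convention, i.e. -90 deg from vertical;
  # knee flexion = thigh - shank = +90
  ja <- joint_angles(s)
  expect_equal(ja$knee_flexion, rep(90, n))
})

test_that("joint angles are invariant to translation and uniform scaling", {
  set.seed(5)
  n <- 30
  ov <- list(
    left_shoulder = cbind(runif(n, 40, 60), runif(n, 90, 110)),
    left_elbow = cbind(runif(n, 30, 70), runif(n, 150, 170)),
    left_wrist = cbind(runif(n, 20, 80), runif(n, 200, 230)),
    left_hip = cbind(runif(n, 45, 55), runif(n, 215, 225)),
    left_knee = cbind(runif(n, 40, 70), runif(n, 300, 320)),
    left_ankle = cbind(runif(n, 30, 80), runif(n, 390, 410)))
  a0 <- joint_angles(toy_keypoints(n, override = ov))
  tf <- function(f) lapply(ov, f)
  a_shift <- joint_angles(toy_keypoints(n, override = tf(function(m)
    cbind(m[, 1] + 123, m[, 2] - 77))))
  a_scale <- joint_angles(toy_keypoints(n, override = tf(function(m) 2.5 * m)))
  cols <- c("hip_flexion", "knee_flexion", "shoulder_flexion", "elbow_flexion",
            "arm_swing")
  for (cc in cols) {
    expect_equal(a_shift[[cc]], a0[[cc]], tolerance = 1e-9)
    expect_equal(a_scale[[cc]], a0[[cc]], tolerance = 1e-9)
  }
})

test_that("degenerate segments flag the frame instead of erroring", {
  n <- 6
  ov <- list(left_knee = cbind(rep(50, n), rep(300, n)),
             left_hip = cbind(c(50, rep(48, n - 1)), rep(300, n)))  # frame 1 coincides
  ja <- joint_angles(toy_keypoints(n, override = ov))
  expect_true(ja$bad_frame[1])
  expect_true(is.na(ja$hip_flexion[1]))
  expect_false(any(ja$bad_frame[-1]))
})

test_that("cv matches the hand-computed two-constant-stride example", {
  # two constant strides at 1 and 3: sigma_i = sd({1,3}) = sqrt(2) at every
  # node, mean |X_i| = 2, so cv = sqrt(2)/2
  ss <- toy_strides(rbind(rep(1, 101), rep(3, 101)))
  expect_equal(coefficient_of_variation(ss), sqrt(2) / 2, tolerance = 1e-12)
  # identical strides: cv = 0
  ss0 <- toy_strides(rbind(rep(5, 101), rep(5, 101), rep(5, 101)))
  expect_equal(coefficient_of_variation(ss0), 0)
})

test_that("cv is scale-invariant but offset-sensitive", {
  set.seed(6)
  m <- matrix(rnorm(5 * 101, mean = 30, sd = 2), 5, 101)
  cv0 <- coefficient_of_variation(toy_strides(m))
  for (c_ in c(0.5, 3, 100))
    expect_equal(coefficient_of_variation(toy_strides(c_ * m)), cv0,
                 tolerance = 1e-12)
  cv_off <- coefficient_of_variation(toy_strides(m + 50))
  expect_false(isTRUE(all.equal(cv_off, cv0)))
  expect_lt(cv_off, cv0)   # larger mean level, same spread
  expect_error(coefficient_of_variation(toy_strides(rbind(rep(0, 101), rep(0, 101)))),
               "undefined-cv")
  expect_error(coefficient_of_variation(toy_strides(rep(1, 101))), "2 strides")
})

test_that("ROM: constants give 0, sinusoids give 2A with small resampling bias", {
  expect_equal(range_of_motion(toy_strides(rep(7, 101))), 0)
  A <- 20
  nodes <- seq(0, 1, length.out = 101)
  ss <- toy_strides(rbind(A * sin(2 * pi * nodes), A * sin(2 * pi * nodes + 1)))
  expect_equal(range_of_motion(ss), 2 * A, tolerance = 1e-3)
  # bias of a 1-cycle sinusoid at 101 nodes is below 0.1%
  expect_lt(abs(range_of_motion(ss) - 2 * A) / (2 * A), 0.001)
})

test_that("non-functional arm strides are excluded on the interior elbow angle", {
  # stored convention: elbow_flexion = 180 - interior angle
  interior_good <- rep(170, 101)               # relaxed arm
  interior_bent <- c(rep(170, 50), 75, rep(170, 50))  # dips below 80
  elbow <- toy_strides(rbind(180 - interior_good, 180 - interior_bent))
  keep <- functional_arm_strides(elbow, threshold_deg = 80)
  expect_identical(keep, c(TRUE, FALSE))
  # threshold 0 disables exclusion
  expect_identical(functional_arm_strides(elbow, threshold_deg = 0), c(TRUE, TRUE))
  # exclusion propagates to all arm stride sets via subset_strides
  arm <- toy_strides(rbind(rep(1, 101), rep(2, 101)))
  kept <- subset_strides(arm, keep)
  expect_equal(nrow(kept$strides), 1)
  expect_equal(kept$strides[1, 1], 1)
  expect_error(subset_strides(arm, c(FALSE, FALSE)), "excluded")
})

test_that("feature table averages the two bouts per participant", {
  bf <- data.frame(participant = c("P1", "P1", "P2", "P2"),
                   bout = c("slow", "fast", "slow", "fast"),
                   stride_time_s = c(1.1, 1.3, 1.2, 1.2),
                   cv_hip = c(0.1, 0.3, 0.2, 0.2))
  tab <- build_feature_table(bf)
  expect_equal(tab$stride_time_s, c(1.2, 1.2))
  expect_equal(tab$cv_hip, c(0.2, 0.2))
  expect_error(build_feature_table(bf[-2, ]), "completeness")
  expect_silent(build_feature_table(bf[-2, ], require_both = FALSE))
})
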