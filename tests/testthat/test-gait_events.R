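test_that("ankle-hip distance is the planar Euclidean distance", {
  n <- 50
  s <- toy_keypoints(n, override = list(
    left_ankle = cbind(rep(100, n), rep(300, n)),
    left_hip = cbind(rep(100, n), rep(300, n))))
  expect_equal(ankle_hip_distance(s), rep(0, n))
  s2 <- toy_keypoints(n, override = list(
    left_ankle = cbind(rep(0, n), rep(100, n)),
    left_hip = cbind(rep(0, n), rep(0, n))))
  expect_equal(ankle_hip_distance(s2), rep(100, n))
})

test_that("ankle-hip distance is invariant to rigid translation", {
  set.seed(3)
  n <- 80
  ax <- runif(n, 0, 50); ay <- runif(n, 400, 500)
  hx <- runif(n, 0, 50); hy <- runif(n, 250, 300)
  base <- toy_keypoints(n, override = list(left_ankle = cbind(ax, ay),
                                           left_hip = cbind(hx, hy)))
  d0 <- ankle_hip_distance(base)
  for (i in 1:5) {
    dx <- runif(1, -500, 500); dy <- runif(1, -500, 500)
    shifted <- toy_keypoints(n, override = list(
      left_ankle = cbind(ax + dx, ay + dy), left_hip = cbind(hx + dx, hy + dy)))
    expect_equal(ankle_hip_distance(shifted), d0, tolerance = 1e-9)
  }
})

test_that("missing keypoints flag frames and trip the data-quality gate", {
  n <- 40
  cf <- matrix(1, n, 17, dimnames = list(NULL, keypoint_names()))
  cf[1:10, "left_ankle"] <- 0
  s <- toy_keypoints(n, conf = cf)
  d <- ankle_hip_distance(s)
  expect_true(all(is.na(d[1:10])))
  cf[1:30, "left_ankle"] <- 0
  expect_error(ankle_hip_distance(toy_keypoints(n, conf = cf)), "data-quality")
})

test_that("heel strikes are sinusoid maxima plus the one-frame offset", {
  # noiseless sinusoidal distance, period 60 frames, 10 cycles
  n <- 600; period <- 60
  d <- 170 + 10 * sin(2 * pi * (seq_len(n) - 1) / period)
  ev <- detect_heel_strikes(d, fps = 50)
  oracle <- bruteforce_maxima(d)            # exhaustive scan
  expect_true(all(ev$heel_strike_frames %in% (oracle + 1L)))
  expect_true(all(diff(ev$heel_strike_frames) == period))
  # offset of one frame at 50 Hz is 0.02 s
  expect_equal(1 / 50, 0.02)
  ev0 <- detect_heel_strikes(d, fps = 50, offset_frames = 0L)
  expect_true(all(ev0$heel_strike_frames %in% oracle))
  expect_equal(ev$heel_strike_frames - 1L, ev0$heel_strike_frames)
})

test_that("degenerate distance series raise insufficient-strides errors", {
  expect_error(detect_heel_strikes(seq_len(500) / 10, fps = 50),
               "insufficient-strides")
  expect_error(detect_heel_strikes(rep(1, 30), fps = 50), "insufficient")
})

test_that("event detection is invariant to uniform scaling and translation", {
  n <- 600
  d <- 170 + 10 * sin(2 * pi * (seq_len(n) - 1) / 57)
  e1 <- detect_heel_strikes(d, fps = 50)$heel_strike_frames
  expect_identical(detect_heel_strikes(3.7 * d, fps = 50)$heel_strike_frames, e1)
  expect_identical(detect_heel_strikes(d + 120, fps = 50)$heel_strike_frames, e1)
})

test_that("GRF heel strikes sit at debounced rising threshold crossings", {
  sr <- 1000
  n <- 6 * sr
  t <- (seq_len(n) - 1) / sr
  f <- ifelse((t %% 1.2) < 0.7, 700, 0)      # square wave, period 1.2 s
  g <- grf_series(f, rev(f), sample_rate = sr)
  ev <- detect_heel_strikes_grf(g, threshold_n = 20, fps = 50)
  # rising edges at t = 1.2, 2.4, 3.6, 4.8 (the t=0 plateau is not an edge)
  expect_equal(ev$heel_strike_frames, round(c(1.2, 2.4, 3.6, 4.8) * 50) + 1L)
  expect_error(detect_heel_strikes_grf(grf_series(rep(0, n), rep(0, n), sr)),
               "insufficient-strides")
})

test_that("stride segmentation arithmetic, exact linear resampling, bounds", {
  ev <- gait_events(c(1, 61), fps = 50)
  sig <- seq(0, 100, length.out = 200)
  ss <- segment_strides(sig, ev)
  expect_equal(nrow(ss$strides), 1)
  expect_equal(ss$stride_times, 1.2)
  # linear ramp stays linear under linear interpolation
  expect_equal(ss$strides[1, ], seq(sig[1], sig[61], length.out = 101),
               tolerance = 1e-12)
  # implausible stride dropped with a count
  ev2 <- gait_events(c(1, 11, 71), fps = 50)   # 0.2 s then 1.2 s
  ss2 <- segment_strides(sig, ev2)
  expect_equal(nrow(ss2$strides), 1)
  expect_equal(attr(ss2, "dropped"), 1L)
  # strides containing non-finite samples are dropped
  ev3 <- gait_events(c(1, 61, 121), fps = 50)
  sig_na <- seq(0, 100, length.out = 200); sig_na[30] <- NA
  ss3 <- segment_strides(sig_na, ev3)
  expect_equal(nrow(ss3$strides), 1)
  expect_equal(attr(ss3, "dropped"), 1L)
})

test_that("stride count equals events minus one minus dropped strides", {
  set.seed(4)
  for (rep in 1:5) {
    n_ev <- sample(4:9, 1)
    gaps <- sample(c(55, 60, 65, 10), n_ev - 1, replace = TRUE)  # 10 -> 0.2 s, dropped
    ev <- gait_events(cumsum(c(1, gaps)), fps = 50)
    sig <- rnorm(sum(gaps) + 10)
    ss <- segment_strides(sig, ev)
    expect_equal(nrow(ss$strides), (n_ev - 1) - attr(ss, "dropped"))
    expect_equal(attr(ss, "dropped"), sum(gaps == 10))
  }
})
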