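test_that("stride segmentation finds swing onsets at period multiples", {
  # constant series: no strides
  expect_equal(segment_strides(rep(3, 100), 100)$n_strides, 0)
  # noise-free sawtooth with 10 detectable swing onsets: 9 strides at exact multiples
  x <- ideal_saw(11, 80, duty = 0.6)[21:821]
  s <- segment_strides(x, 400)
  expect_equal(s$n_strides, 9)
  expect_equal(unique(diff(s$swing_onsets)), 80)
  # one full period only (2 interior peaks): exactly 1 stride
  x1 <- ideal_saw(3, 80, duty = 0.6)[20:170]
  s1 <- segment_strides(x1, 400)
  expect_equal(s1$n_strides, 1)
  # peaks and troughs alternate
  expect_true(all(s$stance_onsets > head(s$swing_onsets, -1) &
                    s$stance_onsets < tail(s$swing_onsets, -1)))
})

test_that("cross-correlation phase matches analytic shifts of a periodic waveform", {
  d <- 80
  x <- ideal_saw(12, d, duty = 0.6)
  onset <- 4 * d + 1; offset <- 5 * d + 1
  shift_by <- function(k) c(rep(x[1], max(k, 0)), head(x, -k))
  circshift <- function(v, k) v[((seq_along(v) - 1 - k) %% length(v)) + 1]
  # identity -> 0
  expect_equal(relative_phase(x, x, onset, offset), 0)
  # other delayed by d/2 -> |phase| = pi
  expect_equal(abs(relative_phase(x, circshift(x, d / 2), onset, offset)), pi,
               tolerance = 2 * pi / d)
  # other shifted EARLIER by d/4 (leads) -> -pi/2
  expect_equal(relative_phase(x, circshift(x, -d / 4), onset, offset), -pi / 2,
               tolerance = 2 * pi / d + 1e-9)
  # other delayed (lags) by d/4 -> +pi/2
  expect_equal(relative_phase(x, circshift(x, d / 4), onset, offset), pi / 2,
               tolerance = 2 * pi / d + 1e-9)
  # zero-variance window is flagged undefined
  expect_true(is.na(relative_phase(rep(1, length(x)), x, onset, offset)))
  expect_true(is.na(relative_phase(x, rep(1, length(x)), onset, offset)))
})

test_that("dual-landmark consistency rule reproduces a wrap-aware recount", {
  expect_false(consistency_filter(0.30 * pi, 0.44 * pi)) # distance 0.14 pi
  expect_true(consistency_filter(0.98 * pi, -0.98 * pi)) # distance 0.04 pi
  x <- runif(200, -pi, pi)
  expect_true(all(consistency_filter(x, x)))
  # monotone in the tolerance: enlarging tol never drops more strides
  set.seed(3)
  a <- runif(500, -pi, pi); b <- runif(500, -pi, pi)
  tols <- seq(0.02, 0.5, by = 0.04) * pi
  kept <- vapply(tols, function(tt) sum(consistency_filter(a, b, tt)), numeric(1))
  expect_true(all(diff(kept) >= 0))
  # brute-force recount at the default tolerance
  expect_equal(sum(consistency_filter(a, b)),
               sum(pmin(abs(a - b), 2 * pi - abs(a - b)) <= 0.1 * pi))
})

test_that("duty factor equals the stance fraction of the constructed waveform", {
  # symmetric triangle wave -> 0.5
  tri <- ideal_saw(8, 100, duty = 0.5)
  s <- segment_strides(tri, 400)
  df <- duty_factor(s, s$strides$onset[3], s$strides$offset[3])
  expect_equal(df, 0.5, tolerance = 0.02)
  # stance (trough-to-peak) segment of 70% -> 0.7
  saw <- ideal_saw(8, 100, duty = 0.7)
  s2 <- segment_strides(saw, 400)
  df2 <- duty_factor(s2, s2$strides$onset[3], s2$strides$offset[3])
  expect_equal(df2, 0.7, tolerance = 0.02)
  # no stance onset inside the interval -> flagged
  expect_true(is.na(duty_factor(s2, 1, 2)))
})

test_that("hindlimb phase categories follow the 0.2 pi bands and wrap", {
  expect_equal(categorize_hindlimb_phase(0.95 * pi), "alternating")
  expect_equal(categorize_hindlimb_phase(0.1 * pi), "synchronized")
  expect_equal(categorize_hindlimb_phase(0.5 * pi), "asymmetric_left_leading")
  expect_equal(categorize_hindlimb_phase(-0.5 * pi), "asymmetric_right_leading")
  x <- runif(300, -pi, pi)
  expect_identical(categorize_hindlimb_phase(x), categorize_hindlimb_phase(x + 2 * pi))
  # boundary membership
  expect_equal(categorize_hindlimb_phase(0.8 * pi), "alternating")
  expect_equal(categorize_hindlimb_phase(0.2 * pi), "synchronized")
})

test_that("stride table recovers true phases on noise-free trials", {
  cfg <- noise_free_cfg(seed = 31L)
  tr <- generate_trajectory_trial(cfg, 1, list(head_height = 44, slope = 0, speed = 20),
                                  seed = 13)
  ps <- posture_series(tr$recording)
  tab <- build_stride_table(tr$recording, ps)
  expect_gt(nrow(tab), 5)
  d <- cfg$stride_period * cfg$frame_rate
  for (lb in c("LF", "RH", "RF")) {
    err <- circ_dist(tab[[paste0("phase_", lb)]], tr$truth$phases[[lb]])
    expect_true(all(err <= 2 * pi / d + 1e-9), label = paste("phase recovery", lb))
  }
  expect_true(all(tab$hindlimb_category == "alternating"))
  # determinism: identical inputs yield identical tables
  tab2 <- build_stride_table(tr$recording, ps)
  expect_identical(tab, tab2)
})

test_that("stride count equals detected swing onsets minus one per bout", {
  cfg <- noise_free_cfg(seed = 32L)
  tr <- generate_trajectory_trial(cfg, 2, list(head_height = 40, slope = 0, speed = 20),
                                  seed = 14)
  ps <- posture_series(tr$recording)
  tab <- build_stride_table(tr$recording, ps)
  seg <- segment_strides(rowMeans(tr$recording$x[, c("LH1", "LH2")]),
                         cfg$frame_rate)
  expect_equal(nrow(tab), length(seg$swing_onsets) - 1)
})

test_that("inflated landmark jitter drops strides per an independent recount", {
  cfg <- small_cfg(landmark_jitter_sd = 0.6, tracking_noise_sd = 0,
                   dropout_frac = 0, seed = 33L)
  tr <- generate_trajectory_trial(cfg, 1, list(head_height = 44, slope = 0, speed = 20),
                                  seed = 15)
  ps <- posture_series(tr$recording)
  tab <- build_stride_table(tr$recording, ps)
  log <- attr(tab, "drop_log")
  # independent recount: re-apply the rule limb by limb on the segmentation
  seg <- segment_strides(rowMeans(tr$recording$x[, c("LH1", "LH2")]),
                         cfg$frame_rate)
  n_dropped <- 0L
  for (i in seq_len(seg$n_strides)) {
    o <- seg$strides$onset[i]; f <- seg$strides$offset[i]
    for (lb in c("LF", "RF", "RH")) {
      ph <- vapply(1:2, function(k)
        relative_phase(tr$recording$x[, paste0("LH", k)],
                       tr$recording$x[, paste0(lb, k)], o, f), numeric(1))
      if (!consistency_filter(ph[1], ph[2])) { n_dropped <- n_dropped + 1L; break }
    }
  }
  expect_equal(unname(log[["consistency"]] + log[["undefined"]]), n_dropped)
  expect_equal(nrow(tab), seg$n_strides - n_dropped)
})
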