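test_that("tracking inclusion rule reproduces direct fraction counts", {
  rec <- toy_recording(n = 200)
  ft <- filter_tracking(rec)
  expect_true(ft$included)
  expect_false(any(ft$interpolated))

  # snout below threshold on 15% of frames: 0.85 < 0.90 -> excluded
  rec2 <- rec
  rec2$likelihood[1:30, "snout"] <- 0.5
  expect_false(filter_tracking(rec2)$included)

  # reference limb exactly at threshold boundary
  rec3 <- rec
  rec3$likelihood[, c("LH1", "LH2")] <- 0.94
  expect_false(filter_tracking(rec3, likelihood_min = 0.95)$included)
  expect_true(filter_tracking(rec3, likelihood_min = 0.94)$included)

  # missing bodypart is a structural error naming it
  rec4 <- rec
  keep <- setdiff(colnames(rec4$x), "snout")
  rec4 <- trajectory_recording(rec4$x[, keep], rec4$y[, keep],
                               rec4$likelihood[, keep], rec4$frame_rate)
  expect_error(filter_tracking(rec4), "snout")
})

test_that("inclusion verdict is monotone in the likelihood threshold", {
  set.seed(5)
  for (i in 1:20) {
    rec <- toy_recording(n = 100)
    rec$likelihood[] <- sample(c(1, 0.97, 0.9, 0.5), length(rec$likelihood),
                               replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.1))
    ths <- sort(runif(5, 0.4, 1))
    verdicts <- vapply(ths, function(th)
      filter_tracking(rec, likelihood_min = th)$included, logical(1))
    # lowering the threshold can only turn excluded into included
    expect_true(all(diff(as.integer(verdicts)) <= 0))
  }
})

test_that("low-likelihood frames are linearly interpolated and flagged", {
  rec <- toy_recording(n = 50)
  rec$x[, "LF1"] <- seq_len(50)
  rec$x[25, "LF1"] <- 999
  rec$likelihood[25, "LF1"] <- 0.1
  ft <- filter_tracking(rec)
  expect_true(ft$interpolated[25, "LF1"])
  expect_equal(unname(ft$recording$x[25, "LF1"]), 25, tolerance = 1e-9)
})

test_that("snout-hump angle follows the obtuse convention and its invariances", {
  # hump -> snout parallel to the surface: 180 degrees
  expect_equal(snout_hump_angle(c(-40, 30), c(5, 30)), 180)
  # 45 degrees below surface-parallel: 135 (snout above hump, forward = -x)
  expect_equal(snout_hump_angle(c(-10, 40), c(0, 30)), 135, tolerance = 1e-9)
  # folding: the same magnitude below the line gives the same obtuse angle
  expect_equal(snout_hump_angle(c(-10, 20), c(0, 30)), 135, tolerance = 1e-9)
  # rotating scene and surface together leaves the angle unchanged
  rot <- function(p, deg) {
    a <- deg * pi / 180
    c(cos(a) * p[1] - sin(a) * p[2], sin(a) * p[1] + cos(a) * p[2])
  }
  s <- c(-10, 40); h <- c(0, 30)
  base <- snout_hump_angle(s, h, slope = 0)
  # lab-frame coordinates rotated by -30 (forward = -x flips the sense)
  expect_equal(snout_hump_angle(rot(s, -30), rot(h, -30), slope = 30),
               base, tolerance = 1e-9)
  # scale invariance
  expect_equal(snout_hump_angle(10 * s, 10 * h), base, tolerance = 1e-9)
  # degenerate geometry
  expect_error(snout_hump_angle(c(1, 1), c(1, 1)), "degenerate")
  # obtuse range whenever the snout lies forward of the hump (forward = -x)
  set.seed(2)
  for (i in 1:50) {
    hp <- runif(2, -50, 50)
    fwd <- runif(1, 0.1, 60); dy <- runif(1, -100, 100)
    sh <- c(hp[1] - fwd, hp[2] + dy)
    a <- snout_hump_angle(sh, hp)
    expect_gte(a, 90); expect_lte(a, 180)
  }
})

test_that("locomotion mask and bouts match a run-length scan", {
  expect_false(any(locomotion_mask(rep(0, 10))))
  m <- locomotion_mask(rep(20, 10))
  expect_true(all(m))
  expect_equal(nrow(locomotor_bouts(m)), 1)
  b <- locomotor_bouts(locomotion_mask(c(0, 2, 2, 0, 2)))
  expect_equal(b$length, c(2, 1))
  expect_equal(b$start, c(2, 5))
  expect_error(locomotion_mask(c(1, NA)), "finite")
})

test_that("posture series reports the generator's requested angle and speed", {
  cfg <- noise_free_cfg(seed = 4L)
  tr <- generate_trajectory_trial(cfg, 1, list(head_height = 50, slope = 0, speed = 25),
                                  seed = 6)
  ps <- posture_series(tr$recording)
  expect_equal(mean(ps$snout_hump_angle), tr$truth$angle, tolerance = 0.1)
  expect_equal(mean(ps$speed), 25, tolerance = 0.5)
  expect_true(all(ps$locomoting))
  # fallback speed from stance drift when the belt channel is absent
  rec2 <- tr$recording
  rec2$belt_speed <- NULL
  ps2 <- posture_series(rec2)
  expect_equal(median(ps2$speed[ps2$speed > 0]), 25, tolerance = 5)
})
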