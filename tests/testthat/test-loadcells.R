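make_load_trial <- function(means, n_s = 8, sr = 50, sd = 0, lead = 0,
                            metadata = list()) {
  n <- n_s * sr
  forces <- sapply(means, function(m) m + rnorm(n, 0, sd))
  colnames(forces) <- names(means)
  if (lead > 0) {
    nl <- lead * sr
    sway <- 5 * sin(2 * pi * 2 * seq_len(nl) / sr)
    forces[seq_len(nl), ] <- forces[seq_len(nl), ] +
      cbind(sway, -0.4 * sway, 0.3 * sway, -0.2 * sway)
  }
  md <- c(list(sample_rate = sr), metadata)
  structure(list(time = (seq_len(n) - 1) / sr, forces = forces, metadata = md),
            class = "load_trial")
}

test_that("weight fractions match channel means over the standstill window", {
  tr <- make_load_trial(c(RF = 5, LF = 5, RH = 5, LH = 5))
  wf <- weight_fractions(tr)
  expect_equal(unname(wf$fractions), rep(0.25, 4))
  tr2 <- make_load_trial(c(RF = 2, LF = 2, RH = 1, LH = 1), sd = 0.001)
  wf2 <- weight_fractions(tr2)
  expect_equal(unname(wf2$fractions), c(1/3, 1/3, 1/6, 1/6), tolerance = 1e-3)
  expect_equal(sum(wf2$fractions), 1)
})

test_that("standstills shorter than the minimum are rejected with a reason", {
  # only 4 s of quiet data after a long noisy lead-in
  tr <- make_load_trial(c(RF = 5, LF = 5, RH = 5, LH = 5), n_s = 10, sd = 0.01,
                        lead = 6)
  expect_error(weight_fractions(tr, standstill_min = 5), "standstill")
  expect_silent(weight_fractions(tr, standstill_min = 3))
  # all-noisy trial: no window at all
  trn <- make_load_trial(c(RF = 5, LF = 5, RH = 5, LH = 5), n_s = 6, sd = 0.01,
                         lead = 6)
  expect_error(weight_fractions(trn, standstill_min = 5), "rejected")
})

test_that("center-of-support index follows the fore-minus-hind formula", {
  expect_equal(center_of_support_index(c(RF = .25, LF = .25, RH = .25, LH = .25)),
               c(CoS_AP_index = 0, CoS_ML_index = 0))
  expect_equal(center_of_support_index(c(RF = .4, LF = .4, RH = .1, LH = .1)),
               c(CoS_AP_index = 0.6, CoS_ML_index = 0))
  expect_equal(center_of_support_index(c(RF = .5, LF = .5, RH = 0, LH = 0))[["CoS_AP_index"]], 1)
  # antisymmetry under fore/hind swap, over random fractions
  set.seed(4)
  for (i in 1:1000) {
    w <- runif(4); w <- w / sum(w); names(w) <- c("RF", "LF", "RH", "LH")
    ws <- setNames(w[c("RH", "LH", "RF", "LF")], c("RF", "LF", "RH", "LH"))
    expect_equal(center_of_support_index(w)[["CoS_AP_index"]],
                 -center_of_support_index(ws)[["CoS_AP_index"]], tolerance = 1e-12)
  }
})

test_that("position-weighted center of support is a load-weighted mean", {
  fp <- data.frame(foot = c("RF", "LF", "RH", "LH"),
                   ap_cm = c(1, 1, -1, -1), ml_cm = c(1, -1, 1, -1))
  w_eq <- c(RF = .25, LF = .25, RH = .25, LH = .25)
  expect_equal(center_of_support_position(w_eq, fp),
               c(CoS_AP_cm = 0, CoS_ML_cm = 0))
  w1 <- c(RF = 1, LF = 0, RH = 0, LH = 0)
  expect_equal(center_of_support_position(w1, fp),
               c(CoS_AP_cm = 1, CoS_ML_cm = 1))
  fp2 <- data.frame(foot = c("RF", "LF", "RH", "LH"),
                    ap_cm = c(2, 2, -2, -2), ml_cm = c(1, -1, 1, -1))
  w2 <- c(RF = .3, LF = .3, RH = .2, LH = .2)
  expect_equal(center_of_support_position(w2, fp2)[["CoS_AP_cm"]], 0.4,
               tolerance = 1e-12)
  # affine equivariance: translating all feet translates the CoS
  fp3 <- fp2; fp3$ap_cm <- fp3$ap_cm + 3; fp3$ml_cm <- fp3$ml_cm - 2
  expect_equal(center_of_support_position(w2, fp3),
               center_of_support_position(w2, fp2) + c(3, -2),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(center_of_support_position(w2, fp2[1:3, ]), "missing foot")
})

test_that("slope correction and offload are consistent and scale-invariant", {
  expect_equal(slope_detectable_weight(30, 0), 30)
  expect_equal(slope_detectable_weight(30, 60), 15, tolerance = 1e-12)
  expect_error(slope_detectable_weight(30, 95), "slope")
  # detected total equal to the cos-corrected weight -> zero offload
  tr <- make_load_trial(c(RF = 6, LF = 6, RH = 6, LH = 6),
                        metadata = list(weight = 24, slope = 0, head_height = 44))
  s <- summarize_load_trial(tr)
  expect_equal(s$offload_fraction, 0, tolerance = 1e-9)
  # uniform rescaling of channels and weight leaves the offload unchanged
  tr2 <- make_load_trial(c(RF = 3, LF = 3, RH = 5, LH = 5),
                         metadata = list(weight = 20, slope = 10, head_height = 40))
  tr3 <- tr2; tr3$forces <- 2.5 * tr3$forces; tr3$metadata$weight <- 50
  expect_equal(summarize_load_trial(tr2)$offload_fraction,
               summarize_load_trial(tr3)$offload_fraction, tolerance = 1e-9)
})

test_that("head-height formulas agree with the empirical linear relation", {
  expect_identical(max_comfortable_height(22), 52)
  expect_identical(max_comfortable_height(0), 24.5)
  expect_equal(max_comfortable_height(24), 54.5)
  expect_equal(weight_adjusted_head_height(52, 22), 1)
  expect_equal(weight_adjusted_head_height(24.5, 17), 0)
  expect_equal(weight_adjusted_head_height(44, 24), 0.65)
  # identity at the maximum comfortable height for any weight
  for (w in c(15, 18.3, 22, 27, 35))
    expect_equal(weight_adjusted_head_height(max_comfortable_height(w), w), 1,
                 tolerance = 1e-12)
})

test_that("exponential decay fitting is exact at zero noise and flags degeneracy", {
  x <- seq(2, 40, length.out = 12)
  y <- 180 - 40 * exp(-0.1 * x)
  f <- fit_exponential_decay(x, y)
  expect_true(f$converged)
  expect_equal(f$A, 180, tolerance = 1e-6 * 180)
  expect_equal(f$B, 40, tolerance = 1e-6 * 40)
  expect_equal(f$k, 0.1, tolerance = 1e-6)
  # constant response: A ~ y, B ~ 0, k unidentifiable (flagged)
  fc <- fit_exponential_decay(x, rep(7, 12))
  expect_false(fc$converged)
  expect_equal(fc$A, 7)
  expect_equal(fc$B, 0)
  expect_true(is.na(fc$k))
  # per-subject fits
  f2 <- fit_exponential_decay(c(x, x), c(y, y + 1),
                              subject = rep(c("a", "b"), each = 12))
  expect_equal(nrow(f2$per_subject), 2)
  expect_true(all(f2$per_subject$converged))
})

test_that("load summaries recover the generator's ground truth", {
  cfg <- cohort_config()
  lt <- generate_load_trial(cfg, list(head_height = 50, slope = 10),
                            weight = 25, seed = 7)
  s <- summarize_load_trial(lt)
  expect_equal(s$offload_fraction, lt$truth$offload, tolerance = 0.01)
  expect_equal(s$CoS_AP_cm, (2 * lt$truth$forelimb_fraction - 1) * cfg$ap_half_cm,
               tolerance = 0.02)
  expect_equal(s$w_RF + s$w_LF + s$w_RH + s$w_LH, 1, tolerance = 1e-12)
  expect_equal(s$weight_adjusted_head_height,
               weight_adjusted_head_height(50, 25))
})
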