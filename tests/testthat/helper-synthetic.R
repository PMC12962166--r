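# Shared fixture builders; everything is generated in code at test time.

# small, fast cohort (reduced frame rate keeps cross-correlations cheap)
small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_mice = 2L, strides_per_trial = 10L, frame_rate = 200), list(...))
  do.call(cohort_config, args)
}

# deterministic, noise-free cohort with matched fore/hind waveforms so that
# cross-correlation recovers phases to one-lag accuracy
noise_free_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_mice = 2L, strides_per_trial = 10L, frame_rate = 200,
         tracking_noise_sd = 0, landmark_jitter_sd = 0,
         dropout_frac = 0, kappa_phase = Inf, kappa_hind = Inf,
         random_effect_sd = 0,
         duty_factor_fore = 0.6, duty_factor_hind = 0.6), list(...))
  do.call(cohort_config, args)
}

# minimal hand-built recording: one bodypart waveform replicated over the
# standard bodypart set
toy_recording <- function(n = 200, frame_rate = 100, lik = 1, belt = 20) {
  bp <- c(paste0(rep(c("LF", "RF", "LH", "RH"), each = 2), 1:2), "snout", "hump")
  t <- seq_len(n)
  x <- sapply(seq_along(bp), function(j) sin(2 * pi * t / 25) * 10 + j)
  colnames(x) <- bp
  y <- x * 0 + 5
  l <- matrix(lik, n, length(bp), dimnames = list(NULL, bp))
  trajectory_recording(x, y, l, frame_rate = frame_rate,
                       belt_speed = rep(belt, n),
                       metadata = list(mouse_id = "m01", slope = 0))
}

# ideal periodic sawtooth under the image convention: peak at swing onset,
# stance (rising) fraction = duty
ideal_saw <- function(n_periods, period, duty, amp = 20) {
  u <- (seq_len(n_periods * period) - 1) / period
  u <- u %% 1
  sw <- 1 - duty
  amp * ifelse(u < sw, 0.5 - u / sw, -0.5 + (u - sw) / duty)
}
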