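#' Cohort configuration for the synthetic generator
#'
#' Bundles every tunable of the synthetic trajectory and load-cell generators.
#' Defaults describe a head-fixed mouse cohort locomoting on a passive
#' treadmill: 400 fps side-view tracking, ~0.2 s stride periods, hindlimb-led
#' duty factors, and a homolateral phase preference that saturates with the
#' snout-hump posture angle through the link
#' \code{mu(x) = mu0 + 2 * atan(beta_angle * (angle - x0) + beta_slope * slope
#' + beta_speed * (speed - speed0)) + mouse_offset}.
#'
#' The default link and load coefficients are mutually consistent: they embed
#' a phase change of a quarter cycle (0.25 pi rad) per 0.4 cm posterior shift
#' of the anteroposterior center of support, composed with linear
#' center-of-support sensitivities of -0.027 cm per degree of snout-hump
#' angle and -0.0096 cm per degree of surface slope.
#'
#' @param n_mice number of animals in the cohort.
#' @param strides_per_trial stride periods generated per trajectory trial.
#' @param frame_rate video frame rate (Hz).
#' @param stride_period stride period (s).
#' @param duty_factor_fore,duty_factor_hind stance fraction per limb pair, in (0,1).
#' @param phase_link_params list with elements \code{mu0} (rad),
#'   \code{beta_angle} (rad/deg), \code{beta_slope} (rad/deg),
#'   \code{beta_speed} (rad per cm/s), \code{x0} (deg), \code{speed0} (cm/s).
#' @param kappa_phase von Mises concentration of homolateral phase draws.
#' @param mu_hind,kappa_hind mean direction and concentration of the
#'   left-right hindlimb phase distribution.
#' @param random_effect_sd SD (rad) of per-mouse phase offsets.
#' @param tracking_noise_sd Gaussian tracking noise SD (mm).
#' @param landmark_jitter_sd SD (rad) of the phase jitter between the two
#'   landmarks tracked on the same foot.
#' @param dropout_frac fraction of frames whose tracking likelihood drops to 0.5.
#' @param head_heights head fixation heights (mm) used across trials.
#' @param slopes surface slopes (deg) used across trials.
#' @param weights body weights (g), one per mouse (recycled).
#' @param speed0 centering speed (cm/s) for the speed covariate.
#' @param angle_e_max,angle_h_scale,angle_h_min parameters of the curvilinear
#'   map from head height (mm) to snout-hump angle (deg):
#'   \code{180 - e_max * exp(-(h - h_min) / h_scale)}.
#' @param load_A,load_B,load_k forelimb load fraction vs head height,
#'   \code{A - B * exp(-k * h)}; defaults follow the angle map so the
#'   center of support is linear in snout-hump angle.
#' @param load_slope_coef shift in forelimb fraction per degree of surface slope.
#' @param offload_max maximal fraction of body weight offloaded to the head
#'   post at the highest head position.
#' @param load_noise_frac per-channel load noise SD as a fraction of body weight.
#' @param load_lr_sd SD of the left/right load split around 0.5.
#' @param load_sample_rate load-cell sampling rate (Hz).
#' @param load_duration_s standstill duration (s) per load trial.
#' @param load_leadin_s duration (s) of a high-variance movement lead-in
#'   prepended to each load trial (exercises standstill detection).
#' @param ap_half_cm,ml_half_cm anteroposterior / mediolateral half-distance
#'   (cm) between foot contact points (stance geometry for cm-valued CoS).
#' @param seed master seed; per-trial seeds are derived as
#'   \code{seed + 1000 * mouse_index + trial_index} (documented counter scheme).
#' @return a list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_mice = 12L,
                          strides_per_trial = 30L,
                          frame_rate = 400,
                          stride_period = 0.2,
                          duty_factor_fore = 0.55,
                          duty_factor_hind = 0.60,
                          phase_link_params = list(
                            mu0 = 0.8 * pi,
                            beta_angle = -0.25 * pi * 0.027 / (2 * 0.4),
                            beta_slope = -0.25 * pi * 0.0096 / (2 * 0.4),
                            beta_speed = -0.0005,
                            x0 = 160,
                            speed0 = 20
                          ),
                          kappa_phase = 8,
                          mu_hind = pi,
                          kappa_hind = 6,
                          random_effect_sd = 0.05 * pi,
                          tracking_noise_sd = 0.5,
                          landmark_jitter_sd = 0.03,
                          dropout_frac = 0.02,
                          head_heights = seq(32, 57, by = 5),
                          slopes = seq(-40, 40, by = 10),
                          weights = seq(20, 28, length.out = n_mice),
                          speed0 = 20,
                          angle_e_max = 36,
                          angle_h_scale = 12,
                          angle_h_min = 32,
                          load_A = 0.392,
                          load_B = -0.0054 * 36 * exp(32 / 12),
                          load_k = 1 / 12,
                          load_slope_coef = -0.0096 / (2 * 2.5),
                          offload_max = 0.15,
                          load_noise_frac = 0.01,
                          load_lr_sd = 0.01,
                          load_sample_rate = 100,
                          load_duration_s = 10,
                          load_leadin_s = 2,
                          ap_half_cm = 2.5,
                          ml_half_cm = 1.0,
                          seed = 1L) {
  cfg <- list(
    n_mice = as.integer(n_mice), strides_per_trial = as.integer(strides_per_trial),
    frame_rate = frame_rate, stride_period = stride_period,
    duty_factor_fore = duty_factor_fore, duty_factor_hind = duty_factor_hind,
    phase_link_params = phase_link_params,
    kappa_phase = kappa_phase, mu_hind = mu_hind, kappa_hind = kappa_hind,
    random_effect_sd = random_effect_sd,
    tracking_noise_sd = tracking_noise_sd,
    landmark_jitter_sd = landmark_jitter_sd, dropout_frac = dropout_frac,
    head_heights = head_heights, slopes = slopes,
    weights = rep_len(weights, n_mice), speed0 = speed0,
    angle_e_max = angle_e_max, angle_h_scale = angle_h_scale,
    angle_h_min = angle_h_min,
    load_A = load_A, load_B = load_B, load_k = load_k,
    load_slope_coef = load_slope_coef, offload_max = offload_max,
    load_noise_frac = load_noise_frac, load_lr_sd = load_lr_sd,
    load_sample_rate = load_sample_rate, load_duration_s = load_duration_s,
    load_leadin_s = load_leadin_s,
    ap_half_cm = ap_half_cm, ml_half_cm = ml_half_cm,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$duty_factor_fore > 0, cfg$duty_factor_fore < 1,
    cfg$duty_factor_hind > 0, cfg$duty_factor_hind < 1,
    cfg$kappa_phase > 0, cfg$frame_rate > 0, cfg$stride_period > 0
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' Per-mouse random phase offsets
#'
#' Drawn once per cohort from the master seed so that every trial of a given
#' mouse shares the same offset.
#'
#' @param config a [cohort_config()].
#' @return numeric vector of length \code{n_mice} (rad).
#' @export
mouse_offsets <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  rnorm(config$n_mice, 0, config$random_effect_sd)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Snout-hump angle implied by a head fixation height
#'
#' Curvilinear map approaching 180 degrees at high head positions.
#'
#' @param head_height head height (mm).
#' @param config a [cohort_config()].
#' @return snout-hump angle (deg), in (90, 180].
#' @export
snout_hump_angle_from_height <- function(head_height, config = cohort_config()) {
  180 - config$angle_e_max * exp(-(head_height - config$angle_h_min) / config$angle_h_scale)
}

#' Mean homolateral phase under the covariate link
#'
#' @param config a [cohort_config()].
#' @param angle snout-hump angle (deg).
#' @param slope surface slope (deg).
#' @param speed locomotor speed (cm/s).
#' @param mouse_offset additive per-mouse offset (rad).
#' @return mean direction (rad), wrapped to \code{[-pi, pi)}.
#' @export
phase_link_mu <- function(config, angle, slope = 0, speed = config$speed0,
                          mouse_offset = 0) {
  p <- config$phase_link_params
  eta <- p$beta_angle * (angle - p$x0) + p$beta_slope * slope +
    p$beta_speed * (speed - p$speed0)
  wrap_pi(p$mu0 + 2 * atan(eta) + mouse_offset)
}

# von Mises draws with (possibly vector) mean; kappa = Inf collapses to mu.
.rvm_shift <- function(mu, kappa) {
  n <- length(mu)
  if (!is.finite(kappa)) return(wrap_pi(mu))
  wrap_pi(rvonmises(n, 0, kappa) + mu)
}

#' Simulate a cohort of per-stride homolateral phases
#'
#' The phase layer of the generator: per-stride covariates and true phases
#' drawn from the covariate link, without waveform synthesis. This is the
#' ground-truth oracle used for regression parameter-recovery experiments.
#'
#' @param config a [cohort_config()].
#' @param n_mice,strides_per_mouse cohort size.
#' @param angle_range range (deg) from which per-stride snout-hump angles are
#'   drawn uniformly.
#' @param slope_range range (deg) for per-stride surface slopes (fixed 0 by default).
#' @param speed_range range (cm/s) for per-stride speeds.
#' @param seed integer seed.
#' @return data.frame with columns \code{mouse}, \code{angle}, \code{slope},
#'   \code{speed}, \code{phase} (rad) plus attributes \code{offsets} and
#'   \code{config}.
#' @export
simulate_phase_cohort <- function(config = cohort_config(),
                                  n_mice = config$n_mice,
                                  strides_per_mouse = 500L,
                                  angle_range = c(140, 180),
                                  slope_range = c(0, 0),
                                  speed_range = c(20, 20),
                                  seed = config$seed) {
  set.seed(seed)
  offsets <- rnorm(n_mice, 0, config$random_effect_sd)
  out <- vector("list", n_mice)
  for (m in seq_len(n_mice)) {
    ang <- runif(strides_per_mouse, angle_range[1], angle_range[2])
    slp <- runif(strides_per_mouse, slope_range[1], slope_range[2])
    spd <- runif(strides_per_mouse, speed_range[1], speed_range[2])
    mu <- phase_link_mu(config, ang, slp, spd, offsets[m])
    out[[m]] <- data.frame(
      mouse = sprintf("m%02d", m), angle = ang, slope = slp, speed = spd,
      phase = .rvm_shift(mu, config$kappa_phase)
    )
  }
  res <- do.call(rbind, out)
  attr(res, "offsets") <- offsets
  attr(res, "config") <- config
  res
}

# piecewise-linear stride waveform, peak (= swing onset) at cycle fraction 0;
# swing falls for (1 - duty), stance rises for duty. Range [-0.5, 0.5].
saw_wave <- function(u, duty) {
  u <- u %% 1
  sw <- 1 - duty
  ifelse(u < sw, 0.5 - u / sw, -0.5 + (u - sw) / duty)
}

#' Generate one synthetic trajectory trial
#'
#' Emits side-view pose series for four feet (two landmarks each), snout and
#' hump, plus a belt-speed channel and full ground truth. Coordinates follow
#' the left side-view image convention: the horizontal coordinate \code{x}
#' increases rearward, so feet drift up in \code{x} during stance and the
#' waveform peaks at swing onset. All coordinates are surface-parallel (the
#' cameras tilt with the rig), so posture angles on generated data are
#' computed with slope = 0.
#'
#' Non-reference limbs replay the reference waveform delayed by a true phase
#' drawn once per trial: the left-right hindlimb phase from
#' \code{VM(mu_hind, kappa_hind)} and each homolateral phase from the
#' covariate link at concentration \code{kappa_phase}.
#'
#' @param config a [cohort_config()].
#' @param mouse_index 1-based mouse index (selects weight and random offset).
#' @param covariates list with \code{head_height} (mm), \code{slope} (deg),
#'   \code{speed} (cm/s).
#' @param seed integer seed for this trial.
#' @return list with elements \code{recording} (a [trajectory_recording()])
#'   and \code{truth} (phases, offsets, swing-onset frames, requested angle).
#' @export
generate_trajectory_trial <- function(config, mouse_index,
                                      covariates = list(head_height = 44, slope = 0, speed = 20),
                                      seed = config$seed) {
  hh <- covariates$head_height %||% 44
  slope <- covariates$slope %||% 0
  speed <- covariates$speed %||% 20
  if (!all(is.finite(c(hh, slope, speed)))) stop("non-finite covariates")
  offsets <- mouse_offsets(config)
  if (mouse_index < 1 || mouse_index > config$n_mice) stop("mouse_index out of range")
  m_off <- offsets[mouse_index]

  set.seed(seed)
  fs <- config$frame_rate
  T_s <- config$stride_period
  n_str <- config$strides_per_trial
  n <- as.integer(round(n_str * T_s * fs))
  t <- (seq_len(n) - 1) / fs
  angle <- snout_hump_angle_from_height(hh, config)

  # true phases relative to the left hindlimb reference
  phi_RH <- .rvm_shift(config$mu_hind, config$kappa_hind)
  mu_hom <- phase_link_mu(config, angle, slope, speed, m_off)
  phi_LF <- .rvm_shift(mu_hom, config$kappa_phase)
  phi_hR <- .rvm_shift(mu_hom, config$kappa_phase) # right homolateral draw
  phi_RF <- wrap_pi(phi_RH + phi_hR)
  phases <- c(LF = phi_LF, RH = phi_RH, RF = phi_RF)

  duty <- c(LF = config$duty_factor_fore, RF = config$duty_factor_fore,
            LH = config$duty_factor_hind, RH = config$duty_factor_hind)
  amp <- c(LF = speed * 10 * T_s * duty[["LF"]],
           RF = speed * 10 * T_s * duty[["RF"]],
           LH = speed * 10 * T_s * duty[["LH"]],
           RH = speed * 10 * T_s * duty[["RH"]])
  base_x <- c(LF = -25, RF = -25, LH = 25, RH = 25) # fore feet forward (-x)
  delay <- c(LF = phi_LF, RF = phi_RF, LH = 0, RH = phi_RH) / (2 * pi)

  w <- max(3L, as.integer(round(0.02 * fs)))
  limbs <- c("LF", "RF", "LH", "RH")
  xs <- ys <- ls <- list()
  truth_onsets <- list()
  for (lb in limbs) {
    jit <- rnorm(2, 0, config$landmark_jitter_sd) / (2 * pi)
    for (k in 1:2) {
      u <- t / T_s - delay[[lb]] - jit[k]
      xv <- base_x[[lb]] + amp[[lb]] * saw_wave(u, duty[[lb]])
      xv <- as.numeric(stats::filter(xv, rep(1 / w, w), circular = TRUE))
      yv <- ifelse(u %% 1 < 1 - duty[[lb]],
                   3 * sin(pi * (u %% 1) / (1 - duty[[lb]])), 0) + k # landmark offset
      nm <- paste0(lb, k)
      xs[[nm]] <- xv + rnorm(n, 0, config$tracking_noise_sd)
      ys[[nm]] <- yv + rnorm(n, 0, config$tracking_noise_sd)
      lik <- rep(1, n)
      nd <- rbinom(1, n, config$dropout_frac)
      if (nd > 0) lik[sample.int(n, nd)] <- 0.5
      ls[[nm]] <- lik
    }
    on_t <- (delay[[lb]] %% 1 + seq(0, n_str + 1)) * T_s
    on_t <- on_t[on_t < n / fs - 1e-9]
    truth_onsets[[lb]] <- as.integer(round(on_t * fs)) + 1L
  }

  e_rad <- (180 - angle) * pi / 180
  L_body <- 45
  snout <- c(x = -40, y = hh)
  hump <- c(x = snout[["x"]] + L_body * cos(e_rad), y = snout[["y"]] - L_body * sin(e_rad))
  for (bp in c("snout", "hump")) {
    p0 <- if (bp == "snout") snout else hump
    xs[[bp]] <- rep(p0[["x"]], n) + rnorm(n, 0, config$tracking_noise_sd)
    ys[[bp]] <- rep(p0[["y"]], n) + rnorm(n, 0, config$tracking_noise_sd)
    lik <- rep(1, n)
    nd <- rbinom(1, n, config$dropout_frac)
    if (nd > 0) lik[sample.int(n, nd)] <- 0.5
    ls[[bp]] <- lik
  }

  rec <- trajectory_recording(
    x = do.call(cbind, xs), y = do.call(cbind, ys),
    likelihood = do.call(cbind, ls),
    frame_rate = fs,
    belt_speed = pmax(speed + rnorm(n, 0, 0.1), 0),
    metadata = list(
      mouse_id = sprintf("m%02d", mouse_index),
      weight = config$weights[mouse_index],
      head_height = hh, slope = slope,
      stim_freq = round(speed / 0.46), stim_side = "left",
      coordinate_frame = "surface"
    )
  )
  truth <- list(
    phases = phases, homolateral_right = phi_hR, mouse_offset = m_off,
    swing_onsets = truth_onsets, stride_period = T_s, duty = duty,
    speed = speed, angle = angle, seed = seed
  )
  list(recording = rec, truth = truth)
}

#' Forelimb load fraction implied by head height and slope
#'
#' \code{A - B * exp(-k * head_height) + load_slope_coef * slope}, clamped to
#' (0.02, 0.98).
#'
#' @param config a [cohort_config()].
#' @param head_height head height (mm).
#' @param slope surface slope (deg).
#' @return forelimb fraction of detected leg load.
#' @export
forelimb_fraction <- function(config, head_height, slope = 0) {
  f <- config$load_A - config$load_B * exp(-config$load_k * head_height) +
    config$load_slope_coef * slope
  pmin(0.98, pmax(0.02, f))
}

# fraction of body weight transferred to the head post
.offload_fraction_true <- function(config, head_height, slope = 0) {
  oh <- config$offload_max *
    pmin(1, pmax(0, (head_height - config$angle_h_min) / 25))
  os <- if (slope < 0) config$offload_max * (-slope / 40) else 0
  pmin(0.5, oh + os)
}

#' Generate one synthetic load-cell trial
#'
#' Four vertical-force channels (RF, LF, RH, LH) sampled during a standstill,
#' preceded by a short high-variance movement lead-in. The channel sum equals
#' the detectable load \code{cos(slope) * weight * (1 - offload)} plus
#' zero-mean noise; the forelimb fraction follows the configured
#' \code{A - B exp(-k h)} relation shifted by slope, and the left/right split
#' is 0.5 plus noise.
#'
#' @param config a [cohort_config()].
#' @param covariates list with \code{head_height} (mm) and \code{slope} (deg).
#' @param weight body weight (g), \code{> 0}.
#' @param seed integer seed.
#' @return list of class \code{"load_trial"}: \code{time} (s), \code{forces}
#'   (matrix, columns RF, LF, RH, LH, grams), \code{metadata} (including the
#'   stance geometry in cm and the implied snout-hump angle), \code{truth}.
#' @export
generate_load_trial <- function(config, covariates = list(head_height = 44, slope = 0),
                                weight, seed = config$seed) {
  hh <- covariates$head_height %||% 44
  slope <- covariates$slope %||% 0
  if (!all(is.finite(c(hh, slope, weight)))) stop("non-finite covariates")
  if (abs(slope) >= 90) stop("|slope| must be < 90 degrees")
  if (weight <= 0) stop("weight must be positive")
  set.seed(seed)
  sr <- config$load_sample_rate
  n_still <- as.integer(round(config$load_duration_s * sr))
  n_lead <- as.integer(round(config$load_leadin_s * sr))
  n <- n_lead + n_still

  offload <- .offload_fraction_true(config, hh, slope)
  detect <- cos(slope * pi / 180) * weight * (1 - offload)
  f_fore <- forelimb_fraction(config, hh, slope)
  lr <- pmin(0.9, pmax(0.1, 0.5 + rnorm(1, 0, config$load_lr_sd)))
  mean_ch <- c(
    RF = detect * f_fore * lr, LF = detect * f_fore * (1 - lr),
    RH = detect * (1 - f_fore) * lr, LH = detect * (1 - f_fore) * (1 - lr)
  )
  noise_sd <- config$load_noise_frac * weight
  forces <- sapply(mean_ch, function(m) m + rnorm(n, 0, noise_sd))
  if (n_lead > 0) {
    # weight shifting during movement: channels sway with distinct gains so
    # the total load fluctuates and the window fails the standstill test
    sway <- sin(2 * pi * 1.5 * seq_len(n_lead) / sr)
    forces[seq_len(n_lead), ] <- forces[seq_len(n_lead), ] +
      0.25 * weight * cbind(sway, -0.5 * sway, -0.2 * sway, 0.4 * sway)
  }
  colnames(forces) <- names(mean_ch)

  feet <- data.frame(
    foot = c("RF", "LF", "RH", "LH"),
    ap_cm = c(config$ap_half_cm, config$ap_half_cm, -config$ap_half_cm, -config$ap_half_cm),
    ml_cm = c(config$ml_half_cm, -config$ml_half_cm, config$ml_half_cm, -config$ml_half_cm)
  )
  structure(list(
    time = (seq_len(n) - 1) / sr,
    forces = forces,
    metadata = list(
      weight = weight, head_height = hh, slope = slope,
      snout_hump_angle = snout_hump_angle_from_height(hh, config),
      sample_rate = sr, foot_positions = feet
    ),
    truth = list(offload = offload, detectable = detect,
                 forelimb_fraction = f_fore, lr_split = lr, seed = seed)
  ), class = "load_trial")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
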